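test_that("criteria counts are sums, symmetric, and demand complete data", {
  expect_identical(criteria_count(matrix(0L, 2, 11)), c(0L, 0L))
  expect_identical(criteria_count(matrix(1L, 1, 11)), 11L)
  row <- c(1, 0, 1, 1, 0, 0, 1, 0, 0, 1, 0)
  for (i in 1:5) {
    perm <- sample(row)
    expect_identical(criteria_count(matrix(perm, 1)), 5L)
  }
  rm <- toy_matrix()
  rm$responses[1, 1] <- NA_integer_
  expect_error(criteria_count(rm), "filter_complete")
})

test_that("severity categories follow the DSM-5 cuts on 0..11", {
  cat11 <- severity_category(0:11)
  expect_identical(as.character(cat11),
                   c("no_aud", "no_aud", "mild", "mild", "moderate",
                     "moderate", rep("severe", 6)))
  # total and deterministic
  expect_false(anyNA(cat11))
  expect_identical(severity_category(0:11), cat11)
  expect_identical(as.character(severity_category(1)), "no_aud")
  expect_identical(as.character(severity_category(4)), "moderate")
  expect_error(severity_category(12), "0..11")
  expect_error(severity_category(-1), "0..11")
})

test_that("tabulation reproduces hand counts and is row-order invariant", {
  rm <- toy_matrix()   # counts: clinic 2,0 ; online 2,3
  rule <- severity_rule(breaks = c(1, 2, 3), max_count = 3,
                        labels = c("none", "low", "mid", "high"))
  ts <- tabulate_severity(rm, rule)
  expect_equal(unname(ts$n), c(2L, 2L))
  expect_equal(unname(ts$mean_criteria), c(1, 2.5))
  clinic_items <- ts$items[ts$items$group == "clinic", ]
  expect_equal(clinic_items$endorsed, c(1L, 1L, 0L))
  expect_equal(clinic_items$proportion, c(0.5, 0.5, 0))
  sev <- ts$severity
  expect_true(all(vapply(split(sev$proportion, sev$group), sum,
                         numeric(1)) == 1))
  expect_s3_class(ts$comparison, "htest")

  perm <- c(3, 1, 4, 2)
  rm2 <- response_matrix(rm$patient_id[perm],
                         as.character(rm$group)[perm],
                         rm$responses[perm, ], reference = "clinic")
  ts2 <- tabulate_severity(rm2, rule)
  expect_equal(ts2$severity$count, ts$severity$count)
  expect_equal(ts2$items$endorsed, ts$items$endorsed)
})

test_that("single-group data omit the comparison", {
  bk <- bank3()
  data <- sim_single(bk, 80, seed = 44)
  ts <- tabulate_severity(data, severity_rule(breaks = c(1, 2, 3),
                                              max_count = 3))
  expect_null(ts$comparison)
  expect_length(ts$n, 1)
})

test_that("observed diagnosis rates match the model-implied rate", {
  # oracle: P(count >= 2) under the generating model, by quadrature over
  # the latent density with a Poisson-binomial recursion at each node
  bank <- asc_item_bank()
  latent <- asc_latent()
  nodes <- seq(-8, 8, length.out = 201)
  model_rate <- function(group) {
    pars <- resolve_items(bank, group)
    w <- dnorm(nodes, latent$mean[group], sqrt(latent$variance[group]))
    w <- w / sum(w)
    p_ge2 <- vapply(nodes, function(t) {
      p <- plogis(pars$a * (t - pars$b))
      p0 <- prod(1 - p)
      p1 <- sum(vapply(seq_along(p), function(k)
        p[k] * prod(1 - p[-k]), numeric(1)))
      1 - p0 - p1
    }, numeric(1))
    sum(w * p_ge2)
  }
  data <- simulate_checklist(sim_config(seed = 404))
  ts <- tabulate_severity(data)
  for (g in c("in_clinic", "online")) {
    n <- unname(ts$n[g])
    sev <- ts$severity[ts$severity$group == g, ]
    observed <- sum(sev$proportion[sev$category != "no_aud"])
    expected <- model_rate(g)
    expect_lt(abs(observed - expected),
              3 * sqrt(expected * (1 - expected) / n))
  }
})

test_that("severity summaries serialize to delimited tables", {
  rm <- toy_matrix()
  rule <- severity_rule(breaks = c(1, 2, 3), max_count = 3)
  ts <- tabulate_severity(rm, rule)
  stem <- file.path(withr::local_tempdir(), "summary")
  write_severity_summary(ts, stem)
  back <- read.csv(paste0(stem, "_severity.csv"))
  expect_equal(back$count, ts$severity$count)
})
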