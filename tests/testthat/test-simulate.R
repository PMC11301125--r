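test_that("latent draws follow the configured group distributions", {
  cfg <- sim_config(seed = 31)
  th <- simulate_latent(cfg)
  expect_equal(nrow(th), 1603 + 1640)
  foc <- th$theta[th$group == "online"]
  # sample moments within 3 standard errors of the generating values
  expect_lt(abs(mean(foc) - (-0.05)), 3 * sqrt(0.90 / length(foc)))
  expect_lt(abs(var(foc) - 0.90), 3 * 0.90 * sqrt(2 / (length(foc) - 1)))
  ref <- th$theta[th$group == "in_clinic"]
  expect_lt(abs(mean(ref)), 3 / sqrt(length(ref)))
  # determinism under the seed
  expect_identical(simulate_latent(cfg)$theta, th$theta)
  expect_false(identical(simulate_latent(sim_config(seed = 32))$theta,
                         th$theta))
  # degenerate variance is rejected at construction
  expect_error(latent_distribution(c("a", "b"), c(0, 0), c(1, 0)),
               "positive")
})

test_that("responses are Bernoulli draws from the item response function", {
  # theta at the item's severity: endorsement probability one half
  bk <- item_bank("only", a = 2.18, b = 0.52, groups = "g")
  th <- data.frame(patient_id = sprintf("p%d", 1:20000), group = "g",
                   theta = 0.52)
  rm <- simulate_responses(th, bk, seed = 8)
  p_hat <- mean(rm$responses)
  expect_lt(abs(p_hat - 0.5), 3 * sqrt(0.25 / 20000))
  # extreme low severity: nothing endorsed
  th$theta <- -30
  expect_true(all(simulate_responses(th, bk, seed = 8)$responses == 0))
  # unknown group rejected
  th$group <- "other"
  expect_error(simulate_responses(th, bk, seed = 8),
               "absent from bank")
})

test_that("marginal endorsement matches the latent-integrated IRF", {
  # quadrature oracle: integrate the IRF against the latent density
  bk <- asc_reference_bank()
  j <- which(bk$item_ids == "larger_longer")
  oracle <- integrate(function(t) plogis(2.18 * (t - 0.52)) * dnorm(t),
                      -Inf, Inf)$value
  data <- sim_single(bk, 50000, seed = 77)
  p_hat <- mean(data$responses[, j])
  expect_lt(abs(p_hat - oracle), 3 * sqrt(oracle * (1 - oracle) / 50000))
})

test_that("contamination respects its rates and feeds the filters", {
  bk <- bank5()
  data <- sim_two(bk, 150, 150, seed = 21)
  # zero rates: identity
  same <- contaminate(data, 0, 0, seed = 5)
  expect_identical(same$responses, data$responses)
  # rates out of range are rejected
  expect_error(contaminate(data, 1, 0, seed = 5), "\\[0, 1\\)")

  dirty <- contaminate(data, 0.3, 0.5, seed = 5)
  n0 <- nrow(data$responses)
  n_dup <- nrow(dirty$responses) - n0
  expect_lt(abs(n_dup - 0.5 * n0), 3 * sqrt(n0 * 0.5 * 0.5))
  n_miss <- sum(rowSums(is.na(dirty$responses)) > 0)
  m <- nrow(dirty$responses)
  expect_lt(abs(n_miss - 0.3 * m), 3 * sqrt(m * 0.3 * 0.7))
  # filtering then removes exactly the rows with blanks
  fc <- filter_complete(dirty, quiet = TRUE)
  expect_equal(nrow(fc$data$responses), m - n_miss)
  expect_equal(sum(fc$excluded), n_miss)
})

test_that("simulated checklists are reproducible under the config seed", {
  cfg <- sim_config(bank5(), latent_distribution(c("ref", "foc")),
                    c(ref = 40, foc = 40), seed = 99,
                    missing_rate = 0.1, duplicate_rate = 0.1)
  a <- simulate_checklist(cfg)
  b <- simulate_checklist(cfg)
  expect_identical(a$responses, b$responses)
  expect_identical(a$patient_id, b$patient_id)
})
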