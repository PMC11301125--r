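test_that("single-group EM recovers generating parameters within 3 SE", {
  bk <- item_bank(paste0("x", 1:5), a = c(1.2, 1.8, 2.0, 2.4, 2.8),
                  b = c(-1.0, -0.3, 0.2, 0.7, 1.2), groups = "g")
  data <- sim_single(bk, 900, seed = 14)
  fit <- fit_single_group(data)
  expect_true(fit$converged)
  est <- resolve_items(fit$bank, "g")
  for (j in 1:5) {
    expect_lt(abs(est$a[j] - bk$a[j, 1]),
              3 * fit$standard_errors[paste0("a:x", j)])
    expect_lt(abs(est$b[j] - bk$b[j, 1]),
              3 * fit$standard_errors[paste0("b:x", j)])
  }
})

test_that("the EM trace is monotone and the fit beats the truth", {
  bk <- bank3()
  data <- sim_single(bk, 300, seed = 5)
  fit <- fit_single_group(data, se = FALSE)
  expect_true(all(diff(fit$trace) >= -1e-8))
  ll_truth <- marginal_loglik(data, bk, latent_distribution("g"))
  expect_gte(fit$loglik, ll_truth)
})

test_that("EM solution matches direct maximization of the marginal likelihood", {
  bk <- bank3()
  data <- sim_single(bk, 250, seed = 8)
  fit <- fit_single_group(data, se = FALSE)
  ld <- latent_distribution("g")
  obj <- function(par) {
    a <- exp(par[1:3])
    cand <- item_bank(bk$item_ids, a = a, b = par[4:6], groups = "g")
    -marginal_loglik(data, cand, ld)
  }
  # multistart direct optimizer over all six parameters
  starts <- list(c(log(c(1, 1, 1)), 0, 0, 0),
                 c(log(c(2, 2, 2)), -0.5, 0, 0.5),
                 c(log(c(1.2, 2, 2.6)), -0.7, 0.1, 0.8))
  best <- min(vapply(starts, function(s)
    optim(s, obj, method = "BFGS", control = list(maxit = 500))$value,
    numeric(1)))
  expect_lt(abs(fit$loglik - (-best)), 1e-3)
})

test_that("degenerate items are refused with the item named", {
  rm <- response_matrix(paste0("p", 1:20), rep("g", 20),
                        cbind(x1 = rep(1L, 20),
                              x2 = rbinom(20, 1, 0.5),
                              x3 = rbinom(20, 1, 0.5)))
  expect_error(fit_single_group(rm), "item 'x1' has all-1 responses")
})

test_that("group routing: each fitter demands its own group count", {
  two <- sim_two(bank5(0), 60, 60, seed = 2)
  expect_error(fit_single_group(two), "use fit_multigroup")
  one <- sim_single(bank3(), 60, seed = 2)
  expect_error(fit_multigroup(one, bank3()), "use fit_single_group")
})

test_that("multigroup null case: focal moments recover 0/1 within 3 SE", {
  bk <- bank5(dif_b = 0)      # identical groups, all parameters shared
  data <- sim_two(bk, 500, 500, seed = 12)
  fit <- fit_multigroup(data, bk)
  expect_true(fit$converged)
  mu <- unname(fit$latent$mean["foc"])
  s2 <- unname(fit$latent$variance["foc"])
  expect_lt(abs(mu - 0), 3 * fit$standard_errors["mean:foc"])
  expect_lt(abs(s2 - 1), 3 * fit$standard_errors["variance:foc"])
})

test_that("anchorless multigroup estimation is refused", {
  bk <- bank5(0)
  data <- sim_two(bk, 60, 60, seed = 3)
  expect_error(fit_multigroup(data, bk, anchors = character()),
               "empty anchor set")
})

test_that("estimates are invariant to item and respondent order", {
  bk <- bank3()
  data <- sim_single(bk, 220, seed = 17)
  fit <- fit_single_group(data, se = FALSE)
  perm_items <- c(3, 1, 2)
  perm_rows <- sample(seq_len(nrow(data$responses)))
  shuffled <- response_matrix(data$patient_id[perm_rows],
                              as.character(data$group)[perm_rows],
                              data$responses[perm_rows, perm_items])
  fit2 <- fit_single_group(shuffled, se = FALSE)
  est1 <- resolve_items(fit$bank, "g")
  est2 <- resolve_items(fit2$bank, "g")
  reord <- match(est1$item_id, est2$item_id)
  expect_equal(est2$a[reord], est1$a, tolerance = 1e-6)
  expect_equal(est2$b[reord], est1$b, tolerance = 1e-6)
})

test_that("standard errors shrink like 1/sqrt(n)", {
  # five moderately discriminating items: enough information that the
  # maximum stays interior at both sample sizes
  bk <- item_bank(paste0("x", 1:5), a = c(1.2, 1.5, 1.8, 2.0, 1.6),
                  b = c(-1.0, -0.4, 0.1, 0.6, 1.1), groups = "g")
  f1 <- fit_single_group(sim_single(bk, 500, seed = 41))
  f2 <- fit_single_group(sim_single(bk, 1000, seed = 42))
  ratio <- median(f1$standard_errors) / median(f2$standard_errors)
  expect_lt(abs(ratio - sqrt(2)), 0.2 * sqrt(2))
})

test_that("observed-information SEs match an independent numerical Hessian", {
  skip_if_not_installed("pracma")
  bk <- bank3()
  data <- sim_single(bk, 150, seed = 23)
  fit <- fit_single_group(data)
  ld <- latent_distribution("g")
  f <- function(par) {
    cand <- item_bank(bk$item_ids, a = par[1:3], b = par[4:6],
                      groups = "g")
    marginal_loglik(data, cand, ld)
  }
  est <- resolve_items(fit$bank, "g")
  H <- pracma::hessian(f, c(est$a, est$b))
  se_oracle <- sqrt(diag(solve(-H)))
  se_fit <- fit$standard_errors[c(paste0("a:x", 1:3), paste0("b:x", 1:3))]
  expect_lt(max(abs(unname(se_fit) - se_oracle)), 1e-4)
})

test_that("non-converged fits are flagged, never silent", {
  bk <- bank3()
  data <- sim_single(bk, 150, seed = 4)
  fit <- suppressWarnings(
    fit_single_group(data, se = FALSE,
                     control = irt_control(max_iter = 2)))
  expect_false(fit$converged)
  expect_error(standard_errors(fit, data), "did not converge")
})
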