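test_that("the Bonferroni threshold divides alpha by the item count", {
  expect_equal(bonferroni_alpha(0.05, 11), 0.05 / 11)
  expect_equal(round(bonferroni_alpha(0.05, 11), 4), 0.0045)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.10, 10), 0.01)
  expect_error(bonferroni_alpha(1.2, 3))
})

test_that("the item-level LR test is nonnegative and localizes DIF", {
  bk <- bank5(dif_b = 0.7)
  data <- sim_two(bk, 400, 400, seed = 6)
  null_bank <- item_bank(bk$item_ids, a = rep(1, 5), b = rep(0, 5),
                         groups = bk$groups, anchors = c("x1", "x2"))
  tst <- lr_test_item(data, null_bank, "x5")
  expect_s3_class(tst, "dif_test")
  expect_gte(tst$joint[["statistic"]], 0)
  expect_equal(tst$joint[["df"]], 2)
  # severity DIF of 0.7 at this n is overwhelming; b test must fire
  expect_lt(tst$joint[["p"]], 1e-4)
  expect_lt(tst$b_only[["p"]], 1e-3)
  # an item that carries no DIF yields a modest statistic
  tst0 <- lr_test_item(data, null_bank, "x3",
                       constrained = tst$fit_constrained)
  expect_gte(tst0$joint[["statistic"]], 0)
  # anchors are off limits
  expect_error(lr_test_item(data, null_bank, "x1"), "anchor")
})

test_that("stepwise detection flags the planted item and is consistent", {
  bk <- bank5(dif_b = 0.7)
  data <- sim_two(bk, 400, 400, seed = 6)
  rep1 <- detect_dif(data, anchors = c("x1", "x2"), quiet = TRUE)
  expect_identical(rep1$flagged, "x5")
  expect_true(rep1$items$flag_b[rep1$items$item == "x5"])
  expect_identical(rep1$per_item_alpha, 0.05 / 5)
  # anchors never flagged / never tested
  expect_true(all(is.na(rep1$items$p_joint[rep1$items$anchor])))

  # freeing parameters never hurts fit
  expect_gte(rep1$fit$loglik, rep1$baseline_loglik)

  # report and final fit are mutually consistent: refitting the reported
  # pattern reproduces the reported log-likelihood
  refit <- fit_multigroup(data, rep1$fit$bank,
                          anchors = rep1$anchors, se = FALSE)
  expect_lt(abs(refit$loglik - rep1$fit$loglik), 1e-4)

  # deterministic given the data
  rep2 <- detect_dif(data, anchors = c("x1", "x2"), quiet = TRUE)
  expect_identical(rep2$flagged, rep1$flagged)
  expect_equal(rep2$fit$loglik, rep1$fit$loglik)
  expect_equal(rep2$items, rep1$items)
})

test_that("with every item anchored there is nothing to test", {
  bk <- bank5(0)
  data <- sim_two(bk, 150, 150, seed = 9)
  all_anchor_data <- data
  rep0 <- detect_dif(all_anchor_data, anchors = bk$item_ids, quiet = TRUE)
  expect_length(rep0$flagged, 0)
  expect_true(all(is.na(rep0$items$p_joint)))
  expect_equal(rep0$fit$loglik, rep0$baseline_loglik, tolerance = 1e-6)
})

test_that("DIF reports serialize with the dash convention", {
  bk <- bank5(dif_b = 0.7)
  data <- sim_two(bk, 400, 400, seed = 6)
  rep1 <- detect_dif(data, anchors = c("x1", "x2"), quiet = TRUE)
  stem <- file.path(withr::local_tempdir(), "dif")
  write_dif_report(rep1, stem)
  tab <- read.csv(paste0(stem, "_parameters.csv"),
                  colClasses = "character")
  expect_equal(nrow(tab), 5)
  # shared parameters dashed, freed ones numeric
  expect_true(all(tab$a_foc[tab$item != "x5"] == "-"))
  expect_false(tab$b_foc[tab$item == "x5"] == "-")
  tests_tab <- read.csv(paste0(stem, "_tests.csv"))
  expect_equal(nrow(tests_tab), 5)
})
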