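test_that("bank invariants: positive a, anchors shared, count match", {
  expect_error(item_bank("i1", a = -1, b = 0, groups = "g"),
               "discrimination must be positive")
  expect_error(
    item_bank(c("i1", "i2"), a = cbind(c(1, 2), c(1, 2.5)),
              b = cbind(c(0, 0), c(0, 0)), groups = c("r", "f"),
              anchors = "i2"),
    "anchor item")
  # all-shared bank resolves identically for both groups
  bk <- item_bank(c("i1", "i2"), a = c(1.5, 2), b = c(0, 1),
                  groups = c("r", "f"))
  expect_identical(resolve_items(bk, "r"), resolve_items(bk, "f"))
  expect_error(resolve_items(bk, "nope"), "group 'nope' not in item bank")
})

test_that("the embedded modality bank matches its published structure", {
  bk <- asc_item_bank()
  expect_identical(bk$anchors,
                   c("time_spent", "phys_psych_problems", "neglect_roles"))
  expect_identical(bk$item_ids[!bk$b_shared],
                   c("tolerance", "larger_longer", "quit_control",
                     "social_interpersonal"))
  expect_identical(bk$item_ids[!bk$a_shared], "social_interpersonal")
  clinic <- resolve_items(bk, "in_clinic")
  online <- resolve_items(bk, "online")
  expect_equal(clinic$a[11], 3.51)
  expect_equal(clinic$b[clinic$item_id == "tolerance"], 0.99)
  expect_equal(online$b[online$item_id == "tolerance"], 0.81)
  expect_equal(online$a[online$item_id == "social_interpersonal"], 2.65)
  # shared rows identical across groups
  sh <- bk$a_shared & bk$b_shared
  expect_identical(clinic[sh, ], online[sh, ])
})

test_that("bank file IO round-trips exactly; dashes mean shared", {
  path <- withr::local_tempfile(fileext = ".csv")
  bk <- asc_item_bank()
  write_item_bank(bk, path)
  back <- read_item_bank(path)
  expect_identical(back$a, bk$a)
  expect_identical(back$b, bk$b)
  expect_identical(back$a_shared, bk$a_shared)
  expect_identical(back$b_shared, bk$b_shared)
  expect_identical(back$anchors, bk$anchors)

  # a written file with an explicit dash parses as shared
  df <- data.frame(item_id = c("i1", "i1"), group = c("r", "f"),
                   a = c("1.5", "-"), b = c("0.3", "0.7"),
                   anchor = c(0, 0))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  bk2 <- read_item_bank(path)
  expect_true(bk2$a_shared)
  expect_false(bk2$b_shared)
  expect_equal(unname(bk2$b[1, ]), c(0.3, 0.7))

  # invalid discrimination rejected at read time
  df$a <- c("-1", "")
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  expect_error(read_item_bank(path), "discrimination must be positive")
})

test_that("set_constraints reshapes the pattern and collapses values", {
  bk <- bank5(dif_b = 0.6)
  shared <- set_constraints(bk, b_shared = rep(TRUE, 5))
  expect_identical(shared$b[, 1], shared$b[, 2])
  freed <- set_constraints(bk, a_shared = c(rep(TRUE, 4), FALSE))
  expect_false(freed$a_shared[5])
})

test_that("latent distributions pin the reference at 0/1", {
  expect_error(latent_distribution(c("r", "f"), mean = c(0.2, 0),
                                   variance = c(1, 1)),
               "reference group must have mean 0 and variance 1")
  expect_error(latent_distribution(c("r", "f"), mean = c(0, 0),
                                   variance = c(1, 0)),
               "variances must be positive")
  ld <- latent_distribution(c("r", "f"), mean = c(0, -0.3),
                            variance = c(1, 0.8))
  expect_identical(ld$groups[1], "r")
  expect_equal(unname(ld$variance["f"]), 0.8)
})
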