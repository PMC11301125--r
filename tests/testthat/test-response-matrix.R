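test_that("construction validates responses and groups", {
  expect_error(
    response_matrix("p1", "g", matrix(2, 1, 1, dimnames = list(NULL, "i1"))),
    "non-binary response at row 1, item 'i1'")
  expect_error(
    response_matrix(c("p1", "p2", "p3"), c("a", "b", "c"),
                    matrix(0, 3, 2)),
    "at most 2 groups")
  rm <- toy_matrix()
  expect_s3_class(rm, "response_matrix")
  expect_identical(levels(rm$group), c("clinic", "online"))
  # declared reference wins regardless of row order
  rm2 <- response_matrix(rev(rm$patient_id), rev(as.character(rm$group)),
                         rm$responses[4:1, ], reference = "clinic")
  expect_identical(levels(rm2$group)[1], "clinic")
})

test_that("read/write round-trips exactly and errors name the bad cell", {
  rm <- toy_matrix()
  rm$responses[2, 3] <- NA_integer_
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(rm, path)
  back <- read_responses(path, reference = "clinic", quiet = TRUE)
  expect_identical(back$responses, rm$responses)
  expect_identical(back$patient_id, rm$patient_id)
  expect_identical(as.character(back$group), as.character(rm$group))

  lines <- readLines(path)
  lines[3] <- sub("0", "2", lines[3])  # corrupt one cell
  writeLines(lines, path)
  expect_error(read_responses(path, reference = "clinic", quiet = TRUE),
               "cannot parse value '2' at row 2")
})

test_that("item columns are matched by name, not position", {
  rm <- toy_matrix()
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(patient_id = rm$patient_id,
                   group = as.character(rm$group),
                   i3 = rm$responses[, "i3"], i1 = rm$responses[, "i1"],
                   i2 = rm$responses[, "i2"])
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  back <- read_responses(path, item_ids = c("i1", "i2", "i3"),
                         reference = "clinic", quiet = TRUE)
  expect_identical(back$responses, rm$responses)
})

test_that("filter_complete drops exactly the incomplete rows, per group", {
  rm <- toy_matrix()
  rm$responses[3, 2] <- NA_integer_
  fc <- filter_complete(rm, quiet = TRUE)
  expect_equal(nrow(fc$data$responses), 3)
  expect_equal(fc$excluded, c(clinic = 0L, online = 1L))
  # idempotent
  fc2 <- filter_complete(fc$data, quiet = TRUE)
  expect_identical(fc2$data$responses, fc$data$responses)
  expect_equal(sum(fc2$excluded), 0L)
  # no missing values: identity
  clean <- filter_complete(toy_matrix(), quiet = TRUE)
  expect_identical(clean$data$responses, toy_matrix()$responses)
  # all rows incomplete: empty result with full counts
  rm$responses[, 1] <- NA_integer_
  fc3 <- filter_complete(rm, quiet = TRUE)
  expect_equal(nrow(fc3$data$responses), 0)
  expect_equal(fc3$excluded, c(clinic = 2L, online = 2L))
})

test_that("one checklist per patient: cardinality, determinism, identity", {
  rm <- response_matrix(
    patient_id = c("a", "a", "b", "c", "c", "c"),
    group = rep(c("g1", "g2"), 3),
    responses = matrix(rbinom(18, 1, 0.5), 6, 3),
    reference = "g1")
  s1 <- select_one_per_patient(rm, seed = 42)
  expect_equal(sort(unique(s1$patient_id)), c("a", "b", "c"))
  expect_false(anyDuplicated(s1$patient_id) > 0)
  expect_identical(select_one_per_patient(rm, seed = 42)$responses,
                   s1$responses)
  # already-unique input is untouched
  u <- toy_matrix()
  expect_identical(select_one_per_patient(u, seed = 1)$responses,
                   u$responses)
})

test_that("patient uniqueness holds across random duplication patterns", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30
    rm <- response_matrix(
      patient_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
      group = sample(c("r", "f"), n, replace = TRUE),
      responses = matrix(rbinom(n * 4, 1, 0.4), n, 4),
      reference = "r")
    out <- select_one_per_patient(rm, seed = seed * 7)
    expect_false(anyDuplicated(out$patient_id) > 0)
    expect_setequal(unique(out$patient_id), unique(rm$patient_id))
  }
})
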