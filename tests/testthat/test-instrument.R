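test_that("published instrument exposes the 14-item bank and a 12-item default", {
  inst <- published_instrument()
  expect_s3_class(inst, "qol_instrument")
  expect_equal(nrow(inst$items), 12)
  expect_equal(inst$n_categories, 5)
  expect_equal(sum(inst$items$has_dna_option), 2)
  expect_equal(sum(inst$items$reverse_scored), 2)

  bank <- published_instrument(bank = TRUE)
  expect_equal(nrow(bank$items), 14)
  expect_equal(sum(bank$items$has_dna_option), 4)
  expect_true(all(grepl("^In the past 4 weeks", bank$items$text)))
  expect_true(all(grepl("how often", bank$items$text[bank$items$scale_group == "frequency"])))

  custom <- published_instrument(active = c(1:10, 13, 14))
  expect_equal(nrow(custom$items), 12)
  expect_error(published_instrument(active = c(1, 99)), "bank")
})

test_that("instrument validation rejects malformed item tables", {
  items <- make_test_instrument(4)$items
  items$id[2] <- items$id[1]
  expect_error(qol_instrument(items), "unique")
  items <- make_test_instrument(4)$items
  items$scale_group[1] <- "sometimes"
  expect_error(qol_instrument(items), "frequency")
})

test_that("raw totals follow the published scoring rules", {
  inst <- published_instrument()
  # items 5 and 6 are reverse-scored: a rating of 1 contributes 5 each
  expect_equal(raw_total(rep(1, 12), inst), 10 * 1 + 2 * 5)
  plain <- make_test_instrument(12)
  expect_equal(raw_total(rep(1, 12), plain), 12)
  expect_equal(raw_total(rep(5, 12), plain), 60)

  # two DNA endorsements + ten minimum ratings give the floor of 10
  dna_inst <- make_test_instrument(12, dna = c(7, 10))
  row <- rep(1, 12); row[c(7, 10)] <- 0
  expect_equal(raw_total(row, dna_inst), 10)

  # reverse-scored items contribute 6 - code
  rev_inst <- make_test_instrument(12, rev = 5)
  row <- rep(1, 12); row[5] <- 4
  expect_equal(raw_total(row, rev_inst), 11 + 2)

  expect_error(raw_total(c(rep(1, 11), NA), plain), "must be completed")
})

test_that("raw_total is monotone nondecreasing in every item code", {
  inst <- make_test_instrument(12, dna = c(7, 10))
  set.seed(42)
  for (rep in 1:25) {
    row <- sample(1:5, 12, replace = TRUE)
    j <- sample(12, 1)
    if (row[j] < 5) {
      up <- row; up[j] <- up[j] + 1
      expect_gte(raw_total(up, inst), raw_total(row, inst))
    }
  }
})

test_that("response validation enforces the special-code rules", {
  inst <- make_test_instrument(3, dna = 2)
  ok <- matrix(c(1, 2, 3, 4, 5, 1), nrow = 2, byrow = TRUE)
  expect_s3_class(response_matrix(ok, inst), "qol_responses")

  bad_dna <- matrix(c(0, 2, 3), nrow = 1)
  expect_error(response_matrix(bad_dna, inst), "q01")
  ok_dna <- matrix(c(1, 0, 3), nrow = 1)
  expect_silent(response_matrix(ok_dna, inst))
  expect_error(response_matrix(matrix(c(1, 2, 6), nrow = 1), inst),
               "invalid code 6")
  expect_error(response_matrix(matrix(c(1, 2, 7), nrow = 1), inst),
               "invalid code 7")
})

test_that("CSV round-trip is the identity, with blanks as missing", {
  inst <- make_test_instrument(12, dna = c(7, 10))
  tr <- sim_truth(inst, dna_rate = 0.2, seed = 8)
  r <- simulate_responses(inst, 30, tr)
  r$values[3, 2] <- NA   # a blank cell
  r <- response_matrix(r$values, inst, person_ids = r$person_ids,
                       covariates = r$covariates)
  path <- withr::local_tempfile(fileext = ".csv")
  write_responses(r, path)
  r2 <- load_responses(path, inst)
  expect_identical(r2$values, r$values)
  expect_true(is.na(r2$values[3, 2]))
  expect_false(isTRUE(r2$values[3, 2] == 0))
  expect_equal(r2$covariates$gender, r$covariates$gender)

  # unknown/missing columns are schema errors
  df <- utils::read.csv(path, check.names = FALSE)
  names(df)[2] <- "mystery"
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, path2, row.names = FALSE, na = "")
  expect_error(load_responses(path2, inst), "lacks item column")
})

test_that("instrument YAML round-trips", {
  inst <- published_instrument()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_instrument(inst, path)
  back <- read_instrument(path)
  expect_equal(back$items, inst$items)
  expect_equal(back$n_categories, inst$n_categories)
})
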