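test_that("built-in instruments match the published battery", {
  specs <- builtin_instruments()
  expect_setequal(names(specs), c("PANSI", "APGAR", "BSSA-10", "BQREB"))

  pansi <- specs$PANSI
  expect_equal(nrow(pansi$items), 14L)
  expect_true(all(pansi$items$min == 1L & pansi$items$max == 5L))
  expect_equal(subscale_range(pansi, "NSI"), c(8L, 40L))
  expect_equal(subscale_range(pansi, "PI"), c(6L, 30L))

  apgar <- specs$APGAR
  expect_true(all(apgar$items$min == 0L & apgar$items$max == 2L))
  expect_equal(subscale_range(apgar, "total"), c(0L, 10L))

  bssa <- specs[["BSSA-10"]]
  expect_setequal(bssa$subscales$SP$item_id, c(1L, 2L, 5L))
  expect_false(any(bssa$subscales$SP$reversed))
  expect_setequal(bssa$subscales$AE$item_id, c(3L, 4L))
  expect_setequal(bssa$subscales$IP$item_id, 6:10)
  expect_true(all(bssa$subscales$IP$reversed))
  # full-scale range 10-60 as the sum of the three sub-scale ranges
  expect_equal(subscale_range(bssa, "SP") + subscale_range(bssa, "AE") +
                 subscale_range(bssa, "IP"), c(10L, 60L))

  bqreb <- specs$BQREB
  expect_equal(vapply(bqreb$subscales, nrow, integer(1L)),
               c(BP = 4L, CM = 3L, R = 3L))
  expect_setequal(unlist(lapply(bqreb$subscales, `[[`, "item_id")), 1:10)
})

test_that("sub-scale scores attain printed ranges at extreme patterns", {
  specs <- builtin_instruments()
  lo <- extreme_responses(which = "min")
  hi <- extreme_responses(which = "max")
  expect_equal(score_subscale(lo, specs$PANSI, "NSI"), c(8L, 8L))
  expect_equal(score_subscale(hi, specs$PANSI, "NSI"), c(40L, 40L))
  expect_equal(score_subscale(lo, specs$PANSI, "PI"), c(6L, 6L))
  expect_equal(score_subscale(hi, specs$PANSI, "PI"), c(30L, 30L))
  expect_equal(score_subscale(lo, specs$APGAR, "total"), c(0L, 0L))
  expect_equal(score_subscale(hi, specs$APGAR, "total"), c(10L, 10L))
  # reversal: IP items 6-10 all at raw max 6 recode to 1 each -> 5
  expect_equal(score_subscale(hi, specs[["BSSA-10"]], "IP"), c(5L, 5L))
  expect_equal(score_subscale(lo, specs[["BSSA-10"]], "IP"), c(30L, 30L))
})

test_that("reverse coding is an involution and scoring is deterministic", {
  raw <- 1:6
  reversed <- (1 + 6) - raw
  expect_equal((1 + 6) - reversed, raw)

  set.seed(7)
  cohort <- generate_cohort(cohort_spec(n = 40, seed = 7))
  specs <- builtin_instruments()
  s1 <- score_cohort(cohort, specs)
  s2 <- score_cohort(cohort, specs)
  expect_identical(s1, s2)
  # permutation invariance over respondents
  perm <- sample(nrow(cohort))
  s3 <- score_cohort(cohort[perm, ], specs)
  expect_identical(unname(as.matrix(s3)), unname(as.matrix(s1)[perm, ]))
})

test_that("missing items exclude a respondent listwise for that sub-scale", {
  specs <- builtin_instruments()
  resp <- constant_responses(n = 3L, value = 2L)
  resp$PANSI_1[2L] <- NA
  nsi <- score_subscale(resp, specs$PANSI, "NSI")
  expect_true(is.na(nsi[2L]))
  expect_false(anyNA(nsi[-2L]))
  # other sub-scales unaffected
  expect_false(anyNA(score_subscale(resp, specs$PANSI, "PI")))
  expect_error(score_subscale(resp, specs$PANSI, "nope"), "unknown")
  resp$PANSI_2[1L] <- NA
  resp$PANSI_3[3L] <- NA
  expect_warning(score_subscale(resp[, ], specs$PANSI, "NSI"), NA)
  all_na <- resp
  for (cc in paste0("PANSI_", 1:14)) all_na[[cc]] <- NA
  expect_warning(score_subscale(all_na, specs$PANSI, "NSI"), "listwise")
})

test_that("APGAR totals classify into the dysfunction bands", {
  expect_equal(classify_apgar(2L), "severe dysfunction")
  expect_equal(classify_apgar(5L), "moderate dysfunction")
  expect_equal(classify_apgar(8L), "mild dysfunction")
  expect_equal(classify_apgar(c(0L, 3L, 4L, 6L, 7L, 10L)),
               c("severe dysfunction", "severe dysfunction",
                 "moderate dysfunction", "moderate dysfunction",
                 "mild dysfunction", "mild dysfunction"))
  expect_error(classify_apgar(11L), "0-10")
  expect_error(classify_apgar(-1L), "0-10")
})

test_that("validate_responses reports violations without mutating input", {
  specs <- builtin_instruments()
  resp <- constant_responses(n = 3L, value = 2L)
  before <- resp
  rep0 <- validate_responses(resp, specs$PANSI)
  expect_equal(nrow(rep0$out_of_range), 0L)
  expect_equal(nrow(rep0$missing), 0L)

  resp$PANSI_3[1L] <- 7L
  resp$APGAR_2[3L] <- NA
  rep1 <- validate_responses(resp, specs$PANSI)
  expect_equal(rep1$out_of_range$row, 1L)
  expect_equal(rep1$out_of_range$column, "PANSI_3")
  expect_equal(rep1$out_of_range$value, 7)
  rep2 <- validate_responses(resp, specs$APGAR)
  expect_equal(rep2$missing$row, 3L)
  expect_equal(rep2$excluded$total, 3L)
  expect_identical(before, constant_responses(n = 3L, value = 2L))
})

test_that("scores CSV round-trips through the documented dialect", {
  cohort <- generate_cohort(cohort_spec(n = 25, seed = 3))
  scores <- score_cohort(cohort)
  path <- withr::local_tempfile(fileext = ".csv")
  write_scores(scores, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), subscale_columns()$column)
  expect_equal(as.matrix(back), as.matrix(scores), ignore_attr = TRUE)

  rpath <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(cohort, rpath, row.names = FALSE)
  expect_equal(as.matrix(read_responses(rpath)), as.matrix(cohort),
               ignore_attr = TRUE)
})
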