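test_that("survey CSV reading converts codings and validates", {
  df <- data.frame(site_id = "s1", respondent_id = as.character(1:3),
                   matrix(rep(c(1L, 3L, 5L), 8), nrow = 3),
                   stringsAsFactors = FALSE)
  names(df)[3:10] <- attribute_names()

  tab <- read_survey_table(write_survey_csv(df))
  expect_s3_class(tab, "lc_survey")
  expect_equal(tab$pleasant, c(1L, 3L, 5L))

  # agree_low: canonical = 6 - raw
  tab_low <- read_survey_table(write_survey_csv(df), coding_config("agree_low"))
  expect_equal(tab_low$pleasant, c(5L, 3L, 1L))
  # involution: applying the flip twice restores the raw values
  expect_equal(6L - (6L - df$pleasant), df$pleasant)

  # label map
  dfl <- df
  for (a in attribute_names()) {
    dfl[[a]] <- c("strongly disagree", "neutral", "strongly agree")
  }
  tab_lab <- read_survey_table(write_survey_csv(dfl), coding_config("labels"))
  expect_equal(tab_lab$annoying, c(1L, 3L, 5L))
})

test_that("survey reading raises distinct named validation errors", {
  df <- data.frame(site_id = "s1", respondent_id = "1",
                   matrix(3L, nrow = 1, ncol = 8))
  names(df)[3:10] <- attribute_names()

  bad <- df; bad$pleasant <- 6L
  expect_error(read_survey_table(write_survey_csv(bad)), class = "lc_error_out_of_range")

  bad <- df; bad$calm <- "maybe"
  expect_error(read_survey_table(write_survey_csv(bad)), class = "lc_error_non_integer")
  expect_error(read_survey_table(write_survey_csv(bad), coding_config("labels")),
               class = "lc_error_unknown_label")

  expect_error(read_survey_table(write_survey_csv(df[, -4])),
               class = "lc_error_missing_column")

  empty <- tempfile(fileext = ".csv")
  writeLines(paste(c("site_id", "respondent_id", attribute_names()), collapse = ","), empty)
  expect_error(read_survey_table(empty), class = "lc_error_empty_file")

  # extra columns ignored with a notice
  extra <- df; extra$age <- 34
  expect_message(read_survey_table(write_survey_csv(extra)), "extra column")
})

test_that("correction table round-trips through JSON", {
  pol <- circumplex_attributes()$valence_polarity
  ct <- correction_table(data.frame(
    attribute = attribute_names(),
    a0 = pol * seq(0.5, 1.2, 0.1), d0 = -pol,
    n0 = c(0.4, NA, 0.3, NA, 0.5, 0.2, 0.1, 0.6),
    b = seq(-0.25, 0.1, 0.05), z = c(1, -1, 1, 1, -1, 1, -1, 1),
    dd = -0.9 * pol, d = -0.4 * pol, n = 0.05, a = 0.45 * pol, aa = 0.9 * pol,
    n0_fallback_used = c(FALSE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE),
    stringsAsFactors = FALSE))
  path <- tempfile(fileext = ".json")
  write_correction_table(ct, path)
  back <- read_correction_table(path)
  expect_equal(as.data.frame(back), as.data.frame(ct))
})

test_that("malformed correction files are rejected, inverted orientation only warns", {
  ct <- identity_correction()
  path <- tempfile(fileext = ".json")
  write_correction_table(ct, path)

  js <- jsonlite::read_json(path)
  js$calm <- NULL
  path2 <- tempfile(fileext = ".json")
  jsonlite::write_json(js, path2, auto_unbox = TRUE, null = "null")
  expect_error(read_correction_table(path2), class = "lc_error_malformed_correction")

  js <- jsonlite::read_json(path)
  js$pleasant$z <- NULL
  jsonlite::write_json(js, path2, auto_unbox = TRUE, null = "null")
  expect_error(read_correction_table(path2), "missing field",
               class = "lc_error_malformed_correction")

  # inverted orientation (pleasant pole flipped) is a warning, not an error
  js <- jsonlite::read_json(path)
  for (f in c("a0", "d0", "dd", "d", "a", "aa")) js$pleasant[[f]] <- -js$pleasant[[f]]
  jsonlite::write_json(js, path2, auto_unbox = TRUE, null = "null")
  expect_warning(read_correction_table(path2), class = "lc_warning_orientation")
})
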