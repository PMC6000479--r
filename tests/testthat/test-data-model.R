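test_that("wide CSV maps to one row per cell and blank cells stay absent", {
  path <- write_wide_fixture()
  tab <- read_score_table(path, tiny_battery(), layout = "wide")
  expect_equal(nrow(tab), 8)  # 2 participants x 2 measures x 2 occasions
  expect_false(any(tab$excluded))

  # blank a cell: the row disappears, nothing is flagged
  txt <- readLines(path)
  txt[2] <- "P1,,29.1,12,14"
  writeLines(txt, path)
  tab2 <- read_score_table(path, tiny_battery(), layout = "wide")
  expect_equal(nrow(tab2), 7)
  expect_equal(sum(tab2$participant_id == "P1" & tab2$measure == "TimeA"), 1)
  expect_false(any(tab2$excluded))
})

test_that("malformed and duplicate rows are rejected with location info", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,occasion,measure,raw_score",
               "P1,1,TimeA,30.5",
               "P1,1,TimeA,31.0"), path)
  expect_error(read_score_table(path, tiny_battery()), "duplicate")

  writeLines(c("participant_id,occasion,measure,raw_score",
               "P1,1,TimeA,oops"), path)
  expect_error(read_score_table(path, tiny_battery()), "raw_score")
})

test_that("unknown measures are reported, long/wide round-trips agree", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("participant_id,occasion,measure,raw_score",
               "P1,1,TimeA,30.5",
               "P1,1,Mystery,1.0"), path)
  expect_warning(tab <- read_score_table(path, tiny_battery()), "Mystery")
  expect_equal(nrow(tab), 1)

  src <- read_score_table(write_wide_fixture(), tiny_battery(), "wide")
  p_long <- tempfile(fileext = ".csv")
  p_wide <- tempfile(fileext = ".csv")
  write_score_table(src, p_long, "long")
  write_score_table(src, p_wide, "wide")
  from_long <- read_score_table(p_long, tiny_battery(), "long")
  from_wide <- read_score_table(p_wide, tiny_battery(), "wide")
  key <- function(d) d[order(d$participant_id, d$measure, d$occasion),
                       c("participant_id", "occasion", "measure", "raw_score")]
  expect_equal(key(as.data.frame(from_long)), key(as.data.frame(from_wide)),
               ignore_attr = TRUE)
})

test_that("score-table validation rejects inconsistent exclusion flags", {
  df <- data.frame(participant_id = "P1", occasion = 1, measure = "TimeA",
                   raw_score = 3, excluded = TRUE, exclusion_reason = "none")
  expect_error(score_table(df), "agree")
  df$exclusion_reason <- "unknown_reason"
  expect_error(score_table(df), "exclusion_reason")
})

test_that("uniqueness validation holds over randomly generated tables", {
  set.seed(402)
  for (i in 1:20) {
    n <- sample(3:20, 1)
    df <- data.frame(
      participant_id = sprintf("P%d", sample(5, n, replace = TRUE)),
      occasion = sample(1:2, n, replace = TRUE),
      measure = sample(c("TimeA", "CountB"), n, replace = TRUE),
      raw_score = runif(n))
    dup <- anyDuplicated(df[, 1:3]) > 0
    if (dup) expect_error(score_table(df), "duplicate")
    else expect_s3_class(score_table(df), "acs_scores")
  }
})

test_that("norm models round-trip through JSON at full precision", {
  m <- acs_norm_models()$ConnectTheDotsI
  m$sd_residual <- m$sd_residual + 1e-13  # exercise full-precision writing
  path <- tempfile(fileext = ".json")
  write_norm_model(m, path)
  back <- read_norm_model(path)
  expect_equal(back$coefficients,
               list(constant = -0.149, age = -0.042, gender = 0.401))
  expect_identical(unclass(back), unclass(m))
})

test_that("invalid models are refused and unknown keys tolerated", {
  expect_error(norm_model("X", "higher_is_better", "none", 0, 1, 49,
                          list(constant = 0), sd_residual = 0), "sd_residual")
  m <- acs_norm_models()$ConnectTheDotsI
  m$sd_residual <- 0  # corrupt after construction
  expect_error(write_norm_model(m, tempfile()), "sd_residual")

  path <- tempfile(fileext = ".json")
  write_norm_model(acs_norm_models()$ConnectTheDotsI, path)
  obj <- jsonlite::read_json(path)
  obj$future_field <- "something"
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_warning(back <- read_norm_model(path), "future_field")
  expect_equal(back$measure, "ConnectTheDotsI")

  obj$schema_version <- 99
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  expect_error(suppressWarnings(read_norm_model(path)), "schema version")
})
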