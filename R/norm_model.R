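NORM_MODEL_SCHEMA <- 1L

#' Construct a norm model
#'
#' A norm model freezes everything needed to convert one raw test score
#' into a demographically corrected norm score: the measure's direction
#' and normalizing transform, the reference sample's mean and SD on the
#' transformed scale, the age-centering constant, the regression
#' coefficients of the demographic model (absent coefficient = pruned
#' predictor), and the residual SD of that regression.
#'
#' @param measure Measure identifier.
#' @param direction,transform As in [measure_spec()].
#' @param ref_mean_transformed,ref_sd_transformed Mean and SD of the
#'   reference sample's transformed scores. May be `NA` when the reference
#'   constants are unpublished; such a model can produce predicted scores
#'   but not norm scores.
#' @param age_center Years; age enters the model as `age - age_center`.
#' @param coefficients Named list/vector; must contain `constant`, may
#'   contain `age`, `age_squared`, `gender`, `education`, and any extra
#'   covariate names.
#' @param sd_residual Residual SD of the regression (> 0).
#' @param r_squared,n_reference Optional fit metadata.
#' @return An object of class `acs_norm_model`.
#' @export
norm_model <- function(measure, direction, transform,
                       ref_mean_transformed, ref_sd_transformed,
                       age_center, coefficients, sd_residual,
                       r_squared = NA_real_, n_reference = NA_integer_) {
  coefficients <- as.list(coefficients)
  if (!"constant" %in% names(coefficients)) {
    stop("coefficients must contain 'constant'")
  }
  if (!is.finite(sd_residual) || sd_residual <= 0) {
    stop("sd_residual must be > 0")
  }
  if (!is.na(ref_sd_transformed) && ref_sd_transformed <= 0) {
    stop("ref_sd_transformed must be > 0 (or NA if unavailable)")
  }
  m <- structure(list(
    measure = as.character(measure),
    direction = match.arg(direction, c("higher_is_better", "lower_is_better")),
    transform = match.arg(transform, c("none", "inverse", "log10", "sqrt")),
    ref_mean_transformed = as.numeric(ref_mean_transformed),
    ref_sd_transformed = as.numeric(ref_sd_transformed),
    age_center = as.numeric(age_center),
    coefficients = lapply(coefficients, as.numeric),
    sd_residual = as.numeric(sd_residual),
    r_squared = as.numeric(r_squared),
    n_reference = as.integer(n_reference)
  ), class = "acs_norm_model")
  m
}

#' @export
print.acs_norm_model <- function(x, ...) {
  cat("Norm model for", x$measure, "\n")
  cat("  transform:", x$transform, "| direction:", x$direction, "\n")
  cat("  reference mean/SD (transformed):",
      format(x$ref_mean_transformed), "/", format(x$ref_sd_transformed), "\n")
  cat("  age centered at", x$age_center, "years\n")
  cf <- unlist(x$coefficients)
  cat("  coefficients:",
      paste(names(cf), format(cf, digits = 4), sep = " = ", collapse = ", "),
      "\n")
  cat("  residual SD:", format(x$sd_residual),
      if (!is.na(x$r_squared)) paste0("| R^2: ", format(x$r_squared)) else "",
      if (!is.na(x$n_reference)) paste0("| n: ", x$n_reference) else "", "\n")
  invisible(x)
}

#' Serialize a norm model to JSON / read one back
#'
#' Models are written with an explicit `schema_version` so that files stay
#' interpretable across releases. Round-trips are lossless at full double
#' precision. Unknown keys in a file are ignored with a warning (forward
#' compatibility); a schema-version mismatch is an error.
#'
#' @param model An `acs_norm_model`.
#' @param path JSON file path.
#' @return `read_norm_model()` returns the model.
#' @export
write_norm_model <- function(model, path) {
  if (!inherits(model, "acs_norm_model")) stop("not an acs_norm_model")
  # re-validate invariants before anything touches disk
  model <- do.call(norm_model, unclass(model))
  payload <- c(list(schema_version = NORM_MODEL_SCHEMA), unclass(model))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_norm_model
#' @export
read_norm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != NORM_MODEL_SCHEMA) {
    stop("norm-model schema version mismatch: file has ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version,
         ", this package reads ", NORM_MODEL_SCHEMA)
  }
  known <- c("schema_version", "measure", "direction", "transform",
             "ref_mean_transformed", "ref_sd_transformed", "age_center",
             "coefficients", "sd_residual", "r_squared", "n_reference")
  extra <- setdiff(names(obj), known)
  if (length(extra)) {
    warning("ignoring unknown keys in norm-model file: ",
            paste(extra, collapse = ", "))
  }
  null_na <- function(x) if (is.null(x)) NA_real_ else x
  norm_model(
    measure = obj$measure, direction = obj$direction,
    transform = obj$transform,
    ref_mean_transformed = null_na(obj$ref_mean_transformed),
    ref_sd_transformed = null_na(obj$ref_sd_transformed),
    age_center = obj$age_center,
    coefficients = obj$coefficients,
    sd_residual = obj$sd_residual,
    r_squared = null_na(obj$r_squared),
    n_reference = if (is.null(obj$n_reference)) NA_integer_ else obj$n_reference
  )
}

#' Published ACS demographic norm models
#'
#' The final pruned regression models for the twelve ACS outcome measures,
#' fitted on the Dutch adult reference samples (main sample n = 248; Place
#' the Beads normed on its own panel sample, n = 421). All models predict
#' the normalized, standardized (mean 0, SD 1) score from age (centered at
#' the reference mean of 49.19 years), age squared, gender (0 = female,
#' 1 = male) and education (0 = high, 1 = low/medium); predictors pruned
#' at p > .05 are absent. The total-score model's age-squared coefficient
#' is 0 at the published precision (its standardized effect, -.117, is
#' small but significant).
#'
#' Transformed-scale reference constants are published only for Connect
#' the Dots I (mean 0.0304, SD 0.00793); for every other measure they are
#' `NA` and norm scores require user-fitted models via [fit_norm_model()].
#'
#' @return Named list of `acs_norm_model` objects.
#' @export
acs_norm_models <- function() {
  mk <- function(measure, transform, direction, coef, sd_res, r2, n,
                 ref_mean = NA_real_, ref_sd = NA_real_) {
    norm_model(measure, direction, transform, ref_mean, ref_sd,
               age_center = 49.19, coefficients = coef,
               sd_residual = sd_res, r_squared = r2, n_reference = n)
  }
  list(
    ConnectTheDotsI = mk("ConnectTheDotsI", "inverse", "lower_is_better",
      list(constant = -0.149, age = -0.042, gender = 0.401),
      0.819, 0.324, 240L, ref_mean = 0.0304, ref_sd = 0.00793),
    ConnectTheDotsII = mk("ConnectTheDotsII", "log10", "lower_is_better",
      list(constant = 0.101, age = -0.045, age_squared = -0.001),
      0.815, 0.330, 246L),
    WordlistLearning = mk("WordlistLearning", "none", "higher_is_better",
      list(constant = -0.001, age = -0.027),
      0.938, 0.116, 241L),
    WordlistDelayedRecall = mk("WordlistDelayedRecall", "none",
      "higher_is_better",
      list(constant = 0.102, age = -0.018, gender = -0.282),
      0.961, 0.068, 241L),
    ReactionSpeed = mk("ReactionSpeed", "inverse", "lower_is_better",
      list(constant = -0.106, age = -0.019, gender = 0.272),
      0.962, 0.067, 241L),
    PlaceTheBeads = mk("PlaceTheBeads", "sqrt", "lower_is_better",
      list(constant = 0.109, age = -0.014, education = -0.226),
      0.968, 0.058, 421L),
    BoxTapping = mk("BoxTapping", "none", "higher_is_better",
      list(constant = -0.145, age = -0.023, gender = 0.372),
      0.939, 0.110, 232L),
    FillTheGrid = mk("FillTheGrid", "inverse", "lower_is_better",
      list(constant = -0.144, age = -0.040, gender = 0.358),
      0.852, 0.267, 241L),
    DigitSequencesI = mk("DigitSequencesI", "none", "higher_is_better",
      list(constant = 0.103, age = -0.010, education = -0.350),
      0.978, 0.036, 245L),
    DigitSequencesII = mk("DigitSequencesII", "none", "higher_is_better",
      list(constant = 0.100, age = -0.015, education = -0.357),
      0.966, 0.060, 242L),
    TotalScore = mk("TotalScore", "none", "higher_is_better",
      list(constant = 0.068, age = -0.025, age_squared = 0,
           gender = 0.120, education = -0.129),
      0.420, 0.351, 206L)
  )
}

#' Published test-retest reference table for the ACS
#'
#' Per-measure test-retest summary statistics of the reference study:
#' number of complete pairs, occasion means and SDs (raw units), paired-t
#' statistic, standard error of measurement, intraclass correlation
#' (two-way, absolute agreement, single measures), retest correlation and
#' its type, and whether a significant practice effect was observed. These
#' are the published inputs to the group smallest-detectable-change
#' arithmetic (see [sdc_group()]).
#'
#' @return A data.frame, one row per measure.
#' @export
acs_reliability_reference <- function() {
  df <- utils::read.table(header = TRUE, stringsAsFactors = FALSE, text = "
measure n mean1 sd1 mean2 sd2 t_stat sem icc corr corr_type practice_effect
ConnectTheDotsI 240 34.83 9.39 32.48 7.79 5.43 4.76 0.67 0.75 spearman TRUE
ConnectTheDotsII 246 58.05 18.45 54.95 17.62 3.60 9.55 0.71 0.74 spearman TRUE
WordlistLearning 241 52.02 10.13 58.11 9.80 -12.31 5.44 0.59 0.75 spearman TRUE
WordlistDelayedRecall 241 11.15 2.71 12.09 2.88 -5.34 3.69 0.50 0.64 spearman TRUE
WordlistRecognition 242 44.17 1.57 44.31 1.72 -1.76 0.90 0.70 0.54 spearman FALSE
ReactionSpeed 241 308.88 44.57 310.49 44.85 -0.69 25.60 0.67 0.74 spearman FALSE
PlaceTheBeads 143 25.63 14.03 21.54 15.81 3.17 11.15 0.45 0.50 spearman TRUE
BoxTapping 232 9.17 2.26 9.70 1.91 -3.91 1.47 0.49 0.46 spearman TRUE
FillTheGrid 241 62.59 12.69 60.73 11.42 3.85 5.30 0.80 0.81 spearman TRUE
DigitSequencesI 245 10.40 2.22 10.61 2.17 -1.52 1.49 0.54 0.54 pearson FALSE
DigitSequencesII 242 8.50 2.72 8.78 2.87 -1.81 1.68 0.64 0.64 pearson FALSE
TotalScore 206 0.06 0.53 0.07 0.55 -0.23 0.05 0.83 0.83 pearson FALSE
")
  df
}
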