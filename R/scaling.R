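#' Normalizing transform for one measure
#'
#' Applies the measure's reverse scoring and normalizing transform in one
#' step so that the transformed scale is always direction-aligned (larger
#' value = better performance):
#' \describe{
#'   \item{inverse}{`1/raw`. The reciprocal itself performs the reversal:
#'     a longer completion time maps to a smaller value. Requires raw > 0.}
#'   \item{log10}{`-log10(raw)` for lower-is-better measures. Requires
#'     raw > 0.}
#'   \item{sqrt}{`-sqrt(raw)` for lower-is-better count measures (e.g.
#'     extra moves). Requires raw >= 0.}
#'   \item{none}{identity, sign-flipped when the measure is
#'     lower-is-better.}
#' }
#'
#' @param raw Numeric vector of raw scores.
#' @param spec A measure description: either a one-row `acs_battery`
#'   subset, an `acs_norm_model`, or any list with `transform`,
#'   `direction`, and optionally `name`/`measure` elements.
#' @return Transformed values.
#' @examples
#' bat <- default_acs_battery()
#' transform_raw(60, bat[bat$name == "ConnectTheDotsI", ])  # 1/60
#' @export
transform_raw <- function(raw, spec) {
  spec <- as_measure_info(spec)
  lower <- spec$direction == "lower_is_better"
  check_domain(raw, spec)
  switch(spec$transform,
    inverse = 1 / raw,
    log10 = if (lower) -log10(raw) else log10(raw),
    sqrt = if (lower) -sqrt(raw) else sqrt(raw),
    none = if (lower) -raw else raw
  )
}

#' Invert a normalizing transform
#'
#' Maps a transformed, direction-aligned value back to the raw score
#' scale; used by the synthetic-data generator and for round-trip checks.
#' Values outside the transform's image (e.g. a non-positive value for an
#' inverse-transformed measure) are an error.
#'
#' @inheritParams transform_raw
#' @param value Transformed values.
#' @export
inverse_transform <- function(value, spec) {
  spec <- as_measure_info(spec)
  lower <- spec$direction == "lower_is_better"
  bad <- switch(spec$transform,
    inverse = value <= 0,
    sqrt = if (lower) value > 0 else value < 0,
    rep(FALSE, length(value))
  )
  if (any(bad, na.rm = TRUE)) {
    stop("transformed value outside the image of transform '",
         spec$transform, "' for measure '", spec$name, "': ",
         value[which(bad)[1]])
  }
  switch(spec$transform,
    inverse = 1 / value,
    log10 = if (lower) 10^(-value) else 10^value,
    sqrt = value^2,
    none = if (lower) -value else value
  )
}

# domain checks shared by transform_raw
check_domain <- function(raw, spec) {
  bad <- switch(spec$transform,
    inverse = ,
    log10 = raw <= 0,
    sqrt = raw < 0,
    none = rep(FALSE, length(raw))
  )
  if (any(bad, na.rm = TRUE)) {
    stop("raw score outside the domain of transform '", spec$transform,
         "' for measure '", spec$name, "': ", raw[which(bad)[1]])
  }
  invisible(TRUE)
}

# normalize the various "measure description" inputs to a plain list
as_measure_info <- function(spec) {
  if (inherits(spec, "acs_norm_model")) {
    return(list(name = spec$measure, direction = spec$direction,
                transform = spec$transform))
  }
  if (is.data.frame(spec)) {
    if (nrow(spec) != 1) stop("expected a single measure specification")
    return(list(name = spec$name, direction = spec$direction,
                transform = spec$transform))
  }
  list(name = if (!is.null(spec$name)) spec$name else spec$measure,
       direction = spec$direction, transform = spec$transform)
}

#' Standardize a transformed score against reference constants
#'
#' @param transformed Transformed score(s).
#' @param ref_mean,ref_sd Reference-sample mean and SD on the transformed
#'   scale (`ref_sd > 0`).
#' @return z-scores.
#' @examples
#' standardize(1 / 60, 0.0304, 0.00793)  # about -1.73
#' @export
standardize <- function(transformed, ref_mean, ref_sd) {
  if (!is.finite(ref_sd) || ref_sd <= 0) stop("ref_sd must be > 0")
  (transformed - ref_mean) / ref_sd
}

#' Reference constants from a cleaned reference cohort
#'
#' Computes each measure's transformed-scale mean and SD from the
#' non-excluded scores of one occasion (occasion 1 by convention: norm
#' scoring of new individuals must not depend on retest data). These
#' constants are what gets frozen into a [norm_model()].
#'
#' @param scores An `acs_scores` table.
#' @param battery An `acs_battery`.
#' @param occasion Occasion whose scores define the reference (default 1).
#' @return data.frame with `measure`, `ref_mean`, `ref_sd`, `n`.
#' @export
reference_constants <- function(scores, battery, occasion = 1L) {
  scores <- score_table(scores)
  battery <- as_battery(battery)
  use <- scores$occasion == occasion & !scores$excluded &
    scores$measure %in% battery$name[!battery$derived]
  measures <- intersect(battery$name, unique(scores$measure[use]))
  out <- lapply(measures, function(m) {
    spec <- battery_row(battery, m)
    x <- transform_raw(scores$raw_score[use & scores$measure == m], spec)
    data.frame(measure = m, ref_mean = mean(x), ref_sd = stats::sd(x),
               n = length(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Standardized (z) scores for a whole table
#'
#' Applies each measure's transform and standardizes against frozen
#' reference constants. Both occasions are standardized with the same
#' constants so that retest shifts remain visible on the z scale.
#' Excluded rows get `NA` z-scores.
#'
#' @param scores An `acs_scores` table.
#' @param battery An `acs_battery`.
#' @param ref Reference constants as returned by [reference_constants()];
#'   computed from occasion 1 of `scores` when omitted.
#' @return The table with a `z` column appended (class `acs_scores`).
#' @export
standardize_scores <- function(scores, battery, ref = NULL) {
  scores <- score_table(scores)
  battery <- as_battery(battery)
  if (is.null(ref)) ref <- reference_constants(scores, battery)
  scores$z <- NA_real_
  for (m in intersect(unique(scores$measure), ref$measure)) {
    r <- ref[ref$measure == m, ]
    rows <- scores$measure == m & !scores$excluded
    spec <- battery_row(battery, m)
    scores$z[rows] <- standardize(
      transform_raw(scores$raw_score[rows], spec), r$ref_mean, r$ref_sd)
  }
  class(scores) <- c("acs_scores", "data.frame")
  scores
}

#' Battery composite (total) score
#'
#' The mean of the direction-aligned z-scores of the battery's composite
#' measures. Complete cases only: if any component is missing the
#' composite is `NA` -- a participant with a missing component is counted
#' out of composite analyses, never imputed with 0.
#'
#' @param z_scores Named numeric vector (or 1-row data.frame) of z-scores,
#'   names = measure names.
#' @param battery An `acs_battery`.
#' @return The composite z, or `NA_real_` if any composite component is
#'   missing.
#' @export
composite_score <- function(z_scores, battery) {
  battery <- as_battery(battery)
  comp <- battery$name[battery$in_composite]
  z <- unlist(z_scores)[comp]
  if (length(z) != length(comp) || anyNA(z)) return(NA_real_)
  mean(z)
}

#' Composite scores per participant and occasion
#'
#' Computes [composite_score()] for every participant x occasion in a
#' standardized table, returning rows for the derived total-score measure.
#'
#' @param zscores Output of [standardize_scores()].
#' @param battery An `acs_battery`.
#' @param name Name for the derived measure (default `"TotalScore"`).
#' @return data.frame with `participant_id`, `occasion`, `measure`,
#'   `raw_score` (the composite z value, which is the total score's raw
#'   scale), `excluded`, `exclusion_reason`.
#' @export
composite_table <- function(zscores, battery, name = "TotalScore") {
  battery <- as_battery(battery)
  comp <- battery$name[battery$in_composite]
  sub <- zscores[zscores$measure %in% comp & !zscores$excluded, ]
  key <- paste(sub$participant_id, sub$occasion, sep = "\r")
  agg <- tapply(sub$z, key, function(v) {
    if (length(v) == length(comp) && !anyNA(v)) mean(v) else NA_real_
  })
  parts <- do.call(rbind, strsplit(names(agg), "\r", fixed = TRUE))
  out <- data.frame(participant_id = parts[, 1],
                    occasion = as.integer(parts[, 2]),
                    measure = name,
                    raw_score = as.numeric(agg),
                    excluded = FALSE,
                    exclusion_reason = "none",
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$raw_score), ]
  rownames(out) <- NULL
  out
}
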