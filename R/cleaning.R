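#' Configuration for robust outlier detection
#'
#' Time-based measures are screened with median-absolute-deviation (MAD)
#' limits computed separately per age group and per occasion; values
#' strictly outside `median +/- mad_multiplier * consistency_constant *
#' MAD` are flagged. The consistency constant 1.4826 rescales the MAD to
#' the SD of a normal distribution; set it to 1 to apply the multiplier to
#' the raw MAD.
#'
#' @param mad_multiplier Positive multiplier on the (scaled) MAD
#'   (default 3.5).
#' @param age_group_bounds Strictly increasing cut ages. The default
#'   `c(41, 60)` yields the groups up to 40, 41-59, and 60 and over
#'   (intervals `[lo, 41)`, `[41, 60)`, `[60, hi]` on continuous age).
#' @param consistency_constant 1.4826 (normal-consistent, default) or 1.
#' @param two_sided If `FALSE`, only the upper limit applies (lower limit
#'   is -Inf); useful for pure reaction-time screening.
#' @return An `acs_outlier_config` list.
#' @export
outlier_config <- function(mad_multiplier = 3.5,
                           age_group_bounds = c(41, 60),
                           consistency_constant = 1.4826,
                           two_sided = TRUE) {
  if (!is.finite(mad_multiplier) || mad_multiplier <= 0) {
    stop("mad_multiplier must be > 0")
  }
  if (length(age_group_bounds) &&
      any(diff(c(-Inf, age_group_bounds)) <= 0)) {
    stop("age_group_bounds must be strictly increasing")
  }
  structure(list(mad_multiplier = mad_multiplier,
                 age_group_bounds = as.numeric(age_group_bounds),
                 consistency_constant = consistency_constant,
                 two_sided = isTRUE(two_sided)),
            class = "acs_outlier_config")
}

# assign age-group labels from the configured bounds
age_groups <- function(age, config) {
  breaks <- c(-Inf, config$age_group_bounds, Inf)
  cut(age, breaks = breaks, right = FALSE)
}

#' MAD-based data limits for one group of values
#'
#' @param values Numeric vector (at least 3 finite values).
#' @param config An [outlier_config()].
#' @return A list with `lower`, `upper`, `median`, `mad` (unscaled), and
#'   `n`. When the MAD is zero the limits collapse to the median and no
#'   exclusions should be applied (a warning is emitted).
#' @examples
#' mad_limits(c(30, 31, 32, 33, 200),
#'            outlier_config(consistency_constant = 1))
#' @export
mad_limits <- function(values, config = outlier_config()) {
  values <- values[is.finite(values)]
  if (length(values) < 3) {
    stop("mad_limits needs at least 3 finite values, got ", length(values))
  }
  med <- stats::median(values)
  mad_raw <- stats::median(abs(values - med))
  if (mad_raw == 0) {
    warning("MAD is zero; limits collapse to the median and no values ",
            "should be flagged")
    return(list(lower = med, upper = med, median = med, mad = 0,
                n = length(values), degenerate = TRUE))
  }
  half_width <- config$mad_multiplier * config$consistency_constant * mad_raw
  lower <- if (config$two_sided) med - half_width else -Inf
  list(lower = lower, upper = med + half_width, median = med,
       mad = mad_raw, n = length(values), degenerate = FALSE)
}

#' Apply the battery's outlier rules to a score table
#'
#' Two rules, mirroring standard practice for self-administered online
#' batteries:
#' \describe{
#'   \item{MAD rule}{For time-based measures (by default those with an
#'     inverse or log10 transform), limits are computed per age group and
#'     per occasion from the non-excluded raw scores; values strictly
#'     outside the limits are flagged `mad_outlier`. Ties at a limit are
#'     retained. Groups with fewer than 3 values, or with MAD = 0, are
#'     skipped with a warning.}
#'   \item{Zero rule}{For count-based measures with `zero_is_invalid`, raw
#'     scores of exactly 0 are flagged `zero_score` (a zero answer pattern
#'     reflects a usability failure, not floor performance).}
#' }
#' Pre-existing exclusions (manual, aid use) are respected: those rows do
#' not enter the limit computation and are never re-flagged. Raw values of
#' flagged rows are preserved.
#'
#' @param scores An `acs_scores` table.
#' @param demo An `acs_demographics` table covering every scored
#'   participant (ages are required for measures under the MAD rule).
#' @param battery An `acs_battery`.
#' @param config An [outlier_config()].
#' @return A list with elements `scores` (flagged table) and `report`
#'   (an `acs_cleaning_report`: per measure x occasion x age group counts
#'   and limits, plus a `flagged` attribute listing every flagged row and
#'   the configuration used).
#' @export
apply_outlier_rules <- function(scores, demo, battery,
                                config = outlier_config()) {
  scores <- score_table(scores)
  battery <- as_battery(battery)
  mad_measures <- battery$name[battery$time_based & !battery$derived]
  zero_measures <- battery$name[battery$zero_is_invalid & !battery$derived]

  # zero-score rule first (disjoint from the MAD measures in the default
  # battery, but ordering is fixed for reproducibility)
  zero_hit <- scores$measure %in% zero_measures & !scores$excluded &
    scores$raw_score == 0
  scores$excluded[zero_hit] <- TRUE
  scores$exclusion_reason[zero_hit] <- "zero_score"

  need_age <- scores$measure %in% mad_measures & !scores$excluded
  idx <- match(scores$participant_id, demo$participant_id)
  if (any(need_age & is.na(idx))) {
    stop("participants without demographics: ",
         paste(unique(scores$participant_id[need_age & is.na(idx)]),
               collapse = ", "))
  }
  age <- demo$age[idx]
  if (any(need_age & is.na(age))) {
    stop("participants without age needed for the MAD rule: ",
         paste(unique(scores$participant_id[need_age & is.na(age)]),
               collapse = ", "))
  }
  grp <- age_groups(age, config)

  report <- list()
  for (meas in union(mad_measures, zero_measures)) {
    is_mad <- meas %in% mad_measures
    for (occ in sort(unique(scores$occasion[scores$measure == meas]))) {
      in_cell <- scores$measure == meas & scores$occasion == occ
      if (is_mad) {
        for (g in levels(grp)) {
          in_group <- in_cell & !is.na(grp) & as.character(grp) == g
          # limits are computed on rows not excluded for *other* reasons;
          # re-including earlier mad_outlier rows keeps the operation
          # idempotent on already-cleaned tables
          base <- which(in_group &
                          scores$exclusion_reason %in% c("none",
                                                         "mad_outlier"))
          rows <- base[!scores$excluded[base]]
          n_zero <- sum(in_group & scores$exclusion_reason == "zero_score")
          if (length(base) < 3) {
            if (length(rows) > 0) {
              warning("fewer than 3 values for ", meas, " occasion ", occ,
                      " age group ", g, "; MAD rule skipped")
            }
            next
          }
          lim <- mad_limits(scores$raw_score[base], config)
          flag <- rows[scores$raw_score[rows] < lim$lower |
                         scores$raw_score[rows] > lim$upper]
          scores$excluded[flag] <- TRUE
          scores$exclusion_reason[flag] <- "mad_outlier"
          report[[length(report) + 1L]] <- data.frame(
            measure = meas, occasion = occ, age_group = g,
            n_checked = length(rows),
            lower_limit = lim$lower, upper_limit = lim$upper,
            n_flagged_mad = length(flag), n_flagged_zero = n_zero,
            stringsAsFactors = FALSE)
        }
      } else {
        report[[length(report) + 1L]] <- data.frame(
          measure = meas, occasion = occ, age_group = "all",
          n_checked = sum(in_cell),
          lower_limit = NA_real_, upper_limit = NA_real_,
          n_flagged_mad = 0L,
          n_flagged_zero = sum(in_cell &
                                 scores$exclusion_reason == "zero_score"),
          stringsAsFactors = FALSE)
      }
    }
  }
  report <- if (length(report)) do.call(rbind, report) else
    data.frame(measure = character(), occasion = integer(),
               age_group = character(), n_checked = integer(),
               lower_limit = numeric(), upper_limit = numeric(),
               n_flagged_mad = integer(), n_flagged_zero = integer())
  flagged <- scores[scores$exclusion_reason %in% c("mad_outlier", "zero_score"),
                    c("participant_id", "occasion", "measure", "raw_score",
                      "exclusion_reason")]
  rownames(flagged) <- NULL
  attr(report, "flagged") <- flagged
  attr(report, "config") <- config
  class(report) <- c("acs_cleaning_report", "data.frame")
  list(scores = score_table(scores), report = report)
}

#' @export
print.acs_cleaning_report <- function(x, ...) {
  cat("Cleaning report (MAD multiplier ",
      attr(x, "config")$mad_multiplier, ", consistency constant ",
      attr(x, "config")$consistency_constant, "):\n", sep = "")
  cat("  ", sum(x$n_flagged_mad), "MAD outliers,",
      sum(x$n_flagged_zero[x$age_group == "all"]), "zero scores flagged\n")
  NextMethod()
}
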