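#' Declare a single battery measure
#'
#' A measure specification records everything the pipeline needs to know
#' about one test outcome: which direction is "better", which normalizing
#' transform applies, whether a raw score of zero signals a usability
#' failure rather than true floor performance, and whether the measure
#' enters the battery composite.
#'
#' @param name Measure identifier, unique within a battery.
#' @param direction `"higher_is_better"` or `"lower_is_better"`. Completion
#'   times and error counts are `"lower_is_better"`.
#' @param transform Normalizing transform: `"none"`, `"inverse"` (1/x, used
#'   for completion times; the reciprocal itself performs the reversal),
#'   `"log10"` or `"sqrt"` (both applied with a sign flip for
#'   lower-is-better measures).
#' @param zero_is_invalid For count-based tests where a zero score reflects
#'   a usability problem (e.g. an unanswered memory test) rather than a
#'   floor: such scores are excluded by the cleaning rules.
#' @param in_composite Whether the measure contributes to the battery
#'   composite (total) score.
#' @param unit Free-text raw-score unit (seconds, words, moves, sequences).
#' @param time_based Whether the per-age-group MAD outlier rule applies.
#'   Defaults to `TRUE` for inverse/log10-transformed measures.
#' @param derived `TRUE` for scores computed from other measures (the
#'   battery total); derived measures are never simulated or cleaned
#'   directly.
#'
#' @return A one-row `data.frame` (class `acs_measure`) that can be bound
#'   into a battery with [as_battery()].
#' @seealso [default_acs_battery()]
#' @export
measure_spec <- function(name,
                         direction = c("higher_is_better", "lower_is_better"),
                         transform = c("none", "inverse", "log10", "sqrt"),
                         zero_is_invalid = FALSE,
                         in_composite = FALSE,
                         unit = NA_character_,
                         time_based = NULL,
                         derived = FALSE) {
  direction <- match.arg(direction)
  transform <- match.arg(transform)
  if (transform %in% c("inverse", "log10") && direction != "lower_is_better") {
    stop("transform '", transform, "' embeds reverse scoring and is only ",
         "meaningful for lower_is_better measures (measure '", name, "')")
  }
  if (is.null(time_based)) time_based <- transform %in% c("inverse", "log10")
  spec <- data.frame(
    name = as.character(name),
    direction = direction,
    transform = transform,
    zero_is_invalid = isTRUE(zero_is_invalid),
    in_composite = isTRUE(in_composite),
    unit = as.character(unit),
    time_based = isTRUE(time_based),
    derived = isTRUE(derived),
    stringsAsFactors = FALSE
  )
  class(spec) <- c("acs_measure", "data.frame")
  spec
}

#' Validate a battery definition
#'
#' @param specs A data.frame of measure specifications (rows as produced by
#'   [measure_spec()]) or a list of such rows.
#' @return The validated battery (class `acs_battery`).
#' @export
as_battery <- function(specs) {
  if (is.list(specs) && !is.data.frame(specs)) {
    specs <- do.call(rbind, specs)
  }
  needed <- c("name", "direction", "transform", "zero_is_invalid",
              "in_composite", "unit", "time_based", "derived")
  missing_cols <- setdiff(needed, names(specs))
  if (length(missing_cols)) {
    stop("battery definition lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (anyDuplicated(specs$name)) {
    stop("duplicate measure names in battery: ",
         paste(unique(specs$name[duplicated(specs$name)]), collapse = ", "))
  }
  bad <- specs$transform %in% c("inverse", "log10") &
    specs$direction != "lower_is_better"
  if (any(bad)) {
    stop("inverse/log10 transforms require direction = lower_is_better: ",
         paste(specs$name[bad], collapse = ", "))
  }
  rownames(specs) <- NULL
  class(specs) <- c("acs_battery", "data.frame")
  specs
}

#' Default Amsterdam Cognition Scan battery definition
#'
#' The twelve outcome measures of the ACS online battery: eleven test
#' measures plus the derived battery total. Completion-time measures
#' (Connect the Dots I/II, Reaction Speed, Fill the Grid) carry
#' normalizing inverse or log10 transforms and are subject to the MAD
#' outlier rule; count-based measures where a zero score indicates a
#' usability failure (Wordlist Learning, Box Tapping, Digit Sequences
#' I/II) carry the zero-score exclusion rule. Nine measures enter the
#' composite; Wordlist Recognition (ceiling effect, insufficient variance)
#' and Place the Beads (normed on a separate reference sample) do not.
#'
#' @return An `acs_battery` data.frame with 12 rows.
#' @examples
#' bat <- default_acs_battery()
#' sum(bat$in_composite)  # 9
#' @export
default_acs_battery <- function() {
  as_battery(list(
    measure_spec("ConnectTheDotsI", "lower_is_better", "inverse",
                 unit = "seconds", in_composite = TRUE),
    measure_spec("ConnectTheDotsII", "lower_is_better", "log10",
                 unit = "seconds", in_composite = TRUE),
    measure_spec("WordlistLearning", "higher_is_better", "none",
                 zero_is_invalid = TRUE, in_composite = TRUE, unit = "words"),
    measure_spec("ReactionSpeed", "lower_is_better", "inverse",
                 unit = "milliseconds", in_composite = TRUE),
    measure_spec("PlaceTheBeads", "lower_is_better", "sqrt",
                 unit = "extra moves"),
    measure_spec("BoxTapping", "higher_is_better", "none",
                 zero_is_invalid = TRUE, in_composite = TRUE,
                 unit = "sequences"),
    measure_spec("FillTheGrid", "lower_is_better", "inverse",
                 unit = "seconds", in_composite = TRUE),
    measure_spec("WordlistDelayedRecall", "higher_is_better", "none",
                 in_composite = TRUE, unit = "words"),
    measure_spec("WordlistRecognition", "higher_is_better", "none",
                 unit = "words"),
    measure_spec("DigitSequencesI", "higher_is_better", "none",
                 zero_is_invalid = TRUE, in_composite = TRUE,
                 unit = "sequences"),
    measure_spec("DigitSequencesII", "higher_is_better", "none",
                 zero_is_invalid = TRUE, in_composite = TRUE,
                 unit = "sequences"),
    measure_spec("TotalScore", "higher_is_better", "none",
                 unit = "z-units", derived = TRUE)
  ))
}

#' Write / read a battery definition as JSON
#'
#' @param battery An `acs_battery`.
#' @param path File path.
#' @return `read_battery()` returns the validated battery.
#' @export
write_battery <- function(battery, path) {
  battery <- as_battery(battery)
  jsonlite::write_json(
    list(schema_version = 1L, measures = as.data.frame(battery)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_battery
#' @export
read_battery <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$schema_version) || obj$schema_version != 1L) {
    stop("unsupported battery schema version: ",
         if (is.null(obj$schema_version)) "<missing>" else obj$schema_version)
  }
  as_battery(obj$measures)
}

# internal: fetch one measure row, error if absent
battery_row <- function(battery, measure) {
  i <- match(measure, battery$name)
  if (is.na(i)) stop("measure '", measure, "' not found in battery")
  battery[i, , drop = FALSE]
}
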