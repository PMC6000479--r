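EXCLUSION_REASONS <- c("none", "mad_outlier", "zero_score", "aid_used", "manual")

#' Build and validate a long-format score table
#'
#' The canonical internal representation of battery scores: one row per
#' participant x occasion x measure. Missing scores are represented by row
#' absence, never by a sentinel value, so that a genuine raw score of zero
#' remains distinguishable from "no data". Excluded rows keep their raw
#' value; exclusion is a flag, not a deletion.
#'
#' @param df A data.frame with columns `participant_id`, `occasion` (1 or
#'   2), `measure`, `raw_score`, and optionally `excluded` (logical) and
#'   `exclusion_reason` (one of none, mad_outlier, zero_score, aid_used,
#'   manual).
#' @return The validated table with class `acs_scores`.
#' @export
score_table <- function(df) {
  needed <- c("participant_id", "occasion", "measure", "raw_score")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("score table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df$participant_id <- as.character(df$participant_id)
  df$occasion <- as.integer(df$occasion)
  df$measure <- as.character(df$measure)
  df$raw_score <- as.numeric(df$raw_score)
  if (is.null(df$excluded)) df$excluded <- FALSE
  if (is.null(df$exclusion_reason)) df$exclusion_reason <- "none"
  df$excluded <- as.logical(df$excluded)
  df$exclusion_reason <- as.character(df$exclusion_reason)
  if (any(!df$occasion %in% c(1L, 2L))) {
    stop("occasion must be 1 or 2")
  }
  bad_reason <- !df$exclusion_reason %in% EXCLUSION_REASONS
  if (any(bad_reason)) {
    stop("unknown exclusion_reason values: ",
         paste(unique(df$exclusion_reason[bad_reason]), collapse = ", "))
  }
  if (any(df$excluded != (df$exclusion_reason != "none"))) {
    stop("excluded flag must agree with exclusion_reason (none <=> not excluded)")
  }
  key <- paste(df$participant_id, df$occasion, df$measure, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), c("participant_id", "occasion", "measure")]
    stop("duplicate (participant, occasion, measure) rows, e.g.: ",
         paste(dup[1, ], collapse = " / "))
  }
  df <- df[, c("participant_id", "occasion", "measure", "raw_score",
               "excluded", "exclusion_reason")]
  rownames(df) <- NULL
  class(df) <- c("acs_scores", "data.frame")
  df
}

#' Read a score table from CSV
#'
#' Two layouts are accepted. `long`: columns `participant_id`, `occasion`,
#' `measure`, `raw_score` (optionally `excluded`, `exclusion_reason`).
#' `wide`: one row per participant with a `participant_id` column followed
#' by one column per measure per occasion named `<measure>_<occasion>`,
#' e.g. `ConnectTheDotsI_1`. Blank cells become absent rows. Columns that
#' do not match any battery measure are reported with a warning and
#' dropped.
#'
#' @param path CSV file path.
#' @param battery An `acs_battery` naming the known measures.
#' @param layout `"long"` or `"wide"`.
#' @return An `acs_scores` table.
#' @export
read_score_table <- function(path, battery, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop("file not found: ", path)
  battery <- as_battery(battery)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  if (layout == "long") {
    unknown <- setdiff(unique(raw$measure), battery$name)
    if (length(unknown)) {
      warning("dropping rows for measures not in battery: ",
              paste(unknown, collapse = ", "))
      raw <- raw[raw$measure %in% battery$name, , drop = FALSE]
    }
    raw$raw_score <- parse_numeric_column(raw$raw_score, "raw_score")
    raw <- raw[!is.na(raw$raw_score), , drop = FALSE]
    if (!is.null(raw$excluded)) {
      raw$excluded <- as.logical(raw$excluded)
    }
    return(score_table(raw))
  }
  # wide layout
  if (!"participant_id" %in% names(raw)) {
    stop("wide layout requires a participant_id column")
  }
  score_cols <- setdiff(names(raw), "participant_id")
  parsed <- regmatches(score_cols, regexec("^(.*)_([12])$", score_cols))
  meas <- vapply(parsed, function(p) if (length(p)) p[2] else NA_character_, "")
  occ <- vapply(parsed, function(p) if (length(p)) p[3] else NA_character_, "")
  known <- !is.na(meas) & meas %in% battery$name
  if (any(!known)) {
    warning("ignoring columns not matching any battery measure: ",
            paste(score_cols[!known], collapse = ", "))
  }
  pieces <- lapply(which(known), function(i) {
    col <- score_cols[i]
    vals <- parse_numeric_column(raw[[col]], col)
    keep <- !is.na(vals)
    data.frame(participant_id = raw$participant_id[keep],
               occasion = as.integer(occ[i]),
               measure = meas[i],
               raw_score = vals[keep],
               stringsAsFactors = FALSE)
  })
  score_table(do.call(rbind, pieces))
}

# parse a character column to numeric, naming the offending cell on failure
parse_numeric_column <- function(x, col) {
  x <- trimws(x)
  x[x == ""] <- NA_character_
  out <- suppressWarnings(as.numeric(x))
  bad <- which(!is.na(x) & is.na(out))
  if (length(bad)) {
    stop("malformed numeric value '", x[bad[1]], "' in column '", col,
         "', row ", bad[1])
  }
  out
}

#' Write a score table to CSV
#'
#' @param scores An `acs_scores` table.
#' @param path Output CSV path.
#' @param layout `"long"` (canonical, keeps exclusion flags) or `"wide"`
#'   (one `<measure>_<occasion>` column per cell; exclusion flags are not
#'   representable and excluded rows are written like any other).
#' @export
write_score_table <- function(scores, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  scores <- score_table(scores)
  if (layout == "long") {
    utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
    return(invisible(path))
  }
  scores$col <- paste(scores$measure, scores$occasion, sep = "_")
  wide <- stats::reshape(
    as.data.frame(scores)[, c("participant_id", "col", "raw_score")],
    idvar = "participant_id", timevar = "col", direction = "wide"
  )
  names(wide) <- sub("^raw_score\\.", "", names(wide))
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.acs_scores <- function(x, ...) {
  cat("Score table:", nrow(x), "rows,",
      length(unique(x$participant_id)), "participants,",
      length(unique(x$measure)), "measures;",
      sum(x$excluded), "excluded\n")
  NextMethod()
}
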