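#' Map the 7-level Verhage education code to the binary norming code
#'
#' Education enters the norm models as a dummy with 0 = high (Verhage 6-7)
#' and 1 = low or medium (Verhage 1-5); low and medium are merged because
#' low-education participants are rare in volunteer reference samples.
#'
#' @param verhage Integer vector with values in 1..7.
#' @param high_levels Verhage levels coded as high education (default 6:7);
#'   override for non-default batteries or other national coding schemes.
#' @return Integer vector, 0 = high, 1 = low/medium.
#' @export
verhage_to_education <- function(verhage, high_levels = 6:7) {
  v <- as.integer(verhage)
  bad <- !is.na(v) & (v < 1L | v > 7L)
  if (any(bad)) {
    stop("Verhage codes out of range 1-7: ",
         paste(unique(v[bad]), collapse = ", "))
  }
  ifelse(is.na(v), NA_integer_, as.integer(!(v %in% high_levels)))
}

#' Assemble and validate a demographics table
#'
#' One row per participant with the predictors the norm models use.
#' Gender is coded 0 = female, 1 = male; education 0 = high, 1 = low or
#' medium (derived from `verhage` when supplied). Additional numeric
#' covariate columns (e.g. a computer-skills z-score) may be passed through
#' `...` and referenced as `extra_covariates` in [fit_config()].
#'
#' @param participant_id Participant identifiers (unique).
#' @param age Age in years, continuous.
#' @param gender 0 = female, 1 = male.
#' @param verhage Optional Verhage education codes (1-7).
#' @param education Optional binary education code (0 = high, 1 =
#'   low/medium). When `verhage` is given, `education` is derived from it
#'   and must not disagree.
#' @param ... Named numeric covariate vectors, recycled to length.
#' @param age_range Plausible age range; ages outside it are an error.
#' @return A `data.frame` of class `acs_demographics`.
#' @export
demographics <- function(participant_id, age, gender,
                         verhage = NULL, education = NULL, ...,
                         age_range = c(18, 81)) {
  n <- length(participant_id)
  if (anyDuplicated(participant_id)) {
    stop("duplicate participant_id values in demographics")
  }
  age <- as.numeric(age)
  out_of_range <- !is.na(age) & (age < age_range[1] | age > age_range[2])
  if (any(out_of_range)) {
    stop("ages outside plausible range [", age_range[1], ", ", age_range[2],
         "] for participants: ",
         paste(participant_id[out_of_range], collapse = ", "))
  }
  gender <- as.integer(gender)
  if (any(!is.na(gender) & !gender %in% c(0L, 1L))) {
    stop("gender must be coded 0 (female) or 1 (male)")
  }
  if (!is.null(verhage)) {
    derived <- verhage_to_education(verhage)
    if (!is.null(education) &&
        any(!is.na(education) & !is.na(derived) & education != derived)) {
      stop("supplied education codes disagree with the Verhage mapping")
    }
    education <- derived
  }
  d <- data.frame(
    participant_id = as.character(participant_id),
    age = age,
    gender = gender,
    stringsAsFactors = FALSE
  )
  if (!is.null(verhage)) d$verhage <- as.integer(verhage)
  if (!is.null(education)) d$education <- as.integer(education)
  extras <- list(...)
  for (nm in names(extras)) d[[nm]] <- as.numeric(extras[[nm]])
  class(d) <- c("acs_demographics", "data.frame")
  d
}

#' @export
print.acs_demographics <- function(x, ...) {
  cat("Demographics:", nrow(x), "participants\n")
  NextMethod()
}
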