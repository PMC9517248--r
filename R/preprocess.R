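#' Dichotomize the two health outcomes
#'
#' Self-rated health on the five-level scale (excellent / very good / good /
#' fair / poor) is collapsed to `srh_poor = 1` for fair or poor and 0
#' otherwise.  Frequent mental distress is `fmd = 1` when the number of
#' mentally unhealthy days in the past 30 is 14 or more.  Missing inputs
#' propagate to missing outputs; rows are never dropped here.  Columns
#' `srh_poor`/`fmd` already present and binary are left untouched, so the
#' function is idempotent and also accepts generator output directly.
#'
#' @param raw Respondent data frame.  Raw scales are read from columns
#'   `srh` (character/factor, five levels) and `mh_days` (integer 0-30) when
#'   present.
#' @return The data frame with binary columns `srh_poor` and `fmd`.
#' @export
#' @examples
#' d <- data.frame(id = 1:3, srh = c("fair", "excellent", NA),
#'                 mh_days = c(14L, 13L, NA))
#' dichotomize_outcomes(d)[, c("srh_poor", "fmd")]
dichotomize_outcomes <- function(raw) {
  srh_levels <- c("excellent", "very good", "good", "fair", "poor")
  if (!is.null(raw[["srh"]])) {
    v <- tolower(as.character(raw[["srh"]]))
    bad <- !is.na(v) & !v %in% srh_levels
    if (any(bad))
      stop("unrecognized self-rated health values in rows: ",
           paste(raw$id[bad], collapse = ", "), call. = FALSE)
    raw$srh_poor <- ifelse(is.na(v), NA_integer_,
                           as.integer(v %in% c("fair", "poor")))
  }
  if (!is.null(raw[["mh_days"]])) {
    d <- raw[["mh_days"]]
    bad <- !is.na(d) & (d < 0 | d > 30)
    if (any(bad))
      stop("mentally-unhealthy-day counts outside 0-30 in rows: ",
           paste(raw$id[bad], collapse = ", "), call. = FALSE)
    raw$fmd <- ifelse(is.na(d), NA_integer_, as.integer(d >= 14))
  }
  for (nm in c("srh_poor", "fmd")) {
    if (!is.null(raw[[nm]]) && !all(raw[[nm]] %in% c(0L, 1L, NA)))
      stop("column '", nm, "' must be binary 0/1 (or missing)", call. = FALSE)
  }
  raw
}

#' Apply the eligibility cascade
#'
#' Drops, in order, respondents with fewer than two observed EQ indicators
#' and then respondents missing age band.  Respondents missing an outcome
#' are retained (flagged in the report): they contribute to the mediator
#' model but not to the outcome likelihood.
#'
#' @param raw Respondent data frame with indicator columns `y1`..`y11`.
#' @return A list with `data` (the analytic sample) and `report`, an
#'   `eq_exclusions` object whose counts telescope: initial n, dropped for
#'   indicators, dropped for missing age, analytic n, and per-outcome
#'   missing-outcome / model-n counts.
#' @export
apply_exclusions <- function(raw) {
  item_cols <- paste0("y", 1:11)
  n0 <- nrow(raw)
  if (n0 == 0L) {
    rep0 <- structure(list(n_initial = 0L, n_dropped_indicators = 0L,
                           n_after_indicators = 0L, n_dropped_age = 0L,
                           n_analytic = 0L, n_missing_outcome = integer(0),
                           n_model = integer(0)), class = "eq_exclusions")
    return(list(data = raw, report = rep0))
  }
  obs <- rowSums(!is.na(as.matrix(raw[item_cols])))
  keep1 <- obs >= 2L
  d1 <- raw[keep1, , drop = FALSE]
  keep2 <- !is.na(d1$age_band)
  d2 <- d1[keep2, , drop = FALSE]
  outcomes <- intersect(c("srh_poor", "fmd"), names(raw))
  n_missing <- vapply(outcomes, function(nm) sum(is.na(d2[[nm]])), 0L)
  report <- structure(list(
    n_initial = n0,
    n_dropped_indicators = sum(!keep1),
    n_after_indicators = nrow(d1),
    n_dropped_age = sum(!keep2),
    n_analytic = nrow(d2),
    n_missing_outcome = n_missing,
    n_model = nrow(d2) - n_missing
  ), class = "eq_exclusions")
  stopifnot(report$n_after_indicators <= report$n_initial,
            report$n_analytic <= report$n_after_indicators)
  list(data = d2, report = report)
}

#' @export
print.eq_exclusions <- function(x, ...) {
  cat("Eligibility cascade\n")
  cat(sprintf("  initial sample:              %6d\n", x$n_initial))
  cat(sprintf("  < 2 observed EQ indicators:  %6d\n", x$n_dropped_indicators))
  cat(sprintf("  missing age:                 %6d\n", x$n_dropped_age))
  cat(sprintf("  analytic sample:             %6d\n", x$n_analytic))
  for (nm in names(x$n_missing_outcome)) {
    cat(sprintf("  %s: missing outcome %d, model n %d\n",
                nm, x$n_missing_outcome[[nm]], x$n_model[[nm]]))
  }
  invisible(x)
}

#' Encode an analytic sample into a design-ready model frame
#'
#' Produces the container consumed by [fit_lca()] and [fit_structural()]:
#' exposure `A` (0 = man, 1 = woman), the confounder dummy block with fixed
#' reference levels (age 30-50, white, US-born, wave 2002), the indicator
#' matrix, the chosen outcome with its observedness flag, and the survey
#' weights.
#'
#' @param clean Analytic sample from [apply_exclusions()].
#' @param outcome Outcome column name, `"srh_poor"` or `"fmd"`.
#' @return An object of class `eq_frame`.
#' @export
encode_covariates <- function(clean, outcome = c("srh_poor", "fmd")) {
  outcome <- match.arg(outcome)
  check_levels <- function(x, levels, nm) {
    v <- as.character(x)
    bad <- !is.na(v) & !v %in% levels
    if (any(bad))
      stop("unseen category in '", nm, "': ",
           paste(unique(v[bad]), collapse = ", "), call. = FALSE)
  }
  check_levels(clean$gender, GENDER_LEVELS, "gender")
  check_levels(clean$age_band, AGE_LEVELS, "age_band")
  check_levels(clean$race_eth, RACE_LEVELS, "race_eth")
  check_levels(clean$nativity, NATIVITY_LEVELS, "nativity")
  check_levels(clean$wave, WAVE_LEVELS, "wave")
  if (any(is.na(clean$age_band)))
    stop("age must be observed in the analytic sample; run apply_exclusions()",
         call. = FALSE)
  if (any(clean$weight <= 0)) stop("weights must be positive", call. = FALSE)
  items <- as.matrix(clean[paste0("y", 1:11)])
  storage.mode(items) <- "integer"
  structure(list(
    data = clean,
    A = as.numeric(clean$gender == "woman"),
    conf = conf_dummies(clean),
    items = items,
    y = as.integer(clean[[outcome]]),
    w = as.numeric(clean$weight),
    outcome = outcome,
    n = nrow(clean)
  ), class = "eq_frame")
}

#' @export
print.eq_frame <- function(x, ...) {
  cat("eq_frame:", x$n, "respondents, outcome", x$outcome,
      sprintf("(%d missing)", sum(is.na(x$y))), "\n")
  invisible(x)
}

#' Decode a model frame back to categorical covariates
#'
#' Inverse of the dummy encoding in [encode_covariates()]; used to verify
#' the encoding round-trips through the data dictionary.
#'
#' @param frame An `eq_frame`.
#' @return Data frame with columns `gender`, `age_band`, `race_eth`,
#'   `nativity`, `wave`.
#' @export
decode_covariates <- function(frame) {
  conf <- frame$conf
  pick <- function(dummies, levels, ref) {
    idx <- rep(match(ref, levels), nrow(conf))
    for (k in seq_along(dummies)) {
      hit <- conf[, dummies[k]] == 1
      idx[hit] <- match(names(dummies)[k], levels)
    }
    factor(levels[idx], levels = levels)
  }
  data.frame(
    gender = factor(GENDER_LEVELS[frame$A + 1], levels = GENDER_LEVELS),
    age_band = pick(c("<30" = "age_lt30", ">50" = "age_gt50"),
                    AGE_LEVELS, "30-50"),
    race_eth = pick(c(black = "race_black", hispanic = "race_hispanic",
                      asian_pi = "race_asian_pi", aian = "race_aian"),
                    RACE_LEVELS, "white"),
    nativity = pick(c(foreign_born = "nativity_foreign"),
                    NATIVITY_LEVELS, "us_born"),
    wave = pick(c("2006" = "wave_2006", "2010" = "wave_2010",
                  "2014" = "wave_2014", "2018" = "wave_2018"),
                WAVE_LEVELS, "2002")
  )
}
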