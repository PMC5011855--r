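#' Instrument metadata for the CCQ, CAT and SGRQ
#'
#' Returns the built-in scale metadata: score ranges for the total scores and
#' domains, scoring direction (higher is worse on all three instruments),
#' literature test-retest reliability (ICC) and the literature MCID for the
#' total scores. The table can be overridden, e.g. to use a different ICC,
#' either with a data frame of replacement rows or with a YAML file holding a
#' list of records with the same field names.
#'
#' @param overrides optional data frame with columns among those of the
#'   built-in table (must include `instrument` and `scale`), or the path to a
#'   YAML file containing a list of such records. Matching rows are replaced
#'   field by field.
#' @return A tibble with columns `instrument`, `scale`, `min`, `max`,
#'   `direction`, `icc`, `literature_mcid` (ICC and literature MCID are `NA`
#'   for domain rows).
#' @examples
#' instrument_specs()
#' @export
instrument_specs <- function(overrides = NULL) {
  specs <- tibble::tribble(
    ~instrument, ~scale,       ~min, ~max, ~icc, ~literature_mcid,
    "ccq",  "total",        0,   6, 0.94, 0.40,
    "ccq",  "symptoms",     0,   6,   NA,   NA,
    "ccq",  "functional",   0,   6,   NA,   NA,
    "ccq",  "mental",       0,   6,   NA,   NA,
    "cat",  "total",        0,  40, 0.80, 2.00,
    "sgrq", "total",        0, 100, 0.91, 4.00,
    "sgrq", "symptoms",     0, 100,   NA,   NA,
    "sgrq", "activities",   0, 100,   NA,   NA,
    "sgrq", "impact",       0, 100,   NA,   NA
  )
  specs$direction <- "higher-is-worse"
  if (is.null(overrides)) return(specs)
  if (is.character(overrides)) {
    overrides <- dplyr::bind_rows(lapply(yaml::read_yaml(overrides), tibble::as_tibble))
  }
  stopifnot(all(c("instrument", "scale") %in% names(overrides)))
  for (i in seq_len(nrow(overrides))) {
    j <- which(specs$instrument == overrides$instrument[i] &
                 specs$scale == overrides$scale[i])
    if (length(j) != 1) {
      stop("unknown instrument/scale in overrides: ",
           overrides$instrument[i], "/", overrides$scale[i])
    }
    for (f in setdiff(names(overrides), c("instrument", "scale"))) {
      specs[[f]][j] <- overrides[[f]][i]
    }
  }
  validate_instrument_specs(specs)
  specs
}

validate_instrument_specs <- function(specs) {
  stopifnot(all(specs$min < specs$max))
  icc <- specs$icc[!is.na(specs$icc)]
  if (any(icc <= 0 | icc >= 1)) stop("icc must lie strictly in (0, 1)")
  lit <- specs$literature_mcid[!is.na(specs$literature_mcid)]
  if (any(lit <= 0)) stop("literature_mcid must be positive")
  invisible(specs)
}

spec_row <- function(instrument, scale = "total", specs = instrument_specs()) {
  row <- specs[specs$instrument == instrument & specs$scale == scale, ]
  if (nrow(row) != 1) stop("no instrument spec for ", instrument, "/", scale)
  row
}

#' Standard CCQ item-to-domain mapping
#'
#' The published Clinical COPD Questionnaire layout: symptoms items 1, 2, 5,
#' 6; mental state items 3, 4; functional state items 7-10. Exposed as
#' configuration so an alternative mapping is a one-line change.
#'
#' @return Named list of integer item indices per domain.
#' @export
ccq_domains <- function() {
  list(symptoms = c(1L, 2L, 5L, 6L),
       mental = c(3L, 4L),
       functional = c(7L, 8L, 9L, 10L))
}

check_items <- function(items, n, lo, hi, label) {
  if (length(items) != n) {
    stop(label, " requires exactly ", n, " item responses, got ", length(items))
  }
  bad <- which(is.na(items) | items < lo | items > hi | items != round(items))
  if (length(bad)) {
    stop(label, " item ", bad[1], " is not an integer in [", lo, ", ", hi,
         "]: ", items[bad[1]])
  }
  invisible(items)
}

#' Score the Clinical COPD Questionnaire from item responses
#'
#' Ten items scored 0 (no impairment) to 6 (maximum impairment); the total is
#' the mean of all ten items, each domain the mean of its items, so every
#' score stays on the 0-6 scale.
#'
#' @param items integer vector of 10 item responses, each in 0-6.
#' @param domains item-to-domain mapping, see [ccq_domains()].
#' @return One-row tibble with columns `symptoms`, `functional`, `mental`,
#'   `total`.
#' @examples
#' score_ccq(c(1, 2, 3, 4, 5, 6, 0, 1, 2, 3))
#' @export
score_ccq <- function(items, domains = ccq_domains()) {
  check_items(items, 10L, 0, 6, "CCQ")
  stopifnot(setequal(unlist(domains), 1:10))
  tibble::tibble(
    symptoms = mean(items[domains$symptoms]),
    functional = mean(items[domains$functional]),
    mental = mean(items[domains$mental]),
    total = mean(items)
  )
}

#' Score the COPD Assessment Test from item responses
#'
#' Eight items scored 0-5; the total is their sum, on a 0-40 scale. The CAT
#' is one-dimensional and has no domain scores.
#'
#' @param items integer vector of 8 item responses, each in 0-5.
#' @return Total score (single number in 0-40).
#' @examples
#' score_cat(c(1, 2, 3, 0, 4, 5, 1, 2))
#' @export
score_cat <- function(items) {
  check_items(items, 8L, 0, 5, "CAT")
  sum(items)
}

#' Compute pre/post change scores with pair-wise deletion
#'
#' Turns a wide cohort table (one row per subject, `<instrument>_<scale>_t0`
#' and `_t1` score columns) into a long table of change scores. A change is
#' defined only where both timepoints are present; a subject missing one
#' instrument at T1 still contributes changes for the others (pair-wise
#' deletion). Negative change means improvement on all three instruments.
#'
#' @param data cohort tibble, see [read_cohort()] or [simulate_cohort()].
#' @param specs instrument metadata, see [instrument_specs()].
#' @param keep_missing if `TRUE`, rows with an undefined change are kept with
#'   `delta = NA` instead of being dropped.
#' @return Tibble with columns `subject_id`, `instrument`, `scale`, `t0`,
#'   `t1`, `delta` (= t1 - t0).
#' @export
compute_changes <- function(data, specs = instrument_specs(), keep_missing = FALSE) {
  rows <- purrr::pmap_dfr(
    specs[, c("instrument", "scale", "min", "max")],
    function(instrument, scale, min, max) {
      c0 <- score_col(instrument, scale, "t0")
      c1 <- score_col(instrument, scale, "t1")
      if (!all(c(c0, c1) %in% names(data))) return(NULL)
      tibble::tibble(
        subject_id = data$subject_id,
        instrument = instrument,
        scale = scale,
        t0 = data[[c0]],
        t1 = data[[c1]],
        delta = data[[c1]] - data[[c0]]
      )
    }
  )
  if (!keep_missing) rows <- dplyr::filter(rows, !is.na(.data$delta))
  rows
}

#' Floor and ceiling effect check
#'
#' A scale shows a floor (ceiling) effect when at least 15% of respondents
#' score within the bottom (top) 10% of the scale range, limiting its ability
#' to register change. The bands are inclusive: a score counts as floor when
#' it is at most `min + 0.10 * width` and as ceiling when it is at least
#' `max - 0.10 * width`.
#'
#' @param scores numeric vector of observed scores (missing values dropped).
#' @param instrument `"ccq"`, `"cat"` or `"sgrq"`.
#' @param scale scale identifier, default `"total"`.
#' @param specs instrument metadata.
#' @param threshold flag share, default 0.15.
#' @return One-row tibble with `instrument`, `scale`, `n`, `floor_pct`,
#'   `ceiling_pct` (percent) and `flagged`.
#' @export
floor_ceiling_check <- function(scores, instrument, scale = "total",
                                specs = instrument_specs(), threshold = 0.15) {
  scores <- scores[!is.na(scores)]
  if (length(scores) == 0) stop("floor_ceiling_check requires at least one score")
  instrument <- match_instrument(instrument)
  row <- spec_row(instrument, match_scale(scale), specs)
  width <- row$max - row$min
  floor_pct <- 100 * mean(scores <= row$min + 0.10 * width)
  ceiling_pct <- 100 * mean(scores >= row$max - 0.10 * width)
  tibble::tibble(
    instrument = instrument, scale = scale, n = length(scores),
    floor_pct = floor_pct, ceiling_pct = ceiling_pct,
    flagged = floor_pct >= 100 * threshold | ceiling_pct >= 100 * threshold
  )
}
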