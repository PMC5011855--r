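#' Standard error of measurement
#'
#' SEM = sigma_x * sqrt(1 - r_xx), where sigma_x is the baseline standard
#' deviation and r_xx the test-retest reliability (ICC) of the instrument.
#' One SEM is a classical distribution-based MCID candidate.
#'
#' @param sd_baseline baseline (T0) standard deviation in score units, > 0.
#' @param icc test-retest reliability coefficient, strictly in (0, 1).
#' @return SEM in score units.
#' @examples
#' sem(1.17, 0.94) # CCQ: 0.29 at 2 dp
#' @export
sem <- function(sd_baseline, icc) {
  stopifnot(sd_baseline > 0)
  if (any(icc <= 0 | icc >= 1)) stop("icc must lie strictly in (0, 1)")
  sd_baseline * sqrt(1 - icc)
}

#' 1.96 times the standard error of measurement
#'
#' The 95%-band variant of the SEM criterion; always exactly 1.96 * [sem()].
#'
#' @inheritParams sem
#' @return 1.96 * SEM in score units.
#' @export
sem196 <- function(sd_baseline, icc) 1.96 * sem(sd_baseline, icc)

#' Half the standard deviation of change
#'
#' 0.5 s.d. of the change score, the third distribution-based MCID estimator.
#' Note the input: SEM uses the baseline s.d., 0.5 s.d. uses the change-score
#' s.d.
#'
#' @param sd_change standard deviation of the T1 - T0 change scores, > 0.
#' @return 0.5 * sd_change in score units.
#' @export
half_sd <- function(sd_change) {
  stopifnot(sd_change > 0)
  0.5 * sd_change
}

#' Distribution-based MCID estimates for a cohort
#'
#' Computes the three distribution-based estimators (SEM, 1.96 SEM, half the
#' change-score s.d.) for each instrument total score from the sample
#' baseline and change standard deviations, with the literature ICCs from
#' the instrument metadata.
#'
#' @param data cohort tibble (wide format).
#' @param specs instrument metadata, see [instrument_specs()].
#' @return Tibble of MCID estimates, one row per instrument x method, with
#'   columns `instrument`, `scale`, `method`, `anchor`, `value`, `ci_low`,
#'   `ci_high`, `n`, `significant`.
#' @export
distribution_referencing <- function(data, specs = instrument_specs()) {
  totals <- specs[specs$scale == "total", ]
  purrr::pmap_dfr(totals[, c("instrument", "icc")], function(instrument, icc) {
    t0 <- data[[score_col(instrument, "total", "t0")]]
    ch <- compute_changes(data, specs)
    ch <- ch$delta[ch$instrument == instrument & ch$scale == "total"]
    sd0 <- stats::sd(t0, na.rm = TRUE)
    sdc <- stats::sd(ch)
    tibble::tibble(
      instrument = instrument, scale = "total",
      method = c("sem", "sem196", "half_sd"),
      anchor = NA_character_,
      value = c(sem(sd0, icc), sem196(sd0, icc), half_sd(sdc)),
      ci_low = NA_real_, ci_high = NA_real_,
      n = c(sum(!is.na(t0)), sum(!is.na(t0)), length(ch)),
      significant = NA
    )
  })
}
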