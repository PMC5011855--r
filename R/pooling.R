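#' Pool the five method-family MCID estimates for a total score
#'
#' The pooled MCID for a total score is the unweighted average of five
#' method families - patient-referencing, criterion-referencing, a single
#' questionnaire-referencing summary value, the SEM and the 0.5 s.d. - each
#' weighted 1/5. When any component is missing the pooled value is withheld
#' and the partial component set is still reported.
#'
#' @param estimates tibble with columns `method` and `value` holding one row
#'   per method family: `patient`, `criterion`, `questionnaire`, `sem`,
#'   `half_sd`.
#' @return One-row tibble with `value`, `rule`, `n_components`, and the
#'   component table (with weights) as attribute `"components"`.
#' @export
pool_total <- function(estimates) {
  families <- c("patient", "criterion", "questionnaire", "sem", "half_sd")
  comp <- tibble::tibble(method = families)
  comp$value <- estimates$value[match(families, estimates$method)]
  comp$weight <- 1 / length(families)
  missing <- is.na(comp$value)
  if (any(missing)) {
    out <- tibble::tibble(value = NA_real_, rule = "equal-weight-5",
                          n_components = sum(!missing))
  } else {
    out <- tibble::tibble(value = sum(comp$weight * comp$value),
                          rule = "equal-weight-5", n_components = 5L)
  }
  attr(out, "components") <- comp
  out
}

#' Pool domain-score MCID estimates
#'
#' Domain scores have no questionnaire-referencing or distribution-based
#' estimates; they pool the patient- and criterion-referencing values. The
#' criterion estimate enters only when its group difference was significant;
#' otherwise the pooled domain MCID is the patient-referencing value alone.
#'
#' @param patient_estimate patient-referencing MCID (improvement magnitude).
#' @param criterion_estimate criterion-referencing MCID, may be `NA`.
#' @param criterion_significant was the criterion group difference
#'   significant?
#' @return One-row tibble with `value`, `rule`, `n_components`.
#' @examples
#' pool_domain(0.55, 0.67, TRUE)   # 0.61
#' pool_domain(13.12, 6.77, FALSE) # 13.12
#' @export
pool_domain <- function(patient_estimate, criterion_estimate,
                        criterion_significant) {
  stopifnot(!is.na(patient_estimate))
  use_criterion <- isTRUE(criterion_significant) && !is.na(criterion_estimate)
  if (use_criterion) {
    tibble::tibble(value = mean(c(patient_estimate, criterion_estimate)),
                   rule = "mean-patient-criterion", n_components = 2L)
  } else {
    tibble::tibble(value = patient_estimate,
                   rule = "patient-only (criterion not significant)",
                   n_components = 1L)
  }
}

#' Standardized effect size of the rehabilitation change
#'
#' The descriptive effect size is the absolute mean change divided by the
#' baseline standard deviation (a Glass-type delta on the T0 spread).
#'
#' @param change_mean mean change score (sign irrelevant).
#' @param sd_baseline baseline standard deviation, > 0.
#' @return Dimensionless effect size.
#' @examples
#' effect_size(-0.58, 1.17) # CCQ: 0.50 at 2 dp
#' @export
effect_size <- function(change_mean, sd_baseline) {
  stopifnot(sd_baseline > 0)
  abs(change_mean) / sd_baseline
}

#' Post hoc power of the paired t-test
#'
#' Power of the two-sided one-sample (paired) t-test at a given standardized
#' effect size, via the noncentral t distribution with noncentrality
#' d * sqrt(n) and n - 1 degrees of freedom.
#'
#' @param d standardized effect size, >= 0.
#' @param n number of pairs, >= 2.
#' @param alpha two-sided significance level, default 0.05.
#' @return Power (probability of rejecting the null).
#' @examples
#' posthoc_power(0.43, 451) # > 0.90
#' @export
posthoc_power <- function(d, n, alpha = 0.05) {
  stopifnot(d >= 0, n >= 2, alpha > 0, alpha < 1)
  df <- n - 1
  tc <- stats::qt(1 - alpha / 2, df)
  ncp <- d * sqrt(n)
  # pt() warns about precision at extreme noncentrality, where the power is
  # 1 to machine precision anyway
  suppressWarnings(stats::pt(-tc, df, ncp) + 1 - stats::pt(tc, df, ncp))
}

#' Express an MCID as a percentage of the scale width
#'
#' Used to compare MCIDs across instruments with different ranges, e.g. a
#' CCQ MCID of 0.40 is about 7% of the 0-6 scale.
#'
#' @param mcid MCID in score units, >= 0.
#' @param instrument `"ccq"`, `"cat"` or `"sgrq"`.
#' @param scale scale identifier, default `"total"`.
#' @param specs instrument metadata.
#' @return Percent of the scale width.
#' @export
scale_fraction <- function(mcid, instrument, scale = "total",
                           specs = instrument_specs()) {
  stopifnot(mcid >= 0)
  row <- spec_row(match_instrument(instrument), match_scale(scale), specs)
  100 * mcid / (row$max - row$min)
}

#' Pooled MCID estimates for a cohort
#'
#' Runs the five method families per instrument total score and the
#' patient/criterion pair per domain, and applies the pooling rules. The
#' questionnaire-referencing summary entering the total-score pool is, by
#' default, the mean of the six revised-anchor estimates (two anchors x
#' three sub-methods); set `qr_summary` to `"literature"` to use the
#' literature-anchor pass, or to `"all"` to average both vintages.
#'
#' @param data cohort tibble.
#' @param qr_grid optional precomputed [qr_iterate()] result (avoids
#'   refitting); computed from `data` when `NULL`.
#' @param qr_summary which questionnaire-referencing estimates to collapse:
#'   `"revised"` (default), `"literature"` or `"all"`.
#' @param specs instrument metadata.
#' @return Tibble with one row per instrument/scale: `instrument`, `scale`,
#'   `value`, `rule`, `n_components`.
#' @export
pooled_estimates <- function(data, qr_grid = NULL, qr_summary = "revised",
                             specs = instrument_specs()) {
  qr_summary <- rlang::arg_match0(qr_summary, c("revised", "literature", "all"))
  if (is.null(qr_grid)) qr_grid <- qr_iterate(data, specs = specs)
  dist <- distribution_referencing(data, specs)
  totals <- purrr::map_dfr(c("ccq", "cat", "sgrq"), function(inst) {
    qr <- qr_grid[qr_grid$instrument == inst, ]
    if (qr_summary != "all" && qr_summary %in% qr$anchor_vintage) {
      qr <- qr[qr$anchor_vintage == qr_summary, ]
    }
    qr_value <- mean(qr$value, na.rm = TRUE)
    if (is.nan(qr_value)) qr_value <- NA_real_
    comp <- tibble::tibble(
      method = c("patient", "criterion", "questionnaire", "sem", "half_sd"),
      value = c(patient_referencing(data, inst, "total", specs)$value,
                criterion_referencing(data, inst, "total", specs)$value,
                qr_value,
                dist$value[dist$instrument == inst & dist$method == "sem"],
                dist$value[dist$instrument == inst & dist$method == "half_sd"])
    )
    pooled <- pool_total(comp)
    tibble::tibble(instrument = inst, scale = "total", value = pooled$value,
                   rule = pooled$rule, n_components = pooled$n_components)
  })
  domain_rows <- specs[!is.na(specs$scale) & specs$scale != "total", ]
  domains <- purrr::pmap_dfr(domain_rows[, c("instrument", "scale")],
    function(instrument, scale) {
      pat <- patient_referencing(data, instrument, scale, specs)
      cri <- criterion_referencing(data, instrument, scale, specs)
      if (is.na(pat$value)) {
        return(tibble::tibble(instrument = instrument, scale = scale,
                              value = NA_real_,
                              rule = "patient estimate undefined",
                              n_components = 0L))
      }
      pooled <- pool_domain(pat$value, abs(cri$value), isTRUE(cri$significant))
      tibble::tibble(instrument = instrument, scale = scale,
                     value = pooled$value, rule = pooled$rule,
                     n_components = pooled$n_components)
    })
  dplyr::bind_rows(totals, domains)
}
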