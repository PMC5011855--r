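#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ROC cut-point analysis
#'
#' @param x an `mcid_roc` object from [qr_roc()].
#' @param ... unused.
#' @return The candidate cut-off grid as a tibble: `cutoff`, `sensitivity`,
#'   `specificity`, `youden`, `selected`.
#' @method tidy mcid_roc
#' @export
tidy.mcid_roc <- function(x, ...) {
  out <- x$curve
  out$selected <- out$cutoff == x$selected_cutoff
  out
}

#' One-row summary of an ROC cut-point analysis
#'
#' @param x an `mcid_roc` object from [qr_roc()].
#' @param ... unused.
#' @return One-row tibble: `auc`, `selected_cutoff`, `sensitivity`,
#'   `specificity`, `selection_rule_satisfied`, `n_achievers`, `n_failures`.
#' @method glance mcid_roc
#' @export
glance.mcid_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, selected_cutoff = x$selected_cutoff,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 selection_rule_satisfied = x$selection_rule_satisfied,
                 n_achievers = x$n_achievers, n_failures = x$n_failures)
}

#' Tidy pipeline results into one estimate per row
#'
#' @param x an `mcid_results` object from [run_mcid_pipeline()].
#' @param ... unused.
#' @return The full MCID estimate tibble.
#' @method tidy mcid_results
#' @export
tidy.mcid_results <- function(x, ...) x$estimates

#' One row per pooled MCID from pipeline results
#'
#' @param x an `mcid_results` object from [run_mcid_pipeline()].
#' @param ... unused.
#' @return The pooled estimate tibble.
#' @method glance mcid_results
#' @export
glance.mcid_results <- function(x, ...) x$pooled
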