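#' Plot an ROC curve with its selected cut-point
#'
#' @param object an `mcid_roc` object from [qr_roc()].
#' @param ... unused.
#' @return A ggplot: the ROC curve in 1 - specificity / sensitivity space,
#'   the chance diagonal, and the selected cut-point highlighted.
#' @method autoplot mcid_roc
#' @export
autoplot.mcid_roc <- function(object, ...) {
  curve <- object$curve[order(1 - object$curve$specificity,
                              object$curve$sensitivity), ]
  sel <- object$curve[object$curve$cutoff == object$selected_cutoff, ]
  ggplot2::ggplot(curve, ggplot2::aes(x = 1 - .data$specificity,
                                      y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = sel, colour = "red", size = 2) +
    ggplot2::labs(
      title = sprintf("%s improvement vs %s MCID %.2f (AUC %.3f)",
                      toupper(object$target), toupper(object$anchor),
                      object$anchor_mcid, object$auc),
      subtitle = sprintf("selected cut-off %.2f (sens %.2f, spec %.2f)",
                         object$selected_cutoff, object$sensitivity,
                         object$specificity),
      x = "1 - specificity", y = "sensitivity") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' Summary plot of all MCID estimates per instrument
#'
#' Horizontal dot-and-interval plot of every MCID estimate, grouped by
#' method class, with a vertical reference line at the literature MCID of
#' each instrument.
#'
#' @param fig1_data summary table from [render_summary()] (or the `fig1`
#'   component of [run_mcid_pipeline()] results).
#' @param instrument optionally restrict to one instrument.
#' @return A ggplot faceted by instrument.
#' @export
plot_mcid_summary <- function(fig1_data, instrument = NULL) {
  d <- fig1_data[fig1_data$scale == "total", ]
  if (!is.null(instrument)) d <- d[d$instrument == match_instrument(instrument), ]
  d$label <- ifelse(is.na(d$anchor), d$method,
                    paste0(d$method, " (", d$anchor, ")"))
  if ("anchor_vintage" %in% names(d)) {
    d$label <- ifelse(is.na(d$anchor_vintage), d$label,
                      paste0(d$label, " [", d$anchor_vintage, "]"))
  }
  d$instrument <- toupper(d$instrument)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value, y = .data$label,
                                  colour = .data$method_class)) +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$literature_mcid),
                        colour = "red") +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high),
                            height = 0.3, na.rm = TRUE) +
    ggplot2::facet_wrap(~instrument, scales = "free_x") +
    ggplot2::labs(x = "MCID estimate (score units, improvement)", y = NULL,
                  colour = "method class",
                  caption = "red line: literature MCID") +
    ggplot2::theme_minimal()
}
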