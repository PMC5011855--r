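#' Normality gate
#'
#' Test selection throughout the pipeline is gated on normality: parametric
#' branches (paired/unpaired t, Pearson) are used when the sample looks
#' normal, rank-based branches (Wilcoxon, Mann-Whitney, Spearman) otherwise.
#' The gate is a Shapiro-Wilk test at the given alpha; a constant (degenerate)
#' sample fails the gate and is flagged.
#'
#' @param x numeric sample, n >= 3 (missing values dropped).
#' @param alpha significance level of the normality test, default 0.05.
#' @return `TRUE`/`FALSE`, with attributes `p` (the Shapiro-Wilk p-value, NA
#'   when degenerate) and `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  if (length(x) < 3) stop("normality_gate requires n >= 3")
  if (stats::sd(x) == 0) {
    return(structure(FALSE, p = NA_real_, degenerate = TRUE))
  }
  # shapiro.test caps n at 5000; a subsample decides for larger cohorts
  if (length(x) > 5000) x <- x[seq(1, length(x), length.out = 5000)]
  p <- stats::shapiro.test(x)$p.value
  structure(p >= alpha, p = p, degenerate = FALSE)
}

test_result <- function(test_name, statistic, p_value, estimate,
                        ci_low, ci_high, normal_gate, n, flag = NA_character_) {
  tibble::tibble(
    test_name = test_name, statistic = unname(statistic),
    p_value = unname(p_value), estimate = unname(estimate),
    ci_low = ci_low, ci_high = ci_high,
    normal_gate = normal_gate, n = n, flag = flag
  )
}

#' Paired location test with normality-gated branch choice
#'
#' One-sample test of the within-subject change scores. On the normal branch
#' a paired t-test reports the mean change with its t-based 95% CI; otherwise
#' a Wilcoxon signed-rank test reports the Hodges-Lehmann pseudo-median with
#' its exact-distribution CI.
#'
#' @param deltas numeric vector of within-subject differences (NAs dropped).
#' @param conf_level confidence level, default 0.95.
#' @param alpha normality-gate level, default 0.05.
#' @return One-row tibble: `test_name`, `statistic`, `p_value`, `estimate`,
#'   `ci_low`, `ci_high`, `normal_gate`, `n`, `flag`.
#' @export
paired_location_test <- function(deltas, conf_level = 0.95, alpha = 0.05) {
  deltas <- deltas[!is.na(deltas)]
  n <- length(deltas)
  if (n < 2) stop("paired_location_test requires n >= 2")
  gate <- if (n >= 3) normality_gate(deltas, alpha) else stats::sd(deltas) > 0
  if (stats::sd(deltas) == 0) {
    # degenerate: all differences equal; CI collapses to the point
    return(test_result("degenerate", NA_real_, if (all(deltas == 0)) 1 else 0,
                       deltas[1], deltas[1], deltas[1], FALSE, n,
                       flag = "constant sample"))
  }
  if (isTRUE(as.logical(gate))) {
    tt <- stats::t.test(deltas, conf.level = conf_level)
    test_result("paired t", tt$statistic, tt$p.value, tt$estimate,
                tt$conf.int[1], tt$conf.int[2], TRUE, n)
  } else {
    if (all(deltas == 0)) {
      return(test_result("wilcoxon signed-rank", NA_real_, 1, 0, 0, 0, FALSE, n,
                         flag = "all-zero differences"))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(deltas, conf.int = TRUE, conf.level = conf_level)
    )
    test_result("wilcoxon signed-rank", wt$statistic, wt$p.value, wt$estimate,
                wt$conf.int[1], wt$conf.int[2], FALSE, n)
  }
}

#' Unpaired location test with normality-gated branch choice
#'
#' Two-sample comparison of independent groups. On the normal branch a Welch
#' t-test reports the difference in means (a - b) with its CI; otherwise a
#' Mann-Whitney U test reports the Hodges-Lehmann shift estimate with its CI.
#'
#' @param a,b numeric samples (NAs dropped), each n >= 2.
#' @inheritParams paired_location_test
#' @return One-row tibble as in [paired_location_test()].
#' @export
unpaired_location_test <- function(a, b, conf_level = 0.95, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) {
    stop("unpaired_location_test requires n >= 2 in both groups")
  }
  n <- length(a) + length(b)
  normal <- (length(a) < 3 || isTRUE(as.logical(normality_gate(a, alpha)))) &&
    (length(b) < 3 || isTRUE(as.logical(normality_gate(b, alpha))))
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    # both groups constant: the difference is exact, no sampling variability
    d <- mean(a) - mean(b)
    return(test_result("degenerate", NA_real_, if (d == 0) 1 else 0, d, d, d,
                       FALSE, n, flag = "constant samples"))
  }
  if (normal) {
    tt <- stats::t.test(a, b, conf.level = conf_level)  # Welch
    test_result("welch t", tt$statistic, tt$p.value,
                tt$estimate[1] - tt$estimate[2],
                tt$conf.int[1], tt$conf.int[2], TRUE, n)
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, conf.int = TRUE, conf.level = conf_level)
    )
    test_result("mann-whitney", wt$statistic, wt$p.value, wt$estimate,
                wt$conf.int[1], wt$conf.int[2], FALSE, n)
  }
}

#' Correlation with gated coefficient choice
#'
#' Spearman's coefficient is forced when the anchor is ordinal (the GRC);
#' otherwise Pearson is used when both samples pass the normality gate and
#' Spearman when either fails it.
#'
#' @param x,y paired numeric vectors; pairs with a missing value are dropped.
#' @param anchor_is_ordinal force Spearman, default `FALSE`.
#' @param alpha normality-gate level.
#' @return One-row tibble with `method`, `r`, `p_value`, `n`, `flag`.
#' @export
cor_gated <- function(x, y, anchor_is_ordinal = FALSE, alpha = 0.05) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("cor_gated requires at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(tibble::tibble(method = NA_character_, r = NA_real_,
                          p_value = NA_real_, n = length(x),
                          flag = "constant input"))
  }
  method <- if (anchor_is_ordinal) {
    "spearman"
  } else if (isTRUE(as.logical(normality_gate(x, alpha))) &&
             isTRUE(as.logical(normality_gate(y, alpha)))) {
    "pearson"
  } else {
    "spearman"
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(method = method, r = unname(ct$estimate),
                 p_value = ct$p.value, n = length(x), flag = NA_character_)
}
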