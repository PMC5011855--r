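#' Parameters of the synthetic pulmonary-rehabilitation cohort
#'
#' The defaults reproduce the statistical structure of the study cohort the
#' package emulates: n = 451 patients with moderate to very severe COPD in a
#' 3-week inpatient rehabilitation programme; baseline and change moments for
#' the CCQ, CAT and SGRQ total and domain scores; change-score correlations
#' between instruments (0.63 SGRQ-CCQ, 0.54 SGRQ-CAT, 0.59 CCQ-CAT); rank
#' correlations of the GRC anchor with the change scores (0.29, 0.23, 0.30);
#' GRC category frequencies (12/98/196/123/25 over the five classes); a 10%
#' exacerbation prevalence with baseline-score elevation of exacerbators
#' (0.62 CCQ, 2.96 CAT, 9.28 SGRQ points); and 1/2/4 missing T1
#' questionnaires for CCQ/CAT/SGRQ.
#'
#' Baseline cross-instrument correlations and the domain-total correlation
#' are not part of the emulated study's reporting; the defaults (0.70 and
#' 0.80) are typical values for these instruments.
#'
#' @param n cohort size.
#' @param scores tibble with one row per instrument/scale: `instrument`,
#'   `scale`, `t0_mean`, `t0_sd`, `change_mean`, `change_sd` (negative change
#'   means improvement).
#' @param change_corr 3x3 correlation matrix of the total change scores
#'   (order ccq, cat, sgrq); must be symmetric positive definite.
#' @param t0_corr 3x3 correlation matrix of the baseline totals.
#' @param domain_total_corr latent correlation of each domain with its
#'   instrument total, in (0, 1).
#' @param grc_corr target (absolute) rank correlations of the GRC with each
#'   instrument's change score.
#' @param grc_category_probs probabilities of the five GRC classes
#'   (deterioration, none, minimal, moderate, major); must sum to 1.
#' @param exacerbation_prevalence fraction experiencing an exacerbation
#'   during rehabilitation, in (0, 1).
#' @param exacerbation_baseline_shift per-instrument mean baseline elevation
#'   of exacerbators, in score units.
#' @param missing_t1 per-instrument number of subjects with a missing T1
#'   questionnaire (completely at random).
#' @param covariates list of covariate distribution parameters (age, sex,
#'   GOLD stage, FEV1 percent predicted).
#' @return A `cohort_params` list, validated.
#' @export
cohort_params <- function(
    n = 451,
    scores = default_score_moments(),
    change_corr = matrix(c(1, 0.59, 0.63,
                           0.59, 1, 0.54,
                           0.63, 0.54, 1), 3, 3,
                         dimnames = list(c("ccq", "cat", "sgrq"),
                                         c("ccq", "cat", "sgrq"))),
    t0_corr = matrix(c(1, 0.7, 0.7,
                       0.7, 1, 0.7,
                       0.7, 0.7, 1), 3, 3,
                     dimnames = list(c("ccq", "cat", "sgrq"),
                                     c("ccq", "cat", "sgrq"))),
    domain_total_corr = 0.80,
    grc_corr = c(ccq = 0.29, cat = 0.23, sgrq = 0.30),
    grc_category_probs = c(deterioration = 12, none = 98, minimal = 196,
                           moderate = 123, major = 25) / 454,
    exacerbation_prevalence = 0.10,
    exacerbation_baseline_shift = c(ccq = 0.62, cat = 2.96, sgrq = 9.28),
    missing_t1 = c(ccq = 1, cat = 2, sgrq = 4),
    covariates = list(age_mean = 57.87, age_sd = 6.56, male_prop = 0.65,
                      gold_probs = c(`2` = 227, `3` = 176, `4` = 48) / 451,
                      fev1_mean = 50.40, fev1_sd = 15.11)) {
  params <- list(n = n, scores = scores, change_corr = change_corr,
                 t0_corr = t0_corr, domain_total_corr = domain_total_corr,
                 grc_corr = grc_corr, grc_category_probs = grc_category_probs,
                 exacerbation_prevalence = exacerbation_prevalence,
                 exacerbation_baseline_shift = exacerbation_baseline_shift,
                 missing_t1 = missing_t1, covariates = covariates)
  class(params) <- "cohort_params"
  validate_cohort_params(params)
  params
}

#' Default score moments of the emulated rehabilitation cohort
#'
#' Baseline mean/s.d. and change mean/s.d. per instrument and scale, in score
#' units (negative change = improvement).
#'
#' @return Tibble with columns `instrument`, `scale`, `t0_mean`, `t0_sd`,
#'   `change_mean`, `change_sd`.
#' @export
default_score_moments <- function() {
  tibble::tribble(
    ~instrument, ~scale,     ~t0_mean, ~t0_sd, ~change_mean, ~change_sd,
    "ccq",  "total",        2.86,  1.17,  -0.58,  0.92,
    "ccq",  "symptoms",     2.87,  1.24,  -0.59,  1.16,
    "ccq",  "functional",   2.86,  1.34,  -0.56,  1.00,
    "ccq",  "mental",       2.86,  1.74,  -0.62,  1.49,
    "cat",  "total",       20.23,  7.33,  -3.11,  5.59,
    "sgrq", "total",       50.69, 17.33,  -9.04, 12.11,
    "sgrq", "symptoms",    63.66, 21.77, -14.22, 21.69,
    "sgrq", "activities",  63.58, 19.82,  -6.71, 13.44,
    "sgrq", "impact",      39.21, 18.81,  -8.78, 13.95
  )
}

check_corr_matrix <- function(m, label) {
  if (!isTRUE(all.equal(m, t(m))) || any(abs(diag(m) - 1) > 1e-8)) {
    stop(label, " must be symmetric with unit diagonal")
  }
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop(label, " is not positive definite (smallest eigenvalue ",
         format(min(ev)), ")")
  }
  invisible(m)
}

validate_cohort_params <- function(p) {
  stopifnot(p$n >= 2, all(p$scores$t0_sd > 0), all(p$scores$change_sd > 0))
  check_corr_matrix(p$change_corr, "change_corr")
  check_corr_matrix(p$t0_corr, "t0_corr")
  stopifnot(p$domain_total_corr > 0, p$domain_total_corr < 1)
  if (abs(sum(p$grc_category_probs) - 1) > 1e-6) {
    stop("grc_category_probs must sum to 1")
  }
  stopifnot(p$exacerbation_prevalence > 0, p$exacerbation_prevalence < 1)
  invisible(p)
}

# latent scaling: for each (instrument, scale), find the pre-clip normal
# parameters whose post-clip moments hit the targets
calibrate_scales <- function(params, specs) {
  purrr::pmap_dfr(params$scores, function(instrument, scale, t0_mean, t0_sd,
                                          change_mean, change_sd) {
    row <- spec_row(instrument, scale, specs)
    t0 <- calibrate_clipped_normal(t0_mean, t0_sd, row$min, row$max)
    ch <- calibrate_change_clipped(t0$mu, t0$sigma, row$min, row$max,
                                   change_mean, change_sd)
    tibble::tibble(instrument = instrument, scale = scale,
                   lo = row$min, hi = row$max,
                   t0_mu = t0$mu, t0_sigma = t0$sigma,
                   ch_mu = ch$mu, ch_sigma = ch$sigma)
  })
}

# Pre-clip change parameters such that delta = clip(t0 + change) - t0 has
# the target moments, with t0 itself a clipped normal. The two latents are
# independent, so a deterministic equal-probability quadrature grid over
# both suffices; fixed-point iteration, <= 20 rounds, 1% tolerance.
calibrate_change_clipped <- function(t0_mu, t0_sigma, lo, hi,
                                     target_mean, target_sd,
                                     grid_size = 301, max_iter = 20,
                                     tol = 0.01) {
  z <- stats::qnorm((seq_len(grid_size) - 0.5) / grid_size)
  t0 <- clip(t0_mu + t0_sigma * z, lo, hi)
  mu <- target_mean; sigma <- target_sd
  for (i in seq_len(max_iter)) {
    t1 <- clip(outer(t0, mu + sigma * z, "+"), lo, hi)
    d <- t1 - t0
    m <- mean(d)
    s <- sqrt(mean((d - m)^2))
    if (abs(m - target_mean) <= tol * max(abs(target_mean), target_sd) &&
        abs(s - target_sd) <= tol * target_sd) break
    mu <- mu + (target_mean - m)
    sigma <- sigma * target_sd / max(s, 1e-8)
  }
  list(mu = mu, sigma = sigma)
}

# Rank correlations target the discretized GRC; the latent Pearson weights
# are inflated by the normal-score factor plus a small discretization
# allowance (tuned once against the generator's own targets).
.grc_inflation <- 1.08

grc_latent_weights <- function(params) {
  rho_star <- pmin(unname(params$grc_corr) * .grc_inflation, 0.95)
  w <- solve(params$change_corr, rho_star)
  noise_var <- 1 - sum(w * rho_star)
  if (noise_var < 0) stop("grc_corr targets are jointly infeasible")
  list(w = w, noise_sd = sqrt(noise_var))
}

# Calibrate the logistic exacerbation model on the baseline latents:
# eta = alpha + b' Z0 with b proportional to R0^{-1} d (d = target shifts in
# s.d. units) so the induced per-instrument baseline shifts are proportional
# to their targets; the latent scale and intercept are solved by Gaussian
# quadrature so prevalence and shift magnitude are hit exactly in
# expectation.
calibrate_exacerbation <- function(params) {
  sd0 <- params$scores$t0_sd[params$scores$scale == "total"]
  d <- unname(params$exacerbation_baseline_shift) / sd0
  R0 <- params$t0_corr
  k <- c(crossprod(d, solve(R0, d)))
  prev <- params$exacerbation_prevalence
  gq_z <- stats::qnorm((seq_len(2001) - 0.5) / 2001)
  expectation <- function(f) mean(f(gq_z))
  solve_alpha <- function(sdu) {
    stats::uniroot(function(al) {
      expectation(function(x) stats::plogis(al + sdu * x)) - prev
    }, c(-(5 * sdu + 30), 5 * sdu + 30))$root
  }
  gap <- function(sdu) {
    al <- solve_alpha(sdu)
    expectation(function(x) x * stats::plogis(al + sdu * x)) / (prev * (1 - prev))
  }
  target_gap <- sqrt(k)  # shift_i (sd units) = (d_i / sqrt(k)) * gap
  if (gap(50) < target_gap) {
    stop("exacerbation baseline shifts are infeasible at this prevalence")
  }
  sdu <- stats::uniroot(function(s) gap(s) - target_gap, c(1e-3, 50))$root
  list(b = (sdu / sqrt(k)) * solve(R0, d), alpha = solve_alpha(sdu))
}

grc_bins <- list(deterioration = -7:-2, none = -1:1, minimal = 2:3,
                 moderate = 4:5, major = 6:7)

#' Generate a synthetic pulmonary-rehabilitation cohort
#'
#' Draws a cohort from a Gaussian-copula-style latent construction: baseline
#' totals from correlated truncated normals; change totals from a correlated
#' multivariate normal clipped so T1 stays in range (pre-clip moments are
#' recalibrated so the post-clip moments match their targets); domain scores
#' as correlated perturbations of the instrument latent; a GRC anchor from a
#' weighted combination of the sign-flipped standardized change latents,
#' discretized by quantile so the category frequencies match their target
#' probabilities; an exacerbation flag from a logistic model on baseline
#' severity calibrated to prevalence and baseline shift; and completely-at-
#' random missing T1 questionnaires.
#'
#' @param params a [cohort_params()] object.
#' @param seed integer seed; the output is fully determined by
#'   `params` + `seed`.
#' @return Wide cohort tibble: `subject_id`, covariates, `exacerbation_pr`,
#'   `grc`, and `<instrument>_<scale>_t0` / `_t1` score columns.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 100), seed = 1)
#' @export
simulate_cohort <- function(params = cohort_params(), seed = 1L) {
  validate_cohort_params(params)
  specs <- instrument_specs()
  set.seed(as.integer(seed))
  n <- params$n
  insts <- c("ccq", "cat", "sgrq")
  cal <- calibrate_scales(params, specs)

  # correlated baseline and change latents for the totals
  Z0 <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(params$t0_corr)
  Zc <- matrix(stats::rnorm(n * 3), n, 3) %*% chol(params$change_corr)
  colnames(Z0) <- colnames(Zc) <- insts

  rho_d <- params$domain_total_corr
  latent_for <- function(Z, instrument, scale) {
    if (scale == "total") return(Z[, instrument])
    rho_d * Z[, instrument] + sqrt(1 - rho_d^2) * stats::rnorm(n)
  }

  scores <- list()
  for (i in seq_len(nrow(cal))) {
    r <- cal[i, ]
    z0 <- latent_for(Z0, r$instrument, r$scale)
    zc <- latent_for(Zc, r$instrument, r$scale)
    t0 <- clip(r$t0_mu + r$t0_sigma * z0, r$lo, r$hi)
    t1 <- clip(t0 + r$ch_mu + r$ch_sigma * zc, r$lo, r$hi)
    scores[[score_col(r$instrument, r$scale, "t0")]] <- t0
    scores[[score_col(r$instrument, r$scale, "t1")]] <- t1
  }

  # GRC: latent improvement score, discretized by quantile to the target
  # category frequencies, then spread over the integer values of each class
  gw <- grc_latent_weights(params)
  L <- c((-Zc) %*% gw$w) + gw$noise_sd * stats::rnorm(n)
  counts <- allocate_counts(n, params$grc_category_probs)
  cat_names <- names(params$grc_category_probs)
  ord <- order(L)
  grc <- integer(n)
  start <- 0
  for (j in seq_along(counts)) {
    idx <- ord[seq_len(counts[j]) + start]
    bins <- grc_bins[[cat_names[j]]]
    sub <- allocate_counts(counts[j], rep(1, length(bins)))
    grc[idx] <- rep(bins, times = sub)
    start <- start + counts[j]
  }

  # exacerbation during rehabilitation, linked to baseline severity
  ex <- calibrate_exacerbation(params)
  p_ex <- stats::plogis(ex$alpha + c(Z0 %*% ex$b))
  exacerbation <- stats::runif(n) < p_ex

  cv <- params$covariates
  cohort <- tibble::tibble(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = round(stats::rnorm(n, cv$age_mean, cv$age_sd), 1),
    sex = ifelse(stats::runif(n) < cv$male_prop, "male", "female"),
    gold = as.integer(sample(names(cv$gold_probs), n, TRUE, cv$gold_probs)),
    fev1pp = round(clip(stats::rnorm(n, cv$fev1_mean, cv$fev1_sd), 10, 110), 1),
    exacerbation_pr = exacerbation,
    grc = grc
  )
  cohort <- dplyr::bind_cols(cohort, tibble::as_tibble(scores))

  # completely-at-random missing T1 questionnaires, per instrument
  for (inst in insts) {
    k <- params$missing_t1[[inst]]
    if (k > 0) {
      miss <- sample.int(n, k)
      cols <- grep(paste0("^", inst, "_.*_t1$"), names(cohort), value = TRUE)
      cohort[miss, cols] <- NA_real_
    }
  }
  cohort
}

#' Generator calibration report
#'
#' Pairs every generator target (baseline and change moments of the total
#' scores, change-score correlations, GRC rank correlations, exacerbation
#' prevalence and baseline shifts, GRC category shares) with its realized
#' sample value and the absolute deviation.
#'
#' @param cohort a cohort tibble from [simulate_cohort()].
#' @param params the [cohort_params()] used to generate it.
#' @return Tibble with columns `quantity`, `where`, `target`, `realized`,
#'   `abs_dev`.
#' @export
calibration_report <- function(cohort, params = cohort_params()) {
  if (nrow(cohort) < 2) stop("calibration_report requires at least 2 records")
  insts <- c("ccq", "cat", "sgrq")
  ch <- compute_changes(cohort)
  totals <- params$scores[params$scores$scale == "total", ]
  rows <- list()
  add <- function(quantity, where, target, realized) {
    rows[[length(rows) + 1]] <<- tibble::tibble(
      quantity = quantity, where = where, target = target,
      realized = realized, abs_dev = abs(realized - target))
  }
  for (i in seq_len(nrow(totals))) {
    inst <- totals$instrument[i]
    t0 <- cohort[[score_col(inst, "total", "t0")]]
    d <- ch$delta[ch$instrument == inst & ch$scale == "total"]
    add("t0_mean", inst, totals$t0_mean[i], mean(t0, na.rm = TRUE))
    add("t0_sd", inst, totals$t0_sd[i], stats::sd(t0, na.rm = TRUE))
    add("change_mean", inst, totals$change_mean[i], mean(d))
    add("change_sd", inst, totals$change_sd[i], stats::sd(d))
  }
  wide <- tidyr::pivot_wider(ch[ch$scale == "total", c("subject_id", "instrument", "delta")],
                             names_from = "instrument", values_from = "delta")
  for (pair in list(c("ccq", "cat"), c("ccq", "sgrq"), c("cat", "sgrq"))) {
    add("change_corr", paste(pair, collapse = "-"),
        params$change_corr[pair[1], pair[2]],
        stats::cor(wide[[pair[1]]], wide[[pair[2]]],
                   use = "complete.obs"))
  }
  for (inst in insts) {
    d <- ch$delta[ch$instrument == inst & ch$scale == "total"]
    g <- cohort$grc[match(ch$subject_id[ch$instrument == inst & ch$scale == "total"],
                          cohort$subject_id)]
    add("grc_rank_corr", inst, params$grc_corr[[inst]],
        abs(stats::cor(g, d, method = "spearman", use = "complete.obs")))
  }
  add("exacerbation_prevalence", "cohort", params$exacerbation_prevalence,
      mean(cohort$exacerbation_pr))
  for (inst in insts) {
    t0 <- cohort[[score_col(inst, "total", "t0")]]
    add("exacerbation_baseline_shift", inst,
        params$exacerbation_baseline_shift[[inst]],
        mean(t0[cohort$exacerbation_pr], na.rm = TRUE) -
          mean(t0[!cohort$exacerbation_pr], na.rm = TRUE))
  }
  cats <- categorize_grc(cohort$grc)$category
  for (nm in names(params$grc_category_probs)) {
    add("grc_category_share", nm, unname(params$grc_category_probs[nm]),
        mean(cats == nm, na.rm = TRUE))
  }
  dplyr::bind_rows(rows)
}
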