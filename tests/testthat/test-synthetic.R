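# a large cohort shared across generator checks
big_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(
      cohort_params(n = 10000, missing_t1 = c(ccq = 1, cat = 2, sgrq = 4)),
      seed = 314)
    cache
  }
})

test_that("parameter validation rejects malformed inputs", {
  bad <- matrix(c(1, 0.99, -0.99, 0.99, 1, 0.99, -0.99, 0.99, 1), 3, 3,
                dimnames = rep(list(c("ccq", "cat", "sgrq")), 2))
  expect_error(cohort_params(change_corr = bad), "eigenvalue")
  expect_error(cohort_params(grc_category_probs = c(
    deterioration = 0.5, none = 0.2, minimal = 0.2, moderate = 0.2,
    major = 0.2)), "sum to 1")
  expect_error(cohort_params(exacerbation_prevalence = 1.2), "prevalence")
})

test_that("default parameters encode the study conditions", {
  p <- cohort_params()
  expect_equal(p$n, 451)
  expect_equal(p$exacerbation_prevalence, 0.10)
  expect_equal(unname(p$exacerbation_baseline_shift["ccq"]), 0.62)
  expect_equal(unname(p$missing_t1), c(1, 2, 4))
  tot <- p$scores[p$scores$scale == "total", ]
  expect_equal(tot$t0_mean, c(2.86, 20.23, 50.69))
  expect_equal(tot$change_sd, c(0.92, 5.59, 12.11))
  expect_equal(p$change_corr["ccq", "sgrq"], 0.63)
  expect_equal(unname(p$grc_corr), c(0.29, 0.23, 0.30))
})

test_that("generation is deterministic given the seed", {
  p <- cohort_params(n = 200, missing_t1 = c(ccq = 1, cat = 1, sgrq = 1))
  a <- simulate_cohort(p, seed = 9)
  b <- simulate_cohort(p, seed = 9)
  expect_identical(a, b)
  c <- simulate_cohort(p, seed = 10)
  expect_false(identical(a, c))
})

test_that("scores never leave the instrument ranges after truncation", {
  co <- big_cohort()
  specs <- instrument_specs()
  for (i in seq_len(nrow(specs))) {
    for (tp in c("t0", "t1")) {
      x <- co[[mcidpr:::score_col(specs$instrument[i], specs$scale[i], tp)]]
      expect_true(all(is.na(x) | (x >= specs$min[i] & x <= specs$max[i])))
    }
  }
})

test_that("realized total-score moments hit their targets at n = 10,000", {
  co <- big_cohort()
  rep <- calibration_report(co, cohort_params(n = 10000))
  n <- 10000
  tot <- rep[rep$quantity %in% c("t0_mean", "t0_sd", "change_mean", "change_sd"), ]
  for (i in seq_len(nrow(tot))) {
    sd_ref <- rep$target[rep$quantity == sub("_mean", "_sd", tot$quantity[i]) &
                           rep$where == tot$where[i]][1]
    mc_se <- if (grepl("_mean", tot$quantity[i])) sd_ref / sqrt(n)
             else tot$target[i] / sqrt(2 * n)
    # within 3 Monte-Carlo standard errors plus the 1% calibration tolerance
    expect_lt(tot$abs_dev[i], 3 * mc_se + 0.01 * abs(tot$target[i]))
  }
  # headline generator contract for the CCQ change distribution
  expect_lt(rep$abs_dev[rep$quantity == "change_mean" & rep$where == "ccq"], 0.03)
  expect_lt(rep$abs_dev[rep$quantity == "change_sd" & rep$where == "ccq"], 0.05)
  # correlation and anchor targets
  expect_true(all(rep$abs_dev[rep$quantity == "change_corr"] < 0.03))
  expect_true(all(rep$abs_dev[rep$quantity == "grc_rank_corr"] < 0.05))
  expect_lt(rep$abs_dev[rep$quantity == "exacerbation_prevalence"], 0.015)
  shifts <- rep[rep$quantity == "exacerbation_baseline_shift", ]
  expect_true(all(shifts$abs_dev / shifts$target < 0.15))
})

test_that("zero change correlations produce independent change scores", {
  p <- cohort_params(n = 10000,
                     change_corr = diag(3) |>
                       (\(m) {dimnames(m) <- rep(list(c("ccq", "cat", "sgrq")), 2); m})(),
                     missing_t1 = c(ccq = 0, cat = 0, sgrq = 0))
  co <- simulate_cohort(p, seed = 271)
  ch <- compute_changes(co)
  wide <- tidyr::pivot_wider(ch[ch$scale == "total",
                                c("subject_id", "instrument", "delta")],
                             names_from = "instrument", values_from = "delta")
  expect_lt(abs(cor(wide$ccq, wide$cat)), 0.03)
  expect_lt(abs(cor(wide$ccq, wide$sgrq)), 0.03)
  expect_lt(abs(cor(wide$cat, wide$sgrq)), 0.03)
})

test_that("exacerbators carry higher baseline severity when shifts are positive", {
  co <- big_cohort()
  for (inst in c("ccq", "cat", "sgrq")) {
    t0 <- co[[paste0(inst, "_total_t0")]]
    expect_gt(mean(t0[co$exacerbation_pr]), mean(t0[!co$exacerbation_pr]))
  }
})

test_that("missingness and GRC strata counts match their parameters", {
  co <- simulate_cohort(cohort_params(), seed = 5)
  expect_equal(sum(is.na(co$ccq_total_t1)), 1)
  expect_equal(sum(is.na(co$cat_total_t1)), 2)
  expect_equal(sum(is.na(co$sgrq_total_t1)), 4)
  # domain columns go missing together with the instrument
  expect_equal(sum(is.na(co$sgrq_act_t1)), 4)
  p <- cohort_params()
  counts <- table(categorize_grc(co$grc)$category)
  expect_equal(sum(counts), 451)
  expect_true(all(abs(counts - 451 * p$grc_category_probs) <= 1))
})

test_that("calibration report covers every generator target", {
  p <- cohort_params(n = 50, missing_t1 = c(ccq = 0, cat = 0, sgrq = 0))
  co <- simulate_cohort(p, seed = 21)
  rep <- calibration_report(co, p)
  expect_setequal(unique(rep$quantity),
                  c("t0_mean", "t0_sd", "change_mean", "change_sd",
                    "change_corr", "grc_rank_corr", "exacerbation_prevalence",
                    "exacerbation_baseline_shift", "grc_category_share"))
  expect_equal(sum(rep$quantity == "change_corr"), 3)
  expect_equal(rep$abs_dev, abs(rep$realized - rep$target))
  expect_error(calibration_report(co[0, ], p), "at least 2")
})
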