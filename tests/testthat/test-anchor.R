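test_that("GRC categories follow the fixed magnitude partition", {
  res <- categorize_grc(c(0, 1, -1, 2, 3, -2, 4, 5, 6, 7, -5, -7))
  expect_equal(as.character(res$category),
               c("none", "none", "none", "minimal", "minimal", "deterioration",
                 "moderate", "moderate", "major", "major", "deterioration",
                 "deterioration"))
  # magnitude is retained for deterioration (e.g. -5 is moderate-sized)
  expect_equal(as.character(res$magnitude[res$grc == -5]), "moderate")
  expect_error(categorize_grc(8), "integer")
  expect_error(categorize_grc(2.5), "integer")
})

test_that("patient-referencing equals the minimal-stratum mean with a t CI", {
  # two subjects with changes -1 and -3: value 2, CI from t with 1 df
  co <- toy_cohort(4, ccq_delta = c(-1, -3, 0, 0), grc = c(2, 3, 0, 0))
  est <- patient_referencing(co, "ccq")
  expect_equal(est$value, 2)
  expect_equal(est$n, 2)
  se <- sd(c(-1, -3)) / sqrt(2)
  hw <- qt(0.975, 1) * se
  # CI straddles zero, so the improvement-magnitude interval starts at 0
  expect_equal(est$ci_low, 0)
  expect_equal(est$ci_high, 2 + hw)
  # all-equal stratum: degenerate CI of width zero
  co2 <- toy_cohort(3, ccq_delta = c(-1, -1, 0), grc = c(2, 3, 0))
  est2 <- patient_referencing(co2, "ccq")
  expect_equal(est2$value, 1)
  expect_equal(est2$ci_high - est2$ci_low, 0)
  # empty stratum: flagged undefined, not silently zero
  co3 <- toy_cohort(3, ccq_delta = c(-1, -1, 0), grc = c(0, 0, 5))
  est3 <- patient_referencing(co3, "ccq")
  expect_true(is.na(est3$value))
  expect_match(est3$note, "fewer than 2")
})

test_that("patient-referencing strata sizes partition the analysable subjects", {
  co <- default_cohort(42)
  est <- patient_referencing(co, "ccq")
  strata <- attr(est, "strata")
  ch <- compute_changes(co)
  n_analysable <- sum(!is.na(co$grc[match(
    ch$subject_id[ch$instrument == "ccq" & ch$scale == "total"],
    co$subject_id)]))
  expect_equal(sum(strata$n), n_analysable)
  expect_equal(est$n, strata$n[strata$category == "minimal"])
})

test_that("criterion-referencing is the baseline difference between groups", {
  co <- toy_cohort(4, ccq_t0 = c(3, 3, 2, 2),
                   exacerbation = c(TRUE, TRUE, FALSE, FALSE))
  est <- criterion_referencing(co, "ccq")
  expect_equal(est$value, 1.0)
  # identical group means: zero difference, not significant
  co2 <- toy_cohort(4, ccq_t0 = c(2.5, 2.5, 2.5, 2.5),
                    exacerbation = c(TRUE, TRUE, FALSE, FALSE))
  est2 <- criterion_referencing(co2, "ccq")
  expect_equal(est2$value, 0)
  expect_false(est2$significant)
  # one-subject group: flagged undefined
  co3 <- toy_cohort(3, exacerbation = c(TRUE, FALSE, FALSE))
  est3 <- criterion_referencing(co3, "ccq")
  expect_true(is.na(est3$value))
})

test_that("anchor eligibility gate thresholds the change-score correlation", {
  set.seed(11)
  d <- rnorm(100, -0.5, 1)
  co <- toy_cohort(100, ccq_delta = d, cat_delta = 3 * d + rnorm(100, 0, 0.1))
  g <- qr_gate(co, "ccq", "cat")
  expect_true(g$eligible)
  expect_gt(g$r, 0.9)
  # independent changes at n=1000: |r| < 0.50, not eligible
  co2 <- toy_cohort(1000, ccq_delta = rnorm(1000), cat_delta = rnorm(1000))
  g2 <- qr_gate(co2, "ccq", "cat")
  expect_lt(abs(g2$r), 0.5)
  expect_false(g2$eligible)
  # constant anchor change: undefined correlation, not eligible
  co3 <- toy_cohort(10, ccq_delta = rnorm(10), cat_delta = rep(-2, 10))
  g3 <- qr_gate(co3, "ccq", "cat")
  expect_true(is.na(g3$r))
  expect_false(g3$eligible)
})

test_that("regression referencing matches the closed-form OLS prediction", {
  # identity: anchoring an instrument on itself returns the anchor MCID
  co <- default_cohort(42)
  for (m in c(0.4, 1, 2.7)) {
    est <- qr_regression(co, "ccq", "ccq", m)
    expect_equal(est$value, m, tolerance = 1e-12)
  }
  # 5-point construction with hand-computed OLS line
  x <- c(-4, -2, 0, 1, 3); y <- c(-2.1, -1.2, -0.3, 0.4, 1.1)
  co2 <- toy_cohort(5, ccq_delta = y / 2, cat_delta = x)
  b1 <- sum((x - mean(x)) * (y / 2 - mean(y / 2))) / sum((x - mean(x))^2)
  b0 <- mean(y / 2) - b1 * mean(x)
  est2 <- qr_regression(co2, "ccq", "cat", 2)
  expect_equal(est2$value, abs(b0 + b1 * (-2)))
  expect_error(qr_regression(toy_cohort(5, cat_delta = rep(0, 5)),
                             "ccq", "cat", 2), "zero variance")
})

test_that("regression estimate is monotone in the anchor MCID for positive slopes", {
  co <- default_cohort(42)
  vals <- vapply(seq(0.5, 6, by = 0.5),
                 function(m) qr_regression(co, "ccq", "cat", m)$value, 0)
  expect_true(all(diff(vals) >= 0))
})

test_that("achiever/failure group means follow the boundary-inclusive split", {
  # everyone achieves; all target changes -0.5
  co <- toy_cohort(5, ccq_delta = rep(-0.5, 5), cat_delta = rep(-3, 5))
  est <- qr_group_means(co, "ccq", "cat", 2)
  expect_equal(est$value, 0.5)
  # two achievers with -1 and -2 (boundary -2 counts as achieving)
  co2 <- toy_cohort(4, ccq_delta = c(-1, -2, 0.5, 1),
                    cat_delta = c(-5, -2, -1, 0))
  est2 <- qr_group_means(co2, "ccq", "cat", 2)
  expect_equal(est2$value, 1.5)
  groups <- attr(est2, "groups")
  expect_equal(groups$n, c(2, 2))
  expect_equal(groups$mean_delta[groups$group == "failed"], 0.75)
})

test_that("ROC scan equals the brute-force oracle on random instances", {
  set.seed(77)
  for (i in 1:60) {
    inst <- random_roc_instance()
    fit <- mcidpr:::roc_scan(inst$score, inst$state)
    orc <- oracle_roc(inst$score, inst$state)
    expect_equal(fit$auc, orc$auc)
    expect_equal(fit$selected_cutoff, orc$cutoff)
    expect_equal(fit$selection_rule_satisfied, orc$satisfied)
  }
})

test_that("perfectly separated classes give AUC 1 and a satisfied rule", {
  co <- toy_cohort(10, ccq_delta = c(rep(-2, 5), rep(1, 5)),
                   cat_delta = c(rep(-4, 5), rep(0, 5)))
  roc <- qr_roc(co, "ccq", "cat", 2)
  expect_equal(roc$auc, 1)
  expect_true(roc$selection_rule_satisfied)
  expect_equal(c(roc$sensitivity, roc$specificity), c(1, 1))
  # the selected cutoff separates the classes (scores -1 vs 2)
  expect_true(roc$selected_cutoff > -1 && roc$selected_cutoff <= 2)
  # selected cutoff is always a member of the candidate grid
  expect_true(roc$selected_cutoff %in% roc$curve$cutoff)
  # single-class input is rejected
  expect_error(qr_roc(toy_cohort(5, cat_delta = rep(-5, 5)), "ccq", "cat", 2),
               "achievers")
})

test_that("ROC agrees with pROC on a default cohort", {
  co <- default_cohort(42)
  roc <- qr_roc(co, "ccq", "cat", 2)
  pairs <- mcidpr:::qr_pairs(co, "ccq", "cat")
  ref <- pROC::roc(pairs$anchor_delta <= -2, -pairs$target_delta,
                   quiet = TRUE, direction = "<")
  expect_equal(roc$auc, as.numeric(ref$auc), tolerance = 1e-10)
})

test_that("tidy/glance/autoplot work on the ROC object", {
  roc <- qr_roc(default_cohort(42), "ccq", "cat", 2)
  td <- tidy(roc)
  expect_true(all(c("cutoff", "sensitivity", "specificity", "selected") %in%
                    names(td)))
  expect_equal(sum(td$selected), 1)
  gl <- glance(roc)
  expect_equal(nrow(gl), 1)
  expect_true(gl$auc >= 0 && gl$auc <= 1)
  expect_s3_class(autoplot(roc), "ggplot")
  expect_output(print(roc), "AUC")
})

test_that("anchor revision averages the other approaches and rounds coarsely", {
  co <- default_cohort(42)
  rev <- revised_anchors(co)
  # under default calibration the revised anchors land on the coarse grid
  expect_equal(as.numeric(rev), c(0.50, 3.00, 7.00))
  un <- attr(rev, "unrounded")
  expect_equal(unname(rev["ccq"]), round_half_up(un[["ccq"]] / 0.05, 0) * 0.05)
  grid <- qr_iterate(co)
  expect_equal(nrow(grid), 2 * 6 * 3)  # 2 vintages x 6 pairs x 3 methods
  expect_setequal(unique(grid$anchor_vintage), c("literature", "revised"))
  # revised == literature anchors make the second pass identical to the first
  grid2 <- qr_iterate(co, revised = c(ccq = 0.40, cat = 2.00, sgrq = 4.00))
  lit <- grid2[grid2$anchor_vintage == "literature", ]
  rev2 <- grid2[grid2$anchor_vintage == "revised", ]
  expect_equal(lit$value, rev2$value)
  expect_equal(lit$auc, rev2$auc)
})
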