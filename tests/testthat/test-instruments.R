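test_that("CCQ scoring matches hand-computed item arithmetic", {
  expect_equal(score_ccq(rep(0, 10)),
               tibble::tibble(symptoms = 0, functional = 0, mental = 0, total = 0))
  expect_equal(score_ccq(rep(6, 10)),
               tibble::tibble(symptoms = 6, functional = 6, mental = 6, total = 6))
  # hand-summed: symptoms items 1,2,5,6 -> (1,2,5,6); mental 3,4 -> (3,4);
  # functional 7-10 -> (0,1,2,3); total = 27/10
  s <- score_ccq(c(1, 2, 3, 4, 5, 6, 0, 1, 2, 3))
  expect_equal(s$total, 2.7)
  expect_equal(s$symptoms, mean(c(1, 2, 5, 6)))
  expect_equal(s$mental, mean(c(3, 4)))
  expect_equal(s$functional, mean(c(0, 1, 2, 3)))
})

test_that("CCQ total is the item-count-weighted mean of domains, always", {
  set.seed(1)
  for (i in 1:50) {
    items <- sample(0:6, 10, replace = TRUE)
    s <- score_ccq(items)
    expect_equal(s$total, (4 * s$symptoms + 4 * s$functional + 2 * s$mental) / 10)
  }
})

test_that("CAT scoring is the item sum", {
  expect_equal(score_cat(rep(0, 8)), 0)
  expect_equal(score_cat(rep(5, 8)), 40)
  expect_equal(score_cat(c(1, 2, 3, 0, 4, 5, 1, 2)), 18)
})

test_that("scoring rejects malformed items with the offending index", {
  expect_error(score_ccq(rep(1, 9)), "exactly 10")
  expect_error(score_ccq(c(rep(1, 5), 7, rep(1, 4))), "item 6")
  expect_error(score_ccq(c(rep(1, 9), 2.5)), "item 10")
  expect_error(score_cat(rep(1, 10)), "exactly 8")
  expect_error(score_cat(c(-1, rep(1, 7))), "item 1")
})

test_that("scoring is monotone and permutation-invariant within domains", {
  set.seed(7)
  for (i in 1:20) {
    items <- sample(0:5, 10, replace = TRUE)
    base <- score_ccq(items)
    j <- sample(10, 1)
    bumped <- items; bumped[j] <- bumped[j] + 1
    up <- score_ccq(bumped)
    expect_true(all(unlist(up) >= unlist(base)))
    # permute items within each domain: all scores unchanged
    perm <- items
    for (d in ccq_domains()) perm[d] <- perm[sample(d)]
    expect_equal(score_ccq(perm), base)
    cat_items <- sample(0:5, 8, replace = TRUE)
    expect_equal(score_cat(sample(cat_items)), score_cat(cat_items))
  }
})

test_that("compute_changes applies pair-wise deletion per instrument", {
  co <- toy_cohort(3, ccq_delta = c(-0.58, 0, 1), cat_delta = c(-3, -3, -3))
  co$ccq_total_t1[2] <- NA  # subject 2 misses CCQ at T1 only
  ch <- compute_changes(co)
  ccq <- ch[ch$instrument == "ccq" & ch$scale == "total", ]
  expect_equal(ccq$subject_id, c("T001", "T003"))
  expect_equal(ccq$delta, c(-0.58, 1))
  # the same subject still contributes the CAT change
  cat_ch <- ch[ch$instrument == "cat" & ch$scale == "total", ]
  expect_equal(nrow(cat_ch), 3)
  expect_equal(cat_ch$delta, rep(-3, 3))
  # t0 = t1 gives delta exactly 0
  expect_true(all(ch$delta[ch$instrument == "sgrq" & ch$scale == "total"] == 0))
  # kept rows as NA when requested
  ch_all <- compute_changes(co, keep_missing = TRUE)
  expect_equal(sum(is.na(ch_all$delta)), 1)
  expect_equal(nrow(ch_all), nrow(ch) + 1)
})

test_that("floor/ceiling shares use inclusive 10% bands and a 15% flag", {
  u <- seq(0, 6, length.out = 100)  # even spread over the CCQ range
  fc <- floor_ceiling_check(u, "ccq")
  expect_equal(fc$floor_pct, 10)
  expect_equal(fc$ceiling_pct, 10)
  expect_false(fc$flagged)

  many_zero <- c(rep(0, 20), rep(3, 80))
  fc2 <- floor_ceiling_check(many_zero, "ccq")
  expect_equal(fc2$floor_pct, 20)
  expect_true(fc2$flagged)

  mid <- rep(3, 50)
  fc3 <- floor_ceiling_check(mid, "ccq")
  expect_equal(c(fc3$floor_pct, fc3$ceiling_pct), c(0, 0))
  expect_false(fc3$flagged)

  expect_error(floor_ceiling_check(numeric(0), "ccq"), "at least one")
})

test_that("instrument metadata is valid and overridable", {
  specs <- instrument_specs()
  expect_true(all(specs$min < specs$max))
  totals <- specs[specs$scale == "total", ]
  expect_equal(totals$icc, c(0.94, 0.80, 0.91))
  expect_equal(totals$literature_mcid, c(0.40, 2.00, 4.00))
  over <- instrument_specs(overrides = tibble::tibble(
    instrument = "cat", scale = "total", icc = 0.85))
  expect_equal(over$icc[over$instrument == "cat"], 0.85)
  expect_error(instrument_specs(overrides = tibble::tibble(
    instrument = "cat", scale = "total", icc = 1.2)), "icc")
  # YAML override path
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines("- instrument: sgrq\n  scale: total\n  icc: 0.88", f)
  over2 <- instrument_specs(overrides = f)
  expect_equal(over2$icc[over2$instrument == "sgrq" & over2$scale == "total"], 0.88)
})
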