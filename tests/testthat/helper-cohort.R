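# Shared fixtures, built in code.

# default-calibrated synthetic cohort, cached per seed within a test run
.cohort_cache <- new.env(parent = emptyenv())
default_cohort <- function(seed = 42) {
  key <- as.character(seed)
  if (is.null(.cohort_cache[[key]])) {
    .cohort_cache[[key]] <- simulate_cohort(cohort_params(), seed = seed)
  }
  .cohort_cache[[key]]
}

# minimal wide cohort built from explicit per-subject values; unspecified
# scores sit at mid-scale so every schema column exists
toy_cohort <- function(n,
                       ccq_t0 = rep(3, n), ccq_delta = rep(0, n),
                       cat_t0 = rep(20, n), cat_delta = rep(0, n),
                       sgrq_t0 = rep(50, n), sgrq_delta = rep(0, n),
                       grc = rep(0, n), exacerbation = rep(FALSE, n)) {
  tibble::tibble(
    subject_id = sprintf("T%03d", seq_len(n)),
    exacerbation_pr = exacerbation, grc = grc,
    ccq_total_t0 = ccq_t0, ccq_total_t1 = ccq_t0 + ccq_delta,
    ccq_sym_t0 = ccq_t0, ccq_sym_t1 = ccq_t0 + ccq_delta,
    ccq_fun_t0 = ccq_t0, ccq_fun_t1 = ccq_t0 + ccq_delta,
    ccq_men_t0 = ccq_t0, ccq_men_t1 = ccq_t0 + ccq_delta,
    cat_total_t0 = cat_t0, cat_total_t1 = cat_t0 + cat_delta,
    sgrq_total_t0 = sgrq_t0, sgrq_total_t1 = sgrq_t0 + sgrq_delta,
    sgrq_sym_t0 = sgrq_t0, sgrq_sym_t1 = sgrq_t0 + sgrq_delta,
    sgrq_act_t0 = sgrq_t0, sgrq_act_t1 = sgrq_t0 + sgrq_delta,
    sgrq_imp_t0 = sgrq_t0, sgrq_imp_t1 = sgrq_t0 + sgrq_delta
  )
}
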