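#' Pipeline configuration
#'
#' Collects every tunable of the estimation pipeline in one serializable
#' list, so a run is reproducible from input + config alone. `config` may
#' also be read from a YAML file holding any subset of these fields.
#'
#' @param qr_gate_threshold anchor eligibility correlation threshold
#'   (default 0.50).
#' @param roc_sens_spec_floor joint sensitivity/specificity floor for ROC
#'   cut-point selection (default 0.70).
#' @param anchor_mcids_literature named vector of literature anchor MCIDs.
#' @param anchor_mcids_revised `"auto"` to derive revised anchors from the
#'   cohort, a named vector to fix them, or `NULL` to skip the revision pass.
#' @param qr_summary collapse rule for the questionnaire-referencing value
#'   entering the pooled total (`"revised"`, `"literature"` or `"all"`).
#' @param rounding_decimals decimals used for the rounded report columns.
#' @param seed stored for provenance (the pipeline itself is deterministic).
#' @return A named list of class `mcid_config`.
#' @export
mcid_config <- function(qr_gate_threshold = 0.50,
                        roc_sens_spec_floor = 0.70,
                        anchor_mcids_literature = c(ccq = 0.40, cat = 2.00,
                                                    sgrq = 4.00),
                        anchor_mcids_revised = "auto",
                        qr_summary = "revised",
                        rounding_decimals = 2,
                        seed = NA_integer_) {
  structure(list(qr_gate_threshold = qr_gate_threshold,
                 roc_sens_spec_floor = roc_sens_spec_floor,
                 anchor_mcids_literature = anchor_mcids_literature,
                 anchor_mcids_revised = anchor_mcids_revised,
                 qr_summary = qr_summary,
                 rounding_decimals = rounding_decimals,
                 seed = seed),
            class = "mcid_config")
}

read_mcid_config <- function(path) {
  vals <- yaml::read_yaml(path)
  for (nm in c("anchor_mcids_literature", "anchor_mcids_revised")) {
    if (!is.null(vals[[nm]]) && is.list(vals[[nm]])) {
      vals[[nm]] <- unlist(vals[[nm]])
    }
  }
  do.call(mcid_config, vals)
}

required_cohort_columns <- function() {
  score_cols <- as.vector(outer(
    c("ccq_total", "ccq_sym", "ccq_fun", "ccq_men", "cat_total",
      "sgrq_total", "sgrq_sym", "sgrq_act", "sgrq_imp"),
    c("_t0", "_t1"), paste0))
  c("subject_id", "exacerbation_pr", "grc", score_cols)
}

score_items_if_present <- function(data) {
  for (tp in c("t0", "t1")) {
    ccq_items <- paste0("ccq_i", 1:10, "_", tp)
    if (all(ccq_items %in% names(data))) {
      scored <- purrr::pmap_dfr(data[ccq_items], function(...) score_ccq(c(...)))
      data[[paste0("ccq_sym_", tp)]] <- scored$symptoms
      data[[paste0("ccq_fun_", tp)]] <- scored$functional
      data[[paste0("ccq_men_", tp)]] <- scored$mental
      data[[paste0("ccq_total_", tp)]] <- scored$total
    }
    cat_items <- paste0("cat_i", 1:8, "_", tp)
    if (all(cat_items %in% names(data))) {
      data[[paste0("cat_total_", tp)]] <-
        purrr::pmap_dbl(data[cat_items], function(...) score_cat(c(...)))
    }
  }
  data
}

#' Validate a cohort table against the expected schema
#'
#' Checks required columns, score ranges against the instrument metadata,
#' and GRC range; every violation is reported with its column.
#'
#' @param data cohort tibble.
#' @param specs instrument metadata.
#' @return The data, invisibly, or an error listing each offending column.
#' @export
validate_cohort <- function(data, specs = instrument_specs()) {
  if (nrow(data) == 0) stop("cohort is empty")
  problems <- character()
  missing <- setdiff(required_cohort_columns(), names(data))
  if (length(missing)) {
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing, collapse = ", ")))
  } else {
    for (i in seq_len(nrow(specs))) {
      for (tp in c("t0", "t1")) {
        col <- score_col(specs$instrument[i], specs$scale[i], tp)
        x <- data[[col]]
        bad <- sum(!is.na(x) & (x < specs$min[i] | x > specs$max[i]))
        if (bad > 0) {
          problems <- c(problems, paste0(col, ": ", bad, " value(s) outside [",
                                         specs$min[i], ", ", specs$max[i], "]"))
        }
      }
    }
    g <- data$grc
    bad_g <- sum(!is.na(g) & (g < -7 | g > 7 | g != round(g)))
    if (bad_g > 0) {
      problems <- c(problems, paste0("grc: ", bad_g,
                                     " value(s) not an integer in [-7, +7]"))
    }
  }
  if (length(problems)) {
    stop("cohort schema violations:\n  ", paste(problems, collapse = "\n  "))
  }
  invisible(data)
}

#' Read a cohort CSV
#'
#' Reads the per-subject cohort table (one row per subject, empty cell =
#' missing). If item-level columns (`ccq_i1_t0` ... or `cat_i1_t0` ...) are
#' present, domain and total scores are computed from them.
#'
#' @param path CSV path.
#' @param specs instrument metadata used for validation.
#' @return Validated cohort tibble.
#' @export
read_cohort <- function(path, specs = instrument_specs()) {
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  data <- score_items_if_present(data)
  validate_cohort(data, specs)
  data
}

cohort_summary_table <- function(data, specs = instrument_specs()) {
  ch <- compute_changes(data, specs)
  purrr::pmap_dfr(specs[, c("instrument", "scale")], function(instrument, scale) {
    t0 <- data[[score_col(instrument, scale, "t0")]]
    t1 <- data[[score_col(instrument, scale, "t1")]]
    d <- ch$delta[ch$instrument == instrument & ch$scale == scale]
    tt <- paired_location_test(d)
    fc <- floor_ceiling_check(t0, instrument, scale, specs)
    tibble::tibble(
      instrument = instrument, scale = scale,
      n_t0 = sum(!is.na(t0)), n_change = length(d),
      t0_mean = mean(t0, na.rm = TRUE), t0_sd = stats::sd(t0, na.rm = TRUE),
      t1_mean = mean(t1, na.rm = TRUE), t1_sd = stats::sd(t1, na.rm = TRUE),
      change_mean = mean(d), change_sd = stats::sd(d),
      change_ci_low = tt$ci_low, change_ci_high = tt$ci_high,
      change_test = tt$test_name, change_p = tt$p_value,
      floor_pct = fc$floor_pct, ceiling_pct = fc$ceiling_pct,
      floor_ceiling_flagged = fc$flagged
    )
  })
}

#' Fig-1-style summary table of every estimate
#'
#' One row per MCID estimate with its method class, value, 95% CI and the
#' literature reference MCID of the instrument, ready for a summary plot
#' (see [plot_mcid_summary()]).
#'
#' @param estimates MCID estimate tibble (e.g. the `estimates` component of
#'   [run_mcid_pipeline()]).
#' @param pooled pooled estimate tibble from [pooled_estimates()]; optional.
#' @param specs instrument metadata providing the literature reference.
#' @return Tibble with `instrument`, `scale`, `method_class`, `method`,
#'   `anchor`, `value`, `ci_low`, `ci_high`, `literature_mcid`.
#' @export
render_summary <- function(estimates, pooled = NULL,
                           specs = instrument_specs()) {
  stopifnot(nrow(estimates) >= 1)
  classes <- c(patient = "anchor: patient", criterion = "anchor: criterion",
               qr_regression = "anchor: questionnaire",
               qr_groups = "anchor: questionnaire",
               qr_roc = "anchor: questionnaire",
               sem = "distribution", sem196 = "distribution",
               half_sd = "distribution", pooled = "pooled")
  out <- estimates[, intersect(c("instrument", "scale", "method", "anchor",
                                 "anchor_vintage", "value", "ci_low", "ci_high"),
                               names(estimates))]
  if (!is.null(pooled) && nrow(pooled)) {
    out <- dplyr::bind_rows(out, tibble::tibble(
      instrument = pooled$instrument, scale = pooled$scale,
      method = "pooled", anchor = NA_character_,
      value = pooled$value, ci_low = NA_real_, ci_high = NA_real_))
  }
  out$method_class <- unname(classes[out$method])
  lit <- specs[specs$scale == "total", c("instrument", "literature_mcid")]
  out$literature_mcid <- lit$literature_mcid[match(out$instrument, lit$instrument)]
  out
}

add_rounded <- function(tbl, digits, cols = c("value", "ci_low", "ci_high")) {
  for (col in intersect(cols, names(tbl))) {
    tbl[[paste0(col, "_rounded")]] <- round_half_up(tbl[[col]], digits)
  }
  tbl
}

#' Run the full MCID estimation pipeline
#'
#' Validates the cohort, computes the cohort summary (health-status outcomes
#' with floor/ceiling diagnostics), the patient-referencing strata table,
#' the questionnaire-referencing grid with iterative anchor revision, every
#' method-level MCID estimate, and the pooled estimates, and writes them to
#' `out_dir` as `cohort_summary.csv`, `table3.csv`, `table4.csv`,
#' `estimates.csv`, `pooled.csv`, `fig1_data.csv` and `run_log.txt`. All
#' outputs are deterministic functions of input + config, so identical runs
#' produce identical files.
#'
#' @param input cohort tibble or path to a cohort CSV.
#' @param out_dir output directory, created if needed; `NULL` skips writing.
#' @param config an [mcid_config()] or path to a YAML config file.
#' @param specs instrument metadata.
#' @return Invisibly, a list of class `mcid_results` with components
#'   `cohort`, `summary`, `strata` (table 3 analogue), `qr_grid` (table 4
#'   analogue), `estimates`, `pooled`, `fig1`, `revised_anchors`, `config`,
#'   `log`.
#' @export
run_mcid_pipeline <- function(input, out_dir = NULL, config = mcid_config(),
                              specs = instrument_specs()) {
  if (is.character(config)) config <- read_mcid_config(config)
  data <- if (is.character(input)) read_cohort(input, specs) else
    validate_cohort(score_items_if_present(input), specs)

  log <- c(paste0("mcidpr version: ", as.character(utils::packageVersion("mcidpr"))),
           paste0("seed: ", config$seed),
           paste0("config hash: ", rlang::hash(unclass(config))),
           paste0("subjects: ", nrow(data)))

  summary_tbl <- cohort_summary_table(data, specs)
  for (i in seq_len(nrow(summary_tbl))) {
    log <- c(log, sprintf("pair-wise deletion %s/%s: %d of %d with both timepoints",
                          summary_tbl$instrument[i], summary_tbl$scale[i],
                          summary_tbl$n_change[i], nrow(data)))
  }

  # method-level estimates -------------------------------------------------
  pat <- purrr::pmap_dfr(specs[, c("instrument", "scale")],
                         function(instrument, scale)
                           patient_referencing(data, instrument, scale, specs))
  cri <- purrr::pmap_dfr(specs[, c("instrument", "scale")],
                         function(instrument, scale)
                           criterion_referencing(data, instrument, scale, specs))
  dist <- distribution_referencing(data, specs)
  qr_grid <- qr_iterate(data,
                        literature = config$anchor_mcids_literature,
                        revised = config$anchor_mcids_revised,
                        gate_threshold = config$qr_gate_threshold,
                        sens_spec_floor = config$roc_sens_spec_floor,
                        specs = specs)
  estimates <- dplyr::bind_rows(pat, cri, dist, qr_grid)
  pooled <- pooled_estimates(data, qr_grid = qr_grid,
                             qr_summary = config$qr_summary, specs = specs)

  strata <- purrr::pmap_dfr(specs[, c("instrument", "scale")],
    function(instrument, scale) {
      tbl <- grc_stratum_table(data, instrument, scale, specs)
      tbl$instrument <- instrument; tbl$scale <- scale
      tbl[, c("instrument", "scale", setdiff(names(tbl), c("instrument", "scale")))]
    })
  fig1 <- render_summary(estimates, pooled, specs)

  digits <- config$rounding_decimals
  outputs <- list(
    cohort_summary = add_rounded(summary_tbl, digits,
                                 c("t0_mean", "t0_sd", "change_mean", "change_sd",
                                   "change_ci_low", "change_ci_high")),
    table3 = add_rounded(strata, digits, c("mean_delta", "ci_low", "ci_high")),
    table4 = add_rounded(qr_grid, digits),
    estimates = add_rounded(estimates, digits),
    pooled = add_rounded(pooled, digits, "value"),
    fig1_data = add_rounded(fig1, digits)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(outputs)) {
      readr::write_csv(outputs[[nm]], file.path(out_dir, paste0(nm, ".csv")),
                       na = "")
    }
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }

  res <- list(cohort = data, summary = outputs$cohort_summary,
              strata = outputs$table3, qr_grid = outputs$table4,
              estimates = outputs$estimates, pooled = outputs$pooled,
              fig1 = outputs$fig1_data,
              revised_anchors = attr(qr_grid, "revised_anchors"),
              config = config, log = log)
  class(res) <- "mcid_results"
  invisible(res)
}

#' @export
print.mcid_results <- function(x, ...) {
  cat("MCID pipeline results: ", nrow(x$cohort), " subjects\n", sep = "")
  cat("Pooled MCID estimates (total scores):\n")
  tot <- x$pooled[x$pooled$scale == "total", ]
  for (i in seq_len(nrow(tot))) {
    cat(sprintf("  %-5s %6.2f\n", toupper(tot$instrument[i]), tot$value[i]))
  }
  if (!is.null(x$revised_anchors)) {
    cat("Revised questionnaire-referencing anchors: ",
        paste(sprintf("%s=%.2f", toupper(names(x$revised_anchors)),
                      x$revised_anchors), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
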