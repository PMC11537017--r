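#' Analysis configuration for the MR workflow
#'
#' Bundles every threshold and seed the workflow uses, so reports can
#' embed the exact effective configuration.
#'
#' @param iv_pvalue Instrument-screening p-value threshold (default 1e-5).
#' @param clump_window_kb,clump_r2 LD clumping window (kb) and r-squared
#'   threshold (defaults 10000 and 0.001).
#' @param min_f Weak-instrument F threshold (default 10).
#' @param r2_method Per-variant variance-explained formula, see
#'   [variance_explained()].
#' @param ivw_model IVW flavour, see [mr_ivw()].
#' @param n_boot Weighted-median bootstrap replicates.
#' @param presso_n_sim MR-PRESSO simulation count.
#' @param palindrome_eaf_window Passed to [harmonize()].
#' @param steiger Apply Steiger directionality filtering (default TRUE).
#' @param diagnostics Run the sensitivity battery in [run_mr()] (Cochran's
#'   Q, leave-one-out, MR-PRESSO, funnel data); turn off for large
#'   simulation screens.
#' @param multiple_testing `"none"` (default, raw p-values) or `"bh_fdr"`.
#' @param significance Significance level used for screen flags.
#' @param case_fraction Outcome case fraction for the power calculation;
#'   `NULL` skips power.
#' @param seed Master seed; per-component seeds are derived from it.
#' @return An `mr_analysis_config` list.
#' @export
mr_config <- function(iv_pvalue = 1e-5, clump_window_kb = 10000,
                      clump_r2 = 0.001, min_f = 10,
                      r2_method = c("eaf_beta", "t_stat"),
                      ivw_model = c("multiplicative_random", "fixed"),
                      n_boot = 1000, presso_n_sim = 1000,
                      palindrome_eaf_window = 0.08,
                      steiger = TRUE, diagnostics = TRUE,
                      multiple_testing = c("none", "bh_fdr"),
                      significance = 0.05, case_fraction = NULL,
                      seed = 1L) {
  assert_number(iv_pvalue, "iv_pvalue", 0, 1, open_lower = TRUE)
  assert_number(clump_window_kb, "clump_window_kb", 0, Inf)
  assert_number(clump_r2, "clump_r2", 0, 1)
  assert_number(min_f, "min_f", 0, Inf)
  assert_number(significance, "significance", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  if (!is.null(case_fraction)) {
    assert_number(case_fraction, "case_fraction", 0, 1,
                  open_lower = TRUE, open_upper = TRUE)
  }
  structure(
    list(iv_pvalue = iv_pvalue, clump_window_kb = clump_window_kb,
         clump_r2 = clump_r2, min_f = min_f,
         r2_method = match.arg(r2_method),
         ivw_model = match.arg(ivw_model),
         n_boot = n_boot, presso_n_sim = presso_n_sim,
         palindrome_eaf_window = palindrome_eaf_window,
         steiger = steiger, diagnostics = diagnostics,
         multiple_testing = match.arg(multiple_testing),
         significance = significance, case_fraction = case_fraction,
         seed = as.integer(seed)),
    class = "mr_analysis_config"
  )
}

# Drop candidate mediator instruments that explain more variance in the
# exposure than in the mediator: such variants reach the outcome through
# the exposure's direct path and would violate the exclusion restriction
# of the mediator-to-outcome MR. Variants absent from the exposure GWAS
# are kept.
filter_mediator_instruments <- function(mediator, exposure,
                                        method = "t_stat") {
  idx <- match(mediator$variant_id, exposure$variant_id)
  r2_med <- variance_explained(mediator, method = method, quiet = TRUE)
  keep <- rep(TRUE, nrow(mediator))
  found <- !is.na(idx)
  if (any(found)) {
    exp_rows <- as_tibble(exposure)[idx[found], , drop = FALSE]
    r2_exp <- variance_explained(exp_rows, method = method, quiet = TRUE)
    keep[found] <- r2_med[found] > r2_exp
  }
  restore_ss(as_tibble(mediator)[keep, , drop = FALSE], mediator)
}

# Selection -> clumping -> weak-instrument filter -> harmonization ->
# Steiger filter. Shared by run_mr() and recovery_suite().
prepare_instruments <- function(exposure, outcome, ld, config) {
  sel <- select_by_pvalue(exposure, config$iv_pvalue, quiet = TRUE)
  if (nrow(sel) == 0) {
    abort_input("no variants pass the instrument p-value threshold")
  }
  cl <- ld_clump(sel, ld, window_kb = config$clump_window_kb,
                 r2_threshold = config$clump_r2, quiet = TRUE)
  iv <- filter_weak_instruments(cl, min_f = config$min_f,
                                method = config$r2_method, quiet = TRUE)
  if (nrow(iv) == 0) abort_input("all instruments weak")
  h <- harmonize(iv, outcome,
                 palindrome_eaf_window = config$palindrome_eaf_window)
  if (config$steiger && nrow(h) > 0) h <- steiger_filter(h, quiet = TRUE)
  attr(h, "instrument_f") <- attr(iv, "f_stat")
  attr(h, "instrument_r2") <- sum(iv$r2)
  h
}

#' Run one two-sample MR analysis end to end
#'
#' Executes the full workflow for one exposure-outcome pair: p-value
#' screening, greedy LD clumping, weak-instrument exclusion,
#' harmonization, Steiger filtering, the four-estimator suite, and (when
#' `config$diagnostics` is on) Cochran's Q, the Egger intercept test,
#' leave-one-out, MR-PRESSO and funnel data, plus the power calculation
#' when a case fraction is configured. With fewer than 3 surviving
#' instruments the report is still emitted, with the estimators marked
#' not computable.
#'
#' @param exposure,outcome `summary_stats` tibbles.
#' @param ld Optional [ld_matrix()] for clumping.
#' @param config An [mr_config()].
#' @return An `mr_report` list: `estimates` (tidy tibble, one row per
#'   estimator, with a `computable` flag), `diagnostics` (list),
#'   `instruments` (selection audit counts), `power`, `status`
#'   (`"ok"` or `"insufficient_instruments"`) and `config`. [tidy()]
#'   returns the estimates table.
#' @export
run_mr <- function(exposure, outcome, ld = NULL, config = mr_config()) {
  exp_lab <- trait_label(exposure) %||% "exposure"
  out_lab <- trait_label(outcome) %||% "outcome"
  h <- tryCatch(prepare_instruments(exposure, outcome, ld, config),
                mrmediate_input_error = function(e) e)
  not_computable <- function(reason) {
    est <- tibble(
      exposure = exp_lab, outcome = out_lab,
      method = c("ivw", "egger", "weighted_median", "raps"),
      estimate = NA_real_, std.error = NA_real_, statistic = NA_real_,
      p.value = NA_real_, conf.low = NA_real_, conf.high = NA_real_,
      or = NA_real_, or.conf.low = NA_real_, or.conf.high = NA_real_,
      n_snps = if (inherits(h, "condition")) 0L else nrow(h),
      computable = FALSE
    )
    structure(list(estimates = est, diagnostics = list(),
                   instruments = list(reason = reason),
                   power = NA_real_,
                   status = "insufficient_instruments", config = config),
              class = "mr_report")
  }
  if (inherits(h, "condition")) return(not_computable(conditionMessage(h)))
  if (nrow(h) < 3) return(not_computable("fewer than 3 instruments survive selection"))

  wm_seed <- derive_seed(config$seed, 11L)
  est <- mr_estimate(h, ivw_model = config$ivw_model,
                     n_boot = config$n_boot, seed = wm_seed)
  est$computable <- TRUE
  diagnostics <- list()
  if (config$diagnostics) {
    egger_fit <- mr_egger(h)
    diagnostics$heterogeneity <- tidy(cochran_q(h))
    diagnostics$egger_intercept <- tibble(
      intercept = egger_fit$extras$egger_intercept,
      std.error = egger_fit$extras$egger_intercept_se,
      p.value = egger_fit$extras$egger_intercept_pvalue
    )
    diagnostics$leave_one_out <- leave_one_out(
      h, model = config$ivw_model, significance = config$significance
    )
    diagnostics$funnel <- funnel_data(h)
    if (nrow(h) >= 4) {
      diagnostics$presso <- mr_presso(
        h, n_sim = config$presso_n_sim, seed = derive_seed(config$seed, 13L),
        model = config$ivw_model
      )
    }
  }
  power <- NA_real_
  if (!is.null(config$case_fraction)) {
    ivw_beta <- est$estimate[startsWith(est$method, "ivw")][1]
    r2_xz <- attr(h, "instrument_r2") %||% NA_real_
    n_out <- stats::median(h$n_outcome)
    if (is.finite(r2_xz) && r2_xz > 0 && r2_xz < 1 && is.finite(n_out)) {
      power <- mr_power(n_out, config$case_fraction, r2_xz, ivw_beta,
                        alpha = config$significance)
    }
  }
  structure(
    list(estimates = est, diagnostics = diagnostics,
         instruments = list(
           n_instruments = nrow(h),
           f_stat = attr(h, "instrument_f"),
           r2_total = attr(h, "instrument_r2"),
           dropped = dropped_rows(h)
         ),
         power = power, status = "ok", config = config),
    class = "mr_report"
  )
}

#' @export
print.mr_report <- function(x, ...) {
  cat(sprintf("<mr_report> %s -> %s [%s]\n",
              x$estimates$exposure[1], x$estimates$outcome[1], x$status))
  print(x$estimates)
  invisible(x)
}

#' @method tidy mr_report
#' @export
tidy.mr_report <- function(x, ...) x$estimates

#' @method glance mr_report
#' @export
glance.mr_report <- function(x, ...) {
  tibble(status = x$status,
         n_instruments = x$instruments$n_instruments %||% 0L,
         f_stat = x$instruments$f_stat %||% NA_real_,
         power = x$power)
}

#' Bidirectional MR between two traits
#'
#' Runs [run_mr()] in both directions, each with direction-specific
#' instrument selection, and flags `forward_only` causation when the
#' forward IVW p-value is below the significance level while the reverse
#' one is not.
#'
#' @param trait_a,trait_b `summary_stats` tibbles.
#' @param ld_a,ld_b Optional LD matrices for each trait's instruments.
#' @param config An [mr_config()].
#' @return An `mr_bidirectional` list: `forward`, `reverse` (both
#'   `mr_report`), and `flags` (tibble with `forward_only`,
#'   `reverse_only`).
#' @export
run_bidirectional <- function(trait_a, trait_b, ld_a = NULL, ld_b = NULL,
                              config = mr_config()) {
  fwd <- run_mr(trait_a, trait_b, ld = ld_a, config = config)
  rev <- run_mr(trait_b, trait_a, ld = ld_b, config = config)
  p_of <- function(rep) {
    p <- rep$estimates$p.value[startsWith(rep$estimates$method, "ivw")][1]
    if (length(p) == 0 || is.na(p)) 1 else p
  }
  sig <- config$significance
  flags <- tibble(
    forward_only = p_of(fwd) < sig && p_of(rev) >= sig,
    reverse_only = p_of(rev) < sig && p_of(fwd) >= sig
  )
  structure(list(forward = fwd, reverse = rev, flags = flags,
                 config = config),
            class = "mr_bidirectional")
}

#' @export
print.mr_bidirectional <- function(x, ...) {
  cat("<mr_bidirectional>\n")
  cat(sprintf("  forward_only: %s, reverse_only: %s\n",
              x$flags$forward_only, x$flags$reverse_only))
  print(x$forward)
  print(x$reverse)
  invisible(x)
}

#' Two-step MR mediation workflow
#'
#' Runs the three constituent MR analyses -- exposure to mediator (step
#' 1), mediator to outcome (step 2, instruments selected from the
#' mediator GWAS), and exposure to outcome (total) -- and decomposes the
#' total effect via [mediate()] using the IVW estimates. Candidate
#' step-2 instruments that explain more variance in the exposure than in
#' the mediator are excluded first: such variants act on the outcome
#' through the exposure's direct path, not the mediator.
#'
#' @param exposure,mediator,outcome `summary_stats` tibbles.
#' @param ld_exposure,ld_mediator Optional LD matrices for the two
#'   instrument sources.
#' @param config An [mr_config()].
#' @param ci_method Passed to [mediate()].
#' @return A `mediation_report` list: `mediation` (a `mediation_result`
#'   or `NULL`), the three `mr_report`s (`total`, `step1`, `step2`), and
#'   `status` (`"ok"` or `"not_computable"`).
#' @export
run_mediation_workflow <- function(exposure, mediator, outcome,
                                   ld_exposure = NULL, ld_mediator = NULL,
                                   config = mr_config(),
                                   ci_method = "delta_indirect_over_fixed_total") {
  total <- run_mr(exposure, outcome, ld = ld_exposure, config = config)
  step1 <- run_mr(exposure, mediator, ld = ld_exposure, config = config)
  med_clean <- filter_mediator_instruments(mediator, exposure)
  step2 <- run_mr(med_clean, outcome, ld = ld_mediator, config = config)
  reports <- list(total = total, step1 = step1, step2 = step2)
  ok <- vapply(reports, function(r) r$status == "ok", logical(1))
  if (!all(ok)) {
    return(structure(c(list(mediation = NULL, status = "not_computable"),
                       reports),
                     class = "mediation_report"))
  }
  ivw_of <- function(rep) {
    row <- rep$estimates[startsWith(rep$estimates$method, "ivw"), ][1, ]
    effect_estimate(row$estimate, row$std.error, label = rep$estimates$exposure[1])
  }
  med <- mediate(ivw_of(total), ivw_of(step1), ivw_of(step2),
                 ci_method = ci_method, quiet = TRUE)
  structure(c(list(mediation = med, status = "ok"), reports),
            class = "mediation_report")
}

#' @export
print.mediation_report <- function(x, ...) {
  cat(sprintf("<mediation_report> [%s]\n", x$status))
  if (!is.null(x$mediation)) print(x$mediation)
  invisible(x)
}

#' @method tidy mediation_report
#' @export
tidy.mediation_report <- function(x, ...) {
  if (is.null(x$mediation)) return(tibble())
  tidy(x$mediation)
}
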