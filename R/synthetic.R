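#' Configuration for the summary-level GWAS triplet simulator
#'
#' Defines the ground-truth causal structure
#' exposure -> mediator -> outcome used by [simulate_triplet()]:
#' `n_snps` variants affect the exposure directly (half-normal effect
#' sizes `|Normal(0, gamma_sd)|`, each variant's effect allele oriented
#' to its trait-increasing allele), `n_mediator_snps` further variants
#' affect the mediator directly (same effect scale); the binary outcome is reached
#' through the direct path (`beta_total - beta_xm * beta_my`) and through
#' the mediator (`beta_my` per mediator unit), plus optional per-variant
#' horizontal pleiotropy. The defaults realize a mediated proportion of
#' `0.3 * 0.1 / 0.2 = 0.15` with strong instruments at biobank-scale
#' sample sizes.
#'
#' @param n_snps Variants with direct exposure effects (>= 4).
#' @param n_mediator_snps Variants with direct mediator effects (default:
#'   `n_snps`); needed so the mediator has its own instruments for step-2
#'   MR.
#' @param n_exposure,n_mediator,n_outcome GWAS sample sizes (>= 100).
#' @param beta_total True total exposure-to-outcome effect (log OR per SD).
#' @param beta_xm True exposure-to-mediator effect (SD per SD).
#' @param beta_my True mediator-to-outcome effect (log OR per SD).
#' @param gamma_sd SD of the true per-variant effects on their own trait.
#' @param pleiotropy `"none"`, `"balanced"` (direct outcome effects
#'   `Normal(0, pleiotropy_scale)`), or `"directional"`
#'   (`Normal(pleiotropy_scale, pleiotropy_scale)`).
#' @param pleiotropy_scale Magnitude of the pleiotropic effects.
#' @param maf_range Minor-allele-frequency interval within (0, 0.5].
#' @param ld_blocks Number of LD blocks variants are split into.
#' @param ld_r2 Within-block squared correlation (0 gives an identity LD
#'   matrix).
#' @param seed Simulation seed; everything is reproducible from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_snps = 50, n_mediator_snps = n_snps,
                       n_exposure = 20000, n_mediator = 20000,
                       n_outcome = 20000,
                       beta_total = 0.2, beta_xm = 0.3, beta_my = 0.1,
                       gamma_sd = 0.08,
                       pleiotropy = c("none", "balanced", "directional"),
                       pleiotropy_scale = 0.02,
                       maf_range = c(0.05, 0.5),
                       ld_blocks = 1, ld_r2 = 0, seed = 1L) {
  pleiotropy <- match.arg(pleiotropy)
  if (n_snps < 4) abort_input("sim_config: n_snps must be at least 4")
  if (n_mediator_snps < 0) abort_input("sim_config: n_mediator_snps must be >= 0")
  for (nm in c("n_exposure", "n_mediator", "n_outcome")) {
    if (get(nm) < 100) abort_input(sprintf("sim_config: %s must be >= 100", nm))
  }
  assert_number(gamma_sd, "gamma_sd", 0, Inf)
  assert_number(pleiotropy_scale, "pleiotropy_scale", 0, Inf)
  if (length(maf_range) != 2 || maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2]) {
    abort_input("sim_config: maf_range must lie within (0, 0.5]")
  }
  if (ld_blocks < 1) abort_input("sim_config: ld_blocks must be >= 1")
  assert_number(ld_r2, "ld_r2", 0, 1)
  structure(
    list(n_snps = as.integer(n_snps),
         n_mediator_snps = as.integer(n_mediator_snps),
         n_exposure = as.integer(n_exposure),
         n_mediator = as.integer(n_mediator),
         n_outcome = as.integer(n_outcome),
         beta_total = beta_total, beta_xm = beta_xm, beta_my = beta_my,
         gamma_sd = gamma_sd, pleiotropy = pleiotropy,
         pleiotropy_scale = pleiotropy_scale, maf_range = maf_range,
         ld_blocks = as.integer(ld_blocks), ld_r2 = ld_r2,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Simulate a two-sample GWAS summary-statistic triplet with known truth
#'
#' Draws per-variant minor-allele frequencies, alleles and true effects
#' under the causal structure of [sim_config()], then generates each
#' study's estimated betas as the true marginal effect plus independent
#' normal noise with standard error `1 / sqrt(2 * n * eaf * (1 - eaf))`
#' (the three samples are non-overlapping by construction); p-values come
#' from the normal distribution. The LD matrix is block diagonal at the
#' configured within-block r-squared. Identical seeds give bit-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return A list of class `mr_simulation` with elements `exposure`,
#'   `mediator`, `outcome` (each a `summary_stats`), `truth` (a
#'   `truth_set`: per-variant tibble of `gamma`, `delta`, `pleiotropy`
#'   plus `beta_total`, `beta_direct`, `beta_indirect`,
#'   `true_proportion`), and `ld` (an [ld_matrix()]).
#' @export
simulate_triplet <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) {
    abort_input("simulate_triplet: `config` must come from sim_config()")
  }
  cfg <- config
  m <- cfg$n_snps + cfg$n_mediator_snps
  beta_indirect <- cfg$beta_xm * cfg$beta_my
  beta_direct <- cfg$beta_total - beta_indirect

  withr::with_seed(cfg$seed, {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    eaf <- ifelse(runif(m) < 0.5, maf, 1 - maf)
    alleles <- t(vapply(seq_len(m),
                        function(i) sample(c("A", "C", "G", "T"), 2),
                        character(2)))
    is_med_snp <- c(rep(FALSE, cfg$n_snps), rep(TRUE, cfg$n_mediator_snps))
    # Effect alleles are oriented to the trait-increasing allele of the
    # variant's own trait (half-normal effects), the convention under
    # which directional pleiotropy is well defined.
    gamma <- ifelse(is_med_snp, 0, abs(rnorm(m, 0, cfg$gamma_sd)))
    delta <- ifelse(is_med_snp, abs(rnorm(m, 0, cfg$gamma_sd)), 0)
    pleio <- switch(cfg$pleiotropy,
                    none = rep(0, m),
                    balanced = rnorm(m, 0, cfg$pleiotropy_scale),
                    directional = rnorm(m, cfg$pleiotropy_scale,
                                        cfg$pleiotropy_scale))
    true_med <- gamma * cfg$beta_xm + delta
    true_out <- gamma * beta_direct + true_med * cfg$beta_my + pleio

    variant_id <- sprintf("rs%06d", seq_len(m))
    block <- ceiling(seq_len(m) / ceiling(m / cfg$ld_blocks))
    chromosome <- as.character(((block - 1) %% 22) + 1)
    within <- stats::ave(seq_len(m), block, FUN = seq_along)
    position <- as.integer(1e6 + ((block - 1) %/% 22) * 5e7 + within * 1000)

    study <- function(true_beta, n, label, type) {
      se <- 1 / sqrt(2 * n * eaf * (1 - eaf))
      beta_hat <- rnorm(m, true_beta, se)
      summary_stats(
        tibble(variant_id = variant_id, chromosome = chromosome,
               position = position,
               effect_allele = alleles[, 1], other_allele = alleles[, 2],
               eaf = eaf, beta = beta_hat, se = se,
               pvalue = pmax(2 * pnorm(-abs(beta_hat / se)), 1e-300),
               n = n),
        trait_label = label, trait_type = type, quiet = TRUE
      )
    }
    exposure <- study(gamma, cfg$n_exposure, "simulated exposure", "quantitative")
    mediator <- study(true_med, cfg$n_mediator, "simulated mediator", "quantitative")
    outcome <- study(true_out, cfg$n_outcome, "simulated outcome", "binary")

    r2 <- diag(m)
    if (cfg$ld_r2 > 0) {
      same_block <- outer(block, block, "==")
      r2[same_block] <- cfg$ld_r2
      diag(r2) <- 1
    }
    ld <- ld_matrix(r2, variant_ids = variant_id)

    truth <- structure(
      list(snps = tibble(variant_id = variant_id, eaf = eaf,
                         gamma = gamma, delta = delta, pleiotropy = pleio,
                         mediator_snp = is_med_snp),
           beta_total = cfg$beta_total, beta_xm = cfg$beta_xm,
           beta_my = cfg$beta_my, beta_direct = beta_direct,
           beta_indirect = beta_indirect,
           true_proportion = if (cfg$beta_total != 0)
             beta_indirect / cfg$beta_total else NA_real_),
      class = "truth_set"
    )
    structure(list(exposure = exposure, mediator = mediator,
                   outcome = outcome, truth = truth, ld = ld,
                   config = cfg),
              class = "mr_simulation")
  })
}

#' Bias, spread and CI coverage of the full pipeline over replicates
#'
#' Repeatedly simulates a triplet, runs the full instrument-selection and
#' estimation pipeline (p-value screen, LD clumping, weak-instrument
#' filter, harmonization, Steiger filter, estimators), and summarizes the
#' bias, empirical SD and 95% CI coverage of each estimator's total-effect
#' estimate against the generating truth, together with the two-step
#' mediated-proportion estimate (IVW in both steps, delta-method CI).
#'
#' @param config A [sim_config()]; replicate `r` uses a seed derived from
#'   `config$seed` and `r`.
#' @param n_reps Number of replicates (>= 2; 100+ for stable summaries).
#' @param methods Estimators to track for the total effect.
#' @param control An [mr_config()] holding selection thresholds.
#' @return A tibble with one row per method plus one
#'   `mediation_proportion` row: `method`, `truth`, `mean_bias`,
#'   `empirical_sd`, `ci_coverage`, `n_reps_used`.
#' @export
recovery_suite <- function(config = sim_config(), n_reps = 100,
                           methods = c("ivw", "egger", "weighted_median", "raps"),
                           control = mr_config()) {
  if (n_reps < 2) abort_input("recovery_suite: n_reps must be at least 2")
  methods <- match.arg(methods, several.ok = TRUE)
  z <- z_crit()
  truth_total <- config$beta_total
  one_rep <- function(r) {
    cfg <- config
    cfg$seed <- derive_seed(config$seed, r)
    sim <- simulate_triplet(cfg)
    h_total <- try(prepare_instruments(sim$exposure, sim$outcome, sim$ld,
                                       control), silent = TRUE)
    if (inherits(h_total, "try-error") || nrow(h_total) < 3) return(NULL)
    est <- purrr::map_dfr(methods, function(mth) {
      fit <- switch(mth,
                    ivw = mr_ivw(h_total, model = control$ivw_model),
                    egger = mr_egger(h_total),
                    weighted_median = mr_weighted_median(
                      h_total, n_boot = control$n_boot,
                      seed = derive_seed(cfg$seed, 7L)),
                    raps = mr_raps(h_total))
      tibble(method = mth, estimate = fit$beta, se = fit$se)
    })
    h1 <- try(prepare_instruments(sim$exposure, sim$mediator, sim$ld,
                                  control), silent = TRUE)
    med_clean <- filter_mediator_instruments(sim$mediator, sim$exposure)
    h2 <- try(prepare_instruments(med_clean, sim$outcome, sim$ld,
                                  control), silent = TRUE)
    med <- NULL
    if (!inherits(h1, "try-error") && !inherits(h2, "try-error") &&
        nrow(h1) >= 1 && nrow(h2) >= 1) {
      res <- mediate(mr_ivw(h_total, model = control$ivw_model),
                     mr_ivw(h1, model = control$ivw_model),
                     mr_ivw(h2, model = control$ivw_model),
                     quiet = TRUE)
      med <- tibble(method = "mediation_proportion",
                    estimate = res$proportion,
                    low = res$proportion_ci[1], high = res$proportion_ci[2])
    }
    list(est = est, med = med)
  }
  reps <- purrr::map(seq_len(n_reps), one_rep)
  reps <- purrr::compact(reps)
  est_all <- purrr::map_dfr(reps, "est")
  med_all <- purrr::map_dfr(reps, "med")
  est_sum <- est_all |>
    dplyr::group_by(.data$method) |>
    dplyr::summarise(
      truth = truth_total,
      mean_bias = mean(.data$estimate - truth_total),
      empirical_sd = sd(.data$estimate),
      ci_coverage = mean(.data$estimate - z * .data$se <= truth_total &
                           truth_total <= .data$estimate + z * .data$se),
      n_reps_used = dplyr::n(),
      .groups = "drop"
    )
  out <- est_sum
  if (nrow(med_all) > 0) {
    tp <- config$beta_xm * config$beta_my / config$beta_total
    med_sum <- tibble(
      method = "mediation_proportion", truth = tp,
      mean_bias = mean(med_all$estimate - tp),
      empirical_sd = sd(med_all$estimate),
      ci_coverage = mean(med_all$low <= tp & tp <= med_all$high),
      n_reps_used = nrow(med_all)
    )
    out <- dplyr::bind_rows(out, med_sum)
  }
  out
}
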