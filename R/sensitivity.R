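#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum w_j (r_j - beta)^2` over the Wald ratios with inverse-variance
#' weights; under homogeneity Q is chi-squared with `J - 1` degrees of
#' freedom. Q is minimized at the fixed-effect IVW estimate, the default
#' evaluation point.
#'
#' @param h A `harmonized_set` with at least 2 instruments.
#' @param beta Causal estimate at which to evaluate Q; `NULL` uses the
#'   fixed-effect IVW estimate.
#' @return A `q_result` list with `q`, `df`, `pvalue`; [tidy()] gives a
#'   one-row tibble.
#' @export
cochran_q <- function(h, beta = NULL) {
  wr <- wald_ratios(h, quiet = TRUE)
  j <- nrow(wr)
  if (j < 2) abort_input("cochran_q needs at least 2 instruments")
  w <- 1 / wr$ratio_se^2
  if (is.null(beta)) beta <- sum(w * wr$ratio) / sum(w)
  q <- sum(w * (wr$ratio - beta)^2)
  df <- j - 1L
  structure(list(q = q, df = df, pvalue = pchisq(q, df, lower.tail = FALSE),
                 beta = beta),
            class = "q_result")
}

#' @export
print.q_result <- function(x, ...) {
  cat(sprintf("<q_result> Q = %.3f on %d df, p = %.3g\n", x$q, x$df, x$pvalue))
  invisible(x)
}

#' @method tidy q_result
#' @export
tidy.q_result <- function(x, ...) {
  tibble(statistic = x$q, df = x$df, p.value = x$pvalue, beta = x$beta)
}

#' Funnel-plot coordinates
#'
#' Per-instrument Wald ratio against its precision (`1 / ratio_se`);
#' asymmetry suggests directional pleiotropy. Use [plot_funnel()] to
#' render.
#'
#' @param h A `harmonized_set` with at least 1 instrument.
#' @return A tibble with columns `variant_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  wr <- wald_ratios(h, quiet = TRUE)
  if (nrow(wr) == 0) abort_input("funnel_data: no usable instruments")
  tibble(variant_id = wr$variant_id, ratio = wr$ratio,
         precision = 1 / wr$ratio_se)
}

#' Leave-one-out influence analysis
#'
#' Re-estimates the IVW causal effect excluding each instrument in turn
#' and flags instruments whose omission flips the sign of the estimate or
#' moves the p-value across the significance boundary.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param model IVW flavour, as in [mr_ivw()].
#' @param significance Boundary for the p-value crossing flag
#'   (default 0.05).
#' @return A `loo_result` tibble, one row per left-out variant
#'   (`variant_id`, `estimate`, `std.error`, `p.value`, `sign_change`,
#'   `crosses_significance`), with attributes `full_beta`, `full_pvalue`.
#' @export
leave_one_out <- function(h, model = "multiplicative_random",
                          significance = 0.05) {
  j <- nrow(h)
  if (j < 3) abort_input("leave_one_out needs at least 3 instruments")
  full <- mr_ivw(h, model = model)
  rows <- purrr::map_dfr(seq_len(j), function(i) {
    fit <- mr_ivw(restore_hs(as_tibble(h)[-i, , drop = FALSE], h), model = model)
    tibble(variant_id = h$variant_id[i], estimate = fit$beta,
           std.error = fit$se, p.value = fit$pvalue)
  })
  rows$sign_change <- sign(rows$estimate) != sign(full$beta)
  rows$crosses_significance <-
    (rows$p.value < significance) != (full$pvalue < significance)
  structure(rows, full_beta = full$beta, full_se = full$se,
            full_pvalue = full$pvalue, model = model,
            class = c("loo_result", class(rows)))
}

#' MR-PRESSO pleiotropy residual sum and outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments:
#' \enumerate{
#'   \item \emph{Global test}: the observed residual sum of squares
#'     `RSS = sum_j (beta_outcome_j - b_(-j) * beta_exposure_j)^2 /
#'     se_outcome_j^2`, where `b_(-j)` is the fixed-effect IVW estimate
#'     without instrument `j`, is compared with its null distribution
#'     obtained by redrawing each outcome beta from
#'     `Normal(b_(-j) * beta_exposure_j, se_outcome_j)` `n_sim` times
#'     (add-one Monte-Carlo p).
#'   \item \emph{Outlier test}: each instrument's own weighted squared
#'     residual gets a per-SNP Monte-Carlo p, Bonferroni-adjusted across
#'     instruments; adjusted p below `outlier_sig` flags an outlier.
#'   \item \emph{Distortion test}: when outliers exist, the shift between
#'     the raw IVW estimate and the outlier-corrected one is compared with
#'     the shifts produced by removing equally many random instruments.
#' }
#'
#' @param h A `harmonized_set` with at least 4 instruments.
#' @param n_sim Simulation replicates (default 1000).
#' @param seed Simulation seed (results are reproducible given the seed).
#' @param outlier_sig Significance level for the Bonferroni-adjusted
#'   outlier test (default 0.05).
#' @param model IVW flavour used for the reported raw/corrected estimates.
#' @return A `presso_result` list: `global_rss_obs`, `global_pvalue`,
#'   `outliers` (tibble of `variant_id`, `outlier_pvalue` -- adjusted),
#'   `distortion_pvalue` (NA without outliers), `beta_raw`,
#'   `beta_corrected` (both `mr_result`). [tidy()] gives the per-variant
#'   table, [glance()] the global summary.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_sig = 0.05,
                      model = "multiplicative_random") {
  x <- as_tibble(h)
  x <- x[x$beta_exposure != 0, , drop = FALSE]
  j <- nrow(x)
  if (j < 4) abort_input("mr_presso needs at least 4 instruments")
  bx <- x$beta_exposure
  by <- x$beta_outcome
  se_y <- x$se_outcome
  r <- by / bx
  w <- bx^2 / se_y^2  # = 1 / ratio_se^2
  sw <- sum(w)
  swr <- sum(w * r)
  b_minus <- (swr - w * r) / (sw - w)  # leave-one-out fixed-effect IVW
  wres_obs <- (by - b_minus * bx)^2 / se_y^2
  rss_obs <- sum(wres_obs)

  sims <- withr::with_seed(seed, {
    ystar <- matrix(rnorm(j * n_sim, mean = b_minus * bx, sd = se_y), nrow = j)
    rstar <- ystar / bx
    swr_star <- colSums(w * rstar)
    # leave-one-out estimates per simulated dataset, J x n_sim
    b_minus_star <- (matrix(swr_star, j, n_sim, byrow = TRUE) - w * rstar) /
      (sw - w)
    wres_star <- (ystar - b_minus_star * bx)^2 / se_y^2
    list(rss = colSums(wres_star), wres = wres_star)
  })
  global_p <- (1 + sum(sims$rss >= rss_obs)) / (1 + n_sim)
  p_snp <- (1 + rowSums(sims$wres >= wres_obs)) / (1 + n_sim)
  p_adj <- pmin(1, j * p_snp)
  is_out <- p_adj < outlier_sig
  if (all(is_out)) {
    abort_estimation("mr_presso: every instrument flagged as an outlier")
  }
  outliers <- tibble(variant_id = x$variant_id[is_out],
                     outlier_pvalue = p_adj[is_out])
  beta_raw <- mr_ivw(h, model = model)
  distortion_p <- NA_real_
  if (any(is_out)) {
    beta_corrected <- mr_ivw(
      restore_hs(x[!is_out, , drop = FALSE], h), model = model
    )
    n_out <- sum(is_out)
    if (j - n_out >= 2) {
      d_obs <- beta_raw$beta - beta_corrected$beta
      d_sim <- withr::with_seed(derive_seed(seed, 1L), {
        vapply(seq_len(n_sim), function(i) {
          drop_idx <- sample.int(j, n_out)
          wk <- w[-drop_idx]
          rk <- r[-drop_idx]
          beta_raw$beta - sum(wk * rk) / sum(wk)
        }, numeric(1))
      })
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (1 + n_sim)
    }
  } else {
    beta_corrected <- beta_raw
  }
  structure(
    list(global_rss_obs = rss_obs, global_pvalue = global_p,
         outliers = outliers, distortion_pvalue = distortion_p,
         beta_raw = beta_raw, beta_corrected = beta_corrected,
         per_snp = tibble(variant_id = x$variant_id,
                          weighted_residual = wres_obs,
                          outlier_pvalue = p_adj,
                          outlier = is_out),
         n_sim = n_sim, seed = seed, outlier_sig = outlier_sig),
    class = "presso_result"
  )
}

#' @export
print.presso_result <- function(x, ...) {
  cat(sprintf("<presso_result> global RSS %.3f, p = %.3g; %d outlier(s); distortion p = %s\n",
              x$global_rss_obs, x$global_pvalue, nrow(x$outliers),
              format(x$distortion_pvalue, digits = 3)))
  invisible(x)
}

#' @method tidy presso_result
#' @export
tidy.presso_result <- function(x, ...) x$per_snp

#' @method glance presso_result
#' @export
glance.presso_result <- function(x, ...) {
  tibble(global_rss = x$global_rss_obs, global_p.value = x$global_pvalue,
         n_outliers = nrow(x$outliers),
         distortion_p.value = x$distortion_pvalue,
         beta_raw = x$beta_raw$beta, beta_corrected = x$beta_corrected$beta)
}
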