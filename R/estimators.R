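#' Per-variant Wald ratios
#'
#' The building block of summary-data MR: for each instrument the causal
#' effect is estimated as the SNP-outcome effect divided by the
#' SNP-exposure effect, with a first-order standard error
#' `se_outcome / |beta_exposure|`. Rows with a zero exposure beta are
#' excluded with a message.
#'
#' @param h A `harmonized_set`.
#' @param quiet Suppress the exclusion message.
#' @return A tibble with columns `variant_id`, `ratio`, `ratio_se`.
#' @export
wald_ratios <- function(h, quiet = FALSE) {
  x <- as_tibble(h)
  zero <- x$beta_exposure == 0
  if (any(zero) && !quiet) {
    inform(sprintf("wald_ratios: excluded %d variant(s) with zero exposure beta",
                   sum(zero)))
  }
  x <- x[!zero, , drop = FALSE]
  tibble(variant_id = x$variant_id,
         ratio = x$beta_outcome / x$beta_exposure,
         ratio_se = x$se_outcome / abs(x$beta_exposure))
}

new_mr_result <- function(method, beta, se, pvalue, n_snps, extras = list()) {
  z <- z_crit()
  structure(
    list(method = method, beta = beta, se = se, pvalue = pvalue,
         n_snps = as.integer(n_snps),
         or_point = exp(beta), or_low = exp(beta - z * se),
         or_high = exp(beta + z * se), extras = extras),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("<mr_result> %s: beta %.4f (se %.4f), p %.3g, OR %.3f [%.3f, %.3f], %d SNP(s)\n",
              x$method, x$beta, x$se, x$pvalue, x$or_point, x$or_low,
              x$or_high, x$n_snps))
  invisible(x)
}

#' Tidy an MR estimate
#'
#' @param x An `mr_result`.
#' @param ... Unused.
#' @return One-row tibble with the estimate on the log scale
#'   (`estimate`, `std.error`, `statistic`, `p.value`, Wald `conf.low` /
#'   `conf.high`) and the odds-ratio view (`or`, `or.conf.low`,
#'   `or.conf.high`), plus `n_snps`.
#' @method tidy mr_result
#' @export
tidy.mr_result <- function(x, ...) {
  z <- z_crit()
  tibble(method = x$method, estimate = x$beta, std.error = x$se,
         statistic = x$beta / x$se, p.value = x$pvalue,
         conf.low = x$beta - z * x$se, conf.high = x$beta + z * x$se,
         or = x$or_point, or.conf.low = x$or_low, or.conf.high = x$or_high,
         n_snps = x$n_snps)
}

#' @method glance mr_result
#' @export
glance.mr_result <- function(x, ...) {
  tibble(method = x$method, n_snps = x$n_snps,
         heterogeneity_q = x$extras$q %||% NA_real_)
}

#' Inverse-variance-weighted estimator
#'
#' Weighted mean of the Wald ratios with weights `1 / ratio_se^2`. The
#' fixed-effect standard error is `(sum w)^(-1/2)`; the default
#' multiplicative random-effects model scales it by
#' `sqrt(max(Q / (J - 1), 1))` with `Q` Cochran's Q at the estimate (no
#' scaling with a single instrument). Two-sided p-values from the normal
#' distribution.
#'
#' @param h A `harmonized_set` with at least one usable instrument.
#' @param model `"multiplicative_random"` (default) or `"fixed"`.
#' @return An `mr_result`; `extras` carries `q` and the model tag.
#' @export
mr_ivw <- function(h, model = c("multiplicative_random", "fixed")) {
  model <- match.arg(model)
  wr <- wald_ratios(h, quiet = TRUE)
  j <- nrow(wr)
  if (j == 0) abort_input("mr_ivw: no usable instruments")
  w <- 1 / wr$ratio_se^2
  beta <- sum(w * wr$ratio) / sum(w)
  se <- sqrt(1 / sum(w))
  q <- sum(w * (wr$ratio - beta)^2)
  if (model == "multiplicative_random" && j > 1) {
    se <- se * sqrt(max(q / (j - 1), 1))
  }
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_result(if (model == "fixed") "ivw_fixed" else "ivw_mre",
                beta, se, p, j, extras = list(q = q, model = model))
}

#' MR-Egger regression
#'
#' Weighted linear regression of the outcome betas on the exposure betas
#' with a free intercept (weights `1 / se_outcome^2`), after orienting all
#' instruments to a non-negative exposure beta. The slope is the causal
#' estimate; a non-zero intercept indicates directional pleiotropy.
#' Standard errors use the regression residual variance inflated to at
#' least 1 (multiplicative model); p-values from the t distribution with
#' `J - 2` degrees of freedom.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return An `mr_result`; `extras` carries `egger_intercept`,
#'   `egger_intercept_se`, `egger_intercept_pvalue` and the residual scale.
#' @export
mr_egger <- function(h) {
  x <- as_tibble(h)
  j <- nrow(x)
  if (j < 3) abort_input("mr_egger needs at least 3 instruments")
  flip <- sign(x$beta_exposure)
  flip[flip == 0] <- 1
  bx <- abs(x$beta_exposure)
  by <- x$beta_outcome * flip
  fit <- lm(by ~ bx, weights = 1 / x$se_outcome^2)
  sm <- summary(fit)
  est <- sm$coefficients[, "Estimate"]
  se_raw <- sm$coefficients[, "Std. Error"]
  se_adj <- se_raw / min(sm$sigma, 1)  # inflate residual SD to >= 1
  p <- 2 * pt(-abs(est / se_adj), df = j - 2)
  new_mr_result("egger", est[["bx"]], se_adj[["bx"]], p[["bx"]], j,
                extras = list(
                  egger_intercept = est[["(Intercept)"]],
                  egger_intercept_se = se_adj[["(Intercept)"]],
                  egger_intercept_pvalue = p[["(Intercept)"]],
                  residual_scale = sm$sigma
                ))
}

# Interpolated weighted median of values b with weights w.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (s[1] >= 0.5) return(b[1])
  below <- max(which(s < 0.5))
  if (below == length(b)) return(b[length(b)])
  b[below] + (b[below + 1] - b[below]) * (0.5 - s[below]) / (s[below + 1] - s[below])
}

#' Weighted-median estimator
#'
#' Consistent when instruments carrying at least half of the weight are
#' valid. The point estimate interpolates the inverse-variance-weighted
#' median of the Wald ratios; the standard error comes from a parametric
#' bootstrap (exposure and outcome betas resampled from normal
#' distributions with their reported SEs).
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed Seed for the bootstrap (deterministic given the seed).
#' @return An `mr_result`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L) {
  x <- as_tibble(h)
  j <- nrow(x)
  if (j < 3) abort_input("mr_weighted_median needs at least 3 instruments")
  wr <- wald_ratios(h, quiet = TRUE)
  beta <- weighted_median_point(wr$ratio, 1 / wr$ratio_se^2)
  boots <- withr::with_seed(seed, {
    bx <- matrix(rnorm(j * n_boot, x$beta_exposure, x$se_exposure), nrow = j)
    by <- matrix(rnorm(j * n_boot, x$beta_outcome, x$se_outcome), nrow = j)
    vapply(seq_len(n_boot), function(i) {
      ok <- bx[, i] != 0
      r <- by[ok, i] / bx[ok, i]
      se_r <- x$se_outcome[ok] / abs(bx[ok, i])
      weighted_median_point(r, 1 / se_r^2)
    }, numeric(1))
  })
  se <- sd(boots)
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_result("weighted_median", beta, se, p, j,
                extras = list(n_boot = n_boot, seed = seed))
}

#' Robust adjusted profile score (RAPS) estimator
#'
#' Profile-likelihood estimator accounting for uncertainty in the
#' SNP-exposure effects: maximizes
#' `-0.5 * sum rho(t_j(beta))` with
#' `t_j = (beta_outcome_j - beta * beta_exposure_j) /
#' sqrt(se_outcome_j^2 + beta^2 * se_exposure_j^2)` over a bracketing
#' interval \[-10, 10\]. `rho` is the square (default) or Huber loss
#' (tuning constant 1.345). This is the simple profile-score variant
#' without an overdispersion parameter. The SE comes from the numerically
#' differentiated observed information.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param loss `"l2"` or `"huber"`.
#' @return An `mr_result`.
#' @export
mr_raps <- function(h, loss = c("l2", "huber")) {
  loss <- match.arg(loss)
  x <- as_tibble(h)
  j <- nrow(x)
  if (j < 3) abort_input("mr_raps needs at least 3 instruments")
  huber_c <- 1.345
  rho <- if (loss == "l2") {
    function(t) t^2
  } else {
    function(t) ifelse(abs(t) <= huber_c, t^2, 2 * huber_c * abs(t) - huber_c^2)
  }
  negll <- function(b) {
    t <- (x$beta_outcome - b * x$beta_exposure) /
      sqrt(x$se_outcome^2 + b^2 * x$se_exposure^2)
    0.5 * sum(rho(t))
  }
  bracket <- c(-10, 10)
  opt <- optimize(negll, bracket, tol = 1e-9)
  beta <- opt$minimum
  if (min(abs(beta - bracket)) < 1e-3) {
    abort_estimation("mr_raps: optimizer at the bracket boundary; the causal effect may lie outside [-10, 10] -- widen the bracket or rescale")
  }
  step <- 1e-5 * (1 + abs(beta))
  info <- (negll(beta + step) - 2 * negll(beta) + negll(beta - step)) / step^2
  se <- if (is.finite(info) && info > 0) 1 / sqrt(info) else NA_real_
  p <- 2 * pnorm(-abs(beta / se))
  new_mr_result("raps", beta, se, p, j, extras = list(loss = loss))
}

#' Run the full estimator suite
#'
#' Applies the requested estimators to one harmonized set and binds their
#' tidy one-row summaries.
#'
#' @param h A `harmonized_set`.
#' @param methods Estimators to run.
#' @param ivw_model Passed to [mr_ivw()].
#' @param n_boot,seed Passed to [mr_weighted_median()].
#' @param raps_loss Passed to [mr_raps()].
#' @return A tibble with one row per estimator (see [tidy.mr_result()]),
#'   prefixed by the exposure and outcome labels.
#' @export
mr_estimate <- function(h, methods = c("ivw", "egger", "weighted_median", "raps"),
                        ivw_model = "multiplicative_random",
                        n_boot = 1000, seed = 1L, raps_loss = "l2") {
  methods <- match.arg(methods, several.ok = TRUE)
  fits <- purrr::map(methods, function(m) {
    switch(m,
           ivw = mr_ivw(h, model = ivw_model),
           egger = mr_egger(h),
           weighted_median = mr_weighted_median(h, n_boot = n_boot, seed = seed),
           raps = mr_raps(h, loss = raps_loss))
  })
  out <- purrr::map_dfr(fits, tidy)
  dplyr::bind_cols(
    tibble(exposure = attr(h, "exposure_label") %||% "exposure",
           outcome = attr(h, "outcome_label") %||% "outcome",
           .rows = nrow(out)),
    out
  )
}
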