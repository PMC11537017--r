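#' Filter variants by association p-value
#'
#' Retains variants with `pvalue < threshold` (strict), preserving input
#' order. The conventional instrument-screening threshold for microbiome
#' and metabolite exposures is 1e-5.
#'
#' @param stats A `summary_stats` tibble.
#' @param threshold P-value threshold in (0, 1\].
#' @param quiet Suppress the empty-result message.
#' @return The filtered `summary_stats` tibble.
#' @export
select_by_pvalue <- function(stats, threshold = 1e-5, quiet = FALSE) {
  assert_number(threshold, "threshold", 0, 1, open_lower = TRUE)
  out <- as_tibble(stats)[stats$pvalue < threshold, , drop = FALSE]
  if (nrow(out) == 0 && !quiet) {
    inform(sprintf("select_by_pvalue: no variants pass p < %g for '%s'",
                   threshold, trait_label(stats) %||% "trait"))
  }
  restore_ss(out, stats)
}

#' Greedy LD clumping
#'
#' Standard index-variant clumping: variants are ranked by ascending
#' p-value (ties broken by `variant_id`); the best remaining variant is
#' taken as index and every remaining variant on the same chromosome within
#' `window_kb` kilobases whose r-squared with the index exceeds
#' `r2_threshold` is removed. Variant pairs absent from `ld` are treated as
#' independent.
#'
#' @param stats A `summary_stats` tibble.
#' @param ld An [ld_matrix()] (or `NULL`: all pairs independent).
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_threshold r-squared above which a neighbour is removed
#'   (default 0.001).
#' @param quiet Suppress messages about variants missing from `ld`.
#' @return The clumped `summary_stats` tibble, input order preserved.
#' @export
ld_clump <- function(stats, ld = NULL, window_kb = 10000, r2_threshold = 0.001,
                     quiet = FALSE) {
  assert_number(window_kb, "window_kb", 0, Inf)
  assert_number(r2_threshold, "r2_threshold", 0, 1)
  if (!is.null(ld) && !inherits(ld, "ld_matrix")) {
    ld <- ld_matrix(ld)  # validates symmetry / diagonal / range
  }
  x <- as_tibble(stats)
  if (nrow(x) <= 1) return(stats)
  if (!is.null(ld) && !quiet) {
    absent <- sum(!(x$variant_id %in% rownames(ld)))
    if (absent > 0) {
      inform(sprintf("ld_clump: %d variant(s) absent from LD matrix, treated as independent",
                     absent))
    }
  }
  ord <- order(x$pvalue, x$variant_id)
  remaining <- ord
  kept <- integer(0)
  while (length(remaining) > 0) {
    idx <- remaining[1]
    kept <- c(kept, idx)
    remaining <- remaining[-1]
    if (length(remaining) == 0) break
    same_chr <- x$chromosome[remaining] == x$chromosome[idx]
    within <- same_chr &
      abs(x$position[remaining] - x$position[idx]) <= window_kb * 1000
    r2 <- ld_r2_lookup(ld, x$variant_id[idx], x$variant_id[remaining])
    remove <- within & r2 > r2_threshold
    remaining <- remaining[!remove]
  }
  restore_ss(x[sort(kept), , drop = FALSE], stats)
}

#' Per-variant proportion of exposure variance explained
#'
#' Two standard formulas for the variance in the exposure explained by a
#' single variant:
#' \itemize{
#'   \item `eaf_beta`: `2 * beta^2 * eaf * (1 - eaf)` (betas in SD units);
#'   \item `t_stat`: `t^2 / (t^2 + n - 2)` with `t = beta / se`.
#' }
#' Under `eaf_beta`, variants with missing eaf fall back to `t_stat` with a
#' note. Results are clamped to \[0, 1).
#'
#' @param stats A `summary_stats` tibble (or any data frame with `beta`,
#'   `se`, `n` and, for `eaf_beta`, `eaf`).
#' @param method `"eaf_beta"` or `"t_stat"`.
#' @param quiet Suppress the fallback note.
#' @return Numeric vector of per-variant R-squared values, aligned to rows.
#' @export
variance_explained <- function(stats, method = c("eaf_beta", "t_stat"),
                               quiet = FALSE) {
  method <- match.arg(method)
  beta <- stats$beta
  r2_t <- function(beta, se, n) {
    t2 <- (beta / se)^2
    t2 / (t2 + n - 2)
  }
  if (method == "t_stat") {
    if (any(stats$n <= 2)) abort_input("t_stat method requires n > 2")
    out <- r2_t(beta, stats$se, stats$n)
  } else {
    out <- 2 * beta^2 * stats$eaf * (1 - stats$eaf)
    miss <- is.na(stats$eaf)
    if (any(miss)) {
      if (!quiet) {
        inform(sprintf("variance_explained: %d variant(s) missing eaf; using t_stat fallback",
                       sum(miss)))
      }
      out[miss] <- r2_t(beta[miss], stats$se[miss], stats$n[miss])
    }
  }
  pmin(pmax(out, 0), 1 - 1e-12)
}

#' Instrument-strength F-statistic
#'
#' `F = R2 * (N - K - 1) / ((1 - R2) * K)` where `R2` is the proportion of
#' exposure variance explained by the `K` instruments jointly and `N` is
#' the exposure sample size. Instruments with `F < 10` are conventionally
#' considered weak.
#'
#' @param r2_total Total variance explained, in \[0, 1).
#' @param n Exposure sample size.
#' @param k Number of instruments.
#' @return The F-statistic.
#' @export
f_statistic <- function(r2_total, n, k) {
  assert_number(r2_total, "r2_total", 0, 1, open_upper = TRUE)
  if (!(k >= 1)) abort_input("`k` must be at least 1")
  if (!(n > k + 1)) abort_input("`n` must exceed k + 1")
  r2_total * (n - k - 1) / ((1 - r2_total) * k)
}

#' Exclude weak instruments by per-variant F-statistic
#'
#' Computes each variant's single-instrument F (`K = 1`, so
#' `F_j = R2_j * (n - 2) / (1 - R2_j)`) and excludes variants with
#' `F_j < min_f`. The overall F over the retained set (variance explained
#' summed across instruments) is stored in the `f_stat` attribute.
#'
#' @param stats A `summary_stats` tibble.
#' @param n Exposure sample size; `NULL` uses each variant's own `n`.
#' @param min_f Exclusion threshold (default 10).
#' @param method R-squared formula, see [variance_explained()].
#' @param quiet Suppress messages.
#' @return An `instrument_set`: the retained `summary_stats` rows with
#'   added columns `r2` and `f_per_snp`, plus attributes `f_stat` (overall
#'   F), `k`, `n_total` and `audit` (excluded variants with reasons).
#'   [glance()] summarises the set.
#' @export
filter_weak_instruments <- function(stats, n = NULL, min_f = 10,
                                    method = c("eaf_beta", "t_stat"),
                                    quiet = FALSE) {
  method <- match.arg(method)
  assert_number(min_f, "min_f", 0, Inf)
  if (nrow(stats) == 0) abort_input("filter_weak_instruments: empty input")
  x <- as_tibble(stats)
  n_vec <- if (is.null(n)) x$n else rep(as.integer(n), nrow(x))
  r2 <- variance_explained(
    tibble(beta = x$beta, se = x$se, n = n_vec, eaf = x$eaf),
    method = method, quiet = quiet
  )
  f_j <- r2 * (n_vec - 2) / (1 - r2)
  weak <- f_j < min_f
  audit <- tibble(variant_id = x$variant_id[weak],
                  exclusion_reason = rep("weak_instrument", sum(weak)))
  kept <- x[!weak, , drop = FALSE]
  kept$r2 <- r2[!weak]
  kept$f_per_snp <- f_j[!weak]
  k <- nrow(kept)
  if (k == 0) {
    if (!quiet) warn("filter_weak_instruments: all instruments weak; empty set")
    f_all <- NA_real_
    n_tot <- NA_integer_
  } else {
    n_tot <- as.integer(round(mean(n_vec[!weak])))
    r2_tot <- min(sum(kept$r2), 1 - 1e-12)
    f_all <- if (n_tot > k + 1) f_statistic(r2_tot, n_tot, k) else NA_real_
  }
  out <- restore_ss(kept, stats)
  structure(out,
            f_stat = f_all, k = k, n_total = n_tot, audit = audit,
            class = c("instrument_set", class(out)))
}

#' @method glance instrument_set
#' @export
glance.instrument_set <- function(x, ...) {
  tibble(k = attr(x, "k"), n = attr(x, "n_total"),
         r2_total = sum(x$r2), f_stat = attr(x, "f_stat"),
         n_excluded = nrow(attr(x, "audit")))
}

#' Steiger directionality filtering
#'
#' Retains instruments that explain strictly more variance in the exposure
#' than in the outcome, guarding against instruments that act through
#' reverse causation. Each retained row also carries the Steiger
#' z-statistic for the difference of the Fisher-transformed correlation
#' magnitudes, using a harmonic-mean sample size:
#' `z = (atanh(|r_x|) - atanh(|r_y|)) / sqrt(2 / (n_h - 3))`.
#'
#' @param h A `harmonized_set`.
#' @param method R-squared formula, see [variance_explained()]; the
#'   `t_stat` default needs only betas, SEs and sample sizes.
#' @param quiet Suppress messages.
#' @return The filtered `harmonized_set` with added columns `r2_exposure`,
#'   `r2_outcome`, `steiger_z`; dropped rows recorded with reason
#'   `"steiger_fail"`.
#' @export
steiger_filter <- function(h, method = c("t_stat", "eaf_beta"), quiet = FALSE) {
  method <- match.arg(method)
  if (nrow(h) == 0) abort_input("steiger_filter: empty harmonized set")
  x <- as_tibble(h)
  r2_exp <- variance_explained(
    tibble(beta = x$beta_exposure, se = x$se_exposure, n = x$n_exposure,
           eaf = x$eaf),
    method = method, quiet = quiet
  )
  r2_out <- variance_explained(
    tibble(beta = x$beta_outcome, se = x$se_outcome, n = x$n_outcome,
           eaf = x$eaf),
    method = method, quiet = quiet
  )
  n_h <- 2 / (1 / x$n_exposure + 1 / x$n_outcome)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) / sqrt(2 / (n_h - 3))
  keep <- r2_exp > r2_out
  kept <- x[keep, , drop = FALSE]
  kept$r2_exposure <- r2_exp[keep]
  kept$r2_outcome <- r2_out[keep]
  kept$steiger_z <- z[keep]
  dropped <- dplyr::bind_rows(
    dropped_rows(h),
    tibble(variant_id = x$variant_id[!keep],
           reason = rep("steiger_fail", sum(!keep)))
  )
  restore_hs(kept, h, dropped = dropped)
}

#' Substitute proxy variants for instruments missing from the outcome data
#'
#' When an instrument is absent from the outcome dataset, a user-supplied
#' proxy in high LD can stand in for it. The proxy table maps missing
#' variant ids to proxy ids; instruments found in `outcome` are left
#' untouched, and a missing instrument whose proxy is present in `outcome`
#' is relabelled to the proxy id (the exposure association is assumed to
#' transfer through LD). Missing instruments without a usable proxy are
#' kept under their own id (and will drop out at harmonization).
#'
#' @param stats Exposure `summary_stats` (typically post-selection).
#' @param outcome Outcome `summary_stats`.
#' @param proxies Data frame with columns `variant_id`, `proxy_id`.
#' @return `stats` with proxy ids substituted where applicable.
#' @export
substitute_proxies <- function(stats, outcome, proxies) {
  if (!all(c("variant_id", "proxy_id") %in% names(proxies))) {
    abort_config("proxy table needs columns `variant_id` and `proxy_id`")
  }
  x <- as_tibble(stats)
  missing_out <- !(x$variant_id %in% outcome$variant_id)
  map <- setNames(as.character(proxies$proxy_id),
                  as.character(proxies$variant_id))
  candidate <- map[x$variant_id]
  usable <- missing_out & !is.na(candidate) &
    candidate %in% outcome$variant_id & !(candidate %in% x$variant_id)
  x$variant_id[usable] <- unname(candidate[usable])
  restore_ss(x, stats)
}
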