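# Fixtures and independent brute-force oracles used across the suite.
# The oracles deliberately share no code with the package internals.

# Random harmonized set with a known causal slope and optional pleiotropy.
make_hs <- function(j, beta = 0.3, seed = 1, se_exp = 0.01, se_out = 0.05,
                    pleio = 0) {
  withr::with_seed(seed, {
    bx <- runif(j, 0.05, 0.3)
    by <- beta * bx + rnorm(j, pleio, se_out)
    harmonized_set(
      variant_id = sprintf("v%03d", seq_len(j)),
      beta_exposure = bx, se_exposure = se_exp,
      beta_outcome = by, se_outcome = se_out,
      n_exposure = 50000L, n_outcome = 50000L
    )
  })
}

# Small valid summary-stats table (quantitative trait).
make_ss <- function(n = 5, seed = 1, label = "trait") {
  withr::with_seed(seed, {
    pairs <- t(replicate(n, sample(c("A", "C", "G", "T"), 2)))
    summary_stats(
      data.frame(
        variant_id = sprintf("rs%04d", seq_len(n)),
        chromosome = "1", position = seq_len(n) * 1000L,
        effect_allele = pairs[, 1], other_allele = pairs[, 2],
        eaf = runif(n, 0.1, 0.4), beta = rnorm(n, 0, 0.1),
        se = runif(n, 0.01, 0.05), pvalue = runif(n, 1e-8, 0.9),
        n = 10000L
      ),
      trait_label = label, quiet = TRUE
    )
  })
}

# Exhaustive greedy clumper: plain loops over a data frame.
oracle_clump <- function(df, r2_mat, window_kb, r2_threshold) {
  df <- df[order(df$pvalue, df$variant_id), , drop = FALSE]
  chosen <- character(0)
  while (nrow(df) > 0) {
    index <- df[1, ]
    chosen <- c(chosen, index$variant_id)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    drop <- logical(nrow(df))
    for (i in seq_len(nrow(df))) {
      if (df$chromosome[i] != index$chromosome) next
      if (abs(df$position[i] - index$position) > window_kb * 1000) next
      r2 <- 0
      if (index$variant_id %in% rownames(r2_mat) &&
          df$variant_id[i] %in% rownames(r2_mat)) {
        r2 <- r2_mat[index$variant_id, df$variant_id[i]]
      }
      if (r2 > r2_threshold) drop[i] <- TRUE
    }
    df <- df[!drop, , drop = FALSE]
  }
  sort(chosen)
}

# Cumulative-weight search for the weighted median, written longhand.
oracle_weighted_median <- function(b, w) {
  ord <- order(b)
  b <- b[ord]
  w <- w[ord] / sum(w)
  acc <- 0
  s <- numeric(length(b))
  for (i in seq_along(b)) {
    s[i] <- acc + w[i] / 2
    acc <- acc + w[i]
  }
  if (s[1] >= 0.5) return(b[1])
  i <- 1
  while (i < length(b) && s[i + 1] < 0.5) i <- i + 1
  if (i + 1 > length(b)) return(b[length(b)])
  b[i] + (b[i + 1] - b[i]) * (0.5 - s[i]) / (s[i + 1] - s[i])
}

# Grid search for the RAPS profile-score minimum.
oracle_raps_grid <- function(h, lo = -2, hi = 2, step = 1e-4) {
  grid <- seq(lo, hi, by = step)
  obj <- vapply(grid, function(b) {
    t <- (h$beta_outcome - b * h$beta_exposure) /
      sqrt(h$se_outcome^2 + b^2 * h$se_exposure^2)
    sum(t^2)
  }, numeric(1))
  grid[which.min(obj)]
}
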