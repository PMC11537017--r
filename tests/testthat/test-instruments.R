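test_that("p-value screening is a strict filter preserving order", {
  ss <- make_ss(6, seed = 2)
  ss$pvalue <- c(1e-6, 1e-4, 1e-8, 0.2, 1e-5, 0.9)
  out <- select_by_pvalue(ss, 1e-5)
  expect_equal(out$variant_id, ss$variant_id[c(1, 3)])  # 1e-5 itself excluded
  expect_equal(nrow(select_by_pvalue(ss, 1)), 6)

  # brute-force scan on 1,000 uniform p-values
  big <- make_ss(1000, seed = 3)
  big$pvalue <- withr::with_seed(4, runif(1000))
  expect_equal(nrow(select_by_pvalue(big, 0.05)),
               sum(vapply(big$pvalue, function(p) p < 0.05, logical(1))))
})

test_that("greedy clumping keeps index variants and respects the window", {
  mk <- function(pos, p, chr = "1") {
    summary_stats(
      data.frame(variant_id = sprintf("rs%d", seq_along(pos)),
                 chromosome = chr, position = pos,
                 effect_allele = "A", other_allele = "G", eaf = 0.3,
                 beta = 0.1, se = 0.02, pvalue = p, n = 10000L),
      trait_label = "t", quiet = TRUE)
  }
  # one tight block: only the smallest p survives
  ss <- mk(c(1000L, 1500L, 2000L), c(1e-8, 1e-7, 1e-6))
  r2 <- matrix(0.9, 3, 3); diag(r2) <- 1
  ld <- ld_matrix(r2, ss$variant_id)
  expect_equal(ld_clump(ss, ld)$variant_id, "rs1")

  # high LD but outside the window: both kept
  ss2 <- mk(c(1L, 20000L * 1000L + 1L), c(1e-8, 1e-7))
  r2b <- matrix(0.9, 2, 2); diag(r2b) <- 1
  expect_equal(nrow(ld_clump(ss2, ld_matrix(r2b, ss2$variant_id))), 2)

  # malformed LD matrices are rejected
  bad <- matrix(c(1, 0.5, 0.4, 1), 2, 2, dimnames = rep(list(ss2$variant_id), 2))
  expect_error(ld_clump(ss2, bad), class = "mrmediate_input_error")
})

test_that("clumping matches an exhaustive brute-force clumper on LD blocks", {
  sim <- simulate_triplet(sim_config(n_snps = 50, n_mediator_snps = 0,
                                     ld_blocks = 5, ld_r2 = 0.6, seed = 9))
  ss <- sim$exposure
  got <- ld_clump(ss, sim$ld, window_kb = 10000, r2_threshold = 0.001)
  want <- oracle_clump(as.data.frame(ss), unclass(sim$ld), 10000, 0.001)
  expect_equal(sort(got$variant_id), want)
  # selected set is independent at the threshold (pairwise check)
  ids <- got$variant_id
  for (a in seq_along(ids)) {
    for (b in seq_len(a - 1L)) {
      same_chr <- got$chromosome[a] == got$chromosome[b]
      near <- abs(got$position[a] - got$position[b]) <= 1e7
      if (same_chr && near) {
        expect_lte(sim$ld[ids[a], ids[b]], 0.001)
      }
    }
  }
})

test_that("variance explained follows both standard formulas", {
  df <- tibble::tibble(beta = c(0, 0.1, 0.1), se = c(0.02, 0.02, 0.02),
                       eaf = c(0.3, 0.5, NA), n = 10000L)
  r2 <- variance_explained(df, method = "eaf_beta", quiet = TRUE)
  expect_equal(r2[1], 0)
  expect_equal(r2[2], 2 * 0.01 * 0.25)  # 0.005
  # missing eaf falls back to the t-statistic formula
  expect_equal(r2[3], 25 / (25 + 9998))
  expect_equal(variance_explained(df, method = "t_stat")[2], 25 / (25 + 9998))
})

test_that("the F-statistic formula and its monotonicity hold", {
  expect_equal(f_statistic(0, 1000, 5), 0)
  expect_equal(f_statistic(0.01, 1000, 1), 0.01 * 998 / 0.99)
  expect_equal(f_statistic(0.02, 5000, 10), 0.02 * 4989 / (0.98 * 10))
  expect_error(f_statistic(0.1, 5, 10), class = "mrmediate_input_error")
  r2s <- seq(0.001, 0.3, length.out = 30)
  expect_true(all(diff(vapply(r2s, f_statistic, numeric(1),
                              n = 5000, k = 10)) > 0))
  ns <- seq(100, 10000, by = 500)
  expect_true(all(diff(vapply(ns, function(n) f_statistic(0.01, n, 5),
                              numeric(1))) > 0))
})

test_that("weak instruments are excluded by per-variant F", {
  mk <- function(t_values, n = 10000L) {
    summary_stats(
      data.frame(variant_id = sprintf("rs%d", seq_along(t_values)),
                 chromosome = "1", position = seq_along(t_values) * 1e6L,
                 effect_allele = "A", other_allele = "G",
                 beta = t_values * 0.01, se = 0.01,
                 pvalue = 2 * pnorm(-abs(t_values)), n = n),
      trait_label = "t", quiet = TRUE)
  }
  # under the t-stat formula the single-instrument F equals t^2
  ss <- mk(c(sqrt(9.9), sqrt(10.0001), 5))
  iv <- filter_weak_instruments(ss, min_f = 10, method = "t_stat",
                                quiet = TRUE)
  expect_equal(iv$variant_id, c("rs2", "rs3"))
  audit <- attr(iv, "audit")
  expect_equal(audit$variant_id, "rs1")
  expect_equal(audit$exclusion_reason, "weak_instrument")
  expect_equal(nrow(filter_weak_instruments(ss, min_f = 0, quiet = TRUE)), 3)

  # independent per-variant arithmetic on 20 random instruments
  ss2 <- make_ss(20, seed = 8)
  iv2 <- filter_weak_instruments(ss2, min_f = 10, method = "eaf_beta",
                                 quiet = TRUE)
  r2_j <- 2 * ss2$beta^2 * ss2$eaf * (1 - ss2$eaf)
  keep <- r2_j * (ss2$n - 2) / (1 - r2_j) >= 10
  expect_setequal(iv2$variant_id, ss2$variant_id[keep])
  expect_equal(glance(iv2)$k, sum(keep))
})

test_that("Steiger filtering keeps exposure-first instruments and is idempotent", {
  h <- harmonized_set(
    variant_id = c("a", "b", "c"),
    beta_exposure = c(0.10, 0.02, 0.05), se_exposure = 0.01,
    beta_outcome = c(0.01, 0.02, 0.05), se_outcome = 0.01,
    n_exposure = 10000L, n_outcome = 10000L
  )
  out <- steiger_filter(h)
  expect_equal(out$variant_id, "a")           # strict inequality drops ties
  expect_true(all(out$steiger_z > 0))
  expect_equal(dropped_rows(out)$reason, rep("steiger_fail", 2))
  out2 <- steiger_filter(out)
  expect_equal(as.data.frame(out2), as.data.frame(out))

  # true exposure -> outcome causation at large n: nearly all retained
  kept <- vapply(1:200, function(r) {
    sim <- simulate_triplet(sim_config(
      n_snps = 10, n_mediator_snps = 0, n_exposure = 100000,
      n_outcome = 100000, beta_total = 0.3, seed = 5000 + r))
    h <- harmonize(sim$exposure, sim$outcome)
    if (nrow(h) == 0) return(c(0, 0))
    c(nrow(steiger_filter(h, quiet = TRUE)), nrow(h))
  }, numeric(2))
  expect_gte(sum(kept[1, ]) / sum(kept[2, ]), 0.95)
})

test_that("proxy substitution relabels instruments missing from the outcome", {
  exp <- make_ss(4, seed = 11, label = "e")
  out <- make_ss(6, seed = 12, label = "o")
  out$variant_id <- c(exp$variant_id[1:2], "px1", "px2", "zz1", "zz2")
  proxies <- data.frame(variant_id = exp$variant_id[3:4],
                        proxy_id = c("px1", "missing_proxy"))
  swapped <- substitute_proxies(exp, out, proxies)
  expect_equal(swapped$variant_id[3], "px1")          # usable proxy applied
  expect_equal(swapped$variant_id[4], exp$variant_id[4])  # no usable proxy
  expect_equal(swapped$variant_id[1:2], exp$variant_id[1:2])
})
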