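test_that("Wald ratios follow the delta formula and exclude zero-gamma rows", {
  h <- harmonized_set(
    variant_id = c("a", "b", "c"),
    beta_exposure = c(0.1, 0.2, 0), se_exposure = 0.01,
    beta_outcome = c(0.02, 0, 0.05), se_outcome = c(0.01, 0.02, 0.01)
  )
  wr <- NULL
  expect_message(wr <- wald_ratios(h), "zero exposure beta")
  expect_equal(wr$variant_id, c("a", "b"))
  expect_equal(wr$ratio, c(0.2, 0))
  expect_equal(wr$ratio_se, c(0.1, 0.1))
})

test_that("IVW reduces to the closed-form weighted mean of Wald ratios", {
  # single instrument: identical to its Wald ratio
  h1 <- harmonized_set("a", 0.1, 0.01, 0.02, 0.01)
  fit1 <- mr_ivw(h1, model = "fixed")
  expect_equal(fit1$beta, 0.2)
  expect_equal(fit1$se, 0.1)

  # two instruments: hand-computed weighted least squares
  h2 <- harmonized_set(c("a", "b"), c(1, 1), 0.001, c(0.1, 0.3), c(0.05, 0.1))
  fit2 <- mr_ivw(h2, model = "fixed")
  expect_equal(fit2$beta, (400 * 0.1 + 100 * 0.3) / 500)  # 0.14
  expect_equal(fit2$se, sqrt(1 / 500))

  # closed-form oracle on random instances; mre never narrower than fixed
  for (seed in 1:10) {
    h <- make_hs(12, beta = 0.25, seed = seed)
    wr <- wald_ratios(h, quiet = TRUE)
    w <- 1 / wr$ratio_se^2
    expect_equal(mr_ivw(h, model = "fixed")$beta, sum(w * wr$ratio) / sum(w))
    expect_gte(mr_ivw(h)$se, mr_ivw(h, model = "fixed")$se)
  }

  # consistency at scale: many instruments, true slope recovered
  h_big <- make_hs(10000, beta = 0.2, seed = 99)
  expect_lt(abs(mr_ivw(h_big)$beta - 0.2), 0.01)
})

test_that("Egger regression recovers exact linear and affine structures", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  mk <- function(by) harmonized_set(sprintf("v%d", 1:5), bx, 0.01, by,
                                    c(0.01, 0.02, 0.01, 0.03, 0.02))
  fit_lin <- mr_egger(mk(0.3 * bx))
  expect_equal(fit_lin$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit_lin$extras$egger_intercept, 0, tolerance = 1e-10)
  fit_aff <- mr_egger(mk(0.05 + 0.3 * bx))
  expect_equal(fit_aff$beta, 0.3, tolerance = 1e-10)
  expect_equal(fit_aff$extras$egger_intercept, 0.05, tolerance = 1e-10)
  expect_error(mr_egger(mk(0.3 * bx)[1:2, ]), "3",
               class = "mrmediate_input_error")

  # normal-equations oracle on a noisy 5-row instance
  h <- make_hs(5, beta = 0.3, seed = 21, se_out = 0.03)
  w <- 1 / h$se_outcome^2
  X <- cbind(1, h$beta_exposure)
  coefs <- solve(t(X) %*% (w * X), t(X) %*% (w * h$beta_outcome))
  fit <- mr_egger(h)
  expect_equal(fit$extras$egger_intercept, coefs[1, 1])
  expect_equal(fit$beta, coefs[2, 1])
})

test_that("estimators are equivariant under exposure sign flip", {
  h <- make_hs(15, beta = 0.25, seed = 31)
  flipped <- as.data.frame(h)
  flipped$beta_exposure <- -flipped$beta_exposure
  h_neg <- harmonized_set(flipped$variant_id, flipped$beta_exposure,
                          flipped$se_exposure, flipped$beta_outcome,
                          flipped$se_outcome)
  expect_equal(mr_ivw(h_neg)$beta, -mr_ivw(h)$beta)
  expect_equal(mr_egger(h_neg)$beta, -mr_egger(h)$beta)
  expect_equal(mr_weighted_median(h_neg, seed = 7)$beta,
               -mr_weighted_median(h, seed = 7)$beta)
  expect_equal(mr_raps(h_neg)$beta, -mr_raps(h)$beta, tolerance = 1e-6)
})

test_that("weighted median interpolates the cumulative-weight search", {
  # degenerate: all ratios equal
  h_const <- harmonized_set(letters[1:4], rep(0.1, 4), 0.01,
                            rep(0.03, 4), 0.01)
  expect_equal(mr_weighted_median(h_const, n_boot = 50)$beta, 0.3)

  # equal weights, ratios {0.1, 0.2, 0.9} -> middle value
  h3 <- harmonized_set(c("a", "b", "c"), c(1, 1, 1), 0.001,
                       c(0.1, 0.2, 0.9), 0.05)
  expect_equal(mr_weighted_median(h3, n_boot = 50)$beta, 0.2)

  # brute-force oracle and permutation invariance on random instances
  for (seed in 1:8) {
    h <- make_hs(9, beta = 0.2, seed = 40 + seed, se_out = 0.04)
    wr <- wald_ratios(h, quiet = TRUE)
    expect_equal(mr_weighted_median(h, n_boot = 50)$beta,
                 oracle_weighted_median(wr$ratio, 1 / wr$ratio_se^2))
    perm <- withr::with_seed(seed, sample(nrow(h)))
    h_perm <- harmonized_set(h$variant_id[perm], h$beta_exposure[perm],
                             h$se_exposure[perm], h$beta_outcome[perm],
                             h$se_outcome[perm])
    expect_equal(mr_weighted_median(h_perm, n_boot = 50)$beta,
                 mr_weighted_median(h, n_boot = 50)$beta)
  }
})

test_that("RAPS solves the profile score and matches IVW in the known-gamma limit", {
  # noiseless: exact slope
  bx <- seq(0.05, 0.3, length.out = 6)
  h_exact <- harmonized_set(sprintf("v%d", 1:6), bx, 1e-8, 0.3 * bx, 1e-6)
  expect_equal(mr_raps(h_exact)$beta, 0.3, tolerance = 1e-6)

  # se_exposure -> 0: profile score collapses to fixed-effect IVW
  h_lim <- make_hs(20, beta = 0.2, seed = 51, se_exp = 1e-9, se_out = 0.03)
  expect_equal(mr_raps(h_lim)$beta, mr_ivw(h_lim, model = "fixed")$beta,
               tolerance = 1e-3)

  # grid-search oracle at step 1e-4 on a 50-instrument instance
  h50 <- make_hs(50, beta = 0.25, seed = 52, se_exp = 0.02, se_out = 0.05)
  expect_lt(abs(mr_raps(h50)$beta - oracle_raps_grid(h50)), 2e-4)

  # huber loss stays close on clean data
  expect_equal(mr_raps(h50, loss = "huber")$beta, mr_raps(h50)$beta,
               tolerance = 0.02)
})

test_that("MR power equals the test size at the null and grows with the NCP", {
  expect_equal(mr_power(10000, 0.3, 0.02, 0), 0.05)
  expect_equal(mr_power(10000, 0.3, 0.02, 0, alpha = 0.01), 0.01)
  p1 <- mr_power(10000, 0.3, 0.02, 0.2)
  p2 <- mr_power(20000, 0.3, 0.02, 0.2)  # doubled NCP
  expect_gte(p2, p1)
  expect_lt(p2, 1)
  expect_error(mr_power(10000, 1.2, 0.02, 0.2),
               class = "mrmediate_input_error")

  # empirical rejection rate of the IVW z-test matches the formula
  n_out <- 20000; cf <- 0.4; r2 <- 0.015; beta <- 0.12; j <- 10; maf <- 0.3
  gamma <- rep(sqrt(r2 / (j * 2 * maf * (1 - maf))), j)
  se_y <- rep(1 / sqrt(2 * maf * (1 - maf) * n_out * cf * (1 - cf)), j)
  rej <- withr::with_seed(77, {
    vapply(seq_len(2000), function(i) {
      by <- rnorm(j, beta * gamma, se_y)
      h <- harmonized_set(sprintf("v%d", 1:j), gamma, 1e-10, by, se_y)
      mr_ivw(h, model = "fixed")$pvalue < 0.05
    }, logical(1))
  })
  expect_lt(abs(mean(rej) - mr_power(n_out, cf, r2, beta)), 0.03)
})

test_that("mr_estimate binds tidy rows for the requested methods", {
  h <- make_hs(12, beta = 0.2, seed = 61)
  tab <- mr_estimate(h, n_boot = 100)
  expect_equal(nrow(tab), 4)
  expect_true(all(c("exposure", "outcome", "method", "estimate", "or",
                    "n_snps") %in% names(tab)))
  expect_equal(tab$or, exp(tab$estimate))
})
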