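#' Statistical power for MR with a binary outcome
#'
#' Non-centrality-parameter approximation in the style of the mRnd power
#' calculator: for a true causal log odds ratio `beta`, instruments
#' explaining a fraction `r2_xz` of the exposure variance, an outcome GWAS
#' of `n_outcome` subjects with a case fraction `case_fraction`,
#' \deqn{NCP = n \cdot R^2_{xz} \cdot \beta^2 \cdot cf (1 - cf)}
#' and the power of the two-sided level-`alpha` test is
#' `pnorm(-z + sqrt(NCP)) + pnorm(-z - sqrt(NCP))` with
#' `z = qnorm(1 - alpha / 2)`. With `beta = 0` this reduces to `alpha`.
#'
#' @param n_outcome Outcome GWAS sample size.
#' @param case_fraction Proportion of cases, in (0, 1).
#' @param r2_xz Variance of the exposure explained by the instruments,
#'   in (0, 1).
#' @param beta True causal effect (log odds ratio per SD of exposure).
#' @param alpha Two-sided significance level (default 0.05).
#' @return The power, a number in (0, 1).
#' @export
mr_power <- function(n_outcome, case_fraction, r2_xz, beta, alpha = 0.05) {
  assert_number(n_outcome, "n_outcome", 1, Inf)
  assert_number(case_fraction, "case_fraction", 0, 1,
                open_lower = TRUE, open_upper = TRUE)
  assert_number(r2_xz, "r2_xz", 0, 1, open_lower = TRUE, open_upper = TRUE)
  assert_number(beta, "beta")
  assert_number(alpha, "alpha", 0, 1, open_lower = TRUE, open_upper = TRUE)
  ncp <- n_outcome * r2_xz * beta^2 * case_fraction * (1 - case_fraction)
  z <- qnorm(1 - alpha / 2)
  pnorm(-z + sqrt(ncp)) + pnorm(-z - sqrt(ncp))
}
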