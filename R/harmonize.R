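#' Harmonize exposure and outcome summary statistics to a common effect allele
#'
#' Aligns the outcome associations to the exposure's effect allele for every
#' variant present in both datasets, the prerequisite for two-sample MR:
#' \itemize{
#'   \item identical allele pairs are kept as-is;
#'   \item swapped pairs (outcome effect allele equals the exposure's other
#'     allele) have the outcome beta negated and eaf complemented;
#'   \item strand-ambiguous palindromic pairs (A/T or C/G) are kept only
#'     when both effect-allele frequencies are available, both fall outside
#'     `0.5 +/- palindrome_eaf_window`, and both lie on the same side of 0.5
#'     after alignment; otherwise they are dropped with reason
#'     `"palindromic_ambiguous"`;
#'   \item incompatible allele sets are dropped with reason
#'     `"allele_mismatch"`.
#' }
#' Kept and dropped variants always partition the variant-id intersection.
#'
#' @param exposure,outcome `summary_stats` tibbles (see [summary_stats()]).
#' @param palindrome_eaf_window Half-width of the ambiguous frequency zone
#'   around 0.5 for palindromic variants (default 0.08, i.e. drop when the
#'   eaf lies in \[0.42, 0.58\]).
#' @return A tibble of class `harmonized_set`, one row per usable
#'   instrument, with columns `variant_id`, `chromosome`, `position`,
#'   `beta_exposure`, `se_exposure`, `beta_outcome`, `se_outcome`, `eaf`
#'   (exposure scale), `n_exposure`, `n_outcome`; attributes
#'   `exposure_label`, `outcome_label`, `outcome_trait_type` and `dropped`.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  assert_number(palindrome_eaf_window, "palindrome_eaf_window", 0, 0.5)
  if (nrow(exposure) == 0 || nrow(outcome) == 0) {
    abort_input("harmonize() needs non-empty exposure and outcome tables")
  }
  exp_lab <- trait_label(exposure) %||% "exposure"
  out_lab <- trait_label(outcome) %||% "outcome"

  j <- dplyr::inner_join(
    as_tibble(exposure), as_tibble(outcome),
    by = "variant_id", suffix = c("_exp", "_out")
  )
  if (nrow(j) == 0) {
    abort_input(sprintf("no shared variants between '%s' and '%s'",
                        exp_lab, out_lab))
  }

  same <- j$effect_allele_exp == j$effect_allele_out &
    j$other_allele_exp == j$other_allele_out
  swapped <- j$effect_allele_exp == j$other_allele_out &
    j$other_allele_exp == j$effect_allele_out
  palin <- is_palindromic(j$effect_allele_exp, j$other_allele_exp)

  beta_out <- ifelse(swapped, -j$beta_out, j$beta_out)
  eaf_out_aligned <- ifelse(swapped, 1 - j$eaf_out, j$eaf_out)

  w <- palindrome_eaf_window
  eaf_ok <- !is.na(j$eaf_exp) & !is.na(eaf_out_aligned) &
    abs(j$eaf_exp - 0.5) > w & abs(eaf_out_aligned - 0.5) > w &
    sign(j$eaf_exp - 0.5) == sign(eaf_out_aligned - 0.5)

  keep <- (same | swapped) & (!palin | eaf_ok)
  reason <- dplyr::case_when(
    !(same | swapped) ~ "allele_mismatch",
    palin & !eaf_ok ~ "palindromic_ambiguous",
    TRUE ~ NA_character_
  )

  rows <- tibble(
    variant_id = j$variant_id[keep],
    chromosome = j$chromosome_exp[keep],
    position = j$position_exp[keep],
    beta_exposure = j$beta_exp[keep],
    se_exposure = j$se_exp[keep],
    beta_outcome = beta_out[keep],
    se_outcome = j$se_out[keep],
    eaf = j$eaf_exp[keep],
    n_exposure = j$n_exp[keep],
    n_outcome = j$n_out[keep]
  )
  dropped <- tibble(variant_id = j$variant_id[!keep], reason = reason[!keep])
  new_harmonized_set(rows, exp_lab, out_lab,
                     outcome_trait_type = trait_type(outcome) %||% "binary",
                     dropped = dropped)
}

new_harmonized_set <- function(rows, exposure_label, outcome_label,
                               outcome_trait_type, dropped) {
  structure(
    as_tibble(rows),
    exposure_label = exposure_label,
    outcome_label = outcome_label,
    outcome_trait_type = outcome_trait_type,
    dropped = dropped,
    class = c("harmonized_set", class(tibble()))
  )
}

restore_hs <- function(x, template, dropped = attr(template, "dropped")) {
  new_harmonized_set(as_tibble(x),
                     exposure_label = attr(template, "exposure_label"),
                     outcome_label = attr(template, "outcome_label"),
                     outcome_trait_type = attr(template, "outcome_trait_type"),
                     dropped = dropped)
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("<harmonized_set> %s -> %s, %d instrument(s), %d dropped\n",
              attr(x, "exposure_label"), attr(x, "outcome_label"),
              nrow(x), nrow(dropped_rows(x))))
  NextMethod()
}

#' Build a harmonized set directly from aligned effect estimates
#'
#' Convenience constructor for simulations and worked examples where the
#' per-variant exposure and outcome effects are already on a common effect
#' allele.
#'
#' @param variant_id,beta_exposure,se_exposure,beta_outcome,se_outcome
#'   Equal-length vectors of per-variant values.
#' @param eaf,n_exposure,n_outcome Optional per-variant frequency and
#'   sample sizes.
#' @param exposure_label,outcome_label Labels carried into reports.
#' @return A `harmonized_set` tibble.
#' @export
harmonized_set <- function(variant_id, beta_exposure, se_exposure,
                           beta_outcome, se_outcome,
                           eaf = NA_real_, n_exposure = NA_integer_,
                           n_outcome = NA_integer_,
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  if (any(se_exposure <= 0) || any(se_outcome <= 0)) {
    abort_input("standard errors must be strictly positive")
  }
  rows <- tibble(
    variant_id = as.character(variant_id),
    chromosome = NA_character_, position = NA_integer_,
    beta_exposure = as.numeric(beta_exposure),
    se_exposure = as.numeric(se_exposure),
    beta_outcome = as.numeric(beta_outcome),
    se_outcome = as.numeric(se_outcome),
    eaf = as.numeric(eaf),
    n_exposure = as.integer(n_exposure),
    n_outcome = as.integer(n_outcome)
  )
  new_harmonized_set(rows, exposure_label, outcome_label,
                     outcome_trait_type = "binary",
                     dropped = tibble(variant_id = character(),
                                      reason = character()))
}
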