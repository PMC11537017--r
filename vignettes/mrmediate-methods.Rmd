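---
title: "Methods: two-sample MR and two-step mediation in mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR and two-step mediation in mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The model

Two-sample Mendelian randomization treats genetic variants as
instrumental variables for an exposure. For variant $j$, let $\gamma_j$
be its estimated effect on the exposure (SD units) and $\Gamma_j$ its
estimated effect on the outcome (log odds for a binary disease), each
with a standard error, taken from two non-overlapping GWAS. If variant
$j$ is a valid instrument — associated with the exposure, affecting the
outcome only through it, independent of confounders — the Wald ratio
$\hat\beta_j = \Gamma_j/\gamma_j$ estimates the causal effect $\beta$,
with first-order standard error $se(\Gamma_j)/|\gamma_j|$ (uncertainty
in $\gamma_j$ is ignored at this step, the usual NO-measurement-error
approximation; the RAPS estimator below drops that approximation).

The estimator suite combines the ratios under progressively weaker
validity assumptions:

* **IVW** — the inverse-variance-weighted mean of the ratios; unbiased
  when all instruments are valid. The default *multiplicative random
  effects* flavour inflates the fixed-effect standard error by
  $\sqrt{\max(Q/(J-1), 1)}$, where $Q$ is Cochran's heterogeneity
  statistic at the estimate, so that over-dispersion widens but never
  narrows the interval. With a single instrument no scaling is applied.
* **MR-Egger** — weighted regression of $\Gamma_j$ on $\gamma_j$ with a
  free intercept, after orienting every variant to $\gamma_j \ge 0$.
  Under the InSIDE assumption the slope is consistent even with
  directional pleiotropy, which the intercept estimates; p-values use
  the $t$ distribution with $J-2$ df and the residual variance is
  inflated to at least 1, mirroring the multiplicative model.
* **Weighted median** — consistent while instruments carrying at least
  half the weight are valid; the point estimate interpolates the
  weighted median of the ratios and its SE comes from a parametric
  bootstrap (default 1000 replicates, seeded).
* **RAPS** — maximizes the profile likelihood
  $-\tfrac12\sum_j \rho\!\left(t_j(\beta)\right)$ with
  $t_j = (\Gamma_j - \beta\gamma_j)/\sqrt{se(\Gamma_j)^2 +
  \beta^2 se(\gamma_j)^2}$, accounting for exposure-side noise. We
  implement the simple profile-score variant (squared or Huber-1.345
  loss, 1-D optimization over $[-10, 10]$, SE from the numerically
  differentiated observed information) without the overdispersion
  parameter of the fuller published method — a deliberate
  simplification; with strong instruments the two agree closely.

## Instrument selection

Instruments are screened at $p < 10^{-5}$ (the conventional threshold
for microbiome and metabolite exposures, where genome-wide hits are
scarce), clumped greedily within 10,000 kb at $r^2 > 0.001$ (ties on
p-value broken lexicographically by variant id, for determinism), and
filtered on the instrument-strength statistic
$F = R^2(N-K-1)/((1-R^2)K)$ with the conventional $F \ge 10$ rule
applied per variant ($K=1$). Per-variant $R^2$ can be computed from
allele frequency and effect size ($2\beta^2 p(1-p)$) or from the
t-statistic ($t^2/(t^2+n-2)$); the first is the default and falls back
to the second when frequencies are missing. Steiger filtering retains
instruments with $R^2_{exposure} > R^2_{outcome}$ (strict), and reports
a z-statistic for the difference of Fisher-transformed correlation
magnitudes normalized by the harmonic-mean sample size — a pragmatic
normal approximation chosen because the exact dependent-correlation
test is not identified from summary data.

Harmonization aligns outcome records to the exposure's effect allele.
Palindromic (A/T, C/G) variants are kept only when both allele
frequencies are available, both lie outside $0.5 \pm 0.08$, and both
fall on the same side of 0.5; otherwise orientation is ambiguous and
the variant is dropped. The 0.08 window is the community default; it is
exposed as a parameter.

## Sensitivity diagnostics

Cochran's $Q$ (evaluated at the fixed-effect IVW estimate, its
minimizer) tests homogeneity against $\chi^2_{J-1}$. Funnel coordinates
(ratio vs. precision) visualize asymmetry. Leave-one-out re-estimates
IVW without each variant and flags sign changes or significance-boundary
crossings. MR-PRESSO simulates the null distribution of the weighted
residual sum of squares around leave-one-out expected values
(add-one Monte-Carlo p-values, so the smallest attainable p is
$1/(n_{sim}+1)$), Bonferroni-adjusts the per-variant outlier tests, and
runs a distortion test comparing the outlier-corrected estimate with
estimates after removing equally many random variants.

## Two-step mediation

The total effect $a$ of the exposure on the outcome decomposes into an
indirect part through the mediator — the product $b_1 b_2$ of the
exposure→mediator and mediator→outcome effects — and the direct
remainder $a - b_1 b_2$. The mediated proportion is $b_1 b_2 / a$. All
arithmetic is on the natural-log (log-OR) scale; published odds ratios
are converted by `or_to_effect()`, with standard errors recovered from
95% CI bounds when available. The indirect effect's delta-method SE is
$\sqrt{b_2^2 se_1^2 + b_1^2 se_2^2}$, assuming independence across the
non-overlapping samples.

Two delta-method CI variants for the proportion are offered, because
the exact variance treatment behind published mediation CIs is often
unstated:

* `delta_indirect_over_fixed_total` (default): the indirect effect's
  Wald interval divided by the total effect. Appropriate when the total
  effect is estimated precisely relative to the steps; it ignores the
  total's sampling noise.
* `delta_full_ratio`: propagates the total effect's SE through the
  ratio as well (independence assumed); always at least as wide.

Proportions outside $[0,1]$ and negative CI bounds are reported as-is —
they are meaningful for weak or inconsistent mediation — with a
warning, never clamped. A mediation signal is interpreted only when the
total and indirect effects share a direction (`consistent_direction`).

In the `run_mediation_workflow()` pipeline, step-2 instruments come
from the mediator's own GWAS (univariable two-step MR, matching the
product method; no multivariable adjustment). Candidate step-2
instruments that explain **more variance in the exposure than in the
mediator** are excluded first: such variants reach the outcome through
the exposure's direct path and would otherwise bias $b_2$ upward. The
recovery experiments below showed this contamination clearly — without
the filter the mean estimated proportion drifts from 0.150 to about
0.17 at biobank-scale sample sizes, and in the noiseless limit $b_2$
tends to $a/b_1$ rather than $b_2$.

## The synthetic-data generator

`simulate_triplet()` emulates the statistical structure of two-sample
MR inputs at the summary level; no individual genotypes are drawn,
which keeps runs desk-scale and matches the two-sample setting (the
three studies get independent noise, i.e. no sample overlap).

* `n_snps` variants carry direct exposure effects with half-normal
  magnitudes $|N(0, \gamma_{sd})|$ — effect alleles are reported
  relative to the trait-increasing allele, the orientation under which
  directional pleiotropy is well defined. A further `n_mediator_snps`
  variants (default: the same number) carry direct mediator effects;
  without them the mediator would have no instruments of its own and
  step-2 MR would be undefined.
* The binary outcome's true per-variant effect is
  $\gamma_j \beta_{direct} + (\gamma_j \beta_{xm} + \delta_j)\beta_{my}
  + \alpha_j$ on the log-odds scale, with
  $\beta_{direct} = \beta_{total} - \beta_{xm}\beta_{my}$ and
  pleiotropy $\alpha_j$ either absent, balanced ($N(0, s)$) or
  directional ($N(s, s)$).
* Estimated betas are true effects plus normal noise with
  $se = 1/\sqrt{2 n \, p(1-p)}$ — the standard GWAS approximation for a
  variance-1 trait, also used for the log-odds outcome (logistic
  asymptotics; no liability-scale machinery). P-values are normal.
* LD is block-diagonal at a configured within-block $r^2$; the matrix
  drives clumping only, while estimation noise stays independent across
  variants — a simplification that leaves clumped analyses unaffected
  but means un-clumped correlated instruments are not realistically
  dependent.
* Defaults — 50 + 50 variants, three studies of 20,000,
  $\beta_{total} = 0.2$, $\beta_{xm} = 0.3$, $\beta_{my} = 0.1$
  (mediated proportion $0.15$), $\gamma_{sd} = 0.08$, MAF uniform on
  $[0.05, 0.5]$ — give a realistic microbiome-scale screen: roughly
  half the exposure variants pass $p<10^{-5}$, per-variant F spans
  10–100, and palindromic drop-outs occur at a realistic rate.

What passing tests on these simulations do **not** show: robustness to
genome-wide realistic LD, winner's curse from discovery/replication
asymmetries, sample overlap, or liability-scale effects — all out of
scope of the generator by design.

## Numerical and design choices

* Log-scale arithmetic throughout; odds ratios are `exp()` views.
* Weighted-median SE: parametric bootstrap, default 1000 replicates,
  with an explicit seed — reports are byte-reproducible given a config.
* RAPS bracket $[-10, 10]$ on the log scale (odds ratios from
  $e^{-10}$ to $e^{10}$) comfortably covers epidemiological effects; an
  estimate at the bracket edge raises an error rather than returning a
  boundary value.
* Monte-Carlo p-values use the add-one rule, bounding them away from 0.
* Degenerate inputs fail loudly and early with classed conditions
  (`mrmediate_input_error`, `mrmediate_config_error`,
  `mrmediate_estimation_error`); a pipeline run with fewer than three
  surviving instruments emits a report with estimators marked not
  computable instead of crashing.
* The screen defaults report raw p-values (`multiple_testing = "none"`)
  with Benjamini-Hochberg available, reflecting how microbiome MR
  screens are usually reported.

## Validation experiments

The test suite and `scripts/acceptance.R` recompute, at fixed seeds:

* the five worked-example mediated percentages from the bundled
  odds-ratio triples (deterministic arithmetic);
* oracle equivalence — IVW vs. the closed-form weighted mean, the
  weighted median vs. a brute-force cumulative-weight search, greedy
  clumping vs. an exhaustive clumper, RAPS vs. a grid search;
* calibration — the fixed-effect IVW z-test's type-I error over 500
  null screens (the unscaled z-test is the calibrated object; the
  random-effects flavour is conservative by construction), Cochran's
  $Q$ against $\chi^2_9$ by Kolmogorov–Smirnov over 1000 homogeneous
  replicates, and the default mediation CI's coverage over 2000
  triples drawn with a precisely estimated total effect
  ($se_{total} = 0.01$ at $\beta_{total} = 0.2$, $se_1 = 0.05$,
  $se_2 = 0.02$) — the regime the fixed-total variant is designed for;
  with a noisy total the full-ratio variant should be preferred, as
  the fixed-total interval undercovers there;
* recovery — the full pipeline's mean estimated mediated proportion
  over 500 simulated replicates at truth 0.15, and the
  directional-pleiotropy contrast in which IVW's absolute bias exceeds
  MR-Egger's over 200 replicates.

Problem sizes (500/1000/2000/200 replicates at 50–100 variants) were
chosen so the whole validation battery runs in a few minutes on a
single core while leaving Monte-Carlo noise well inside the asserted
bands.

## Known limitations

* No multivariable MR: mediators are treated marginally, so jointly
  mediated fractions do not sum meaningfully across correlated
  mediators.
* The published full Bayesian-weighted and overdispersed-RAPS variants
  are not implemented; the robustness suite (median, RAPS, PRESSO)
  covers the same failure modes.
* Proxy-variant support substitutes user-supplied proxies by id and
  assumes the exposure association transfers through LD; no reference
  panel lookup is performed.
* Published mediation CIs are generally not recoverable from printed
  ORs alone — the variance inputs are unpublished — so only the
  mediated proportions, not their intervals, are reproduced in the
  worked example.
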