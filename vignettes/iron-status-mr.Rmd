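---
title: "Methods: two-sample Mendelian randomisation for iron status and heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomisation for iron status and heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ironmr)
```

## The question and the design

Observationally, both iron deficiency and iron overload accompany heart
failure (HF), but observational associations cannot separate cause from
consequence. Two-sample Mendelian randomisation (MR) uses genetic variants
as instrumental variables: because alleles are randomised at conception, a
variant that robustly shifts an iron-status biomarker — and affects HF risk
only through that biomarker — identifies the causal effect of the biomarker
on HF free of reverse causation and classical confounding.

`ironmr` implements this workflow end to end for summary statistics: per-SNP
associations with four systemic iron-status biomarkers (ferritin, serum
iron, transferrin, transferrin saturation) from a GWAS meta-analysis of
48,972 Europeans, and per-SNP associations with HF from the Neale-lab UK
Biobank analysis (n = 361,194). The packaged instrument table
(`iron_hf_instruments()`) carries 12 unique SNPs; three (rs1800562,
rs1799945, rs855791, in *HFE* and *TMPRSS6*) instrument all four
biomarkers.

An instrument must satisfy three premises: (1) robust association with the
exposure, (2) independence from confounders, (3) no path to the outcome
except through the exposure. Premise (1) is enforced by the significance
and F-statistic filters; (2) and (3) are untestable and are probed instead
by the sensitivity and pleiotropy diagnostics below.

## Instrument selection and harmonisation

The selection cascade, each step logged per SNP (`selection_log()`):

* **Significance**: keep SNPs with exposure p-value strictly below
  `p_select` (default 5e-8, the genome-wide convention).
* **LD pruning** (`ld_prune()`): greedy clumping in ascending p-value
  order against a user-supplied r² matrix; a SNP joins the kept set only
  if its r² with every kept SNP is below `ld_r2` (default 0.01). The
  greedy-by-significance order is the standard clumping convention; ties
  beyond p-value fall back to input order.
* **Harmonisation** (`harmonise()`): outcome effects are aligned to the
  exposure's effect allele — copied when alleles match, sign-flipped (and
  EAF mirrored) when swapped, strand-complemented first when the pair
  matches only under complement. Palindromic SNPs (A/T, C/G) are dropped
  outright because their strand cannot be resolved from alleles alone; we
  deliberately do not attempt EAF-window inference, so no allele-frequency
  heuristic can silently mis-orient an instrument. Irreconcilable allele
  sets are dropped and logged, never guessed.
* **Proxies** (`find_proxy()`): an exposure SNP absent from the outcome
  table may be replaced by its strongest LD partner with r² > 0.8 (ties:
  smaller p, then lexicographic rsID); the proxy's own beta and SE are used
  unchanged and provenance is kept in `proxy_of`.
* **Instrument strength**: `f_statistic()` defaults to F = (β/se)², the
  standard summary-data approximation; instruments with F below 10 are
  removed. An alternative estimator based on variance explained,
  F = R²(n−2)/(1−R²) with R² = 2·EAF(1−EAF)·β², is available via
  `method = "r2"`. Neither form reproduces the F values printed alongside
  the published instrument table (e.g. (0.204/0.016)² ≈ 163 where 256 is
  printed), whose defining formula and sample are unstated; the package
  therefore documents the discrepancy and relies only on the F > 10 bound,
  which every packaged instrument clears under both estimators
  (minimum computed F ≈ 30.9).

The packaged fixture reproduces the printed per-SNP values exactly. The
published table omits the non-effect allele, so the fixture ships synthetic
non-palindromic `other_allele` metadata (flagged in the file headers and
documentation); this keeps the full 12-SNP set flowing through the default
filter cascade, matching the published account that no SNP was lost to
palindromy or LD. The real rs1799945 variant is a C/G substitution that the
published analysis retained by frequency-based strand inference, a policy
this package intentionally does not implement.

## Univariable estimators

For instrument *j* with exposure effect β~Xj~ (SE σ~Xj~) and outcome effect
β~Yj~ (SE σ~Yj~):

* **Wald ratio**: θ̂~j~ = β~Yj~/β~Xj~, first-order delta SE σ~Yj~/|β~Xj~|
  (the convention of the standard two-sample toolchain, and the default
  here for reproducibility of published p-values); a second-order SE adding
  the β~Yj~²σ~Xj~²/β~Xj~⁴ term is available via `order = "second"`.
* **IVW** (`mr_ivw()`): inverse-variance weighted mean of the ratios;
  fixed-effect SE (Σw~j~)^−1/2^, the principal analysis; the multiplicative
  random-effects model inflates the SE by max(1, √(Q/(J−1))). P-values are
  two-sided normal.
* **MR-Egger** (`mr_egger()`): WLS of β~Y~ on β~X~ with intercept and
  weights 1/σ~Y~², after orienting all β~X~ ≥ 0 (the standard Egger
  convention; the sign of both members of a pair is arbitrary). The
  intercept estimates average directional pleiotropy; inference uses
  t(J−2), an honest small-J choice where the source is silent.
* **Weighted median** (`mr_weighted_median()`): ratio estimates sorted,
  weights normalised, cumulative weight evaluated at interval midpoints
  s~j~ = Σ~i≤j~p~i~ − p~j~/2, and the estimate linearly interpolated at
  s = 0.5. Consistent when valid instruments carry > 50% of weight. The SE
  is a parametric bootstrap (resampling β~X~, β~Y~ from normals with the
  reported SEs); `n_boot` defaults to 5000 and the seed is mandatory, so
  every reported SE is reproducible.

Results are reported as odds ratios per SD of biomarker via exp(θ̂) with
normal-theory CIs. A caveat inherited from the data source: the UK Biobank
outcome betas are linear-model effects on a 0/1 trait, and ORs are shown as
exp(beta)-per-SD without case-prevalence rescaling, matching the published
presentation (all ORs ≈ 1). No multiple-testing adjustment is applied
across the four biomarkers — the published analysis reports nominal
p-values, and the package follows it; this is stated in the report rather
than silently assumed.

## Sensitivity diagnostics

* **Cochran's Q** (`cochran_q()`): Q = Σw~j~(θ̂~j~ − θ̂~IVW~)² with
  first-order weights fixed at their full-set values (the standard
  two-sample convention), referred to χ²(J−1). Per-SNP contributions are
  returned and sum to Q.
* **Leave-one-out** (`leave_one_out()`): J re-fits each excluding one SNP,
  plus the full fit. On the packaged table the iron, transferrin and
  transferrin-saturation estimates stay null under every exclusion;
  ferritin — already borderline on the full set — crosses nominal
  significance when its *TMPRSS6* instrument is removed, a fragility the
  numbers expose even though the published account (based on visual
  inspection of the plots) reports no perturbation.
* **Funnel coordinates** (`funnel_data()`): θ̂~j~ against precision
  1/se(θ̂~j~), exported as data; symmetry is judged visually
  (`plot_funnel()`), mirroring practice — no asymmetry test is fitted.

## Model-averaged multivariable MR

The four biomarkers are biologically entangled (shared *HFE*/*TMPRSS6*
loci), so the package also implements Bayesian model averaging over
risk-factor subsets. On the inverse-variance-weighted scale (every row
divided by σ~Yj~), the outcome vector under subset S is modelled as

$$\tilde y \sim N(0,\; I + \sigma^2 \tilde X_S \tilde X_S^\top),$$

a closed-form marginal likelihood evaluated with the determinant lemma and
Woodbury identity (p×p algebra; the tests verify it against a dense J×J
multivariate-normal log-density to 1e-8). Combined with an independent
inclusion prior (`prior_prob` per factor) this yields posterior
probabilities (PP) over all 2⁴−1 = 15 non-empty subsets — the empty model
is excluded because only risk-factor-bearing models are ranked. Per factor:

* **MIP** = Σ PP over models containing the factor;
* **MACE** = the PP-weighted average of its conditional (ridge posterior
  mean) estimates, zero whenever MIP is zero;
* the best-model PP and conditional estimate for every factor.

**Priors.** `prior_prob = 0.1` and `sigma = 0.5` follow the method's
reference implementation; the source analysis prints neither. Both are
mandatory, echoed fields of the pipeline configuration so that runs are
self-documenting, and the factor ranking — ferritin first by a wide margin
— is stable across reasonable prior choices even though the numeric MIP is
prior-conditional. Exposure columns are not re-standardised beyond the
1/σ~Y~ weighting; implementations that additionally scale columns will
report different conditional estimates.

**Input matrix.** The instruments-by-factors matrix zero-fills cells where
a SNP is not a genome-wide-significant instrument of a factor, because the
published table prints no sub-threshold associations. This matters mostly
after instruments are excluded: the first-stage results match the published
ones closely, while later stages agree in ranking but not exactly in MIP —
consistent with the original analysis having used full (unprinted)
association estimates.

**Per-variant diagnostics** (`variant_diagnostics()`). For every credible
model — each model whose PP reaches `pp_threshold` (default 0.02, the
published best-model rule) — the weighted-scale squared residuals (the
per-variant Q statistic) and Cook's distances are computed, and each
variant is summarised by its worst value across those models. Judging a
variant against every credible model, not only the single top one, is what
the published exclusion sequence implies: the ABO-locus instrument
rs651007 is unremarkable inside ferritin-containing models but exceeds the
Q cut-off of 10 in every credible model that lacks ferritin. The Cook's
threshold defaults to the median of F(p, J−p) per model, the usual
influence rule-of-thumb, since the source states only that a threshold was
exceeded.

**Iterative exclusion** (`mr_bma_exclude()`). Outliers are removed one per
pass (worst q above `q_max = 10`), re-assessing after each removal since
the fit changes. Influence flags, by contrast, are taken from the full-set
fit — influence is a leverage property of the design that practitioners
read off the full-set diagnostic plots — and flagged variants are then
removed worst-first, one per stage. A refitted panel is emitted after every
removal; on the packaged table this gives the three-stage trail 12 → 11
(rs651007, outlier) → 10 (rs1800562, influential), with ferritin ranked
first at every stage.

**Permutation p-values** (`bma_permutation_p()`): the weighted outcome
vector is permuted across instruments; the per-factor p is the
add-one-smoothed share of permutations whose MIP reaches the observed one
(so p ∈ [1/(n+1), 1]). The published table's p column has no described
generating procedure; permutation is the reference-implementation
convention and its values are not treated as a reproduction target.

## Multivariable IVW

`mvmr_ivw()` fits WLS of β~Y~ on all exposure columns jointly (no
intercept, weights 1/σ~Y~²), giving direct effects; SEs come from the
weighted normal equations scaled by the residual variance, and p-values use
t(J−K). Collinearity is checked via the condition number of the weighted
design and per-exposure VIFs; exactly collinear columns abort with the
offending exposures named. The published multivariable table used an
independent HF outcome sample and unstated per-exposure instrument subsets,
so exact numeric reproduction is out of reach; the module is validated by
simulation (planted direct effects recovered within 95% CIs) and by
reproducing the output schema.

## The synthetic-data generator

`mr_scenario()` + `simulate_summary_stats()` emulate the two-sample
structure with known truth: exposure effects half-normal with scale
`beta_x_scale = 0.15` (positive — the oriented convention of harmonised
data, where the effect allele is the exposure-increasing one; with
sign-symmetric effects a "directional" pleiotropic shift cancels in ratio
space, defeating the scenario's purpose), truncated at half the scale so no
draw is a degenerately weak instrument; measurement SEs `se_x = se_y =
0.01`, placing instrument F far above 10; EAFs uniform on (0.05, 0.95);
alleles drawn non-palindromic unless a scenario asks otherwise to exercise
the palindrome filter. Pleiotropy is `none` (default — the null world the
study reports), `balanced` (zero-mean direct effects) or `directional`
(mean `pleiotropy_mean = 0.05`, SD 0.01) applied to a fraction
`invalid_fraction = 0.3` of instruments — the textbook stress case where
fewer than half the instruments are invalid, so the weighted median should
hold while IVW drifts.

What the generator does *not* emulate: LD between instruments, sample
overlap between the two GWAS, winner's-curse in instrument selection, and
binary-outcome link misspecification. Passing calibration tests therefore
demonstrates correctness of the estimators under their stated assumptions,
not robustness to these real-data complications.

## Problem sizes and numerical choices

The test suite verifies, among others: IVW type-I error within
[0.035, 0.065] over 1000 null replicates at J = 20; weighted-median bias
below 0.05 under 30% directional pleiotropy over 500 replicates at
J = 200; IVW coverage within [92%, 98%] over 500 replicates at J = 50;
closed-form versus dense marginal likelihoods to 1e-8 on J ≤ 8 instances.
These sizes give Monte-Carlo error comfortably below the tolerances while
keeping the default suite fast.

Other numerical choices: Wald ratios abort (naming the SNP) when
β~X~ = 0 rather than returning infinities; the weighted-median bootstrap
replaces an exactly zero resampled β~X~ by machine epsilon; Q uses
full-set weights (not iteratively reweighted); p-values below the smallest
double underflow to zero on file read and are retained, since they pass
any threshold; all permutation and bootstrap p-values are seeded and
reports are byte-identical under identical configurations.

## Known limitations

* Strand resolution for palindromic SNPs is not attempted; studies whose
  instruments include palindromic variants lose them under the default
  policy.
* The MIP values are prior-conditional; only their ranking is robust.
* ORs for the UK Biobank outcome are on the linear-probability scale
  (see above), adequate for a null result but not for effect-size
  interpretation.
* The dichotomous-exposure pipeline (`run_binary_exposure_mr()`) reports
  estimates with a caveat banner: with a 0/1 exposure the ratio estimand
  is a liability-scale contrast among the genetically susceptible, and
  competing-risk bias cannot be excluded.
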