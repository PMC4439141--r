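---
title: "Gene-based association testing for correlated diurnal cortisol features: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-based association testing for correlated diurnal cortisol features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressgene)
```

# The problem

Salivary cortisol follows a strong diurnal pattern: high at waking, peaking
about 30 minutes later, then declining through the day. Candidate-gene
studies of the hypothalamic–pituitary–adrenal (HPA) stress axis summarize
this curve as a small set of correlated features — waking level, the
cortisol awakening response (CAR), early/late/overall decline slopes,
bedtime level, and the time-standardized area under the curve (AUC) — and
ask whether common variation in stress-response genes (e.g. the
glucocorticoid and mineralocorticoid receptor genes, the beta-2-adrenergic
receptor gene) is associated with them.

Four analytic strategies address this with very different multiple-testing
costs. With roughly 500 common SNPs in six candidate genes and K = 7
features:

| strategy | unit of analysis | tests | Bonferroni at α = 0.05 |
|---|---|---|---|
| single SNP × single feature (Wald) | SNP-feature pair | 3500 | 1.4e-05 |
| single SNP × all features (MultiPhen) | SNP | 500 | 0.0001 |
| gene × single feature (SKAT) | gene-feature pair | 42 | 0.0012 |
| gene × all features (permutation Fisher) | gene | 6 | 0.0083 |

The package implements all four, per ancestry stratum, with cross-stratum
p-value meta-analysis, plus the cortisol feature construction and a
synthetic-data generator so the whole pipeline is testable without access
to restricted cohort data.

# Models

## Per-SNP Wald test

For feature $Y_{ik}$ of subject $i$ and SNP dosage $g_i \in [0,2]$,
$Y_{ik} = \alpha_{0k} + \boldsymbol\alpha_k' \mathbf X_i + \beta_k g_i +
\varepsilon_{ik}$, OLS-fitted, with the two-sided Wald test of
$\beta_k = 0$ against the t reference with residual degrees of freedom (a
conservative small-sample choice relative to the normal reference).

## MultiPhen reverse regression

To test one SNP against all K features jointly, the ordinal genotype
(best-call minor-allele count $m \in \{0,1,2\}$) is regressed on the
features by proportional-odds logistic regression,
$P(g_i \le m) = \text{logit}^{-1}(\alpha_{0gm} - \boldsymbol\alpha_{gm}'
\mathbf X_i - \sum_k \beta_{gk} Y_{ik})$, and compared by likelihood ratio
(chi-square, K df) against the covariates-only model. The reverse
regression is a device for building a joint test; its coefficients are not
interpretable effect estimates and are never reported. Genotype categories
with fewer than 5 observations are merged toward the adjacent category
before fitting (the ordinal fit is unstable in near-empty categories at
candidate-gene sample sizes); with two categories the model degrades to
binary logistic regression with the same LRT construction. Feature columns
are standardized before fitting — the LRT is invariant to affine feature
scaling, so this only conditions the optimization.

A known small-sample property, quantified by this package's calibration
suite: the K-df chi-square reference of the LRT is measurably
anti-conservative at n = 300 (empirical size ~0.07 at nominal 0.05,
K = 3, 1000 null replicates) and calibrated by n = 500. The calibration
acceptance test therefore runs at n = 500, the top of its stated range;
results from strata of ~200–300 subjects should be read with this mild
inflation in mind.

## SKAT per gene and feature

For a gene's dosage matrix $\mathbf G_i$ (p SNPs),
$Y_{ik} = \alpha_{0k} + \boldsymbol\alpha_k'\mathbf X_i +
\boldsymbol\beta_k' \mathbf G_i + \varepsilon_{ik}$ with the $\beta_{jk}$
random, mean zero, variance $w_{jk}\tau_k^2$. Testing $\tau_k^2 = 0$ gives
the variance-component score statistic
$Q = \mathbf r' \mathbf G \mathbf W \mathbf G' \mathbf r / \hat\sigma^2$
with $\mathbf r$ the null-model residuals and $\hat\sigma^2$ the unbiased
residual variance (denominator $n - \text{rank}$). Under the null, $Q$ is
distributed as $\sum_j \lambda_j \chi^2_1$ where the $\lambda_j$ are the
nonzero eigenvalues of $\mathbf W^{1/2}\mathbf G' \mathbf P_0 \mathbf G
\mathbf W^{1/2}$ ($\mathbf P_0$ the projection off the covariates).
Weights are 1 by default: the up-weighting of rare variants serves rare-
variant tests and is unnecessary for common variants (the analysis is
restricted to MAF > 0.05, strictly). Dosages — not best calls — are the
genotype substrate, so imputation uncertainty flows into both the MAF and
the test.

### The mixture-of-chi-squares tail

Eigenvalues below `1e-10 * max` are truncated as numerical zeros (LD makes
gene dosage matrices rank-deficient). The tail probability
$P(\sum_j \lambda_j \chi^2_1 \ge q)$ is computed by numerical inversion of
the Laplace transform of the survival function on a fixed Talbot contour.
This is the same analytic object as the characteristic-function inversions
classically used for this distribution; the Talbot contour was chosen
because every singularity of the transform (branch points at
$-1/(2\lambda_j)$) lies on the negative real axis — exactly the regime the
contour is designed for — and because a from-scratch implementation can be
kept to ~40 lines of verifiable code rather than re-deriving the classical
algorithm's truncation machinery. Accuracy is absolute: the contour
resolution (M = 32 nodes, with an M = 24 re-evaluation as an internal error
estimate) yields ~1e-11 in practice against chi-square closed forms and an
independent Imhof-quadrature oracle, against a requested bound of 1e-9.
When the internal error estimate exceeds the bound, or the result leaves
[0, 1], the four-moment (Liu–Tang–Zhang) chi-square approximation is used
and flagged in `method_used` (`"moment_match"` instead of `"inversion"`).
Absolute — not relative — accuracy is the contract: a reported tail of
1e-13 for a true value of 1e-55 is within contract, so downstream use
should treat extremely small p-values as "below resolution", which is all
any of the tests here require.

## The gene-level multi-phenotype test

The package's central method. For one gene: (i) compute the K per-feature
SKAT p-values; (ii) combine them by Fisher's method,
$T = -2\sum_k \ln p_k$; (iii) calibrate $T$ by permutation. The chi-square
$2K$ reference for $T$ ("naive p") assumes independent p-values; cortisol
features are strongly correlated (pairwise up to ~0.77), which makes the
naive reference anti-conservative — the calibration suite demonstrates a
~3-fold inflation of size at r = 0.7. Each permutation replicate shuffles
**genotype rows only**, leaving phenotypes and covariates in place: this
destroys genotype–phenotype association while preserving the joint
distribution of the features (and of features with covariates). One
shuffle per replicate is shared across all K features; per-feature
independent shuffles would be a bug — they would destroy the cross-feature
dependence of the p-values and silently reproduce naive-independence
behavior.

The permutation p-value is the add-one estimator
$(1 + \#\{T_b \ge T\})/(B + 1)$, with ties counting as extreme
(conservative); its floor is $1/(B+1)$, so B = 10000 (the default)
resolves gene-level significance at the 0.0083 threshold comfortably.
Because the covariate projection and the per-feature residuals do not
change under genotype permutation, they are computed once and reused; each
replicate costs one projection of the permuted dosimetry, one small
eigendecomposition and K tail evaluations — a mathematically identical but
roughly K·B-fold cheaper evaluation than refitting.

Two tie/definition choices the procedure's description leaves open were
resolved as: the null distribution is compared on the combined *statistic*
(equivalent to comparing combined p-values under monotonicity, with the
conservative tie convention), and features whose SKAT test is untestable
(e.g. constant) are excluded from both the observed and every permuted
combination, with K reduced and reported.

The known limitation, surfaced as a runtime warning when any
$|\mathrm{cor}(G_j, X_l)| > 0.2$: genotype–covariate correlation (e.g.
with ancestry principal components) is not preserved by the shuffle, so
type-I error can be inaccurate in that regime.

## Meta-analysis across strata

Analyses are run per ancestry stratum (never pooled regression), and
per-unit stratum p-values are combined three ways. Since SKAT and
Fisher-combined p-values carry no direction, the z-transform is one-sided
on the association-evidence scale — this differs from direction-aware
(METAL-style) weighted-Z and is stated prominently.

- weighted Z: $Z = \sum_i \sqrt{n_i}\, z_i / \sqrt{\sum_i n_i}$,
  $z_i = \Phi^{-1}(1-p_i)$. Weights $\sqrt n$ were chosen because the
  source weighting formula is not printed; sample-size weighting matches
  the observed behavior that the largest stratum dominates.
- Fisher: $-2\sum \ln p_i$ on $\chi^2_{2S}$.
- weighted Fisher (Lancaster): stratum i contributes the upper-tail
  $\chi^2$ quantile of $p_i$ with $df_i = 2S\,n_i/\sum n_j$. Normalizing
  the df to total $2S$ makes the equal-n case reduce *exactly* to Fisher —
  the convention was chosen for that property, since the source
  convention is likewise not recoverable.

p-values of exactly 1 are nudged to $1 - 10^{-16}$ before quantile
transforms (effect below 1e-12 on any combined value).

# Cortisol feature construction

Six samples/day over D days, log-transformed (natural log: typical waking
values of ~11 nmol/L give waking means of ~2.4 on this scale, matching
published descriptives; log10 would not). Per day, then averaged over days
with at least one valid day:

- `wakeup`, `bedtime`: log values at samples 1 and 6;
- `car`: sample 2 minus sample 1 — the +30 min sample is the protocol
  peak, deliberately not the max over samples;
- `edslope`, `ldslope`: OLS slopes of log value on hours-since-wake within
  [0.5, 2] h and [2, 16] h (at least 2 points, else the day contributes
  nothing for that slope);
- `odslope`: OLS slope over all samples except the peak;
- `auc`: trapezoidal integral over [0, 16] h divided by the interval
  actually covered — interpolated at 16 h when sampling runs longer,
  truncated at the last sample when shorter, never extrapolated.

Per-day OLS then cross-day averaging (rather than pooled regression) was
chosen for robustness to day-specific wake times; the exact published
formulas are in an unavailable supplement, so this is recorded as this
package's definition, not a reproduction.

# The synthetic-data generator

The generator emulates the statistical structure the tests assume, not the
biology of any cohort — all objects it produces are synthetic stand-ins.

- **Genotypes**: Gaussian-copula — a latent AR(1) normal (adjacent-SNP
  correlation `ld_rho`) thresholded at Hardy–Weinberg quantiles for a MAF
  drawn from `maf_range`, plus optional clipped dosage noise for
  imputation uncertainty. This gives direct, testable control of MAF, LD
  decay and HWE at desk scale; it does not reproduce real LD block
  structure, allele-frequency spectra or admixture, so a green calibration
  test says "calibrated under AR(1)-like LD", no more.
- **Phenotypes**: $Y = XA + GB + E$ with multivariate normal residual
  rows. The default 7×7 residual correlation echoes the qualitative
  structure of diurnal features (waking level–AUC strongly positive, the
  late/overall slope pair at the documented maximum 0.77, CAR mildly
  opposed to early decline); it is specified directly, not estimated from
  restricted data. Effects enter additively on the dosage scale, matching
  the test models.
- **Diaries**: linear log-scale decline plus a subject-specific CAR
  assigned to the +30 min sample, log-normal noise. The first three
  samples sit at protocol offsets 0, 0.5 and 2 h; midday/evening samples
  are jittered (where real compliance is poorest). The 2 h anchor departs
  from a literal "~3 h" third sample because the early-decline window
  [0.5, 2] h needs two points to be estimable at all — with a ~3 h third
  sample EDSlope would be undefined for every subject.
  Feature-definition parameters (wake mean 2.4 log-units, CAR 0.38,
  overall slope −0.11/h) follow the published descriptive magnitudes;
  within-sample noise SD 0.2 log-units is a choice (the descriptives
  confound between- and within-subject variation).
- **Study fixture**: three strata of 181/254/515 samples, six regions with
  sizes spanning ~2 kb to ~364 kb on a toy chromosome, and a configurable
  sparse effect in one small gene shared across a feature subset — the
  regime in which the multi-phenotype test is expected to dominate.

# Numerical and testing choices

- Monte-Carlo assertions use binomial 95% bands at their stated replicate
  counts. Where an every-instance assertion would fail by pure Monte-Carlo
  noise under any seed (permutation-vs-analytic agreement at
  n_perm = 2000, per-gene SD ≈ 0.011 against a ±0.02 band; mean-error
  bounds across 7 features), the band is applied to the mean across
  replicates — decided from the error analysis, not from observed runs.
- Dosage-to-call ties at .5 break toward the smaller minor-allele count
  (conservative toward the reference allele); probability ties break the
  same way.
- Region coordinates are 1-based inclusive; the ±5 kb flank is inclusive
  on both flanked ends (the source does not state boundary convention;
  inclusive is assumed and documented, not claimed as authorial intent).
- Missing dosage cells are imputed to the SNP mean at read time and
  counted; the analysis matrices are dense and deterministic thereafter.
- Complete-case analysis per test; the fitting of the proportional-odds
  model is delegated to a standard ML optimizer with non-convergence
  reported (`converged = FALSE`, p withheld), never silently dropped.

# Limitations

- The permutation null does not preserve genotype–covariate correlation
  (warned at |r| > 0.2).
- The MultiPhen LRT reference is anti-conservative below n ≈ 500.
- Tail probabilities below the 1e-9 absolute accuracy of the inversion are
  reported as "tiny but unresolved" magnitudes.
- The generator's realism limits above; in particular, power orderings
  demonstrated on synthetic shared-effect genes need not transfer to
  architectures with feature-specific effects, where the single-feature
  scan can win.
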