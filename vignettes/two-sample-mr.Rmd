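---
title: "Two-sample Mendelian randomization with mrcausal: models, conventions and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrcausal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrcausal)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure on an outcome from GWAS summary statistics of two
independent cohorts, using genetic variants as instrumental variables. For
instrument $j$, let $\hat\beta_{Xj}$ (se $\sigma_{Xj}$) be its estimated
per-allele effect on the exposure and $\hat\beta_{Yj}$ (se $\sigma_{Yj}$)
its effect on the outcome, both on the log-odds scale for binary traits.
Under the instrumental-variable assumptions — relevance (the SNP is
strongly associated with the exposure), independence (no confounding of
the SNP-outcome relation) and exclusion restriction (no effect on the
outcome except through the exposure) — each instrument supplies a Wald
ratio $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ with first-order
standard error $\sigma_{Yj}/|\hat\beta_{Xj}|$.

The estimators combine these ratios:

* **IVW (fixed effects)** — the inverse-variance-weighted mean of the
  ratios, equivalently a weighted zero-intercept regression of
  $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ with weights
  $1/\sigma_{Yj}^2$. Consistent when every instrument is valid.
* **IVW (multiplicative random effects)** — the same point estimate with
  the standard error inflated by $\max\{1, \sqrt{Q/(k-1)}\}$, where $Q$ is
  Cochran's Q of the ratios; never narrower than the fixed-effects
  interval. An additive DerSimonian–Laird flavor is available for
  comparison (`mr_ivw(..., effects = "dl")`).
* **MR-Egger** — weighted regression of outcome on exposure effects *with*
  an intercept after orienting all $\hat\beta_{Xj} \ge 0$. The slope is
  consistent under the weaker InSIDE assumption (instrument strength
  independent of direct effects); the intercept estimates the average
  directional pleiotropy, and its test is the pleiotropy diagnostic.
* **Weighted median** — the inverse-variance-weighted median of the
  ratios, consistent when instruments carrying at least half the weight
  are valid; its standard error comes from a parametric bootstrap.

## Conventions and numerical choices

Several conventions are genuinely open in the field; the package fixes
them as follows and exposes switches where both choices are defensible.

* **Reference distributions.** IVW and the weighted median use the normal
  reference; MR-Egger uses Student's t with $k-2$ degrees of freedom.
  All intervals are 95% by default.
* **Wald-ratio standard error.** First-order ($\sigma_{Yj}/|\beta_{Xj}|$)
  by default, which makes fixed-effects IVW an exact inverse-variance
  meta-analysis of the ratios; the second-order delta form (adding
  $\beta_{Yj}^2\sigma_{Xj}^2/\beta_{Xj}^4$) is available by flag.
* **Egger residual scale.** Standard errors are rescaled by
  $\max\{1, \sqrt{RSS_w/(k-2)}\}$ — the multiplicative random-effects
  convention with the scale floored at one, so under-dispersion never
  shrinks an interval.
* **Weighted median interpolation.** The $j$-th order statistic of the
  ratios sits at cumulative weight $S_j - w_{(j)}/2$; the estimate
  interpolates linearly across 0.5. The bootstrap resamples each
  instrument's $(\hat\beta_X, \hat\beta_Y)$ from normals at their stated
  standard errors, with 1000 replicates and seed 2019 by default; the
  replicate count is configurable because no single convention exists.
* **Degenerate inputs.** A single instrument degenerates IVW to the Wald
  ratio; $\hat\beta_X = 0$ is an undefined-ratio error; MR-Egger requires
  $k \ge 3$ and non-identical exposure effects; MR-PRESSO requires
  $k \ge 4$ so each leave-one-out prediction rests on at least three
  instruments.

## Harmonization

`harmonize_pair()` matches SNPs by identifier and reorients the outcome
study onto the exposure's effect allele: identical orientation is kept,
swapped alleles flip the sign of $\hat\beta_Y$ and replace the frequency
by its complement, and complementary (strand-flipped) representations are
resolved by complementing first. Palindromic SNPs (A/T, C/G) cannot be
resolved from alleles alone: by default they are retained only when both
effect-allele frequencies are available and fall outside
$0.5 \pm 0.08$, in which case the orientation that makes the frequencies
consistent is applied; everything else is dropped and logged. Because
practice varies, `palindromic = "drop"` discards all palindromic SNPs
instead. Every shared SNP receives exactly one log row, so the retained
and dropped counts always reconcile with the intersection.

## Instrument selection

The selection cascade mirrors the standard design: (A) keep exposure
associations with $p < 5\times10^{-8}$ (strict inequality) and prune to
independent index SNPs; (B1) remove instruments with outcome
$p < 1\times10^{-5}$ (strict); (B2) remove instruments within 1 Mb
(inclusive) of a known outcome-associated locus; (C) remove instruments on
named, user-supplied exclusion lists (e.g. lipid-associated SNPs or hits
from variant-database lookups). Index-SNP independence is decided by
greedy distance pruning: survivors are visited in ascending p-value order
and accepted only if no accepted SNP on the same chromosome lies within
the 1 Mb window. This is a documented proxy for LD clumping — no LD
reference is bundled — and a user-supplied pairwise $r^2$ matrix switches
the criterion to $r^2 < 0.001$ clumping. Strict-versus-inclusive boundary
choices follow the conventions above and are pinned by tests.

Instrument strength is reported as the observed-scale variance explained
$\mathrm{PVE}_j = 2\beta_j^2 f_j(1-f_j) / (2\beta_j^2 f_j(1-f_j) +
2\sigma_j^2 N f_j(1-f_j))$ and the one-instrument
$F_j = (N-2)\,\mathrm{PVE}_j/(1-\mathrm{PVE}_j)$, with the familiar
$\beta^2/\sigma^2$ approximation available; the overall F across $k$
instruments uses $(N-k-1)/k \cdot R^2/(1-R^2)$ on the summed PVE.

## Sensitivity analyses

Cochran's Q (with $I^2$), leave-one-out IVW (flagging omissions that move
the estimate across zero or change significance at 0.05), funnel data with
the Egger-intercept asymmetry p-value, and a regional Pearson correlation
of effect sizes over a 1-based inclusive genomic window (Fisher-z
interval; `stats::cor.test` is the engine).

MR-PRESSO follows the published resampling algorithm: the global statistic
is the weighted residual sum of squares of outcome effects about their
leave-one-out IVW predictions, compared against parametric simulations
drawn at the stated standard errors; per-SNP squared residuals are
compared to their own simulated distributions with Bonferroni adjustment
across instruments, and both raw and adjusted p-values are reported
because published analyses are often ambiguous about which they quote.
The distortion test here compares the shift in the IVW estimate caused by
removing the flagged outliers against the distribution of shifts from
removing equally many instruments at random — a definition chosen for
transparency and documented as such. Defaults: 1000 simulations, outlier
level 0.05, seed 2019; identical seeds give bit-identical results.

## Meta-analysis and power

`dl_meta()` pools study-level odds ratios on the log scale with
DerSimonian–Laird moments (`tau2 = max(0, (Q-(m-1))/(\sum w - \sum
w^2/\sum w))`), reconstructing each standard error from its 95% interval
under log-scale symmetry. REML is available through metafor when a
likelihood-based $\tau^2$ is preferred. The packaged table of twelve
observational studies of type 2 diabetes and ALS pools to OR 0.73
(0.59–0.90) over the eleven European-ancestry rows and 0.77 (0.62–0.96)
over all twelve — the package's tests pin both.

`mr_power_binary()` implements the analytic binary-outcome power
approximation of the mRnd calculator (Brion et al.): the causal odds
ratio is attenuated to the risk-difference scale,
$b = K(\mathrm{OR}/(1+K(\mathrm{OR}-1))-1)$ with $K$ the outcome case
fraction, the estimator variance is $(K(1-K)-b^2)/(N R^2)$, and power is
the non-central $\chi^2_1$ tail. An alternative log-odds parameterization
($\lambda = N R^2 K(1-K)\log^2\mathrm{OR}$) is provided; it is the one
under which power at OR and 1/OR coincide exactly, whereas the
risk-difference form is only approximately symmetric — so both directions
of a hypothesized effect are worth reporting, and the package evaluates
vectors of ORs directly. A Monte Carlo oracle (`mr_power_sim()`)
generates two-sample summary statistics at the same parameters and counts
IVW rejections; the analytic and simulated powers agree within a few
percentage points at the sample sizes shipped in
`gwas_sample_sizes()` (9% at OR 1.20 for the East Asian ALS study of
4,084; 75% at OR 0.80 for the European study of 80,610).

## The synthetic-data generator

`simulate_two_sample()` emulates the two-sample summary-statistic design
directly at the summary level: observed effects are normal draws around
truth with the logistic-score standard error
$1/\sqrt{2 n f(1-f)\,K(1-K)}$ for binary traits — no individual-level
genotypes are simulated, which is sufficient for every estimator here and
orders of magnitude cheaper. Defaults reproduce the study conditions the
package is validated under: 67 instruments jointly explaining 0.61% of
exposure variance, exposure study of 659,316 (9.5% cases), outcome study
of 80,610 (25.8% cases), causal effect $\log(0.93)$.

Design choices worth knowing:

* Per-instrument variance-explained shares are proportional to
  $U(0.5, 1.5)$ draws and sum exactly to the PVE target, so instrument
  strengths spread about three-fold and none is near zero — matching
  genome-wide-significant index SNPs, whose F statistics are bounded well
  away from the selection threshold. (A generator with mass near zero
  would manufacture sign-flip artifacts in MR-Egger's orientation step
  that real instrument sets do not exhibit.)
* The effect allele is the exposure-increasing allele, so directional
  pleiotropy ("directional" mode, mean $\delta$) has a well-defined sign;
  "balanced" draws mean-zero direct effects (InSIDE holds), and
  "inside_violating" makes the direct effect proportional to instrument
  strength plus noise — a documented negative control under which IVW and
  Egger are both biased.
* Allele labels exercise harmonization: configurable fractions of SNPs
  are palindromic, written allele-swapped, or written strand-flipped in
  the outcome file; effect-allele frequencies differ between studies by
  N(0, 0.005) noise.
* No linkage disequilibrium is simulated (the estimators assume
  independent instruments); positional clustering for pruning tests comes
  from assigned coordinates only. Consequently, passing tests demonstrate
  estimator and pipeline correctness under the stated model, not
  robustness to LD misspecification, allele-frequency mismatch between
  ancestries, or sample overlap — none of which the generator emulates.

## Validation design and problem sizes

The test suite checks algebraic identities against independent oracles
(explicit normal equations for Egger, inverse-variance pooling of Wald
ratios for IVW, hand-walked interpolation for the weighted median,
brute-force all-pairs scans for the selection filters) and statistical
behavior by simulation: mean recovery of $\log(0.93)$ by IVW, Egger and
the weighted median over 1000 seeded replicates with the outcome study
reduced to 8,061 (a tenth of scale; the exposure study stays at full size
so instrument F remains ~60 and the check measures estimator correctness
rather than the known weak-instrument attenuation of order $\theta/F$);
Egger-intercept recovery of a planted $\delta = 0.01$ under directional
pleiotropy; Egger type-I error at 5% over 1000 balanced-pleiotropy
replicates; and MR-PRESSO catching a planted $10\sigma$ outlier in at
least 95 of 100 seeded replicates while staying quiet on clean data.
These sizes were chosen to make Monte-Carlo error small relative to the
effects being verified.

## Limitations

The package deliberately omits LD-aware clumping with a reference panel,
LD-score regression, Steiger filtering, multivariable and mode-based MR,
and any external variant-database lookups (exclusion lists are
user-supplied files). Estimates assume independent instruments and
non-overlapping samples; the power approximation inherits the analytic
calculator's assumptions (strong instruments, risk-difference
linearization). Real summary-statistic idiosyncrasies — build mismatches,
indel representation, imputation quality — are out of scope beyond the
validation rules documented above.
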