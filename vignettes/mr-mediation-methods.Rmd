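---
title: "Two-sample MR and two-step mediation: models, conventions, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample MR and two-step mediation: models, conventions, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

# The problem

Observational associations between body mass index, circulating
metabolites, and gallstone disease (cholelithiasis) are confounded by diet,
lifestyle, and reverse causation. Two-sample Mendelian randomization (MR)
side-steps this by using genetic variants as instruments: a SNP that
raises BMI was assigned at conception, so its downstream association with
cholelithiasis estimates a causal effect, provided the instrument
assumptions hold. Two-step mediation MR extends the logic to ask *through
what* BMI acts: step one estimates the effect of BMI on each candidate
metabolite ($\beta_1$), step two the effect of that metabolite on
cholelithiasis ($\beta_2$), and the product $\beta_1\beta_2$ is the
indirect (mediated) effect, reported as a percentage of the total effect.

`mrmediate` implements this workflow end to end on GWAS summary
statistics: instrument selection with greedy LD clumping, allele
harmonization, the IVW, MR-Egger and weighted-median estimators,
Cochran's Q, the Egger-intercept pleiotropy screen, an MR-PRESSO-style
outlier scan, Benjamini–Hochberg FDR over screen families, and the
mediation synthesis. A synthetic three-trait generator with known causal
structure makes every stage testable without any data download.

# Estimators

With harmonized per-SNP effects $\hat\beta_{X,j}$ (exposure, standard
error $\sigma_{X,j}$) and $\hat\beta_{Y,j}$ (outcome, $\sigma_{Y,j}$):

**Wald ratio.** $\hat\theta_j = \hat\beta_{Y,j}/\hat\beta_{X,j}$ with the
first-order standard error $\sigma_{Y,j}/|\hat\beta_{X,j}|$. The exposure
side's uncertainty is deliberately ignored, matching the weighting used by
IVW; second-order weights are out of scope.

**IVW.** The inverse-variance-weighted mean of the Wald ratios,
$$\hat\theta_{IVW}
  = \frac{\sum_j w_j \hat\beta_{X,j}\hat\beta_{Y,j}}
         {\sum_j w_j \hat\beta_{X,j}^2},\qquad w_j = \sigma_{Y,j}^{-2},$$
equivalently weighted least squares of outcome on exposure effects through
the origin. The fixed-effects standard error is
$(\sum_j w_j\hat\beta_{X,j}^2)^{-1/2}$. Cochran's Q
($\sum_j w_j\hat\beta_{X,j}^2(\hat\theta_j - \hat\theta_{IVW})^2$, df
$n-1$) gates the error model: when its p-value falls below 0.05 the
standard error is inflated by $\max(1, \sqrt{Q/df})$ — multiplicative
random effects, the dominant convention for two-sample summary data — and
the estimate is tagged `ivw_random`. The inflation never deflates, so the
random-effects SE is always at least the fixed-effects SE. IVW p-values
use the normal distribution.

**MR-Egger.** Weighted regression *with* a free intercept after orienting
every pair so $\hat\beta_{X,j} \ge 0$. The slope is a
pleiotropy-robust effect estimate under the InSIDE assumption; the
intercept estimates the mean directional pleiotropic effect, and its
two-sided t test (df $n-2$) is the pleiotropy screen used throughout the
pipeline. The residual SD is floored at 1 so Egger SEs never undercut the
fixed-effects level. The t convention for Egger p-values (rather than
normal) is what reproduces the packaged reference tables' intercept
p-values.

**Weighted median.** Wald ratios are ordered; the estimate sits where the
cumulative normalized inverse-variance weight crosses one half
(mid-point convention $\sum_{k\le j} w_k - w_j/2$, linear interpolation
between adjacent ratios). It is consistent when valid instruments carry
more than half the weight. Its SE comes from a seeded parametric
bootstrap (default 1000 resamples of both effect columns from normals at
their SEs); results are bit-reproducible under a fixed seed.

**MR-PRESSO.** For each SNP the leave-one-out IVW estimate
$\hat\theta^{(-j)}$ yields a weighted squared residual
$w_j(\hat\beta_{Y,j} - \hat\theta^{(-j)}\hat\beta_{X,j})^2$. The observed
global RSS is compared with `n_sim` (default 1000) simulated datasets
drawn under the no-pleiotropy model; empirical p-values use the plus-one
rule so they are never zero. Per-SNP p-values are Bonferroni-corrected by
the SNP count; flagged outliers trigger a distortion test against random
pseudo-outlier sets of equal size, and the IVW estimate is re-fit without
them (`beta_corrected`) rather than silently substituted.

# The pipeline and its gates

`run_full_analysis()` follows four stages: (1) total exposure-to-outcome
effect; (2) exposure → mediator screen; (3) mediator → outcome screen;
(4) mediation synthesis. A mediator is reported only when both screens
are significant after Benjamini–Hochberg FDR within their families
(`fdr_alpha` 0.05) *and* neither step's Egger intercept is flagged at
0.05. `bh_adjust()` is the standard step-up procedure (delegating to
`stats::p.adjust`); one family per (source, direction) screen, matching
how the reference screens were built (249 metabolite tests per family).

Instrument conventions: genome-wide significance $p < 5\times10^{-8}$,
clumping at $r^2 < 0.001$ within 10,000 kb, and exclusion of SNPs
associated with the outcome at $p < 5\times10^{-8}$. The exclusion is
applied where the analysis outcome is the disease endpoint (stages 1 and
3); in stage 2 the mediator occupies the outcome slot and no exclusion is
applied. Clumping consumes an explicit `LdMatrix`; when none is supplied
SNPs are treated as unlinked with a logged message — the correct behaviour
for the synthetic panels, which are generated without LD. The package
never downloads data and never computes LD from genotypes.

Harmonization follows the standard two-sample convention: allele-swapped
records flip the outcome effect's sign and complement its frequency;
strand flips are matched after complementing; palindromic (A/T, C/G)
variants are kept only when both allele frequencies are available, both
fall outside $0.5 \pm 0.08$, and they agree in orientation — otherwise
dropped, never guessed. The 0.08 band is a package convention (the
dominant community default), not a statement of the original screen.
Missing allele frequencies are an explicit `NA`, never 0 or 0.5.
P-value ties in clumping break by (chromosome, position, id) so every
run is deterministic.

# The synthetic generator

`simulate_three_trait_gwas()` emulates the two-sample structure of linked
GWAS: per-SNP instrument effects $\gamma_j \sim N(0, 0.05^2)$ on the
exposure, observed effect sizes with homoscedastic per-study noise
(`se_exp` and `se_med` 0.004, `se_out` 0.01 on the log-odds scale —
the order of magnitude of large-biobank GWAS), and causal propagation
with defaults $\theta_1 = 0.2$, $\theta_2 = 0.3$, direct effect
$\tau = 0.3$: true total effect $0.36$ and true proportion mediated
$100\times0.06/0.36 = 16.7\%$, with 30 SNPs per instrument block so
instruments are strong ($\gamma$ SD at least ten times the exposure SE).

One design point deserves emphasis: **each mediator gets its own
instrument block** — SNPs with direct effects $\delta$ on the mediator
that reach the outcome only as $\theta_2\delta$. Without them the
mediator's only "instruments" would be the exposure's SNPs, which are
invalid for the mediator → outcome step (the direct path $\tau$ reaches
the outcome around the mediator), and the step-two Wald ratio would
identify $(\tau + \theta_1\theta_2)/\theta_1$ instead of $\theta_2$.
Two-step MR is only coherent when mediators have instruments of their
own, and the generator reflects that.

Horizontal pleiotropy is layered on as per-SNP intercepts aligned with
the exposure-increasing allele: `balanced` draws $N(0, 0.01^2)$,
`directional` draws $N(0.05, 0.01^2)$, both independent of instrument
strength (InSIDE holds). Alleles come from non-palindromic pairs with
frequencies in $(0.05, 0.5)$, and SNPs are placed more than one clumping
window apart, so harmonization and selection are exact; the palindromic
and LD code paths are exercised by dedicated hand-built tests instead.
What the generator does *not* emulate: LD between instruments (optional
block structure was considered and dropped — clumping is tested against
an enumeration oracle on explicit LD matrices), eaf-dependent standard
errors, sample overlap between studies, and liability-scale case–control
sampling (binary outcomes are generated directly on the log-odds scale,
mirroring how FinnGen-style summary statistics are consumed). Passing
calibration on these synthetics therefore shows the estimators and gates
are implemented correctly, not that real metabolite GWAS meet the
assumptions.

# Numerical choices and degenerate inputs

* `beta_exp = 0` makes a Wald ratio degenerate: an error, not an `Inf`.
* One instrument: IVW falls back to the Wald ratio; Egger and the
  weighted median require three, MR-PRESSO four — each errors below its
  minimum rather than returning something ill-defined.
* Empirical p-values use $(1 + \#\{\cdot\})/(n_{sim}+1)$ and are never 0;
  analytic p-values are floored at `1e-300` to respect the $(0,1]$
  invariant under extreme signals.
* An exact linear relationship gives Egger a residual SD of ~0; the
  unscaled covariance is used directly so SEs stay finite.
* Duplicate SNP ids in one file keep the smallest p-value; rows violating
  record invariants are dropped and counted, with counts carried as
  provenance on every object.
* All stochastic components (`weighted_median`, `presso`, the generator)
  take explicit seeds, restore the caller's RNG state, and are
  bit-reproducible.

# Calibration results, and one honest caveat

The test suite and `scripts/acceptance.R` measure (rather than assume):
Cochran's Q rejecting at its nominal 5% under homogeneity; IVW 95% CI
coverage within the binomial 99% band of 95% over 500 clean replicates;
the Egger intercept averaging the planted 0.05 directional-pleiotropy
mean over 200 replicates while IVW is (as theory predicts) badly biased;
MR-PRESSO recalling a 10-SE planted outlier in effectively every seeded
replicate at `n_sim = 1000`; and the end-to-end pipeline recovering the
planted 16.7% proportion mediated to within 2 percentage points on
average over 200 replicates. `analysis/05_calibration.R` reruns a smaller
version of the same study and writes `results/calibration.tsv`.

The caveat: because the Q gate inflates standard errors in the ~5% of
null datasets that trip it, null IVW p-values are *slightly conservative*
rather than exactly uniform — visible as a small (<0.05) KS distance at
large family sizes. The suite asserts near-uniformity plus validity (no
anti-conservatism at the 5% level), which is what the gated estimator
actually guarantees.

# Packaged reference tables

`reference_tables()` ships the numeric columns of a published screen's
three result tables (176 BMI-associated metabolic traits, 85
cholelithiasis-associated traits, 49 mediators). `verify_fixtures()`
recomputes every derivable cell — OR and CI from $(\beta, se)$, Egger
intercept p from $(\hat\alpha, se, n)$, mediation effects as
$\beta_1\beta_2$ — and checks consistency *allowing for the printed
inputs' three-significant-figure rounding* (plain recomputation from
rounded inputs can legitimately move a p-value by several units in its
third significant figure). On the shipped tables all 666 checked cells
are consistent, the 49 mediators are exactly the intersection of the two
screens, and the total effect implied by effect/proportion is constant
across all 49 rows within 1% (mean 0.428 log-odds). The full-scale
screens themselves are not reproducible at desk scale — they require the
original GWAS downloads — which is exactly why the packaged arithmetic
and the synthetic calibration together form the package's evidence.

# Known limitations

Single-mediator decomposition only (no multivariable MR, no
mediator–mediator interactions); no Steiger directionality filtering,
MR-RAPS, or mode-based estimators; proportions mediated are reported
signed and unclamped (negative and >100% values pass through, flagged by
their sign, as the reference tables themselves contain negative
proportions); the delta-method (Sobel) SE attached to each mediation
effect is an extension beyond the reference screen, which reported none.
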