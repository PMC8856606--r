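---
title: "Methods: two-sample MR screening with mrscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening with mrscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrscreen)
```

## The model

Two-sample Mendelian randomization treats genetic variants as
instruments for an exposure. For instrument $j$ we observe an estimated
SNP–exposure effect $\hat\beta_{X,j}$ with standard error
$\sigma_{X,j}$ from one GWAS and a SNP–outcome effect $\hat\beta_{Y,j}$
with standard error $\sigma_{Y,j}$ from an independent GWAS. Under the
instrumental-variable assumptions (relevance, independence from
confounders, and exclusion — the variant affects the outcome only
through the exposure), each instrument carries the same causal signal:

$$\beta_{Y,j} = b\,\beta_{X,j},$$

and $b$ is the causal effect of the exposure on the outcome on the
standardized scale. All estimators in this package are different ways
of combining the per-instrument ratio information while tolerating
different violations of the exclusion assumption.

- **Wald ratio** ($k = 1$): $\hat b = \hat\beta_Y/\hat\beta_X$, with
  the first-order standard error $\sigma_Y/|\hat\beta_X|$.
- **IVW**: weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
  through the origin with weights $1/\sigma_Y^2$ — exactly the
  inverse-variance weighted average of the Wald ratios. It is the
  primary decision statistic, consistent only when no instrument is
  pleiotropic.
- **Profile maximum likelihood**: models both sides as normal around
  true effects $\gamma_j$ and $b\gamma_j$, propagating the
  SNP–exposure uncertainty that IVW conditions away. Profiling out
  $\gamma_j$ in closed form leaves a one-dimensional objective
  $\tfrac12\sum_j (\hat\beta_{Y,j} - b\hat\beta_{X,j})^2 /
  (\sigma_{Y,j}^2 + b^2\sigma_{X,j}^2)$, minimized numerically.
- **MR-Egger**: the same weighted regression with a free intercept,
  after orienting every instrument to $\hat\beta_X \ge 0$. The
  intercept estimates average directional pleiotropy; the slope is a
  causal estimate that remains consistent under the InSIDE assumption.
  Inference uses $t_{k-2}$.
- **Weighted median**: the 50% point of the weighted empirical
  distribution of ratio estimates, with first-order weights
  $\hat\beta_X^2/\sigma_Y^2$; consistent while less than half the
  weight is pleiotropic. Its standard error comes from a parametric
  bootstrap (betas redrawn around their observed values).

IVW and Egger use a *multiplicative random-effects* dispersion: the
fixed-effect standard error is scaled by the residual standard
deviation floored at 1, so over-dispersion (heterogeneity) widens the
interval but under-dispersion never narrows it. A fixed-effect IVW is
available by flag. With a single instrument the IVW formula reduces
algebraically to the Wald ratio, so `mr_ivw()` accepts $k = 1$ rather
than erroring.

## Instrument processing

Candidate instruments are selected at $P < 10^{-5}$ (strict
inequality), the conventional suggestive threshold for small-sample
exposure GWAS such as microbiome meta-analyses. Clumping is the
PLINK-style greedy procedure: repeatedly take the smallest-$p$
unselected SNP as an index (ties broken by chromosome, position, then
identifier, making the output deterministic) and discard unselected
SNPs on the same chromosome within 500 kb with $r^2 \ge 0.1$ against
the index. A distance strictly greater than the window never triggers
the $r^2$ check. SNPs absent from the LD reference are retained as
their own index with a warning (mirroring common practice when a
reference panel lacks a variant); a strict mode drops them instead.

Palindromic SNPs (A/T or C/G) are deleted outright before
harmonization, whatever their allele frequency. Because of this,
harmonization never needs frequency-based strand inference: outcome
alleles either match the exposure's pair (kept), match it swapped
(outcome beta negated, frequency reflected), match after complementing
both outcome alleles (strand flip, kept), match swapped after
complementing (negated), or are irreconcilable (dropped as ambiguous).
Any identifier appearing more than once in either input has all copies
removed — the conservative reading of "duplicated SNPs removed".

Instrument strength is summarized by the variance explained per SNP,
$2f(1-f)\beta^2$ for a standardized trait with effect-allele frequency
$f$, their sum $R^2$, and

$$F = \frac{R^2\,(n - 1 - k)}{(1 - R^2)\,k},$$

with $F < 10$ flagged as weak. When per-SNP sample sizes differ the
minimum exposure-side $n$ enters $F$ (a conservative choice; in
practice $n$ is constant within a GWAS). An optional confounder filter
removes instruments nominally associated ($P < 0.05$) with any trait in
a user-supplied SNP × trait p-value table, mirroring the practice of
excluding instruments linked to chronic bowel disease when screening
gut-microbiota exposures.

## Sensitivity analyses

**Heterogeneity.** Cochran's $Q$ around the IVW fit
($\mathrm{df} = k-1$) and Rücker's $Q'$ around the Egger fit
($\mathrm{df} = k-2$), both with weights $1/\sigma_Y^2$ and upper-tail
chi-square p-values. $Q' \le Q$ always, since the Egger fit nests IVW.

**Leave-one-out.** The IVW estimate recomputed omitting each
instrument in turn; a causal signal carried by a single SNP shows up as
one omission shifting the estimate far more than the rest.

**Steiger directionality.** The instruments should explain more
variance in the exposure than in the outcome if the causal arrow points
forward. Both sides use the same $2f(1-f)\beta^2$ formula; the p-value
compares the implied correlations $\sqrt{R^2}$ on Fisher's $z$ scale at
the two sample sizes. The comparison is strict: equal variances do not
certify the forward direction. The same formula is applied to binary
outcomes (on their standardized scale); a liability-scale refinement is
deliberately out of scope.

**MR-PRESSO.** The global test measures whether the weighted residual
sum of squares around leave-one-out IVW fits,
$\mathrm{RSS} = \sum_j w_j(\hat\beta_{Y,j} - \hat b_{(-j)}\hat\beta_{X,j})^2$,
is larger than expected under a no-pleiotropy parametric simulation;
the per-SNP outlier test compares each observed weighted residual to
its simulated distribution. P-values use the add-one estimator
$(1 + \#\{\text{sim} \ge \text{obs}\})/(n_{\mathrm{sim}}+1)$, so with
the default $n_{\mathrm{sim}} = 1000$ the smallest attainable p-value
is $1/1001$ — worth remembering when reading "p = 0.000999". Outlier
p-values are Bonferroni-adjusted by $k$ for reporting; the pruning
recursion ranks SNPs by the raw values.

The pruning loop follows the screening procedure literally: if the
initial global test is significant ($P \le 0.05$; equality continues
pruning), SNPs are sorted once by ascending initial outlier p-value
and removed one at a time in that fixed order, re-running the global
test after each removal, until it becomes non-significant. Re-ranking
after each removal is available behind a flag but is not the default.
Because many SNPs can saturate at the $1/(n_{\mathrm{sim}}+1)$ floor,
ties in the ranking are broken by the observed weighted residual,
largest first — without this, the removal order among tied SNPs would
be arbitrary and genuine outliers could be passed over. Pruning that
would leave fewer than four instruments (the minimum for the global
test) while still significant raises an error: the pair is reported as
un-correctable rather than silently truncated. The "outlier-corrected"
estimate is the plain IVW fit on the survivors; the original
distortion-style re-estimate is a possible alternative but is not what
the screen reports.

## The screen and multiple testing

`run_screen()` composes the full pipeline per exposure–outcome pair —
select, clump, drop palindromes, harmonize, optionally
confounder-filter, PRESSO-prune (when $k \ge 4$), estimate by every
applicable method, and run the sensitivity suite. Pairs failing a
precondition carry a status code (`no_instruments`,
`presso_unavailable`, `presso_uncorrectable`, ...) and keep their row.
Every stochastic step derives its seed deterministically from the
config seed plus the pair index, so identical config and inputs give
identical tables.

Significance uses per-taxonomic-level Bonferroni thresholds
$0.05/n_\ell$, where $n_\ell$ is the number of taxa *tested* at level
$\ell$. The printed divisors in the motivating study equal the raw
per-level taxa counts, so raw counts are the default; an effective
number of independent taxa can be supplied instead by passing adjusted
counts to `level_thresholds()`. The reverse screen applies one flat
threshold $0.05/(\text{number of reverse pairs})$, since the reverse
direction tests a single family of pairs rather than per-level
families. Alongside the IVW decision, each row annotates how many
complementary methods (MLE, Egger, WME, PRESSO-corrected) agree with
the IVW sign and are nominally significant — the "cross-validated by
more than two tests" notion.

## The synthetic generator

`simulate_pair()` emulates the statistical structure of the real
screening setting without any downloads:

- standardized-trait standard errors
  $\sigma = 1/\sqrt{2f(1-f)n}$ on both sides, with default sample
  sizes 18,473 (exposure; the scale of current microbiome GWAS
  meta-analyses) and 46,351 (outcome; a typical large case-control
  psychiatric GWAS);
- true instrument effects with per-instrument variance shares drawn
  uniformly in $[0.8, 1.2]$ and rescaled so
  $\sum_j 2f_j(1-f_j)\gamma_j^2$ equals the target $R^2$ *exactly*
  (default 2.61%, a realistic mid-range value). Keeping the shares
  roughly even means every planted instrument's expected association
  clears the $10^{-5}$ selection threshold — the generator plants
  instruments a real selection step would have found, and winner's
  curse is deliberately not corrected;
- pleiotropy regimes: none, balanced ($\alpha_j \sim N(0, s^2)$),
  directional ($\alpha_j \sim N(s, (s/2)^2)$), and outliers (a chosen
  fraction of instruments shifted by $\pm 10$ outcome standard
  errors);
- AR(1) LD blocks (default 10 SNPs, $\rho = 0.5$, $r^2 =
  \rho^{2|i-j|}$), one pseudo-chromosome per block, 10 kb spacing, so
  window logic is exercised; instruments occupy block heads first so
  clumping retains them when possible;
- optional fractions of palindromic allele pairs, strand-flipped
  outcome records, and duplicated identifiers, all recorded in the
  returned truth object.

What the generator does *not* emulate: logistic-scale effects for
binary traits (everything is standardized linear), multi-ancestry
allele-frequency structure, cross-cohort heterogeneity within a
meta-analysis, and realistic 16S abundance distributions. Passing
simulation-based tests therefore demonstrates the pipeline's
statistical correctness under its stated model, not robustness to
those real-data complications.

## Numerical choices

- Two-sided p-values throughout, floored at the smallest positive
  double rather than 0.
- MLE: optimization bracket $b \in [-50, 50]$ (standardized effects
  make $|b| \gg 10$ implausible), convergence tolerance $10^{-10}$,
  standard error from a central-difference curvature of the profile
  log-likelihood with step $\max(10^{-4}, |b|\cdot 10^{-4})$; a
  solution at the bracket edge or non-positive curvature is an error,
  not a result. A dense grid search over the profiled likelihood (in
  its un-profiled $\gamma_j$ form) serves as the independent
  cross-check in the tests.
- Weighted median: linear interpolation of the centered cumulative
  weight function at probability 1/2; values outside the first/last
  midpoint return the extreme ratio. Bootstrap seeded by the caller;
  `n_boot = 0` returns the point estimate alone.
- The write path prints 17 significant digits so write/read round
  trips are bit-exact.
- Degenerate inputs error early and specifically: $\beta_X = 0$ for a
  Wald ratio, all-zero $\beta_X$ for IVW, frequencies outside
  $(0, 1)$, $n \le k + 1$ in the F statistic, empty harmonized
  intersections.

## Problem sizes used in the test suite

Calibration and recovery checks run at the study's scale where that is
cheap (type-I error: 1000 null replicates at $k = 20$; effect
recovery: 1000 replicates per scenario across true effects from
$-0.46$ to $0.24$ with instrument counts and $R^2$ matched to the
identified associations; Steiger orientation: 500 replicates; PRESSO
detection: 200 runs; pruning exactness: 100 runs at
$n_{\mathrm{sim}} = 1000$). Screen-level benches use 12 features × 3
outcomes with scaled-down PRESSO/bootstrap replicate counts, sizes
chosen so the whole suite runs in about a minute while keeping
Monte-Carlo error well below the margins being asserted.

## Known limitations

- MR-Egger and the weighted median are *conservative* under the null
  here: the dispersion floor and the bootstrap standard error
  over-cover slightly (empirical type-I error around 0.02–0.03 at
  nominal 0.05 with $k = 20$), which is the standard behavior of these
  estimators, at the cost of power. IVW and the MLE are
  well-calibrated.
- No proxy-SNP lookup: instruments absent from the outcome GWAS are
  simply lost at harmonization.
- No correlated-instrument (generalized) IVW; clumping is assumed to
  have made instruments approximately independent.
- Binary traits are treated on the standardized scale throughout,
  including in Steiger's variance comparison.
- The MR-PRESSO distortion test and Egger-SIMEX are not implemented;
  neither enters the screen's reported decisions.
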