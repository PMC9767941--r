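---
title: "Combining correlated GWAS summary statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining correlated GWAS summary statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(cgwas)
```

## The problem

A study that measures many related phenotypes in (partly) the same
individuals produces K correlated GWASs. Testing each variant against the
null "no effect on **any** trait" with more power than the per-trait minimum
p-value requires dealing with two distinct correlation structures:

* the **background correlation** $\psi$ (matrix $\Psi$): the correlation of
  the studies' T statistics *under the null*, driven by sample overlap and
  non-genetic phenotype correlation. For two studies of sizes $N_1, N_2$
  sharing $N_c$ individuals with residual phenotype correlation $\rho$,
  $\psi = \rho\,N_c/\sqrt{N_1 N_2}$;
* the **effect correlation** $\pi$ (matrix $\Pi$): the correlation of the
  *true* per-variant effects across the genome.

The package combines K summary-statistics tables into a single genome-wide
p-value vector that is uniform under the null — directly comparable with any
standard GWAS — while exploiting $|\Pi - \Psi|$ for power. Only summary
statistics are needed; all estimators are LD-free (they operate on
approximately unlinked variant subsets obtained by systematic sampling).

## The combination statistic

For one variant with statistic vector $\mathbf t$, standard errors
$\sigma$ and precision vector $e = 1/\sigma$, the effect-based inverse
covariance weighted (EbICoW) statistic is

$$
t_E \;=\; \frac{(h \circ e)^{\mathsf T}\, \Psi^{-1}\, \mathbf t}
{\sqrt{(h \circ e)^{\mathsf T}\, \Psi^{-1}\, (h \circ e)}},
$$

a weighted linear combination that is standard normal under the null
*regardless of the effect vector* $h$ — $h$ moves power only. Three
constructions of $h$ are carried along and chosen between by a data-driven
rule (`optimize_pair()`):

* `all` — from the genome-wide second-moment excess
  $H = (Z - \Psi)\circ\sigma\sigma^{\mathsf T}$ with
  $Z_{ij} = \mathrm E(t_i t_j)$, best under polygenicity;
* `sig` — the same excess computed on Wald-significant variants only
  (threshold `L`, default $10^{-5}$), with $\Psi_{\text{nosig}}$ from the
  rest; aimed at major-gene architectures;
* `stb` — all-ones effect correlation with
  $h_k \propto \sigma_k\sqrt{Z_{kk}-1}$, a stable fallback when $H$ is
  noisy.

Direction matters: when $\pi < \psi$ the anti-correlated combination is more
powerful, so $h = \operatorname{sign}(\Pi-\Psi)_k\,H$ with
$\operatorname{sign}(0)=+1$. Setting $\Psi = I$ and $h \propto \mathbf 1$
recovers classical inverse-variance-weighted meta-analysis; keeping general
$\Psi$ with $h \propto \mathbf 1$ gives the homogeneous-effect statistic
whose square is the 1-df chi-squared S_Hom.

When $|\Pi - \Psi|$ is small the Wald test
$t^{\mathsf T}\Psi^{-1}t \sim \chi^2_K$ is the better tool, since it does not
depend on $\Pi$ at all. The pipeline therefore uses both.

## The iterative pairwise loop

`iterative_ebicow()` repeatedly picks the study pair with the largest entry
of $D = |\Pi - \Psi|$ (above the floor `F = 0.05`), builds the three
candidate combinations, and accepts the winner only if it *demonstrably
dominates* a set of comparators — the pair Wald test, the Tippett-normalized
pair minimum p, and each input study alone — on a grid of probe thresholds
$10^{-3}\dots10^{-6}$, and passes a null-calibration check. Design choices
worth knowing:

* **Acceptance margin.** The loop screens up to $K(K-1)/2$ pairs, three
  data-adapted candidates each, so a plain "counts at least as large"
  dominance rule fires on noise in a substantial fraction of pure-null
  panels. The aggregate excess over the probe grid must instead clear a
  Poisson-scale z-value chosen for a ~1% familywise false-acceptance rate
  per panel ($z = \Phi^{-1}(1 - 0.01/3n_{\text{pairs}})$). Measured on 40
  pure-null panels (K = 10, M = 50{,}000): zero spurious acceptances, while
  clearly beneficial pairs (fully correlated effects over $\psi=0.5$, or
  $\pi = 0.9$ over $\psi = 0$) are accepted.
* **Per-input dominance.** Without it, pairing a strong study with an
  unrelated null study is "accepted" with near-zero weight on the null
  study: the result is statistically identical to its stronger input and
  brings no pairwise gain, but trivially beats the Wald and minimum-p
  comparators.
* **Null-calibration check.** The mean of $t_E^2$ over the non-significant
  stratum ($p \ge 0.01$) is compared with its truncated $\chi^2_1$
  expectation (band 0.95–1.05). Genuine sub-threshold signal inflates any
  fixed stratum, so an out-of-band value escalates to the mixture-model
  inflation fit (below), which separates a causal minority from a mis-scaled
  null.
* **Forced combinations.** Pairs with $\psi^2 > 0.5$ make $\Psi$
  ill-conditioned and are combined unconditionally — with the
  *homogeneous* form ($h \propto \mathbf 1$). Near collinearity amplifies
  any estimated asymmetry of $h$ by roughly $1/(1-\psi)$ into a pure-noise
  contrast: with three nearly identical cohort GWASs, the estimated-$h$
  combination correlated only 0.93 with the pooled-sample GWAS, the
  homogeneous form 0.999.
* **Background updates in closed form.** A combined statistic is a linear
  map of the input statistics, so its background correlation with every
  remaining study follows exactly from the representative combination
  coefficients; $\Psi$ is estimated once and updated analytically (the
  coefficient matrix is returned for null replay). With constant per-study
  standard errors this is exact; with strongly variant-specific standard
  errors it is a median-weight approximation.

## The truncated Wald scan and its calibration

For each variant, `twt_genome()` performs the Wald test on every nested
subset defined by p-value thresholds $r_q = 10^{-q/3}$, $q = 1\dots18$, plus
the single-best-study column ($\min p$), giving an $M \times (Q{+}1)$ matrix
of subset p-values (missing where a subset is empty). The winning subset per
variant is chosen *after* making the columns comparable:

1. **Effective test numbers.** `estimate_n_independent()` fits, per column,
   the `Neff` that makes the Tippett transform $1-(1-p)^{N_{\text{eff}}}$
   map the column's simulated-null quantiles onto the uniform, by least
   squares on the log scale over levels $10^{-1}$ down to the depth the
   simulation supports. Empty subsets count as $p = 1$ ("no evidence"), so
   the fit is unconditional — a rarely non-missing deep column converges to
   the min-p column's correction rather than to no correction. (Fitting the
   conditional distribution instead leaves deep columns unpenalized and
   collapses the scan's ranking toward the raw minimum p; we measured a
   2–4 point power loss that way.)
2. **Quantile coefficients.** The row minima of the adjusted matrix are
   still not uniform (a minimum over dependent columns never is), so
   `fit_quantile_coefficients()` maps the simulated null minima onto the
   uniform on a dense log-spaced quantile grid, mirrored toward $u = 1$
   where the null CDF is strongly curved. The application is value-indexed
   (log–log interpolation of the uniform level over the null quantile), so
   the map is strictly monotone and preserves significance order; beyond
   the deepest stable grid point ($30/N_S$) the tail continues with the
   constant log–log slope fitted on the deepest decade. Grid points are
   never anchored on single extreme order statistics, which are
   stochastically small and would make the tail conservative.

With $N_S = 10^6$ null draws, the final p-values of pure-null panels
(K = 10, M = 50{,}000, $\psi \in \{0, 0.5\}$) pass Kolmogorov–Smirnov
uniformity and the study-wide type-I error at the Bonferroni threshold
$0.05/M$ is 3–5% over hundreds of replicates. Production applications
should scale $N_S$ to at least 100 times the number of independent
variants; quantiles below the simulation's resolution are slope-extrapolated
and the run report flags this.

## Estimators

**Inflation (`estimate_inflation`).** Squared statistics are modeled as the
mixture $(1-p)\,(1{+}I)\chi^2_1 + p\,(1{+}I{+}\Lambda)\chi^2_1$ with moments
$\mathrm E(t^2) = 1 + I + p\Lambda$ and
$\operatorname{Var}(t^2) = 2\mathrm E(t^2)^2 + 3\Lambda^2 p(1-p)$. For each
candidate $I$ the pair $(\Lambda, p)$ follows from the observed moments; $I$
is chosen by matching the implied mixture CDF to the empirical lower
quantiles (levels 0.1–0.5), where contamination by true effects is minimal.
Two numerical points: (i) when the fitted mixture degenerates
($p \to 1$) the objective is exactly flat along $I + p\Lambda = $ const, so
a monotone penalty of order $1/M$ resolves the ridge toward the largest $I$
— inflation is by definition the scale shared by *all* variants — and any
fitted "effect" component carried by $\ge 95\%$ of variants is folded into
$I$; (ii) unlike the genomic-control median ratio, the estimate is unbiased
under polygenic effects (measured: $|\hat s - s| < 0.02$ on average for
$s \in \{1, 1.1, 1.2\}$ with 10% causal variants of variance 3, where
$\lambda_{GC}$ is biased upward by 0.1–0.3). Statistics are adjusted as
$t/\sqrt{s}$, standard errors as $\sigma\sqrt{s}$.

**Background correlation (`estimate_psi`).** Starting from the crude
correlation, iterate: keep variants whose joint 2-df form
$(t_1,t_2)\Psi_0^{-1}(t_1,t_2)^{\mathsf T}$ has upper-tail probability above
0.5 under the current estimate, recompute the correlation on the kept set,
stop at $|\Delta\psi| \le 10^{-4}$. Truncation by the elliptical form
preserves the correlation under the null, so the estimate is unbiased with
no or cross-study-independent true effects (measured $|$bias$| < 0.01$ at
M = 100{,}000). A limitation worth stating: when the contaminating effects
are themselves strongly correlated across studies ($\pi = 0.8$, 10% causal,
variance 3), a residual bias of about $+0.02$ at $\psi = 0$ remains — the
retained "insignificant" set still carries a genuinely shared effect
component that no null-based estimator can fully remove at finite M. The
naive all-variant correlation is an order of magnitude worse in the same
setting.

**Effect correlation (`estimate_effect_model`).** $Z$ is the uncentered
second-moment matrix of the statistics; $\Pi$ is the correlation form of
$Z - \Psi$ with diagonals floored at $10^{-3}$ (a study with
$\mathrm E(\chi^2) < 1.001$ would otherwise make the normalization blow
up). Under the null, $\hat\Pi$ off-diagonals are noise amplified to $\pm 1$
by the floor — which is why the iterative loop's accept/reject decision,
not $D$ alone, carries the type-I control.

## The synthetic-data generators

`simulate_summary_scenario()` draws null statistics from
$N(0, \Psi)$, adds per-study $N(0, I_k)$ inflation, and gives the first
$\lfloor pM \rfloor$ variants an effect draw from
$N(0, \Pi \circ \theta\theta^{\mathsf T})$, so study k's mean chi-squared is
$1 + p\theta_k^2 + I_k$ by construction. Variants are independent — the
generator emulates the unlinked-subset world in which the estimators
operate, not LD structure; passing tests therefore say nothing about
LD-induced miscalibration, clumping, or winner's curse in real panels.
Defaults mirror the study conditions used throughout the tests:
M = 50{,}000, 10% causal, $\theta^2 = 3$ (mean $\chi^2 = 1.3$).

`simulate_overlap_cohorts()` builds individual-level data: synthetic
genotypes Binomial(2, f) with $f \sim U(0.05, 0.5)$ at 20{,}000 independent
variants for 2{,}000 individuals, a phenotype in which 1% of variants
explain 10% of the variance, and three cohort GWASs by least squares under
a configurable overlap pattern (disjoint 20/30/50% splits; partial 50/70/80%
subsets; "full" = 99.5% subsets, so the cohorts are nearly but not exactly
identical and concordance with the pooled-sample GWAS is a non-trivial
check). Passing `cohort_sizes = rep(n, 3)` gives exactly identical cohorts.

`run_power_study()` compares the effect-weighted combination, the Wald
test, the calibrated truncated scan, and the calibrated minimum p at a
common per-variant threshold, sharing one calibration per configuration.
Replicate counts default to desk scale (100 rather than 1000); the
acceptance tests use M = 50{,}000 with 100 replicates per configuration and
$N_S = 10^6$, sizes chosen so the whole suite completes on a single CPU.

## Post-hoc statistics

`mte()` scores how *spread* a significant variant's effect is across
independent trait directions: project $\mathbf t$ onto the top eigenvectors
of $\Psi$ covering 95% of its trace, scale to unit null variance, and return
$2\sqrt2$ minus the skewness of the squared projections (squared null
projections are 1-df chi-squares with skewness exactly
$(15-6-1)/2\sqrt2 = 2\sqrt2$). Negative values mean no evidence of a
multi-trait effect. Finite-R caveat: the sample skewness of R values is
bounded by $(R-2)/\sqrt{R-1}$, so the null MTE mean is *positive* at finite
R (about $+1.6$ at R = 9) and negative values are impossible altogether for
R < 11; the statistic is reported uncorrected, and comparisons should be
made at fixed R.

`power_gain_ratio()` is the mean-chi-squared excess ratio
$(\mathrm E(\chi^2_a) - c_a)/(\mathrm E(\chi^2_b) - c_b)$ with
confounding intercepts $c$ supplied externally (e.g. LD-score regression
intercepts — intentionally out of scope here). `fisher_combined()` is the
classical $-2\sum\log p \sim \chi^2_{2N}$ replication test.
`derive_studywide_threshold()` converts a conventional genome-wide level
into the equivalent raw-scale threshold by multiplying with the pipeline's
effective-test and calibration-coefficient burdens.

## Known limitations

* Variants are treated as independent throughout; LD pruning/clumping and
  LD-score-based estimation are out of scope, and intercept-style inputs
  are accepted rather than estimated.
* The background-correlation estimator retains a small positive bias under
  strongly cross-correlated polygenic contamination (above).
* The truncated scan pays a genuine multiplicity cost for its subset search
  (a minimum over 19 dependent columns); in configurations where the full
  study set is already the best subset and the background correlation is
  substantial, the plain Wald test can be a few power points stronger.
* With heavily variant-specific standard errors, the closed-form background
  updates inside the iterative loop use representative (median) weights;
  re-estimating $\Psi$ from the combined statistics is the fallback when
  that approximation is a concern.
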