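---
title: "Methods: environmental-correlation scans under a population-structure null"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: environmental-correlation scans under a population-structure null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(ecoscan)
```

## The inference problem

Populations that live along an environmental gradient differ in allele
frequency at most loci simply because they differ in history: drift
accumulates along the population tree, and migration makes nearby
populations similar. A locus under spatially varying selection adds a
systematic component on top of this — its frequency tracks the environment
more closely than history alone predicts. The scan implemented here asks,
per SNP and per environmental variable, how much better a linear
environmental effect explains the observed frequencies than population
structure alone, and then converts that evidence into rank-based statistics
robust to the null's inevitable misspecification.

## Null model and Bayes factor

Counts $k_l$ of $n_l$ chromosomes in population $l$ are summarized by the
pooled frequency $\hat\varepsilon$ and standardized deviations
$y_l = (k_l/n_l - \hat\varepsilon)/\sqrt{\hat\varepsilon(1-\hat\varepsilon)}$.
The null treats $y$ as multivariate normal with covariance
$\Sigma = \hat\Omega + D$: $\hat\Omega$ captures correlated drift, $D_{ll} =
1/\bar n_l$ the binomial sampling noise. This Gaussian approximation to
drift is the model's central assumption; it degrades near frequency 0 or 1,
which is one reason inference downstream uses ranks, not BF magnitudes.

Three modelling choices deserve comment.

**Moment estimation of $\hat\Omega$.** We use the raw second-moment matrix
of $y$ over a seeded random subset of control SNPs (default 20,000 per
ascertainment panel; at least $\max(500, 5L)$ required), computed
pairwise-complete over masked genotypes, minus $D$, then projected to
positive semi-definiteness by flooring eigenvalues at $10^{-6}$ times the
mean positive eigenvalue. A full Bayesian treatment would sample $\Omega$
by MCMC; the deterministic moment estimator is orders of magnitude faster,
reproducible, and adequate for a null whose job is to absorb structure —
the oracle tests on the Bayes factor guard the combination. Note an
identifiability limit: because $\hat\varepsilon$ is estimated from the same
populations, the component of drift shared by all populations (the
sample-size-weighted mean direction) is absorbed into the reference and
cannot be recovered. $\hat\Omega$ therefore estimates covariance *relative
to the weighted mean*; every consumer of $\hat\Omega$ in the package uses
the same transform, so the reference cancels, and estimator-accuracy tests
measure error after projecting that direction out.

**Conjugate effect prior.** The alternative shifts the mean of $y$ by
$\beta z$, $z$ the variable standardized over the population set (mean 0,
denominator-$L$ sd, making the BF exactly invariant to affine changes of
raw units). With $\beta \sim N(0, \tau^2)$ the marginal likelihood ratio is
closed-form:
$\mathrm{BF} = (1+\tau^2A)^{-1/2}\exp\{\tau^2b^2/(2(1+\tau^2A))\}$ with
$A = z^\top\Sigma^{-1}z$, $b = z^\top\Sigma^{-1}y$. The default prior scale
$\tau = 1$ places the effect on the same standardized scale as drift;
because $A$ is constant within a panel and variable, any fixed $\tau > 0$
yields the same within-bin ranks (the BF is monotone in $b^2$), so the
choice affects reported magnitudes, not downstream inference. A test
verifies the closed form against brute-force trapezoid integration over
$\beta$ to relative error below $10^{-6}$.

**Plug-in $\hat\varepsilon$.** We do not integrate over the ancestral
frequency; the pooled estimate is plugged in. This is the second deliberate
simplification relative to a full MCMC treatment, again traded for
determinism and speed, and again covered by rank-level calibration tests.

SNPs monomorphic within the analyzed population set carry no information
and are flagged and excluded from covariance estimation, scanning and
ranking (a SNP may be scanned worldwide yet excluded in a subset).

## Ranks, bins and tie-breaking

BF magnitudes are comparable only among SNPs with similar ascertainment and
frequency, so ranking is stratified: bins are the cross of ascertainment
panel and derived-allele-frequency tenth (equal-width, half-open
$[j/10,(j+1)/10)$; frequency 1 goes to the top bin) — 30 bins when 3 panels
have all tenths occupied. Within each bin and variable, SNPs are sorted by
decreasing BF with ties broken by ascending SNP id (determinism over
average-rank conventions), and the SNP at rank $r$ of $N$ gets
$q = r/N \in (0,1]$. We use $r/N$ rather than $(r-1)/(N-1)$ so the best
possible rank is $1/N$ — of order $10^{-5}$ in genome-scale bins — and zero
never occurs. Occupied bins with fewer than 50 SNPs are merged into the
adjacent lower-frequency bin (recursively; an undersized lowest bin merges
upward), with each merge reported. The per-SNP minimum of $q$ across
variables condenses the nine tests into one statistic for "climate as a
whole"; under independence its CDF would be $1-(1-q)^V$, a closed form used
to test the machinery.

For comparison against GWAS catalogs (discovered mostly in European-ancestry
cohorts), ranks can be recomputed with binning on the pooled frequency of a
reference region (`region_frequencies()`, default `Europe`), and catalog
SNPs are retained when some variable's rank is below $5\times10^{-4}$ and
the reported association p-value is below $10^{-5}$ (both strict).

## Tail enrichment and the block bootstrap

For disjoint SNP classes $A$ (e.g. genic) and $B$ (nongenic), the tail
ratio at cutoff $c$ is the class-conditional tail rate ratio
$\frac{|A\cap\{q\le c\}|/|A|}{|B\cap\{q\le c\}|/|B|}$, identical
algebraically to the tail-composition ratio normalized by genome-wide
composition. Cutoffs default to 5%, 1% and 0.5%. Because selected SNPs
cluster by linkage, significance comes from resampling 500-kb half-open
genome windows, not SNPs: each of 1000 replicates draws, with replacement
from the occupied windows, a number of windows equal to the spanned genome
length divided by 500 kb (the occupied-window restriction keeps replicate
sizes comparable; the draw count follows the genome length), pools their
SNPs with multiplicity, and recomputes the ratios. An enrichment is called
significant (one-tailed) when at least 95% of replicates have ratio above
1, with tiers at 95/97.5/99%. Replicates whose denominator tail is empty
are counted as *not* enriched — the conservative resolution of an ambiguous
corner — and their count is reported. Windows are resampled genome-wide
(not within chromosome), and no multiplicity correction is applied across
gene sets; both choices are deliberate and the latter is a known caveat of
the approach. Gene-set enrichment uses the same machinery with numerator
"SNPs of the set's genes" against denominator "all other genic SNPs".

## What the synthetic generator emulates

The generator is the scan's generative twin, by design: latent population
frequencies are drawn from the same Gaussian drift model the scan assumes
(mean $\varepsilon + \beta z\sqrt{\varepsilon(1-\varepsilon)}$, covariance
$\varepsilon(1-\varepsilon)\Omega_{true}$), clipped to
$[1/(2\bar n), 1-1/(2\bar n)]$, then observed through binomial sampling.
Parameter recovery is therefore a meaningful end-to-end test of the
estimators, not of a foreign simulator. Its components:

- **Structure**: $\Omega_{true}$ comes from random ultrametric
  (coalescent) trees — a region backbone (7 regions, mean root-to-tip depth
  0.05) with shorter within-region subtrees (depth 0.015), so populations
  of a region are more correlated than populations across regions and every
  population carries the same total drift, as under a molecular clock. The
  total depth (~0.065) is in the range of worldwide human array data, whose
  ascertainment deflates apparent drift variance.
- **Environments**: each of 9 climate-like variables is
  $\rho \cdot (\text{draw with covariance } \Omega_{true}) +
  (1-\rho)\cdot\text{noise}$, mapped to native-looking units by a fixed
  affine transform. $\rho$ (default 0.5) is the structure–environment
  confounding knob; $\rho = 1$ is the worst case where migration history
  mimics a climate gradient.
- **Ascertainment**: 3 panels with different Beta distributions for
  $\varepsilon$, clamped to $[0.15, 0.85]$. Array SNPs are discovered in
  small panels and are overwhelmingly common; the clamp also keeps the
  Gaussian drift draw from piling mass on the frequency boundaries, i.e.
  keeps the generator inside the validity region of the very approximation
  it shares with the scan (with a permissive clamp, boundary truncation
  distorts a material fraction of the drift variance and the generator
  contradicts its own model).
- **Effects**: a configurable fraction of SNPs (default 5%) receives a
  linear effect on one uniformly chosen variable, scaled in units of the
  per-SNP drift SD (default scale 1: selection on the order of drift;
  `beta_kind = "fixed"` plants exact-magnitude effects for power studies).
  A warning fires when effect sizes are so large that clipping of
  effect-SNP frequencies exceeds the pure-drift baseline by more than 10
  percentage points.
- **Annotations**: classes (nongenic/genic/nonsynonymous, defaults
  0.55/0.42/0.03) are drawn per SNP, with effect SNPs reweighted by
  configurable relative risks; consecutive genic SNPs form genes (5 per
  gene, keeping genes local, as the block bootstrap assumes), and
  designated gene sets oversample genes containing effect SNPs.

What it does *not* emulate: linkage disequilibrium within blocks (SNPs are
conditionally independent given coordinates), admixture or migration events
off the tree, real geography, Wright–Fisher dynamics at the boundaries, or
realistic ascertainment of the frequency spectrum. Passing tests therefore
demonstrate internal consistency and statistical calibration of the
pipeline under its own assumptions — not performance on real genotype data,
where the null is only an approximation.

## Numerical and degenerate-input conventions

- Coordinates are 0-based; blocks are half-open `[start, start + 500000)`;
  missing per-SNP genotypes are encoded by reduced $n_l$ and masked in the
  standardization, with pairwise-complete covariance averaging.
- The PSD floor ($10^{-6}\times$ mean positive eigenvalue) also absorbs the
  near-null eigendirection created by the mean-reference identifiability
  limit; $\Sigma = \hat\Omega + D$ is then strictly positive definite.
- $\tau = 0$ returns BF $= 1$ exactly. Constant variables within a
  population set are skipped with a warning. Classes with no SNPs are
  errors; tails with an empty denominator return an undefined-flagged
  ratio.
- All generators and resampling loops are pure functions of (config, seed).

## Problem sizes in the test suite

The acceptance-style tests run the full pipeline at the generator's default
scale — 60 populations, 20,000 SNPs, 9 variables, 1000 bootstrap replicates
— across 20 seeds per property, with smaller configurations (24
populations, 1,500–6,000 SNPs) for unit-level checks; these sizes exercise
the 30-bin stratification and the 500-kb block machinery while keeping a
full run in minutes on one core. The planted-effect recovery check uses 5
effect SNPs per replicate at 5× the drift scale so that per-SNP recovery is
not confounded by two planted SNPs competing for the top rank of the same
bin and variable.

## Known limitations

- BF magnitudes inherit every misspecification of the null (Gaussian drift,
  plug-in $\hat\varepsilon$, estimated $\hat\Omega$) and are not comparable
  across variables; use ranks.
- The covariance null cannot represent admixture-driven structure that is
  poorly approximated by any PSD matrix on the standardized scale, nor can
  any method distinguish selection along a gradient from unmodeled history
  perfectly collinear with it.
- Equal-width frequency bins (not deciles of the realized spectrum) are the
  literal stratification; with strongly skewed spectra several bins merge.
- The bootstrap treats 500-kb windows as exchangeable genome-wide; long-range
  LD and chromosome-scale features are outside its resolution.
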