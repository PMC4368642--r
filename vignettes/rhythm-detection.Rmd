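---
title: "Rank-based rhythm detection with an empirical null"
author: "rhythmscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rank-based rhythm detection with an empirical null}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmscan)
```

## The model

A genome-wide expression time series is a short vector of measurements at
zeitgeber times (hours after lights-on), usually with few points per period
and few or no replicates. `rhythmscan` tests each series against a family
of reference waveforms using the Kendall rank correlation

$$\tau(\vec x,\vec y)=\frac{\sum_{1\le i<j\le n}
  \operatorname{sgn}(x_j-x_i)\,\operatorname{sgn}(y_j-y_i)}{n(n-1)/2},$$

with $\operatorname{sgn}(0)=0$ and every pair included. Because only rank
order matters, the references are triangle waves: value $1$ at the phase
$\phi$ (the time of the peak), a linear fall to $-1$ over the *asymmetry*
$a$ hours, and a linear rise back over the remaining $T-a$ hours. The
symmetric case $a = T/2$ orders samples exactly like a cosine; other values
capture sawtooth-like expression profiles (rapid fall / slow rise or vice
versa) that a cosine reference misses. Per series the method reports the
maximal $\tau$ over the family and the arg-max $(\phi, a)$.

The maximum over $m$ hypotheses is not distributed like a single $\tau$.
Rather than correcting per-waveform p-values (Bonferroni controls the
family-wise error rate but over-corrects; Benjamini–Hochberg within the
family is milder but still conservative, since the family members are
strongly correlated), the package computes the null of the *entire
procedure*: `sampleNull()` applies the same max-over-family search to
$N$ i.i.d. standard Gaussian series on the same grid — under the null only
rank order matters, and i.i.d. continuous draws induce uniformly random
rank orders, so this is an exact stand-in for explicit permutation. The
empirical p-value of an observed $\tau^*$ is the add-one rank
$(1+\#\{\text{null}\ge\tau^*\})/(N+1)$: never zero, floored at $1/(N+1)$,
ties counted as exceedances (the conservative direction). Across series,
false-discovery control uses the Benjamini–Hochberg adjustment of these
empirical p-values; the adjustment's uniformity assumption is what the
empirical null restores.

## Parameters that matter

* `period` (hours, default 24): the rhythm tested. Other periods are
  searched simply by changing it (also in the F24 comparator).
* `phaseStep` (hours, default 2) and `asymmetries` (default 2–22 by 2): the
  search grids. The conventional choices are "by 2 h" (12 phases × 11
  asymmetries = 132 hypotheses), "by 4 h" (6 × 5 = 30), and symmetric-only
  (6 phases, 6 hypotheses at a 4 h phase step). The grids should not exceed
  the resolution of the data — extra hypotheses add selection bias without
  adding rank information — and `bestCorrelation()` refuses denser grids
  unless `denseSearch = TRUE`.
* `nNull` (default 2 × 10⁵): Monte-Carlo null size, which sets the p-value
  floor $1/(N+1)$. Two runs with the same seed, grid and family are
  bit-identical, and the null can be cached on disk keyed by those
  signatures. A desk-scale analysis is fine at the default; 2 × 10⁶ gives a
  floor of 5 × 10⁻⁷.
* `tieNorm`: the $\tau$ denominator. The default (`"a"`) is the total pair
  count $n(n-1)/2$ even for tied data, exactly as in the formula above;
  consequently a noiseless series matched against itself on a replicated
  grid scores slightly below 1, because replicate pairs and symmetric-limb
  ties contribute zero to the numerator. The tie-corrected option (`"b"`)
  divides by the untied pair counts and restores $\tau = 1$ for a perfect
  self-match. All significance machinery uses the default; the option
  matters only if raw $\tau$ values are compared across designs with
  different tie structure.

## Comparator methods

**F24** projects the series onto the Fourier basis function at the test
period; the statistic is the modulus of the (un-normalized) projection —
only its rank against its own permutation null matters — and the phase
estimate is the closed-form arg-max of the cosine projection. The
permutation null (default 100 permutations) is summarized by a Gamma
distribution fit by the method of moments. The Gamma is an approximation:
against a 5 × 10⁴-permutation reference its CDF deviates by up to ≈ 0.04 in
the mid-range even with exact moments, so mid-range F24 p-values carry that
systematic uncertainty (tail behaviour, where calls are made, is much
better). `pMethod = "rank"` switches to the raw add-one permutation rank.

**ANOVA** groups samples by time point modulo the period (samples from
successive periods act as replicates) and applies the classical one-way F
test. It is undefined for single-replicate designs; benchmark reports map
that error to AUROC 0.5 by convention. `makePseudoReplicates()` adds one
interpolated observation per time point (cyclic-neighbour mean), which lets
ANOVA run on single-replicate data — but interpolation correlates the data
points, so p-values must then come from the Monte-Carlo null of the
augmented procedure (`anovaMCNull()`), not from the F distribution; the
uncorrected nominal p-values are measurably anti-conservative.

## What the simulated benchmarks emulate

`simWaveformData()` generates the waveform benchmark: sine, ramp (rising
ramp with an instantaneous drop at the phase — the maximal-asymmetry limit
of the triangle; orientation can be flipped), step (12 h high / 12 h low),
impulse (triangular pulse, full width at half maximum 2 h, on a flat
baseline), and triangle shapes, each spanning a peak-to-trough amplitude of
2, with phases uniform on $[0, T)$ and pointwise Gaussian noise whose sd is
`noiseFraction` × amplitude (presets 0.25 and 0.50). `simMixtureData()`
generates the genome-wide-like benchmark: 10% triangle series over a phase ×
asymmetry grid, 90% pure Gaussian noise, 24 samples as two periods of 12
points; the full-scale preset is 15,840 series. Ground-truth labels ride
along in the object.

These generators emulate stationary single-period rhythms with homoscedastic
Gaussian noise and equal amplitudes across series. Real expression data add
features deliberately not modelled: amplitude heterogeneity,
intensity-dependent (multiplicative) noise, temporal drift, correlated
replicates, and waveforms outside the five shapes. Passing benchmarks
therefore demonstrate the statistical machinery — calibration of the null,
the value of asymmetry search, FDR control — not performance guarantees on
any particular experimental platform.

## Multi-study preprocessing

`zscoreMerge()` converts each gene in each study to Z-scores (sample sd;
the population convention would differ only by a constant factor, which
ranks ignore) and pools the columns, keeping native zeitgeber labels —
ZT24 folds to ZT0, a ZT1 grid stays offset from a ZT0 grid (references are
evaluated at the literal times; nothing is interpolated onto a common
grid). Same-ZT columns across studies become replicates. `collapseProbes()`
keeps the highest-mean probe per gene (lexicographic tie-break).
`applyNAPolicy()` discards series with strictly more than half their points
missing (exactly half is retained), then replaces remaining gaps with
seeded Gaussian draws matching the global mean and sd of the retained
matrix — one shared null then serves every series, instead of one null per
missing-data pattern. Discarding precedes the moment computation.
Imputation adds noise: with long pooled series (≈ 48–57 points) and clear
rhythms, masking a quarter of the points and imputing preserves ≈ 99% of
FDR-0.05 calls; on short 24-point series the masking itself (not the
imputation) removes ~44% of rank pairs and pushes borderline detections
under the threshold, so the policy is best reserved for the pooled
multi-study setting it was designed for.

## Numerical choices and edge cases

* **Arg-max ties** are broken deterministically: smallest
  $|a - T/2|$ first, then smaller $a$, then smaller phase.
* **Constant series** have every pair tied; $\tau$ is identically 0 against
  all references and the row is flagged `degenerate`. All-equal ANOVA input
  is defined as $F = 0$, $p = 1$; a constant F24 series gets statistic 0,
  $p = 1$.
* **Initial p-values** (used only by the Bonferroni/BH comparator variants)
  come from the normal approximation to Kendall's $S$ (variance
  $n(n-1)(2n+5)/18$) with a continuity correction of 1 on the $S$ scale;
  against exhaustive enumeration of all $7!$ rank orders the Kolmogorov
  distance is ≈ 0.01 (≈ 0.065 without the correction).
* **Statistic granularity.** The max-$\tau$ statistic is discrete; its
  resolution improves with series length. Distributional checks of p-value
  uniformity use a 12-point × 3-replicate design ($n = 36$), where the
  largest atom of the null carries ≈ 1.6% mass and the Kolmogorov distance
  of empirical p-values from uniform is ≈ 0.012 at $N = 10^5$; at $n = 24$
  the largest atom alone (≈ 3.7%) exceeds a 2% band, a property of the
  statistic rather than of the null sampling.
* **Within-series BH minimum** under the null bunches just below 1, so its
  CDF necessarily recrosses the uniform diagonal around $p \approx 0.9$;
  conservativeness holds throughout the significance range (verified for
  $p \le 0.8$).
* **Seeds.** All randomness descends from one integer seed split into named
  streams (null, per-series permutations, simulation, imputation); every
  result table carries the seed, grid and family signatures, and null size
  in its metadata, so a run is reconstructible from its output.

## Problem sizes used by the shipped checks

The test suite exercises the full machinery at desk scale: $10^4$ noise
series against a $10^5$-sample null for the uniformity study, the
15,840-series benchmark for composition checks, a 1,320-series reduced
benchmark (132 rhythmic) with a $2\times10^4$ null for FDR calibration, 500
series per class for the replicates-versus-density comparison, and
exhaustive $7!$ enumeration for the small-$n$ oracle. The full-scale
settings (2 × 10⁶ nulls, 10,000 series per condition) are reachable through
the same arguments.

## Known limitations

* No automatic period scan: any single period can be tested, but grids over
  periods are the caller's loop.
* The reference family is unimodal triangle/cosine; multi-peak or arbitrary
  user waveforms are not implemented.
* The empirical null assumes exchangeable (i.i.d.) values under the null;
  autocorrelated noise violates it and will inflate significance.
* Gamma-summarized F24 p-values carry the ≈ 0.04 mid-range approximation
  error noted above.
* Detection resolution of phase and asymmetry equals the search grid; the
  method separates rhythmic from arrhythmic series robustly but does not
  refine parameter estimates below the sampling density.
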