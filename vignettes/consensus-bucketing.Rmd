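---
title: "Consensus bucketing of 1D NMR spectra by fused group lasso"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus bucketing of 1D NMR spectra by fused group lasso}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bucketfuse)
```

## The problem

A cohort of 1D ^1^H NMR spectra of biofluids (urine, plasma) arrives as a
samples × positions bucket table at fine resolution, typically 0.001 ppm.
Before any statistics, signals must be aggregated into features that
represent the same metabolite in every sample. The standard answer,
equidistant binning, cuts the axis into fixed-width buckets and sums
intensities — simple, but it splits peaks that drift between samples (pH,
ionic strength, temperature, protein binding all shift resonances) and it
merges unrelated signals in crowded regions.

`bucketfuse` instead *learns* a segmentation that is shared by all spectra.
It fits every spectrum with a piecewise-constant curve under the constraint
that the pieces start and end at the same positions in every sample, and
lets those consensus pieces ("plateaus") become the buckets.

## The model

Let $Y \in \mathbb{R}^{n \times p}$ hold the log2-transformed intensities of
$n$ spectra at $p$ positions. The fit solves

$$\hat B = \arg\min_B \; \lVert Y - B \rVert_F^2 \;+\;
  \lambda\sqrt{n} \sum_{j=1}^{p-1} \lVert B_{\cdot j} - B_{\cdot j+1} \rVert_2 ,$$

a fused *group* lasso: the $\ell_2$ norm couples the adjacent-difference of
position $j$ across **all** samples, so a boundary either fuses in every
spectrum simultaneously (the whole difference column is exactly zero) or in
none. Maximal runs of fused boundaries are the plateaus; the stretches in
between are retained as secondary "non-plateau" features.

**Why the $\sqrt{n}$ coefficient.** For a fixed per-sample difference
$\delta$ at some boundary, the group norm grows like $\sqrt{n}\,\delta$.
With the coefficient $\lambda\sqrt{n}$ a boundary fuses roughly when the
root-mean-square per-sample difference falls below $\lambda/\rho$,
independent of the cohort size — so a $\lambda$ tuned on a pilot set carries
over to a larger study. Penalty scalings that are constant or decay in $n$
lose this property: their effective smoothing vanishes as the cohort grows,
and at practically useful $\lambda$ values no plateaus form at all.

Values of $\lambda$ around 1–5 are appropriate at 0.001 ppm resolution;
$\lambda = 0$ reproduces the input exactly (the penalty vanishes — the
package returns this limit analytically rather than iterating), and
$\lambda \to \infty$ collapses each spectrum to its mean, one plateau over
the whole segment.

## The solver

The problem is convex and is solved by ADMM with the splitting $G = BD$,
where $D$ is the $p \times (p-1)$ first-difference operator. All three
updates are closed forms:

* **B-step** — a linear solve with the SPD tridiagonal matrix
  $I + \tfrac{\rho}{2} D D^\top$. Its sparse Cholesky factor is computed
  once per $(p, \rho)$ and reused across iterations and segments
  ($O(p)$ per solve; $p$ is in the thousands for real spectra).
* **G-step** — column-wise group soft-thresholding
  $R_t(x) = \max(0, 1 - t/\lVert x\rVert_2)\, x$ with
  $t = \lambda\sqrt{n}/\rho$. This produces *exact* zero columns, which is
  why plateau detection needs no epsilon.
* **U-step** — dual ascent on the constraint $BD = G$.

All matrices start at zero. Iteration stops when the scaled primal residual
$\lVert BD - G\rVert_F / \sqrt{n(p-1)}$ and dual residual
$\rho\lVert (G_k - G_{k-1})D^\top\rVert_F / \sqrt{np}$ both drop below their
tolerances (default $10^{-6}$), or at `max_iter` (default 10000, with a
warning, never an error). $\rho$ is fixed (default 1): adaptive step sizes
would change the prox threshold mid-run and break the exact-zero semantics.
The solver is deterministic.

Masked regions (water, urea, internal standards; see `apply_exclusions()`)
split the axis into segments that are solved independently — fusing across
a physical gap would be meaningless — and excluded columns are masked, not
deleted, so indices remain traceable to the original axis.

### Independent verification

`bf_reference_fit()` solves the same program by a different route:
accelerated projected gradient ascent on the Fenchel dual
$\max_{\lVert V_{\cdot j}\rVert \le \lambda\sqrt{n}}
\langle V, YD\rangle - \tfrac14 \lVert V D^\top \rVert_F^2$, recovering the
primal as $B = Y - \tfrac12 V D^\top$. Strong duality makes the duality gap
a *certificate*: the returned objective is provably within `tol_gap` of the
true optimum regardless of either solver's iteration path. The test suite
compares the ADMM objective against this certificate on seeded instances at
$10^{-6}$ relative tolerance.

## From fit to features

A boundary is fused iff its column of $G$ is exactly zero
(`fused_boundaries()`). Per segment, maximal fused runs become plateaus (a
run of $r$ boundaries spans $r+1$ bins) and the complementary maximal
stretches become non-plateau regions; both kinds then pass the
minimum-width filter: regions of width `min_region_bins` bins or fewer
(default 2, i.e. ≤ 0.002 ppm on a 0.001 ppm grid) are moved to the
`dropped` list. Before and after the filter, retained ∪ dropped regions
tile every included segment exactly — an invariant the tests assert on
every extraction, together with mass conservation: summed feature values
plus dropped-region mass equal the total included intensity.

At $\lambda = 0$ no boundary fuses, so the construction yields one maximal
non-plateau region per contiguous segment (a single consensus region in the
degenerate sense). We keep that literal outcome rather than special-casing
it.

Feature values are always sums of the **linear-scale** intensities over the
retained regions, even though the fit runs on log2 spectra;
`summarize_features()` refuses log-scale input outright. Region boundaries
are a function of the fit alone, so a `region_set` can be serialized
(`write_region_set()`) and applied to held-out spectra on the same axis
(`apply_regions()`) — the train/apply workflow used to study sample-size
dependence.

## Preprocessing

* `log2_abs_transform()` — the fit runs on log2 intensities to tame the
  dynamic range. Baseline distortion occasionally leaves small negative
  values; these are replaced by their absolute values, and exact zeros are
  floored at `zero_floor` (default $2^{-30} \times \max|Y|$, far below any
  signal; an exact zero needs *some* floor for the log to be defined, and a
  relative floor keeps the transform scale-free).
* `pqn_normalize()` — probabilistic quotient normalization in its minimal
  published form: reference = position-wise median spectrum over included
  positions, per-sample factor = median of quotients against it (skipping
  non-positive reference positions), no prior total-area normalization.
  Passing a frozen reference makes the operation idempotent, which the
  tests pin at $10^{-12}$. Applied on the linear scale, before the log —
  standard PQN practice.
* `internal_standard_normalize()` — division by the summed intensity over a
  reference region (TSP, formic acid).
* `equidistant_bin()` / `equidistant_bin_ppm()` — the fixed-width baseline
  (0.01 / 0.02 ppm are the conventional widths); blocks never straddle an
  excluded gap, and a trailing block is kept only if wider than the
  minimum-width filter.

The intended order is: normalization (if any) on linear intensities →
log2 transform → fit; feature summation always returns to the linear
matrix. `bucket_fuse()` wires the last three steps.

## The synthetic generator

`synthetic_config()` / `simulate_spectra()` produce spectrum stacks with
known ground truth so every claim above is testable without real cohorts.
The generator emulates the features of real data that matter for
bucketing: several metabolites with Lorentzian (optionally Gaussian)
multiplets, amplitudes proportional to latent log-normal per-sample
concentrations, per-metabolite-per-sample center jitter (all peaks of one
metabolite shift together, as the underlying physical causes act on the
molecule), additive Gaussian noise, and occasional negative baseline dips
that exercise the absolute-value rule.

Default study conditions, fixed once: 40 samples, 600 positions at
0.001 ppm, 4 metabolites with half-widths 0.002–0.003 ppm, jitter up to
0.004 ppm, concentration sdlog 0.5, noise sd 0.02 on a unit peak-height
scale, 2% negative-dip positions. These are realistic for well-resolved
small-molecule signals in a mid-field spectrum region, and the jitter is
chosen to be larger than a 0.01 ppm bin boundary tolerance — the regime
where consensus bucketing should, and in the tests does, beat equidistant
binning on best-feature Spearman recovery of the latent concentrations.

What the generator does **not** emulate: J-coupling fine structure,
solvent/baseline artifacts, phase errors, peak-shape asymmetry, and
correlated (smoothed) noise between neighboring bins. Passing tests
therefore demonstrate the mechanism under idealized lineshapes, not
performance on any particular real cohort. One consequence of the
independent per-bin noise is that log2 noise differences are heavier than
in apodized real spectra, so on these fixtures fusion starts at somewhat
larger $\lambda$ than the real-data working range.

## Evaluation tools

`best_feature_match()` reproduces the correlation benchmark: for each
absolutely quantified metabolite, the feature with the largest Spearman
correlation (average ranks; ties on the correlation break to the leftmost
feature for determinism; metabolites with fewer than 3 paired observations
are skipped). `welch_t_test()` and `pvalue_histogram()` implement the
two-class differential analysis on raw p-values — no multiple-testing
correction by default, because the diagnostic is the *shape* of the raw
distribution (excess mass in [0, 0.05] over the uniform background,
reported as `low_bin_excess`), optionally split by plateau / non-plateau
kind. `permutation_null()` provides the seeded label-permutation
calibration.

Calibration is checked with Gaussian feature matrices, for which the
Welch-test null is exact, so the Kolmogorov–Smirnov uniformity check
isolates the permutation machinery. Two caveats are inherent to the
design: pooled p-values across permutations of the same data are not
independent, which makes the KS test slightly anti-conservative, and on
strongly skewed features the t-test null itself is only asymptotically
uniform.

## Numerical choices and degenerate inputs

* Regions use 1-based closed index intervals; ppm bounds are the member
  positions' shifts ± half a bin width. Exclusion boundaries are inclusive
  on both ends.
* Length-1 segments pass through the solver as trivial converged fits and
  are dropped by the width filter.
* Zero-variance features are excluded from testing and counted.
* The $\lambda = 0$ solve returns $Y$ analytically (exact limit).
* Validation problem sizes: solver-vs-certificate checks run on
  $n \le 3$, $p \le 30$ instances; extraction-level properties on
  20–40-sample, 300–600-position fixtures; null calibration on 40 × 200
  feature tables with 50 permutations.

## Limitations

The method sums intensities within learned regions; it performs no
deconvolution, so completely overlapping signals (a singlet under a
multiplet) remain confounded whatever the segmentation. $\lambda$ trades
resolution against consensus: too large merges adjacent metabolites, too
small yields fragmented, jitter-sensitive regions. Warm starts across
$\lambda$ grids and accelerated ADMM variants are out of scope, as are raw
vendor formats, phasing, baseline correction, and chemical-shift
referencing — input is expected as an already-binned bucket table.
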