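# bucketfuse

Consensus bucketing of 1D ¹H NMR spectra by a fused group lasso.

## What problem this solves

Untargeted NMR metabolomics of biofluids starts from a samples × positions
bucket table at fine resolution (typically 0.001 ppm). Before statistics,
those thousands of positions must be aggregated into metabolite features
that mean the same thing in every sample — but resonance positions drift
between specimens (pH, ionic strength, temperature, protein binding), so
fixed-width "equidistant" buckets split drifting peaks and merge unrelated
ones.

`bucketfuse` learns the buckets from the data instead. Every spectrum is
fitted with a piecewise-constant curve whose pieces start and end at the
same positions in *all* spectra; those consensus plateaus become the
buckets. For log2 intensities `Y` (n samples × p positions) the fit solves
the convex program

    B̂ = argmin_B ‖Y − B‖²_F + λ√n Σⱼ ‖B·ⱼ − B·ⱼ₊₁‖₂ ,

a fused group lasso: the ℓ₂ penalty couples each adjacent-position
difference across all samples, so a boundary fuses either in every spectrum
at once (the difference column becomes exactly zero) or not at all. The √n
coefficient keeps λ transferable across cohort sizes; λ ≈ 1–5 suits
0.001 ppm data, λ = 0 returns the input, λ → ∞ one whole-axis plateau. The
solver is ADMM with a cached banded Cholesky factorization and an exact
group soft-thresholding step, run independently on each contiguous segment
between excluded regions (water, urea, internal standards).

Around the core fit the package provides the full workflow: bucket-table
IO, exclusion masking, PQN and internal-standard normalization, the log2
transform with absolute-value handling of negative baseline values,
equidistant-binning baselines, feature summation, best-feature Spearman
matching against quantified concentrations, Welch-test p-value histograms
with permutation nulls, a certified reference solver for validation, and a
seeded synthetic-spectrum generator with known ground truth.

## Worked example

```r
library(bucketfuse)

sim <- simulate_spectra(synthetic_config(seed = 42))  # 40 samples, 600 bins
sim$spectra
#> <spectrum_set> 40 samples x 600 positions (linear scale)
#>   ppm 4.0995 .. 3.5005 | 600 included / 0 excluded positions in 1 segment

res <- bucket_fuse(sim$spectra, lambda = 2.5)
res
#> <bucket_fuse> lambda = 2.5 | 2 plateau + 27 non-plateau regions retained, 32 dropped
#>   mean plateau width 0.0035 ppm | 40 samples x 29 features
```

The spectra carry four simulated metabolites whose peak positions jitter by
up to 0.004 ppm between samples. Matching each metabolite's latent
concentration to its best-correlating feature:

```r
recovery_score(res$features, sim$truth)
#> # A tibble: 4 × 3
#>   metabolite_id best_rho support_coverage
#>   <chr>            <dbl>            <dbl>
#> 1 met1             0.998                1
#> 2 met2             0.999                1
#> 3 met3             0.989                1
#> 4 met4             0.999                1

median(recovery_score(equidistant_bin_ppm(sim$spectra, 0.01), sim$truth)$best_rho)
#> [1] 0.8437148
```

The learned buckets recover the planted concentrations with median Spearman
ρ ≈ 0.998 versus ≈ 0.844 for 0.01 ppm equidistant binning on the same data
— the jittered peaks fall across fixed bin edges but inside learned
plateaus. `tidy(res)` lists the regions, `glance(res)` one row of fit
diagnostics, `autoplot(res)` draws the fitted spectra with plateau
(cyan) / non-plateau (yellow) shading, and `write_region_set()` /
`apply_regions()` transfer a learned segmentation to held-out samples.

A thin command-line front end covering simulate / fit / extract / ebin /
evaluate lives at `inst/cli/bf.R`:

```sh
Rscript inst/cli/bf.R extract --input buckets.tsv --lambda 2.5 \
    --output features.tsv --regions-out regions.json
```

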