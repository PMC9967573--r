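# p31corr

Monte Carlo analysis of **overlap-induced spectral correlations in in vivo
³¹P MRS of human brain**, at 3 T and 7 T.

## Why

When ³¹P spectra are quantified by linear-combination-model (LCM) fitting,
metabolites whose resonances overlap trade amplitude against each other:
across noise realizations their fitting errors are *negatively correlated*
even with no biological correlation present. Clinical correlation studies
that treat fitted concentrations as independent variables inherit these
spectral correlations as confounders. `p31corr` measures them on fully
synthetic data with known ground truth, so the correlation observed is, by
construction, purely spectral.

The pipeline: density-matrix simulation of each metabolite's coupled
³¹P spin system → composite spectra with realistic amplitudes, linewidths,
a downfield-dominant background baseline and noise calibrated to in vivo
PCr SNR (82 at 3 T, 171 at 7 T) → the standard processing chain
(initial-point zeroing, 1-Hz apodization, zero-filling, FFT) → a
constrained LCM fit over −20..10 ppm (non-negative amplitudes, polynomial
baseline, NAD⁺/NADH linewidths tied to the ATP linewidth − 1.5 Hz, total
ATP = 9 mM as internal reference) → thousands of seeded noise realizations
→ Pearson correlation matrices, partial correlations

r(A,B|C) = (r_AB − r_AC·r_BC) / √(1−r_AC²)·√(1−r_BC²),

coefficient-of-variation tables, and baseline/linewidth difference
summaries. An analytic oracle — the normalized amplitude block of
(XᵀX)⁻¹ for the linearized fit — predicts every Monte Carlo correlation and
is used throughout the tests.

## Worked example

```r
library(p31corr)

basis <- build_basis_set("3T")              # 11-signal 3 T basis (no UDPG)
scn   <- scenario("3T")                     # PCr 6.3 Hz, SNR 82, ATP 9 mM
mc    <- run_realizations(scn, basis, 500, base_seed = 1,
                          config = fit_config(baseline_degree = NA))

pearson_matrix(mc)$r["NAD+", "NADH"]
#> [1] -0.669
pearson_matrix(mc)$r["PC", "PE"]
#> [1] -0.224
head(cv_table(mc)[, 1:2])
#>   metabolite cv_percent
#> 1        PCr  1.0932327
#> 2        ATP  0.6922485
#> 3       NAD+ 14.4913847
#> 4       NADH 48.4597290
#> 5        GPC  8.6512434
#> 6        GPE  8.6457713
```

The NAD⁺–NADH pair, separated by only 0.15 ppm and overlapped by α-ATP,
shows the strong negative error correlation (−0.67) that survives even at
7 T (≈ −0.53 there); the weakly overlapping PC–PE pair is milder (−0.22).
Adding the downfield background baseline to the data and a degree-6
polynomial to the fit barely moves the upfield NAD correlation but flips
the downfield PC–PE correlation positive-ward:

```r
scn_bl <- with_default_baseline(scn, basis)
mc_bl  <- run_realizations(scn_bl, basis, 500, base_seed = 2,
                           config = fit_config(baseline_degree = 6))
pearson_matrix(mc_bl)$r["NAD+", "NADH"]   #> -0.636
pearson_matrix(mc_bl)$r["PC", "PE"]       #>  0.059
```

Full study-scale drivers: `run_experiment_invivo()` (2 fields × 5 jittered
subjects × baseline on/off) and `run_experiment_linewidth()` (line
broadening 0/4/8 Hz at 3 T, 0/10/20 Hz at 7 T), both reproducible
bit-for-bit from a base seed, plus `run_pipeline()`/`write_report()` for a
YAML-configured end-to-end run (see
`inst/extdata/paper_3T_quick.yaml`).

## Documentation

The methods vignette (`vignettes/spectral-correlations.Rmd`) documents the
spin-system tables, the processing chain and its conventions, the noise
calibration, the fit constraints and numerical choices, what the synthetic
generator does and does not emulate, and known limitations.
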