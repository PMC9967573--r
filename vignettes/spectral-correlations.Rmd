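---
title: "Overlap-induced spectral correlations in 31P MRS: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Overlap-induced spectral correlations in 31P MRS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p31corr)
```

## The problem

In vivo ³¹P MRS quantifies phosphorus metabolites — PCr, ATP, NAD⁺/NADH,
UDPG, inorganic phosphate pools, phosphomono- and diesters, and a broad
membrane-phospholipid (MP) signal — by fitting a measured spectrum as a
linear combination of simulated per-metabolite basis signals. Where two
basis signals overlap, over-estimating one is compensated by
under-estimating the other, so the *fitting errors* of overlapping
metabolites are negatively correlated across noise realizations even when
the underlying biology is uncorrelated. Clinical studies that correlate
fitted concentrations with outcome measures inherit these purely spectral
correlations as confounders.

`p31corr` quantifies this effect on synthetic brain spectra at 3 T and 7 T:
it simulates spectra with known ground truth, refits them under many noise
realizations, and summarizes the resulting amplitude correlations, their
dependence on the background baseline and on linewidth, and the precision
(CV) of each metabolite.

## Basis simulation

Each metabolite is a system of up to three coupled ³¹P spin-½ nuclei with
chemical shifts $\delta_i$ (ppm, PCr = 0) and scalar couplings $J_{ij}$
(Hz). The pulse-acquire FID is computed exactly from the density operator:
the rotating-frame Hamiltonian

$$H = \sum_i 2\pi \nu_i I_{iz} + \sum_{i<j} 2\pi J_{ij}
\, \mathbf{I}_i\cdot\mathbf{I}_j, \qquad \nu_i = \delta_i \cdot f_{\mathrm{larmor}},$$

is diagonalized in full, so strong coupling is handled without first-order
approximations (the NAD⁺/NADH pyrophosphate AB pairs are strongly coupled at
both fields: $J = 20$ Hz against center splittings of 3–7 Hz). After an
ideal 90° pulse ($\rho_0 = F_x$) the detected signal is
$\mathrm{Tr}[(F_x + iF_y)\,\rho(t)]$, normalized so the FID starts at the
number of ³¹P nuclei (per-phosphorus normalization; the ATP signal carries
its α, β and γ moieties in one basis component).

Two pragmatic reductions, both standard for this problem:

* **Effective ¹H multiplets.** Spectra are modeled as acquired without ¹H
  decoupling. For single-³¹P metabolites the ¹H–³¹P coupling is applied as
  a first-order modulation $\cos(\pi J t)^{m-1}$ (PE/GPE triplets at
  ≈ 7.3 Hz, PC/GPC at ≈ 6.3 Hz). A full heteronuclear simulation would add
  4–8 proton spins per metabolite for what amounts to a symmetric
  sub-linewidth splitting at both fields.
* **MP as one broad Lorentzian** at 1.7 ppm, FWHM 250 Hz at 3 T and 450 Hz
  at 7 T, with amplitude chosen so the MP hump dominates the downfield
  region at 3 T and is small at 7 T.

The shift/J table is configuration, not ground truth: defaults follow the
usual literature conventions (ATP at −2.53/−7.56/−16.18 ppm with
$J \approx 16.3$ Hz; NAD⁺ and NADH centered at −8.30 and −8.15 ppm; UDPG at
−9.8/−11.6 ppm, included only in the 7 T model where it is detectable), and
any table can be supplied as YAML (`load_spin_systems()`).

## Processing chain

`process_fid()` reproduces the conventional chain: the first two FID points
are zeroed (suppressing broad fast-decaying signal at the cost of a smooth
spectral pedestal later absorbed by the fitted baseline), 1-Hz exponential
apodization, zero-filling (default ×4: 1024 → 4096 points for smooth
lineshape interpolation), FFT, exact phasing (phases are known in a
synthetic pipeline), and optional PCr re-referencing. The chain is linear
in the FID — the property that makes linear-combination fitting of a
composite spectrum exact.

Linewidths are parameterized throughout as the *target total Lorentzian
FWHM in the processed spectrum*, so the in vivo PCr values (6.3 Hz at 3 T,
9.3 Hz at 7 T) are entered directly; the composer applies
$\max(\mathrm{lw} - \mathrm{intrinsic} - \mathrm{lb}_{proc},\,0)$ of extra
decay. Measured FWHMs additionally carry ≈ 3% truncation ripple from the
0.2048 s acquisition — visible in the tests' tolerances, and present in any
real measurement with this raster.

## Synthetic scenarios

A `scenario()` is one synthetic "participant": concentrations (mM),
per-metabolite linewidths, a global line-broadening factor (shim
degradation), an optional baseline, and a noise level. Defaults:

| parameter | 3 T | 7 T | rationale |
|---|---|---|---|
| PCr FWHM | 6.3 Hz | 9.3 Hz | in vivo values |
| ATP FWHM | 14 Hz | 22 Hz | CSA relaxation grows with field; in vivo α-ATP reports ~12–15 Hz (3 T), ~20–25 Hz (7 T) |
| NAD⁺/NADH FWHM | ATP − 1.5 Hz | ATP − 1.5 Hz | the fitting constraint, applied to truth as well |
| ester/Pi FWHM | 12 Hz | 15 Hz | typical undecoupled in vivo widths |
| PCr SNR | 82 | 171 | in vivo values |
| concentrations | ATP 9 (reference), PCr 4.5, PE 1.8, GPC/GPE/Pi_in 1.0, PC 0.6, NAD⁺ 0.35, Pi_ex 0.3, NADH 0.1, UDPG 0.1 | same | literature-style table; overridable |

Noise is added in the time domain (physically correct) as i.i.d. complex
Gaussian noise and calibrated in the frequency domain: under the unscaled
FFT the real-part noise SD is exactly $\sigma\sqrt{\sum_t w_t^2}$ with
$w_t$ the apodization weights, so `calibrate_noise_for_snr()` is
deterministic and closed-form. Realization $i$ uses seed
$\mathrm{base} + i - 1$, giving reproducible, bit-identical streams.

The synthetic background baseline is a degree-6 polynomial obtained by
projecting a Gaussian hump (center 5 ppm, FWHM 6 ppm) onto the normalized
fit window, scaled to the scenario's MP peak height — downfield-dominant
and field-dependent like the in vivo baseline. Between-participant
variability (`subject_scenarios()`) jitters all linewidths by a common
factor matched to the in vivo PCr spread (6.3 ± 0.9 Hz, 9.3 ± 2.1 Hz), SNR
by its in vivo spread (82 ± 21, 171 ± 27), and concentrations by 10%
multiplicative noise with the ATP reference held at 9 mM.

What the generator does *not* emulate: participant physiology (real
metabolite covariation), T₁ saturation by TR, coil sensitivity, frequency
drift, eddy currents, and non-Lorentzian shim lineshapes. Passing tests
therefore demonstrate the overlap-driven error structure of the fit, not
properties of any in vivo cohort.

## The constrained LCM fit

`fit_lcm()` minimizes the squared residual of the real part over the
−20..10 ppm window in the model

$$y(\nu) = \sum_m a_m\, \mathrm{Re}\,S_m(\nu;\,\mathrm{lw}_m, d_m)
 + \sum_{k=0}^{K} b_k P_k(\nu) + \varepsilon,$$

with amplitudes $a_m \ge 0$ and baseline coefficients $b_k$ linear, and
per-metabolite total linewidths and shifts bounded nonlinear parameters.
The linear subproblem is solved exactly at every nonlinear step (variable
projection): baseline columns are projected out by QR, the non-negative
amplitude problem is solved by Lawson–Hanson NNLS, and the baseline is
back-substituted. The NAD⁺ and NADH linewidths are never free — they are
tied to the ATP linewidth minus 1.5 Hz (floored at zero) at start values
and during optimization, so the constraint holds exactly in every output.

Design choices made where the design was genuinely open:

* **Real-part frequency-domain fitting.** Phases are exactly known here, so
  absorption-mode fitting loses nothing and keeps the design matrix real.
* **Baseline degree 6** on the normalized window: flexible enough to follow
  the synthetic hump and the initial-point-zeroing pedestal, stiff enough
  not to absorb metabolite lines.
* **Starting values = ground truth** in synthetic pipelines. The Monte
  Carlo default is the fit *linearized at truth* (`optimize_* = FALSE`):
  for error-correlation analysis the linearization is the object of
  interest — its amplitude covariance is exactly
  $\sigma^2 (X^\top X)^{-1}$, which `analytic_correlation_oracle()`
  computes and the Monte Carlo must reproduce. Full bounded refinement
  (`optimize_linewidths`, `optimize_shifts`, L-BFGS-B) is available and
  tested; at thousands of realizations it changes runtime, not the
  correlation structure.
* **Non-negativity** censors a small fraction of draws for the weakest
  signal (NADH, ~2% at 3 T); this is the physically faithful estimator and
  slightly attenuates the NAD⁺–NADH correlation relative to the
  unconstrained linear fit.
* **Concentration scale.** Monte Carlo tables are scaled to mM once per
  condition (9 mM / mean fitted ATP). Per-realization division by fitted
  ATP would pin ATP at exactly 9, destroying its CV and correlation
  entries, which the study design clearly retains; `quantify_concentrations()`
  still provides per-spectrum ATP referencing for single in vivo-style fits.

Degenerate inputs are flagged, not thrown: an all-zero spectrum fits to
zero amplitudes with a flag, non-convergence flags the result, and
zero-ATP results carry undefined concentrations.

## Monte Carlo experiments and statistics

`run_experiment_invivo()` mirrors the baseline experiment — per field, five
jittered subjects × baseline on/off, 2000 realizations each at full scale
(40,000 fits) — and `run_experiment_linewidth()` the line-broadening
experiment: the mean scenario per field under lb factors 0/4/8 Hz (3 T) and
0/10/20 Hz (7 T), baseline on/off, with the noise sigma held at the
field's calibrated level across lb conditions (24,000 fits at full scale).
Both drivers accept reduced `n_realizations`; the packaged tests and the
acceptance script run 400–2000 realizations per condition, which keeps the
Monte Carlo SE of a correlation coefficient in the 0.01–0.03 range while
finishing in seconds per condition.

Statistics follow the standard definitions: Pearson product-moment
correlations over realizations; CVs as $100\cdot\mathrm{SD}/\mathrm{mean}$
with the sample SD; difference matrices as with-baseline minus without;
across subjects, per-pair mean ± SD, paired Cohen's
$d = \overline{\Delta r}/\mathrm{SD}(\Delta r)$ (flagged undefined at zero
SD) and an optional paired t-test. The partial correlation

$$r_{AB|C} = \frac{r_{AB} - r_{AC}r_{BC}}
{\sqrt{1-r_{AC}^2}\sqrt{1-r_{BC}^2}}$$

is provided for confounder analysis; the paired effect size is our
interpretation of the study's unspecified formula and is labeled as such.

## A small worked run

```{r example, eval = FALSE}
basis <- build_basis_set("3T")
scn <- scenario("3T")
mc <- run_realizations(scn, basis, 500, base_seed = 1,
                       config = fit_config(baseline_degree = NA))
pearson_matrix(mc)$r["NAD+", "NADH"]  # strong negative overlap correlation
cv_table(mc)
```

## Known limitations

* The absolute CV values depend on the concentration table; only their
  monotone increase with line broadening is a robust prediction.
* Downfield correlations (PC–PE and neighbours) are sensitive to the exact
  ester linewidths and the baseline shape; with the literature-default
  12 Hz ester widths the PC–PE trade-off is weaker than with broader in
  vivo lineshapes, though its sign and its positive-ward shift under the
  baseline are robust.
* The MP component and the background baseline are stylized (one Lorentzian,
  one polynomial hump); real macromolecule signals have structure.
* Automatic phasing, eddy-current correction and vendor data formats are
  out of scope; the pipeline is synthetic end to end.
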