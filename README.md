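# glycorelax

Time-domain NMR (TD-NMR) relaxometry analysis of protein glycation.

## What it does, and for whom

Heat-induced glycation — the Maillard reaction between protein free amino
groups and reducing sugars — is a storage/transport risk for
biopharmaceutical formulations. The reference assay (OPA, absorbance of
derivatized free amino groups) is invasive and consumes sample. TD-NMR
measures the same degradation non-invasively: glycation removes
hydrogen-bonding sites, lowers hydration and water mobility, and thereby
shortens the longitudinal (T1) and transverse (T2) proton relaxation
times of the formulation.

`glycorelax` is for analysts who have (or want to simulate) benchtop
relaxometry data of heated protein–sugar formulations and need the full
chain from raw decays to a quantitative glycation metric:

* exact forward models for saturation-recovery (SR), CPMG and IR-CPMG
  pulse sequences;
* monoexponential T1/T2 fitting (Levenberg–Marquardt, analytic Jacobians,
  log-linear initialization);
* Tikhonov-regularized nonnegative 1D inverse Laplace transforms
  (T1-ILT / T2-ILT spectra) with L-curve selection of the regularization
  weight and peak detection;
* SVD-compressed 2D inversion of IR-CPMG surfaces into T1–T2 correlation
  maps, proton-pool segmentation, and extraction of the
  (T1/T2)_Map / (T2/T1)_Map ratios of the dominant (alpha) pool — the
  quantitative glycation metric;
* a method-agreement layer: min–max normalization, reciprocal
  orientation, MAE / RMSE / correlation p-values against the reference
  assay, and per-timepoint one-way ANOVA with Tukey grouping;
* a synthetic study generator emulating a three-arm heating experiment
  (55 / 70 / 85 °C, triplicates) with calibrated trends, used by the
  test suite and the acceptance script.

## The core computation

Relaxation decays are multiexponential; their amplitude distribution over
relaxation time solves the ill-posed Fredholm problem

    min_{x >= 0}  || K x - s ||^2  +  alpha^2 || x ||^2

where `K` discretizes the sequence kernel (`1 - exp(-t/T)` for SR,
`exp(-t/T)` for CPMG, `(1 - 2 exp(-tau1/T1)) exp(-tau2/T2)` for IR-CPMG
on a T2 x T1 grid). The 2D problem is compressed by truncated SVD of both
kernels; the regularized normal equations inherit the Kronecker structure
`(K1c'K1c) ⊗ (K2c'K2c) + alpha^2 I` and are solved by fast active-set
nonnegative least squares. Pools are 4-connected above-threshold regions
of the map; the alpha-pool center ratio `(T2/T1)_Map` decreases
monotonically with glycation extent and is compared, after per-arm
min–max normalization, against the free-amino reference series.

## Worked example

```r
library(glycorelax)

# simulate the default three-arm study (60 records, snr = 200, seed 1)
study  <- generate_study(study_design(seed = 1))
fits   <- fit_study(study)              # T1/T2 per record
ratios <- pool_ratio_series(study)      # alpha-pool map ratios per record
tab    <- build_comparison_table(study, fits, ratios)
subset(tab, method == "(T2/T1)Map")
```

```
       method temperature_C      p_value        mae       rmse
22 (T2/T1)Map            55 5.884797e-05 0.05232972 0.06676519
23 (T2/T1)Map            70 1.459455e-05 0.04920433 0.06909179
24 (T2/T1)Map            85 1.351258e-04 0.06671092 0.08311208
```

Each row compares the normalized (T2/T1)_Map series of one temperature
arm against the normalized free-amino reference of the same arm: the map
ratio tracks the reference to within a mean absolute error of about 0.05
on the [0, 1] scale, with the correlation significant (p < 0.05) in every
arm — the map ratio is a valid stand-in for the invasive assay on these
data.

The relaxation-time spectra of the unheated control (pooled time-zero
replicates) show the expected structure:

```r
pk <- detect_peaks_1d(invert_1d(pool_control(study, "sr"), alpha = 1e-3))
pk[!pk$minor, c("center_s", "mass_fraction")]
```

```
  center_s mass_fraction
1 1.672904    0.90460341
2 0.464159    0.08373417
```

a dominant T1 peak at 1.67 s (solute-surface water) and a second peak at
0.46 s (solute–solute hydrogen bonding), with the corresponding T1–T2 map
resolving exactly two proton pools whose (T2/T1) center ratio at time
zero is 0.513.

The end-to-end pipeline (simulation, fits, spectra, maps, comparison
table, run log) is one call — or one shell command via the thin CLI at
`inst/cli/glycorelax.R`:

```r
res <- run_pipeline(default_pipeline_config())
```

## Layout

```
R/                  signal models, synthetic study, fitting, 1D/2D ILT,
                    quantification, I/O, pipeline
tests/testthat/     unit + property tests, incl. independent solver oracles
scripts/acceptance.R   headline-quantity recomputation (JSON output)
vignettes/          methods vignette (models, parameters, design choices)
inst/cli/           thin command-line front end
```
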