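---
title: "Quantifying protein glycation by TD-NMR relaxometry: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying protein glycation by TD-NMR relaxometry: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycorelax)
```

## The problem

Glycation — the non-enzymatic Maillard reaction between protein free amino
groups and reducing sugars — degrades biopharmaceutical formulations during
storage and transport at elevated temperature. The established reference
assay (an o-phthalaldehyde, "OPA", method) quantifies the remaining free
amino groups but is invasive: the container must be opened and the sample
consumed. Time-domain NMR (TD-NMR) relaxometry offers a non-invasive
alternative: glycation removes hydrogen-bonding sites and increases solute
hydrophobicity and aggregation, which reduces hydration and water mobility
and therefore shortens both the longitudinal (T1) and transverse (T2)
proton relaxation times of the formulation.

`glycorelax` implements the full analysis chain that turns raw relaxation
decays into a quantitative glycation readout and an agreement table against
the reference assay, together with a synthetic study generator used to
validate every stage.

## Signal models

Three pulse sequences are modeled exactly:

* saturation recovery (SR): $S(t) = A\,(1 - e^{-t/T_1})$;
* CPMG echo train: $S(t) = A\,e^{-t/T_2}$;
* inversion-recovery CPMG (IR-CPMG):
  $S(\tau_1, \tau_2) = \sum_i A_i\,(1 - (1{+}f)\,e^{-\tau_1/T_{1,i}})\,
  e^{-\tau_2/T_{2,i}}$,

with inversion efficiency $f = 1$ (ideal) by default. The SR model carries
no baseline offset by default (an offset term is available as an argument).
Default acquisition grids mirror the benchtop instrument settings: 20 SR
recovery delays; 12,500 CPMG echoes at a 10 ms interval (TR 13 s); 200
IR-CPMG echoes at 15 ms with 10 inversion delays. The emulated protocol
fixes only the counts and echo intervals; the spans of the SR and IR delay
grids (log-spaced 0.02–10 s and 0.05–10 s) are package choices that cover
the relaxation times seen in these formulations. All times are seconds
internally; file I/O accepts `ms` with an explicit unit declaration.

## Monoexponential fitting

`fit_t1()` / `fit_t2()` estimate $(A, T)$ by damped (Levenberg–Marquardt)
least squares with analytic Jacobians, initialized from the log-linear
transform of the data (regression of $\log(A_{\mathrm{plateau}} - S)$ or
$\log S$ on $t$). The SSE surface of a monoexponential on these grids is
well-behaved, so no multi-start is used. Convergence is declared at a
relative SSE change of $10^{-10}$ (at most 200 iterations); degenerate
curves (constant, all-zero, fewer than 4 points) are rejected.

Because the true signal contains two proton pools, the monoexponential
estimate is an *effective* relaxation time. Its value is pulled below the
dominant pool's time by an amount that depends on the replicate-specific
minor pool, which is why downstream comparisons rely primarily on the 2D
map ratios rather than the raw fits.

## Inverse Laplace transforms

Relaxation-time spectra are the regularized nonnegative solution of the
discretized Fredholm problem

$$\min_{x \ge 0}\; \lVert K x - s \rVert^2 + \alpha^2 \lVert L x \rVert^2,$$

solved through the augmented-system active-set construction
(`invert_1d()`). The penalty $L$ is the identity by default (zeroth-order
Tikhonov); a second-difference option exists. The default spectrum grid is
64 log-spaced points over 0.01–10 s. Long CPMG trains are subsampled
(every 10th echo) before inversion: the kernel then stays at most
1250 x 64 and, at these relaxation times, adjacent echoes carry virtually
no independent information. Signals are scaled to unit maximum internally
so that $\alpha$ is comparable across records.

`select_alpha()` offers a fixed value (default 0.01) or the L-curve
criterion: a 25-point log-spaced ladder over $[10^{-5}, 10]$, returning
the maximum-curvature corner of (log residual norm, log solution norm).
On noiseless data the corner collapses toward small $\alpha$; on the
instrument-length CPMG train the selected $\alpha$ grows with the noise
level. On the 20-point SR curve, however, the residual-norm branch of the
L-curve is too flat for the corner to be located reliably, and the
selection can jump an order of magnitude between noise realizations — one
reason the package characterizes control material from pooled curves with
a fixed weight (below).

The 2D inversion (`invert_2d()`) solves the same problem for the IR-CPMG
kernel pair $K_1$ (inversion-recovery factor, over the T1 grid) and $K_2$
(CPMG factor, over the T2 grid), with the map $X \ge 0$ on a default
48 x 48 log-spaced grid over 0.02–5 s. Both kernels are first compressed
by truncated SVD (default ranks 8 for the 10-delay IR axis, 16 for the
echo axis); the normal equations in the compressed domain inherit the
Kronecker structure $(K_{1c}'K_{1c}) \otimes (K_{2c}'K_{2c}) + \alpha^2 I$
and are solved by a fast active-set NNLS on the cross-products. Because
the regularized problem is strictly convex, the compressed solution at
full rank coincides with the uncompressed one; the test suite verifies
this equivalence and, on small grids, agreement with an exhaustive
enumeration oracle to $10^{-8}$. The rank-8 truncation of the IR kernel
discards a singular value of order $10^{-2}$ (the 10-delay IR kernel has
slowly decaying singular values), so compression at the default ranks is
an approximation with a reconstruction error of order $10^{-4}$ —
negligible against measurement noise but not machine precision; the test
suite asserts the explicitly computed singular-value bound.

### Peak and pool detection

1D peaks are contiguous above-threshold runs (default 5 % of the spectrum
maximum): amplitude-weighted centroid, mass fraction, and bounds extended
by half a log-step. Peaks holding less than 2 % of total mass are flagged
*minor* — small features at these mass fractions are not reliably
distinguishable from noise.

2D pools are 4-connected above-threshold regions (default 3 % of map
height) after a morphological closing of the mask (`gap_fill = 2` cells).
Two numerical facts motivate these choices. First, an active-set NNLS
represents a relaxation environment that falls between grid nodes as a
*pair of bracketing spikes*; closing re-joins such pairs without bridging
the much larger alpha–beta separation (about 15 grid cells). Second, a
pure height threshold is fragile: how sharply the dominant pool
concentrates depends on its accidental alignment with the grid, so the
minor/major decision uses integrated mass (< 2 % of map mass) instead.
The 2D regularization default ($\alpha = 0.03$) is chosen so that a
single environment reconstructs as one contiguous blob rather than a
spike pair while keeping the centroid bias of the dominant pool's
(T2/T1) ratio below 1 %. The most intense non-minor pool is labeled
*alpha*, the next *beta*; exact ties go to the larger center T1. A pool
with $T_1 < T_2$ triggers a warning (unphysical half-plane), not an error.

Pool centers are amplitude-weighted centroids — the study this package
emulates read pool centers manually from contour maps, and no printed
criterion for "center" exists, so the centroid convention is this
package's decision. Ratios $(T_1/T_2)_{\mathrm{Map}}$ and its reciprocal
$(T_2/T_1)_{\mathrm{Map}}$ are taken from the alpha-pool center;
`pool_ratio_series()` extracts them per record across a study.

### Characterizing the control material

All time-zero records are the same unheated control formulation, so
`pool_control()` averages their acquisitions before inversion (noise
shrinks with the square root of the pooled count). This matters for the
T1 spectrum: with only 20 SR samples, a single curve at the default noise
level cannot reliably resolve the weak beta contribution (5–25 % of the
alpha amplitude, at 2–4x shorter T1) — inversions of single curves
misplace or merge the second peak for a substantial fraction of noise
realizations. On the pooled control curve with $\alpha = 10^{-3}$
(appropriate for the averaged, higher-SNR curve; results are stable over
at least $[3\times10^{-4}, 3\times10^{-3}]$), the two T1 peaks fall
robustly inside the reference windows (1.5–2.0 s and 0.4–0.9 s), as does
the single dominant T2 peak (0.4–1.2 s).

## The synthetic study

The generator (`generate_study()`) emulates the three-arm heating study:
55 °C sampled daily to 6 days, 70 °C to 48 h, 85 °C to 6 h, three
replicates each (60 records). A latent glycation extent follows
first-order kinetics $g(t) = 1 - e^{-k_T t}$ — the simplest monotone
saturating form with one parameter per arm. Since strict first-order
kinetics never reaches $g = 1$ at a finite time, $k_T$ is set so that
$g = 0.95$ at the arm's final time point and the free-amino decline is
scaled so its endpoint matches the reference reductions exactly: 15 %
(55 °C), 30 % (70 °C), 40 % (85 °C).

From $g$, each record derives:

* **alpha pool** (deterministic): T1 interpolates 1.75 s → 1.30 s and T2
  0.90 s → 0.45 s, so the (T2/T1) ratio falls 0.514 → 0.346. The
  endpoints are configuration values chosen to keep the inversion peaks
  inside the reference windows, not physical claims.
* **beta pool** (re-drawn per replicate): T1 uniform in 0.4–0.9 s, T2 in
  0.05–0.3 s, amplitude 5–25 % of alpha — encoding the observation that
  this pool's placement and intensity are not persistent between
  replicates.
* **assay panel**: free-amino percentage $100 f + \varepsilon$
  ($\varepsilon \sim N(0, 2)$ percentage points by default); early-product
  absorbance $0.02 + 0.5\,g/(g + 0.2)$ (saturating); late-product
  absorbance $0.02 + g^2$ (late, sharp rise); soluble-protein readout
  declining at half the free-amino rate. The 0.02 instrument blank keeps
  reciprocal series defined at time zero, as they are for real
  spectrophotometer data.

Decay noise is additive Gaussian with sd = (max signal)/snr, default
snr = 200 — a typical benchtop figure; the instrument's true SNR is not
published, so this is a free configuration value. Rician (magnitude-mode)
noise is deliberately not modeled. The generator is strictly monotone in
time within each arm; the transient T1 uptick reported at the last 55 °C
time point of the real study (attributed to a transitional
misfolding/aggregation state) is intentionally **not** emulated.

What passing tests on this generator do and do not show: they validate
the solvers, the pool bookkeeping and the statistical layer under a
faithful trend structure; they cannot validate behavior on real
formulations — exchange between pools, temperature drift, non-Gaussian
noise, baseline artifacts and gelation near the end of the heating window
are all absent.

One structural consequence is worth stating plainly: because the
generator's alpha-pool T1 and T2 are *linear* in $g$ and the reference
percentage is too, the normalized fitted T1/T2 series agree with the
normalized reference almost perfectly (limited only by noise and the
beta-pool contamination of the effective fits). On synthetic data the map
ratio therefore does not dominate every other TD-NMR metric the way it
does in the real study — the generator reproduces trend shapes, not the
relative noise budgets of real instruments. The package asserts the map
ratio's own agreement bounds (MAE ≤ 0.10, RMSE ≤ 0.12, p < 0.05 per arm)
rather than its supremacy.

## Method agreement

`build_comparison_table()` produces the 30-row agreement table: ten
methods (raw and reciprocal browning at 420 nm and 294 nm, T1, T2, both
map ratios, raw and reciprocal soluble protein) by three arms. Replicates
are averaged per time point before normalization (the emulated study
reports one value per arm and time point; per-replicate normalization is
available via the underlying functions). Min–max normalization is
per-arm. The p-value is the two-sided significance of the Pearson
correlation between the normalized series — the emulated study does not
state its test, so this is the package's documented choice — with
significance read at p < 0.05. MAE and RMSE are computed on the
normalized series, so MAE ≤ RMSE holds exactly. `anova_tukey()` provides
the per-timepoint one-way ANOVA with Tukey HSD grouping and a compact
letter display (insert-and-absorb algorithm).

## Reproducibility and configuration

One seed drives the whole study; analysis stages are deterministic given
their inputs, communicate through plain CSV files with `#` comment
headers (seed and config hash included), and are orchestrated by
`run_pipeline()` from a YAML/JSON configuration whose defaults are all in
`default_pipeline_config()`. Problem sizes used in the validation suite:
the full 60-record study for end-to-end checks, 200 seeded replicates for
fitter bias, 24 x 24 map grids for solver-equivalence oracles, and
10–12-point spectrum grids for the exhaustive NNLS oracle.

## Known limitations

* No uncertainty quantification of spectra or maps (bootstrap hooks are a
  natural extension); no Butler–Reeds–Dawson alpha optimization — the
  L-curve suffices at this scale.
* No exchange modeling between pools or off-diagonal exchange peaks.
* The monoexponential fits report effective relaxation times in the
  presence of multiple pools (by design, matching the emulated protocol).
* Vendor instrument file formats are not read; data enter as delimited
  text.
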