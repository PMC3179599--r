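---
title: "Simulated first-pass myocardial perfusion in mice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated first-pass myocardial perfusion in mice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

First-pass contrast-enhanced perfusion MRI acquires one short-axis image
per heartbeat while a gadolinium bolus transits the heart. At murine
heart rates (~500 beats/min) this is only feasible with aggressive k-t
undersampling and a reconstruction that exploits spatiotemporal
redundancy. `ktperf` implements that pipeline end to end against a
digital mouse-heart phantom with known ground truth, so every stage —
acquisition, reconstruction, quantification — can be validated
quantitatively.

```{r, eval = FALSE}
library(ktperf)
res <- run_pipeline(run_config(seed = 1L), "run1")
res$metrics
```

## The phantom

`render_phantom()` builds a 128 x 128 short-axis scene over a 25 x 25 mm
field of view (0.195 mm pixels): an LV cavity disc (endocardial radius
1.6 mm), a myocardial annulus (epicardial radius 2.8 mm) split into
three equal-angle sectors from the anterior RV insertion (90 degrees),
an optional RV crescent whose enhancement leads the LV by 0.35 s, and a
static body disc. One frame is simulated per cardiac cycle at 495.1
beats/min; 60 frames (7.3 s) cover the first pass.

**Arterial input.** The bolus is a normalized gamma-variate
`C(t) = A u^a exp(a (1 - u))`, `u = (t - t0)/(a b)`, which peaks at
exactly `A` mM. Defaults `t0 = 0.6 s` (about five pre-contrast frames),
`a = 3`, `b = 0.6 s`, `A = 1.15` mM were chosen once so that, through
the signal model below, the LV blood-pool enhancement ratio lands near
6.4 and the myocardial enhancement ratio near 1.4 at normal flow — the
regime reported in healthy mice. In vivo AIF shapes and peak
concentrations are rarely measured in the mouse; the published
enhancement ratios are the only anchors, and this is the main sense in
which the phantom is calibrated rather than measured.

**Tissue kinetics.** Each sector's contrast concentration is the causal
convolution of the AIF with a Fermi impulse response
`h(t) = F / (1 + exp(k (t - tau0)))` (`k = 0.2`/s, `tau0 = 1.0` s
shared; `F` set per sector). Flow is defined as
`MBF = h(0) * 60 / rho` with myocardial density `rho = 1.05` g/mL, the
standard value. Defaults give 7.3 mL/g/min in all sectors
(`phantom_config()`) or 1.2 mL/g/min in the anterolateral sector
(`infarct_config()`), matching normal and infarcted mouse myocardium.

**Signal model.** Saturation-recovery with preparation delay
`TD = 100` ms: `SI = s0 (1 - exp(-TD (1/T1 + r C)))`, relaxivity
`r = 3.7` L/mmol/s (typical for Gd-DTPA at 3 T), pre-contrast T1 of
1.9 s (blood), 1.4 s (myocardium), 0.9 s (body). Readout-train
relaxation and flip-angle history are deliberately ignored: the pure
saturation-recovery exponential is the simplest model consistent with
the acquisition, and nothing downstream depends on the omitted terms.

**Noise.** Complex Gaussian noise is added in k-space (not image
space), so magnitude images acquire Rician statistics as on a scanner.
`noise_sd` is expressed as the equivalent image-domain standard
deviation per component so the value transfers across grid sizes; the
default 5.5 (with `s0 = 1000`) puts baseline myocardial pixel SNR near
12, a realistic level for this protocol.

**What the phantom does not emulate.** No respiratory or cardiac
motion, no multi-slice effects, no coil sensitivity structure, no B0 or
flow artifacts, and no intrinsic AIF dispersion between LV and tissue
(delay enters only through `tau0`). Gibbs ringing at the sharp
blood-myocardium edge emerges naturally from k-space truncation and is
not corrected — the dark-rim-like bias it causes is part of what the
tests see. Passing tests therefore validate the algorithms under ideal
geometry and stationarity, not robustness to motion or field artifacts.

## Acquisition and reconstruction

`make_pattern()` generates the sheared-lattice scheme: every frame
acquires 3 central training profiles plus every 10th remaining ky line,
the lattice offset advancing one line per frame (direction fixed for
reproducibility), so 10 consecutive frames cover k-space. Net
acceleration for the 128-line configuration is ~8.3 — training overhead
lowers the nominal factor. Partial Fourier (`pf_fraction < 1`) drops
one ky edge; the reconstruction simply treats those lines as
unacquired (zero-filled, no homodyne), since the acquisition it
emulates reported using partial Fourier without stating factor or
reconstruction. Missingness is always carried as an explicit mask —
never encoded as numeric zero.

`build_basis()` learns the temporal prior from the training lines:
per-pixel temporal means are removed, the frames-by-frames covariance
of the training pixel time-courses is eigendecomposed, and the leading
`n_pc = 8` eigenvectors form the basis. The squared projections of each
pixel's training time-course onto the basis are per-pixel weight
variances — the spatial prior.

`kt_unfold()` solves, for all pixels jointly, the regularized least
squares problem in the spatial-principal-component domain: each pixel's
time-course is `mean + B w`, and the weights minimize the masked
k-space misfit plus a Tikhonov term `lambda * vbar / V` per weight,
so components without training support are shrunk toward zero.
`lambda_reg = 1e-3` is expressed relative to the mean training weight
variance (`vbar`), making the default transfer across signal scales.

Three numerical choices matter and deserve their rationale:

* **Matrix-free conjugate gradients, not closed-form alias sets.** For
  a sheared lattice whose acceleration divides the matrix size, the
  aliasing of each pixel is a closed-form set of R partners. Here
  R = 10 does not divide 128 lines, the point-spread replicas fall off
  the pixel grid, and no exact alias set exists. The normal equations
  are instead solved matrix-free (FFT along the phase-encode dimension
  only, after inverting the fully sampled readout dimension once) by
  preconditioned conjugate gradients. The Jacobi preconditioner is
  exact for this operator's diagonal and is what makes the
  badly-spread spectrum (ridge weights span ~4 orders of magnitude)
  converge in tens of iterations. Tolerance 1e-8 on the relative
  residual, cap 150 iterations, everything deterministic.
* **Separate temporal-mean handling.** The static image is first
  estimated from time-averaged k-space (each ky line averaged over the
  frames in which it was acquired — dense for training lines, 1-in-R
  for the rest) and the basis fit is applied to the residual;
  otherwise the dominant DC energy swamps the component fit.
* **Variance refinement with a training floor.** Three training lines
  give ~40-pixel effective ky resolution: the bright blood pool's
  variance is blurred across the 1.2 mm mouse myocardium, and the
  first-pass solution resolves sector curves poorly. Two refinement
  passes re-estimate the per-pixel weight variances from the current
  magnitude reconstruction (full resolution) and re-solve. Unbounded
  refinement, however, feeds the reconstruction's own band-limits back
  into the prior and acts as a progressive temporal low-pass — enough
  to shift the flat LV peak by a frame. The refined variances are
  therefore floored at 0.3 of the training estimate
  (`refine_floor`), keeping every component the support the training
  data attest to.

Finally, acquired k-space samples are reinserted verbatim into the
solution (hard data consistency). This is why fully sampled input
reproduces the plain inverse-Fourier reconstruction exactly, and why
the consistency limit (rank up, regularization down) is exact rather
than asymptotic.

## Sectors, curves, quantification

`sector_partition()` assigns every annulus pixel to one of three
sectors by the angular position of its center about the centerline
centroid, counterclockwise from the RV insertion: septal,
anterolateral, inferolateral. Angular division is used rather than
centerline arc length — for near-circular mouse ventricles the two
coincide, and the angular rule is exactly rotation-consistent (rotating
the insertion by 120 degrees permutes the masks). Pixels are wholly
assigned, matching ROI-mean practice; no partial-volume weighting.

Quantification follows standard semiquantitative and model-based
practice:

* **Baseline**: mean of the pre-arrival frames; arrival is auto-detected
  on the LV curve as the first frame exceeding the running baseline
  mean by 5 baseline SDs (threshold configurable; at least 3 baseline
  frames required), and the same window is applied to every ROI.
* **First pass**: curves are cropped at the first local minimum of the
  LV curve after its global peak (the trough before recirculation),
  falling back to the first frame below 30% of the corrected peak,
  and to the final frame if neither exists; one cut index for all ROIs.
* **Enhancement ratio**: `(SI_max - SI_baseline)/SI_baseline` on the
  uncorrected curve.
* **Maximal upslope**: ordinary least-squares slope in every contiguous
  five-point window; the maximum is reported. The normalized upslope
  is the tissue maximum over the LV maximum, both on corrected,
  cropped curves. Note it is a proper fraction (~0.1-0.2 for normal
  myocardium here); published values above 1 for this index are
  consistent with the same formula only as percentages or as the
  inverted ratio, so comparisons should check units first.
* **Fermi-constrained deconvolution**: bounded Levenberg-Marquardt
  least squares fits `h(t) = F/(1 + exp(k (t - tau0)))` so that
  `dt * (LV ⊛ h)` matches the tissue curve, with `F >= 0`, `k > 0`,
  `tau0 >= 0`, gradient/step tolerances 1e-10, at most 500 iterations,
  and three deterministic starts bracketing fast, medium and slow
  kinetics (the amplitude start is scaled from the tissue peak and the
  running AIF integral, so starts transfer across signal scales). Ties
  are broken by lowest residual sum of squares, then lowest `F`.
  `MBF = h(0) * 60 / 1.05`.

SI curves are treated as proportional to concentration — no T1
nonlinearity correction — mirroring how such data are analysed in
practice. The phantom's saturation nonlinearity therefore produces a
real, known bias: at an LV enhancement ratio near 6, the blood signal
is visibly compressed at peak while the myocardium stays nearly linear,
and SI-based deconvolution overestimates MBF by roughly 10-15%. This
bias is documented, not corrected; the accuracy tests budget for it.

## Problem sizes and what the tests verify

The test suite validates each operation against independent oracles
(double-loop convolution, all-window OLS, direct covariance
eigendecomposition, per-frame loop-and-average) and checks the
pipeline's study-level claims: exactness of the fully sampled limit on
a 32 x 32, 20-frame phantom; series NRMSE below 0.05 and LV peak-frame
preservation at 10-fold undersampling on the full 128 x 128, 60-frame
phantom; recovery of generating MBF within 2% from noiseless
synthetic curve pairs; median MBF error under 15% and correct
hypoperfusion ordering in at least 95% of 50 seeded noisy phantoms;
and exact sector-partition properties. The training-benefit guard
(NRMSE never rising more than 1e-3 as training lines go 1 to 5) is
asserted at 64 x 64, 40 frames. End-to-end pipeline tests run at
48 x 48, 40 frames with 6-fold acceleration; these sizes were chosen to
exercise every code path at full numerical fidelity while keeping the
suite quick to run.

## Known limitations

* The anterolateral sector-mean curve from the default 10-fold
  reconstruction can deviate by up to ~7% of the curve range on
  isolated frames (the other sectors stay under 5%). Suppressing this
  entirely (unfloored refinement) costs a one-frame shift of the
  saturation-flattened LV peak; the default favors temporal fidelity.
* Reported MBF inherits the +10-15% SI-saturation bias discussed
  above whenever the LV enhancement is strong; rest-flow contrasts and
  orderings are unaffected.
* The argmax-based peak-frame index is fragile when saturation
  flattens the LV peak to sub-percent frame-to-frame differences; for
  real data a vertex fit around the peak would be more stable.
* Reconstruction rank and regularization are validated only against
  the phantom; in-vivo tuning would need its own validation.
* Contours come from ground truth (or user files); there is no
  automatic segmentation, and respiratory-motion correction is only
  emulated through scripted rigid contour shifts.
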