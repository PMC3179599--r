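# ktperf

First-pass contrast-enhanced myocardial perfusion MRI in mice, end to
end and fully simulated: a digital mouse-heart phantom with known
myocardial blood flow (MBF), a k-t undersampled acquisition simulator,
a k-t PCA constrained reconstruction, and semiquantitative plus
absolute perfusion quantification. It is aimed at cardiac MR physicists
and preclinical imaging methodologists who want a tested, reproducible
reference implementation of this pipeline — for validating
reconstruction or quantification changes against ground truth before
touching animal data.

## The science in brief

At murine heart rates (~500 beats/min) a complete image must be
acquired each cardiac cycle within ~43 ms, which is only possible with
roughly 10-fold k-space/time undersampling. The package implements the
standard chain:

* **Acquisition**: sheared-lattice sampling — frame *t* acquires ky
  lines with `ky ≡ t (mod R)` plus a few central *training profiles*
  every frame; `R = 10`, 3 training lines, optional partial Fourier.
* **Reconstruction (k-t PCA)**: temporal principal components
  `B` are learned from the low-resolution training data; each pixel's
  time-course is modelled as `x(t) = x̄ + Σ_p w_p B_p(t)` and the
  weights solve the variance-regularized least-squares problem
  `min_w ‖M F (x̄ + Bw) − d‖² + λ Σ |w|²/σ²_w`
  by preconditioned conjugate gradients, with hard data consistency on
  acquired samples.
* **Quantification**: per-sector signal-intensity curves (three
  equal-angle sectors from the anterior RV insertion), enhancement
  ratio `(SI_max − SI_base)/SI_base`, five-point maximal upslope,
  normalized upslope (myocardium/LV), and absolute MBF by
  Fermi-constrained deconvolution: fit
  `h(t) = F / (1 + exp(k(t − τ₀)))` such that `C_myo = C_LV ⊛ h`,
  then `MBF = h(0)·60/ρ` with `ρ = 1.05` g/mL.

The phantom generates saturation-recovery signal
(`SI = s0(1 − e^{−TD(1/T1 + rC)})`, TD = 100 ms) from a gamma-variate
arterial input and Fermi tissue responses with configurable per-sector
MBF (7.3 mL/g/min normal, 1.2 mL/g/min infarct by default), and adds
seeded complex Gaussian noise in k-space. See the methods vignette
(`vignettes/perfusion-pipeline.Rmd`) for every model, default and
design decision.

## Worked example

An infarcted-mouse study at reduced size (64 x 64, 48 frames, 8-fold
acceleration) so it runs in seconds:

```r
library(ktperf)
cfg <- run_config(phantom = infarct_config(grid_size = 64L, n_frames = 48L),
                  R = 8L, seed = 1L)
res <- run_pipeline(cfg, "demo_run")
res$metrics[, c("roi", "n_pixels", "baseline_si", "peak_si",
                "enhancement_ratio", "normalized_upslope", "mbf_ml_g_min")]
```

```
            roi n_pixels baseline_si peak_si enhancement_ratio
1            lv       24        52.6   381.6             6.252
2        septal       37        70.9   167.6             1.365
3 anterolateral       38        71.9    85.4             0.187
4 inferolateral       37        70.9   167.1             1.356
  normalized_upslope mbf_ml_g_min
1             1.0000           NA
2             0.1591        7.680
3             0.0324        0.876
4             0.1659        8.053
```

Reading the output: the LV blood pool enhances about 6-fold while
remote myocardium enhances ~1.4-fold — the normal first-pass regime.
The anterolateral sector, whose ground-truth flow was set to
1.2 mL/g/min, shows a collapsed enhancement ratio (0.19), a depressed
normalized upslope, and a Fermi-deconvolution MBF of 0.9 mL/g/min
versus ~7.7-8.1 in the remote sectors (ground truth 7.3; the ~10%
overestimate is the documented SI-saturation bias of deconvolving
signal rather than concentration). The run directory contains the
phantom and reconstruction as NIfTI, curves and metrics as CSV, the
k-t data, and a manifest with per-file checksums — rerunning the same
configuration reproduces every file bit-identically.

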