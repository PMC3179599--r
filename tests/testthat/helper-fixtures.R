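# shared fixtures; everything is generated in code, nothing read from disk

# small, fast phantom configuration (noiseless unless asked otherwise)
tiny_config <- function(grid_size = 32L, n_frames = 20L, noise_sd = 0, ...) {
  phantom_config(grid_size = grid_size, n_frames = n_frames,
                 noise_sd = noise_sd, ...)
}

# O(n^2) double-loop causal convolution oracle, independent of the
# FFT-based implementation
conv_oracle <- function(a, h, dt) {
  n <- length(a)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (j in seq_len(i)) s <- s + a[j] * h[i - j + 1]
    out[i] <- s * dt
  }
  out
}

# synthetic uncorrected SI curve: `n_base` flat baseline frames at
# `baseline`, then a gamma-shaped first pass scaled to reach `peak`
bolus_curve <- function(n = 40, n_base = 8, baseline = 300, peak = 1500,
                        dt = 0.12, label = "roi") {
  t <- (seq_len(n) - 1) * dt
  t0 <- (n_base - 0.5) * dt
  u <- pmax(t - t0, 0) / (3 * 0.35)
  shape <- ifelse(t > t0, u^3 * exp(3 * (1 - u)), 0)
  si_curve(t, baseline + (peak - baseline) * shape / max(shape), label)
}

# fully sampled magnitude reconstruction of a series (test oracle path)
full_reference <- function(series) {
  pat <- make_pattern(dim(series$data)[1], dim(series$data)[3],
                      R = 1L, n_train = 0L)
  recon_reference(kt_encode(series, pat))
}
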