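test_that("gamma-variate AIF is zero before onset and peaks at its amplitude", {
  p <- aif_params(onset_s = 0.5, amplitude_mM = 2.5, shape_alpha = 3,
                  shape_beta_s = 0.4)
  expect_identical(aif_gamma_variate(c(0, 0.2, 0.5), p), c(0, 0, 0))
  t_peak <- p$onset_s + p$shape_alpha * p$shape_beta_s
  expect_equal(aif_gamma_variate(t_peak, p), p$amplitude_mM, tolerance = 1e-12)
  # peak is a maximum
  expect_lt(aif_gamma_variate(t_peak - 0.05, p), p$amplitude_mM)
  expect_lt(aif_gamma_variate(t_peak + 0.05, p), p$amplitude_mM)
  expect_error(aif_params(shape_alpha = -1), "shape")
  expect_error(aif_gamma_variate(-1, p), ">= 0")
})

test_that("AIF area matches trapezoidal quadrature of the closed form", {
  # closed form: integral = beta * e^alpha * alpha^-alpha * Gamma(alpha + 1)
  p <- aif_params(onset_s = 0, amplitude_mM = 1, shape_alpha = 3,
                  shape_beta_s = 1)
  tt <- seq(0, 40, by = 1e-3)
  y <- aif_gamma_variate(tt, p)
  trapz <- sum((y[-1] + y[-length(y)]) / 2) * 1e-3
  expect_equal(trapz, exp(3) / 27 * gamma(4), tolerance = 1e-6)
})

test_that("Fermi impulse response has the documented shape", {
  t <- seq(0, 8, by = 0.1)
  expect_identical(fermi_impulse_response(t, 0, 1, 1), rep(0, length(t)))
  # logistic at its center when k * tau0 = 0
  expect_equal(fermi_impulse_response(0, 0.4, 2, 0), 0.2)
  for (seed in 1:5) {
    set.seed(seed)
    F <- runif(1, 0.01, 1); k <- runif(1, 0.05, 5); tau <- runif(1, 0, 3)
    h <- fermi_impulse_response(t, F, k, tau)
    expect_true(all(diff(h) <= 0))          # non-increasing everywhere
    expect_equal(h[1], F / (1 + exp(-k * tau)), tolerance = 1e-12)
  }
  expect_error(fermi_impulse_response(t, 0.1, 0, 1), "k_per_s")
})

test_that("MBF <-> Fermi amplitude conversions are exact inverses", {
  for (mbf in c(0.5, 1.2, 7.3, 12)) {
    F <- fermi_from_mbf(mbf, 0.2, 1.0)
    expect_equal(mbf_from_fermi(F, 0.2, 1.0), mbf, tolerance = 1e-12)
  }
})

test_that("tissue concentration equals the double-loop convolution oracle", {
  dt <- 0.12
  # identity: unit impulse response
  a <- aif_gamma_variate((0:39) * dt, aif_params())
  h_id <- c(1 / dt, rep(0, 39))
  expect_equal(tissue_concentration(a, h_id, dt), a, tolerance = 1e-12)
  expect_equal(tissue_concentration(rep(0, 40), runif(40), dt), rep(0, 40),
               tolerance = 1e-12)
  set.seed(42)
  for (i in 1:3) {
    a <- runif(40); h <- runif(40)
    expect_equal(tissue_concentration(a, h, dt), conv_oracle(a, h, dt),
                 tolerance = 1e-10)
  }
  expect_error(tissue_concentration(1:5, 1:4, dt), "equal length")
})

test_that("saturation-recovery signal model matches its closed form", {
  expect_equal(signal_model(0, t1_pre_s = 1.4, prep_delay_s = 0.1, s0 = 1000),
               1000 * (1 - exp(-0.1 / 1.4)), tolerance = 1e-12)
  expect_equal(signal_model(0, 1.4, 3.7, 0.1, 1000), 68.9372, tolerance = 1e-4)
  # saturation limit and strict monotonicity in concentration
  expect_equal(signal_model(1e6, 1.4), 1000, tolerance = 1e-6)
  c1 <- sort(runif(20, 0, 5))
  expect_true(all(diff(signal_model(c1, 1.4)) > 0))
  expect_error(signal_model(0.5, t1_pre_s = -1), "> 0")
})

test_that("phantom rendering is bit-identical per seed", {
  cfg <- tiny_config(noise_sd = 5.5, seed = 99L)
  a <- render_phantom(cfg)
  b <- render_phantom(cfg)
  expect_identical(a$series$data, b$series$data)
  expect_identical(a$truth$mbf_map, b$truth$mbf_map)
  c <- render_phantom(tiny_config(noise_sd = 5.5, seed = 100L))
  expect_false(identical(a$series$data, c$series$data))
})

test_that("uniform-flow noiseless phantom has identical sector curves", {
  ph <- render_phantom(tiny_config(grid_size = 64L))
  sm <- ph$truth$sector_map
  curves <- lapply(1:3, function(s)
    extract_curve(ph$series, sm == s, paste0("s", s))$si)
  expect_equal(curves[[1]], curves[[2]], tolerance = 1e-12)
  expect_equal(curves[[2]], curves[[3]], tolerance = 1e-12)
  # all pixel time-courses within a sector agree
  px <- which(sm == 1, arr.ind = TRUE)
  ref <- ph$series$data[px[1, 1], px[1, 2], ]
  for (i in seq_len(min(10, nrow(px))))
    expect_equal(ph$series$data[px[i, 1], px[i, 2], ], ref, tolerance = 1e-9)
})

test_that("phantom ground truth is self-consistent", {
  cfg <- infarct_config(grid_size = 64L, n_frames = 30L, noise_sd = 0)
  ph <- render_phantom(cfg)
  # frame times are k * 60 / heart rate, exactly
  expect_identical(ph$series$frame_times_s,
                   (0:29) * (60 / cfg$heart_rate_bpm))
  expect_equal(ph$series$pixel_mm, cfg$fov_mm / cfg$grid_size)
  # stored Fermi parameters reproduce the configured MBF in closed form
  for (s in 1:3) {
    f <- ph$truth$fermi[[s]]
    expect_equal(mbf_from_fermi(f$F_per_s, f$k_per_s, f$tau0_s),
                 cfg$sector_mbf_ml_g_min[s], tolerance = 1e-12)
  }
  expect_true(all(ph$truth$mbf_map >= 0))
  expect_true(all(ph$truth$concentration_series >= 0))
  expect_true(all(ph$series$data >= 0))
  # the anterolateral sector carries the infarct flow
  expect_equal(sort(unique(ph$truth$mbf_map[ph$truth$sector_map == 2L])), 1.2)
})

test_that("default phantom lands in the reported LV enhancement regime", {
  ph <- render_phantom(phantom_config(noise_sd = 0))
  lv <- extract_curve(ph$series, ph$truth$lv_roi_mask, "lv")
  er <- enhancement_ratio(lv)
  expect_gt(er, 5); expect_lt(er, 8)
  myo <- extract_curve(ph$series, ph$truth$sector_map == 1L, "septal")
  er_myo <- enhancement_ratio(myo, n_baseline = detect_arrival(lv) - 1L)
  expect_gt(er_myo, 1.0); expect_lt(er_myo, 1.8)
})

test_that("impossible geometry is rejected", {
  expect_error(phantom_config(geometry = list(endo_radius_mm = 3,
                                              epi_radius_mm = 2)),
               "smaller")
  expect_error(render_phantom(phantom_config(fov_mm = 6)),
               "field of view")
  expect_error(phantom_config(n_frames = 5L), ">= 10")
  expect_error(phantom_config(sector_mbf_ml_g_min = c(1, -1, 1)),
               "non-negative")
})
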