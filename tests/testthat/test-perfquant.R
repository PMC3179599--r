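test_that("baseline correction subtracts the pre-arrival mean", {
  # flat curve: corrected to zero, baseline is the constant
  flat <- si_curve((0:19) * 0.12, rep(123.4, 20), "flat")
  out <- baseline_correct(flat, n_baseline = 8)
  expect_equal(out$si, rep(0, 20))
  expect_equal(attr(out, "baseline"), 123.4)

  # eight pre-contrast frames averaging 290.8, as in a healthy myocardium
  pre <- 290.8 + c(-40, 40, -25, 25, -10, 10, -5, 5)
  cv <- si_curve((0:19) * 0.12, c(pre, seq(350, 700, length.out = 12)), "myo")
  out <- baseline_correct(cv, n_baseline = 8)
  expect_equal(attr(out, "baseline"), 290.8, tolerance = 1e-12)
  expect_equal(out$si[1:8], pre - 290.8)
})

test_that("automatic arrival detection finds a constructed step", {
  step <- si_curve((0:19) * 0.12, c(rep(100, 10), rep(300, 10)), "lv")
  expect_identical(detect_arrival(step), 11L)
  out <- baseline_correct(step)
  expect_identical(attr(out, "n_baseline"), 10L)
  # arrival too early leaves no baseline
  early <- si_curve((0:19) * 0.12, c(100, 100, 400, seq(500, 600,
                                                        length.out = 17)), "lv")
  expect_error(baseline_correct(early), "baseline|arrival")
  expect_error(baseline_correct(flat <- si_curve(0:6, rep(1, 7), "x"),
                                n_baseline = 4), "frames")
})

test_that("first-pass cropping cuts at the trough before recirculation", {
  t <- (0:29) * 0.12
  # rise to a peak at frame 11, fall to a trough at frame 19, then a bump
  si <- c(seq(0, 100, length.out = 11), seq(95, 30, length.out = 8),
          seq(35, 50, length.out = 6), seq(48, 40, length.out = 5))
  lv <- si_curve(t, si, "lv")
  cropped <- crop_first_pass(lv, lv)
  expect_identical(attr(cropped, "cut_index"), 19L)
  # the same cut is imposed on a tissue curve
  tis <- si_curve(t, sqrt(seq_len(30)), "myo")
  expect_identical(attr(crop_first_pass(tis, lv), "cut_index"), 19L)
  expect_equal(length(crop_first_pass(tis, lv)$si), 19L)
  # a curve already ending at its trough is untouched
  mono <- si_curve(t[1:19], si[1:19], "lv")
  expect_identical(attr(crop_first_pass(mono, mono), "cut_index"), 19L)
  expect_error(crop_first_pass(si_curve(t, seq(0, 29), "lv"),
                               si_curve(t, seq(0, 29), "lv")), "peak")
})

test_that("enhancement ratio reproduces the printed worked examples", {
  mk <- function(base, peak) bolus_curve(40, 8, base, peak)
  # infarcted anterolateral segment group means
  expect_equal(round(enhancement_ratio(mk(376.0, 543.5), n_baseline = 8), 2),
               0.45)
  # control LV group means: ratio of printed means is 6.31 (the printed
  # cohort figure 6.32 averages per-animal ratios)
  expect_equal(round(enhancement_ratio(mk(293.8, 2148.8), n_baseline = 8), 2),
               6.31)
  # constant curve has zero enhancement
  expect_equal(enhancement_ratio(si_curve(0:19, rep(50, 20), "x"),
                                 n_baseline = 8), 0)
  # invariant under positive rescaling
  cv <- mk(300, 1500)
  cv2 <- si_curve(cv$t_s, cv$si * 3.7, "x")
  expect_equal(enhancement_ratio(cv2, n_baseline = 8),
               enhancement_ratio(cv, n_baseline = 8), tolerance = 1e-12)
  neg <- si_curve(0:19, c(rep(-5, 8), seq(1, 40, length.out = 12)), "x")
  expect_error(enhancement_ratio(neg, n_baseline = 8), "baseline")
})

test_that("five-point maximal upslope equals the all-windows OLS oracle", {
  t <- (0:29) * 0.12
  # an exact line returns its slope from any window
  line <- si_curve(t, 7.5 * t + 3, "x")
  expect_equal(max_upslope(line)$slope, 7.5, tolerance = 1e-10)
  expect_equal(max_upslope(si_curve(t, rep(4, 30), "x"))$slope, 0)
  set.seed(21)
  for (i in 1:3) {
    y <- cumsum(rnorm(30))
    cv <- si_curve(t, y, "x")
    got <- max_upslope(cv, window = 5L)
    slopes <- vapply(1:26, function(j)
      unname(stats::coef(stats::lm(y[j:(j + 4)] ~ t[j:(j + 4)]))[2]),
      numeric(1))
    expect_equal(got$slope, max(slopes), tolerance = 1e-10)
    expect_identical(got$window_start, which.max(slopes))
  }
  expect_error(max_upslope(si_curve(0:2, 1:3, "x")), "window")
})

test_that("normalized upslope is 1 for identical curves and scales linearly", {
  lv <- bolus_curve(40, 8, 300, 2000, label = "lv")
  expect_equal(normalized_upslope(lv, lv), 1, tolerance = 1e-12)
  half <- si_curve(lv$t_s, 300 + 0.5 * (lv$si - 300), "myo")
  expect_equal(normalized_upslope(half, lv), 0.5, tolerance = 1e-10)
})

test_that("Fermi deconvolution recovers noiseless generating parameters", {
  dt <- 60 / 495.1
  t <- (0:59) * dt
  a <- aif_gamma_variate(t, aif_params())
  for (mbf in c(7.3, 1.2)) {
    F <- fermi_from_mbf(mbf, 0.2, 1.0)
    ct <- tissue_concentration(a, fermi_impulse_response(t, F, 0.2, 1.0), dt)
    fit <- fermi_deconvolve(si_curve(t, a, "lv"), si_curve(t, ct, "myo"))
    expect_true(fit$converged)
    expect_equal(fit$mbf_ml_g_min, mbf, tolerance = 0.02)
  }
  # zero tissue signal means zero flow
  fit0 <- fermi_deconvolve(si_curve(t, a, "lv"), si_curve(t, 0 * a, "myo"))
  expect_equal(fit0$mbf_ml_g_min, 0)
  # scaling the tissue curve scales the recovered amplitude
  F <- fermi_from_mbf(7.3, 0.2, 1.0)
  ct <- tissue_concentration(a, fermi_impulse_response(t, F, 0.2, 1.0), dt)
  f1 <- fermi_deconvolve(si_curve(t, a, "lv"), si_curve(t, ct, "myo"))
  f2 <- fermi_deconvolve(si_curve(t, a, "lv"), si_curve(t, 0.37 * ct, "myo"))
  expect_equal(f2$F_per_s / f1$F_per_s, 0.37, tolerance = 1e-3)
  # non-uniform grids are rejected
  tbad <- t; tbad[10] <- tbad[10] + 0.05
  expect_error(fermi_deconvolve(si_curve(tbad, a, "lv"),
                                si_curve(tbad, ct, "myo")), "uniform")
})

test_that("quantify_curves reports one row per ROI with the LV first", {
  ph <- render_phantom(infarct_config(grid_size = 64L, n_frames = 40L,
                                      noise_sd = 0))
  sm <- ph$truth$sector_map
  curves <- list(lv = extract_curve(ph$series, ph$truth$lv_roi_mask, "lv"),
                 septal = extract_curve(ph$series, sm == 1L, "septal"),
                 anterolateral = extract_curve(ph$series, sm == 2L,
                                               "anterolateral"),
                 inferolateral = extract_curve(ph$series, sm == 3L,
                                               "inferolateral"))
  m <- quantify_curves(curves)
  expect_equal(nrow(m), 4L)
  expect_identical(m$roi[1], "lv")
  expect_true(all(is.na(m$mbf_ml_g_min[1])))
  expect_true(all(m$mbf_ml_g_min[-1] > 0))
  # normalized upslope of tissue is a proper fraction and lowest in the
  # hypoperfused sector, matching the direction seen in vivo
  nus <- m$normalized_upslope[match(c("septal", "anterolateral",
                                      "inferolateral"), m$roi)]
  expect_true(all(nus > 0 & nus < 1))
  expect_lt(nus[2], min(nus[c(1, 3)]))
  # enhancement ratio collapses in the infarcted sector
  er <- m$enhancement_ratio[match(c("septal", "anterolateral"), m$roi)]
  expect_lt(er[2], 0.5 * er[1])
})
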