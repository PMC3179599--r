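circle <- function(r_px, c0 = 63.5, n = 72, label = "roi") {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  roi_contour(cbind(x = c0 + r_px * cos(th), y = c0 + r_px * sin(th)), label)
}

test_that("equal-angle partition of a concentric annulus is balanced", {
  epi <- circle(14, label = "epicardial")
  endo <- circle(8, label = "endocardial")
  sp <- sector_partition(epi, endo, 90, grid = c(128L, 128L))
  counts <- vapply(sp$masks, sum, integer(1))
  expect_true(all(abs(counts - mean(counts)) / mean(counts) < 0.02))
  expect_named(sp$masks, c("septal", "anterolateral", "inferolateral"))
  # exact partition: pairwise disjoint, union = annulus
  expect_identical(sp$masks[[1]] | sp$masks[[2]] | sp$masks[[3]], sp$annulus)
  expect_equal(sum(counts), sum(sp$annulus))
  expect_false(any(sp$masks[[1]] & sp$masks[[2]]))
  expect_false(any(sp$masks[[2]] & sp$masks[[3]]))
  expect_false(any(sp$masks[[1]] & sp$masks[[3]]))
})

test_that("rotating the insertion point by 120 degrees permutes sectors", {
  epi <- circle(14, label = "epicardial")
  endo <- circle(8, label = "endocardial")
  a <- sector_partition(epi, endo, 90, grid = c(128L, 128L))
  b <- sector_partition(epi, endo, 210, grid = c(128L, 128L))
  expect_identical(b$masks$septal, a$masks$anterolateral)
  expect_identical(b$masks$anterolateral, a$masks$inferolateral)
  expect_identical(b$masks$inferolateral, a$masks$septal)
})

test_that("partition properties hold across randomized geometries", {
  set.seed(11)
  for (i in 1:5) {
    r_endo <- runif(1, 5, 9)
    r_epi <- r_endo + runif(1, 3, 6)
    ang <- runif(1, 0, 360)
    sp <- sector_partition(circle(r_epi, label = "epicardial"),
                           circle(r_endo, label = "endocardial"),
                           ang, grid = c(128L, 128L))
    u <- Reduce(`|`, sp$masks)
    expect_identical(u, sp$annulus)
    expect_equal(sum(vapply(sp$masks, sum, integer(1))), sum(u))
  }
  expect_error(sector_partition(circle(8, label = "epicardial"),
                                circle(14, label = "endocardial"),
                                90, grid = c(128L, 128L)),
               "intersect")
})

test_that("phantom infarct localizes to the anterolateral sector label", {
  ph <- render_phantom(infarct_config(noise_sd = 0, n_frames = 10L))
  sp <- sector_partition(ph$truth$epi_contour, ph$truth$endo_contour,
                         ph$truth$rv_insertion_angle_deg,
                         grid = dim(ph$truth$mbf_map))
  infarct_px <- ph$truth$mbf_map == 1.2
  expect_true(all(infarct_px == sp$masks$anterolateral))
})

test_that("curve extraction equals a per-frame loop-and-average oracle", {
  set.seed(3)
  data <- array(runif(16 * 16 * 12, 50, 150), c(16, 16, 12))
  series <- dynamic_series(data, 0:11, 1)
  # constant series gives a flat curve
  flat <- extract_curve(dynamic_series(array(100, c(16, 16, 12)), 0:11, 1),
                        matrix(TRUE, 16, 16), "flat")
  expect_equal(flat$si, rep(100, 12))
  # single pixel equals its own time-course
  m1 <- matrix(FALSE, 16, 16); m1[5, 9] <- TRUE
  expect_equal(extract_curve(series, m1, "px")$si, data[5, 9, ])
  # 50-pixel mask vs explicit oracle
  mask <- matrix(FALSE, 16, 16)
  mask[sample(256, 50)] <- TRUE
  cv <- extract_curve(series, mask, "roi")
  oracle <- numeric(12)
  for (k in 1:12) {
    s <- 0; n <- 0
    for (i in 1:16) for (j in 1:16) if (mask[i, j]) {
      s <- s + data[i, j, k]; n <- n + 1
    }
    oracle[k] <- s / n
  }
  expect_equal(cv$si, oracle, tolerance = 1e-12)
  expect_equal(cv$n_pixels, 50L)
  expect_error(extract_curve(series, matrix(FALSE, 16, 16)), "empty")
})

test_that("contour shifting is rigid, invertible and equivariant", {
  ct <- circle(6, c0 = 10, label = "roi")
  same <- shift_contours(list(ct), 0, 0)[[1]][[1]]
  expect_equal(same$points, ct$points)
  back <- shift_contours(shift_contours(list(ct), 1, 0)[[1]], -1, 0)[[1]][[1]]
  expect_equal(back$points, ct$points)

  # curve from shifted contours on a shifted series = original curve
  set.seed(5)
  data <- array(runif(24 * 24 * 6), c(24, 24, 6))
  shifted <- array(0, c(24, 24, 6))
  shifted[, 2:24, ] <- data[, 1:23, ]        # +1 pixel in x (columns)
  ct0 <- circle(5, c0 = 11, label = "roi")
  ct1 <- shift_contours(list(ct0), 1, 0)[[1]][[1]]
  m0 <- ktperf:::contour_mask(ct0, c(24L, 24L))
  m1 <- ktperf:::contour_mask(ct1, c(24L, 24L))
  c0v <- extract_curve(dynamic_series(data, 0:5, 1), m0, "a")$si
  c1v <- extract_curve(dynamic_series(shifted, 0:5, 1), m1, "a")$si
  expect_equal(c1v, c0v, tolerance = 1e-12)
  expect_error(shift_contours(list(ct), NA, 0), "finite")
})

test_that("contours and curves round-trip through JSON and CSV", {
  ph <- render_phantom(tiny_config(n_frames = 12L))
  path <- tempfile(fileext = ".json")
  write_contours(list(ph$truth$epi_contour, ph$truth$endo_contour), path)
  back <- read_contours(path)
  expect_equal(back$epicardial$points, ph$truth$epi_contour$points,
               tolerance = 1e-12)
  curves <- list(lv = extract_curve(ph$series, ph$truth$lv_roi_mask, "lv"),
                 septal = extract_curve(ph$series, ph$truth$sector_map == 1L,
                                        "septal"))
  cpath <- tempfile(fileext = ".csv")
  write_curves(curves, cpath)
  back2 <- read_curves(cpath)
  expect_equal(back2$lv$si, curves$lv$si, tolerance = 1e-9)
  expect_equal(back2$septal$t_s, curves$septal$t_s, tolerance = 1e-9)
})
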