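#' Detect bolus arrival on an SI curve
#'
#' Arrival is the first frame whose signal exceeds the running baseline
#' mean by `sd_factor` baseline standard deviations; frames before it
#' form the baseline. A noiseless step therefore triggers on the first
#' enhanced frame.
#'
#' @param curve an [si_curve()] (normally the LV blood-pool curve).
#' @param sd_factor detection threshold in baseline SDs.
#' @param min_baseline minimum number of pre-arrival frames required.
#' @return The 1-based arrival frame index.
#' @export
detect_arrival <- function(curve, sd_factor = 5, min_baseline = 3L) {
  si <- curve$si
  n <- length(si)
  if (n < min_baseline + 2L)
    stop("curve too short for arrival detection", call. = FALSE)
  arrival <- n + 1L
  for (j in (min_baseline + 1L):n) {
    base <- si[seq_len(j - 1L)]
    thr <- mean(base) + sd_factor * stats::sd(base)
    if (si[j] > thr) { arrival <- j; break }
  }
  if (arrival > n) stop("no bolus arrival detected", call. = FALSE)
  if (arrival - 1L < min_baseline)
    stop("insufficient baseline: arrival at frame ", arrival, call. = FALSE)
  arrival
}

#' Baseline-correct an SI curve
#'
#' The baseline is the mean of the pre-arrival frames; it is subtracted
#' from the whole curve. In auto mode (`n_baseline = NULL`) the arrival
#' frame is detected on `reference` (normally the LV curve, so that the
#' same baseline window is applied to every ROI of a study) via
#' [detect_arrival()].
#'
#' @param curve an [si_curve()].
#' @param n_baseline number of baseline frames, or `NULL` for auto
#'   detection. The curve must have at least `n_baseline + 5` frames.
#' @param reference curve used for arrival detection in auto mode.
#' @param sd_factor threshold passed to [detect_arrival()].
#' @return The corrected [si_curve()], with attributes `baseline`
#'   (subtracted value) and `n_baseline`.
#' @export
baseline_correct <- function(curve, n_baseline = NULL, reference = curve,
                             sd_factor = 5) {
  if (is.null(n_baseline))
    n_baseline <- detect_arrival(reference, sd_factor = sd_factor) - 1L
  n_baseline <- as.integer(n_baseline)
  if (n_baseline < 1L) stop("`n_baseline` must be >= 1", call. = FALSE)
  if (length(curve$si) < n_baseline + 5L)
    stop("curve needs at least `n_baseline` + 5 frames", call. = FALSE)
  baseline <- mean(curve$si[seq_len(n_baseline)])
  out <- si_curve(curve$t_s, curve$si - baseline,
                  roi_label = curve$roi_label, n_pixels = curve$n_pixels)
  attr(out, "baseline") <- baseline
  attr(out, "n_baseline") <- n_baseline
  out
}

# 1-based index of the end of the first pass on an LV curve: first
# local minimum after the global peak, falling back to the first frame
# below `fallback_frac` of the peak (above baseline); the last frame
# when neither occurs
first_pass_end <- function(lv, fallback_frac = 0.30) {
  si <- lv$si
  n <- length(si)
  ip <- which.max(si)
  if (ip == n || ip == 1L)
    stop("no first-pass peak found on the LV curve", call. = FALSE)
  if (ip + 1L <= n - 1L) {
    for (i in (ip + 1L):(n - 1L)) {
      if (si[i] <= si[i - 1L] && si[i] < si[i + 1L]) return(i)
    }
  }
  thr <- fallback_frac * si[ip]             # curve assumed corrected

  below <- which(si[(ip + 1L):n] < thr)
  if (length(below) > 0L) return(ip + below[1L])
  n
}

#' Crop curves to the first pass
#'
#' The end of the first pass is the first local minimum of the LV
#' curve after its global peak (the trough before recirculation); when
#' no local minimum exists, the first frame where the LV signal falls
#' below 30% of its peak, and failing that the final frame. The same
#' cut index is applied to the tissue curve and the LV curve.
#'
#' @param curve tissue [si_curve()] to crop (pass the LV curve itself to
#'   crop the LV).
#' @param lv_curve baseline-corrected LV blood-pool curve on the same
#'   time grid.
#' @param fallback_frac peak fraction of the fallback rule.
#' @return The cropped [si_curve()] with attribute `cut_index`.
#' @export
crop_first_pass <- function(curve, lv_curve, fallback_frac = 0.30) {
  if (length(curve$t_s) != length(lv_curve$t_s) ||
      max(abs(curve$t_s - lv_curve$t_s)) > 1e-9)
    stop("curves do not share a time grid", call. = FALSE)
  cut <- first_pass_end(lv_curve, fallback_frac)
  out <- si_curve(curve$t_s[seq_len(cut)], curve$si[seq_len(cut)],
                  roi_label = curve$roi_label, n_pixels = curve$n_pixels)
  attr(out, "baseline") <- attr(curve, "baseline")
  attr(out, "cut_index") <- cut
  out
}

#' Enhancement ratio of an SI curve
#'
#' `(SI_max - SI_baseline) / SI_baseline`, computed on the uncorrected
#' curve with the baseline taken as the mean of the pre-arrival frames.
#' Invariant under multiplication of the whole curve by a positive
#' constant.
#'
#' @param curve uncorrected [si_curve()].
#' @param n_baseline baseline frame count, or `NULL` for auto detection
#'   on this curve.
#' @inheritParams baseline_correct
#' @return The dimensionless enhancement ratio.
#' @export
enhancement_ratio <- function(curve, n_baseline = NULL, reference = curve,
                              sd_factor = 5) {
  if (is.null(n_baseline))
    n_baseline <- detect_arrival(reference, sd_factor = sd_factor) - 1L
  baseline <- mean(curve$si[seq_len(n_baseline)])
  if (baseline <= 0)
    stop("non-positive baseline; enhancement ratio undefined", call. = FALSE)
  (max(curve$si) - baseline) / baseline
}

#' Maximal upslope by sliding-window least squares
#'
#' Fits an ordinary least-squares line to the signal in every
#' contiguous window of `window` points and returns the steepest slope
#' and where it occurs.
#'
#' @param curve an [si_curve()] with at least `window` frames.
#' @param window number of points per fit (default five-point fitting).
#' @return A list: `slope` (SI units per second), `window_start`
#'   (1-based index of the window's first frame).
#' @export
max_upslope <- function(curve, window = 5L) {
  n <- length(curve$si)
  window <- as.integer(window)
  if (n < window) stop("curve shorter than the fitting window", call. = FALSE)
  slopes <- vapply(seq_len(n - window + 1L), function(i) {
    idx <- i:(i + window - 1L)
    tt <- curve$t_s[idx]; yy <- curve$si[idx]
    sum((tt - mean(tt)) * (yy - mean(yy))) / sum((tt - mean(tt))^2)
  }, numeric(1))
  best <- which.max(slopes)
  list(slope = slopes[best], window_start = best)
}

#' Normalized SI upslope
#'
#' Ratio of the maximal five-point upslope of the myocardial curve to
#' that of the LV blood-pool curve, both baseline corrected and cropped
#' to the first pass with the cut derived from the LV curve.
#'
#' @param myo,lv uncorrected myocardial and LV [si_curve()]s on a
#'   shared time grid.
#' @param window points per upslope fit.
#' @inheritParams baseline_correct
#' @return The dimensionless normalized upslope (myocardium / LV).
#' @export
normalized_upslope <- function(myo, lv, window = 5L, n_baseline = NULL,
                               sd_factor = 5) {
  lv_c <- baseline_correct(lv, n_baseline = n_baseline, sd_factor = sd_factor)
  myo_c <- baseline_correct(myo, n_baseline = attr(lv_c, "n_baseline"))
  lv_fp <- crop_first_pass(lv_c, lv_c)
  myo_fp <- crop_first_pass(myo_c, lv_c)
  lv_slope <- max_upslope(lv_fp, window)$slope
  if (lv_slope <= 0)
    stop("non-positive LV upslope; normalized upslope undefined", call. = FALSE)
  max_upslope(myo_fp, window)$slope / lv_slope
}

#' Fermi-constrained deconvolution of a tissue curve
#'
#' Fits the Fermi impulse response
#' `h(t) = F / (1 + exp(k * (t - tau0)))` so that the causal
#' convolution of the (baseline-corrected, first-pass-cropped) LV
#' curve with `h` matches the tissue curve in the least-squares sense,
#' subject to `F >= 0`, `k > 0`, `tau0 >= 0`. Myocardial blood flow is
#' read off the fitted response as `h(0) * 60 / density_g_ml`.
#'
#' Optimization uses bounded Levenberg-Marquardt least squares with
#' three deterministic multi-starts (fast, medium and slow flow); ties
#' are broken by lowest residual sum of squares, then lowest `F`.
#'
#' @param lv,tissue baseline-corrected, first-pass-cropped
#'   [si_curve()]s on a shared uniform time grid.
#' @param init optional numeric `c(F, k, tau0)` replacing the automatic
#'   multi-starts.
#' @param density_g_ml myocardial density used for the mL/g/min
#'   conversion.
#' @param max_iter iteration cap per start.
#' @return An object of class `fermi_fit`: `F_per_s`, `k_per_s`,
#'   `tau0_s`, `mbf_ml_g_min`, `rss`, `converged`, `n_iter`, and the
#'   `fitted` tissue curve.
#' @export
fermi_deconvolve <- function(lv, tissue, init = NULL, density_g_ml = 1.05,
                             max_iter = 500L) {
  if (length(lv$si) != length(tissue$si))
    stop("LV and tissue curves must have equal length", call. = FALSE)
  dt <- curve_dt(lv)                      # errors on non-uniform grids
  t_s <- lv$t_s - lv$t_s[1]
  y <- tissue$si
  a <- lv$si
  t_max <- max(t_s)

  forward <- function(p)
    tissue_concentration(a, fermi_impulse_response(t_s, p[1], p[2], p[3]), dt)
  residual <- function(p) y - forward(p)

  if (max(abs(y)) == 0) {
    fit <- list(par = c(0, 1, 0), rss = 0, converged = TRUE, n_iter = 0L)
  } else {
    # amplitude scale from a constant-response approximation at the
    # tissue peak; multi-starts bracket fast, medium and slow kinetics
    ipk <- which.max(y)
    denom <- sum(a[seq_len(ipk)]) * dt
    f0 <- if (denom > 0) max(y) / denom else 1
    starts <- if (is.null(init)) {
      list(c(2.0 * f0, 1.0, 0.5), c(f0, 0.4, 1.0), c(0.3 * f0, 0.15, 2.0))
    } else {
      list(as.numeric(init))
    }
    lower <- c(0, 1e-6, 0)
    upper <- c(Inf, 100, max(t_max, 1))
    fits <- lapply(starts, function(p0) {
      p0 <- pmin(pmax(p0, lower + c(0, 1e-6, 0)), upper)
      res <- try(minpack.lm::nls.lm(
        par = p0, lower = lower, upper = upper, fn = residual,
        control = minpack.lm::nls.lm.control(
          maxiter = max_iter, ftol = 1e-10, ptol = 1e-10, gtol = 1e-10)),
        silent = TRUE)
      if (inherits(res, "try-error")) return(NULL)
      list(par = res$par, rss = sum(res$fvec^2),
           converged = res$info %in% 1:4, n_iter = res$niter)
    })
    fits <- Filter(Negate(is.null), fits)
    if (length(fits) == 0L)
      stop("Fermi deconvolution failed in every start", call. = FALSE)
    ord <- order(vapply(fits, `[[`, numeric(1), "rss"),
                 vapply(fits, function(f) f$par[1], numeric(1)))
    fit <- fits[[ord[1]]]
  }

  p <- fit$par
  structure(list(F_per_s = p[1], k_per_s = p[2], tau0_s = p[3],
                 mbf_ml_g_min = mbf_from_fermi(p[1], p[2], p[3], density_g_ml),
                 rss = fit$rss, converged = fit$converged,
                 n_iter = fit$n_iter,
                 fitted = forward(p)),
            class = "fermi_fit")
}

#' @export
print.fermi_fit <- function(x, ...) {
  cat(sprintf(
    "<fermi_fit> MBF %.2f mL/g/min (F = %.4g /s, k = %.3g /s, tau0 = %.3g s)\n",
    x$mbf_ml_g_min, x$F_per_s, x$k_per_s, x$tau0_s))
  cat(sprintf("  rss %.4g, %s in %d iterations\n", x$rss,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Quantify perfusion for a set of ROI curves
#'
#' Runs the full per-ROI analysis used for reporting: baseline
#' correction (arrival detected on the LV curve and shared by all
#' ROIs), first-pass cropping at the LV-derived cut, enhancement ratio,
#' five-point maximal upslope, normalized upslope, and
#' Fermi-deconvolution MBF for the tissue ROIs.
#'
#' @param curves named list of uncorrected [si_curve()]s including one
#'   labelled `lv`.
#' @param window points per upslope fit.
#' @param sd_factor arrival detection threshold in baseline SDs.
#' @param density_g_ml myocardial density for the MBF conversion.
#' @return A `data.frame` with one row per ROI (LV first): columns
#'   `roi`, `n_pixels`, `baseline_si`, `peak_si`, `enhancement_ratio`,
#'   `max_upslope`, `normalized_upslope`, `mbf_ml_g_min`, `fermi_F`,
#'   `fermi_k`, `fermi_tau0`, `fermi_rss`, `fermi_converged`.
#' @export
quantify_curves <- function(curves, window = 5L, sd_factor = 5,
                            density_g_ml = 1.05) {
  if (!"lv" %in% names(curves))
    stop("`curves` must contain an element named 'lv'", call. = FALSE)
  lv <- curves[["lv"]]
  n_base <- detect_arrival(lv, sd_factor = sd_factor) - 1L
  lv_c <- baseline_correct(lv, n_baseline = n_base)
  lv_fp <- crop_first_pass(lv_c, lv_c)
  lv_slope <- max_upslope(lv_fp, window)$slope

  rows <- lapply(names(curves), function(lb) {
    cv <- curves[[lb]]
    cv_c <- baseline_correct(cv, n_baseline = n_base)
    cv_fp <- crop_first_pass(cv_c, lv_c)
    slope <- max_upslope(cv_fp, window)$slope
    er <- enhancement_ratio(cv, n_baseline = n_base)
    if (lb == "lv") {
      mbf <- NA_real_; ff <- NULL
    } else {
      fit <- fermi_deconvolve(lv_fp, cv_fp, density_g_ml = density_g_ml)
      mbf <- fit$mbf_ml_g_min; ff <- fit
    }
    data.frame(
      roi = lb, n_pixels = cv$n_pixels,
      baseline_si = attr(cv_c, "baseline"),
      peak_si = max(cv$si),
      enhancement_ratio = er,
      max_upslope = slope,
      normalized_upslope = if (lb == "lv") 1 else slope / lv_slope,
      mbf_ml_g_min = mbf,
      fermi_F = if (is.null(ff)) NA_real_ else ff$F_per_s,
      fermi_k = if (is.null(ff)) NA_real_ else ff$k_per_s,
      fermi_tau0 = if (is.null(ff)) NA_real_ else ff$tau0_s,
      fermi_rss = if (is.null(ff)) NA_real_ else ff$rss,
      fermi_converged = if (is.null(ff)) NA else ff$converged,
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$roi != "lv"), , drop = FALSE]
}
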