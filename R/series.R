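#' Dynamic image series
#'
#' The central exchange object of the package: a stack of short-axis
#' frames, one per cardiac cycle, with the acquisition time of each
#' frame and the isotropic in-plane pixel spacing. Frame `k` (1-based)
#' is acquired at `(k-1) * 60 / heart_rate_bpm` seconds.
#'
#' @param data 3-D array, `rows x cols x frames`. Usually real and
#'   non-negative (magnitude images); complex data are permitted for
#'   intermediate objects such as low-resolution training series.
#' @param frame_times_s numeric vector of frame times in seconds,
#'   strictly increasing, one per frame.
#' @param pixel_mm isotropic in-plane pixel spacing in mm.
#' @return An object of class `dynamic_series`: a list with elements
#'   `data`, `frame_times_s` and `pixel_mm`.
#' @export
dynamic_series <- function(data, frame_times_s, pixel_mm) {
  if (length(dim(data)) != 3L)
    stop("`data` must be a 3-D array (rows x cols x frames)", call. = FALSE)
  if (dim(data)[3] != length(frame_times_s))
    stop("frame count does not match length of `frame_times_s`", call. = FALSE)
  if (any(diff(frame_times_s) <= 0))
    stop("`frame_times_s` must be strictly increasing", call. = FALSE)
  if (!all(is.finite(Mod(data))))
    stop("`data` must be finite", call. = FALSE)
  if (!is.numeric(pixel_mm) || length(pixel_mm) != 1L || pixel_mm <= 0)
    stop("`pixel_mm` must be a single positive number", call. = FALSE)
  structure(list(data = data, frame_times_s = as.numeric(frame_times_s),
                 pixel_mm = as.numeric(pixel_mm)),
            class = "dynamic_series")
}

#' @export
print.dynamic_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dynamic_series> %d x %d pixels, %d frames\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel %.4g mm, frame interval %.4g s (%.4g s total)\n",
              x$pixel_mm, if (d[3] > 1) diff(x$frame_times_s)[1] else NA_real_,
              max(x$frame_times_s)))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[3]

#' Signal-intensity/time curve
#'
#' One region of interest reduced to its mean signal per frame; the unit
#' of perfusion quantification.
#'
#' @param t_s frame times in seconds.
#' @param si mean ROI signal intensity per frame (arbitrary units).
#' @param roi_label character label for the ROI (e.g. `"lv"`, `"septal"`).
#' @param n_pixels number of pixels averaged into the curve.
#' @return An object of class `si_curve`.
#' @export
si_curve <- function(t_s, si, roi_label = "roi", n_pixels = 1L) {
  if (length(t_s) != length(si))
    stop("`t_s` and `si` must have equal length", call. = FALSE)
  if (!all(is.finite(si))) stop("`si` must be finite", call. = FALSE)
  if (n_pixels < 1L) stop("`n_pixels` must be >= 1", call. = FALSE)
  structure(list(t_s = as.numeric(t_s), si = as.numeric(si),
                 roi_label = as.character(roi_label),
                 n_pixels = as.integer(n_pixels)),
            class = "si_curve")
}

#' @export
print.si_curve <- function(x, ...) {
  cat(sprintf("<si_curve> '%s': %d frames, %d pixels, SI range [%.4g, %.4g]\n",
              x$roi_label, length(x$si), x$n_pixels, min(x$si), max(x$si)))
  invisible(x)
}

# uniform frame spacing of a curve (errors when the grid is not uniform)
curve_dt <- function(curve, tol = 1e-6) {
  dts <- diff(curve$t_s)
  if (length(dts) == 0L) stop("curve has a single frame", call. = FALSE)
  if (max(abs(dts - dts[1])) > tol * abs(dts[1]))
    stop("curve time grid is not uniform", call. = FALSE)
  dts[1]
}

#' Write or read a dynamic series as NIfTI-1
#'
#' The series is stored with dimensions (x, y, z = 1, t); pixel spacing
#' goes into `pixdim[1:2]` and the (uniform) frame interval into
#' `pixdim[4]`, so timing round-trips through the file. Frame times are
#' reconstructed on load as `(k-1) * dt`.
#'
#' @param series a [dynamic_series()].
#' @param path output file, `.nii` or `.nii.gz`.
#' @return `save_series` returns `path` invisibly; `load_series` returns
#'   a [dynamic_series()].
#' @export
save_series <- function(series, path) {
  d <- dim(series$data)
  dt <- if (d[3] > 1) diff(series$frame_times_s)[1] else 1
  arr <- array(Re(series$data), dim = c(d[1], d[2], 1L, d[3]))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(series$pixel_mm, series$pixel_mm, 1, dt)
  RNifti::pixunits(img) <- c("mm", "s")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname save_series
#' @export
load_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) < 3L) stop("file is not a dynamic series: ", path, call. = FALSE)
  if (length(d) == 3L) d <- c(d[1:2], 1L, d[3])  # defensive; we always write 4-D
  pd <- RNifti::pixdim(img)
  dt <- if (length(pd) >= 4 && pd[4] > 0) pd[4] else 1
  dynamic_series(array(as.array(img), dim = c(d[1], d[2], d[4])),
                 frame_times_s = (seq_len(d[4]) - 1) * dt,
                 pixel_mm = pd[1])
}
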