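#' Sheared-lattice k-t sampling pattern
#'
#' Builds the acquisition scheme used for accelerated first-pass
#' imaging: every frame acquires a small set of central "training"
#' ky lines plus every `R`-th remaining line, with the lattice offset
#' advancing by one line per frame so that any `R` consecutive frames
#' jointly cover k-space. Partial Fourier optionally drops the lines at
#' one edge of ky space (zero-filled at reconstruction).
#'
#' ky indices are 1-based rows of the centered k-space matrix, with DC
#' at row `floor(n_ky/2) + 1`.
#'
#' @param n_ky number of phase-encode lines (matrix rows).
#' @param n_frames number of dynamic frames.
#' @param R nominal acceleration factor (lattice spacing), `1 <= R <= n_ky`.
#' @param n_train number of central training profiles acquired every
#'   frame, `0 <= n_train < n_ky`, centered on DC.
#' @param pf_fraction fraction of ky space acquired under partial
#'   Fourier, in `(0.5, 1]`; `1` means full Fourier.
#' @return An object of class `sampling_pattern`: list with `mask`
#'   (`n_frames x n_ky` logical, `TRUE` = acquired), `training_lines`,
#'   `R`, `n_train`, `pf_fraction`, `n_ky`, `n_frames`.
#' @export
make_pattern <- function(n_ky, n_frames, R = 10L, n_train = 3L,
                         pf_fraction = 1.0) {
  n_ky <- as.integer(n_ky); n_frames <- as.integer(n_frames)
  R <- as.integer(R); n_train <- as.integer(n_train)
  if (R < 1L || R > n_ky)
    stop("`R` must satisfy 1 <= R <= n_ky", call. = FALSE)
  if (n_train < 0L || n_train >= n_ky)
    stop("`n_train` must satisfy 0 <= n_train < n_ky", call. = FALSE)
  if (pf_fraction <= 0.5 || pf_fraction > 1)
    stop("`pf_fraction` must be in (0.5, 1]", call. = FALSE)

  dc <- floor(n_ky / 2) + 1L
  training <- if (n_train > 0L)
    dc + seq.int(-floor((n_train - 1L) / 2), ceiling((n_train - 1L) / 2))
  else integer(0)

  ky0 <- 0:(n_ky - 1L)                      # 0-based line index
  mask <- matrix(FALSE, n_frames, n_ky)
  for (f in seq_len(n_frames)) {
    mask[f, (ky0 %% R) == ((f - 1L) %% R)] <- TRUE
  }
  n_pf_drop <- round((1 - pf_fraction) * n_ky)
  if (n_pf_drop > 0L) mask[, seq_len(n_pf_drop)] <- FALSE
  mask[, training] <- TRUE

  structure(list(mask = mask, training_lines = training, R = R,
                 n_train = n_train, pf_fraction = pf_fraction,
                 n_ky = n_ky, n_frames = n_frames),
            class = "sampling_pattern")
}

#' Net acceleration of a sampling pattern
#'
#' Acquired phase-encode lines per frame relative to the full matrix:
#' `n_ky * pf_fraction / mean(lines per frame)`. Training overhead makes
#' this lower than the nominal lattice factor `R` (about 8.3 for the
#' 128-line, R = 10, 3-training-profile configuration).
#'
#' @param pattern a [make_pattern()] result.
#' @return The net acceleration factor (dimensionless).
#' @export
net_acceleration <- function(pattern) {
  stopifnot(inherits(pattern, "sampling_pattern"))
  pattern$n_ky * pattern$pf_fraction / mean(rowSums(pattern$mask))
}

#' @export
print.sampling_pattern <- function(x, ...) {
  cat(sprintf(
    "<sampling_pattern> %d ky x %d frames, R = %d, %d training lines, pf = %.2f\n",
    x$n_ky, x$n_frames, x$R, x$n_train, x$pf_fraction))
  cat(sprintf("  %.1f lines/frame, net acceleration %.2f\n",
              mean(rowSums(x$mask)), net_acceleration(x)))
  invisible(x)
}

#' Encode a dynamic series into undersampled k-t space
#'
#' Applies a per-frame centered 2-D discrete Fourier transform, adds
#' seeded complex Gaussian noise, and marks unacquired ky lines as
#' missing (`NA`, never numeric zero); the logical sampling mask is
#' carried alongside the data.
#'
#' @param series a [dynamic_series()]; its row count must equal the
#'   pattern's `n_ky`.
#' @param pattern a [make_pattern()] result with matching frame count.
#' @param noise_sd complex Gaussian noise level, as the equivalent
#'   image-domain standard deviation per component (see
#'   [phantom_config()]).
#' @param seed integer seed for the noise.
#' @return An object of class `kt_data`: list with `kspace` (complex
#'   `n_ky x n_x x n_frames`, `NA` where unacquired), `mask`
#'   (`n_frames x n_ky`), `pattern`, `frame_times_s`, `pixel_mm`.
#' @export
kt_encode <- function(series, pattern, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(series, "dynamic_series"),
            inherits(pattern, "sampling_pattern"))
  d <- dim(series$data)
  if (d[1] != pattern$n_ky)
    stop("series row count does not match pattern `n_ky`", call. = FALSE)
  if (d[3] != pattern$n_frames)
    stop("series frame count does not match pattern `n_frames`", call. = FALSE)

  ksp <- array(complex(real = 0), dim = d)
  for (k in seq_len(d[3])) ksp[, , k] <- fft2c(series$data[, , k])
  if (noise_sd > 0) {
    ksd <- noise_sd * sqrt(d[1] * d[2])
    ksp <- with_seed(seed, {
      ntot <- length(ksp)
      ksp + complex(real = stats::rnorm(ntot, sd = ksd),
                    imaginary = stats::rnorm(ntot, sd = ksd))
    })
  }
  for (k in seq_len(d[3])) ksp[!pattern$mask[k, ], , k] <- NA_complex_

  structure(list(kspace = ksp, mask = pattern$mask, pattern = pattern,
                 frame_times_s = series$frame_times_s,
                 pixel_mm = series$pixel_mm),
            class = "kt_data")
}

#' @export
print.kt_data <- function(x, ...) {
  d <- dim(x$kspace)
  cat(sprintf("<kt_data> %d ky x %d kx x %d frames (%.1f%% acquired)\n",
              d[1], d[2], d[3], 100 * mean(x$mask)))
  invisible(x)
}

# raised-cosine taper over the training band; the DC line always keeps
# weight 1 so the band retains the per-frame spatial mean exactly
training_window <- function(training_lines) {
  L <- length(training_lines)
  d_edge <- pmin(seq_len(L) - 1L, L - seq_len(L))
  tw <- min(2L, floor((L - 1L) / 2L))
  w <- rep(1, L)
  if (tw > 0L) {
    idx <- d_edge < tw
    w[idx] <- 0.5 * (1 - cos(pi * (d_edge[idx] + 1) / (tw + 1)))
  }
  w
}

#' Extract the low-resolution training series
#'
#' Keeps only the central training profiles (acquired every frame),
#' applies a raised-cosine taper across the band edges to suppress
#' truncation ringing, zero-fills the rest of k-space and inverse
#' transforms per frame. The result has the full matrix size but low ky
#' resolution, and full temporal resolution: it is the data from which
#' the temporal basis of the reconstruction is learned.
#'
#' @param ktdat a [kt_encode()] result.
#' @param pattern the [make_pattern()] used; defaults to the one stored
#'   in `ktdat`.
#' @return A [dynamic_series()] with complex-valued data.
#' @export
extract_training <- function(ktdat, pattern = ktdat$pattern) {
  stopifnot(inherits(ktdat, "kt_data"))
  if (pattern$n_train < 1L)
    stop("pattern has no training profiles", call. = FALSE)
  d <- dim(ktdat$kspace)
  w <- training_window(pattern$training_lines)
  out <- array(complex(real = 0), dim = d)
  for (k in seq_len(d[3])) {
    kf <- matrix(complex(real = 0), d[1], d[2])
    kf[pattern$training_lines, ] <- w * ktdat$kspace[pattern$training_lines, , k]
    out[, , k] <- ifft2c(kf)
  }
  dynamic_series(out, ktdat$frame_times_s, ktdat$pixel_mm)
}
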