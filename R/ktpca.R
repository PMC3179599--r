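#' Reconstruction settings
#'
#' @param n_pc number of temporal principal components retained.
#' @param lambda_reg Tikhonov regularization scale, relative to the mean
#'   training weight variance (so the default transfers across signal
#'   scales).
#' @param n_refine number of variance-refinement passes: after each
#'   solve, the per-pixel weight variances are re-estimated from the
#'   current reconstruction (full spatial resolution) and the system is
#'   solved again, sharpening the spatial prior that the
#'   low-resolution training data can only blur.
#' @param refine_floor fraction of the training weight variance kept as
#'   a lower bound during refinement. Refinement that shrinks a
#'   variance all the way to the reconstruction's own (band-limited)
#'   estimate feeds back as progressive temporal smoothing; the floor
#'   keeps every component the support the training data attest to.
#' @param handle_dc if `TRUE` (default) the temporal mean is
#'   reconstructed separately from the time-averaged k-space (each ky
#'   line averaged over the frames in which it was acquired) and the
#'   basis fit is applied to the residual; otherwise the training
#'   temporal mean is used as the static image.
#' @param cg_tol relative residual tolerance of the conjugate-gradient
#'   solver of the normal equations.
#' @param cg_maxiter iteration cap of the solver.
#' @return An object of class `recon_config`.
#' @export
recon_config <- function(n_pc = 8L, lambda_reg = 1e-3, handle_dc = TRUE,
                         n_refine = 2L, refine_floor = 0.3,
                         cg_tol = 1e-8, cg_maxiter = 150L) {
  if (n_pc < 1L) stop("`n_pc` must be >= 1", call. = FALSE)
  if (lambda_reg <= 0) stop("`lambda_reg` must be > 0", call. = FALSE)
  if (n_refine < 0L) stop("`n_refine` must be >= 0", call. = FALSE)
  if (refine_floor < 0 || refine_floor > 1)
    stop("`refine_floor` must be in [0, 1]", call. = FALSE)
  structure(list(n_pc = as.integer(n_pc), lambda_reg = lambda_reg,
                 handle_dc = isTRUE(handle_dc), n_refine = as.integer(n_refine),
                 refine_floor = refine_floor,
                 cg_tol = cg_tol, cg_maxiter = as.integer(cg_maxiter)),
            class = "recon_config")
}

#' Learn the temporal principal-component basis from training data
#'
#' Removes the per-pixel temporal mean, forms the frames-by-frames
#' covariance of the training pixel time-courses and eigendecomposes
#' it; the leading `n_pc` eigenvectors (ordered by decreasing variance)
#' are the temporal basis, and the squared projections of each pixel's
#' time-course onto the basis are the per-pixel weight variances that
#' regularize the unfolding.
#'
#' @param training low-resolution [dynamic_series()] from
#'   [extract_training()] (complex data allowed).
#' @param n_pc number of components to retain, `<=` frame count.
#' @return An object of class `pc_basis`: list with `basis`
#'   (`n_frames x n_pc`, orthonormal columns), `weight_variance`
#'   (`n_pixels x n_pc`), `temporal_mean` (matrix), `n_pc`, `dim`,
#'   `explained_variance` (all eigenvalues, descending).
#' @export
build_basis <- function(training, n_pc = 8L) {
  stopifnot(inherits(training, "dynamic_series"))
  d <- dim(training$data)
  nt <- d[3]
  if (n_pc > nt)
    stop("`n_pc` cannot exceed the number of frames", call. = FALSE)
  X <- matrix(training$data, nrow = d[1] * d[2], ncol = nt)
  mu <- rowMeans(X)
  Xc <- X - mu
  C <- (Conj(t(Xc)) %*% Xc) / nrow(Xc)     # nt x nt Hermitian
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(Re(eg$values), 0)
  B <- eg$vectors[, seq_len(n_pc), drop = FALSE]
  W <- Xc %*% Conj(B)                      # per-pixel projections
  structure(list(basis = B, weight_variance = Mod(W)^2,
                 temporal_mean = matrix(mu, d[1], d[2]),
                 n_pc = as.integer(n_pc), dim = d[1:2],
                 explained_variance = ev),
            class = "pc_basis")
}

#' @export
print.pc_basis <- function(x, ...) {
  tot <- sum(x$explained_variance)
  expl <- if (tot > 0) sum(x$explained_variance[seq_len(x$n_pc)]) / tot else 1
  cat(sprintf("<pc_basis> %d x %d pixels, %d of %d components (%.2f%% variance)\n",
              x$dim[1], x$dim[2], x$n_pc, nrow(x$basis), 100 * expl))
  invisible(x)
}

#' Reference reconstruction of fully sampled k-t data
#'
#' Per-frame centered inverse 2-D Fourier transform followed by the
#' magnitude operation; the oracle against which accelerated
#' reconstructions are judged.
#'
#' @param ktdat a [kt_encode()] result with every line acquired.
#' @return A [dynamic_series()] of magnitude images.
#' @export
recon_reference <- function(ktdat) {
  stopifnot(inherits(ktdat, "kt_data"))
  if (!all(ktdat$mask))
    stop("data contain missing lines; `recon_reference` needs fully sampled input",
         call. = FALSE)
  d <- dim(ktdat$kspace)
  out <- array(0, dim = d)
  for (k in seq_len(d[3])) out[, , k] <- Mod(ifft2c(ktdat$kspace[, , k]))
  dynamic_series(out, ktdat$frame_times_s, ktdat$pixel_mm)
}

#' k-t PCA constrained reconstruction
#'
#' Resolves the aliasing of the sheared-lattice undersampling by
#' restricting every pixel's time-course to the temporal
#' principal-component subspace learned from the training data and
#' solving a regularized least-squares problem for the component
#' weights of all pixels jointly. Components with small training
#' variance at a pixel are shrunk toward zero. The temporal mean is
#' handled separately (see [recon_config()]), and acquired k-space
#' samples are reinserted into the solution (hard data consistency), so
#' fully sampled data reproduce the plain inverse-Fourier
#' reconstruction exactly.
#'
#' The normal equations `(E^H E + Lambda) w = E^H d` are solved by
#' conjugate gradients with the Fourier encoding applied matrix-free
#' along the phase-encode dimension; every step is deterministic.
#'
#' @param ktdat undersampled [kt_encode()] result.
#' @param basis a [build_basis()] result with matching frame count.
#' @param cfg a [recon_config()].
#' @param pattern sampling pattern; defaults to the one in `ktdat`.
#' @return A [dynamic_series()] of magnitude images with an attribute
#'   `cg` recording iterations and final relative residual.
#' @export
kt_unfold <- function(ktdat, basis, cfg = recon_config(),
                      pattern = ktdat$pattern) {
  stopifnot(inherits(ktdat, "kt_data"), inherits(basis, "pc_basis"),
            inherits(cfg, "recon_config"))
  d <- dim(ktdat$kspace)
  nr <- d[1]; nc <- d[2]; nt <- d[3]
  if (nrow(basis$basis) != nt)
    stop("basis frame count does not match the data", call. = FALSE)
  if (!identical(basis$dim, d[1:2]))
    stop("basis spatial dimensions do not match the data", call. = FALSE)
  if (basis$n_pc > cfg$n_pc) {
    basis$basis <- basis$basis[, seq_len(cfg$n_pc), drop = FALSE]
    basis$weight_variance <- basis$weight_variance[, seq_len(cfg$n_pc), drop = FALSE]
    basis$n_pc <- cfg$n_pc
  } else if (basis$n_pc < cfg$n_pc) {
    stop("basis holds fewer components than `cfg$n_pc`", call. = FALSE)
  }
  np <- basis$n_pc
  npx <- nr * nc

  mask3 <- aperm(array(t(pattern$mask), dim = c(nr, nt, nc)), c(1L, 3L, 2L))
  ksp <- ktdat$kspace
  ksp[is.na(ksp)] <- 0

  # unitary scale; hybrid (ky, x, t) domain: invert the fully sampled
  # readout dimension once, leaving the encoding one FFT along ky
  Ku <- ksp / sqrt(npx)
  Dhyb <- fft_dim2_u(Ku, inverse = TRUE)

  # static (temporal-mean) image
  if (cfg$handle_dc) {
    counts <- colSums(pattern$mask)                   # acquisitions per line
    ksum <- apply(ksp, c(1, 2), sum)
    kbar <- ksum / ifelse(counts > 0, counts, 1)
    kbar[counts == 0, ] <- 0
    xbar <- ifft2c(kbar)
  } else {
    xbar <- basis$temporal_mean
  }

  xbar_ky <- fft_dim1_u_mat(xbar)
  Dres <- Dhyb - mask3 * array(xbar_ky, dim = c(nr, nc, nt))

  B <- basis$basis
  Bt <- t(B); BH <- Conj(B)
  cdot <- function(a, b) Re(sum(Conj(a) * b))

  E_fwd <- function(W) {                  # weights -> masked hybrid k-space
    img <- array(W %*% Bt, dim = c(nr, nc, nt))
    mask3 * fft_dim1_u(img)
  }
  E_adj <- function(Dk) {                 # masked hybrid k-space -> weights
    img <- fft_dim1_u(mask3 * Dk, inverse = TRUE)
    matrix(img, npx, nt) %*% BH
  }

  # Jacobi preconditioner; the diagonal of E^H E is exact: the unitary
  # DFT spreads each acquired (ky, t) sample evenly over y, so
  # diag = sum_t |B(t,p)|^2 * n_acq(t) / n_ky, constant over pixels
  nacq <- rowSums(pattern$mask)
  dscal <- as.numeric(crossprod(Mod(B)^2, nacq)) / nr

  solve_weights <- function(V) {
    vbar <- mean(V)
    if (vbar <= 0)
      return(list(W = matrix(complex(real = 0), npx, np),
                  cg = list(iterations = 0L, rel_residual = 0)))
    lam <- cfg$lambda_reg * vbar / (V + 1e-6 * vbar)
    A_apply <- function(W) E_adj(E_fwd(W)) + lam * W
    Minv <- 1 / (outer(rep(1, npx), dscal) + lam)

    rhs <- E_adj(Dres)
    W <- matrix(complex(real = 0), npx, np)
    r <- rhs
    z <- Minv * r
    p <- z
    rz <- cdot(r, z)
    rhs_norm <- sqrt(cdot(rhs, rhs))
    iter <- 0L
    rs <- cdot(r, r)
    if (rhs_norm > 0) {
      for (iter in seq_len(cfg$cg_maxiter)) {
        Ap <- A_apply(p)
        alpha <- rz / cdot(p, Ap)
        W <- W + alpha * p
        r <- r - alpha * Ap
        rs <- cdot(r, r)
        if (sqrt(rs) <= cfg$cg_tol * rhs_norm) break
        z <- Minv * r
        rz_new <- cdot(r, z)
        p <- z + (rz_new / rz) * p
        rz <- rz_new
      }
    }
    list(W = W, cg = list(iterations = iter,
                          rel_residual = if (rhs_norm > 0) sqrt(rs) / rhs_norm
                                         else 0))
  }

  # alternate weight solves with re-estimation of the per-pixel weight
  # variances from the current full-resolution reconstruction: the
  # low-ky-resolution training variances blur the bright blood pool
  # across the thin mouse myocardium, and refinement sharpens the
  # spatial prior without touching the temporal basis
  V <- basis$weight_variance
  cg_info <- NULL
  x <- NULL
  for (pass in seq_len(1L + max(0L, cfg$n_refine))) {
    sol <- solve_weights(V)
    cg_info <- sol$cg
    x <- array(as.vector(xbar) + sol$W %*% Bt, dim = c(nr, nc, nt))
    # hard data consistency: acquired samples are retained verbatim
    Kx <- fft_dim1_u(x)
    Kx[mask3] <- Dhyb[mask3]
    x <- fft_dim1_u(Kx, inverse = TRUE)
    # magnitude images: residual phase of the intermediate solution
    # would otherwise leak ghost energy into the variance estimates
    Xc <- matrix(Mod(x), npx, nt)
    V <- pmax(Mod((Xc - rowMeans(Xc)) %*% BH)^2,
              cfg$refine_floor * basis$weight_variance)
  }

  out <- dynamic_series(Mod(x), ktdat$frame_times_s, ktdat$pixel_mm)
  attr(out, "cg") <- cg_info
  out
}

# unitary centered FFT along rows of a single matrix
fft_dim1_u_mat <- function(m) {
  fft_dim1_u(array(m, dim = c(nrow(m), ncol(m), 1L)))[, , 1L]
}

#' Normalized root-mean-square error between two series
#'
#' `||a - b|| / ||b||` over all pixels and frames; `b` is the reference.
#'
#' @param a,b [dynamic_series()] objects of identical dimensions.
#' @return A single non-negative number.
#' @export
series_nrmse <- function(a, b) {
  stopifnot(identical(dim(a$data), dim(b$data)))
  sqrt(sum((Mod(a$data) - Mod(b$data))^2) / sum(Mod(b$data)^2))
}
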