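# Centered discrete Fourier transform helpers.
#
# Convention: image-space arrays are indexed (row = phase-encode y,
# col = readout x); k-space arrays are "centered", i.e. the DC sample
# sits at index floor(n/2) + 1 along each transformed dimension.
# fft2c/ifft2c are unnormalised (forward multiplies energy by N), the
# *_u variants are unitary; the reconstruction works in unitary scale.

fftshift_idx <- function(n) c((floor(n / 2) + 1L):n, seq_len(floor(n / 2)))
ifftshift_idx <- function(n) c((ceiling(n / 2) + 1L):n, seq_len(ceiling(n / 2)))

fftshift2 <- function(m) m[fftshift_idx(nrow(m)), fftshift_idx(ncol(m)), drop = FALSE]
ifftshift2 <- function(m) m[ifftshift_idx(nrow(m)), ifftshift_idx(ncol(m)), drop = FALSE]

# centered 2-D FFT of one frame (unnormalised)
fft2c <- function(img) fftshift2(stats::fft(ifftshift2(img)))

# centered 2-D inverse FFT of one frame
ifft2c <- function(k) fftshift2(stats::fft(ifftshift2(k), inverse = TRUE)) / length(k)

# unitary centered 1-D FFT along dimension 1 of a 3-D array (all
# columns/frames at once via mvfft); `inverse` gives the adjoint.
fft_dim1_u <- function(a, inverse = FALSE) {
  d <- dim(a)
  m <- matrix(a, nrow = d[1])
  m <- m[ifftshift_idx(d[1]), , drop = FALSE]
  m <- stats::mvfft(m, inverse = inverse)
  m <- m[fftshift_idx(d[1]), , drop = FALSE]
  array(m / sqrt(d[1]), dim = d)
}

# same along dimension 2 (readout); used once to move measured k-space
# into the hybrid (ky, x, t) domain
fft_dim2_u <- function(a, inverse = FALSE) {
  b <- aperm(a, c(2L, 1L, 3L))
  b <- fft_dim1_u(b, inverse = inverse)
  aperm(b, c(2L, 1L, 3L))
}
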