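# 3-D convolution utilities shared by the dose engine and the synthetic
# PET point-spread blur. Plain-R FFT with zero padding (no wraparound).

# Centered convolution of x with kernel k (odd dims, center at (dim+1)/2).
.fft_conv3 <- function(x, k) {
  d <- dim(x); dk <- dim(k)
  dp <- d + dk - 1L
  xp <- array(0, dp); xp[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- x
  kp <- array(0, dp); kp[seq_len(dk[1]), seq_len(dk[2]), seq_len(dk[3])] <- k
  full <- Re(stats::fft(stats::fft(xp) * stats::fft(kp), inverse = TRUE)) /
    prod(dp)
  off <- (dk + 1L) %/% 2L
  full[off[1]:(off[1] + d[1] - 1L),
       off[2]:(off[2] + d[2] - 1L),
       off[3]:(off[3] + d[3] - 1L)]
}

# Isotropic Gaussian blur with sigma in mm; kernel truncated at 4 sigma
# and renormalized, so the array total is preserved.
.gaussian_blur3 <- function(x, sigma_mm, spacing_mm) {
  if (sigma_mm <= 0) return(x)
  if (length(spacing_mm) == 1) spacing_mm <- rep(spacing_mm, 3)
  half <- pmax(ceiling(4 * sigma_mm / spacing_mm), 1L)
  ax <- lapply(1:3, function(i) (-half[i]:half[i]) * spacing_mm[i])
  g <- lapply(ax, function(v) exp(-v^2 / (2 * sigma_mm^2)))
  k <- outer(outer(g[[1]], g[[2]]), g[[3]])
  dim(k) <- c(length(g[[1]]), length(g[[2]]), length(g[[3]]))
  k <- k / sum(k)
  .fft_conv3(x, k)
}

fwhm_to_sigma <- function(fwhm) fwhm / (2 * sqrt(2 * log(2)))
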