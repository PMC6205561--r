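#' Compute an incoherent point spread function with residual defocus
#'
#' Standard Fourier-optics model: the PSF is the squared modulus of the
#' Fourier transform of the generalized pupil function. The pupil is a
#' circular aperture of diameter `pupil_diameter` carrying a defocus
#' wavefront W(rho) = (defocus/2) * (a * rho)^2 metres of optical path
#' difference, where a is the pupil radius in metres and rho in [0, 1] the
#' normalized pupil radius. The result is sampled on a square retinal grid at
#' `pixel_scale` arcmin/px and normalized to unit sum. Only the magnitude of
#' the defocus matters (the incoherent PSF is symmetric in its sign).
#'
#' @param wavelength Wavelength, nm (543 nm for a mid-spectrum stimulus).
#' @param pupil_diameter Pupil diameter, mm (6.5 mm for a dilated eye).
#' @param defocus Residual defocus, diopters (0.05 D models a well-corrected
#'   adaptive-optics system).
#' @param pixel_scale Arcmin per pixel of the retinal grid.
#' @param grid_size Samples per grid side; must capture essentially all PSF
#'   energy (>= 64 px at ~0.11 arcmin/px).
#' @return An object of class `psf_model`: list with `psf` (grid_size x
#'   grid_size matrix summing to 1), `pixel_scale`, `wavelength`,
#'   `pupil_diameter`, `defocus`.
#' @examples
#' p <- compute_psf(543, 6.5, 0.05)
#' sum(p$psf)
#' @export
compute_psf <- function(wavelength = 543, pupil_diameter = 6.5, defocus = 0.05,
                        pixel_scale = 0.95 * 60 / 512, grid_size = 128) {
  if (wavelength <= 0 || pupil_diameter <= 0) {
    stop("`wavelength` and `pupil_diameter` must be positive")
  }
  if (grid_size < 64) stop("`grid_size` too small to contain the PSF")
  lambda_m <- wavelength * 1e-9
  a_m <- pupil_diameter * 1e-3 / 2
  theta_px <- pixel_scale / 60 * pi / 180 # radians per retinal pixel
  # pupil-plane sampling implied by the desired image-plane sampling
  d_xi <- lambda_m / (grid_size * theta_px)
  n <- grid_size
  idx <- seq_len(n) - (n %/% 2 + 1)
  xi <- idx * d_xi
  XX <- matrix(xi, n, n)
  YY <- t(XX)
  r <- sqrt(XX^2 + YY^2)
  inside <- r <= a_m
  rho <- ifelse(inside, r / a_m, 0)
  w_opd <- (abs(defocus) / 2) * (a_m * rho)^2 # metres of OPD
  pupil <- matrix(0 + 0i, n, n)
  pupil[inside] <- exp(2i * pi * w_opd[inside] / lambda_m)
  field <- stats::fft(fftshift(pupil))
  psf <- fftshift(Mod(field)^2)
  psf <- psf / sum(psf)
  structure(list(psf = psf, pixel_scale = pixel_scale,
                 wavelength = wavelength, pupil_diameter = pupil_diameter,
                 defocus = defocus),
            class = "psf_model")
}

# swap quadrants so the origin moves between corner and center
fftshift <- function(m) {
  n1 <- nrow(m); n2 <- ncol(m)
  s1 <- n1 %/% 2; s2 <- n2 %/% 2
  m[c((s1 + 1):n1, 1:s1), c((s2 + 1):n2, 1:s2)]
}

#' Retinal light profile of a square stimulus
#'
#' Convolves a uniform `stim_px` x `stim_px` pixel square (the raster-drawn
#' increment) with the PSF and renormalizes, giving the expected retinal
#' irradiance profile of one flash.
#'
#' @param psf A `psf_model`.
#' @param stim_px Stimulus side in pixels (odd; 3 px is ~0.35 arcmin at the
#'   default raster scale).
#' @return An object of class `stimulus_profile`: list with `profile` (matrix
#'   summing to 1) and `pixel_scale`.
#' @export
stimulus_profile <- function(psf, stim_px = 3) {
  stopifnot(inherits(psf, "psf_model"))
  if (stim_px < 1 || stim_px %% 2 == 0) stop("`stim_px` must be odd and >= 1")
  n <- nrow(psf$psf)
  if (stim_px > n) stop("stimulus larger than the PSF grid")
  prof <- if (stim_px == 1) {
    psf$psf
  } else {
    kern <- matrix(1 / stim_px^2, stim_px, stim_px)
    conv2_same(psf$psf, kern)
  }
  prof <- prof / sum(prof)
  structure(list(profile = prof, pixel_scale = psf$pixel_scale),
            class = "stimulus_profile")
}

# 2-D linear convolution via FFT, cropped to the size of `a` ("same")
conv2_same <- function(a, k) {
  na <- dim(a); nk <- dim(k)
  nf <- na + nk - 1
  pa <- matrix(0, nf[1], nf[2]); pa[1:na[1], 1:na[2]] <- a
  pk <- matrix(0, nf[1], nf[2]); pk[1:nk[1], 1:nk[2]] <- k
  full <- Re(stats::fft(stats::fft(pa) * stats::fft(pk), inverse = TRUE)) /
    prod(nf)
  r0 <- (nk[1] - 1) %/% 2
  c0 <- (nk[2] - 1) %/% 2
  out <- full[(r0 + 1):(r0 + na[1]), (c0 + 1):(c0 + na[2])]
  pmax(out, 0)
}
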