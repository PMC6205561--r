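psf0 <- compute_psf(543, 6.5, 0)
psf05 <- compute_psf(543, 6.5, 0.05)
prof <- stimulus_profile(psf05, 3)

test_that("the PSF is normalized and nonnegative", {
  expect_equal(sum(psf0$psf), 1, tolerance = 1e-9)
  expect_equal(sum(psf05$psf), 1, tolerance = 1e-9)
  expect_true(all(psf0$psf >= 0))
  expect_error(compute_psf(-543, 6.5, 0), "positive")
  expect_error(compute_psf(543, 6.5, 0, grid_size = 32), "grid_size")
})

test_that("the diffraction-limited PSF has its first minimum at the Airy radius", {
  # 1.22 * lambda / D = 0.350 arcmin at 543 nm / 6.5 mm
  n <- nrow(psf0$psf); c0 <- n %/% 2 + 1
  radial <- psf0$psf[c0, c0:n]
  first_min_px <- which(diff(radial) > 0)[1] - 1
  airy_arcmin <- 1.22 * 543e-9 / 6.5e-3 * 180 / pi * 60
  expect_equal(first_min_px * psf0$pixel_scale, airy_arcmin,
               tolerance = psf0$pixel_scale / airy_arcmin) # within one pixel
})

test_that("defocus spreads the PSF and lowers its peak", {
  expect_lt(max(psf05$psf), max(psf0$psf))
  # sign of defocus is irrelevant for the incoherent PSF
  psf_neg <- compute_psf(543, 6.5, -0.05)
  expect_equal(psf_neg$psf, psf05$psf, tolerance = 1e-12)
})

second_moment <- function(m, scale) {
  n <- nrow(m); c0 <- n %/% 2 + 1
  ax <- (seq_len(n) - c0) * scale
  sum(outer(ax^2, rep(1, n)) * m) + sum(outer(rep(1, n), ax^2) * m)
}

test_that("PSF width grows with defocus and shrinks with pupil diameter", {
  w <- vapply(c(0, 0.05, 0.1), function(d)
    second_moment(compute_psf(543, 6.5, d)$psf, 0.11), 0)
  expect_true(all(diff(w) > 0))
  w2 <- vapply(c(4, 6.5), function(p)
    second_moment(compute_psf(543, p, 0)$psf, 0.11), 0)
  expect_gt(w2[1], w2[2])
})

test_that("stimulus profiles convolve, normalize and add second moments", {
  expect_equal(stimulus_profile(psf05, 1)$profile, psf05$psf)
  expect_equal(sum(prof$profile), 1, tolerance = 1e-9)
  px <- psf05$pixel_scale
  m_psf <- second_moment(psf05$psf, px)
  m_prof <- second_moment(prof$profile, px)
  # uniform 3x3 square: per-axis variance 2/3 px^2, two axes
  m_square <- 2 * (2 / 3) * px^2
  expect_equal(m_prof, m_psf + m_square, tolerance = 0.02 * m_prof)
  expect_error(stimulus_profile(psf05, 2), "odd")
  expect_error(stimulus_profile(psf05, 999), "larger than")
})

test_that("delivery error summarizes 2-D scatter", {
  expect_equal(delivery_error(cbind(rep(1, 5), rep(2, 5))), 0)
  # 4-point cross of half-width d: per-axis SD = sqrt(2 d^2 / 3)
  d <- 0.3
  cross <- rbind(c(d, 0), c(-d, 0), c(0, d), c(0, -d))
  expect_equal(delivery_error(cross), sqrt(2 * d^2 / 3), tolerance = 1e-12)
  # homogeneity: scaling positions scales the error
  set.seed(4)
  pos <- matrix(rnorm(30), ncol = 2)
  expect_equal(delivery_error(pos * 3), 3 * delivery_error(pos),
               tolerance = 1e-12)
  expect_error(delivery_error(matrix(1, 1, 2)), "at least 2")
})

test_that("trial filtering is boundary-inclusive and order-preserving", {
  tr <- data.frame(trial_id = 1:3, delivery_error_arcmin = c(0.2, 0.36, 0.35))
  kept <- filter_trials(tr)
  expect_equal(kept$trial_id, c(1, 3))
  expect_equal(nrow(filter_trials(tr[0, ])), 0)
  all0 <- data.frame(trial_id = 1:4, delivery_error_arcmin = 0)
  expect_equal(nrow(filter_trials(all0)), 4)
})

test_that("capture fractions renormalize, respect symmetry and translation", {
  one <- manual_mosaic(0, 0, "L")
  tr <- cbind(rep(0, 5), rep(0, 5))
  expect_equal(capture_fractions(one, prof, tr, 1)$targeted_fraction, 1)

  two <- manual_mosaic(c(-0.55, 0.55), c(0, 0), c("L", "L"))
  mid <- capture_fractions(two, prof, cbind(0, 0), 1)
  expect_equal(sum(mid$fractions), 1, tolerance = 1e-9)
  expect_equal(unname(mid$fractions[1]), unname(mid$fractions[2]),
               tolerance = 1e-9)

  m <- hex_patch()
  a <- capture_fractions(m, prof, cbind(0.1, -0.05), 1)
  shifted <- manual_mosaic(m$cones$x_arcmin + 3, m$cones$y_arcmin - 2,
                           m$cones$type)
  b <- capture_fractions(shifted, prof, cbind(3.1, -2.05), 1)
  expect_equal(a$fractions, b$fractions, tolerance = 1e-6)
  expect_error(capture_fractions(m, prof, cbind(0, 0), 99), "not in mosaic")
})

test_that("on-center capture share sits in the expected band at the standard geometry", {
  m <- generate_mosaic(1.1, extent = 12, positional_jitter = 0, seed = 2)
  ctr <- m$cones$cone_id[which.min((m$cones$x_arcmin - 6)^2 +
                                     (m$cones$y_arcmin - 6)^2)]
  sm <- session_capture_summary(m, prof, still_traces(m, ctr))
  expect_gt(sm$overall[["targeted_mean"]], 0.7)
  expect_lt(sm$overall[["targeted_mean"]], 0.9)
})

test_that("capture decreases with wider apertures and with delivery jitter", {
  m <- generate_mosaic(1.1, extent = 12, positional_jitter = 0, seed = 2)
  ctr <- m$cones$cone_id[which.min((m$cones$x_arcmin - 6)^2 +
                                     (m$cones$y_arcmin - 6)^2)]
  tr <- still_traces(m, ctr)
  caps <- vapply(c(0.40, 0.48, 0.56), function(ap)
    session_capture_summary(m, prof, tr, aperture_fraction = ap)$
      overall[["targeted_mean"]], 0)
  expect_true(all(diff(caps) < 0))

  i <- match(ctr, m$cones$cone_id)
  jit <- lapply(1:25, function(r) list(
    targeted_id = ctr,
    positions = simulate_delivery_trace(
      c(m$cones$x_arcmin[i], m$cones$y_arcmin[i]), 0.2, 15, seed = r)))
  cap_jit <- session_capture_summary(m, prof, jit)$overall[["targeted_mean"]]
  caps0 <- session_capture_summary(m, prof, tr)$overall[["targeted_mean"]]
  expect_lt(cap_jit, caps0)
})

test_that("simulated delivery traces are seeded and sized correctly", {
  t1 <- simulate_delivery_trace(c(1, 2), 0.1, 15, seed = 8)
  t2 <- simulate_delivery_trace(c(1, 2), 0.1, 15, seed = 8)
  expect_identical(t1, t2)
  expect_equal(dim(t1), c(15, 2))
  t0 <- simulate_delivery_trace(c(1, 2), 0, 15, seed = 8)
  expect_equal(delivery_error(t0), 0)
})
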