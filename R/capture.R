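#' Scalar delivery error of a stimulus trace
#'
#' During a trial the stimulus is re-delivered on every raster frame; the
#' recovered landing positions scatter because of residual eye motion and
#' tracking error. The per-trial delivery error summarizes that scatter as a
#' single arcminute value. The default collapses the two axes isotropically as
#' the root-mean-square of the per-axis standard deviations; `method = "max"`
#' takes the worse axis instead.
#'
#' @param positions Two-column matrix (x, y in arcmin), one row per frame.
#' @param method `"rms"` (default) or `"max"`.
#' @return Delivery error in arcmin.
#' @export
delivery_error <- function(positions, method = c("rms", "max")) {
  method <- match.arg(method)
  positions <- as.matrix(positions)
  if (nrow(positions) < 2) stop("need at least 2 delivery positions")
  sds <- apply(positions, 2, stats::sd)
  switch(method,
         rms = sqrt(mean(sds^2)),
         max = max(sds))
}

#' Filter trials by delivery error
#'
#' Trials whose per-frame landing positions scattered by more than
#' `max_error` arcmin are removed (boundary inclusive); order is preserved.
#'
#' @param trials Data frame with a `delivery_error_arcmin` (or
#'   `delivery_error`) column.
#' @param max_error Cutoff in arcmin (default 0.35).
#' @return The retained rows of `trials`.
#' @export
filter_trials <- function(trials, max_error = 0.35) {
  col <- intersect(c("delivery_error_arcmin", "delivery_error"), names(trials))
  if (length(col) == 0L) stop("`trials` must carry a delivery-error column")
  trials[trials[[col[1]]] <= max_error, , drop = FALSE]
}

#' Simulate a per-frame delivery trace
#'
#' Landing positions are i.i.d. isotropic Gaussian around the target: the
#' stimulus is re-aimed independently on every frame, so frame-to-frame
#' tracking errors are approximately independent.
#'
#' @param target_xy Length-2 vector, intended position (arcmin).
#' @param jitter_sd Per-axis SD of landing positions, arcmin.
#' @param frames Frames per trial (15 frames over a 500 ms flash at 30 Hz).
#' @param seed Integer seed.
#' @return Matrix `frames` x 2 of landing positions.
#' @export
simulate_delivery_trace <- function(target_xy, jitter_sd = 0.15, frames = 15,
                                    seed) {
  stopifnot(length(target_xy) == 2, frames >= 1, jitter_sd >= 0)
  if (missing(seed)) stop("`seed` is required")
  with_seed(seed, {
    cbind(target_xy[1] + stats::rnorm(frames, sd = jitter_sd),
          target_xy[2] + stats::rnorm(frames, sd = jitter_sd))
  })
}

#' Precompute the aperture-smoothed stimulus field
#'
#' The light a cone at offset r from a delivery site absorbs is the integral
#' of the stimulus profile against the cone's Gaussian aperture — a
#' convolution of profile and aperture evaluated at r. Precomputing that
#' convolution once makes per-trial capture a cheap interpolation.
#'
#' @param profile A `stimulus_profile`.
#' @param inner_segment_diameter Cone inner-segment diameter, arcmin.
#' @param aperture_fraction Aperture FWHM as a fraction of the inner-segment
#'   diameter (0.48, the classical psychophysical estimate).
#' @return A `capture_field` object.
#' @export
capture_field <- function(profile, inner_segment_diameter,
                          aperture_fraction = 0.48) {
  stopifnot(inherits(profile, "stimulus_profile"))
  px <- profile$pixel_scale
  fwhm <- aperture_fraction * inner_segment_diameter
  sigma_px <- fwhm / (2 * sqrt(2 * log(2))) / px
  half <- max(3L, ceiling(4 * sigma_px))
  ax <- (-half):half
  g1 <- exp(-ax^2 / (2 * sigma_px^2))
  kern <- outer(g1, g1) # aperture sensitivity profile; peak 1, not normalized
  field <- conv2_same_pad(profile$profile, kern)
  n <- nrow(field)
  c0 <- n %/% 2 + 1
  structure(list(field = field, pixel_scale = px, center = c0,
                 aperture_fwhm = fwhm),
            class = "capture_field")
}

# convolution that grows the grid so aperture tails are not clipped
conv2_same_pad <- function(a, k) {
  nk <- dim(k)[1]
  pad <- (nk - 1) %/% 2
  n <- nrow(a) + 2 * pad
  big <- matrix(0, n, n)
  big[(pad + 1):(pad + nrow(a)), (pad + 1):(pad + ncol(a))] <- a
  conv2_same(big, k)
}

# bilinear interpolation of matrix `m` at fractional (row, col) indices;
# zero outside the grid
interp2 <- function(m, ri, ci) {
  n1 <- nrow(m); n2 <- ncol(m)
  out <- numeric(length(ri))
  ok <- ri >= 1 & ri <= n1 & ci >= 1 & ci <= n2
  r0 <- pmin(floor(ri[ok]), n1 - 1); c0 <- pmin(floor(ci[ok]), n2 - 1)
  fr <- ri[ok] - r0; fc <- ci[ok] - c0
  out[ok] <- m[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    m[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    m[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    m[cbind(r0 + 1, c0 + 1)] * fr * fc
  out
}

#' Per-cone capture fractions for one trial
#'
#' For every frame of the delivery trace the stimulus profile is centered on
#' the landing position; each cone absorbs the profile integrated under its
#' Gaussian aperture. Absorptions are summed over frames and re-expressed as
#' each cone's share of the total light absorbed by the mosaic.
#'
#' @param mosaic A `cone_mosaic`.
#' @param profile A `stimulus_profile`, or a precomputed `capture_field`.
#' @param trace Delivery positions, matrix with columns x, y (arcmin).
#' @param targeted_id Id of the targeted cone.
#' @param aperture_fraction Aperture FWHM / inner-segment diameter (used only
#'   when `profile` is a `stimulus_profile`).
#' @return A `capture_result`: list with `fractions` (named numeric over cone
#'   ids, summing to 1), `targeted_id`, `targeted_fraction`,
#'   `nearest_neighbor_fraction` (largest share among non-targeted cones).
#' @export
capture_fractions <- function(mosaic, profile, trace, targeted_id,
                              aperture_fraction = 0.48) {
  cone_row(mosaic, targeted_id) # validates the id
  cf <- if (inherits(profile, "capture_field")) profile else
    capture_field(profile, mosaic$inner_segment_diameter, aperture_fraction)
  trace <- as.matrix(trace)
  px <- cf$pixel_scale
  cones <- mosaic$cones
  absorbed <- numeric(nrow(cones))
  for (f in seq_len(nrow(trace))) {
    dx <- cones$x_arcmin - trace[f, 1]
    dy <- cones$y_arcmin - trace[f, 2]
    absorbed <- absorbed +
      interp2(cf$field, cf$center + dy / px, cf$center + dx / px)
  }
  total <- sum(absorbed)
  if (total <= 0) stop("no light absorbed: deliveries fell outside the mosaic")
  frac <- absorbed / total
  names(frac) <- cones$cone_id
  t_i <- match(targeted_id, cones$cone_id)
  structure(list(fractions = frac,
                 targeted_id = targeted_id,
                 targeted_fraction = frac[[t_i]],
                 nearest_neighbor_fraction =
                   if (length(frac) > 1) max(frac[-t_i]) else 0),
            class = "capture_result")
}

#' Session-level light-capture summary
#'
#' Runs the capture model over every retained trial of a session and
#' summarizes, per targeted cone and overall, the mean and SD of the targeted
#' cone's share of absorbed light and of the largest neighboring share.
#'
#' @param mosaic A `cone_mosaic`.
#' @param profile A `stimulus_profile`.
#' @param traces List of trials; each element a list with `targeted_id` and
#'   `positions` (frames x 2 matrix).
#' @param aperture_fraction Aperture FWHM / inner-segment diameter.
#' @param max_error Delivery-error cutoff in arcmin; trials above it are
#'   discarded before summarizing.
#' @return List with `per_cone` (data frame: cone_id, n_trials, mean/sd of
#'   targeted and neighbor shares), `overall` (means and SDs across retained
#'   trials), `n_retained`, `n_discarded`.
#' @export
session_capture_summary <- function(mosaic, profile, traces,
                                    aperture_fraction = 0.48,
                                    max_error = 0.35) {
  errs <- vapply(traces, function(tr) delivery_error(tr$positions), 0)
  keep <- errs <= max_error
  if (!any(keep)) stop("no trials retained after delivery-error filtering")
  cf <- capture_field(profile, mosaic$inner_segment_diameter,
                      aperture_fraction)
  res <- lapply(traces[keep], function(tr) {
    cr <- capture_fractions(mosaic, cf, tr$positions, tr$targeted_id)
    c(targeted = cr$targeted_fraction, neighbor = cr$nearest_neighbor_fraction)
  })
  res <- do.call(rbind, res)
  ids <- vapply(traces[keep], function(tr) tr$targeted_id, 0)
  per_cone <- do.call(rbind, lapply(split(seq_along(ids), ids), function(ix) {
    data.frame(cone_id = ids[ix[1]], n_trials = length(ix),
               targeted_mean = mean(res[ix, "targeted"]),
               targeted_sd = stats::sd(res[ix, "targeted"]),
               neighbor_mean = mean(res[ix, "neighbor"]),
               neighbor_sd = stats::sd(res[ix, "neighbor"]))
  }))
  rownames(per_cone) <- NULL
  list(per_cone = per_cone,
       overall = c(targeted_mean = mean(res[, "targeted"]),
                   targeted_sd = stats::sd(res[, "targeted"]),
                   neighbor_mean = mean(res[, "neighbor"]),
                   neighbor_sd = stats::sd(res[, "neighbor"])),
       n_retained = sum(keep), n_discarded = sum(!keep))
}
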