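#' Synthetic observer parameters
#'
#' Bundles the generative model of a psychophysical observer: detection
#' follows a Weibull frequency-of-seeing function per cone type, brightness a
#' Stevens power law with Gaussian rating noise, and hue scaling a
#' five-category multinomial whose probabilities derive from a cone-specific
#' latent locus in the uniform appearance diagram (UAD).
#'
#' Each simulated cone is given a latent UAD locus equal to its type's mean
#' locus plus isotropic Gaussian scatter (`locus_sd`), truncated to the UAD
#' diamond |x| + |y| <= 1: real cones of one type share a stereotyped hue
#' direction but differ measurably from one another. Type mean loci default to
#' the hue directions characteristic of parafoveal cones — L reddish-yellow
#' near -35.6 deg, M green/blue near +74.5 deg — at moderate saturation, with
#' S cones toward blue. S-cone thresholds are elevated by `s_sensitivity`
#' (a 543 nm probe is roughly 300 times less effective at exciting S cones).
#'
#' @param threshold Named numeric, Weibull threshold t (au) per type L/M/S
#'   (S entry is the pre-elevation base threshold).
#' @param slope Weibull slope b (shared across types).
#' @param blank_rate False-alarm rate g on blank trials.
#' @param kappa,I_theta,n Stevens law psi = kappa * (I - I_theta)^n.
#' @param brightness_noise_sd Gaussian rating noise SD (rating units).
#' @param type_locus List of length-2 numeric (x, y) mean UAD loci per type.
#' @param locus_sd Cone-level dispersion of latent loci (UAD units).
#' @param s_sensitivity Relative stimulus effectiveness for S cones (1/300).
#' @param intensity_coupling Optional slope coupling saturation to intensity
#'   (0 = hue and saturation independent of intensity, the default regime).
#' @return An `observer_params` list.
#' @export
observer_params <- function(threshold = c(L = 0.35, M = 0.35, S = 0.35),
                            slope = 2.5,
                            blank_rate = 0.05,
                            kappa = 4.5, I_theta = 0.05, n = 0.7,
                            brightness_noise_sd = 0.8,
                            type_locus = list(
                              L = locus_from_hue_sat(-35.6, 0.4),
                              M = locus_from_hue_sat(74.5, 0.4),
                              S = locus_from_hue_sat(180, 0.5)),
                            locus_sd = 0.30,
                            s_sensitivity = 1 / 300,
                            intensity_coupling = 0) {
  stopifnot(all(threshold > 0), slope > 0,
            blank_rate >= 0, blank_rate < 1,
            kappa > 0, n > 0, brightness_noise_sd >= 0,
            locus_sd >= 0, s_sensitivity > 0)
  for (l in type_locus) {
    if (sum(abs(l)) > 1 + 1e-9) stop("type locus outside the UAD diamond")
  }
  structure(list(threshold = threshold, slope = slope,
                 blank_rate = blank_rate,
                 kappa = kappa, I_theta = I_theta, n = n,
                 brightness_noise_sd = brightness_noise_sd,
                 type_locus = type_locus, locus_sd = locus_sd,
                 s_sensitivity = s_sensitivity,
                 intensity_coupling = intensity_coupling),
            class = "observer_params")
}

#' UAD coordinates of a locus given hue angle and city-block saturation
#'
#' @param hue_deg Hue angle in degrees (0 = +x, counterclockwise).
#' @param sat City-block saturation |x| + |y| of the locus.
#' @return Length-2 numeric (x, y).
#' @export
locus_from_hue_sat <- function(hue_deg, sat) {
  stopifnot(sat >= 0, sat <= 1)
  th <- hue_deg * pi / 180
  cx <- cos(th); cy <- sin(th)
  nrm <- abs(cx) + abs(cy)
  if (nrm == 0) return(c(0, 0))
  c(cx, cy) * sat / nrm
}

#' Sample a brightness rating from the Stevens model
#'
#' Rating = round(clamp(kappa * (I - I_theta)^n + noise, 0, 5)); because a
#' seen trial must carry a nonzero rating, the floor for seen trials is 1.
#'
#' @param I Effective stimulus intensity (au).
#' @param observer An `observer_params`.
#' @param seed Integer seed.
#' @return Integer rating in 1..5.
#' @export
sample_brightness <- function(I, observer, seed) {
  with_seed(seed, sample_brightness_(I, observer))
}

sample_brightness_ <- function(I, observer) {
  base <- if (I > observer$I_theta) {
    observer$kappa * (I - observer$I_theta)^observer$n
  } else 0
  r <- round(min(5, max(0, base + stats::rnorm(1, sd = observer$brightness_noise_sd))))
  max(1L, as.integer(r))
}

#' Sample five hue-scaling button presses for a latent locus
#'
#' The five presses are i.i.d. draws from a five-category distribution:
#' P(white) = 1 - saturation, and the chromatic categories split the
#' remaining mass in proportion to the positive parts of (-y, +y, -x, +x)
#' for (red, green, blue, yellow) — the inverse of the UAD axis definitions.
#'
#' @param locus Length-2 numeric (x, y), |x|+|y| <= 1.
#' @param saturation Optional saturation override; defaults to |x| + |y| of
#'   the locus.
#' @param seed Integer seed.
#' @return Named integer vector (r, g, b, y, w) summing to 5.
#' @export
sample_button_presses <- function(locus, saturation = sum(abs(locus)), seed) {
  with_seed(seed, sample_button_presses_(locus, saturation))
}

sample_button_presses_ <- function(locus, saturation = sum(abs(locus))) {
  if (length(locus) != 2 || sum(abs(locus)) > 1 + 1e-9) {
    stop("locus must be (x, y) with |x| + |y| <= 1")
  }
  if (saturation < 0 || saturation > 1) stop("saturation must be in [0, 1]")
  x <- locus[1]; y <- locus[2]
  chro <- c(r = max(0, -y), g = max(0, y), b = max(0, -x), y = max(0, x))
  p <- if (sum(chro) > 0) chro / sum(chro) * saturation else c(r = 0, g = 0, b = 0, y = 0)
  p <- c(p, w = 1 - saturation)
  draws <- stats::rmultinom(1, 5, p)[, 1]
  names(draws) <- c("r", "g", "b", "y", "w")
  draws
}

#' Simulate a cone-targeted psychophysics session
#'
#' Emulates the standard session design: each targeted cone is flashed
#' `reps` times at each of the given intensities, plus `blank_fraction`
#' additional blank (zero-intensity) catch trials; trial order is randomized
#' across cones and intensities. Detection is Weibull per the targeted cone's
#' type (S cones see their threshold divided by `s_sensitivity`); blanks are
#' "seen" at the false-alarm rate; seen trials receive a Stevens brightness
#' rating and five hue-scaling presses from the cone's latent UAD locus.
#' Delivery errors are drawn from simulated per-frame traces so downstream
#' filtering has realistic input.
#'
#' @param mosaic A `cone_mosaic`.
#' @param targeted_ids Cone ids to target (typically 4-6 per session).
#' @param observer An `observer_params`.
#' @param intensities Three (or more) positive, distinct flash intensities (au).
#' @param reps Flashes per cone per intensity (default 10).
#' @param blank_fraction Extra blank trials as a fraction of stimulus trials.
#' @param delivery_jitter_sd Per-frame delivery jitter SD, arcmin.
#' @param frames Frames per trial.
#' @param capture_scaling Optional named vector of per-cone capture fractions;
#'   when supplied, effective intensity = intensity x fraction.
#' @param session_id Session label stored on each trial.
#' @param seed Integer seed; output is fully deterministic given it.
#' @return Data frame of trials: `trial_id, session_id, cone_id, intensity_au,
#'   blank, brightness, r, g, b, y, w, delivery_error_arcmin`. Press columns
#'   are NA on unseen trials.
#' @export
simulate_session <- function(mosaic, targeted_ids, observer, intensities,
                             reps = 10, blank_fraction = 0.10,
                             delivery_jitter_sd = 0.1, frames = 15,
                             capture_scaling = NULL,
                             session_id = 1L, seed) {
  stopifnot(inherits(observer, "observer_params"),
            all(intensities > 0), !anyDuplicated(intensities))
  if (missing(seed)) stop("`seed` is required")
  for (id in targeted_ids) cone_row(mosaic, id)

  grid <- expand.grid(cone_id = targeted_ids, intensity = intensities,
                      rep = seq_len(reps))
  n_stim <- nrow(grid)
  n_blank <- round(blank_fraction * n_stim)

  with_seed(seed, {
    loci <- lapply(targeted_ids, function(id) {
      ty <- cone_row(mosaic, id)$type
      latent_locus(observer$type_locus[[ty]], observer$locus_sd)
    })
    names(loci) <- as.character(targeted_ids)

    trials <- data.frame(
      cone_id = c(grid$cone_id, sample(targeted_ids, n_blank, replace = TRUE)),
      intensity_au = c(grid$intensity, rep(0, n_blank)),
      blank = c(rep(FALSE, n_stim), rep(TRUE, n_blank))
    )
    trials <- trials[sample(nrow(trials)), ]

    out <- vector("list", nrow(trials))
    for (i in seq_len(nrow(trials))) {
      tr <- trials[i, ]
      focal <- cone_row(mosaic, tr$cone_id)
      pos <- cbind(focal$x_arcmin + stats::rnorm(frames, sd = delivery_jitter_sd),
                   focal$y_arcmin + stats::rnorm(frames, sd = delivery_jitter_sd))
      derr <- delivery_error(pos)
      if (tr$blank) {
        seen <- stats::runif(1) < observer$blank_rate
        i_eff <- 0
      } else {
        i_eff <- tr$intensity_au
        if (!is.null(capture_scaling)) {
          i_eff <- i_eff * capture_scaling[[as.character(tr$cone_id)]]
        }
        th <- observer$threshold[[focal$type]]
        if (focal$type == "S") th <- th / observer$s_sensitivity
        p_seen <- weibull_fos(i_eff, g = observer$blank_rate, t = th,
                              a = 0.5, b = observer$slope)
        seen <- stats::runif(1) < p_seen
      }
      if (seen) {
        brightness <- sample_brightness_(i_eff, observer)
        loc <- loci[[as.character(tr$cone_id)]]
        sat <- min(1, max(0, sum(abs(loc)) +
                            observer$intensity_coupling * tr$intensity_au))
        presses <- sample_button_presses_(loc, sat)
      } else {
        brightness <- 0L
        presses <- c(r = NA_integer_, g = NA_integer_, b = NA_integer_,
                     y = NA_integer_, w = NA_integer_)
      }
      out[[i]] <- data.frame(
        cone_id = tr$cone_id, intensity_au = tr$intensity_au,
        blank = tr$blank, brightness = brightness,
        r = presses[["r"]], g = presses[["g"]], b = presses[["b"]],
        y = presses[["y"]], w = presses[["w"]],
        delivery_error_arcmin = derr)
    }
    res <- do.call(rbind, out)
    res <- cbind(trial_id = seq_len(nrow(res)), session_id = session_id, res)
    rownames(res) <- NULL
    res
  })
}

# type mean + isotropic Gaussian scatter, truncated to the UAD diamond
latent_locus <- function(mean_locus, sd) {
  for (i in 1:200) {
    l <- mean_locus + stats::rnorm(2, sd = sd)
    if (sum(abs(l)) <= 1) return(l)
  }
  mean_locus
}

#' Read / write a trial table
#'
#' Comma-delimited text with the `simulate_session` column layout; unseen
#' trials carry empty press fields.
#'
#' @param trials Trial data frame.
#' @param path File path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "cone_id", "intensity_au", "blank", "brightness",
            "r", "g", "b", "y", "w")
  if (!all(need %in% names(tr))) {
    stop("trial file must have columns ", paste(need, collapse = ","))
  }
  tr$blank <- as.logical(tr$blank)
  tr
}
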