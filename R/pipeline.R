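#' Default pipeline configuration
#'
#' All defaults reproduce the study conditions the analyses assume: a 512 px /
#' 0.95 deg raster, 543 nm stimulus through a 6.5 mm pupil with 0.05 D
#' residual defocus, 3 x 3 px flashes, Gaussian cone apertures at 0.48 of the
#' inner-segment diameter, a 0.35 arcmin delivery-error cutoff, sessions of
#' 10 repetitions at each of three intensities per cone with 10% blanks, and
#' a ~2:1 L:M mosaic at ~1 arcmin spacing.
#'
#' @param seed Master seed; every stage draws from a named substream of it.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1) {
  list(
    seed = seed,
    raster = list(field_deg = 0.95, pixels = 512),
    stimulus = list(log_troland_at_1au = 5.19, wavelength_nm = 543,
                    stim_px = 3),
    background = list(sources = list(imaging_raster = 2.02,
                                     stimulus_leak = 1.99,
                                     projector = 2.52)),
    optics = list(pupil_mm = 6.5, defocus_d = 0.05, aperture_fraction = 0.48,
                  delivery_jitter_sd = 0.2, frames = 15,
                  max_delivery_error = 0.35, psf_grid = 128),
    mosaic = list(spacing = 1.05, extent = 14, positional_jitter = 0.05,
                  lm_ratio = 2, s_fraction = 0.05),
    session = list(n_cones = 5, reps = 10,
                   intensities = c(0.25, 0.5, 1.0), blank_fraction = 0.10),
    observer = list(threshold = c(L = 0.35, M = 0.35, S = 0.35), slope = 2.5,
                    blank_rate = 0.05, kappa = 4.5, I_theta = 0.05, n = 0.7,
                    brightness_noise_sd = 0.8,
                    hue_deg = c(L = -35.6, M = 74.5, S = 180),
                    sat = c(L = 0.4, M = 0.4, S = 0.5),
                    locus_sd = 0.30, s_sensitivity = 1 / 300,
                    intensity_coupling = 0)
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file and merges it over [default_config()]; unknown keys are
#' rejected with the offending paths listed.
#'
#' @param path YAML file path, or NULL for defaults.
#' @param seed Optional seed override.
#' @return Validated configuration list.
#' @export
load_config <- function(path = NULL, seed = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    bad <- setdiff(names(user), names(cfg))
    if (length(bad) > 0) stop("unknown config keys: ", paste(bad, collapse = ", "))
    for (k in names(user)) {
      if (is.list(cfg[[k]]) && is.list(user[[k]])) {
        bad2 <- setdiff(names(user[[k]]), names(cfg[[k]]))
        if (length(bad2) > 0) {
          stop("unknown config keys: ",
               paste(paste(k, bad2, sep = "."), collapse = ", "))
        }
        cfg[[k]][names(user[[k]])] <- user[[k]]
      } else {
        cfg[[k]] <- user[[k]]
      }
    }
  }
  if (!is.null(seed)) cfg$seed <- seed
  stopifnot(cfg$raster$field_deg > 0, cfg$raster$pixels > 0,
            cfg$optics$pupil_mm > 0,
            all(cfg$session$intensities > 0))
  cfg
}

observer_from_config <- function(cfg) {
  ob <- cfg$observer
  observer_params(
    threshold = unlist(ob$threshold), slope = ob$slope,
    blank_rate = ob$blank_rate, kappa = ob$kappa, I_theta = ob$I_theta,
    n = ob$n, brightness_noise_sd = ob$brightness_noise_sd,
    type_locus = list(
      L = locus_from_hue_sat(ob$hue_deg[["L"]], ob$sat[["L"]]),
      M = locus_from_hue_sat(ob$hue_deg[["M"]], ob$sat[["M"]]),
      S = locus_from_hue_sat(ob$hue_deg[["S"]], ob$sat[["S"]])),
    locus_sd = ob$locus_sd, s_sensitivity = ob$s_sensitivity,
    intensity_coupling = ob$intensity_coupling)
}

#' Run the full analysis pipeline on synthetic data
#'
#' Generates a mosaic and multi-session trial set from the configured
#' synthetic observer, then runs every analysis stage: delivery-error
#' filtering, light-capture summary, Weibull and Stevens fits per cone type,
#' per-cone UAD summaries, percent-variance-explained, ANOVA + Tukey-Kramer
#' post hoc matrices, intensity-consistency and neighbor regressions, and
#' subjective classification. All outputs are written as delimited or JSON
#' text under `out_dir`, with a run log recording the seed and record counts
#' at each filtering stage. Fully deterministic given `config$seed`.
#'
#' @param config Configuration from [default_config()] / [load_config()].
#' @param out_dir Output directory (created if missing); NULL skips writing.
#' @param n_sessions Number of simulated sessions (cones per session comes
#'   from the config).
#' @return Invisible list with all in-memory results.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         n_sessions = 8) {
  log_lines <- character(0)
  say <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }
  say("seed: %d", config$seed)

  px <- sampling_resolution(config$raster$field_deg, config$raster$pixels)
  mosaic <- generate_mosaic(
    spacing = config$mosaic$spacing, extent = config$mosaic$extent,
    positional_jitter = config$mosaic$positional_jitter,
    lm_ratio = config$mosaic$lm_ratio, s_fraction = config$mosaic$s_fraction,
    pixel_scale = px, seed = substream_seed(config$seed, "mosaic"))
  say("mosaic: %d cones (%s)", nrow(mosaic$cones),
      paste(sprintf("%s=%d", names(table(mosaic$cones$type)),
                    as.integer(table(mosaic$cones$type))), collapse = " "))

  observer <- observer_from_config(config)

  # interior cones only, so every target has six true neighbors
  ctr <- config$mosaic$extent / 2
  d2 <- (mosaic$cones$x_arcmin - ctr)^2 + (mosaic$cones$y_arcmin - ctr)^2
  interior <- mosaic$cones$cone_id[order(d2)]
  n_target <- min(n_sessions * config$session$n_cones, length(interior))
  target_sets <- split(interior[seq_len(n_target)],
                       rep(seq_len(n_sessions), each = config$session$n_cones,
                           length.out = n_target))

  trials <- do.call(rbind, lapply(seq_along(target_sets), function(s) {
    simulate_session(
      mosaic, target_sets[[s]], observer,
      intensities = config$session$intensities,
      reps = config$session$reps,
      blank_fraction = config$session$blank_fraction,
      delivery_jitter_sd = config$optics$delivery_jitter_sd,
      frames = config$optics$frames, session_id = s,
      seed = substream_seed(config$seed, paste0("observer", s)))
  }))
  trials$trial_id <- seq_len(nrow(trials))
  say("trials simulated: %d (%d blanks)", nrow(trials), sum(trials$blank))

  retained <- filter_trials(trials, config$optics$max_delivery_error)
  say("trials after %.2f arcmin delivery filter: %d (discarded %d)",
      config$optics$max_delivery_error, nrow(retained),
      nrow(trials) - nrow(retained))

  psf <- compute_psf(config$stimulus$wavelength_nm, config$optics$pupil_mm,
                     config$optics$defocus_d, pixel_scale = px,
                     grid_size = config$optics$psf_grid)
  profile <- stimulus_profile(psf, config$stimulus$stim_px)
  capture_ids <- target_sets[[1]]
  capture_traces <- with_seed(substream_seed(config$seed, "optics"), {
    unlist(lapply(capture_ids, function(id) {
      focal <- cone_row(mosaic, id)
      lapply(seq_len(20), function(r) list(
        targeted_id = id,
        positions = cbind(
          focal$x_arcmin + stats::rnorm(config$optics$frames,
                                        sd = config$optics$delivery_jitter_sd),
          focal$y_arcmin + stats::rnorm(config$optics$frames,
                                        sd = config$optics$delivery_jitter_sd))))
    }), recursive = FALSE)
  })
  capture <- session_capture_summary(
    mosaic, profile, capture_traces,
    aperture_fraction = config$optics$aperture_fraction,
    max_error = config$optics$max_delivery_error)
  say("capture: targeted %.1f%%, nearest neighbor %.1f%% (n = %d trials)",
      100 * capture$overall[["targeted_mean"]],
      100 * capture$overall[["neighbor_mean"]], capture$n_retained)

  # psychometric fits pooled by cone type
  types <- mosaic$cones$type[match(retained$cone_id, mosaic$cones$cone_id)]
  fits <- lapply(c(L = "L", M = "M"), function(ty) {
    sub <- retained[types == ty | retained$blank, ]
    fd <- fos_data(sub)
    wb <- tryCatch(fit_weibull(fd$intensity, fd$n_trials, fd$n_seen,
                               fd$n_blank, fd$n_false_alarm),
                   error = function(e) NULL)
    seen <- sub[binarize_seen(sub$brightness) & !sub$blank, ]
    st <- tryCatch(fit_stevens(seen$intensity_au, seen$brightness),
                   error = function(e) NULL)
    list(weibull = wb, stevens = st)
  })
  fitted_ok <- !vapply(fits, function(f)
    is.null(f$weibull) || is.null(f$stevens), TRUE)
  if (all(fitted_ok)) {
    say("Weibull t: L %.3f, M %.3f; Stevens n: L %.2f, M %.2f",
        fits$L$weibull$t, fits$M$weibull$t,
        fits$L$stevens$n, fits$M$stevens$n)
  } else {
    say("psychometric fits skipped for: %s",
        paste(names(fits)[!fitted_ok], collapse = ", "))
  }

  summaries <- summarize_cones(retained, mosaic)
  summaries_hue <- low_saturation_filter(summaries)
  say("cone summaries: %d cones, %d pass the low-saturation filter",
      nrow(summaries), nrow(summaries_hue))

  lm_sum <- summaries[summaries$type %in% c("L", "M") & summaries$n_seen > 0, ]
  lm_hue <- low_saturation_filter(lm_sum)
  pve <- tryCatch(list(
    hue = percent_variance_explained(lm_sum$hue_deg, lm_sum$type, "hue_angle"),
    hue_filtered = percent_variance_explained(lm_hue$hue_deg, lm_hue$type,
                                              "hue_angle"),
    saturation = percent_variance_explained(lm_sum$sat_mean, lm_sum$type,
                                            "saturation")),
    error = function(e) NULL)
  if (is.null(pve)) {
    say("variance decomposition skipped: %s", "too few cones per type")
  } else {
    say("variance explained by type: hue %.1f%% (filtered %.1f%%), saturation %.1f%%",
        pve$hue$percent, pve$hue_filtered$percent, pve$saturation$percent)
  }

  posthoc <- cone_anova_posthoc(retained)

  ints <- sort(config$session$intensities, decreasing = TRUE)
  consistency <- list(
    hue = intensity_consistency(retained, ints[2], ints[1], "hue_angle"),
    saturation = intensity_consistency(retained, ints[2], ints[1],
                                       "saturation"))

  counts <- vapply(lm_sum$cone_id,
                   function(id) count_nonlike_neighbors(mosaic, id), 0L)
  names(counts) <- lm_sum$cone_id
  neighbors <- list(
    saturation = neighbor_regression(lm_sum, counts, "saturation"),
    hue_L = neighbor_regression(lm_hue, counts, "hue_angle", types = "L"),
    hue_M = neighbor_regression(lm_hue, counts, "hue_angle", types = "M"))

  if (all(table(factor(lm_sum$type, levels = c("L", "M"))) >= 4)) {
    classifier <- train_classifier(lm_sum[, c("x_mean", "y_mean")],
                                   lm_sum$type)
    predicted <- predict_types(classifier, lm_sum[, c("x_mean", "y_mean")])
    agree <- agreement(predicted, lm_sum$type,
                       seed = substream_seed(config$seed, "bootstrap"))
    agree_loo <- loo_agreement(lm_sum[, c("x_mean", "y_mean")], lm_sum$type,
                               seed = substream_seed(config$seed, "bootstrap"))
    say("classification agreement: resubstitution %.1f%% (kappa %.3f), LOO %.1f%%",
        agree$agreement_percent, agree$kappa, agree_loo$agreement_percent)
  } else {
    classifier <- NULL; agree <- NULL; agree_loo <- NULL
    say("classification skipped: fewer than 4 cones in a class")
  }

  results <- list(config = config, mosaic = mosaic, trials = trials,
                  retained = retained, capture = capture, fits = fits,
                  summaries = summaries, pve = pve, posthoc = posthoc,
                  consistency = consistency, neighbors = neighbors,
                  classifier = classifier, agreement = agree,
                  agreement_loo = agree_loo, log = log_lines)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_mosaic(mosaic, file.path(out_dir, "mosaic.csv"))
    write_trials(trials, file.path(out_dir, "trials.csv"))
    write_summaries(summaries, file.path(out_dir, "cone_summaries.csv"))
    utils::write.csv(capture$per_cone, file.path(out_dir, "capture.csv"),
                     row.names = FALSE, quote = FALSE)
    write_posthoc_matrix(posthoc$yb$p_matrix,
                         file.path(out_dir, "posthoc_yb.csv"))
    write_posthoc_matrix(posthoc$gr$p_matrix,
                         file.path(out_dir, "posthoc_gr.csv"))
    if (!is.null(classifier)) {
      write_classifier(classifier, file.path(out_dir, "classifier.json"))
    }
    report <- list(
      capture_overall = as.list(capture$overall),
      weibull = lapply(Filter(function(f) !is.null(f$weibull), fits),
                       function(f) f$weibull[c("g", "t", "a", "b", "k")]),
      stevens = lapply(Filter(function(f) !is.null(f$stevens), fits),
                       function(f)
                         list(kappa = f$stevens$kappa,
                              I_theta = f$stevens$I_theta, n = f$stevens$n)))
    if (!is.null(pve)) {
      report$percent_variance <- lapply(pve, function(p) p$percent)
    }
    if (!is.null(agree)) {
      report$agreement <- agree[c("agreement_percent", "n_agree", "n",
                                  "kappa")]
      report$agreement_loo <- agree_loo[c("agreement_percent", "n_agree", "n")]
    }
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA)
    writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  }
  invisible(results)
}

#' Recompute the desk-scale reference quantities
#'
#' Computes, from the installed code alone, the headline numbers that a
#' correctly assembled pipeline must reproduce: the combined background
#' level, the stimulus-to-background luminance ratio, the raster sampling
#' resolution, the Weibull value at threshold, and the light-capture shares
#' at the standard geometry. Returns a table of computed versus expected
#' values.
#'
#' @param seed Seed for the capture simulation.
#' @param n_capture_trials Trials in the capture simulation.
#' @return Data frame with `quantity`, `computed`, `expected`.
#' @export
acceptance_report <- function(seed = 1, n_capture_trials = 500) {
  cfg <- default_config(seed)
  cap <- capture_experiment(cfg, n_trials = n_capture_trials)
  at_t <- weibull_fos(0.3, g = 0.05, t = 0.3, a = 0.5, b = 2)
  data.frame(
    quantity = c("background log Td", "stimulus/background ratio",
                 "arcmin per pixel", "FoS at threshold (%)",
                 "targeted capture (%)", "neighbor capture (%)",
                 "targeted/neighbor ratio"),
    computed = c(
      combine_sources(unlist(cfg$background$sources)),
      luminance_ratio(cfg$stimulus$log_troland_at_1au,
                      combine_sources(unlist(cfg$background$sources))),
      sampling_resolution(cfg$raster$field_deg, cfg$raster$pixels),
      100 * at_t,
      100 * cap$overall[["targeted_mean"]],
      100 * cap$overall[["neighbor_mean"]],
      cap$overall[["targeted_mean"]] / cap$overall[["neighbor_mean"]]),
    expected = c(2.73, 290, 0.111, 50, 76.4, 8.1, 9))
}

#' Light-capture simulation at the standard geometry
#'
#' Builds the configured mosaic, PSF and stimulus profile, simulates jittered
#' delivery traces to centrally located cones, filters on delivery error and
#' summarizes capture shares. This is the simulation behind the capture rows
#' of [acceptance_report()].
#'
#' @param config Pipeline configuration.
#' @param n_trials Total delivery trials to simulate.
#' @return As [session_capture_summary()].
#' @export
capture_experiment <- function(config = default_config(), n_trials = 500) {
  px <- sampling_resolution(config$raster$field_deg, config$raster$pixels)
  mosaic <- generate_mosaic(
    spacing = config$mosaic$spacing, extent = config$mosaic$extent,
    positional_jitter = config$mosaic$positional_jitter,
    lm_ratio = config$mosaic$lm_ratio, s_fraction = config$mosaic$s_fraction,
    pixel_scale = px, seed = substream_seed(config$seed, "mosaic"))
  psf <- compute_psf(config$stimulus$wavelength_nm, config$optics$pupil_mm,
                     config$optics$defocus_d, pixel_scale = px,
                     grid_size = config$optics$psf_grid)
  profile <- stimulus_profile(psf, config$stimulus$stim_px)
  ctr <- config$mosaic$extent / 2
  d2 <- (mosaic$cones$x_arcmin - ctr)^2 + (mosaic$cones$y_arcmin - ctr)^2
  ids <- mosaic$cones$cone_id[order(d2)][seq_len(config$session$n_cones)]
  per_cone <- ceiling(n_trials / length(ids))
  traces <- with_seed(substream_seed(config$seed, "optics"), {
    unlist(lapply(ids, function(id) {
      focal <- cone_row(mosaic, id)
      lapply(seq_len(per_cone), function(r) list(
        targeted_id = id,
        positions = cbind(
          focal$x_arcmin + stats::rnorm(config$optics$frames,
                                        sd = config$optics$delivery_jitter_sd),
          focal$y_arcmin + stats::rnorm(config$optics$frames,
                                        sd = config$optics$delivery_jitter_sd))))
    }), recursive = FALSE)
  })
  session_capture_summary(mosaic, profile, traces,
                          aperture_fraction = config$optics$aperture_fraction,
                          max_error = config$optics$max_delivery_error)
}
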