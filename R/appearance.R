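#' Uniform appearance diagram coordinates from button presses
#'
#' Hue-scaling responses (five presses over red, green, blue, yellow, white;
#' each press = 20%) map to an opponent plane: x = (yellow - blue) / T and
#' y = (green - red) / T with T = 5 total presses. Pure white sits at the
#' origin; fully saturated responses on the diamond |x| + |y| = 1.
#'
#' @param r,g,b,y,w Press counts (nonnegative, summing to `T_presses`).
#' @param T_presses Total presses (5).
#' @return List with `x`, `y`, `saturation` (= |x| + |y|), `hue_deg`
#'   (NA for pure white, where the angle is undefined).
#' @examples
#' uad_from_presses(0, 1, 1, 0, 3) # a desaturated teal: x = -0.2, y = 0.2
#' @export
uad_from_presses <- function(r, g, b, y, w, T_presses = 5) {
  counts <- unname(c(r, g, b, y, w))
  if (any(counts < 0) || sum(counts) != T_presses) {
    stop("press counts must be nonnegative and sum to ", T_presses)
  }
  x <- (counts[4] - counts[3]) / T_presses
  yy <- (counts[2] - counts[1]) / T_presses
  list(x = x, y = yy,
       saturation = cityblock_saturation(x, yy),
       hue_deg = hue_angle(x, yy))
}

#' City-block saturation of a UAD point
#'
#' Distance from the origin in the city-block (L1) metric: 0 for pure white,
#' 1 on the fully saturated diamond edge.
#'
#' @param x,y UAD coordinates.
#' @return |x| + |y|.
#' @export
cityblock_saturation <- function(x, y) abs(x) + abs(y)

#' Hue angle of a UAD point
#'
#' Counterclockwise angle from the +x (yellow) direction, in (-180, 180]
#' degrees. The origin (pure white, five white presses) has no defined hue
#' and returns NA; such trials are excluded from hue-angle statistics.
#'
#' @param x,y UAD coordinates.
#' @return Angle in degrees, or NA at the origin.
#' @export
hue_angle <- function(x, y) {
  ifelse(x == 0 & y == 0, NA_real_, atan2(y, x) * 180 / pi)
}

#' Circular mean (and dispersion) of hue angles
#'
#' Averages angles as unit vectors so values straddling the -180/+180 cut do
#' not cancel; SEM derives from the circular standard deviation.
#'
#' @param deg Angles in degrees (NAs dropped).
#' @return List `mean`, `sem`, `n`.
#' @keywords internal
circular_mean_deg <- function(deg) {
  deg <- deg[!is.na(deg)]
  n <- length(deg)
  if (n == 0) return(list(mean = NA_real_, sem = NA_real_, n = 0L))
  th <- deg * pi / 180
  s <- mean(sin(th)); c <- mean(cos(th))
  mu <- atan2(s, c) * 180 / pi
  R <- sqrt(s^2 + c^2)
  csd <- if (R > 0) sqrt(-2 * log(R)) * 180 / pi else NA_real_
  list(mean = mu, sem = if (n > 1) csd / sqrt(n) else NA_real_, n = n)
}

#' Summarize all seen trials of one cone in the UAD
#'
#' Converts each seen trial's presses to a UAD point and aggregates:
#' arithmetic means with SEM for x, y and saturation (pure-white trials
#' included — they are legitimate percepts with zero saturation), a circular
#' mean hue angle over hue-defined (non-white) trials only, and the pooled
#' press histogram. Saturation is averaged per trial, not taken of the mean
#' point, so two opposed saturated percepts average to high saturation at a
#' near-white mean position.
#'
#' @param trials Trial rows for a single cone (see [simulate_session()]).
#' @param intensities Optional intensity filter (keep these levels only).
#' @param hue_mean `"circular"` (default) or `"arithmetic"`.
#' @return A `cone_summary` one-row data frame: `cone_id, n_seen, x_mean,
#'   x_sem, y_mean, y_sem, sat_mean, sat_sem, hue_deg, hue_sem, n_hue,
#'   nr, ng, nb, ny, nw`. When the cone has no seen trials, `n_seen` is 0 and
#'   the statistics are NA.
#' @export
summarize_cone <- function(trials, intensities = NULL,
                           hue_mean = c("circular", "arithmetic")) {
  hue_mean <- match.arg(hue_mean)
  if (length(unique(trials$cone_id)) > 1) {
    stop("`trials` must come from a single cone")
  }
  if (!is.null(intensities)) {
    trials <- trials[trials$intensity_au %in% intensities, , drop = FALSE]
  }
  seen <- trials[binarize_seen(trials$brightness) & !trials$blank, ,
                 drop = FALSE]
  cone_id <- trials$cone_id[1]
  if (nrow(seen) == 0) {
    return(data.frame(cone_id = cone_id, n_seen = 0L,
                      x_mean = NA_real_, x_sem = NA_real_,
                      y_mean = NA_real_, y_sem = NA_real_,
                      sat_mean = NA_real_, sat_sem = NA_real_,
                      hue_deg = NA_real_, hue_sem = NA_real_, n_hue = 0L,
                      nr = 0L, ng = 0L, nb = 0L, ny = 0L, nw = 0L))
  }
  x <- (seen$y - seen$b) / 5
  y <- (seen$g - seen$r) / 5
  sat <- cityblock_saturation(x, y)
  hue <- hue_angle(x, y)
  sem <- function(v) if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else NA_real_
  hu <- if (hue_mean == "circular") {
    circular_mean_deg(hue)
  } else {
    hh <- hue[!is.na(hue)]
    list(mean = if (length(hh)) mean(hh) else NA_real_,
         sem = sem(hh), n = length(hh))
  }
  data.frame(cone_id = cone_id, n_seen = nrow(seen),
             x_mean = mean(x), x_sem = sem(x),
             y_mean = mean(y), y_sem = sem(y),
             sat_mean = mean(sat), sat_sem = sem(sat),
             hue_deg = hu$mean, hue_sem = hu$sem, n_hue = as.integer(hu$n),
             nr = sum(seen$r), ng = sum(seen$g), nb = sum(seen$b),
             ny = sum(seen$y), nw = sum(seen$w))
}

#' Per-cone UAD summaries for a whole trial table
#'
#' @param trials Full trial table.
#' @param mosaic Optional `cone_mosaic`; when given, a `type` column is added.
#' @param ... Passed to [summarize_cone()].
#' @return Data frame, one row per targeted cone.
#' @export
summarize_cones <- function(trials, mosaic = NULL, ...) {
  out <- do.call(rbind, lapply(split(trials, trials$cone_id),
                               summarize_cone, ...))
  rownames(out) <- NULL
  if (!is.null(mosaic)) {
    out <- cbind(out[, "cone_id", drop = FALSE],
                 type = mosaic$cones$type[match(out$cone_id,
                                                mosaic$cones$cone_id)],
                 out[, setdiff(names(out), "cone_id")])
  }
  out
}

#' Exclude low-saturation cones from hue analyses
#'
#' Mean hue angles of nearly achromatic cones rest on a handful of chromatic
#' presses and are inherently noisy; cones with mean saturation below
#' `threshold` are excluded (strictly below: a mean of exactly `threshold` is
#' retained). Applies to hue-angle analyses only.
#'
#' @param summaries Output of [summarize_cones()].
#' @param threshold Saturation cutoff (default 0.1).
#' @return Retained rows.
#' @export
low_saturation_filter <- function(summaries, threshold = 0.1) {
  summaries[!is.na(summaries$sat_mean) & summaries$sat_mean >= threshold, ,
            drop = FALSE]
}

#' Write / read a per-cone summary table
#'
#' @param summaries Output of [summarize_cones()].
#' @param path File path.
#' @export
write_summaries <- function(summaries, path) {
  utils::write.csv(summaries, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_summaries
#' @export
read_summaries <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
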