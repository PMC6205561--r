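#' Mean square difference between two aligned response sets
#'
#' d(x, y) = (1/N) * sum |x_c - y_c|^2 over cones c. For hue angles the
#' difference is wrapped to (-180, 180] first (`circular = TRUE`), since a
#' squared difference across the +/-180 cut would be meaningless.
#'
#' @param xs,ys Equal-length numeric vectors (one value per cone).
#' @param circular Wrap differences circularly (degrees)?
#' @return The mean square difference.
#' @export
mean_square_difference <- function(xs, ys, circular = FALSE) {
  if (length(xs) != length(ys)) stop("`xs` and `ys` must be the same length")
  d <- xs - ys
  if (circular) d <- wrap_deg(d)
  mean(d^2)
}

# wrap degrees to (-180, 180]
wrap_deg <- function(d) {
  w <- ((d + 180) %% 360) - 180
  ifelse(w == -180, 180, w)
}

#' Percent variance in a percept metric explained by cone type
#'
#' Compares how well each cone's mean response is predicted by its type mean
#' versus the grand mean:
#' percent = 100 * (1 - d(X_c, X_type) / d(X_c, X_grand)),
#' where d is the mean square difference across cones, X_type assigns every
#' cone its own type's mean and X_grand the mean over all cones. 100% means
#' type membership absorbs all between-cone variance; 0% means type means are
#' no better than the grand mean; negative values (type means predict worse
#' than the grand mean) are possible and reported as-is. Hue-angle metrics
#' use circular (wrapped) differences and circular means.
#'
#' @param cone_means Per-cone mean metric values (hue angle in degrees, or
#'   saturation).
#' @param cone_types Types aligned with `cone_means`; only L and M enter.
#' @param metric `"hue_angle"` or `"saturation"` (controls circular handling).
#' @return List with `percent`, `d_type`, `d_grand`, `n`, `metric`.
#' @export
percent_variance_explained <- function(cone_means, cone_types,
                                       metric = c("hue_angle", "saturation")) {
  metric <- match.arg(metric)
  stopifnot(length(cone_means) == length(cone_types))
  keep <- cone_types %in% c("L", "M") & !is.na(cone_means)
  cone_means <- cone_means[keep]
  cone_types <- cone_types[keep]
  if (!all(c("L", "M") %in% cone_types) ||
      min(table(cone_types)) < 2) {
    stop("need at least two L and two M cones")
  }
  circ <- metric == "hue_angle"
  center <- function(v) {
    if (circ) circular_mean_deg(v)$mean else mean(v)
  }
  type_mean <- vapply(c(L = "L", M = "M"),
                      function(ty) center(cone_means[cone_types == ty]), 0)
  grand <- center(cone_means)
  d_type <- mean_square_difference(cone_means, type_mean[cone_types],
                                   circular = circ)
  d_grand <- mean_square_difference(cone_means, rep(grand, length(cone_means)),
                                    circular = circ)
  list(percent = 100 * (1 - d_type / d_grand),
       d_type = d_type, d_grand = d_grand,
       n = length(cone_means), metric = metric)
}

#' Per-cone ANOVA with Tukey-Kramer post hoc matrices
#'
#' For each UAD dimension (y-b and g-r separately), runs a one-way ANOVA of
#' per-trial values on cone identity, pooling intensities, then all-pairs
#' Tukey-Kramer comparisons (the studentized-range test with unequal group
#' sizes, via [stats::TukeyHSD()]). Cones with fewer than 2 seen trials are
#' dropped with a warning.
#'
#' @param trials Trial table; only seen, non-blank trials enter.
#' @param dimensions Which UAD dimensions to analyze.
#' @return Named list per dimension: `anova` (F, df, p) and `p_matrix`, a
#'   symmetric cone x cone matrix of adjusted p-values with unit diagonal.
#' @export
cone_anova_posthoc <- function(trials, dimensions = c("yb", "gr")) {
  seen <- trials[binarize_seen(trials$brightness) & !trials$blank, ,
                 drop = FALSE]
  counts <- table(seen$cone_id)
  drop_ids <- names(counts)[counts < 2]
  if (length(drop_ids) > 0) {
    warning("dropping cones with < 2 seen trials: ",
            paste(drop_ids, collapse = ", "))
    seen <- seen[!(seen$cone_id %in% drop_ids), , drop = FALSE]
  }
  if (length(unique(seen$cone_id)) < 2) stop("need >= 2 cones with >= 2 trials")
  vals <- list(yb = (seen$y - seen$b) / 5, gr = (seen$g - seen$r) / 5)
  out <- lapply(dimensions, function(dim) {
    df <- data.frame(v = vals[[dim]], cone = factor(seen$cone_id))
    fit <- stats::aov(v ~ cone, data = df)
    an <- summary(fit)[[1]]
    tk <- stats::TukeyHSD(fit)$cone
    ids <- levels(df$cone)
    p <- matrix(1, length(ids), length(ids), dimnames = list(ids, ids))
    pair <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
    p[cbind(pair[, 1], pair[, 2])] <- tk[, "p adj"]
    p[cbind(pair[, 2], pair[, 1])] <- tk[, "p adj"]
    list(anova = list(F = an$`F value`[1],
                      df = c(an$Df[1], an$Df[2]),
                      p = an$`Pr(>F)`[1]),
         p_matrix = p)
  })
  names(out) <- dimensions
  out
}

#' Consistency of per-cone percepts across two intensity levels
#'
#' Ordinary least-squares regression of each cone's mean metric at intensity
#' level B on its mean at level A, with 95% CI on the slope. Hue judged
#' independent of intensity shows a slope near 1 with high R^2. Hue-angle
#' comparisons first drop cones whose overall mean saturation falls below the
#' low-saturation cutoff.
#'
#' @param trials Trial table.
#' @param level_a,level_b The two intensities to compare (au).
#' @param metric `"hue_angle"` or `"saturation"`.
#' @param sat_threshold Low-saturation exclusion for hue comparisons.
#' @return List with `slope`, `intercept`, `r_squared`, `p`, `ci` (95% CI on
#'   the slope), `n` cones, and the per-cone table.
#' @export
intensity_consistency <- function(trials, level_a, level_b,
                                  metric = c("hue_angle", "saturation"),
                                  sat_threshold = 0.1) {
  metric <- match.arg(metric)
  sa <- summarize_cones(trials, intensities = level_a)
  sb <- summarize_cones(trials, intensities = level_b)
  col <- if (metric == "hue_angle") "hue_deg" else "sat_mean"
  if (metric == "hue_angle") {
    overall <- summarize_cones(trials)
    keep <- overall$cone_id[!is.na(overall$sat_mean) &
                              overall$sat_mean >= sat_threshold]
    sa <- sa[sa$cone_id %in% keep, ]
    sb <- sb[sb$cone_id %in% keep, ]
  }
  m <- merge(sa[, c("cone_id", col)], sb[, c("cone_id", col)],
             by = "cone_id", suffixes = c("_a", "_b"))
  m <- m[stats::complete.cases(m), ]
  if (nrow(m) < 3) stop("need >= 3 cones present at both levels")
  fit <- stats::lm(m[[paste0(col, "_b")]] ~ m[[paste0(col, "_a")]])
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       ci = unname(stats::confint(fit)[2, ]),
       n = nrow(m),
       per_cone = m)
}

#' Regression of a percept metric on the nonlike-neighbor count
#'
#' Tests whether the composition of a cone's immediate neighborhood (number
#' of its six nearest neighbors with a different spectral type) predicts its
#' mean saturation or hue angle. Plain least squares on the integer counts;
#' any x-jitter belongs to plotting, never to the fit.
#'
#' @param summaries Per-cone summaries (with `type` column).
#' @param nonlike_counts Named vector (by cone id) or vector aligned with
#'   `summaries`, values in 0..6.
#' @param metric `"hue_angle"` or `"saturation"`.
#' @param types Restrict to these cone types (e.g. "M" only).
#' @return List with `slope`, `r_squared`, `p`, `n`, `degenerate` (TRUE when
#'   every count is identical, leaving the slope undefined).
#' @export
neighbor_regression <- function(summaries, nonlike_counts,
                                metric = c("hue_angle", "saturation"),
                                types = c("L", "M")) {
  metric <- match.arg(metric)
  stopifnot(all(nonlike_counts >= 0 & nonlike_counts <= 6))
  if (!is.null(names(nonlike_counts))) {
    nonlike_counts <- nonlike_counts[as.character(summaries$cone_id)]
  }
  col <- if (metric == "hue_angle") "hue_deg" else "sat_mean"
  keep <- summaries$type %in% types & !is.na(summaries[[col]])
  yv <- summaries[[col]][keep]
  xv <- as.numeric(nonlike_counts[keep])
  if (length(unique(xv)) < 2) {
    return(list(slope = NA_real_, r_squared = NA_real_, p = NA_real_,
                n = length(xv), degenerate = TRUE))
  }
  fit <- stats::lm(yv ~ xv)
  sm <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4],
       n = length(xv), degenerate = FALSE)
}

#' Write a post hoc p-value matrix as delimited text
#'
#' @param p_matrix Square matrix with cone ids in dimnames.
#' @param path File path.
#' @export
write_posthoc_matrix <- function(p_matrix, path) {
  utils::write.csv(as.data.frame(p_matrix), path, quote = FALSE)
  invisible(path)
}
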