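#' Binarize a brightness rating into seen / not seen
#'
#' A rating of 0 means the flash was not seen; any nonzero rating implies the
#' subject saw the flash well enough to rate it, so the default criterion is
#' `rating > 0`. A stricter `"> 1"` criterion is available for sensitivity
#' analyses.
#'
#' @param rating Integer rating(s) in 0..5.
#' @param criterion `">0"` (default) or `">1"`.
#' @return Logical vector.
#' @export
binarize_seen <- function(rating, criterion = c(">0", ">1")) {
  criterion <- match.arg(criterion)
  if (any(is.na(rating)) || any(rating < 0 | rating > 5)) {
    stop("ratings must be in 0..5")
  }
  if (criterion == ">0") rating > 0 else rating > 1
}

#' Weibull frequency-of-seeing function
#'
#' FoS(x) = 1 - (1 - g) * exp(-(k x / t)^b) with
#' k = (-log((1 - a) / (1 - g)))^(1 / b), so that FoS(0) = g (the blank
#' false-alarm rate) and FoS(t) = a exactly: the threshold t is the intensity
#' at which the defining proportion a (here 0.5) is seen.
#'
#' @param x Stimulus intensity (au), >= 0.
#' @param g Blank false-alarm rate in [0, 1).
#' @param t Threshold intensity, > 0.
#' @param a Proportion seen that defines the threshold (default 0.5).
#' @param b Slope, > 0.
#' @return Probability of seeing.
#' @examples
#' weibull_fos(0.35, g = 0.05, t = 0.35, b = 2) # = 0.5
#' @export
weibull_fos <- function(x, g, t, a = 0.5, b) {
  stopifnot(all(x >= 0), g >= 0, g < 1, t > 0, b > 0)
  if (a <= g) stop("`a` must exceed `g`: threshold proportion below chance")
  k <- (-log((1 - a) / (1 - g)))^(1 / b)
  1 - (1 - g) * exp(-(k * x / t)^b)
}

#' Fit the Weibull frequency-of-seeing function by maximum likelihood
#'
#' `g` is fixed at the observed blank false-alarm rate (0 when no blanks are
#' supplied) and `a` at 0.5; only threshold `t` and slope `b` are free. The
#' binomial log-likelihood is maximized over (log t, log b) by Nelder-Mead
#' from a 5 x 5 multistart grid (t spanning the data range, b in [0.5, 8]);
#' ties go to the highest likelihood, then the smallest slope. Data in which
#' every trial was seen (or none was) leave the threshold unidentified; the
#' fit is returned with `converged = FALSE` rather than raising an error.
#'
#' @param intensity Stimulus intensities (au), one per level.
#' @param n_trials,n_seen Trials and seen counts per level.
#' @param n_blank,n_false_alarm Blank-trial totals (optional; fix `g`).
#' @param a Defining proportion (default 0.5).
#' @return A `weibull_fit`: list with `g, t, a, b, k, loglik, converged`.
#' @export
fit_weibull <- function(intensity, n_trials, n_seen,
                        n_blank = 0, n_false_alarm = 0, a = 0.5) {
  stopifnot(length(intensity) == length(n_trials),
            length(intensity) == length(n_seen),
            all(n_seen >= 0), all(n_seen <= n_trials),
            all(intensity > 0), !anyDuplicated(intensity))
  if (length(intensity) < 2) stop("need >= 2 intensity levels")
  g <- if (n_blank > 0) n_false_alarm / n_blank else 0
  if (g >= a) stop("false-alarm rate exceeds the defining proportion")

  identifiable <- sum(n_seen) > 0 && sum(n_seen) < sum(n_trials)

  nll <- function(par) {
    t <- exp(par[1]); b <- exp(par[2])
    p <- weibull_fos(intensity, g = g, t = t, a = a, b = b)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n_seen * log(p) + (n_trials - n_seen) * log(1 - p))
  }

  t_grid <- exp(seq(log(min(intensity) / 2), log(max(intensity) * 2),
                    length.out = 5))
  b_grid <- seq(0.5, 8, length.out = 5)
  best <- NULL
  for (t0 in t_grid) for (b0 in b_grid) {
    fit <- tryCatch(
      stats::optim(c(log(t0), log(b0)), nll, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9 ||
        (abs(fit$value - best$value) <= 1e-9 && fit$par[2] < best$par[2])) {
      best <- fit
    }
  }
  t_hat <- exp(best$par[1]); b_hat <- exp(best$par[2])
  structure(list(
    g = g, t = t_hat, a = a, b = b_hat,
    k = (-log((1 - a) / (1 - g)))^(1 / b_hat),
    loglik = -best$value,
    converged = identifiable && best$convergence == 0
  ), class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat(sprintf("Weibull FoS fit: t = %.4g au, b = %.3g (g = %.3g, a = %.2g)%s\n",
              x$t, x$b, x$g, x$a,
              if (!x$converged) " [non-identifiable or not converged]" else ""))
  invisible(x)
}

#' Stevens power-law brightness function
#'
#' psi(I) = kappa * (I - I_theta)^n for I > I_theta, else 0.
#'
#' @param I Intensity (au).
#' @param kappa Scale, > 0.
#' @param I_theta Threshold intercept, >= 0.
#' @param n Exponent, > 0 (n < 1 compressive, n > 1 expansive).
#' @return Predicted brightness.
#' @export
stevens_law <- function(I, kappa, I_theta, n) {
  stopifnot(kappa > 0, n > 0, I_theta >= 0)
  ifelse(I > I_theta, kappa * (I - I_theta)^n, 0)
}

#' Fit Stevens' power law to brightness ratings
#'
#' Least-squares fit of (kappa, I_theta, n) to seen-trial brightness ratings,
#' either per trial or to per-intensity mean ratings. Parameters are
#' constrained to kappa > 0, n > 0, 0 <= I_theta < min(I) by an internal
#' transform; optimization is Nelder-Mead from a small multistart grid over
#' the exponent. With exactly three intensity levels of mean data the model
#' interpolates the data exactly; such fits are flagged `degenerate = TRUE`.
#'
#' @param intensity Intensities (au) of seen trials (or level means).
#' @param brightness Corresponding ratings.
#' @return A `stevens_fit`: list with `kappa, I_theta, n, rss, degenerate`.
#' @export
fit_stevens <- function(intensity, brightness) {
  stopifnot(length(intensity) == length(brightness), all(intensity > 0))
  levels <- sort(unique(intensity))
  if (length(levels) < 3) stop("need >= 3 intensity levels")
  i_min <- min(intensity)

  # parameters: log kappa, logit-scaled I_theta in [0, i_min), log n
  unpack <- function(par) {
    list(kappa = exp(par[1]),
         I_theta = i_min * stats::plogis(par[2]) * 0.999,
         n = exp(par[3]))
  }
  rss <- function(par) {
    p <- unpack(par)
    sum((brightness - stevens_law(intensity, p$kappa, p$I_theta, p$n))^2)
  }
  best <- NULL
  for (n0 in c(0.5, 0.7, 1, 1.5)) for (th0 in c(-4, 0)) {
    k0 <- max(mean(brightness) / mean(intensity)^n0, 1e-3)
    fit <- stats::optim(c(log(k0), th0, log(n0)), rss,
                        method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-14))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  p <- unpack(best$par)
  structure(list(kappa = p$kappa, I_theta = p$I_theta, n = p$n,
                 rss = best$value,
                 degenerate = length(levels) == 3 &&
                   length(intensity) == 3),
            class = "stevens_fit")
}

#' @export
print.stevens_fit <- function(x, ...) {
  cat(sprintf("Stevens fit: kappa = %.3g, I_theta = %.3g au, n = %.3g (%s)%s\n",
              x$kappa, x$I_theta, x$n,
              if (x$n < 1) "compressive" else if (x$n > 1) "expansive" else "linear",
              if (x$degenerate) " [exact 3-point interpolation]" else ""))
  invisible(x)
}

#' Tabulate frequency-of-seeing data from a trial table
#'
#' @param trials Trial data frame (see [simulate_session()]).
#' @param criterion Seen criterion passed to [binarize_seen()].
#' @return List with per-level `intensity`, `n_trials`, `n_seen`, and blank
#'   totals `n_blank`, `n_false_alarm`.
#' @export
fos_data <- function(trials, criterion = ">0") {
  seen <- binarize_seen(trials$brightness, criterion)
  stim <- !trials$blank
  tab <- split(seen[stim], trials$intensity_au[stim])
  list(intensity = as.numeric(names(tab)),
       n_trials = vapply(tab, length, 0L),
       n_seen = vapply(tab, sum, 0L),
       n_blank = sum(!stim),
       n_false_alarm = sum(seen[!stim]))
}
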