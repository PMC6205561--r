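test_that("mean square difference is the averaged squared gap", {
  expect_equal(mean_square_difference(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mean_square_difference(c(1, 2), c(0, 0)), 2.5)
  set.seed(2)
  xs <- rnorm(8); ys <- rnorm(8)
  expect_equal(mean_square_difference(3 * xs, 3 * ys),
               9 * mean_square_difference(xs, ys))
  expect_error(mean_square_difference(1:3, 1:4), "length")
  # circular wrapping keeps angular gaps small across the cut
  expect_equal(mean_square_difference(179, -179, circular = TRUE), 4)
})

test_that("percent variance explained matches hand arithmetic", {
  # L means (10, 20), M means (30, 40): d_type = 25, d_grand = 125 -> 80%
  pve <- percent_variance_explained(c(10, 20, 30, 40),
                                    c("L", "L", "M", "M"), "saturation")
  expect_equal(pve$d_type, 25)
  expect_equal(pve$d_grand, 125)
  expect_equal(pve$percent, 80)
  expect_equal(pve$n, 4)
})

test_that("percent variance explained hits its fixed points", {
  # every cone equals its type mean (types differ) -> 100%
  p1 <- percent_variance_explained(c(1, 1, 5, 5), c("L", "L", "M", "M"),
                                   "saturation")
  expect_equal(p1$percent, 100)
  # type means equal the grand mean -> 0%
  p0 <- percent_variance_explained(c(1, 3, 1, 3), c("L", "L", "M", "M"),
                                   "saturation")
  expect_equal(p0$percent, 0, tolerance = 1e-9)
})

test_that("percent variance explained is shift- and relabel-invariant", {
  set.seed(3)
  v <- rnorm(12); ty <- rep(c("L", "M"), 6)
  a <- percent_variance_explained(v, ty, "saturation")$percent
  b <- percent_variance_explained(v + 7, ty, "saturation")$percent
  expect_equal(a, b)
  perm <- sample(12)
  c_ <- percent_variance_explained(v[perm], ty[perm], "saturation")$percent
  expect_equal(a, c_)
})

test_that("percent variance explained can be negative and is not clipped", {
  # with arithmetic means d_type <= d_grand always; negativity arises only
  # for hue angles, where the circular mean does not minimize squared
  # wrapped deviations. A widely dispersed L set realizes the case:
  v <- c(-62.75, -71.51, 93.41, 133.77, 17.27, 33.46)
  ty <- c("L", "L", "L", "L", "M", "M")
  neg <- percent_variance_explained(v, ty, "hue_angle")
  expect_lt(neg$percent, 0)
  # brute-force cross-check of the same instance
  circ_mean <- function(a) atan2(mean(sin(a * pi / 180)),
                                 mean(cos(a * pi / 180))) * 180 / pi
  wrap <- function(d) { w <- ((d + 180) %% 360) - 180; ifelse(w == -180, 180, w) }
  tm <- ifelse(ty == "L", circ_mean(v[ty == "L"]), circ_mean(v[ty == "M"]))
  d_type <- mean(wrap(v - tm)^2)
  d_grand <- mean(wrap(v - circ_mean(v))^2)
  expect_equal(neg$percent, 100 * (1 - d_type / d_grand), tolerance = 1e-9)
})

test_that("hue-angle variance uses circular differences", {
  # cone means straddling the cut: circular treatment sees tight clusters
  v <- c(175, -175, 5, -5)
  ty <- c("L", "L", "M", "M")
  pve <- percent_variance_explained(v, ty, "hue_angle")
  expect_gt(pve$percent, 99)
  expect_error(percent_variance_explained(c(1, 2, 3), c("L", "L", "L"),
                                          "hue_angle"), "two L and two M")
})

sim_two_cone_trials <- function(locus1, locus2, n_each, seed) {
  presses <- t(vapply(seq_len(2 * n_each), function(i) {
    loc <- if (i <= n_each) locus1 else locus2
    sample_button_presses(loc, seed = seed * 1e4 + i)
  }, integer(5)))
  data.frame(cone_id = rep(c(1, 2), each = n_each), intensity_au = 1,
             blank = FALSE, brightness = 3,
             r = presses[, 1], g = presses[, 2], b = presses[, 3],
             y = presses[, 4], w = presses[, 5])
}

test_that("the posthoc matrix is symmetric with unit diagonal and finds real gaps", {
  tr <- sim_two_cone_trials(c(0.3, -0.2), c(-0.1, 0.4), 30, seed = 1)
  ph <- cone_anova_posthoc(tr)
  for (dim in c("yb", "gr")) {
    p <- ph[[dim]]$p_matrix
    expect_equal(p, t(p))
    expect_equal(unname(diag(p)), rep(1, nrow(p)))
  }
  # loci separated by ~5 SDs of the press noise: tiny p
  expect_lt(ph$yb$p_matrix["1", "2"], 1e-3)
  expect_gt(ph$yb$anova$F, 10)
})

test_that("the posthoc test holds its nominal size on null data", {
  # identical generating loci: significant fraction near alpha
  hits <- 0; reps <- 150
  for (r in seq_len(reps)) {
    tr <- sim_two_cone_trials(c(0.1, 0.1), c(0.1, 0.1), 25, seed = r + 100)
    ph <- cone_anova_posthoc(tr, dimensions = "gr")
    hits <- hits + (ph$gr$p_matrix["1", "2"] < 0.05)
  }
  # binomial 3-sigma band around 0.05
  expect_lt(hits / reps, 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("posthoc p-values rank like a brute-force permutation test", {
  set.seed(12)
  loci <- list(c(0.3, -0.3), c(0.25, -0.2), c(-0.1, 0.35), c(0.0, 0.0))
  presses <- list(); ids <- integer(0)
  for (ci in seq_along(loci)) {
    presses[[ci]] <- t(vapply(1:10, function(i)
      sample_button_presses(loci[[ci]], seed = ci * 100 + i), integer(5)))
    ids <- c(ids, rep(ci, 10))
  }
  pm <- do.call(rbind, presses)
  tr <- data.frame(cone_id = ids, intensity_au = 1, blank = FALSE,
                   brightness = 3, r = pm[, 1], g = pm[, 2], b = pm[, 3],
                   y = pm[, 4], w = pm[, 5])
  ph <- cone_anova_posthoc(tr, dimensions = "gr")$gr$p_matrix

  # permutation oracle: difference of group means under label shuffles
  gr <- (tr$g - tr$r) / 5
  perm_p <- function(i, j, B = 400) {
    vi <- gr[tr$cone_id == i]; vj <- gr[tr$cone_id == j]
    obs <- abs(mean(vi) - mean(vj))
    pool <- c(vi, vj); n1 <- length(vi)
    stat <- replicate(B, {
      s <- sample(pool)
      abs(mean(s[1:n1]) - mean(s[-(1:n1)]))
    })
    mean(stat >= obs - 1e-12)
  }
  pairs <- utils::combn(4, 2)
  tukey_p <- apply(pairs, 2, function(p) ph[as.character(p[1]),
                                            as.character(p[2])])
  brute_p <- apply(pairs, 2, function(p) perm_p(p[1], p[2]))
  expect_gt(stats::cor(rank(tukey_p), rank(brute_p)), 0.7)
})

test_that("cones with a single trial are dropped with a warning", {
  tr <- sim_two_cone_trials(c(0.3, -0.2), c(-0.1, 0.4), 10, seed = 2)
  lone <- tr[1, ]; lone$cone_id <- 99
  expect_warning(ph <- cone_anova_posthoc(rbind(tr, lone)), "dropping")
  expect_false("99" %in% rownames(ph$yb$p_matrix))
})

sim_multi_cone_trials <- function(loci, n_each, seed, intensities = 1) {
  rows <- list()
  k <- 0
  for (ci in seq_along(loci)) for (ii in seq_along(intensities)) {
    presses <- t(vapply(1:n_each, function(i) {
      sample_button_presses(loci[[ci]], seed = seed * 1e5 + ci * 731 +
                              ii * 97 + i)
    }, integer(5)))
    k <- k + 1
    rows[[k]] <- data.frame(cone_id = ci, intensity_au = intensities[ii],
                            blank = FALSE, brightness = 3,
                            r = presses[, 1], g = presses[, 2],
                            b = presses[, 3], y = presses[, 4],
                            w = presses[, 5])
  }
  do.call(rbind, rows)
}

test_that("intensity consistency reads identical percepts as slope 1", {
  set.seed(8)
  loci <- lapply(1:12, function(i) locus_from_hue_sat(runif(1, -90, 90),
                                                      runif(1, 0.3, 0.8)))
  # same generating locus at both levels: slope near 1
  tr <- sim_multi_cone_trials(loci, 40, seed = 3, intensities = c(0.5, 1))
  res <- intensity_consistency(tr, 0.5, 1, "hue_angle")
  expect_equal(res$slope, 1, tolerance = 0.2)
  expect_gt(res$r_squared, 0.8)
  expect_true(res$ci[1] <= 1 && res$ci[2] >= 1)
  res_sat <- intensity_consistency(tr, 0.5, 1, "saturation")
  expect_equal(res_sat$slope, 1, tolerance = 0.35)
  expect_error(intensity_consistency(tr[tr$cone_id < 3, ], 0.5, 1,
                                     "saturation"), ">= 3 cones")
})

test_that("forced intensity coupling is detected as a slope away from 1", {
  mos <- generate_mosaic(1.05, extent = 10, positional_jitter = 0.05,
                         s_fraction = 0, seed = 4)
  obs <- observer_params(intensity_coupling = 0.45)
  ctr <- mos$cones$cone_id[order((mos$cones$x_arcmin - 5)^2 +
                                   (mos$cones$y_arcmin - 5)^2)][1:10]
  tr <- simulate_session(mos, ctr, obs, intensities = c(0.5, 1.0, 1.5),
                         reps = 25, seed = 5)
  res <- intensity_consistency(tr, 1.0, 1.5, "saturation")
  # saturation rises with intensity: points sit above the unity line
  expect_gt(mean(res$per_cone[[3]] - res$per_cone[[2]]), 0.05)
})

test_that("neighbor regressions calibrate under the null and recover signal", {
  set.seed(9)
  n <- 40
  counts <- sample(0:6, n, replace = TRUE)
  null_summaries <- data.frame(cone_id = 1:n, type = "L",
                               sat_mean = rnorm(n, 0.4, 0.05),
                               hue_deg = rnorm(n, -35, 10))
  res0 <- neighbor_regression(null_summaries, counts, "saturation")
  expect_false(res0$degenerate)
  expect_lt(abs(res0$slope), 0.05)
  expect_true(res0$r_squared >= 0 && res0$r_squared <= 1)

  dep <- null_summaries
  dep$sat_mean <- 0.5 - 0.04 * counts + rnorm(n, 0, 0.01)
  res1 <- neighbor_regression(dep, counts, "saturation")
  expect_equal(res1$slope, -0.04, tolerance = 0.25)
  expect_lt(res1$p, 1e-4)

  allsame <- neighbor_regression(null_summaries, rep(3, n), "saturation")
  expect_true(allsame$degenerate)
})
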