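test_that("press counts map to UAD coordinates by the axis formulas", {
  teal <- uad_from_presses(0, 1, 1, 0, 3)
  expect_equal(teal$x, -0.2)
  expect_equal(teal$y, 0.2)
  expect_equal(teal$saturation, 0.4)
  white <- uad_from_presses(0, 0, 0, 0, 5)
  expect_equal(c(white$x, white$y), c(0, 0))
  expect_true(is.na(white$hue_deg))
  red <- uad_from_presses(5, 0, 0, 0, 0)
  expect_equal(c(red$x, red$y), c(0, -1))
  expect_equal(red$saturation, 1)
  expect_error(uad_from_presses(1, 1, 1, 1, 0), "sum to 5")
  expect_error(uad_from_presses(-1, 2, 2, 1, 1), "sum to 5")
})

test_that("saturation and boundary properties hold for all 126 press compositions", {
  comps <- press_compositions()
  expect_equal(nrow(comps), 126)
  for (i in seq_len(nrow(comps))) {
    p <- comps[i, ]
    u <- uad_from_presses(p["r"], p["g"], p["b"], p["y"], p["w"])
    expect_lte(u$saturation, 1)
    expect_equal(u$saturation, abs(u$x) + abs(u$y))
    # saturation 1 iff no white presses and no opponent cancellation
    full <- p["w"] == 0 && (p["r"] == 0 || p["g"] == 0) &&
      (p["b"] == 0 || p["y"] == 0)
    expect_equal(u$saturation == 1, unname(full))
  }
})

test_that("hue angles follow the stated convention", {
  expect_equal(hue_angle(0.5, 0), 0)
  expect_equal(hue_angle(0, 0.5), 90)
  expect_equal(hue_angle(-0.5, 0), 180)
  expect_equal(hue_angle(0, -0.5), -90)
  expect_true(is.na(hue_angle(0, 0)))
})

test_that("swapping opponent presses mirrors the hue angle", {
  comps <- press_compositions()
  for (i in seq_len(nrow(comps))) {
    p <- comps[i, ]
    u <- uad_from_presses(p["r"], p["g"], p["b"], p["y"], p["w"])
    # swap green <-> red: y flips sign, x unchanged
    v <- uad_from_presses(p["g"], p["r"], p["b"], p["y"], p["w"])
    if (!is.na(u$hue_deg) && abs(u$hue_deg) != 180) {
      expect_equal(v$hue_deg, -u$hue_deg)
    }
  }
})

make_trials <- function(presses, cone_id = 1, intensity = 1) {
  data.frame(cone_id = cone_id, intensity_au = intensity, blank = FALSE,
             brightness = 3,
             r = presses[, 1], g = presses[, 2], b = presses[, 3],
             y = presses[, 4], w = presses[, 5])
}

test_that("identical trials summarize to zero SEM at the common point", {
  tr <- make_trials(matrix(rep(c(0, 1, 1, 0, 3), 8), ncol = 5, byrow = TRUE))
  s <- summarize_cone(tr)
  expect_equal(s$x_mean, -0.2)
  expect_equal(s$y_mean, 0.2)
  expect_equal(s$x_sem, 0)
  expect_equal(s$sat_sem, 0)
  expect_equal(s$n_seen, 8L)
  expect_equal(s$nw, 24L)
})

test_that("saturation averages per trial, not at the mean point", {
  # half pure red, half pure green: mean position at the origin but mean
  # saturation 1 -- the order of operations matters
  tr <- make_trials(rbind(matrix(rep(c(5, 0, 0, 0, 0), 4), ncol = 5, byrow = TRUE),
                          matrix(rep(c(0, 5, 0, 0, 0), 4), ncol = 5, byrow = TRUE)))
  s <- summarize_cone(tr)
  expect_equal(s$x_mean, 0)
  expect_equal(s$y_mean, 0)
  expect_equal(s$sat_mean, 1)
  # triangle inequality: mean saturation >= saturation of the mean point
  set.seed(6)
  for (i in 1:10) {
    comps <- press_compositions()
    pick <- comps[sample(nrow(comps), 12, replace = TRUE), ]
    s2 <- summarize_cone(make_trials(pick))
    expect_gte(s2$sat_mean + 1e-12,
               cityblock_saturation(s2$x_mean, s2$y_mean))
  }
})

test_that("circular hue means handle the wraparound cut", {
  # two trials straddling +/-180: pure blue-ish angles 170 and -170
  tr <- make_trials(rbind(c(0, 1, 4, 0, 0),    # x=-0.8, y=0.2 -> 166
                          c(1, 0, 4, 0, 0)))   # x=-0.8, y=-0.2 -> -166
  s <- summarize_cone(tr)
  expect_equal(abs(s$hue_deg), 180, tolerance = 1e-6)
  s_arith <- summarize_cone(tr, hue_mean = "arithmetic")
  expect_equal(s_arith$hue_deg, 0) # the naive mean lands on the wrong side
})

test_that("summaries recover a known generating locus", {
  locus <- c(-0.25, 0.3)
  presses <- t(vapply(1:300, function(s)
    sample_button_presses(locus, seed = s), integer(5)))
  s <- summarize_cone(make_trials(presses))
  expect_lt(abs(s$x_mean - locus[1]), 2 * s$x_sem + 1e-3)
  expect_lt(abs(s$y_mean - locus[2]), 2 * s$y_sem + 1e-3)
})

test_that("pure-white trials enter position means but not hue statistics", {
  tr <- make_trials(rbind(c(0, 0, 0, 5, 0),
                          c(0, 0, 0, 0, 5)))
  s <- summarize_cone(tr)
  expect_equal(s$x_mean, 0.5)  # white trial pulls the mean position inward
  expect_equal(s$n_hue, 1L)    # but only one trial defines a hue
  expect_equal(s$hue_deg, 0)
})

test_that("cones with no seen trials yield an empty flagged summary", {
  tr <- data.frame(cone_id = 7, intensity_au = 1, blank = FALSE,
                   brightness = 0, r = NA, g = NA, b = NA, y = NA, w = NA)
  s <- summarize_cone(tr)
  expect_equal(s$n_seen, 0L)
  expect_true(is.na(s$x_mean))
})

test_that("the low-saturation filter is inclusive at the threshold", {
  s <- data.frame(cone_id = 1:4, sat_mean = c(0.09, 0.10, 0, 0.5))
  kept <- low_saturation_filter(s)
  expect_equal(kept$cone_id, c(2, 4))
})
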