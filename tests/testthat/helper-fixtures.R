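# Hand-built mosaics and small simulation helpers shared across tests.

# mosaic from explicit coordinates; spacing/diameter chosen by the caller
manual_mosaic <- function(x, y, type, spacing = 1.05,
                          inner_segment_diameter = 0.9 * spacing,
                          pixel_scale = 0.95 * 60 / 512) {
  structure(list(
    cones = data.frame(cone_id = seq_along(x), x_arcmin = x, y_arcmin = y,
                       type = type, stringsAsFactors = FALSE),
    spacing = spacing,
    inner_segment_diameter = inner_segment_diameter,
    pixel_scale = pixel_scale
  ), class = "cone_mosaic")
}

# a 7-cone hexagonal patch: center cone 1 at origin, six neighbors at `spacing`
hex_patch <- function(types = rep("L", 7), spacing = 1.05) {
  ang <- seq(0, 300, by = 60) * pi / 180
  manual_mosaic(c(0, spacing * cos(ang)), c(0, spacing * sin(ang)), types,
                spacing = spacing)
}

# small shared PSF/profile (cheap enough to build once per test file)
test_profile <- function(defocus = 0.05, grid_size = 128) {
  stimulus_profile(compute_psf(543, 6.5, defocus, grid_size = grid_size), 3)
}

# stationary delivery traces, one trial per cone rep
still_traces <- function(mosaic, ids, reps = 1, frames = 15) {
  unlist(lapply(ids, function(id) {
    i <- match(id, mosaic$cones$cone_id)
    lapply(seq_len(reps), function(r) list(
      targeted_id = id,
      positions = cbind(rep(mosaic$cones$x_arcmin[i], frames),
                        rep(mosaic$cones$y_arcmin[i], frames))))
  }), recursive = FALSE)
}

# all 126 ways to split 5 presses over 5 categories
press_compositions <- function() {
  out <- list()
  for (r in 0:5) for (g in 0:(5 - r)) for (b in 0:(5 - r - g))
    for (y in 0:(5 - r - g - b)) {
      out[[length(out) + 1]] <- c(r = r, g = g, b = b, y = y,
                                  w = 5 - r - g - b - y)
    }
  do.call(rbind, out)
}
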