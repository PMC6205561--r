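#' Generate a synthetic cone mosaic
#'
#' Cone positions are laid out on a triangular (hexagonal-packing) lattice, the
#' arrangement of parafoveal cone inner segments, and perturbed by i.i.d.
#' Gaussian jitter. Jittered draws that would bring two cones closer than half
#' the nominal spacing are rejected and resampled, preserving a physical
#' exclusion zone. Spectral types are assigned i.i.d.: each cone is S with
#' probability `s_fraction`, otherwise L or M with odds `lm_ratio` : 1 — the
#' fine-grain arrangement of L and M cones in human retina is approximately
#' random.
#'
#' @param spacing Nominal center-to-center spacing, arcmin. At 1.5 deg
#'   eccentricity human cones sit roughly 1.0-1.3 arcmin apart.
#' @param extent Side of the square region to fill, arcmin.
#' @param positional_jitter Jitter SD as a fraction of `spacing` (<= 0.2 keeps
#'   rejection rates negligible).
#' @param lm_ratio L:M odds among non-S cones (near 2 in most trichromats).
#' @param s_fraction Proportion of S cones.
#' @param inner_segment_diameter Cone inner-segment diameter, arcmin. Default
#'   0.9 x spacing (inner segments nearly tile the mosaic at this
#'   eccentricity).
#' @param pixel_scale Raster scale, arcmin per pixel.
#' @param seed Integer seed; the mosaic is deterministic given the seed.
#' @return An object of class `cone_mosaic`: a list with `cones` (data.frame
#'   `cone_id`, `x_arcmin`, `y_arcmin`, `type`), `spacing`,
#'   `inner_segment_diameter`, `pixel_scale`.
#' @examples
#' m <- generate_mosaic(spacing = 1.1, extent = 10, seed = 1)
#' table(m$cones$type)
#' @export
generate_mosaic <- function(spacing, extent,
                            positional_jitter = 0.1,
                            lm_ratio = 2, s_fraction = 0.05,
                            inner_segment_diameter = 0.9 * spacing,
                            pixel_scale = 0.95 * 60 / 512,
                            seed) {
  stopifnot(spacing > 0, s_fraction >= 0, s_fraction < 1,
            positional_jitter >= 0, lm_ratio > 0)
  if (missing(seed)) stop("`seed` is required: mosaics must be reproducible")
  if (extent < spacing) stop("`extent` must be at least one spacing")

  # triangular lattice: rows spacing*sqrt(3)/2 apart, odd rows offset by half
  row_h <- spacing * sqrt(3) / 2
  rows <- seq(0, extent, by = row_h)
  pts <- do.call(rbind, lapply(seq_along(rows), function(i) {
    off <- if (i %% 2 == 0) spacing / 2 else 0
    xs <- seq(off, extent, by = spacing)
    cbind(xs, rows[i])
  }))
  n <- nrow(pts)
  sigma <- positional_jitter * spacing
  min_d <- 0.5 * spacing

  drawn <- with_seed(seed, {
    jittered <- pts
    if (sigma > 0) {
      jittered <- pts + matrix(stats::rnorm(2 * n, sd = sigma), ncol = 2)
      # rejection-resample any cone violating the minimum-distance invariant
      bad <- integer(0)
      for (pass in 1:100) {
        dd <- as.matrix(stats::dist(jittered))
        diag(dd) <- Inf
        bad <- which(apply(dd, 1, min) < min_d)
        if (length(bad) == 0L) break
        jittered[bad, ] <- pts[bad, ] +
          matrix(stats::rnorm(2 * length(bad), sd = sigma), ncol = 2)
      }
      if (length(bad) > 0L) jittered[bad, ] <- pts[bad, ] # fall back to lattice
    }
    list(jittered = jittered, u = stats::runif(n))
  })
  jittered <- drawn$jittered
  p_l <- (1 - s_fraction) * lm_ratio / (lm_ratio + 1)
  p_m <- (1 - s_fraction) / (lm_ratio + 1)
  type <- ifelse(drawn$u < p_l, "L", ifelse(drawn$u < p_l + p_m, "M", "S"))

  structure(list(
    cones = data.frame(
      cone_id = seq_len(n),
      x_arcmin = jittered[, 1],
      y_arcmin = jittered[, 2],
      type = type,
      stringsAsFactors = FALSE
    ),
    spacing = spacing,
    inner_segment_diameter = inner_segment_diameter,
    pixel_scale = pixel_scale
  ), class = "cone_mosaic")
}

#' @export
print.cone_mosaic <- function(x, ...) {
  cat(sprintf("Cone mosaic: %d cones (%s), spacing %.2f arcmin, IS diameter %.2f arcmin\n",
              nrow(x$cones),
              paste(sprintf("%s=%d", names(table(x$cones$type)),
                            as.integer(table(x$cones$type))), collapse = ", "),
              x$spacing, x$inner_segment_diameter))
  invisible(x)
}

cone_row <- function(mosaic, cone_id) {
  i <- match(cone_id, mosaic$cones$cone_id)
  if (is.na(i)) stop(sprintf("cone_id %s not in mosaic", cone_id))
  mosaic$cones[i, ]
}

#' K nearest neighbors of a cone
#'
#' @param mosaic A `cone_mosaic`.
#' @param cone_id Query cone.
#' @param k Number of neighbors (default 6, the hexagonal coordination number).
#' @return Integer vector of `k` cone ids sorted by increasing Euclidean
#'   distance; distance ties broken by id.
#' @export
nearest_neighbors <- function(mosaic, cone_id, k = 6) {
  focal <- cone_row(mosaic, cone_id)
  others <- mosaic$cones[mosaic$cones$cone_id != cone_id, ]
  if (nrow(others) < k) stop("mosaic has fewer than k other cones")
  d <- sqrt((others$x_arcmin - focal$x_arcmin)^2 +
            (others$y_arcmin - focal$y_arcmin)^2)
  ord <- order(d, others$cone_id)
  others$cone_id[ord[seq_len(k)]]
}

#' Number of nearest neighbors with a different spectral type
#'
#' Counts, among the six nearest cones, those whose type differs from the
#' targeted cone's type — the local-neighborhood covariate used to test
#' whether surround composition biases hue or saturation reports.
#'
#' @inheritParams nearest_neighbors
#' @return Integer in 0..6.
#' @export
count_nonlike_neighbors <- function(mosaic, cone_id) {
  focal <- cone_row(mosaic, cone_id)
  nn <- nearest_neighbors(mosaic, cone_id, k = 6)
  types <- mosaic$cones$type[match(nn, mosaic$cones$cone_id)]
  sum(types != focal$type)
}

#' Read / write a cone mosaic table
#'
#' Plain comma-delimited text with header `cone_id,x_arcmin,y_arcmin,type`.
#' `write_mosaic`/`read_mosaic` round-trip exactly. Spacing and diameter are
#' not stored in the table; supply them on read.
#'
#' @param mosaic A `cone_mosaic`.
#' @param path File path.
#' @export
write_mosaic <- function(mosaic, path) {
  utils::write.csv(mosaic$cones, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_mosaic
#' @param spacing,inner_segment_diameter,pixel_scale Geometry not carried by
#'   the table.
#' @export
read_mosaic <- function(path, spacing, inner_segment_diameter = 0.9 * spacing,
                        pixel_scale = 0.95 * 60 / 512) {
  cones <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cone_id", "x_arcmin", "y_arcmin", "type")
  if (!all(need %in% names(cones))) {
    stop("mosaic file must have columns ", paste(need, collapse = ","))
  }
  if (anyDuplicated(cones$cone_id)) stop("duplicate cone_id in mosaic file")
  if (!all(cones$type %in% c("L", "M", "S"))) {
    stop("cone types must be L, M or S")
  }
  structure(list(cones = cones[need], spacing = spacing,
                 inner_segment_diameter = inner_segment_diameter,
                 pixel_scale = pixel_scale),
            class = "cone_mosaic")
}
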