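#' Build the Cartesian detector map of a block-geometry scanner
#'
#' Lays the rectangular crystal blocks flat on the faces of the regular
#' polygon, tangent to the circle of radius `inner_radius`, and records the
#' detection position of every crystal: the crystal center displaced by
#' `average_doi` along the block's outward normal (measured from the crystal
#' inner face).  Within a block, crystal centers are spaced by
#' crystal size + crystal gap; adjacent blocks are separated by the block
#' gap; each side's block assembly is centered on its face, and the whole
#' stack is centered axially on z = 0.
#'
#' Transaxial crystal index 0 is the crystal on side 0 (face centered on the
#' +x axis) with the smallest non-negative azimuth; the index increases
#' counter-clockwise viewed from +z.  Ring index 0 has the smallest z.
#'
#' @param spec A [scanner_spec()].
#' @return A `detector_map` with fields `mode`, `spec`, `positions`
#'   (num_rings x detectors_per_ring rows, ring-major, columns x/y/z in mm),
#'   `xy` (per-crystal transaxial position), `ring_z` (per-ring z), and
#'   `crystal_azimuth` (rad).
#' @seealso [build_cylindrical_detector_map()], [detection_position()]
#' @export
build_block_detector_map <- function(spec) {
  validate_scanner_spec(spec)
  nd <- spec$detectors_per_ring
  nr <- spec$num_rings
  bps <- spec$n_blocks_transaxial / spec$n_sides
  m <- bps * spec$n_crystals_per_block_transaxial # crystals per side

  # transaxial coordinate along a face, centered on the face
  fp <- side_footprint(spec)
  pitch_c <- spec$crystal_size[1] + spec$crystal_gap_transaxial
  bw <- block_width_transaxial(spec)
  j <- seq_len(m) - 1L
  blk <- j %/% spec$n_crystals_per_block_transaxial
  within <- j %% spec$n_crystals_per_block_transaxial
  u <- -fp / 2 + blk * (bw + spec$block_gap_transaxial) +
    within * pitch_c + spec$crystal_size[1] / 2

  r_det <- spec$inner_radius + spec$average_doi
  alpha <- 2 * pi * (seq_len(spec$n_sides) - 1L) / spec$n_sides
  # all crystals, sides concatenated in ccw order
  x <- as.vector(outer(u, alpha, function(uu, a) r_det * cos(a) - uu * sin(a)))
  y <- as.vector(outer(u, alpha, function(uu, a) r_det * sin(a) + uu * cos(a)))
  # rows of outer(): u fastest -> order is (side 0 crystals), (side 1), ...
  az <- atan2(y, x)
  # rotate the enumeration so crystal 0 is the side-0 crystal with the
  # smallest non-negative azimuth
  first <- which(az >= -1e-12)
  first <- first[which.min(az[first])]
  ord <- c(first:nd, seq_len(first - 1L))
  xy <- cbind(x = x[ord], y = y[ord])
  az <- az[ord]

  ring_z <- block_ring_z(spec)

  positions <- cbind(
    x = rep(xy[, 1], times = nr),
    y = rep(xy[, 2], times = nr),
    z = rep(ring_z, each = nd)
  )
  structure(
    list(
      mode = "blocks-on-cylindrical",
      spec = spec,
      positions = positions,
      xy = xy,
      ring_z = ring_z,
      crystal_azimuth = az
    ),
    class = "detector_map"
  )
}

block_ring_z <- function(spec) {
  nr <- spec$num_rings
  hb <- block_height_axial(spec)
  pitch_c <- spec$crystal_size[2] + spec$crystal_gap_axial
  ext <- axial_extent(spec)
  r <- seq_len(nr) - 1L
  ab <- r %/% spec$n_crystals_per_block_axial
  k <- r %% spec$n_crystals_per_block_axial
  -ext / 2 + ab * (hb + spec$block_gap_axial) + k * pitch_c +
    spec$crystal_size[2] / 2
}

#' Build the idealized cylindrical detector map of a scanner
#'
#' The cylindrical model places `detectors_per_ring` crystals at equal
#' azimuthal steps on a cylinder of radius `inner_radius + average_doi`
#' (same inner radius as the block model, with the same average
#' depth-of-interaction treatment), and `num_rings` equally spaced detector
#' planes.  The equal ring spacing is chosen so the first and last ring
#' centers coincide with those of the block map; for a scanner with one
#' crystal per block and all gaps equal the two maps are identical.
#'
#' @inheritParams build_block_detector_map
#' @return A `detector_map` (see [build_block_detector_map()]).
#' @export
build_cylindrical_detector_map <- function(spec) {
  validate_scanner_spec(spec)
  nd <- spec$detectors_per_ring
  nr <- spec$num_rings
  r_det <- spec$inner_radius + spec$average_doi
  az <- 2 * pi * (seq_len(nd) - 1L) / nd
  az <- ifelse(az > pi, az - 2 * pi, az) # match atan2 range
  xy <- cbind(x = r_det * cos(az), y = r_det * sin(az))

  bz <- block_ring_z(spec)
  if (nr > 1) {
    span <- bz[nr] - bz[1]
    ring_z <- -span / 2 + (seq_len(nr) - 1L) * span / (nr - 1)
  } else {
    ring_z <- 0
  }
  positions <- cbind(
    x = rep(xy[, 1], times = nr),
    y = rep(xy[, 2], times = nr),
    z = rep(ring_z, each = nd)
  )
  structure(
    list(
      mode = "cylindrical",
      spec = spec,
      positions = positions,
      xy = xy,
      ring_z = ring_z,
      crystal_azimuth = az
    ),
    class = "detector_map"
  )
}

#' Look up a detection position
#'
#' Pure lookup of the stored Cartesian detection position of one crystal.
#'
#' @param map A `detector_map`.
#' @param ring 0-based ring index.
#' @param crystal 0-based transaxial crystal index.
#' @return Numeric length 3 (x, y, z) in mm.
#' @export
detection_position <- function(map, ring, crystal) {
  nd <- map$spec$detectors_per_ring
  nr <- map$spec$num_rings
  if (any(ring < 0 | ring >= nr)) stop("ring index out of range")
  if (any(crystal < 0 | crystal >= nd)) stop("crystal index out of range")
  map$positions[ring * nd + crystal + 1L, , drop = length(ring) == 1]
}

#' @export
print.detector_map <- function(x, ...) {
  cat(sprintf(
    "detector_map (%s): %d rings x %d crystals, detection radius %.2f-%.2f mm\n",
    x$mode, x$spec$num_rings, x$spec$detectors_per_ring,
    min(sqrt(rowSums(x$xy^2))), max(sqrt(rowSums(x$xy^2)))
  ))
  invisible(x)
}
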