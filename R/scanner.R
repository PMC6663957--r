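#' Describe a block-geometry PET scanner
#'
#' A `scanner_spec` holds the full parameterization of a PET scanner whose
#' detectors are rectangular blocks of scintillator crystals laid flat on the
#' faces of a regular polygonal prism.  The same specification also defines
#' the idealized cylindrical model of the scanner (rings of equally spaced
#' crystals), used by [build_cylindrical_detector_map()].
#'
#' Conventions: all lengths are millimetres.  `inner_radius` is measured from
#' the scanner axis to the flat inner face of the crystal blocks.  Detection
#' positions sit `average_doi` millimetres behind the inner face (into the
#' crystal, away from the axis).  Ring and crystal indices are 0-based
#' throughout the package: ring 0 has the smallest z, transaxial crystal
#' index increases counter-clockwise (viewed from +z) starting at the crystal
#' nearest azimuth 0, with the first polygon side centered on the +x axis.
#'
#' @param name Scanner name (free text).
#' @param inner_radius Axis to crystal inner face, mm.
#' @param n_sides Number of polygon sides (e.g. 12 for a dodecagon).
#' @param n_blocks_transaxial Total number of blocks around the polygon;
#'   must be a positive multiple of `n_sides`.
#' @param n_blocks_axial Number of blocks along the axis.
#' @param n_crystals_per_block_transaxial,n_crystals_per_block_axial
#'   Crystals per block in each direction.
#' @param crystal_size Length-3 numeric: transaxial x axial x depth, mm.
#' @param crystal_gap_transaxial,crystal_gap_axial Gap between crystals
#'   within a block, mm.
#' @param block_gap_transaxial,block_gap_axial Gap between adjacent blocks,
#'   mm.
#' @param average_doi Average depth of interaction measured inward from the
#'   crystal inner face, mm.  Default: half the crystal depth.
#'
#' @return An object of class `scanner_spec` with derived fields
#'   `num_rings` and `detectors_per_ring`.
#' @seealso [scanner_b_spec()], [build_block_detector_map()]
#' @export
scanner_spec <- function(name,
                         inner_radius,
                         n_sides,
                         n_blocks_transaxial,
                         n_blocks_axial,
                         n_crystals_per_block_transaxial,
                         n_crystals_per_block_axial,
                         crystal_size,
                         crystal_gap_transaxial = 0,
                         crystal_gap_axial = 0,
                         block_gap_transaxial = 0,
                         block_gap_axial = 0,
                         average_doi = NULL) {
  stopifnot(length(crystal_size) == 3, all(crystal_size > 0))
  if (is.null(average_doi)) average_doi <- crystal_size[3] / 2
  spec <- structure(
    list(
      name = as.character(name),
      inner_radius = as.numeric(inner_radius),
      n_sides = as.integer(n_sides),
      n_blocks_transaxial = as.integer(n_blocks_transaxial),
      n_blocks_axial = as.integer(n_blocks_axial),
      n_crystals_per_block_transaxial = as.integer(n_crystals_per_block_transaxial),
      n_crystals_per_block_axial = as.integer(n_crystals_per_block_axial),
      crystal_size = as.numeric(crystal_size),
      crystal_gap_transaxial = as.numeric(crystal_gap_transaxial),
      crystal_gap_axial = as.numeric(crystal_gap_axial),
      block_gap_transaxial = as.numeric(block_gap_transaxial),
      block_gap_axial = as.numeric(block_gap_axial),
      average_doi = as.numeric(average_doi)
    ),
    class = "scanner_spec"
  )
  spec$num_rings <- spec$n_blocks_axial * spec$n_crystals_per_block_axial
  spec$detectors_per_ring <-
    spec$n_blocks_transaxial * spec$n_crystals_per_block_transaxial
  validate_scanner_spec(spec)
  spec
}

validate_scanner_spec <- function(spec) {
  if (spec$inner_radius <= 0) stop("inner_radius must be positive")
  if (spec$n_sides < 3) stop("need at least 3 polygon sides")
  if (spec$n_blocks_transaxial <= 0 ||
      spec$n_blocks_transaxial %% spec$n_sides != 0) {
    stop("n_blocks_transaxial must be a positive multiple of n_sides")
  }
  if (spec$average_doi < 0 || spec$average_doi > spec$crystal_size[3]) {
    stop("average_doi must lie within [0, crystal depth]")
  }
  fp <- side_footprint(spec)
  side_len <- polygon_side_length(spec)
  if (fp > side_len + 1e-9) {
    stop(sprintf(
      "blocks overflow a polygon side: footprint %.6g mm > side length %.6g mm",
      fp, side_len
    ))
  }
  invisible(spec)
}

# transaxial extent (mm) of crystal material + gaps of all blocks on one side
side_footprint <- function(spec) {
  bps <- spec$n_blocks_transaxial / spec$n_sides
  bw <- block_width_transaxial(spec)
  bps * bw + (bps - 1) * spec$block_gap_transaxial
}

block_width_transaxial <- function(spec) {
  n <- spec$n_crystals_per_block_transaxial
  n * spec$crystal_size[1] + (n - 1) * spec$crystal_gap_transaxial
}

block_height_axial <- function(spec) {
  n <- spec$n_crystals_per_block_axial
  n * spec$crystal_size[2] + (n - 1) * spec$crystal_gap_axial
}

polygon_side_length <- function(spec) {
  2 * spec$inner_radius * tan(pi / spec$n_sides)
}

# crystal material extent along z, first crystal face to last crystal face
axial_extent <- function(spec) {
  spec$n_blocks_axial * block_height_axial(spec) +
    (spec$n_blocks_axial - 1) * spec$block_gap_axial
}

#' @export
print.scanner_spec <- function(x, ...) {
  cat(sprintf(
    "scanner_spec '%s': %d sides, %d x %d blocks of %d x %d crystals\n",
    x$name, x$n_sides, x$n_blocks_transaxial, x$n_blocks_axial,
    x$n_crystals_per_block_transaxial, x$n_crystals_per_block_axial
  ))
  cat(sprintf(
    "  %d rings x %d detectors/ring, inner radius %.2f mm, DOI %.2f mm\n",
    x$num_rings, x$detectors_per_ring, x$inner_radius, x$average_doi
  ))
  cat(sprintf(
    "  crystal %.4g x %.4g x %.4g mm, gaps crystal %.3g/%.3g block %.3g/%.3g mm\n",
    x$crystal_size[1], x$crystal_size[2], x$crystal_size[3],
    x$crystal_gap_transaxial, x$crystal_gap_axial,
    x$block_gap_transaxial, x$block_gap_axial
  ))
  invisible(x)
}

#' Published scanner configurations
#'
#' Convenience constructors for the three scanner designs used throughout the
#' package examples and tests.
#'
#' * Scanner A: a ring scanner with a single crystal per block -- 41 rings of
#'   180 crystals (2.0 x 2.0 x 12 mm), 2.2 mm pitch in both directions, inner
#'   radius 63.02 mm.  Modeled as a 180-sided polygon with one 1 x 1 block
#'   per side slot; crystal and block gaps 0.2 mm give the 2.2 mm pitch.
#' * Scanner B: 24 (transaxial) x 2 (axial) blocks of 8 x 8 crystals
#'   (2.1 x 2.1 x 12 mm) on a dodecagon of inner radius 67.75 mm; crystal
#'   gap 0.1 mm and block gap 0.6 mm in both directions.
#' * Scanner C: 24 x 2 blocks of 16 x 16 crystals (1.0 x 1.0 x 10 mm) on a
#'   dodecagon of inner radius 67 mm; crystal gap 0.1 mm, block gap 0.3 mm.
#'
#' @param n_blocks_axial Number of axial blocks; lower it (e.g. to 1) for
#'   reduced-scale experiments.
#' @param n_rings For `scanner_a_spec`, the number of rings (axial blocks).
#' @return A [scanner_spec()].
#' @export
scanner_b_spec <- function(n_blocks_axial = 2) {
  scanner_spec(
    name = "Scanner B",
    inner_radius = 67.75,
    n_sides = 12,
    n_blocks_transaxial = 24,
    n_blocks_axial = n_blocks_axial,
    n_crystals_per_block_transaxial = 8,
    n_crystals_per_block_axial = 8,
    crystal_size = c(2.1, 2.1, 12.0),
    crystal_gap_transaxial = 0.1,
    crystal_gap_axial = 0.1,
    block_gap_transaxial = 0.6,
    block_gap_axial = 0.6
  )
}

#' @rdname scanner_b_spec
#' @export
scanner_a_spec <- function(n_rings = 41) {
  scanner_spec(
    name = "Scanner A",
    inner_radius = 63.02,
    n_sides = 180,
    n_blocks_transaxial = 180,
    n_blocks_axial = n_rings,
    n_crystals_per_block_transaxial = 1,
    n_crystals_per_block_axial = 1,
    crystal_size = c(2.0, 2.0, 12.0),
    crystal_gap_transaxial = 0.2,
    crystal_gap_axial = 0.2,
    block_gap_transaxial = 0.2,
    block_gap_axial = 0.2
  )
}

#' @rdname scanner_b_spec
#' @export
scanner_c_spec <- function(n_blocks_axial = 2) {
  scanner_spec(
    name = "Scanner C",
    inner_radius = 67,
    n_sides = 12,
    n_blocks_transaxial = 24,
    n_blocks_axial = n_blocks_axial,
    n_crystals_per_block_transaxial = 16,
    n_crystals_per_block_axial = 16,
    crystal_size = c(1.0, 1.0, 10.0),
    crystal_gap_transaxial = 0.1,
    crystal_gap_axial = 0.1,
    block_gap_transaxial = 0.3,
    block_gap_axial = 0.3
  )
}
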