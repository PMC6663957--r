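#' Projection-data parameterization for a scanner geometry
#'
#' Describes the 3D sinogram grid of a scanner: segments (signed ring
#' difference, span 1 -- no axial compression), axial positions, views and
#' tangential positions, together with the detector map used to turn bins
#' into lines of response.  The bin/detector-pair correspondence follows the
#' standard interleaved no-arc-correction convention.  With `Nd` detectors
#' per ring the defining inverse mapping from (view `v`, tangential `t`) to
#' the canonical transaxial crystal pair is
#'
#'     c1 = (v + floor(t / 2))            mod Nd
#'     c2 = (v - floor((t + 1) / 2) + Nd/2) mod Nd
#'
#' with `t` ranging over `-Nd/2 + 1 ... Nd/2 - 1`; this enumerates every
#' unordered crystal pair with `c1 != c2` exactly once.  The forward mapping
#' (equivalently `view = floor(((c1 + c2 + Nd/2 + 1) mod Nd) / 2)`) is
#' realized as a precomputed lookup table.  The detector pair order given by
#' the inverse above is the canonical ordering; `segment = r1 - r2` with
#' detector 1 the canonical first, and `axial_pos = min(r1, r2)`.
#' Pairs sharing the same transaxial crystal index have no bin in this
#' parameterization and are rejected by the histogrammer.
#'
#' @param spec A [scanner_spec()].
#' @param mode `"blocks-on-cylindrical"` or `"cylindrical"` -- which detector
#'   map is used for LOR coordinates.
#' @param max_ring_difference Largest |segment| kept; default all ring
#'   differences.
#' @param num_tangential Number of tangential positions kept (trimming);
#'   default `detectors_per_ring / 2` rounded to even.  Tangential indices
#'   run from `-floor(num_tangential/2)` upward.
#' @return A `proj_data_info` object.
#' @export
proj_data_info <- function(spec,
                           mode = c("blocks-on-cylindrical", "cylindrical"),
                           max_ring_difference = NULL,
                           num_tangential = NULL) {
  mode <- match.arg(mode)
  nd <- spec$detectors_per_ring
  nr <- spec$num_rings
  if (nd %% 2L != 0L) stop("detectors_per_ring must be even")
  nv <- nd %/% 2L
  if (is.null(max_ring_difference)) max_ring_difference <- nr - 1L
  max_ring_difference <- as.integer(max_ring_difference)
  if (max_ring_difference < 0L || max_ring_difference > nr - 1L) {
    stop("max_ring_difference out of range")
  }
  if (is.null(num_tangential)) {
    num_tangential <- nv - nv %% 2L
  }
  num_tangential <- as.integer(num_tangential)
  if (num_tangential < 1L || num_tangential > nd - 1L) {
    stop("num_tangential must be in [1, detectors_per_ring - 1]")
  }

  # full-range view/tangential <-> crystal-pair tables
  t_full <- seq.int(-(nd %/% 2L) + 1L, nd %/% 2L - 1L)
  v <- rep(0:(nv - 1L), each = length(t_full))
  t <- rep(t_full, times = nv)
  c1 <- (v + t %/% 2L) %% nd
  c2 <- (v - (t + 1L) %/% 2L + nd %/% 2L) %% nd
  vt2c1 <- matrix(c1, nrow = length(t_full), ncol = nv)
  vt2c2 <- matrix(c2, nrow = length(t_full), ncol = nv)
  d2v <- d2t <- matrix(NA_integer_, nd, nd)
  d2first <- matrix(NA, nd, nd)
  d2v[cbind(c1 + 1L, c2 + 1L)] <- v
  d2v[cbind(c2 + 1L, c1 + 1L)] <- v
  d2t[cbind(c1 + 1L, c2 + 1L)] <- t
  d2t[cbind(c2 + 1L, c1 + 1L)] <- t
  d2first[cbind(c1 + 1L, c2 + 1L)] <- TRUE
  d2first[cbind(c2 + 1L, c1 + 1L)] <- FALSE

  segs <- seq.int(-max_ring_difference, max_ring_difference)
  n_ax <- nr - abs(segs)
  seg_offset <- c(0L, cumsum(n_ax))[seq_along(segs)]
  names(seg_offset) <- names(n_ax) <- as.character(segs)

  map <- if (mode == "blocks-on-cylindrical") {
    build_block_detector_map(spec)
  } else {
    build_cylindrical_detector_map(spec)
  }

  tmin <- -(num_tangential %/% 2L)
  structure(
    list(
      spec = spec,
      mode = mode,
      max_ring_difference = max_ring_difference,
      num_views = nv,
      num_tangential = num_tangential,
      tang_min = tmin,
      tang_max = tmin + num_tangential - 1L,
      segments = segs,
      seg_n_axial = n_ax,
      seg_offset = seg_offset,
      detector_map = map,
      vt2c1 = vt2c1,
      vt2c2 = vt2c2,
      t_full_min = t_full[1L],
      d2v = d2v,
      d2t = d2t,
      d2first = d2first
    ),
    class = "proj_data_info"
  )
}

#' @export
print.proj_data_info <- function(x, ...) {
  cat(sprintf(
    "proj_data_info (%s): %d sinograms x %d views x %d tangential (max ring diff %d)\n",
    x$mode, num_sinograms(x), x$num_views, x$num_tangential,
    x$max_ring_difference
  ))
  invisible(x)
}

#' Number of (2D) sinograms in a 3D data set
#'
#' Sum over segments of the number of axial positions; equals
#' `num_rings^2` when all ring differences are kept (span 1).
#'
#' @param info A [proj_data_info()].
#' @return Integer count.
#' @export
num_sinograms <- function(info) {
  sum(info$seg_n_axial)
}

#' 0-based flat sinogram index of (segment, axial position)
#'
#' Segments are stored in increasing order from `-max_ring_difference` to
#' `+max_ring_difference`, each holding `num_rings - |segment|` axial
#' positions.
#'
#' @param info A [proj_data_info()].
#' @param segment Signed ring difference.
#' @param axial_pos 0-based axial position within the segment.
#' @return 0-based flat index (vectorized).
#' @export
sinogram_index <- function(info, segment, axial_pos) {
  key <- as.character(segment)
  if (any(!key %in% names(info$seg_offset))) stop("segment out of range")
  if (any(axial_pos < 0 | axial_pos >= info$seg_n_axial[key])) {
    stop("axial_pos out of range")
  }
  unname(info$seg_offset[key]) + axial_pos
}

#' Empty projection data
#'
#' A `proj_data` holds the dense count (or factor) array of a 3D sinogram
#' stack, dimensioned `[tangential, view, sinogram]` (tangential fastest,
#' matching the on-disk order sinogram/view/tangential).
#'
#' @param info A [proj_data_info()].
#' @param fill Fill value, default 0.
#' @return A `proj_data` object with fields `info` and `counts`.
#' @export
proj_data <- function(info, fill = 0) {
  counts <- array(fill, dim = c(info$num_tangential, info$num_views,
                                num_sinograms(info)))
  structure(list(info = info, counts = counts), class = "proj_data")
}

#' @export
print.proj_data <- function(x, ...) {
  cat(sprintf(
    "proj_data (%s): %d x %d x %d [tang x view x sino], total %.6g\n",
    x$info$mode, dim(x$counts)[1], dim(x$counts)[2], dim(x$counts)[3],
    sum(x$counts)
  ))
  invisible(x)
}

# internal: vectorized bin computation for detector-index pairs.
# r1,c1,r2,c2: equal-length 0-based integer vectors. Returns list of vectors
# with NA view/tang for pairs without a bin (same transaxial crystal) and
# accept flag honouring the tangential trim.
bins_from_pairs_vec <- function(r1, c1, r2, c2, info) {
  nd <- info$spec$detectors_per_ring
  nr <- info$spec$num_rings
  if (any(c1 < 0L | c1 >= nd | c2 < 0L | c2 >= nd, na.rm = FALSE) ||
      any(r1 < 0L | r1 >= nr | r2 < 0L | r2 >= nr)) {
    bad <- which(c1 < 0L | c1 >= nd | c2 < 0L | c2 >= nd |
                   r1 < 0L | r1 >= nr | r2 < 0L | r2 >= nr)[1]
    stop(sprintf("invalid detector index in record %d", bad))
  }
  idx <- cbind(c1 + 1L, c2 + 1L)
  view <- info$d2v[idx]
  tang <- info$d2t[idx]
  first1 <- info$d2first[idx]
  seg <- ifelse(first1, r1 - r2, r2 - r1)
  ax <- pmin(r1, r2)
  accept <- !is.na(view) &
    tang >= info$tang_min & tang <= info$tang_max &
    abs(seg) <= info$max_ring_difference
  list(segment = seg, axial_pos = ax, view = view, tangential_pos = tang,
       accept = accept)
}

#' Sinogram bin of a detector pair
#'
#' Computes the bin parameters (segment, axial position, view, tangential
#' position) directly from two detector index pairs, without going through
#' LOR coordinates.  Exactly opposed crystals on the same ring map to
#' tangential position 0 of that ring's direct sinogram.
#'
#' @param d1,d2 Length-2 integer vectors `c(ring, crystal)`, 0-based.
#' @param info A [proj_data_info()].
#' @return A list with class `pet_bin` (fields `segment`, `axial_pos`,
#'   `view`, `tangential_pos`), or `NULL` when the pair is rejected (outside
#'   the trimmed tangential range, |segment| beyond the maximum ring
#'   difference, or two crystals sharing a transaxial index).
#' @export
bin_from_detector_pair <- function(d1, d2, info) {
  b <- bins_from_pairs_vec(as.integer(d1[1]), as.integer(d1[2]),
                           as.integer(d2[1]), as.integer(d2[2]), info)
  if (!b$accept) return(NULL)
  structure(list(segment = b$segment, axial_pos = b$axial_pos,
                 view = b$view, tangential_pos = b$tangential_pos),
            class = "pet_bin")
}

#' Bin constructor
#'
#' @param segment Signed ring difference.
#' @param axial_pos 0-based axial position.
#' @param view 0-based view index.
#' @param tangential_pos Signed tangential index.
#' @return A `pet_bin`.
#' @export
pet_bin <- function(segment, axial_pos, view, tangential_pos) {
  structure(list(segment = as.integer(segment),
                 axial_pos = as.integer(axial_pos),
                 view = as.integer(view),
                 tangential_pos = as.integer(tangential_pos)),
            class = "pet_bin")
}

check_bin_range <- function(bin, info) {
  key <- as.character(bin$segment)
  if (!key %in% names(info$seg_offset)) stop("bin segment out of range")
  if (bin$axial_pos < 0 || bin$axial_pos >= info$seg_n_axial[key]) {
    stop("bin axial_pos out of range")
  }
  if (bin$view < 0 || bin$view >= info$num_views) stop("bin view out of range")
  if (bin$tangential_pos < info$tang_min || bin$tangential_pos > info$tang_max) {
    stop("bin tangential_pos out of range")
  }
  invisible(TRUE)
}

#' Detector pair of a bin
#'
#' Exact inverse of [bin_from_detector_pair()]; returns the canonical
#' detector ordering.
#'
#' @param bin A `pet_bin`.
#' @param info A [proj_data_info()].
#' @return List with `d1`, `d2`: length-2 0-based `c(ring, crystal)`.
#' @export
detector_pair_from_bin <- function(bin, info) {
  check_bin_range(bin, info)
  ti <- bin$tangential_pos - info$t_full_min + 1L
  c1 <- info$vt2c1[ti, bin$view + 1L]
  c2 <- info$vt2c2[ti, bin$view + 1L]
  if (bin$segment >= 0) {
    r1 <- bin$axial_pos + bin$segment
    r2 <- bin$axial_pos
  } else {
    r1 <- bin$axial_pos
    r2 <- bin$axial_pos - bin$segment
  }
  list(d1 = c(r1, c1), d2 = c(r2, c2))
}

#' Line of response of a bin
#'
#' Reads the two Cartesian detection positions of the bin's detector pair
#' from the detector map of `info` -- the block map in
#' blocks-on-cylindrical mode, the idealized cylindrical map in cylindrical
#' mode (reproducing the remapping distortion of the cylindrical model when
#' the data came from a block scanner).
#'
#' @param bin A `pet_bin`.
#' @param info A [proj_data_info()].
#' @return List with `p1`, `p2`: numeric xyz in mm.
#' @export
lor_from_bin <- function(bin, info) {
  pr <- detector_pair_from_bin(bin, info)
  list(
    p1 = detection_position(info$detector_map, pr$d1[1], pr$d1[2]),
    p2 = detection_position(info$detector_map, pr$d2[1], pr$d2[2])
  )
}

#' Histogram list-mode coincidence events into a 3D sinogram
#'
#' Each accepted event increments exactly one bin.  Events whose tangential
#' position falls outside the trimmed range, whose ring difference exceeds
#' the maximum, or whose two crystals share a transaxial index are counted
#' as rejected.  Malformed records (non-finite or out-of-range detector
#' indices) raise an error naming the record number.
#'
#' @param events Integer matrix with columns `ring1, crystal1, ring2,
#'   crystal2` (0-based), one row per coincidence.
#' @param info A [proj_data_info()].
#' @return A `proj_data` with attributes `n_accepted` and `n_rejected`.
#' @export
histogram_listmode <- function(events, info) {
  events <- as.matrix(events)
  if (nrow(events) > 0 &&
      (ncol(events) != 4 || any(!is.finite(events)) ||
       any(events != round(events)))) {
    bad <- if (ncol(events) == 4) which(rowSums(!is.finite(events) |
                                                  events != round(events)) > 0)[1]
           else 1L
    stop(sprintf("malformed event record %d", bad))
  }
  pd <- proj_data(info)
  if (nrow(events) == 0) {
    attr(pd, "n_accepted") <- 0L
    attr(pd, "n_rejected") <- 0L
    return(pd)
  }
  storage.mode(events) <- "integer"
  b <- bins_from_pairs_vec(events[, 1], events[, 2], events[, 3], events[, 4],
                           info)
  acc <- b$accept
  nt <- info$num_tangential
  nv <- info$num_views
  sino <- unname(info$seg_offset[as.character(b$segment[acc])]) +
    b$axial_pos[acc]
  lin <- (b$tangential_pos[acc] - info$tang_min) +
    nt * (b$view[acc] + nv * sino)
  cnt <- tabulate(lin + 1L, nbins = nt * nv * num_sinograms(info))
  pd$counts[] <- cnt
  attr(pd, "n_accepted") <- sum(acc)
  attr(pd, "n_rejected") <- sum(!acc)
  pd
}

# internal: full bin list in counts-array order (tangential fastest, then
# view, then sinogram).  Returns 0-based integer vectors.
all_bins <- function(info) {
  if (!is.null(info$.bins_cache)) return(info$.bins_cache)
  nt <- info$num_tangential
  nv <- info$num_views
  ns <- num_sinograms(info)
  nd <- info$spec$detectors_per_ring
  segs <- rep.int(info$segments, info$seg_n_axial)
  ax_by_sino <- unlist(lapply(info$seg_n_axial, function(n) 0:(n - 1L)),
                       use.names = FALSE)
  t <- rep.int(info$tang_min:info$tang_max, nv * ns)
  v <- rep.int(rep(0:(nv - 1L), each = nt), ns)
  sino <- rep(0:(ns - 1L), each = nt * nv)
  seg <- segs[sino + 1L]
  ax <- ax_by_sino[sino + 1L]
  ti <- t - info$t_full_min + 1L
  vt <- cbind(ti, v + 1L)
  c1 <- info$vt2c1[vt]
  c2 <- info$vt2c2[vt]
  r1 <- ifelse(seg >= 0L, ax + seg, ax)
  r2 <- ifelse(seg >= 0L, ax, ax - seg)
  list(seg = seg, ax = ax, view = v, tang = t, sino = sino,
       d1 = r1 * nd + c1, d2 = r2 * nd + c2)
}
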