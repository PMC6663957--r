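#' Mean LOR direction angle of each view
#'
#' For every view, the circular mean (modulo pi) over the trimmed tangential
#' range of the transaxial direction angle of the segment-0 LORs, computed
#' from the Cartesian detector map of `info`.  For a block-geometry map the
#' angles are not exactly evenly spaced.
#'
#' @param info A [proj_data_info()].
#' @return Numeric vector of length `num_views`, angles in `[0, pi)`.
#' @export
view_direction_angles <- function(info) {
  nv <- info$num_views
  xy <- info$detector_map$xy
  ti <- (info$tang_min:info$tang_max) - info$t_full_min + 1L
  vapply(seq_len(nv), function(v) {
    c1 <- info$vt2c1[ti, v]
    c2 <- info$vt2c2[ti, v]
    d <- xy[c2 + 1L, , drop = FALSE] - xy[c1 + 1L, , drop = FALSE]
    th <- atan2(d[, 2], d[, 1])
    ang <- Arg(mean(exp(2i * th))) / 2
    ang %% pi
  }, numeric(1))
}

#' Views almost orthogonal to a plane source
#'
#' Selects the contiguous block of `num_views / n_positions` views whose
#' direction is closest to the normal of a plane source at azimuth
#' `plane_angle` (a plane containing the scanner axis).  With `n_positions`
#' equally spaced plane angles over 180 degrees the selected sets tile all
#' views disjointly.
#'
#' @param plane_angle Plane azimuth in radians, in `[0, pi)`.
#' @param info A [proj_data_info()].
#' @param n_positions Number of plane positions the acquisition used.
#' @param n_views Number of views to extract; default
#'   `num_views / n_positions`.
#' @return Integer vector of 0-based view indices, contiguous modulo
#'   `num_views`.
#' @export
extract_orthogonal_views <- function(plane_angle, info, n_positions = 6,
                                     n_views = NULL) {
  nv <- info$num_views
  if (is.null(n_views)) {
    if (nv %% n_positions != 0) {
      stop("n_positions must divide num_views when n_views is not given")
    }
    n_views <- nv %/% n_positions
  }
  target <- (plane_angle + pi / 2) %% pi
  ang <- view_direction_angles(info)
  delta <- (ang - target + pi / 2) %% pi - pi / 2 # signed, (-pi/2, pi/2]
  # tie-break toward the counter-clockwise neighbour so equally spaced
  # plane angles produce consistently shifted, disjoint windows
  score <- abs(delta) - 1e-9 * sign(delta)
  v_star <- which.min(score) - 1L
  (seq.int(v_star - n_views %/% 2L, length.out = n_views)) %% nv
}

# bin permutation under a rigid symmetry acting on detector indices.
# crystal_shift: added to both crystals (mod Nd); axial_mirror: rings
# reflected through the scanner center.  Returns 1-based linear indices
# into the counts array, NA where the image bin leaves the trimmed range.
bin_permutation <- function(info, crystal_shift = 0L, axial_mirror = FALSE) {
  bins <- all_bins(info)
  nd <- info$spec$detectors_per_ring
  nr <- info$spec$num_rings
  r1 <- bins$d1 %/% nd
  c1 <- bins$d1 %% nd
  r2 <- bins$d2 %/% nd
  c2 <- bins$d2 %% nd
  c1 <- (c1 + crystal_shift) %% nd
  c2 <- (c2 + crystal_shift) %% nd
  if (axial_mirror) {
    r1 <- nr - 1L - r1
    r2 <- nr - 1L - r2
  }
  b <- bins_from_pairs_vec(r1, c1, r2, c2, info)
  lin <- rep(NA_integer_, length(r1))
  acc <- b$accept
  sino <- unname(info$seg_offset[as.character(b$segment[acc])]) +
    b$axial_pos[acc]
  lin[acc] <- 1L + (b$tangential_pos[acc] - info$tang_min) +
    info$num_tangential * (b$view[acc] + info$num_views * sino)
  lin
}

# average each bin over its orbit under the scanner's rotational symmetry
# (crystal shifts by whole polygon sides) and the axial mirror
fold_symmetric_bins <- function(arr, info) {
  nd <- info$spec$detectors_per_ring
  nv <- info$num_views
  k <- nd %/% info$spec$n_sides # crystals per side
  shifts <- 0L
  if (k > 0L && nv %% k == 0L) shifts <- k * (0:(nv %/% k - 1L))
  v <- as.vector(arr)
  acc <- numeric(length(v))
  cnt <- numeric(length(v))
  for (s in shifts) {
    for (mir in c(FALSE, TRUE)) {
      p <- bin_permutation(info, crystal_shift = s, axial_mirror = mir)
      ok <- !is.na(p)
      acc[ok] <- acc[ok] + v[p[ok]]
      cnt[ok] <- cnt[ok] + 1
    }
  }
  out <- ifelse(cnt > 0, acc / cnt, 0)
  array(out, dim = dim(arr))
}

#' Build normalization factors from rotating-plane-source acquisitions
#'
#' For each plane position the almost-orthogonal views are extracted and
#' assembled into one complete 3D sinogram; bins are then averaged over
#' their orbit under the scanner's rotational symmetry and the axial mirror
#' to raise the per-bin statistics, inverted, and rescaled to mean 1 over
#' the hit bins.  Bins never hit (inverse of zero, i.e. infinity) receive
#' `cap_value`.
#'
#' @param plane_sinos List of `proj_data`, one per plane position.
#' @param angles Plane azimuths in radians; must be equally spaced over
#'   180 degrees.
#' @param info A [proj_data_info()].
#' @param cap_value Replacement for infinite factors; default the maximum
#'   finite factor.
#' @return A `normalization_sinogram`: fields `factors` (array shaped like
#'   the counts array, all positive), `cap_value`, `source_stats` (mean
#'   counts per hit bin after folding), `info`.
#' @export
build_normalization <- function(plane_sinos, angles, info, cap_value = NULL) {
  n_pos <- length(plane_sinos)
  stopifnot(length(angles) == n_pos, n_pos >= 1)
  if (n_pos > 1) {
    spacing <- diff(sort(angles %% pi))
    if (max(abs(spacing - pi / n_pos)) > 1e-6) {
      stop("plane angles must be equally spaced over 180 degrees")
    }
  }
  nv <- info$num_views
  assembled <- array(0, dim = c(info$num_tangential, nv, num_sinograms(info)))
  covered <- integer(0)
  for (i in seq_len(n_pos)) {
    vs <- extract_orthogonal_views(angles[i], info, n_positions = n_pos)
    if (length(intersect(vs, covered))) {
      stop("extracted view sets overlap; check plane angles")
    }
    covered <- c(covered, vs)
    assembled[, vs + 1L, ] <- plane_sinos[[i]]$counts[, vs + 1L, ]
  }
  if (length(covered) < nv) {
    stop(sprintf(
      "plane positions cover only %d of %d views; more positions needed",
      length(covered), nv
    ))
  }

  folded <- fold_symmetric_bins(assembled, info)
  hit <- folded > 0
  if (!any(hit)) stop("no counts in any bin; cannot normalize")
  f <- array(Inf, dim = dim(folded))
  f[hit] <- 1 / folded[hit]
  f[hit] <- f[hit] / mean(f[hit])
  if (is.null(cap_value)) cap_value <- max(f[hit])
  f[!hit] <- cap_value
  structure(
    list(factors = f, cap_value = cap_value,
         source_stats = mean(folded[hit]), info = info),
    class = "normalization_sinogram"
  )
}

#' Expected relative statistical error of normalization factors
#'
#' Poisson counting at `mean_counts` per sinogram bin propagates into a
#' relative factor error of `100 / sqrt(mean_counts)` percent (about 3.2%
#' at 1000 counts per bin).
#'
#' @param mean_counts Mean counts per sinogram bin.
#' @return Percent relative error.
#' @export
normalization_relative_error <- function(mean_counts) {
  100 / sqrt(mean_counts)
}

#' Attenuation-correction sinogram from a mu-map
#'
#' Per bin, the attenuation factor `exp(-sum(length_cm * mu))` along each
#' ray of the bin's tangential ray bundle, averaged over rays.  Factors lie
#' in (0, 1] and equal 1 exactly where the mu-map is empty along the LOR.
#'
#' @param mu A [voxel_image()] of linear attenuation coefficients in 1/cm
#'   (0.096 for water at 511 keV).
#' @param info A [proj_data_info()].
#' @param n_rays Rays per bin.
#' @return An `attenuation_sinogram` with fields `factors` and `info`.
#' @export
attenuation_sinogram <- function(mu, info, n_rays = 1) {
  if (any(mu$values < 0)) stop("attenuation coefficients must be non-negative")
  bins <- all_bins(info)
  ep <- bin_endpoints(info, bins)
  pitch <- crystal_pitch(info$spec)
  d <- ep$P2[, 1:2] - ep$P1[, 1:2]
  nrm <- sqrt(rowSums(d^2))
  nrm[nrm < 1e-12] <- 1
  td <- cbind(-d[, 2] / nrm, d[, 1] / nrm, 0)
  off <- if (n_rays == 1) 0 else
    pitch * ((seq_len(n_rays) - 0.5) / n_rays - 0.5)
  acc <- 0
  for (e in off) {
    li <- cpp_forward_rays(as.vector(mu$values), as.integer(dim(mu$values)),
                           mu$voxel_size, mu$origin,
                           ep$P1 + e * td, ep$P2 + e * td, 1L, pitch)
    acc <- acc + exp(-0.1 * li) # mm path lengths, mu in 1/cm
  }
  factors <- array(acc / length(off),
                   dim = c(info$num_tangential, info$num_views,
                           num_sinograms(info)))
  structure(list(factors = factors, info = info),
            class = "attenuation_sinogram")
}
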