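#' Regions of interest
#'
#' Simple analytic ROIs evaluated by voxel-center inclusion:
#' `roi_cylinder` (axis along z), `roi_sphere`, `roi_annulus` (spherical
#' shell between two diameters), and `roi_circle` (single-plane disc,
#' voxels whose center z is nearest the given z).
#'
#' @param center ROI center (xyz, mm).
#' @param diameter,length,inner_diameter,outer_diameter Dimensions, mm.
#' @return A `pet_roi`.
#' @name rois
NULL

#' @rdname rois
#' @export
roi_cylinder <- function(center, diameter, length) {
  structure(list(kind = "cylinder", center = center, diameter = diameter,
                 length = length), class = "pet_roi")
}

#' @rdname rois
#' @export
roi_sphere <- function(center, diameter) {
  structure(list(kind = "sphere", center = center, diameter = diameter),
            class = "pet_roi")
}

#' @rdname rois
#' @export
roi_annulus <- function(center, inner_diameter, outer_diameter) {
  if (!(outer_diameter > inner_diameter && inner_diameter > 0)) {
    stop("annulus requires outer > inner > 0")
  }
  structure(list(kind = "annulus", center = center,
                 inner_diameter = inner_diameter,
                 outer_diameter = outer_diameter), class = "pet_roi")
}

#' @rdname rois
#' @export
roi_circle <- function(center, diameter) {
  structure(list(kind = "circle", center = center, diameter = diameter),
            class = "pet_roi")
}

#' Logical mask of an ROI on an image grid
#'
#' Membership by voxel-center inclusion.
#'
#' @param roi A `pet_roi`.
#' @param img A [voxel_image()].
#' @return Logical array shaped like `img$values`.
#' @export
roi_mask <- function(roi, img) {
  d <- dim(img$values)
  x <- rep(voxel_centers(img, 1), times = d[2] * d[3]) - roi$center[1]
  y <- rep(rep(voxel_centers(img, 2), each = d[1]), times = d[3]) -
    roi$center[2]
  z <- rep(voxel_centers(img, 3), each = d[1] * d[2]) - roi$center[3]
  m <- switch(roi$kind,
    cylinder = x^2 + y^2 <= (roi$diameter / 2)^2 &
      abs(z) <= roi$length / 2,
    sphere = x^2 + y^2 + z^2 <= (roi$diameter / 2)^2,
    annulus = {
      r2 <- x^2 + y^2 + z^2
      r2 > (roi$inner_diameter / 2)^2 & r2 <= (roi$outer_diameter / 2)^2
    },
    circle = {
      zc <- voxel_centers(img, 3)
      iz <- which.min(abs(zc - roi$center[3]))
      x^2 + y^2 <= (roi$diameter / 2)^2 &
        z == zc[iz] - roi$center[3]
    },
    stop("unknown ROI kind")
  )
  array(m, dim = d)
}

#' Coefficient of variation over an ROI
#'
#' `100 * sd / mean` of the voxel values whose centers fall in the ROI,
#' using the sample (n - 1 denominator) standard deviation.
#'
#' @param img A [voxel_image()].
#' @param roi A `pet_roi`.
#' @return Percent COV.
#' @export
cov_roi <- function(img, roi) {
  v <- img$values[roi_mask(roi, img)]
  if (length(v) == 0) stop("empty ROI")
  m <- mean(v)
  if (m <= 0) stop("ROI mean must be positive for COV")
  100 * stats::sd(v) / m
}

#' Full width at half maximum of a 1D profile
#'
#' Linear interpolation to the half-maximum crossings on each side of the
#' (unique) peak.
#'
#' @param profile Numeric samples.
#' @param spacing Sample spacing, mm.
#' @return FWHM in mm.
#' @export
fwhm <- function(profile, spacing = 1) {
  n <- length(profile)
  ipk <- which.max(profile)
  half <- profile[ipk] / 2
  # left crossing
  li <- ipk
  while (li > 1 && profile[li - 1] >= half) li <- li - 1
  if (li == 1 && profile[1] >= half) stop("half maximum not bracketed (left)")
  xl <- (li - 1) - (profile[li] - half) / (profile[li] - profile[li - 1])
  # right crossing
  ri <- ipk
  while (ri < n && profile[ri + 1] >= half) ri <- ri + 1
  if (ri == n && profile[n] >= half) stop("half maximum not bracketed (right)")
  xr <- (ri - 1) + (profile[ri] - half) / (profile[ri] - profile[ri + 1])
  (xr - xl) * spacing
}

#' Spill-over ratio around a spherical source
#'
#' Mean of the spherical-shell ROI (inner diameter equal to the sphere
#' diameter, outer diameter twice it) divided by the mean of the spherical
#' ROI.
#'
#' @param img A [voxel_image()].
#' @param sphere_center Sphere center (xyz, mm).
#' @param sphere_diameter Sphere diameter, mm.
#' @return The ratio.
#' @export
spill_over_ratio <- function(img, sphere_center, sphere_diameter) {
  sph <- roi_mask(roi_sphere(sphere_center, sphere_diameter), img)
  ann <- roi_mask(roi_annulus(sphere_center, sphere_diameter,
                              2 * sphere_diameter), img)
  if (!any(sph) || !any(ann)) stop("empty ROI")
  ms <- mean(img$values[sph])
  if (ms == 0) stop("sphere ROI mean is zero")
  mean(img$values[ann]) / ms
}

#' Peak-to-valley ratio of a profile across sources
#'
#' Peaks are local maxima searched within half the inter-center spacing of
#' each expected source position; valleys are the minima between
#' consecutive peaks.  Returns mean(peaks) / mean(valleys); `Inf` (with
#' attribute `capped = TRUE`) when the valleys are exactly zero.
#'
#' @param profile Numeric samples along the line.
#' @param centers Expected source positions in sample units (1-based,
#'   possibly fractional); at least 2.
#' @return Ratio, possibly `Inf`.
#' @export
peak_to_valley <- function(profile, centers) {
  if (length(centers) < 2) stop("need at least two expected source positions")
  centers <- sort(centers)
  w <- min(diff(centers)) / 2
  n <- length(profile)
  peaks <- numeric(length(centers))
  locs <- numeric(length(centers))
  for (i in seq_along(centers)) {
    lo <- max(1, ceiling(centers[i] - w))
    hi <- min(n, floor(centers[i] + w))
    if (lo > hi) stop("no identifiable peak near position ", centers[i])
    seg <- profile[lo:hi]
    peaks[i] <- max(seg)
    locs[i] <- lo + which.max(seg) - 1
  }
  valleys <- vapply(seq_len(length(centers) - 1), function(i) {
    min(profile[locs[i]:locs[i + 1]])
  }, numeric(1))
  mv <- mean(valleys)
  if (mv == 0) {
    return(structure(Inf, capped = TRUE))
  }
  mean(peaks) / mv
}

# trilinear interpolation of img at points (n x 3 world mm)
interp3 <- function(img, pts) {
  d <- dim(img$values)
  g <- function(a) (pts[, a] - img$origin[a]) / img$voxel_size[a] +
    (d[a] + 1) / 2 # fractional 1-based index
  fx <- g(1); fy <- g(2); fz <- g(3)
  i0 <- pmin(pmax(floor(fx), 1), d[1] - 1)
  j0 <- pmin(pmax(floor(fy), 1), d[2] - 1)
  k0 <- pmin(pmax(floor(fz), 1), d[3] - 1)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  tz <- pmin(pmax(fz - k0, 0), 1)
  v <- function(i, j, k) img$values[cbind(i, j, k)]
  (1 - tx) * (1 - ty) * (1 - tz) * v(i0, j0, k0) +
    tx * (1 - ty) * (1 - tz) * v(i0 + 1, j0, k0) +
    (1 - tx) * ty * (1 - tz) * v(i0, j0 + 1, k0) +
    tx * ty * (1 - tz) * v(i0 + 1, j0 + 1, k0) +
    (1 - tx) * (1 - ty) * tz * v(i0, j0, k0 + 1) +
    tx * (1 - ty) * tz * v(i0 + 1, j0, k0 + 1) +
    (1 - tx) * ty * tz * v(i0, j0 + 1, k0 + 1) +
    tx * ty * tz * v(i0 + 1, j0 + 1, k0 + 1)
}

#' Resample an image onto a finer grid by trilinear interpolation
#'
#' Useful for evaluating small ROIs (voxel-center membership) on
#' reconstructions whose voxels are comparable to the ROI size.
#'
#' @param img A [voxel_image()].
#' @param dims New grid size.
#' @param voxel_size New voxel size, mm.
#' @return A [voxel_image()] on the new grid (same origin).
#' @export
resample_image <- function(img, dims, voxel_size) {
  out <- voxel_image(dims = dims, voxel_size = voxel_size,
                     origin = img$origin)
  d <- dim(out$values)
  x <- rep(voxel_centers(out, 1), times = d[2] * d[3])
  y <- rep(rep(voxel_centers(out, 2), each = d[1]), times = d[3])
  z <- rep(voxel_centers(out, 3), each = d[1] * d[2])
  out$values[] <- interp3(img, cbind(x, y, z))
  out
}

#' Interpolated line profile through an image
#'
#' Trilinear interpolation along the segment from `p1` to `p2`, sampled
#' with a step of half the smallest voxel dimension by default.
#'
#' @param img A [voxel_image()].
#' @param p1,p2 Endpoints (xyz, mm).
#' @param step Sampling step, mm.
#' @return Data frame with `s` (distance from `p1`, mm) and `value`.
#' @export
line_profile <- function(img, p1, p2, step = NULL) {
  if (is.null(step)) step <- min(img$voxel_size) / 2
  L <- sqrt(sum((p2 - p1)^2))
  s <- seq(0, L, by = step)
  pts <- cbind(p1[1] + s / L * (p2[1] - p1[1]),
               p1[2] + s / L * (p2[2] - p1[2]),
               p1[3] + s / L * (p2[3] - p1[3]))
  data.frame(s = s, value = interp3(img, pts))
}

#' NEMA NU-4 recovery coefficients of the hot rods
#'
#' Slices over the central part of the rod section are averaged; for each
#' rod the maximum pixel inside a circular search region of twice the rod
#' diameter is located, the axial profile at that transverse position is
#' taken, and RC = mean(profile) / mean(uniform region).  The percentage
#' standard deviation combines the profile and uniform-region relative
#' errors in quadrature.
#'
#' @param img A [voxel_image()] of the reconstructed IQ phantom.
#' @param uniform_roi A `pet_roi` over the uniform hot region.
#' @param rods Data frame with columns `x`, `y` (rod centers, mm) and
#'   `diameter` (mm).
#' @param z_range Length-2 mm range of the averaged slab (central 10 mm of
#'   the rod section).
#' @return Data frame with `diameter`, `RC`, `pct_std`.
#' @export
recovery_coefficients <- function(img, uniform_roi, rods, z_range) {
  d <- dim(img$values)
  zc <- voxel_centers(img, 3)
  slab <- which(zc >= z_range[1] & zc <= z_range[2])
  if (length(slab) == 0) stop("no image slices inside z_range")
  mean2d <- apply(img$values[, , slab, drop = FALSE], c(1, 2), mean)
  xc <- voxel_centers(img, 1)
  yc <- voxel_centers(img, 2)
  uv <- img$values[roi_mask(uniform_roi, img)]
  if (length(uv) < 2) stop("uniform region ROI too small")
  mu_u <- mean(uv)
  sd_u <- stats::sd(uv)
  out <- lapply(seq_len(nrow(rods)), function(i) {
    rr <- (outer(xc - rods$x[i], rep(1, d[2])) ^ 2 +
             outer(rep(1, d[1]), yc - rods$y[i]) ^ 2)
    search <- rr <= rods$diameter[i]^2 # radius = diameter (2x diameter circle)
    if (!any(search)) stop("rod search region outside image")
    vals <- mean2d
    vals[!search] <- -Inf
    pk <- arrayInd(which.max(vals), dim(vals))
    prof <- img$values[pk[1], pk[2], slab]
    rc <- mean(prof) / mu_u
    pct <- 100 * sqrt((stats::sd(prof) / mean(prof))^2 + (sd_u / mu_u)^2)
    data.frame(diameter = rods$diameter[i], RC = rc, pct_std = pct)
  })
  do.call(rbind, out)
}
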