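#' Phantom specifications
#'
#' Analytic phantom descriptions used by [voxelize_phantom()]:
#'
#' * `uniform_cylinder_phantom()`: water cylinder, uniformly active.
#' * `derenzo_phantom()`: six 60-degree sectors of spherical sources, one
#'   diameter per sector, on a triangular lattice with center-to-center
#'   spacing twice the sphere diameter, inside a water cylinder.
#' * `point_source_phantom()`: a point source embedded in a 10 mm
#'   water-equivalent cube.
#' * `nema_iq_phantom()`: image-quality phantom; a 20 mm section of five
#'   hot rods (1-5 mm diameter) in cold material and a 30 mm uniformly hot
#'   section with two 8 mm cold rods.
#' * `plane_source_phantom()`: thin air-filled active slab containing the
#'   scanner axis, for normalization acquisitions.
#'
#' All dimensions in mm; `center`/`offset` shift the phantom in the FOV.
#' @param length,diameter Cylinder dimensions.
#' @param center Phantom center (xyz, mm).
#' @param diameters Sphere diameters, one per sector.
#' @param margin Distance from the phantom axis to the innermost sphere
#'   edge.
#' @param position Point-source position (xyz, mm).
#' @param offset_z Axial shift of the IQ phantom.
#' @param width,height,thickness Plane-source transaxial width, axial
#'   height, and thickness.
#' @param angle Plane azimuth, radians.
#' @return A `phantom_spec` list.
#' @name phantoms
NULL

#' @rdname phantoms
#' @export
uniform_cylinder_phantom <- function(length = 25, diameter = 60,
                                     center = c(0, 0, 0)) {
  structure(list(kind = "uniform_cylinder", length = length,
                 diameter = diameter, center = center),
            class = "phantom_spec")
}

#' @rdname phantoms
#' @export
derenzo_phantom <- function(diameters = c(1.6, 1.8, 2.0, 2.2, 2.4, 2.8),
                            length = 25, diameter = 30, margin = 2,
                            center = c(0, 0, 0)) {
  stopifnot(length(diameters) == 6)
  structure(list(kind = "derenzo", diameters = diameters, length = length,
                 diameter = diameter, margin = margin, center = center),
            class = "phantom_spec")
}

#' @rdname phantoms
#' @export
point_source_phantom <- function(position = c(0, 0, 0)) {
  structure(list(kind = "point_source", position = position,
                 cube_side = 10),
            class = "phantom_spec")
}

#' @rdname phantoms
#' @export
nema_iq_phantom <- function(offset_z = 0) {
  structure(list(kind = "nema_iq", body_diameter = 30,
                 rod_section_length = 20, uniform_section_length = 30,
                 hot_rod_diameters = 1:5, hot_rod_radius = 7,
                 cold_rod_diameter = 8, cold_rod_offset = 7.5,
                 offset_z = offset_z),
            class = "phantom_spec")
}

#' @rdname phantoms
#' @export
plane_source_phantom <- function(width = 120, height = 32, thickness = 1,
                                 angle = 0) {
  structure(list(kind = "plane_source", width = width, height = height,
                 thickness = thickness, angle = angle),
            class = "phantom_spec")
}

#' Sphere centers of a Derenzo phantom
#'
#' Triangular lattice per sector: row `i` holds `i + 1` spheres, lateral
#' spacing twice the diameter, rows advancing radially by `sqrt(3)`
#' times the diameter; the innermost sphere edge sits `margin` mm from the
#' phantom axis, and spheres keep 0.5 mm clearance from the cylinder wall.
#'
#' @param spec A [derenzo_phantom()].
#' @return Data frame with `x`, `y`, `z`, `diameter`, `sector`.
#' @export
derenzo_sphere_centers <- function(spec) {
  out <- list()
  r_cyl <- spec$diameter / 2
  for (k in seq_along(spec$diameters)) {
    d <- spec$diameters[k]
    s <- 2 * d
    theta <- (k - 1) * pi / 3 + pi / 6
    er <- c(cos(theta), sin(theta))
    et <- c(-sin(theta), cos(theta))
    for (i in 0:9) {
      rho <- spec$margin + d / 2 + i * s * sqrt(3) / 2
      lat <- (0:i - i / 2) * s
      pts <- cbind(rho * er[1] + lat * et[1], rho * er[2] + lat * et[2])
      # rows are kept only whole, so every sector is a complete triangle
      if (any(sqrt(rowSums(pts^2)) + d / 2 > r_cyl - 0.5)) break
      for (l in seq_len(nrow(pts))) {
        out[[length(out) + 1L]] <-
          data.frame(x = pts[l, 1] + spec$center[1],
                     y = pts[l, 2] + spec$center[2],
                     z = spec$center[3], diameter = d, sector = k)
      }
    }
  }
  do.call(rbind, out)
}

# indicator functions (vectorized over equal-length x, y, z in mm) for the
# active region and the water region of a phantom
phantom_regions <- function(spec) {
  switch(spec$kind,
    uniform_cylinder = {
      inside <- function(x, y, z) {
        (x - spec$center[1])^2 + (y - spec$center[2])^2 <=
          (spec$diameter / 2)^2 &
          abs(z - spec$center[3]) <= spec$length / 2
      }
      list(activity = inside, water = inside)
    },
    derenzo = {
      ctr <- derenzo_sphere_centers(spec)
      act <- function(x, y, z) {
        ins <- rep(FALSE, length(x))
        for (i in seq_len(nrow(ctr))) {
          ins <- ins | ((x - ctr$x[i])^2 + (y - ctr$y[i])^2 +
                          (z - ctr$z[i])^2 <= (ctr$diameter[i] / 2)^2)
        }
        ins
      }
      wat <- function(x, y, z) {
        (x - spec$center[1])^2 + (y - spec$center[2])^2 <=
          (spec$diameter / 2)^2 &
          abs(z - spec$center[3]) <= spec$length / 2
      }
      list(activity = act, water = wat)
    },
    point_source = {
      act <- function(x, y, z) {
        pmax(abs(x - spec$position[1]), abs(y - spec$position[2]),
             abs(z - spec$position[3])) <= 0.5
      }
      wat <- function(x, y, z) {
        pmax(abs(x - spec$position[1]), abs(y - spec$position[2]),
             abs(z - spec$position[3])) <= spec$cube_side / 2
      }
      list(activity = act, water = wat)
    },
    nema_iq = {
      z0 <- spec$offset_z
      # rod section: z in [-rod_len, 0] + z0; uniform section above
      nrod <- length(spec$hot_rod_diameters)
      ang <- 2 * pi * (seq_len(nrod) - 1) / nrod
      rx <- spec$hot_rod_radius * cos(ang)
      ry <- spec$hot_rod_radius * sin(ang)
      act <- function(x, y, z) {
        zz <- z - z0
        body <- x^2 + y^2 <= (spec$body_diameter / 2)^2
        in_rod_sec <- body & zz >= -spec$rod_section_length & zz < 0
        in_uni_sec <- body & zz >= 0 & zz <= spec$uniform_section_length
        hot <- rep(FALSE, length(x))
        for (i in seq_len(nrod)) {
          hot <- hot | ((x - rx[i])^2 + (y - ry[i])^2 <=
                          (spec$hot_rod_diameters[i] / 2)^2)
        }
        cold <- ((x - spec$cold_rod_offset)^2 + y^2 <=
                   (spec$cold_rod_diameter / 2)^2) |
          ((x + spec$cold_rod_offset)^2 + y^2 <=
             (spec$cold_rod_diameter / 2)^2)
        (in_rod_sec & hot) | (in_uni_sec & !cold)
      }
      wat <- function(x, y, z) {
        zz <- z - z0
        x^2 + y^2 <= (spec$body_diameter / 2)^2 &
          zz >= -spec$rod_section_length & zz <= spec$uniform_section_length
      }
      list(activity = act, water = wat)
    },
    plane_source = {
      ep <- c(cos(spec$angle), sin(spec$angle))
      act <- function(x, y, z) {
        u <- x * ep[1] + y * ep[2]
        w <- -x * ep[2] + y * ep[1]
        abs(u) <= spec$width / 2 & abs(w) <= spec$thickness / 2 &
          abs(z) <= spec$height / 2
      }
      # air filled: no attenuating material
      list(activity = act, water = function(x, y, z) rep(FALSE, length(x)))
    },
    stop("unknown phantom kind: ", spec$kind)
  )
}

smallest_feature <- function(spec) {
  switch(spec$kind,
    uniform_cylinder = spec$diameter,
    derenzo = min(spec$diameters),
    point_source = 1,
    nema_iq = min(spec$hot_rod_diameters),
    plane_source = spec$thickness,
    Inf
  )
}

#' Voxelize a phantom onto an image grid
#'
#' Rasterizes the analytic phantom with 3x3x3 sub-voxel sampling, so voxel
#' activity is proportional to the source volume inside the voxel
#' (partial-volume weighting).  The mu-map is 0.096 1/cm in water regions
#' and 0 in air.
#'
#' @param spec A `phantom_spec`.
#' @param grid A [voxel_image()] template.
#' @param mu_water Attenuation coefficient of water at 511 keV, 1/cm.
#' @return List with `activity` and `mu` [voxel_image()]s.
#' @export
voxelize_phantom <- function(spec, grid, mu_water = 0.096) {
  vs <- grid$voxel_size
  if (smallest_feature(spec) < max(vs)) {
    warning(sprintf(
      "phantom feature (%.3g mm) below grid resolution (%.3g mm)",
      smallest_feature(spec), max(vs)
    ))
  }
  reg <- phantom_regions(spec)
  d <- dim(grid$values)
  xc <- voxel_centers(grid, 1)
  yc <- voxel_centers(grid, 2)
  zc <- voxel_centers(grid, 3)
  x <- rep(xc, times = d[2] * d[3])
  y <- rep(rep(yc, each = d[1]), times = d[3])
  z <- rep(zc, each = d[1] * d[2])
  sub <- (c(1, 2, 3) - 2) / 3
  act <- numeric(length(x))
  wat <- numeric(length(x))
  for (dx in sub) for (dy in sub) for (dz in sub) {
    xs <- x + dx * vs[1]
    ys <- y + dy * vs[2]
    zs <- z + dz * vs[3]
    act <- act + reg$activity(xs, ys, zs)
    wat <- wat + reg$water(xs, ys, zs)
  }
  list(
    activity = voxel_image(array(act / 27, dim = d), vs, origin = grid$origin),
    mu = voxel_image(array(mu_water * wat / 27, dim = d), vs,
                     origin = grid$origin)
  )
}

#' Simulate a synthetic PET acquisition
#'
#' Analytic stand-in for a Monte Carlo acquisition with back-to-back 511 keV
#' emission: the expected sinogram is the attenuation-weighted forward
#' projection of the activity image through the true block geometry with a
#' fine tangential ray bundle, rescaled to `total_counts` expected
#' coincidences, and then Poisson sampled.  No positron range,
#' non-collinearity, scatter or randoms are simulated.
#'
#' @param activity A [voxel_image()] of activity.
#' @param mu Optional mu-map [voxel_image()] (1/cm); `NULL` disables
#'   attenuation.
#' @param info_block A blocks-on-cylindrical [proj_data_info()]; ground
#'   truth is always the block geometry.
#' @param total_counts Expected total coincidences (> 0).
#' @param seed Integer seed; fixed seed gives identical output.
#' @param n_rays Rays per bin for the expectation (>= 10 recommended).
#' @param attn Optional precomputed `attenuation_sinogram` (overrides `mu`).
#' @return A `proj_data` of Poisson counts, with attribute `expected`.
#' @export
simulate_acquisition <- function(activity, mu, info_block, total_counts,
                                 seed, n_rays = 10, attn = NULL) {
  if (info_block$mode != "blocks-on-cylindrical") {
    stop("simulation requires the block-geometry ProjDataInfo (ground truth)")
  }
  if (total_counts <= 0) stop("total_counts must be positive")
  expected <- as.vector(forward_project(activity, info_block,
                                        n_rays = n_rays)$counts)
  if (is.null(attn) && !is.null(mu)) {
    attn <- attenuation_sinogram(mu, info_block, n_rays = n_rays)
  }
  if (!is.null(attn)) expected <- expected * as.vector(attn$factors)
  s <- sum(expected)
  pd <- proj_data(info_block)
  if (s > 0) {
    expected <- expected * (total_counts / s)
    set.seed(as.integer(seed))
    pd$counts[] <- stats::rpois(length(expected), expected)
  }
  attr(pd, "expected") <- array(expected, dim = dim(pd$counts))
  pd
}

#' Simulate rotating-plane-source normalization runs
#'
#' One acquisition per plane position, angles equally spaced over 180
#' degrees; the plane is air filled (no attenuation), matching a
#' back-to-back-emission normalization scan.
#'
#' @param info_block A blocks-on-cylindrical [proj_data_info()].
#' @param n_positions Number of plane angles (default 6).
#' @param counts_per_position Expected counts per acquisition.
#' @param seed Base seed; position `i` uses `seed + i - 1`.
#' @param grid Optional voxelization grid; default covers the scanner bore.
#' @param plane A [plane_source_phantom()] template (its `angle` is
#'   overridden per position).
#' @param n_rays Rays per bin.
#' @return List with `sinograms` (list of `proj_data`) and `angles` (rad).
#' @export
simulate_plane_runs <- function(info_block, n_positions = 6,
                                counts_per_position = 1e7, seed = 20190729,
                                grid = NULL, plane = plane_source_phantom(),
                                n_rays = 10) {
  if (n_positions < 1) stop("n_positions must be >= 1")
  spec <- info_block$spec
  if (is.null(grid)) {
    bore <- 2 * spec$inner_radius
    n_xy <- 2L * ceiling(bore / 2 / 1.1) + 1L
    n_z <- max(spec$num_rings, 3L)
    ext_z <- axial_extent(spec)
    grid <- voxel_image(voxel_size = c(1.1, 1.1, ext_z / n_z),
                        dims = c(n_xy, n_xy, n_z))
  }
  angles <- (seq_len(n_positions) - 1) * pi / n_positions
  sinos <- vector("list", n_positions)
  for (i in seq_len(n_positions)) {
    p <- plane
    p$angle <- angles[i]
    vox <- voxelize_phantom(p, grid)
    sinos[[i]] <- simulate_acquisition(vox$activity, mu = NULL, info_block,
                                       total_counts = counts_per_position,
                                       seed = as.integer(seed) + i - 1L,
                                       n_rays = n_rays)
  }
  list(sinograms = sinos, angles = angles)
}

#' Remap block-scanner data onto the virtual cylindrical scanner
#'
#' Re-histograms detector-index data acquired on the true block geometry
#' under the cylindrical-mode parameterization: each physical detection
#' position is assigned to the nearest virtual cylindrical detector
#' (nearest ring plane in z, nearest equal-step azimuth), and the event is
#' binned from those indices.  Because the physical azimuths are not
#' uniform, some virtual detectors are never assigned, producing
#' systematically empty bins -- the distortion the block model removes.
#'
#' @param x A block-mode `proj_data`, or an integer event matrix
#'   (`ring1, crystal1, ring2, crystal2`).
#' @param info_cyl A cylindrical-mode [proj_data_info()] of the same
#'   scanner.
#' @return A `proj_data` under `info_cyl` with attributes `n_accepted`,
#'   `n_rejected`.
#' @export
remap_to_cylindrical <- function(x, info_cyl) {
  if (info_cyl$mode != "cylindrical") {
    stop("info_cyl must be a cylindrical-mode proj_data_info")
  }
  spec <- info_cyl$spec
  block_map <- if (inherits(x, "proj_data")) {
    if (x$info$mode != "blocks-on-cylindrical") {
      stop("input proj_data must be block-mode (ground truth)")
    }
    x$info$detector_map
  } else {
    build_block_detector_map(spec)
  }
  nd <- spec$detectors_per_ring
  # nearest-detector index maps, physical -> virtual
  az <- block_map$crystal_azimuth %% (2 * pi)
  cmap <- as.integer(round(az * nd / (2 * pi))) %% nd
  zc <- build_cylindrical_detector_map(spec)$ring_z
  rmap <- vapply(block_map$ring_z,
                 function(z) which.min(abs(zc - z)) - 1L, integer(1))

  if (inherits(x, "proj_data")) {
    bins <- all_bins(x$info)
    cnt <- as.vector(x$counts)
    nz <- which(cnt > 0)
    r1 <- rmap[bins$d1[nz] %/% nd + 1L]
    c1 <- cmap[bins$d1[nz] %% nd + 1L]
    r2 <- rmap[bins$d2[nz] %/% nd + 1L]
    c2 <- cmap[bins$d2[nz] %% nd + 1L]
    wts <- cnt[nz]
  } else {
    ev <- as.matrix(x)
    r1 <- rmap[ev[, 1] + 1L]
    c1 <- cmap[ev[, 2] + 1L]
    r2 <- rmap[ev[, 3] + 1L]
    c2 <- cmap[ev[, 4] + 1L]
    wts <- rep(1, nrow(ev))
  }
  b <- bins_from_pairs_vec(as.integer(r1), as.integer(c1),
                           as.integer(r2), as.integer(c2), info_cyl)
  acc <- b$accept
  pd <- proj_data(info_cyl)
  nt <- info_cyl$num_tangential
  nv <- info_cyl$num_views
  sino <- unname(info_cyl$seg_offset[as.character(b$segment[acc])]) +
    b$axial_pos[acc]
  lin <- 1L + (b$tangential_pos[acc] - info_cyl$tang_min) +
    nt * (b$view[acc] + nv * sino)
  agg <- rowsum(wts[acc], group = lin)
  pd$counts[as.integer(rownames(agg))] <- agg[, 1]
  attr(pd, "n_accepted") <- sum(wts[acc])
  attr(pd, "n_rejected") <- sum(wts[!acc])
  pd
}
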