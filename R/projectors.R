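#' Voxelized image volume
#'
#' A 3D image on an axis-aligned voxel grid whose center coincides with the
#' scanner's geometric center (plus an optional `origin` offset).  Values
#' are stored x-fastest: `values[ix, iy, iz]`, matching the on-disk order
#' z/y/x with x fastest.
#'
#' @param values 3D numeric array, or `NULL` to create a zero image of
#'   dimension `dims`.
#' @param voxel_size Length-3 mm triple (x, y, z).
#' @param dims Length-3 integer grid size, required when `values` is `NULL`.
#' @param origin World coordinate of the grid center, default the scanner
#'   center `c(0, 0, 0)`.
#' @return A `voxel_image`.
#' @export
voxel_image <- function(values = NULL, voxel_size, dims = NULL,
                        origin = c(0, 0, 0)) {
  if (is.null(values)) {
    stopifnot(!is.null(dims), length(dims) == 3)
    values <- array(0, dim = as.integer(dims))
  }
  stopifnot(length(dim(values)) == 3, length(voxel_size) == 3,
            all(voxel_size > 0))
  structure(
    list(values = values, voxel_size = as.numeric(voxel_size),
         origin = as.numeric(origin)),
    class = "voxel_image"
  )
}

#' @export
print.voxel_image <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf(
    "voxel_image: %d x %d x %d voxels of %.4g x %.4g x %.4g mm, sum %.6g\n",
    d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
    sum(x$values)
  ))
  invisible(x)
}

# world coordinates of voxel centers along one axis (1-based axis)
voxel_centers <- function(img, axis) {
  n <- dim(img$values)[axis]
  img$origin[axis] + (seq_len(n) - (n + 1) / 2) * img$voxel_size[axis]
}

#' Siddon ray trace through a voxel grid
#'
#' Exact lengths of the intersection of the segment `p1`--`p2` with every
#' voxel it crosses, ordered along the ray.  The summed lengths equal the
#' chord of the segment clipped to the grid bounding box; voxel intervals
#' are half-open so boundary rays are never double counted.
#'
#' @param p1,p2 Cartesian endpoints, mm.
#' @param grid A [voxel_image()] supplying the grid geometry.
#' @return A data frame with 1-based voxel indices `ix, iy, iz` and
#'   `length` (mm); zero rows when the ray misses the grid.
#' @export
siddon_path <- function(p1, p2, grid) {
  if (sum((as.numeric(p1) - as.numeric(p2))^2) == 0) {
    stop("degenerate ray: p1 == p2")
  }
  d <- dim(grid$values)
  res <- cpp_siddon_path(as.numeric(p1), as.numeric(p2), as.integer(d),
                         grid$voxel_size, grid$origin)
  lin <- res$voxel
  ix <- lin %% d[1]
  iy <- (lin %/% d[1]) %% d[2]
  iz <- lin %/% (d[1] * d[2])
  data.frame(ix = ix + 1L, iy = iy + 1L, iz = iz + 1L, length = res$length)
}

# transaxial crystal pitch used for multi-ray sampling
crystal_pitch <- function(spec) {
  spec$crystal_size[1] + spec$crystal_gap_transaxial
}

#' Ray bundle of a bin for multi-ray tangential sampling
#'
#' `n_rays` parallel endpoint pairs offset symmetrically in the tangential
#' direction (perpendicular to the LOR, in the transaxial plane), evenly
#' spread across one crystal pitch and centered on the nominal LOR.  Offsets
#' are `pitch * ((k - 1/2)/n - 1/2)`, `k = 1..n`, so their mean is zero;
#' `n_rays = 1` returns the nominal LOR itself.
#'
#' @param bin A `pet_bin`.
#' @param info A [proj_data_info()].
#' @param n_rays Number of rays, >= 1.
#' @return List of `n_rays` lists with fields `p1`, `p2`.
#' @export
rays_for_bin <- function(bin, info, n_rays) {
  if (n_rays < 1) stop("n_rays must be >= 1")
  lor <- lor_from_bin(bin, info)
  pitch <- crystal_pitch(info$spec)
  dxy <- (lor$p2 - lor$p1)[1:2]
  nrm <- sqrt(sum(dxy^2))
  td <- if (nrm < 1e-12) c(1, 0, 0) else c(-dxy[2], dxy[1], 0) / nrm
  off <- if (n_rays == 1) 0 else pitch * ((seq_len(n_rays) - 0.5) / n_rays - 0.5)
  lapply(off, function(e) list(p1 = lor$p1 + e * td, p2 = lor$p2 + e * td))
}

# endpoint matrices of a set of bins (rows of all_bins selected by `sel`)
bin_endpoints <- function(info, bins, sel = NULL) {
  pos <- info$detector_map$positions
  if (is.null(sel)) {
    list(P1 = pos[bins$d1 + 1L, , drop = FALSE],
         P2 = pos[bins$d2 + 1L, , drop = FALSE])
  } else {
    list(P1 = pos[bins$d1[sel] + 1L, , drop = FALSE],
         P2 = pos[bins$d2[sel] + 1L, , drop = FALSE])
  }
}

# internal: forward projection over a selection of bins -> numeric vector
fp_bins <- function(f, info, n_rays, bins, sel = NULL, cache = NULL) {
  if (!is.null(cache)) {
    v <- as.numeric(cache %*% as.vector(f$values))
    return(if (is.null(sel)) v else v[sel])
  }
  ep <- bin_endpoints(info, bins, sel)
  cpp_forward_rays(as.vector(f$values), as.integer(dim(f$values)),
                   f$voxel_size, f$origin, ep$P1, ep$P2,
                   as.integer(n_rays), crystal_pitch(info$spec))
}

# internal: back projection of values `q` over a bin selection -> 3D array
bp_bins <- function(q, info, n_rays, bins, grid, sel = NULL, cache = NULL) {
  if (!is.null(cache)) {
    full <- numeric(nrow(cache))
    if (is.null(sel)) full <- q else full[sel] <- q
    v <- as.numeric(Matrix::crossprod(cache, full))
    return(array(v, dim = dim(grid$values)))
  }
  ep <- bin_endpoints(info, bins, sel)
  v <- cpp_back_rays(as.numeric(q), as.integer(dim(grid$values)),
                     grid$voxel_size, grid$origin, ep$P1, ep$P2,
                     as.integer(n_rays), crystal_pitch(info$spec))
  array(v, dim = dim(grid$values))
}

#' Forward project an image into projection data
#'
#' Computes, per bin, the average over its tangential ray bundle of the
#' Siddon line integral through the image: the geometric operator X of the
#' factorized forward model q = N L X f.
#'
#' @param f A [voxel_image()] (activity).
#' @param info A [proj_data_info()].
#' @param n_rays Rays per bin for tangential sampling (default 1).
#' @param cache Optional precomputed sparse system matrix from
#'   [system_matrix()]; must match `info`, grid and `n_rays`.
#' @return A `proj_data`.
#' @export
forward_project <- function(f, info, n_rays = 1, cache = NULL) {
  bins <- all_bins(info)
  pd <- proj_data(info)
  pd$counts[] <- fp_bins(f, info, n_rays, bins, cache = cache)
  pd
}

#' Back project projection data into image space
#'
#' Exact adjoint of [forward_project()]: for all images f and data q,
#' `sum(forward(f) * q) == sum(f * back(q))`.
#'
#' @param q A `proj_data`.
#' @param grid A [voxel_image()] template defining the output grid.
#' @param n_rays Rays per bin, matching the forward projector.
#' @param cache Optional sparse system matrix from [system_matrix()].
#' @return A [voxel_image()].
#' @export
back_project <- function(q, grid, n_rays = 1, cache = NULL) {
  info <- q$info
  bins <- all_bins(info)
  vals <- bp_bins(as.vector(q$counts), info, n_rays, bins, grid,
                  cache = cache)
  voxel_image(vals, grid$voxel_size, origin = grid$origin)
}

#' Precompute (cache) the sparse system matrix
#'
#' Builds the bins x voxels sparse matrix of ray-averaged intersection
#' lengths once, so repeated forward/back projections become sparse
#' matrix-vector products.  Results are identical to the on-the-fly
#' projectors; only memory/speed trade-offs differ.  Intended for small
#' problems (memory grows with bins x traversed voxels).
#'
#' @param info A [proj_data_info()].
#' @param grid A [voxel_image()] template.
#' @param n_rays Rays per bin.
#' @return A `dgCMatrix` with `num_bins` rows.
#' @export
system_matrix <- function(info, grid, n_rays = 1) {
  bins <- all_bins(info)
  ep <- bin_endpoints(info, bins)
  tr <- cpp_system_rows(as.integer(dim(grid$values)), grid$voxel_size,
                        grid$origin, ep$P1, ep$P2, as.integer(n_rays),
                        crystal_pitch(info$spec))
  nb <- length(bins$d1)
  nvox <- prod(dim(grid$values))
  Matrix::sparseMatrix(i = tr$i + 1L, j = tr$j + 1L, x = tr$x,
                       dims = c(nb, nvox))
}
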