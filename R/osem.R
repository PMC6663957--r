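#' OSEM reconstruction configuration
#'
#' @param n_subsets Number of view-interleaved subsets; must divide the
#'   number of views.  1 gives plain MLEM.
#' @param n_subiterations Total number of subset updates (one subiteration =
#'   one subset update; with 6 subsets, 24 subiterations are 4 full passes).
#' @param n_rays Tangential rays per LOR for the projectors.
#' @param initial_value Uniform starting activity inside the FOV cylinder.
#' @param nonneg_floor Floor applied to the model estimate in the data /
#'   estimate ratio, avoiding 0/0 in empty bins.
#' @param cache_system_matrix Precompute sparse projector rows per subset
#'   (memory-hungry; small problems only).  Results are unchanged.
#' @param track_loglik Record the Poisson log-likelihood after every
#'   subiteration (costs one extra full forward projection each).
#' @return A `recon_config`.
#' @export
recon_config <- function(n_subsets, n_subiterations, n_rays = 10,
                         initial_value = 1, nonneg_floor = 1e-20,
                         cache_system_matrix = FALSE, track_loglik = FALSE) {
  if (n_subiterations < 1) stop("n_subiterations must be >= 1")
  if (n_subsets < 1) stop("n_subsets must be >= 1")
  structure(
    list(n_subsets = as.integer(n_subsets),
         n_subiterations = as.integer(n_subiterations),
         n_rays = as.integer(n_rays),
         initial_value = initial_value,
         nonneg_floor = nonneg_floor,
         cache_system_matrix = isTRUE(cache_system_matrix),
         track_loglik = isTRUE(track_loglik)),
    class = "recon_config"
  )
}

#' View-interleaved OSEM subsets
#'
#' Subset `k` (0-based) contains the views congruent to `k` modulo
#' `n_subsets`; subsets are disjoint and exhaustive.
#'
#' @param info A [proj_data_info()].
#' @param n_subsets Must divide `num_views`.
#' @return List of 0-based view index vectors.
#' @export
make_subsets <- function(info, n_subsets) {
  nv <- info$num_views
  if (nv %% n_subsets != 0) {
    stop(sprintf("n_subsets (%d) must divide num_views (%d)", n_subsets, nv))
  }
  n_subsets <- as.integer(n_subsets)
  lapply(0:(n_subsets - 1L), function(k) seq.int(k, nv - 1L, by = n_subsets))
}

# per-bin model weights c_b = attenuation / normalization (N L diagonal)
bin_weights <- function(info, norm = NULL, attn = NULL) {
  nb <- info$num_tangential * info$num_views * num_sinograms(info)
  w <- rep(1, nb)
  if (!is.null(norm)) w <- w / as.vector(norm$factors)
  if (!is.null(attn)) w <- w * as.vector(attn$factors)
  w
}

#' Subset sensitivity image
#'
#' Back projection, over the bins of one view subset, of the model weights
#' (attenuation factor times inverse normalization factor): the column sums
#' (N L X)^T 1 restricted to the subset.
#'
#' @param info A [proj_data_info()].
#' @param subset 0-based view indices (one element of [make_subsets()]).
#' @param grid A [voxel_image()] template.
#' @param norm Optional `normalization_sinogram` (treated as 1 if absent).
#' @param attn Optional `attenuation_sinogram` (treated as 1 if absent).
#' @param n_rays Rays per bin.
#' @return A [voxel_image()].
#' @export
sensitivity_image <- function(info, subset, grid, norm = NULL, attn = NULL,
                              n_rays = 1) {
  bins <- all_bins(info)
  sel <- which(bins$view %in% subset)
  w <- bin_weights(info, norm, attn)
  vals <- bp_bins(w[sel], info, n_rays, bins, grid, sel = sel)
  voxel_image(vals, grid$voxel_size, origin = grid$origin)
}

#' Poisson log-likelihood of projection data under a model estimate
#'
#' `sum(q * log(qbar) - qbar)` over bins, with the estimate floored to keep
#' the logarithm finite in empty bins.
#'
#' @param q Measured counts (vector or `proj_data`).
#' @param qbar Model estimate, same length.
#' @param floor Floor for `qbar` inside the logarithm.
#' @return Scalar log-likelihood (additive constants dropped).
#' @export
poisson_loglik <- function(q, qbar, floor = 1e-20) {
  if (inherits(q, "proj_data")) q <- as.vector(q$counts)
  if (inherits(qbar, "proj_data")) qbar <- as.vector(qbar$counts)
  sum(q * log(pmax(qbar, floor)) - qbar)
}

#' Fully-3D OSEM reconstruction
#'
#' Ordered-subsets expectation maximization with the factorized system
#' model N L X (scatter and randoms set to zero): per subiteration the
#' image is updated multiplicatively,
#'
#'     f  <-  (f / sens_k) * X_k^T ( c_k * q_k / max(c_k * X_k f, floor) )
#'
#' where `c = attenuation / normalization` and `sens_k = X_k^T c_k` is the
#' subset sensitivity.  Subsets are visited sequentially `0 .. n-1` within
#' each full pass.  The image starts uniform inside the field-of-view
#' cylinder inscribed in the grid; voxels with zero subset sensitivity stay
#' at zero, and the output is non-negative.
#'
#' @param q A `proj_data` of measured counts (non-negative).
#' @param cfg A [recon_config()].
#' @param grid A [voxel_image()] template for the reconstruction.
#' @param norm Optional `normalization_sinogram`.
#' @param attn Optional `attenuation_sinogram`.
#' @param initial Optional [voxel_image()] to start from instead of the
#'   uniform disc (e.g. to verify fixed points).
#' @param verbose Print per-subiteration progress.
#' @return A [voxel_image()]; when `cfg$track_loglik` is set, attribute
#'   `loglik` holds the per-subiteration Poisson log-likelihood.
#' @export
osem_reconstruct <- function(q, cfg, grid, norm = NULL, attn = NULL,
                             initial = NULL, verbose = FALSE) {
  info <- q$info
  qv <- as.vector(q$counts)
  if (any(!is.finite(qv)) || any(qv < 0)) {
    stop("projection data must be finite and non-negative")
  }
  if (sum(qv) == 0) {
    warning("all-zero projection data; returning zero image")
    return(voxel_image(voxel_size = grid$voxel_size,
                       dims = dim(grid$values), origin = grid$origin))
  }
  subsets <- make_subsets(info, cfg$n_subsets)
  bins <- all_bins(info)
  w <- bin_weights(info, norm, attn)

  sel_list <- lapply(subsets, function(s) which(bins$view %in% s))
  caches <- vector("list", cfg$n_subsets)
  full_cache <- NULL
  if (cfg$cache_system_matrix) {
    full_cache <- system_matrix(info, grid, cfg$n_rays)
    caches <- lapply(sel_list, function(sel) full_cache[sel, , drop = FALSE])
  }

  dims <- dim(grid$values)
  sens <- vector("list", cfg$n_subsets)
  for (k in seq_len(cfg$n_subsets)) {
    sens[[k]] <- if (is.null(caches[[k]])) {
      bp_bins(w[sel_list[[k]]], info, cfg$n_rays, bins, grid,
              sel = sel_list[[k]])
    } else {
      array(as.numeric(Matrix::crossprod(caches[[k]], w[sel_list[[k]]])),
            dim = dims)
    }
  }

  if (is.null(initial)) {
    # uniform start inside the FOV cylinder inscribed in the grid
    xc <- voxel_centers(grid, 1)
    yc <- voxel_centers(grid, 2)
    r_fov <- min(dims[1] * grid$voxel_size[1],
                 dims[2] * grid$voxel_size[2]) / 2
    inside <- outer(xc^2, yc^2, `+`) <= r_fov^2
    f <- array(0, dim = dims)
    f[] <- cfg$initial_value * rep(inside, times = dims[3])
  } else {
    stopifnot(all(dim(initial$values) == dims))
    f <- initial$values
  }

  loglik <- numeric(0)
  for (it in seq_len(cfg$n_subiterations)) {
    k <- (it - 1L) %% cfg$n_subsets + 1L
    sel <- sel_list[[k]]
    fimg <- voxel_image(f, grid$voxel_size, origin = grid$origin)
    fwd <- if (is.null(caches[[k]])) {
      fp_bins(fimg, info, cfg$n_rays, bins, sel = sel)
    } else {
      as.numeric(caches[[k]] %*% as.vector(f))
    }
    qbar <- w[sel] * fwd
    ratio <- qv[sel] / pmax(qbar, cfg$nonneg_floor)
    upd <- if (is.null(caches[[k]])) {
      bp_bins(w[sel] * ratio, info, cfg$n_rays, bins, grid, sel = sel)
    } else {
      array(as.numeric(Matrix::crossprod(caches[[k]], w[sel] * ratio)),
            dim = dims)
    }
    m <- sens[[k]] > 0
    f[m] <- f[m] * upd[m] / sens[[k]][m]
    f[!m] <- 0
    if (cfg$track_loglik) {
      fimg <- voxel_image(f, grid$voxel_size, origin = grid$origin)
      fwd_all <- if (is.null(full_cache)) {
        fp_bins(fimg, info, cfg$n_rays, bins)
      } else {
        as.numeric(full_cache %*% as.vector(f))
      }
      loglik <- c(loglik, poisson_loglik(qv, w * fwd_all,
                                         floor = cfg$nonneg_floor))
    }
    if (verbose) {
      message(sprintf("subiteration %d/%d (subset %d), image sum %.6g",
                      it, cfg$n_subiterations, k - 1L, sum(f)))
    }
  }
  out <- voxel_image(f, grid$voxel_size, origin = grid$origin)
  if (cfg$track_loglik) attr(out, "loglik") <- loglik
  out
}
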