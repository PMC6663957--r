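# small scanners and grids used across tests

# 8 detectors per ring, 2 rings: small enough for exhaustive enumeration
mini_scanner_spec <- function() {
  scanner_spec(
    name = "mini", inner_radius = 10, n_sides = 4,
    n_blocks_transaxial = 4, n_blocks_axial = 2,
    n_crystals_per_block_transaxial = 2, n_crystals_per_block_axial = 1,
    crystal_size = c(2, 2, 10),
    crystal_gap_transaxial = 0.2, crystal_gap_axial = 0.2,
    block_gap_transaxial = 0.4, block_gap_axial = 0.4
  )
}

# 24 detectors per ring, 4 rings: fast but non-trivial block scanner
toy_scanner_spec <- function() {
  scanner_spec(
    name = "toy", inner_radius = 30, n_sides = 6,
    n_blocks_transaxial = 6, n_blocks_axial = 1,
    n_crystals_per_block_transaxial = 4, n_crystals_per_block_axial = 4,
    crystal_size = c(4, 4, 10),
    crystal_gap_transaxial = 0.2, crystal_gap_axial = 0.2,
    block_gap_transaxial = 1, block_gap_axial = 1
  )
}

toy_grid <- function(dims = c(21, 21, 5), voxel = c(2, 2, 3.5)) {
  voxel_image(dims = dims, voxel_size = voxel)
}

# independent Siddon oracle: all parametric plane crossings, sorted
# (vectorized closed-form computation, no incremental traversal)
siddon_oracle <- function(p1, p2, grid) {
  d <- dim(grid$values)
  vs <- grid$voxel_size
  lo <- grid$origin - d * vs / 2
  hi <- lo + d * vs
  dd <- p2 - p1
  a0 <- 0
  a1 <- 1
  for (ax in 1:3) {
    if (abs(dd[ax]) < 1e-12) {
      if (p1[ax] < lo[ax] || p1[ax] >= hi[ax]) a1 <- -Inf
    } else {
      t0 <- (lo[ax] - p1[ax]) / dd[ax]
      t1 <- (hi[ax] - p1[ax]) / dd[ax]
      a0 <- max(a0, min(t0, t1))
      a1 <- min(a1, max(t0, t1))
    }
  }
  empty <- data.frame(ix = integer(0), iy = integer(0), iz = integer(0),
                      length = numeric(0))
  if (a1 <= a0) return(empty)
  alphas <- c(a0, a1)
  for (ax in 1:3) {
    if (abs(dd[ax]) > 1e-12) {
      av <- (lo[ax] + (0:d[ax]) * vs[ax] - p1[ax]) / dd[ax]
      alphas <- c(alphas, av[av > a0 & av < a1])
    }
  }
  alphas <- sort(unique(alphas))
  L <- sqrt(sum(dd^2))
  am <- (alphas[-1] + alphas[-length(alphas)]) / 2
  len <- diff(alphas) * L
  ix <- floor((p1[1] + am * dd[1] - lo[1]) / vs[1])
  iy <- floor((p1[2] + am * dd[2] - lo[2]) / vs[2])
  iz <- floor((p1[3] + am * dd[3] - lo[3]) / vs[3])
  ok <- len > 0 & ix >= 0 & ix < d[1] & iy >= 0 & iy < d[2] &
    iz >= 0 & iz < d[3]
  data.frame(ix = ix[ok] + 1L, iy = iy[ok] + 1L, iz = iz[ok] + 1L,
             length = len[ok])
}

# per-voxel length table of a path result, for order-insensitive comparison
path_table <- function(p, d) {
  key <- (p$ix - 1) + d[1] * ((p$iy - 1) + d[2] * (p$iz - 1))
  tapply(p$length, key, sum)
}
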