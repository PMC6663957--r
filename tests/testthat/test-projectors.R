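test_that("siddon_path handles closed-form rays", {
  g <- voxel_image(dims = c(11, 11, 11), voxel_size = c(1, 1, 1))
  # axis-aligned ray through 11 unit voxels
  p <- siddon_path(c(-10, 0.2, 0.3), c(10, 0.2, 0.3), g)
  expect_equal(nrow(p), 11)
  expect_equal(p$length, rep(1, 11), tolerance = 1e-12)
  expect_equal(p$iy, rep(6L, 11))
  # main diagonal of a single 1 mm cube
  g1 <- voxel_image(dims = c(1, 1, 1), voxel_size = c(1, 1, 1))
  p <- siddon_path(c(-0.5, -0.5, -0.5), c(0.5, 0.5, 0.5), g1)
  expect_equal(nrow(p), 1)
  expect_equal(p$length, sqrt(3), tolerance = 1e-12)
  # miss
  p <- siddon_path(c(-10, 20, 0), c(10, 20, 0), g)
  expect_equal(nrow(p), 0)
  # degenerate
  expect_error(siddon_path(c(1, 2, 3), c(1, 2, 3), g), "degenerate")
})

test_that("siddon_path matches an independent oracle on random rays", {
  g <- voxel_image(dims = c(11, 11, 11), voxel_size = c(1, 1, 1))
  d <- dim(g$values)
  set.seed(3)
  n_checked <- 0
  for (i in 1:200) {
    p1 <- runif(3, -9, 9)
    p2 <- runif(3, -9, 9)
    if (sum((p1 - p2)^2) < 1) next
    sp <- siddon_path(p1, p2, g)
    or <- siddon_oracle(p1, p2, g)
    a <- path_table(sp, d)
    b <- path_table(or, d)
    keys <- union(names(a), names(b))
    av <- ifelse(keys %in% names(a), a[keys], 0)
    bv <- ifelse(keys %in% names(b), b[keys], 0)
    expect_lt(max(abs(av - bv), 0), 1e-6)
    n_checked <- n_checked + 1
    # chord-length conservation against the clipped chord
    expect_equal(sum(sp$length), sum(or$length), tolerance = 1e-9)
  }
  expect_gt(n_checked, 150)
})

test_that("dense point sampling agrees at its quantization limit", {
  # equidistant point sampling bounds per-voxel error by ~L/n_points;
  # at 1e5 points that is ~3e-4 mm on this grid (the exact-crossing oracle
  # above carries the 1e-6 comparison)
  g <- voxel_image(dims = c(11, 11, 11), voxel_size = c(1, 1, 1))
  d <- dim(g$values)
  set.seed(4)
  for (i in 1:5) {
    p1 <- runif(3, -5, 5)
    p2 <- runif(3, -5, 5)
    if (sum((p1 - p2)^2) < 4) next
    sp <- siddon_path(p1, p2, g)
    n <- 1e5
    t <- (seq_len(n) - 0.5) / n
    L <- sqrt(sum((p2 - p1)^2))
    pts <- cbind(p1[1] + t * (p2[1] - p1[1]), p1[2] + t * (p2[2] - p1[2]),
                 p1[3] + t * (p2[3] - p1[3]))
    idx <- floor(sweep(pts, 2, g$origin - d / 2))
    inb <- rowSums(idx >= 0 & idx < matrix(d, n, 3, byrow = TRUE)) == 3
    key <- idx[inb, 1] + d[1] * (idx[inb, 2] + d[2] * idx[inb, 3])
    brute <- tapply(rep(L / n, sum(inb)), key, sum)
    a <- path_table(sp, d)
    keys <- union(names(a), names(brute))
    av <- ifelse(keys %in% names(a), a[keys], 0)
    bv <- ifelse(keys %in% names(brute), brute[keys], 0)
    expect_lt(max(abs(av - bv)), 5 * L / n)
  }
})

test_that("chord length is conserved for rays through the grid", {
  g <- voxel_image(dims = c(9, 7, 5), voxel_size = c(1.3, 0.9, 2.1))
  set.seed(5)
  for (i in 1:50) {
    # endpoints well outside the grid so the chord is the full box crossing
    th <- runif(1, 0, 2 * pi)
    p1 <- c(30 * cos(th), 30 * sin(th), runif(1, -4, 4))
    p2 <- -p1 + c(0, 0, runif(1, -2, 2))
    sp <- siddon_path(p1, p2, g)
    or <- siddon_oracle(p1, p2, g)
    expect_equal(sum(sp$length), sum(or$length), tolerance = 1e-9)
  }
})

test_that("rays_for_bin spreads rays evenly over one crystal pitch", {
  info <- proj_data_info(toy_scanner_spec())
  b <- pet_bin(0, 1, 3, 2)
  lor <- lor_from_bin(b, info)
  # n_rays = 1: the nominal LOR
  r1 <- rays_for_bin(b, info, 1)
  expect_equal(r1[[1]]$p1, lor$p1)
  expect_equal(r1[[1]]$p2, lor$p2)
  # n_rays = 2: offsets +- pitch/4
  r2 <- rays_for_bin(b, info, 2)
  pitch <- toy_scanner_spec()$crystal_size[1] +
    toy_scanner_spec()$crystal_gap_transaxial
  off2 <- vapply(r2, function(r) {
    s <- r$p1 - lor$p1
    sign(sum(s)) * sqrt(sum(s^2))
  }, numeric(1))
  expect_equal(sort(abs(off2)), rep(pitch / 4, 2), tolerance = 1e-12)
  # n_rays = 10: symmetric offsets, zero mean
  r10 <- rays_for_bin(b, info, 10)
  offs <- t(vapply(r10, function(r) r$p1 - lor$p1, numeric(3)))
  expect_equal(unname(colMeans(offs)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(nrow(unique(round(offs, 9))), 10)
  expect_error(rays_for_bin(b, info, 0), "n_rays")
})

test_that("forward projection is linear and matches siddon_path per bin", {
  info <- proj_data_info(toy_scanner_spec())
  grid <- toy_grid()
  set.seed(6)
  f1 <- voxel_image(array(runif(prod(dim(grid$values))),
                          dim(grid$values)), grid$voxel_size)
  f2 <- voxel_image(array(runif(prod(dim(grid$values))),
                          dim(grid$values)), grid$voxel_size)
  z <- voxel_image(dims = dim(grid$values), voxel_size = grid$voxel_size)
  expect_equal(sum(forward_project(z, info, 2)$counts), 0)
  qa <- forward_project(f1, info, 2)
  qb <- forward_project(f2, info, 2)
  qc <- forward_project(
    voxel_image(2 * f1$values + 3 * f2$values, grid$voxel_size),
    info, 2
  )
  expect_equal(qc$counts, 2 * qa$counts + 3 * qb$counts, tolerance = 1e-9)
  # per-bin recomputation with siddon_path for random bins, single ray
  q1 <- forward_project(f1, info, 1)
  bins <- blockpet:::all_bins(info)
  set.seed(7)
  for (idx in sample(length(bins$d1), 20)) {
    lor <- list(
      p1 = info$detector_map$positions[bins$d1[idx] + 1, ],
      p2 = info$detector_map$positions[bins$d2[idx] + 1, ]
    )
    sp <- siddon_path(lor$p1, lor$p2, grid)
    v <- sum(sp$length * f1$values[cbind(sp$ix, sp$iy, sp$iz)])
    expect_equal(as.vector(q1$counts)[idx], v, tolerance = 1e-9)
  }
})

test_that("back projector is the exact adjoint of the forward projector", {
  info <- proj_data_info(toy_scanner_spec())
  grid <- toy_grid()
  set.seed(8)
  for (i in 1:10) {
    f <- voxel_image(array(runif(prod(dim(grid$values))),
                           dim(grid$values)), grid$voxel_size)
    q <- proj_data(info)
    q$counts[] <- runif(length(q$counts))
    for (nr in c(1, 3)) {
      lhs <- sum(forward_project(f, info, nr)$counts * q$counts)
      rhs <- sum(f$values * back_project(q, grid, nr)$values)
      expect_equal(lhs, rhs, tolerance = 1e-6)
    }
  }
})

test_that("back-projecting a one-bin impulse lights exactly its ray voxels", {
  info <- proj_data_info(toy_scanner_spec())
  grid <- toy_grid()
  bins <- blockpet:::all_bins(info)
  idx <- 500L
  q <- proj_data(info)
  q$counts[idx] <- 1
  img <- back_project(q, grid, 1)
  sp <- siddon_path(info$detector_map$positions[bins$d1[idx] + 1, ],
                    info$detector_map$positions[bins$d2[idx] + 1, ], grid)
  lit <- which(img$values > 0, arr.ind = TRUE)
  expect_equal(nrow(lit), nrow(sp))
  expect_setequal(
    paste(lit[, 1], lit[, 2], lit[, 3]),
    paste(sp$ix, sp$iy, sp$iz)
  )
})

test_that("cached system-matrix projection equals the on-the-fly path", {
  info <- proj_data_info(toy_scanner_spec())
  grid <- toy_grid()
  set.seed(9)
  f <- voxel_image(array(runif(prod(dim(grid$values))),
                         dim(grid$values)), grid$voxel_size)
  X <- system_matrix(info, grid, n_rays = 3)
  q0 <- forward_project(f, info, 3)
  q1 <- forward_project(f, info, 3, cache = X)
  expect_equal(q1$counts, q0$counts, tolerance = 1e-9)
  b0 <- back_project(q0, grid, 3)
  b1 <- back_project(q0, grid, 3, cache = X)
  expect_equal(b1$values, b0$values, tolerance = 1e-9)
})
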