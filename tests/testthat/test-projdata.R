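test_that("sinogram dimensioning matches the published scanner tables", {
  # counts for the three published scanner designs (all ring differences)
  expect_equal(num_sinograms(proj_data_info(scanner_a_spec())), 41^2)
  infoB <- proj_data_info(scanner_b_spec())
  expect_equal(num_sinograms(infoB), 256)
  expect_equal(infoB$num_views, 96L)
  expect_equal(num_sinograms(proj_data_info(scanner_c_spec())), 1024)
  # single ring
  one <- scanner_spec("one", inner_radius = 10, n_sides = 4,
                      n_blocks_transaxial = 4, n_blocks_axial = 1,
                      n_crystals_per_block_transaxial = 2,
                      n_crystals_per_block_axial = 1,
                      crystal_size = c(2, 2, 10))
  expect_equal(num_sinograms(proj_data_info(one)), 1L)
})

test_that("bin map is a bijection on the 8-detector 2-ring mini scanner", {
  info <- proj_data_info(mini_scanner_spec(), num_tangential = 7)
  nd <- 8L
  nr <- 2L
  seen <- character(0)
  n_pairs <- 0L
  for (r1 in 0:(nr - 1)) for (c1 in 0:(nd - 1)) {
    for (r2 in 0:(nr - 1)) for (c2 in 0:(nd - 1)) {
      if (r1 * nd + c1 >= r2 * nd + c2) next
      if (c1 == c2) next # no bin for same-transaxial-index pairs
      n_pairs <- n_pairs + 1L
      b <- bin_from_detector_pair(c(r1, c1), c(r2, c2), info)
      expect_false(is.null(b))
      key <- paste(b$segment, b$axial_pos, b$view, b$tangential_pos)
      expect_false(key %in% seen) # injective
      seen <- c(seen, key)
      pr <- detector_pair_from_bin(b, info)
      expect_setequal(
        list(paste(pr$d1, collapse = ","), paste(pr$d2, collapse = ",")),
        list(paste(c(r1, c1), collapse = ","),
             paste(c(r2, c2), collapse = ","))
      )
    }
  }
  # surjective onto the full bin grid: rings^2 sinograms x views x tangs
  expect_equal(n_pairs, num_sinograms(info) * info$num_views *
                 info$num_tangential)
})

test_that("opposed detector pairs map to tangential position zero", {
  info <- proj_data_info(mini_scanner_spec(), num_tangential = 7)
  for (r in 0:1) for (c1 in 0:7) {
    b <- bin_from_detector_pair(c(r, c1), c(r, (c1 + 4) %% 8), info)
    expect_equal(b$tangential_pos, 0L)
    expect_equal(b$segment, 0L)
    expect_equal(b$axial_pos, r)
  }
  # segment-s bins return rings differing by s
  b <- pet_bin(1, 0, 2, 1)
  pr <- detector_pair_from_bin(b, proj_data_info(mini_scanner_spec(),
                                                 num_tangential = 7))
  expect_equal(abs(pr$d1[1] - pr$d2[1]), 1)
})

test_that("tangential trimming rejects out-of-range pairs", {
  info <- proj_data_info(mini_scanner_spec(), num_tangential = 3)
  # adjacent crystals: |tangential| near Nd/2, outside the trim
  expect_null(bin_from_detector_pair(c(0, 0), c(0, 1), info))
  # opposed pair still accepted
  expect_false(is.null(bin_from_detector_pair(c(0, 0), c(0, 4), info)))
})

test_that("segment-0 tangential-0 LORs pass through the axis (cylindrical)", {
  info <- proj_data_info(toy_scanner_spec(), mode = "cylindrical")
  for (v in c(0L, 3L, 7L)) {
    lor <- lor_from_bin(pet_bin(0, 1, v, 0), info)
    d <- lor$p2 - lor$p1
    # distance of the segment from the z axis
    cr <- abs(lor$p1[1] * d[2] - lor$p1[2] * d[1]) / sqrt(sum(d[1:2]^2))
    expect_lt(cr, 1e-9)
  }
})

test_that("block and cylindrical LOR endpoints differ for a block scanner", {
  sb <- scanner_b_spec(1)
  ib <- proj_data_info(sb)
  ic <- proj_data_info(sb, mode = "cylindrical")
  dmax <- 0
  for (t in seq(ib$tang_min, ib$tang_max, by = 8)) {
    lb <- lor_from_bin(pet_bin(0, 0, 10, t), ib)
    lc <- lor_from_bin(pet_bin(0, 0, 10, t), ic)
    dmax <- max(dmax, sqrt(sum((lb$p1 - lc$p1)^2)),
                sqrt(sum((lb$p2 - lc$p2)^2)))
  }
  expect_gt(dmax, 0.1)
})

test_that("cylindrical mode assigns one azimuth class per view", {
  # two tangentially adjacent cylindrical LORs share their azimuth class
  # (the view) while the block-mode directions differ within a view
  sb <- scanner_b_spec(1)
  ic <- proj_data_info(sb, mode = "cylindrical")
  ib <- proj_data_info(sb)
  ang <- function(lor) {
    d <- lor$p2 - lor$p1
    atan2(d[2], d[1]) %% pi
  }
  a_cyl <- vapply(0:1, function(t) ang(lor_from_bin(pet_bin(0, 0, 5, t), ic)),
                  numeric(1))
  a_blk <- vapply(0:1, function(t) ang(lor_from_bin(pet_bin(0, 0, 5, t), ib)),
                  numeric(1))
  # adjacent even/odd tangential positions in one view: same azimuth pair
  # structure in the cylindrical model has a fixed interleave; block angles
  # deviate from the cylindrical ones
  expect_gt(max(abs(a_blk - a_cyl)), 1e-4)
})

test_that("histogramming conserves counts and validates records", {
  info <- proj_data_info(mini_scanner_spec(), num_tangential = 7)
  # empty stream
  pd0 <- histogram_listmode(matrix(integer(0), ncol = 4), info)
  expect_equal(sum(pd0$counts), 0)
  expect_equal(attr(pd0, "n_accepted"), 0L)
  # one opposed-pair event
  pd1 <- histogram_listmode(matrix(c(0L, 0L, 0L, 4L), nrow = 1), info)
  expect_equal(sum(pd1$counts), 1)
  expect_equal(max(pd1$counts), 1)
  # random admissible events, recounted independently
  set.seed(11)
  n <- 10000
  ev <- cbind(sample(0:1, n, TRUE), sample(0:7, n, TRUE),
              sample(0:1, n, TRUE), sample(0:7, n, TRUE))
  ev <- ev[ev[, 2] != ev[, 4], ]
  pd <- histogram_listmode(ev, info)
  expect_equal(attr(pd, "n_accepted") + attr(pd, "n_rejected"), nrow(ev))
  expect_equal(sum(pd$counts), attr(pd, "n_accepted"))
  # independent recount: every admissible unordered pair hits one bin
  recount <- 0L
  for (i in seq_len(nrow(ev))) {
    b <- bin_from_detector_pair(ev[i, 1:2], ev[i, 3:4], info)
    if (!is.null(b)) recount <- recount + 1L
  }
  expect_equal(sum(pd$counts), recount)
  # malformed / invalid records
  expect_error(histogram_listmode(matrix(c(0, 0.5, 0, 4), nrow = 1), info),
               "malformed")
  expect_error(histogram_listmode(matrix(c(0L, 0L, 5L, 4L), nrow = 1), info),
               "record 1")
})
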