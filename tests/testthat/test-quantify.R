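test_that("region volumes follow the voxel-count arithmetic", {
  lab <- array(0L, c(12, 12, 12))
  lab[1:10, 1:10, 1:10] <- 1L
  ann <- LabelVolume(lab, spacing = c(10, 10, 10))
  v <- region_volumes(ann, 1L)
  expect_equal(unname(v), 1000 * 1000 * 1e-9)   # 10^3 voxels of 10^3 um^3
  expect_equal(unname(region_volumes(ann, 2L)), 0)
  # partitioning regions sum to the brain volume
  ph <- small_phantom()
  vols <- region_volumes(ph$annotation)
  brain_vox <- sum(ph$annotation$labels > 0L)
  expect_equal(sum(vols), brain_vox * prod(ph$annotation$spacing) * 1e-9)
})

test_that("centroid counts conserve the total and split by containing voxel", {
  ph <- small_phantom()
  ann <- ph$annotation
  set.seed(29)
  n <- 500
  pts <- cbind(runif(n, -50, 660), runif(n, -50, 660), runif(n, -50, 660))
  counts <- count_per_region(pts, ann)
  expect_equal(sum(counts), n)
  # all-inside-one-region points count there
  vox <- which(ann$labels == 1L, arr.ind = TRUE) - 1L
  p10 <- birdreg:::voxel_to_phys(vox[1:10, ], grid_of(ann))
  c10 <- count_per_region(p10, ann)
  expect_equal(unname(c10[["1"]]), 10L)
  # a point on a voxel boundary resolves deterministically
  onb <- matrix(rep(10, 3), 1, 3)   # exactly between voxel centres 0 and 1
  expect_equal(sum(count_per_region(onb, ann)), 1)
  expect_identical(count_per_region(onb, ann),
                   count_per_region(onb, ann))
})

test_that("Poisson-seeded counts land within 3 sigma of expectation", {
  ph <- small_phantom()
  ann <- ph$annotation
  vols <- region_volumes(ann)
  rate <- c("1" = 4000, "2" = 1000, "3" = 250, "4" = 2000)  # per mm^3
  set.seed(37)
  pts <- NULL
  for (id in names(rate)) {
    vox <- which(ann$labels == as.integer(id), arr.ind = TRUE) - 1L
    lambda <- rate[[id]] * vols[[id]]
    k <- rpois(1, lambda)
    sel <- vox[sample.int(nrow(vox), k, replace = TRUE), , drop = FALSE]
    jit <- matrix(runif(3 * k, -0.49, 0.49), k, 3)
    pts <- rbind(pts, birdreg:::voxel_to_phys(sel + jit, grid_of(ann)))
  }
  counts <- count_per_region(pts, ann)
  for (id in names(rate)) {
    lambda <- rate[[id]] * vols[[id]]
    expect_lt(abs(counts[[id]] - lambda), 3 * sqrt(lambda) + 3)
  }
  dens <- density_per_region(counts, vols)
  expect_equal(unname(dens[["2"]] * vols[["2"]]),
               unname(as.numeric(counts[["2"]])))
})

test_that("densities divide counts by volumes with missing-volume guards", {
  expect_equal(density_per_region(c("5" = 10L), c("5" = 2)), c("5" = 5))
  expect_equal(density_per_region(c("5" = 0L), c("5" = 2)), c("5" = 0))
  expect_true(is.na(density_per_region(c("5" = 3L), c("5" = 0))[["5"]]))
})

test_that("projection strengths normalise to the reference region", {
  l <- c(VIS = 10, CP = 5)
  s <- projection_strength(l, "VIS")
  expect_equal(s, c(VIS = 1, CP = 0.5))
  expect_true(all(projection_strength(c(a = 3, b = 3, c = 3), "b") == 1))
  expect_error(projection_strength(l, "TH"), "absent")
  expect_error(projection_strength(c(VIS = 0, CP = 5), "VIS"),
               "non-positive")
})

test_that("axon lengths accumulate per region via segment midpoints", {
  lab <- array(0L, c(20, 8, 8))
  lab[1:10, , ] <- 1L; lab[11:20, , ] <- 2L
  ann <- LabelVolume(lab, spacing = c(10, 10, 10),
                     id_to_name = c("1" = "VIS", "2" = "CP"))
  # straight path along x: 60 um inside region 1, then 60 um in region 2
  path <- cbind(seq(35, 155, by = 10), 35, 35)
  lens <- axon_region_lengths(path, ann)
  expect_equal(sum(lens), 120)
  expect_equal(unname(lens[["VIS"]]), 60)
  expect_equal(unname(lens[["CP"]]), 60)
  ps <- projection_strength(as.list(lens), "VIS")
  expect_equal(unname(ps[["CP"]]), 1)
})

test_that("SWC reconstructions load as polylines", {
  p <- file.path(tempdir(), "n.swc")
  writeLines(c("# comment", "1 2 0 0 0 1 -1", "2 2 10 0 0 1 1",
               "3 2 10 10 0 1 2"), p)
  poly <- read_swc(p)
  expect_equal(dim(poly), c(3, 3))
  expect_equal(poly[2, 1], 10)
})

test_that("region_stats assembles the summary table", {
  ph <- small_phantom()
  st <- region_stats(ph$annotation)
  expect_equal(st$id, 1:4)
  expect_true(all(st$volume_mm3 > 0))
})
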