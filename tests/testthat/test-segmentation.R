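spacing <- c(400, 200, 200)

test_that("despeckle is the 1x1x3 z-median with replicated edges", {
  const <- voxel_stack(array(7, c(5, 3, 3)), spacing)
  expect_equal(despeckle(const)$values, const$values)

  v <- array(0, c(3, 1, 1))
  v[, 1, 1] <- c(0, 9, 0)
  out <- despeckle(voxel_stack(v, spacing))$values
  expect_equal(out[2, 1, 1], 0)   # median(0, 9, 0)

  v[, 1, 1] <- c(5, 5, 9)
  out <- despeckle(voxel_stack(v, spacing))$values
  expect_equal(out[2, 1, 1], 5)   # median(5, 5, 9)
  expect_equal(out[3, 1, 1], 9)   # edge replicates: median(5, 9, 9)
})

test_that("despeckle output range is within input range and kills speckles", {
  set.seed(42)
  for (rep in 1:5) {
    v <- array(runif(6 * 10 * 10, 0, 100), c(6, 10, 10))
    sp_at <- cbind(sample(2:5, 3), sample(1:10, 3), sample(1:10, 3))
    v[sp_at] <- 1e4  # isolated speckles flanked by dimmer z-neighbours
    out <- despeckle(voxel_stack(v, spacing))$values
    expect_gte(min(out), min(v))
    expect_lte(max(out), 100)    # every speckle suppressed
  }
})

test_that("despeckle warns and passes through stacks with < 3 planes", {
  vs <- voxel_stack(array(1, c(2, 4, 4)), spacing)
  expect_warning(out <- despeckle(vs), "fewer than 3")
  expect_equal(out$values, vs$values)
})

test_that("cylinder objective peaks at the true parameters on an indicator cylinder", {
  dims <- c(10, 24, 24)
  v <- make_cylinder_image(dims, cy = 12, cx = 13, r = 6, z_lo = 3, z_hi = 8)
  truth_obj <- breakfish:::cylinder_objective(v, 12, 13, 6, 3, 8, beta = 0.5)
  for (dcy in c(-2, 0, 2)) for (dr in c(-2, 0, 2)) for (dz in c(-1, 0, 1)) {
    if (dcy == 0 && dr == 0 && dz == 0) next
    pert <- breakfish:::cylinder_objective(v, 12 + dcy, 13, 6 + dr,
                                           max(1, 3 + dz), 8, beta = 0.5)
    expect_gte(truth_obj, pert)
  }
})

test_that("fit_cylinder recovers an indicator cylinder from an interior seed", {
  dims <- c(12, 30, 30)
  v <- make_cylinder_image(dims, cy = 15, cx = 16, r = 7, z_lo = 4, z_hi = 9)
  fit <- fit_cylinder(v, seed = c(6, 15, 16))
  expect_lt(abs(fit$center_y - 15), 1)
  expect_lt(abs(fit$center_x - 16), 1)
  expect_lt(abs(fit$radius - 7) / 7, 0.1)
  expect_equal(c(fit$z_lo, fit$z_hi), c(4, 9))
  expect_false(fit$unstable)
})

test_that("fit_cylinder flags a uniform image as unstable and rejects NaN", {
  fit <- fit_cylinder(array(5, c(6, 20, 20)), seed = c(3, 10, 10))
  expect_true(fit$unstable)
  bad <- array(1, c(4, 5, 5)); bad[2, 2, 2] <- NaN
  expect_error(fit_cylinder(bad, seed = c(1, 1, 1)), "non-finite")
  expect_error(fit_cylinder(array(0, c(4, 5, 5)), seed = c(1, 1, 1)), "positive")
})

test_that("a seed on an isolated bright voxel degenerates to the radius floor", {
  v <- array(0, c(6, 20, 20))
  v[3, 10, 10] <- 50
  fit <- fit_cylinder(v, seed = c(3, 10, 10), init_radius = 3)
  expect_lt(fit$n_voxels, 1000)   # removed later by the nucleus size filter
})

test_that("detect_nuclei finds nothing in an all-zero stack", {
  expect_equal(detect_nuclei(voxel_stack(array(0, c(6, 30, 30)), spacing)), list())
})

test_that("detect_nuclei recovers one and two planted cylinders", {
  dims <- c(12, 60, 60)
  v1 <- make_cylinder_image(dims, cy = 30, cx = 20, r = 8, z_lo = 3, z_hi = 10)
  nuc <- detect_nuclei(voxel_stack(v1, spacing), min_vox = 500)
  expect_length(nuc, 1)
  expect_lt(abs(nuc[[1]]$center_y - 30), 1)
  expect_lt(abs(nuc[[1]]$center_x - 20), 1)
  expect_lt(abs(nuc[[1]]$radius - 8) / 8, 0.1)

  # second cylinder three radii away
  v2 <- v1 + make_cylinder_image(dims, cy = 30, cx = 44, r = 8, z_lo = 3, z_hi = 10)
  nuc2 <- detect_nuclei(voxel_stack(v2, spacing), min_vox = 500)
  expect_length(nuc2, 2)
  got_x <- sort(vapply(nuc2, `[[`, numeric(1), "center_x"))
  expect_lt(max(abs(got_x - c(20, 44))), 1)
})

test_that("detect_objects isolates planted spots with accurate centroids", {
  dims <- c(12, 60, 60)
  dapi <- make_cylinder_image(dims, cy = 30, cx = 30, r = 20, z_lo = 2, z_hi = 11)
  nuc <- detect_nuclei(voxel_stack(dapi, spacing), min_vox = 500)
  expect_length(nuc, 1)

  spot <- array(0, dims)
  spot <- breakfish:::add_gaussian_spot(spot, c(dz = 400, dy = 200, dx = 200),
                                        c(29 * 200, 29 * 200, 5 * 400), 1000, 200)
  obs <- detect_objects(voxel_stack(spot, spacing, "probe1"), nuc[[1]],
                        "locus", top_k = 50)
  expect_length(obs, 1)
  cen <- weighted_centroid(obs[[1]], spacing)$position
  err_vox <- sqrt(((cen[1] - 29 * 200) / 200)^2 + ((cen[2] - 29 * 200) / 200)^2 +
                  ((cen[3] - 5 * 400) / 400)^2)
  expect_lt(err_vox, 1)

  # two spots 20 voxels apart -> two components
  spot2 <- breakfish:::add_gaussian_spot(spot, c(dz = 400, dy = 200, dx = 200),
                                         c(29 * 200, 9 * 200, 5 * 400), 1000, 200)
  obs2 <- detect_objects(voxel_stack(spot2, spacing, "probe1"), nuc[[1]],
                         "locus", top_k = 100)
  expect_length(obs2, 2)

  expect_equal(detect_objects(voxel_stack(spot, spacing), nuc[[1]],
                              "locus", top_k = 0), list())
  expect_warning(detect_objects(voxel_stack(spot, spacing), nuc[[1]],
                                "locus", top_k = 1e7), "exceeds")
})

test_that("components agree with brute-force flood fill at every connectivity", {
  set.seed(7)
  dims <- c(8, 12, 12)
  for (conn in c(6, 18, 26)) {
    for (rep in 1:5) {
      n <- 25
      zyx <- unique(cbind(sample(1:8, n, TRUE), sample(1:12, n, TRUE),
                          sample(1:12, n, TRUE)))
      got <- breakfish:::connected_components(zyx, conn, dims)
      want <- brute_components(zyx, conn)
      # same partition (labels may differ)
      expect_equal(outer(got, got, "=="), outer(want, want, "=="))
    }
  }
})

test_that("size_filter keeps only objects within the voxel-count bounds", {
  mk <- function(n) structure(list(voxels = cbind(seq_len(n), 1L, 1L),
                                   weights = rep(1, n), channel = "p",
                                   mode = "locus", nucleus_id = 1L),
                              class = "detected_object")
  objs <- list(mk(1), mk(5), mk(500))
  out <- size_filter(objs, 2, 100)
  expect_length(out, 1)
  expect_equal(nrow(out[[1]]$voxels), 5)
  expect_equal(size_filter(objs, 1, Inf), objs)
  expect_length(size_filter(list(mk(1)), 2, 10), 0)
  expect_error(size_filter(objs, 5, 2))
})
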