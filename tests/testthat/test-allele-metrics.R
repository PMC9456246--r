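spacing <- c(400, 200, 200)

mk_obj <- function(vox, w, channel = "probe1", mode = "locus") {
  structure(list(voxels = vox, weights = w, channel = channel, mode = mode,
                 nucleus_id = 1L), class = "detected_object")
}

test_that("weighted_centroid is the brightness-weighted centre of mass in nm", {
  one <- mk_obj(cbind(z = 1L, y = 1L, x = 1L), 5)
  expect_equal(unname(weighted_centroid(one, spacing)$position), c(0, 0, 0))

  # two voxels at x-index 1 and 5 (dx = 200 nm would give 0 and 800);
  # use dx = 100 nm for the analytically forced case: (0*1 + 400*3)/4 = 300
  two <- mk_obj(cbind(z = c(1L, 1L), y = c(1L, 1L), x = c(1L, 5L)), c(1, 3))
  expect_equal(unname(weighted_centroid(two, c(400, 200, 100))$position[1]), 300)

  # uniform weights over a symmetric object -> geometric centre
  sym <- mk_obj(as.matrix(expand.grid(z = 1:3, y = 2:4, x = 5:7)), rep(1, 27))
  expect_equal(unname(weighted_centroid(sym, spacing)$position),
               c((6 - 1) * 200, (3 - 1) * 200, (2 - 1) * 400))

  expect_error(weighted_centroid(mk_obj(cbind(1L, 1L, 1L), 0), spacing),
               "weights")
})

test_that("pair_distance is a metric restriction on centroids", {
  expect_equal(pair_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(pair_distance(c(0, 0, 0), c(300, 400, 0)), 500)
  set.seed(3)
  for (i in 1:20) {
    a <- runif(3, 0, 5000); b <- runif(3, 0, 5000)
    expect_equal(pair_distance(a, b), sqrt(sum((a - b)^2)))  # recomputation
    expect_equal(pair_distance(a, b), pair_distance(b, a))
    expect_gte(pair_distance(a, b), 0)
  }
})

test_that("pair_loci pairs mutual nearest neighbours and keeps leftovers", {
  g <- rbind(c(0, 0, 0), c(10e3, 10e3, 10e3))
  r <- rbind(c(1e3, 0, 0), c(9e3, 10e3, 10e3))
  out <- pair_loci(g, r)
  expect_equal(out$pairs$green, 1:2)
  expect_equal(out$pairs$red, 1:2)
  expect_length(out$unpaired_green, 0)

  out2 <- pair_loci(rbind(c(0, 0, 0)), matrix(numeric(0), 0, 3))
  expect_equal(nrow(out2$pairs), 0)
  expect_equal(out2$unpaired_green, 1L)

  # greens at x = 0 and 3, reds at x = 1 and 10 -> (G1,R1), (G2,R2)
  g3 <- rbind(c(0, 0, 0), c(3, 0, 0))
  r3 <- rbind(c(1, 0, 0), c(10, 0, 0))
  out3 <- pair_loci(g3, r3)
  expect_equal(out3$pairs$green, 1:2)
  expect_equal(out3$pairs$red, 1:2)
  bf <- brute_min_matching(g3, r3)
  expect_equal(sum(out3$pairs$distance_nm), bf$total)
})

test_that("greedy pairing equals exhaustive matching on planted instances", {
  set.seed(11)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    # planted pairs much closer than inter-allele spacing
    centers <- matrix(runif(3 * k, 0, 2e4), k, 3)
    g <- centers + matrix(rnorm(3 * k, 0, 100), k, 3)
    r <- centers + matrix(rnorm(3 * k, 0, 100), k, 3)
    out <- pair_loci(g, r)
    bf <- brute_min_matching(g, r)
    expect_equal(sum(out$pairs$distance_nm), bf$total, tolerance = 1e-12)
    # symmetry in channel labels
    sw <- pair_loci(r, g)
    expect_equal(sw$pairs[order(sw$pairs$red), c("red", "green")],
                 out$pairs[order(out$pairs$green), c("green", "red")],
                 ignore_attr = TRUE)
    # partition: no locus reused
    expect_equal(sort(c(out$pairs$green, out$unpaired_green)), seq_len(k))
    expect_equal(sort(c(out$pairs$red, out$unpaired_red)), seq_len(k))
  }
})

test_that("signed territory distance matches the analytic sphere", {
  dims <- c(24, 40, 40)
  r_nm <- 2000
  center_vox <- c(12, 20, 20)
  terr <- make_sphere_territory(center_vox, r_nm, spacing, dims)
  center_nm <- c((center_vox[3] - 1) * 200, (center_vox[2] - 1) * 200,
                 (center_vox[1] - 1) * 400)
  diag_nm <- sqrt(sum(spacing^2))
  set.seed(5)
  for (i in 1:60) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2))
    # planted clearly off the surface (at least one voxel) on either side
    d_true <- sample(c(-1, 1), 1) * runif(1, 500, 1400)
    p <- center_nm + u * (r_nm + d_true)
    got <- signed_territory_distance(p, terr, spacing)
    expect_equal(sign(got), sign(d_true))
    expect_lt(abs(abs(got) - abs(d_true)), diag_nm)
  }
  # a territory voxel centre itself is inside (non-positive)
  vc <- breakfish:::zyx_to_nm(terr$voxels[1, , drop = FALSE],
                              c(dz = 400, dy = 200, dx = 200))
  expect_lte(signed_territory_distance(as.numeric(vc), terr, spacing), 0)
})

test_that("a single-voxel territory is measured against its surface", {
  terr <- mk_obj(cbind(z = 1L, y = 1L, x = 1L), 1, mode = "territory")
  d <- signed_territory_distance(c(600, 0, 0), terr, spacing)
  expect_gt(d, 0)                     # outside
  expect_lt(abs(d - 500), 200)        # ~600 nm to centre, 500 to the face
})

test_that("distance cutoff removes pairs beyond 2000 nm on any measure", {
  pairs <- data.frame(pair_distance_nm = c(2500, 1999, 800),
                      territory_dist1_nm = c(100, 300, 2100),
                      territory_dist2_nm = c(0, -150, -100))
  out <- apply_distance_cutoff(pairs)
  expect_equal(out$pair_distance_nm, 1999)           # only the clean pair kept
  expect_equal(nrow(attr(out, "removed")), 2)
  # boundary equality is retained (strict comparison)
  eq <- data.frame(pair_distance_nm = 2000,
                   territory_dist1_nm = -2000, territory_dist2_nm = 0)
  expect_equal(nrow(apply_distance_cutoff(eq)), 1)
})

test_that("cell QC applies the retention rules in order", {
  good_pairs <- data.frame(pair_distance_nm = c(400, 600),
                           territory_dist1_nm = c(-100, 50),
                           territory_dist2_nm = c(-20, 100))
  cell <- list(n_probe1 = 2L, n_probe2 = 2L, n_territories = 2L,
               pairs = good_pairs)
  expect_true(qc_cell(cell)$qc_pass)

  c2 <- cell; c2$n_probe1 <- 3L
  expect_false(qc_cell(c2)$qc_pass)
  expect_equal(qc_cell(c2)$qc_reason, "locus count")

  c3 <- cell; c3$n_territories <- 0L
  expect_equal(qc_cell(c3)$qc_reason, "territory count")
  c4 <- cell; c4$n_territories <- 3L
  expect_equal(qc_cell(c4)$qc_reason, "territory count")

  c5 <- cell; c5$pairs$pair_distance_nm[1] <- 2500
  expect_equal(qc_cell(c5)$qc_reason, "distance cutoff")
})
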