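#' Simulate a multi-channel break-apart FISH z-stack with known truth
#'
#' Emulates the geometry of a confocal break-apart FISH experiment:
#' nuclei rendered as bright cylinders (axis along z) in the counterstain
#' channel; each nucleus carries two alleles, each allele one spot per
#' probe channel (isotropic 3D Gaussian point-spread in physical nm); two
#' chromosome-territory blobs per nucleus in the paint channel. A
#' configurable fraction of alleles is planted broken: their two probe
#' spots are separated by the intact separation plus `broken_shift_nm`,
#' always beyond `break_distance_nm`; intact separations stay below it.
#' Gaussian background noise and isolated single-voxel speckles
#' (exercising the despeckle filter) are added last. The default grid is
#' a scaled-down field (256 x 256 x 20 voxels at 200/200/400 nm) so that
#' full detection runs stay fast; the full 1024 x 1024 geometry is
#' available through `dims`.
#'
#' @param n_nuclei number of nuclei (default 10).
#' @param dims grid size `(nz, ny, nx)` in voxels.
#' @param spacing voxel spacing `(dz, dy, dx)` nm.
#' @param nucleus_radius_nm,nucleus_value cylinder radius and counterstain
#'   brightness.
#' @param territory_radius_nm,territory_value territory ball radius and
#'   paint brightness (rendered, then blurred by one voxel).
#' @param spot_amplitude,spot_sigma_nm probe spot peak brightness and
#'   Gaussian point-spread sigma (nm, isotropic in physical units).
#' @param intact_mean_nm,intact_sd_nm normal model of the intact
#'   inter-probe separation (negative draws are resampled).
#' @param broken_fraction fraction of alleles planted broken in `[0, 1]`.
#' @param broken_shift_nm extra separation given to broken alleles.
#' @param break_distance_nm the generator's break-distance parameter:
#'   planted broken alleles separate beyond it, intact alleles stay below
#'   it (draws violating this are resampled).
#' @param outside_fraction fraction of alleles deliberately placed outside
#'   their territory (but inside the nucleus); recorded per locus in
#'   `planted_outside`.
#' @param noise `"moderate"` (default: background mean 100, sd 30, speckle
#'   rate 1e-4 at brightness 3000), `"none"`, or a list with elements
#'   `bg_mean`, `bg_sd`, `speckle_rate`, `speckle_value`.
#' @param nucleus_centers optional n x 2 matrix of `(x, y)` nm centres;
#'   centres closer than the sum of their radii are an error.
#' @param seed integer RNG seed; identical seeds give identical output.
#' @return A `fish_sim`: list with `channels` (named [voxel_stack()]s:
#'   `dapi`, `probe1`, `probe2`, `paint`) and `truth` (a `fish_truth`:
#'   data.frames `nuclei`, `territories`, `alleles`, `loci`).
#' @export
simulate_fish_stack <- function(n_nuclei = 10,
                                dims = c(nz = 20, ny = 256, nx = 256),
                                spacing = c(dz = 400, dy = 200, dx = 200),
                                nucleus_radius_nm = 4000,
                                nucleus_value = 1000,
                                territory_radius_nm = 1500,
                                territory_value = 800,
                                spot_amplitude = 3000,
                                spot_sigma_nm = 200,
                                intact_mean_nm = 400,
                                intact_sd_nm = 150,
                                broken_fraction = 0,
                                broken_shift_nm = 2000,
                                break_distance_nm = 1500,
                                outside_fraction = 0,
                                noise = "moderate",
                                nucleus_centers = NULL,
                                seed = 1) {
  stopifnot(broken_fraction >= 0, broken_fraction <= 1,
            outside_fraction >= 0, outside_fraction <= 1)
  dims <- as.integer(dims)
  sp <- as_spacing(spacing)
  nz <- dims[1]; ny <- dims[2]; nx <- dims[3]
  if (nucleus_radius_nm / min(sp[["dy"]], sp[["dx"]]) < 2 ||
      territory_radius_nm / min(sp[["dy"]], sp[["dx"]]) < 2)
    stop("radii must be at least 2 voxels after spacing conversion")
  set.seed(as.integer(seed))

  noise <- resolve_noise(noise)
  ext_x <- (nx - 1) * sp[["dx"]]
  ext_y <- (ny - 1) * sp[["dy"]]

  # --- nucleus layout -------------------------------------------------
  margin <- nucleus_radius_nm + 3 * max(sp[["dy"]], sp[["dx"]])
  if (is.null(nucleus_centers)) {
    nucleus_centers <- place_centers(n_nuclei, ext_x, ext_y, margin,
                                     min_sep = 2.2 * nucleus_radius_nm)
  } else {
    nucleus_centers <- as.matrix(nucleus_centers)
    stopifnot(nrow(nucleus_centers) == n_nuclei)
    if (n_nuclei > 1) {
      dd <- as.matrix(stats::dist(nucleus_centers))
      diag(dd) <- Inf
      if (any(dd < 2 * nucleus_radius_nm))
        stop("overlapping nuclei: centres closer than the sum of their radii")
    }
  }
  z_lo <- 4L
  z_hi <- nz - 3L
  if (z_hi - z_lo < 3L) stop("stack too shallow for the nucleus z-extent")
  z_lo_nm <- (z_lo - 1) * sp[["dz"]]
  z_hi_nm <- (z_hi - 1) * sp[["dz"]]
  cz_nm <- (z_lo_nm + z_hi_nm) / 2

  nuclei <- data.frame(nucleus = seq_len(n_nuclei),
                       cx_nm = nucleus_centers[, 1], cy_nm = nucleus_centers[, 2],
                       cz_nm = cz_nm, radius_nm = nucleus_radius_nm,
                       z_lo = z_lo, z_hi = z_hi,
                       z_lo_nm = z_lo_nm, z_hi_nm = z_hi_nm)

  # --- territories, alleles, loci ------------------------------------
  n_alleles <- 2L * n_nuclei
  broken <- rep(FALSE, n_alleles)
  n_broken <- stats::rbinom(1L, n_alleles, broken_fraction)
  if (n_broken > 0) broken[sample.int(n_alleles, n_broken)] <- TRUE

  territories <- NULL; alleles <- NULL; loci <- NULL
  allele_idx <- 0L
  for (i in seq_len(n_nuclei)) {
    tcs <- place_territory_pair(nucleus_centers[i, ],
                                0.55 * nucleus_radius_nm,
                                min_sep = 2.2 * territory_radius_nm)
    for (a in 1:2) {
      allele_idx <- allele_idx + 1L
      tc <- tcs[a, ]
      tz <- cz_nm + stats::runif(1, -1000, 1000)
      territories <- rbind(territories,
                           data.frame(nucleus = i, allele = a,
                                      cx_nm = tc[1], cy_nm = tc[2], cz_nm = tz,
                                      radius_nm = territory_radius_nm))
      # allele separation
      sep <- sample_separation(intact_mean_nm, intact_sd_nm,
                               broken[allele_idx], broken_shift_nm,
                               break_distance_nm)
      out_flag <- stats::runif(1) < outside_fraction
      pts <- place_allele(tc, tz, territory_radius_nm, sep, out_flag,
                          nucleus_centers[i, ], nucleus_radius_nm,
                          z_lo_nm, z_hi_nm)
      alleles <- rbind(alleles,
                       data.frame(nucleus = i, allele = a,
                                  broken = broken[allele_idx],
                                  separation_nm = sep))
      loci <- rbind(loci,
                    data.frame(nucleus = rep(i, 2), allele = rep(a, 2),
                               probe = 1:2,
                               x_nm = pts[, 1], y_nm = pts[, 2], z_nm = pts[, 3],
                               planted_outside = rep(out_flag, 2)))
    }
  }

  # --- rendering ------------------------------------------------------
  dapi <- array(0, dims); probe1 <- array(0, dims)
  probe2 <- array(0, dims); paint <- array(0, dims)
  for (i in seq_len(n_nuclei))
    dapi <- add_cylinder(dapi, sp, nucleus_centers[i, ], nucleus_radius_nm,
                         z_lo, z_hi, nucleus_value)
  for (k in seq_len(nrow(territories)))
    paint <- add_ball(paint, sp,
                      c(territories$cx_nm[k], territories$cy_nm[k], territories$cz_nm[k]),
                      territory_radius_nm, territory_value)
  paint <- gaussian_blur3d(paint, sigma = 1)
  for (k in seq_len(nrow(loci))) {
    p <- c(loci$x_nm[k], loci$y_nm[k], loci$z_nm[k])
    if (loci$probe[k] == 1L)
      probe1 <- add_gaussian_spot(probe1, sp, p, spot_amplitude, spot_sigma_nm)
    else
      probe2 <- add_gaussian_spot(probe2, sp, p, spot_amplitude, spot_sigma_nm)
  }

  channels <- list(dapi = dapi, probe1 = probe1, probe2 = probe2, paint = paint)
  if (noise$bg_sd > 0 || noise$bg_mean > 0 || noise$speckle_rate > 0) {
    nvox <- prod(dims)
    for (nm in names(channels)) {
      v <- channels[[nm]]
      if (noise$bg_mean > 0 || noise$bg_sd > 0)
        v <- v + pmax(stats::rnorm(nvox, noise$bg_mean, noise$bg_sd), 0)
      if (noise$speckle_rate > 0) {
        nspeck <- stats::rbinom(1L, nvox, noise$speckle_rate)
        if (nspeck > 0) {
          at <- sample.int(nvox, nspeck)
          v[at] <- v[at] + noise$speckle_value
        }
      }
      channels[[nm]] <- v
    }
  }
  channels <- Map(function(v, nm) voxel_stack(v, sp, nm), channels, names(channels))

  truth <- structure(list(nuclei = nuclei, territories = territories,
                          alleles = alleles, loci = loci,
                          params = list(seed = seed,
                                        break_distance_nm = break_distance_nm,
                                        broken_fraction = broken_fraction)),
                     class = "fish_truth")
  structure(list(channels = channels, truth = truth), class = "fish_sim")
}

resolve_noise <- function(noise) {
  if (is.character(noise)) {
    noise <- switch(noise,
                    none = list(bg_mean = 0, bg_sd = 0, speckle_rate = 0, speckle_value = 0),
                    moderate = list(bg_mean = 100, bg_sd = 30,
                                    speckle_rate = 1e-4, speckle_value = 3000),
                    stop("noise must be 'none', 'moderate' or a list"))
  }
  stopifnot(is.list(noise),
            all(c("bg_mean", "bg_sd", "speckle_rate", "speckle_value") %in% names(noise)))
  noise
}

place_centers <- function(n, ext_x, ext_y, margin, min_sep, max_tries = 5000) {
  centers <- matrix(numeric(0), 0, 2)
  tries <- 0
  while (nrow(centers) < n) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place nuclei without overlap; reduce n_nuclei or radius")
    cand <- c(stats::runif(1, margin, ext_x - margin),
              stats::runif(1, margin, ext_y - margin))
    if (nrow(centers) == 0 ||
        all(sqrt((centers[, 1] - cand[1])^2 + (centers[, 2] - cand[2])^2) >= min_sep))
      centers <- rbind(centers, cand)
  }
  unname(centers)
}

sample_in_disc <- function(center_xy, max_r) {
  theta <- stats::runif(1, 0, 2 * pi)
  r <- max_r * sqrt(stats::runif(1))
  center_xy + r * c(cos(theta), sin(theta))
}

# the two homologue territories occupy distinct sub-volumes; keep their
# centres at least min_sep apart so spots of different alleles cannot
# blend in the clean limit
place_territory_pair <- function(center_xy, max_r, min_sep, max_tries = 5000) {
  for (k in seq_len(max_tries)) {
    t1 <- sample_in_disc(center_xy, max_r)
    t2 <- sample_in_disc(center_xy, max_r)
    if (sqrt(sum((t2 - t1)^2)) >= min_sep) return(rbind(t1, t2))
  }
  stop("could not place two separated territories; radius too large for the nucleus")
}

sample_separation <- function(mean_nm, sd_nm, broken, shift_nm, break_distance_nm,
                              max_tries = 1000) {
  for (k in seq_len(max_tries)) {
    s <- stats::rnorm(1, mean_nm, sd_nm)
    if (s < 0) next
    if (broken) s <- s + shift_nm
    if (broken && s > break_distance_nm) return(s)
    if (!broken && s <= break_distance_nm) return(s)
  }
  stop("could not sample a separation consistent with break_distance_nm")
}

# place the two probe points of one allele; returns 2 x 3 matrix (x,y,z nm)
place_allele <- function(terr_xy, terr_z, terr_r, sep, outside,
                         nuc_xy, nuc_r, z_lo_nm, z_hi_nm, max_tries = 500) {
  zmargin <- 600
  xymargin <- 500
  inside_nucleus <- function(p) {
    sqrt((p[1] - nuc_xy[1])^2 + (p[2] - nuc_xy[2])^2) <= nuc_r - xymargin &&
      p[3] >= z_lo_nm + zmargin && p[3] <= z_hi_nm - zmargin
  }
  for (k in seq_len(max_tries)) {
    if (outside) {
      # midpoint outside the territory but inside the nucleus
      u <- random_unit3()
      mid <- c(terr_xy, terr_z) + u * stats::runif(1, terr_r + 400, terr_r + 1200)
    } else {
      u <- random_unit3()
      mid <- c(terr_xy, terr_z) + u * (0.4 * terr_r * stats::runif(1)^(1 / 3))
    }
    dirn <- random_unit3()
    dirn[3] <- dirn[3] * 0.3   # keep the pair near one focal plane band
    dirn <- dirn / sqrt(sum(dirn^2))
    p1 <- mid - dirn * sep / 2
    p2 <- mid + dirn * sep / 2
    if (inside_nucleus(p1) && inside_nucleus(p2))
      return(rbind(p1, p2))
  }
  stop("could not place locus inside its nucleus; separation too large for the geometry")
}

random_unit3 <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-9) return(v / n)
  }
}

add_cylinder <- function(v, sp, center_xy, radius_nm, z_lo, z_hi, value) {
  dims <- dim(v)
  cyv <- center_xy[2] / sp[["dy"]] + 1
  cxv <- center_xy[1] / sp[["dx"]] + 1
  ry <- radius_nm / sp[["dy"]]; rx <- radius_nm / sp[["dx"]]
  ys <- max(1, ceiling(cyv - ry)):min(dims[2], floor(cyv + ry))
  xs <- max(1, ceiling(cxv - rx)):min(dims[3], floor(cxv + rx))
  m <- outer(((ys - cyv) * sp[["dy"]])^2, ((xs - cxv) * sp[["dx"]])^2, "+") <= radius_nm^2
  for (z in z_lo:z_hi) {
    plane <- v[z, ys, xs]
    plane[m] <- plane[m] + value
    v[z, ys, xs] <- plane
  }
  v
}

add_ball <- function(v, sp, center_xyz, radius_nm, value) {
  dims <- dim(v)
  czv <- center_xyz[3] / sp[["dz"]] + 1
  cyv <- center_xyz[2] / sp[["dy"]] + 1
  cxv <- center_xyz[1] / sp[["dx"]] + 1
  zs <- max(1, ceiling(czv - radius_nm / sp[["dz"]])):min(dims[1], floor(czv + radius_nm / sp[["dz"]]))
  ys <- max(1, ceiling(cyv - radius_nm / sp[["dy"]])):min(dims[2], floor(cyv + radius_nm / sp[["dy"]]))
  xs <- max(1, ceiling(cxv - radius_nm / sp[["dx"]])):min(dims[3], floor(cxv + radius_nm / sp[["dx"]]))
  if (length(zs) == 0 || length(ys) == 0 || length(xs) == 0) return(v)
  d2yx <- outer(((ys - cyv) * sp[["dy"]])^2, ((xs - cxv) * sp[["dx"]])^2, "+")
  for (z in zs) {
    dz2 <- ((z - czv) * sp[["dz"]])^2
    m <- d2yx + dz2 <= radius_nm^2
    if (!any(m)) next
    plane <- v[z, ys, xs]
    plane[m] <- plane[m] + value
    v[z, ys, xs] <- plane
  }
  v
}

add_gaussian_spot <- function(v, sp, center_xyz, amplitude, sigma_nm) {
  dims <- dim(v)
  reach <- 3.5 * sigma_nm
  czv <- center_xyz[3] / sp[["dz"]] + 1
  cyv <- center_xyz[2] / sp[["dy"]] + 1
  cxv <- center_xyz[1] / sp[["dx"]] + 1
  zs <- max(1, floor(czv - reach / sp[["dz"]])):min(dims[1], ceiling(czv + reach / sp[["dz"]]))
  ys <- max(1, floor(cyv - reach / sp[["dy"]])):min(dims[2], ceiling(cyv + reach / sp[["dy"]]))
  xs <- max(1, floor(cxv - reach / sp[["dx"]])):min(dims[3], ceiling(cxv + reach / sp[["dx"]]))
  gz <- exp(-(((zs - czv) * sp[["dz"]])^2) / (2 * sigma_nm^2))
  gy <- exp(-(((ys - cyv) * sp[["dy"]])^2) / (2 * sigma_nm^2))
  gx <- exp(-(((xs - cxv) * sp[["dx"]])^2) / (2 * sigma_nm^2))
  spot <- amplitude * (gz %o% gy %o% gx)
  v[zs, ys, xs] <- v[zs, ys, xs] + spot
  v
}

#' Simulate a labelled cohort of allele pair distances
#'
#' Draws `n_alleles` inter-probe distances from a normal intact model,
#' with `round(broken_fraction * n_alleles)` of them shifted upwards by
#' `broken_shift_nm` and labelled broken. Negative draws are resampled
#' (distances are magnitudes). Labels are preserved so recovery of the
#' planted broken fraction can be checked downstream.
#'
#' @param n_alleles cohort size.
#' @param intact_mean_nm,intact_sd_nm intact separation model (nm).
#' @param broken_fraction fraction in `[0, 1]`.
#' @param broken_shift_nm shift added to broken alleles (nm).
#' @param seed RNG seed.
#' @return data.frame with columns `distance_nm` and `broken` (logical).
#' @export
simulate_distance_cohort <- function(n_alleles,
                                     intact_mean_nm = 400, intact_sd_nm = 150,
                                     broken_fraction = 0, broken_shift_nm = 1500,
                                     seed = 1) {
  stopifnot(broken_fraction >= 0, broken_fraction <= 1, n_alleles >= 1)
  set.seed(as.integer(seed))
  n_broken <- round(broken_fraction * n_alleles)
  broken <- rep(FALSE, n_alleles)
  if (n_broken > 0) broken[sample.int(n_alleles, n_broken)] <- TRUE
  d <- stats::rnorm(n_alleles, intact_mean_nm, intact_sd_nm)
  while (any(d < 0)) {
    neg <- d < 0
    d[neg] <- stats::rnorm(sum(neg), intact_mean_nm, intact_sd_nm)
  }
  d[broken] <- d[broken] + broken_shift_nm
  data.frame(distance_nm = d, broken = broken)
}

#' Write a simulated FISH field to disk
#'
#' One 16-bit multi-page TIFF per channel plus a JSON truth sidecar.
#'
#' @param sim a `fish_sim` from [simulate_fish_stack()].
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return Named vector of written paths, invisibly.
#' @export
write_fish_stack <- function(sim, dir, prefix = "field") {
  stopifnot(inherits(sim, "fish_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (nm in names(sim$channels)) {
    p <- file.path(dir, sprintf("%s_%s.tif", prefix, nm))
    write_stack_tiff(sim$channels[[nm]], p)
    paths[nm] <- p
  }
  tj <- file.path(dir, sprintf("%s_truth.json", prefix))
  jsonlite::write_json(lapply(sim$truth[c("nuclei", "territories", "alleles", "loci")],
                              as.data.frame),
                       tj, digits = NA, dataframe = "rows")
  paths["truth"] <- tj
  invisible(paths)
}
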