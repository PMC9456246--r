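#' Despeckle a stack with a 1 x 1 x 3 median filter along z
#'
#' Isolated single-voxel speckles (hot pixels, stray fluorophore granules)
#' are confined to one focal plane, whereas genuine signal extends over
#' neighbouring planes. Replacing each voxel by the median of itself and
#' its two z-neighbours therefore suppresses speckles while leaving
#' in-focus structure almost untouched. Edge planes use nearest-plane
#' replication.
#'
#' @param stack a [voxel_stack()] with at least 3 z-planes; smaller stacks
#'   are returned unchanged with a warning.
#' @return The filtered [voxel_stack()]. Output values are bounded by the
#'   input minimum and maximum (a median never extrapolates).
#' @export
despeckle <- function(stack) {
  stopifnot(inherits(stack, "voxel_stack"))
  v <- stack$values
  nz <- dim(v)[1]
  if (nz < 3L) {
    warning("despeckle: fewer than 3 z-planes, returning stack unchanged")
    return(stack)
  }
  out <- v
  for (z in seq_len(nz)) {
    a <- v[max(z - 1L, 1L), , ]
    b <- v[z, , ]
    cc <- v[min(z + 1L, nz), , ]
    # median of three without sorting
    out[z, , ] <- pmax(pmin(a, b), pmin(pmax(a, b), cc))
  }
  stack$values <- out
  stack
}

#' 3D Gaussian blur (separable)
#'
#' Isotropic Gaussian smoothing in voxel units, applied as three 1D
#' convolutions. Borders are handled by edge replication. Used before
#' nucleus seeding and before territory detection.
#'
#' @param values 3D array or [voxel_stack()].
#' @param sigma standard deviation in voxels (default 1).
#' @param radius kernel half-width in voxels (default `ceiling(3 * sigma)`).
#' @return Same type as the input (array in, array out).
#' @export
gaussian_blur3d <- function(values, sigma = 1, radius = ceiling(3 * sigma)) {
  is_stack <- inherits(values, "voxel_stack")
  v <- if (is_stack) values$values else values
  stopifnot(is.array(v), length(dim(v)) == 3L, sigma > 0)
  k <- stats::dnorm(seq(-radius, radius), sd = sigma)
  k <- k / sum(k)
  for (axis in 1:3) {
    n <- dim(v)[axis]
    acc <- array(0, dim(v))
    for (j in seq_along(k)) {
      off <- j - radius - 1L
      idx <- pmin(pmax(seq_len(n) + off, 1L), n)
      acc <- acc + k[j] * switch(axis,
                                 v[idx, , , drop = FALSE],
                                 v[, idx, , drop = FALSE],
                                 v[, , idx, drop = FALSE])
    }
    v <- acc
  }
  if (is_stack) {
    values$values <- v
    values
  } else v
}

# ---- cylinder geometry ------------------------------------------------

# Voxel (z,y,x) index matrix of all voxels inside a nucleus cylinder.
cylinder_voxels <- function(nucleus, dimv) {
  nz <- dimv[1]; ny <- dimv[2]; nx <- dimv[3]
  zs <- max(1L, nucleus$z_lo):min(nz, nucleus$z_hi)
  r <- nucleus$radius
  ys <- max(1L, ceiling(nucleus$center_y - r)):min(ny, floor(nucleus$center_y + r))
  xs <- max(1L, ceiling(nucleus$center_x - r)):min(nx, floor(nucleus$center_x + r))
  if (length(ys) == 0L || length(xs) == 0L)
    return(matrix(integer(0), 0, 3, dimnames = list(NULL, c("z", "y", "x"))))
  inside <- outer((ys - nucleus$center_y)^2, (xs - nucleus$center_x)^2, "+") <= r * r
  yy <- ys[row(inside)[inside]]
  xx <- xs[col(inside)[inside]]
  n_xy <- length(yy)
  cbind(z = rep(zs, each = n_xy),
        y = rep.int(yy, length(zs)),
        x = rep.int(xx, length(zs)))
}

# In-cylinder brightness objective: total brightness scaled by a volume
# penalty. Raw total brightness grows without bound with volume, so the
# fit maximises mean brightness x volume^beta (beta in (0,1); beta = 0.5
# default), i.e. S * V^(beta - 1).
cylinder_objective <- function(v, cy, cx, r, z_lo, z_hi, beta) {
  dimv <- dim(v)
  zs <- z_lo:z_hi
  ys <- max(1L, ceiling(cy - r)):min(dimv[2], floor(cy + r))
  xs <- max(1L, ceiling(cx - r)):min(dimv[3], floor(cx + r))
  if (length(ys) == 0L || length(xs) == 0L) return(-Inf)
  m <- outer((ys - cy)^2, (xs - cx)^2, "+") <= r * r
  vol <- sum(m) * length(zs)
  if (vol == 0) return(-Inf)
  sub <- v[zs, ys, xs, drop = FALSE]
  zplane <- colSums(sub)                    # sums over z -> (ys, xs)
  s <- sum(zplane[m])
  s * vol^(beta - 1)
}

#' Fit a cylindrical nucleus model by coordinate ascent
#'
#' Interphase nuclei flattened on a coverslip are well approximated by a
#' cylinder with its axis along the optical (z) axis. Starting from a seed
#' voxel, the fit maximises total in-cylinder brightness scaled by a
#' volume penalty (`mean brightness x volume^beta`) over the continuous
#' centre `(y, x)`, the radius, and the inclusive z-plane range, using
#' deterministic coordinate-wise finite-difference ascent with step
#' halving. No randomness is involved: identical inputs give identical
#' fits.
#'
#' @param stack [voxel_stack()] or 3D array (usually despeckled and
#'   Gaussian-blurred counterstain).
#' @param seed integer `(z, y, x)` voxel index with positive brightness
#'   (typically the global brightest voxel).
#' @param init_radius initial radius in voxels (default 10).
#' @param beta volume-penalty exponent in `(0, 1)`; 0.5 biases towards
#'   dense cylinders without collapsing to the seed voxel.
#' @param step_init initial step for the continuous parameters, voxels.
#' @param tol stop when the continuous step falls below this (voxels).
#' @param max_iter maximum number of ascent sweeps.
#' @param min_radius smallest admissible radius (voxels); a seed on an
#'   isolated bright voxel degenerates to this floor and is later removed
#'   by the size filter.
#' @return A `nucleus_model`: list with `center_y`, `center_x` (continuous
#'   voxel coordinates), `radius` (voxels), `z_lo`, `z_hi` (inclusive
#'   planes), `n_voxels`, `total_brightness`, `objective`, and `unstable`
#'   (`TRUE` when the objective surface is locally flat, e.g. on a uniform
#'   image).
#' @export
fit_cylinder <- function(stack, seed, init_radius = 10, beta = 0.5,
                         step_init = 2, tol = 1e-3, max_iter = 200,
                         min_radius = 1) {
  v <- if (inherits(stack, "voxel_stack")) stack$values else stack
  if (any(!is.finite(v))) stop("fit_cylinder: non-finite values in image")
  dimv <- dim(v)
  seed <- as.integer(seed)
  stopifnot(length(seed) == 3L, all(seed >= 1L), all(seed <= dimv))
  if (v[seed[1], seed[2], seed[3]] <= 0)
    stop("fit_cylinder: seed brightness must be positive")

  cy <- as.numeric(seed[2]); cx <- as.numeric(seed[3])
  r <- min(init_radius, max(dimv[2], dimv[3]))
  z_lo <- 1L; z_hi <- dimv[1]
  cur <- cylinder_objective(v, cy, cx, r, z_lo, z_hi, beta)
  step <- step_init
  eps <- 1e-12

  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (par in c("cy", "cx", "r")) {
      for (dir in c(1, -1)) {
        cand <- list(cy = cy, cx = cx, r = r)
        cand[[par]] <- cand[[par]] + dir * step
        if (cand$r < min_radius) next
        if (cand$cy < 1 || cand$cy > dimv[2] || cand$cx < 1 || cand$cx > dimv[3]) next
        val <- cylinder_objective(v, cand$cy, cand$cx, cand$r, z_lo, z_hi, beta)
        if (val > cur + eps) {
          cy <- cand$cy; cx <- cand$cx; r <- cand$r
          cur <- val; improved <- TRUE
          break
        }
      }
    }
    for (mv in list(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))) {
      nlo <- z_lo + mv[1]; nhi <- z_hi + mv[2]
      if (nlo < 1L || nhi > dimv[1] || nlo > nhi) next
      val <- cylinder_objective(v, cy, cx, r, nlo, nhi, beta)
      if (val > cur + eps) {
        z_lo <- nlo; z_hi <- nhi
        cur <- val; improved <- TRUE
      }
    }
    if (!improved) {
      step <- step / 2
      if (step < tol) break
    }
  }

  # flatness probe: a uniform image gives equal objective under small moves
  probe <- max(tol, 0.5)
  flat <- all(vapply(list(c(probe, 0), c(-probe, 0), c(0, probe), c(0, -probe)),
                     function(d) {
                       ncy <- cy + d[1]; ncx <- cx + d[2]
                       if (ncy < 1 || ncy > dimv[2] || ncx < 1 || ncx > dimv[3]) return(TRUE)
                       abs(cylinder_objective(v, ncy, ncx, r, z_lo, z_hi, beta) - cur) <=
                         1e-9 * max(1, abs(cur))
                     }, logical(1)))

  model <- list(center_y = cy, center_x = cx, radius = r,
                z_lo = z_lo, z_hi = z_hi, objective = cur,
                unstable = flat)
  vox <- cylinder_voxels(model, dimv)
  model$n_voxels <- nrow(vox)
  model$total_brightness <- sum(v[zyx_to_linear(vox, dimv)])
  class(model) <- "nucleus_model"
  model
}

#' @export
print.nucleus_model <- function(x, ...) {
  cat(sprintf("<nucleus_model> centre (y=%.2f, x=%.2f) r=%.2f vox, z %d..%d, %d voxels%s\n",
              x$center_y, x$center_x, x$radius, x$z_lo, x$z_hi, x$n_voxels,
              if (isTRUE(x$unstable)) " [unstable]" else ""))
  invisible(x)
}

#' Detect nuclei by iterative cylinder fitting
#'
#' The counterstain channel is Gaussian-blurred (sigma = 1 voxel); the
#' global brightest voxel seeds a cylinder fit; the fitted cylinder is
#' zeroed out of the working image and the process repeats from the next
#' brightest voxel until the seed brightness drops below `stop_frac` of
#' the initial global maximum. Fits outside the voxel-count thresholds are
#' discarded. Each iteration zeroes at least the seed voxel, so the loop
#' always terminates.
#'
#' @param stack despeckled counterstain [voxel_stack()].
#' @param min_vox,max_vox voxel-count retention thresholds for a nucleus.
#' @param stop_frac stop when the next seed is dimmer than this fraction
#'   of the initial global maximum (default 0.3).
#' @param max_seeds hard cap on fit iterations (safety; default 200).
#' @param clear_margin extra radius (voxels) zeroed around a removed
#'   nucleus so its Gaussian-blur halo cannot re-seed a duplicate fit
#'   (default 4, the blur kernel reach plus one).
#' @param ... passed to [fit_cylinder()].
#' @return List of `nucleus_model`s, each with a `nucleus_id` field, in
#'   detection (brightness) order. An all-zero stack yields an empty list.
#' @export
detect_nuclei <- function(stack, min_vox = 1000, max_vox = 1e6,
                          stop_frac = 0.3, max_seeds = 200, clear_margin = 4, ...) {
  stopifnot(inherits(stack, "voxel_stack"))
  blur <- gaussian_blur3d(stack$values, sigma = 1)
  init_max <- max(blur)
  if (init_max <= 0) return(list())
  dimv <- dim(blur)
  work <- blur
  out <- list()
  for (i in seq_len(max_seeds)) {
    peak <- which.max(work)
    m <- work[peak]
    if (m <= 0 || m < stop_frac * init_max) break
    seed <- arrayInd(peak, dimv)[1, ]
    fit <- fit_cylinder(work, seed, ...)
    vox <- cylinder_voxels(fit, dimv)
    halo <- cylinder_voxels(list(center_y = fit$center_y, center_x = fit$center_x,
                                 radius = fit$radius + clear_margin,
                                 z_lo = fit$z_lo - 1L, z_hi = fit$z_hi + 1L),
                            dimv)
    if (nrow(halo) > 0) work[zyx_to_linear(halo, dimv)] <- 0
    work[peak] <- 0  # guarantees strict progress even for degenerate fits
    fit$total_brightness <- if (nrow(vox) > 0)
      sum(stack$values[zyx_to_linear(vox, dimv)]) else 0
    # unstable fits arise on locally flat brightness (pure background);
    # they are not nuclei and would otherwise swallow the field
    if (!fit$unstable && fit$n_voxels >= min_vox && fit$n_voxels <= max_vox) {
      fit$nucleus_id <- length(out) + 1L
      out[[length(out) + 1L]] <- fit
    }
  }
  out
}

# ---- connected components --------------------------------------------

neighbor_offsets <- function(connectivity = 26) {
  g <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# Label connected components among a set of (z,y,x) voxels. Returns an
# integer component label per row, in order of first (lexicographic)
# encounter. Uses a dense integer lookup over the full grid for O(1)
# neighbour membership.
connected_components <- function(zyx, connectivity, dimv) {
  n <- nrow(zyx)
  if (n == 0L) return(integer(0))
  offs <- neighbor_offsets(connectivity)
  lin <- zyx_to_linear(zyx, dimv)
  lut <- integer(prod(dimv))
  lut[lin] <- seq_len(n)
  comp <- integer(n)
  ncomp <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    ncomp <- ncomp + 1L
    comp[s] <- ncomp
    queue <- s
    head <- 1L
    while (head <= length(queue)) {
      i <- queue[head]; head <- head + 1L
      nz <- zyx[i, 1] + offs[, 1]
      ny <- zyx[i, 2] + offs[, 2]
      nx <- zyx[i, 3] + offs[, 3]
      ok <- nz >= 1L & nz <= dimv[1] & ny >= 1L & ny <= dimv[2] & nx >= 1L & nx <= dimv[3]
      if (!any(ok)) next
      j <- lut[nz[ok] + (ny[ok] - 1L) * dimv[1] + (nx[ok] - 1L) * dimv[1] * dimv[2]]
      j <- j[j > 0L]
      j <- j[comp[j] == 0L]
      if (length(j)) {
        comp[j] <- ncomp
        queue <- c(queue, j)
      }
    }
  }
  comp
}

#' Detect loci or chromosome territories inside a nucleus
#'
#' Restricts the channel to the voxels inside the nucleus cylinder,
#' selects the `top_k` brightest (ties broken by lexicographic `(z,y,x)`
#' order for reproducibility), and returns the connected components of the
#' selection. Territory mode first applies a 3D Gaussian blur
#' (sigma = 1 voxel) to the channel, because a paint probe labels a
#' diffuse sub-volume rather than a point source. Zero-brightness voxels
#' carry no signal and are never selected.
#'
#' @param stack the probe or paint [voxel_stack()] (despeckled).
#' @param nucleus a `nucleus_model` from [detect_nuclei()].
#' @param mode `"locus"` or `"territory"`.
#' @param top_k number of brightest in-nucleus voxels to select
#'   (defaults: 300 for loci, 3000 for territories). If `top_k` exceeds
#'   the in-nucleus voxel count, all are used with a warning.
#' @param connectivity 6, 18 or 26 (default 26).
#' @return List of `detected_object`s: each a list with `voxels`
#'   (n x 3 `(z,y,x)` matrix), `weights` (brightness of each voxel in the
#'   image the selection was made on), `channel`, `mode`, `nucleus_id`.
#' @export
detect_objects <- function(stack, nucleus, mode = c("locus", "territory"),
                           top_k = NULL, connectivity = 26) {
  stopifnot(inherits(stack, "voxel_stack"), inherits(nucleus, "nucleus_model"))
  mode <- match.arg(mode)
  if (is.null(top_k)) top_k <- if (mode == "locus") 300L else 3000L
  if (top_k <= 0) return(list())
  v <- if (mode == "territory") gaussian_blur3d(stack$values, sigma = 1) else stack$values
  dimv <- dim(v)
  vox <- cylinder_voxels(nucleus, dimv)
  if (nrow(vox) == 0L) stop("detect_objects: nucleus volume is empty within channel bounds")
  if (top_k > nrow(vox)) {
    warning(sprintf("top_k (%d) exceeds in-nucleus voxel count (%d); using all",
                    top_k, nrow(vox)))
    top_k <- nrow(vox)
  }
  b <- v[zyx_to_linear(vox, dimv)]
  ord <- order(-b, vox[, 1], vox[, 2], vox[, 3])[seq_len(top_k)]
  sel <- vox[ord, , drop = FALSE]
  w <- b[ord]
  keep <- w > 0
  sel <- sel[keep, , drop = FALSE]
  w <- w[keep]
  if (nrow(sel) == 0L) return(list())
  comp <- connected_components(sel, connectivity, dimv)
  lapply(seq_len(max(comp)), function(k) {
    idx <- comp == k
    structure(list(voxels = sel[idx, , drop = FALSE],
                   weights = w[idx],
                   channel = stack$channel,
                   mode = mode,
                   nucleus_id = nucleus$nucleus_id %||% NA_integer_),
              class = "detected_object")
  })
}

#' Filter detected objects by voxel count
#'
#' Removes objects whose voxel count falls outside `[min_vox, max_vox]`,
#' preserving input order. Detection noise produces tiny components and
#' saturated regions produce huge ones; both are implausible for their
#' object class.
#'
#' @param objects list of `detected_object`s.
#' @param min_vox,max_vox inclusive voxel-count bounds
#'   (`min_vox <= max_vox`).
#' @return The surviving sub-list.
#' @export
size_filter <- function(objects, min_vox = 1, max_vox = Inf) {
  stopifnot(min_vox <= max_vox)
  Filter(function(o) {
    n <- nrow(o$voxels)
    n >= min_vox && n <= max_vox
  }, objects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
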