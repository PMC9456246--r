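#' Brightness-weighted centroid of a detected object
#'
#' A locus is reduced to a single point: the centre of mass of its voxels
#' with voxel brightness as the weight, converted to physical nm with the
#' per-axis spacing.
#'
#' @param object a `detected_object` from [detect_objects()].
#' @param spacing voxel spacing `(dz, dy, dx)` in nm.
#' @return A `locus_point`: list with `position` (named `x`, `y`, `z`, in
#'   nm), `channel`, `n_voxels`, `total_weight`.
#' @export
weighted_centroid <- function(object, spacing) {
  stopifnot(inherits(object, "detected_object"), nrow(object$voxels) >= 1)
  w <- object$weights
  if (all(w == 0)) stop("weighted_centroid: all weights are zero")
  nm <- zyx_to_nm(object$voxels, as_spacing(spacing))
  pos <- colSums(nm * w) / sum(w)
  structure(list(position = pos, channel = object$channel,
                 n_voxels = nrow(object$voxels), total_weight = sum(w)),
            class = "locus_point")
}

as_spacing <- function(spacing) {
  if (!is.null(names(spacing)) && all(c("dz", "dy", "dx") %in% names(spacing)))
    return(spacing[c("dz", "dy", "dx")])
  spacing <- as.numeric(spacing)
  c(dz = spacing[1], dy = spacing[2], dx = spacing[3])
}

locus_positions <- function(points) {
  if (length(points) == 0L)
    return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z"))))
  t(vapply(points, function(p) {
    if (inherits(p, "locus_point")) p$position else as.numeric(p)
  }, numeric(3)))
}

#' Euclidean distance between two locus points, nm
#'
#' @param a,b `locus_point`s or numeric `(x, y, z)` nm vectors.
#' @return Non-negative distance in nm.
#' @export
pair_distance <- function(a, b) {
  pa <- if (inherits(a, "locus_point")) a$position else as.numeric(a)
  pb <- if (inherits(b, "locus_point")) b$position else as.numeric(b)
  sqrt(sum((pa - pb)^2))
}

#' Pair two-colour locus signals by mutual nearest neighbours
#'
#' In a break-apart assay each allele carries one signal in each probe
#' channel; the two cross-channel signals that are closest to each other
#' form a pair, and a valid pair must be mutually nearest (if green G1 is
#' nearest to red R1, then R1 is nearest to G1). This is implemented as
#' greedy extraction: repeatedly take the globally closest remaining
#' cross-channel pair and remove both members. Every extracted pair is
#' mutually nearest among the points remaining at the time of extraction.
#' Distance ties are broken by index order (first green, then red), so the
#' result is deterministic.
#'
#' @param greens,reds lists of `locus_point`s (or n x 3 matrices of
#'   `(x, y, z)` nm positions) for the two probe channels.
#' @return List with `pairs` (data.frame: `green`, `red` indices,
#'   `distance_nm`) and `unpaired_green`, `unpaired_red` (leftover
#'   indices). Pairs and leftovers partition the inputs.
#' @export
pair_loci <- function(greens, reds) {
  pg <- if (is.matrix(greens)) greens else locus_positions(greens)
  pr <- if (is.matrix(reds)) reds else locus_positions(reds)
  ng <- nrow(pg); nr <- nrow(pr)
  pairs <- data.frame(green = integer(0), red = integer(0), distance_nm = numeric(0))
  if (ng == 0L || nr == 0L)
    return(list(pairs = pairs, unpaired_green = seq_len(ng), unpaired_red = seq_len(nr)))
  d <- matrix(0, ng, nr)
  for (j in seq_len(nr)) d[, j] <- sqrt(colSums((t(pg) - pr[j, ])^2))
  for (k in seq_len(min(ng, nr))) {
    best <- which.min(d)  # first minimum in column-major order: ties -> lowest (green, red)
    if (!is.finite(d[best])) break
    gi <- (best - 1L) %% ng + 1L
    ri <- (best - 1L) %/% ng + 1L
    pairs <- rbind(pairs, data.frame(green = gi, red = ri, distance_nm = d[best]))
    d[gi, ] <- Inf
    d[, ri] <- Inf
  }
  list(pairs = pairs,
       unpaired_green = setdiff(seq_len(ng), pairs$green),
       unpaired_red = setdiff(seq_len(nr), pairs$red))
}

#' Boundary voxels of a detected object
#'
#' A voxel belongs to the boundary when at least one of its neighbours
#' (26-connectivity by default) is not part of the object; voxels at the
#' grid edge count as boundary. The territory surface used for signed
#' distances is built from these voxels.
#'
#' @param object a `detected_object`.
#' @param connectivity 6, 18 or 26.
#' @return Matrix of `(z, y, x)` indices (possibly 0 rows).
#' @export
boundary_voxels <- function(object, connectivity = 26) {
  vox <- object$voxels
  n <- nrow(vox)
  if (n == 0L) return(vox)
  offs <- neighbor_offsets(connectivity)
  keys <- voxel_key(vox)
  is_boundary <- logical(n)
  for (k in seq_len(nrow(offs))) {
    nb <- voxel_key(cbind(vox[, 1] + offs[k, 1], vox[, 2] + offs[k, 2], vox[, 3] + offs[k, 3]))
    is_boundary <- is_boundary | !(nb %in% keys)
    if (all(is_boundary)) break
  }
  vox[is_boundary, , drop = FALSE]
}

# collision-free key for (z,y,x) indices up to 2^17 per axis
voxel_key <- function(zyx) {
  (zyx[, 1] * 2^17 + zyx[, 2]) * 2^17 + zyx[, 3]
}

# territory surface sampled at boundary-face midpoints: halfway between
# each object voxel and each outside 6-neighbour; (x, y, z) nm matrix
boundary_surface_points <- function(object, sp) {
  vox <- object$voxels
  keys <- voxel_key(vox)
  faces <- list(c(1L, 0L, 0L), c(-1L, 0L, 0L), c(0L, 1L, 0L),
                c(0L, -1L, 0L), c(0L, 0L, 1L), c(0L, 0L, -1L))
  out <- vector("list", length(faces))
  for (k in seq_along(faces)) {
    off <- faces[[k]]
    nb <- cbind(vox[, 1] + off[1], vox[, 2] + off[2], vox[, 3] + off[3])
    open_face <- !(voxel_key(nb) %in% keys)
    if (!any(open_face)) next
    v <- vox[open_face, , drop = FALSE]
    out[[k]] <- cbind(x = (v[, 3] - 1 + off[3] / 2) * sp[["dx"]],
                      y = (v[, 2] - 1 + off[2] / 2) * sp[["dy"]],
                      z = (v[, 1] - 1 + off[1] / 2) * sp[["dz"]])
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- matrix(numeric(0), 0, 3, dimnames = list(NULL, c("x", "y", "z")))
  res
}

#' Signed distance from a locus point to a chromosome territory
#'
#' The distance from the locus point to the plane through the three
#' territory surface points nearest to it (in physical nm), signed by
#' position: positive when the locus lies outside the territory, negative
#' when inside. The territory surface is sampled at boundary-face
#' midpoints — halfway between each object voxel and an outside
#' face-neighbour — which centres the discretisation error on the true
#' surface (voxel centres sit systematically inside it, by up to a full
#' z-step in anisotropic stacks). Inside/outside is decided by voxel
#' membership of the grid voxel nearest to the point, which stays
#' correct for concave territories where plane orientation would not.
#' The plane is a local tangent refinement: when the triple is
#' collinear, not a compact patch, or falls more than half a voxel
#' diagonal below the nearest-sample bound (a tilted plane through a
#' near-degenerate triple cannot be the local tangent), the estimate
#' falls back to the nearest-surface-point distance. Territories too
#' small to expose three surface points use the nearest-point distance
#' with a warning.
#'
#' @param point a `locus_point` or `(x, y, z)` nm vector.
#' @param territory a `detected_object` in territory mode.
#' @param spacing voxel spacing `(dz, dy, dx)` in nm.
#' @param connectivity connectivity used for the boundary (default 26).
#' @return Signed distance in nm.
#' @export
signed_territory_distance <- function(point, territory, spacing, connectivity = 26) {
  stopifnot(inherits(territory, "detected_object"), nrow(territory$voxels) >= 1)
  sp <- as_spacing(spacing)
  p <- if (inherits(point, "locus_point")) point$position else as.numeric(point)

  # inside/outside by membership of the nearest grid voxel
  idx <- c(round(p[3] / sp[["dz"]]) + 1,   # z
           round(p[2] / sp[["dy"]]) + 1,   # y
           round(p[1] / sp[["dx"]]) + 1)   # x
  inside <- voxel_key(matrix(idx, 1)) %in% voxel_key(territory$voxels)
  sgn <- if (inside) -1 else 1

  bnm <- boundary_surface_points(territory, sp)
  if (nrow(bnm) < 3L) {
    warning("signed_territory_distance: fewer than 3 surface points; using nearest-point distance")
    if (nrow(bnm) == 0L) bnm <- zyx_to_nm(territory$voxels, sp)
    return(unname(sgn * sqrt(min(rowSums((bnm - rep(p, each = nrow(bnm)))^2)))))
  }
  d2 <- (bnm[, 1] - p[1])^2 + (bnm[, 2] - p[2])^2 + (bnm[, 3] - p[3])^2
  ord <- order(d2, bnm[, 3], bnm[, 2], bnm[, 1])
  nearest <- sqrt(d2[ord[1]])
  a <- bnm[ord[1], ]; b <- bnm[ord[2], ]; cc <- bnm[ord[3], ]
  u <- b - a; w <- cc - a
  nrm <- c(u[2] * w[3] - u[3] * w[2],
           u[3] * w[1] - u[1] * w[3],
           u[1] * w[2] - u[2] * w[1])
  nlen <- sqrt(sum(nrm^2))
  diag_nm <- sqrt(sum(sp^2))
  # the plane is trusted as the local tangent only when the triple is a
  # compact surface patch (points within two voxel diagonals of each
  # other), is not collinear, and does not fall far below the
  # nearest-sample bound; otherwise the nearest boundary voxel bounds
  # the error by about one voxel diagonal
  compact <- max(sum((b - a)^2), sum((cc - a)^2), sum((cc - b)^2)) <= (2 * diag_nm)^2
  dist <- if (nlen < 1e-9 || !compact) nearest else abs(sum((p - a) * nrm)) / nlen
  if (nearest - dist > diag_nm / 2) dist <- nearest
  unname(sgn * dist)
}

#' Remove allele pairs beyond the distance cutoff
#'
#' Pairs whose inter-signal distance, or whose absolute locus-to-territory
#' distance on either locus, exceeds the cutoff are treated as detection
#' errors and removed (strictly greater than the cutoff; equality is
#' retained). Missing territory distances (`NA`) do not trigger removal.
#'
#' @param pairs data.frame with columns `pair_distance_nm`,
#'   `territory_dist1_nm`, `territory_dist2_nm` (the latter two optional).
#' @param cutoff_nm removal cutoff, default 2000 nm.
#' @return The retained rows; the removed rows are attached as
#'   `attr(, "removed")`.
#' @export
apply_distance_cutoff <- function(pairs, cutoff_nm = 2000) {
  if (nrow(pairs) == 0L) {
    attr(pairs, "removed") <- pairs
    return(pairs)
  }
  bad <- pairs$pair_distance_nm > cutoff_nm
  for (col in c("territory_dist1_nm", "territory_dist2_nm")) {
    if (col %in% names(pairs)) {
      v <- abs(pairs[[col]])
      bad <- bad | (!is.na(v) & v > cutoff_nm)
    }
  }
  out <- pairs[!bad, , drop = FALSE]
  attr(out, "removed") <- pairs[bad, , drop = FALSE]
  out
}

#' Cell-level quality control
#'
#' A cell is retained only when its detection output is unambiguous:
#' exactly two objects in each probe channel (one per allele), one or two
#' chromosome territories (two homologues that may merge into one), and
#' both allele pairs within the distance cutoff. `qc_reason` records the
#' first failing rule (`"locus count"`, `"territory count"`,
#' `"distance cutoff"`).
#'
#' @param cell a list (class `cell_record` applied on return) with
#'   elements `n_probe1`, `n_probe2`, `n_territories` and `pairs` (a
#'   data.frame as in [apply_distance_cutoff()]).
#' @param cutoff_nm distance cutoff in nm (default 2000).
#' @param max_territories maximum territory count (default 2).
#' @return The cell with `qc_pass` (logical) and `qc_reason` (character)
#'   set.
#' @export
qc_cell <- function(cell, cutoff_nm = 2000, max_territories = 2) {
  fail <- function(reason) {
    cell$qc_pass <- FALSE
    cell$qc_reason <- reason
    class(cell) <- "cell_record"
    cell
  }
  if (cell$n_probe1 != 2L || cell$n_probe2 != 2L) return(fail("locus count"))
  if (cell$n_territories < 1L || cell$n_territories > max_territories)
    return(fail("territory count"))
  kept <- apply_distance_cutoff(cell$pairs, cutoff_nm)
  if (nrow(cell$pairs) != 2L || nrow(kept) != 2L) return(fail("distance cutoff"))
  cell$qc_pass <- TRUE
  cell$qc_reason <- ""
  class(cell) <- "cell_record"
  cell
}
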