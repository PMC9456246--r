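# Independent oracles used across test files. These deliberately use
# naive algorithms (flood fill, exhaustive matching, double loops) so
# they share no code path with the implementation they check.

# brute-force flood fill over a set of (z,y,x) voxels
brute_components <- function(zyx, connectivity) {
  n <- nrow(zyx)
  adj <- function(a, b) {
    d <- abs(zyx[a, ] - zyx[b, ])
    if (max(d) > 1) return(FALSE)
    s <- sum(d)
    if (connectivity == 6) s == 1
    else if (connectivity == 18) s >= 1 && s <= 2
    else s >= 1
  }
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s]) next
    cur <- cur + 1L
    stack <- s
    comp[s] <- cur
    while (length(stack)) {
      i <- stack[1]; stack <- stack[-1]
      for (j in seq_len(n)) {
        if (!comp[j] && adj(i, j)) {
          comp[j] <- cur
          stack <- c(stack, j)
        }
      }
    }
  }
  comp
}

# exhaustive minimum-total-distance matching between two point sets
# (k = min(n, m) pairs); returns the minimal total distance
brute_min_matching <- function(pg, pr) {
  ng <- nrow(pg); nr <- nrow(pr)
  k <- min(ng, nr)
  d <- matrix(0, ng, nr)
  for (j in seq_len(nr)) d[, j] <- sqrt(colSums((t(pg) - pr[j, ])^2))
  best <- Inf
  best_pairs <- NULL
  gsets <- utils::combn(ng, k, simplify = FALSE)
  for (gs in gsets) {
    perms <- perm_all(seq_len(nr), k)
    for (pr_idx in perms) {
      tot <- sum(d[cbind(gs, pr_idx)])
      if (tot < best) {
        best <- tot
        best_pairs <- cbind(green = gs, red = pr_idx)
      }
    }
  }
  list(total = best, pairs = best_pairs)
}

perm_all <- function(v, k) {
  if (k == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_along(v))
    for (rest in perm_all(v[-i], k - 1))
      out[[length(out) + 1]] <- c(v[i], rest)
  out
}

# brute-force window profile: double loop over fragments x windows
brute_window_profile <- function(signals, window) {
  lens <- attr(signals, "chrom_lengths")
  rows <- NULL
  for (ci in names(lens)) {
    L <- lens[[ci]]
    nwin <- max(1, ceiling(L / window))
    for (w in seq_len(nwin)) {
      lo <- (w - 1) * window
      hi <- lo + window
      cnt <- 0
      for (i in seq_len(nrow(signals))) {
        if (signals$chrom[i] != ci || signals$raw[i] < 1) next
        mid <- (signals$start[i] + signals$end[i]) %/% 2
        if (mid >= lo && mid < hi) cnt <- cnt + 1
      }
      rows <- rbind(rows, data.frame(chrom = ci, start = lo,
                                     end = min(hi, L), value = cnt))
    }
  }
  rows
}

# voxelised spherical territory as a detected_object
make_sphere_territory <- function(center_vox, radius_nm, spacing, dims) {
  spacing <- unname(spacing)
  sp <- c(dz = spacing[1], dy = spacing[2], dx = spacing[3])
  grid <- expand.grid(z = seq_len(dims[1]), y = seq_len(dims[2]), x = seq_len(dims[3]))
  dz <- (grid$z - center_vox[1]) * sp[["dz"]]
  dy <- (grid$y - center_vox[2]) * sp[["dy"]]
  dx <- (grid$x - center_vox[3]) * sp[["dx"]]
  keep <- dz^2 + dy^2 + dx^2 <= radius_nm^2
  vox <- as.matrix(grid[keep, c("z", "y", "x")])
  colnames(vox) <- c("z", "y", "x")
  structure(list(voxels = vox, weights = rep(1, nrow(vox)),
                 channel = "paint", mode = "territory", nucleus_id = 1L),
            class = "detected_object")
}

# small noise-free image containing one indicator cylinder
make_cylinder_image <- function(dims, cy, cx, r, z_lo, z_hi, value = 100) {
  v <- array(0, dims)
  for (z in z_lo:z_hi)
    for (y in seq_len(dims[2]))
      for (x in seq_len(dims[3]))
        if ((y - cy)^2 + (x - cx)^2 <= r^2) v[z, y, x] <- value
  v
}
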