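#' Construct a voxel stack
#'
#' A `voxel_stack` is the substrate of all 3D detection: one channel's
#' brightness values on a regular grid, indexed `(z, y, x)`, together with
#' the physical voxel spacing in nanometres. Confocal stacks are strongly
#' anisotropic (the z step, set by the focal interval, is typically 2-4x
#' the xy pixel size), so every physical distance downstream is computed
#' with the per-axis spacing.
#'
#' @param values 3D numeric array of non-negative brightness values,
#'   dimension `(nz, ny, nx)`.
#' @param spacing numeric length-3, voxel spacing `(dz, dy, dx)` in nm;
#'   all strictly positive.
#' @param channel character label for the channel (e.g. `"dapi"`,
#'   `"probe1"`, `"paint"`).
#' @return An object of class `voxel_stack`: a list with elements
#'   `values`, `spacing` (named `dz`, `dy`, `dx`) and `channel`.
#' @examples
#' vs <- voxel_stack(array(0, c(5, 16, 16)), c(600, 200, 200), "dapi")
#' dim(vs)
#' @export
voxel_stack <- function(values, spacing, channel = "unnamed") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("`values` must be a 3D array indexed (z, y, x)")
  if (anyNA(values) || any(values < 0))
    stop("brightness values must be non-negative and non-missing")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be three strictly positive values (dz, dy, dx) in nm")
  structure(
    list(values = values,
         spacing = c(dz = spacing[1], dy = spacing[2], dx = spacing[3]),
         channel = as.character(channel)[1]),
    class = "voxel_stack"
  )
}

#' @export
dim.voxel_stack <- function(x) dim(x$values)

#' @export
print.voxel_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<voxel_stack '%s'> %d x %d x %d (z,y,x), spacing %g/%g/%g nm, range [%g, %g]\n",
              x$channel, d[1], d[2], d[3],
              x$spacing["dz"], x$spacing["dy"], x$spacing["dx"],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Write a voxel stack as a multi-page 16-bit TIFF
#'
#' One page per z-plane. Values are stored as 16-bit unsigned integers;
#' brightness above 65535 is clipped.
#'
#' @param stack a [voxel_stack()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stack_tiff <- function(stack, path) {
  v <- round(pmin(stack$values, 65535)) / 65535
  pages <- lapply(seq_len(dim(v)[1]), function(z) v[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-page TIFF as a voxel stack
#'
#' @param path TIFF file; each page is one z-plane.
#' @param spacing voxel spacing `(dz, dy, dx)` in nm (TIFF carries no
#'   reliable physical-spacing metadata; it must be supplied, usually from
#'   the run configuration).
#' @param channel channel label.
#' @return A [voxel_stack()] with 16-bit integer brightness restored.
#' @export
read_stack_tiff <- function(path, spacing, channel = "unnamed") {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (is.matrix(pages)) pages <- list(pages)
  nz <- length(pages)
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  v <- array(0, c(nz, ny, nx))
  for (z in seq_len(nz)) v[z, , ] <- round(pages[[z]] * 65535)
  voxel_stack(v, spacing, channel)
}

# Linear index (column-major over dim (nz,ny,nx)) for an n x 3 matrix of
# (z,y,x) voxel indices.
zyx_to_linear <- function(zyx, dimv) {
  zyx[, 1] + (zyx[, 2] - 1) * dimv[1] + (zyx[, 3] - 1) * dimv[1] * dimv[2]
}

# Physical coordinates (nm) of voxel centres; voxel (1,1,1) sits at the
# origin. Returns an n x 3 matrix with columns x, y, z.
zyx_to_nm <- function(zyx, spacing) {
  cbind(x = (zyx[, 3] - 1) * spacing[["dx"]],
        y = (zyx[, 2] - 1) * spacing[["dy"]],
        z = (zyx[, 1] - 1) * spacing[["dz"]])
}
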