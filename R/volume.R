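#' 3D scalar image volume
#'
#' The common currency of the pipeline: a 3D grid of scalar intensities with
#' an isotropic physical voxel size. Array axes are ordered (x, y, z) with x
#' varying fastest (R column-major, matching NIfTI on-disk layout); voxel
#' `(i, j, k)` has its centre at physical position
#' `((i-1), (j-1), (k-1)) * voxel_size` (0-based world origin at the first
#' voxel centre). World coordinates are in micrometres throughout.
#'
#' @param data numeric 3D array of finite intensities, axes (x, y, z).
#' @param voxel_size_nm isotropic voxel side length in nanometres (> 0).
#' @param provenance free-text note on where the volume came from.
#' @return an `image_volume` object.
#' @export
image_volume <- function(data, voxel_size_nm, provenance = "") {
  if (length(dim(data)) != 3L) stop("`data` must be a 3D array")
  if (!all(is.finite(data))) stop("`data` must contain only finite values")
  if (!is.numeric(voxel_size_nm) || length(voxel_size_nm) != 1L ||
      voxel_size_nm <= 0) {
    stop("`voxel_size_nm` must be a single positive number")
  }
  structure(list(data = data, voxel_size_nm = as.numeric(voxel_size_nm),
                 provenance = as.character(provenance)),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<image_volume> %d x %d x %d voxels @ %g nm (%.2f x %.2f x %.2f um)\n",
              d[1], d[2], d[3], x$voxel_size_nm,
              d[1] * nm_to_um(x$voxel_size_nm),
              d[2] * nm_to_um(x$voxel_size_nm),
              d[3] * nm_to_um(x$voxel_size_nm)))
  cat(sprintf("  intensity range [%.4g, %.4g]", min(x$data), max(x$data)))
  if (nzchar(x$provenance)) cat("  |", x$provenance)
  cat("\n")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Voxel size in micrometres
#' @param volume an `image_volume` (or anything with `$voxel_size_nm`).
#' @return scalar voxel size in um.
#' @export
voxel_size_um <- function(volume) nm_to_um(volume$voxel_size_nm)

block_mean_axis <- function(a, f, axis) {
  d <- dim(a)
  n <- d[axis]
  m <- n %/% f
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 2L, 1L))
  b <- if (axis == 1L) a else aperm(a, perm)
  db <- dim(b)
  b <- b[seq_len(m * f), , , drop = FALSE]
  dim(b) <- c(f, m * db[2] * db[3])
  out <- colMeans(b)
  dim(out) <- c(m, db[2], db[3])
  if (axis == 1L) out else aperm(out, perm)
}

#' Downsample a volume by block averaging
#'
#' Replaces each `factor^3` cube by its arithmetic mean and multiplies the
#' voxel size accordingly. If `factor` does not divide a grid dimension the
#' trailing remainder is cropped with a warning.
#'
#' @param volume an [image_volume()].
#' @param factor integer >= 1.
#' @return the downsampled `image_volume`.
#' @export
downsample_volume <- function(volume, factor) {
  stopifnot(inherits(volume, "image_volume"))
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1L) stop("`factor` must be an integer >= 1")
  if (factor == 1L) return(volume)
  d <- dim(volume$data)
  if (any(d %% factor != 0L)) {
    warning(sprintf("grid %s not divisible by %d; cropping remainder",
                    paste(d, collapse = "x"), factor))
  }
  if (any(d %/% factor < 1L)) stop("`factor` larger than the grid")
  a <- volume$data
  for (ax in 1:3) a <- block_mean_axis(a, factor, ax)
  image_volume(a, volume$voxel_size_nm * factor,
               provenance = paste0(volume$provenance,
                                   sprintf(" [downsampled x%d]", factor)))
}
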