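# Volume and streamline file I/O.
#
# Volumes: NIfTI (voxel size in the header, mm units, via RNifti) or
# multi-page TIFF stacks with a JSON sidecar manifest carrying the voxel size
# (TIFF has no spacing metadata) and the affine rescale applied for storage.
# Streamlines: TCK (binary track format with a text header; coordinates are
# written in um, stated in the header).

#' Read a 3D volume from NIfTI or TIFF
#'
#' NIfTI: the isotropic voxel size is taken from the header (mm, converted to
#' nm); anisotropic voxels are not supported. TIFF: a multi-page stack (pages
#' are z slices); the voxel size must come from a JSON sidecar manifest
#' `<file>.json` with at least `voxel_size_nm` (written by [write_volume()]).
#'
#' @param path file path (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return an [image_volume()].
#' @export
read_volume <- function(path) {
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::readNifti(path)
    pd <- RNifti::pixdim(img)[1:3]
    if (max(pd) - min(pd) > 1e-9 * max(pd)) {
      stop(sprintf("anisotropic voxels (%s mm) are not supported",
                   paste(signif(pd, 6), collapse = " x ")))
    }
    a <- array(as.numeric(img), dim(img)[1:3])
    image_volume(a, mm_to_nm(pd[1]), provenance = path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    manifest_path <- paste0(path, ".json")
    if (!file.exists(manifest_path)) {
      stop(sprintf(
        "TIFF carries no voxel size; provide a manifest at %s with {\"voxel_size_nm\": ...}",
        manifest_path))
    }
    man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
    if (is.null(man$voxel_size_nm)) {
      stop(sprintf("manifest %s lacks `voxel_size_nm`", manifest_path))
    }
    pages <- tiff::readTIFF(path, all = TRUE)
    d <- dim(pages[[1]])
    a <- array(0, c(d[2], d[1], length(pages)))   # pages are y (rows) x x (cols)
    for (k in seq_along(pages)) a[, , k] <- t(pages[[k]])
    scale <- man$intensity_scale %||% 1
    offset <- man$intensity_offset %||% 0
    image_volume(a * scale + offset, man$voxel_size_nm, provenance = path)
  } else {
    stop("unsupported volume format; use .nii[.gz] or .tif[f]")
  }
}

#' Write a 3D volume to NIfTI or TIFF
#'
#' NIfTI stores doubles with the voxel size in the header (mm). TIFF stores
#' 32-bit float pages rescaled to `[0, 1]`; the voxel size and the rescale
#' are recorded in a JSON sidecar manifest `<file>.json`, which
#' [read_volume()] uses to restore intensities (exact to float32 precision).
#'
#' @param volume an [image_volume()].
#' @param path destination (`.nii`, `.nii.gz`, `.tif`, `.tiff`).
#' @return the path, invisibly.
#' @export
write_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    img <- RNifti::asNifti(volume$data)
    RNifti::pixdim(img) <- rep(nm_to_mm(volume$voxel_size_nm), 3)
    RNifti::writeNifti(img, path)
  } else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    a <- volume$data
    r <- range(a)
    scale <- if (r[2] > r[1]) r[2] - r[1] else 1
    offset <- r[1]
    norm <- (a - offset) / scale
    pages <- lapply(seq_len(dim(a)[3]), function(k) t(norm[, , k]))
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    jsonlite::write_json(
      list(voxel_size_nm = volume$voxel_size_nm,
           intensity_scale = scale, intensity_offset = offset,
           axis_order = "x fastest; TIFF pages are z slices (rows y, cols x)",
           provenance = volume$provenance),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported volume format; use .nii[.gz] or .tif[f]")
  }
  invisible(path)
}

#' Write streamlines in TCK format
#'
#' MRtrix track format: a text header, then little-endian float32 point
#' triplets, streamlines separated by a NaN triplet and the stream terminated
#' by an Inf triplet. Coordinates are written as stored (um here; stated in
#' the header `units` field).
#'
#' @param streamlines a `streamline_set` or list of n x 3 matrices (um).
#' @param path destination `.tck` path.
#' @return the path, invisibly.
#' @export
write_streamlines <- function(streamlines, path) {
  if (inherits(streamlines, "streamline_set")) {
    streamlines <- streamlines$streamlines
  }
  header <- c("mrtrix tracks",
              "datatype: Float32LE",
              sprintf("count: %d", length(streamlines)),
              "units: um",
              sprintf("fibretensor_version: %s",
                      as.character(utils::packageVersion("fibretensor"))))
  # compute the data offset: header + "file: . OFFSET\nEND\n"
  base_len <- sum(nchar(header, type = "bytes")) + length(header)  # + newlines
  probe <- function(off) base_len + nchar(sprintf("file: . %d\n", off)) + 4L
  off <- base_len + 32L
  off <- probe(off)
  off <- probe(off)   # fixed point (offset digits stable at these sizes)
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(header, sprintf("file: . %d", off), "END"), con, sep = "\n")
  pad <- off - (base_len + nchar(sprintf("file: . %d\n", off)) + 4L)
  if (pad > 0) writeBin(raw(pad), con)
  for (s in streamlines) {
    writeBin(as.numeric(t(as.matrix(s))), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  invisible(path)
}

#' Read streamlines from a TCK file
#'
#' @param path `.tck` file path.
#' @return list of n x 3 point matrices (in the file's units).
#' @export
read_streamlines <- function(path) {
  raw_all <- readBin(path, "raw", n = file.size(path))
  # locate END of header
  txt_end <- NULL
  nl <- which(raw_all == as.raw(10L))
  prev <- 0L
  offset <- NULL
  for (i in nl) {
    line <- rawToChar(raw_all[(prev + 1L):(i - 1L)])
    if (prev == 0L && line != "mrtrix tracks") {
      stop(sprintf("malformed TCK header at byte 0: expected 'mrtrix tracks', got '%s'",
                   line))
    }
    if (grepl("^file: \\. ", line)) {
      offset <- as.integer(sub("^file: \\. ", "", line))
    }
    if (line == "END") { txt_end <- i; break }
    prev <- i
  }
  if (is.null(txt_end) || is.null(offset)) {
    stop(sprintf("malformed TCK header: no END/file field found within %d bytes",
                 length(raw_all)))
  }
  vals <- readBin(raw_all[(offset + 1L):length(raw_all)], "numeric",
                  n = (length(raw_all) - offset) / 4L, size = 4,
                  endian = "little")
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  is_nan <- rowSums(is.na(m) & !is.infinite(m)) > 0
  is_inf <- rowSums(is.infinite(m)) > 0
  out <- list()
  start <- 1L
  for (i in seq_len(nrow(m))) {
    if (is_nan[i] || is_inf[i]) {
      if (i > start) out[[length(out) + 1L]] <- m[start:(i - 1L), , drop = FALSE]
      start <- i + 1L
      if (is_inf[i]) break
    }
  }
  out
}
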