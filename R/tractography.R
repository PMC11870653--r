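# Deterministic FACT tractography on the structure-tensor principal-direction
# field: mask generation, seeding, voxel-face propagation and ROI filtering.

#' ROI mask
#'
#' @param mask logical 3D array.
#' @param voxel_size_nm voxel size in nm.
#' @param label free text (`"seed"`, `"inclusion"`, `"rejection"`,
#'   `"tracking"`, `"exclusion"`, ...).
#' @return an `roi_mask`.
#' @export
roi_mask <- function(mask, voxel_size_nm, label = "") {
  if (length(dim(mask)) != 3L) stop("`mask` must be a 3D array")
  structure(list(mask = mask & TRUE, voxel_size_nm = voxel_size_nm,
                 label = as.character(label)),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat(sprintf("<roi_mask> '%s': %d / %d voxels (%.1f%%)\n", x$label,
              sum(x$mask), length(x$mask), 100 * mean(x$mask)))
  invisible(x)
}

#' Axis-aligned box mask
#'
#' @param grid_shape integer 3-vector.
#' @param lo,hi inclusive 1-based voxel corners.
#' @param voxel_size_nm voxel size in nm.
#' @param label mask label.
#' @return an `roi_mask`.
#' @export
box_mask <- function(grid_shape, lo, hi, voxel_size_nm, label = "box") {
  m <- array(FALSE, grid_shape)
  m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  roi_mask(m, voxel_size_nm, label)
}

# Otsu threshold of a numeric array: maximise the between-class variance
# over a 256-bin histogram.
otsu_threshold <- function(x, n_bins = 256L) {
  r <- range(x)
  if (r[1] == r[2]) return(r[1])
  h <- tabulate(pmin(n_bins, 1L + floor((x - r[1]) / (r[2] - r[1]) * n_bins)),
                nbins = n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- r[1] + (seq_len(n_bins) - 0.5) / n_bins * (r[2] - r[1])
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  denom <- omega * (1 - omega)
  sb2 <- ifelse(denom > 0, (mu_t * omega - mu)^2 / denom, 0)
  mids[which.max(sb2)]
}

ball_offsets <- function(radius) {
  r <- as.integer(ceiling(radius))
  g <- expand.grid(dx = -r:r, dy = -r:r, dz = -r:r)
  g[g$dx^2 + g$dy^2 + g$dz^2 <= radius^2, , drop = FALSE]
}

shift_mask <- function(m, off, pad) {
  d <- dim(m)
  out <- array(pad, d)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    o <- off[[ax]]
    if (o >= 0) {
      if (o >= d[ax]) return(out)
      dst[[ax]] <- 1L:(d[ax] - o)
      src[[ax]] <- (1L + o):d[ax]
    } else {
      if (-o >= d[ax]) return(out)
      dst[[ax]] <- (1L - o):d[ax]
      src[[ax]] <- 1L:(d[ax] + o)
    }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

binary_morph <- function(m, radius, op = c("erode", "dilate")) {
  op <- match.arg(op)
  if (radius <= 0) return(m)
  offs <- ball_offsets(radius)
  out <- if (op == "erode") array(TRUE, dim(m)) else array(FALSE, dim(m))
  # outside-the-grid is background: erosion sees FALSE, dilation sees FALSE
  for (i in seq_len(nrow(offs))) {
    s <- shift_mask(m, c(offs$dx[i], offs$dy[i], offs$dz[i]),
                    pad = (op == "erode"))
    out <- if (op == "erode") out & s else out | s
  }
  out
}

binary_opening <- function(m, radius) {
  binary_morph(binary_morph(m, radius, "erode"), radius, "dilate")
}

binary_closing <- function(m, radius) {
  binary_morph(binary_morph(m, radius, "dilate"), radius, "erode")
}

#' Generate a mask by thresholding and morphology
#'
#' Thresholds image intensity or FA (Otsu-derived or fixed), keeps the side
#' requested (`"above"` for FA-like signals, `"below"` for dark myelin on a
#' bright background), then applies binary opening (removes small spurious
#' regions) and closing (fills holes), in that order.
#'
#' @param source an [image_volume()], an `eigen_field` (its FA is used), or a
#'   numeric 3D array.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold numeric threshold when `method = "fixed"`.
#' @param select keep voxels `"above"` or `"below"` the threshold.
#' @param opening_radius,closing_radius morphology radii in voxels (0 = off).
#' @param voxel_size_nm required when `source` is a bare array.
#' @param label mask label.
#' @return an `roi_mask`; warns (not errors) if the result is empty or full.
#' @export
make_mask <- function(source, method = c("otsu", "fixed"), threshold = NULL,
                      select = c("above", "below"),
                      opening_radius = 0, closing_radius = 0,
                      voxel_size_nm = NULL, label = "mask") {
  method <- match.arg(method)
  select <- match.arg(select)
  if (opening_radius < 0 || closing_radius < 0) stop("radii must be >= 0")
  if (inherits(source, "image_volume")) {
    a <- source$data; vs <- source$voxel_size_nm
  } else if (inherits(source, "eigen_field")) {
    if (is.null(source$fa)) stop("eigen field has no FA")
    a <- source$fa; vs <- source$voxel_size_nm
  } else {
    a <- source
    vs <- voxel_size_nm %||% stop("`voxel_size_nm` needed for a bare array")
  }
  thr <- if (method == "otsu") otsu_threshold(a) else
    threshold %||% stop("`threshold` needed for method = 'fixed'")
  m <- if (select == "above") a > thr else a < thr
  if (opening_radius > 0) m <- binary_opening(m, opening_radius)
  if (closing_radius > 0) m <- binary_closing(m, closing_radius)
  if (!any(m)) warning("mask is empty after thresholding/morphology")
  if (all(m)) warning("mask covers the whole grid")
  out <- roi_mask(m, vs, label)
  attr(out, "threshold") <- thr
  out
}

#' Tracking configuration
#'
#' @param angle_threshold_deg maximum turning angle between successive steps
#'   (0, 90]; default 60.
#' @param min_length_um discard streamlines shorter than this (default 10
#'   voxel side lengths at tracking time if `NULL`).
#' @param max_length_um terminate a streamline at this length.
#' @param seed_density seeds per seed-mask voxel (integer >= 1); 1 places
#'   seeds at voxel centres, more adds uniform jitter inside the voxel.
#' @param bidirectional propagate both ways from each seed (default TRUE).
#' @param rng_seed seed for jittered seeding.
#' @return a `tracking_config`.
#' @export
tracking_config <- function(angle_threshold_deg = 60, min_length_um = NULL,
                            max_length_um = Inf, seed_density = 1L,
                            bidirectional = TRUE, rng_seed = 1L) {
  if (angle_threshold_deg <= 0 || angle_threshold_deg > 90) {
    stop("`angle_threshold_deg` must lie in (0, 90]")
  }
  if (!is.null(min_length_um) && min_length_um < 0) {
    stop("`min_length_um` must be >= 0")
  }
  seed_density <- as.integer(seed_density)
  if (seed_density < 1L) stop("`seed_density` must be >= 1")
  structure(list(angle_threshold_deg = angle_threshold_deg,
                 min_length_um = min_length_um,
                 max_length_um = max_length_um,
                 seed_density = seed_density,
                 bidirectional = isTRUE(bidirectional),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_config")
}

#' Place seed points in a mask
#'
#' @param mask an [roi_mask()] (non-empty).
#' @param config a [tracking_config()]; `seed_density` seeds per voxel.
#' @return matrix of seed positions in um (one row per seed), with the seed
#'   voxel index as attribute `"voxel"`.
#' @export
place_seeds <- function(mask, config = tracking_config()) {
  stopifnot(inherits(mask, "roi_mask"))
  if (!any(mask$mask)) stop("seed mask is empty")
  vs <- nm_to_um(mask$voxel_size_nm)
  vox <- which(mask$mask, arr.ind = TRUE)
  dens <- config$seed_density
  centres <- (vox - 1) * vs
  if (dens == 1L) {
    seeds <- centres
    voxrep <- vox
  } else {
    voxrep <- vox[rep(seq_len(nrow(vox)), each = dens), , drop = FALSE]
    seeds <- with_seed(config$rng_seed, {
      (voxrep - 1) * vs +
        matrix(stats::runif(length(voxrep), -vs / 2, vs / 2), ncol = 3)
    })
  }
  colnames(seeds) <- c("x", "y", "z")
  attr(seeds, "voxel") <- voxrep
  seeds
}

# Extract the principal-direction field as three plain arrays for fast
# scalar indexing inside the tracking loop.
direction_arrays <- function(directions) {
  if (inherits(directions, "eigen_field")) {
    d <- dim(directions$l1s)
    v <- matrix(directions$v1, ncol = 3)
    zero <- as.vector(directions$zero_mask)
    v[zero, ] <- 0
    list(x = array(v[, 1], d), y = array(v[, 2], d), z = array(v[, 3], d),
         dim = d)
  } else {
    stopifnot(length(dim(directions)) == 4L, dim(directions)[4] == 3L)
    d <- dim(directions)[1:3]
    list(x = directions[, , , 1], y = directions[, , , 2],
         z = directions[, , , 3], dim = d)
  }
}

# Propagate one direction from a seed; returns points (excluding the seed)
# and the termination reason.
fact_walk <- function(dirs, mask, p0, vox0, dir0, vs, cfg, len0 = 0) {
  d <- dirs$dim
  amax <- cos(cfg$angle_threshold_deg * pi / 180)
  pts <- matrix(NA_real_, 4096L, 3L)
  npt <- 0L
  p <- p0
  vox <- vox0
  prev <- dir0
  len <- len0
  first <- TRUE
  reason <- "mask-exit"
  repeat {
    dx <- dirs$x[vox[1], vox[2], vox[3]]
    dy <- dirs$y[vox[1], vox[2], vox[3]]
    dz <- dirs$z[vox[1], vox[2], vox[3]]
    nrm <- sqrt(dx * dx + dy * dy + dz * dz)
    if (!is.finite(nrm) || nrm < 1e-12) { reason <- "zero-direction"; break }
    dx <- dx / nrm; dy <- dy / nrm; dz <- dz / nrm
    dp <- dx * prev[1] + dy * prev[2] + dz * prev[3]
    if (dp < 0) { dx <- -dx; dy <- -dy; dz <- -dz; dp <- -dp }
    if (!first && dp < amax) { reason <- "angle"; break }
    # distance to the exit face along each axis
    tmin <- Inf
    for (a in 1:3) {
      da <- c(dx, dy, dz)[a]
      if (abs(da) < 1e-12) next
      face <- (vox[a] - 1 + 0.5 * sign(da)) * vs
      t_a <- (face - p[a]) / da
      if (t_a < tmin) tmin <- t_a
    }
    if (!is.finite(tmin)) { reason <- "zero-direction"; break }
    tmin <- max(tmin, 0)
    q <- p + tmin * c(dx, dy, dz)
    len <- len + tmin
    npt <- npt + 1L
    if (npt > nrow(pts)) pts <- rbind(pts, matrix(NA_real_, nrow(pts), 3L))
    pts[npt, ] <- q
    if (len >= cfg$max_length_um) { reason <- "length"; break }
    # advance across every face hit within tolerance (corner crossings)
    for (a in 1:3) {
      da <- c(dx, dy, dz)[a]
      if (abs(da) < 1e-12) next
      face <- (vox[a] - 1 + 0.5 * sign(da)) * vs
      if (abs((face - p[a]) / da - tmin) <= 1e-9) {
        vox[a] <- vox[a] + as.integer(sign(da))
      }
    }
    if (any(vox < 1L) || any(vox > d)) { reason <- "mask-exit"; break }
    if (!mask[vox[1], vox[2], vox[3]]) { reason <- "mask-exit"; break }
    p <- q
    prev <- c(dx, dy, dz)
    first <- FALSE
  }
  list(points = pts[seq_len(npt), , drop = FALSE], reason = reason, length = len)
}

#' Deterministic FACT tractography
#'
#' Fibre Assignment by Continuous Tracking: from each seed the streamline
#' travels along the current voxel's axial direction (sign chosen to keep the
#' turning angle acute) to the voxel's exit face, voxel by voxel, until it
#' leaves the tracking mask, turns by more than the angle threshold, exceeds
#' the maximum length, or hits a zero-direction voxel. With
#' `config$bidirectional` both half-tracks from the seed are concatenated.
#' Streamlines shorter than `config$min_length_um` are discarded.
#'
#' @param directions converted `eigen_field` (its `v1` is the fibre
#'   direction) or a `dims x 3` array of axial unit vectors.
#' @param seeds seed matrix from [place_seeds()] (um), or any n x 3 matrix.
#' @param tracking_mask an [roi_mask()]; streamlines stay inside it. Seeds
#'   outside are skipped (with a message).
#' @param config a [tracking_config()].
#' @return a `streamline_set`: list of streamlines (matrices of points in
#'   um, with attributes `seed` index and `reason` = the two termination
#'   reasons), plus the voxel size and the config.
#' @export
track_fact <- function(directions, seeds, tracking_mask,
                       config = tracking_config()) {
  stopifnot(inherits(tracking_mask, "roi_mask"))
  dirs <- direction_arrays(directions)
  if (!identical(dim(tracking_mask$mask), as.integer(dirs$dim)) &&
      !identical(dim(tracking_mask$mask), dirs$dim)) {
    stop("tracking mask grid does not match the direction field")
  }
  vs <- nm_to_um(tracking_mask$voxel_size_nm)
  min_len <- config$min_length_um %||% (10 * vs)
  mask <- tracking_mask$mask
  out <- vector("list", nrow(seeds))
  kept <- 0L
  skipped <- 0L
  for (si in seq_len(nrow(seeds))) {
    p0 <- as.numeric(seeds[si, ])
    vox <- as.integer(round(p0 / vs)) + 1L
    if (any(vox < 1L) || any(vox > dirs$dim) ||
        !mask[vox[1], vox[2], vox[3]]) {
      skipped <- skipped + 1L
      next
    }
    d0 <- c(dirs$x[vox[1], vox[2], vox[3]],
            dirs$y[vox[1], vox[2], vox[3]],
            dirs$z[vox[1], vox[2], vox[3]])
    if (sqrt(sum(d0^2)) < 1e-12) { skipped <- skipped + 1L; next }
    d0 <- d0 / sqrt(sum(d0^2))
    fwd <- fact_walk(dirs, mask, p0, vox, d0, vs, config)
    if (config$bidirectional) {
      # max_length_um bounds the whole streamline: the backward half starts
      # from the length already spent forward
      bwd <- fact_walk(dirs, mask, p0, vox, -d0, vs, config,
                       len0 = fwd$length)
      pts <- rbind(bwd$points[rev(seq_len(nrow(bwd$points))), , drop = FALSE],
                   matrix(p0, 1), fwd$points)
      reasons <- c(bwd$reason, fwd$reason)
    } else {
      pts <- rbind(matrix(p0, 1), fwd$points)
      reasons <- c("seed", fwd$reason)
    }
    if (nrow(pts) < 2L) { next }
    seg <- sqrt(rowSums(diff(pts)^2))
    keep <- c(TRUE, seg > 1e-12)   # drop consecutive duplicates
    pts <- pts[keep, , drop = FALSE]
    if (nrow(pts) < 2L || sum(sqrt(rowSums(diff(pts)^2))) < min_len) next
    attr(pts, "seed") <- si
    attr(pts, "reason") <- reasons
    kept <- kept + 1L
    out[[kept]] <- pts
  }
  if (skipped > 0) {
    message(sprintf("%d seed(s) outside the tracking mask or on zero directions; skipped",
                    skipped))
  }
  structure(list(streamlines = out[seq_len(kept)],
                 voxel_size_nm = tracking_mask$voxel_size_nm,
                 config = config),
            class = "streamline_set")
}

#' @export
print.streamline_set <- function(x, ...) {
  n <- length(x$streamlines)
  if (n) {
    lens <- vapply(x$streamlines, streamline_length, 0)
    cat(sprintf("<streamline_set> %d streamlines, length %.1f-%.1f um (median %.1f)\n",
                n, min(lens), max(lens), stats::median(lens)))
  } else {
    cat("<streamline_set> empty\n")
  }
  invisible(x)
}

#' @export
length.streamline_set <- function(x) length(x$streamlines)

#' Total arc length of a streamline (um)
#' @param s n x 3 point matrix.
#' @return length in um.
#' @export
streamline_length <- function(s) {
  if (nrow(s) < 2L) return(0)
  sum(sqrt(rowSums(diff(s)^2)))
}

# Voxels visited by a streamline: the voxels of the midpoints of consecutive
# point pairs (points themselves lie on voxel faces) plus both endpoints.
visited_voxels <- function(s, vs) {
  if (nrow(s) == 1L) {
    m <- s
  } else {
    m <- rbind((s[-1, , drop = FALSE] + s[-nrow(s), , drop = FALSE]) / 2,
               s[1, ], s[nrow(s), ])
  }
  unique(matrix(as.integer(round(m / vs)) + 1L, ncol = 3))
}

#' Filter streamlines by inclusion/rejection ROIs and length
#'
#' Keeps streamlines that visit every inclusion mask, visit no rejection
#' mask, and are at least `min_length_um` long.
#'
#' @param sset a `streamline_set`.
#' @param inclusion list of [roi_mask()]s each streamline must reach.
#' @param rejection list of [roi_mask()]s no streamline may touch.
#' @param min_length_um minimum arc length in um.
#' @return the filtered `streamline_set`.
#' @export
apply_roi_filters <- function(sset, inclusion = list(), rejection = list(),
                              min_length_um = 0) {
  stopifnot(inherits(sset, "streamline_set"))
  if (inherits(inclusion, "roi_mask")) inclusion <- list(inclusion)
  if (inherits(rejection, "roi_mask")) rejection <- list(rejection)
  vs <- nm_to_um(sset$voxel_size_nm)
  keep <- vapply(sset$streamlines, function(s) {
    if (streamline_length(s) < min_length_um) return(FALSE)
    vox <- visited_voxels(s, vs)
    for (m in inclusion) {
      dims <- dim(m$mask)
      inb <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
        vox[, 2] >= 1 & vox[, 2] <= dims[2] &
        vox[, 3] >= 1 & vox[, 3] <= dims[3]
      if (!any(m$mask[vox[inb, , drop = FALSE]])) return(FALSE)
    }
    for (m in rejection) {
      dims <- dim(m$mask)
      inb <- vox[, 1] >= 1 & vox[, 1] <= dims[1] &
        vox[, 2] >= 1 & vox[, 2] <= dims[2] &
        vox[, 3] >= 1 & vox[, 3] <= dims[3]
      if (any(m$mask[vox[inb, , drop = FALSE]])) return(FALSE)
    }
    TRUE
  }, TRUE)
  sset$streamlines <- sset$streamlines[keep]
  sset
}
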