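# Orientation statistics: principal-direction extraction under ROIs, the
# area-normalised fibre orientation distribution (FOD) on the sphere, and FA
# kernel-density summaries.

#' Extract principal directions and FA under ROI masks
#'
#' Returns the principal (fibre) direction and FA of every voxel inside the
#' inclusion mask, excluding the union of exclusion masks, the zero-tensor
#' mask and the filter border flags.
#'
#' @param eigen a converted `eigen_field` with FA.
#' @param include logical array (inclusion ROI) or `NULL` for all voxels.
#' @param exclude list of logical arrays to exclude (e.g. blood-vessel or
#'   non-tissue masks).
#' @param drop_border drop border-flagged voxels (default TRUE).
#' @return data.frame with columns `x, y, z` (axial unit vector components)
#'   and `fa`.
#' @export
extract_principal_directions <- function(eigen, include = NULL,
                                         exclude = list(),
                                         drop_border = TRUE) {
  stopifnot(inherits(eigen, "eigen_field"))
  if (is.null(eigen$fa)) stop("eigen field has no FA; run fractional_anisotropy()")
  d <- dim(eigen$fa)
  sel <- if (is.null(include)) array(TRUE, d) else as_mask_array(include, d)
  n_inc <- sum(sel)
  for (ex in exclude) sel <- sel & !as_mask_array(ex, d)
  sel <- sel & !eigen$zero_mask
  if (drop_border) sel <- sel & !eigen$border_mask
  if (!any(sel)) {
    stop(sprintf(
      "empty selection: include %d voxels, %d exclusion mask(s), %d zero, %d border",
      n_inc, length(exclude), sum(eigen$zero_mask), sum(eigen$border_mask)))
  }
  v <- matrix(eigen$v1, ncol = 3)[as.vector(sel), , drop = FALSE]
  data.frame(x = v[, 1], y = v[, 2], z = v[, 3], fa = eigen$fa[sel])
}

as_mask_array <- function(m, d) {
  a <- if (inherits(m, "roi_mask")) m$mask else m
  if (!identical(dim(a), as.integer(d)) && !identical(dim(a), d)) {
    stop("mask grid does not match the eigen field grid")
  }
  a & TRUE
}

dirs_as_matrix <- function(directions) {
  if (is.data.frame(directions)) {
    as.matrix(directions[, c("x", "y", "z")])
  } else {
    m <- as.matrix(directions)
    stopifnot(ncol(m) == 3)
    m
  }
}

axis_vectors <- list(x = c(1, 0, 0), y = c(0, 1, 0), z = c(0, 0, 1))

#' Choose the pole axis with the least directional contribution
#'
#' The spherical-histogram pole should point where few fibres point, since
#' azimuth is degenerate at the pole. Returns the grid axis minimising the
#' mean absolute dot product with the directions; ties break in the order
#' z, y, x.
#'
#' @param directions axial unit vectors (n x 3 matrix or the data.frame from
#'   [extract_principal_directions()]).
#' @return `"x"`, `"y"` or `"z"`.
#' @export
auto_pole_axis <- function(directions) {
  v <- dirs_as_matrix(directions)
  if (nrow(v) < 1) stop("need at least one direction")
  score <- vapply(c("z", "y", "x"),
                  function(ax) mean(abs(v %*% axis_vectors[[ax]])), 0)
  names(score)[which.min(score)]   # which.min takes the first on ties
}

pole_basis <- function(pole_axis) {
  switch(pole_axis,
         z = list(e = c(0, 0, 1), u1 = c(1, 0, 0), u2 = c(0, 1, 0)),
         y = list(e = c(0, 1, 0), u1 = c(0, 0, 1), u2 = c(1, 0, 0)),
         x = list(e = c(1, 0, 0), u1 = c(0, 1, 0), u2 = c(0, 0, 1)),
         stop("`pole_axis` must be 'x', 'y' or 'z'"))
}

#' Fibre orientation distribution as an area-normalised spherical histogram
#'
#' Axial directions are mapped to the hemisphere around the pole axis
#' (pole-axis component >= 0; `v` and `-v` give identical histograms) and
#' binned by azimuth and elevation. Because those bins subtend unequal solid
#' angles, each bin's probability density is its count divided by
#' `n * solid_angle`, making the histogram a proper density on the
#' hemisphere: `sum(p * solid_angle) = 1`. The band touching the pole is a
#' single cap bin (azimuth is degenerate there).
#'
#' @param directions axial unit vectors (n x 3 or data.frame).
#' @param pole_axis `"x"`, `"y"`, `"z"` or `"auto"` (see [auto_pole_axis()]).
#' @param bin_width_deg bin width in degrees for both azimuth and elevation
#'   (1 to 30; default 5, which resolves a 35-degree laminar separation with
#'   margin).
#' @return a `spherical_histogram`: data.frame `bins` (azimuth/elevation
#'   edges in degrees, solid angle in steradians, count, density) plus the
#'   pole axis, bin width and total count.
#' @export
build_fod <- function(directions, pole_axis = "auto", bin_width_deg = 5) {
  v <- dirs_as_matrix(directions)
  if (nrow(v) < 1) stop("need at least one direction")
  if (bin_width_deg < 1 || bin_width_deg > 30) {
    stop("`bin_width_deg` must lie in [1, 30]")
  }
  if (pole_axis == "auto") pole_axis <- auto_pole_axis(v)
  b <- pole_basis(pole_axis)
  # hemisphere mapping resolves the antipodal ambiguity before binning;
  # directions exactly on the equator are canonicalised by their in-plane
  # components so v and -v always land in the same bin
  pc <- as.vector(v %*% b$e)
  s <- sign(pc)
  eq <- abs(pc) < 1e-12
  if (any(eq)) {
    s1 <- sign(v[eq, , drop = FALSE] %*% b$u1)
    s2 <- sign(v[eq, , drop = FALSE] %*% b$u2)
    s[eq] <- ifelse(s1 != 0, s1, s2)
  }
  s[s == 0] <- 1
  v <- v * s
  # equator directions can keep a -1e-16-scale pole component after the flip;
  # clamp so they land in the first elevation band
  el <- pmax(asin(pmin(1, pmax(-1, v %*% b$e))) * 180 / pi, 0)   # [0, 90]
  az <- (atan2(v %*% b$u2, v %*% b$u1) * 180 / pi) %% 360
  az[az >= 360] <- 0
  w <- bin_width_deg
  el_edges <- seq(0, 90, by = w)
  if (el_edges[length(el_edges)] < 90) el_edges <- c(el_edges, 90)
  n_el <- length(el_edges) - 1L
  cap_lo <- el_edges[n_el]                  # cap band: elevation >= cap_lo
  az_edges <- seq(0, 360, by = w)
  if (az_edges[length(az_edges)] < 360) az_edges <- c(az_edges, 360)
  n_az <- length(az_edges) - 1L
  rows <- list()
  for (ie in seq_len(n_el)) {
    e_lo <- el_edges[ie]; e_hi <- el_edges[ie + 1L]
    sin_lo <- sin(e_lo * pi / 180); sin_hi <- sin(e_hi * pi / 180)
    in_band <- el >= e_lo & (el < e_hi | (ie == n_el & el <= 90))
    if (ie == n_el) {
      # single pole-cap bin over all azimuths
      rows[[length(rows) + 1L]] <- data.frame(
        az_lo = 0, az_hi = 360, el_lo = e_lo, el_hi = 90,
        solid_angle = 2 * pi * (1 - sin_lo), count = sum(in_band))
    } else {
      cnt <- tabulate(findInterval(az[in_band], az_edges,
                                   rightmost.closed = TRUE), nbins = n_az)
      rows[[length(rows) + 1L]] <- data.frame(
        az_lo = az_edges[-(n_az + 1L)], az_hi = az_edges[-1L],
        el_lo = e_lo, el_hi = e_hi,
        solid_angle = (az_edges[-1L] - az_edges[-(n_az + 1L)]) * pi / 180 *
          (sin_hi - sin_lo),
        count = cnt)
    }
  }
  bins <- do.call(rbind, rows)
  n <- nrow(v)
  bins$density <- bins$count / (n * bins$solid_angle)
  structure(list(bins = bins, pole_axis = pole_axis,
                 bin_width_deg = w, n = n),
            class = "spherical_histogram")
}

#' @export
print.spherical_histogram <- function(x, ...) {
  cat(sprintf("<spherical_histogram> %d directions, pole %s, %g deg bins, %d bins\n",
              x$n, x$pole_axis, x$bin_width_deg, nrow(x$bins)))
  cat(sprintf("  sum(p * domega) = %.6f\n",
              sum(x$bins$density * x$bins$solid_angle)))
  invisible(x)
}

#' Unit direction at the centre of a histogram bin
#' @noRd
fod_bin_direction <- function(fod, i) {
  b <- fod$bins[i, ]
  bb <- pole_basis(fod$pole_axis)
  if (b$el_hi >= 90 && b$az_lo == 0 && b$az_hi == 360) return(bb$e)
  el <- (b$el_lo + b$el_hi) / 2 * pi / 180
  az <- (b$az_lo + b$az_hi) / 2 * pi / 180
  cos(el) * cos(az) * bb$u1 + cos(el) * sin(az) * bb$u2 + sin(el) * bb$e
}

#' Modal directions of a FOD
#'
#' @param fod a `spherical_histogram`.
#' @param k number of modes to return.
#' @param min_separation_deg suppress secondary peaks within this acute angle
#'   of an already-selected stronger peak.
#' @return matrix of k unit direction vectors (rows), strongest first.
#' @export
fod_modes <- function(fod, k = 1, min_separation_deg = 15) {
  ord <- order(fod$bins$density, decreasing = TRUE)
  out <- list()
  for (i in ord) {
    dir_i <- fod_bin_direction(fod, i)
    if (all(vapply(out, function(u) acute_angle(u, dir_i) > min_separation_deg,
                   TRUE))) {
      out[[length(out) + 1L]] <- dir_i
      if (length(out) == k) break
    }
  }
  do.call(rbind, out)
}

#' Perturb axial directions with angular jitter
#'
#' Adds an isotropic tangential Gaussian perturbation of the given angular
#' scale to each direction and renormalises. Useful for studying how
#' dispersion indices respond to angular spread.
#'
#' @param directions n x 3 axial unit vectors (or data.frame).
#' @param sd_deg angular jitter standard deviation in degrees.
#' @param rng_seed seed.
#' @return n x 3 matrix of unit vectors.
#' @export
jitter_directions <- function(directions, sd_deg, rng_seed = 1L) {
  v <- dirs_as_matrix(directions)
  if (sd_deg == 0) return(v)
  with_seed(rng_seed, {
    t1 <- matrix(stats::rnorm(length(v)), ncol = 3)
    t1 <- t1 - rowSums(t1 * v) * v            # tangential component
    n1 <- sqrt(rowSums(t1^2))
    n1[n1 == 0] <- 1
    ang <- stats::rnorm(nrow(v), 0, sd_deg * pi / 180)
    out <- v * cos(ang) + (t1 / n1) * sin(ang)
    out / sqrt(rowSums(out^2))
  })
}

#' FA kernel-density summary
#'
#' Gaussian KDE of FA values with Scott's-rule bandwidth by default and
#' boundary reflection at 0 and 1 so the density integrates to one on the
#' supported range. Reports mean, sd, median and IQR.
#'
#' @param fa_values numeric vector in `[0, 1]`.
#' @param bandwidth `"scott"` or a numeric bandwidth.
#' @param n_grid evaluation grid size on `[0, 1]`.
#' @return a `distribution_summary`: grid `x`, density `y`, `mean`, `sd`,
#'   `median`, `iqr`, `n` and a `degenerate` flag (fewer than two distinct
#'   values: no KDE).
#' @export
fa_density <- function(fa_values, bandwidth = "scott", n_grid = 512) {
  fa_values <- fa_values[is.finite(fa_values)]
  if (length(fa_values) == 0L) stop("no FA values supplied")
  n <- length(fa_values)
  degenerate <- length(unique(fa_values)) < 2L
  med <- stats::median(fa_values)
  iqr <- stats::IQR(fa_values)
  if (degenerate) {
    return(structure(list(x = NULL, y = NULL, mean = mean(fa_values),
                          sd = 0, median = med, iqr = iqr, n = n,
                          bandwidth = NA_real_, degenerate = TRUE),
                     class = "distribution_summary"))
  }
  bw <- if (identical(bandwidth, "scott")) {
    stats::sd(fa_values) * n^(-1 / 5)
  } else {
    as.numeric(bandwidth)
  }
  aug <- c(fa_values, -fa_values, 2 - fa_values)   # reflect at both edges
  de <- stats::density(aug, bw = bw, from = 0, to = 1, n = n_grid)
  structure(list(x = de$x, y = de$y * 3, mean = mean(fa_values),
                 sd = stats::sd(fa_values), median = med, iqr = iqr,
                 n = n, bandwidth = bw, degenerate = FALSE),
            class = "distribution_summary")
}

#' @export
print.distribution_summary <- function(x, ...) {
  cat(sprintf("<distribution_summary> n = %d, mean %.3f +/- %.3f, median/IQR: %.2f/%.2f%s\n",
              x$n, x$mean, x$sd, x$median, x$iqr,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Volume fraction of a component within a reference region
#'
#' @param mask logical array (or `roi_mask`): the component (e.g. cells and
#'   blood vessels).
#' @param reference logical array (or `roi_mask`): the reference region.
#' @return percentage `100 * |mask AND reference| / |reference|`.
#' @export
component_volume_fraction <- function(mask, reference) {
  ref <- if (inherits(reference, "roi_mask")) reference$mask else reference
  m <- if (inherits(mask, "roi_mask")) mask$mask else mask
  if (!identical(dim(m), dim(ref))) stop("mask and reference grids differ")
  if (!any(ref)) stop("empty reference region")
  100 * sum(m & ref) / sum(ref)
}
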