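# Synthetic white-matter phantoms with exact ground truth.
#
# The generators emulate the appearance of osmium-stained myelinated tissue
# in phase-contrast tomography: myelinated axons are dark tubes on a brighter
# background, cell bodies and blood vessels are bright, and demyelination
# shows as reduced fibre/background contrast. Every voxel of a phantom has a
# known axial fibre orientation and region label, so orientation estimation,
# tractography and the shape metrics can be validated quantitatively.

LABELS <- c(background = 0L, population1 = 1L, population2 = 2L,
            obstacle = 3L, demyelinated = 4L)

#' Phantom specification
#'
#' Declarative description of a synthetic fibre volume. Defaults are chosen
#' to mimic the tissue geometry observed in high-resolution synchrotron scans
#' of white matter: fibre (axon) radii of a couple of micrometres, laminae up
#' to 40-45 um thick with inclination angles up to ~35 degrees, and
#' near-orthogonal crossings between major pathways.
#'
#' @param grid_shape integer 3-vector, voxels per (x, y, z) axis (>= 16 each).
#' @param voxel_size_nm isotropic voxel size in nm.
#' @param fibre_axis unit 3-vector, main fibre direction.
#' @param fibre_radius_um fibre tube radius in um; a pair gives two
#'   populations of different calibre in the two halves of the grid
#'   (for scale-space tests).
#' @param fibre_spacing_um centre-to-centre lattice spacing in um.
#' @param lamina_thickness_um slab thickness for laminar/crossing phantoms.
#' @param lamina_inclination_deg angle between fibre directions of
#'   alternating laminae, in `[0, 90)`.
#' @param crossing_angle_deg angle between the two crossing populations,
#'   in `[0, 90]`.
#' @param fibre_intensity,background_intensity arbitrary intensity units;
#'   myelin is dark, so `fibre_intensity < background_intensity`.
#' @param noise_sigma additive Gaussian noise standard deviation (same
#'   units); applied only by [add_imaging_noise()].
#' @param jitter_um uniform jitter of lattice positions (0 = regular grid).
#' @param rng_seed integer seed making all stochastic choices reproducible.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape = c(128L, 128L, 128L),
                         voxel_size_nm = 550,
                         fibre_axis = c(1, 0, 0),
                         fibre_radius_um = 2,
                         fibre_spacing_um = 6,
                         lamina_thickness_um = 40,
                         lamina_inclination_deg = 35,
                         crossing_angle_deg = 90,
                         fibre_intensity = 60,
                         background_intensity = 100,
                         noise_sigma = 0,
                         jitter_um = 0,
                         rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L)) {
    stop("`grid_shape` must be three integers >= 16")
  }
  if (voxel_size_nm <= 0) stop("`voxel_size_nm` must be > 0")
  fibre_axis <- unit3(fibre_axis)
  if (any(fibre_radius_um <= 0) || fibre_spacing_um <= 0 ||
      lamina_thickness_um <= 0) {
    stop("radii, spacings and thicknesses must be > 0")
  }
  if (length(fibre_radius_um) > 2L) stop("`fibre_radius_um` takes 1 or 2 values")
  if (crossing_angle_deg < 0 || crossing_angle_deg > 90) {
    stop("`crossing_angle_deg` must lie in [0, 90]")
  }
  if (!(fibre_intensity < background_intensity) || fibre_intensity <= 0) {
    stop("need 0 < fibre_intensity < background_intensity (myelin is dark)")
  }
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  structure(list(grid_shape = grid_shape, voxel_size_nm = voxel_size_nm,
                 fibre_axis = fibre_axis, fibre_radius_um = fibre_radius_um,
                 fibre_spacing_um = fibre_spacing_um,
                 lamina_thickness_um = lamina_thickness_um,
                 lamina_inclination_deg = lamina_inclination_deg,
                 crossing_angle_deg = crossing_angle_deg,
                 fibre_intensity = fibre_intensity,
                 background_intensity = background_intensity,
                 noise_sigma = noise_sigma, jitter_um = jitter_um,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# World-coordinate extent of the grid in um: voxel centres at (i-1)*vs, the
# volume spans [-vs/2, (n-1/2)*vs] per axis.
grid_extent_um <- function(grid_shape, vs_um) {
  rbind(lo = rep(-vs_um / 2, 3), hi = (grid_shape - 0.5) * vs_um)
}

# Clip the line p0 + t*d to the grid box and sample it every `step` um.
# Returns NULL if the intersection is shorter than 2 steps.
sample_line_in_box <- function(p0, d, grid_shape, vs_um, step) {
  ext <- grid_extent_um(grid_shape, vs_um)
  t_lo <- -Inf; t_hi <- Inf
  for (a in 1:3) {
    if (abs(d[a]) < 1e-12) {
      if (p0[a] < ext["lo", a] || p0[a] > ext["hi", a]) return(NULL)
    } else {
      t1 <- (ext["lo", a] - p0[a]) / d[a]
      t2 <- (ext["hi", a] - p0[a]) / d[a]
      t_lo <- max(t_lo, min(t1, t2))
      t_hi <- min(t_hi, max(t1, t2))
    }
  }
  if (!is.finite(t_lo) || !is.finite(t_hi) || t_hi - t_lo < 2 * step) return(NULL)
  tt <- seq(t_lo, t_hi, by = step)
  if (tt[length(tt)] < t_hi) tt <- c(tt, t_hi)
  outer(tt, d) + rep(p0, each = length(tt))
}

# Generate straight centreline paths along direction `d` on a square lattice
# in the perpendicular plane. When `slab_axis`/`slab_range` (um) are given,
# lattice rows along that axis are aligned to the slab (first row half a
# spacing above its floor) and rows whose tube of radius `radius_um` would
# bleed across a slab boundary are dropped, so labels stay slab-consistent.
lattice_paths <- function(d, spec, population, radius_um,
                          slab_axis = NULL, slab_range = NULL,
                          jitter = 0) {
  gs <- spec$grid_shape
  vs <- nm_to_um(spec$voxel_size_nm)
  sp <- spec$fibre_spacing_um
  centre <- (gs - 1) * vs / 2
  half_diag <- sqrt(sum((gs * vs)^2)) / 2
  m <- ceiling(half_diag / sp)
  paths <- list()
  add_path <- function(off) {
    pts <- sample_line_in_box(off, d, gs, vs, step = vs)
    if (is.null(pts)) return()
    attr(pts, "population") <- population
    attr(pts, "radius_um") <- radius_um
    paths[[length(paths) + 1L]] <<- pts
  }
  if (is.null(slab_axis)) {
    ref <- if (abs(d[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
    e1 <- unit3(pracma::cross(d, ref))
    e2 <- pracma::cross(d, e1)
    for (a in -m:m) {
      for (b in -m:m) {
        j1 <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
        j2 <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
        off <- centre + (a * sp + j1) * e1 + (b * sp + j2) * e2
        off <- off - sum((off - centre) * d) * d
        add_path(off)
      }
    }
  } else {
    n <- c(0, 0, 0); n[slab_axis] <- 1
    e_p <- unit3(pracma::cross(d, n))   # in-plane, perpendicular to the slabs
    levels <- seq(slab_range[1] + sp / 2, slab_range[2], by = sp)
    levels <- levels[levels - radius_um >= slab_range[1] &
                       levels + radius_um <= slab_range[2]]
    for (lev in levels) {
      for (a in -m:m) {
        j1 <- if (jitter > 0) stats::runif(1, -jitter, jitter) else 0
        off <- centre + (a * sp + j1) * e_p
        off[slab_axis] <- lev
        add_path(off)
      }
    }
  }
  paths
}

# Render anti-aliased dark tubes from centreline paths.
# Coverage of a voxel is a linear ramp over one voxel width across the tube
# wall, so intensity gradients at fibre boundaries are smooth (sub-voxel
# information the structure tensor relies on). Returns volume intensities,
# per-voxel coverage, population labels and axial orientations.
render_paths <- function(paths, grid_shape, vs_um, background, fibre_int) {
  gs <- grid_shape
  cov <- array(0, gs)
  lab <- array(LABELS[["background"]], gs)
  ori <- array(NA_real_, c(gs, 3L))
  for (p in paths) {
    r <- attr(p, "radius_um")
    popl <- attr(p, "population")
    n <- nrow(p)
    # dominant axis: largest chord component
    chord <- p[n, ] - p[1, ]
    ax <- which.max(abs(chord))
    o1 <- c(2L, 1L, 1L)[ax]; o2 <- c(3L, 3L, 2L)[ax]   # the two slice axes
    if (chord[ax] < 0) p <- p[n:1, , drop = FALSE]
    # voxel slices along the dominant axis touched by the path
    lo_i <- max(1L, as.integer(floor(min(p[, ax]) / vs_um + 1.5)))
    hi_i <- min(gs[ax], as.integer(ceiling(max(p[, ax]) / vs_um + 0.5)))
    if (hi_i < lo_i) next
    s_pos <- (seq(lo_i, hi_i) - 1) * vs_um
    # interpolate centreline at each slice position; tangents per segment
    cy <- stats::approx(p[, ax], p[, o1], xout = s_pos, rule = 2)$y
    cz <- stats::approx(p[, ax], p[, o2], xout = s_pos, rule = 2)$y
    seg_mid <- (p[-n, ax] + p[-1, ax]) / 2
    w <- max(1L, as.integer(ceiling((r + vs_um) / vs_um)))
    for (si in seq_along(s_pos)) {
      i <- lo_i + si - 1L
      # local unit tangent from the segment whose span covers this slice
      k <- findInterval(s_pos[si], seg_mid, all.inside = TRUE)
      tg <- unit3(p[min(k + 1L, n), ] - p[max(k, 1L), ])
      cj <- as.integer(round(cy[si] / vs_um)) + 1L
      ck <- as.integer(round(cz[si] / vs_um)) + 1L
      jj <- max(1L, cj - w):min(gs[o1], cj + w)
      kk <- max(1L, ck - w):min(gs[o2], ck + w)
      if (!length(jj) || !length(kk)) next
      dy <- (jj - 1) * vs_um - cy[si]
      dz <- (kk - 1) * vs_um - cz[si]
      DY <- matrix(dy, length(jj), length(kk))
      DZ <- matrix(dz, length(jj), length(kk), byrow = TRUE)
      # true perpendicular distance to the (locally straight) centreline:
      # remove the in-plane offset's component along the tangent
      along <- DY * tg[o1] + DZ * tg[o2]
      dist <- sqrt(pmax(0, DY^2 + DZ^2 - along^2))
      cv <- pmin(1, pmax(0, (r + vs_um / 2 - dist) / vs_um))
      if (all(cv == 0)) next
      idx <- array(0L, c(length(jj) * length(kk), 3L))
      idx[, ax] <- i
      idx[, o1] <- rep(jj, times = length(kk))
      idx[, o2] <- rep(kk, each = length(jj))
      old <- cov[idx]
      sel <- cv > old
      if (!any(sel)) next
      isel <- idx[sel, , drop = FALSE]
      cov[isel] <- cv[sel]
      fib <- cv[sel] >= 0.5
      if (any(fib)) {
        lab[isel[fib, , drop = FALSE]] <- popl
        for (cc in 1:3) {
          ori[cbind(isel[fib, , drop = FALSE], cc)] <- tg[cc]
        }
      }
    }
  }
  vol <- background - (background - fibre_int) * cov
  list(volume = vol, coverage = cov, labels = lab, orientation = ori)
}

new_ground_truth <- function(spec, paths, render, slab_directions = NULL) {
  structure(list(orientation = render$orientation,
                 labels = render$labels,
                 coverage = render$coverage,
                 fibre_paths = paths,
                 slab_directions = slab_directions,
                 spec = spec,
                 obstacles = list(),
                 cells = list(),
                 demyelination = NULL,
                 voxel_size_nm = spec$voxel_size_nm),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  tab <- table(factor(x$labels, levels = LABELS,
                      labels = names(LABELS)))
  cat("<ground_truth>", length(x$fibre_paths), "fibre paths; labels:\n")
  print(tab)
  invisible(x)
}

check_radius_resolvable <- function(radius_um, vs_um) {
  bad <- radius_um < 2 * vs_um
  if (any(bad)) {
    stop(sprintf(
      "fibre radius %.3g um not resolvable at voxel size %.3g um; minimum radius is %.3g um",
      min(radius_um[bad]), vs_um, 2 * vs_um))
  }
}

#' Parallel-fibre phantom
#'
#' Densely packed parallel dark tubes along `spec$fibre_axis` on a regular
#' (optionally jittered) square lattice, emulating a corpus-callosum-like
#' region where fasciculi all run in one direction. If `fibre_radius_um` has
#' two values, the two halves of the grid (split along the last axis
#' perpendicular to the fibre axis) get fibres of different calibre and are
#' labelled population 1 and 2.
#'
#' @param spec a [phantom_spec()].
#' @return list with elements `volume` ([image_volume()]) and `truth`
#'   (`ground_truth`: per-voxel axial orientation where fibre, region labels,
#'   true centreline paths in um).
#' @export
build_parallel_fibre_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  vs <- nm_to_um(spec$voxel_size_nm)
  check_radius_resolvable(spec$fibre_radius_um, vs)
  d <- spec$fibre_axis
  with_seed(spec$rng_seed, {
    if (length(spec$fibre_radius_um) == 1L) {
      paths <- lattice_paths(d, spec, LABELS[["population1"]],
                             spec$fibre_radius_um, jitter = spec$jitter_um)
    } else {
      # split perpendicular to the fibre axis: use the last world axis that
      # is not the dominant fibre axis; each half gets its own calibre, with
      # tubes kept strictly inside their half
      ax <- which.max(abs(d))
      split_axis <- max(setdiff(1:3, ax))
      ext <- grid_extent_um(spec$grid_shape, vs)
      mid <- (ext["lo", split_axis] + ext["hi", split_axis]) / 2
      paths <- c(
        lattice_paths(d, spec, LABELS[["population1"]],
                      spec$fibre_radius_um[1], slab_axis = split_axis,
                      slab_range = c(ext["lo", split_axis], mid),
                      jitter = spec$jitter_um),
        lattice_paths(d, spec, LABELS[["population2"]],
                      spec$fibre_radius_um[2], slab_axis = split_axis,
                      slab_range = c(mid, ext["hi", split_axis]),
                      jitter = spec$jitter_um))
    }
    rend <- render_paths(paths, spec$grid_shape, vs,
                         spec$background_intensity, spec$fibre_intensity)
    vol <- image_volume(rend$volume, spec$voxel_size_nm,
                        provenance = "phantom: parallel fibres")
    list(volume = vol, truth = new_ground_truth(spec, paths, rend))
  })
}

rotate_in_plane <- function(v, axis_normal, angle_deg) {
  # Rodrigues rotation of v about axis_normal; components that are zero up to
  # floating-point rotation noise are snapped to exact zero so special angles
  # (0, 90 degrees) give exact axis directions
  th <- angle_deg * pi / 180
  k <- unit3(axis_normal)
  out <- v * cos(th) + pracma::cross(k, v) * sin(th) +
    k * sum(k * v) * (1 - cos(th))
  out[abs(out) < 1e-12] <- 0
  unit3(out)
}

laminar_like_volume <- function(spec, dir1, dir2, normal_axis, provenance) {
  vs <- nm_to_um(spec$voxel_size_nm)
  check_radius_resolvable(spec$fibre_radius_um[1], vs)
  gs <- spec$grid_shape
  th <- spec$lamina_thickness_um
  extent <- gs[normal_axis] * vs
  n_slabs <- ceiling(extent / th)
  with_seed(spec$rng_seed, {
    paths <- list()
    for (s in seq_len(n_slabs)) {
      lo <- -vs / 2 + (s - 1) * th
      hi <- min(lo + th, extent - vs / 2)
      odd <- s %% 2L == 1L
      d <- if (odd) dir1 else dir2
      popl <- if (odd) LABELS[["population1"]] else LABELS[["population2"]]
      slab_paths <- lattice_paths(d, spec, popl, spec$fibre_radius_um[1],
                                  slab_axis = normal_axis,
                                  slab_range = c(lo, hi),
                                  jitter = spec$jitter_um)
      paths <- c(paths, slab_paths)
    }
    rend <- render_paths(paths, gs, vs, spec$background_intensity,
                         spec$fibre_intensity)
    vol <- image_volume(rend$volume, spec$voxel_size_nm, provenance)
    truth <- new_ground_truth(spec, paths, rend,
                              slab_directions = rbind(dir1, dir2))
    list(volume = vol, truth = truth)
  })
}

#' Laminar phantom
#'
#' Alternating slabs (laminae) of parallel fibres whose directions differ by
#' `spec$lamina_inclination_deg`, both lying in the plane containing
#' `spec$fibre_axis`. Slabs are stacked along the z axis (or y if the fibre
#' axis is z). Emulates the sheet-like laminar organisation of axonal
#' fasciculi, with inclination angles up to ~35 degrees and thicknesses up
#' to 40-45 um as seen in real tissue.
#'
#' @inheritParams build_parallel_fibre_volume
#' @return as [build_parallel_fibre_volume()]; `truth$slab_directions` holds
#'   the two axial directions.
#' @export
build_laminar_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  incl <- spec$lamina_inclination_deg
  if (incl < 0 || incl >= 90) stop("lamina inclination must lie in [0, 90)")
  f <- spec$fibre_axis
  normal_axis <- if (abs(f[3]) > 0.9) 2L else 3L
  normal <- c(0, 0, 0); normal[normal_axis] <- 1
  dir1 <- rotate_in_plane(f, normal, -incl / 2)
  dir2 <- rotate_in_plane(f, normal, +incl / 2)
  laminar_like_volume(spec, dir1, dir2, normal_axis,
                      sprintf("phantom: laminae %g deg / %g um", incl,
                              spec$lamina_thickness_um))
}

#' Crossing-fibre phantom
#'
#' Two interleaved laminar fibre populations whose directions differ by
#' `spec$crossing_angle_deg`, emulating near-orthogonal crossings of major
#' pathways. With the default fibre axis +x and a 90 degree crossing the two
#' populations run along x and z, interleaved in slabs along y.
#'
#' @inheritParams build_parallel_fibre_volume
#' @return as [build_laminar_volume()].
#' @export
build_crossing_volume <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  ang <- spec$crossing_angle_deg
  if (ang <= 0) stop("`crossing_angle_deg` must be > 0 for a crossing phantom")
  f <- spec$fibre_axis
  normal_axis <- if (abs(f[2]) > 0.9) 3L else 2L
  normal <- c(0, 0, 0); normal[normal_axis] <- 1
  dir1 <- f
  dir2 <- rotate_in_plane(f, normal, ang)
  laminar_like_volume(spec, dir1, dir2, normal_axis,
                      sprintf("phantom: %g deg crossing", ang))
}

#' Obstacle specification
#'
#' A bright spherical cell body or tubular blood vessel that displaces the
#' fibres around it.
#'
#' @param kind `"sphere"` or `"cylinder"`.
#' @param center_vox 3-vector, centre in (1-based) voxel coordinates.
#' @param radius_um obstacle radius in um (> 0).
#' @param axis unit 3-vector, cylinder axis (ignored for spheres).
#' @param intensity intensity of the obstacle (bright relative to fibres).
#' @param deflection_halo_um distance beyond the obstacle surface over which
#'   fibres are displaced; must be >= `radius_um`. Fibres at undeflected
#'   distance `r` from the obstacle centre/axis are pushed radially outward
#'   (within the plane perpendicular to the fibre axis) by
#'   `R * (R + h - r) / h`, decaying smoothly to zero at the halo edge, so
#'   the maximum deviation is on the scale of the obstacle radius.
#' @return an `obstacle_spec` object.
#' @export
obstacle_spec <- function(kind = c("sphere", "cylinder"), center_vox,
                          radius_um, axis = c(0, 0, 1), intensity = 140,
                          deflection_halo_um = radius_um) {
  kind <- match.arg(kind)
  if (radius_um <= 0) stop("`radius_um` must be > 0")
  if (deflection_halo_um < radius_um) {
    stop("`deflection_halo_um` must be >= `radius_um`")
  }
  structure(list(kind = kind, center_vox = as.numeric(center_vox),
                 radius_um = radius_um, axis = unit3(axis),
                 intensity = intensity,
                 deflection_halo_um = deflection_halo_um),
            class = "obstacle_spec")
}

# Vector from the obstacle centre (sphere) or axis (cylinder) to each point;
# points is n x 3 in um.
obstacle_radial <- function(ob, points, vs_um) {
  c0 <- (ob$center_vox - 1) * vs_um
  u <- sweep(points, 2, c0)
  if (ob$kind == "cylinder") {
    along <- u %*% ob$axis
    u <- u - along %*% t(ob$axis)
  }
  u
}

deflect_path <- function(p, ob, vs_um) {
  u <- obstacle_radial(ob, p, vs_um)
  r <- sqrt(rowSums(u^2))
  R <- ob$radius_um; h <- ob$deflection_halo_um
  mag <- ifelse(r < R + h, R * (R + h - pmin(r, R + h)) / h, 0)
  if (all(mag == 0)) return(p)
  f <- unit3(p[nrow(p), ] - p[1, ])            # overall fibre direction
  w <- u - (u %*% f) %*% t(f)                  # restrict to plane perp. to fibre
  wn <- sqrt(rowSums(w^2))
  # head-on points (radial parallel to fibre axis): deterministic sideways
  # escape perpendicular to the fibre (and, for vessels, to the vessel axis)
  if (any(wn < 1e-9 & mag > 0)) {
    side <- if (ob$kind == "cylinder") pracma::cross(f, ob$axis) else c(0, 0, 0)
    if (sqrt(sum(side^2)) < 1e-6) {
      ref <- if (abs(f[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
      side <- ref - sum(ref * f) * f
    }
    side <- unit3(side)
    w[wn < 1e-9, ] <- rep(side, each = sum(wn < 1e-9))
    wn[wn < 1e-9] <- 1
  }
  p + (mag / pmax(wn, 1e-12)) * w
}

# Stamp anti-aliased bright obstacles into a rendered volume.
stamp_obstacle <- function(vol, lab, ob, vs_um) {
  gs <- dim(vol)
  c0 <- (ob$center_vox - 1) * vs_um
  R <- ob$radius_um
  w <- ceiling((R + vs_um) / vs_um)
  if (ob$kind == "sphere") {
    rng <- lapply(1:3, function(a) {
      max(1L, floor(ob$center_vox[a] - w)):min(gs[a], ceiling(ob$center_vox[a] + w))
    })
  } else {
    rng <- lapply(1:3, function(a) {
      if (abs(ob$axis[a]) > 0.2) seq_len(gs[a])  # generous along the axis
      else max(1L, floor(ob$center_vox[a] - w)):min(gs[a], ceiling(ob$center_vox[a] + w))
    })
  }
  grid <- as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  pts <- (grid - 1) * vs_um
  u <- obstacle_radial(ob, pts, vs_um)
  dist <- sqrt(rowSums(u^2))
  cv <- pmin(1, pmax(0, (R + vs_um / 2 - dist) / vs_um))
  sel <- cv > 0
  if (!any(sel)) return(list(volume = vol, labels = lab))
  gi <- grid[sel, , drop = FALSE]
  vol[gi] <- vol[gi] * (1 - cv[sel]) + ob$intensity * cv[sel]
  lab[gi[cv[sel] >= 0.5, , drop = FALSE]] <- LABELS[["obstacle"]]
  list(volume = vol, labels = lab)
}

#' Insert obstacles and deflect fibres around them
#'
#' Obstacle voxels take the (bright) obstacle intensity; fibre centrelines
#' within the deflection halo are displaced radially away from the obstacle
#' surface, with displacement decaying smoothly to zero at the halo edge, and
#' the image is re-rendered from the deflected centrelines so image, paths
#' and orientations stay mutually consistent.
#'
#' @param volume the phantom [image_volume()].
#' @param truth its `ground_truth`.
#' @param obstacles list of [obstacle_spec()] objects.
#' @return list(volume, truth) with deflected paths, updated orientations and
#'   labels (obstacle voxels labelled as such).
#' @export
insert_obstacles <- function(volume, truth, obstacles) {
  stopifnot(inherits(volume, "image_volume"), inherits(truth, "ground_truth"))
  if (length(obstacles) == 0L) return(list(volume = volume, truth = truth))
  spec <- truth$spec
  vs <- nm_to_um(spec$voxel_size_nm)
  gs <- spec$grid_shape
  for (ob in obstacles) {
    stopifnot(inherits(ob, "obstacle_spec"))
    if (any(ob$center_vox < 1) || any(ob$center_vox > gs)) {
      stop("obstacle centre outside the grid")
    }
    perp <- if (ob$kind == "cylinder") which(abs(ob$axis) < 0.9) else 1:3
    if (2 * ob$radius_um >= min((gs[perp] - 1) * vs)) {
      stop("obstacle covers the entire cross-section of the grid")
    }
  }
  paths <- truth$fibre_paths
  ext <- grid_extent_um(gs, vs)
  for (ob in obstacles) {
    paths <- lapply(paths, function(p) {
      at <- attributes(p)
      q <- deflect_path(p, ob, vs)
      # keep deflected centrelines inside the volume
      for (a in 1:3) q[, a] <- pmin(pmax(q[, a], ext["lo", a]), ext["hi", a])
      attributes(q) <- at[setdiff(names(at), "dim")]
      dim(q) <- dim(p)
      q
    })
  }
  rend <- render_paths(paths, gs, vs, spec$background_intensity,
                       spec$fibre_intensity)
  vol <- rend$volume; lab <- rend$labels
  for (ob in obstacles) {
    st <- stamp_obstacle(vol, lab, ob, vs)
    vol <- st$volume; lab <- st$labels
  }
  truth$fibre_paths <- paths
  truth$orientation <- rend$orientation
  truth$coverage <- rend$coverage
  truth$labels <- lab
  truth$obstacles <- c(truth$obstacles, obstacles)
  out_vol <- image_volume(vol, spec$voxel_size_nm,
                          provenance = paste0(volume$provenance, " + obstacles"))
  list(volume = out_vol, truth = truth)
}

#' Focal demyelination
#'
#' Within a box region, multiplies the fibre/background intensity gap by
#' `contrast_factor` (reduced myelin contrast) and sprinkles additional
#' bright spherical cell bodies at the stated density, emulating a
#' cuprizone-type lesion. Fibre geometry and orientations are untouched: the
#' structure tensor should still find a clear directional signal, only
#' weaker.
#'
#' @param volume the phantom [image_volume()].
#' @param truth its `ground_truth`.
#' @param region list with integer 3-vectors `lo` and `hi`: the voxel box
#'   (inclusive) to demyelinate.
#' @param contrast_factor fraction in (0, 1]; 1 leaves contrast unchanged.
#' @param extra_cell_density_mm3 added cell bodies per cubic millimetre.
#' @param cell_radius_um radius range the added cells are drawn from.
#' @param rng_seed seed for cell placement (default derived from the spec).
#' @return list(volume, truth); region voxels labelled demyelinated, added
#'   cells labelled obstacle.
#' @export
apply_demyelination <- function(volume, truth, region, contrast_factor,
                                extra_cell_density_mm3 = 0,
                                cell_radius_um = c(2.5, 7),
                                rng_seed = truth$spec$rng_seed + 1L) {
  stopifnot(inherits(volume, "image_volume"), inherits(truth, "ground_truth"))
  if (contrast_factor <= 0 || contrast_factor > 1) {
    stop("`contrast_factor` must lie in (0, 1]")
  }
  gs <- dim(volume$data)
  lo <- as.integer(region$lo); hi <- as.integer(region$hi)
  if (any(lo < 1L) || any(hi > gs) || any(lo > hi)) {
    stop("`region` box lies outside the grid")
  }
  vs <- nm_to_um(volume$voxel_size_nm)
  v <- volume$data
  bg <- truth$spec$background_intensity
  sub <- v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  dark <- sub < bg
  sub[dark] <- bg - (bg - sub[dark]) * contrast_factor
  v[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
  lab <- truth$labels
  lsub <- lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  lsub[lsub != LABELS[["obstacle"]]] <- LABELS[["demyelinated"]]
  lab[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- lsub
  cells <- list()
  if (extra_cell_density_mm3 > 0) {
    vol_mm3 <- prod(hi - lo + 1) * vs^3 / 1e9
    n_cells <- round(extra_cell_density_mm3 * vol_mm3)
    if (n_cells > 0) {
      cells <- with_seed(rng_seed, {
        lapply(seq_len(n_cells), function(i) {
          ctr <- stats::runif(3, lo, hi)
          obstacle_spec("sphere", center_vox = ctr,
                        radius_um = stats::runif(1, cell_radius_um[1],
                                                 cell_radius_um[2]),
                        intensity = truth$spec$background_intensity * 1.4)
        })
      })
      for (cell in cells) {
        st <- stamp_obstacle(v, lab, cell, vs)
        v <- st$volume; lab <- st$labels
      }
    }
  }
  truth$labels <- lab
  truth$cells <- c(truth$cells, cells)
  truth$demyelination <- list(region = list(lo = lo, hi = hi),
                              contrast_factor = contrast_factor,
                              extra_cell_density_mm3 = extra_cell_density_mm3,
                              rng_seed = rng_seed)
  out <- image_volume(v, volume$voxel_size_nm,
                      provenance = paste0(volume$provenance, " + demyelination"))
  list(volume = out, truth = truth)
}

#' Additive Gaussian imaging noise
#'
#' @param volume an [image_volume()].
#' @param noise_sigma standard deviation in intensity units (>= 0).
#' @param rng_seed integer seed; the same seed gives bit-identical output.
#' @return the noisy `image_volume`.
#' @export
add_imaging_noise <- function(volume, noise_sigma, rng_seed = 1L) {
  stopifnot(inherits(volume, "image_volume"))
  if (noise_sigma < 0) stop("`noise_sigma` must be >= 0")
  if (noise_sigma == 0) return(volume)
  noisy <- with_seed(rng_seed, {
    volume$data + array(stats::rnorm(length(volume$data), 0, noise_sigma),
                        dim(volume$data))
  })
  image_volume(noisy, volume$voxel_size_nm,
               provenance = paste0(volume$provenance,
                                   sprintf(" + noise sd %g", noise_sigma)))
}

#' Re-render a phantom volume from its ground truth
#'
#' Rendering is a pure function of the ground truth (fibre paths, obstacles,
#' demyelination record, cells), so the returned volume reproduces the
#' generator output exactly (before any imaging noise).
#'
#' @param truth a `ground_truth`.
#' @return an [image_volume()].
#' @export
render_from_truth <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  spec <- truth$spec
  vs <- nm_to_um(spec$voxel_size_nm)
  rend <- render_paths(truth$fibre_paths, spec$grid_shape, vs,
                       spec$background_intensity, spec$fibre_intensity)
  vol <- rend$volume; lab <- rend$labels
  for (ob in truth$obstacles) {
    st <- stamp_obstacle(vol, lab, ob, vs)
    vol <- st$volume; lab <- st$labels
  }
  if (!is.null(truth$demyelination)) {
    dm <- truth$demyelination
    lo <- dm$region$lo; hi <- dm$region$hi
    bg <- spec$background_intensity
    sub <- vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
    dark <- sub < bg
    sub[dark] <- bg - (bg - sub[dark]) * dm$contrast_factor
    vol[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- sub
    for (cell in truth$cells) {
      st <- stamp_obstacle(vol, lab, cell, vs)
      vol <- st$volume; lab <- st$labels
    }
  }
  image_volume(vol, spec$voxel_size_nm, provenance = "re-rendered from truth")
}

#' Fibre-interior voxel mask
#'
#' Voxels fully covered by a fibre tube (coverage ~ 1), optionally eroded so
#' wall voxels with mixed gradients are excluded. Useful as the evaluation
#' region for orientation-recovery checks.
#'
#' @param truth a `ground_truth`.
#' @param erode number of 6-neighbour erosion passes (default 0; tubes only a
#'   few voxels across leave no voxels after erosion).
#' @return logical array of the grid shape.
#' @export
fibre_interior <- function(truth, erode = 0L) {
  m <- truth$coverage >= 0.999
  for (e in seq_len(erode)) m <- erode6(m)
  m
}

# one pass of 6-neighbourhood binary erosion (borders treated as outside)
erode6 <- function(m) {
  d <- dim(m)
  out <- m
  shift <- function(a, ax, by) {
    idx <- rep(list(quote(expr = )), 3)
    n <- d[ax]
    src <- pmin(pmax(seq_len(n) + by, 1L), n)
    idx[[ax]] <- src
    pad <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
    # out-of-range positions become FALSE
    if (by > 0) {
      edge <- (n - by + 1L):n
    } else {
      edge <- 1L:(-by)
    }
    idx2 <- rep(list(quote(expr = )), 3)
    idx2[[ax]] <- edge
    pad <- do.call(`[<-`, c(list(pad), idx2, list(value = FALSE)))
    pad
  }
  for (ax in 1:3) {
    out <- out & shift(m, ax, 1L) & shift(m, ax, -1L)
  }
  out
}
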