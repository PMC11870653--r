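# 3D structure tensor estimation, diffusion-like conversion, FA and
# scale-space dominant-scale selection.
#
# The structure tensor at a voxel is the Gaussian(rho)-weighted local average
# of g g^T, where g is the image gradient obtained with derivative-of-
# Gaussian(sigma) filters. Its eigenvector with the smallest eigenvalue is
# the direction of least intensity variation: the fibre direction. The raw
# tensor is converted to a diffusion-like tensor through the single-parameter
# model lambda_i = exp(-lambda_i*/gamma) (after which the eigenvalue ordering
# reverses and the principal eigenvector is the fibre direction), and shape
# is summarised by fractional anisotropy.

#' Scale parameters for the structure tensor
#'
#' @param sigma,rho numeric vectors of equal length: per-scale standard
#'   deviations (in voxels) of the gradient (sigma) and integration (rho)
#'   Gaussians. The defaults are the eight-scale suite used for
#'   high-resolution scans: rho 5.50, 4.50, 3.50, 3.50, 2.50, 2.50, 1.50,
#'   1.00 paired with sigma 3.00, 2.75, 2.50, 1.50, 1.50, 1.00, 1.00, 0.50.
#' @param gamma structure-tensor conversion parameter (> 0), typically
#'   0.25-0.35.
#' @param downsample_factor integer >= 1 block-mean downsampling applied
#'   before analysis.
#' @return a `scale_params` object.
#' @export
scale_params <- function(rho = c(5.50, 4.50, 3.50, 3.50, 2.50, 2.50, 1.50, 1.00),
                         sigma = c(3.00, 2.75, 2.50, 1.50, 1.50, 1.00, 1.00, 0.50),
                         gamma = 0.30,
                         downsample_factor = 1L) {
  if (length(sigma) != length(rho) || length(sigma) == 0L) {
    stop("`sigma` and `rho` must be non-empty vectors of equal length")
  }
  if (any(sigma <= 0) || any(rho <= 0)) stop("all sigma and rho must be > 0")
  if (gamma <= 0) stop("`gamma` must be > 0")
  downsample_factor <- as.integer(downsample_factor)
  if (downsample_factor < 1L) stop("`downsample_factor` must be >= 1")
  structure(list(scales = data.frame(sigma = sigma, rho = rho),
                 gamma = gamma, downsample_factor = downsample_factor),
            class = "scale_params")
}

#' Physical integration-kernel size
#'
#' The reported "kernel size" of a structure-tensor analysis is the full
#' width of the truncated integration (rho) kernel converted to physical
#' distance: Gaussian kernels are truncated at radius `ceiling(2 * rho)`
#' voxels, so the width is `2 * ceiling(2 * rho) + 1` voxels times the
#' effective voxel size (native voxel size times any downsampling factor).
#'
#' @param rho integration standard deviation in voxels (of the downsampled
#'   grid).
#' @param voxel_size_nm native voxel size in nm.
#' @param scaling_factor downsampling factor applied before analysis.
#' @return kernel size in um.
#' @export
kernel_size_um <- function(rho, voxel_size_nm, scaling_factor = 1) {
  (2 * ceiling(2 * rho) + 1) * nm_to_um(voxel_size_nm) * scaling_factor
}

#' Compute the 3D structure tensor field
#'
#' Three steps: (1) image gradients by separable filtering with
#' derivative-of-Gaussian kernels (standard deviation `sigma` voxels,
#' truncated at `ceiling(4 sigma)`); (2) per-voxel outer product of the
#' gradient with itself; (3) aggregation over the local neighbourhood by
#' Gaussian smoothing with standard deviation `rho` voxels (the "patch
#' size", truncated at `ceiling(2 rho)`). Mirror-reflection boundary
#' handling; voxels within one rho-kernel radius of the border are flagged.
#'
#' @param volume an [image_volume()].
#' @param sigma,rho Gaussian standard deviations in voxels (> 0).
#' @param scale_id integer tag carried into downstream fields.
#' @return a `tensor_field`: the six unique components (`xx, xy, xz, yy,
#'   yz, zz`) as 3D arrays, plus voxel size, parameters and a border mask.
#' @export
compute_structure_tensor <- function(volume, sigma, rho, scale_id = 0L) {
  stopifnot(inherits(volume, "image_volume"))
  if (sigma <= 0 || rho <= 0) stop("`sigma` and `rho` must be > 0")
  a <- volume$data
  d <- dim(a)
  r_d <- ceiling(4 * sigma); r_s <- ceiling(2 * rho)
  need <- max(r_d, r_s) + 1L
  if (any(d < need)) {
    stop(sprintf("volume %s too small for sigma=%g, rho=%g; need >= %d voxels per axis",
                 paste(d, collapse = "x"), sigma, rho, need))
  }
  gk <- gaussian_kernel(sigma, trunc_mult = 4)
  dk <- gaussian_deriv_kernel(sigma, trunc_mult = 4)
  rk <- gaussian_kernel(rho, trunc_mult = 2)
  smooth_except <- function(x, axis_d) {
    for (ax in 1:3) {
      x <- conv_axis(x, if (ax == axis_d) dk else gk, ax)
    }
    x
  }
  gx <- smooth_except(a, 1L)
  gy <- smooth_except(a, 2L)
  gz <- smooth_except(a, 3L)
  agg <- function(x) {
    for (ax in 1:3) x <- conv_axis(x, rk, ax)
    x
  }
  comp <- list(xx = agg(gx * gx), xy = agg(gx * gy), xz = agg(gx * gz),
               yy = agg(gy * gy), yz = agg(gy * gz), zz = agg(gz * gz))
  intensity_scale <- sqrt(mean(a^2))
  border <- array(FALSE, d)
  w <- r_s
  if (any(d <= 2 * w)) {
    border[] <- TRUE
  } else {
    border[c(1:w, (d[1] - w + 1L):d[1]), , ] <- TRUE
    border[, c(1:w, (d[2] - w + 1L):d[2]), ] <- TRUE
    border[, , c(1:w, (d[3] - w + 1L):d[3])] <- TRUE
  }
  structure(c(comp, list(voxel_size_nm = volume$voxel_size_nm,
                         sigma = sigma, rho = rho,
                         scale_id = as.integer(scale_id),
                         intensity_scale = intensity_scale,
                         border_mask = border)),
            class = "tensor_field")
}

#' @export
print.tensor_field <- function(x, ...) {
  cat(sprintf("<tensor_field> %s voxels, sigma=%g rho=%g (scale %d)\n",
              paste(dim(x$xx), collapse = "x"), x$sigma, x$rho, x$scale_id))
  invisible(x)
}

# --- vectorised symmetric 3x3 eigendecomposition ---------------------------

# Analytic eigenvalues (trigonometric method) of fields of symmetric 3x3
# matrices, returned sorted descending. Inputs are arrays/vectors of the six
# components; fully vectorised.
eig3_values <- function(xx, xy, xz, yy, yz, zz) {
  q <- (xx + yy + zz) / 3
  p1 <- xy^2 + xz^2 + yz^2
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  iso <- p <= .Machine$double.eps * pmax(abs(q), 1e-300)
  ps <- ifelse(iso, 1, p)
  bxx <- (xx - q) / ps; byy <- (yy - q) / ps; bzz <- (zz - q) / ps
  bxy <- xy / ps; bxz <- xz / ps; byz <- yz / ps
  detb <- bxx * (byy * bzz - byz^2) - bxy * (bxy * bzz - byz * bxz) +
    bxz * (bxy * byz - byy * bxz)
  r <- pmin(pmax(detb / 2, -1), 1)
  phi <- acos(r) / 3
  l1 <- q + 2 * p * cos(phi)
  l3 <- q + 2 * p * cos(phi + 2 * pi / 3)
  l2 <- 3 * q - l1 - l3
  l1[iso] <- q[iso]; l2[iso] <- q[iso]; l3[iso] <- q[iso]
  list(l1 = l1, l2 = l2, l3 = l3)
}

# Eigenvector for eigenvalue lam of each symmetric 3x3 matrix, as the best-
# conditioned cross product of two rows of (A - lam I). Vectorised; rows are
# n-vectors. Returns an n x 3 matrix of unit vectors (unnormalised sign).
eig3_vector <- function(xx, xy, xz, yy, yz, zz, lam) {
  r1x <- xx - lam; r1y <- xy;       r1z <- xz
  r2x <- xy;       r2y <- yy - lam; r2z <- yz
  r3x <- xz;       r3y <- yz;       r3z <- zz - lam
  cr <- function(ax, ay, az, bx, by, bz) {
    cbind(ay * bz - az * by, az * bx - ax * bz, ax * by - ay * bx)
  }
  c12 <- cr(r1x, r1y, r1z, r2x, r2y, r2z)
  c13 <- cr(r1x, r1y, r1z, r3x, r3y, r3z)
  c23 <- cr(r2x, r2y, r2z, r3x, r3y, r3z)
  n12 <- rowSums(c12^2); n13 <- rowSums(c13^2); n23 <- rowSums(c23^2)
  best <- max.col(cbind(n12, n13, n23), ties.method = "first")
  v <- c12
  v[best == 2L, ] <- c13[best == 2L, ]
  v[best == 3L, ] <- c23[best == 3L, ]
  nv <- sqrt(rowSums(v^2))
  ok <- nv > 0
  v[ok, ] <- v[ok, ] / nv[ok]
  # fully degenerate rows: deterministic fallback
  v[!ok, ] <- matrix(rep(c(1, 0, 0), each = sum(!ok)), ncol = 3)
  v
}

# Deterministic axial sign convention: first component larger than `tol` in
# magnitude is made positive.
fix_sign <- function(v, tol = 1e-9) {
  s <- ifelse(abs(v[, 1]) > tol, sign(v[, 1]),
              ifelse(abs(v[, 2]) > tol, sign(v[, 2]), sign(v[, 3])))
  s[s == 0] <- 1
  v * s
}

#' Eigendecompose a structure tensor field
#'
#' Per voxel: eigenvalues sorted `lambda1* >= lambda2* >= lambda3*`, clipped
#' at zero and normalised to unit sum wherever the tensor trace exceeds a
#' relative zero tolerance; voxels below it are flagged in `zero_mask` (their
#' eigenvalues are set isotropic by convention). Eigenvectors are orthonormal
#' with a deterministic axial sign convention. For nearly degenerate pairs
#' the best-conditioned eigenvector is computed first and the remaining pair
#' completed by orthogonalisation, keeping the frame orthonormal.
#'
#' @param tensors a `tensor_field` from [compute_structure_tensor()].
#' @param zero_tol relative trace tolerance defining the zero mask.
#' @return an `eigen_field` with raw normalised eigenvalue arrays
#'   (`l1s, l2s, l3s`), trace, eigenvector arrays `v1, v2, v3` (dims x 3;
#'   paired with the raw ordering), `zero_mask` and `border_mask`.
#' @export
eigendecompose_field <- function(tensors, zero_tol = 1e-12) {
  stopifnot(inherits(tensors, "tensor_field"))
  d <- dim(tensors$xx)
  xx <- as.vector(tensors$xx); xy <- as.vector(tensors$xy)
  xz <- as.vector(tensors$xz); yy <- as.vector(tensors$yy)
  yz <- as.vector(tensors$yz); zz <- as.vector(tensors$zz)
  tr <- xx + yy + zz
  # relative to the strongest tensor, with an absolute floor at the square of
  # the volume's round-off gradient scale (catches constant volumes whose
  # "gradients" are pure floating-point noise)
  noise_floor <- ((tensors$intensity_scale %||% 0) * 1e-13)^2
  ztol <- max(1e-300, zero_tol * max(tr, 0), noise_floor)
  zero <- tr <= ztol
  ev <- eig3_values(xx, xy, xz, yy, yz, zz)
  l1 <- pmax(ev$l1, 0); l2 <- pmax(ev$l2, 0); l3 <- pmax(ev$l3, 0)
  s <- l1 + l2 + l3
  s[s == 0 | zero] <- 1
  l1s <- l1 / s; l2s <- l2 / s; l3s <- l3 / s
  l1s[zero] <- 1 / 3; l2s[zero] <- 1 / 3; l3s[zero] <- 1 / 3
  # eigenvectors: compute the two extreme ones, best-conditioned first
  gap12 <- ev$l1 - ev$l2
  gap23 <- ev$l2 - ev$l3
  v_top <- eig3_vector(xx, xy, xz, yy, yz, zz, ev$l1)
  v_bot <- eig3_vector(xx, xy, xz, yy, yz, zz, ev$l3)
  first_is_top <- gap12 >= gap23
  v_first <- v_top
  v_first[!first_is_top, ] <- v_bot[!first_is_top, , drop = FALSE]
  v_second <- v_bot
  v_second[!first_is_top, ] <- v_top[!first_is_top, , drop = FALSE]
  # orthogonalise the weaker one against the stronger
  dp <- rowSums(v_second * v_first)
  v_second <- v_second - dp * v_first
  ns <- sqrt(rowSums(v_second^2))
  weak <- ns < 1e-6
  if (any(weak)) {
    # deterministic completion: any unit vector perpendicular to v_first
    ref <- cbind(as.numeric(abs(v_first[, 3]) < 0.9) * 0,
                 0 * v_first[, 1],
                 rep(1, nrow(v_first)))
    ref[abs(v_first[, 3]) >= 0.9, ] <- rep(c(0, 1, 0), each = sum(abs(v_first[, 3]) >= 0.9))
    alt <- ref - rowSums(ref * v_first) * v_first
    v_second[weak, ] <- alt[weak, , drop = FALSE]
    ns[weak] <- sqrt(rowSums(v_second[weak, , drop = FALSE]^2))
  }
  v_second <- v_second / ns
  v_mid <- cbind(v_first[, 2] * v_second[, 3] - v_first[, 3] * v_second[, 2],
                 v_first[, 3] * v_second[, 1] - v_first[, 1] * v_second[, 3],
                 v_first[, 1] * v_second[, 2] - v_first[, 2] * v_second[, 1])
  v1 <- v_first; v3 <- v_second
  v1[!first_is_top, ] <- v_second[!first_is_top, , drop = FALSE]
  v3[!first_is_top, ] <- v_first[!first_is_top, , drop = FALSE]
  v1 <- fix_sign(v1); v2 <- fix_sign(v_mid); v3 <- fix_sign(v3)
  # canonical frame on the zero mask
  if (any(zero)) {
    v1[zero, ] <- rep(c(1, 0, 0), each = sum(zero))
    v2[zero, ] <- rep(c(0, 1, 0), each = sum(zero))
    v3[zero, ] <- rep(c(0, 0, 1), each = sum(zero))
  }
  shape4 <- c(d, 3L)
  structure(list(l1s = array(l1s, d), l2s = array(l2s, d), l3s = array(l3s, d),
                 trace = array(tr, d),
                 v1 = array(v1, shape4), v2 = array(v2, shape4),
                 v3 = array(v3, shape4),
                 l1 = NULL, l2 = NULL, l3 = NULL, fa = NULL,
                 gamma = NULL,
                 zero_mask = array(zero, d),
                 border_mask = tensors$border_mask,
                 voxel_size_nm = tensors$voxel_size_nm,
                 sigma = tensors$sigma, rho = tensors$rho,
                 scale_id = tensors$scale_id),
            class = "eigen_field")
}

#' @export
print.eigen_field <- function(x, ...) {
  cat(sprintf("<eigen_field> %s voxels, sigma=%g rho=%g%s\n",
              paste(dim(x$l1s), collapse = "x"), x$sigma, x$rho,
              if (!is.null(x$fa)) sprintf(", gamma=%g (converted)", x$gamma) else ""))
  cat(sprintf("  zero: %.1f%%  border: %.1f%%\n",
              100 * mean(x$zero_mask), 100 * mean(x$border_mask)))
  invisible(x)
}

#' Convert raw structure-tensor eigenvalues to diffusion-like eigenvalues
#'
#' Applies `lambda_i = exp(-lambda_i* / gamma)` to the normalised raw
#' eigenvalues and renormalises to unit sum. Because `exp(-x/gamma)` is
#' decreasing, the converted ordering is the reverse of the raw ordering; the
#' eigenvector paired with the largest converted eigenvalue is the raw
#' smallest-eigenvalue direction, i.e. the fibre direction. After conversion
#' `v1` of the returned field is the principal (fibre) direction.
#'
#' @param eigen an `eigen_field` from [eigendecompose_field()].
#' @param gamma conversion parameter (> 0).
#' @return the `eigen_field` with converted eigenvalues `l1 >= l2 >= l3`
#'   (summing to 1 off the zero mask) and eigenvectors re-paired.
#' @export
convert_eigenvalues <- function(eigen, gamma) {
  stopifnot(inherits(eigen, "eigen_field"))
  if (gamma <= 0) stop("`gamma` must be > 0")
  e1 <- exp(-eigen$l1s / gamma)   # smallest converted (raw largest)
  e2 <- exp(-eigen$l2s / gamma)
  e3 <- exp(-eigen$l3s / gamma)   # largest converted (raw smallest)
  s <- e1 + e2 + e3
  eigen$l1 <- e3 / s
  eigen$l2 <- e2 / s
  eigen$l3 <- e1 / s
  # re-pair: principal converted direction = raw minor direction
  tmp <- eigen$v1
  eigen$v1 <- eigen$v3
  eigen$v3 <- tmp
  eigen$gamma <- gamma
  eigen
}

#' Fractional anisotropy of the converted tensor field
#'
#' `FA = sqrt(3/2 * sum((lambda_i - mean)^2) / sum(lambda_i^2))`, in
#' `[0, 1]`; set to 0 on the zero mask by convention.
#'
#' @param eigen an `eigen_field` with converted eigenvalues (see
#'   [convert_eigenvalues()]).
#' @return the `eigen_field` with an `fa` array added.
#' @export
fractional_anisotropy <- function(eigen) {
  stopifnot(inherits(eigen, "eigen_field"))
  if (is.null(eigen$l1)) {
    stop("converted eigenvalues missing; call convert_eigenvalues() first")
  }
  l1 <- eigen$l1; l2 <- eigen$l2; l3 <- eigen$l3
  lm <- (l1 + l2 + l3) / 3
  num <- (l1 - lm)^2 + (l2 - lm)^2 + (l3 - lm)^2
  den <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * num / pmax(den, 1e-300))
  fa[eigen$zero_mask] <- 0
  eigen$fa <- pmin(fa, 1)
  eigen
}

#' Structure tensor analysis at one scale
#'
#' Convenience wrapper: structure tensor, eigendecomposition, gamma
#' conversion and FA in one call.
#'
#' @inheritParams compute_structure_tensor
#' @param gamma conversion parameter.
#' @return an `eigen_field` with FA; `v1` is the fibre direction field.
#' @export
structure_tensor_analysis <- function(volume, sigma, rho, gamma = 0.30,
                                      scale_id = 0L) {
  tf <- compute_structure_tensor(volume, sigma, rho, scale_id = scale_id)
  ef <- eigendecompose_field(tf)
  ef <- convert_eigenvalues(ef, gamma)
  fractional_anisotropy(ef)
}

#' Scale-space dominant-scale selection
#'
#' Runs over a list of per-scale eigen fields and selects, per voxel, the
#' scale with the largest scale-normalised FA: each scale's FA map is divided
#' by that scale's maximum FA over all voxels, and the scale with the largest
#' normalised value wins (ties broken by the lowest scale index). The output
#' field copies the winning scale's eigen data per voxel.
#'
#' @param per_scale list of `eigen_field`s with FA, one per scale, sharing
#'   grid and voxel size.
#' @param params the [scale_params()] describing the suite (used for
#'   bookkeeping; lengths must agree).
#' @return list: `eigen` (composite `eigen_field`) and `dominant`
#'   (`dominant_scale_map` with per-voxel winning scale index `d`, 1-based,
#'   and the winning normalised score).
#' @export
scale_space_select <- function(per_scale, params = NULL) {
  if (length(per_scale) == 0L) stop("need at least one scale")
  if (!is.null(params) && nrow(params$scales) != length(per_scale)) {
    stop("`params` lists a different number of scales than `per_scale`")
  }
  d <- dim(per_scale[[1]]$l1s)
  for (ef in per_scale) {
    if (is.null(ef$fa)) stop("all eigen fields need FA; run fractional_anisotropy()")
    if (!identical(dim(ef$l1s), d)) stop("eigen fields must share the grid")
    if (ef$voxel_size_nm != per_scale[[1]]$voxel_size_nm) {
      stop("eigen fields must share the voxel size")
    }
  }
  nsc <- length(per_scale)
  if (nsc == 1L) {
    dom <- structure(list(d = array(1L, d),
                          score = per_scale[[1]]$fa /
                            max(per_scale[[1]]$fa, .Machine$double.xmin)),
                     class = "dominant_scale_map")
    return(list(eigen = per_scale[[1]], dominant = dom))
  }
  best_score <- array(-Inf, d)
  best_idx <- array(1L, d)
  for (i in seq_len(nsc)) {
    mx <- max(per_scale[[i]]$fa)
    if (mx <= 0) {
      message(sprintf("scale %d has zero maximum FA; contributes score 0", i))
      score <- array(0, d)
    } else {
      score <- per_scale[[i]]$fa / mx
    }
    win <- score > best_score   # strict: ties keep the lower index
    best_score[win] <- score[win]
    best_idx[win] <- i
  }
  out <- per_scale[[1]]
  fields3 <- c("l1s", "l2s", "l3s", "l1", "l2", "l3", "fa", "trace")
  for (i in 2:nsc) {
    sel <- best_idx == i
    if (!any(sel)) next
    for (f in fields3) {
      if (!is.null(out[[f]]) && !is.null(per_scale[[i]][[f]])) {
        out[[f]][sel] <- per_scale[[i]][[f]][sel]
      }
    }
    for (f in c("v1", "v2", "v3")) {
      m_out <- matrix(out[[f]], ncol = 3)
      m_in <- matrix(per_scale[[i]][[f]], ncol = 3)
      m_out[sel, ] <- m_in[sel, , drop = FALSE]
      out[[f]] <- array(m_out, c(d, 3L))
    }
    out$zero_mask[sel] <- per_scale[[i]]$zero_mask[sel]
    out$border_mask <- out$border_mask | per_scale[[i]]$border_mask
  }
  out$scale_id <- NA_integer_
  dom <- structure(list(d = best_idx, score = best_score),
                   class = "dominant_scale_map")
  list(eigen = out, dominant = dom)
}

#' @export
print.dominant_scale_map <- function(x, ...) {
  cat("<dominant_scale_map> scale index counts:\n")
  print(table(x$d))
  invisible(x)
}
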