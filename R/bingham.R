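# Bingham distribution fit to axial direction samples, and the derived
# dispersion indices ODI and DA.
#
# The antipodally symmetric Bingham density used here is
#   f(x) = exp(-k1 (a1.x)^2 - k2 (a2.x)^2) / (4 pi c(k1, k2))
# on the unit sphere, with orthonormal axes (a1, a2, a3): a3 is the mean
# (least-penalised) axis, k1 >= k2 >= 0 penalise spread toward a1 and a2.
# Large equal concentrations mean a tight circular peak around a3; unequal
# concentrations mean the spread is anisotropic (girdle-like along a2).

# Dawson function F(x) = exp(-x^2) * int_0^x exp(t^2) dt, stable for all
# x >= 0: erfi-based for small x, asymptotic series for large x.
dawson_fn <- function(x) {
  out <- numeric(length(x))
  small <- x < 5
  if (any(small)) {
    xs <- x[small]
    out[small] <- sqrt(pi) / 2 * exp(-xs^2) * pracma::erfi(xs)
  }
  if (any(!small)) {
    xl <- x[!small]
    ix2 <- 1 / (2 * xl^2)
    out[!small] <- 1 / (2 * xl) * (1 + ix2 + 3 * ix2^2 + 15 * ix2^3 + 105 * ix2^4)
  }
  out
}

# g(a) = int_{-1}^{1} exp(-a (1 - u^2)) du = 2 F(sqrt(a)) / sqrt(a), g(0) = 2.
bingham_g <- function(a) {
  out <- rep(2, length(a))
  pos <- a > 1e-12
  sa <- sqrt(a[pos])
  out[pos] <- 2 * dawson_fn(sa) / sa
  out
}

# Normalising integral c(k1, k2) = (1/4pi) int_{S2} exp(-k1 x^2 - k2 y^2) dS.
# Writing the z-integral in closed form via the Dawson function reduces it to
# a smooth periodic 1D integral over azimuth, done by the trapezoid rule
# (exponentially convergent for periodic integrands); 1024 nodes give ~1e-10.
bingham_const <- function(k1, k2, n_phi = 1024) {
  phi <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  a <- k1 * cos(phi)^2 + k2 * sin(phi)^2
  mean(bingham_g(a)) / 2
}

#' Fit a Bingham distribution to axial directions
#'
#' The axes come from the eigen-decomposition of the orientation scatter
#' matrix `S = (1/n) sum v v^T` (`a3` = largest-eigenvalue axis, the mean
#' axis); the concentrations `k1 >= k2 >= 0` are estimated by maximum
#' likelihood of the antipodally symmetric Bingham density, with the
#' normalising constant evaluated numerically. Concentrations are capped at
#' `1e4` (numerically "perfectly aligned").
#'
#' @param directions axial unit vectors (n x 3 matrix or data.frame with
#'   x, y, z); n >= 10.
#' @param max_kappa upper cap for the concentrations.
#' @return a `bingham_fit`: orthonormal `axes` (columns a1, a2, a3),
#'   `kappa = c(k1, k2)`, `odi`, `da`, log-likelihood, `n`, and a
#'   `degenerate` flag for (near-)uniform samples.
#' @export
fit_bingham <- function(directions, max_kappa = 1e4) {
  v <- dirs_as_matrix(directions)
  n <- nrow(v)
  if (n < 10) stop("need at least 10 directions to fit a Bingham distribution")
  v <- v / sqrt(rowSums(v^2))
  S <- crossprod(v) / n
  es <- eigen(S, symmetric = TRUE)   # eigenvalues descending
  a3 <- es$vectors[, 1]              # mean axis
  a2 <- es$vectors[, 2]
  a1 <- es$vectors[, 3]              # least-populated axis, most penalised
  t1 <- mean((v %*% a1)^2)
  t2 <- mean((v %*% a2)^2)
  nll <- function(k) k[1] * t1 + k[2] * t2 + log(bingham_const(k[1], k[2]))
  k0 <- pmin(pmax(c(1 / (2 * t1 + 1e-8), 1 / (2 * t2 + 1e-8)) - 1, 0), max_kappa)
  opt <- stats::optim(k0, nll, method = "L-BFGS-B",
                      lower = c(0, 0), upper = c(max_kappa, max_kappa),
                      control = list(factr = 1e4))
  k <- opt$par
  if (k[1] < k[2]) {   # keep k1 >= k2; swap the paired axes with them
    k <- rev(k)
    tmp <- a1; a1 <- a2; a2 <- tmp
  }
  degenerate <- all(k < 1e-3)
  fit <- structure(list(axes = cbind(a1 = a1, a2 = a2, a3 = a3),
                        kappa = c(k1 = k[1], k2 = k[2]),
                        loglik = -n * opt$value, n = n,
                        scatter_eigenvalues = es$values,
                        degenerate = degenerate),
                   class = "bingham_fit")
  di <- dispersion_indices(fit)
  fit$odi <- di[["odi"]]
  fit$da <- di[["da"]]
  fit
}

#' @export
print.bingham_fit <- function(x, ...) {
  cat(sprintf("<bingham_fit> n = %d, kappa = (%.3g, %.3g), ODI = %.3f, DA = %.3f%s\n",
              x$n, x$kappa[1], x$kappa[2], x$odi, x$da,
              if (x$degenerate) " [degenerate: near-uniform]" else ""))
  invisible(x)
}

#' Orientation dispersion and dispersion anisotropy indices
#'
#' `ODI = (2/pi) atan(1 / sqrt(k1 k2))` describes the overall angular spread
#' of the fibre population (0 = perfectly aligned, 1 = uniform); it is 1 by
#' convention when either concentration is 0. `DA = (2/pi) atan((k1 - k2) /
#' k2)` describes how anisotropic (non-circular) that spread is (0 =
#' isotropic spread, 1 = maximally anisotropic); it is 0 when `k1 = k2` and 1
#' when `k2 = 0 < k1`. Both lie in `[0, 1]`.
#'
#' @param fit a `bingham_fit`.
#' @return named numeric vector `c(odi =, da =)`.
#' @export
dispersion_indices <- function(fit) {
  stopifnot(inherits(fit, "bingham_fit"))
  k1 <- fit$kappa[[1]]; k2 <- fit$kappa[[2]]
  odi <- if (k1 * k2 <= 0) 1 else (2 / pi) * atan(1 / sqrt(k1 * k2))
  da <- if (k1 <= 0) {
    0
  } else if (k2 <= 0) {
    1
  } else {
    (2 / pi) * atan((k1 - k2) / k2)
  }
  c(odi = odi, da = da)
}

#' Sample axial directions from a Bingham distribution
#'
#' Rejection sampler against the uniform sphere (the unnormalised density is
#' bounded by 1). Mainly used to validate parameter recovery.
#'
#' @param n number of directions.
#' @param axes 3 x 3 orthonormal matrix, columns (a1, a2, a3).
#' @param kappa `c(k1, k2)` with `k1 >= k2 >= 0`.
#' @param rng_seed seed.
#' @return n x 3 matrix of unit vectors.
#' @export
rbingham <- function(n, axes, kappa, rng_seed = 1L) {
  stopifnot(length(kappa) == 2)
  with_seed(rng_seed, {
    out <- matrix(NA_real_, n, 3)
    got <- 0L
    while (got < n) {
      m <- max(2L * (n - got), 1000L)
      u <- matrix(stats::rnorm(3 * m), m, 3)
      u <- u / sqrt(rowSums(u^2))
      f <- exp(-kappa[1] * (u %*% axes[, 1])^2 - kappa[2] * (u %*% axes[, 2])^2)
      acc <- stats::runif(m) < f
      take <- min(sum(acc), n - got)
      if (take > 0) {
        out[(got + 1):(got + take), ] <- u[which(acc)[seq_len(take)], ,
                                           drop = FALSE]
        got <- got + take
      }
    }
    out
  })
}
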