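#' @keywords internal
#' @aliases fibretensor-package
"_PACKAGE"

#' @importFrom stats approx density median IQR sd rnorm runif optim pf
#'   ks.test wilcox.test
#' @importFrom utils packageVersion write.csv
NULL

utils::globalVariables(".data")

# Unit converters. Voxel sizes are carried in nm, all streamline/kernel
# geometry in um; keep every conversion in one place.
nm_to_um <- function(x) x / 1000
um_to_nm <- function(x) x * 1000
nm_to_mm <- function(x) x / 1e6
mm_to_nm <- function(x) x * 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalise a 3-vector to unit length
#' @noRd
unit3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) stop("zero vector cannot be normalised")
  v / n
}

#' Acute angle (degrees) between two axial directions
#'
#' Directions are axial: `v` and `-v` are the same axis, so the angle is
#' folded into \[0, 90\] degrees.
#'
#' @param a,b unit 3-vectors, or n x 3 matrices of unit vectors.
#' @return angle(s) in degrees in \[0, 90\].
#' @export
acute_angle <- function(a, b) {
  if (is.null(dim(a))) a <- matrix(a, 1)
  if (is.null(dim(b))) b <- matrix(b, 1)
  if (nrow(a) == 1 && nrow(b) > 1) a <- a[rep(1, nrow(b)), , drop = FALSE]
  if (nrow(b) == 1 && nrow(a) > 1) b <- b[rep(1, nrow(a)), , drop = FALSE]
  d <- abs(rowSums(a * b))
  acos(pmin(1, d)) * 180 / pi
}

# Half-sample symmetric ("mirror") reflection of indices 1..n; i may lie
# outside [1, n] by any amount smaller than ~n periods.
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n
  j <- ((i - 1L) %% p + p) %% p   # 0 .. 2n-1
  ifelse(j < n, j + 1L, p - j)
}

# 1D convolution along a given axis of a 3D array with mirror boundary,
# realised as a banded matrix product so BLAS does the heavy lifting.
conv_axis <- function(a, kernel, axis) {
  d <- dim(a)
  n <- d[axis]
  r <- (length(kernel) - 1L) %/% 2L
  if (2L * r + 1L > 2L * n) {
    stop(sprintf("axis %d has %d voxels; kernel of %d taps needs at least %d",
                 axis, n, 2L * r + 1L, r + 1L))
  }
  M <- matrix(0, n, n)
  idx <- seq_len(n)
  for (t in -r:r) {
    j <- reflect_index(idx + t, n)
    M[cbind(idx, j)] <- M[cbind(idx, j)] + kernel[t + r + 1L]
  }
  if (axis == 1L) {
    out <- M %*% matrix(a, nrow = n)
    dim(out) <- d
    out
  } else {
    perm <- if (axis == 2L) c(2L, 1L, 3L) else c(3L, 2L, 1L)
    b <- aperm(a, perm)
    out <- M %*% matrix(b, nrow = n)
    dim(out) <- dim(b)
    aperm(out, perm)
  }
}

#' Gaussian and derivative-of-Gaussian kernels
#'
#' Smoothing kernels are truncated at radius `ceiling(trunc_mult * sd)` and
#' normalised to unit sum; derivative kernels are the exact derivative of the
#' normalised Gaussian at the same truncation.
#' @noRd
gaussian_kernel <- function(sd, trunc_mult = 2) {
  r <- max(1L, as.integer(ceiling(trunc_mult * sd)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sd^2))
  k / sum(k)
}

gaussian_deriv_kernel <- function(sd, trunc_mult = 4) {
  r <- max(1L, as.integer(ceiling(trunc_mult * sd)))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sd^2))
  g <- g / sum(g)
  -x / sd^2 * g
}

# Evaluate an expression with the RNG seeded, restoring the caller's RNG
# state afterwards so library code never perturbs user randomness.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

# FNV-1a hash of a character scalar, returned as 8 hex digits. Used to stamp
# run outputs with a configuration fingerprint without extra dependencies.
# The 32-bit modular multiply is done in 16-bit halves so doubles stay exact.
fnv1a_hash <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  prime <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    lo <- h %% 65536; hi <- floor(h / 65536)
    h <- (lo * prime + ((hi * prime) %% 65536) * 65536) %% 4294967296
  }
  paste0(format(as.hexmode(floor(h / 65536)), width = 4),
         format(as.hexmode(h %% 65536), width = 4))
}
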