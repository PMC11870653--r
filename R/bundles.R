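# QuickBundles streamline clustering (minimum average direct-flip distance,
# running centroids) and the two streamline shape metrics: tortuosity and
# maximum deviation. Plus the three-test non-parametric group comparison.

#' Resample a streamline to k equally spaced points
#'
#' Points are equally spaced in arc length; the endpoints are preserved
#' exactly.
#'
#' @param s n x 3 point matrix (um).
#' @param k number of points (>= 2).
#' @return k x 3 matrix.
#' @export
resample_streamline <- function(s, k) {
  s <- as.matrix(s)
  if (k < 2) stop("`k` must be >= 2")
  if (nrow(s) < 2) stop("streamline needs at least 2 points")
  seg <- sqrt(rowSums(diff(s)^2))
  L <- sum(seg)
  if (L <= 0) stop("degenerate zero-length streamline")
  arc <- c(0, cumsum(seg))
  tt <- seq(0, L, length.out = k)
  out <- vapply(1:3, function(c) stats::approx(arc, s[, c], xout = tt,
                                               ties = "ordered")$y,
                numeric(k))
  out[1, ] <- s[1, ]
  out[k, ] <- s[nrow(s), ]
  out
}

#' Minimum average direct-flip (MDF) distance
#'
#' Mean pointwise Euclidean distance between two streamlines resampled to the
#' same number of points, minimised over the two possible orientations
#' (direct and flipped). Symmetric; zero iff the polylines coincide in either
#' orientation.
#'
#' @param a,b k x 3 matrices with equal k.
#' @return distance in um.
#' @export
mdf_distance <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("streamlines must be resampled to the same number of points")
  }
  direct <- mean(sqrt(rowSums((a - b)^2)))
  flipped <- mean(sqrt(rowSums((a - b[nrow(b):1, , drop = FALSE])^2)))
  min(direct, flipped)
}

#' QuickBundles clustering
#'
#' Single-pass sequential clustering in input order: each streamline
#' (resampled to `k` points) joins the first bundle whose running centroid is
#' within `threshold_um` MDF distance, flipped if that orientation is closer;
#' otherwise it founds a new bundle. Centroids are running means of the
#' flip-aligned resampled members. Deterministic given the input order.
#'
#' @param streamlines a `streamline_set` or list of n x 3 matrices.
#' @param threshold_um MDF distance threshold in um (> 0); chosen per sample
#'   in practice.
#' @param k resample points (default 18).
#' @return list of `bundle` objects: `centroid` (k x 3), `members` (input
#'   indices), `threshold_um`, `k`.
#' @export
quickbundles_cluster <- function(streamlines, threshold_um, k = 18) {
  if (inherits(streamlines, "streamline_set")) {
    streamlines <- streamlines$streamlines
  }
  if (threshold_um <= 0) stop("`threshold_um` must be > 0")
  if (length(streamlines) == 0L) return(list())
  rs <- lapply(streamlines, resample_streamline, k = k)
  sums <- list(); counts <- integer(); members <- list()
  for (i in seq_along(rs)) {
    s <- rs[[i]]
    placed <- FALSE
    for (b in seq_along(sums)) {
      ctr <- sums[[b]] / counts[b]
      direct <- mean(sqrt(rowSums((s - ctr)^2)))
      flip <- mean(sqrt(rowSums((s[k:1, , drop = FALSE] - ctr)^2)))
      if (min(direct, flip) <= threshold_um) {
        aligned <- if (flip < direct) s[k:1, , drop = FALSE] else s
        sums[[b]] <- sums[[b]] + aligned
        counts[b] <- counts[b] + 1L
        members[[b]] <- c(members[[b]], i)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      sums[[length(sums) + 1L]] <- s
      counts <- c(counts, 1L)
      members[[length(members) + 1L]] <- i
    }
  }
  lapply(seq_along(sums), function(b) {
    structure(list(centroid = sums[[b]] / counts[b], members = members[[b]],
                   threshold_um = threshold_um, k = k),
              class = "bundle")
  })
}

#' @export
print.bundle <- function(x, ...) {
  cat(sprintf("<bundle> %d member(s), centroid %d points, threshold %g um\n",
              length(x$members), nrow(x$centroid), x$threshold_um))
  invisible(x)
}

#' Streamline tortuosity
#'
#' The ratio `tau = L / d` of the piecewise trajectory length `L` to the
#' straight-line distance `d` between the endpoints; bounded below by 1
#' (perfectly straight). Undefined for coincident endpoints (`d = 0`): these
#' return `NA` with a warning and should be excluded from distributions.
#'
#' @param s n x 3 point matrix (um).
#' @return tortuosity (unitless, >= 1), or `NA` if undefined.
#' @export
tortuosity <- function(s) {
  s <- as.matrix(s)
  if (nrow(s) < 2) return(NA_real_)
  L <- streamline_length(s)
  d <- sqrt(sum((s[nrow(s), ] - s[1, ])^2))
  if (d <= 0) {
    warning("coincident endpoints: tortuosity undefined")
    return(NA_real_)
  }
  max(L / d, 1)
}

#' Maximum deviation from the endpoint chord
#'
#' The largest orthogonal distance of the interior points (i = 2..N-1) from
#' the straight line between the endpoints; the streamline's maximum
#' "amplitude" in um. Zero by convention for N <= 2; undefined (`NA`, with a
#' warning) for coincident endpoints.
#'
#' @param s n x 3 point matrix (um).
#' @return maximum deviation in um.
#' @export
max_deviation <- function(s) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (n <= 2) return(0)
  vd <- s[n, ] - s[1, ]
  d2 <- sum(vd^2)
  if (d2 <= 0) {
    warning("coincident endpoints: maximum deviation undefined")
    return(NA_real_)
  }
  rel <- sweep(s[2:(n - 1), , drop = FALSE], 2, s[1, ])
  proj <- (rel %*% vd) / d2
  perp <- rel - proj %*% t(vd)
  sqrt(max(rowSums(perp^2)))
}

#' Shape metrics for a set of streamlines or bundle centroids
#'
#' @param x a `streamline_set`, a list of bundles from
#'   [quickbundles_cluster()], or a list of point matrices.
#' @param on_centroids when `x` is a bundle list, compute on centroids
#'   (default, mirroring the practice of quantifying fasciculi by their
#'   centroid streamline); set FALSE to pool raw members.
#' @return data.frame with `length_um`, `endpoint_distance_um`, `tortuosity`,
#'   `max_deviation_um` per streamline (rows with undefined metrics dropped,
#'   with a message).
#' @export
streamline_metrics <- function(x, on_centroids = TRUE) {
  sl <- if (inherits(x, "streamline_set")) {
    x$streamlines
  } else if (length(x) && inherits(x[[1]], "bundle")) {
    if (on_centroids) lapply(x, `[[`, "centroid") else stop(
      "raw-member metrics need the original streamline_set; pass it directly")
  } else {
    x
  }
  if (!length(sl)) {
    return(data.frame(length_um = numeric(), endpoint_distance_um = numeric(),
                      tortuosity = numeric(), max_deviation_um = numeric()))
  }
  res <- data.frame(
    length_um = vapply(sl, streamline_length, 0),
    endpoint_distance_um = vapply(sl, function(s) {
      sqrt(sum((s[nrow(s), ] - s[1, ])^2))
    }, 0))
  res$tortuosity <- suppressWarnings(vapply(sl, tortuosity, 0))
  res$max_deviation_um <- suppressWarnings(vapply(sl, max_deviation, 0))
  bad <- !is.finite(res$tortuosity) | !is.finite(res$max_deviation_um)
  if (any(bad)) {
    message(sprintf("%d streamline(s) with coincident endpoints excluded", sum(bad)))
    res <- res[!bad, , drop = FALSE]
  }
  res
}

# Brown-Forsythe test for equality of variance between two samples: one-way
# ANOVA F statistic on the absolute deviations from the group medians.
brown_forsythe <- function(a, b) {
  za <- abs(a - stats::median(a))
  zb <- abs(b - stats::median(b))
  na <- length(za); nb <- length(zb)
  zbar <- mean(c(za, zb))
  ssb <- na * (mean(za) - zbar)^2 + nb * (mean(zb) - zbar)^2
  ssw <- sum((za - mean(za))^2) + sum((zb - mean(zb))^2)
  df2 <- na + nb - 2L
  if (ssw <= 0) {
    return(list(statistic = NA_real_, p.value = NA_real_, df = c(1L, df2)))
  }
  f <- ssb / (ssw / df2)
  list(statistic = f, p.value = stats::pf(f, 1, df2, lower.tail = FALSE),
       df = c(1L, df2))
}

#' Compare two metric distributions with three non-parametric tests
#'
#' Two-sample Kolmogorov-Smirnov (equality of distributions), two-sided
#' Wilcoxon rank-sum (equality of medians) and Brown-Forsythe (equality of
#' variance; ANOVA on absolute deviations from the group medians), with
#' significance decisions at level `alpha`.
#'
#' @param a,b numeric samples (each n >= 5).
#' @param alpha significance level (default 0.05).
#' @return a `test_report`: data.frame `tests` (test, statistic, p_value,
#'   reject), sample sizes, alpha, and a `degenerate` flag when the pooled
#'   sample has no variation.
#' @export
compare_groups <- function(a, b, alpha = 0.05) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 5 || length(b) < 5) stop("each group needs n >= 5")
  degenerate <- length(unique(c(a, b))) == 1L
  ks <- suppressWarnings(stats::ks.test(a, b))
  wx <- suppressWarnings(stats::wilcox.test(a, b))
  bf <- brown_forsythe(a, b)
  tests <- data.frame(
    test = c("kolmogorov-smirnov", "wilcoxon-rank-sum", "brown-forsythe"),
    statistic = c(unname(ks$statistic), unname(wx$statistic), bf$statistic),
    p_value = c(ks$p.value, wx$p.value, bf$p.value))
  tests$reject <- !is.na(tests$p_value) & tests$p_value < alpha
  structure(list(tests = tests, n = c(a = length(a), b = length(b)),
                 alpha = alpha, degenerate = degenerate),
            class = "test_report")
}

#' @export
print.test_report <- function(x, ...) {
  cat(sprintf("<test_report> n = (%d, %d), alpha = %g%s\n", x$n[1], x$n[2],
              x$alpha, if (x$degenerate) " [degenerate: no variation]" else ""))
  print(x$tests, row.names = FALSE)
  invisible(x)
}
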