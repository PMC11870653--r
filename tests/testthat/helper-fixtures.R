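# Shared fixtures, built once per test run and cached.

small_spec <- function(...) {
  phantom_spec(grid_shape = c(48, 48, 48), voxel_size_nm = 1000,
               fibre_radius_um = 2, fibre_spacing_um = 6, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

parallel_phantom_48 <- function() {
  cached("parallel48", build_parallel_fibre_volume(small_spec()))
}

parallel_eigen_48 <- function() {
  cached("parallel48_eigen", {
    ph <- parallel_phantom_48()
    structure_tensor_analysis(ph$volume, sigma = 1, rho = 4, gamma = 0.3)
  })
}

# Independent brute-force 3D convolution with mirror boundary (triple loop),
# used as the oracle for the separable filtering path.
brute_conv3 <- function(a, kx, ky, kz) {
  d <- dim(a)
  rx <- (length(kx) - 1) / 2; ry <- (length(ky) - 1) / 2
  rz <- (length(kz) - 1) / 2
  refl <- function(i, n) {
    p <- 2 * n
    j <- ((i - 1) %% p + p) %% p
    ifelse(j < n, j + 1, p - j)
  }
  out <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    s <- 0
    for (u in -rx:rx) for (v in -ry:ry) for (w in -rz:rz) {
      s <- s + kx[u + rx + 1] * ky[v + ry + 1] * kz[w + rz + 1] *
        a[refl(i + u, d[1]), refl(j + v, d[2]), refl(k + w, d[3])]
    }
    out[i, j, k] <- s
  }
  out
}

# Independent re-implementation of the sequential QuickBundles rule (first
# bundle within threshold wins; running flip-aligned centroid means), written
# against the published description rather than the package code.
qb_oracle <- function(streamlines, threshold, k) {
  resamp <- function(s) {
    seg <- sqrt(rowSums(diff(s)^2)); arc <- c(0, cumsum(seg))
    tt <- seq(0, arc[length(arc)], length.out = k)
    cbind(approx(arc, s[, 1], tt)$y, approx(arc, s[, 2], tt)$y,
          approx(arc, s[, 3], tt)$y)
  }
  rs <- lapply(streamlines, resamp)
  clusters <- list()   # each: list(sum =, n =, members =)
  for (i in seq_along(rs)) {
    s <- rs[[i]]
    assigned <- FALSE
    for (ci in seq_along(clusters)) {
      ctr <- clusters[[ci]]$sum / clusters[[ci]]$n
      dd <- mean(sqrt(rowSums((s - ctr)^2)))
      df <- mean(sqrt(rowSums((s[k:1, ] - ctr)^2)))
      if (min(dd, df) <= threshold) {
        add <- if (df < dd) s[k:1, ] else s
        clusters[[ci]]$sum <- clusters[[ci]]$sum + add
        clusters[[ci]]$n <- clusters[[ci]]$n + 1
        clusters[[ci]]$members <- c(clusters[[ci]]$members, i)
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      clusters[[length(clusters) + 1]] <- list(sum = s, n = 1, members = i)
    }
  }
  lapply(clusters, `[[`, "members")
}

random_streamlines <- function(n, n_pts = 8, scale = 50) {
  lapply(seq_len(n), function(i) {
    start <- runif(3, 0, scale)
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    tt <- seq(0, scale, length.out = n_pts)
    sweep(outer(tt, dir), 2, start, `+`) +
      matrix(rnorm(n_pts * 3, 0, 1), n_pts, 3)
  })
}
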