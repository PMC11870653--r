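test_that("ROI selection arithmetic on principal directions", {
  ef <- parallel_eigen_48()
  d <- dim(ef$fa)
  # no masks: everything off the zero mask and border
  all_dirs <- extract_principal_directions(ef)
  expect_equal(nrow(all_dirs), sum(!ef$zero_mask & !ef$border_mask))
  # exclusion removes exactly its share
  half <- array(FALSE, d); half[1:(d[1] / 2), , ] <- TRUE
  kept <- extract_principal_directions(ef, exclude = list(half))
  expect_equal(nrow(kept), sum(!ef$zero_mask & !ef$border_mask & !half))
  # include == exclude: empty selection errors with mask sizes
  full <- array(TRUE, d)
  expect_error(extract_principal_directions(ef, include = full,
                                            exclude = list(full)),
               "empty selection")
})

test_that("auto pole axis picks the axis with least directional contribution", {
  x_dirs <- matrix(rep(c(1, 0, 0), 20), ncol = 3, byrow = TRUE)
  expect_equal(auto_pole_axis(x_dirs), "z")    # tie z/y broken toward z
  # directions uniform in the x-y plane: z has zero mean |dot|
  set.seed(1)
  th <- runif(500, 0, 2 * pi)
  xy <- cbind(cos(th), sin(th), 0)
  expect_equal(auto_pole_axis(xy), "z")
  z_dirs <- matrix(rep(c(0, 0, 1), 20), ncol = 3, byrow = TRUE)
  expect_true(auto_pole_axis(z_dirs) %in% c("y", "x"))
})

test_that("FOD histograms are area-normalised densities on the hemisphere", {
  set.seed(5)
  v <- matrix(rnorm(3000), ncol = 3); v <- v / sqrt(rowSums(v^2))
  for (bw in c(5, 10, 30)) {
    fod <- build_fod(v, pole_axis = "z", bin_width_deg = bw)
    expect_lt(abs(sum(fod$bins$density * fod$bins$solid_angle) - 1), 1e-6)
    expect_true(all(fod$bins$density >= 0))
  }
  expect_error(build_fod(v, "z", 0.5), "bin_width")
  # directions lying exactly on the equator must still be fully binned
  eq <- rbind(matrix(rep(c(1, 0, 0), 50), ncol = 3, byrow = TRUE),
              matrix(rep(c(0, 0, 1), 50), ncol = 3, byrow = TRUE),
              matrix(rep(c(0, 0, -1), 50), ncol = 3, byrow = TRUE))
  feq <- build_fod(eq, "y", 5)
  expect_equal(sum(feq$bins$count), nrow(eq))
  expect_lt(abs(sum(feq$bins$density * feq$bins$solid_angle) - 1), 1e-6)
})

test_that("point-mass, antipodal and pole-direction inputs bin correctly", {
  # all directions identical (off-pole): one bin holds all mass, p = 1/dOmega
  u <- matrix(rep(c(cos(0.3), sin(0.3), 0.4), 50), ncol = 3, byrow = TRUE)
  u <- u / sqrt(rowSums(u^2))
  fod <- build_fod(u, "z", 5)
  hot <- fod$bins[fod$bins$count > 0, ]
  expect_equal(nrow(hot), 1L)
  expect_equal(hot$density, 1 / hot$solid_angle)
  # v and -v give identical histograms
  mixed <- rbind(u, -u)
  f2 <- build_fod(mixed, "z", 5)
  expect_equal(f2$bins$count, 2L * fod$bins$count)
  # directions exactly at the pole land in the single cap bin
  pole <- matrix(rep(c(0, 0, 1), 10), ncol = 3, byrow = TRUE)
  fp <- build_fod(pole, "z", 5)
  cap <- fp$bins[fp$bins$el_hi >= 90 & fp$bins$az_hi == 360, ]
  expect_equal(cap$count, 10L)
})

test_that("uniform axes give a flat FOD within Monte Carlo tolerance", {
  set.seed(1)
  v <- matrix(rnorm(3e6), ncol = 3); v <- v / sqrt(rowSums(v^2))
  fod <- build_fod(v, "z", 15)
  rel <- max(abs(fod$bins$density - 1 / (2 * pi))) / (1 / (2 * pi))
  expect_lt(rel, 0.05)
})

test_that("Bingham fit recovers self-generated parameters", {
  smp <- rbingham(5000, diag(3), c(50, 50), rng_seed = 3)
  fit <- fit_bingham(smp)
  expect_lt(abs(fit$kappa[1] - 50) / 50, 0.2)
  expect_lt(abs(fit$kappa[2] - 50) / 50, 0.2)
  expect_lt(acute_angle(fit$axes[, 3], c(0, 0, 1)), 3)
  expect_false(fit$degenerate)
})

test_that("Bingham limits: aligned, uniform and n < 10", {
  aligned <- matrix(rep(c(1, 0, 0), 100), ncol = 3, byrow = TRUE)
  fit <- fit_bingham(aligned)
  expect_equal(unname(fit$kappa[1]), 1e4)
  expect_lt(fit$odi, 0.001)
  set.seed(2)
  unif <- matrix(rnorm(6000), ncol = 3); unif <- unif / sqrt(rowSums(unif^2))
  fu <- fit_bingham(unif)
  # finite-sample scatter keeps the ML concentrations slightly above zero;
  # ODI approaches 1 from below
  expect_gt(fu$odi, 0.8)
  expect_lt(max(fu$kappa), 1)
  expect_error(fit_bingham(matrix(rnorm(9), 3)), "at least 10")
})

test_that("dispersion indices follow their closed forms and limits", {
  mk <- function(k1, k2) {
    structure(list(axes = diag(3), kappa = c(k1 = k1, k2 = k2), n = 100),
              class = "bingham_fit")
  }
  expect_equal(unname(dispersion_indices(mk(50, 50))["da"]), 0)
  expect_equal(unname(dispersion_indices(mk(100, 10))["da"]),
               (2 / pi) * atan(9), tolerance = 1e-12)
  expect_equal(round(unname(dispersion_indices(mk(100, 10))["da"]), 3), 0.930)
  expect_equal(unname(dispersion_indices(mk(0, 0))["odi"]), 1)
  expect_equal(unname(dispersion_indices(mk(120, 0))["da"]), 1)
  odi_big <- dispersion_indices(mk(1e4, 1e4))["odi"]
  expect_lt(unname(odi_big), 1e-3)    # kappa -> inf: no dispersion
  di <- dispersion_indices(mk(7, 3))
  expect_true(all(di >= 0 & di <= 1))
})

test_that("Bingham normalising constant matches direct spherical quadrature", {
  # independent oracle: brute-force midpoint-rule lat-long quadrature
  brute_c <- function(k1, k2, n_t = 4000, n_p = 800) {
    dt <- pi / n_t; dp <- 2 * pi / n_p
    th <- seq(dt / 2, pi - dt / 2, by = dt)
    ph <- seq(dp / 2, 2 * pi - dp / 2, by = dp)
    f <- outer(th, ph, function(t, p) {
      exp(-k1 * (sin(t) * cos(p))^2 - k2 * (sin(t) * sin(p))^2) * sin(t)
    })
    sum(f) * dt * dp / (4 * pi)
  }
  # tolerance set by the oracle's own discretisation error at high kappa
  for (k in list(c(0, 0), c(5, 2), c(60, 10), c(300, 300))) {
    expect_equal(fibretensor:::bingham_const(k[1], k[2]),
                 brute_c(k[1], k[2]), tolerance = 1e-4)
  }
})

test_that("angular jitter strictly increases ODI", {
  base <- matrix(rep(c(1, 0, 0), 4000), ncol = 3, byrow = TRUE)
  odis <- vapply(c(0, 5, 10, 20), function(j) {
    fit_bingham(jitter_directions(base, j, rng_seed = 11))$odi
  }, 0)
  expect_true(all(diff(odis) > 0))
})

test_that("FA density summaries behave across regimes", {
  # degenerate constant input
  dg <- fa_density(rep(0.5, 100))
  expect_true(dg$degenerate)
  expect_equal(dg$median, 0.5)
  expect_equal(dg$iqr, 0)
  # uniform sample: median near 0.5, density integrates to 1
  set.seed(4)
  u <- runif(1e5)
  s <- fa_density(u)
  expect_lt(abs(s$median - 0.5), 0.01)
  trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2) * diff(x[1:2])
  expect_lt(abs(trapz(s$x, s$y) - 1), 1e-3)
  # beta-shaped sample also integrates to 1
  b <- fa_density(rbeta(5000, 5, 2))
  expect_lt(abs(trapz(b$x, b$y) - 1), 1e-3)
  expect_error(fa_density(numeric()), "no FA values")
})

test_that("component volume fractions are plain voxel ratios", {
  ref <- array(FALSE, c(5, 5, 4)); ref[1:5, 1:5, 1] <- TRUE   # 25 voxels
  m <- array(FALSE, c(5, 5, 4)); m[1:5, 1, 1] <- TRUE          # 5 inside
  expect_equal(component_volume_fraction(m, ref), 20)
  expect_equal(component_volume_fraction(ref, ref), 100)
  expect_equal(component_volume_fraction(!ref, ref), 0)
  expect_error(component_volume_fraction(m, array(FALSE, c(5, 5, 4))),
               "empty reference")
})
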