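test_that("parallel phantom geometry matches its ground truth", {
  ph <- parallel_phantom_48()
  o <- matrix(ph$truth$orientation, ncol = 3)
  fib <- !is.na(o[, 1])
  expect_true(all(abs(o[fib, 1]) == 1))         # every orientation is +x
  expect_true(all(o[fib, 2] == 0 & o[fib, 3] == 0))
  # dark tubes on bright background
  expect_lt(min(ph$volume$data), ph$truth$spec$background_intensity)
  expect_equal(max(ph$volume$data), ph$truth$spec$background_intensity)
})

test_that("fibre volume fraction is close to the analytic packing fraction", {
  ph <- parallel_phantom_48()
  sp <- ph$truth$spec
  frac <- mean(ph$truth$labels %in% c(1L, 2L))
  analytic <- pi * sp$fibre_radius_um^2 / sp$fibre_spacing_um^2
  expect_lt(abs(frac - analytic) / analytic, 0.10)
})

test_that("two-radius phantom partitions the halves by population", {
  sp <- phantom_spec(grid_shape = c(48, 48, 48), voxel_size_nm = 500,
                     fibre_radius_um = c(1, 4), fibre_spacing_um = 10)
  ph <- build_parallel_fibre_volume(sp)
  lab <- ph$truth$labels
  nz <- dim(lab)[3]
  lower <- lab[, , 1:(nz / 2)]
  upper <- lab[, , (nz / 2 + 1):nz]
  expect_true(all(lower[lower != 0] == 1L))
  expect_true(all(upper[upper != 0] == 2L))
})

test_that("unresolvable fibre radius errors with the minimum radius", {
  sp <- small_spec()
  sp$fibre_radius_um <- 1.2   # < 2 voxels at 1 um
  expect_error(build_parallel_fibre_volume(sp), "minimum radius is 2")
})

test_that("laminar phantom alternates directions by the inclination angle", {
  sp <- small_spec(lamina_thickness_um = 16, lamina_inclination_deg = 35)
  ph <- build_laminar_volume(sp)
  dirs <- ph$truth$slab_directions
  expect_equal(acute_angle(dirs[1, ], dirs[2, ]), 35, tolerance = 1e-9)
  # slab boundaries sit at multiples of the thickness along z: every fibre
  # voxel's label matches the parity of its slab index, and all slabs with
  # room for a tube are populated
  lab <- ph$truth$labels
  fib <- which(lab != 0L, arr.ind = TRUE)
  z_um <- (fib[, 3] - 1) * 1                      # voxel size 1 um
  slab <- floor((z_um + 0.5) / 16)                # grid starts at -0.5 um
  expected <- ifelse(slab %% 2 == 0, 1L, 2L)
  expect_true(all(lab[fib] == expected))
  expect_equal(sort(unique(slab)), 0:2)           # 48 um / 16 um slabs
  expect_error(build_laminar_volume(small_spec(lamina_inclination_deg = 95)),
               "inclination")
})

test_that("zero inclination reduces the laminar phantom to parallel fibres", {
  sp <- small_spec(lamina_thickness_um = 16, lamina_inclination_deg = 0)
  ph <- build_laminar_volume(sp)
  o <- matrix(ph$truth$orientation, ncol = 3)
  o <- o[!is.na(o[, 1]), , drop = FALSE]
  expect_lt(max(acute_angle(o, c(1, 0, 0))), 1e-9)
})

test_that("crossing phantom populations are orthogonal at 90 degrees with balanced volumes", {
  sp <- small_spec(lamina_thickness_um = 12, crossing_angle_deg = 90)
  ph <- build_crossing_volume(sp)
  dirs <- ph$truth$slab_directions
  expect_equal(abs(sum(dirs[1, ] * dirs[2, ])), 0, tolerance = 1e-12)
  n1 <- sum(ph$truth$labels == 1L)
  n2 <- sum(ph$truth$labels == 2L)
  expect_lt(abs(n1 - n2) / max(n1, n2), 0.05)
  # the ground-truth FOD has exactly two nonzero modes
  o <- matrix(ph$truth$orientation, ncol = 3)
  o <- o[!is.na(o[, 1]), , drop = FALSE]
  fod <- build_fod(o, pole_axis = "y", bin_width_deg = 5)
  expect_equal(sum(fod$bins$count > 0), 2L)
})

test_that("re-rendering from ground truth reproduces the volume exactly", {
  ph <- parallel_phantom_48()
  rr <- render_from_truth(ph$truth)
  expect_identical(rr$data, ph$volume$data)
})

test_that("obstacle insertion deflects nearby paths and leaves far ones alone", {
  ph <- parallel_phantom_48()
  # empty obstacle list: identity
  same <- insert_obstacles(ph$volume, ph$truth, list())
  expect_identical(same$volume$data, ph$volume$data)
  ob <- obstacle_spec("cylinder", center_vox = c(24.5, 24.5, 24),
                      radius_um = 6, axis = c(0, 0, 1),
                      deflection_halo_um = 12)
  res <- insert_obstacles(ph$volume, ph$truth, list(ob))
  disp <- vapply(seq_along(ph$truth$fibre_paths), function(i) {
    max(sqrt(rowSums((res$truth$fibre_paths[[i]] -
                        ph$truth$fibre_paths[[i]])^2)))
  }, 0)
  b <- vapply(ph$truth$fibre_paths, function(p) {
    min(sqrt((p[, 2] - 23.5)^2 + 0))   # impact parameter in y
  }, 0)
  nearest <- which.min(b)
  expect_gte(disp[nearest], 6)                 # at least the radius
  expect_lte(max(disp), 12)                    # at most the halo
  expect_true(all(disp[b > 6 + 12] == 0))      # outside halo: untouched
  # image re-rendered consistently with the deflected truth
  expect_identical(render_from_truth(res$truth)$data, res$volume$data)
  # an obstacle spanning the whole cross-section is rejected
  big <- obstacle_spec("cylinder", center_vox = c(24, 24, 24),
                       radius_um = 30, axis = c(0, 0, 1),
                       deflection_halo_um = 30)
  expect_error(insert_obstacles(ph$volume, ph$truth, list(big)),
               "entire cross-section")
})

test_that("demyelination halves the intensity gap inside the region only", {
  ph <- parallel_phantom_48()
  region <- list(lo = c(9, 9, 9), hi = c(40, 40, 40))
  # identity case
  same <- apply_demyelination(ph$volume, ph$truth, region, contrast_factor = 1)
  expect_identical(same$volume$data, ph$volume$data)
  res <- apply_demyelination(ph$volume, ph$truth, region,
                             contrast_factor = 0.5)
  bg <- ph$truth$spec$background_intensity
  inside <- array(FALSE, dim(ph$volume$data))
  inside[9:40, 9:40, 9:40] <- TRUE
  fib <- ph$truth$labels != 0
  gap_in <- mean(bg - res$volume$data[inside & fib])
  gap_out <- mean(bg - res$volume$data[!inside & fib])
  expect_equal(gap_in / gap_out, 0.5, tolerance = 0.05)
  # orientations untouched
  expect_identical(res$truth$orientation, ph$truth$orientation)
  expect_true(all(res$truth$labels[inside & fib] == 4L))
  expect_error(
    apply_demyelination(ph$volume, ph$truth,
                        list(lo = c(0, 1, 1), hi = c(10, 10, 10)), 0.5),
    "outside the grid")
  expect_error(
    apply_demyelination(ph$volume, ph$truth, region, contrast_factor = 0),
    "contrast_factor")
})

test_that("added cells appear at the requested density", {
  ph <- parallel_phantom_48()
  region <- list(lo = c(5, 5, 5), hi = c(44, 44, 44))
  dens <- 3e5   # per mm^3; region is 40^3 um^3 = 6.4e-5 mm^3 -> ~19 cells
  res <- apply_demyelination(ph$volume, ph$truth, region, 1,
                             extra_cell_density_mm3 = dens)
  expect_equal(length(res$truth$cells), round(dens * 40^3 / 1e9))
  expect_gt(max(res$volume$data), ph$truth$spec$background_intensity)
})

test_that("imaging noise is unbiased, has the requested sd, and is seed-reproducible", {
  v <- image_volume(array(50, c(100, 100, 100)), 550)
  expect_identical(add_imaging_noise(v, 0)$data, v$data)
  n1 <- add_imaging_noise(v, 3, rng_seed = 7)
  n2 <- add_imaging_noise(v, 3, rng_seed = 7)
  expect_identical(n1$data, n2$data)
  resid <- n1$data - v$data
  expect_lt(abs(sd(resid) - 3) / 3, 0.02)
  expect_lt(abs(mean(resid)), 0.05)
})

test_that("phantom generation is reproducible from spec and seed", {
  sp <- small_spec(jitter_um = 0.5, rng_seed = 11)
  a <- build_parallel_fibre_volume(sp)
  b <- build_parallel_fibre_volume(sp)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$truth$fibre_paths, b$truth$fibre_paths)
})
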