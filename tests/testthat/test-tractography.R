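test_that("Otsu masking separates a two-level image exactly", {
  a <- array(0, c(16, 16, 16))
  a[5:12, 5:12, 5:12] <- 1
  m <- make_mask(a, method = "otsu", voxel_size_nm = 1000)
  expect_identical(m$mask, a == 1)
  # opening larger than every component empties the mask (with a warning)
  sm <- array(0, c(16, 16, 16)); sm[8, 8, 8] <- 1
  expect_warning(me <- make_mask(sm, method = "fixed", threshold = 0.5,
                                 opening_radius = 2, voxel_size_nm = 1000),
                 "empty")
  expect_false(any(me$mask))
})

test_that("midpoint intensity threshold recovers the phantom fibre mask", {
  ph <- parallel_phantom_48()
  m <- make_mask(ph$volume, method = "fixed",
                 threshold = mean(range(ph$volume$data)), select = "below")
  fib <- ph$truth$labels != 0
  expect_gt(sum(m$mask & fib) / sum(fib), 0.95)
})

test_that("seed placement is exact at density 1 and contained when jittered", {
  msk <- array(FALSE, c(10, 10, 10))
  msk[2:6, 3, 4] <- TRUE; msk[8, 8, 8:12 - 4] <- TRUE
  rm <- roi_mask(msk, 1000, "seed")
  s1 <- place_seeds(rm, tracking_config(seed_density = 1))
  expect_equal(nrow(s1), sum(msk))
  vox <- which(msk, arr.ind = TRUE)
  expect_equal(s1[order(s1[, 1], s1[, 2], s1[, 3]), , drop = FALSE],
               {
                 ctr <- (vox - 1) * 1
                 colnames(ctr) <- c("x", "y", "z")
                 ctr[order(ctr[, 1], ctr[, 2], ctr[, 3]), , drop = FALSE]
               })
  s4 <- place_seeds(rm, tracking_config(seed_density = 4, rng_seed = 2))
  expect_equal(nrow(s4), 4L * sum(msk))
  home <- attr(s4, "voxel")
  expect_true(all(abs(s4 - (home - 1) * 1) <= 0.5 + 1e-12))
  s4b <- place_seeds(rm, tracking_config(seed_density = 4, rng_seed = 2))
  expect_identical(s4, s4b)
  expect_error(place_seeds(roi_mask(array(FALSE, c(4, 4, 4)), 1000)),
               "empty")
})

test_that("FACT tracks a uniform field straight across the volume", {
  d <- c(20, 20, 20)
  dirs <- array(0, c(d, 3)); dirs[, , , 1] <- 1
  mask <- roi_mask(array(TRUE, d), 1000, "tracking")
  ss <- track_fact(dirs, matrix(c(9.5, 10, 10), 1), mask, tracking_config())
  expect_length(ss$streamlines, 1L)
  s <- ss$streamlines[[1]]
  expect_equal(range(s[, 1]), c(-0.5, 19.5))
  expect_equal(tortuosity(s), 1, tolerance = 1e-12)
  expect_equal(attr(s, "reason"), c("mask-exit", "mask-exit"))
})

test_that("FACT terminates on sharp turns and zero directions", {
  d <- c(20, 20, 20)
  dirs <- array(0, c(d, 3))
  dirs[1:10, , , 1] <- 1; dirs[11:20, , , 3] <- 1   # 90-degree interface
  mask <- roi_mask(array(TRUE, d), 1000, "tracking")
  ss <- track_fact(dirs, matrix(c(2, 10, 10), 1), mask,
                   tracking_config(angle_threshold_deg = 60))
  s <- ss$streamlines[[1]]
  expect_true("angle" %in% attr(s, "reason"))
  expect_lte(max(s[, 1]), 9.5)                      # stopped at the interface
  dz <- array(0, c(d, 3)); dz[, , , 1] <- 1
  dz[15:20, , , ] <- 0                              # zero-direction region
  sz <- track_fact(dz, matrix(c(2, 10, 10), 1), mask,
                   tracking_config(angle_threshold_deg = 89))
  expect_true("zero-direction" %in% attr(sz$streamlines[[1]], "reason"))
  # seeds outside the mask are skipped with a message
  m2 <- array(TRUE, d); m2[1:5, , ] <- FALSE
  expect_message(
    s2 <- track_fact(dirs, matrix(c(2, 10, 10), 1),
                     roi_mask(m2, 1000, "t"), tracking_config()),
    "skipped")
  expect_length(s2$streamlines, 0L)
})

test_that("a circular tangent field yields the quarter-arc tortuosity", {
  n <- 200
  dn <- c(n, n, 3)
  cx <- (n - 1) / 2; cy <- (n - 1) / 2
  dirs <- array(0, c(dn, 3))
  ii <- matrix(seq_len(n) - 1, n, n)
  dx <- ii - cx; dy <- t(ii) - cy
  r <- sqrt(dx^2 + dy^2); r[r < 1e-6] <- Inf
  for (k in 1:3) {
    dirs[, , k, 1] <- -dy / r
    dirs[, , k, 2] <- dx / r
  }
  mask <- roi_mask(array(TRUE, dn), 1000, "t")
  cfg <- tracking_config(angle_threshold_deg = 10,
                         max_length_um = 2 * pi * 50 / 4,
                         bidirectional = FALSE)
  ss <- track_fact(dirs, matrix(c(cx + 50, cy, 1), 1), mask, cfg)
  tau <- tortuosity(ss$streamlines[[1]])
  expect_lt(abs(tau - (pi / 2) / sqrt(2)) / ((pi / 2) / sqrt(2)), 0.02)
})

test_that("tracking is deterministic and invariant to global sign flips", {
  ph <- parallel_phantom_48()
  ef <- parallel_eigen_48()
  d <- dim(ph$volume$data)
  mask <- roi_mask(array(TRUE, d), 1000, "tracking")
  sm <- array(FALSE, d); sm[4, seq(4, 45, by = 6), seq(4, 45, by = 6)] <- TRUE
  seeds <- place_seeds(roi_mask(sm, 1000, "seed"))
  a <- track_fact(ef, seeds, mask, tracking_config())
  b <- track_fact(ef, seeds, mask, tracking_config())
  expect_identical(a$streamlines, b$streamlines)
  flipped <- array(-matrix(ef$v1, ncol = 3), c(d, 3))
  cfgd <- tracking_config()
  c2 <- track_fact(flipped, seeds, mask, cfgd)
  norm_set <- function(ss) {
    lapply(ss$streamlines, function(s) {
      s <- unclass(s); attributes(s) <- list(dim = dim(s))
      if (nrow(s) > 1 && (s[1, 1] > s[nrow(s), 1])) s <- s[nrow(s):1, ]
      round(s, 9)
    })
  }
  c1 <- track_fact(array(matrix(ef$v1, ncol = 3), c(d, 3)), seeds, mask, cfgd)
  expect_equal(norm_set(c2), norm_set(c1))
})

test_that("spanning streamlines on the noiseless parallel phantom are straight", {
  ph <- parallel_phantom_48()
  ef <- parallel_eigen_48()
  d <- dim(ph$volume$data)
  mask <- roi_mask(array(TRUE, d), 1000, "tracking")
  sm <- array(FALSE, d)
  sm[4, , ] <- TRUE
  sm <- sm & (ph$truth$labels != 0)
  seeds <- place_seeds(roi_mask(sm, 1000, "seed"))
  ss <- track_fact(ef, seeds, mask, tracking_config())
  inc_far <- box_mask(d, c(45, 1, 1), c(48, 48, 48), 1000, "far-end")
  inc_near <- box_mask(d, c(1, 1, 1), c(4, 48, 48), 1000, "near-end")
  spanning <- apply_roi_filters(ss, inclusion = list(inc_near, inc_far))
  expect_gte(length(spanning) / nrow(seeds), 0.95)
  taus <- vapply(spanning$streamlines, tortuosity, 0)
  expect_true(all(taus < 1.005))
})

test_that("ROI filters keep exactly the streamlines that satisfy the masks", {
  d <- c(20, 20, 20)
  dirs <- array(0, c(d, 3)); dirs[, , , 1] <- 1
  mask <- roi_mask(array(TRUE, d), 1000, "tracking")
  seeds <- rbind(c(9.5, 5, 5), c(9.5, 15, 15))
  ss <- track_fact(dirs, seeds, mask, tracking_config())
  # no masks, zero min length: identity
  id <- apply_roi_filters(ss)
  expect_identical(id$streamlines, ss$streamlines)
  # rejection mask on one lane removes exactly that streamline
  rej <- array(FALSE, d); rej[, 14:16, 14:16] <- TRUE
  kept <- apply_roi_filters(ss, rejection = list(roi_mask(rej, 1000, "rej")))
  expect_length(kept$streamlines, 1L)
  vox <- fibretensor:::visited_voxels(kept$streamlines[[1]], 1)
  vox <- vox[apply(vox >= 1 & vox <= matrix(d, nrow(vox), 3, byrow = TRUE),
                   1, all), , drop = FALSE]
  expect_false(any(rej[vox]))
  # inclusion mask both ends: both survive; impossible inclusion: none
  inc <- array(FALSE, d); inc[19:20, , ] <- TRUE
  expect_length(
    apply_roi_filters(ss, inclusion = list(roi_mask(inc, 1000, "i")))$streamlines,
    2L)
  far <- array(FALSE, d); far[, 1, 20] <- TRUE
  expect_length(
    apply_roi_filters(ss, inclusion = list(roi_mask(far, 1000, "i")))$streamlines,
    0L)
  # min length filter
  expect_length(apply_roi_filters(ss, min_length_um = 100)$streamlines, 0L)
})
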