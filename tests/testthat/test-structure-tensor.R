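test_that("constant volume yields a zero tensor everywhere", {
  v <- image_volume(array(5, c(24, 24, 24)), 1000)
  tf <- compute_structure_tensor(v, sigma = 1, rho = 2)
  # all that remains of a constant volume is squared round-off noise
  expect_lt(max(abs(tf$xx), abs(tf$yy), abs(tf$zz)), 1e-25)
  ef <- eigendecompose_field(tf)
  expect_true(all(ef$zero_mask))
  # zero-mask voxels get isotropic eigenvalues by convention
  expect_true(all(ef$l1s == 1 / 3))
})

test_that("a tube along x gives raw minor eigenvectors within 5 degrees of x", {
  ph <- parallel_phantom_48()
  tf <- compute_structure_tensor(ph$volume, sigma = 1, rho = 4)
  ef <- eigendecompose_field(tf)
  interior <- fibre_interior(ph$truth) & !ef$border_mask
  v3 <- matrix(ef$v3, ncol = 3)[as.vector(interior), , drop = FALSE]
  expect_gt(nrow(v3), 100)
  expect_lt(max(acute_angle(v3, c(1, 0, 0))), 5)
})

test_that("separable filtering equals brute-force 3D convolution", {
  set.seed(3)
  a <- array(rnorm(16^3), c(16, 16, 16))
  k <- fibretensor:::gaussian_kernel(1.2, 2)
  sep <- fibretensor:::conv_axis(
    fibretensor:::conv_axis(fibretensor:::conv_axis(a, k, 1), k, 2), k, 3)
  bf <- brute_conv3(a, k, k, k)
  expect_lt(max(abs(sep - bf)) / max(abs(bf)), 1e-6)
})

test_that("too-small volumes are rejected with the required size", {
  v <- image_volume(array(rnorm(8^3), c(8, 8, 8)), 1000)
  expect_error(compute_structure_tensor(v, sigma = 3, rho = 6), "need >=")
})

test_that("eigendecomposition matches base eigen() on random PSD tensors", {
  set.seed(42)
  d <- c(4, 4, 4)
  n <- prod(d)
  As <- replicate(n, crossprod(matrix(rnorm(9), 3, 3)))
  tf <- structure(list(
    xx = array(As[1, 1, ], d), xy = array(As[1, 2, ], d),
    xz = array(As[1, 3, ], d), yy = array(As[2, 2, ], d),
    yz = array(As[2, 3, ], d), zz = array(As[3, 3, ], d),
    voxel_size_nm = 100, sigma = 1, rho = 1, scale_id = 0L,
    border_mask = array(FALSE, d)), class = "tensor_field")
  ef <- eigendecompose_field(tf)
  v1 <- matrix(ef$v1, ncol = 3); v2 <- matrix(ef$v2, ncol = 3)
  v3 <- matrix(ef$v3, ncol = 3)
  tr <- as.vector(ef$trace)
  l <- cbind(as.vector(ef$l1s), as.vector(ef$l2s), as.vector(ef$l3s)) * tr
  for (i in seq_len(n)) {
    # spectral reconstruction: sum lambda_i* (trace) v_i v_i^T equals input
    R <- l[i, 1] * tcrossprod(v1[i, ]) + l[i, 2] * tcrossprod(v2[i, ]) +
      l[i, 3] * tcrossprod(v3[i, ])
    expect_lt(max(abs(R - As[, , i])), 1e-8)
    # orthonormal frame
    G <- rbind(v1[i, ], v2[i, ], v3[i, ])
    expect_lt(max(abs(G %*% t(G) - diag(3))), 1e-9)
    # sorted eigenvalues agree with base eigen()
    expect_equal(sort(l[i, ], decreasing = TRUE), l[i, ])
    expect_equal(l[i, ], eigen(As[, , i], symmetric = TRUE)$values,
                 tolerance = 1e-10)
  }
})

test_that("identity and diagonal tensors decompose as expected", {
  d <- c(2, 2, 2)
  mk <- function(xx, yy, zz) {
    structure(list(xx = array(xx, d), xy = array(0, d), xz = array(0, d),
                   yy = array(yy, d), yz = array(0, d), zz = array(zz, d),
                   voxel_size_nm = 100, sigma = 1, rho = 1, scale_id = 0L,
                   border_mask = array(FALSE, d)), class = "tensor_field")
  }
  ef <- eigendecompose_field(mk(1, 1, 1))
  expect_equal(as.vector(ef$l1s), rep(1 / 3, 8))
  ef2 <- eigendecompose_field(mk(4, 1, 0))
  expect_equal(as.vector(ef2$l1s), rep(0.8, 8))
  expect_equal(as.vector(ef2$l2s), rep(0.2, 8))
  expect_equal(as.vector(ef2$l3s), rep(0, 8))
  v1 <- matrix(ef2$v1, ncol = 3)
  expect_equal(abs(v1[, 1]), rep(1, 8))
})

test_that("gamma conversion reproduces the worked example and reverses ordering", {
  d <- c(2, 2, 2)
  ef <- structure(list(
    l1s = array(1, d), l2s = array(0, d), l3s = array(0, d),
    trace = array(1, d),
    v1 = array(rep(c(1, 0, 0), each = 8), c(d, 3)),
    v2 = array(rep(c(0, 1, 0), each = 8), c(d, 3)),
    v3 = array(rep(c(0, 0, 1), each = 8), c(d, 3)),
    l1 = NULL, l2 = NULL, l3 = NULL, fa = NULL, gamma = NULL,
    zero_mask = array(FALSE, d), border_mask = array(FALSE, d),
    voxel_size_nm = 100, sigma = 1, rho = 1, scale_id = 0L),
    class = "eigen_field")
  conv <- convert_eigenvalues(ef, gamma = 0.3)
  # lambda* = (1, 0, 0), gamma 0.3: exp(-1/0.3) = 0.03567;
  # normalised descending = (0.4912, 0.4912, 0.0175)
  expect_equal(conv$l1[1, 1, 1], 1 / (2 + exp(-1 / 0.3)), tolerance = 1e-4)
  expect_equal(round(conv$l1[1, 1, 1], 4), 0.4912)
  expect_equal(round(conv$l3[1, 1, 1], 4), 0.0175)
  # the fibre direction (largest converted) is the raw smallest-lambda* axis
  expect_equal(matrix(conv$v1, ncol = 3)[1, ], c(0, 0, 1))
  # isotropic input stays isotropic for any gamma
  ef$l1s[] <- 1 / 3; ef$l2s[] <- 1 / 3; ef$l3s[] <- 1 / 3
  for (g in c(0.1, 0.3, 1)) {
    ci <- convert_eigenvalues(ef, g)
    expect_equal(as.vector(ci$l1), rep(1 / 3, 8))
  }
  # monotonicity: conversion reverses every strict ordering
  set.seed(1)
  for (i in 1:20) {
    raw <- sort(runif(3), decreasing = TRUE); raw <- raw / sum(raw)
    conv_i <- exp(-raw / 0.25); conv_i <- conv_i / sum(conv_i)
    expect_true(all(diff(conv_i) >= 0))
  }
  expect_error(convert_eigenvalues(ef, gamma = 0), "gamma")
})

test_that("fractional anisotropy reproduces its closed-form cases", {
  d <- c(2, 2, 2)
  base <- structure(list(
    l1s = array(1 / 3, d), l2s = array(1 / 3, d), l3s = array(1 / 3, d),
    trace = array(1, d),
    v1 = array(rep(c(1, 0, 0), each = 8), c(d, 3)),
    v2 = array(rep(c(0, 1, 0), each = 8), c(d, 3)),
    v3 = array(rep(c(0, 0, 1), each = 8), c(d, 3)),
    zero_mask = array(FALSE, d), border_mask = array(FALSE, d),
    voxel_size_nm = 100, sigma = 1, rho = 1, scale_id = 0L),
    class = "eigen_field")
  iso <- base; iso$l1 <- array(1 / 3, d); iso$l2 <- array(1 / 3, d)
  iso$l3 <- array(1 / 3, d)
  expect_equal(max(abs(fractional_anisotropy(iso)$fa)), 0)
  stick <- base; stick$l1 <- array(1, d); stick$l2 <- array(0, d)
  stick$l3 <- array(0, d)
  expect_equal(min(fractional_anisotropy(stick)$fa), 1)
  mid <- base; mid$l1 <- array(0.6, d); mid$l2 <- array(0.3, d)
  mid$l3 <- array(0.1, d)
  expect_equal(fractional_anisotropy(mid)$fa[1, 1, 1], 0.6426846,
               tolerance = 1e-6)
})

test_that("dominant-scale selection follows the normalised-argmax rule", {
  d <- c(2, 1, 1)
  mk_fa <- function(fa_vals) {
    structure(list(
      l1s = array(0.5, d), l2s = array(0.3, d), l3s = array(0.2, d),
      trace = array(1, d),
      l1 = array(0.5, d), l2 = array(0.3, d), l3 = array(0.2, d),
      v1 = array(rep(c(1, 0, 0), each = 2), c(d, 3)),
      v2 = array(rep(c(0, 1, 0), each = 2), c(d, 3)),
      v3 = array(rep(c(0, 0, 1), each = 2), c(d, 3)),
      fa = array(fa_vals, d),
      zero_mask = array(FALSE, d), border_mask = array(FALSE, d),
      voxel_size_nm = 100, sigma = 1, rho = 1, scale_id = 0L),
      class = "eigen_field")
  }
  # hand-evaluated: A = (0.8, 0.2) -> normalised (1.0, 0.25);
  #                 B = (0.5, 0.45) -> (1.0, 0.9)  =>  winners (A, B)
  sel <- scale_space_select(list(mk_fa(c(0.8, 0.2)), mk_fa(c(0.5, 0.45))))
  expect_equal(as.vector(sel$dominant$d), c(1L, 2L))
  expect_equal(sel$eigen$fa[2, 1, 1], 0.45)
  # single scale: trivially scale 1 everywhere
  s1 <- scale_space_select(list(mk_fa(c(0.8, 0.2))))
  expect_true(all(s1$dominant$d == 1L))
  # proportional FA maps tie everywhere: lowest index wins
  s2 <- scale_space_select(list(mk_fa(c(0.8, 0.4)), mk_fa(c(0.4, 0.2))))
  expect_true(all(s2$dominant$d == 1L))
  # an all-zero-FA scale contributes score 0 (message, not an error)
  expect_message(
    s3 <- scale_space_select(list(mk_fa(c(0.8, 0.2)), mk_fa(c(0, 0)))),
    "zero maximum FA")
  expect_true(all(s3$dominant$d == 1L))
})

test_that("principal directions are equivariant under a 90-degree volume rotation", {
  ph <- parallel_phantom_48()
  ef <- parallel_eigen_48()
  # rotate +90 degrees about z: x-fibres become y-fibres
  rot <- aperm(ph$volume$data, c(2, 1, 3))[, dim(ph$volume$data)[1]:1, ]
  efr <- structure_tensor_analysis(image_volume(rot, 1000), 1, 4, 0.3)
  fib <- fibre_interior(ph$truth) & !ef$border_mask
  fibr <- aperm(fib, c(2, 1, 3))[, dim(fib)[1]:1, ]
  v1r <- matrix(efr$v1, ncol = 3)[as.vector(fibr), , drop = FALSE]
  expect_lt(max(acute_angle(v1r, c(0, 1, 0))), 2)
})

test_that("converted eigenvalues sum to one off the zero mask", {
  ef <- parallel_eigen_48()
  s <- ef$l1 + ef$l2 + ef$l3
  expect_lt(max(abs(s[!ef$zero_mask] - 1)), 1e-12)
})

test_that("kernel-size bookkeeping uses the truncated width times effective voxel size", {
  # width (2 ceil(2 rho) + 1) voxels x (voxel size x scaling)
  expect_equal(kernel_size_um(2, 1000, 1), 9)
  expect_equal(kernel_size_um(2.5, 550, 2), 12.1)
})
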