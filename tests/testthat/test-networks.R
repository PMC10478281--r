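test_that("generator preserves shape and bounds its output", {
  set.seed(1)
  G <- build_generator(generator_config(base_channels = 4,
                                        n_residual_blocks = 2))
  for (n in c(64L, 256L)) {
    x <- array(runif(n * n, -1, 1), c(n, n, 1))
    y <- generator_apply(G, x)
    expect_equal(dim(y), c(n, n, 1))
    expect_true(all(y >= -1 & y <= 1))
  }
  expect_error(generator_apply(G, array(0, c(30, 30, 1))), "divisible by 4")
})

test_that("zero-initialized generator head emits the window midpoint", {
  set.seed(1)
  G <- build_generator(generator_config(base_channels = 4,
                                        n_residual_blocks = 1),
                       zero_init_head = TRUE)
  y <- generator_apply(G, array(runif(64 * 64, -1, 1), c(64, 64, 1)))
  expect_true(all(y == 0))  # tanh(0); denormalizes to 500 HU
  expect_equal(denormalize_hu(y[, , 1], c(-1000, 2000))$values[1, 1], 500)
})

test_that("registration network is the zero field at initialization", {
  set.seed(2)
  R <- build_registration(registration_config(encoder_depth = 3,
                                              base_channels = 4))
  a <- matrix(runif(64 * 64, -1, 1), 64, 64)
  b <- matrix(runif(64 * 64, -1, 1), 64, 64)
  f <- registration_apply(R, a, b)
  expect_equal(dim(f), c(64, 64, 2))
  expect_true(all(f == 0))
  expect_error(registration_apply(R, a, matrix(0, 32, 32)),
               "same spatial shape")
})

test_that("discriminator emits a patch score map, not a scalar", {
  set.seed(3)
  D <- build_discriminator(discriminator_config(base_channels = 4))
  s <- discriminator_apply(D, array(runif(256 * 256, -1, 1), c(256, 256, 1)))
  expect_equal(dim(s)[1], dim(s)[2])
  expect_gte(dim(s)[1], 8)   # 256 -> 128 -> 64 -> 32 -> 31 under stride 2,2,2,1
  s1 <- discriminator_apply(D, array(0.3, c(64, 64, 1)))
  s2 <- discriminator_apply(D, array(-0.4, c(64, 64, 1)))
  expect_false(identical(s1, s2))
  expect_error(discriminator_apply(D, array(0, c(8, 8, 1))), "too small")
})

test_that("warp with the zero field is the identity", {
  set.seed(4)
  img <- matrix(rnorm(32 * 32), 32, 32)
  f0 <- array(0, c(32, 32, 2))
  expect_lt(max(abs(warp(img, f0) - img)), 1e-6)
})

test_that("a unit column shift relocates a ramp image exactly", {
  ramp <- matrix(rep(0:4, each = 5), 5, 5)  # columns are 0,1,2,3,4
  f <- array(0, c(5, 5, 2)); f[, , 2] <- 1  # sample one column to the right
  out <- warp(ramp, f)
  expect_equal(out[, 1:4], ramp[, 2:5])
  const <- matrix(7, 5, 5)
  expect_equal(warp(const, f), const)
})

test_that("warping is linear in the image argument", {
  set.seed(5)
  i1 <- matrix(rnorm(24 * 24), 24, 24)
  i2 <- matrix(rnorm(24 * 24), 24, 24)
  f <- unclass(random_deformation(c(24, 24), 3, 4, 6))
  lhs <- warp(2.5 * i1 - 1.3 * i2, f)
  rhs <- 2.5 * warp(i1, f) - 1.3 * warp(i2, f)
  expect_lt(max(abs(lhs - rhs)), 1e-6)
})

test_that("composing two smooth warps approximates the composed field", {
  img <- smooth_norm_image(64)
  f <- unclass(random_deformation(c(64, 64), 2, 10, 7))
  g <- unclass(random_deformation(c(64, 64), 2, 10, 8))
  two_step <- warp(warp(img, f), g)
  # composed field: g followed by f sampled at the g-displaced positions
  comp <- g
  comp[, , 1] <- g[, , 1] + warp(f[, , 1], g)
  comp[, , 2] <- g[, , 2] + warp(f[, , 2], g)
  one_step <- warp(img, comp)
  # tolerance from the interpolation error scale of a single resampling
  expect_lt(mean(abs(two_step - one_step)), 0.01)
})

test_that("parameter counting sees every layer", {
  G <- build_generator(generator_config(base_channels = 4,
                                        n_residual_blocks = 1))
  # stem 7x7x1x4+4, down 3x3x4x8+8 and 3x3x8x16+16, res 2*(3x3x16x16+16),
  # up 3x3x8x16+8 and 3x3x4x8+4, head 7x7x4x1+1
  expect_equal(count_params(G),
               (7*7*1*4 + 4) + (3*3*4*8 + 8) + (3*3*8*16 + 16) +
                 2 * (3*3*16*16 + 16) + (3*3*8*16 + 8) + (3*3*4*8 + 4) +
                 (7*7*4*1 + 1))
})
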