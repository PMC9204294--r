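test_that("convolution kernel agrees with the direct-summation oracle", {
  set.seed(10)
  d <- c(4, 5, 3); Cin <- 2; Cout <- 3; N <- 2
  x <- array(rnorm(prod(d) * Cin * N), c(d, Cin, N))
  w <- array(rnorm(27 * Cin * Cout), c(3, 3, 3, Cin, Cout))
  b <- rnorm(Cout)
  y <- recnn:::.conv3d_forward(x, as.integer(dim(x)), w, b)
  for (n in 1:N)
    expect_equal(array(y[, , , , n], c(d, Cout)),
                 naive_conv3d(array(x[, , , , n], c(d, Cin)), w, b),
                 tolerance = 1e-12)
})

test_that("ceil-mode pooling agrees with the window-max oracle on odd extents", {
  set.seed(11)
  d <- c(5, 7, 4); C <- 2; N <- 2
  x <- array(rnorm(prod(d) * C * N), c(d, C, N))
  pl <- recnn:::.maxpool3d_forward(x, as.integer(dim(x)))
  expect_equal(dim(pl$y), c(3, 4, 2, C, N))
  for (n in 1:N) for (c in 1:C)
    expect_equal(pl$y[, , , c, n], naive_maxpool3d(x[, , , c, n]))
  # argmax points at the voxel that produced each maximum
  expect_equal(as.numeric(x[pl$argmax]), as.numeric(pl$y))
})

test_that("forward pass honours the published shape contract", {
  # 2^5 exact division collapses to a single voxel per map
  a <- recnn_arch(input_shape = c(32, 32, 32), channels = c(2, 2, 2, 2, 2))
  fv <- backbone_forward(a, array(rnorm(32^3), c(32, 32, 32)), seed = 1)
  expect_equal(fv$spatial, c(1, 1, 1))
  expect_equal(fv$channels, 2)

  # odd extents ride the ceil chain 50 -> 25 -> 13 -> 7 -> 4 -> 2
  a2 <- recnn_arch(input_shape = c(50, 50, 50), channels = c(2, 3, 4, 5, 6))
  fv2 <- backbone_forward(a2, array(rnorm(50^3), c(50, 50, 50)), seed = 1)
  expect_equal(fv2$spatial, c(2, 2, 2))
  expect_equal(fv2$channels, 6)

  expect_error(backbone_forward(a, array(0, c(10, 10, 10))),
               "expected 32x32x32")
})

test_that("inference forward is deterministic for fixed weights", {
  a <- recnn_arch(input_shape = c(16, 16, 16), channels = c(2, 2, 2, 2, 2))
  x <- array(rnorm(16^3), c(16, 16, 16))
  f1 <- backbone_forward(a, x, seed = 9)
  f2 <- backbone_forward(a, x, seed = 9)
  expect_identical(f1$data, f2$data)
})

test_that("flatten uses the documented channel-slowest order", {
  fv <- array(0, c(3, 4, 3, 5))
  # 0-based (i, j, k, c) lands at i + 3*(j + 4*(k + 3*c))
  fv[2, 3, 1, 4] <- 99  # i=1, j=2, k=0, c=3 -> index 1 + 3*(2 + 4*(0 + 3*3)) = 115
  h <- flatten_features(fv)
  expect_length(h, 3 * 4 * 3 * 5)
  expect_equal(which(h == 99) - 1, 1 + 3 * (2 + 4 * (0 + 3 * 3)))
  # default architecture flattens to 4608
  expect_equal(recnn_arch()$feature_dim, 128 * 3 * 4 * 3)
  expect_length(flatten_features(array(1, c(1, 1, 1, 1))), 1)
  # batch flattening stacks samples in rows, same per-sample order
  b <- array(rnorm(3 * 4 * 3 * 5 * 2), c(3, 4, 3, 5, 2))
  H <- flatten_features(b)
  expect_equal(dim(H), c(2, 180))
  expect_equal(H[2, ], as.numeric(b[, , , , 2]))
})
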