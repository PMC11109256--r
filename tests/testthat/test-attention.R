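test_that("channel squeeze is global average pooling", {
  f <- array(3, c(5, 7, 4))
  expect_equal(channel_squeeze(f), rep(3, 4))
  f2 <- array(c(1, 3, 2, 4), c(2, 2, 1))  # column-major [[1,2],[3,4]]
  expect_equal(channel_squeeze(f2), 2.5)
  set.seed(1)
  fr <- array(rnorm(60), c(3, 4, 5))
  expect_equal(channel_squeeze(fr + fr), 2 * channel_squeeze(fr))
})

test_that("channel attention matches scalar hand computation", {
  f <- array(rnorm(36), c(3, 3, 4))
  expect_equal(channel_attention(f, ca_params(4, ratio = 2, init = "zero")),
               rep(0.5, 4))

  # C = 2, r = 2: single hidden unit, verifiable by hand
  fc <- array(0, c(2, 2, 2)); fc[, , 1] <- 1; fc[, , 2] <- -2
  p <- ca_params(2, ratio = 2, init = "zero")
  p$w0 <- matrix(c(0.5, 1), 1, 2)     # hidden = relu(0.5*1 + 1*(-2)) = 0
  p$w1 <- matrix(c(2, -3), 2, 1)
  p$b0 <- 0.7                          # hidden = relu(-1.5 + 0.7) = 0
  p$b1 <- c(0.1, -0.2)
  expect_equal(channel_attention(fc, p), plogis(c(0.1, -0.2)))
  p$b0 <- 2                            # hidden = relu(-1.5 + 2) = 0.5
  expect_equal(channel_attention(fc, p),
               plogis(c(2, -3) * 0.5 + c(0.1, -0.2)))

  a <- channel_attention(array(rnorm(200), c(5, 5, 8)), ca_params(8, seed = 1))
  expect_length(a, 8)
  expect_true(all(a > 0 & a < 1))
  expect_error(channel_attention(fc, ca_params(4, 2)), "expect 4 channels")
})

test_that("gates rescale the feature map by broadcasting", {
  f <- array(rnorm(24), c(2, 3, 4))
  expect_equal(apply_channel(f, rep(1, 4)), f)
  expect_equal(apply_channel(f, rep(0.5, 4)), 0.5 * f)
  expect_error(apply_channel(f, rep(1, 3)), "does not match")
  for (i in 1:5) {
    fr <- array(rnorm(100, sd = 3), c(5, 5, 4))
    a <- channel_attention(fr, ca_params(4, 2, seed = i))
    expect_true(all(abs(apply_channel(fr, a)) <= abs(fr) + 1e-12))
  }
  a_s <- matrix(0, 2, 3); a_s[1, 1] <- 1
  gated <- apply_spatial(f, a_s)
  expect_equal(gated[1, 1, ], f[1, 1, ])
  expect_true(all(gated[-1, , ] == 0) && all(gated[, -1, ] == 0))
  expect_equal(apply_spatial(f, matrix(1, 2, 3)), f)
  expect_error(apply_spatial(f, matrix(1, 3, 2)), "spatial gate")
})

test_that("spatial descriptors pool across channels", {
  f1 <- array(rnorm(12), c(3, 4, 1))
  d1 <- spatial_descriptors(f1)
  expect_equal(d1$avg, f1[, , 1])
  expect_equal(d1$max, f1[, , 1])
  f2 <- array(0, c(1, 1, 2)); f2[1, 1, ] <- c(1, 3)
  d2 <- spatial_descriptors(f2)
  expect_equal(c(d2$avg, d2$max), c(2, 3))
  fr <- array(rnorm(120), c(4, 5, 6))
  dr <- spatial_descriptors(fr)
  expect_true(all(dr$max >= dr$avg))
})

test_that("spatial attention is a sigmoid-gated 7x7 convolution", {
  f <- array(rnorm(80), c(4, 5, 4))
  expect_equal(spatial_attention(f, sa_params(init = "zero")),
               matrix(0.5, 4, 5))
  # 1x1 spatial map: only the kernel centre taps see the descriptors
  f11 <- array(2, c(1, 1, 3))  # avg = 2, max = 2
  p <- sa_params(init = "zero")
  p$kernel[4, 4, 1] <- 1       # centre tap on the avg channel
  expect_equal(spatial_attention(f11, p)[1, 1], plogis(2), tolerance = 1e-12)
  expect_equal(plogis(2), 0.8808, tolerance = 1e-4)
  a_s <- spatial_attention(array(rnorm(200), c(5, 8, 5)), sa_params(seed = 2))
  expect_equal(dim(a_s), c(5, 8))
  expect_true(all(a_s > 0 & a_s < 1))
})

test_that("refinement variants compose the gates as specified", {
  set.seed(7)
  f <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  ca <- ca_params(8, 4, seed = 1)
  sa <- sa_params(seed = 2)

  expect_identical(dla_refine(f, ca, sa, "none"), f)
  caz <- ca_params(8, 4, init = "zero"); saz <- sa_params(init = "zero")
  expect_equal(dla_refine(f, caz, saz, "sequential"), 0.25 * f)

  seqv <- dla_refine(f, ca, sa, "sequential")
  parv <- dla_refine(f, ca, sa, "parallel")
  expect_gt(max(abs(seqv - parv)), 1e-8)  # SA sees gated vs raw features

  expect_equal(dla_refine(f, ca, sa, "ca"),
               apply_channel(f, channel_attention(f, ca)))
  expect_error(dla_refine(f, ca, sa, "both"), "unknown attention variant")

  # gate range implies max-norm contraction for every variant
  for (v in c("ca_only", "sa_only", "sequential", "parallel"))
    expect_lte(max(abs(dla_refine(f, ca, sa, v))), max(abs(f)))
})

test_that("channel attention is equivariant under channel permutation", {
  set.seed(8)
  f <- array(rnorm(90), c(3, 3, 10))
  ca <- ca_params(10, 2, seed = 3)
  perm <- sample(10)
  ca_p <- ca
  ca_p$w0 <- ca$w0[, perm]
  ca_p$w1 <- ca$w1[perm, , drop = FALSE]
  ca_p$b1 <- ca$b1[perm]
  expect_equal(channel_attention(f[, , perm], ca_p),
               channel_attention(f, ca)[perm])
})

test_that("spatial attention is translation-equivariant away from borders", {
  set.seed(9)
  f <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  sa <- sa_params(seed = 4)
  dr <- 2; dc <- 1
  fs <- array(0, dim(f))
  fs[(1 + dr):16, (1 + dc):16, ] <- f[1:(16 - dr), 1:(16 - dc), ]
  a <- spatial_attention(f, sa)
  as_ <- spatial_attention(fs, sa)
  # interior: receptive fields (radius 3) avoid both borders and shifted-in zeros
  rows <- (4 + dr):(16 - 3); cols <- (4 + dc):(16 - 3)
  expect_equal(as_[rows, cols], a[rows - dr, cols - dc], tolerance = 1e-12)
})

test_that("sequential refinement matches the scalar loop reference", {
  set.seed(10)
  for (i in 1:10) {
    d <- c(sample(2:6, 2, replace = TRUE), sample(2:8, 1))
    f <- array(rnorm(prod(d), sd = 2), d)
    ca <- ca_params(d[3], ratio = sample(c(2, 4, 16), 1), seed = i)
    sa <- sa_params(seed = 100 + i)
    expect_equal(dla_refine(f, ca, sa, "sequential"),
                 ref_dla_sequential(f, ca, sa), tolerance = 1e-6)
  }
})
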