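test_that("tfm_to_image scales, resizes and replicates channels", {
  set.seed(1)
  amp <- matrix(runif(20 * 30, 1, 5), 20, 30)
  img <- tfm_to_image(amp, size = c(16, 16))
  expect_equal(dim(img), c(16, 16, 3))
  expect_true(all(img >= 0 & img <= 1))
  expect_equal(img[, , 1], img[, , 3])

  # identity when already at size with full [0,1] range
  amp2 <- matrix(runif(64), 8, 8)
  amp2[1] <- 0
  amp2[64] <- 1
  img2 <- tfm_to_image(amp2, size = c(8, 8))
  expect_equal(img2[, , 1], amp2[rev(1:8), ], tolerance = 1e-12)

  # min-max invariance to amplitude scaling
  expect_equal(tfm_to_image(amp * 10, size = c(16, 16)), img,
               tolerance = 1e-12)

  # constant map -> all-zero image
  expect_true(all(tfm_to_image(matrix(2, 5, 5), size = c(4, 4)) == 0))

  # low frequency (row 1 of the map) lands on the bottom image row
  ramp <- matrix(seq(0, 1, length.out = 6), 6, 4)
  img3 <- tfm_to_image(ramp, size = c(6, 4))
  expect_equal(img3[6, 1, 1], 0) # bottom row = lowest voice
  expect_equal(img3[1, 1, 1], 1)
})

test_that("backbone presets propagate shapes to the documented feature dims", {
  alex <- backbone_spec("alexnet")
  expect_equal(backbone_dim(alex), 4096L)
  expect_equal(alex$input_size, c(227L, 227L, 3L))
  # conv1 geometry is fixed across presets
  for (preset in c("alexnet", "small")) {
    c1 <- backbone_spec(preset)$layers[[1]]
    expect_equal(c1$filters, 96L)
    expect_equal(c1$kernel, 11L)
    expect_equal(c1$stride, 4L)
  }
  expect_equal(backbone_dim(backbone_spec("small")), 512L)
  expect_error(backbone_spec("small", feature_tap = "fc9"), "not a layer")
})

test_that("feature extraction is deterministic and shape-checked", {
  spec <- backbone_spec("small")
  set.seed(99)
  img <- array(runif(prod(spec$input_size)), dim = spec$input_size)
  f1 <- extract_features(img, backbone_init(spec, seed = 7))
  f2 <- extract_features(img, backbone_init(spec, seed = 7))
  expect_identical(f1, f2)
  expect_length(f1, 512)
  expect_true(all(is.finite(f1)))
  # different seeds give different projections
  f3 <- extract_features(img, backbone_init(spec, seed = 8))
  expect_gt(max(abs(f1 - f3)), 0)
  # shape mismatch is an error
  expect_error(
    extract_features(array(0, dim = c(10, 10, 3)), backbone_init(spec, 7)),
    "does not match"
  )
})

test_that("a ReLU-dead channel contributes nothing to the features", {
  spec <- backbone_spec("small")
  m1 <- backbone_init(spec, seed = 7)
  m2 <- backbone_init(spec, seed = 7)
  # drive conv1 channel 1 permanently negative in both models, then change
  # its incoming weights only in m2: the dead channel must not leak
  m1$weights$conv1$b[1] <- -1e9
  m2$weights$conv1$b[1] <- -1e9
  m2$weights$conv1$W[, 1] <- rnorm(nrow(m2$weights$conv1$W))
  set.seed(1)
  img <- array(runif(prod(spec$input_size)), dim = spec$input_size)
  expect_identical(extract_features(img, m1), extract_features(img, m2))
})

test_that("backbone weights round-trip through the weights file", {
  spec <- backbone_spec("small")
  m <- backbone_init(spec, seed = 3)
  path <- tempfile(fileext = ".rds")
  save_backbone(m, path)
  m2 <- backbone_init(spec, weights_file = path)
  set.seed(2)
  img <- array(runif(prod(spec$input_size)), dim = spec$input_size)
  expect_identical(extract_features(img, m), extract_features(img, m2))
})

test_that("patient fusion concatenates AV, PV, TV, MV with zero-fill", {
  v <- fuse_patient(
    list(AV = rep(1, 8), PV = rep(2, 8), TV = rep(3, 8), MV = rep(4, 8))
  )
  expect_length(v, 32)
  expect_equal(as.vector(v), rep(1:4, each = 8))
  expect_false(any(attr(v, "missing")))

  # missing TV -> zero segment + mask
  v <- fuse_patient(list(AV = rep(1, 8), PV = rep(2, 8), MV = rep(4, 8)))
  expect_equal(as.vector(v)[17:24], rep(0, 8))
  expect_equal(attr(v, "missing")[["TV"]], TRUE)

  # multiple recordings at one location are averaged
  v <- fuse_patient(list(MV = list(c(1, 1), c(3, 3))), dim = 2)
  expect_equal(as.vector(v)[7:8], c(2, 2))

  # input order never matters
  a <- fuse_patient(list(AV = 1:4, MV = 5:8), dim = 4)
  b <- fuse_patient(list(MV = 5:8, AV = 1:4), dim = 4)
  expect_identical(a, b)

  expect_error(fuse_patient(list()), "at least one")
  expect_error(fuse_patient(list(XX = 1:4)), "unknown location")
  expect_error(fuse_patient(list(AV = 1:4, PV = 1:3)), "length")
})
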