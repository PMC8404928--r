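test_that("render_layer stamps open discs and honours markers and flips", {
  # single-sample spline at (5,5), r = 3: the open digital disc
  sp <- bspline_branch(1, rbind(c(5, 5, 3), c(5, 5, 3)))
  l <- sdmd:::new_encoded_layer(100, flip = FALSE, splines = list(sp))
  got <- render_layer(l, 12, 12, 1)$mask
  xg <- matrix(rep(0:11, each = 12), 12); yg <- matrix(rep(0:11, 12), 12)
  expect_identical(got, (xg - 5)^2 + (yg - 5)^2 < 9)
  # markers
  full <- render_layer(sdmd:::new_encoded_layer(1, FALSE, full = TRUE), 4, 4, 1)
  expect_true(all(full$mask))
  empty <- render_layer(sdmd:::new_encoded_layer(1, FALSE, empty = TRUE), 4, 4, 1)
  expect_false(any(empty$mask))
  # flip on an empty spline set: all-true
  flipped <- render_layer(sdmd:::new_encoded_layer(1, TRUE, empty = TRUE), 4, 4, 1)
  expect_true(all(flipped$mask))
})

test_that("disc stamping equals the naive per-sample oracle on random encodings", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(2:6, 1)
    x <- runif(n, 0, 19); y <- runif(n, 0, 19); r <- runif(n, 0.5, 6)
    got <- sdmd:::cpp_stamp_discs(20, 20, x, y, r, TRUE)
    expect_identical(got, brute_discs(20, 20, x, y, r))
  }
})

test_that("compositing follows painter's order and reproduces quantization", {
  m1 <- matrix(TRUE, 8, 8)
  m2 <- matrix(FALSE, 8, 8); m2[3:6, 3:6] <- TRUE
  plane <- composite_layers(list(list(intensity = 50L, mask = m1),
                                 list(intensity = 200L, mask = m2)))
  expect_equal(sort(unique(as.vector(plane))), c(50L, 200L))
  expect_equal(plane[4, 4], 200L)
  expect_equal(plane[1, 1], 50L)
  # idempotence: compositing a layer twice changes nothing
  twice <- composite_layers(list(list(intensity = 50L, mask = m1),
                                 list(intensity = 200L, mask = m2),
                                 list(intensity = 200L, mask = m2)))
  expect_identical(twice, plane)
  # nested discs -> concentric intensities
  xg <- matrix(rep(0:15, each = 16), 16); yg <- matrix(rep(0:15, 16), 16)
  inner <- (xg - 8)^2 + (yg - 8)^2 <= 9
  outer <- (xg - 8)^2 + (yg - 8)^2 <= 36
  p <- composite_layers(list(list(intensity = 100L, mask = outer),
                             list(intensity = 200L, mask = inner),
                             list(intensity = 0L, mask = matrix(TRUE, 16, 16))))
  expect_equal(p[9, 9], 200L)
  expect_equal(p[9, 14], 100L)
  expect_equal(p[1, 1], 0L)
  # exact-threshold composite equals layer-wise quantization on a ramp
  ramp <- matrix(rep(seq(0L, 252L, by = 4L), each = 8), 8, byrow = FALSE)
  ramp <- ramp[, 1:56, drop = FALSE]
  sel <- c(0L, 60L, 120L, 180L, 240L)
  layers <- lapply(sel, function(i) list(intensity = i, mask = ramp >= i))
  got <- composite_layers(layers)
  q <- vapply(as.vector(ramp), function(v) max(sel[sel <= v]), 0L)
  expect_identical(as.vector(got), q)
})

test_that("interpolation blends by symmetric normalized distance", {
  # flat bands 100/200; layer 100 has its lower boundary at column 1
  m100 <- matrix(TRUE, 9, 21); m100[, 1] <- FALSE
  m200 <- matrix(FALSE, 9, 21); m200[, 17:21] <- TRUE
  m0 <- matrix(TRUE, 9, 21)
  layers <- list(list(intensity = 0L, mask = m0),
                 list(intensity = 100L, mask = m100),
                 list(intensity = 200L, mask = m200))
  plane <- composite_layers(layers)
  out <- interpolate_layers(plane, layers)
  # equidistant pixel between the two layer boundaries -> midpoint value
  # d_in at column j (1-based): j - 1; d_up: 17 - j; equal at j = 9
  expect_equal(out[5, 9], 150L)
  # adjacent to the upper layer: close to 200
  expect_gte(out[5, 16], 190L)
  # pixels of the top layer keep their value
  expect_true(all(out[, 17:21] == 200L))
  # banding shrinks on a linear ramp encoded with L = 8
  vals <- as.integer(round(seq(0, 255, length.out = 128)))
  ramp <- raster_image(matrix(rep(vals, each = 64), 64))
  enc <- encode_image(ramp, encoder_params(L = 8, eps = 0))
  with_i <- decode_image(enc, interpolate = TRUE)
  without <- decode_image(enc, interpolate = FALSE)
  expect_lt(mean(abs(with_i$data - ramp$data)),
            mean(abs(without$data - ramp$data)))
})

test_that("decode is deterministic and respects the size contract", {
  img <- make_fixture("cartoon", 96, 9)
  enc <- encode_image(img, encoder_params(L = 8))
  d1 <- decode_image(enc); d2 <- decode_image(enc)
  expect_identical(d1$data, d2$data)
  d15 <- decode_image(enc, scale = 1.5)
  expect_equal(c(d15$h, d15$w), c(144, 144))
})

test_that("cross-scale decodes agree after box downsampling", {
  img <- make_fixture("gradient_disc", 128, 2)
  enc <- encode_image(img, encoder_params(L = 10))
  d1 <- decode_image(enc)
  d2 <- decode_image(enc, scale = 2)
  a <- sdmd:::luma_plane(d1); m <- sdmd:::luma_plane(d2)
  dn <- (m[seq(1, 255, 2), seq(1, 255, 2)] + m[seq(2, 256, 2), seq(1, 255, 2)] +
         m[seq(1, 255, 2), seq(2, 256, 2)] + m[seq(2, 256, 2), seq(2, 256, 2)]) / 4
  expect_lte(mean(abs(dn - a)), 2)
})

test_that("flipped layers paint the complement (exhaustive on small masks)", {
  set.seed(62)
  for (rep in 1:10) {
    mask <- matrix(runif(36) < 0.5, 6, 6)
    sp <- list()  # build a layer whose rendered mask is exactly `mask`?
    # direct semantic check on finish(): complement-then-paint equals
    # painting the complement
    l <- sdmd:::new_encoded_layer(80, flip = TRUE, empty = TRUE)
    r <- render_layer(l, 6, 6, 1)
    expect_true(all(r$mask))
    plane <- composite_layers(list(list(intensity = 0L, mask = matrix(TRUE, 6, 6)),
                                   list(intensity = 80L, mask = !mask)))
    ref <- matrix(0L, 6, 6); ref[!mask] <- 80L
    expect_identical(plane, ref)
  }
})
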