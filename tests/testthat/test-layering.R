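test_that("thresholding matches its set definition and polarity duality", {
  ch <- matrix(c(50L, 200L, 50L, 200L, 120L, 0L), 2, 3)
  up <- threshold_layer(ch, 100, "upper")
  expect_identical(up$mask, ch >= 100)
  expect_identical(threshold_layer(ch, 100, "lower")$mask, ch <= 100)
  # constant-0 channel, i = 0, upper -> all-true
  expect_true(all(threshold_layer(matrix(0L, 3, 3), 0, "upper")$mask))
  # upper(i) is the complement of lower(i-1), exhaustively per intensity
  set.seed(21)
  ch <- matrix(sample(0:255, 60, TRUE), 6, 10)
  for (i in 1:255) {
    expect_identical(threshold_layer(ch, i, "upper")$mask,
                     !threshold_layer(ch, i - 1, "lower")$mask)
  }
  # monotone nesting of upper masks
  m1 <- threshold_layer(ch, 60, "upper")$mask
  m2 <- threshold_layer(ch, 180, "upper")$mask
  expect_true(all(m1[m2]))
})

test_that("select_layers covers degenerate and two-tone channels and stays within L", {
  expect_identical(select_layers(matrix(37L, 4, 4), 10), 37L)
  two <- matrix(c(50L, 200L), 4, 4)
  expect_identical(select_layers(two, 2, "histogram"), c(50L, 200L))
  expect_identical(select_layers(two, 2, "uniform"), c(50L, 200L))
  set.seed(22)
  ch <- matrix(sample(0:255, 400, TRUE), 20, 20)
  for (strategy in c("histogram", "uniform")) {
    sel <- select_layers(ch, 7, strategy)
    expect_lte(length(sel), 7)
    expect_true(all(diff(sel) > 0))
    expect_equal(sel[1], min(ch))
    expect_true(all(sel %in% ch))
  }
  expect_error(select_layers(ch, 0), "L must be")
})

test_that("histogram selection is per-step greedy-optimal on small ramps", {
  # exhaustive per-step oracle: each added intensity must minimize the
  # quantization error among all candidates, on 8-level ramp channels
  set.seed(23)
  for (rep in 1:5) {
    levels <- sort(sample(0:255, 8))
    ch <- matrix(rep(levels, each = 8), 8, 8)
    counts <- tabulate(as.vector(ch) + 1L, nbins = 256L)
    err_for <- function(sel) {
      pres <- which(counts > 0) - 1L
      idx <- findInterval(pres, sel)
      sum(counts[pres + 1L] * (pres - sel[idx]))
    }
    sel <- min(ch)
    for (step in 1:3) {
      cand <- setdiff(levels, sel)
      errs <- vapply(cand, function(c) err_for(sort(c(sel, c))), 0)
      best <- cand[which.min(errs)]
      sel <- sort(c(sel, best))
    }
    got <- select_layers(ch, 4, "histogram")
    expect_identical(got, as.integer(sel))
  }
})

test_that("remove_islands removes small components, fills small holes, and is idempotent", {
  # big component + speck: speck removed (5 < 0.01 * 1005)
  m <- matrix(FALSE, 40, 40)
  m[2:32, 2:34] <- TRUE            # ~1000 px
  m[38, 2:6] <- TRUE               # 5 px speck
  lay <- structure(list(intensity = 0L, polarity = "upper", mask = m),
                   class = "binary_layer")
  out <- remove_islands(lay, 0.01)
  expect_false(any(out$mask[38, ]))
  expect_true(all(out$mask[2:32, 2:34]))
  # eps = 0 leaves the layer unchanged
  expect_identical(remove_islands(lay, 0)$mask, m)
  # hole filling: small 4-connected enclosed hole
  m2 <- m; m2[10:11, 10:11] <- FALSE
  lay2 <- structure(list(intensity = 0L, polarity = "upper", mask = m2),
                    class = "binary_layer")
  out2 <- remove_islands(lay2, 0.01)
  expect_true(all(out2$mask[10:11, 10:11]))
  # surviving component set equals the brute-force size filter on random blobs
  set.seed(24)
  for (rep in 1:5) {
    mm <- random_mask(30, 30, 0.45)
    lay3 <- structure(list(intensity = 0L, polarity = "upper", mask = mm),
                      class = "binary_layer")
    eps <- 0.02
    out3 <- remove_islands(lay3, eps)
    # oracle: label, keep components >= eps * |T|, then fill small holes
    lab <- sdmd:::cpp_label(mm, 8L)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab, 1))
    thr <- eps * sum(mm)
    ref <- mm & !(lab %in% which(sizes < thr))
    labb <- sdmd:::cpp_label(!ref, 4L)
    szb <- tabulate(labb[labb > 0], nbins = max(labb, 1))
    border <- unique(c(labb[1, ], labb[30, ], labb[, 1], labb[, 30]))
    ref[labb %in% setdiff(which(szb < thr), border)] <- TRUE
    expect_identical(out3$mask, ref)
  }
  # idempotence on realistic threshold layers
  img <- make_fixture("treemap", 128, 1)
  y <- rgb_to_ycbcr(img)$Y
  for (i in select_layers(y, 8)) {
    l1 <- remove_islands(threshold_layer(y, i, "upper"), 0.01)
    expect_identical(remove_islands(l1, 0.01)$mask, l1$mask)
  }
})

test_that("salient maps apply the component-majority epsilon rule", {
  m <- matrix(FALSE, 40, 60)
  m[2:32, 2:34] <- TRUE           # main component, ~1000 px
  m[10:11, 50:51] <- TRUE         # 4 px island inside the salient zone
  m[35:36, 5:6] <- TRUE           # 4 px island outside it
  sal <- matrix(FALSE, 40, 60); sal[, 40:60] <- TRUE
  lay <- structure(list(intensity = 0L, polarity = "upper", mask = m),
                   class = "binary_layer")
  sm <- salient_map(sal, eps_salient = 0.001, eps_background = 0.01)
  out <- remove_islands(lay, 0.01, sm)
  expect_true(all(out$mask[10:11, 50:51]))    # kept: 4 >= 0.001 * |T|
  expect_false(any(out$mask[35:36, 5:6]))     # removed: 4 < 0.01 * |T|
  expect_error(salient_map(sal, 0.5, 0.1), "eps_salient")
})
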