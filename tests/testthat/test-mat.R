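test_that("distance transform is exact and rejects unbounded layers", {
  m <- matrix(c(FALSE, TRUE, FALSE), 1, 3)
  expect_equal(distance_transform(m)[1, 2], 1)
  m2 <- matrix(FALSE, 7, 7); m2[2:6, 2:6] <- TRUE
  expect_equal(distance_transform(m2)[4, 4], 3)
  expect_error(distance_transform(matrix(TRUE, 4, 4)), "unbounded layer")
  # zero outside the foreground, 1-Lipschitz property
  set.seed(31)
  d <- distance_transform(random_mask(20, 20))
  expect_true(all(d[!random_mask(20, 20) & d == 0] == 0))
  expect_true(all(abs(diff(d)) <= 1 + 1e-9))
})

test_that("compute_mat handles degenerate shapes and marks maximal-disc centres", {
  # single foreground pixel
  m <- matrix(FALSE, 5, 5); m[3, 3] <- TRUE
  mat <- compute_mat(m)
  expect_equal(nrow(mat), 1)
  expect_equal(c(mat$x, mat$y, mat$dt), c(2, 2, 1))
  # digital disc: the dominant regularized pixel is the analytic centre
  xg <- matrix(rep(0:24, each = 25), 25); yg <- matrix(rep(0:24, 25), 25)
  disc <- sqrt((xg - 12)^2 + (yg - 12)^2) <= 10
  reg <- regularize_mat(compute_mat(disc), 1.0)
  top <- reg[which.max(reg$dt), ]
  expect_lte(max(abs(c(top$x, top$y) - 12)), 1)
  expect_lte(abs(top$dt - 10), 1)
  # every MAT pixel is a two-nearest-boundary maximal disc centre (1 px tol)
  set.seed(32)
  for (rep in 1:4) {
    mm <- random_blob(32, 4, 1)
    mat <- compute_mat(mm)
    bg <- which(!mm, arr.ind = TRUE) - 1  # (row=y, col=x), 0-based
    ok <- vapply(seq_len(nrow(mat)), function(i) {
      for (dy in -1:1) for (dx in -1:1) {
        x <- mat$x[i] + dx; y <- mat$y[i] + dy
        if (x < 0 || y < 0 || x > 31 || y > 31) next
        if (!mm[y + 1, x + 1]) next
        d <- sqrt((bg[, 2] - x)^2 + (bg[, 1] - y)^2)
        near <- bg[d <= min(d) + 1, , drop = FALSE]
        if (nrow(near) >= 2) {
          sep <- max(dist(near))
          if (sep > 2) return(TRUE)   # two separate boundary contacts
        }
      }
      FALSE
    }, logical(1))
    expect_gte(mean(ok), 0.95)
  }
})

test_that("MAT invariants: sigma*dt = rho, determinism, monotone regularization", {
  set.seed(33)
  mm <- random_blob(48)
  mat <- compute_mat(mm)
  expect_equal(mat$sigma * mat$dt, mat$rho, tolerance = 1e-12)
  expect_identical(compute_mat(mm), mat)
  r1 <- regularize_mat(mat, 0.8); r2 <- regularize_mat(mat, 1.6)
  expect_identical(regularize_mat(mat, 0), mat)
  expect_true(all(paste(r2$x, r2$y) %in% paste(r1$x, r1$y)))
  # arithmetic of the saliency example: rho 12, dt 6 -> sigma 2
  expect_equal(regularize_mat(data.frame(x = 0, y = 0, dt = 6, rho = 12,
                                         sigma = 2), 1.4)$sigma, 2)
})

test_that("disc union of the unregularized MAT reproduces the layer within 1%", {
  set.seed(34)
  for (rep in 1:6) {
    mm <- random_blob(64)
    mat <- compute_mat(mm)
    rec <- sdmd:::cpp_stamp_discs(64, 64, mat$x, mat$y, mat$dt, TRUE)
    expect_lte(sum(xor(rec, mm)), 0.01 * sum(mm))
  }
})

test_that("saliency pruning suppresses a boundary bump but keeps square diagonals", {
  sq <- matrix(FALSE, 80, 80)
  sq[11:70, 11:70] <- TRUE
  bump <- sq; bump[38:43, 71:73] <- TRUE   # small bump on the right side
  reg <- regularize_mat(compute_mat(bump, complete = FALSE), 1.0)
  # the bump contributes at most a residual stub at its root, no branch
  # reaching into the protrusion
  expect_lte(sum(reg$x >= 70), 2)
  expect_false(any(reg$x >= 72))
  # main diagonals retained (within a pixel of the exact diagonals)
  expect_gte(sum(abs(reg$x - reg$y) <= 1), 30)
  expect_gte(sum(abs(reg$x + reg$y - 80) <= 1), 30)
  # disc-union of the pruned skeleton still reproduces the square up to
  # the corner rounding that saliency pruning is designed to introduce
  rec <- sdmd:::cpp_stamp_discs(80, 80, reg$x, reg$y, reg$dt, TRUE)
  expect_lte(sum(xor(rec, sq)) / sum(sq), 0.10)
  expect_equal(sum(rec & !bump), 0)   # never paints outside the shape
})

test_that("border segments equal a brute-force run-length scan", {
  m <- matrix(FALSE, 30, 30)
  m[5:10, 5:10] <- TRUE
  expect_equal(nrow(detect_border_segments(m)), 0)
  # vertical stripe columns 11..21 touching the top edge
  m2 <- matrix(FALSE, 30, 30); m2[1:15, 11:21] <- TRUE
  segs <- detect_border_segments(m2)
  top <- segs[segs$side == "top", ]
  expect_equal(c(top$ax, top$ay, top$bx, top$by), c(10, 0, 20, 0))
  # random masks vs scanline oracle
  set.seed(35)
  for (rep in 1:5) {
    mm <- random_mask(15, 15, 0.5)
    segs <- detect_border_segments(mm)
    for (side in c("top", "bottom", "left", "right")) {
      v <- switch(side, top = mm[1, ], bottom = mm[15, ],
                  left = mm[, 1], right = mm[, 15])
      r <- rle(v)
      expect_equal(sum(segs$side == side), sum(r$values))
    }
  }
})

test_that("semi-disc extension adds outward semi-discs and removes border Y-junctions", {
  m <- matrix(FALSE, 30, 30)
  expect_equal(semi_disc_extend(m)$band, 0)
  # stripe touching the top edge: semi-disc centred at (15, 0), radius 5
  m2 <- matrix(FALSE, 30, 30); m2[1:12, 11:21] <- TRUE
  ext <- semi_disc_extend(m2)
  expect_equal(ext$band, 5)
  expect_true(ext$mask[5 + 1 - 4, 5 + 16])  # 4 px above the old frame top
  expect_false(ext$mask[1, 5 + 16 + 10])    # beyond the semi-disc radius
  # junction census: a full-height stripe's skeleton has junctions without
  # extension (Y-structures) and none with it
  stripe <- matrix(FALSE, 40, 40); stripe[, 16:24] <- TRUE
  count_junctions <- function(mat) {
    if (!nrow(mat)) return(0)
    z <- complex(real = mat$x, imaginary = mat$y)
    off <- complex(real = rep(-1:1, 3), imaginary = rep(-1:1, each = 3))
    off <- off[off != 0]
    deg <- rowSums(vapply(off, function(o) (z + o) %in% z, logical(length(z))))
    sum(deg >= 3)
  }
  plain <- compute_mat(stripe)
  ext2 <- semi_disc_extend(stripe)
  fixed <- compute_mat(ext2$mask)
  fixed$x <- fixed$x - ext2$band; fixed$y <- fixed$y - ext2$band
  fixed <- clip_mat(fixed, 40, 40)
  expect_gte(count_junctions(plain), 1)
  expect_equal(count_junctions(fixed), 0)
})

test_that("clip_mat keeps exactly the in-frame pixels and flags cut endpoints", {
  mat <- data.frame(x = c(-2L, 0L, 5L, 39L, 41L), y = c(3L, 3L, 5L, 20L, 20L),
                    dt = 1, rho = 2, sigma = 2)
  out <- clip_mat(mat, 40, 40)
  expect_equal(out$x, c(0L, 5L, 39L))
  # none of the kept pixels neighbours a removed one here except (39,20)?
  expect_false(out$border[out$x == 5])
  # pixel adjacent to a clipped-out neighbour is flagged
  mat2 <- data.frame(x = c(38L, 39L, 40L), y = 10L, dt = 1, rho = 2, sigma = 2)
  out2 <- clip_mat(mat2, 40, 40)
  expect_identical(out2$border, c(FALSE, TRUE))
  # identity when fully inside
  inside <- data.frame(x = 1:5, y = 1:5, dt = 1, rho = 2, sigma = 2)
  expect_equal(clip_mat(inside, 40, 40)[, 1:5], inside)
})

test_that("branch tracing partitions the skeleton deterministically", {
  # straight 10-pixel segment -> one branch of 10 pixels
  seg <- data.frame(x = 0:9, y = 5L, dt = 1, rho = 2, sigma = 2)
  br <- trace_branches(seg)
  expect_equal(length(br), 1)
  expect_equal(nrow(br[[1]]), 10)
  expect_equal(attr(br[[1]], "endpoints"), c("free-end", "free-end"))
  # X shape (the diagonal cross keeps a single junction in 8-connectivity):
  # 4 branches sharing the duplicated centre junction
  plus <- unique(data.frame(x = c(3:7, 3:7), y = c(3:7, 7:3),
                            dt = 1, rho = 2, sigma = 2))
  br <- trace_branches(plus)
  expect_equal(length(br), 4)
  centre_in <- vapply(br, function(b) any(b$x == 5 & b$y == 5), logical(1))
  expect_true(all(centre_in))
  # coverage census on random skeletons: every pixel in >= 1 branch,
  # non-junction pixels in exactly one
  set.seed(36)
  for (rep in 1:5) {
    mm <- random_blob(40)
    mat <- compute_mat(mm)
    br <- trace_branches(mat)
    all_px <- do.call(rbind, br)
    key <- paste(all_px$x, all_px$y)
    expect_true(all(paste(mat$x, mat$y) %in% key))
    z <- complex(real = mat$x, imaginary = mat$y)
    off <- complex(real = rep(-1:1, 3), imaginary = rep(-1:1, each = 3))
    off <- off[off != 0]
    deg <- rowSums(vapply(off, function(o) (z + o) %in% z, logical(length(z))))
    njx <- paste(mat$x, mat$y)[deg < 3]
    counts <- table(key)
    expect_true(all(counts[njx] == 1))
  }
})

test_that("border-branch extension follows the 45-degree plane stopping rule", {
  # endpoint at (5, 0) moving up with dt 3, slope 0: stops at distance 3
  b <- data.frame(x = c(5, 5), y = c(1, 0), dt = c(3, 3))
  out <- extend_border_branch(b, 40, 40, ends = c(FALSE, TRUE))
  added <- out[-(1:2), ]
  expect_equal(nrow(added), 3)
  expect_equal(added$y, c(-1, -2, -3))
  expect_equal(added$dt, rep(3, 3))
  # steep negative radius slope: nothing to add
  b2 <- data.frame(x = c(5, 5), y = c(1, 0), dt = c(1.2, 0))
  out2 <- extend_border_branch(b2, 40, 40, ends = c(FALSE, TRUE))
  expect_equal(nrow(out2), 2)
  expect_error(extend_border_branch(b, 40, 40, ends = c(FALSE, FALSE)),
               "border-touch")
})
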