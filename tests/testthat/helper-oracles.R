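# Shared fixtures and independent brute-force oracles used across the suite.

# random logical mask with at least one background pixel
random_mask <- function(h, w, p = 0.55) {
  m <- matrix(runif(h * w) < p, h, w)
  if (all(m)) m[1, 1] <- FALSE
  m
}

# random smooth blob shape: union of discs minus a few discs
random_blob <- function(size, n_add = 6, n_sub = 2) {
  xg <- matrix(rep(0:(size - 1), each = size), size)
  yg <- matrix(rep(0:(size - 1), size), size)
  m <- matrix(FALSE, size, size)
  for (i in seq_len(n_add)) {
    cx <- runif(1, 0.2, 0.8) * size; cy <- runif(1, 0.2, 0.8) * size
    r <- runif(1, 0.08, 0.22) * size
    m <- m | ((xg - cx)^2 + (yg - cy)^2 <= r^2)
  }
  for (i in seq_len(n_sub)) {
    cx <- runif(1, 0.2, 0.8) * size; cy <- runif(1, 0.2, 0.8) * size
    r <- runif(1, 0.05, 0.12) * size
    m <- m & !((xg - cx)^2 + (yg - cy)^2 <= r^2)
  }
  if (all(m)) m[1, 1] <- FALSE
  m
}

# O(n^2) exact distance transform oracle
brute_edt <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  bg <- which(!mask, arr.ind = TRUE)
  out <- matrix(0, h, w)
  for (i in which(mask)) {
    y <- (i - 1) %% h + 1; x <- (i - 1) %/% h + 1
    out[i] <- sqrt(min((bg[, 1] - y)^2 + (bg[, 2] - x)^2))
  }
  out
}

# naive per-sample disc stamping oracle (open discs)
brute_discs <- function(h, w, x, y, r) {
  out <- matrix(FALSE, h, w)
  for (s in seq_along(x)) {
    for (px in 0:(w - 1)) for (py in 0:(h - 1)) {
      if ((px - x[s])^2 + (py - y[s])^2 < r[s]^2 - 1e-9)
        out[py + 1, px + 1] <- TRUE
    }
  }
  out
}

# naive windowed SSIM oracle: explicit 11x11 window extraction per position
naive_ssim <- function(a, b) {
  a <- matrix(as.double(a), nrow(a)); b <- matrix(as.double(b), nrow(b))
  k1d <- dnorm(-5:5, sd = 1.5); k1d <- k1d / sum(k1d)
  k2d <- outer(k1d, k1d)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  h <- nrow(a); w <- ncol(a)
  vals <- c()
  for (i in 1:(h - 10)) for (j in 1:(w - 10)) {
    wa <- a[i:(i + 10), j:(j + 10)]; wb <- b[i:(i + 10), j:(j + 10)]
    mx <- sum(k2d * wa); my <- sum(k2d * wb)
    sxx <- sum(k2d * wa * wa) - mx^2
    syy <- sum(k2d * wb * wb) - my^2
    sxy <- sum(k2d * wa * wb) - mx * my
    vals <- c(vals, ((2 * mx * my + C1) * (2 * sxy + C2)) /
                ((mx^2 + my^2 + C1) * (sxx + syy + C2)))
  }
  mean(vals)
}

# total control points of an encoding
total_ncp <- function(enc) {
  sum(vapply(enc$channels, function(ch)
    sum(vapply(ch$layers, function(l) l$n_control, 0L)), 0))
}

# per-layer maximal fit error across an encoding
max_fit_err <- function(enc) {
  max(0, unlist(lapply(enc$channels, function(ch)
    lapply(ch$layers, function(l) l$max_err))))
}

# random valid sdmd_file for container fuzzing
random_sdmd_file <- function(w = NULL, h = NULL) {
  if (is.null(w)) w <- sample(4:300, 1)
  if (is.null(h)) h <- sample(4:300, 1)
  diagpx <- sqrt(w^2 + h^2)
  mode <- sample(c("gray", "ycbcr"), 1)
  nchan <- if (mode == "gray") 1L else 3L
  chans <- lapply(seq_len(nchan), function(k) {
    nl <- sample(1:4, 1)
    ints <- sort(sample(0:255, nl))
    layers <- lapply(ints, function(i) {
      kind <- sample(c("full", "empty", "splines"), 1, prob = c(.2, .2, .6))
      if (kind == "splines") {
        ns <- sample(1:3, 1)
        spl <- lapply(seq_len(ns), function(s) {
          d <- sample(1:3, 1)
          m <- d + sample(1:4, 1)
          cp <- cbind(runif(m, -w, 2 * w), runif(m, -h, 2 * h),
                      runif(m, 0, diagpx))
          bspline_branch(d, cp)
        })
        sdmd:::new_encoded_layer(i, flip = runif(1) < .5, splines = spl)
      } else {
        sdmd:::new_encoded_layer(i, flip = runif(1) < .5,
                                 empty = kind == "empty",
                                 full = kind == "full")
      }
    })
    list(layers = layers, params = NULL)
  })
  structure(list(w = w, h = h, colormode = mode, channels = chans,
                 interpolation = TRUE),
            class = "sdmd_file")
}

# compare two sdmd_file objects up to container quantization
expect_file_roundtrip <- function(f) {
  bytes <- sdmd_serialize(f)
  g <- sdmd_deserialize(bytes)
  expect_equal(g$w, f$w)
  expect_equal(g$h, f$h)
  expect_equal(g$colormode, f$colormode)
  expect_equal(length(g$channels), length(f$channels))
  tol_xy <- 3 * max(f$w, f$h) / 65535
  tol_r <- sqrt(f$w^2 + f$h^2) / 65535
  for (k in seq_along(f$channels)) {
    la <- f$channels[[k]]$layers; lb <- g$channels[[k]]$layers
    expect_equal(length(la), length(lb))
    for (j in seq_along(la)) {
      expect_equal(lb[[j]]$intensity, la[[j]]$intensity)
      expect_equal(lb[[j]]$flip, la[[j]]$flip)
      expect_equal(lb[[j]]$empty, la[[j]]$empty)
      expect_equal(lb[[j]]$full, la[[j]]$full)
      expect_equal(length(lb[[j]]$splines), length(la[[j]]$splines))
      for (s in seq_along(la[[j]]$splines)) {
        sa <- la[[j]]$splines[[s]]; sb <- lb[[j]]$splines[[s]]
        expect_equal(sb$degree, sa$degree)
        expect_lte(max(abs(sb$cp[, 1:2] - sa$cp[, 1:2])), tol_xy)
        expect_lte(max(abs(sb$cp[, 3] - sa$cp[, 3])), tol_r)
      }
    }
  }
  invisible(bytes)
}
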