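#' Deterministic synthetic benchmark images
#'
#' Generates the image families used throughout the tests and examples:
#' shapes overlaid on smooth or flat backgrounds, the regime medial-descriptor
#' codecs are designed for.  All geometry is expressed in units relative to
#' `size`, and the random draws do not depend on `size`, so
#' `make_fixture(kind, 2 * size, seed)` is a double-resolution re-render of
#' the same scene.
#'
#' Kinds: `spiral` (black Archimedean spiral crossing the frame border,
#' grayscale), `treemap` (nested rectangles with parabolic luminance
#' cushions), `gradient_disc` (anti-aliased flat discs over a linear
#' gradient), `border_stripes` (flat colour bands crossing the full frame),
#' `cartoon` (flat blobs with thin dark outlines) and `text` (glyph-like
#' strokes, grayscale).
#'
#' @param kind fixture family (see above)
#' @param size image side in pixels, `>= 64`
#' @param seed integer seed; the same `(kind, size, seed)` always yields the
#'   identical image
#' @return a [raster_image()]
#' @export
make_fixture <- function(kind = c("spiral", "treemap", "gradient_disc",
                                  "border_stripes", "cartoon", "text"),
                         size = 512L, seed = 1L) {
  kind <- match.arg(kind)
  if (size < 64) stop("size must be >= 64")
  size <- as.integer(size)
  gen <- switch(kind,
    spiral = fixture_spiral, treemap = fixture_treemap,
    gradient_disc = fixture_gradient_disc,
    border_stripes = fixture_border_stripes,
    cartoon = fixture_cartoon, text = fixture_text)
  gen(size, as.integer(seed))
}

# fixed-count uniform draws, preserving the caller's RNG state
fixture_rng <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n)
}

clamp255 <- function(m) {
  m <- rhu(m); m[m < 0] <- 0L; m[m > 255] <- 255L
  storage.mode(m) <- "integer"; m
}

# stamp discs of radius r at points (x, y) into a logical size x size mask
stamp_path <- function(size, x, y, r) {
  cpp_stamp_discs(size, size, x, y, rep(r, length(x)), FALSE)
}

fixture_spiral <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 7, 2)
  phi0 <- 2 * pi * u[1]
  b <- size / (20 * pi) * (0.9 + 0.2 * u[2])   # inter-arm gap ~ size/10
  cx <- cy <- (size - 1) / 2
  rmax <- 0.78 * size                          # well past the frame corners
  theta <- 0; xs <- ys <- numeric(0)
  pts <- list()
  while (b * theta < rmax) {
    r <- b * theta
    pts[[length(pts) + 1L]] <- c(cx + r * cos(theta + phi0),
                                 cy + r * sin(theta + phi0))
    theta <- theta + 1 / max(r, 2)
  }
  p <- do.call(rbind, pts)
  sw <- size / 56
  mask <- stamp_path(size, p[, 1], p[, 2], sw)
  img <- matrix(255L, size, size)
  img[mask] <- 0L
  raster_image(img)
}

fixture_treemap <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 19, 64)
  ui <- 0
  draw <- function() { ui <<- ui + 1; u[(ui - 1) %% 64 + 1] }
  rects <- list(c(0, 0, 1, 1))               # relative [x0, y0, x1, y1]
  for (depth in 1:4) {
    nxt <- list()
    for (rc in rects) {
      wd <- rc[3] - rc[1]; ht <- rc[4] - rc[2]
      f <- 0.35 + 0.3 * draw()
      if (wd >= ht) {
        xm <- rc[1] + f * wd
        nxt <- c(nxt, list(c(rc[1], rc[2], xm, rc[4]), c(xm, rc[2], rc[3], rc[4])))
      } else {
        ym <- rc[2] + f * ht
        nxt <- c(nxt, list(c(rc[1], rc[2], rc[3], ym), c(rc[1], ym, rc[3], rc[4])))
      }
    }
    rects <- nxt
  }
  arr <- array(0, c(size, size, 3))
  for (rc in rects) {
    x0 <- rhu(rc[1] * size); x1 <- max(x0 + 1, rhu(rc[3] * size))
    y0 <- rhu(rc[2] * size); y1 <- max(y0 + 1, rhu(rc[4] * size))
    x1 <- min(x1, size); y1 <- min(y1, size)
    base <- c(70 + 160 * draw(), 70 + 160 * draw(), 70 + 160 * draw())
    px <- (seq(x0, x1 - 1) - x0 + 0.5) / (x1 - x0)
    py <- (seq(y0, y1 - 1) - y0 + 0.5) / (y1 - y0)
    shade <- outer(4 * py * (1 - py), 4 * px * (1 - px)) * 0.45 + 0.55
    for (k in 1:3)
      arr[(y0 + 1):y1, (x0 + 1):x1, k] <- base[k] * shade
  }
  out <- array(0L, c(size, size, 3))
  for (k in 1:3) out[, , k] <- clamp255(arr[, , k])
  raster_image(out)
}

fixture_gradient_disc <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 37, 40)
  c0 <- 40 + 120 * u[1:3]; c1 <- 120 + 120 * u[4:6]
  g <- outer(seq(0, 1, length.out = size), seq(0, 1, length.out = size),
             function(a, b) (a + b) / 2)
  arr <- array(0, c(size, size, 3))
  for (k in 1:3) arr[, , k] <- c0[k] + (c1[k] - c0[k]) * g
  xg <- matrix(rep(0:(size - 1), each = size), size)
  yg <- matrix(rep(0:(size - 1), size), size)
  for (d in 0:4) {
    cx <- (0.15 + 0.7 * u[7 + d * 6]) * size
    cy <- (0.15 + 0.7 * u[8 + d * 6]) * size
    r <- (0.07 + 0.12 * u[9 + d * 6]) * size
    col <- 30 + 200 * u[10 + d * 6 + 0:2]
    dist <- sqrt((xg - cx)^2 + (yg - cy)^2)
    alpha <- pmin(pmax(r + 0.5 - dist, 0), 1)   # anti-aliased rim
    for (k in 1:3) arr[, , k] <- alpha * col[k] + (1 - alpha) * arr[, , k]
  }
  out <- array(0L, c(size, size, 3))
  for (k in 1:3) out[, , k] <- clamp255(arr[, , k])
  raster_image(out)
}

fixture_border_stripes <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 53, 24)
  nb <- 8L
  edges <- rhu(seq(0, size, length.out = nb + 1))
  out <- array(0L, c(size, size, 3))
  for (j in seq_len(nb)) {
    col <- clamp255(matrix(30 + 210 * u[(j - 1) * 3 + 1:3], 1))
    xs <- (edges[j] + 1):edges[j + 1]
    for (k in 1:3) out[, xs, k] <- col[k]
  }
  raster_image(out)
}

fixture_cartoon <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 71, 60)
  bg <- 200 + 40 * u[1:3]
  arr <- array(0, c(size, size, 3))
  for (k in 1:3) arr[, , k] <- bg[k]
  xg <- matrix(rep(0:(size - 1), each = size), size)
  yg <- matrix(rep(0:(size - 1), size), size)
  tline <- max(2, size / 256)                  # outline thickness
  for (bdx in 0:4) {
    o <- 4 + bdx * 8
    cx <- (0.18 + 0.64 * u[o + 1]) * size
    cy <- (0.18 + 0.64 * u[o + 2]) * size
    a <- (0.08 + 0.14 * u[o + 3]) * size
    b <- (0.08 + 0.14 * u[o + 4]) * size
    phi <- pi * u[o + 5]
    col <- 40 + 180 * u[o + 6:8]
    dx <- xg - cx; dy <- yg - cy
    q <- sqrt((( dx * cos(phi) + dy * sin(phi)) / a)^2 +
              ((-dx * sin(phi) + dy * cos(phi)) / b)^2)
    fill <- q <= 1
    rim <- q <= 1 & q > 1 - tline / min(a, b)
    for (k in 1:3) {
      pl <- arr[, , k]
      pl[fill] <- col[k]
      pl[rim] <- 25
      arr[, , k] <- pl
    }
  }
  out <- array(0L, c(size, size, 3))
  for (k in 1:3) out[, , k] <- clamp255(arr[, , k])
  raster_image(out)
}

fixture_text <- function(size, seed) {
  u <- fixture_rng(seed * 131 + 97, 200)
  img <- matrix(255L, size, size)
  sw <- size / 80
  cells <- expand.grid(cx = 0:3, cy = 0:2)
  ui <- 0
  draw <- function() { ui <<- ui + 1; u[(ui - 1) %% 200 + 1] }
  for (ci in seq_len(nrow(cells))) {
    x0 <- (0.06 + 0.23 * cells$cx[ci]) * size
    y0 <- (0.10 + 0.30 * cells$cy[ci]) * size
    cw <- 0.16 * size; chh <- 0.22 * size
    anchors <- rbind(
      c(0, 0), c(0.5, 0), c(1, 0), c(0, 0.5), c(1, 0.5),
      c(0, 1), c(0.5, 1), c(1, 1), c(0.5, 0.5))
    ns <- 2 + (draw() > 0.5) + (draw() > 0.5)
    for (s in seq_len(ns)) {
      a <- anchors[1 + floor(draw() * 8.999), ]
      b <- anchors[1 + floor(draw() * 8.999), ]
      if (all(a == b)) b <- anchors[(which(anchors[, 1] == a[1])[1] %% 9) + 1, ]
      p0 <- c(x0 + a[1] * cw, y0 + a[2] * chh)
      p1 <- c(x0 + b[1] * cw, y0 + b[2] * chh)
      len <- sqrt(sum((p1 - p0)^2))
      t <- seq(0, 1, length.out = max(2, ceiling(len * 2)))
      mask <- stamp_path(size, p0[1] + t * (p1[1] - p0[1]),
                         p0[2] + t * (p1[2] - p0[2]), sw)
      img[mask] <- 0L
    }
  }
  raster_image(img)
}
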