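#' Construct a raster image
#'
#' An 8-bit raster image: a `h x w` integer matrix (grayscale) or a
#' `h x w x 3` array (RGB), values in `[0, 255]`.  Pixel coordinates are
#' integers with `x` rightward, `y` downward and origin `(0, 0)` at the
#' top-left pixel centre; all other functions in the package inherit this
#' convention.
#'
#' @param values integer matrix (`h x w`) or array (`h x w x 3`) in `[0, 255]`.
#' @return an object of class `raster_image` with fields `w`, `h`,
#'   `channels`, `data`.
#' @export
raster_image <- function(values) {
  if (is.matrix(values)) {
    channels <- 1L
  } else if (is.array(values) && length(dim(values)) == 3 && dim(values)[3] == 3) {
    channels <- 3L
  } else {
    stop("values must be a h x w matrix or h x w x 3 array")
  }
  storage.mode(values) <- "integer"
  if (anyNA(values) || min(values) < 0L || max(values) > 255L)
    stop("pixel values must be integers in [0, 255]")
  h <- dim(values)[1]; w <- dim(values)[2]
  if (h < 1 || w < 1) stop("image must be at least 1 x 1")
  structure(list(w = as.integer(w), h = as.integer(h),
                 channels = channels, data = values),
            class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  cat(sprintf("raster_image %d x %d, %d channel(s)\n", x$w, x$h, x$channels))
  invisible(x)
}

#' Extract one channel plane as an integer matrix
#' @param img a `raster_image`
#' @param k channel index
#' @return `h x w` integer matrix
#' @export
channel_plane <- function(img, k = 1L) {
  if (img$channels == 1L) img$data else img$data[, , k, drop = TRUE]
}

#' Read a raster image (PNG, PPM/PGM, or uncompressed BMP)
#'
#' 16-bit inputs are rescaled to 8 bits with round-half-up; an alpha channel
#' is composited over white (the codec has no transparency model).
#'
#' @param path file path
#' @return a [raster_image()]
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("cannot read image: no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = tryCatch(png::readPNG(path), error = function(e)
      stop("cannot read PNG '", path, "': ", conditionMessage(e))),
    ppm = ,
    pgm = read_pnm(path),
    bmp = read_bmp(path),
    stop("unsupported image format '", ext, "' for ", path)
  )
  # readPNG returns doubles in [0,1]; PNM/BMP readers return the same
  if (length(dim(arr)) == 3) {
    nc <- dim(arr)[3]
    if (nc == 2) {           # gray + alpha
      a <- arr[, , 2]
      arr <- arr[, , 1] * a + (1 - a)
    } else if (nc == 4) {    # rgb + alpha
      a <- arr[, , 4]
      arr <- arr[, , 1:3] * rep(a, 3) + rep(1 - a, 3)
      dim(arr) <- c(nrow(a), ncol(a), 3)
    } else if (nc == 1) {
      arr <- arr[, , 1]
    }
  }
  vals <- rhu(arr * 255)
  vals[vals < 0] <- 0L; vals[vals > 255] <- 255L
  storage.mode(vals) <- "integer"
  raster_image(vals)
}

#' Write a raster image as a lossless PNG
#' @param img a [raster_image()]
#' @param path output path (PNG)
#' @export
write_image <- function(img, path) {
  stopifnot(inherits(img, "raster_image"))
  ok <- tryCatch({ png::writePNG(img$data / 255, target = path); TRUE },
                 error = function(e) stop("cannot write PNG '", path, "': ",
                                          conditionMessage(e)))
  invisible(ok)
}

# minimal PNM (P2/P3/P5/P6) reader, returning doubles in [0,1]
read_pnm <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P3", "P5", "P6"))
    stop("unsupported PNM magic '", magic, "' in ", path)
  toks <- integer(0)
  # header tokens: width height maxval (comments allowed)
  read_tok <- function() {
    repeat {
      ch <- readChar(con, 1L, useBytes = TRUE)
      while (length(ch) && grepl("^\\s$", ch)) ch <- readChar(con, 1L, useBytes = TRUE)
      if (!length(ch)) stop("truncated PNM header in ", path)
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L, useBytes = TRUE)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (!length(ch) || grepl("^\\s$", ch)) break
        tok <- paste0(tok, ch)
      }
      return(as.integer(tok))
    }
  }
  w <- read_tok(); h <- read_tok(); maxval <- read_tok()
  nch <- if (magic %in% c("P3", "P6")) 3L else 1L
  n <- w * h * nch
  if (magic %in% c("P5", "P6")) {
    if (maxval < 256) {
      v <- as.integer(readBin(con, "raw", n))
    } else {
      v <- readBin(con, "integer", n, size = 2, signed = FALSE, endian = "big")
    }
  } else {
    v <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(v) < n) stop("truncated PNM pixel data in ", path)
  v <- v / maxval
  if (nch == 1L) {
    matrix(v, nrow = h, ncol = w, byrow = TRUE)
  } else {
    a <- array(0, c(h, w, 3))
    for (k in 1:3) a[, , k] <- matrix(v[seq(k, n, by = 3)], h, w, byrow = TRUE)
    a
  }
}

# minimal uncompressed 24-bit / 8-bit-gray BMP reader, doubles in [0,1]
read_bmp <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 54 || rawToChar(raw[1:2]) != "BM")
    stop("not a BMP file: ", path)
  u32 <- function(o) sum(as.integer(raw[o + 1:4]) * 256^(0:3))
  u16 <- function(o) sum(as.integer(raw[o + 1:2]) * 256^(0:1))
  off <- u32(10); w <- u32(18); h <- u32(22)
  bpp <- u16(28); comp <- u32(30)
  if (comp != 0) stop("compressed BMP not supported: ", path)
  if (!bpp %in% c(8, 24)) stop("only 8/24-bit BMP supported: ", path)
  if (bpp == 24) {
    stride <- ((w * 3 + 3) %/% 4) * 4
    a <- array(0, c(h, w, 3))
    for (row in 0:(h - 1)) {
      base <- off + row * stride
      px <- as.integer(raw[base + seq_len(w * 3)])
      y <- h - row            # BMP rows are bottom-up
      a[y, , 1] <- px[seq(3, w * 3, 3)] / 255
      a[y, , 2] <- px[seq(2, w * 3, 3)] / 255
      a[y, , 3] <- px[seq(1, w * 3, 3)] / 255
    }
    a
  } else {
    stride <- ((w + 3) %/% 4) * 4
    m <- matrix(0, h, w)
    for (row in 0:(h - 1)) {
      base <- off + row * stride
      m[h - row, ] <- as.integer(raw[base + seq_len(w)]) / 255
    }
    m
  }
}

# full-range BT.601 forward matrix
.ycc_fwd <- matrix(c(0.299, 0.587, 0.114,
                     -0.168735892, -0.331264108, 0.5,
                     0.5, -0.418687589, -0.081312411),
                   nrow = 3, byrow = TRUE)

#' RGB to YCbCr conversion (full-range BT.601)
#'
#' Values are rounded to the nearest integer (half up) and clamped to
#' `[0, 255]`.  The round trip with [ycbcr_to_rgb()] differs by at most one
#' level per channel.
#'
#' @param img a 3-channel [raster_image()]
#' @return list with integer matrices `Y`, `Cb`, `Cr`
#' @export
rgb_to_ycbcr <- function(img) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels != 3L) stop("rgb_to_ycbcr requires a 3-channel image")
  r <- matrix(img$data[, , 1], img$h, img$w)
  g <- matrix(img$data[, , 2], img$h, img$w)
  b <- matrix(img$data[, , 3], img$h, img$w)
  y  <- .ycc_fwd[1, 1] * r + .ycc_fwd[1, 2] * g + .ycc_fwd[1, 3] * b
  cb <- 128 + .ycc_fwd[2, 1] * r + .ycc_fwd[2, 2] * g + .ycc_fwd[2, 3] * b
  cr <- 128 + .ycc_fwd[3, 1] * r + .ycc_fwd[3, 2] * g + .ycc_fwd[3, 3] * b
  clamp8 <- function(m) {
    m <- rhu(m); m[m < 0] <- 0L; m[m > 255] <- 255L
    storage.mode(m) <- "integer"; m
  }
  list(Y = clamp8(y), Cb = clamp8(cb), Cr = clamp8(cr))
}

#' YCbCr to RGB conversion (inverse full-range BT.601)
#' @param Y,Cb,Cr integer matrices of equal size
#' @return a 3-channel [raster_image()]
#' @export
ycbcr_to_rgb <- function(Y, Cb, Cr) {
  if (!all(dim(Y) == dim(Cb)) || !all(dim(Y) == dim(Cr)))
    stop("Y, Cb, Cr planes must have identical dimensions")
  cb <- Cb - 128; cr <- Cr - 128
  r <- Y + 1.402 * cr
  g <- Y - 0.344136286 * cb - 0.714136286 * cr
  b <- Y + 1.772 * cb
  clamp8 <- function(m) {
    m <- rhu(m); m[m < 0] <- 0L; m[m > 255] <- 255L
    storage.mode(m) <- "integer"; m
  }
  a <- array(0L, c(nrow(Y), ncol(Y), 3))
  a[, , 1] <- clamp8(r); a[, , 2] <- clamp8(g); a[, , 3] <- clamp8(b)
  raster_image(a)
}

# luma plane of any raster image (identity for grayscale)
luma_plane <- function(img) {
  if (img$channels == 1L) img$data else rgb_to_ycbcr(img)$Y
}
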