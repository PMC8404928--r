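#' Encoder parameters
#'
#' The four quality/compression knobs and the feature flags of the encoder.
#' `L` is the number of selected layers, `eps` the island-removal fraction,
#' `sigma_thr` the skeleton saliency threshold and `gamma` the B-spline fit
#' tolerance as a fraction of the image diagonal.  For colour images the
#' chroma channels (Cb, Cr) are compressed harder than luma using
#' `(round(n1*L), min(1, n2*eps), n3*sigma_thr, n4*gamma)`.
#'
#' @param L layer count, in `[1, 256]` (default 18)
#' @param eps island fraction (default 0.01)
#' @param sigma_thr saliency threshold (default 1.0)
#' @param gamma fit tolerance fraction (default 0.002)
#' @param n1,n2,n3,n4 chroma multipliers (defaults 0.5, 5, 2, 1)
#' @param adaptive_polarity encode the cheaper of the upper/lower threshold
#'   set per layer (default TRUE)
#' @param y_structure_removal remove border Y-structures by semi-disc
#'   extension and MAT clipping (default TRUE)
#' @param interpolation inter-layer distance-weighted interpolation at
#'   decode (default TRUE)
#' @param layer_strategy `"histogram"` or `"uniform"` (see [select_layers()])
#' @export
encoder_params <- function(L = 18L, eps = 0.01, sigma_thr = 1.0,
                           gamma = 0.002, n1 = 0.5, n2 = 5, n3 = 2, n4 = 1,
                           adaptive_polarity = TRUE,
                           y_structure_removal = TRUE,
                           interpolation = TRUE,
                           layer_strategy = c("histogram", "uniform")) {
  layer_strategy <- match.arg(layer_strategy)
  if (L < 1 || L > 256) stop("L must be in [1, 256]")
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  if (sigma_thr < 0) stop("sigma_thr must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  structure(list(L = as.integer(L), eps = eps, sigma_thr = sigma_thr,
                 gamma = gamma, n1 = n1, n2 = n2, n3 = n3, n4 = n4,
                 adaptive_polarity = isTRUE(adaptive_polarity),
                 y_structure_removal = isTRUE(y_structure_removal),
                 interpolation = isTRUE(interpolation),
                 layer_strategy = layer_strategy),
            class = "encoder_params")
}

# chroma parameter set derived from the luma set
chroma_params <- function(params) {
  p <- params
  p$L <- max(1L, as.integer(rhu(params$n1 * params$L)))
  p$eps <- min(1, params$n2 * params$eps)
  p$sigma_thr <- params$n3 * params$sigma_thr
  p$gamma <- params$n4 * params$gamma
  p
}

new_encoded_layer <- function(intensity, flip, splines = list(),
                              empty = FALSE, full = FALSE, max_err = 0) {
  n <- if (length(splines))
    sum(vapply(splines, function(s) nrow(s$cp), 0L)) else 0L
  structure(list(intensity = as.integer(intensity), flip = isTRUE(flip),
                 empty = isTRUE(empty), full = isTRUE(full),
                 splines = splines, n_control = as.integer(n),
                 max_err = max_err),
            class = "encoded_layer")
}

#' Encode one threshold layer as B-spline MATs
#'
#' Pipeline: threshold, island removal, optional semi-disc border extension,
#' MAT computation, saliency regularization, clipping back to the frame,
#' branch tracing and per-branch spline fitting.  A layer that covers the
#' whole frame is stored as a `full` marker (no MAT exists for it); a layer
#' with no foreground (or no surviving skeleton) is stored as `empty`.
#'
#' For `polarity = "lower"` the set `{I <= i-1}` is encoded, whose
#' complement at decode time is exactly the upper set `{I >= i}`.
#'
#' @param channel integer matrix
#' @param i layer intensity
#' @param polarity `"upper"` or `"lower"` (lower sets the flip flag)
#' @param params [encoder_params()]
#' @param salient optional [salient_map()]
#' @return an `encoded_layer`
#' @export
encode_layer <- function(channel, i, polarity = "upper", params = encoder_params(),
                         salient = NULL) {
  w <- ncol(channel); h <- nrow(channel)
  flip <- polarity == "lower"
  layer <- if (flip) threshold_layer(channel, max(i - 1, 0), "lower")
           else threshold_layer(channel, i, "upper")
  if (flip && i == 0) layer$mask[] <- FALSE   # {I <= -1} is empty
  layer <- remove_islands(layer, params$eps, salient)
  if (!any(layer$mask))
    return(new_encoded_layer(i, flip, empty = TRUE))
  if (all(layer$mask))
    return(new_encoded_layer(i, flip, full = TRUE))
  band <- 0L
  mask <- layer$mask
  if (params$y_structure_removal) {
    ext <- semi_disc_extend(mask)
    mask <- ext$mask
    band <- ext$band
  }
  mat <- compute_mat(mask, complete = FALSE)
  mat <- regularize_mat(mat, params$sigma_thr)
  if (band > 0) {
    mat$x <- mat$x - band
    mat$y <- mat$y - band
  }
  mat <- clip_mat(mat, w, h)
  if (!nrow(mat))
    return(new_encoded_layer(i, flip, empty = TRUE))
  branches <- trace_branches(mat)
  # the island fraction applied at the MAT level: a skeletal fragment (< 4
  # samples) whose disc union cannot cover more than eps*|T_i| pixels
  # encodes boundary micro-detail of the same scale the island filter
  # removes; longer branches always carry real structure and are kept
  if (params$eps > 0 && length(branches) > 1) {
    total <- sum(layer$mask)
    keep <- vapply(branches, function(b) {
      r <- max(b$dt)
      nrow(b) >= 4 || pi * r^2 + 2 * r * nrow(b) >= params$eps * total
    }, logical(1))
    if (any(keep) && !all(keep)) {
      branches <- branches[keep]
      # dropping fragments removes junctions; re-trace the remaining pixel
      # set so artificially split chains merge back into single branches
      px <- unique(do.call(rbind, lapply(branches, function(b)
        b[, c("x", "y", "dt", "rho", "sigma", "border")])))
      branches <- trace_branches(px)
    }
  }
  diagpx <- sqrt(w^2 + h^2)
  splines <- list()
  max_err <- 0
  for (b in branches) {
    f <- fit_branch(b, params$gamma, diagpx)
    splines <- c(splines, f$splines)
    max_err <- max(max_err, f$max_err)
  }
  # least-squares control points may overshoot the representable ranges
  # (e.g. slightly negative radii); clamp to the container's fixed-point span
  splines <- lapply(splines, function(s) {
    s$cp[, 1] <- pmin(pmax(s$cp[, 1], -w), 2 * w)
    s$cp[, 2] <- pmin(pmax(s$cp[, 2], -h), 2 * h)
    s$cp[, 3] <- pmin(pmax(s$cp[, 3], 0), diagpx)
    s
  })
  new_encoded_layer(i, flip, splines = splines, max_err = max_err)
}

#' Choose the cheaper polarity for one layer
#'
#' Encodes both the upper and the lower threshold set and keeps the one
#' needing fewer B-spline control points (ties go to upper, flip unset).
#' With `adaptive_polarity` off the upper set is used unconditionally.
#'
#' @inheritParams encode_layer
#' @return the chosen `encoded_layer`, with attributes `n_upper`/`n_lower`
#'   when both were tried
#' @export
choose_polarity <- function(channel, i, params = encoder_params(),
                            salient = NULL) {
  up <- encode_layer(channel, i, "upper", params, salient)
  if (!params$adaptive_polarity) return(up)
  lo <- encode_layer(channel, i, "lower", params, salient)
  chosen <- if (lo$n_control < up$n_control) lo else up
  attr(chosen, "n_upper") <- up$n_control
  attr(chosen, "n_lower") <- lo$n_control
  chosen
}

encode_channel <- function(channel, params, salient = NULL) {
  intens <- select_layers(channel, params$L, params$layer_strategy)
  layers <- lapply(intens, function(i) choose_polarity(channel, i, params, salient))
  list(layers = layers, params = params)
}

#' Encode a raster image
#'
#' Grayscale images are encoded as one channel; colour images are converted
#' to YCbCr and the chroma channels are compressed harder (see
#' [encoder_params()]).  Per channel, layer intensities are selected and
#' each is encoded with the cheaper polarity.
#'
#' @param img a [raster_image()]
#' @param params [encoder_params()]
#' @param salient optional [salient_map()]
#' @param diagnostics keep per-layer polarity costs as attributes
#' @return an `sdmd_file` object (see [sdmd_serialize()])
#' @export
encode_image <- function(img, params = encoder_params(), salient = NULL,
                         diagnostics = FALSE) {
  stopifnot(inherits(img, "raster_image"))
  if (img$channels == 1L) {
    chans <- list(encode_channel(img$data, params, salient))
    mode <- "gray"
  } else {
    ycc <- rgb_to_ycbcr(img)
    cp <- chroma_params(params)
    chans <- list(encode_channel(ycc$Y, params, salient),
                  encode_channel(ycc$Cb, cp, salient),
                  encode_channel(ycc$Cr, cp, salient))
    mode <- "ycbcr"
  }
  structure(list(w = img$w, h = img$h, colormode = mode,
                 channels = chans, interpolation = params$interpolation),
            class = "sdmd_file")
}

#' @export
print.sdmd_file <- function(x, ...) {
  cat(sprintf("sdmd_file %d x %d (%s)\n", x$w, x$h, x$colormode))
  for (k in seq_along(x$channels)) {
    ly <- x$channels[[k]]$layers
    ncp <- sum(vapply(ly, function(l) l$n_control, 0L))
    cat(sprintf("  channel %d: %d layers, %d control points\n",
                k, length(ly), ncp))
  }
  invisible(x)
}

# --- binary container ------------------------------------------------------

# unsigned LEB128 varint
varint_encode <- function(x) {
  x <- as.numeric(x)
  out <- integer(0)
  repeat {
    b <- x %% 128
    x <- x %/% 128
    if (x > 0) out <- c(out, b + 128L) else { out <- c(out, b); break }
  }
  as.integer(out)
}

u16q <- function(v) c(v %% 256L, v %/% 256L)    # little-endian byte pair

# fixed-point quantizers: positions over [-w, 2w] x [-h, 2h], radii [0, diag]
quant_pos <- function(v, span0, span) {
  q <- rhu((v - span0) / span * 65535)
  if (any(q < 0 | q > 65535))
    stop("serialization error: coordinate out of range")
  as.integer(q)
}
dequant_pos <- function(q, span0, span) q / 65535 * span + span0

#' Serialize an SDMD file to bytes
#'
#' Deterministic little-endian layout: magic `"SDMD"`, u8 version, u16 w,
#' u16 h, u8 colormode, then per channel a varint layer count and per layer
#' `{u8 intensity, u8 flags, varint spline count, per spline {u8 degree,
#' varint control-point count, 3 x u16 per point}}`.  Coordinates are
#' quantized to 16-bit fixed point over `[-w, 2w] x [-h, 2h]`, radii over
#' `[0, diag]`; counts are unsigned LEB128 varints.
#'
#' @param file an `sdmd_file` from [encode_image()]
#' @return raw vector
#' @export
sdmd_serialize <- function(file) {
  stopifnot(inherits(file, "sdmd_file"))
  w <- file$w; h <- file$h
  if (w > 65535 || h > 65535) stop("serialization error: image too large")
  diagpx <- sqrt(w^2 + h^2)
  parts <- list(as.integer(charToRaw("SDMD")), 1L,
                u16q(w), u16q(h),
                if (file$colormode == "gray") 0L else 1L)
  for (ch in file$channels) {
    ly <- ch$layers
    parts[[length(parts) + 1L]] <- varint_encode(length(ly))
    for (l in ly) {
      flags <- l$flip + 2L * l$empty + 4L * l$full
      parts[[length(parts) + 1L]] <- c(l$intensity, flags,
                                       varint_encode(length(l$splines)))
      for (s in l$splines) {
        cp <- s$cp
        qx <- quant_pos(cp[, 1], -w, 3 * w)
        qy <- quant_pos(cp[, 2], -h, 3 * h)
        qr <- quant_pos(cp[, 3], 0, diagpx)
        b <- rbind(qx %% 256L, qx %/% 256L, qy %% 256L, qy %/% 256L,
                   qr %% 256L, qr %/% 256L)
        parts[[length(parts) + 1L]] <- c(s$degree,
                                         varint_encode(nrow(cp)),
                                         as.integer(b))
      }
    }
  }
  as.raw(unlist(parts))
}

#' Deserialize SDMD bytes
#'
#' Exact inverse of [sdmd_serialize()] up to the documented 16-bit fixed
#' point quantization.  Corrupt input (bad magic, version mismatch,
#' truncation) raises an error naming the byte offset.
#'
#' @param bytes raw vector
#' @return an `sdmd_file`
#' @export
sdmd_deserialize <- function(bytes) {
  stopifnot(is.raw(bytes))
  v <- as.integer(bytes)
  pos <- 1L
  need <- function(n) {
    if (pos + n - 1L > length(v))
      stop("sdmd decode error: truncated stream at offset ", pos - 1L)
  }
  take <- function(n) { need(n); out <- v[pos:(pos + n - 1L)]; pos <<- pos + n; out }
  take_varint <- function() {
    x <- 0; shift <- 1
    repeat {
      b <- take(1L)
      x <- x + (b %% 128) * shift
      if (b < 128) break
      shift <- shift * 128
      if (shift > 2^42) stop("sdmd decode error: varint overflow at offset ", pos - 1L)
    }
    x
  }
  take_u16 <- function(n = 1L) {
    b <- take(2L * n)
    b[seq(1, 2 * n, 2)] + 256 * b[seq(2, 2 * n, 2)]
  }
  if (!identical(rawToChar(bytes[1:4]), "SDMD"))
    stop("sdmd decode error: bad magic at offset 0")
  pos <- 5L
  ver <- take(1L)
  if (ver != 1L) stop("sdmd decode error: unsupported version ", ver, " at offset 4")
  w <- take_u16(); h <- take_u16()
  mode <- take(1L)
  if (!mode %in% c(0L, 1L))
    stop("sdmd decode error: bad colormode at offset ", pos - 2L)
  diagpx <- sqrt(w^2 + h^2)
  nchan <- if (mode == 0L) 1L else 3L
  chans <- vector("list", nchan)
  for (k in seq_len(nchan)) {
    nl <- take_varint()
    layers <- vector("list", nl)
    for (j in seq_len(nl)) {
      intensity <- take(1L)
      flags <- take(1L)
      ns <- take_varint()
      splines <- vector("list", ns)
      for (s in seq_len(ns)) {
        degree <- take(1L)
        if (degree < 1 || degree > 3)
          stop("sdmd decode error: bad degree at offset ", pos - 2L)
        ncp <- take_varint()
        if (ncp < degree + 1)
          stop("sdmd decode error: too few control points at offset ", pos - 1L)
        q <- take_u16(3L * ncp)
        qm <- matrix(q, ncol = 3, byrow = TRUE)
        cp <- cbind(dequant_pos(qm[, 1], -w, 3 * w),
                    dequant_pos(qm[, 2], -h, 3 * h),
                    dequant_pos(qm[, 3], 0, diagpx))
        splines[[s]] <- bspline_branch(degree, cp)
      }
      layers[[j]] <- new_encoded_layer(intensity, flip = flags %% 2 == 1,
                                       splines = splines,
                                       empty = (flags %/% 2) %% 2 == 1,
                                       full = (flags %/% 4) %% 2 == 1)
    }
    chans[[k]] <- list(layers = layers, params = NULL)
  }
  if (pos <= length(v))
    stop("sdmd decode error: trailing bytes at offset ", pos - 1L)
  structure(list(w = w, h = h,
                 colormode = if (mode == 0L) "gray" else "ycbcr",
                 channels = chans, interpolation = TRUE),
            class = "sdmd_file")
}

#' Write / read an `.sdmd` container file
#' @param file an `sdmd_file`
#' @param path file path
#' @export
write_sdmd <- function(file, path) {
  writeBin(sdmd_serialize(file), path)
  invisible(path)
}

#' @rdname write_sdmd
#' @export
read_sdmd <- function(path) {
  sdmd_deserialize(readBin(path, "raw", file.size(path)))
}

#' Compression ratio
#'
#' Raw bitmap byte size (`w * h * channels`) divided by the encoded byte
#' size.  Values below 1 (encoding larger than raw) are reported as-is.
#'
#' @param img a [raster_image()]
#' @param encoded raw vector (serialized SDMD encoding)
#' @export
compression_ratio <- function(img, encoded) {
  stopifnot(length(encoded) > 0)
  (img$w * img$h * img$channels) / length(encoded)
}
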