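#' Render one encoded layer as a boolean mask
#'
#' Rasterizes every spline of the layer at the target scale, extends chains
#' whose endpoints touch the frame border (45-degree-plane rule, see
#' [extend_border_branch()]), stamps an open disc of radius `r` at every
#' chain sample and clips to the scaled frame.  `empty`/`full` markers
#' produce all-false/all-true masks.  If the layer's flip flag is set the
#' mask is complemented, so the returned mask always carries upper-set
#' semantics.
#'
#' @param layer an `encoded_layer`
#' @param w,h original frame size in pixels
#' @param scale target scale factor `>= 1`
#' @return list with `intensity` and the boolean `mask` at
#'   `round(scale*h) x round(scale*w)`
#' @export
render_layer <- function(layer, w, h, scale = 1) {
  if (scale < 1) stop("scale must be >= 1")
  ws <- as.integer(rhu(scale * w)); hs <- as.integer(rhu(scale * h))
  finish <- function(mask) {
    if (layer$flip) mask <- !mask
    list(intensity = layer$intensity, mask = mask)
  }
  if (layer$full) return(finish(matrix(TRUE, hs, ws)))
  if (layer$empty || !length(layer$splines))
    return(finish(matrix(FALSE, hs, ws)))
  xs <- ys <- rs <- numeric(0)
  near_edge <- function(p) {
    # clipped branch ends lie exactly on the frame ring (0.1 px covers the
    # container's fixed-point quantization)
    min(p[1], w - 1 - p[1], p[2], h - 1 - p[2]) <= 0.1
  }
  off <- (scale - 1) / 2
  for (s in layer$splines) {
    chain <- rasterize_spline(s, scale)
    xs <- c(xs, chain$xf); ys <- c(ys, chain$yf); rs <- c(rs, chain$r)
    # prolong clipped ends beyond the frame (45-degree-plane rule), taking
    # the direction and radius slope from the spline's end control legs so
    # the extension is independent of the rasterization scale
    m <- nrow(s$cp)
    for (end in 1:2) {
      p_end <- if (end == 1) s$cp[1, ] else s$cp[m, ]
      p_in  <- if (end == 1) s$cp[2, ] else s$cp[m - 1, ]
      if (!near_edge(p_end) || sum((p_end[1:2] - p_in[1:2])^2) < 1e-12) next
      seg <- rbind(c(p_in[1:2] * scale + off, p_in[3] * scale),
                   c(p_end[1:2] * scale + off, p_end[3] * scale))
      branch <- data.frame(x = seg[, 1], y = seg[, 2], dt = seg[, 3])
      ext <- extend_border_branch(branch, ws, hs, ends = c(FALSE, TRUE))
      if (nrow(ext) > 2) {
        added <- ext[-(1:2), , drop = FALSE]
        xs <- c(xs, added$x); ys <- c(ys, added$y); rs <- c(rs, added$dt)
      }
    }
  }
  finish(cpp_stamp_discs(hs, ws, xs, ys, rs, TRUE))
}

#' Composite reconstructed layers in increasing luminance order
#'
#' Starts from the lowest selected intensity as background and paints each
#' layer's mask with its intensity, in increasing order (painter's
#' algorithm).
#'
#' @param layers list of `list(intensity, mask)` (upper-set semantics)
#' @param background background intensity; defaults to the lowest layer
#'   intensity
#' @return integer channel plane
#' @export
composite_layers <- function(layers, background = NULL) {
  stopifnot(length(layers) > 0)
  ints <- vapply(layers, function(l) l$intensity, 0L)
  ord <- order(ints)
  if (is.null(background)) background <- min(ints)
  dims <- dim(layers[[ord[1]]]$mask)
  plane <- matrix(as.integer(background), dims[1], dims[2])
  for (k in ord) plane[layers[[k]]$mask] <- as.integer(layers[[k]]$intensity)
  plane
}

#' Inter-layer distance-weighted interpolation
#'
#' Smooths the banding between consecutive reconstructed layers: a pixel
#' lying in layer `i` but not in layer `i+1` is blended as
#' `v_i + (v_{i+1} - v_i) * d_i / (d_i + d_{i+1})`, where `d_i` is its
#' distance into layer `i` (to the layer boundary) and `d_{i+1}` its
#' distance to layer `i+1`; the weights are symmetric so the blend is
#' continuous at both layer boundaries.  Pixels in the top layer keep their
#' value.
#'
#' @param plane composited integer plane (from [composite_layers()])
#' @param layers the same layer list passed to [composite_layers()]
#' @return interpolated integer plane
#' @export
interpolate_layers <- function(plane, layers) {
  ints <- vapply(layers, function(l) l$intensity, 0L)
  ord <- order(ints)
  layers <- layers[ord]; ints <- ints[ord]
  k <- length(layers)
  if (k < 2) return(plane)
  # band index: the highest layer containing each pixel
  idx <- matrix(0L, nrow(plane), ncol(plane))
  for (j in seq_len(k)) idx[layers[[j]]$mask] <- j
  out <- plane
  for (j in seq_len(k - 1)) {
    sel <- idx == j
    if (!any(sel)) next
    lower_mask <- layers[[j]]$mask
    upper_mask <- layers[[j + 1]]$mask
    # a full layer has no boundary inside the frame: its band is not
    # "between" two isocontours, so it keeps its own intensity
    if (all(lower_mask) || !any(upper_mask)) next
    d_in <- cpp_edt(lower_mask)             # distance to outside layer j
    d_up <- cpp_edt(!upper_mask)            # distance to layer j+1
    v0 <- ints[j]; v1 <- ints[j + 1]
    di <- d_in[sel]; du <- d_up[sel]
    tot <- di + du
    val <- ifelse(tot > 0, v0 + (v1 - v0) * di / tot, v0)
    out[sel] <- pmax(0L, pmin(255L, as.integer(rhu(val))))
  }
  out
}

decode_channel <- function(layers, w, h, scale, interpolate) {
  rendered <- lapply(layers, render_layer, w = w, h = h, scale = scale)
  plane <- composite_layers(rendered)
  if (interpolate) plane <- interpolate_layers(plane, rendered)
  plane
}

#' Decode an SDMD file to a raster image
#'
#' Renders all layers of each channel at the requested scale, composites
#' them in luminance order, optionally applies inter-layer interpolation,
#' and converts YCbCr back to RGB for colour files.  Any `scale >= 1`
#' (non-integer allowed) yields a `round(scale*w) x round(scale*h)` image
#' from the same stored control points (super-resolution decode).
#'
#' @param file an `sdmd_file` (from [encode_image()] or [read_sdmd()])
#' @param scale target scale factor `>= 1`
#' @param interpolate apply inter-layer interpolation
#' @return a [raster_image()]
#' @export
decode_image <- function(file, scale = 1, interpolate = TRUE) {
  stopifnot(inherits(file, "sdmd_file"))
  if (scale < 1) stop("scale must be >= 1")
  w <- file$w; h <- file$h
  planes <- lapply(file$channels, function(ch)
    decode_channel(ch$layers, w, h, scale, interpolate))
  if (file$colormode == "gray") {
    raster_image(planes[[1]])
  } else {
    ycbcr_to_rgb(planes[[1]], planes[[2]], planes[[3]])
  }
}
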