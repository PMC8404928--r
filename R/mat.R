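#' Exact Euclidean distance transform of a binary layer
#'
#' Distance from each foreground pixel centre to the nearest background
#' pixel centre (exact, not chamfer); 0 outside the foreground.  Disc radii
#' at reconstruction use the same convention, so the transform/stamping pair
#' is self-consistent.
#'
#' @param layer a [threshold_layer()] (or any object with a logical `mask`)
#' @return numeric matrix of distances
#' @export
distance_transform <- function(layer) {
  mask <- if (inherits(layer, "binary_layer")) layer$mask else layer
  stopifnot(is.logical(mask), is.matrix(mask))
  if (all(mask))
    stop("unbounded layer: mask has no background pixels")
  cpp_edt(mask)
}

#' Compute the saliency-annotated medial axis transform of a layer
#'
#' Returns the skeletal pixels of the layer together with their disc radius
#' `dt` (exact Euclidean distance transform), boundary importance `rho` (arc
#' length, in boundary pixels, of the boundary interval collapsing onto the
#' pixel, computed by parameterizing every boundary contour by arc length
#' and taking the largest circular parameter jump to a neighbour's nearest
#' boundary point) and saliency `sigma = rho / dt`.  The skeleton is thinned
#' to one-pixel width with a connectivity-preserving (Guo-Hall) pass;
#' pixels whose importance does not exceed one boundary pixel are excluded
#' by construction.
#'
#' @param layer a [threshold_layer()] (or logical mask)
#' @param complete add coverage-completion pixels (inscribed-disc centres
#'   added in decreasing radius order) until the open-disc union reproduces
#'   the layer exactly.  The encoder disables this: its saliency and island
#'   pruning discard sub-threshold detail anyway, and on border-extended
#'   canvases completion would plant oversized discs near the frame.
#' @return data frame with columns `x`, `y` (0-based pixel coordinates),
#'   `dt`, `rho`, `sigma`
#' @export
compute_mat <- function(layer, complete = TRUE) {
  mask <- if (inherits(layer, "binary_layer")) layer$mask else layer
  stopifnot(is.logical(mask), is.matrix(mask))
  if (all(mask))
    stop("unbounded layer: mask has no background pixels")
  res <- cpp_mat(mask, isTRUE(complete))
  idx <- which(res$skel)
  h <- nrow(mask)
  y <- (idx - 1L) %% h
  x <- (idx - 1L) %/% h
  dt <- res$dt[idx]
  rho <- res$rho[idx]
  mp <- data.frame(x = as.integer(x), y = as.integer(y),
                   dt = dt, rho = rho, sigma = rho / dt)
  mp[order(mp$y, mp$x), , drop = FALSE]
}

#' Prune a MAT by saliency
#'
#' Keeps the skeletal pixels with `sigma >= sigma_thr`; monotone in the
#' threshold and the identity at `sigma_thr = 0`.
#'
#' @param mat data frame from [compute_mat()]
#' @param sigma_thr saliency threshold (>= 0)
#' @export
regularize_mat <- function(mat, sigma_thr) {
  if (sigma_thr < 0) stop("sigma_thr must be >= 0")
  mat[mat$sigma >= sigma_thr, , drop = FALSE]
}

#' Detect foreground runs along the image border
#'
#' Maximal runs of foreground pixels along each of the four frame edges,
#' reported as segments `(A, B)` (inclusive endpoints, 0-based coordinates).
#' A run spanning a corner is reported once per edge.
#'
#' @param layer a [threshold_layer()] (or logical mask)
#' @return data frame with columns `side`, `ax`, `ay`, `bx`, `by`
#' @export
detect_border_segments <- function(layer) {
  mask <- if (inherits(layer, "binary_layer")) layer$mask else layer
  h <- nrow(mask); w <- ncol(mask)
  runs <- function(v) {
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cbind(starts[r$values], ends[r$values])
  }
  out <- list()
  add <- function(side, se, horiz, fixed) {
    if (!nrow(se)) return()
    for (k in seq_len(nrow(se))) {
      s <- se[k, 1] - 1L; e <- se[k, 2] - 1L
      out[[length(out) + 1L]] <<- if (horiz)
        data.frame(side = side, ax = s, ay = fixed, bx = e, by = fixed)
      else
        data.frame(side = side, ax = fixed, ay = s, bx = fixed, by = e)
    }
  }
  add("top",    runs(mask[1, ]),  TRUE,  0L)
  add("bottom", runs(mask[h, ]),  TRUE,  h - 1L)
  add("left",   runs(mask[, 1]),  FALSE, 0L)
  add("right",  runs(mask[, w]),  FALSE, w - 1L)
  if (!length(out))
    return(data.frame(side = character(), ax = integer(), ay = integer(),
                      bx = integer(), by = integer()))
  do.call(rbind, out)
}

#' Extend a layer with semi-discs over its border segments
#'
#' Removes spurious skeletal Y-structures at the image border: the canvas is
#' enlarged by a band on all four sides and, for every border segment, the
#' outward semi-disc centred at `(A+B)/2` with radius `|A-B|/2` is added as
#' foreground.  The band is `ceiling(max |A-B| / 2)` (0 when there are no
#' segments).
#'
#' @param layer a [threshold_layer()] (or logical mask)
#' @return list with the extended logical `mask` and the `band` width in
#'   pixels; the original foreground sits at offset `(band, band)`
#' @export
semi_disc_extend <- function(layer) {
  mask <- if (inherits(layer, "binary_layer")) layer$mask else layer
  segs <- detect_border_segments(mask)
  if (!nrow(segs)) return(list(mask = mask, band = 0L))
  h <- nrow(mask); w <- ncol(mask)
  len <- sqrt((segs$bx - segs$ax)^2 + (segs$by - segs$ay)^2)
  # pushing the Y-junction outside the frame needs a bump of the shape's
  # local thickness; an uncapped semi-disc over a frame-spanning segment
  # would dwarf the shape and pull its medial axis out of the frame
  if (!all(mask)) {
    d <- cpp_edt(mask)
    for (k in seq_len(nrow(segs))) {
      px <- (segs$ax[k]:segs$bx[k]) + 1L
      py <- (segs$ay[k]:segs$by[k]) + 1L
      local_dt <- max(d[cbind(rep(py, length.out = max(length(px), length(py))),
                              rep(px, length.out = max(length(px), length(py))))])
      len[k] <- min(len[k], max(2, 4 * local_dt))
    }
  }
  band <- as.integer(ceiling(max(len) / 2))
  if (band < 1L) band <- 1L
  ext <- matrix(FALSE, h + 2L * band, w + 2L * band)
  ext[band + seq_len(h), band + seq_len(w)] <- mask
  for (k in seq_len(nrow(segs))) {
    cx <- (segs$ax[k] + segs$bx[k]) / 2 + band
    cy <- (segs$ay[k] + segs$by[k]) / 2 + band
    r <- len[k] / 2
    disc <- cpp_stamp_discs(nrow(ext), ncol(ext), cx, cy, r, FALSE)
    # keep only the outward half (beyond the original frame edge)
    keep <- matrix(FALSE, nrow(ext), ncol(ext))
    side <- segs$side[k]
    if (side == "top")    keep[seq_len(band + 1L), ] <- TRUE
    if (side == "bottom") keep[(band + h):nrow(ext), ] <- TRUE
    if (side == "left")   keep[, seq_len(band + 1L)] <- TRUE
    if (side == "right")  keep[, (band + w):ncol(ext)] <- TRUE
    ext <- ext | (disc & keep)
  }
  list(mask = ext, band = band)
}

#' Clip a MAT to the image frame
#'
#' Keeps pixels with `0 <= x < w`, `0 <= y < h` (positions must already be
#' expressed in original-frame coordinates).  Pixels that had a skeletal
#' 8-neighbour in the removed (outside) set are flagged `border`: branch
#' endpoints created by the clipping.
#'
#' @param mat data frame from [compute_mat()]
#' @param w,h frame size in pixels
#' @return the clipped MAT with an additional logical `border` column
#' @export
clip_mat <- function(mat, w, h) {
  inside <- mat$x >= 0 & mat$x < w & mat$y >= 0 & mat$y < h
  out <- mat[inside, , drop = FALSE]
  removed <- mat[!inside, , drop = FALSE]
  border <- rep(FALSE, nrow(out))
  if (nrow(removed) && nrow(out)) {
    zr <- complex(real = removed$x, imaginary = removed$y)
    zo <- complex(real = out$x, imaginary = out$y)
    off <- complex(real = rep(-1:1, 3), imaginary = rep(-1:1, each = 3))
    off <- off[off != 0]
    for (o in off) border <- border | (zo + o) %in% zr
  }
  out$border <- border
  rownames(out) <- NULL
  out
}

#' Partition a MAT into simple branches
#'
#' Splits the skeletal pixel set at junctions (pixels with 3 or more
#' skeletal 8-neighbours); junction pixels are duplicated into each incident
#' branch so every branch can be fitted independently.  Branches are
#' returned sorted by their lexicographically smallest endpoint `(y, x)`,
#' and traversal prefers the smaller `(y, x)` neighbour, so the partition is
#' deterministic.  Endpoints are flagged `"free-end"`, `"junction"` or
#' `"border-touch"` (from the `border` column, when present).
#'
#' @param mat data frame from [compute_mat()] / [clip_mat()]
#' @return list of branch data frames; each has an `endpoints` attribute
#'   with the two endpoint flags
#' @export
trace_branches <- function(mat) {
  n <- nrow(mat)
  if (!n) return(list())
  has_border <- "border" %in% names(mat)
  ord <- order(mat$y, mat$x)
  mat <- mat[ord, , drop = FALSE]
  rownames(mat) <- NULL
  z <- complex(real = mat$x, imaginary = mat$y)
  offs <- complex(real = rep(-1:1, 3), imaginary = rep(-1:1, each = 3))
  offs <- offs[offs != 0]
  # neighbour index matrix (n x 8), NA where absent; offsets ordered so that
  # smaller (y, x) neighbours come first
  oord <- order(Im(offs), Re(offs))
  offs <- offs[oord]
  nbr <- vapply(offs, function(o) match(z + o, z), integer(n))
  if (n == 1L) nbr <- matrix(nbr, nrow = 1L)
  deg <- rowSums(!is.na(nbr))
  junction <- deg >= 3
  flag_of <- function(i) {
    if (junction[i]) "junction"
    else if (has_border && mat$border[i]) "border-touch"
    else "free-end"
  }
  visited <- rep(FALSE, n)            # for non-junction pixels
  branches <- list()
  emit <- function(path) {
    b <- mat[path, , drop = FALSE]
    rownames(b) <- NULL
    attr(b, "endpoints") <- c(flag_of(path[1]), flag_of(path[length(path)]))
    branches[[length(branches) + 1L]] <<- b
  }
  walk <- function(start, from) {
    path <- if (is.na(from)) integer(0) else from
    cur <- start
    repeat {
      path <- c(path, cur)
      visited[cur] <<- TRUE
      nb <- nbr[cur, ]
      nb <- nb[!is.na(nb)]
      nxt <- nb[!junction[nb] & !visited[nb]]
      if (length(nxt)) { cur <- nxt[1]; next }
      jn <- nb[junction[nb]]
      if (!is.na(from) && length(path) == 2L) jn <- setdiff(jn, from)
      else jn <- setdiff(jn, path[length(path) - 1L])
      if (length(jn)) path <- c(path, jn[1])
      break
    }
    path
  }
  # open branches: start at free ends and at junction-adjacent pixels
  is_start <- !junction & (deg <= 1 |
    vapply(seq_len(n), function(i) {
      nb <- nbr[i, ]; any(junction[nb[!is.na(nb)]])
    }, logical(1)))
  for (i in which(is_start)) {
    if (visited[i]) next
    nb <- nbr[i, ]; nb <- nb[!is.na(nb)]
    jn <- nb[junction[nb]]
    emit(walk(i, if (length(jn)) jn[1] else NA_integer_))
  }
  # remaining cycles (no junction, no free end)
  for (i in seq_len(n)) {
    if (visited[i] || junction[i]) next
    emit(walk(i, NA_integer_))
  }
  # junction pixels not covered by any incident branch
  covered <- rep(FALSE, n)
  for (b in branches) covered[match(complex(real = b$x, imaginary = b$y), z)] <- TRUE
  for (i in which(junction & !covered)) emit(i)
  # deterministic order: by smallest endpoint (y, x)
  key <- vapply(branches, function(b) {
    e <- b[c(1, nrow(b)), c("y", "x")]
    min(e$y * 1e6 + e$x)
  }, 0)
  branches[order(key)]
}

#' Extend a border-touching branch beyond the frame
#'
#' Linearly extrapolates `(x, y, dt)` from the last two samples of the
#' touching end, appending unit steps until the extrapolated medial disc is
#' tangent to the frame (the 45-degree outer-plane condition: the sample's
#' Euclidean distance outside the frame reaches its `dt`).  Applied at
#' decode time before disc stamping so acute corners where a shape meets the
#' border are covered.
#'
#' @param branch data frame with columns `x`, `y`, `dt` (any resolution)
#' @param w,h frame size in pixels at the branch's resolution
#' @param ends which ends to extend: logical `c(first, last)`
#' @return the branch with extrapolated samples appended
#' @export
extend_border_branch <- function(branch, w, h, ends = c(TRUE, TRUE)) {
  if (!any(ends)) stop("branch has no border-touch endpoint to extend")
  dist_outside <- function(x, y) {
    dx <- pmax(0, -x, x - (w - 1))
    dy <- pmax(0, -y, y - (h - 1))
    sqrt(dx^2 + dy^2)
  }
  extend_one <- function(p_end, p_prev) {
    d <- p_end - p_prev
    nrm <- sqrt(sum(d[1:2]^2))
    if (nrm < 1e-12) return(NULL)
    dir <- d[1:2] / nrm
    slope <- d[3] / nrm
    out <- list()
    dprev <- dist_outside(p_end[1], p_end[2])
    for (k in seq_len(ceiling(2 * max(1, p_end[3])) + 2L)) {
      p <- c(p_end[1:2] + k * dir, p_end[3] + k * slope)
      if (p[3] <= 0) break
      dout <- dist_outside(p[1], p[2])
      # the extrapolation must actually leave the frame; a direction that
      # hugs the border would sweep large discs along the edge
      if (dout <= dprev) break
      dprev <- dout
      out[[length(out) + 1L]] <- p
      if (dout >= p[3]) break
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  n <- nrow(branch)
  if (n < 2) return(branch)
  pts <- as.matrix(branch[, c("x", "y", "dt")])
  pre <- post <- NULL
  if (ends[1]) {
    e <- extend_one(pts[1, ], pts[2, ])
    if (!is.null(e)) pre <- e[rev(seq_len(nrow(e))), , drop = FALSE]
  }
  if (ends[2]) post <- extend_one(pts[n, ], pts[n - 1, ])
  res <- rbind(pre, pts, post)
  out <- data.frame(x = res[, 1], y = res[, 2], dt = res[, 3])
  attr(out, "endpoints") <- attr(branch, "endpoints")
  out
}
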