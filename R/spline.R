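#' B-spline branch representation
#'
#' A clamped uniform-knot B-spline of degree `d` in (x, y, r) space, where
#' `r` is the medial disc radius.  Knots are implied (clamped uniform) and
#' not stored, which keeps the container compact.
#'
#' @param degree spline degree in `[1, 3]`
#' @param cp control point matrix (`m x 3`, columns x, y, r), `m >= degree+1`
#' @export
bspline_branch <- function(degree, cp) {
  cp <- as.matrix(cp)
  if (!is.numeric(cp) || ncol(cp) != 3) stop("cp must be an m x 3 matrix")
  degree <- as.integer(degree)
  if (degree < 1 || degree > 3) stop("degree must be in [1, 3]")
  if (nrow(cp) < degree + 1) stop("need at least degree+1 control points")
  structure(list(degree = degree, cp = unname(cp)), class = "bspline_branch")
}

# clamped uniform knot vector on [0, 1] for m control points, degree d
bspline_knots <- function(d, m) {
  ni <- m - d - 1L
  inner <- if (ni > 0) seq_len(ni) / (ni + 1) else numeric(0)
  c(rep(0, d + 1), inner, rep(1, d + 1))
}

# basis matrix via splines::splineDesign (evaluation clamps t to [0,1])
bspline_basis <- function(d, m, t) {
  kn <- bspline_knots(d, m)
  t <- pmin(pmax(t, 0), 1)
  # splineDesign is open on the right; nudge exact 1s inside and fix up
  at_end <- t >= 1
  t[at_end] <- 1 - 1e-12
  B <- splines::splineDesign(kn, t, ord = d + 1)
  if (any(at_end)) {
    B[at_end, ] <- 0
    B[at_end, m] <- 1
  }
  B
}

# chord-length parameterization of 3D samples
chord_params <- function(points) {
  n <- nrow(points)
  if (n == 1) return(0)
  d <- sqrt(rowSums((points[-1, , drop = FALSE] -
                     points[-n, , drop = FALSE])^2))
  s <- c(0, cumsum(d))
  if (s[n] <= 0) return(NULL)           # degenerate: all samples coincide
  s / s[n]
}

#' Least-squares B-spline fit with clamped endpoints
#'
#' Fits a clamped uniform-knot B-spline of degree `d` with `m` control
#' points to chord-length-parameterized 3D samples, fixing the first and
#' last control points to the first and last samples and solving the
#' interior control points in the least-squares sense.
#'
#' @param points `n x 3` matrix of (x, y, r) samples, `n >= m`
#' @param d degree in `[1, 3]`
#' @param m number of control points, `m >= d + 1`
#' @return list with `spline` ([bspline_branch()]), `max_err` (max 3D
#'   deviation at the sample parameters), and per-sample `errs`
#' @export
least_squares_fit <- function(points, d, m) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (m < d + 1) stop("need m >= d + 1")
  if (n < m) stop("need at least m samples")
  t <- chord_params(points)
  if (is.null(t)) stop("sdmd_fit_failure: degenerate parameterization")
  if (d == 1 && m == n) {
    # interpolating polyline: the curve passes through every sample
    sp <- bspline_branch(1L, points)
    return(list(spline = sp, max_err = 0, errs = rep(0, n)))
  }
  B <- bspline_basis(d, m, t)
  p0 <- points[1, ]; pn <- points[n, ]
  if (m == 2) {
    cp <- rbind(p0, pn)
  } else {
    A <- B[, 2:(m - 1), drop = FALSE]
    rhs <- points - outer(B[, 1], p0) - outer(B[, m], pn)
    qa <- qr(A)
    if (qa$rank < m - 2) stop("sdmd_fit_failure: singular normal equations")
    cint <- qr.coef(qa, rhs)
    cp <- rbind(p0, cint, pn)
  }
  curve <- B %*% cp
  errs <- sqrt(rowSums((points - curve)^2))
  list(spline = bspline_branch(d, cp), max_err = max(errs), errs = errs)
}

#' Fit a MAT branch with the fewest control points within tolerance
#'
#' Searches control-point counts upward (and degrees 1..3 for each count),
#' accepting the first fit whose maximum 3D deviation is at most
#' `gamma * diag`.  When no fit with at most `min(n, 64)` control points
#' succeeds, the branch is split at its worst-fit sample and both halves are
#' fitted recursively (fit-and-split).  Branches with 3 samples or fewer are
#' stored directly as degree-1 polylines.
#'
#' @param branch data frame with columns `x`, `y`, `dt` (skeletal samples in
#'   order), or an `n x 3` matrix
#' @param gamma tolerance as a fraction of the image diagonal
#' @param diag image diagonal `sqrt(w^2 + h^2)` in pixels
#' @return list with `splines` (list of [bspline_branch()]) and `max_err`
#' @export
fit_branch <- function(branch, gamma, diag) {
  if (gamma <= 0) stop("gamma must be > 0")
  pts <- if (is.data.frame(branch)) as.matrix(branch[, c("x", "y", "dt")])
         else as.matrix(branch)
  tau <- gamma * diag
  fit_rec <- function(points) {
    n <- nrow(points)
    if (n == 1) {
      sp <- bspline_branch(1L, rbind(points[1, ], points[1, ]))
      return(list(splines = list(sp), max_err = 0))
    }
    if (n <= 3 || is.null(chord_params(points))) {
      sp <- bspline_branch(1L, points[c(1, seq_len(n)[-1]), , drop = FALSE])
      return(list(splines = list(sp), max_err = 0))
    }
    m_max <- min(n, 64L)
    best <- NULL
    for (m in 2:m_max) {
      for (d in 1:min(3L, m - 1L)) {
        f <- tryCatch(least_squares_fit(points, d, m), error = function(e) NULL)
        if (is.null(f)) next
        if (f$max_err <= tau)
          return(list(splines = list(f$spline), max_err = f$max_err))
        if (is.null(best) || f$max_err < best$max_err) best <- f
      }
    }
    # split at the worst-fit sample and recurse
    k <- if (is.null(best)) ceiling(n / 2) else which.max(best$errs)
    if (k <= 1 || k >= n) k <- ceiling(n / 2)
    left <- fit_rec(points[1:k, , drop = FALSE])
    right <- fit_rec(points[k:n, , drop = FALSE])
    list(splines = c(left$splines, right$splines),
         max_err = max(left$max_err, right$max_err))
  }
  fit_rec(pts)
}

# --- Bezier conversion and de Casteljau evaluation ------------------------

# insert knot u once (Boehm's algorithm); returns list(knots, cp)
insert_knot <- function(knots, cp, d, u) {
  m <- nrow(cp)
  k <- max(which(knots <= u))           # knots[k] <= u < knots[k+1]
  if (k > m) k <- m
  Q <- matrix(0, m + 1, ncol(cp))
  for (i in seq_len(m + 1)) {
    if (i <= k - d) Q[i, ] <- cp[i, ]
    else if (i > k) Q[i, ] <- cp[i - 1, ]
    else {
      a <- (u - knots[i]) / (knots[i + d] - knots[i])
      Q[i, ] <- (1 - a) * cp[i - 1, ] + a * cp[i, ]
    }
  }
  list(knots = sort(c(knots, u)), cp = Q)
}

# split a clamped B-spline into Bezier segments (list of (d+1) x 3 matrices)
# plus the breakpoints in [0,1]
bezier_segments <- function(spline) {
  d <- spline$degree; cp <- spline$cp
  knots <- bspline_knots(d, nrow(cp))
  inner <- unique(knots[knots > 0 & knots < 1])
  for (u in inner) {
    mult <- sum(abs(knots - u) < 1e-12)
    while (mult < d) {
      r <- insert_knot(knots, cp, d, u)
      knots <- r$knots; cp <- r$cp
      mult <- mult + 1
    }
  }
  breaks <- unique(c(0, inner, 1))
  segs <- lapply(seq_len(length(breaks) - 1), function(j) {
    cp[((j - 1) * d + 1):((j - 1) * d + d + 1), , drop = FALSE]
  })
  list(segments = segs, breaks = breaks)
}

# de Casteljau evaluation of one Bezier segment at local parameters u
decasteljau <- function(cp, u) {
  n <- nrow(cp)
  P <- lapply(seq_len(n), function(i)
    matrix(cp[i, ], length(u), ncol(cp), byrow = TRUE))
  if (n > 1)
    for (r in seq_len(n - 1))
      for (i in seq_len(n - r))
        P[[i]] <- (1 - u) * P[[i]] + u * P[[i + 1]]
  P[[1]]
}

#' Evaluate a B-spline at global parameters
#'
#' Evaluates by Bezier-segment conversion (knot insertion) and de
#' Casteljau's algorithm.  Parameters 0 and 1 return the first and last
#' control points exactly (clamped knots).
#'
#' @param spline a [bspline_branch()]
#' @param t parameter vector in `[0, 1]`
#' @return `length(t) x 3` matrix of (x, y, r) points
#' @export
eval_bspline <- function(spline, t) {
  bz <- bezier_segments(spline)
  t <- pmin(pmax(t, 0), 1)
  seg <- findInterval(t, bz$breaks, rightmost.closed = TRUE)
  seg[seg < 1] <- 1
  out <- matrix(0, length(t), 3)
  for (j in unique(seg)) {
    sel <- seg == j
    a <- bz$breaks[j]; b <- bz$breaks[j + 1]
    out[sel, ] <- decasteljau(bz$segments[[j]], (t[sel] - a) / (b - a))
  }
  out
}

#' Rasterize a B-spline into a connected pixel chain
#'
#' Control points are mapped to the target resolution (`p -> scale * p +
#' offset` for x and y, radii scaled by `scale`), the curve is converted to
#' Bezier segments and evaluated by de Casteljau with adaptive subdivision
#' until consecutive samples are 8-connected after rounding.  The default
#' offset `(scale - 1) / 2` preserves pixel-centre alignment between
#' resolutions.
#'
#' @param spline a [bspline_branch()]
#' @param scale target scale factor `>= 1`
#' @param offset coordinate offset applied after scaling
#' @return data frame `x`, `y` (integer pixel positions), `r` (radius)
#' @export
rasterize_spline <- function(spline, scale = 1, offset = (scale - 1) / 2) {
  if (scale < 1) stop("scale must be >= 1")
  sp <- spline
  sp$cp <- cbind(spline$cp[, 1:2] * scale + offset, spline$cp[, 3] * scale)
  bz <- bezier_segments(sp)
  pieces <- lapply(bz$segments, function(cpseg) {
    poly_len <- sum(sqrt(rowSums(
      (cpseg[-1, 1:2, drop = FALSE] - cpseg[-nrow(cpseg), 1:2, drop = FALSE])^2)))
    u <- seq(0, 1, length.out = max(2L, ceiling(poly_len) + 1L))
    for (pass in 1:40) {
      pts <- decasteljau(cpseg, u)
      rx <- rhu(pts[, 1]); ry <- rhu(pts[, 2])
      gap <- pmax(abs(diff(rx)), abs(diff(ry)))
      bad <- which(gap > 1)
      if (!length(bad)) break
      u <- sort(c(u, (u[bad] + u[bad + 1]) / 2))
    }
    cbind(rhu(pts[, 1]), rhu(pts[, 2]), pts[, 3], pts[, 1], pts[, 2])
  })
  all <- do.call(rbind, pieces)
  keep <- c(TRUE, abs(diff(all[, 1])) + abs(diff(all[, 2])) > 0)
  all <- all[keep, , drop = FALSE]
  # xf, yf carry the sub-pixel sample positions used for disc stamping
  data.frame(x = as.integer(all[, 1]), y = as.integer(all[, 2]), r = all[, 3],
             xf = all[, 4], yf = all[, 5])
}
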