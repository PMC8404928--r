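#' Threshold a channel plane into a binary layer
#'
#' Upper polarity selects `{x : I(x) >= i}` (the threshold set `T_i`), lower
#' polarity selects `{x : I(x) <= i}`.
#'
#' @param channel integer matrix (one channel plane)
#' @param i intensity in `[0, 255]`
#' @param polarity `"upper"` or `"lower"`
#' @return a `binary_layer`: list with `intensity`, `polarity`, `mask`
#' @export
threshold_layer <- function(channel, i, polarity = c("upper", "lower")) {
  polarity <- match.arg(polarity)
  if (i < 0 || i > 255) stop("intensity must be in [0, 255]")
  mask <- if (polarity == "upper") channel >= i else channel <= i
  structure(list(intensity = as.integer(i), polarity = polarity, mask = mask),
            class = "binary_layer")
}

#' Select the intensities used to layer a channel
#'
#' `"uniform"` spaces up to `L` intensities evenly over the channel's
#' `[min, max]` range (both ends included).  `"histogram"` (the default used
#' by the encoder) greedily adds the intensity whose inclusion most reduces
#' the total per-pixel quantization error `sum(|I(x) - q(x)|)`, where `q`
#' quantizes each pixel down to the largest selected intensity `<= I(x)`.
#' Both strategies always include the channel minimum (the base layer), and
#' return strictly increasing intensities that occur in the channel.
#'
#' @param channel integer matrix
#' @param L maximum number of layers, in `[1, 256]`
#' @param strategy `"histogram"` or `"uniform"`
#' @return increasing integer vector of intensities, length `<= L`
#' @export
select_layers <- function(channel, L, strategy = c("histogram", "uniform")) {
  strategy <- match.arg(strategy)
  if (L < 1 || L > 256) stop("L must be in [1, 256]")
  L <- as.integer(L)
  vals <- sort(unique(as.vector(channel)))
  if (length(vals) <= L && strategy == "uniform")
    return(vals)
  if (length(vals) == 1L) return(vals)
  if (strategy == "uniform") {
    lo <- vals[1]; hi <- vals[length(vals)]
    cand <- unique(rhu(seq(lo, hi, length.out = L)))
    # snap each candidate to the nearest present value, keep increasing
    snapped <- vapply(cand, function(v) vals[which.min(abs(vals - v))], 0L)
    sel <- sort(unique(c(vals[1], snapped)))
    return(utils::head(sel, L))
  }
  # histogram: greedy quantization-error minimization on the 256-bin histogram
  counts <- tabulate(as.vector(channel) + 1L, nbins = 256L)
  present <- which(counts > 0) - 1L      # intensities 0..255 present
  sel <- vals[1]
  err_for <- function(sel_sorted) {
    # q(v) = largest selected <= v; error sum_v counts[v]*(v - q(v))
    idx <- findInterval(present, sel_sorted)
    sum(counts[present + 1L] * (present - sel_sorted[idx]))
  }
  current <- err_for(sel)
  # adding layers below half-a-level mean error encodes rounding noise only
  floor_err <- 0.5 * sum(counts)
  while (length(sel) < L && current > floor_err) {
    cand <- setdiff(present, sel)
    if (!length(cand)) break
    errs <- vapply(cand, function(c) err_for(sort(c(sel, c))), 0)
    best <- which.min(errs)       # ties: smallest intensity (cand is sorted)
    if (errs[best] >= current) break
    sel <- sort(c(sel, cand[best]))
    current <- errs[best]
  }
  as.integer(sel)
}

#' Construct a salient-region map
#'
#' A boolean mask of salient pixels plus the two island-removal fractions:
#' components lying mostly inside the map keep small details
#' (`eps_salient`), components outside are cleaned more aggressively
#' (`eps_background`).
#'
#' @param mask logical matrix, `TRUE` = salient
#' @param eps_salient island fraction used for salient components
#' @param eps_background island fraction used elsewhere
#' @export
salient_map <- function(mask, eps_salient, eps_background) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!(eps_salient >= 0 && eps_salient <= eps_background && eps_background <= 1))
    stop("need 0 <= eps_salient <= eps_background <= 1")
  structure(list(mask = mask, eps_salient = eps_salient,
                 eps_background = eps_background),
            class = "salient_map")
}

#' Read a salient-region map from a binary image (nonzero = salient)
#' @param path image path (see [read_image()])
#' @inheritParams salient_map
#' @export
read_salient_map <- function(path, eps_salient, eps_background) {
  img <- read_image(path)
  salient_map(luma_plane(img) > 0, eps_salient, eps_background)
}

#' Remove small islands (and fill small holes) in a binary layer
#'
#' Every 8-connected foreground component smaller than `eps * |T_i|` pixels
#' is removed, and every 4-connected enclosed background hole smaller than
#' the same bound is filled; `|T_i|` is the foreground pixel count of the
#' input layer.  With a [salient_map()], the fraction applied to a component
#' is `eps_salient` when the majority of its pixels are salient and
#' `eps_background` otherwise (`eps` is ignored).
#'
#' @param layer a [threshold_layer()]
#' @param eps island fraction in `[0, 1]`
#' @param salient optional [salient_map()]
#' @return the cleaned `binary_layer`
#' @export
remove_islands <- function(layer, eps, salient = NULL) {
  stopifnot(inherits(layer, "binary_layer"))
  if (eps < 0 || eps > 1) stop("eps must be in [0, 1]")
  mask <- layer$mask
  total <- sum(mask)
  if (total == 0 || (eps == 0 && is.null(salient))) return(layer)
  comp_thresholds <- function(lab, ncomp) {
    # per-component eps, honouring the salient map by majority overlap
    if (is.null(salient)) return(rep(eps, ncomp))
    cnt <- tabulate(lab[lab > 0], nbins = ncomp)
    sal <- tabulate(lab[lab > 0 & salient$mask], nbins = ncomp)
    ifelse(sal > cnt / 2, salient$eps_salient, salient$eps_background)
  }
  # islands: small foreground components (8-connected)
  lab <- cpp_label(mask, 8L)
  ncomp <- max(lab)
  if (ncomp > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = ncomp)
    thr <- comp_thresholds(lab, ncomp) * total
    kill <- which(sizes < thr)
    if (length(kill)) mask[lab %in% kill] <- FALSE
  }
  # holes: small enclosed background components (4-connected)
  labb <- cpp_label(!mask, 4L)
  ncompb <- max(labb)
  if (ncompb > 0) {
    border <- unique(c(labb[1, ], labb[nrow(labb), ], labb[, 1], labb[, ncol(labb)]))
    sizes <- tabulate(labb[labb > 0], nbins = ncompb)
    thr <- comp_thresholds(labb, ncompb) * total
    fill <- setdiff(which(sizes < thr), border)
    if (length(fill)) mask[labb %in% fill] <- TRUE
  }
  layer$mask <- mask
  layer
}
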