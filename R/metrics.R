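#' Structural similarity index (SSIM)
#'
#' Classic single-scale SSIM with an 11 x 11 Gaussian window (sd 1.5),
#' constants `K1 = 0.01`, `K2 = 0.03`, dynamic range `L = 255`, averaged
#' over all fully-valid windows.  Colour images are compared on their luma
#' (Y) plane.
#'
#' @param a,b [raster_image()] objects (or integer matrices) of equal size
#' @return similarity in `[-1, 1]`; 1 means identical images
#' @export
ssim <- function(a, b) {
  pa <- if (inherits(a, "raster_image")) luma_plane(a) else a
  pb <- if (inherits(b, "raster_image")) luma_plane(b) else b
  if (!all(dim(pa) == dim(pb))) stop("ssim: images must have equal dimensions")
  x <- matrix(as.double(pa), nrow(pa)); y <- matrix(as.double(pb), nrow(pb))
  k <- dnorm(-5:5, sd = 1.5); k <- k / sum(k)
  C1 <- (0.01 * 255)^2; C2 <- (0.03 * 255)^2
  mu_x <- cpp_sepconv_valid(x, k)
  mu_y <- cpp_sepconv_valid(y, k)
  sxx <- cpp_sepconv_valid(x * x, k) - mu_x^2
  syy <- cpp_sepconv_valid(y * y, k) - mu_y^2
  sxy <- cpp_sepconv_valid(x * y, k) - mu_x * mu_y
  num <- (2 * mu_x * mu_y + C1) * (2 * sxy + C2)
  den <- (mu_x^2 + mu_y^2 + C1) * (sxx + syy + C2)
  mean(num / den)
}

#' Encode, decode and score an image
#'
#' Runs the full codec round trip and reports the reconstruction quality
#' and compression ratio.
#'
#' @param img a [raster_image()]
#' @param params [encoder_params()]
#' @param salient optional [salient_map()]
#' @return list with `ssim`, `cr`, `bytes`, and the decoded image
#'   (`decoded`)
#' @export
evaluate_quality <- function(img, params = encoder_params(), salient = NULL) {
  enc <- encode_image(img, params, salient)
  bytes <- sdmd_serialize(enc)
  dec <- decode_image(sdmd_deserialize(bytes),
                      interpolate = params$interpolation)
  list(ssim = ssim(img, dec), cr = compression_ratio(img, bytes),
       bytes = length(bytes), decoded = dec)
}
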