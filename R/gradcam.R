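#' Gradient-weighted saliency map for a 1D spectrum
#'
#' Grad-CAM adapted to 1D regression: channel weights are the spatial average
#' of the gradient of the scalar output with respect to each feature map of
#' the final convolutional layer; the map is the rectified weighted sum of
#' those feature maps, linearly interpolated to the input length and min-max
#' normalized to [0, 1]. A constant (all-equal) raw map is returned as all
#' zeros with a degenerate flag.
#'
#' @param net A fitted [isnet()].
#' @param spectrum A standardized input spectrum (vector) or matrix of
#'   spectra (one map per row is returned in a list).
#' @param layer Target layer; only the final convolution (`"conv2"`) is
#'   convolutional ahead of the head, anything else is an error.
#' @return A `saliency_map` (list with `values`, `layer`, `degenerate`), or a
#'   list of them for matrix input.
#' @export
grad_cam_1d <- function(net, spectrum, layer = "conv2") {
  stopifnot(inherits(net, "isnet"))
  vf_check(identical(layer, "conv2"), "vibrofirm_domain_error",
           "target layer must be the final convolutional layer ('conv2')")
  single <- is.null(dim(spectrum))
  x <- if (single) matrix(spectrum, nrow = 1) else as.matrix(spectrum)
  cfg <- net$config
  ws <- new.env(parent = emptyenv())
  nb <- nrow(x)
  fw <- isnet_fwd(net$params, net$buffers, x, cfg, ws, train = FALSE,
                  keep_cache = TRUE)
  head <- isnet_bwd_head(net$params, cfg, fw$cache, rep(1, nb))
  L1 <- cfg$L1
  Msum <- fw$cache$idx$Msum
  A <- fw$cache$r2$Y                       # post-activation feature maps
  alpha <- (head$dr2 %*% Msum) / L1        # channels x samples
  weighted <- colSums(A * alpha[, fw$cache$idx$gidx, drop = FALSE])
  weighted <- pmax(weighted, 0)
  grid_in <- seq(1, cfg$input_length, length.out = L1)
  maps <- lapply(seq_len(nb), function(i) {
    m <- weighted[((i - 1) * L1 + 1):(i * L1)]
    up <- stats::approx(grid_in, m, xout = seq_len(cfg$input_length),
                        rule = 2)$y
    rng <- range(up)
    if (diff(rng) == 0) {
      structure(list(values = rep(0, cfg$input_length), layer = layer,
                     degenerate = TRUE), class = "saliency_map")
    } else {
      structure(list(values = (up - rng[1]) / diff(rng), layer = layer,
                     degenerate = FALSE), class = "saliency_map")
    }
  })
  if (single) maps[[1]] else maps
}

#' Mean saliency over a frequency band
#'
#' Arithmetic mean of saliency values whose frequencies fall in the half-open
#' band `[lo, hi)`.
#'
#' @param map A `saliency_map` from [grad_cam_1d()], or a plain numeric
#'   vector of saliency values.
#' @param band Length-2 numeric `(lo, hi)` in Hz.
#' @param frequencies Frequency grid matching the map length.
#' @return Scalar mean saliency in the band.
#' @export
band_saliency <- function(map, band, frequencies) {
  v <- if (inherits(map, "saliency_map")) map$values else as.numeric(map)
  vf_check(length(v) == length(frequencies), "vibrofirm_domain_error",
           "map and frequency grid length mismatch")
  sel <- frequencies >= band[1] & frequencies < band[2]
  vf_check(any(sel), "vibrofirm_domain_error", "empty frequency band")
  mean(v[sel])
}
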