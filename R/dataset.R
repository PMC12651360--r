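#' Reference firmness from puncture curves
#'
#' The reference firmness of a fruit is the mean of the least-squares slopes of
#' its three puncture force-displacement curves over the initial region
#' `[0, fit_depth]` mm.
#'
#' @param curves List of exactly three `force_curve` objects.
#' @param fit_depth Displacement window (mm) for the initial slope.
#' @return Firmness (N/mm).
#' @export
firmness_from_force_curves <- function(curves, fit_depth = 2) {
  vf_check(is.list(curves) && length(curves) == 3, "vibrofirm_domain_error",
           "exactly three puncture curves required")
  slopes <- vapply(curves, function(cv) {
    vf_check(max(cv$displacement) >= fit_depth, "vibrofirm_domain_error",
             "curve does not reach fit_depth")
    sel <- cv$displacement <= fit_depth
    stats::coef(stats::lm(cv$force[sel] ~ cv$displacement[sel]))[[2]]
  }, numeric(1))
  mean(slopes)
}

#' Aggregate replicate spectra
#'
#' Pointwise mean (default) or median power across repeated excitations of the
#' same fruit, on the shared frequency grid.
#'
#' @param spectra List of [vib_spectrum()] on a common grid.
#' @param method `"mean"` or `"median"`.
#' @return A single [vib_spectrum()].
#' @export
aggregate_replicates <- function(spectra, method = c("mean", "median")) {
  method <- match.arg(method)
  vf_check(length(spectra) >= 1, "vibrofirm_domain_error", "no spectra supplied")
  f <- spectra[[1]]$frequencies
  same <- vapply(spectra, function(s) isTRUE(all.equal(s$frequencies, f)),
                 logical(1))
  vf_check(all(same), "vibrofirm_domain_error", "spectra on mismatched grids")
  P <- do.call(rbind, lapply(spectra, function(s) s$power))
  pw <- if (method == "mean") colMeans(P) else apply(P, 2, stats::median)
  vib_spectrum(f, pw, source_id = spectra[[1]]$source_id)
}

#' Deterministic stratified dataset split
#'
#' Shuffles ids within each stratum under the given seed and assigns them to
#' partitions whose sizes follow largest-remainder rounding of the requested
#' ratios (ties broken toward the earlier partition). With `stratify = NULL`
#' the whole id set is a single stratum, so 471 ids at 7:1:2 give 330/47/94
#' and 120 ids at 4:1 give 96/24.
#'
#' @param ids Character or integer vector of sample identifiers.
#' @param ratios Positive numeric partition ratios, e.g. `c(7, 1, 2)`.
#' @param seed Integer seed.
#' @param stratify Optional factor-like vector, same length as `ids`.
#' @param names Partition names (defaults to train/val/test or train/val).
#' @return Named list of disjoint id vectors covering `ids`, with the seed and
#'   ratios attached as attributes.
#' @export
split_dataset <- function(ids, ratios = c(7, 1, 2), seed = 1L,
                          stratify = NULL, names = NULL) {
  vf_check(all(ratios > 0), "vibrofirm_domain_error", "ratios must be positive")
  k <- length(ratios)
  if (is.null(names)) {
    names <- if (k == 3) c("train", "val", "test")
             else if (k == 2) c("train", "val")
             else paste0("part", seq_len(k))
  }
  vf_check(length(ids) >= 1, "vibrofirm_domain_error", "no ids to split")
  strata <- if (is.null(stratify)) rep(1L, length(ids)) else stratify
  vf_check(length(strata) == length(ids), "vibrofirm_domain_error",
           "stratify must match ids in length")
  set.seed(as.integer(seed %% 2147483647))
  parts <- rep(list(character(0)), k)
  for (s in unique(strata)) {
    sub <- ids[strata == s]
    vf_check(length(sub) >= 1, "vibrofirm_domain_error", "empty stratum")
    sub <- sample(sub)
    sizes <- largest_remainder(length(sub), ratios)
    stops <- cumsum(sizes)
    starts <- c(1L, utils::head(stops, -1) + 1L)
    for (j in seq_len(k)) {
      if (sizes[j] > 0) parts[[j]] <- c(parts[[j]], sub[starts[j]:stops[j]])
    }
  }
  names(parts) <- names
  structure(parts, seed = seed, ratios = ratios)
}

#' Per-frequency standardizer
#'
#' Learns per-bin mean and standard deviation from training spectra only;
#' degenerate bins (zero SD) have their SD replaced by 1 so the transform stays
#' invertible. Applying the fitted standardizer to its own training matrix
#' yields per-bin mean 0 and SD 1 at every non-degenerate bin.
#'
#' @param x Numeric matrix, training samples x bins.
#' @return Object of class `standardizer` with `center`, `scale` and
#'   `degenerate` flags.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  vf_check(nrow(x) >= 2, "vibrofirm_domain_error",
           "need >= 2 training samples to standardize")
  ctr <- colMeans(x)
  sc <- apply(x, 2, stats::sd)
  degen <- !is.finite(sc) | sc == 0
  sc[degen] <- 1
  structure(list(center = ctr, scale = sc, degenerate = degen),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A fitted `standardizer`.
#' @param newdata Matrix or vector on the same bin grid.
#' @export
apply_standardizer <- function(std, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  vf_check(ncol(newdata) == length(std$center), "vibrofirm_domain_error",
           "bin count mismatch")
  sweep(sweep(newdata, 2, std$center), 2, std$scale, "/")
}

#' @rdname fit_standardizer
#' @export
invert_standardizer <- function(std, newdata) {
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1)
  sweep(sweep(newdata, 2, std$scale, "*"), 2, std$center, "+")
}

#' Assemble the model feature matrix from spectra
#'
#' Stacks per-fruit spectra into a samples x bins matrix. By default power is
#' log10-transformed before any standardization, since spectral density spans
#' several orders of magnitude across the 0-5000 Hz grid.
#'
#' @param spectra List of [vib_spectrum()] on a common grid.
#' @param log_power Apply `log10` (with a tiny floor) to power. Default TRUE.
#' @return Numeric matrix with `frequencies` attribute.
#' @export
spectrum_matrix <- function(spectra, log_power = TRUE) {
  f <- spectra[[1]]$frequencies
  P <- do.call(rbind, lapply(spectra, function(s) s$power))
  if (log_power) P <- log10(pmax(P, 1e-300))
  rownames(P) <- vapply(spectra, function(s) as.character(s$source_id),
                        character(1))
  attr(P, "frequencies") <- f
  P
}
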