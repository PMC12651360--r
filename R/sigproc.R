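#' Detect excitation onset in a vibration record
#'
#' Estimates the noise floor from the first `noise_window` seconds and returns
#' the first sample index at which `|x|` exceeds `k` times the noise SD for
#' `m` consecutive samples. When the noise window has zero variance the
#' threshold degenerates and the first nonzero sample is returned directly.
#'
#' @param record A [vibration_record()] or numeric vector.
#' @param noise_window Seconds of leading record assumed excitation-free.
#' @param k Threshold multiplier on the noise SD.
#' @param m Required consecutive supra-threshold samples.
#' @param sampling_rate Required when `record` is a plain vector.
#' @return 1-based onset sample index.
#' @export
detect_onset <- function(record, noise_window = 0.5, k = 5, m = 10,
                         sampling_rate = NULL) {
  if (inherits(record, "vibration_record")) {
    x <- record$samples; fs <- record$sampling_rate
  } else {
    x <- as.numeric(record); fs <- sampling_rate
    vf_check(!is.null(fs), "vibrofirm_domain_error",
             "sampling_rate required for plain vectors")
  }
  nw <- round(noise_window * fs)
  vf_check(nw >= 2 && nw < length(x), "vibrofirm_domain_error",
           "record shorter than noise window")
  s0 <- stats::sd(x[seq_len(nw)])
  if (s0 == 0) {
    hit <- which(x != 0)
    vf_check(length(hit) > 0, "vibrofirm_no_onset", "no onset found")
    return(hit[1])
  }
  over <- abs(x) > k * s0
  runs <- as.numeric(stats::filter(over, rep(1, m), sides = 1))
  hit <- which(runs == m)
  vf_check(length(hit) > 0, "vibrofirm_no_onset", "no onset found")
  as.integer(hit[1] - m + 1L)
}

#' Extract the analysis segment around onset
#'
#' Returns the contiguous slice spanning `pre` seconds before to `post`
#' seconds after the onset sample, of length `round((pre + post) * fs)`. No
#' implicit padding: insufficient context on either side is an error.
#'
#' @param record A [vibration_record()] or numeric vector.
#' @param onset 1-based onset index; defaults to the record's stored onset.
#' @param pre,post Seconds before/after onset.
#' @param sampling_rate Required for plain vectors.
#' @return Numeric vector of length `round((pre + post) * fs)`.
#' @export
extract_segment <- function(record, onset = NULL, pre = 1.5, post = 1.5,
                            sampling_rate = NULL) {
  if (inherits(record, "vibration_record")) {
    x <- record$samples; fs <- record$sampling_rate
    if (is.null(onset)) onset <- record$onset_index
  } else {
    x <- as.numeric(record); fs <- sampling_rate
    vf_check(!is.null(fs), "vibrofirm_domain_error",
             "sampling_rate required for plain vectors")
    vf_check(!is.null(onset), "vibrofirm_domain_error", "onset required")
  }
  len <- round((pre + post) * fs)
  i0 <- onset - round(pre * fs)
  i1 <- i0 + len - 1L
  vf_check(i0 >= 1 && i1 <= length(x), "vibrofirm_segment_bounds",
           sprintf("segment [%d, %d] outside record of length %d", i0, i1, length(x)))
  x[i0:i1]
}

#' Autoregressive model by Burg's method
#'
#' Fits an AR(p) model with the Burg (maximum-entropy) recursion, which
#' minimises the summed forward and backward prediction-error power and
#' guarantees a stable (minimum-phase) model. Coefficients are reported in the
#' whitening convention `x[n] + sum_k a_k x[n-k] = e[n]`, i.e. the negated
#' one-step predictor coefficients.
#'
#' @param segment Numeric vector, length > `order`, not constant.
#' @param order AR order p >= 1.
#' @param sampling_rate Sampling frequency (Hz), stored for spectrum
#'   evaluation.
#' @return Object of class `ar_model` with `coefficients`, `noise_variance`
#'   (final prediction-error power), `reflection` (partial correlations) and
#'   `order`.
#' @export
burg_ar <- function(segment, order, sampling_rate) {
  segment <- as.numeric(segment)
  vf_check(order >= 1, "vibrofirm_domain_error", "order must be >= 1")
  vf_check(length(segment) > order, "vibrofirm_domain_error",
           "segment must be longer than the AR order")
  vf_check(diff(range(segment)) > 0, "vibrofirm_degenerate_signal",
           "constant segment: AR model undefined")
  fit <- stats::ar.burg(segment, aic = FALSE, order.max = order,
                        demean = TRUE, var.method = 1)
  structure(list(order = as.integer(order),
                 coefficients = -as.numeric(fit$ar),
                 noise_variance = as.numeric(fit$var.pred),
                 reflection = as.numeric(fit$partialacf),
                 sampling_rate = sampling_rate),
            class = "ar_model")
}

#' Power spectrum container
#'
#' @param frequencies Strictly increasing uniform frequency grid (Hz).
#' @param power Non-negative spectral density values, same length.
#' @param source_id Identifier of the originating record/fruit.
#' @return Object of class `vib_spectrum`.
#' @export
vib_spectrum <- function(frequencies, power, source_id = NA_character_) {
  vf_check(length(frequencies) == length(power), "vibrofirm_domain_error",
           "frequencies and power must have equal length")
  vf_check(all(diff(frequencies) > 0), "vibrofirm_domain_error",
           "frequency grid must be strictly increasing")
  vf_check(all(power >= 0), "vibrofirm_domain_error", "power must be >= 0")
  structure(list(frequencies = frequencies, power = power,
                 source_id = source_id), class = "vib_spectrum")
}

#' @export
print.vib_spectrum <- function(x, ...) {
  cat(sprintf("<vib_spectrum> %d points, %.4g-%.4g Hz\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies)))
  invisible(x)
}

#' AR power spectral density on a fixed frequency grid
#'
#' Evaluates the one-sided AR spectral density
#' `P(f) = 2 * sigma^2 / (fs * |1 + sum_k a_k exp(-i 2 pi f k / fs)|^2)`
#' on the inclusive uniform grid from 0 to `f_max` with `n_points` points
#' (default 2623 points over 0--5000 Hz, grid step 5000/2622 Hz).
#'
#' @param model An `ar_model` from [burg_ar()] (an order-0 model, i.e. empty
#'   coefficient vector, gives the flat white-noise density `2 sigma^2 / fs`).
#' @param f_max Upper frequency (Hz); must not exceed Nyquist.
#' @param n_points Number of grid points, >= 2.
#' @param source_id Identifier carried onto the spectrum.
#' @return A [vib_spectrum()].
#' @export
ar_psd <- function(model, f_max = 5000, n_points = 2623,
                   source_id = NA_character_) {
  stopifnot(inherits(model, "ar_model") || is.list(model))
  fs <- model$sampling_rate
  vf_check(n_points >= 2, "vibrofirm_domain_error", "n_points must be >= 2")
  vf_check(f_max <= fs / 2, "vibrofirm_domain_error",
           "f_max must not exceed the Nyquist frequency")
  f <- seq(0, f_max, length.out = n_points)
  a <- model$coefficients
  if (length(a) == 0) {
    p <- rep(2 * model$noise_variance / fs, n_points)
  } else {
    ph <- outer(f, seq_along(a), function(fr, k) -2 * pi * fr * k / fs)
    A <- 1 + (exp(1i * ph) %*% a)
    p <- as.numeric(2 * model$noise_variance / (fs * Mod(A)^2))
  }
  vib_spectrum(f, p, source_id = source_id)
}

# interior local maxima of a numeric vector (strict left, non-strict right)
local_maxima <- function(p) {
  n <- length(p)
  if (n < 3) return(integer(0))
  i <- 2:(n - 1)
  i[p[i] > p[i - 1] & p[i] >= p[i + 1]]
}

# topographic prominence of peak at index i
peak_prominence <- function(p, i) {
  h <- p[i]
  left <- p[seq_len(i - 1)]
  right <- p[(i + 1):length(p)]
  lhigher <- which(left > h)
  rhigher <- which(right > h)
  lmin <- if (length(lhigher)) min(left[(max(lhigher) + 1):length(left)]) else min(left)
  rmin <- if (length(rhigher)) min(right[seq_len(min(rhigher) - 1)]) else min(right)
  h - max(lmin, rmin)
}

#' Locate resonant peaks in a spectrum
#'
#' Finds the `n_peaks` lowest-frequency local maxima above `min_freq` whose
#' topographic prominence exceeds `prominence_fraction` times the global
#' maximum power. The first two qualifying peaks define the first and second
#' resonant frequencies; ties are broken toward lower frequency by the
#' low-to-high scan order.
#'
#' @param spectrum A [vib_spectrum()].
#' @param n_peaks Number of peaks required (default 2).
#' @param min_freq Ignore maxima below this frequency (Hz).
#' @param prominence_fraction Prominence threshold as a fraction of the global
#'   maximum power.
#' @param mass Optional fruit mass (kg); when supplied the elasticity index
#'   `f2^2 * mass` is attached.
#' @return Object of class `resonance_set` with `f1`, `f2`, `frequencies`,
#'   `peak_powers` and optionally `elasticity_index`.
#' @export
find_resonances <- function(spectrum, n_peaks = 2, min_freq = 200,
                            prominence_fraction = 0.05, mass = NULL) {
  stopifnot(inherits(spectrum, "vib_spectrum"))
  p <- spectrum$power; f <- spectrum$frequencies
  cand <- local_maxima(p)
  cand <- cand[f[cand] > min_freq]
  thr <- prominence_fraction * max(p)
  keep <- cand[vapply(cand, function(i) peak_prominence(p, i) > thr, logical(1))]
  vf_check(length(keep) >= n_peaks, "vibrofirm_insufficient_peaks",
           sprintf("found %d qualifying peaks, need %d", length(keep), n_peaks))
  sel <- keep[seq_len(n_peaks)]
  res <- list(f1 = f[sel[1]], f2 = f[sel[2]], frequencies = f[sel],
              peak_powers = p[sel])
  if (!is.null(mass)) res$elasticity_index <- elasticity_index(res$f2, mass)
  structure(res, class = "resonance_set")
}

#' Elasticity index
#'
#' Classical acoustic stiffness surrogate for intact fruit: the squared second
#' resonant frequency times the fruit mass.
#'
#' @param f2 Second resonant frequency (Hz), > 0.
#' @param mass Fruit mass (kg), > 0.
#' @return `f2^2 * mass` (Hz^2 kg).
#' @export
elasticity_index <- function(f2, mass) {
  vf_check(all(f2 > 0), "vibrofirm_domain_error", "f2 must be positive")
  vf_check(all(mass > 0), "vibrofirm_domain_error", "mass must be positive")
  f2^2 * mass
}

#' Per-frequency correlation between spectra and firmness
#'
#' Computes the Pearson correlation between spectral power and firmness at
#' every frequency bin across a set of samples. Bins with zero power variance
#' get `r = 0` and are flagged.
#'
#' @param spectra List of [vib_spectrum()] on a common grid, or a numeric
#'   matrix (samples x bins).
#' @param firmness Numeric vector, one value per sample.
#' @param frequencies Grid, required when `spectra` is a matrix.
#' @return Object of class `correlation_profile` with `frequencies`, `r` and
#'   `degenerate` (logical flags).
#' @export
correlation_profile <- function(spectra, firmness, frequencies = NULL) {
  if (is.matrix(spectra)) {
    P <- spectra
    vf_check(!is.null(frequencies), "vibrofirm_domain_error",
             "frequencies required for matrix input")
    f <- frequencies
  } else {
    f <- spectra[[1]]$frequencies
    same <- vapply(spectra, function(s) isTRUE(all.equal(s$frequencies, f)),
                   logical(1))
    vf_check(all(same), "vibrofirm_domain_error", "spectra on mismatched grids")
    P <- do.call(rbind, lapply(spectra, function(s) s$power))
  }
  vf_check(nrow(P) == length(firmness) && nrow(P) >= 3,
           "vibrofirm_domain_error", "need >= 3 samples with matching firmness")
  r <- suppressWarnings(as.numeric(stats::cor(P, firmness)))
  degen <- !is.finite(r)
  r[degen] <- 0
  structure(list(frequencies = f, r = r, degenerate = degen),
            class = "correlation_profile")
}
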