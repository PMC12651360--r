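#' Vibration record
#'
#' Container for a single-excitation velocity time series together with its
#' acquisition metadata and ground truth.
#'
#' @param samples Numeric vector of finite velocity samples.
#' @param sampling_rate Sampling frequency (Hz).
#' @param onset_index 1-based sample index of excitation onset.
#' @param fruit_id,replicate_id,cultivar Identifiers.
#' @param firmness Reference firmness (N/mm).
#' @param mass Fruit mass (kg).
#' @return Object of class `vibration_record`.
#' @export
vibration_record <- function(samples, sampling_rate, onset_index,
                             fruit_id = "fruit", replicate_id = 1L,
                             cultivar = NA_character_, firmness = NA_real_,
                             mass = NA_real_) {
  vf_check(all(is.finite(samples)), "vibrofirm_domain_error",
           "all samples must be finite")
  vf_check(sampling_rate > 0, "vibrofirm_domain_error", "sampling_rate must be > 0")
  vf_check(onset_index >= 1 && onset_index <= length(samples),
           "vibrofirm_domain_error", "onset_index out of range")
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 onset_index = as.integer(onset_index), fruit_id = fruit_id,
                 replicate_id = replicate_id, cultivar = cultivar,
                 firmness = firmness, mass = mass),
            class = "vibration_record")
}

#' @export
print.vibration_record <- function(x, ...) {
  cat(sprintf("<vibration_record> %s/%s (%s): %d samples @ %g Hz, firmness %.3g N/mm\n",
              x$fruit_id, as.character(x$replicate_id), x$cultivar,
              length(x$samples), x$sampling_rate, x$firmness))
  invisible(x)
}

# closed-form damped multi-mode response evaluated at delays td (>= 0);
# freq_scale is the per-fruit multiplicative resonance confound
modal_response <- function(profile, firmness, td, n_modes, freq_scale = 1) {
  fr <- drop(mode_frequencies(profile, firmness)) * freq_scale
  n_modes <- min(n_modes, length(profile$damping_ratios), length(fr))
  s <- numeric(length(td))
  for (k in seq_len(n_modes)) {
    f <- fr[k]; z <- profile$damping_ratios[k]; A <- profile$mode_amplitudes[k]
    s <- s + A * exp(-2 * pi * f * z * td) * sin(2 * pi * f * sqrt(1 - z^2) * td)
  }
  s
}

# band-limited stochastic component: white noise through a second-order
# band-pass centred on the profile's high band, rescaled to a target variance
highband_component <- function(n, fs, center, target_var, half_width = 200) {
  lo <- max(center - half_width, 1) / (fs / 2)
  hi <- min(center + half_width, fs / 2 - 1) / (fs / 2)
  bf <- signal::butter(1, c(lo, hi), type = "pass")
  z <- as.numeric(signal::filter(bf, stats::rnorm(n)))
  s <- stats::sd(z)
  if (s == 0) return(numeric(n))
  z * sqrt(target_var) / s
}

#' Simulate one noncontact vibration record
#'
#' Generates a velocity time series emulating an impact-excited fruit observed
#' by a noncontact vibrometer: zero-mean noise before the excitation onset,
#' then a sum of exponentially decaying sinusoidal modes whose frequencies are
#' affine in firmness, a band-limited stochastic high-frequency component whose
#' power increases affinely with firmness, and additive measurement noise. The
#' output is bit-reproducible for a fixed seed.
#'
#' @param profile A [cultivar_profile()].
#' @param firmness Firmness (N/mm); must lie in `profile$firmness_range`.
#' @param mass Fruit mass (kg), > 0.
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @param amplitude_scale Multiplier on modal amplitudes (per-record coupling
#'   variation; drawn by [simulate_dataset()], default 1).
#' @param highband_scale Multiplier on the high-band power (default 1).
#' @param freq_scale Multiplier on both mode frequencies (per-fruit resonance
#'   confound; drawn by [simulate_dataset()], default 1).
#' @param fruit_id,replicate_id Identifiers stored on the record.
#' @return A [vibration_record()].
#' @export
simulate_signal <- function(profile, firmness, mass, config = sim_config(),
                            seed = 1L, amplitude_scale = 1, highband_scale = 1,
                            freq_scale = 1,
                            fruit_id = "fruit", replicate_id = 1L) {
  stopifnot(inherits(profile, "cultivar_profile"), inherits(config, "sim_config"))
  vf_check(firmness >= profile$firmness_range[1] &&
             firmness <= profile$firmness_range[2],
           "vibrofirm_domain_error", "firmness outside profile firmness_range")
  vf_check(mass > 0, "vibrofirm_domain_error", "mass must be positive")

  fs <- config$sampling_rate
  n <- round((config$pre_window + config$post_window) * fs)
  onset <- round(config$pre_window * fs) + 1L
  vf_check(onset <= n, "vibrofirm_domain_error", "post_window too short")

  set.seed(as.integer(seed %% 2147483647))
  x <- if (config$noise_sd > 0) stats::rnorm(n, 0, config$noise_sd) else numeric(n)

  td <- (seq.int(onset, n) - onset) / fs
  env <- if (config$excitation_rise > 0) 1 - exp(-td / config$excitation_rise) else 1
  sig <- amplitude_scale *
    modal_response(profile, firmness, td, config$n_modes, freq_scale)

  hb_var <- profile$highband_level * (1 + profile$highband_slope * firmness) *
    highband_scale
  if (hb_var > 0) {
    sig <- sig + highband_component(length(td), fs, profile$highband_center, hb_var)
  }
  x[onset:n] <- x[onset:n] + env * sig

  vibration_record(x, fs, onset, fruit_id = fruit_id,
                   replicate_id = replicate_id, cultivar = profile$name,
                   firmness = firmness, mass = mass)
}

# draw all per-fruit and per-record parameters for a dataset in one seeded
# sweep; both the in-memory and the streaming generator consume this table so
# their draws are identical
draw_dataset_params <- function(profiles, n_per_cultivar, config, seed) {
  vf_check(length(profiles) >= 1, "vibrofirm_domain_error",
           "at least one cultivar profile required")
  if (inherits(profiles, "cultivar_profile")) profiles <- list(profiles)
  vf_check(all(n_per_cultivar >= 1), "vibrofirm_domain_error",
           "counts must be >= 1")
  n_per_cultivar <- rep_len(n_per_cultivar, length(profiles))
  set.seed(as.integer(seed %% 2147483647))
  rows <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    nf <- n_per_cultivar[i]
    rng <- p$firmness_range
    firm <- rtruncnorm(nf, p$mean_firmness, diff(rng) / 4, rng[1], rng[2])
    mass <- stats::runif(nf, p$mass_range[1], p$mass_range[2])
    hb_fruit <- exp(stats::rnorm(nf, 0, 0.35))
    # the modal stiffness driving the spectrum is a noisy proxy of the
    # puncture label; the resonance confound is shared by all replicates
    firm_sig <- pmin(pmax(firm + stats::rnorm(nf, 0, config$label_noise_sd),
                          rng[1]), rng[2])
    freq_scale <- exp(stats::rnorm(nf, 0, config$freq_jitter_sd))
    for (j in seq_len(nf)) {
      nr <- config$replicates_per_fruit
      rows[[length(rows) + 1L]] <- data.frame(
        profile_idx = i,
        fruit_id = sprintf("%s_%03d", p$name, j),
        cultivar = p$name,
        replicate_id = seq_len(nr),
        firmness = firm[j], firmness_signal = firm_sig[j],
        freq_scale = freq_scale[j], mass = mass[j],
        amplitude_scale = exp(stats::rnorm(nr, 0, config$amplitude_jitter_sd)),
        highband_scale = hb_fruit[j] *
          exp(stats::rnorm(nr, 0, config$highband_jitter_sd)),
        rec_seed = sample.int(2147483646L, nr)
      )
    }
  }
  do.call(rbind, rows)
}

#' Simulate a multi-cultivar vibration dataset
#'
#' Draws per-fruit firmness (truncated normal centred at the cultivar mean with
#' SD one quarter of the admissible range) and mass (uniform), then generates
#' `replicates_per_fruit` records per fruit sharing the fruit's firmness and
#' mass. Replicates differ in modal coupling amplitude, high-band power jitter
#' and measurement noise, emulating repeated excitations of the same fruit.
#'
#' @param profiles List of [cultivar_profile()] objects (or a single profile).
#' @param n_per_cultivar Integer vector of fruit counts, recycled over profiles.
#' @param config A [sim_config()].
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return Object of class `vibration_dataset`: a list of per-fruit entries
#'   (`fruit_id`, `cultivar`, `firmness`, `mass`, `records`), with a `meta`
#'   attribute holding the per-fruit sample table.
#' @export
simulate_dataset <- function(profiles, n_per_cultivar, config = sim_config(),
                             seed = 1L) {
  params <- draw_dataset_params(profiles, n_per_cultivar, config, seed)
  if (inherits(profiles, "cultivar_profile")) profiles <- list(profiles)
  fruits <- split(params, factor(params$fruit_id, levels = unique(params$fruit_id)))
  out <- lapply(fruits, function(fp) {
    recs <- lapply(seq_len(nrow(fp)), function(r) {
      rec <- simulate_signal(profiles[[fp$profile_idx[r]]],
                             fp$firmness_signal[r], fp$mass[r],
                             config, seed = fp$rec_seed[r],
                             amplitude_scale = fp$amplitude_scale[r],
                             highband_scale = fp$highband_scale[r],
                             freq_scale = fp$freq_scale[r],
                             fruit_id = fp$fruit_id[r],
                             replicate_id = fp$replicate_id[r])
      rec$firmness <- fp$firmness[r]    # records carry the reference label
      rec
    })
    list(fruit_id = fp$fruit_id[1], cultivar = fp$cultivar[1],
         firmness = fp$firmness[1], mass = fp$mass[1], records = recs)
  })
  meta <- unique(params[c("fruit_id", "cultivar", "firmness", "mass")])
  rownames(meta) <- NULL
  structure(out, meta = meta, class = "vibration_dataset")
}

#' @export
print.vibration_dataset <- function(x, ...) {
  meta <- attr(x, "meta")
  cat(sprintf("<vibration_dataset> %d fruits, %d records (%s)\n",
              length(x), sum(vapply(x, function(f) length(f$records), 1L)),
              paste(unique(meta$cultivar), collapse = ", ")))
  invisible(x)
}

#' Simulate a puncture force-displacement curve
#'
#' Produces a toy puncture curve on a 0--15 mm displacement grid whose initial
#' linear region has slope exactly equal to the requested firmness (the
#' operational definition of firmness used throughout the package), followed by
#' a bioyield plateau and gradual softening, plus optional Gaussian force
#' noise.
#'
#' @param firmness Target initial slope (N/mm), > 0.
#' @param noise_sd Force noise SD (N).
#' @param seed Integer seed.
#' @param yield_depth Displacement (mm) at which the linear region ends.
#' @param step Displacement grid step (mm).
#' @return Object of class `force_curve` with `displacement` (mm) and
#'   `force` (N).
#' @export
simulate_force_curve <- function(firmness, noise_sd = 0, seed = 1L,
                                 yield_depth = 4, step = 0.05) {
  vf_check(firmness > 0, "vibrofirm_domain_error", "firmness must be positive")
  d <- seq(0, 15, by = step)
  fy <- firmness * yield_depth
  f <- ifelse(d <= yield_depth, firmness * d,
              fy * (1 - 0.25 * (1 - exp(-(d - yield_depth) / 3))))
  if (noise_sd > 0) {
    set.seed(as.integer(seed %% 2147483647))
    f <- f + stats::rnorm(length(f), 0, noise_sd)
  }
  structure(list(displacement = d, force = f), class = "force_curve")
}
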