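#' Cultivar vibration profile
#'
#' A `cultivar_profile` captures everything the signal simulator needs to know
#' about one fruit cultivar: where its first two resonant modes sit at the
#' cultivar's mean firmness, how those modes shift with firmness, modal damping
#' and relative amplitudes, the location and firmness-sensitivity of the broad
#' high-frequency band whose power tracks tissue elasticity, and the plausible
#' firmness and mass ranges of the population.
#'
#' Mode frequencies are affine in firmness: `f_k(F) = f_k_at_mean +
#' slope_k * (F - mean_firmness)`. The slope of the first mode may be negative,
#' which is how a cultivar can combine high firmness with a low first resonance
#' (the cross-cultivar relation between the first resonance and firmness is
#' non-monotonic). The second-mode slope must be positive so that the classical
#' elasticity index `f2^2 * m` stays monotone in firmness within a cultivar.
#'
#' @param name Label for the cultivar.
#' @param f1_at_mean,f2_at_mean First and second resonant frequencies (Hz) at
#'   `mean_firmness`.
#' @param mean_firmness Population mean firmness (N/mm).
#' @param f1_slope,f2_slope Frequency shift per unit firmness (Hz per N/mm).
#' @param damping_ratios Damping ratio per mode, each in (0, 1).
#' @param mode_amplitudes Relative velocity amplitude per mode.
#' @param highband_center Centre (Hz) of the broad elasticity-sensitive band.
#' @param highband_level Relative power of the band at unit scale.
#' @param highband_slope Relative power increase per N/mm; band power is
#'   `highband_level * (1 + highband_slope * firmness)`.
#' @param firmness_range Length-2 numeric, admissible firmness (N/mm), min > 0.
#' @param mass_range Length-2 numeric, fruit mass range (kg).
#' @return An object of class `cultivar_profile`.
#' @seealso [default_cultivar_profiles()], [simulate_signal()]
#' @export
cultivar_profile <- function(name, f1_at_mean, f2_at_mean, mean_firmness,
                             f1_slope, f2_slope,
                             damping_ratios = c(0.008, 0.005),
                             mode_amplitudes = c(1, 0.6),
                             highband_center = 3000,
                             highband_level = 0.002,
                             highband_slope = 0.3,
                             firmness_range, mass_range = c(0.15, 0.30)) {
  vf_check(length(firmness_range) == 2 && firmness_range[1] > 0 &&
             firmness_range[1] < firmness_range[2],
           "vibrofirm_domain_error", "firmness_range must be (min, max) with min > 0")
  vf_check(all(damping_ratios > 0 & damping_ratios < 1),
           "vibrofirm_domain_error", "damping ratios must lie in (0, 1)")
  vf_check(f2_slope > 0, "vibrofirm_domain_error", "f2_slope must be positive")
  vf_check(length(damping_ratios) == length(mode_amplitudes),
           "vibrofirm_domain_error", "one amplitude per mode required")
  p <- structure(list(
    name = name, f1_at_mean = f1_at_mean, f2_at_mean = f2_at_mean,
    mean_firmness = mean_firmness, f1_slope = f1_slope, f2_slope = f2_slope,
    damping_ratios = damping_ratios, mode_amplitudes = mode_amplitudes,
    highband_center = highband_center, highband_level = highband_level,
    highband_slope = highband_slope,
    firmness_range = as.numeric(firmness_range),
    mass_range = as.numeric(mass_range)
  ), class = "cultivar_profile")
  # modes must stay ordered and below the 5 kHz analysis ceiling over the range
  fr <- mode_frequencies(p, firmness_range)
  vf_check(all(fr > 0) && all(fr[, 1] < fr[, 2]) && all(fr < 5000),
           "vibrofirm_domain_error",
           "mode frequencies must satisfy 0 < f1 < f2 < 5000 over firmness_range")
  p
}

# first/second mode frequencies at given firmness values; rows = firmness
mode_frequencies <- function(profile, firmness) {
  d <- firmness - profile$mean_firmness
  cbind(f1 = profile$f1_at_mean + profile$f1_slope * d,
        f2 = profile$f2_at_mean + profile$f2_slope * d)
}

#' Default peach cultivar profiles
#'
#' Three profiles emulating soft, intermediate and firm peach cultivars. The
#' resonance anchors at each cultivar's mean firmness are (841.7, 1293.2) Hz at
#' 2.01 N/mm, (900.3, 1401.9) Hz at 4.63 N/mm and (665.7, 1403.8) Hz at
#' 6.07 N/mm. The third (firmest) cultivar carries a negative first-mode slope,
#' so pooled across cultivars the first resonance is not an increasing function
#' of firmness even though it is within each of the first two cultivars.
#'
#' @return Named list of three [cultivar_profile()] objects.
#' @export
default_cultivar_profiles <- function() {
  list(
    hujing = cultivar_profile(
      "hujing", f1_at_mean = 841.7, f2_at_mean = 1293.2, mean_firmness = 2.01,
      f1_slope = 25, f2_slope = 45, firmness_range = c(0.87, 5.08)),
    jinqiuhong = cultivar_profile(
      "jinqiuhong", f1_at_mean = 900.3, f2_at_mean = 1401.9, mean_firmness = 4.63,
      f1_slope = 25, f2_slope = 45, firmness_range = c(1.26, 8.92)),
    dongxue = cultivar_profile(
      "dongxue", f1_at_mean = 665.7, f2_at_mean = 1403.8, mean_firmness = 6.07,
      f1_slope = -25, f2_slope = 35, firmness_range = c(2.22, 8.29))
  )
}

#' Simulation configuration
#'
#' Acquisition-side parameters of the synthetic vibrometer: sampling rate, the
#' analysis window around excitation onset, excitation rise time, measurement
#' noise and the number of repeated excitations per fruit.
#'
#' @param sampling_rate Sampling frequency in Hz.
#' @param pre_window,post_window Seconds of record kept before/after onset.
#' @param excitation_rise Rise time constant (s) of the excitation envelope;
#'   0 gives an instantaneous onset.
#' @param noise_sd Standard deviation of additive measurement noise
#'   (velocity units; modal amplitudes are order 1).
#' @param n_modes Number of resonant modes simulated (>= 2).
#' @param replicates_per_fruit Number of repeated excitations per fruit.
#' @param amplitude_jitter_sd Log-scale SD of the per-record modal amplitude
#'   factor (repeat excitations of one fruit differ in coupling strength).
#' @param highband_jitter_sd Log-scale SD of the per-record high-band power.
#' @param freq_jitter_sd Log-scale SD of the per-fruit multiplicative
#'   resonance confound: size, shape and density shift both modes by a common
#'   factor independent of firmness, so absolute peak position is only a
#'   confounded firmness cue (the f1/f2 ratio is confound-free, which makes
#'   the firmness-to-spectrum map deliberately nonlinear).
#' @param label_noise_sd SD (N/mm) of the decoupling between the puncture
#'   reference label and the modal stiffness driving the spectrum
#'   (destructive reference measurements are themselves noisy proxies).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 312500, pre_window = 1.5,
                       post_window = 1.5, excitation_rise = 0.005,
                       noise_sd = 0.05, n_modes = 2,
                       replicates_per_fruit = 3,
                       amplitude_jitter_sd = 0.35,
                       highband_jitter_sd = 0.4,
                       freq_jitter_sd = 0.06,
                       label_noise_sd = 0.3) {
  vf_check(sampling_rate > 0, "vibrofirm_domain_error", "sampling_rate must be > 0")
  vf_check(pre_window >= 0 && post_window >= 0,
           "vibrofirm_domain_error", "windows must be >= 0")
  vf_check(replicates_per_fruit >= 1,
           "vibrofirm_domain_error", "replicates_per_fruit must be >= 1")
  vf_check(n_modes >= 2, "vibrofirm_domain_error", "n_modes must be >= 2")
  structure(list(
    sampling_rate = sampling_rate, pre_window = pre_window,
    post_window = post_window, excitation_rise = excitation_rise,
    noise_sd = noise_sd, n_modes = n_modes,
    replicates_per_fruit = replicates_per_fruit,
    amplitude_jitter_sd = amplitude_jitter_sd,
    highband_jitter_sd = highband_jitter_sd,
    freq_jitter_sd = freq_jitter_sd,
    label_noise_sd = label_noise_sd
  ), class = "sim_config")
}
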