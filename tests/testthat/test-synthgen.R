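# Synthetic vibration generator: closed forms, determinism, population
# statistics and puncture-curve construction.

test_that("noise-free single-mode record equals the closed-form damped sinusoid", {
  prof <- cultivar_profile("mono", f1_at_mean = 1000, f2_at_mean = 2000,
                           mean_firmness = 3, f1_slope = 10, f2_slope = 10,
                           damping_ratios = c(0.01, 0.01),
                           mode_amplitudes = c(1, 0),
                           highband_level = 0, firmness_range = c(1, 5))
  cfg <- sim_config(sampling_rate = 5000, pre_window = 0.1, post_window = 0.2,
                    excitation_rise = 0, noise_sd = 0)
  rec <- simulate_signal(prof, 3, 0.2, cfg, seed = 1)
  n <- round(0.3 * 5000)
  onset <- round(0.1 * 5000) + 1
  expect_length(rec$samples, n)
  expect_identical(rec$onset_index, as.integer(onset))
  expect_true(all(rec$samples[seq_len(onset - 1)] == 0))
  td <- (seq(onset, n) - onset) / 5000
  z <- 0.01
  expected <- exp(-2 * pi * 1000 * z * td) * sin(2 * pi * 1000 * sqrt(1 - z^2) * td)
  expect_equal(rec$samples[onset:n], expected, tolerance = 1e-12)
})

test_that("identical seed and arguments give bit-identical records", {
  prof <- default_cultivar_profiles()$hujing
  cfg <- cheap_config()
  r1 <- simulate_signal(prof, 2.01, 0.2, cfg, seed = 99)
  r2 <- simulate_signal(prof, 2.01, 0.2, cfg, seed = 99)
  expect_identical(r1$samples, r2$samples)
  r3 <- simulate_signal(prof, 2.01, 0.2, cfg, seed = 100)
  expect_false(identical(r1$samples, r3$samples))
})

test_that("noise-free modal frequencies are recoverable by an independent periodogram", {
  # oracle: zero-padded FFT periodogram, independent of the Burg spectral path
  for (prof in default_cultivar_profiles()) {
    cfg <- sim_config(sampling_rate = 12500, pre_window = 0, post_window = 1,
                      excitation_rise = 0, noise_sd = 0)
    prof$highband_level <- 0
    rec <- simulate_signal(prof, prof$mean_firmness, 0.2, cfg, seed = 1)
    nfft <- 2^18
    mag <- Mod(stats::fft(c(rec$samples, numeric(nfft - length(rec$samples)))))
    freq <- (seq_len(nfft) - 1) * rec$sampling_rate / nfft
    half <- freq < rec$sampling_rate / 2
    f_peak <- freq[half][which.max(mag[half])]
    expect_lt(abs(f_peak - prof$f1_at_mean), rec$sampling_rate / nfft + 1)
  }
})

test_that("domain errors: firmness out of range, bad mass", {
  prof <- default_cultivar_profiles()$hujing
  cfg <- cheap_config()
  expect_error(simulate_signal(prof, 9, 0.2, cfg), class = "vibrofirm_domain_error")
  expect_error(simulate_signal(prof, 2, -1, cfg), class = "vibrofirm_domain_error")
})

test_that("dataset counts, grouping and replicate sharing are correct", {
  profs <- default_cultivar_profiles()
  cfg <- cheap_config()
  ds <- simulate_dataset(profs, c(2, 3, 4), cfg, seed = 5)
  expect_length(ds, 9)
  expect_equal(sum(vapply(ds, function(f) length(f$records), 1L)), 27)
  for (f in ds) {
    firm <- vapply(f$records, function(r) r$firmness, numeric(1))
    expect_true(all(firm == firm[1]))
  }
  ds1 <- simulate_dataset(profs, c(1, 1, 1),
                          cheap_config(replicates_per_fruit = 1), seed = 5)
  expect_equal(sum(vapply(ds1, function(f) length(f$records), 1L)), 3)
  expect_error(simulate_dataset(list(), 3, cfg), class = "vibrofirm_domain_error")
})

test_that("per-cultivar sample mean firmness approaches the profile mean", {
  prof <- default_cultivar_profiles()$jinqiuhong
  cfg <- cheap_config(pre_window = 0.01, post_window = 0.02,
                      replicates_per_fruit = 1)
  ds <- simulate_dataset(prof, 400, cfg, seed = 21)
  firm <- vapply(ds, function(f) f$firmness, numeric(1))
  expect_true(all(firm >= prof$firmness_range[1] & firm <= prof$firmness_range[2]))
  se <- sd(firm) / sqrt(length(firm))
  # truncation at the range bounds is mild, so the mean stays near the target
  expect_lt(abs(mean(firm) - prof$mean_firmness), 3 * se + 0.05)
})

test_that("force curves have the requested initial slope", {
  fit_slope <- function(cv, depth = 2) {
    sel <- cv$displacement <= depth
    unname(coef(lm(cv$force[sel] ~ cv$displacement[sel]))[2])
  }
  expect_equal(fit_slope(simulate_force_curve(2)), 2, tolerance = 1e-12)
  expect_equal(fit_slope(simulate_force_curve(6.07)), 6.07, tolerance = 1e-12)
  expect_error(simulate_force_curve(0), class = "vibrofirm_domain_error")
})

test_that("noisy force curves recover the slope within 5% in >= 95/100 seeds", {
  hits <- vapply(1:100, function(s) {
    cv <- simulate_force_curve(4, noise_sd = 0.05, seed = s)
    sel <- cv$displacement <= 2
    sl <- unname(coef(lm(cv$force[sel] ~ cv$displacement[sel]))[2])
    abs(sl - 4) / 4 < 0.05
  }, logical(1))
  expect_gte(sum(hits), 95)
})

test_that("the full study reproduces the cross-cultivar statistical structure", {
  sim <- get_study()
  meta <- sim$meta
  res <- t(vapply(sim$spectra, function(s) {
    r <- find_resonances(s)
    c(r$f1, r$f2)
  }, numeric(2)))

  # pooled, the first resonance is not an increasing function of firmness,
  # although it is within the two softer cultivars
  pooled <- cor(res[, 1], meta$firmness)
  expect_lt(pooled, 0.1)
  for (cv in c("hujing", "jinqiuhong")) {
    i <- meta$cultivar == cv
    expect_gt(cor(res[i, 1], meta$firmness[i]), 0)
  }

  # log power near the high band correlates positively with firmness
  X <- spectrum_matrix(sim$spectra, log_power = FALSE)
  f <- attr(X, "frequencies")
  hb <- rowMeans(X[, f >= 2900 & f < 3100])
  expect_gt(cor(log(hb), meta$firmness), 0.3)

  # per-bin correlation profile: high band positive and above the
  # between-resonance region
  cp <- correlation_profile(X, meta$firmness, frequencies = f)
  m_hb <- mean(cp$r[f >= 2900 & f < 3100])
  m_res <- mean(cp$r[f >= 900 & f < 1100])
  expect_gt(m_hb, 0)
  expect_gt(m_hb, m_res)
})
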