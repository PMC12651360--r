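# Onset detection, segmentation, Burg AR estimation and spectral evaluation.

test_that("onset detection: impulse on silence, false-positive rate, simulator truth", {
  x <- numeric(5000); x[3000] <- 1
  expect_equal(detect_onset(x, noise_window = 1, sampling_rate = 1000), 3000)

  # pure stationary noise should almost never trigger at k = 8, m = 10
  false_pos <- vapply(1:100, function(s) {
    set.seed(s)
    z <- rnorm(20000)
    !inherits(tryCatch(detect_onset(z, noise_window = 1, k = 8, m = 10,
                                    sampling_rate = 10000),
                       vibrofirm_no_onset = function(e) e),
              "vibrofirm_no_onset")
  }, logical(1))
  expect_lte(sum(false_pos), 1)

  # consecutive-sample onset rule needs the production-scale sampling rate
  # (at reduced rates m = 10 samples spans most of an oscillation period)
  cfg <- sim_config(sampling_rate = 312500, pre_window = 0.2,
                    post_window = 0.1)
  rec <- simulate_signal(default_cultivar_profiles()$hujing, 2.01, 0.2,
                         cfg, seed = 2)
  est <- detect_onset(rec, noise_window = 0.1)
  expect_lt(abs(est - rec$onset_index) / rec$sampling_rate, 0.005)
})

test_that("segment extraction lengths and bounds", {
  x <- numeric(937500)
  seg <- extract_segment(x, onset = 468751, pre = 1.5, post = 1.5,
                         sampling_rate = 312500)
  expect_length(seg, 937500)
  expect_length(extract_segment(numeric(2000), onset = 1000, pre = 0.5,
                                post = 0.5, sampling_rate = 1000), 1000)
  expect_error(extract_segment(numeric(2000), onset = 1, pre = 1.5,
                               post = 0.1, sampling_rate = 1000),
               class = "vibrofirm_segment_bounds")
})

test_that("Burg on white noise: near-zero coefficients, variance consistency", {
  set.seed(1)
  x <- rnorm(65536)
  m <- burg_ar(x, 4, 1000)
  expect_true(all(abs(m$coefficients) < 0.05))
  expect_lt(abs(m$noise_variance - var(x)) / var(x), 0.05)
})

test_that("Burg recovers AR(2) coefficients and agrees with Yule-Walker", {
  # truth in the whitening convention: x[n] - 1.0 x[n-1] + 0.5 x[n-2] = e[n]
  truth <- c(-1.0, 0.5)
  for (s in 1:20) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = c(1.0, -0.5)), 8192))
    bg <- burg_ar(x, 2, 1000)
    yw <- -stats::ar.yw(x, aic = FALSE, order.max = 2)$ar
    expect_true(all(abs(bg$coefficients - truth) < 0.05))
    expect_true(all(abs(bg$coefficients - yw) < 0.02))
  }
})

test_that("Burg models are stable: reflection in [-1,1], minimum phase", {
  for (s in 1:5) {
    set.seed(s)
    x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3, 0.2)), 4096)) +
      sin(2 * pi * 0.123 * seq_len(4096))
    m <- burg_ar(x, 20, 1000)
    expect_true(all(abs(m$reflection) <= 1))
    roots <- polyroot(c(1, m$coefficients))
    expect_true(all(Mod(roots) > 1))
  }
})

test_that("degenerate Burg inputs raise domain errors", {
  expect_error(burg_ar(rep(1, 100), 4, 1000),
               class = "vibrofirm_degenerate_signal")
  expect_error(burg_ar(rnorm(10), 10, 1000), class = "vibrofirm_domain_error")
})

test_that("AR spectral density grid, white-noise level and low-pass shape", {
  m <- structure(list(order = 0L, coefficients = numeric(0),
                      noise_variance = 2, sampling_rate = 312500),
                 class = "ar_model")
  sp <- ar_psd(m)
  expect_length(sp$frequencies, 2623)
  expect_equal(range(sp$frequencies), c(0, 5000))
  expect_equal(diff(sp$frequencies)[1], 5000 / 2622, tolerance = 1e-12)
  expect_true(all(abs(sp$power - 2 * 2 / 312500) < 1e-15))

  # AR(1) low-pass: strictly decreasing over the analysis band
  m1 <- structure(list(order = 1L, coefficients = -0.9, noise_variance = 1,
                       sampling_rate = 312500), class = "ar_model")
  p1 <- ar_psd(m1)
  expect_true(all(diff(p1$power) < 0))
  # closed-form oracle at an arbitrary frequency
  f0 <- p1$frequencies[100]
  expect_equal(p1$power[100],
               2 / (312500 * Mod(1 - 0.9 * exp(-2i * pi * f0 / 312500))^2),
               tolerance = 1e-12)

  expect_error(ar_psd(m1, f_max = 2e5), class = "vibrofirm_domain_error")
})

test_that("white-noise PSD integrates to the expected mean level", {
  set.seed(3)
  x <- rnorm(32768)
  m <- burg_ar(x, 8, 2000)
  sp <- ar_psd(m, f_max = 1000, n_points = 512)
  expect_lt(abs(mean(sp$power) - 2 * var(x) / 2000) / (2 * var(x) / 2000), 0.1)
})

test_that("resonance picking on constructed spectra", {
  f <- seq(0, 5000, length.out = 1001)
  p <- rep(0.001, 1001); p[300] <- 1; p[500] <- 0.6
  rs <- find_resonances(vib_spectrum(f, p))
  expect_equal(rs$f1, f[300])
  expect_equal(rs$f2, f[500])
  expect_error(find_resonances(vib_spectrum(f, seq(1, 2, length.out = 1001))),
               class = "vibrofirm_insufficient_peaks")
})

test_that("elasticity index identities", {
  expect_equal(elasticity_index(1, 1), 1)
  expect_equal(elasticity_index(1401.9, 0.2), 393064.722)
  expect_equal(elasticity_index(2 * 700, 0.3), 4 * elasticity_index(700, 0.3))
  expect_error(elasticity_index(-1, 1), class = "vibrofirm_domain_error")
})

test_that("correlation profile: perfect, degenerate and mismatched grids", {
  f <- c(0, 1, 2)
  s <- lapply(1:5, function(i) vib_spectrum(f, c(i, 2, 3 * i)))
  firm <- 1:5
  cp <- correlation_profile(s, firm)
  expect_equal(cp$r[1], 1)
  expect_equal(cp$r[3], 1)
  expect_equal(cp$r[2], 0)        # zero-variance bin: flagged, r = 0
  expect_true(cp$degenerate[2])
  expect_true(all(abs(cp$r) <= 1))
  bad <- c(s[1:4], list(vib_spectrum(c(0, 1, 3), c(1, 2, 3))))
  expect_error(correlation_profile(bad, firm), class = "vibrofirm_domain_error")
})
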