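# Reference firmness, replicate aggregation, splitting and standardization.

test_that("reference firmness is the mean initial slope of three curves", {
  lin <- function(sl) structure(list(displacement = seq(0, 15, 0.05),
                                     force = sl * seq(0, 15, 0.05)),
                                class = "force_curve")
  expect_equal(firmness_from_force_curves(list(lin(2), lin(2), lin(2))), 2)
  expect_equal(firmness_from_force_curves(list(lin(1), lin(2), lin(3))), 2)
  expect_error(firmness_from_force_curves(list(lin(1), lin(2))),
               class = "vibrofirm_domain_error")
  short <- structure(list(displacement = seq(0, 1, 0.05),
                          force = seq(0, 1, 0.05)), class = "force_curve")
  expect_error(firmness_from_force_curves(list(short, lin(1), lin(2))),
               class = "vibrofirm_domain_error")
})

test_that("noisy puncture triplets recover firmness within 5%", {
  est <- vapply(1:20, function(s) {
    curves <- lapply(1:3, function(k)
      simulate_force_curve(4.63, noise_sd = 0.05, seed = 100 * s + k))
    firmness_from_force_curves(curves)
  }, numeric(1))
  expect_true(all(abs(est - 4.63) / 4.63 < 0.05))
})

test_that("replicate aggregation: idempotence, mean, variance reduction", {
  f <- seq(0, 10, length.out = 5)
  s1 <- vib_spectrum(f, c(1, 2, 3, 4, 5))
  expect_equal(aggregate_replicates(list(s1, s1, s1))$power, s1$power)
  s2 <- vib_spectrum(f, c(3, 2, 1, 0, 1))
  expect_equal(aggregate_replicates(list(s1, s2))$power, c(2, 2, 2, 2, 3))
  expect_error(aggregate_replicates(list(s1, vib_spectrum(f + 1, 1:5))),
               class = "vibrofirm_domain_error")

  # averaging replicates reduces spread across repeated acquisitions
  prof <- default_cultivar_profiles()$hujing
  cfg <- cheap_config()
  single <- c(); aggd <- c()
  for (s in 1:12) {
    specs <- lapply(1:3, function(r) {
      rec <- simulate_signal(prof, 2.5, 0.2, cfg, seed = 1000 * s + r,
                             amplitude_scale = exp(rnorm(1, 0, 0.35)))
      ar_psd(burg_ar(rec$samples, 40, rec$sampling_rate))
    })
    bin <- which.min(abs(specs[[1]]$frequencies - 841.7))
    single <- c(single, log(specs[[1]]$power[bin]))
    aggd <- c(aggd, log(aggregate_replicates(specs)$power[bin]))
  }
  expect_lt(var(aggd), var(single))
})

test_that("split sizes follow largest-remainder rounding", {
  sp <- split_dataset(sprintf("f%03d", 1:471), c(7, 1, 2), seed = 1)
  expect_equal(lengths(sp), c(train = 330, val = 47, test = 94))
  sp2 <- split_dataset(as.character(1:120), c(4, 1), seed = 3)
  expect_equal(lengths(sp2), c(train = 96, val = 24))
})

test_that("splits are disjoint, covering, reproducible and stratified", {
  ids <- sprintf("s%03d", 1:200)
  grp <- rep(c("a", "b"), c(80, 120))
  sp <- split_dataset(ids, c(7, 1, 2), seed = 42, stratify = grp)
  all_ids <- unlist(sp)
  expect_setequal(all_ids, ids)
  expect_equal(anyDuplicated(all_ids), 0L)
  sp_again <- split_dataset(ids, c(7, 1, 2), seed = 42, stratify = grp)
  expect_identical(sp, sp_again)
  # per-stratum proportions preserved (80 ids in stratum "a": 56/8/16)
  expect_equal(sum(sp$train %in% ids[grp == "a"]), 56)
  expect_equal(sum(sp$test %in% ids[grp == "a"]), 16)
  expect_error(split_dataset(character(0), c(7, 1, 2)),
               class = "vibrofirm_domain_error")
})

test_that("standardizer: unit moments, degenerate bins, round trip, leakage guard", {
  set.seed(9)
  X <- cbind(matrix(rnorm(50 * 4, mean = 3, sd = 2), 50), 7)
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_true(all(abs(colMeans(Z)) < 1e-9))
  expect_true(all(abs(apply(Z[, 1:4], 2, sd) - 1) < 1e-9))
  expect_true(std$degenerate[5])
  expect_true(all(Z[, 5] == 0))
  back <- invert_standardizer(std, Z)
  expect_equal(back, unname(X), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(fit_standardizer(X[1, , drop = FALSE]),
               class = "vibrofirm_domain_error")

  # statistics depend on the training rows only
  extra <- rbind(X, matrix(rnorm(20 * 5, 100), 20))
  std2 <- fit_standardizer(extra[1:50, ])
  expect_identical(std, std2)
})
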