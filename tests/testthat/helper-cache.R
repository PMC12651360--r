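# Shared fixtures, built once per test run and memoised across test files.
# Everything is generated in code under fixed seeds; the expensive artifacts
# (the full synthetic dataset and trained networks) are reused by several
# test files.

.vf_cache <- new.env(parent = emptyenv())

memo <- function(key, maker) {
  if (is.null(.vf_cache[[key]])) .vf_cache[[key]] <- maker()
  .vf_cache[[key]]
}

# reduced-rate acquisition: Nyquist still above the 5 kHz analysis ceiling
reduced_config <- function(...) sim_config(sampling_rate = 12500, ...)

# short-window cheap config for tests that only exercise bookkeeping
cheap_config <- function(...) {
  args <- utils::modifyList(list(sampling_rate = 12500, pre_window = 0.3,
                                 post_window = 0.3), list(...))
  do.call(sim_config, args)
}

# the full-scale synthetic study: 471 fruits over three cultivars, seed 7,
# with both per-fruit aggregated and per-excitation spectra
get_study <- function() memo("study", function() {
  simulate_spectra_dataset(default_cultivar_profiles(), c(128, 167, 176),
                           reduced_config(), seed = 7, order = 50,
                           keep_replicates = TRUE)
})

# features + split + standardizers derived from the study; Z is the
# fruit-level (baseline) space, Zn the network space (replicate-fitted
# standardizer), Zr the standardized per-excitation training/validation data
get_features <- function() memo("features", function() {
  sim <- get_study()
  meta <- sim$meta
  X <- spectrum_matrix(sim$spectra)
  Xr <- spectrum_matrix(sim$replicate_spectra)
  sp <- split_dataset(meta$fruit_id, c(7, 1, 2),
                      seed = vibrofirm:::derive_seed(7, 1),
                      stratify = meta$cultivar)
  tr <- match(sp$train, meta$fruit_id)
  va <- match(sp$val, meta$fruit_id)
  te <- match(sp$test, meta$fruit_id)
  rmeta <- sim$replicate_meta
  rtr <- which(rmeta$fruit_id %in% sp$train)
  rva <- which(rmeta$fruit_id %in% sp$val)
  std <- fit_standardizer(X[tr, , drop = FALSE])
  std_net <- fit_standardizer(Xr[rtr, , drop = FALSE])
  list(Z = apply_standardizer(std, X),
       Zn = apply_standardizer(std_net, X),
       Zr_tr = apply_standardizer(std_net, Xr[rtr, , drop = FALSE]),
       y_r_tr = rmeta$firmness[rtr],
       Zr_va = apply_standardizer(std_net, Xr[rva, , drop = FALSE]),
       y_r_va = rmeta$firmness[rva],
       y = meta$firmness, meta = meta,
       frequencies = attr(X, "frequencies"), std = std, std_net = std_net,
       tr = tr, va = va, te = te)
})

# PLS baseline on the study (latent count selected on the validation set)
get_pls <- function() memo("pls", function() {
  fe <- get_features()
  lv <- select_latent_variables(fe$Z[fe$tr, ], fe$y[fe$tr],
                                fe$Z[fe$va, ], fe$y[fe$va], max_lv = 60)
  pred <- predict(lv$model, fe$Z[fe$te, ], ncomp = lv$ncomp)
  list(lv = lv, test = regression_metrics(fe$y[fe$te], pred, "test"))
})

# scaled training schedule for desk-size runs (see the methods vignette)
scaled_control <- function(seed) vibrofirm:::pipeline_isnet_control(seed)

# trained network per seed: per-excitation training and validation
get_net <- function(seed) memo(paste0("net", seed), function() {
  fe <- get_features()
  isnet(fe$Zr_tr, fe$y_r_tr, fe$Zr_va, fe$y_r_va,
        control = scaled_control(seed))
})

# shifted-mapping target cultivar used by the transfer-learning tests: softer
# population with a different resonance-firmness mapping than any pretraining
# cultivar
transfer_profile <- function() {
  cultivar_profile("target", f1_at_mean = 760, f2_at_mean = 1180,
                   mean_firmness = 1.79, f1_slope = 40, f2_slope = 60,
                   highband_slope = 0.15, firmness_range = c(0.45, 4.47),
                   mass_range = c(0.12, 0.25))
}

# 120-fruit target-cultivar dataset, standardized with the study standardizer
get_transfer_data <- function() memo("transfer", function() {
  fe <- get_features()
  sim <- simulate_spectra_dataset(transfer_profile(), 120, reduced_config(),
                                  seed = 11, order = 50)
  X <- spectrum_matrix(sim$spectra)
  list(Z = apply_standardizer(fe$std_net, X), y = sim$meta$firmness,
       meta = sim$meta)
})

# tiny architecture used by gradient and saliency oracles
tiny_config <- function(input_length = 40, dropout = 0) {
  isnet_config(input_length = input_length, stem_filters = 4,
               inception_filters = c(3, 3, 3, 3), se_reduction = 4,
               post_filters = 5, post_kernel = 5, fc_units = 6,
               dropout = dropout)
}

tiny_net <- function(seed = 42, input_length = 40) {
  set.seed(seed)
  cfg <- tiny_config(input_length)
  structure(list(params = vibrofirm:::isnet_init(cfg),
                 buffers = vibrofirm:::isnet_buffers(cfg),
                 config = cfg,
                 control = isnet_control(max_epochs = 2, patience = 1),
                 history = data.frame(epoch = 1, train_loss = NA,
                                      val_loss = NA),
                 best_epoch = 1L, data = NULL),
            class = "isnet")
}
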