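#' Hierarchical transfer-learning plan
#'
#' Partitions the network's trainable layers into three groups for adapting a
#' pretrained ISNet-1D to a new cultivar: all convolutional layers except the
#' last (stem, Inception branches, SE block, batch-norm parameters) are
#' frozen; the last convolutional layer trains at a reduced learning rate;
#' the two fully connected layers train at the standard rate. Setting both
#' factors to zero freezes the whole network (fine-tuning then leaves weights
#' and metrics untouched).
#'
#' @param lr_factor Learning-rate factor for the last convolutional layer,
#'   in \[0, 1\].
#' @param head_lr_factor Factor for the fully connected head (default 1).
#' @return Object of class `transfer_plan` with the three layer-name sets and
#'   per-parameter learning-rate factors.
#' @export
transfer_plan <- function(lr_factor = 0.1, head_lr_factor = 1) {
  vf_check(lr_factor >= 0 && lr_factor <= 1 &&
             head_lr_factor >= 0 && head_lr_factor <= 1,
           "vibrofirm_domain_error", "learning-rate factors must be in [0, 1]")
  frozen <- c("conv1_W", "conv1_b", "bn_gamma", "bn_beta",
              "i1_W", "i1_b", "i2a_W", "i2a_b", "i2b_W", "i2b_b",
              "i3a_W", "i3a_b", "i3b_W", "i3b_b", "i4_W", "i4_b",
              "se1_W", "se1_b", "se2_W", "se2_b")
  reduced <- c("conv2_W", "conv2_b")
  full <- c("fc1_W", "fc1_b", "out_W", "out_b")
  factors <- c(stats::setNames(rep(0, length(frozen)), frozen),
               stats::setNames(rep(lr_factor, length(reduced)), reduced),
               stats::setNames(rep(head_lr_factor, length(full)), full))
  structure(list(frozen = frozen, reduced = reduced, full = full,
                 lr_factor = lr_factor, head_lr_factor = head_lr_factor,
                 lr_factors = as.list(factors)),
            class = "transfer_plan")
}

#' Fine-tune a pretrained ISNet-1D on a new cultivar
#'
#' Splits the new samples into train/validation partitions (default 4:1),
#' evaluates the pretrained network on the validation partition, then
#' fine-tunes under the given [transfer_plan()]: frozen layers stay
#' bit-identical (their Adam updates are skipped entirely and batch-norm runs
#' on its stored statistics), the last convolutional layer moves at a reduced
#' learning rate, and the fully connected head at the standard rate. Returns
#' the adapted network together with before/after validation metrics.
#'
#' @param pretrained A fitted [isnet()].
#' @param x,y New-cultivar spectra (standardized with the pretraining
#'   standardizer) and firmness values; at least 10 samples.
#' @param plan A [transfer_plan()].
#' @param control An [isnet_control()] for the fine-tuning schedule (default:
#'   100 epochs with the standard initial learning rate).
#' @param ratios Train/validation split ratios.
#' @return Object of class `isnet_transfer`: `net` (adapted `isnet`),
#'   `before`/`after` ([regression_metrics()] on the held-out partition),
#'   `train_before`/`train_after`, `plan` and `split`.
#' @export
fine_tune <- function(pretrained, x, y, plan = transfer_plan(),
                      control = isnet_control(max_epochs = 100, patience = 30,
                                              seed = 1L),
                      ratios = c(4, 1)) {
  stopifnot(inherits(pretrained, "isnet"), inherits(plan, "transfer_plan"))
  x <- as.matrix(x)
  cfg <- pretrained$config
  vf_check(ncol(x) == cfg$input_length, "vibrofirm_domain_error",
           "input length does not match the pretrained architecture")
  vf_check(nrow(x) >= 10 && length(y) == nrow(x), "vibrofirm_domain_error",
           "need >= 10 matched new samples")
  sp <- split_dataset(seq_len(nrow(x)), ratios = ratios, seed = control$seed)
  tr <- as.integer(sp$train); va <- as.integer(sp$val)
  before <- regression_metrics(y[va], predict(pretrained, x[va, , drop = FALSE]),
                               label = "validation (pretrained)")
  train_before <- regression_metrics(y[tr], predict(pretrained, x[tr, , drop = FALSE]),
                                     label = "train (pretrained)")
  set.seed(control$seed)
  fit <- isnet_engine(pretrained$params, pretrained$buffers,
                      x[tr, , drop = FALSE], y[tr],
                      x[va, , drop = FALSE], y[va],
                      cfg, control, lr_factors = plan$lr_factors,
                      bn_train = FALSE)
  net <- structure(list(params = fit$par, buffers = fit$buffers, config = cfg,
                        control = control, history = fit$history,
                        best_epoch = fit$best_epoch,
                        data = list(x = x[tr, , drop = FALSE], y = y[tr],
                                    x_val = x[va, , drop = FALSE],
                                    y_val = y[va])),
                   class = "isnet")
  after <- regression_metrics(y[va], predict(net, x[va, , drop = FALSE]),
                              label = "validation (fine-tuned)")
  train_after <- regression_metrics(y[tr], predict(net, x[tr, , drop = FALSE]),
                                    label = "train (fine-tuned)")
  structure(list(net = net, before = before, after = after,
                 train_before = train_before, train_after = train_after,
                 plan = plan, split = sp),
            class = "isnet_transfer")
}

#' @export
print.isnet_transfer <- function(x, ...) {
  cat("<isnet_transfer>\n  before: "); print(x$before)
  cat("  after : "); print(x$after)
  invisible(x)
}
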