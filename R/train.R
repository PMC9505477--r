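# Adam training loop, evaluation and the ablation runner.

zero_like <- function(x) {
  if (is.list(x)) lapply(x, zero_like) else x * 0
}

adam_new <- function(par) {
  list(m = zero_like(par), v = zero_like(par), t = 0L)
}

adam_update <- function(par, grad, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(par)) {
    out <- list(par = par, m = m, v = v)
    for (n in names(par)) {
      r <- adam_update(par[[n]], grad[[n]], m[[n]], v[[n]], lr, t, b1, b2, eps)
      out$par[[n]] <- r$par; out$m[[n]] <- r$m; out$v[[n]] <- r$v
    }
    out
  } else {
    g <- grad
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g * g
    mh <- m / (1 - b1^t)
    vh <- v / (1 - b2^t)
    list(par = par - lr * mh / (sqrt(vh) + eps), m = m, v = v)
  }
}

# extract the gradient tree matching a leaf_tree() of the parameters
grad_tree <- function(pn, grads) {
  if (is.list(pn) && is.null(pn$id)) {
    lapply(pn, grad_tree, grads = grads)
  } else {
    g <- grads[[pn$id]]
    if (is.null(g)) pn$value * 0 else g
  }
}

# assemble [H, W, B, C] image and [H, W, B, 1] mask arrays from samples
batch_arrays <- function(samples) {
  d <- dim(samples[[1]]$image)
  B <- length(samples)
  x <- array(0, c(d[2], d[3], B, d[1]))
  y <- array(0, c(d[2], d[3], B, 1L))
  for (b in seq_len(B)) {
    x[, , b, ] <- aperm(samples[[b]]$image, c(2, 3, 1))
    y[, , b, 1] <- samples[[b]]$mask
  }
  list(x = x, y = y)
}

# one optimiser step on an assembled batch; returns updated model/opt, the
# loss, and the batch's (training-mode) Dice
hea_train_step <- function(model, opt, x, y, lr) {
  tp <- tape_new()
  pn <- leaf_tree(tp, model$par)
  logits <- tp_hea_forward(model, pn, tp_leaf(tp, x), training = TRUE)
  cfg <- model$cfg
  loss <- tp_seg_loss(logits, y, cfg$w_ce, cfg$w_dice, cfg$dice_smooth)
  if (!is.finite(loss$value)) stop("training aborted: loss is not finite")
  grads <- tape_backward(tp, loss)
  gt <- grad_tree(pn, grads)
  opt$t <- opt$t + 1L
  upd <- adam_update(model$par, gt, opt$m, opt$v, lr, opt$t)
  model$par <- upd$par; opt$m <- upd$m; opt$v <- upd$v
  pb <- logits$value >= 0      # sigmoid(z) >= 0.5  <=>  z >= 0
  gb <- y == 1
  tp_ <- sum(pb & gb); fp_ <- sum(pb & !gb); fn_ <- sum(!pb & gb)
  dice <- if (2 * tp_ + fp_ + fn_ == 0) 1 else 2 * tp_ / (2 * tp_ + fp_ + fn_)
  list(model = model, opt = opt, loss = loss$value, dice = dice)
}

#' Overfit a single fixed batch
#'
#' Runs `steps` Adam updates on one batch and records loss and
#' (training-mode) Dice per step — the capacity smoke test for the
#' architecture.
#'
#' @param model an `hea_model`.
#' @param images `[B, C, H, W]` batch; @param masks `[B, H, W]` binary.
#' @param steps optimiser steps; @param lr learning rate (defaults to the
#'   model config's).
#' @return list with the trained `model`, `loss` and `dice` trajectories.
#' @export
train_on_batch <- function(model, images, masks, steps = 200L, lr = NULL) {
  lr <- lr %||% model$cfg$lr
  d <- dim(images)
  x <- aperm(images, c(3, 4, 1, 2))
  y <- array(aperm(masks, c(2, 3, 1)), c(d[3], d[4], d[1], 1L))
  opt <- adam_new(model$par)
  loss_h <- dice_h <- numeric(steps)
  for (s in seq_len(steps)) {
    st <- hea_train_step(model, opt, x, y, lr)
    model <- st$model; opt <- st$opt
    loss_h[s] <- st$loss; dice_h[s] <- st$dice
  }
  list(model = model, loss = loss_h, dice = dice_h)
}

#' Evaluate a model on a set of samples
#'
#' Deterministic inference (running batch-norm statistics), per-image Dice
#' and IoU via pixel confusion counts.
#'
#' @param model an `hea_model`; @param samples list of `SegSample`s.
#' @param threshold binarisation threshold.
#' @return a [metric_report].
#' @export
evaluate_heanet <- function(model, samples, threshold = 0.5) {
  if (!length(samples)) stop("empty evaluation set")
  bs <- model$cfg$batch_size
  preds <- vector("list", length(samples))
  i <- 1L
  while (i <= length(samples)) {
    j <- min(i + bs - 1L, length(samples))
    ba <- batch_arrays(samples[i:j])
    tp <- tape_new()
    pn <- leaf_tree(tp, model$par)
    logits <- tp_hea_forward(model, pn, tp_leaf(tp, ba$x), training = FALSE)
    pr <- 1 / (1 + exp(-logits$value))
    for (b in seq_len(j - i + 1L)) preds[[i + b - 1L]] <- pr[, , b, 1]
    i <- j + 1L
  }
  metric_report(preds, lapply(samples, `[[`, "mask"),
                ids = vapply(samples, `[[`, "", "id"), threshold = threshold)
}

#' Train HEA-Net
#'
#' Adam with the config's learning rate and batch size, the combined
#' cross-entropy + Dice loss, online flip/rotation augmentation on the
#' training split only, a seeded 80/20 train/validation split, and
#' best-checkpoint selection by validation Dice.
#'
#' @param cfg an [net_config]; @param data a list of `SegSample`s (e.g. from
#'   [generate_dataset]) or a dataset directory for [read_dataset].
#' @param epochs training epochs.
#' @param val_frac held-out fraction of `data`.
#' @param augment apply online augmentation to training batches.
#' @param log_file optional path; per-epoch records are appended as
#'   line-delimited JSON.
#' @param verbose print per-epoch progress.
#' @return list of class `hea_run`: `model` (best checkpoint), `log`
#'   (data frame: epoch, train_loss, val_dice, val_iou), `cfg`.
#' @export
train_heanet <- function(cfg, data, epochs = 10L, val_frac = 0.2,
                         augment = TRUE, log_file = NULL, verbose = FALSE) {
  if (is.character(data)) data <- read_dataset(data)
  if (!length(data)) stop("empty dataset")
  model <- build_hea_net(cfg)
  set.seed(cfg$seed)
  idx <- sample(length(data))
  n_val <- max(1L, round(val_frac * length(data)))
  val <- data[idx[seq_len(n_val)]]
  trn <- data[idx[-seq_len(n_val)]]
  if (!length(trn)) stop("training split is empty")
  opt <- adam_new(model$par)
  log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                    val_dice = numeric(0), val_iou = numeric(0))
  best <- list(dice = -Inf, model = NULL)
  for (ep in seq_len(epochs)) {
    ord <- sample(length(trn))
    losses <- c()
    i <- 1L
    while (i <= length(trn)) {
      j <- min(i + cfg$batch_size - 1L, length(trn))
      batch <- trn[ord[i:j]]
      if (augment) batch <- lapply(batch, augment_sample)
      ba <- batch_arrays(batch)
      st <- hea_train_step(model, opt, ba$x, ba$y, cfg$lr)
      model <- st$model; opt <- st$opt
      losses <- c(losses, st$loss)
      i <- j + 1L
    }
    rep <- evaluate_heanet(model, val)
    row <- data.frame(epoch = ep, train_loss = mean(losses),
                      val_dice = attr(rep, "mean_dice"),
                      val_iou = attr(rep, "mean_iou"))
    log <- rbind(log, row)
    if (row$val_dice > best$dice) best <- list(dice = row$val_dice, model = clone_model(model))
    if (!is.null(log_file))
      cat(jsonlite::toJSON(as.list(row), auto_unbox = TRUE, digits = NA), "\n",
          file = log_file, append = TRUE, sep = "")
    if (verbose)
      message(sprintf("epoch %d: loss %.4f, val dice %.4f", ep, row$train_loss, row$val_dice))
  }
  structure(list(model = best$model, log = log, cfg = cfg), class = "hea_run")
}

#' Run the five-variant ablation sweep
#'
#' Trains the baseline (no EAM, no DS-MLP), EAM without its batch-norm
#' channel branch, EAM alone, DS-MLP alone, and the full model under
#' identical data and seeds, and reports validation Dice/IoU per variant
#' and seed.
#'
#' @param cfg base [net_config]; ablation flags are overridden per variant
#'   and `cfg$seed` per repeat.
#' @param style synthetic dataset style.
#' @param n_images dataset size per seed; @param epochs epochs per run.
#' @param seeds integer vector of seeds.
#' @return data frame (variant, seed, val_dice, val_iou).
#' @export
run_ablation <- function(cfg, style = "gland", n_images = 32L, epochs = 5L,
                         seeds = 1:5) {
  variants <- list(
    baseline = list(use_eam = FALSE, use_bn_in_eam = FALSE, use_ds_mlp = FALSE),
    eam_no_bn = list(use_eam = TRUE, use_bn_in_eam = FALSE, use_ds_mlp = FALSE),
    eam = list(use_eam = TRUE, use_bn_in_eam = TRUE, use_ds_mlp = FALSE),
    dsmlp = list(use_eam = FALSE, use_bn_in_eam = FALSE, use_ds_mlp = TRUE),
    full = list(use_eam = TRUE, use_bn_in_eam = TRUE, use_ds_mlp = TRUE))
  out <- list()
  for (sd in seeds) {
    data <- generate_dataset(
      synth_params(style, image_size = cfg$input_size, seed = sd), n_images)
    for (vn in names(variants)) {
      vc <- cfg
      vc[names(variants[[vn]])] <- variants[[vn]]
      vc$seed <- sd
      run <- train_heanet(vc, data, epochs = epochs)
      best <- run$log[which.max(run$log$val_dice), ]
      out[[length(out) + 1L]] <- data.frame(variant = vn, seed = sd,
                                            val_dice = best$val_dice,
                                            val_iou = best$val_iou)
    }
  }
  do.call(rbind, out)
}
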