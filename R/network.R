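# HEA-Net assembly.
#
# Encoder: four stages of double 3x3 conv + BN + ReLU, each followed by an
# EAM gate (when enabled) and 2x2 max pooling. Bottleneck: one conv block
# plus the DS-MLP block (when enabled). Skips: the four pre-pooling stage
# outputs are patch-embedded, fused by the CCT, reconstructed by nearest
# up-broadcast and added residually to the original skip. Decoder: bilinear
# x2 upsampling, CCA fusion with the skip, and a conv block per stage; a
# 1x1 convolution produces a single logit channel.

#' Network configuration
#'
#' Collects every architecture and training hyperparameter of HEA-Net.
#'
#' @param in_channels input image channels (3 for RGB).
#' @param base_width width of the first encoder stage; stages use
#'   `base_width * c(1, 2, 4, 8)`.
#' @param n_heads,n_layers heads and depth of the CCT skip transformer.
#' @param lambda_energy regulariser of the EAM minimum-energy function.
#' @param input_size square input resolution; must be divisible by 16.
#' @param seed seed for weight initialisation.
#' @param use_eam,use_bn_in_eam,use_ds_mlp ablation switches: EAM gates in
#'   the encoder, the batch-norm channel branch inside EAM, and the DS-MLP
#'   bottleneck.
#' @param w_ce,w_dice weights of the cross-entropy and Dice terms of the
#'   training loss.
#' @param lr,batch_size Adam learning rate and batch size.
#' @param patch_sizes per-scale patch sizes of the CCT token embedding;
#'   the defaults give every scale the same token count.
#' @param dice_smooth smoothing constant of the soft Dice loss.
#' @return an object of class `hea_config`.
#' @export
net_config <- function(in_channels = 3L, base_width = 64L, n_heads = 4L,
                       n_layers = 4L, lambda_energy = 1e-4, input_size = 224L,
                       seed = 42L, use_eam = TRUE, use_bn_in_eam = TRUE,
                       use_ds_mlp = TRUE, w_ce = 0.5, w_dice = 0.5,
                       lr = 1e-3, batch_size = 4L,
                       patch_sizes = c(8L, 4L, 2L, 1L), dice_smooth = 1e-5) {
  if (input_size %% 16 != 0) stop("input_size must be divisible by 16")
  scales <- input_size / c(1L, 2L, 4L, 8L)
  if (any(scales %% patch_sizes != 0))
    stop("scale resolutions not divisible by patch sizes")
  d <- (scales / patch_sizes)^2
  if (length(unique(d)) != 1)
    stop("patch sizes must give the same token count at every scale; got ",
         paste(d, collapse = ", "))
  if (lambda_energy <= 0) stop("lambda_energy must be positive")
  widths <- base_width * c(1L, 2L, 4L, 8L)
  if ((8L * base_width) %% 8L != 0) stop("bottleneck width must be divisible by 8")
  if (sum(widths) %% n_heads != 0) stop("sum of stage widths must be divisible by n_heads")
  structure(list(in_channels = in_channels, base_width = base_width,
                 widths = widths, n_heads = n_heads, n_layers = n_layers,
                 lambda_energy = lambda_energy, input_size = input_size,
                 seed = seed, use_eam = use_eam, use_bn_in_eam = use_bn_in_eam,
                 use_ds_mlp = use_ds_mlp, w_ce = w_ce, w_dice = w_dice,
                 lr = lr, batch_size = batch_size, patch_sizes = patch_sizes,
                 dice_smooth = dice_smooth),
            class = "hea_config")
}

conv_init <- function(cin, cout) matrix(rnorm(9 * cin * cout) * sqrt(2 / (9 * cin)), cin, 9 * cout)
lin_init <- function(cin, cout) matrix(rnorm(cin * cout) * sqrt(2 / cin), cin, cout)

# parameters of one double-conv block
conv_block_params <- function(cin, cout) {
  list(W1 = conv_init(cin, cout), g1 = rep(1, cout), be1 = rep(0, cout),
       W2 = conv_init(cout, cout), g2 = rep(1, cout), be2 = rep(0, cout))
}

#' Build a seeded HEA-Net model
#'
#' Initialises all weights from `cfg$seed`; the same config and seed always
#' produce bitwise-identical parameters. The ablation flags in `cfg` control
#' whether the EAM gates and the DS-MLP bottleneck are instantiated (turning
#' them on strictly adds parameters).
#'
#' @param cfg an [net_config] object.
#' @return an object of class `hea_model`: `cfg`, a flat named parameter
#'   list `par`, and an environment `state` holding batch-norm running
#'   statistics.
#' @export
build_hea_net <- function(cfg) {
  stopifnot(inherits(cfg, "hea_config"))
  set.seed(cfg$seed)
  w <- cfg$widths
  par <- list()
  cin <- cfg$in_channels
  for (i in 1:4) {
    par[[paste0("enc", i)]] <- conv_block_params(cin, w[i])
    if (cfg$use_eam)
      par[[paste0("eam", i)]] <- list(gamma = rep(1, w[i]), beta = rep(0, w[i]))
    cin <- w[i]
  }
  par$bot <- conv_block_params(w[4], w[4])
  if (cfg$use_ds_mlp) {
    C <- w[4]; C2 <- C / 2L; h <- max(4L, C %/% 8L)
    par$dsmlp <- list(cs_w = rnorm(3) * sqrt(1 / 3), cs_b = 0,
                      sa1_W = lin_init(C2, h), sa1_b = rep(0, h),
                      sa2_W = lin_init(h, 2 * C2), sa2_b = rep(0, 2 * C2),
                      out_W = lin_init(C2, C), out_b = rep(0, C))
  }
  Ct <- sum(w)
  par$cct <- lapply(seq_len(cfg$n_layers), function(l) {
    per_scale <- lapply(w, function(C) {
      hidden <- 4L * C
      list(Wq = matrix(rnorm(C * C) * sqrt(1 / C), C, C),
           lnq_g = rep(1, C), lnq_b = rep(0, C),
           lnm_g = rep(1, C), lnm_b = rep(0, C),
           W1 = lin_init(C, hidden), b1 = rep(0, hidden),
           W2 = lin_init(hidden, C), b2 = rep(0, C))
    })
    list(scales = per_scale,
         lnkv_g = rep(1, Ct), lnkv_b = rep(0, Ct),
         Wk = matrix(rnorm(Ct * Ct) * sqrt(1 / Ct), Ct, Ct),
         Wv = matrix(rnorm(Ct * Ct) * sqrt(1 / Ct), Ct, Ct))
  })
  dec_in <- c(w[2] + w[1], w[3] + w[2], w[4] + w[3], 2L * w[4])
  for (i in 4:1) {
    cd <- if (i == 4) w[4] else w[i + 1]
    par[[paste0("cca", i)]] <- list(W = lin_init(cd, w[i]), b = rep(0, w[i]))
    par[[paste0("dec", i)]] <- conv_block_params(dec_in[i], w[i])
  }
  par$head <- list(W = lin_init(w[1], 1L), b = 0)
  state <- new.env(parent = emptyenv())
  for (i in 1:4) {
    state[[paste0("enc", i, ".bn1")]] <- bn_state_new(w[i])
    state[[paste0("enc", i, ".bn2")]] <- bn_state_new(w[i])
    if (cfg$use_eam) state[[paste0("eam", i)]] <- bn_state_new(w[i])
    state[[paste0("dec", i, ".bn1")]] <- bn_state_new(w[i])
    state[[paste0("dec", i, ".bn2")]] <- bn_state_new(w[i])
  }
  state$bot.bn1 <- bn_state_new(w[4])
  state$bot.bn2 <- bn_state_new(w[4])
  structure(list(cfg = cfg, par = par, state = state), class = "hea_model")
}

#' Count model parameters
#' @param model an `hea_model`.
#' @return total number of scalar parameters.
#' @export
n_parameters <- function(model) {
  sum(rapply(model$par, length, how = "unlist"))
}

tp_conv_block <- function(x, pn, st1, st2, training) {
  h <- tp_relu(tp_bn2d(tp_conv2d3(x, pn$W1), pn$g1, pn$be1, st1, training))
  tp_relu(tp_bn2d(tp_conv2d3(h, pn$W2), pn$g2, pn$be2, st2, training))
}

# builds the full forward graph; returns the logits node
tp_hea_forward <- function(model, pn, xnode, training) {
  cfg <- model$cfg
  st <- model$state
  skips <- vector("list", 4)
  x <- xnode
  for (i in 1:4) {
    e <- tp_conv_block(x, pn[[paste0("enc", i)]],
                       st[[paste0("enc", i, ".bn1")]],
                       st[[paste0("enc", i, ".bn2")]], training)
    if (cfg$use_eam) {
      ep <- pn[[paste0("eam", i)]]
      e <- tp_eam(e, ep$gamma, ep$beta, st[[paste0("eam", i)]], training,
                  cfg$lambda_energy, cfg$use_bn_in_eam)
    }
    skips[[i]] <- e
    x <- tp_maxpool2(e)
  }
  z <- tp_conv_block(x, pn$bot, st$bot.bn1, st$bot.bn2, training)
  if (cfg$use_ds_mlp) z <- tp_ds_mlp(z, pn$dsmlp)
  tokens <- lapply(1:4, function(i) tp_tokenize(skips[[i]], cfg$patch_sizes[i]))
  tokens <- tp_cct_forward(tokens, list(layers = pn$cct), cfg$n_heads, cfg$n_layers)
  for (i in 1:4) {
    hw <- dim(skips[[i]]$value)[1:2]
    skips[[i]] <- tp_add(skips[[i]], tp_detokenize(tokens[[i]], hw, cfg$patch_sizes[i]))
  }
  for (i in 4:1) {
    u <- tp_upsample2(z)
    cp <- pn[[paste0("cca", i)]]
    f <- tp_cca(u, skips[[i]], cp$W, cp$b)
    z <- tp_conv_block(f, pn[[paste0("dec", i)]],
                       st[[paste0("dec", i, ".bn1")]],
                       st[[paste0("dec", i, ".bn2")]], training)
  }
  tp_conv1x1(z, pn$head$W, pn$head$b)
}

#' Forward pass of a HEA-Net model
#'
#' @param model an `hea_model` from [build_hea_net].
#' @param images `[B, C, H, W]` (or `[C, H, W]`) array; `H`, `W` must be
#'   divisible by 16.
#' @param training if `TRUE`, batch statistics are used in every batch norm
#'   and the running statistics are updated; inference mode is deterministic.
#' @return logits, `[B, 1, H, W]` (or `[1, H, W]`), same spatial size.
#' @export
hea_forward <- function(model, images, training = FALSE) {
  d <- dim(images)
  hw <- if (length(d) == 3L) d[2:3] else d[3:4]
  if (any(hw %% 16 != 0)) stop("spatial dims must be divisible by 16")
  conv <- as_hwbc(images, "images")
  tp <- tape_new()
  pn <- leaf_tree(tp, model$par)
  out <- tp_hea_forward(model, pn, tp_leaf(tp, conv$arr), training)
  from_hwbc(out$value, conv$batched)
}

#' Predicted foreground probabilities
#'
#' @inheritParams hea_forward
#' @return sigmoid of the logits, same shape contract as [hea_forward].
#' @export
predict_heanet <- function(model, images) {
  1 / (1 + exp(-hea_forward(model, images, training = FALSE)))
}

# combined loss node: w_ce * BCE + w_dice * (1 - soft Dice), masks constant
tp_seg_loss <- function(logits, mask, w_ce, w_dice, smooth) {
  bce <- tp_bce_logits(logits, mask)
  p <- tp_sigmoid(logits)
  inter <- tp_sum(tp_cmul(p, mask))
  num <- tp_shift(tp_scale(inter, 2), smooth)
  den <- tp_shift(tp_sum(p), sum(mask) + smooth)
  dloss <- tp_shift(tp_scale(tp_div(num, den), -1), 1)
  tp_add(tp_scale(bce, w_ce), tp_scale(dloss, w_dice))
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the config, all parameters and the batch-norm
#' running statistics into a single RDS file.
#'
#' @param model an `hea_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  st <- lapply(ls(model$state), function(n) as.list(model$state[[n]]))
  names(st) <- ls(model$state)
  saveRDS(list(cfg = model$cfg, par = model$par, state = st), path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored `hea_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (n in names(ck$state)) {
    e <- new.env(parent = emptyenv())
    e$mean <- ck$state[[n]]$mean
    e$var <- ck$state[[n]]$var
    state[[n]] <- e
  }
  structure(list(cfg = ck$cfg, par = ck$par, state = state), class = "hea_model")
}

# deep copy of a model (parameters and running stats)
clone_model <- function(model) {
  st <- new.env(parent = emptyenv())
  for (n in ls(model$state)) {
    e <- new.env(parent = emptyenv())
    e$mean <- model$state[[n]]$mean
    e$var <- model$state[[n]]$var
    st[[n]] <- e
  }
  structure(list(cfg = model$cfg, par = model$par, state = st), class = "hea_model")
}
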