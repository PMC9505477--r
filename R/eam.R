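# Efficient Attention Module (EAM).
#
# Channel branch: batch-norm scale factors gamma_i are normalised to weights
# w_i = |gamma_i| / sum_j |gamma_j| (absolute values keep the weights a
# convex combination when scale factors go negative during training), and
# the channel map is sigmoid(w ⊗ BN(x)).
#
# Spatial branch: each pixel t of a channel gets the closed-form minimum
# energy e*_t = 4(sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda),
# with mu and the biased variance sigma^2 computed over that channel's H*W
# pixels; pixel importance is 1 / e*_t. A constant channel therefore gets
# weight 1/2 everywhere.
#
# The block output is E = sigmoid(w_C ⊗ w_S) ⊗ x: a multiplicative gate in
# (0, 1), so the block can only attenuate, never amplify.

#' EAM parameter set
#'
#' Bundles the batch-norm scale/shift factors, their running statistics and
#' the energy regulariser used by the Efficient Attention Module.
#'
#' @param channels number of channels the module operates on.
#' @param lambda positive energy regulariser; default `1e-4`.
#' @param gamma,beta batch-norm scale and shift vectors, length `channels`;
#'   default to 1 and 0 (the usual initialisation).
#' @param running_mean,running_var per-channel statistics used in inference
#'   mode; default to 0 and 1.
#' @return an object of class `eam_params`.
#' @export
eam_params <- function(channels, lambda = 1e-4,
                       gamma = rep(1, channels), beta = rep(0, channels),
                       running_mean = rep(0, channels),
                       running_var = rep(1, channels)) {
  if (lambda <= 0) stop("lambda must be positive")
  if (length(gamma) != channels || length(beta) != channels)
    stop("gamma and beta must have length `channels`")
  structure(list(channels = channels, lambda = lambda, gamma = gamma,
                 beta = beta, running_mean = running_mean,
                 running_var = running_var),
            class = "eam_params")
}

#' Normalised channel weights from batch-norm scale factors
#'
#' `w_i = |gamma_i| / sum_j |gamma_j|`; the absolute value keeps the weights
#' a convex combination even when scale factors have gone negative, so they
#' always sum to 1.
#'
#' @param gamma numeric vector of batch-norm scale factors.
#' @return weight vector of the same length, summing to 1.
#' @export
gamma_weights <- function(gamma) {
  s <- sum(abs(gamma))
  if (s == 0) stop("degenerate batch-norm scale factors: sum |gamma| is zero")
  abs(gamma) / s
}

# tape composition of the normalised channel weights; errors on degenerate
# gamma
tp_gamma_weights <- function(gamma_node) {
  a <- tp_abs(gamma_node)
  s <- sum(a$value)
  if (s == 0) stop("degenerate batch-norm scale factors: sum |gamma| is zero")
  tp_div(a, tp_expand(tp_sum(a), length(gamma_node$value)))
}

tp_eam_channel <- function(x, gamma, beta, state, training) {
  d <- dim(x$value)
  w <- tp_gamma_weights(gamma)
  bn <- tp_bn2d(x, gamma, beta, state, training)
  tp_sigmoid(tp_mul(tp_expand(w, d), bn))
}

tp_energy_weights <- function(x, lambda) {
  d <- dim(x$value)
  mu <- tp_gap(x)
  xm <- tp_sub(x, tp_expand(mu, d))
  sq <- tp_mul(xm, xm)
  va <- tp_gap(sq)
  num <- tp_shift(tp_scale(va, 4), 4 * lambda)    # 4(sigma^2 + lambda)
  den2 <- tp_shift(tp_scale(va, 2), 2 * lambda)   # 2 sigma^2 + 2 lambda
  tp_div(tp_add(sq, tp_expand(den2, d)), tp_expand(num, d))
}

# full EAM gate; with use_bn = FALSE the channel branch collapses to uniform
# weights 1/C (the "without BN" ablation), the energy branch is untouched
tp_eam <- function(x, gamma, beta, state, training, lambda, use_bn = TRUE) {
  ws <- tp_energy_weights(x, lambda)
  gate_arg <- if (use_bn) {
    tp_mul(tp_eam_channel(x, gamma, beta, state, training), ws)
  } else {
    tp_scale(ws, 1 / dim(x$value)[4])
  }
  tp_mul(tp_sigmoid(gate_arg), x)
}

eam_state_from <- function(p) {
  e <- new.env(parent = emptyenv())
  e$mean <- p$running_mean
  e$var <- p$running_var
  e
}

check_eam_input <- function(x, p, name = "x") {
  d <- dim(x)
  C <- if (length(d) == 3L) d[1] else d[2]
  if (C != p$channels)
    stop("channel mismatch: input has ", C, " channels, params have ", p$channels)
}

#' Channel-dimension attention map
#'
#' Computes `sigmoid(w ⊗ BN(x))` where `w_i = |gamma_i| / sum_j |gamma_j|`
#' are the normalised batch-norm scale factors, broadcast per channel. All
#' outputs lie strictly in (0, 1).
#'
#' @param x feature map, `[C, H, W]` or `[B, C, H, W]` array.
#' @param p an [eam_params] object with matching channel count.
#' @param training if `TRUE` batch statistics are used for the normalisation
#'   (and the running statistics in `p` are left untouched: the stateful
#'   update only happens inside a training loop); otherwise the running
#'   statistics stored in `p` are used.
#' @return array of the same shape as `x`.
#' @export
channel_weight_map <- function(x, p, training = FALSE) {
  check_eam_input(x, p)
  st <- eam_state_from(p)
  run_on_array(x, function(xn, tp) {
    tp_eam_channel(xn, tp_leaf(tp, p$gamma), tp_leaf(tp, p$beta), st, training)
  })
}

#' Spatial minimum-energy attention map
#'
#' For every pixel `t` of every channel, computes the minimum energy
#' `e* = 4(sigma^2 + lambda) / ((t - mu)^2 + 2 sigma^2 + 2 lambda)` from the
#' channel mean `mu` and biased variance `sigma^2`, and returns the
#' importance `1 / e*`. Constant channels yield exactly 0.5 everywhere.
#'
#' @param x feature map, `[C, H, W]` or `[B, C, H, W]` array.
#' @param lambda positive regulariser (default `1e-4`).
#' @return array of the same shape as `x`, strictly positive.
#' @export
spatial_energy_weights <- function(x, lambda = 1e-4) {
  if (lambda <= 0) stop("lambda must be positive")
  run_on_array(x, function(xn, tp) tp_energy_weights(xn, lambda))
}

#' Efficient Attention Module forward pass
#'
#' Applies `E = sigmoid(w_C ⊗ w_S) ⊗ x`: the channel map from
#' [channel_weight_map] and the spatial map from [spatial_energy_weights]
#' are multiplied, squashed through a sigmoid, and gate the input
#' multiplicatively, so `|E| <= |x|` elementwise and shapes are preserved.
#'
#' @inheritParams channel_weight_map
#' @return array of the same shape as `x`.
#' @export
eam_forward <- function(x, p, training = FALSE) {
  check_eam_input(x, p)
  st <- eam_state_from(p)
  run_on_array(x, function(xn, tp) {
    tp_eam(xn, tp_leaf(tp, p$gamma), tp_leaf(tp, p$beta), st, training,
           p$lambda, use_bn = TRUE)
  })
}
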