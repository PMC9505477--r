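# Dual-channel Shift MLP bottleneck block.
#
# The input is split into two channel halves. The first half is mixed
# spatially by shifting its four channel quarters one pixel in four
# directions; the second half is gated by a channel-shift descriptor built
# from global max pooling and a kernel-3 1-d convolution across channels.
# The two branches are fused by 2-way split attention (a softmax convex
# combination whose logits come from a small bottleneck MLP on pooled
# statistics), and a final linear channel projection restores the full
# channel count.

#' DS-MLP parameter set
#'
#' Creates seeded weights for a dual-channel shift MLP block operating on
#' `channels` channels (`channels` must be divisible by 8 so the spatial
#' branch's four quarters are equal).
#'
#' @param channels channel count of the block input.
#' @param seed integer seed for the weight draw.
#' @return an object of class `ds_mlp_params`: `cs_w`/`cs_b` the 1-d
#'   convolution of the channel-shift branch; `sa1_*`, `sa2_*` the split
#'   attention MLPs (`C/2 -> max(4, C/8) -> C`); `out_*` the output
#'   projection `C/2 -> C`.
#' @export
ds_mlp_params <- function(channels, seed = 1L) {
  if (channels %% 8 != 0) stop("channels must be divisible by 8")
  C2 <- channels / 2L
  h <- max(4L, channels %/% 8L)
  set.seed(seed)
  structure(list(
    channels = channels,
    cs_w = rnorm(3) * sqrt(1 / 3),
    cs_b = 0,
    sa1_W = matrix(rnorm(C2 * h) * sqrt(2 / C2), C2, h),
    sa1_b = rep(0, h),
    sa2_W = matrix(rnorm(h * 2 * C2) * sqrt(2 / h), h, 2 * C2),
    sa2_b = rep(0, 2 * C2),
    out_W = matrix(rnorm(C2 * channels) * sqrt(2 / C2), C2, channels),
    out_b = rep(0, channels)
  ), class = "ds_mlp_params")
}

#' Split a feature map into two channel halves
#'
#' @param x feature map `[C, H, W]` or `[B, C, H, W]`, `C` even.
#' @return list with `t1` (channels `1..C/2`) and `t2` (channels
#'   `C/2+1..C`); concatenating them along channels reconstructs `x`.
#' @export
split_channels <- function(x) {
  d <- dim(x)
  C <- if (length(d) == 3L) d[1] else d[2]
  if (C %% 2 != 0) stop("channel count must be even, got ", C)
  h <- C / 2
  if (length(d) == 3L) {
    list(t1 = x[1:h, , , drop = FALSE], t2 = x[(h + 1):C, , , drop = FALSE])
  } else {
    list(t1 = x[, 1:h, , , drop = FALSE], t2 = x[, (h + 1):C, , , drop = FALSE])
  }
}

#' Four-direction spatial shift
#'
#' Shifts the four channel quarters of `x` by one pixel: +1 and -1 along the
#' width for quarters 1 and 2, +1 and -1 along the height for quarters 3 and
#' 4. Border lines that the shift does not write keep their original values.
#'
#' @param x feature map `[C, H, W]` or `[B, C, H, W]`, `C` divisible by 4.
#' @return array of the same shape.
#' @export
spatial_shift <- function(x) {
  d <- dim(x)
  C <- if (length(d) == 3L) d[1] else d[2]
  if (C %% 4 != 0) stop("channel count must be divisible by 4, got ", C)
  run_on_array(x, function(xn, tp) tp_spatial_shift(xn))
}

tp_channel_shift <- function(t2, w, b) {
  g <- tp_sigmoid(tp_conv1d3(tp_gmp(t2), w, b))
  tp_mul(t2, tp_expand(g, dim(t2$value)))
}

#' Channel shift gating
#'
#' Computes `sigmoid(conv1d_k3(GMP(x))) ⊗ x`: global max pooling collapses
#' each channel to one value, a same-padded kernel-3 1-d convolution mixes
#' neighbouring channels, and the sigmoid of the result re-weights the input
#' per channel, so `|output| <= |x|` elementwise.
#'
#' @param x feature map `[C, H, W]` or `[B, C, H, W]`.
#' @param weights length-3 convolution kernel.
#' @param bias scalar bias.
#' @return array of the same shape as `x`.
#' @export
channel_shift <- function(x, weights = c(0.25, 0.5, 0.25), bias = 0) {
  stopifnot(length(weights) == 3)
  run_on_array(x, function(xn, tp) {
    tp_channel_shift(xn, tp_leaf(tp, weights), tp_leaf(tp, bias))
  })
}

# split attention over S = 2 branches; softmax over two logits is computed
# exactly as sigmoid of their difference
tp_split_attention <- function(t1p, t2p, sa1_W, sa1_b, sa2_W, sa2_b) {
  d <- dim(t1p$value)
  C2 <- d[4]
  alpha <- tp_add(tp_gap(t1p), tp_gap(t2p))
  hh <- tp_gelu(tp_linear(alpha, sa1_W, sa1_b))
  logits <- tp_linear(hh, sa2_W, sa2_b)
  a1 <- tp_narrow_last(logits, 1L, C2)
  a2 <- tp_narrow_last(logits, C2 + 1L, 2L * C2)
  w1 <- tp_sigmoid(tp_sub(a1, a2))
  w2 <- tp_shift(tp_scale(w1, -1), 1)
  tp_add(tp_mul(t1p, tp_expand(w1, d)), tp_mul(t2p, tp_expand(w2, d)))
}

#' Split attention fusion of two branches
#'
#' Pools both branches spatially, sums the pooled statistics, passes them
#' through a bottleneck MLP (`MLP2(GELU(MLP1(.)))`) to obtain two logits per
#' channel, softmaxes across the two branches and returns the resulting
#' convex combination of the branch feature maps.
#'
#' @param t1p,t2p feature maps of identical shape (`[C', H, W]` or batched).
#' @param p a [ds_mlp_params] object whose `sa*` weights match `C' = C/2`.
#' @return array of the same shape as `t1p`.
#' @export
split_attention <- function(t1p, t2p, p) {
  if (!identical(dim(t1p), dim(t2p))) stop("branch shapes differ")
  c1 <- as_hwbc(t1p, "t1p"); c2 <- as_hwbc(t2p, "t2p")
  tp <- tape_new()
  out <- tp_split_attention(tp_leaf(tp, c1$arr), tp_leaf(tp, c2$arr),
                            tp_leaf(tp, p$sa1_W), tp_leaf(tp, p$sa1_b),
                            tp_leaf(tp, p$sa2_W), tp_leaf(tp, p$sa2_b))
  from_hwbc(out$value, c1$batched)
}

tp_ds_mlp <- function(x, pn) {
  C <- dim(x$value)[4]
  C2 <- C / 2L
  t1 <- tp_narrow_last(x, 1L, C2)
  t2 <- tp_narrow_last(x, C2 + 1L, C)
  t1s <- tp_spatial_shift(t1)
  t2s <- tp_channel_shift(t2, pn$cs_w, pn$cs_b)
  fused <- tp_split_attention(t1s, t2s, pn$sa1_W, pn$sa1_b, pn$sa2_W, pn$sa2_b)
  tp_conv1x1(fused, pn$out_W, pn$out_b)
}

#' Dual-channel shift MLP forward pass
#'
#' Full bottleneck block: channel split, spatial shift of the first half,
#' channel-shift gating of the second half, split-attention fusion, and a
#' linear channel projection back to the input width, so the output has
#' exactly the input's `[C, H, W]`.
#'
#' @param x feature map `[C, H, W]` or `[B, C, H, W]`, `C` divisible by 8.
#' @param p a [ds_mlp_params] object for `C` channels.
#' @return array of the same shape as `x`.
#' @export
ds_mlp_forward <- function(x, p) {
  d <- dim(x)
  C <- if (length(d) == 3L) d[1] else d[2]
  if (C %% 8 != 0) stop("channel count must be divisible by 8, got ", C)
  if (C != p$channels) stop("params built for ", p$channels, " channels")
  run_on_array(x, function(xn, tp) {
    pn <- lapply(p[c("cs_w", "cs_b", "sa1_W", "sa1_b", "sa2_W", "sa2_b",
                     "out_W", "out_b")], function(v) tp_leaf(tp, v))
    tp_ds_mlp(xn, pn)
  })
}
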