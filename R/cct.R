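# Channel-wise cross fusion transformer (CCT) skip connections and
# channel-wise cross attention (CCA) decoder fusion.
#
# Each encoder scale is patch-embedded (average pooling) to a token matrix
# [d, C_i] with a shared token count d. Per transformer layer, every scale
# projects queries from its own tokens while keys and values are projected
# from the channel-wise concatenation of all four scales; attention runs
# along the channel axis (the attention matrix is C_i x C_total), its logits
# are standardised before the softmax, and the N head outputs are averaged.
# The layer output is O_i = MCA_i + MLP(LN(Q_i + MCA_i)). In the decoder,
# CCA gates the skip features with a sigmoid channel-attention vector
# derived from the pooled decoder features, then concatenates.

pool_matrix <- function(n, p) {
  if (n %% p != 0) stop("dimension ", n, " not divisible by patch size ", p)
  k <- n %/% p
  A <- matrix(0, k, n)
  for (i in seq_len(k)) A[i, ((i - 1) * p + 1):(i * p)] <- 1 / p
  A
}

broadcast_matrix <- function(n, p) {
  # nearest up-broadcast: each token value repeated over its p x p patch
  t(pool_matrix(n, p)) * p
}

tp_tokenize <- function(x, p) {
  d <- dim(x$value)
  pooled <- tp_axismat(tp_axismat(x, pool_matrix(d[1], p), 1L),
                       pool_matrix(d[2], p), 2L)
  dp <- dim(pooled$value)
  tp_reshape(pooled, c(dp[1] * dp[2], dp[3], dp[4]))
}

tp_detokenize <- function(tok, hw, p) {
  d <- dim(tok$value)
  x <- tp_reshape(tok, c(hw[1] %/% p, hw[2] %/% p, d[2], d[3]))
  tp_axismat(tp_axismat(x, broadcast_matrix(hw[1], p), 1L),
             broadcast_matrix(hw[2], p), 2L)
}

#' Patch-embed multi-scale feature maps into token matrices
#'
#' Average-pools each scale with its patch size, yielding one token matrix
#' `[d, C_i]` per scale; patch sizes must be chosen so all scales produce the
#' same token count `d`.
#'
#' @param features list of feature maps (`[C, H, W]` or `[B, C, H, W]`).
#' @param patch_sizes integer vector, one patch size per scale; each scale's
#'   spatial dims must be divisible by its patch size.
#' @return list of token arrays, `[d, C_i]` (or `[d, B, C_i]` for batched
#'   input), one per scale.
#' @export
tokenize_multiscale <- function(features, patch_sizes) {
  stopifnot(length(features) == length(patch_sizes))
  out <- vector("list", length(features))
  ds <- integer(length(features))
  for (i in seq_along(features)) {
    conv <- as_hwbc(features[[i]], paste0("features[[", i, "]]"))
    tp <- tape_new()
    tok <- tp_tokenize(tp_leaf(tp, conv$arr), patch_sizes[i])
    v <- tok$value
    ds[i] <- dim(v)[1]
    out[[i]] <- if (conv$batched) v else array(v, dim(v)[c(1, 3)])
  }
  if (length(unique(ds)) != 1)
    stop("patch sizes give unequal token counts: ", paste(ds, collapse = ", "))
  out
}

#' Reverse a patch embedding by nearest up-broadcast
#'
#' @param tokens token array `[d, C]` (or `[d, B, C]`).
#' @param height,width spatial size to restore.
#' @param patch_size patch size used by the embedding.
#' @return feature map `[C, height, width]` (or batched).
#' @export
detokenize <- function(tokens, height, width, patch_size) {
  dm <- dim(tokens)
  batched <- length(dm) == 3L
  if (!batched) dim(tokens) <- c(dm[1], 1L, dm[2])
  tp <- tape_new()
  out <- tp_detokenize(tp_leaf(tp, tokens), c(height, width), patch_size)
  from_hwbc(out$value, batched)
}

# Multi-head channel-wise cross attention, one fused tape node per
# (layer, scale). Q: [d, B, Ci]; K, V: [d, B, Ct]. The Ct key/value channels
# are partitioned across heads; each head emits a full [d, Ci] map and the
# head outputs are averaged. Attention logits are standardised (zero mean,
# unit variance over the logit matrix) before the channel-axis softmax.
tp_cct_attention <- function(Q, K, V, n_heads, eps = 1e-5) {
  dq <- dim(Q$value)
  d <- dq[1]; B <- dq[2]; Ci <- dq[3]
  Ct <- dim(K$value)[3]
  stopifnot(Ct %% n_heads == 0)
  Cg <- Ct %/% n_heads
  sc <- 1 / sqrt(d)
  Qv <- Q$value; Kv <- K$value; Vv <- V$value
  O <- array(0, c(d, B, Ci))
  cache <- vector("list", B)
  for (b in seq_len(B)) {
    Qb <- matrix(Qv[, b, ], d, Ci)
    cb <- vector("list", n_heads)
    for (h in seq_len(n_heads)) {
      cols <- ((h - 1) * Cg + 1):(h * Cg)
      Kg <- matrix(Kv[, b, cols], d, Cg)
      Vg <- matrix(Vv[, b, cols], d, Cg)
      L <- crossprod(Qb, Kg) * sc
      mu <- mean(L)
      s <- sqrt(mean((L - mu)^2) + eps)
      Ls <- (L - mu) / s
      E <- exp(Ls - apply(Ls, 1L, max))
      A <- E / rowSums(E)
      O[, b, ] <- O[, b, ] + Vg %*% t(A) / n_heads
      cb[[h]] <- list(A = A, Ls = Ls, s = s, Kg = Kg, Vg = Vg, cols = cols)
    }
    cache[[b]] <- list(Qb = Qb, heads = cb)
  }
  tp_node(Q$tp, O, c(Q$id, K$id, V$id), function(g) {
    dQ <- array(0, dq); dK <- array(0, dim(Kv)); dV <- array(0, dim(Vv))
    for (b in seq_len(B)) {
      dO <- matrix(g[, b, ], d, Ci) / n_heads
      Qb <- cache[[b]]$Qb
      for (h in seq_len(n_heads)) {
        cc <- cache[[b]]$heads[[h]]
        dV[, b, cc$cols] <- dV[, b, cc$cols] + dO %*% cc$A
        dA <- crossprod(dO, cc$Vg)
        dLs <- cc$A * (dA - rowSums(dA * cc$A))
        dL <- (dLs - mean(dLs) - cc$Ls * mean(dLs * cc$Ls)) / cc$s
        dQ[, b, ] <- dQ[, b, ] + cc$Kg %*% t(dL) * sc
        dK[, b, cc$cols] <- dK[, b, cc$cols] + Qb %*% dL * sc
      }
    }
    list(dQ, dK, dV)
  })
}

#' CCT parameter set
#'
#' Seeded weights for an `n_layers`-deep channel-wise cross fusion
#' transformer over four token scales.
#'
#' @param channels integer vector of the four scale widths `C_i`.
#' @param n_heads,n_layers heads and layers; both default to 4.
#' @param mlp_ratio hidden-width multiple of each scale's output MLP.
#' @param seed integer seed for the weight draw.
#' @return an object of class `cct_params`.
#' @export
cct_params <- function(channels, n_heads = 4L, n_layers = 4L, mlp_ratio = 4,
                       seed = 1L) {
  Ct <- sum(channels)
  if (Ct %% n_heads != 0) stop("sum of channel widths must be divisible by n_heads")
  set.seed(seed)
  layers <- lapply(seq_len(n_layers), function(l) {
    per_scale <- lapply(channels, function(C) {
      hidden <- round(mlp_ratio * C)
      list(Wq = matrix(rnorm(C * C) * sqrt(1 / C), C, C),
           lnq_g = rep(1, C), lnq_b = rep(0, C),
           lnm_g = rep(1, C), lnm_b = rep(0, C),
           W1 = matrix(rnorm(C * hidden) * sqrt(2 / C), C, hidden),
           b1 = rep(0, hidden),
           W2 = matrix(rnorm(hidden * C) * sqrt(2 / hidden), hidden, C),
           b2 = rep(0, C))
    })
    list(scales = per_scale,
         lnkv_g = rep(1, Ct), lnkv_b = rep(0, Ct),
         Wk = matrix(rnorm(Ct * Ct) * sqrt(1 / Ct), Ct, Ct),
         Wv = matrix(rnorm(Ct * Ct) * sqrt(1 / Ct), Ct, Ct))
  })
  structure(list(channels = channels, n_heads = n_heads, n_layers = n_layers,
                 layers = layers),
            class = "cct_params")
}

# LN + linear applied to [d, B, C] tokens through a [d*B, C] reshape
tp_tok_ln <- function(tok, gamma, beta) {
  dm <- dim(tok$value)
  m <- tp_layernorm(tp_reshape(tok, c(dm[1] * dm[2], dm[3])), gamma, beta)
  tp_reshape(m, dm)
}

tp_tok_mm <- function(tok, W) {
  dm <- dim(tok$value)
  m <- tp_matmul(tp_reshape(tok, c(dm[1] * dm[2], dm[3])), W)
  tp_reshape(m, c(dm[1], dm[2], ncol(W$value)))
}

tp_tok_linear <- function(tok, W, b) {
  dm <- dim(tok$value)
  m <- tp_linear(tp_reshape(tok, c(dm[1] * dm[2], dm[3])), W, b)
  tp_reshape(m, c(dm[1], dm[2], ncol(W$value)))
}

# One CCT layer over the list of [d, B, Ci] token nodes.
tp_cct_layer <- function(tokens, lp, n_heads) {
  tcat <- tp_concat_last(tokens)
  kvn <- tp_tok_ln(tcat, lp$lnkv_g, lp$lnkv_b)
  K <- tp_tok_mm(kvn, lp$Wk)
  V <- tp_tok_mm(kvn, lp$Wv)
  lapply(seq_along(tokens), function(i) {
    sp <- lp$scales[[i]]
    Qi <- tp_tok_mm(tp_tok_ln(tokens[[i]], sp$lnq_g, sp$lnq_b), sp$Wq)
    mca <- tp_cct_attention(Qi, K, V, n_heads)
    z <- tp_tok_ln(tp_add(Qi, mca), sp$lnm_g, sp$lnm_b)
    h <- tp_gelu(tp_tok_linear(z, sp$W1, sp$b1))
    tp_add(mca, tp_tok_linear(h, sp$W2, sp$b2))
  })
}

leaf_tree <- function(tp, x) {
  if (is.list(x)) lapply(x, function(e) leaf_tree(tp, e)) else tp_leaf(tp, x)
}

tp_cct_forward <- function(tokens, pn, n_heads, n_layers) {
  for (l in seq_len(n_layers)) tokens <- tp_cct_layer(tokens, pn$layers[[l]], n_heads)
  tokens
}

#' Channel-wise cross fusion transformer forward pass
#'
#' Runs `n_layers` of channel-axis cross attention over the four token
#' scales; token shapes are preserved.
#'
#' @param tokens list of token arrays `[d, C_i]` (or `[d, B, C_i]`), e.g.
#'   from [tokenize_multiscale].
#' @param p a [cct_params] object with matching widths.
#' @return list of token arrays with the input shapes.
#' @export
cct_forward <- function(tokens, p) {
  batched <- length(dim(tokens[[1]])) == 3L
  toks <- lapply(tokens, function(t) {
    dm <- dim(t)
    if (!batched) dim(t) <- c(dm[1], 1L, dm[2])
    t
  })
  tp <- tape_new()
  pn <- leaf_tree(tp, p[c("layers")])
  nodes <- lapply(toks, function(t) tp_leaf(tp, t))
  out <- tp_cct_forward(nodes, pn, p$n_heads, p$n_layers)
  lapply(out, function(o) {
    v <- o$value
    if (!batched) array(v, dim(v)[c(1, 3)]) else v
  })
}

tp_cca <- function(dec, skip, W, b) {
  gate <- tp_sigmoid(tp_linear(tp_gap(dec), W, b))
  tp_concat_last(list(dec, tp_mul(skip, tp_expand(gate, dim(skip$value)))))
}

#' Channel-wise cross attention decoder fusion
#'
#' Global-average-pools the decoder features, maps the pooled vector through
#' a linear layer + sigmoid to one weight per skip channel, re-weights the
#' skip features and concatenates decoder and re-weighted skip along
#' channels.
#'
#' @param decoder_feat,skip_feat feature maps with equal spatial dims
#'   (`[C, H, W]` or batched).
#' @param W linear map `[C_dec, C_skip]`; @param b bias `[C_skip]`.
#' @return array with `C_dec + C_skip` channels.
#' @export
cca_fuse <- function(decoder_feat, skip_feat, W, b = rep(0, ncol(W))) {
  cd <- as_hwbc(decoder_feat, "decoder_feat")
  cs <- as_hwbc(skip_feat, "skip_feat")
  if (!identical(dim(cd$arr)[1:2], dim(cs$arr)[1:2]))
    stop("decoder and skip spatial dims differ")
  tp <- tape_new()
  out <- tp_cca(tp_leaf(tp, cd$arr), tp_leaf(tp, cs$arr),
                tp_leaf(tp, W), tp_leaf(tp, b))
  from_hwbc(out$value, cd$batched)
}
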