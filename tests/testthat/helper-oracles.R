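# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity with naive loops, never by calling the package's
# own vectorised code paths.

# per-pixel minimum-energy importance, one channel at a time
naive_energy_weights <- function(x, lambda) {
  # x: [C, H, W]
  d <- dim(x)
  out <- array(0, d)
  for (c in seq_len(d[1])) {
    px <- as.vector(x[c, , ])
    M <- length(px)
    mu <- sum(px) / M
    s2 <- sum((px - mu)^2) / M
    for (h in seq_len(d[2])) for (w in seq_len(d[3])) {
      t <- x[c, h, w]
      e <- 4 * (s2 + lambda) / ((t - mu)^2 + 2 * s2 + 2 * lambda)
      out[c, h, w] <- 1 / e
    }
  }
  out
}

# literal slice-assignment reading of the four-direction shift
naive_spatial_shift <- function(x) {
  # x: [C, H, W]; quarters along C; +1/-1 width then +1/-1 height
  d <- dim(x)
  C <- d[1]; H <- d[2]; W <- d[3]
  q <- C / 4
  y <- x
  for (c in 1:q) for (h in 1:H) for (w in W:2)
    y[c, h, w] <- x[c, h, w - 1]
  for (c in (q + 1):(2 * q)) for (h in 1:H) for (w in 1:(W - 1))
    y[c, h, w] <- x[c, h, w + 1]
  for (c in (2 * q + 1):(3 * q)) for (h in H:2) for (w in 1:W)
    y[c, h, w] <- x[c, h - 1, w]
  for (c in (3 * q + 1):C) for (h in 1:(H - 1)) for (w in 1:W)
    y[c, h + 1 - 1, w] <- x[c, h + 1, w]
  y
}

# explicit max loop + explicit sliding kernel-3 dot product + gating
naive_channel_shift <- function(x, w, b) {
  # x: [C, H, W]
  d <- dim(x)
  C <- d[1]
  gmp <- numeric(C)
  for (c in seq_len(C)) {
    m <- -Inf
    for (h in seq_len(d[2])) for (ww in seq_len(d[3]))
      if (x[c, h, ww] > m) m <- x[c, h, ww]
    gmp[c] <- m
  }
  conv <- numeric(C)
  for (c in seq_len(C)) {
    acc <- b
    for (k in -1:1) {
      j <- c + k
      if (j >= 1 && j <= C) acc <- acc + w[k + 2] * gmp[j]
    }
    conv[c] <- acc
  }
  gate <- 1 / (1 + exp(-conv))
  out <- x
  for (c in seq_len(C)) out[c, , ] <- x[c, , ] * gate[c]
  out
}

# per-channel re-derivation of 2-way split attention
naive_split_attention <- function(t1, t2, p) {
  # t1, t2: [C', H, W]; p: ds_mlp_params for C = 2*C'
  d <- dim(t1)
  Cp <- d[1]
  N <- d[2] * d[3]
  alpha <- numeric(Cp)
  for (c in seq_len(Cp)) alpha[c] <- sum(t1[c, , ]) / N + sum(t2[c, , ]) / N
  h <- as.vector(alpha %*% p$sa1_W) + p$sa1_b
  h <- h * pnorm(h)                       # GELU
  logits <- as.vector(h %*% p$sa2_W) + p$sa2_b
  out <- array(0, d)
  for (c in seq_len(Cp)) {
    l1 <- logits[c]; l2 <- logits[Cp + c]
    e1 <- exp(l1 - max(l1, l2)); e2 <- exp(l2 - max(l1, l2))
    w1 <- e1 / (e1 + e2); w2 <- e2 / (e1 + e2)
    out[c, , ] <- w1 * t1[c, , ] + w2 * t2[c, , ]
  }
  out
}

# set-overlap Dice/IoU from explicit pixel index sets
naive_dice_iou <- function(pred_bin, gt) {
  a <- which(pred_bin == 1)
  b <- which(gt == 1)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  if (length(a) + length(b) == 0) return(list(dice = 1, iou = 1))
  list(dice = 2 * inter / (length(a) + length(b)), iou = inter / uni)
}

# connected components of a binary matrix (4-connectivity), BFS flood fill
count_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] == 1 && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      queue <- matrix(c(i0, j0), 1)
      lab[i0, j0] <- cur
      while (nrow(queue)) {
        i <- queue[1, 1]; j <- queue[1, 2]
        queue <- queue[-1, , drop = FALSE]
        for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
          if (nb[1] >= 1 && nb[1] <= nrow(mask) && nb[2] >= 1 && nb[2] <= ncol(mask) &&
              mask[nb[1], nb[2]] == 1 && lab[nb[1], nb[2]] == 0L) {
            lab[nb[1], nb[2]] <- cur
            queue <- rbind(queue, nb)
          }
        }
      }
    }
  }
  cur
}

# central-difference gradient of a scalar function of one array argument
num_grad <- function(f, x, eps = 1e-6) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

rand_fmap <- function(C, H, W, sd = 1) array(rnorm(C * H * W, sd = sd), c(C, H, W))
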