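# Minimal reverse-mode autodiff tape.
#
# Every differentiable quantity is a "node": a list holding a value (an R
# array), the ids of its parent nodes and a backward closure that maps the
# node's output gradient to gradients for each parent. Nodes are appended to
# a tape (an environment) in execution order; tape_backward() walks the tape
# in reverse, accumulating gradients. Feature maps use the [H, W, B, C]
# layout so that per-channel reductions are column operations.

tape_new <- function() {
  tp <- new.env(parent = emptyenv())
  tp$nodes <- vector("list", 256L)
  tp$n <- 0L
  tp
}

tp_node <- function(tp, value, parents = integer(0), backward = NULL) {
  # force arguments before reserving an id: R's lazy evaluation would
  # otherwise let nested op calls append their nodes after this one,
  # breaking the tape's topological order
  force(value); force(parents); force(backward)
  tp$n <- tp$n + 1L
  if (tp$n > length(tp$nodes)) tp$nodes <- c(tp$nodes, vector("list", length(tp$nodes)))
  nd <- list(tp = tp, id = tp$n, value = value, parents = parents, backward = backward)
  tp$nodes[[tp$n]] <- nd
  nd
}

tp_leaf <- function(tp, value) tp_node(tp, value)

# Backward pass from a scalar root; returns a list of gradients indexed by
# node id (NULL where the root does not depend on the node).
tape_backward <- function(tp, root) {
  grads <- vector("list", tp$n)
  rv <- root$value
  grads[[root$id]] <- if (is.null(dim(rv))) rep(1, length(rv)) else array(1, dim(rv))
  for (i in seq(tp$n, 1L)) {
    g <- grads[[i]]
    if (is.null(g)) next
    nd <- tp$nodes[[i]]
    if (!length(nd$parents)) next
    pg <- nd$backward(g)
    for (k in seq_along(nd$parents)) {
      gk <- pg[[k]]
      if (is.null(gk)) next
      p <- nd$parents[k]
      grads[[p]] <- if (is.null(grads[[p]])) gk else grads[[p]] + gk
    }
  }
  grads
}

.dims <- function(x) if (is.null(dim(x))) length(x) else dim(x)

# set dims without array()'s unconditional copy; safe on freshly allocated
# values (refcount 1), where `dim<-` modifies in place
setdim <- function(x, d) {
  dim(x) <- d
  x
}

# ---- elementwise arithmetic ------------------------------------------------

tp_add <- function(a, b) {
  tp_node(a$tp, a$value + b$value, c(a$id, b$id), function(g) list(g, g))
}

tp_sub <- function(a, b) {
  tp_node(a$tp, a$value - b$value, c(a$id, b$id), function(g) list(g, -g))
}

tp_mul <- function(a, b) {
  av <- a$value; bv <- b$value
  tp_node(a$tp, av * bv, c(a$id, b$id), function(g) list(g * bv, g * av))
}

tp_div <- function(a, b) {
  av <- a$value; bv <- b$value
  y <- av / bv
  tp_node(a$tp, y, c(a$id, b$id), function(g) list(g / bv, -g * y / bv))
}

# multiply / add by non-differentiable constants
tp_scale <- function(a, k) tp_node(a$tp, a$value * k, a$id, function(g) list(g * k))
tp_shift <- function(a, k) tp_node(a$tp, a$value + k, a$id, function(g) list(g))
tp_cmul <- function(a, const) {
  tp_node(a$tp, a$value * const, a$id, function(g) list(g * const))
}

tp_abs <- function(a) {
  s <- sign(a$value)
  tp_node(a$tp, abs(a$value), a$id, function(g) list(g * s))
}

tp_sum <- function(a) {
  d <- .dims(a$value)
  tp_node(a$tp, sum(a$value), a$id, function(g) list(array(as.numeric(g), d)))
}

# Broadcast `a` (whose dims equal the trailing dims `axes` of `dim_out`) up
# to dim_out by replication over the leading axes.
tp_expand <- function(a, dim_out) {
  da <- .dims(a$value)
  lead <- prod(dim_out) / prod(da)
  v <- setdim(rep(a$value, each = lead), dim_out)
  tp_node(a$tp, v, a$id, function(g) {
    gs <- colSums(setdim(g, c(lead, prod(da))))
    list(setdim(gs, da))
  })
}

# ---- activations -----------------------------------------------------------

tp_relu <- function(a) {
  m <- a$value > 0
  tp_node(a$tp, a$value * m, a$id, function(g) list(g * m))
}

tp_sigmoid <- function(a) {
  y <- 1 / (1 + exp(-a$value))
  tp_node(a$tp, y, a$id, function(g) list(g * y * (1 - y)))
}

tp_gelu <- function(a) {
  x <- a$value
  ph <- pnorm(x)
  tp_node(a$tp, x * ph, a$id, function(g) list(g * (ph + x * dnorm(x))))
}

# ---- linear algebra --------------------------------------------------------

tp_matmul <- function(a, b) {
  av <- a$value; bv <- b$value
  tp_node(a$tp, av %*% bv, c(a$id, b$id),
          function(g) list(tcrossprod(g, bv), crossprod(av, g)))
}

# y = x %*% W + b  (x: [n, p], W: [p, q], b: [q])
tp_linear <- function(x, W, b) {
  xv <- x$value; Wv <- W$value
  y <- xv %*% Wv
  y <- y + rep(b$value, each = nrow(y))
  tp_node(x$tp, y, c(x$id, W$id, b$id), function(g) {
    g <- setdim(g, dim(y))
    list(tcrossprod(g, Wv), crossprod(xv, g), colSums(g))
  })
}

tp_reshape <- function(a, dims) {
  d0 <- .dims(a$value)
  tp_node(a$tp, array(a$value, dims), a$id, function(g) list(array(g, d0)))
}

# Contract a constant matrix A over axis 1 or 2 of a [H, W, B, C] array;
# used for bilinear up/down-sampling and patch pooling, whose adjoint is the
# same contraction with t(A).
tp_axismat <- function(x, A, axis) {
  d <- .dims(x$value)
  contract <- function(v, M, dd) {
    if (axis == 1L) {
      array(M %*% matrix(v, dd[1], prod(dd[-1])), c(nrow(M), dd[-1]))
    } else {
      vp <- aperm(array(v, dd), c(2L, 1L, 3L, 4L))
      yp <- array(M %*% matrix(vp, dd[2], prod(dd[-2])), c(nrow(M), dd[1], dd[3], dd[4]))
      aperm(yp, c(2L, 1L, 3L, 4L))
    }
  }
  y <- contract(x$value, A, d)
  dy <- .dims(y)
  tp_node(x$tp, y, x$id, function(g) list(contract(g, t(A), dy)))
}

# ---- convolution / pooling -------------------------------------------------

# 3x3 stride-1 pad-1 convolution, bias-free (a batch norm always follows).
# W is stored [Cin, 9*Cout], the 9 column blocks being the kernel taps, so
# the forward pass is one GEMM on the raw input followed by an offset
# scatter-add (col2im3); the backward pass gathers the output gradient with
# im2col3 and needs no further scatter. This keeps the lowered matrix at
# width 9*Cout rather than 9*Cin, which matters in the decoder where the
# concatenated inputs are wide.
tp_conv2d3 <- function(x, W) {
  d <- .dims(x$value)
  H <- d[1]; Wd <- d[2]; B <- d[3]; C <- d[4]
  Wv <- W$value
  Cout <- ncol(Wv) %/% 9L
  Xmat <- matrix(x$value, H * Wd * B, C)
  y <- col2im3(Xmat %*% Wv, H, Wd, B, Cout)
  tp_node(x$tp, setdim(y, c(H, Wd, B, Cout)), c(x$id, W$id), function(g) {
    G9 <- im2col3(g, H, Wd, B, Cout)
    list(setdim(tcrossprod(G9, Wv), d), crossprod(Xmat, G9))
  })
}

# 1x1 convolution as a channel-space linear map; W [Cin, Cout].
tp_conv1x1 <- function(x, W, b) {
  d <- .dims(x$value)
  xm <- tp_reshape(x, c(prod(d[1:3]), d[4]))
  y <- tp_linear(xm, W, b)
  tp_reshape(y, c(d[1:3], ncol(W$value)))
}

# 2x2 max pooling, stride 2. Ties resolve to the first window element.
tp_maxpool2 <- function(x) {
  d <- .dims(x$value)
  H <- d[1]; W <- d[2]
  io <- seq(1L, H, 2L); jo <- seq(1L, W, 2L)
  a <- x$value[io, jo, , , drop = FALSE]
  b <- x$value[io + 1L, jo, , , drop = FALSE]
  cc <- x$value[io, jo + 1L, , , drop = FALSE]
  dd <- x$value[io + 1L, jo + 1L, , , drop = FALSE]
  m <- pmax(a, b, cc, dd)
  tp_node(x$tp, m, x$id, function(g) {
    wa <- a == m
    wb <- (b == m) & !wa
    wc <- (cc == m) & !(wa | wb)
    wd <- !(wa | wb | wc)
    dx <- array(0, d)
    dx[io, jo, , ] <- g * wa
    dx[io + 1L, jo, , ] <- g * wb
    dx[io, jo + 1L, , ] <- g * wc
    dx[io + 1L, jo + 1L, , ] <- g * wd
    list(dx)
  })
}

# Interpolation matrix for x2 bilinear upsampling of an axis of length n
# (half-pixel centers, edges clamped).
upsample2_matrix <- function(n) {
  A <- matrix(0, 2L * n, n)
  for (o in seq_len(2L * n)) {
    src <- (o - 0.5) / 2 - 0.5
    lo <- floor(src)
    whi <- src - lo
    lo <- min(max(lo, 0), n - 1)
    hi <- min(lo + 1, n - 1)
    A[o, lo + 1] <- A[o, lo + 1] + (1 - whi)
    A[o, hi + 1] <- A[o, hi + 1] + whi
  }
  A
}

tp_upsample2 <- function(x) {
  d <- .dims(x$value)
  tp_axismat(tp_axismat(x, upsample2_matrix(d[1]), 1L), upsample2_matrix(d[2]), 2L)
}

# ---- normalisation ---------------------------------------------------------

# 2-D batch norm over (H, W, B) per channel. `state` is an environment slot
# carrying running mean/var (vectors [C]); updated only when training.
tp_bn2d <- function(x, gamma, beta, state, training, momentum = 0.1, eps = 1e-5) {
  d <- .dims(x$value)
  m <- prod(d[1:3]); C <- d[4]
  xm <- matrix(x$value, m, C)
  gv <- gamma$value; bv <- beta$value
  if (training) {
    mu <- colMeans(xm)
    va <- colMeans(xm * xm) - mu * mu
    state$mean <- (1 - momentum) * state$mean + momentum * mu
    state$var <- (1 - momentum) * state$var + momentum * va * m / max(m - 1, 1)
    ivar <- 1 / sqrt(va + eps)
  } else {
    mu <- state$mean
    ivar <- 1 / sqrt(state$var + eps)
  }
  # fused affine: y = x * (gamma*ivar) + (beta - mu*gamma*ivar)
  sc <- gv * ivar
  sh <- bv - mu * sc
  y <- xm * rep(sc, each = m) + rep(sh, each = m)
  if (!training) {
    return(tp_node(x$tp, setdim(y, d), c(x$id, gamma$id, beta$id), function(g) {
      g <- setdim(g, c(m, C))
      xhat <- (xm - rep(mu, each = m)) * rep(ivar, each = m)
      list(setdim(g * rep(sc, each = m), d), colSums(g * xhat), colSums(g))
    }))
  }
  tp_node(x$tp, setdim(y, d), c(x$id, gamma$id, beta$id), function(g) {
    g <- setdim(g, c(m, C))
    xhat <- (xm - rep(mu, each = m)) * rep(ivar, each = m)
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dx <- (g - rep(dbeta / m, each = m) - xhat * rep(dgamma / m, each = m)) *
      rep(sc, each = m)
    list(setdim(dx, d), dgamma, dbeta)
  })
}

# Layer norm over the last axis of a [n, C] matrix.
tp_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  C <- ncol(xv)
  mu <- rowMeans(xv)
  xc <- xv - mu
  va <- rowMeans(xc * xc)
  ivar <- 1 / sqrt(va + eps)
  xhat <- xc * ivar
  gv <- gamma$value
  y <- sweep(sweep(xhat, 2L, gv, "*"), 2L, beta$value, "+")
  tp_node(x$tp, y, c(x$id, gamma$id, beta$id), function(g) {
    g <- matrix(g, nrow(xv))
    dgamma <- colSums(g * xhat)
    dbeta <- colSums(g)
    dxhat <- sweep(g, 2L, gv, "*")
    dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * ivar
    list(dx, dgamma, dbeta)
  })
}

# ---- spatial reductions ----------------------------------------------------

# Global average pool over H, W: [H, W, B, C] -> [B, C].
tp_gap <- function(x) {
  d <- .dims(x$value)
  hw <- d[1] * d[2]
  y <- array(colMeans(matrix(x$value, hw, d[3] * d[4])), c(d[3], d[4]))
  tp_node(x$tp, y, x$id, function(g) {
    list(array(rep(as.vector(g) / hw, each = hw), d))
  })
}

# Global max pool over H, W: [H, W, B, C] -> [B, C]; gradient routes to the
# first arg-max element.
tp_gmp <- function(x) {
  d <- .dims(x$value)
  hw <- d[1] * d[2]
  xm <- matrix(x$value, hw, d[3] * d[4])
  idx <- apply(xm, 2L, which.max)
  y <- array(xm[cbind(idx, seq_along(idx))], c(d[3], d[4]))
  tp_node(x$tp, y, x$id, function(g) {
    dm <- matrix(0, hw, d[3] * d[4])
    dm[cbind(idx, seq_along(idx))] <- as.vector(g)
    list(array(dm, d))
  })
}

# ---- structural ops --------------------------------------------------------

# Concatenate along the LAST axis (channel axis in every layout used here).
tp_concat_last <- function(nodes) {
  tp <- nodes[[1]]$tp
  dims <- lapply(nodes, function(n) .dims(n$value))
  lead <- dims[[1]][-length(dims[[1]])]
  cs <- vapply(dims, function(d) d[length(d)], numeric(1))
  v <- array(unlist(lapply(nodes, function(n) as.vector(n$value))), c(lead, sum(cs)))
  offs <- cumsum(c(0, cs))
  tp_node(tp, v, vapply(nodes, function(n) n$id, integer(1)), function(g) {
    gm <- matrix(g, prod(lead), sum(cs))
    lapply(seq_along(nodes), function(k) {
      array(gm[, (offs[k] + 1):offs[k + 1], drop = FALSE], dims[[k]])
    })
  })
}

# Select channels [from, to] along the last axis.
tp_narrow_last <- function(x, from, to) {
  d <- .dims(x$value)
  nd <- length(d)
  lead <- prod(d[-nd])
  xm <- matrix(x$value, lead, d[nd])
  v <- array(xm[, from:to, drop = FALSE], c(d[-nd], to - from + 1L))
  tp_node(x$tp, v, x$id, function(g) {
    dm <- matrix(0, lead, d[nd])
    dm[, from:to] <- matrix(g, lead)
    list(array(dm, d))
  })
}

# Four-direction spatial shift over channel quarters of a [H, W, B, C] map:
# quarter 1 shifts +1 in width, quarter 2 -1 in width, quarter 3 +1 in
# height, quarter 4 -1 in height; border lines keep their original values
# (slice-assignment semantics).
tp_spatial_shift <- function(x) {
  d <- .dims(x$value)
  H <- d[1]; W <- d[2]; C <- d[4]
  stopifnot(C %% 4 == 0)
  q <- C / 4
  i1 <- 1:q; i2 <- (q + 1):(2 * q); i3 <- (2 * q + 1):(3 * q); i4 <- (3 * q + 1):C
  y <- x$value
  if (W > 1) {
    y[, 2:W, , i1] <- x$value[, 1:(W - 1), , i1]
    y[, 1:(W - 1), , i2] <- x$value[, 2:W, , i2]
  }
  if (H > 1) {
    y[2:H, , , i3] <- x$value[1:(H - 1), , , i3]
    y[1:(H - 1), , , i4] <- x$value[2:H, , , i4]
  }
  tp_node(x$tp, y, x$id, function(g) {
    dx <- array(0, d)
    if (W > 1) {
      dx[, 1:(W - 1), , i1] <- g[, 2:W, , i1]
      dx[, 1, , i1] <- dx[, 1, , i1] + g[, 1, , i1]
      dx[, 2:W, , i2] <- g[, 1:(W - 1), , i2]
      dx[, W, , i2] <- dx[, W, , i2] + g[, W, , i2]
    } else {
      dx[, , , c(i1, i2)] <- g[, , , c(i1, i2)]
    }
    if (H > 1) {
      dx[1:(H - 1), , , i3] <- dx[1:(H - 1), , , i3] + g[2:H, , , i3]
      dx[1, , , i3] <- dx[1, , , i3] + g[1, , , i3]
      dx[2:H, , , i4] <- dx[2:H, , , i4] + g[1:(H - 1), , , i4]
      dx[H, , , i4] <- dx[H, , , i4] + g[H, , , i4]
    } else {
      dx[, , , c(i3, i4)] <- g[, , , c(i3, i4)]
    }
    list(dx)
  })
}

# Kernel-3 same-padded 1-d convolution along the channel axis of a [B, C]
# matrix (single filter, weights w [3], bias scalar).
tp_conv1d3 <- function(v, w, b) {
  vv <- v$value
  B <- nrow(vv); C <- ncol(vv)
  wv <- w$value
  pad <- cbind(0, vv, 0)
  y <- wv[1] * pad[, 1:C, drop = FALSE] +
    wv[2] * pad[, 2:(C + 1), drop = FALSE] +
    wv[3] * pad[, 3:(C + 2), drop = FALSE] + b$value
  tp_node(v$tp, y, c(v$id, w$id, b$id), function(g) {
    g <- matrix(g, B, C)
    gp <- cbind(0, g, 0)
    dv <- wv[1] * gp[, 3:(C + 2), drop = FALSE] +
      wv[2] * gp[, 2:(C + 1), drop = FALSE] +
      wv[3] * gp[, 1:C, drop = FALSE]
    dw <- c(sum(g * pad[, 1:C]), sum(g * pad[, 2:(C + 1)]), sum(g * pad[, 3:(C + 2)]))
    list(dv, dw, sum(g))
  })
}

# ---- losses ----------------------------------------------------------------

# Mean binary cross-entropy on logits against a constant 0/1 target.
tp_bce_logits <- function(z, target) {
  zv <- z$value
  n <- length(zv)
  val <- sum(pmax(zv, 0) - zv * target + log1p(exp(-abs(zv)))) / n
  tp_node(z$tp, val, z$id, function(g) {
    p <- 1 / (1 + exp(-zv))
    list(as.numeric(g) * (p - target) / n)
  })
}
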