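# The autodiff tape is the substrate every block runs on; each primitive's
# backward pass is checked against central differences, and the convolution
# against an explicit quintuple loop.

h <- asNamespace("heanet")

# gradcheck helper: f_node builds a scalar node from a leaf; compares the
# tape gradient with numeric differentiation of the value path
check_grad <- function(x, build, tol = 1e-6, eps = 1e-6) {
  tp <- h$tape_new()
  leaf <- h$tp_leaf(tp, x)
  root <- build(leaf, tp)
  grads <- h$tape_backward(tp, root)
  ana <- grads[[leaf$id]]
  num <- num_grad(function(v) {
    tp2 <- h$tape_new()
    as.numeric(build(h$tp_leaf(tp2, v), tp2)$value)
  }, x, eps = eps)
  expect_lt(max(abs(ana - num)), tol * max(1, max(abs(num))))
}

test_that("elementwise and reduction ops backpropagate correctly", {
  set.seed(1)
  x <- array(rnorm(24), c(2, 3, 2, 2))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(l, l)))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_sigmoid(l)))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_gelu(l)))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_div(h$tp_shift(l, 3), h$tp_shift(h$tp_mul(l, l), 1))))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(h$tp_gap(l), h$tp_gap(l))))
  v <- rnorm(5)
  check_grad(v, function(l, tp) h$tp_sum(h$tp_mul(h$tp_expand(l, c(4, 5)), h$tp_expand(l, c(4, 5)))))
})

test_that("conv2d matches an explicit loop and its gradient is exact", {
  set.seed(2)
  H <- 4; W <- 5; B <- 2; Ci <- 3; Co <- 2
  x <- array(rnorm(H * W * B * Ci), c(H, W, B, Ci))
  Wm <- matrix(rnorm(Ci * 9 * Co) * 0.4, Ci, 9 * Co)
  tp <- h$tape_new()
  y <- h$tp_conv2d3(h$tp_leaf(tp, x), h$tp_leaf(tp, Wm))
  # naive evaluation of the same linear map: output t accumulates the
  # input at t - offset_k times kernel tap k (zero padding outside)
  yn <- array(0, c(H, W, B, Co))
  for (k in 0:8) {
    dy <- k %% 3 - 1; dx <- k %/% 3 - 1
    for (co in 1:Co) for (ci in 1:Ci) for (b in 1:B)
      for (hh in 1:H) for (ww in 1:W) {
        hs <- hh - dy; ws <- ww - dx
        if (hs >= 1 && hs <= H && ws >= 1 && ws <= W)
          yn[hh, ww, b, co] <- yn[hh, ww, b, co] + x[hs, ws, b, ci] * Wm[ci, k * Co + co]
      }
  }
  expect_equal(y$value, yn, tolerance = 1e-12)
  check_grad(x, function(l, tp2) h$tp_sum(h$tp_mul(
    h$tp_conv2d3(l, h$tp_leaf(tp2, Wm)),
    h$tp_conv2d3(l, h$tp_leaf(tp2, Wm)))))
  # weight gradient
  tp3 <- h$tape_new()
  wl <- h$tp_leaf(tp3, Wm)
  root <- h$tp_sum(h$tp_mul(h$tp_conv2d3(h$tp_leaf(tp3, x), wl),
                            h$tp_conv2d3(h$tp_leaf(tp3, x), wl)))
  gw <- h$tape_backward(tp3, root)[[wl$id]]
  nw <- num_grad(function(v) {
    tp4 <- h$tape_new()
    wlv <- h$tp_leaf(tp4, v)
    h$tp_sum(h$tp_mul(h$tp_conv2d3(h$tp_leaf(tp4, x), wlv),
                      h$tp_conv2d3(h$tp_leaf(tp4, x), wlv)))$value
  }, Wm)
  expect_lt(max(abs(gw - nw)), 1e-5)
})

test_that("pooling, upsampling and structural ops backpropagate correctly", {
  set.seed(3)
  x <- array(rnorm(4 * 4 * 2 * 3), c(4, 4, 2, 3))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(h$tp_maxpool2(l), h$tp_maxpool2(l))))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(h$tp_upsample2(l), h$tp_upsample2(l))))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(h$tp_gmp(l), h$tp_gmp(l))))
  check_grad(x, function(l, tp) h$tp_sum(h$tp_mul(h$tp_narrow_last(l, 2, 3),
                                                  h$tp_narrow_last(l, 2, 3))))
  check_grad(x, function(l, tp) {
    cc <- h$tp_concat_last(list(l, h$tp_scale(l, 2)))
    h$tp_sum(h$tp_mul(cc, cc))
  })
  x4 <- array(rnorm(3 * 3 * 2 * 4), c(3, 3, 2, 4))
  check_grad(x4, function(l, tp) h$tp_sum(h$tp_mul(h$tp_spatial_shift(l), h$tp_spatial_shift(l))))
  # bilinear x2: rows of the interpolation matrix are convex weights
  A <- h$upsample2_matrix(6)
  expect_equal(rowSums(A), rep(1, 12))
  expect_true(all(A >= 0))
})

test_that("batch norm and layer norm match their definitions and gradients", {
  set.seed(4)
  x <- array(rnorm(4 * 3 * 2 * 3, mean = 2, sd = 3), c(4, 3, 2, 3))
  gamma <- runif(3, 0.5, 1.5); beta <- rnorm(3)
  st <- h$bn_state_new(3)
  tp <- h$tape_new()
  y <- h$tp_bn2d(h$tp_leaf(tp, x), h$tp_leaf(tp, gamma), h$tp_leaf(tp, beta),
                 st, training = TRUE)
  xm <- matrix(x, 24, 3)
  mu <- colMeans(xm); va <- colMeans(sweep(xm, 2, mu)^2)
  yref <- sweep(sweep(sweep(xm, 2, mu), 2, sqrt(va + 1e-5), "/"), 2, gamma, "*")
  yref <- sweep(yref, 2, beta, "+")
  expect_equal(as.vector(y$value), as.vector(yref), tolerance = 1e-10)
  # training-mode input gradient
  st2 <- h$bn_state_new(3)
  check_grad(x, function(l, tp2) {
    stl <- h$bn_state_new(3)
    b <- h$tp_bn2d(l, h$tp_leaf(tp2, gamma), h$tp_leaf(tp2, beta), stl, TRUE)
    h$tp_sum(h$tp_mul(b, b))
  }, tol = 1e-5)
  # inference mode uses running statistics: output differs from training
  st3 <- h$bn_state_new(3)
  st3$mean <- mu; st3$var <- va
  tp5 <- h$tape_new()
  ye <- h$tp_bn2d(h$tp_leaf(tp5, x), h$tp_leaf(tp5, gamma), h$tp_leaf(tp5, beta),
                  st3, training = FALSE)
  expect_equal(as.vector(ye$value), as.vector(yref), tolerance = 1e-10)

  m <- matrix(rnorm(12, 1, 2), 4, 3)
  check_grad(m, function(l, tp2)
    h$tp_sum(h$tp_mul(h$tp_layernorm(l, h$tp_leaf(tp2, gamma), h$tp_leaf(tp2, beta)),
                      h$tp_layernorm(l, h$tp_leaf(tp2, gamma), h$tp_leaf(tp2, beta)))),
    tol = 1e-5)
})

test_that("conv1d, losses and attention backpropagate correctly", {
  set.seed(5)
  v <- matrix(rnorm(2 * 6), 2, 6)
  w <- rnorm(3); b <- 0.3
  check_grad(v, function(l, tp) h$tp_sum(h$tp_mul(h$tp_conv1d3(l, h$tp_leaf(tp, w), h$tp_leaf(tp, b)),
                                                  h$tp_conv1d3(l, h$tp_leaf(tp, w), h$tp_leaf(tp, b)))))
  z <- array(rnorm(16), c(4, 4))
  y <- matrix(rbinom(16, 1, 0.5), 4, 4)
  check_grad(z, function(l, tp) h$tp_bce_logits(l, y), tol = 1e-5)
  Q <- array(rnorm(5 * 2 * 4), c(5, 2, 4))
  K <- array(rnorm(5 * 2 * 8), c(5, 2, 8))
  V <- array(rnorm(5 * 2 * 8), c(5, 2, 8))
  check_grad(Q, function(l, tp) {
    a <- h$tp_cct_attention(l, h$tp_leaf(tp, K), h$tp_leaf(tp, V), 2L)
    h$tp_sum(h$tp_mul(a, a))
  }, tol = 1e-5)
  check_grad(K, function(l, tp) {
    a <- h$tp_cct_attention(h$tp_leaf(tp, Q), l, h$tp_leaf(tp, V), 2L)
    h$tp_sum(h$tp_mul(a, a))
  }, tol = 1e-5)
  check_grad(V, function(l, tp) {
    a <- h$tp_cct_attention(h$tp_leaf(tp, Q), h$tp_leaf(tp, K), l, 2L)
    h$tp_sum(h$tp_mul(a, a))
  }, tol = 1e-5)
})
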