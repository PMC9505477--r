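# Channel-wise cross fusion transformer skips and decoder cross attention.

h <- asNamespace("heanet")

make_scales <- function(widths = c(4, 8, 16, 32), base = 32, seed = 1) {
  set.seed(seed)
  sizes <- base / c(1, 2, 4, 8)
  lapply(seq_along(widths), function(i) rand_fmap(widths[i], sizes[i], sizes[i]))
}

test_that("patch embedding gives a shared token count and inverts in shape", {
  feats <- make_scales()
  toks <- tokenize_multiscale(feats, c(8, 4, 2, 1))
  expect_equal(vapply(toks, function(t) dim(t)[1], numeric(1)), rep(16, 4))
  expect_equal(vapply(toks, function(t) dim(t)[2], numeric(1)), c(4, 8, 16, 32))
  # unequal token counts are rejected
  expect_error(tokenize_multiscale(feats, c(4, 4, 2, 1)), "unequal token counts")
  expect_error(tokenize_multiscale(feats, c(7, 4, 2, 1)), "not divisible")
  # constant maps tokenize to that constant
  cf <- array(3.25, c(5, 8, 8))
  tk <- tokenize_multiscale(list(cf), 4L)[[1]]
  expect_equal(as.vector(tk), rep(3.25, 4 * 5))
  # de-tokenization restores the spatial shape
  back <- detokenize(tk, 8, 8, 4)
  expect_identical(dim(back), c(5L, 8L, 8L))
  expect_equal(back, cf)
  # average pooling then nearest broadcast is idempotent on patch-constant maps
  x <- rand_fmap(3, 6, 6)
  t1 <- tokenize_multiscale(list(x), 3L)[[1]]
  x2 <- detokenize(t1, 6, 6, 3)
  t2 <- tokenize_multiscale(list(x2), 3L)[[1]]
  expect_equal(t1, t2, tolerance = 1e-12)
})

test_that("channel-wise attention normalises over channels and matches an oracle", {
  set.seed(2)
  d <- 6; B <- 2; Ci <- 4; Ct <- 8; n_heads <- 2
  Q <- array(rnorm(d * B * Ci), c(d, B, Ci))
  K <- array(rnorm(d * B * Ct), c(d, B, Ct))
  V <- array(rnorm(d * B * Ct), c(d, B, Ct))
  tp <- h$tape_new()
  out <- h$tp_cct_attention(h$tp_leaf(tp, Q), h$tp_leaf(tp, K), h$tp_leaf(tp, V), n_heads)
  expect_equal(dim(out$value), c(d, B, Ci))
  # independent re-derivation, head by head, with explicit softmax checks
  Cg <- Ct / n_heads
  ref <- array(0, c(d, B, Ci))
  for (b in 1:B) {
    for (hh in 1:n_heads) {
      cols <- ((hh - 1) * Cg + 1):(hh * Cg)
      L <- t(Q[, b, ]) %*% K[, b, cols] / sqrt(d)
      Ls <- (L - mean(L)) / sqrt(mean((L - mean(L))^2) + 1e-5)
      A <- exp(Ls) / rowSums(exp(Ls))
      expect_equal(rowSums(A), rep(1, Ci), tolerance = 1e-12)
      ref[, b, ] <- ref[, b, ] + V[, b, cols] %*% t(A) / n_heads
    }
  }
  expect_equal(out$value, ref, tolerance = 1e-10)
})

test_that("the CCT preserves token shapes and is deterministic", {
  feats <- make_scales(seed = 3)
  toks <- tokenize_multiscale(feats, c(8, 4, 2, 1))
  p <- cct_params(c(4, 8, 16, 32), n_heads = 4, n_layers = 2, seed = 5)
  out <- cct_forward(toks, p)
  expect_equal(lapply(out, dim), lapply(toks, dim))
  expect_true(all(vapply(out, function(o) all(is.finite(o)), TRUE)))
  expect_identical(cct_forward(toks, p), out)
  # the output actually mixes scales: perturbing scale 4 changes scale 1
  toks2 <- toks
  toks2[[4]] <- toks2[[4]] + 1
  out2 <- cct_forward(toks2, p)
  expect_gt(max(abs(out2[[1]] - out[[1]])), 1e-8)
})

test_that("CCA gates the skip with pooled decoder features and concatenates", {
  set.seed(6)
  dec <- rand_fmap(6, 8, 8)
  skip <- rand_fmap(4, 8, 8)
  W <- matrix(rnorm(24) * 0.3, 6, 4)
  b <- rnorm(4)
  out <- cca_fuse(dec, skip, W, b)
  expect_identical(dim(out), c(10L, 8L, 8L))
  expect_equal(out[1:6, , ], dec)
  gated <- out[7:10, , ]
  expect_true(all(abs(gated) <= abs(skip)))
  # hand evaluation of the gate
  gap <- apply(dec, 1, mean)
  gate <- 1 / (1 + exp(-(as.vector(gap %*% W) + b)))
  for (c in 1:4)
    expect_equal(gated[c, , ], skip[c, , ] * gate[c], tolerance = 1e-10)
  # zero decoder features leave only the bias in the gate
  out0 <- cca_fuse(array(0, c(6, 8, 8)), skip, W, b)
  for (c in 1:4)
    expect_equal(out0[6 + c, , ], skip[c, , ] / (1 + exp(-b[c])), tolerance = 1e-10)
  expect_error(cca_fuse(dec, rand_fmap(4, 4, 4), W, b), "spatial dims differ")
})
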