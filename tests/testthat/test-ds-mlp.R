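# Dual-channel shift MLP: channel split, four-direction spatial shift,
# GMP + 1-d-conv channel gating, split-attention fusion, full block.

test_that("channel split is lossless and rejects odd widths", {
  set.seed(1)
  x <- rand_fmap(4, 3, 5)
  sp <- split_channels(x)
  expect_equal(sp$t1, x[1:2, , , drop = FALSE])
  expect_equal(sp$t2, x[3:4, , , drop = FALSE])
  # concatenating the halves along the channel axis reconstructs the input
  y <- array(0, dim(x))
  y[1:2, , ] <- sp$t1; y[3:4, , ] <- sp$t2
  expect_identical(y, x)
  expect_error(split_channels(rand_fmap(3, 2, 2)), "even")
  xb <- array(rnorm(2 * 6 * 3 * 3), c(2, 6, 3, 3))
  spb <- split_channels(xb)
  expect_identical(dim(spb$t1), c(2L, 3L, 3L, 3L))
})

test_that("spatial shift equals the literal slice-assignment oracle", {
  # the worked 4-channel 2x2 example: channel k holds 4k+1..4k+4
  x <- array(0, c(4, 2, 2))
  for (k in 0:3) x[k + 1, , ] <- matrix(4 * k + 1:4, 2, 2, byrow = TRUE)
  expect_identical(spatial_shift(x), naive_spatial_shift(x))
  set.seed(2)
  for (i in 1:10) {
    C <- 4 * sample(1:2, 1); H <- sample(2:5, 1); W <- sample(2:5, 1)
    x <- rand_fmap(C, H, W)
    expect_identical(spatial_shift(x), naive_spatial_shift(x))
  }
  # constants are invariant under shifting
  xc <- array(2.5, c(8, 4, 4))
  expect_equal(spatial_shift(xc), xc)
  expect_error(spatial_shift(rand_fmap(6, 3, 3)), "divisible by 4")
  # the interior multiset of each channel is preserved (values move, none
  # are created)
  x <- rand_fmap(4, 5, 5)
  y <- spatial_shift(x)
  for (c in 1:4)
    expect_true(all(y[c, , ] %in% x[c, , ]))
})

test_that("channel shift gating matches a from-scratch re-evaluation", {
  set.seed(3)
  for (i in 1:8) {
    C <- sample(2:12, 1); H <- sample(2:6, 1); W <- sample(2:6, 1)
    x <- rand_fmap(C, H, W)
    w <- rnorm(3); b <- rnorm(1)
    expect_equal(channel_shift(x, w, b), naive_channel_shift(x, w, b),
                 tolerance = 1e-6)
  }
  # zero input is annihilated; gates in (0,1) bound the output
  expect_equal(channel_shift(array(0, c(4, 3, 3))), array(0, c(4, 3, 3)))
  x <- rand_fmap(6, 4, 4)
  y <- channel_shift(x, rnorm(3), rnorm(1))
  expect_true(all(abs(y) <= abs(x)))
})

test_that("split attention is a per-channel convex combination", {
  set.seed(4)
  p <- ds_mlp_params(16, seed = 7)
  t1 <- rand_fmap(8, 5, 4); t2 <- rand_fmap(8, 5, 4)
  out <- split_attention(t1, t2, p)
  expect_identical(dim(out), dim(t1))
  expect_equal(out, naive_split_attention(t1, t2, p), tolerance = 1e-6)
  # forcing zero logits gives the exact midpoint of the branches
  p0 <- p
  p0$sa2_W[] <- 0; p0$sa2_b[] <- 0
  expect_equal(split_attention(t1, t2, p0), (t1 + t2) / 2, tolerance = 1e-12)
  expect_error(split_attention(t1, rand_fmap(8, 4, 4), p), "differ")
})

test_that("the full DS-MLP block preserves shape and handles zeros", {
  set.seed(5)
  p <- ds_mlp_params(16, seed = 1)
  x <- rand_fmap(16, 7, 5)
  y <- ds_mlp_forward(x, p)
  expect_identical(dim(y), c(16L, 7L, 5L))
  expect_error(ds_mlp_forward(rand_fmap(12, 4, 4), p), "divisible by 8")
  # zero input: every branch collapses to zero, so the output is the
  # output-projection bias, constant over space
  pb <- p
  pb$out_b <- rnorm(16)
  z <- ds_mlp_forward(array(0, c(16, 4, 4)), pb)
  for (c in 1:16)
    expect_equal(as.vector(z[c, , ]), rep(pb$out_b[c], 16), tolerance = 1e-12)
  # batched input agrees with per-image evaluation
  xb <- array(rnorm(2 * 16 * 4 * 4), c(2, 16, 4, 4))
  yb <- ds_mlp_forward(xb, p)
  expect_equal(yb[1, , , ], ds_mlp_forward(xb[1, , , ], p), tolerance = 1e-12)
})
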