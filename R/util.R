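# Layout helpers. The public API follows the channel-first convention common
# in segmentation work: a feature map is [C, H, W], optionally with a leading
# batch axis [B, C, H, W]. Internally everything runs in [H, W, B, C].

as_hwbc <- function(x, name = "x") {
  d <- dim(x)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop(name, " must be a [C, H, W] or [B, C, H, W] array")
  if (any(!is.finite(x))) stop(name, " contains non-finite values")
  if (length(d) == 3L) {
    y <- aperm(x, c(2L, 3L, 1L))
    dim(y) <- c(d[2], d[3], 1L, d[1])
    list(arr = y, batched = FALSE)
  } else {
    list(arr = aperm(x, c(3L, 4L, 1L, 2L)), batched = TRUE)
  }
}

from_hwbc <- function(arr, batched) {
  d <- dim(arr)
  if (!batched) {
    dim(arr) <- c(d[1], d[2], d[4])
    aperm(arr, c(3L, 1L, 2L))
  } else {
    aperm(arr, c(3L, 4L, 1L, 2L))
  }
}

# run a tape computation on a plain array and return a plain array in the
# caller's layout
run_on_array <- function(x, fn) {
  conv <- as_hwbc(x)
  tp <- tape_new()
  out <- fn(tp_leaf(tp, conv$arr), tp)
  from_hwbc(out$value, conv$batched)
}

bn_state_new <- function(C) {
  e <- new.env(parent = emptyenv())
  e$mean <- rep(0, C)
  e$var <- rep(1, C)
  e
}
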