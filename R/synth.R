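# Seeded synthetic histopathology-style image/mask generators.
#
# Two styles are emulated: "gland" (a few large, deformed, lumen-bearing
# blobs whose intensity sits close to a textured background, with blurred
# borders — the low-contrast regime where attention gating should help) and
# "nuclei" (many small, partly touching elliptical nuclei on a stain-like
# background). Masks are exact by construction; all randomness is seeded.

#' Synthetic dataset parameters
#'
#' @param style `"gland"` or `"nuclei"`.
#' @param image_size square image size; defaults: 64 (gland), 96 (nuclei).
#' @param n_objects integer range (length 2) of object counts per image;
#'   defaults: `c(2, 6)` glands, `c(30, 120)` nuclei.
#' @param obj_scale range of object radii as a fraction of image size.
#' @param blur_sigma Gaussian blur applied to the rendered image (pixels).
#' @param bg_texture amplitude of the smooth background texture.
#' @param intensity_gap mean grey-level gap between foreground and
#'   background; kept small for glands so boundaries stay faint.
#' @param touch_frac fraction of nuclei placed touching another nucleus
#'   (nuclei style only).
#' @param fg_range admissible foreground fraction of a mask; images are
#'   redrawn until the mask lands inside this range.
#' @param seed base seed; identical parameters give bitwise-identical data.
#' @return an object of class `synth_params`.
#' @export
synth_params <- function(style = c("gland", "nuclei"), image_size = NULL,
                         n_objects = NULL, obj_scale = NULL,
                         blur_sigma = NULL, bg_texture = 0.08,
                         intensity_gap = NULL, touch_frac = 0.3,
                         fg_range = NULL, seed = 1L) {
  style <- match.arg(style)
  defaults <- if (style == "gland") {
    list(image_size = 64L, n_objects = c(2L, 6L), obj_scale = c(0.12, 0.28),
         blur_sigma = 1.5, intensity_gap = 0.15, fg_range = c(0.05, 0.60))
  } else {
    list(image_size = 96L, n_objects = c(30L, 120L), obj_scale = c(0.015, 0.035),
         blur_sigma = 0.6, intensity_gap = 0.35, fg_range = c(0.03, 0.50))
  }
  p <- list(style = style,
            image_size = image_size %||% defaults$image_size,
            n_objects = n_objects %||% defaults$n_objects,
            obj_scale = obj_scale %||% defaults$obj_scale,
            blur_sigma = blur_sigma %||% defaults$blur_sigma,
            bg_texture = bg_texture,
            intensity_gap = intensity_gap %||% defaults$intensity_gap,
            touch_frac = touch_frac, fg_range = fg_range %||% defaults$fg_range,
            seed = as.integer(seed))
  if (p$image_size < 16) stop("image_size too small")
  if (p$n_objects[1] < 1 || p$n_objects[2] < p$n_objects[1])
    stop("invalid n_objects range")
  structure(p, class = "synth_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw one integer from an inclusive range (safe when lo == hi, where
# sample() would silently draw from 1:lo)
sample_range <- function(lo, hi) {
  if (lo >= hi) return(lo)
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# separable Gaussian blur via a reflect-padded band matrix
gauss_blur <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  n <- nrow(mat)
  r <- max(1L, ceiling(3 * sigma))
  w <- dnorm(seq(-r, r), sd = sigma)
  w <- w / sum(w)
  B <- matrix(0, n, n)
  idx <- seq_len(n)
  for (o in -r:r) {
    j <- reflect_idx(idx + o, n)
    B[cbind(idx, j)] <- B[cbind(idx, j)] + w[o + r + 1]
  }
  B %*% mat %*% t(B)
}

reflect_idx <- function(v, n) {
  if (n == 1L) return(rep(1L, length(v)))
  v2 <- abs(v - 1) %% (2L * (n - 1L))
  as.integer(ifelse(v2 < n, v2 + 1, 2 * n - 1 - v2))
}

# smooth low-frequency texture field in [-1, 1]
smooth_noise <- function(n, cell = 8L) {
  k <- max(2L, n %/% cell)
  g <- matrix(runif(k * k, -1, 1), k, k)
  # bilinear resize k -> n
  xs <- seq(1, k, length.out = n)
  lo <- pmin(floor(xs), k - 1L)
  fr <- xs - lo
  A <- matrix(0, n, k)
  A[cbind(seq_len(n), lo)] <- 1 - fr
  A[cbind(seq_len(n), lo + 1L)] <- A[cbind(seq_len(n), lo + 1L)] + fr
  A %*% g %*% t(A)
}

render_gland <- function(p) {
  S <- p$image_size
  xs <- matrix(rep(seq_len(S), S), S, S)        # row coordinate
  ys <- t(xs)                                   # column coordinate
  for (try in 1:25) {
    m <- sample_range(p$n_objects[1], p$n_objects[2])
    mask <- matrix(FALSE, S, S)
    lumen <- matrix(FALSE, S, S)
    for (k in seq_len(m)) {
      cx <- runif(1, 0.18, 0.82) * S
      cy <- runif(1, 0.18, 0.82) * S
      r0 <- runif(1, p$obj_scale[1], p$obj_scale[2]) * S
      aj <- runif(3, -0.12, 0.12)
      ph <- runif(3, 0, 2 * pi)
      dx <- xs - cx; dy <- ys - cy
      th <- atan2(dy, dx)
      rr <- sqrt(dx * dx + dy * dy)
      rb <- r0 * (1 + aj[1] * cos(2 * th + ph[1]) + aj[2] * cos(3 * th + ph[2]) +
                    aj[3] * cos(4 * th + ph[3]))
      blob <- rr <= rb
      mask <- mask | blob
      lumen <- lumen | (rr <= 0.45 * rb)
    }
    fg <- mean(mask)
    if (fg >= p$fg_range[1] && fg <= p$fg_range[2]) break
  }
  bg_base <- 0.55
  tex <- smooth_noise(S) * p$bg_texture
  grey <- bg_base + tex
  grey[mask] <- bg_base + p$intensity_gap + 0.5 * tex[mask]
  # lumens look like background: the gland interior reverts towards it
  grey[lumen] <- bg_base + 0.5 * tex[lumen]
  grey <- grey + matrix(rnorm(S * S, 0, 0.02), S, S)
  grey <- gauss_blur(grey, p$blur_sigma)
  img <- array(0, c(3, S, S))
  img[1, , ] <- grey * 0.95 + 0.04
  img[2, , ] <- grey * 0.78 + 0.02
  img[3, , ] <- grey * 0.90 + 0.03
  list(image = pmin(pmax(img, 0), 1), mask = mask * 1L)
}

render_nuclei <- function(p) {
  S <- p$image_size
  xs <- matrix(rep(seq_len(S), S), S, S)
  ys <- t(xs)
  for (try in 1:25) {
    m <- sample_range(p$n_objects[1], p$n_objects[2])
    n_touch <- floor(p$touch_frac * m)
    n_free <- max(1L, m - n_touch)
    n_touch <- m - n_free
    # ellipse params: cx, cy, major a, minor b, orientation th
    ell <- matrix(0, 0, 5)
    new_axes <- function() {
      a <- runif(1, p$obj_scale[1], p$obj_scale[2]) * S
      c(a = a, b = a * runif(1, 0.65, 1), th = runif(1, 0, pi))
    }
    # free-standing nuclei keep a separation margin so only the configured
    # fraction of nuclei touches another one
    for (k in seq_len(n_free)) {
      ax <- new_axes()
      for (t2 in 1:80) {
        cx <- runif(1, 0.06, 0.94) * S
        cy <- runif(1, 0.06, 0.94) * S
        if (nrow(ell) == 0) break
        dd <- sqrt((ell[, 1] - cx)^2 + (ell[, 2] - cy)^2)
        if (all(dd > ell[, 3] + ax[1] + 3)) break
      }
      ell <- rbind(ell, c(cx, cy, ax))
    }
    # touching nuclei attach to distinct hosts, offset by less than the sum
    # of the minor radii (guaranteed overlap), in the direction pointing
    # away from the host's nearest neighbour so no third nucleus is hit
    hosts <- if (n_touch > 0) sample.int(n_free, n_touch, replace = n_touch > n_free) else integer(0)
    for (k in seq_len(n_touch)) {
      h <- hosts[k]
      ax <- new_axes()
      dctr <- 0.9 * (ell[h, 4] + ax[2])
      best <- NULL
      for (t2 in 1:60) {
        ang <- runif(1, 0, 2 * pi)
        cand <- ell[h, 1:2] + dctr * c(cos(ang), sin(ang))
        others <- seq_len(nrow(ell))[-h]
        if (!length(others)) { best <- cand; break }
        dd <- sqrt((ell[others, 1] - cand[1])^2 + (ell[others, 2] - cand[2])^2)
        # touch only the host: stay clear of every other nucleus
        if (all(dd > ell[others, 3] + ax[1] + 1)) { best <- cand; break }
        if (is.null(best)) best <- cand
      }
      ell <- rbind(ell, c(best, ax))
    }
    mask <- matrix(FALSE, S, S)
    jit <- matrix(0, S, S)
    for (k in seq_len(nrow(ell))) {
      dx <- xs - ell[k, 1]; dy <- ys - ell[k, 2]
      u <- dx * cos(ell[k, 5]) + dy * sin(ell[k, 5])
      v <- -dx * sin(ell[k, 5]) + dy * cos(ell[k, 5])
      e <- (u / ell[k, 3])^2 + (v / ell[k, 4])^2 <= 1
      mask <- mask | e
      jit[e] <- runif(1, -0.08, 0.08)   # per-nucleus stain jitter
    }
    fg <- mean(mask)
    if (fg >= p$fg_range[1] && fg <= p$fg_range[2]) break
  }
  tex <- smooth_noise(S) * p$bg_texture
  base <- list(r = 0.86, g = 0.72, b = 0.80)     # eosin-like background
  nuc <- list(r = 0.38, g = 0.26, b = 0.52)      # hematoxylin-like nuclei
  img <- array(0, c(3, S, S))
  mk <- mask == 1
  for (ci in 1:3) {
    ch <- matrix(base[[ci]], S, S) + tex
    ch[mk] <- nuc[[ci]] + jit[mk] + 0.3 * tex[mk]
    ch <- ch + matrix(rnorm(S * S, 0, 0.015), S, S)
    img[ci, , ] <- gauss_blur(ch, p$blur_sigma)
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask * 1L)
}

#' Generate a seeded synthetic dataset
#'
#' @param p a [synth_params] object.
#' @param n number of image/mask pairs (`n >= 1`).
#' @return list of `SegSample`s: each a list with `image` (`[3, H, W]`, in
#'   `[0, 1]`), `mask` (`[H, W]` 0/1) and `id`.
#' @export
generate_dataset <- function(p, n) {
  stopifnot(inherits(p, "synth_params"), n >= 1)
  lapply(seq_len(n), function(k) {
    set.seed((p$seed + 7919L * k) %% .Machine$integer.max)
    s <- if (p$style == "gland") render_gland(p) else render_nuclei(p)
    s$id <- sprintf("%s_%04d", p$style, k)
    s
  })
}

# bilinear sampling of a matrix at fractional coordinates; outside pixels
# either reflect (images) or contribute zero (masks)
sample_bilinear <- function(mat, xi, yi, fill = c("reflect", "zero")) {
  fill <- match.arg(fill)
  n <- nrow(mat); m <- ncol(mat)
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  gv <- function(ix, iy) {
    if (fill == "reflect") {
      mat[cbind(reflect_idx(ix, n), reflect_idx(iy, m))]
    } else {
      ok <- ix >= 1 & ix <= n & iy >= 1 & iy <= m
      out <- numeric(length(ix))
      out[ok] <- mat[cbind(ix[ok], iy[ok])]
      out
    }
  }
  v <- gv(x0, y0) * (1 - fx) * (1 - fy) + gv(x0 + 1, y0) * fx * (1 - fy) +
    gv(x0, y0 + 1) * (1 - fx) * fy + gv(x0 + 1, y0 + 1) * fx * fy
  matrix(v, n, m)
}

rotate_mat <- function(mat, angle_deg, fill) {
  if (angle_deg == 0) return(mat)
  n <- nrow(mat); m <- ncol(mat)
  a <- angle_deg * pi / 180
  cx <- (n + 1) / 2; cy <- (m + 1) / 2
  ii <- rep(seq_len(n), m) - cx
  jj <- rep(seq_len(m), each = n) - cy
  xi <- cos(a) * ii - sin(a) * jj + cx
  yi <- sin(a) * ii + cos(a) * jj + cy
  sample_bilinear(mat, xi, yi, fill)
}

#' Augment a sample by flips and rotation
#'
#' Vertical and horizontal flips each occur independently with probability
#' 0.5, followed by rotation through an angle drawn uniformly from
#' `(-max_angle, max_angle)` degrees; the identical transform is applied to
#' image and mask. Image rotation samples with reflect padding, the mask
#' with zero fill, and the mask is re-binarised at 0.5 afterwards.
#'
#' @param s a `SegSample` (list with `image` `[3, H, W]` and `mask`).
#' @param seed optional seed for the transform draw.
#' @param flip_v,flip_h,angle override the random draws (useful for
#'   deterministic round-trip checks).
#' @param max_angle rotation range in degrees (default 30).
#' @return the transformed `SegSample`.
#' @export
augment_sample <- function(s, seed = NULL, flip_v = NULL, flip_h = NULL,
                           angle = NULL, max_angle = 30) {
  if (!is.null(seed)) set.seed(seed)
  flip_v <- flip_v %||% (runif(1) < 0.5)
  flip_h <- flip_h %||% (runif(1) < 0.5)
  angle <- angle %||% runif(1, -max_angle, max_angle)
  img <- s$image; msk <- s$mask
  if (flip_v) {
    img <- img[, rev(seq_len(dim(img)[2])), , drop = FALSE]
    msk <- msk[rev(seq_len(nrow(msk))), , drop = FALSE]
  }
  if (flip_h) {
    img <- img[, , rev(seq_len(dim(img)[3])), drop = FALSE]
    msk <- msk[, rev(seq_len(ncol(msk))), drop = FALSE]
  }
  if (angle != 0) {
    for (ci in seq_len(dim(img)[1]))
      img[ci, , ] <- rotate_mat(img[ci, , ], angle, "reflect")
    msk <- (rotate_mat(msk, angle, "zero") >= 0.5) * 1L
  }
  list(image = img, mask = msk, id = s$id)
}

#' Write / read an image+mask folder dataset
#'
#' Uses the conventional layout `images/<id>.png` (8-bit RGB) and
#' `masks/<id>.png` (8-bit grey, 0 = background, 255 = foreground), the
#' same layout the generic folder reader consumes for real gland/nucleus
#' benchmarks.
#'
#' @param samples list of `SegSample`s; @param dir target directory.
#' @export
write_dataset <- function(samples, dir) {
  dir.create(file.path(dir, "images"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), recursive = TRUE, showWarnings = FALSE)
  for (s in samples) {
    png::writePNG(aperm(s$image, c(2, 3, 1)),
                  file.path(dir, "images", paste0(s$id, ".png")))
    png::writePNG(s$mask * 1.0, file.path(dir, "masks", paste0(s$id, ".png")))
  }
  invisible(dir)
}

#' @rdname write_dataset
#' @return `read_dataset` returns the list of `SegSample`s.
#' @export
read_dataset <- function(dir) {
  files <- sort(list.files(file.path(dir, "images"), pattern = "\\.(png|PNG)$"))
  if (!length(files)) stop("no images found under ", dir)
  lapply(files, function(f) {
    im <- png::readPNG(file.path(dir, "images", f))
    if (length(dim(im)) == 2L) im <- array(rep(im, 3), c(dim(im), 3))
    mk <- png::readPNG(file.path(dir, "masks", f))
    if (length(dim(mk)) == 3L) mk <- mk[, , 1]
    list(image = aperm(im[, , 1:3, drop = FALSE], c(3, 1, 2)),
         mask = (mk >= 0.5) * 1L,
         id = sub("\\.png$", "", f, ignore.case = TRUE))
  })
}
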