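# Minimal neural-network engine used by the mask-regression CNNs, the
# stacked autoencoder and the attention U-Net.
#
# Convolutions are evaluated as im2col gathers followed by BLAS matrix
# products; backward passes scatter gradients with rowsum(). Everything is
# plain double-precision R, deterministic given the RNG state, and sized for
# the small ROI-scale inputs this package works on (64x64 to 128x128).
#
# Array convention: feature maps are (H, W, C) arrays, column-major; conv
# weights are (kh*kw*Cin) x F matrices whose rows are ordered (di, dj, c) to
# match the im2col column order; batches are lists of arrays except where a
# layer is inherently batched (dense).

# linear indices of all kh x kw x c patches of an hp x wp x c array
im2col_index <- function(hp, wp, c, kh, kw) {
  oh <- hp - kh + 1L
  ow <- wp - kw + 1L
  base <- as.vector(outer(seq_len(oh), (seq_len(ow) - 1L) * hp, "+"))
  off_sp <- as.vector(outer(seq_len(kh) - 1L, (seq_len(kw) - 1L) * hp, "+"))
  off <- as.vector(outer(off_sp, (seq_len(c) - 1L) * (hp * wp), "+"))
  idx <- outer(base, off, "+")
  storage.mode(idx) <- "integer"
  idx
}

pad_array <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2L * p, d[2] + 2L * p, d[3]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), ] <- x
  out
}

unpad_array <- function(x, p, h, w) {
  if (p == 0) return(x)
  x[(p + 1):(p + h), (p + 1):(p + w), , drop = FALSE]
}

as_hwc <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# --- convolution ----------------------------------------------------------

conv_geom <- function(in_shape, kernel, filters, padding) {
  h <- in_shape[1]; w <- in_shape[2]; c <- in_shape[3]
  p <- if (padding == "same") (kernel - 1L) %/% 2L else 0L
  hp <- h + 2L * p; wp <- w + 2L * p
  oh <- hp - kernel + 1L
  ow <- wp - kernel + 1L
  if (oh < 1 || ow < 1) {
    stop(sprintf("convolution kernel %d does not fit %dx%d input",
                 kernel, h, w), call. = FALSE)
  }
  list(kernel = kernel, filters = filters, pad = p,
       in_shape = in_shape, out_shape = c(oh, ow, filters),
       idx = im2col_index(hp, wp, c, kernel, kernel))
}

conv_patches <- function(x, geom) {
  xp <- pad_array(as_hwc(x), geom$pad)
  cpp_gather(xp, geom$idx, nrow(geom$idx), ncol(geom$idx))
}

conv_fwd <- function(x, geom, W, b) {
  patches <- conv_patches(x, geom)
  z <- patches %*% W
  z <- z + rep(b, each = nrow(z))
  list(z = array(z, geom$out_shape), patches = patches)
}

conv_bwd <- function(dz, geom, W, patches, need_dx = TRUE) {
  os <- geom$out_shape
  dz_mat <- matrix(dz, nrow = os[1] * os[2], ncol = os[3])
  dW <- crossprod(patches, dz_mat)
  db <- colSums(dz_mat)
  dx <- NULL
  if (need_dx) {
    dpatch <- tcrossprod(dz_mat, W)
    is <- geom$in_shape
    p <- geom$pad
    hp <- is[1] + 2L * p; wp <- is[2] + 2L * p
    dxp <- cpp_scatter_add(dpatch, geom$idx, hp * wp * is[3])
    dim(dxp) <- c(hp, wp, is[3])
    dx <- unpad_array(dxp, p, is[1], is[2])
  }
  list(dW = dW, db = db, dx = dx)
}

# --- pooling (stride = window size, non-overlapping) ----------------------

pool_geom <- function(in_shape, size) {
  h <- in_shape[1]; w <- in_shape[2]; c <- in_shape[3]
  if (h %% size != 0 || w %% size != 0) {
    stop(sprintf("pool size %d does not divide %dx%d input", size, h, w),
         call. = FALSE)
  }
  oh <- h %/% size; ow <- w %/% size
  tl <- as.vector(outer(
    as.vector(outer((seq_len(oh) - 1L) * size + 1L,
                    (seq_len(ow) - 1L) * size * h, "+")),
    (seq_len(c) - 1L) * (h * w), "+"))
  off <- as.vector(outer(seq_len(size) - 1L, (seq_len(size) - 1L) * h, "+"))
  idx <- outer(tl, off, "+")
  storage.mode(idx) <- "integer"
  list(size = size, in_shape = in_shape, out_shape = c(oh, ow, c), idx = idx)
}

pool_fwd <- function(x, geom, kind) {
  x <- as_hwc(x)
  m <- cpp_gather(x, geom$idx, nrow(geom$idx), ncol(geom$idx))
  if (kind == "avg") {
    list(z = array(rowMeans(m), geom$out_shape), amax = NULL)
  } else {
    j <- max.col(m, ties.method = "first")
    sel <- cbind(seq_len(nrow(m)), j)
    list(z = array(m[sel], geom$out_shape), amax = geom$idx[sel])
  }
}

pool_bwd <- function(dz, geom, kind, amax) {
  dx <- array(0, geom$in_shape)
  dzv <- as.vector(dz)
  if (kind == "avg") {
    dx[as.vector(geom$idx)] <- rep(dzv / geom$size^2, ncol(geom$idx))
  } else {
    dx[amax] <- dzv
  }
  dx
}

# --- transposed convolution, kernel 2x2 stride 2 (non-overlapping) --------

convT_geom <- function(in_shape, filters) {
  h <- in_shape[1]; w <- in_shape[2]; c <- in_shape[3]
  list(filters = filters, in_shape = in_shape,
       out_shape = c(2L * h, 2L * w, filters))
}

# W: C x (4*F), column blocks ordered (d1, d2, d3, d4) per filter where the
# 2x2 output block is filled column-major: (1,1),(2,1),(1,2),(2,2)
convT_fwd <- function(x, geom, W, b) {
  x <- as_hwc(x)
  is <- geom$in_shape
  xm <- matrix(x, nrow = is[1] * is[2], ncol = is[3])
  z4 <- xm %*% W                                  # P x (4F)
  h <- is[1]; w <- is[2]; f <- geom$filters
  z <- array(0, geom$out_shape)
  z4a <- array(z4, c(h, w, 4L, f))
  z[seq(1, 2 * h, 2), seq(1, 2 * w, 2), ] <- z4a[, , 1L, ]
  z[seq(2, 2 * h, 2), seq(1, 2 * w, 2), ] <- z4a[, , 2L, ]
  z[seq(1, 2 * h, 2), seq(2, 2 * w, 2), ] <- z4a[, , 3L, ]
  z[seq(2, 2 * h, 2), seq(2, 2 * w, 2), ] <- z4a[, , 4L, ]
  z <- z + rep(b, each = 4L * h * w)
  list(z = z, xm = xm)
}

convT_bwd <- function(dz, geom, W, xm) {
  is <- geom$in_shape
  h <- is[1]; w <- is[2]; f <- geom$filters
  d4 <- array(0, c(h, w, 4L, f))
  d4[, , 1L, ] <- dz[seq(1, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE]
  d4[, , 2L, ] <- dz[seq(2, 2 * h, 2), seq(1, 2 * w, 2), , drop = FALSE]
  d4[, , 3L, ] <- dz[seq(1, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]
  d4[, , 4L, ] <- dz[seq(2, 2 * h, 2), seq(2, 2 * w, 2), , drop = FALSE]
  d4m <- matrix(d4, nrow = h * w, ncol = 4L * f)
  dW <- crossprod(xm, d4m)
  db <- colSums(matrix(dz, nrow = 4L * h * w, ncol = f))
  dx <- array(tcrossprod(d4m, W), is)
  list(dW = dW, db = db, dx = dx)
}

# --- batch normalization (spatial, per channel) ---------------------------

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

# xs: list of (H,W,C) arrays (the batch). Batch statistics over batch and
# spatial positions during training; running averages at inference.
bn_fwd <- function(xs, bn, training, momentum = 0.99, eps = 1e-3) {
  C <- dim(xs[[1]])[3]
  n_sp <- prod(dim(xs[[1]])[1:2])
  if (training) {
    sums <- Reduce(`+`, lapply(xs, function(x) {
      colSums(matrix(x, ncol = C))
    }))
    n_tot <- n_sp * length(xs)
    mu <- sums / n_tot
    sq <- Reduce(`+`, lapply(xs, function(x) {
      colSums(matrix(x, ncol = C)^2)
    }))
    v <- sq / n_tot - mu^2
    bn$run_mean <- momentum * bn$run_mean + (1 - momentum) * mu
    bn$run_var <- momentum * bn$run_var + (1 - momentum) * v
  } else {
    mu <- bn$run_mean
    v <- bn$run_var
    n_tot <- NA
  }
  inv_sd <- 1 / sqrt(v + eps)
  xhat <- lapply(xs, function(x) {
    d <- dim(x)
    array(sweep(sweep(matrix(x, ncol = C), 2, mu, "-"), 2, inv_sd, "*"), d)
  })
  ys <- lapply(xhat, function(xh) {
    d <- dim(xh)
    array(sweep(sweep(matrix(xh, ncol = C), 2, bn$gamma, "*"),
                2, bn$beta, "+"), d)
  })
  list(ys = ys, xhat = xhat, inv_sd = inv_sd, n_tot = n_tot, bn = bn)
}

bn_bwd <- function(dys, cache, bn) {
  C <- length(bn$gamma)
  n <- cache$n_tot
  dgamma <- Reduce(`+`, Map(function(dy, xh) {
    colSums(matrix(dy, ncol = C) * matrix(xh, ncol = C))
  }, dys, cache$xhat))
  dbeta <- Reduce(`+`, lapply(dys, function(dy) colSums(matrix(dy, ncol = C))))
  sum_dxhat <- Reduce(`+`, lapply(dys, function(dy) {
    colSums(sweep(matrix(dy, ncol = C), 2, bn$gamma, "*"))
  }))
  sum_dxhat_xhat <- Reduce(`+`, Map(function(dy, xh) {
    colSums(sweep(matrix(dy, ncol = C), 2, bn$gamma, "*") *
              matrix(xh, ncol = C))
  }, dys, cache$xhat))
  dxs <- Map(function(dy, xh) {
    d <- dim(dy)
    dxhat <- sweep(matrix(dy, ncol = C), 2, bn$gamma, "*")
    t1 <- sweep(dxhat, 2, sum_dxhat / n, "-")
    t2 <- sweep(matrix(xh, ncol = C), 2, sum_dxhat_xhat / n, "*")
    array(sweep(t1 - t2, 2, cache$inv_sd, "*"), d)
  }, dys, cache$xhat)
  list(dxs = dxs, dgamma = dgamma, dbeta = dbeta)
}

# --- activations ----------------------------------------------------------

act_fwd <- function(z, activation) {
  switch(activation,
         relu = pmax(z, 0),
         sigmoid = 1 / (1 + exp(-z)),
         linear = z,
         stop("unknown activation: ", activation, call. = FALSE))
}

# derivative through the activation given its output a and pre-activation z
act_bwd <- function(da, a, z, activation) {
  switch(activation,
         relu = da * (z > 0),
         sigmoid = da * a * (1 - a),
         linear = da,
         stop("unknown activation: ", activation, call. = FALSE))
}

# --- initializers ---------------------------------------------------------

init_weights <- function(n_in, n_out, fan_in, fan_out, scheme) {
  n <- n_in * n_out
  w <- switch(scheme,
              zero = rep(0, n),
              random_uniform = {
                lim <- sqrt(6 / (fan_in + fan_out))
                stats::runif(n, -lim, lim)
              },
              random_normal = stats::rnorm(n, 0, sqrt(2 / (fan_in + fan_out))),
              stop("unknown init scheme: ", scheme, call. = FALSE))
  matrix(w, n_in, n_out)
}

# --- Adam optimizer -------------------------------------------------------

adam_state <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# In-place fused Adam step (see src/adam.cpp). The optimizer state and the
# parameter tensors are owned exclusively by the training loop, so the
# in-place mutation never leaks: callers observe the update through the
# same list they passed in.
adam_update <- function(params, grads, state, step, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  corr <- sqrt(1 - beta2^step) / (1 - beta1^step)
  lr_t <- lr * corr
  eps_t <- eps * sqrt(1 - beta2^step)
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    cpp_adam_step(params[[nm]], state[[nm]]$m, state[[nm]]$v, g,
                  lr_t, beta1, beta2, eps_t)
  }
  invisible(params)
}
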