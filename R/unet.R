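# Attention U-Net with squeeze-and-excitation recalibration for myocardial
# infarction localization on 128x128x3 ROI inputs.
#
# Topology (encoder / bottleneck / decoder):
#   [conv 3x3 relu, BN, conv 3x3 relu, SE, maxpool] at 32 then 64 channels,
#   bottleneck [conv, BN, conv, SE] at 128 channels, decoder with 2x2
#   transposed convolutions, attention-gated skip connections,
#   concatenation, one 3x3 conv per stage, and a final 1x1 sigmoid conv.
# The attention gate combines a spatial map (two parallel 1x1 convolutions
# on skip and gating features, concatenated, 1x1 conv, sigmoid) with a
# channel map (global average pooling, fully connected layer, sigmoid);
# gated features are the elementwise product of both maps with the skip.

#' Replicate a grayscale frame across three channels
#'
#' @param frame 2-D numeric matrix.
#' @return `(H, W, 3)` array with three identical channels.
#' @export
gray_to_3channel <- function(frame) {
  assert_frame(frame)
  array(rep(frame, 3), c(dim(frame), 3L))
}

# ---- 1x1 convolution (pointwise) -----------------------------------------

conv1x1_fwd <- function(x, W, b = NULL) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  z <- xm %*% W
  if (!is.null(b)) z <- z + rep(b, each = nrow(z))
  array(z, c(d[1], d[2], ncol(W)))
}

conv1x1_bwd <- function(dz, x, W) {
  d <- dim(x)
  xm <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
  dzm <- matrix(dz, nrow = d[1] * d[2], ncol = ncol(W))
  list(dW = crossprod(xm, dzm), db = colSums(dzm),
       dx = array(tcrossprod(dzm, W), d))
}

# ---- squeeze-and-excitation ----------------------------------------------

#' Parameters of a squeeze-and-excitation block
#'
#' Global average pooling squeezes each channel to a scalar descriptor; a
#' two-layer bottleneck (`C -> C/r` ReLU, `C/r -> C` sigmoid) produces
#' per-channel gates in `(0, 1)` that rescale the feature map.
#'
#' @param channels Number of feature channels `C`.
#' @param reduction_ratio Bottleneck reduction ratio `r` (must divide `C`).
#' @param init One of `"random_uniform"`, `"random_normal"`, `"zero"`.
#' @return A list with `W1`, `b1`, `W2`, `b2`.
#' @export
se_params <- function(channels, reduction_ratio = 8,
                      init = "random_uniform") {
  if (channels %% reduction_ratio != 0) {
    stop(sprintf("channels (%d) not divisible by reduction ratio (%d)",
                 channels, reduction_ratio), call. = FALSE)
  }
  mid <- channels %/% reduction_ratio
  list(W1 = init_weights(channels, mid, channels, mid, init),
       b1 = rep(0, mid),
       W2 = init_weights(mid, channels, mid, channels, init),
       b2 = rep(0, channels))
}

#' Squeeze-and-excitation channel recalibration
#'
#' @param f `(H, W, C)` feature map.
#' @param params An [se_params()] list for `C` channels.
#' @return A list with `y` (recalibrated map, same shape), `gates` (the
#'   per-channel sigmoid gates) and an internal cache used by training.
#' @export
se_recalibrate <- function(f, params) {
  d <- dim(f)
  fm <- matrix(f, nrow = d[1] * d[2], ncol = d[3])
  s <- colMeans(fm)
  z1 <- as.numeric(s %*% params$W1 + params$b1)
  h <- pmax(z1, 0)
  z2 <- as.numeric(h %*% params$W2 + params$b2)
  g <- 1 / (1 + exp(-z2))
  y <- array(sweep(fm, 2, g, "*"), d)
  list(y = y, gates = g, cache = list(s = s, z1 = z1, h = h, fm = fm, d = d))
}

se_bwd <- function(dy, out, params) {
  ca <- out$cache
  d <- ca$d
  dym <- matrix(dy, nrow = d[1] * d[2], ncol = d[3])
  dx_direct <- sweep(dym, 2, out$gates, "*")
  dg <- colSums(dym * ca$fm)
  dz2 <- dg * out$gates * (1 - out$gates)
  dW2 <- outer(ca$h, dz2)
  db2 <- dz2
  dh <- as.numeric(params$W2 %*% dz2)
  dz1 <- dh * (ca$z1 > 0)
  dW1 <- outer(ca$s, dz1)
  db1 <- dz1
  ds <- as.numeric(params$W1 %*% dz1)
  dx_pool <- matrix(rep(ds / (d[1] * d[2]), each = d[1] * d[2]),
                    nrow = d[1] * d[2])
  list(dx = array(dx_direct + dx_pool, d),
       grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2))
}

# ---- attention gate ------------------------------------------------------

#' Parameters of an attention gate
#'
#' @param channels Channels `C` of the skip (and gating) features.
#' @param inter_channels Width of the two parallel 1x1 convolutions
#'   (default `C/2`).
#' @param init Initializer name.
#' @return Parameter list (`Wf`, `Wg`, their biases, the spatial `psi`
#'   convolution and the channel-attention `Wc`, `bc`).
#' @export
attention_params <- function(channels, inter_channels = NULL,
                             init = "random_uniform") {
  ic <- inter_channels %||% max(1L, channels %/% 2L)
  list(Wf = init_weights(channels, ic, channels, ic, init),
       bf = rep(0, ic),
       Wg = init_weights(channels, ic, channels, ic, init),
       bg = rep(0, ic),
       Wpsi = init_weights(2L * ic, 1L, 2L * ic, 1L, init),
       bpsi = 0,
       Wc = init_weights(channels, channels, channels, channels, init),
       bc = rep(0, channels))
}

#' Apply an attention gate to skip-connection features
#'
#' Spatial attention: two parallel 1x1 convolutions of the skip features
#' `F` and the gating signal, concatenated, reduced by a 1x1 convolution
#' and squashed by a sigmoid into a per-pixel map in `(0, 1)`. Channel
#' attention: global average pooling of `F`, a fully connected layer and a
#' sigmoid give per-channel weights. The output is
#' `A_spatial * A_channel * F` (both maps broadcast).
#'
#' @param f `(H, W, C)` skip feature map.
#' @param gate `(H, W, C)` gating feature map (decoder side), spatially
#'   aligned with `f`.
#' @param params An [attention_params()] list.
#' @return List with `y` (gated features), `a_spatial` (`H` x `W`),
#'   `a_channel` (length `C`) and a training cache.
#' @export
attention_gate <- function(f, gate, params) {
  d <- dim(f)
  if (!all(dim(gate) == d)) stop("skip and gating shapes differ",
                                 call. = FALSE)
  f1 <- conv1x1_fwd(f, params$Wf, params$bf)
  f2 <- conv1x1_fwd(gate, params$Wg, params$bg)
  s <- array(c(f1, f2), c(d[1], d[2], 2L * dim(f1)[3]))
  zpsi <- conv1x1_fwd(s, params$Wpsi, params$bpsi)
  a_sp <- 1 / (1 + exp(-zpsi[, , 1]))
  fm <- matrix(f, nrow = d[1] * d[2], ncol = d[3])
  pool <- colMeans(fm)
  zc <- as.numeric(pool %*% params$Wc + params$bc)
  a_ch <- 1 / (1 + exp(-zc))
  w <- sweep(matrix(as.vector(a_sp), d[1] * d[2], d[3]), 2, a_ch, "*")
  y <- array(fm * w, d)
  list(y = y, a_spatial = a_sp, a_channel = a_ch,
       cache = list(f1 = f1, f2 = f2, s = s, pool = pool, fm = fm, w = w,
                    d = d))
}

attention_bwd <- function(dy, out, f, gate, params) {
  ca <- out$cache
  d <- ca$d
  np <- d[1] * d[2]
  dym <- matrix(dy, nrow = np, ncol = d[3])
  # through y = fm * a_sp * a_ch
  dfm_direct <- dym * ca$w
  da_sp_mat <- dym * sweep(ca$fm, 2, out$a_channel, "*")
  da_sp <- rowSums(da_sp_mat)
  da_ch <- colSums(dym * ca$fm * matrix(as.vector(out$a_spatial), np, d[3]))
  # channel branch
  dzc <- da_ch * out$a_channel * (1 - out$a_channel)
  dWc <- outer(ca$pool, dzc)
  dbc <- dzc
  dpool <- as.numeric(params$Wc %*% dzc)
  dfm_pool <- matrix(rep(dpool / np, each = np), nrow = np)
  # spatial branch
  asv <- as.vector(out$a_spatial)
  dzpsi <- array(da_sp * asv * (1 - asv), c(d[1], d[2], 1L))
  bw_psi <- conv1x1_bwd(dzpsi, ca$s, params$Wpsi)
  ic <- dim(ca$f1)[3]
  ds1 <- bw_psi$dx[, , seq_len(ic), drop = FALSE]
  ds2 <- bw_psi$dx[, , ic + seq_len(ic), drop = FALSE]
  bw_f <- conv1x1_bwd(ds1, f, params$Wf)
  bw_g <- conv1x1_bwd(ds2, gate, params$Wg)
  df <- array(dfm_direct + dfm_pool, d) + bw_f$dx
  dgate <- bw_g$dx
  list(df = df, dgate = dgate,
       grads = list(Wf = bw_f$dW, bf = bw_f$db,
                    Wg = bw_g$dW, bg = bw_g$db,
                    Wpsi = bw_psi$dW, bpsi = bw_psi$db,
                    Wc = dWc, bc = dbc))
}

# ---- losses (Dice + Focal composite) -------------------------------------

#' Focal loss parameters
#'
#' @param alpha Class-balance weight on the foreground term (default 0.25).
#' @param gamma Focusing exponent (default 2).
#' @param symmetric_alpha Also weight the background term by `1 - alpha`?
#'   The default (`FALSE`) keeps the background term unweighted, exactly as
#'   the loss is defined here.
#' @export
focal_params <- function(alpha = 0.25, gamma = 2, symmetric_alpha = FALSE) {
  stopifnot(alpha > 0, alpha <= 1, gamma >= 0)
  structure(list(alpha = alpha, gamma = gamma,
                 symmetric_alpha = symmetric_alpha),
            class = "focal_params")
}

#' Composite loss specification (Dice and Focal weights)
#'
#' @param dice_weight,focal_weight Non-negative weights summing to 1.
#' @param epsilon Dice smoothing constant.
#' @export
composite_loss_spec <- function(dice_weight = 0.5, focal_weight = 0.5,
                                epsilon = 1) {
  stopifnot(abs(dice_weight + focal_weight - 1) < 1e-12)
  structure(list(dice_weight = dice_weight, focal_weight = focal_weight,
                 epsilon = epsilon),
            class = "composite_loss_spec")
}

#' Soft Dice loss
#'
#' `1 - (2 * sum(y * p) + eps) / (sum(y) + sum(p) + eps)`.
#'
#' @param y_true Binary mask (matrix/array/vector).
#' @param y_pred Probability map, same shape, values in `[0, 1]`.
#' @param epsilon Smoothing constant.
#' @export
dice_loss <- function(y_true, y_pred, epsilon = 1) {
  y <- as.numeric(y_true); p <- as.numeric(y_pred)
  stopifnot(length(y) == length(p))
  1 - (2 * sum(y * p) + epsilon) / (sum(y) + sum(p) + epsilon)
}

#' Focal loss
#'
#' Mean over pixels of
#' `-alpha * (1-p)^gamma * y * log(p) - (1-y) * p^gamma * log(1-p)`;
#' with `alpha = 1, gamma = 0` it reduces to binary cross-entropy.
#'
#' @inheritParams dice_loss
#' @param params A [focal_params()].
#' @param eps Clipping bound keeping `p` inside `(0, 1)`.
#' @export
focal_loss <- function(y_true, y_pred, params = focal_params(),
                       eps = 1e-7) {
  y <- as.numeric(y_true)
  p <- pmin(pmax(as.numeric(y_pred), eps), 1 - eps)
  bg_w <- if (params$symmetric_alpha) 1 - params$alpha else 1
  mean(-params$alpha * (1 - p)^params$gamma * y * log(p) -
         bg_w * (1 - y) * p^params$gamma * log(1 - p))
}

#' Composite Dice + Focal loss
#'
#' `dice_weight * DiceLoss + focal_weight * FocalLoss` (0.5/0.5 by
#' default).
#'
#' @inheritParams focal_loss
#' @param spec A [composite_loss_spec()].
#' @param fp A [focal_params()].
#' @export
total_loss <- function(y_true, y_pred, spec = composite_loss_spec(),
                       fp = focal_params()) {
  spec$dice_weight * dice_loss(y_true, y_pred, spec$epsilon) +
    spec$focal_weight * focal_loss(y_true, y_pred, fp)
}

# gradient of the composite loss wrt p over a batch (flattened vectors)
total_loss_grad <- function(y, p, spec, fp, eps = 1e-7) {
  n <- length(y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  s <- sum(y * pc); a <- sum(y) + sum(pc)
  ddice <- -(2 * y * (a + spec$epsilon) - (2 * s + spec$epsilon)) /
    (a + spec$epsilon)^2
  g <- fp$gamma
  bg_w <- if (fp$symmetric_alpha) 1 - fp$alpha else 1
  fg_focus <- if (g > 0) g * (1 - pc)^(g - 1) * log(pc) else 0
  bg_focus <- if (g > 0) g * pc^(g - 1) * log(1 - pc) else 0
  dfocal_fg <- -fp$alpha * y * ((1 - pc)^g / pc - fg_focus)
  dfocal_bg <- -bg_w * (1 - y) * (bg_focus - pc^g / (1 - pc))
  spec$dice_weight * ddice +
    spec$focal_weight * (dfocal_fg + dfocal_bg) / n
}

# ---- model construction --------------------------------------------------

mi_geoms <- function() {
  list(
    c1 = conv_geom(c(128L, 128L, 3L), 3L, 32L, "same"),
    c2 = conv_geom(c(128L, 128L, 32L), 3L, 32L, "same"),
    p1 = pool_geom(c(128L, 128L, 32L), 2L),
    c3 = conv_geom(c(64L, 64L, 32L), 3L, 64L, "same"),
    c4 = conv_geom(c(64L, 64L, 64L), 3L, 64L, "same"),
    p2 = pool_geom(c(64L, 64L, 64L), 2L),
    c5 = conv_geom(c(32L, 32L, 64L), 3L, 128L, "same"),
    c6 = conv_geom(c(32L, 32L, 128L), 3L, 128L, "same"),
    t1 = convT_geom(c(32L, 32L, 128L), 64L),
    c7 = conv_geom(c(64L, 64L, 128L), 3L, 64L, "same"),
    t2 = convT_geom(c(64L, 64L, 64L), 32L),
    c8 = conv_geom(c(128L, 128L, 64L), 3L, 32L, "same"),
    c9 = conv_geom(c(128L, 128L, 32L), 1L, 1L, "valid"))
}

mi_conv_init <- function(geom, init) {
  k <- geom$kernel
  cin <- geom$in_shape[3]
  f <- geom$filters
  list(W = init_weights(k * k * cin, f, k * k * cin, k * k * f, init),
       b = rep(0, f))
}

#' Build the attention U-Net for infarct localization
#'
#' Constructs the full parameter set (convolutions, batch-norm, SE blocks,
#' attention gates, transposed convolutions) for the 128x128x3 input
#' topology. Initialization is drawn from the current RNG state of the
#' caller unless a seed is given.
#'
#' @param seed Optional integer seed for the initialization draws.
#' @param reduction_ratio SE bottleneck ratio.
#' @param init Initializer name.
#' @return An object of class `cineseg_mi_model`.
#' @export
build_mi_model <- function(seed = NULL, reduction_ratio = 8,
                           init = "random_uniform") {
  build <- function() {
    g <- mi_geoms()
    params <- list(
      c1 = mi_conv_init(g$c1, init), bn1 = bn_init(32L),
      c2 = mi_conv_init(g$c2, init),
      se1 = se_params(32L, reduction_ratio, init),
      c3 = mi_conv_init(g$c3, init), bn2 = bn_init(64L),
      c4 = mi_conv_init(g$c4, init),
      se2 = se_params(64L, reduction_ratio, init),
      c5 = mi_conv_init(g$c5, init), bn3 = bn_init(128L),
      c6 = mi_conv_init(g$c6, init),
      se3 = se_params(128L, reduction_ratio, init),
      t1 = list(W = init_weights(128L, 4L * 64L, 128L, 4L * 64L, init),
                b = rep(0, 64L)),
      ag1 = attention_params(64L, init = init),
      c7 = mi_conv_init(g$c7, init),
      t2 = list(W = init_weights(64L, 4L * 32L, 64L, 4L * 32L, init),
                b = rep(0, 32L)),
      ag2 = attention_params(32L, init = init),
      c8 = mi_conv_init(g$c8, init),
      c9 = mi_conv_init(g$c9, init))
    structure(list(geoms = g, params = params,
                   reduction_ratio = reduction_ratio),
              class = "cineseg_mi_model")
  }
  if (is.null(seed)) build() else with_phantom_seed(seed, build())
}

#' Layer-by-layer shape audit of the attention U-Net
#'
#' Walks the built model's geometry and reports every layer with its output
#' shape, kernel and activation — the programmatic counterpart of the
#' architecture table.
#'
#' @param model A `cineseg_mi_model` (a fresh one is built by default).
#' @return A tibble with columns `block`, `layer`, `out_h`, `out_w`,
#'   `out_c`, `kernel`, `activation`.
#' @export
mi_shape_audit <- function(model = build_mi_model(seed = 1L)) {
  g <- model$geoms
  row <- function(block, layer, shape, kernel = NA, activation = NA) {
    tibble::tibble(block = block, layer = layer,
                   out_h = shape[1], out_w = shape[2], out_c = shape[3],
                   kernel = kernel, activation = activation)
  }
  dplyr::bind_rows(
    row("input", "input", c(128L, 128L, 3L)),
    row("encoder", "conv", g$c1$out_shape, 3, "relu"),
    row("encoder", "batch_norm", g$c1$out_shape),
    row("encoder", "conv", g$c2$out_shape, 3, "relu"),
    row("encoder", "se_block", g$c2$out_shape),
    row("encoder", "max_pool", g$p1$out_shape, 2),
    row("encoder", "conv", g$c3$out_shape, 3, "relu"),
    row("encoder", "batch_norm", g$c3$out_shape),
    row("encoder", "conv", g$c4$out_shape, 3, "relu"),
    row("encoder", "se_block", g$c4$out_shape),
    row("encoder", "max_pool", g$p2$out_shape, 2),
    row("bottleneck", "conv", g$c5$out_shape, 3, "relu"),
    row("bottleneck", "batch_norm", g$c5$out_shape),
    row("bottleneck", "conv", g$c6$out_shape, 3, "relu"),
    row("bottleneck", "se_block", g$c6$out_shape),
    row("decoder", "conv_transpose", g$t1$out_shape, 2),
    row("decoder", "attention_gate", g$t1$out_shape, NA, "sigmoid"),
    row("decoder", "concatenate",
        c(g$t1$out_shape[1:2], 2L * g$t1$out_shape[3])),
    row("decoder", "conv", g$c7$out_shape, 3, "relu"),
    row("decoder", "conv_transpose", g$t2$out_shape, 2),
    row("decoder", "attention_gate", g$t2$out_shape, NA, "sigmoid"),
    row("decoder", "concatenate",
        c(g$t2$out_shape[1:2], 2L * g$t2$out_shape[3])),
    row("decoder", "conv", g$c8$out_shape, 3, "relu"),
    row("output", "conv", g$c9$out_shape, 1, "sigmoid"))
}

# ---- forward / backward over a batch (list of samples) -------------------

mi_forward <- function(model, xs, training = FALSE) {
  g <- model$geoms
  P <- model$params
  conv_relu <- function(x, geom, pp) {
    fw <- conv_fwd(x, geom, pp$W, pp$b)
    list(z = fw$z, a = pmax(fw$z, 0), x = x)
  }
  # encoder block 1
  c1 <- lapply(xs, conv_relu, geom = g$c1, pp = P$c1)
  bn1 <- bn_fwd(lapply(c1, `[[`, "a"), P$bn1, training)
  if (training) model$params$bn1 <- bn1$bn
  c2 <- lapply(bn1$ys, conv_relu, geom = g$c2, pp = P$c2)
  se1 <- lapply(c2, function(o) se_recalibrate(o$a, P$se1))
  p1 <- lapply(se1, function(o) pool_fwd(o$y, g$p1, "max"))
  # encoder block 2
  c3 <- lapply(p1, function(o) conv_relu(o$z, g$c3, P$c3))
  bn2 <- bn_fwd(lapply(c3, `[[`, "a"), P$bn2, training)
  if (training) model$params$bn2 <- bn2$bn
  c4 <- lapply(bn2$ys, conv_relu, geom = g$c4, pp = P$c4)
  se2 <- lapply(c4, function(o) se_recalibrate(o$a, P$se2))
  p2 <- lapply(se2, function(o) pool_fwd(o$y, g$p2, "max"))
  # bottleneck
  c5 <- lapply(p2, function(o) conv_relu(o$z, g$c5, P$c5))
  bn3 <- bn_fwd(lapply(c5, `[[`, "a"), P$bn3, training)
  if (training) model$params$bn3 <- bn3$bn
  c6 <- lapply(bn3$ys, conv_relu, geom = g$c6, pp = P$c6)
  se3 <- lapply(c6, function(o) se_recalibrate(o$a, P$se3))
  # decoder stage 1
  t1 <- lapply(se3, function(o) convT_fwd(o$y, g$t1, P$t1$W, P$t1$b))
  ag1 <- Map(function(sk, up) attention_gate(sk$y, up$z, P$ag1), se2, t1)
  cat1 <- Map(function(up, gt) {
    array(c(up$z, gt$y), c(64L, 64L, 128L))
  }, t1, ag1)
  c7 <- lapply(cat1, conv_relu, geom = g$c7, pp = P$c7)
  # decoder stage 2
  t2 <- lapply(c7, function(o) convT_fwd(o$a, g$t2, P$t2$W, P$t2$b))
  ag2 <- Map(function(sk, up) attention_gate(sk$y, up$z, P$ag2), se1, t2)
  cat2 <- Map(function(up, gt) {
    array(c(up$z, gt$y), c(128L, 128L, 64L))
  }, t2, ag2)
  c8 <- lapply(cat2, conv_relu, geom = g$c8, pp = P$c8)
  c9 <- lapply(c8, function(o) conv_fwd(o$a, g$c9, P$c9$W, P$c9$b))
  probs <- lapply(c9, function(o) 1 / (1 + exp(-o$z[, , 1])))
  list(probs = probs, model = model,
       cache = list(xs = xs, c1 = c1, bn1 = bn1, c2 = c2, se1 = se1,
                    p1 = p1, c3 = c3, bn2 = bn2, c4 = c4, se2 = se2,
                    p2 = p2, c5 = c5, bn3 = bn3, c6 = c6, se3 = se3,
                    t1 = t1, ag1 = ag1, cat1 = cat1, c7 = c7, t2 = t2,
                    ag2 = ag2, cat2 = cat2, c8 = c8, c9 = c9))
}

# accumulate a conv layer's backward over the batch
acc_conv_bwd <- function(dzs, geom, pp, xs, need_dx = TRUE) {
  dW <- pp$W * 0; db <- pp$b * 0
  dxs <- vector("list", length(dzs))
  for (k in seq_along(dzs)) {
    xp <- pad_array(as_hwc(xs[[k]]), geom$pad)
    patches <- matrix(xp[geom$idx], nrow = nrow(geom$idx))
    bw <- conv_bwd(dzs[[k]], geom, pp$W, patches, need_dx)
    dW <- dW + bw$dW; db <- db + bw$db
    if (need_dx) dxs[[k]] <- bw$dx
  }
  list(dW = dW, db = db, dxs = dxs)
}

mi_backward <- function(model, fw, dprobs) {
  g <- model$geoms
  P <- model$params
  ca <- fw$cache
  B <- length(dprobs)
  grads <- rapply(P, function(p) p * 0, how = "replace")
  add_g <- function(tag, gl) {
    for (nm in names(gl)) grads[[tag]][[nm]] <<- grads[[tag]][[nm]] + gl[[nm]]
  }
  relu_bwd_list <- function(dlist, convs) {
    Map(function(dz, o) dz * (o$z > 0), dlist, convs)
  }
  # output conv (sigmoid)
  dz9 <- Map(function(dp, pmap) {
    array(dp * pmap * (1 - pmap), c(128L, 128L, 1L))
  }, dprobs, fw$probs)
  bw9 <- acc_conv_bwd(dz9, g$c9, P$c9, lapply(ca$c8, `[[`, "a"))
  add_g("c9", list(W = bw9$dW, b = bw9$db))
  # c8
  dz8 <- relu_bwd_list(bw9$dxs, ca$c8)
  bw8 <- acc_conv_bwd(dz8, g$c8, P$c8, ca$cat2)
  add_g("c8", list(W = bw8$dW, b = bw8$db))
  # split cat2 -> (t2 up, ag2 gated)
  dt2 <- lapply(bw8$dxs, function(d) d[, , 1:32, drop = FALSE])
  dag2 <- lapply(bw8$dxs, function(d) d[, , 33:64, drop = FALSE])
  # attention gate 2
  dskip1 <- vector("list", B)  # into se1 outputs
  for (k in seq_len(B)) {
    bw <- attention_bwd(dag2[[k]], ca$ag2[[k]], ca$se1[[k]]$y,
                        ca$t2[[k]]$z, P$ag2)
    add_g("ag2", bw$grads)
    dskip1[[k]] <- bw$df
    dt2[[k]] <- dt2[[k]] + bw$dgate
  }
  # transposed conv 2
  dc7a <- vector("list", B)
  for (k in seq_len(B)) {
    bw <- convT_bwd(dt2[[k]], g$t2, P$t2$W, ca$t2[[k]]$xm)
    add_g("t2", list(W = bw$dW, b = bw$db))
    dc7a[[k]] <- bw$dx
  }
  # c7
  dz7 <- relu_bwd_list(dc7a, ca$c7)
  bw7 <- acc_conv_bwd(dz7, g$c7, P$c7, ca$cat1)
  add_g("c7", list(W = bw7$dW, b = bw7$db))
  dt1 <- lapply(bw7$dxs, function(d) d[, , 1:64, drop = FALSE])
  dag1 <- lapply(bw7$dxs, function(d) d[, , 65:128, drop = FALSE])
  # attention gate 1
  dskip2 <- vector("list", B)  # into se2 outputs
  for (k in seq_len(B)) {
    bw <- attention_bwd(dag1[[k]], ca$ag1[[k]], ca$se2[[k]]$y,
                        ca$t1[[k]]$z, P$ag1)
    add_g("ag1", bw$grads)
    dskip2[[k]] <- bw$df
    dt1[[k]] <- dt1[[k]] + bw$dgate
  }
  # transposed conv 1 -> gradient into se3 outputs
  dse3 <- vector("list", B)
  for (k in seq_len(B)) {
    bw <- convT_bwd(dt1[[k]], g$t1, P$t1$W, ca$t1[[k]]$xm)
    add_g("t1", list(W = bw$dW, b = bw$db))
    dse3[[k]] <- bw$dx
  }
  # bottleneck: SE3 <- c6 <- bn3 <- c5 <- pool p2
  dc6a <- vector("list", B)
  for (k in seq_len(B)) {
    bw <- se_bwd(dse3[[k]], ca$se3[[k]], P$se3)
    add_g("se3", bw$grads)
    dc6a[[k]] <- bw$dx
  }
  dz6 <- relu_bwd_list(dc6a, ca$c6)
  bw6 <- acc_conv_bwd(dz6, g$c6, P$c6, ca$bn3$ys)
  add_g("c6", list(W = bw6$dW, b = bw6$db))
  bnb3 <- bn_bwd(bw6$dxs, ca$bn3, P$bn3)
  add_g("bn3", list(gamma = bnb3$dgamma, beta = bnb3$dbeta))
  dz5 <- relu_bwd_list(bnb3$dxs, ca$c5)
  bw5 <- acc_conv_bwd(dz5, g$c5, P$c5, lapply(ca$p2, `[[`, "z"))
  add_g("c5", list(W = bw5$dW, b = bw5$db))
  # pool p2 back into se2 outputs (add skip gradient)
  dse2 <- Map(function(dp, po, dsk) {
    pool_bwd(dp, g$p2, "max", po$amax) + dsk
  }, bw5$dxs, ca$p2, dskip2)
  # encoder block 2
  dc4a <- vector("list", B)
  for (k in seq_len(B)) {
    bw <- se_bwd(dse2[[k]], ca$se2[[k]], P$se2)
    add_g("se2", bw$grads)
    dc4a[[k]] <- bw$dx
  }
  dz4 <- relu_bwd_list(dc4a, ca$c4)
  bw4 <- acc_conv_bwd(dz4, g$c4, P$c4, ca$bn2$ys)
  add_g("c4", list(W = bw4$dW, b = bw4$db))
  bnb2 <- bn_bwd(bw4$dxs, ca$bn2, P$bn2)
  add_g("bn2", list(gamma = bnb2$dgamma, beta = bnb2$dbeta))
  dz3 <- relu_bwd_list(bnb2$dxs, ca$c3)
  bw3 <- acc_conv_bwd(dz3, g$c3, P$c3, lapply(ca$p1, `[[`, "z"))
  add_g("c3", list(W = bw3$dW, b = bw3$db))
  dse1 <- Map(function(dp, po, dsk) {
    pool_bwd(dp, g$p1, "max", po$amax) + dsk
  }, bw3$dxs, ca$p1, dskip1)
  # encoder block 1
  dc2a <- vector("list", B)
  for (k in seq_len(B)) {
    bw <- se_bwd(dse1[[k]], ca$se1[[k]], P$se1)
    add_g("se1", bw$grads)
    dc2a[[k]] <- bw$dx
  }
  dz2 <- relu_bwd_list(dc2a, ca$c2)
  bw2 <- acc_conv_bwd(dz2, g$c2, P$c2, ca$bn1$ys)
  add_g("c2", list(W = bw2$dW, b = bw2$db))
  bnb1 <- bn_bwd(bw2$dxs, ca$bn1, P$bn1)
  add_g("bn1", list(gamma = bnb1$dgamma, beta = bnb1$dbeta))
  dz1 <- relu_bwd_list(bnb1$dxs, ca$c1)
  bw1 <- acc_conv_bwd(dz1, g$c1, P$c1, ca$xs, need_dx = FALSE)
  add_g("c1", list(W = bw1$dW, b = bw1$db))
  grads
}

# flatten nested param/grad lists for the Adam updates
flatten_params <- function(p) {
  out <- list()
  for (tag in names(p)) {
    for (nm in names(p[[tag]])) {
      out[[paste(tag, nm, sep = ".")]] <- p[[tag]][[nm]]
    }
  }
  out
}

# ---- training ------------------------------------------------------------

#' Training configuration for the infarct model
#'
#' Adam with learning rate 1e-4, early stopping on validation loss with
#' patience 5, and plateau learning-rate reduction (factor 0.5, patience 3,
#' also monitored on validation loss).
#'
#' @param learning_rate Initial Adam learning rate.
#' @param max_epochs Epoch cap (early stopping usually ends training first).
#' @param batch_size Minibatch size.
#' @param early_stop_patience Epochs without validation improvement before
#'   stopping.
#' @param lr_reduce_factor Multiplier applied to the learning rate on a
#'   plateau.
#' @param lr_reduce_patience Epochs without improvement before a reduction.
#' @param seed Integer seed.
#' @export
mi_train_config <- function(learning_rate = 1e-4, max_epochs = 100L,
                            batch_size = 4L, early_stop_patience = 5L,
                            lr_reduce_factor = 0.5, lr_reduce_patience = 3L,
                            seed = 1L) {
  stopifnot(early_stop_patience >= 1, lr_reduce_patience >= 1)
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 early_stop_patience = as.integer(early_stop_patience),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_reduce_patience = as.integer(lr_reduce_patience),
                 seed = as.integer(seed)),
            class = "mi_train_config")
}

#' One step of the early-stopping / LR-plateau controller
#'
#' Pure state machine shared by [train_mi_model()]: an epoch whose
#' validation loss improves on the best so far resets both patience
#' counters; otherwise both counters advance, the learning rate is halved
#' (by `lr_reduce_factor`) whenever the plateau counter reaches its
#' patience, and `stop` is raised when the early-stopping counter reaches
#' its patience.
#'
#' @param state List with `best`, `es_wait`, `lr_wait`, `lr`, `stop`
#'   (initialize with `best = Inf`, zero counters).
#' @param val_loss Validation loss of the finished epoch.
#' @param config An [mi_train_config()].
#' @return The updated state.
#' @export
callback_step <- function(state, val_loss, config) {
  if (val_loss < state$best) {
    state$best <- val_loss
    state$es_wait <- 0L
    state$lr_wait <- 0L
  } else {
    state$es_wait <- state$es_wait + 1L
    state$lr_wait <- state$lr_wait + 1L
    if (state$lr_wait >= config$lr_reduce_patience) {
      state$lr <- state$lr * config$lr_reduce_factor
      state$lr_wait <- 0L
    }
  }
  if (state$es_wait >= config$early_stop_patience) state$stop <- TRUE
  state
}

mi_eval_loss <- function(model, data, loss_spec, fp) {
  fw <- mi_forward(model, lapply(data, `[[`, "x"), training = FALSE)
  y <- unlist(lapply(data, function(it) as.numeric(it$y)))
  p <- unlist(lapply(fw$probs, as.numeric))
  total_loss(y, p, loss_spec, fp)
}

#' Train the attention U-Net on infarct ROI data
#'
#' Minimizes the composite Dice + Focal loss with Adam, early stopping on
#' validation loss and plateau learning-rate reduction. Deterministic given
#' the seed.
#'
#' @param model A `cineseg_mi_model` (rebuilt under the training seed when
#'   `NULL`).
#' @param train_data,val_data Lists of items `list(x = 128x128x3 array,
#'   y = 128x128 binary mask)`.
#' @param config An [mi_train_config()].
#' @param loss_spec A [composite_loss_spec()].
#' @param fp A [focal_params()].
#' @return A list of class `cineseg_mi_trained`: `model`, `history`
#'   (tibble of epoch, train_loss, val_loss, lr), `config`.
#' @export
train_mi_model <- function(model = NULL, train_data, val_data,
                           config = mi_train_config(),
                           loss_spec = composite_loss_spec(),
                           fp = focal_params()) {
  if (length(train_data) == 0 || length(val_data) == 0) {
    stop("train and validation splits must both be non-empty", call. = FALSE)
  }
  with_phantom_seed(config$seed, {
    if (is.null(model)) model <- build_mi_model()
    flat <- flatten_params(model$params)
    opt <- adam_state(flat)
    step <- 0L
    state <- list(best = Inf, es_wait = 0L, lr_wait = 0L,
                  lr = config$learning_rate, stop = FALSE)
    history <- list()
    n <- length(train_data)
    bs <- min(config$batch_size, n)
    for (epoch in seq_len(config$max_epochs)) {
      ord <- sample(n)
      batch_losses <- c()
      for (b0 in seq(1, n, by = bs)) {
        ids <- ord[b0:min(b0 + bs - 1, n)]
        xs <- lapply(train_data[ids], `[[`, "x")
        ys <- lapply(train_data[ids], `[[`, "y")
        fw <- mi_forward(model, xs, training = TRUE)
        model <- fw$model  # running BN statistics
        yv <- unlist(lapply(ys, as.numeric))
        pv <- unlist(lapply(fw$probs, as.numeric))
        L <- total_loss(yv, pv, loss_spec, fp)
        if (!is.finite(L)) {
          stop(sprintf("non-finite infarct-model loss at epoch %d", epoch),
               call. = FALSE)
        }
        batch_losses <- c(batch_losses, L)
        dp_all <- total_loss_grad(yv, pv, loss_spec, fp)
        npix <- 128L * 128L
        dprobs <- lapply(seq_along(ids), function(k) {
          matrix(dp_all[(k - 1) * npix + seq_len(npix)], 128L, 128L)
        })
        grads <- mi_backward(model, fw, dprobs)
        step <- step + 1L
        adam_update(flatten_params(model$params), flatten_params(grads),
                    opt, step, state$lr)
      }
      val_loss <- mi_eval_loss(model, val_data, loss_spec, fp)
      state <- callback_step(state, val_loss, config)
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = mean(batch_losses),
                                         val_loss = val_loss,
                                         lr = state$lr)
      if (state$stop) break
    }
    structure(list(model = model, history = dplyr::bind_rows(history),
                   config = config, loss_spec = loss_spec, fp = fp),
              class = "cineseg_mi_trained")
  })
}

#' Predict an infarct probability map for one ROI
#'
#' @param trained A `cineseg_mi_trained` (or bare `cineseg_mi_model`).
#' @param roi `(128, 128, 3)` array (use [gray_to_3channel()] on grayscale
#'   input).
#' @return 128x128 probability map in `[0, 1]`.
#' @export
predict_infarct <- function(trained, roi) {
  model <- if (inherits(trained, "cineseg_mi_trained")) {
    trained$model
  } else {
    trained
  }
  stopifnot(inherits(model, "cineseg_mi_model"))
  if (!all(dim(roi) == c(128L, 128L, 3L))) {
    stop("infarct model input must be 128x128x3", call. = FALSE)
  }
  fw <- mi_forward(model, list(roi), training = FALSE)
  fw$probs[[1]]
}
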