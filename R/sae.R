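# Stacked-autoencoder mask refinement.
#
# A three-stage denoising autoencoder over 64x64 segmentation masks: a
# first encoder compresses the flattened mask into a 100-dimensional latent
# code, a second encoder refines that code, and a joint decoder reconstructs
# the mask. The SAE is trained on (degraded mask, clean mask) pairs only —
# never on raw images — and acts purely as shape regularization after the
# CNN stage. The first two stages are pre-trained greedily as autoencoders;
# the full stack is then fine-tuned with the configured loss.

#' Stacked-autoencoder specification
#'
#' @param input_size Flattened mask length (64*64 by default).
#' @param latent1 Width of the first latent stage (100).
#' @param latent2 Width of the second latent stage (100).
#' @return An object of class `sae_spec`.
#' @export
sae_spec <- function(input_size = 4096L, latent1 = 100L, latent2 = 100L) {
  stopifnot(input_size >= 4, latent1 >= 1, latent2 >= 1)
  structure(list(input_size = as.integer(input_size),
                 latent1 = as.integer(latent1),
                 latent2 = as.integer(latent2)),
            class = "sae_spec")
}

#' Hybrid SAE loss parameters
#'
#' The default variant combines mean absolute error with a pixel-wise
#' Bernoulli Kullback-Leibler divergence:
#' `L = (alpha/2) * MAE(y, p) + beta * KL(y || p)`, with `alpha = 1e-4` and
#' `beta = 3`. Alternative variants replace the objective with plain MSE
#' (`"mse_mse"`) or the KL term alone (`"kl_mse"`), mirroring the loss
#' ablation.
#'
#' @param alpha Weight of the MAE term (applied as `alpha/2`).
#' @param beta Weight of the KL term.
#' @param variant One of `"custom_mae_kl"`, `"mse_mse"`, `"kl_mse"`.
#' @export
sae_loss_params <- function(alpha = 1e-4, beta = 3,
                            variant = c("custom_mae_kl", "mse_mse",
                                        "kl_mse")) {
  variant <- match.arg(variant)
  stopifnot(alpha >= 0, beta >= 0)
  structure(list(alpha = alpha, beta = beta, variant = variant),
            class = "sae_loss_params")
}

# pixel-wise Bernoulli KL(y || p), epsilon-clipped, with 0*log(0) = 0
bernoulli_kl <- function(y, p, eps = 1e-7) {
  p <- pmin(pmax(p, eps), 1 - eps)
  yc <- pmin(pmax(y, eps), 1 - eps)
  term1 <- ifelse(y > 0, y * log(yc / p), 0)
  term2 <- ifelse(y < 1, (1 - y) * log((1 - yc) / (1 - p)), 0)
  term1 + term2
}

#' Evaluate the SAE reconstruction loss
#'
#' @param y_true Reference mask (matrix or vector, values in `[0, 1]`).
#' @param y_pred Predicted map, same shape.
#' @param params An [sae_loss_params()].
#' @return Scalar loss.
#' @examples
#' sae_loss(matrix(1), matrix(0.5), sae_loss_params())  # ~ 3 * log(2)
#' @export
sae_loss <- function(y_true, y_pred, params = sae_loss_params()) {
  if (!all(dim(y_true) %||% length(y_true) ==
           dim(y_pred) %||% length(y_pred))) {
    stop("y_true and y_pred shapes differ", call. = FALSE)
  }
  y <- as.numeric(y_true); p <- as.numeric(y_pred)
  switch(params$variant,
         custom_mae_kl = (params$alpha / 2) * mean(abs(y - p)) +
           params$beta * mean(bernoulli_kl(y, p)),
         mse_mse = mean((y - p)^2),
         kl_mse = mean(bernoulli_kl(y, p)))
}

# gradient of the fine-tuning loss wrt p
sae_loss_grad <- function(y, p, params, eps = 1e-7) {
  n <- length(y)
  pc <- pmin(pmax(p, eps), 1 - eps)
  switch(params$variant,
         custom_mae_kl = {
           (params$alpha / 2) * sign(p - y) / n +
             params$beta * (-y / pc + (1 - y) / (1 - pc)) / n
         },
         mse_mse = 2 * (p - y) / n,
         kl_mse = (-y / pc + (1 - y) / (1 - pc)) / n)
}

#' SAE training configuration
#'
#' @param pretrain_epochs Epochs for each greedy pre-training stage.
#' @param finetune_epochs Epochs for end-to-end fine-tuning.
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param seed Integer seed (training is deterministic given the seed).
#' @export
sae_train_config <- function(pretrain_epochs = 10L, finetune_epochs = 30L,
                             learning_rate = 0.001, batch_size = 16L,
                             seed = 1L) {
  structure(list(pretrain_epochs = as.integer(pretrain_epochs),
                 finetune_epochs = as.integer(finetune_epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)),
            class = "sae_train_config")
}

# one dense layer forward/backward on a batch matrix
dense_fwd <- function(X, W, b, activation) {
  Z <- X %*% W + rep(b, each = nrow(X))
  list(Z = Z, A = act_fwd(Z, activation))
}

# train a simple MLP (list of layers: n_in, n_out, activation) with Adam
train_mlp <- function(Xin, Xout, widths, activations, epochs, lr, bs,
                      grad_fn, loss_fn, params0 = NULL) {
  n <- nrow(Xin)
  L <- length(widths) - 1
  params <- params0
  if (is.null(params)) {
    params <- list()
    for (l in seq_len(L)) {
      params[[sprintf("W%d", l)]] <- init_weights(widths[l], widths[l + 1],
                                                  widths[l], widths[l + 1],
                                                  "random_uniform")
      params[[sprintf("b%d", l)]] <- rep(0, widths[l + 1])
    }
  }
  opt <- adam_state(params)
  step <- 0L
  history <- numeric(epochs)
  bs <- min(bs, n)
  for (ep in seq_len(epochs)) {
    ord <- sample(n)
    losses <- c()
    for (b0 in seq(1, n, by = bs)) {
      ids <- ord[b0:min(b0 + bs - 1, n)]
      X <- Xin[ids, , drop = FALSE]
      Y <- Xout[ids, , drop = FALSE]
      acts <- list(X)
      zs <- list()
      for (l in seq_len(L)) {
        fw <- dense_fwd(acts[[l]], params[[sprintf("W%d", l)]],
                        params[[sprintf("b%d", l)]], activations[l])
        zs[[l]] <- fw$Z
        acts[[l + 1]] <- fw$A
      }
      P <- acts[[L + 1]]
      losses <- c(losses, loss_fn(Y, P))
      dA <- grad_fn(Y, P)
      grads <- list()
      for (l in rev(seq_len(L))) {
        dZ <- act_bwd(dA, acts[[l + 1]], zs[[l]], activations[l])
        grads[[sprintf("W%d", l)]] <- crossprod(acts[[l]], dZ)
        grads[[sprintf("b%d", l)]] <- colSums(dZ)
        if (l > 1) dA <- tcrossprod(dZ, params[[sprintf("W%d", l)]])
      }
      step <- step + 1L
      adam_update(params, grads, opt, step, lr)
    }
    history[ep] <- mean(losses)
  }
  list(params = params, history = history)
}

#' Train the three-stage stacked autoencoder on mask pairs
#'
#' Stage 1 pre-trains the first encoder as a denoising autoencoder
#' (degraded in, clean out, MSE); stage 2 pre-trains the second encoder on
#' the stage-1 latent codes; stage 3 fine-tunes the full
#' encoder-encoder-decoder stack end to end with the configured loss
#' variant.
#'
#' @param dataset List of training items, each a list with `corrupted` and
#'   `clean` 64x64 masks (values in `[0, 1]`).
#' @param spec An [sae_spec()].
#' @param loss_params An [sae_loss_params()].
#' @param config An [sae_train_config()].
#' @return An object of class `cineseg_sae` (encoder/decoder weights plus
#'   the fine-tuning loss history).
#' @export
train_sae <- function(dataset, spec = sae_spec(),
                      loss_params = sae_loss_params(),
                      config = sae_train_config()) {
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  stopifnot(inherits(spec, "sae_spec"))
  side <- as.integer(sqrt(spec$input_size))
  Xc <- do.call(rbind, lapply(dataset, function(it) {
    stopifnot(all(dim(it$corrupted) == c(side, side)),
              all(dim(it$clean) == c(side, side)))
    as.vector(it$corrupted)
  }))
  Xk <- do.call(rbind, lapply(dataset, function(it) as.vector(it$clean)))
  with_phantom_seed(config$seed, {
    # stage 1: denoising AE around the first latent code
    s1 <- train_mlp(Xc, Xk,
                    widths = c(spec$input_size, spec$latent1,
                               spec$input_size),
                    activations = c("relu", "sigmoid"),
                    epochs = config$pretrain_epochs,
                    lr = config$learning_rate, bs = config$batch_size,
                    grad_fn = function(Y, P) 2 * (P - Y) / length(Y),
                    loss_fn = function(Y, P) mean((P - Y)^2))
    H1 <- act_fwd(Xc %*% s1$params$W1 + rep(s1$params$b1, each = nrow(Xc)),
                  "relu")
    # stage 2: autoencode the latent codes
    s2 <- train_mlp(H1, H1,
                    widths = c(spec$latent1, spec$latent2, spec$latent1),
                    activations = c("relu", "linear"),
                    epochs = config$pretrain_epochs,
                    lr = config$learning_rate, bs = config$batch_size,
                    grad_fn = function(Y, P) 2 * (P - Y) / length(Y),
                    loss_fn = function(Y, P) mean((P - Y)^2))
    # stage 3: full stack, fine-tuned with the configured loss
    # decoder bias starts at the background log-odds: masks are
    # foreground-sparse, and a background-favouring output prior keeps
    # degenerate (empty) inputs reconstructing as low-energy maps
    params0 <- list(W1 = s1$params$W1, b1 = s1$params$b1,
                    W2 = s2$params$W1, b2 = s2$params$b1,
                    W3 = init_weights(spec$latent2, spec$input_size,
                                      spec$latent2, spec$input_size,
                                      "random_uniform"),
                    b3 = rep(-2, spec$input_size))
    s3 <- train_mlp(Xc, Xk,
                    widths = c(spec$input_size, spec$latent1, spec$latent2,
                               spec$input_size),
                    activations = c("relu", "relu", "sigmoid"),
                    epochs = config$finetune_epochs,
                    lr = config$learning_rate, bs = config$batch_size,
                    grad_fn = function(Y, P) {
                      sae_loss_grad(as.numeric(Y), as.numeric(P), loss_params)
                    },
                    loss_fn = function(Y, P) sae_loss(Y, P, loss_params),
                    params0 = params0)
    structure(list(spec = spec, params = s3$params,
                   loss_params = loss_params, config = config,
                   loss_history = s3$history, side = side),
              class = "cineseg_sae")
  })
}

#' Encode a mask into the SAE's first latent code
#'
#' @param sae A trained `cineseg_sae`.
#' @param mask A mask at the SAE's native side length.
#' @return Numeric vector of length `latent1`.
#' @export
sae_encode <- function(sae, mask) {
  stopifnot(inherits(sae, "cineseg_sae"))
  x <- as.vector(mask)
  as.numeric(act_fwd(x %*% sae$params$W1 + sae$params$b1, "relu"))
}

#' Refine a predicted mask with the trained SAE
#'
#' 32x32 inputs (the CNN's native output) are first upsampled to 64x64 with
#' nearest-neighbour interpolation; the SAE then reconstructs a smoothed
#' probability map in `[0, 1]`.
#'
#' @param sae A trained `cineseg_sae`.
#' @param cnn_mask Binary mask or probability map, 32x32 or 64x64.
#' @return 64x64 probability map.
#' @export
refine_mask <- function(sae, cnn_mask) {
  stopifnot(inherits(sae, "cineseg_sae"))
  m <- cnn_mask
  if (!all(dim(m) == c(sae$side, sae$side))) {
    if (all(m %in% c(0, 1))) {
      m <- resample_mask(m, sae$side)
    } else {
      m <- resample_frame(m, sae$side)
    }
  }
  x <- as.vector(m)
  h1 <- act_fwd(x %*% sae$params$W1 + sae$params$b1, "relu")
  h2 <- act_fwd(h1 %*% sae$params$W2 + sae$params$b2, "relu")
  p <- act_fwd(h2 %*% sae$params$W3 + sae$params$b3, "sigmoid")
  matrix(as.numeric(p), sae$side, sae$side)
}

#' Degrade a clean mask into a CNN-artifact-like prediction
#'
#' Emulates typical raw-CNN segmentation defects on a clean mask: punched
#' holes inside the foreground, spurious blobs near (and off) the boundary,
#' a small random translation, and salt-and-pepper label flips. Used to
#' build SAE training pairs and refinement benchmarks.
#'
#' @param mask Clean binary mask.
#' @param seed Integer seed; the corruption is deterministic given
#'   `(mask, seed)`.
#' @param n_holes Number of punched disks inside the foreground.
#' @param hole_radius Range of hole radii (pixels).
#' @param n_spurs Number of spurious foreground disks added.
#' @param spur_radius Range of spur radii (pixels).
#' @param max_shift Maximum absolute translation (pixels) per axis.
#' @param flip_prob Probability of flipping any single pixel.
#' @return A degraded binary mask of the same shape.
#' @export
corrupt_mask <- function(mask, seed, n_holes = 6, hole_radius = c(3, 7),
                         n_spurs = 6, spur_radius = c(2, 4),
                         max_shift = 4, flip_prob = 0.02) {
  assert_mask(mask)
  h <- nrow(mask); w <- ncol(mask)
  with_phantom_seed(seed, {
    out <- mask
    dr <- sample(-max_shift:max_shift, 1)
    dc <- sample(-max_shift:max_shift, 1)
    if (dr != 0 || dc != 0) {
      shifted <- matrix(0, h, w)
      rs <- pmax(1, 1 + dr):pmin(h, h + dr)
      cs <- pmax(1, 1 + dc):pmin(w, w + dc)
      shifted[rs, cs] <- out[rs - dr, cs - dc]
      out <- shifted
    }
    fg <- which(out == 1)
    punch <- function(m, center, r, value) {
      ci <- arrayInd(center, c(h, w))
      rows <- pmax(1, ci[1] - r):pmin(h, ci[1] + r)
      cols <- pmax(1, ci[2] - r):pmin(w, ci[2] + r)
      for (rr in rows) for (cc in cols) {
        if ((rr - ci[1])^2 + (cc - ci[2])^2 <= r^2) m[rr, cc] <- value
      }
      m
    }
    if (length(fg) > 0) {
      for (i in seq_len(n_holes)) {
        r <- sample(hole_radius[1]:hole_radius[2], 1)
        out <- punch(out, sample(fg, 1), r, 0)
      }
      for (i in seq_len(n_spurs)) {
        r <- sample(spur_radius[1]:spur_radius[2], 1)
        out <- punch(out, sample(seq_len(h * w), 1), r, 1)
      }
    }
    flips <- stats::runif(h * w) < flip_prob
    out[flips] <- 1 - out[flips]
    out
  })
}
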