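# The four benchmarked mask-regression CNNs (shallow, max-pooling, larger,
# deeper) plus the ReLU parameter-variant of the shallow network.
#
# Each network takes a 64x64 grayscale ROI and regresses a flattened mask
# through a dense 1024-unit layer reshaped to 32x32. Convolutions use valid
# padding and pooling strides equal to the pool size; both conventions are
# forced by the published trainable-parameter counts. L2 regularization
# (lambda = 1e-4) applies to the dense-layer weights.

ARCH_NAMES <- c("shallow", "max_pool", "larger", "deeper", "shallow_relu")

#' Build one of the benchmarked CNN architecture specifications
#'
#' `shallow`: one 100-filter 11x11 ReLU convolution, 6x6 average pooling,
#' dense 1024 sigmoid. `max_pool`: identical but with max pooling.
#' `larger`: 200 filters. `deeper`: 64-filter 11x11 conv, 2x2 average pool,
#' 128-filter 10x10 conv, 2x2 average pool, dense. `shallow_relu`: the
#' shallow network with the dense layer's sigmoid replaced by ReLU — a
#' parameter-level activation variant, not a distinct architecture.
#'
#' @param name One of `"shallow"`, `"max_pool"`, `"larger"`, `"deeper"`,
#'   `"shallow_relu"`.
#' @return An object of class `architecture_spec`.
#' @export
build_architecture <- function(name) {
  if (!name %in% ARCH_NAMES) {
    stop("unknown architecture '", name, "'; valid names: ",
         paste(ARCH_NAMES, collapse = ", "), call. = FALSE)
  }
  conv <- function(filters, kernel) {
    list(type = "conv", filters = filters, kernel = kernel,
         activation = "relu", padding = "valid")
  }
  pool <- function(kind, size) list(type = "pool", kind = kind, size = size)
  dense <- function(activation) {
    list(type = "dense", units = 1024L, activation = activation,
         l2_lambda = 1e-4)
  }
  layers <- switch(
    name,
    shallow = list(conv(100L, 11L), pool("avg", 6L), list(type = "flatten"),
                   dense("sigmoid"), list(type = "reshape", shape = c(32L, 32L))),
    max_pool = list(conv(100L, 11L), pool("max", 6L), list(type = "flatten"),
                    dense("sigmoid"), list(type = "reshape", shape = c(32L, 32L))),
    larger = list(conv(200L, 11L), pool("avg", 6L), list(type = "flatten"),
                  dense("sigmoid"), list(type = "reshape", shape = c(32L, 32L))),
    deeper = list(conv(64L, 11L), pool("avg", 2L), conv(128L, 10L),
                  pool("avg", 2L), list(type = "flatten"), dense("sigmoid"),
                  list(type = "reshape", shape = c(32L, 32L))),
    shallow_relu = list(conv(100L, 11L), pool("avg", 6L),
                        list(type = "flatten"), dense("relu"),
                        list(type = "reshape", shape = c(32L, 32L))))
  structure(list(name = name, input_size = c(64L, 64L, 1L), layers = layers),
            class = "architecture_spec")
}

# Compile a sequential spec against its input shape: trace shapes, build
# im2col/pool geometry, allocate parameters under the current RNG state.
compile_sequential <- function(spec, init_scheme = "random_uniform") {
  shape <- spec$input_size
  compiled <- list()
  params <- list()
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    nm <- sprintf("L%d", i)
    if (ly$type == "conv") {
      g <- conv_geom(shape, ly$kernel, ly$filters, ly$padding)
      k <- ly$kernel
      fan_in <- k * k * shape[3]
      fan_out <- k * k * ly$filters
      params[[paste0(nm, ".W")]] <- init_weights(fan_in, ly$filters,
                                                 fan_in, fan_out, init_scheme)
      params[[paste0(nm, ".b")]] <- rep(0, ly$filters)
      ly$geom <- g
      shape <- g$out_shape
    } else if (ly$type == "pool") {
      g <- pool_geom(shape, ly$size)
      ly$geom <- g
      shape <- g$out_shape
    } else if (ly$type == "flatten") {
      ly$n <- prod(shape)
      shape <- c(ly$n)
    } else if (ly$type == "dense") {
      if (length(shape) != 1) {
        stop(sprintf("layer %s: dense applied to non-flat input", nm),
             call. = FALSE)
      }
      n_in <- shape[1]
      params[[paste0(nm, ".W")]] <- init_weights(n_in, ly$units,
                                                 n_in, ly$units, init_scheme)
      params[[paste0(nm, ".b")]] <- rep(0, ly$units)
      ly$n_in <- n_in
      shape <- c(ly$units)
    } else if (ly$type == "reshape") {
      if (prod(ly$shape) != prod(shape)) {
        stop(sprintf("layer %s: cannot reshape %s units to %s", nm,
                     prod(shape), paste(ly$shape, collapse = "x")),
             call. = FALSE)
      }
      shape <- ly$shape
    }
    compiled[[i]] <- ly
  }
  structure(list(spec = spec, layers = compiled, params = params,
                 output_shape = shape),
            class = "cineseg_net")
}

#' Count trainable parameters of an architecture
#'
#' Builds the network against its 64x64x1 input (tracing every layer shape)
#' and counts the elements of all allocated weight and bias tensors.
#'
#' @param spec An `architecture_spec` from [build_architecture()], or an
#'   architecture name.
#' @return Integer parameter count.
#' @examples
#' count_trainable_params("shallow")  # 8307624
#' @export
count_trainable_params <- function(spec) {
  if (is.character(spec)) spec <- build_architecture(spec)
  stopifnot(inherits(spec, "architecture_spec"))
  net <- compile_sequential(spec, init_scheme = "zero")
  sum(vapply(net$params, length, numeric(1)))
}

#' Training configuration for the structure CNNs
#'
#' Defaults follow the benchmark protocol: Adam with learning rate 0.001,
#' batch size 16, 20 epochs, MSE loss on the continuous sigmoid output
#' against the flattened binary 32x32 target.
#'
#' @param learning_rate Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Number of training epochs (fixed duration, no early stop).
#' @param loss One of `"mse"`, `"bce"`, `"dice"`, `"bce_dice"`.
#' @param init_scheme One of `"zero"`, `"random_uniform"`,
#'   `"random_normal"` (Glorot scaling for the random schemes).
#' @param augment Optional [augment_params()] for online augmentation; `NULL`
#'   disables augmentation.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 16L,
                         epochs = 20L, loss = "mse",
                         init_scheme = "random_uniform",
                         augment = NULL, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1,
            loss %in% c("mse", "bce", "dice", "bce_dice"),
            init_scheme %in% c("zero", "random_uniform", "random_normal"))
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), loss = loss,
                 init_scheme = init_scheme, augment = augment,
                 seed = as.integer(seed)),
            class = "train_config")
}

# ---- conv/pool stack forward & backward ----------------------------------
#
# All zoo architectures are a valid-padding conv/pool stack followed by one
# dense layer, so the stack is evaluated per sample with the im2col GEMM
# formulation. Pre-activations are bias-added and rectified in place
# (cpp_add_bias_relu); between layers activations travel as plain vectors
# whose column-major layout coincides with the (h, w, c) array layout, so
# pooling can gather from them directly. When augmentation is off, the
# first layer's im2col patches are computed once per item and reused across
# epochs.

zoo_forward <- function(net, x, patches1 = NULL) {
  types <- vapply(net$layers, `[[`, "", "type")
  iflat <- which(types == "flatten")[1]
  cur <- as.numeric(x)
  caches <- vector("list", iflat - 1)
  for (i in seq_len(iflat - 1)) {
    ly <- net$layers[[i]]
    nm <- sprintf("L%d", i)
    if (ly$type == "conv") {
      patches <- if (i == 1 && !is.null(patches1)) {
        patches1
      } else {
        cpp_gather(cur, ly$geom$idx, nrow(ly$geom$idx), ncol(ly$geom$idx))
      }
      Z <- patches %*% net$params[[paste0(nm, ".W")]]
      cpp_add_bias_relu(Z, net$params[[paste0(nm, ".b")]])  # Z is now A
      caches[[i]] <- list(patches = patches, A = Z)
      cur <- Z
    } else if (ly$type == "pool") {
      m <- cpp_gather(cur, ly$geom$idx, nrow(ly$geom$idx), ncol(ly$geom$idx))
      if (ly$kind == "avg") {
        cur <- rowMeans(m)
        caches[[i]] <- list(in_len = prod(ly$geom$in_shape))
      } else {
        j <- max.col(m, ties.method = "first")
        sel <- cbind(seq_len(nrow(m)), j)
        cur <- m[sel]
        caches[[i]] <- list(amax = ly$geom$idx[sel],
                            in_len = prod(ly$geom$in_shape))
      }
    }
  }
  list(flat = cur, caches = caches)
}

zoo_backward <- function(net, dflat, caches, grads) {
  types <- vapply(net$layers, `[[`, "", "type")
  iflat <- which(types == "flatten")[1]
  dcur <- as.numeric(dflat)
  for (i in rev(seq_len(iflat - 1))) {
    ly <- net$layers[[i]]
    nm <- sprintf("L%d", i)
    if (ly$type == "pool") {
      ca <- caches[[i]]
      s2 <- ly$geom$size^2
      dvec <- numeric(ca$in_len)
      if (ly$kind == "avg") {
        dvec[as.vector(ly$geom$idx)] <- rep(dcur / s2,
                                            times = ncol(ly$geom$idx))
      } else {
        dvec[ca$amax] <- dcur
      }
      dcur <- dvec
    } else if (ly$type == "conv") {
      ca <- caches[[i]]
      cpp_relu_bwd(dcur, ca$A)  # all zoo convs are ReLU; in place
      dim(dcur) <- dim(ca$A)
      gW <- paste0(nm, ".W"); gb <- paste0(nm, ".b")
      grads[[gW]] <- grads[[gW]] + crossprod(ca$patches, dcur)
      grads[[gb]] <- grads[[gb]] + colSums(dcur)
      if (i > 1) {
        dpatch <- tcrossprod(dcur, net$params[[gW]])
        dcur <- cpp_scatter_add(dpatch, ly$geom$idx,
                                prod(ly$geom$in_shape))
      } else {
        break
      }
    }
  }
  grads
}

# loss value and gradient wrt the activated predictions P (B x n), targets Y
structure_loss <- function(P, Y, loss, eps_dice = 1) {
  n <- length(P)
  if (loss == "mse") {
    L <- mean((P - Y)^2)
    dP <- 2 * (P - Y) / n
  } else if (loss == "bce") {
    Pc <- pmin(pmax(P, 1e-7), 1 - 1e-7)
    L <- -mean(Y * log(Pc) + (1 - Y) * log(1 - Pc))
    dP <- (Pc - Y) / (Pc * (1 - Pc)) / n
  } else if (loss == "dice") {
    s <- sum(P * Y); a <- sum(P) + sum(Y)
    L <- 1 - (2 * s + eps_dice) / (a + eps_dice)
    dP <- -(2 * Y * (a + eps_dice) - (2 * s + eps_dice)) / (a + eps_dice)^2
  } else {  # bce_dice
    b <- structure_loss(P, Y, "bce")
    d <- structure_loss(P, Y, "dice", eps_dice)
    L <- b$L + d$L
    dP <- b$dP + d$dP
  }
  list(L = L, dP = dP)
}

#' Train a structure-segmentation CNN on ROI/mask pairs
#'
#' Trains with the configured loss and Adam, recording the mean training
#' loss of every epoch (including the dense-layer L2 penalty). Training is
#' deterministic for a fixed seed: initialization, batch shuffling and any
#' augmentation draws all derive from `config$seed`.
#'
#' @param spec An `architecture_spec` (or architecture name).
#' @param dataset A list of training items, each a list with `x` (64x64
#'   numeric matrix in `[0, 1]`) and `y` (binary mask, 32x32, or 64x64 which
#'   is resampled to 32x32 with nearest-neighbour).
#' @param config A [train_config()].
#' @return An object of class `cineseg_trained_model` with elements `spec`,
#'   `net` (parameter store), `config` and `loss_history`.
#' @export
train_structure_model <- function(spec, dataset, config = train_config()) {
  if (is.character(spec)) spec <- build_architecture(spec)
  stopifnot(inherits(spec, "architecture_spec"),
            inherits(config, "train_config"))
  if (length(dataset) == 0) stop("empty dataset", call. = FALSE)
  dataset <- lapply(dataset, function(it) {
    stopifnot(all(dim(it$x) == spec$input_size[1:2]))
    y <- it$y
    assert_mask(y, "y")
    if (!all(dim(y) == c(32L, 32L))) y <- resample_mask(y, 32L)
    list(x = it$x, y = y)
  })
  with_phantom_seed(config$seed, {
    net <- compile_sequential(spec, config$init_scheme)
    opt <- adam_state(net$params)
    step <- 0L
    n <- length(dataset)
    bs <- min(config$batch_size, n)
    types <- vapply(net$layers, `[[`, "", "type")
    idense <- which(types == "dense")[1]
    dly <- net$layers[[idense]]
    dW_name <- sprintf("L%d.W", idense)
    db_name <- sprintf("L%d.b", idense)
    conv_par <- setdiff(names(net$params), c(dW_name, db_name))
    lambda <- dly$l2_lambda
    loss_history <- numeric(config$epochs)
    draw <- 0L
    n_in <- dly$n_in
    g1 <- net$layers[[1]]$geom
    # first-layer im2col patches are input-dependent only: reusable across
    # epochs unless online augmentation changes the inputs every draw
    patch_cache <- if (is.null(config$augment)) {
      lapply(dataset, function(it) {
        cpp_gather(as.numeric(it$x), g1$idx, nrow(g1$idx), ncol(g1$idx))
      })
    } else {
      NULL
    }
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      batch_losses <- c()
      for (b0 in seq(1, n, by = bs)) {
        ids <- ord[b0:min(b0 + bs - 1, n)]
        B <- length(ids)
        X <- matrix(0, B, n_in)
        Y <- matrix(0, B, 1024L)
        caches <- vector("list", B)
        for (k in seq_len(B)) {
          it <- dataset[[ids[k]]]
          x <- it$x; y <- it$y
          if (!is.null(config$augment)) {
            draw <- draw + 1L
            tr <- sample_transform(config$augment, draw)
            x <- apply_transform(x, tr, is_mask = FALSE)
            y <- apply_transform(y, tr, is_mask = TRUE)
          }
          fw <- zoo_forward(net, x,
                            patches1 = if (is.null(patch_cache)) NULL
                                       else patch_cache[[ids[k]]])
          X[k, ] <- fw$flat
          caches[[k]] <- fw$caches
          Y[k, ] <- as.vector(y)
        }
        W <- net$params[[dW_name]]
        Z <- X %*% W + rep(net$params[[db_name]], each = B)
        P <- act_fwd(Z, dly$activation)
        ls <- structure_loss(P, Y, config$loss)
        if (!is.finite(ls$L)) {
          stop(sprintf("non-finite training loss at epoch %d (loss=%s); %s",
                       epoch, config$loss,
                       "check input scaling and learning rate"),
               call. = FALSE)
        }
        batch_losses <- c(batch_losses, ls$L + lambda * sum(W^2))
        dZ <- act_bwd(ls$dP, P, Z, dly$activation)
        # zero-init only the (small) conv gradients; the dense gradient is
        # written directly and the L2 term folded in without a temporary
        grads <- lapply(net$params[conv_par], function(p) p * 0)
        grads[[dW_name]] <- crossprod(X, dZ)
        cpp_axpy(grads[[dW_name]], W, 2 * lambda)
        grads[[db_name]] <- colSums(dZ)
        dX <- tcrossprod(dZ, W)
        for (k in seq_len(B)) {
          grads <- zoo_backward(net, dX[k, ], caches[[k]], grads)
        }
        step <- step + 1L
        adam_update(net$params, grads, opt, step, config$learning_rate)
      }
      loss_history[epoch] <- mean(batch_losses)
    }
    structure(list(spec = spec, net = net, config = config,
                   loss_history = loss_history),
              class = "cineseg_trained_model")
  })
}

#' Predict a structure probability map from a 64x64 ROI
#'
#' @param model A `cineseg_trained_model` from [train_structure_model()].
#' @param roi_frame 64x64 numeric matrix.
#' @return A 32x32 probability map (values in `[0, 1]` for the sigmoid
#'   variants; the ReLU variant is unbounded above).
#' @export
predict_structure_mask <- function(model, roi_frame) {
  stopifnot(inherits(model, "cineseg_trained_model"))
  if (!all(dim(roi_frame) == model$spec$input_size[1:2])) {
    stop(sprintf("input must be %dx%d", model$spec$input_size[1],
                 model$spec$input_size[2]), call. = FALSE)
  }
  net <- model$net
  fw <- zoo_forward(net, roi_frame)
  types <- vapply(net$layers, `[[`, "", "type")
  idense <- which(types == "dense")[1]
  dly <- net$layers[[idense]]
  z <- fw$flat %*% net$params[[sprintf("L%d.W", idense)]] +
    net$params[[sprintf("L%d.b", idense)]]
  p <- act_fwd(z, dly$activation)
  matrix(as.vector(p), 32L, 32L)
}

#' Loss-sensitivity harness for the structure CNNs
#'
#' Trains the same architecture under each requested loss with an identical
#' seed and train/evaluation split, then reports mean Dice and mean IoU of
#' the binarized predictions on the evaluation items. The ordering across
#' losses is reported, not asserted: it is data-dependent.
#'
#' @param arch Architecture name or `architecture_spec`.
#' @param train_items,eval_items Lists of `list(x, y)` ROI items.
#' @param losses Character vector of losses to compare.
#' @param epochs,seed Passed to [train_config()].
#' @return A tibble with one row per loss: `loss`, `dice`, `iou`,
#'   `final_train_loss`.
#' @export
loss_comparison <- function(arch, train_items, eval_items,
                            losses = c("mse", "bce", "dice", "bce_dice"),
                            epochs = 20L, seed = 1L) {
  purrr::map_dfr(losses, function(ls) {
    m <- train_structure_model(arch, train_items,
                               train_config(epochs = epochs, loss = ls,
                                            seed = seed))
    scores <- vapply(eval_items, function(it) {
      pred <- binarize(predict_structure_mask(m, it$x))
      truth <- if (all(dim(it$y) == c(32L, 32L))) it$y else
        resample_mask(it$y, 32L)
      inter <- sum(pred * truth)
      union <- sum(pred) + sum(truth) - inter
      c(dice = as.numeric(dsc(pred, truth)),
        iou = if (union == 0) 1 else inter / union)
    }, numeric(2))
    tibble::tibble(loss = ls, dice = mean(scores["dice", ]),
                   iou = mean(scores["iou", ]),
                   final_train_loss = utils::tail(m$loss_history, 1))
  })
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability is greater than or equal to
#' the threshold.
#'
#' @param map Numeric matrix of finite values.
#' @param threshold Decision threshold (default 0.5).
#' @export
binarize <- function(map, threshold = 0.5) {
  stopifnot(all(is.finite(map)))
  matrix(as.numeric(map >= threshold), nrow(map), ncol(map))
}

#' @export
print.cineseg_trained_model <- function(x, ...) {
  cat(sprintf("<cineseg_trained_model> arch '%s', %d epochs, final loss %.5f\n",
              x$spec$name, length(x$loss_history),
              utils::tail(x$loss_history, 1)))
  invisible(x)
}

#' Save / load a trained model checkpoint
#'
#' A checkpoint directory holds `spec.json` (architecture, training
#' configuration, and the name/length of every parameter tensor) plus
#' `weights.bin` (the concatenated parameter values as native doubles).
#' The loader rebuilds the network from the spec and validates that the
#' stored tensor lengths match before restoring the weights.
#'
#' @param model A `cineseg_trained_model`.
#' @param dir Checkpoint directory.
#' @return `dir` (save) or the restored model (load).
#' @export
save_checkpoint <- function(model, dir) {
  stopifnot(inherits(model, "cineseg_trained_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sizes <- vapply(model$net$params, length, numeric(1))
  jsonlite::write_json(
    list(arch = model$spec$name,
         loss = model$config$loss,
         init_scheme = model$config$init_scheme,
         seed = model$config$seed,
         loss_history = model$loss_history,
         param_names = names(model$net$params),
         param_sizes = unname(sizes)),
    file.path(dir, "spec.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "weights.bin"), "wb")
  on.exit(close(con))
  for (nm in names(model$net$params)) {
    writeBin(as.vector(model$net$params[[nm]]), con, size = 8)
  }
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  spec <- build_architecture(meta$arch)
  net <- compile_sequential(spec, init_scheme = "zero")
  if (!identical(names(net$params), meta$param_names) ||
      !identical(vapply(net$params, length, numeric(1)) |> unname(),
                 as.numeric(meta$param_sizes))) {
    stop("checkpoint weights do not match architecture '", meta$arch, "'",
         call. = FALSE)
  }
  con <- file(file.path(dir, "weights.bin"), "rb")
  on.exit(close(con))
  for (nm in names(net$params)) {
    tmpl <- net$params[[nm]]
    vals <- readBin(con, "double", n = length(tmpl), size = 8)
    net$params[[nm]] <- if (is.matrix(tmpl)) {
      matrix(vals, nrow(tmpl), ncol(tmpl))
    } else {
      vals
    }
  }
  cfg <- train_config(loss = meta$loss, init_scheme = meta$init_scheme,
                      seed = meta$seed)
  structure(list(spec = spec, net = net, config = cfg,
                 loss_history = meta$loss_history),
            class = "cineseg_trained_model")
}
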