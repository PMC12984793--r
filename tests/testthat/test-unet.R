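num_grad <- function(f, x, eps = 1e-6) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x1[i] <- x1[i] + eps
    x2 <- x; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

test_that("grayscale frames are replicated across three channels", {
  fr <- matrix(runif(128 * 128), 128, 128)
  x <- gray_to_3channel(fr)
  expect_equal(dim(x), c(128, 128, 3))
  expect_equal(x[, , 1], fr)
  expect_identical(x[, , 2], x[, , 3])
  expect_true(all(gray_to_3channel(matrix(0, 8, 8)) == 0))
})

test_that("SE recalibration gates channels within (0,1)", {
  x <- array(rnorm(8 * 8 * 16), c(8, 8, 16))
  out <- se_recalibrate(x, se_params(16, 4, init = "random_normal"))
  expect_equal(dim(out$y), dim(x))
  expect_true(all(out$gates > 0 & out$gates < 1))
  expect_true(all(abs(out$y) <= abs(x) + 1e-12))
  expect_true(all(se_recalibrate(x * 0, se_params(16, 4))$y == 0))
  # saturated gates (large positive bias) approach the identity
  sp <- se_params(16, 4, init = "zero")
  sp$b2 <- rep(30, 16)
  expect_lt(max(abs(se_recalibrate(x, sp)$y - x)), 1e-8)
  expect_error(se_params(10, 4), "divisible")
})

test_that("the attention gate is a bounded elementwise product", {
  f <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  g <- array(rnorm(8 * 8 * 8), c(8, 8, 8))
  ap <- attention_params(8, init = "random_normal")
  out <- attention_gate(f, g, ap)
  expect_equal(dim(out$y), dim(f))
  expect_true(all(out$a_spatial > 0 & out$a_spatial < 1))
  expect_true(all(out$a_channel > 0 & out$a_channel < 1))
  expect_true(all(abs(out$y) <= abs(f) + 1e-12))
  expect_true(all(attention_gate(f * 0, g, ap)$y == 0))
  # saturated attention (large biases) approaches the identity
  ap0 <- attention_params(8, init = "zero")
  ap0$bpsi <- 30
  ap0$bc <- rep(30, 8)
  expect_lt(max(abs(attention_gate(f, g, ap0)$y - f)), 1e-6)
  expect_error(attention_gate(f, array(0, c(4, 4, 8)), ap), "differ")
})

test_that("component backward passes match finite differences", {
  set.seed(12)
  sp <- se_params(4, 2, init = "random_normal")
  xs <- array(rnorm(3 * 3 * 4), c(3, 3, 4))
  out <- cineseg:::se_recalibrate(xs, sp)
  dy <- array(cos(out$y), dim(out$y))
  bw <- cineseg:::se_bwd(dy, out, sp)
  gx <- num_grad(function(v) {
    sum(sin(se_recalibrate(array(v, c(3, 3, 4)), sp)$y))
  }, as.vector(xs))
  expect_lt(rel_err(as.vector(bw$dx), gx), 1e-6)

  ap <- attention_params(4, init = "random_normal")
  f <- array(rnorm(36), c(3, 3, 4)); g <- array(rnorm(36), c(3, 3, 4))
  ao <- attention_gate(f, g, ap)
  bwa <- cineseg:::attention_bwd(array(cos(ao$y), dim(ao$y)), ao, f, g, ap)
  gf <- num_grad(function(v) {
    sum(sin(attention_gate(array(v, c(3, 3, 4)), g, ap)$y))
  }, as.vector(f))
  gg <- num_grad(function(v) {
    sum(sin(attention_gate(f, array(v, c(3, 3, 4)), ap)$y))
  }, as.vector(g))
  expect_lt(rel_err(as.vector(bwa$df), gf), 1e-6)
  expect_lt(rel_err(as.vector(bwa$dgate), gg), 1e-6)

  geomT <- cineseg:::convT_geom(c(3L, 3L, 2L), 2L)
  Wt <- matrix(rnorm(16), 2, 8); bt <- rnorm(2)
  xt <- array(rnorm(18), c(3, 3, 2))
  fwt <- cineseg:::convT_fwd(xt, geomT, Wt, bt)
  bwt <- cineseg:::convT_bwd(array(cos(fwt$z), dim(fwt$z)), geomT, Wt,
                             fwt$xm)
  gxt <- num_grad(function(v) {
    sum(sin(cineseg:::convT_fwd(array(v, c(3, 3, 2)), geomT, Wt, bt)$z))
  }, as.vector(xt))
  gWt <- num_grad(function(w) {
    sum(sin(cineseg:::convT_fwd(xt, geomT, matrix(w, 2, 8), bt)$z))
  }, as.vector(Wt))
  expect_lt(rel_err(as.vector(bwt$dx), gxt), 1e-6)
  expect_lt(rel_err(as.vector(bwt$dW), gWt), 1e-6)
})

test_that("the built model reproduces every published layer shape", {
  audit <- mi_shape_audit()
  expect_equal(audit$out_c[audit$layer == "input"], 3)
  # encoder: two conv blocks at 32 and 64 channels with SE and pooling
  enc <- audit[audit$block == "encoder", ]
  expect_equal(enc$out_c, c(32, 32, 32, 32, 32, 64, 64, 64, 64, 64))
  expect_equal(enc$out_h, c(128, 128, 128, 128, 64, 64, 64, 64, 64, 32))
  # bottleneck at 32 x 32 x 128
  bot <- audit[audit$block == "bottleneck", ]
  expect_true(all(bot$out_h == 32 & bot$out_c == 128))
  # decoder shapes, including post-concatenation widths
  dec <- audit[audit$block == "decoder", ]
  cat1 <- dec[dec$layer == "concatenate", ]
  expect_equal(cat1$out_c, c(128, 64))
  expect_equal(cat1$out_h, c(64, 128))
  out <- audit[audit$block == "output", ]
  expect_equal(unlist(out[, c("out_h", "out_w", "out_c")]),
               c(out_h = 128, out_w = 128, out_c = 1))
  expect_equal(out$activation, "sigmoid")
})

test_that("dice, focal and composite losses satisfy their identities", {
  set.seed(5)
  y <- matrix(rbinom(64, 1, 0.3), 8, 8)
  p <- matrix(runif(64), 8, 8)
  # perfect prediction drives both terms to zero
  expect_lt(dice_loss(y, y, epsilon = 1e-9), 1e-8)
  expect_lt(focal_loss(y, y * 0.999999 + 1e-7), 1e-4)
  expect_lt(total_loss(y, pmin(pmax(y, 1e-7), 1 - 1e-7),
                       composite_loss_spec(epsilon = 1e-9)), 1e-4)
  # disjoint masks: dice loss -> 1
  a <- matrix(0, 4, 4); a[1, 1:4] <- 1
  b <- matrix(0, 4, 4); b[3, 1:4] <- 1
  expect_equal(dice_loss(a, b, epsilon = 1e-12), 1, tolerance = 1e-9)
  # direct count: 4 true, 2 predicted hits, epsilon ~ 0 -> 1/3
  g <- matrix(0, 4, 4); g[1, 1:4] <- 1
  q <- matrix(0, 4, 4); q[1, 1:2] <- 1
  expect_equal(dice_loss(g, q, epsilon = 1e-12), 1 / 3, tolerance = 1e-9)
  # single pixel focal evaluation: 0.25 * 0.25 * (-ln 0.5)
  expect_equal(focal_loss(matrix(1), matrix(0.5)),
               0.25 * 0.25 * log(2), tolerance = 1e-9)
  # alpha = 1, gamma = 0 reduces focal to binary cross-entropy
  bce <- -mean(y * log(pmax(p, 1e-7)) + (1 - y) * log(pmax(1 - p, 1e-7)))
  expect_equal(focal_loss(y, p, focal_params(alpha = 1, gamma = 0)),
               bce, tolerance = 1e-9)
  # composite equals the weighted mean of its parts, to machine precision
  expect_equal(total_loss(y, p),
               0.5 * dice_loss(y, p) + 0.5 * focal_loss(y, p),
               tolerance = 1e-15)
  # toy composite from the two verified components
  expect_equal(0.5 * (1 / 3) + 0.5 * (0.25 * 0.25 * log(2)),
               0.5 * dice_loss(g, q, 1e-12) +
                 0.5 * focal_loss(matrix(1), matrix(0.5)),
               tolerance = 1e-6)
})

test_that("the composite loss gradient matches finite differences", {
  set.seed(8)
  y <- as.numeric(rbinom(20, 1, 0.4))
  p <- runif(20, 0.05, 0.95)
  spec <- composite_loss_spec()
  fp <- focal_params()
  g <- cineseg:::total_loss_grad(y, p, spec, fp)
  gn <- num_grad(function(v) total_loss(y, v, spec, fp), p)
  expect_lt(rel_err(g, gn), 1e-5)
})

test_that("early stopping and LR plateau follow their patience rules", {
  cfg <- mi_train_config(early_stop_patience = 5, lr_reduce_patience = 3,
                         lr_reduce_factor = 0.5, learning_rate = 1e-4)
  st <- list(best = Inf, es_wait = 0L, lr_wait = 0L, lr = 1e-4,
             stop = FALSE)
  # strictly improving validation loss: never stops, never reduces
  for (v in seq(1, 0.1, by = -0.1)) st <- callback_step(st, v, cfg)
  expect_false(st$stop)
  expect_equal(st$lr, 1e-4)
  # constant validation loss: LR halves after 3, stops after 5
  st <- list(best = Inf, es_wait = 0L, lr_wait = 0L, lr = 1e-4,
             stop = FALSE)
  st <- callback_step(st, 0.5, cfg)        # first epoch sets the best
  lrs <- c()
  for (i in 1:5) {
    st <- callback_step(st, 0.5, cfg)
    lrs <- c(lrs, st$lr)
  }
  expect_true(st$stop)
  expect_equal(st$es_wait, 5L)
  expect_equal(lrs[3], 5e-5)               # reduced at the 3rd stale epoch
  expect_equal(st$lr, 5e-5)                # not yet reduced a second time
})

test_that("infarct training runs, declines and predicts in range", {
  set.seed(71)
  mk_item <- function(s) {
    fr <- matrix(runif(128 * 128, 0, 0.3), 128, 128)
    y <- matrix(0, 128, 128)
    r0 <- 30 + (s * 13) %% 40
    c0 <- 30 + (s * 29) %% 40
    y[r0:(r0 + 23), c0:(c0 + 23)] <- 1
    fr[y == 1] <- fr[y == 1] + 0.5
    list(x = gray_to_3channel(fr), y = y)
  }
  items <- lapply(1:6, mk_item)
  cfg <- mi_train_config(max_epochs = 3, batch_size = 2, seed = 1,
                         learning_rate = 1e-3)
  tr <- train_mi_model(NULL, items[1:4], items[5:6], cfg)
  expect_lt(tr$history$train_loss[3], tr$history$train_loss[1])
  expect_equal(nrow(tr$history), 3)
  p <- predict_infarct(tr, items[[5]]$x)
  expect_equal(dim(p), c(128, 128))
  expect_true(all(p >= 0 & p <= 1))
  # thresholded prediction agrees with the metric-suite Dice
  bin <- binarize(p)
  expect_equal(as.numeric(dsc(bin, items[[5]]$y)),
               2 * sum(bin * items[[5]]$y) /
                 (sum(bin) + sum(items[[5]]$y)))
  expect_error(train_mi_model(NULL, list(), items[5:6], cfg), "non-empty")
  expect_error(predict_infarct(tr, array(0, c(64, 64, 3))), "128x128x3")
})
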