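# Fixtures shared across the CNN tests: a small ROI dataset built from
# phantoms (64x64 frames, 64x64 masks downsampled to 32x32 by the trainer).
zoo_items <- local({
  ds <- phantom_roi_dataset(10, frames_per_case = 2, seed = 301)
  unlist(lapply(ds$cases, identity), recursive = FALSE, use.names = FALSE)
})

test_that("architecture specs match their published layer lists", {
  sh <- build_architecture("shallow")
  expect_equal(sh$layers[[1]][c("filters", "kernel", "activation", "padding")],
               list(filters = 100L, kernel = 11L, activation = "relu",
                    padding = "valid"))
  expect_equal(sh$layers[[2]][c("kind", "size")], list(kind = "avg",
                                                       size = 6L))
  expect_equal(sh$layers[[4]][c("units", "activation", "l2_lambda")],
               list(units = 1024L, activation = "sigmoid", l2_lambda = 1e-4))
  mp <- build_architecture("max_pool")
  expect_equal(mp$layers[[2]]$kind, "max")
  expect_equal(mp$layers[[1]]$filters, 100L)
  dp <- build_architecture("deeper")
  expect_equal(vapply(dp$layers[c(1, 3)], `[[`, integer(1), "filters"),
               c(64L, 128L))
  expect_equal(vapply(dp$layers[c(1, 3)], `[[`, integer(1), "kernel"),
               c(11L, 10L))
  rl <- build_architecture("shallow_relu")
  expect_equal(rl$layers[[4]]$activation, "relu")
  expect_error(build_architecture("resnet"), "shallow")
})

test_that("trainable-parameter counts equal the closed-form oracle", {
  # shape trace: 64 -> 54 (11x11 valid) -> 9 (6x6 pool) for the one-conv
  # nets; 64 -> 54 -> 27 -> 18 -> 9 for the deeper net
  oracle <- list(
    shallow = oracle_param_count(list(
      list(kind = "conv", kh = 11, kw = 11, cin = 1, cout = 100),
      list(kind = "dense", nin = 9 * 9 * 100, nout = 1024))),
    max_pool = oracle_param_count(list(
      list(kind = "conv", kh = 11, kw = 11, cin = 1, cout = 100),
      list(kind = "dense", nin = 9 * 9 * 100, nout = 1024))),
    larger = oracle_param_count(list(
      list(kind = "conv", kh = 11, kw = 11, cin = 1, cout = 200),
      list(kind = "dense", nin = 9 * 9 * 200, nout = 1024))),
    deeper = oracle_param_count(list(
      list(kind = "conv", kh = 11, kw = 11, cin = 1, cout = 64),
      list(kind = "conv", kh = 10, kw = 10, cin = 64, cout = 128),
      list(kind = "dense", nin = 9 * 9 * 128, nout = 1024))),
    shallow_relu = oracle_param_count(list(
      list(kind = "conv", kh = 11, kw = 11, cin = 1, cout = 100),
      list(kind = "dense", nin = 9 * 9 * 100, nout = 1024))))
  for (nm in names(oracle)) {
    expect_identical(count_trainable_params(nm), oracle[[nm]],
                     label = nm)
  }
})

test_that("binarize thresholds with p >= threshold foreground", {
  m <- matrix(c(0.4999, 0.5, 0.51, 0), 2, 2)
  expect_equal(binarize(m), matrix(c(0, 1, 1, 0), 2, 2))
  expect_equal(sum(binarize(matrix(0, 4, 4))), 0)
  expect_true(all(binarize(matrix(runif(16), 4, 4), threshold = 0) == 1))
  expect_error(binarize(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("training is deterministic and records per-epoch losses", {
  cfg <- train_config(epochs = 2, seed = 42)
  m1 <- train_structure_model("shallow", zoo_items[1:12], cfg)
  m2 <- train_structure_model("shallow", zoo_items[1:12], cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$net$params, m2$net$params)
  expect_length(m1$loss_history, 2)
  one <- train_structure_model("shallow", zoo_items[1:8],
                               train_config(epochs = 1, seed = 1))
  expect_length(one$loss_history, 1)
  expect_error(train_structure_model("shallow", list(), cfg), "empty")
})

test_that("predictions have the right shape and range", {
  m <- train_structure_model("shallow", zoo_items[1:8],
                             train_config(epochs = 1, seed = 3))
  p <- predict_structure_mask(m, zoo_items[[9]]$x)
  expect_equal(dim(p), c(32, 32))
  expect_true(all(p >= 0 & p <= 1))
  expect_error(predict_structure_mask(m, matrix(0, 32, 32)), "64x64")
  # the ReLU variant is unbounded above but non-negative
  mr <- train_structure_model("shallow_relu", zoo_items[1:8],
                              train_config(epochs = 1, seed = 3))
  pr <- predict_structure_mask(mr, zoo_items[[9]]$x)
  expect_true(all(pr >= 0))
})

test_that("all four losses train and reduce the objective", {
  for (loss in c("mse", "bce", "dice", "bce_dice")) {
    m <- train_structure_model("shallow", zoo_items[1:16],
                               train_config(epochs = 3, seed = 7,
                                            loss = loss))
    expect_lt(m$loss_history[3], m$loss_history[1])
  }
})

test_that("the loss harness compares losses on a fixed seed and split", {
  out <- loss_comparison("shallow", zoo_items[1:12], zoo_items[13:20],
                         epochs = 3, seed = 5)
  expect_equal(out$loss, c("mse", "bce", "dice", "bce_dice"))
  expect_true(all(out$dice >= 0 & out$dice <= 1))
  expect_true(all(out$iou <= out$dice + 1e-12))  # IoU never exceeds Dice
  out2 <- loss_comparison("shallow", zoo_items[1:12], zoo_items[13:20],
                          epochs = 3, seed = 5)
  expect_identical(out, out2)
})

test_that("init schemes are honoured, including all-zero", {
  mz <- train_structure_model("shallow", zoo_items[1:8],
                              train_config(epochs = 1, seed = 5,
                                           init_scheme = "zero"))
  # conv weights start at zero; only the dense bias path learns at first,
  # so conv weights stay zero after one epoch (zero conv output blocks
  # their gradient through the dense layer input)
  expect_true(is.finite(mz$loss_history[1]))
  mn <- train_structure_model("shallow", zoo_items[1:8],
                              train_config(epochs = 1, seed = 5,
                                           init_scheme = "random_normal"))
  expect_false(identical(mz$net$params$L1.W, mn$net$params$L1.W))
})

test_that("online augmentation changes the training stream deterministically", {
  aug <- augment_params(seed = 2)
  cfg <- train_config(epochs = 1, seed = 9, augment = aug)
  m1 <- train_structure_model("shallow", zoo_items[1:8], cfg)
  m2 <- train_structure_model("shallow", zoo_items[1:8], cfg)
  expect_identical(m1$loss_history, m2$loss_history)
  m3 <- train_structure_model("shallow", zoo_items[1:8],
                              train_config(epochs = 1, seed = 9))
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("checkpoints round-trip weights and validate the architecture", {
  m <- train_structure_model("shallow", zoo_items[1:8],
                             train_config(epochs = 1, seed = 13))
  dir <- withr::local_tempdir()
  save_checkpoint(m, dir)
  m2 <- load_checkpoint(dir)
  expect_identical(m$net$params, m2$net$params)
  expect_equal(m$loss_history, m2$loss_history)
  p1 <- predict_structure_mask(m, zoo_items[[9]]$x)
  p2 <- predict_structure_mask(m2, zoo_items[[9]]$x)
  expect_identical(p1, p2)
  # tampered spec is rejected
  meta <- jsonlite::read_json(file.path(dir, "spec.json"),
                              simplifyVector = TRUE)
  meta$arch <- "deeper"
  jsonlite::write_json(meta, file.path(dir, "spec.json"),
                       auto_unbox = TRUE, digits = NA)
  expect_error(load_checkpoint(dir), "do not match")
})

test_that("glance and autoplot summarize trained models", {
  m <- train_structure_model("shallow", zoo_items[1:8],
                             train_config(epochs = 2, seed = 1))
  g <- glance(m)
  expect_equal(g$arch, "shallow")
  expect_equal(g$n_params, 8307624)
  expect_equal(g$epochs, 2)
  expect_s3_class(autoplot(m), "ggplot")
})
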