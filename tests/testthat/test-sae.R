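sae_dataset <- local({
  ds <- phantom_roi_dataset(16, frames_per_case = 1, seed = 401)
  items <- unlist(lapply(ds$cases, identity), recursive = FALSE,
                  use.names = FALSE)
  lapply(seq_along(items), function(i) {
    list(corrupted = corrupt_mask(items[[i]]$y, seed = 500 + i),
         clean = items[[i]]$y)
  })
})

test_that("the hybrid loss evaluates its closed form", {
  # identical binary masks: zero under the epsilon-clipped convention
  y <- matrix(c(1, 0, 1, 0), 2, 2)
  expect_lt(sae_loss(y, y), 1e-5)
  # beta = 0 isolates the (alpha/2) * MAE term
  p <- matrix(c(0.8, 0.1, 0.6, 0.3), 2, 2)
  par0 <- sae_loss_params(alpha = 0.2, beta = 0)
  expect_equal(sae_loss(y, p, par0), 0.1 * mean(abs(y - p)))
  # single pixel, y = 1, p = 0.5, alpha = 1e-4, beta = 3:
  # (1e-4 / 2) * 0.5 + 3 * ln 2, confirmed by direct hand computation
  expect_equal(sae_loss(matrix(1), matrix(0.5)),
               0.0001 / 2 * 0.5 + 3 * log(2), tolerance = 1e-6)
  # variants substitute the objective
  expect_equal(sae_loss(y, p, sae_loss_params(variant = "mse_mse")),
               mean((y - p)^2))
  expect_gt(sae_loss(matrix(1), matrix(0.5),
                     sae_loss_params(variant = "kl_mse")), 0.69)
  expect_error(sae_loss(matrix(1), matrix(c(0.5, 0.5), 1, 2)), "differ")
})

test_that("SAE training is seeded, bottlenecked at 100 and reconstructs", {
  cfg <- sae_train_config(pretrain_epochs = 3, finetune_epochs = 8, seed = 2)
  sae <- train_sae(sae_dataset, config = cfg)
  sae2 <- train_sae(sae_dataset, config = cfg)
  expect_identical(sae$loss_history, sae2$loss_history)
  expect_length(sae_encode(sae, sae_dataset[[1]]$clean), 100)
  expect_error(train_sae(list()), "empty")
  # reconstruction of clean-on-clean pairs converges to low MAE
  clean_pairs <- lapply(sae_dataset[1:12], function(it) {
    list(corrupted = it$clean, clean = it$clean)
  })
  sae_c <- train_sae(clean_pairs,
                     config = sae_train_config(pretrain_epochs = 5,
                                               finetune_epochs = 40,
                                               seed = 3))
  maes <- vapply(clean_pairs, function(it) {
    mean(abs(refine_mask(sae_c, it$clean) - it$clean))
  }, numeric(1))
  expect_lt(mean(maes), 0.05)
})

test_that("refinement maps into [0,1] and improves corrupted masks", {
  sae <- train_sae(sae_dataset[1:12],
                   config = sae_train_config(pretrain_epochs = 5,
                                             finetune_epochs = 25, seed = 4))
  held <- sae_dataset[13:16]
  d_raw <- vapply(held, function(it) {
    as.numeric(dsc(it$corrupted, it$clean))
  }, numeric(1))
  d_ref <- vapply(held, function(it) {
    r <- refine_mask(sae, it$corrupted)
    expect_true(all(r >= 0 & r <= 1))
    as.numeric(dsc(binarize(r), it$clean))
  }, numeric(1))
  expect_gt(mean(d_ref), mean(d_raw))
  # an all-background input reconstructs to a low-energy map
  zero_out <- binarize(refine_mask(sae, matrix(0, 64, 64)))
  expect_lt(mean(zero_out), 0.05)
  # 32x32 inputs are upsampled transparently
  small <- resample_mask(held[[1]]$corrupted, 32)
  expect_equal(dim(refine_mask(sae, small)), c(64, 64))
})

test_that("mask corruption is deterministic and yields binary masks", {
  m <- make_disk_mask(64, c(32, 32), 14)
  a <- corrupt_mask(m, seed = 1)
  expect_identical(a, corrupt_mask(m, seed = 1))
  expect_false(identical(a, corrupt_mask(m, seed = 2)))
  expect_true(all(a %in% c(0, 1)))
  expect_lt(as.numeric(dsc(a, m)), 1)
})
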