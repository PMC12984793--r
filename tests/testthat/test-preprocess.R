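test_that("bilinear frame resampling preserves constants and identity", {
  const <- matrix(0.37, 128, 128)
  up <- resample_frame(const, 256)
  expect_equal(dim(up), c(256, 256))
  expect_true(all(up == 0.37))
  expect_identical(resample_frame(const, 128), const)
  expect_error(resample_frame(matrix(numeric(0), 0, 0), 64), "non-empty")
})

test_that("a smooth ramp survives an up/down resampling round trip", {
  ramp <- outer(seq(0, 1, length.out = 96), seq(0, 1, length.out = 96),
                function(a, b) (a + b) / 2)
  back <- resample_frame(resample_frame(ramp, 192), 96)
  expect_lt(max(abs(back - ramp)), 0.02)
})

test_that("mask resampling is nearest-neighbour and stays binary", {
  disk <- make_disk_mask(128, c(64, 64), 20)
  up <- resample_mask(disk, 256)
  expect_true(all(up %in% c(0, 1)))
  # analytic area scaling: 2x linear upsampling ~ 4x area
  expect_lt(abs(sum(up) / (4 * sum(disk)) - 1), 0.05)
  full <- matrix(1, 16, 16)
  expect_true(all(resample_mask(full, 48) == 1))
  expect_error(resample_mask(matrix(0.5, 4, 4), 8), "binary")
})

test_that("intensity normalization is min-max with an all-zero degenerate", {
  fr <- matrix(c(100, 150, 200, 300), 2, 2)
  expect_equal(normalize_intensity(fr), (fr - 100) / 200)
  expect_true(all(normalize_intensity(matrix(7, 5, 5)) == 0))
  already <- matrix(c(0, 0.25, 0.5, 1), 2, 2)
  expect_equal(normalize_intensity(already), already)
})

test_that("morph_clean matches the brute-force disk-2 morphology oracle", {
  # single isolated pixel is removed by the opening
  iso <- matrix(0, 11, 11); iso[6, 6] <- 1
  expect_equal(sum(morph_clean(iso)), 0)
  expect_identical(morph_clean(iso), oracle_open_close(iso, 2))
  # a solid square: the oracle rounds 3 pixels off each corner
  sq <- matrix(0, 30, 30); sq[6:25, 6:25] <- 1
  got <- morph_clean(sq)
  expect_identical(got, oracle_open_close(sq, 2))
  expect_equal(sum(sq) - sum(got), 12)
  # empty mask passes through
  empty <- matrix(0, 8, 8)
  expect_identical(morph_clean(empty), empty)
  # randomized agreement with the oracle
  set.seed(31)
  for (i in 1:5) {
    m <- matrix(rbinom(400, 1, 0.4), 20, 20)
    expect_identical(morph_clean(m), oracle_open_close(m, 2))
  }
})

test_that("ROI extraction pads, clamps and errors on empty masks", {
  m <- matrix(0, 40, 40)
  m[11:21, 13:23] <- 1  # rows 10-20, cols 12-22 in 0-based coordinates
  box <- extract_roi(m, padding = 4)
  expect_equal(c(box$row_min, box$row_max, box$col_min, box$col_max),
               c(6, 25, 8, 27))
  m2 <- matrix(0, 40, 40); m2[1:5, 1:5] <- 1
  box2 <- extract_roi(m2, padding = 4)
  expect_equal(box2$row_min, 0)
  expect_equal(box2$col_min, 0)
  expect_error(extract_roi(matrix(0, 8, 8)), "empty prediction")
})

test_that("the inference-path ROI API takes no ground-truth argument", {
  expect_false(any(grepl("truth|gt|label", names(formals(localize_roi)),
                         ignore.case = TRUE)))
  expect_warning(box <- localize_roi(matrix(0, 64, 64)), "empty prediction")
  expect_equal(c(box$row_min, box$row_max), c(16, 48))
})

test_that("crop_and_resize handles identity, masks and degenerate boxes", {
  fr <- matrix(runif(64 * 64), 64, 64)
  full <- extract_roi(matrix(1, 64, 64), padding = 0)
  expect_equal(crop_and_resize(fr, full, 64), fr)
  m <- make_disk_mask(64, c(32, 32), 10)
  box <- extract_roi(m, padding = 4)
  crop <- crop_and_resize(m, box, 64, is_mask = TRUE)
  expect_true(all(crop %in% c(0, 1)))
  const <- matrix(0.5, 64, 64)
  expect_true(all(crop_and_resize(const, box, 64) == 0.5))
  degenerate <- structure(list(row_min = 5, row_max = 5, col_min = 1,
                               col_max = 10, padding = 0),
                          class = "roi_box")
  expect_error(crop_and_resize(fr, degenerate, 32), "degenerate")
})

test_that("augmentation is deterministic, paired and mask-safe", {
  fr <- make_disk_image(64, c(32, 32), 14)
  mk <- make_disk_mask(64, c(32, 32), 14)
  id <- augment_params(max_rotation_deg = 0, allow_hflip = FALSE,
                       max_shift_fraction = 0, seed = 1)
  out <- augment_pair(fr, mk, id, 1)
  expect_equal(out$frame, fr)
  expect_equal(out$mask, mk)
  par <- augment_params(seed = 11)
  a <- augment_pair(fr, mk, par, 5)
  b <- augment_pair(fr, mk, par, 5)
  expect_identical(a, b)
  c2 <- augment_pair(fr, mk, par, 6)
  expect_false(identical(a$mask, c2$mask))
  # a centred disk keeps its area under any sampled rotation/flip/shift
  for (draw in 1:10) {
    out <- augment_pair(fr, mk, augment_params(max_shift_fraction = 0,
                                               seed = 3), draw)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_lt(abs(sum(out$mask) / sum(mk) - 1), 0.10)
  }
})
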