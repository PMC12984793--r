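test_that("phantom generation is bit-identical for equal configs", {
  cfg <- small_phantom_config(seed = 7, noise_sd = 0.04)
  expect_identical(generate_phantom(cfg), generate_phantom(cfg))
})

test_that("zero contraction freezes the masks across the cycle", {
  case <- generate_phantom(small_phantom_config(seed = 3,
                                                contraction_amplitude = 0))
  for (t in 2:length(case$masks)) {
    expect_identical(case$masks[[t]], case$masks[[1]])
  }
})

test_that("noiseless phantoms take exactly the configured intensity levels", {
  lv <- c(background = 0.2, myocardium = 0.5, blood_pool = 0.9)
  case <- generate_phantom(small_phantom_config(seed = 5, noise_sd = 0,
                                                intensity_levels = lv))
  expect_setequal(unique(as.vector(case$frames[[1]])), unname(lv))
})

test_that("mask topology holds across a 50-seed sweep", {
  for (seed in 1:50) {
    case <- generate_phantom(phantom_config(
      image_size = 96L, n_frames = 2L, endo_radius_range = c(12, 16),
      wall_thickness_range = c(5, 7), rv_offset = 30, seed = seed))
    for (m in case$masks) {
      expect_true(all(unlist(m) %in% c(0, 1)))
      # cavity and myocardium disjoint
      expect_equal(sum(m$lv_cavity * m$lv_myocardium), 0)
      expect_equal(sum(m$rv_cavity * (m$lv_cavity + m$lv_myocardium)), 0)
      # enclosure: every cavity boundary pixel touches myocardium (8-adj)
      cav <- m$lv_cavity
      myo <- m$lv_myocardium
      fg <- which(cav == 1, arr.ind = TRUE)
      h <- nrow(cav); w <- ncol(cav)
      for (i in seq_len(nrow(fg))) {
        r <- fg[i, 1]; c <- fg[i, 2]
        nb_r <- max(1, r - 1):min(h, r + 1)
        nb_c <- max(1, c - 1):min(w, c + 1)
        if (any(cav[nb_r, nb_c] == 0)) {
          expect_true(any(myo[nb_r, nb_c] == 1),
                      label = sprintf("seed %d pixel (%d,%d) enclosed",
                                      seed, r, c))
        }
      }
    }
  }
})

test_that("cavity area follows a sinusoid within the sampling bound", {
  amp <- 0.25
  case <- generate_phantom(phantom_config(n_frames = 20L, noise_sd = 0,
                                          contraction_amplitude = amp,
                                          seed = 2))
  areas <- vapply(case$masks, function(m) sum(m$lv_cavity), numeric(1))
  # end-diastole at t = 0, minimum near mid-cycle
  expect_equal(which.max(areas), 1)
  expect_true(abs(which.min(areas) - 11) <= 1)
  # derivative bound of the squared-cosine contraction model
  bound <- 2 * pi * amp * max(areas) / length(areas)
  expect_lt(max(abs(diff(areas))), bound)
})

test_that("infarct injection with neutral parameters only adds the mask", {
  case <- generate_phantom(small_phantom_config(seed = 9))
  inf <- inject_infarct(case, 40, 120, intensity_delta = 0,
                        motion_damping = 1)
  expect_identical(inf$frames, case$frames)
  expect_identical(inf$masks, case$masks)
  expect_false(is.null(inf$infarct_mask))
})

test_that("infarct mask is confined to the myocardium on every frame", {
  case <- generate_phantom(small_phantom_config(seed = 10))
  inf <- inject_infarct(case, 10, 100, intensity_delta = -0.2,
                        motion_damping = 0.4)
  for (t in seq_along(inf$infarct_mask)) {
    expect_true(all(inf$infarct_mask[[t]] <= inf$masks[[t]]$lv_myocardium))
  }
})

test_that("a 90-degree arc covers about a quarter of the myocardium", {
  # oracle: pixel count of a brute-force sector rasterization
  case <- generate_phantom(phantom_config(seed = 4, noise_sd = 0))
  inf <- inject_infarct(case, 15, 90, intensity_delta = 0,
                        motion_damping = 1)
  frac <- sum(inf$infarct_mask[[1]]) / sum(inf$masks[[1]]$lv_myocardium)
  expect_lt(abs(frac - 0.25), 0.05)
  # brute-force sector count over the myocardium pixels
  cfg <- case$config
  myo <- which(inf$masks[[1]]$lv_myocardium == 1, arr.ind = TRUE)
  ang <- (atan2((myo[, 2] - cfg$lv_center[2]) / 0.9,
                myo[, 1] - cfg$lv_center[1]) * 180 / pi - 15) %% 360
  expect_equal(sum(inf$infarct_mask[[1]]), sum(ang < 90))
})

test_that("invalid configurations name the offending field", {
  expect_error(phantom_config(contraction_amplitude = 0.5),
               "contraction_amplitude")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(endo_radius_range = c(100, 120)),
               "endo_radius_range")
  case <- generate_phantom(small_phantom_config())
  expect_error(inject_infarct(case, 0, 0), "arc_span_deg")
  expect_error(inject_infarct(case, 0, 400), "arc_span_deg")
})

test_that("phantom cases serialize to PNG with a JSON sidecar", {
  case <- generate_phantom(small_phantom_config(seed = 2, n_frames = 2L))
  dir <- withr::local_tempdir()
  write_phantom_case(case, dir)
  expect_true(file.exists(file.path(dir, "frame_001.png")))
  expect_true(file.exists(file.path(dir, "mask_lv_cavity_002.png")))
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  expect_equal(cfg$seed, 2)
  # masks survive the 8-bit round trip exactly
  m <- read_mask(file.path(dir, "mask_lv_cavity_001.png"))
  expect_identical(m, case$masks[[1]]$lv_cavity)
})
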