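# End-to-end orchestration: phantom data -> preprocessing -> structure CNN
# -> SAE + snake refinement -> metrics, and ROI -> attention U-Net -> MI
# metrics. Splits are case-level and seeded; every run emits a manifest
# (seeds, configuration hash, result hashes) so reruns can be verified to
# be bit-identical.

#' Split case identifiers into train/validation/test sets
#'
#' Case-level splitting (never slice-level: all frames of one phantom stay
#' in the same split) with largest-remainder rounding of the fractions.
#' Deterministic under the seed.
#'
#' @param case_ids Vector of case identifiers (length >= 3).
#' @param fractions Numeric triple summing to 1.
#' @param seed Integer seed.
#' @return A list with `train`, `val`, `test`.
#' @export
split_dataset <- function(case_ids, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  n <- length(case_ids)
  if (n < 3) stop("need at least 3 cases to split", call. = FALSE)
  if (abs(sum(fractions) - 1) > 1e-9 || any(fractions <= 0)) {
    stop("split fractions must be positive and sum to 1", call. = FALSE)
  }
  exact <- fractions * n
  sizes <- floor(exact)
  rem <- exact - sizes
  short <- n - sum(sizes)
  if (short > 0) {
    order_rem <- order(rem, decreasing = TRUE)
    sizes[order_rem[seq_len(short)]] <- sizes[order_rem[seq_len(short)]] + 1
  }
  if (any(sizes == 0)) {
    stop("too few cases for the requested fractions", call. = FALSE)
  }
  with_phantom_seed(seed, {
    ord <- sample(case_ids)
    list(train = ord[seq_len(sizes[1])],
         val = ord[sizes[1] + seq_len(sizes[2])],
         test = ord[sizes[1] + sizes[2] + seq_len(sizes[3])])
  })
}

# ROI training items for one phantom case: normalized full frame, truth-mask
# ROI box (training path), bilinear 64x64 frame crop, nearest 64x64 mask crop
phantom_roi_items <- function(case, structure = "lv_cavity",
                              roi_padding = 8, roi_size = 64L,
                              frames = NULL) {
  nt <- length(case$frames)
  frames <- frames %||% seq_len(nt)
  purrr::map(frames, function(t) {
    fr <- normalize_intensity(case$frames[[t]])
    mk <- case$masks[[t]][[structure]]
    box <- extract_roi(mk, padding = roi_padding)
    list(x = crop_and_resize(fr, box, roi_size),
         y = crop_and_resize(mk, box, roi_size, is_mask = TRUE),
         box = box, frame_index = t)
  })
}

#' Build a case-level phantom ROI dataset
#'
#' Generates `n_cases` phantoms (seeds `seed + 1 .. seed + n_cases`),
#' normalizes each frame, extracts the padded ROI around the target
#' structure and returns 64x64 frame/mask pairs grouped by case.
#'
#' @param n_cases Number of phantom cases.
#' @param structure One of `"lv_cavity"`, `"lv_myocardium"`, `"rv_cavity"`.
#' @param frames_per_case How many cine frames per case to keep (evenly
#'   spaced through the cycle).
#' @param seed Integer seed.
#' @param roi_padding ROI padding in pixels at the full-frame scale.
#' @param image_size Phantom frame side (smaller sizes speed up tests).
#' @param ... Further arguments to [phantom_config()].
#' @return A list with `cases` (named list of per-case item lists) and
#'   `case_ids`.
#' @export
phantom_roi_dataset <- function(n_cases, structure = "lv_cavity",
                                frames_per_case = 2, seed = 1L,
                                roi_padding = 8, image_size = 256L, ...) {
  ids <- sprintf("case%03d", seq_len(n_cases))
  cases <- purrr::map(seq_len(n_cases), function(i) {
    cfg <- phantom_config(image_size = image_size, seed = seed + i, ...)
    case <- generate_phantom(cfg)
    keep <- unique(round(seq(1, cfg$n_frames, length.out = frames_per_case)))
    phantom_roi_items(case, structure, roi_padding, frames = keep)
  })
  names(cases) <- ids
  list(cases = cases, case_ids = ids)
}

#' Pipeline configuration
#'
#' @param n_cases Number of phantom cases.
#' @param structure Target structure label.
#' @param split_fractions Train/validation/test fractions.
#' @param seed Master seed for the run.
#' @param arch Structure CNN architecture name.
#' @param train Structure-CNN [train_config()] overrides (list).
#' @param ablation One of `"cnn"`, `"cnn+sae"`, `"full"`.
#' @param frames_per_case Cine frames kept per case.
#' @param image_size Phantom frame side.
#' @param sae_config An [sae_train_config()].
#' @param snake An [snake_params()].
#' @param n_boot Bootstrap iterations in the metric report.
#' @param out_dir Optional directory for metric CSVs and the manifest.
#' @export
pipeline_config <- function(n_cases = 20, structure = "lv_cavity",
                            split_fractions = c(0.70, 0.15, 0.15),
                            seed = 1L, arch = "shallow", train = list(),
                            ablation = c("full", "cnn", "cnn+sae"),
                            frames_per_case = 2, image_size = 256L,
                            sae_config = NULL, snake = snake_params(),
                            n_boot = 1000, out_dir = NULL) {
  ablation <- match.arg(ablation)
  if (abs(sum(split_fractions) - 1) > 1e-9) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  structure(list(n_cases = n_cases, structure = structure,
                 split_fractions = split_fractions, seed = as.integer(seed),
                 arch = arch, train = train, ablation = ablation,
                 frames_per_case = frames_per_case,
                 image_size = image_size,
                 sae_config = sae_config %||% sae_train_config(seed = seed),
                 snake = snake, n_boot = n_boot, out_dir = out_dir),
            class = "pipeline_config")
}

items_for <- function(dataset, ids) {
  unlist(lapply(dataset$cases[ids], identity), recursive = FALSE,
         use.names = FALSE)
}

#' Run the cardiac-structure segmentation pipeline on phantoms
#'
#' Generates phantom data, splits it at case level, trains the configured
#' CNN on the training split, optionally trains the SAE on the CNN's own
#' training-split predictions versus ground truth and applies SAE (and
#' snake) refinement, and reports test-split metrics. The returned manifest
#' carries the seed, a configuration hash and hashes of the result tables,
#' so two runs with the same configuration can be compared bit for bit.
#'
#' @param config A [pipeline_config()].
#' @return A list of class `cineseg_structure_run`: `report`
#'   (a [metric_report()]), `model`, `sae` (or `NULL`), `split`,
#'   `manifest`.
#' @export
run_structure_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  ds <- phantom_roi_dataset(config$n_cases, config$structure,
                            config$frames_per_case, config$seed,
                            image_size = config$image_size)
  split <- split_dataset(ds$case_ids, config$split_fractions, config$seed)
  train_items <- items_for(ds, split$train)
  test_items <- items_for(ds, split$test)

  tc <- do.call(train_config,
                utils::modifyList(list(seed = config$seed), config$train))
  model <- train_structure_model(config$arch, train_items, tc)

  refine_with_sae <- config$ablation %in% c("cnn+sae", "full")
  sae <- NULL
  if (refine_with_sae) {
    pairs <- lapply(train_items, function(it) {
      pred <- binarize(predict_structure_mask(model, it$x))
      list(corrupted = resample_mask(pred, 64L), clean = it$y)
    })
    sae <- train_sae(pairs, config = config$sae_config)
  }

  preds <- vector("list", length(test_items))
  probs <- vector("list", length(test_items))
  for (i in seq_along(test_items)) {
    it <- test_items[[i]]
    pm <- predict_structure_mask(model, it$x)
    mask <- resample_mask(binarize(pm), 64L)
    probs[[i]] <- resample_frame(pm, 64L)
    if (refine_with_sae) {
      ref <- refine_mask(sae, mask)
      mask <- binarize(ref)
      probs[[i]] <- ref
    }
    if (config$ablation == "full" && sum(mask) > 0) {
      ct <- evolve_contour(it$x, mask, config$snake)
      snake_mask <- contour_to_mask(ct, dim(it$x))
      if (sum(snake_mask) > 0) mask <- snake_mask
    }
    preds[[i]] <- mask
  }
  truths <- lapply(test_items, `[[`, "y")
  report <- metric_report(preds, truths, probs, n_boot = config$n_boot,
                          seed = config$seed)
  manifest <- make_manifest(config, list(per_case = report$per_case,
                                         summary = report$summary))
  if (!is.null(config$out_dir)) {
    write_run_outputs(config$out_dir, report, manifest)
  }
  structure(list(report = report, model = model, sae = sae, split = split,
                 manifest = manifest),
            class = "cineseg_structure_run")
}

#' Run the infarct-localization pipeline on phantoms
#'
#' Generates infarcted phantoms, localizes a myocardial ROI from the image
#' (prediction-driven: no ground truth enters the inference path), trains
#' the attention U-Net on the training split with validation-based early
#' stopping, and reports test-split metrics with bootstrap CIs plus the
#' pooled ROC-AUC.
#'
#' @param n_cases Number of infarcted phantom cases.
#' @param seed Master seed.
#' @param image_size Phantom frame side.
#' @param mi_config An [mi_train_config()].
#' @param n_boot Bootstrap iterations.
#' @param out_dir Optional output directory.
#' @return A list of class `cineseg_mi_run` with `report`, `trained`,
#'   `split`, `manifest`.
#' @export
run_mi_pipeline <- function(n_cases = 12, seed = 1L, image_size = 256L,
                            mi_config = NULL, n_boot = 1000,
                            out_dir = NULL) {
  mi_config <- mi_config %||% mi_train_config(seed = seed)
  ids <- sprintf("case%03d", seq_len(n_cases))
  items <- purrr::map(seq_len(n_cases), function(i) {
    with_phantom_seed(seed + 7919L * i, {
      arc_start <- stats::runif(1, 0, 360)
      arc_span <- stats::runif(1, 60, 120)
    })
    cfg <- phantom_config(image_size = image_size, seed = seed + i,
                          infarct = list(arc_start_deg = arc_start,
                                         arc_span_deg = arc_span,
                                         intensity_delta = -0.18,
                                         motion_damping = 0.3))
    case <- generate_phantom(cfg)
    t <- 1L
    fr <- normalize_intensity(case$frames[[t]])
    # prediction-driven localization: threshold the image itself
    coarse <- binarize(fr, 0.6)
    coarse <- morph_clean(largest_component(coarse))
    box <- localize_roi(coarse, padding = 24)
    x <- gray_to_3channel(crop_and_resize(fr, box, 128L))
    y <- crop_and_resize(case$infarct_mask[[t]], box, 128L, is_mask = TRUE)
    list(x = x, y = y)
  })
  names(items) <- ids
  split <- split_dataset(ids, seed = seed)
  trained <- train_mi_model(NULL, items[split$train], items[split$val],
                            config = mi_config)
  test_items <- items[split$test]
  probs <- lapply(test_items, function(it) predict_infarct(trained, it$x))
  preds <- lapply(probs, binarize)
  truths <- lapply(test_items, `[[`, "y")
  report <- metric_report(preds, truths, probs, n_boot = n_boot,
                          seed = seed)
  manifest <- make_manifest(
    list(n_cases = n_cases, seed = seed, image_size = image_size,
         mi = unclass(mi_config)),
    list(per_case = report$per_case, summary = report$summary))
  if (!is.null(out_dir)) write_run_outputs(out_dir, report, manifest)
  structure(list(report = report, trained = trained, split = split,
                 manifest = manifest),
            class = "cineseg_mi_run")
}

make_manifest <- function(config, results) {
  cfg <- rapply(unclass(config), unclass, how = "replace")
  cfg$out_dir <- NULL  # output location must not affect the run identity
  list(seed = config$seed %||% NA,
       config_hash = rlang::hash(cfg),
       result_hashes = lapply(results, rlang::hash),
       package_version = as.character(utils::packageVersion("cineseg")))
}

write_run_outputs <- function(dir, report, manifest) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_case, file.path(dir, "metrics_per_case.csv"),
                   row.names = FALSE)
  utils::write.csv(report$summary, file.path(dir, "metrics_summary.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Refinement ablation benchmark on corrupted phantom masks
#'
#' Builds clean 64x64 phantom structure masks, degrades an evaluation set
#' with CNN-artifact-like corruption (the raw-prediction stand-in), trains
#' the SAE on an independent corrupted/clean training set, and measures
#' mean Dice and mean Hausdorff distance at each refinement stage:
#' corrupted masks alone, after SAE refinement, and after SAE plus
#' active-contour refinement against the ROI image.
#'
#' @param n_eval Evaluation masks.
#' @param n_train SAE training pairs.
#' @param seed Integer seed.
#' @param sae_config An [sae_train_config()].
#' @param snake An [snake_params()].
#' @return A list with `stages` (tibble: stage, mean_dice, mean_hd) and
#'   `per_case` (tibble of per-case Dice/HD per stage).
#' @export
refinement_ablation <- function(n_eval = 100, n_train = 120, seed = 1L,
                                sae_config = sae_train_config(seed = seed),
                                snake = snake_params()) {
  total <- n_eval + n_train
  ds <- phantom_roi_dataset(total, frames_per_case = 1, seed = seed)
  items <- items_for(ds, ds$case_ids)
  corrupt <- function(it, i) corrupt_mask(it$y, seed = seed + 31L * i)
  train_pairs <- lapply(seq_len(n_train), function(i) {
    it <- items[[i]]
    list(corrupted = corrupt(it, i), clean = it$y)
  })
  sae <- train_sae(train_pairs, config = sae_config)
  eval_items <- items[n_train + seq_len(n_eval)]
  per_case <- purrr::map_dfr(seq_len(n_eval), function(i) {
    it <- eval_items[[i]]
    raw <- corrupt(it, n_train + i)
    refined <- binarize(refine_mask(sae, raw))
    snake_mask <- refined
    if (sum(refined) > 0) {
      ct <- evolve_contour(it$x, refined, snake)
      cm <- contour_to_mask(ct, dim(it$x))
      if (sum(cm) > 0) snake_mask <- cm
    }
    truth <- it$y
    gct <- extract_contour(truth)
    stage_row <- function(stage, m) {
      hd <- if (sum(m) > 0) hausdorff(extract_contour(m), gct) else NA_real_
      tibble::tibble(case = i, stage = stage,
                     dice = as.numeric(dsc(m, truth)), hd = hd)
    }
    dplyr::bind_rows(stage_row("cnn", raw),
                     stage_row("cnn+sae", refined),
                     stage_row("cnn+sae+snake", snake_mask))
  })
  stages <- per_case |>
    dplyr::group_by(.data$stage) |>
    dplyr::summarise(mean_dice = mean(.data$dice),
                     mean_hd = mean(.data$hd, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::arrange(factor(.data$stage,
                          levels = c("cnn", "cnn+sae", "cnn+sae+snake")))
  list(stages = stages, per_case = per_case)
}
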