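# Synthetic short-axis cine phantoms with pixel-exact ground truth.
#
# The generator draws a contracting elliptical LV blood pool inside an annular
# myocardium plus a crescent-shaped RV cavity, over one cardiac cycle, and
# rasterizes noise-free binary masks for each structure alongside the noisy
# intensity frames. It exists so that every downstream stage (ROI extraction,
# CNN training, SAE/snake refinement, infarct localization, metrics) can be
# exercised end-to-end without any clinical download.

#' Configuration for the synthetic cine phantom generator
#'
#' All stochastic behaviour of [generate_phantom()] is governed by this
#' configuration, including the seed, so equal configurations yield
#' bit-identical phantoms.
#'
#' @param image_size Pixels per side of the square frame.
#' @param n_frames Number of cine frames covering one cardiac cycle.
#' @param lv_center `(row, col)` centre of the left ventricle in pixels.
#'   Defaults to slightly right of the frame centre so the right ventricle
#'   fits on the left.
#' @param endo_radius_range Range (pixels) from which the end-diastolic
#'   endocardial radius is drawn uniformly, per case.
#' @param wall_thickness_range Range (pixels) for the myocardial wall
#'   thickness, drawn uniformly per case.
#' @param rv_offset Column offset (pixels) of the right-ventricular cavity
#'   centre, to the left of `lv_center`.
#' @param contraction_amplitude Fractional radius reduction at end-systole,
#'   in `[0, 0.4]`. The endocardial radius follows
#'   `r(t) = r0 * (1 - a * (1 - cos(2*pi*t/T)) / 2)`, i.e. end-diastole at
#'   `t = 0`.
#' @param intensity_levels Named numeric vector `(background, myocardium,
#'   blood_pool)` in `[0, 1]`.
#' @param noise_sd Standard deviation of the additive Gaussian intensity
#'   noise (applied after rasterization, clipped to `[0, 1]`). Masks are
#'   never noisy.
#' @param infarct Optional list with fields `arc_start_deg`, `arc_span_deg`,
#'   `intensity_delta` and `motion_damping` (in `[0, 1]`; 1 = no damping)
#'   describing an infarcted angular sector of the myocardium.
#' @param seed Integer seed controlling all randomness of the generator.
#'
#' @return An object of class `phantom_config`.
#' @seealso [generate_phantom()], [inject_infarct()]
#' @export
phantom_config <- function(image_size = 256L,
                           n_frames = 20L,
                           lv_center = NULL,
                           endo_radius_range = c(24, 34),
                           wall_thickness_range = c(10, 14),
                           rv_offset = 62,
                           contraction_amplitude = 0.25,
                           intensity_levels = c(background = 0.15,
                                                myocardium = 0.45,
                                                blood_pool = 0.85),
                           noise_sd = 0.03,
                           infarct = NULL,
                           seed = 1L) {
  if (is.null(lv_center)) {
    lv_center <- c(image_size / 2, image_size / 2 + image_size / 16)
  }
  cfg <- structure(
    list(image_size = as.integer(image_size),
         n_frames = as.integer(n_frames),
         lv_center = as.numeric(lv_center),
         endo_radius_range = as.numeric(endo_radius_range),
         wall_thickness_range = as.numeric(wall_thickness_range),
         rv_offset = as.numeric(rv_offset),
         contraction_amplitude = as.numeric(contraction_amplitude),
         intensity_levels = intensity_levels,
         noise_sd = as.numeric(noise_sd),
         infarct = infarct,
         seed = as.integer(seed)),
    class = "phantom_config")
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid phantom configuration: field '%s' %s", field, msg),
         call. = FALSE)
  }
  if (cfg$image_size < 32) stop_cfg("image_size", "must be at least 32")
  if (cfg$n_frames < 1) stop_cfg("n_frames", "must be at least 1")
  if (cfg$contraction_amplitude < 0 || cfg$contraction_amplitude > 0.4) {
    stop_cfg("contraction_amplitude", "must lie in [0, 0.4]")
  }
  if (cfg$noise_sd < 0) stop_cfg("noise_sd", "must be non-negative")
  if (any(cfg$intensity_levels < 0) || any(cfg$intensity_levels > 1)) {
    stop_cfg("intensity_levels", "must lie in [0, 1]")
  }
  margin <- 4
  if (max(cfg$endo_radius_range) + max(cfg$wall_thickness_range) + margin >=
      cfg$image_size / 2) {
    stop_cfg("endo_radius_range",
             "plus wall thickness and margin must fit within half the frame")
  }
  if (!is.null(cfg$infarct)) {
    inf <- cfg$infarct
    need <- c("arc_start_deg", "arc_span_deg", "intensity_delta",
              "motion_damping")
    missing <- setdiff(need, names(inf))
    if (length(missing)) {
      stop_cfg("infarct", paste("is missing", paste(missing, collapse = ", ")))
    }
    if (inf$arc_span_deg <= 0 || inf$arc_span_deg > 360) {
      stop_cfg("infarct$arc_span_deg", "must lie in (0, 360]")
    }
    if (inf$motion_damping < 0 || inf$motion_damping > 1) {
      stop_cfg("infarct$motion_damping", "must lie in [0, 1]")
    }
  }
  invisible(cfg)
}

# Run code under a private RNG stream, restoring the caller's stream after.
with_phantom_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic cine phantom case
#'
#' Renders `n_frames` short-axis frames of a contracting heart phantom and
#' the matching noise-free binary masks for the LV cavity, LV myocardium and
#' RV cavity. If the configuration carries an `infarct` block, an additional
#' per-frame infarct mask is produced; infarcted myocardium has its intensity
#' shifted by `intensity_delta` and its local radial contraction scaled by
#' `motion_damping`.
#'
#' The generator is deterministic for a fixed configuration: the per-case
#' anatomy (end-diastolic radius, wall thickness) and the per-frame noise are
#' drawn from a private RNG stream seeded with `config$seed`.
#'
#' @param config A [phantom_config()].
#' @return An object of class `phantom_case`: a list with `frames` (list of
#'   `image_size` x `image_size` matrices in `[0, 1]`), `masks` (per frame, a
#'   list with binary matrices `lv_cavity`, `lv_myocardium`, `rv_cavity`),
#'   `infarct_mask` (per-frame binary matrices, or `NULL`), and `config`.
#' @examples
#' case <- generate_phantom(phantom_config(image_size = 96, n_frames = 4))
#' range(case$frames[[1]])
#' sum(case$masks[[1]]$lv_cavity * case$masks[[1]]$lv_myocardium)  # disjoint
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  with_phantom_seed(config$seed, {
    n <- config$image_size
    nt <- config$n_frames
    r_endo0 <- stats::runif(1, config$endo_radius_range[1],
                            config$endo_radius_range[2])
    wall <- stats::runif(1, config$wall_thickness_range[1],
                         config$wall_thickness_range[2])
    a <- config$contraction_amplitude
    cx <- config$lv_center[1]
    cy <- config$lv_center[2]
    aspect <- 0.9  # column semi-axis relative to row semi-axis

    rows <- matrix(seq_len(n), n, n)
    cols <- matrix(seq_len(n), n, n, byrow = TRUE)
    dr <- rows - cx
    dc <- (cols - cy) / aspect
    rad <- sqrt(dr^2 + dc^2)          # elliptical radius in row-pixel units
    theta <- atan2(dc, dr) * 180 / pi # degrees in [-180, 180]

    inf <- config$infarct
    damp <- matrix(1, n, n)
    if (!is.null(inf) && inf$motion_damping < 1) {
      in_arc <- angle_in_arc(theta, inf$arc_start_deg, inf$arc_span_deg)
      damp[in_arc] <- inf$motion_damping
    }

    # RV geometry: outer ellipse minus an inner ellipse shifted toward the
    # LV, clipped against the LV structures, giving a thin crescent.
    rv_cy <- cy - config$rv_offset
    rv_r0 <- r_endo0 * 1.15
    drv <- rows - cx
    dcv <- (cols - rv_cy) / 1.25
    rv_rad_out <- sqrt(drv^2 + dcv^2)
    dcv_in <- (cols - (rv_cy + 0.45 * rv_r0)) / 1.25
    rv_rad_in <- sqrt(drv^2 + dcv_in^2)

    lv <- config$intensity_levels
    frames <- vector("list", nt)
    masks <- vector("list", nt)
    infarct_masks <- if (is.null(inf)) NULL else vector("list", nt)

    for (t in seq_len(nt)) {
      phase <- (1 - cos(2 * pi * (t - 1) / nt)) / 2
      contr <- 1 - a * damp * phase
      r_endo_t <- r_endo0 * contr
      r_epi_t <- r_endo0 * contr + wall

      cavity <- rad <= r_endo_t
      myo <- rad <= r_epi_t & !cavity
      rv_contr <- 1 - a * 0.6 * phase
      rv <- rv_rad_out <= rv_r0 * rv_contr &
        rv_rad_in > rv_r0 * 0.85 * rv_contr &
        !cavity & !myo

      img <- matrix(lv[["background"]], n, n)
      img[myo] <- lv[["myocardium"]]
      img[cavity] <- lv[["blood_pool"]]
      img[rv] <- lv[["blood_pool"]]

      if (!is.null(inf)) {
        arc <- angle_in_arc(theta, inf$arc_start_deg, inf$arc_span_deg)
        infarct <- myo & arc
        img[infarct] <- pmin(1, pmax(0, img[infarct] + inf$intensity_delta))
        infarct_masks[[t]] <- mode_binary(infarct)
      }
      if (config$noise_sd > 0) {
        img <- img + matrix(stats::rnorm(n * n, 0, config$noise_sd), n, n)
        img <- matrix(pmin(pmax(img, 0), 1), n, n)
      }
      frames[[t]] <- img
      masks[[t]] <- list(lv_cavity = mode_binary(cavity),
                         lv_myocardium = mode_binary(myo),
                         rv_cavity = mode_binary(rv))
    }

    structure(list(frames = frames, masks = masks,
                   infarct_mask = infarct_masks, config = config),
              class = "phantom_case")
  })
}

angle_in_arc <- function(theta_deg, start_deg, span_deg) {
  rel <- (theta_deg - start_deg) %% 360
  rel < span_deg
}

mode_binary <- function(x) {
  m <- matrix(as.numeric(x), nrow(x), ncol(x))
  m
}

#' Add an infarcted sector to an existing phantom case
#'
#' Re-renders the case from its own configuration (same seed, hence same
#' anatomy and noise) with an infarct arc added: myocardial pixels inside
#' the angular sector get their intensity shifted by `intensity_delta` and
#' their radial contraction scaled by `motion_damping`. With
#' `motion_damping = 1` and `intensity_delta = 0` the frames are identical
#' to the input and only the infarct mask is added.
#'
#' @param case A `phantom_case`.
#' @param arc_start_deg Start angle of the sector (degrees).
#' @param arc_span_deg Angular span (degrees), in `(0, 360]`.
#' @param intensity_delta Additive intensity change inside the sector.
#' @param motion_damping Multiplier in `[0, 1]` on the local contraction
#'   amplitude; 1 leaves motion unchanged, 0 freezes the sector.
#' @return A new `phantom_case` with `infarct_mask` populated.
#' @export
inject_infarct <- function(case, arc_start_deg, arc_span_deg,
                           intensity_delta = -0.15, motion_damping = 0.3) {
  stopifnot(inherits(case, "phantom_case"))
  if (arc_span_deg <= 0 || arc_span_deg > 360) {
    stop("arc_span_deg must lie in (0, 360]", call. = FALSE)
  }
  cfg <- case$config
  cfg$infarct <- list(arc_start_deg = arc_start_deg,
                      arc_span_deg = arc_span_deg,
                      intensity_delta = intensity_delta,
                      motion_damping = motion_damping)
  validate_phantom_config(cfg)
  generate_phantom(cfg)
}

#' @export
print.phantom_case <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<phantom_case> %d frames of %dx%d, seed %d%s\n",
              cfg$n_frames, cfg$image_size, cfg$image_size, cfg$seed,
              if (is.null(cfg$infarct)) "" else ", with infarct"))
  invisible(x)
}

#' Per-frame structure areas of a phantom case
#'
#' @param case A `phantom_case`.
#' @return A tibble with one row per frame and structure, and the foreground
#'   pixel count of that structure's mask.
#' @export
phantom_areas <- function(case) {
  stopifnot(inherits(case, "phantom_case"))
  purrr::map_dfr(seq_along(case$masks), function(t) {
    m <- case$masks[[t]]
    tibble::tibble(frame = t,
                   structure = names(m),
                   area_px = purrr::map_dbl(m, sum))
  })
}

#' Write a phantom case to disk
#'
#' Writes frames and masks as 8-bit grayscale PNG plus a JSON sidecar with
#' the generating configuration; optionally also a 4-D NIfTI stack of the
#' frames (time on the fourth axis).
#'
#' @param case A `phantom_case`.
#' @param dir Output directory (created if absent).
#' @param nifti Also write `frames.nii.gz`?
#' @return `dir`, invisibly.
#' @export
write_phantom_case <- function(case, dir, nifti = FALSE) {
  stopifnot(inherits(case, "phantom_case"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nt <- length(case$frames)
  for (t in seq_len(nt)) {
    png::writePNG(case$frames[[t]],
                  file.path(dir, sprintf("frame_%03d.png", t)))
    for (s in names(case$masks[[t]])) {
      png::writePNG(case$masks[[t]][[s]],
                    file.path(dir, sprintf("mask_%s_%03d.png", s, t)))
    }
    if (!is.null(case$infarct_mask)) {
      png::writePNG(case$infarct_mask[[t]],
                    file.path(dir, sprintf("mask_infarct_%03d.png", t)))
    }
  }
  cfg <- case$config
  cfg_out <- unclass(cfg)
  jsonlite::write_json(cfg_out, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  if (nifti) {
    arr <- array(unlist(case$frames),
                 dim = c(dim(case$frames[[1]]), 1, nt))
    RNifti::writeNifti(RNifti::asNifti(arr), file.path(dir, "frames.nii.gz"))
  }
  invisible(dir)
}
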