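# Frame/mask preprocessing: two-stage resampling, intensity normalization,
# prediction-driven ROI extraction, morphological cleanup and online
# augmentation.
#
# Interpolation discipline is fixed throughout the package: grayscale
# intensity frames are resampled bilinearly, binary masks with
# nearest-neighbour interpolation so labels never mix. Pixel coordinates are
# 0-based and half-open; matrices are row-major (row, col).

assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("'%s' must be a matrix", arg),
                             call. = FALSE)
  if (!all(mask %in% c(0, 1))) {
    stop(sprintf("'%s' must be strictly binary (values in {0, 1})", arg),
         call. = FALSE)
  }
  invisible(mask)
}

assert_frame <- function(frame, arg = "frame") {
  if (!is.matrix(frame) || nrow(frame) == 0 || ncol(frame) == 0) {
    stop(sprintf("'%s' must be a non-empty numeric matrix", arg),
         call. = FALSE)
  }
  invisible(frame)
}

#' Resample an intensity frame to a square target size
#'
#' Bilinear interpolation; used for grayscale cine frames. Values stay
#' within the input's range.
#'
#' @param frame Numeric matrix.
#' @param target_size Output side length in pixels.
#' @return A `target_size` x `target_size` matrix.
#' @export
resample_frame <- function(frame, target_size) {
  assert_frame(frame)
  stopifnot(target_size > 0)
  if (nrow(frame) == target_size && ncol(frame) == target_size) return(frame)
  out <- EBImage::resize(frame, w = target_size, h = target_size,
                         filter = "bilinear")
  matrix(pmin(max(frame), pmax(min(frame), out)), target_size, target_size)
}

#' Resample a binary mask to a square target size
#'
#' Nearest-neighbour interpolation so the output stays strictly binary.
#'
#' @inheritParams resample_frame
#' @param mask Binary matrix.
#' @export
resample_mask <- function(mask, target_size) {
  assert_mask(mask)
  stopifnot(target_size > 0)
  if (nrow(mask) == target_size && ncol(mask) == target_size) return(mask)
  out <- EBImage::resize(mask, w = target_size, h = target_size,
                         filter = "none")
  matrix(as.numeric(out), target_size, target_size)
}

#' Min-max intensity normalization to [0, 1]
#'
#' Applied after full-frame resampling. Normalization is per frame; a
#' constant frame maps to all zeros (the degenerate case of a zero range).
#'
#' @param frame Numeric matrix.
#' @export
normalize_intensity <- function(frame) {
  assert_frame(frame)
  lo <- min(frame)
  hi <- max(frame)
  if (hi == lo) return(matrix(0, nrow(frame), ncol(frame)))
  (frame - lo) / (hi - lo)
}

#' Euclidean disk structuring element
#'
#' Pixels whose centre lies within Euclidean distance `radius` of the
#' element's centre (the same convention as scikit-image's `disk`).
#'
#' @param radius Radius in pixels.
#' @return A `(2*radius+1)` square 0/1 matrix.
#' @export
disk_kernel <- function(radius) {
  r <- as.integer(radius)
  ix <- seq(-r, r)
  k <- outer(ix, ix, function(i, j) as.numeric(i * i + j * j <= r * r))
  k
}

#' Morphological cleanup of a binary mask
#'
#' Binary opening followed by closing with a disk-shaped structuring element
#' (default radius 2 pixels): removes small isolated artifacts, then fills
#' comparable gaps and smooths region boundaries.
#'
#' @param mask Binary matrix.
#' @param radius Disk radius in pixels.
#' @export
morph_clean <- function(mask, radius = 2) {
  assert_mask(mask)
  if (sum(mask) == 0) return(mask)
  k <- disk_kernel(radius)
  out <- EBImage::closing(EBImage::opening(mask, k), k)
  matrix(as.numeric(out > 0.5), nrow(mask), ncol(mask))
}

#' Padded bounding box of a mask's foreground
#'
#' The tight foreground bounding box, expanded by `padding` pixels on every
#' side and clamped to the image. Coordinates are 0-based and half-open:
#' the box covers rows `[row_min, row_max)` and columns `[col_min, col_max)`.
#'
#' Errors on an empty mask ("empty prediction"); callers that need a total
#' pipeline should fall back explicitly (see [localize_roi()]).
#'
#' @param mask Binary matrix with at least one foreground pixel.
#' @param padding Padding in pixels on each side.
#' @return A list of class `roi_box` with `row_min`, `row_max`, `col_min`,
#'   `col_max`, `padding`.
#' @export
extract_roi <- function(mask, padding = 8) {
  assert_mask(mask)
  fg <- which(mask == 1, arr.ind = TRUE)
  if (nrow(fg) == 0) {
    stop("empty prediction: mask has no foreground pixels", call. = FALSE)
  }
  h <- nrow(mask); w <- ncol(mask)
  box <- list(
    row_min = max(0L, min(fg[, 1]) - 1L - padding),
    row_max = min(h, max(fg[, 1]) + padding),
    col_min = max(0L, min(fg[, 2]) - 1L - padding),
    col_max = min(w, max(fg[, 2]) + padding),
    padding = padding)
  structure(box, class = "roi_box")
}

#' Prediction-driven ROI localization for inference
#'
#' Builds an ROI box from a predicted mask only; there is deliberately no
#' ground-truth parameter on the inference path. When the prediction is
#' empty, falls back (with a warning) to a centred box of half the frame
#' side so the pipeline stays total.
#'
#' @param pred_mask Predicted binary mask (full-frame scale).
#' @param padding Padding in pixels.
#' @return An `roi_box`.
#' @export
localize_roi <- function(pred_mask, padding = 8) {
  assert_mask(pred_mask, "pred_mask")
  if (sum(pred_mask) == 0) {
    warning("empty prediction; falling back to a centred half-frame ROI",
            call. = FALSE)
    h <- nrow(pred_mask); w <- ncol(pred_mask)
    return(structure(list(row_min = as.integer(h / 4),
                          row_max = as.integer(3 * h / 4),
                          col_min = as.integer(w / 4),
                          col_max = as.integer(3 * w / 4),
                          padding = padding),
                     class = "roi_box"))
  }
  extract_roi(pred_mask, padding)
}

#' Crop a frame (or mask) to an ROI box and resize
#'
#' Crops the half-open box then resizes to `out_size` x `out_size`;
#' bilinear for intensity frames, nearest-neighbour when `is_mask = TRUE`.
#'
#' @param frame Numeric matrix.
#' @param box An `roi_box` within the frame.
#' @param out_size Output side length.
#' @param is_mask Use nearest-neighbour interpolation and keep the output
#'   binary?
#' @export
crop_and_resize <- function(frame, box, out_size, is_mask = FALSE) {
  assert_frame(frame)
  stopifnot(inherits(box, "roi_box"))
  if (box$row_max <= box$row_min || box$col_max <= box$col_min) {
    stop("degenerate ROI box with zero area", call. = FALSE)
  }
  if (box$row_min < 0 || box$col_min < 0 ||
      box$row_max > nrow(frame) || box$col_max > ncol(frame)) {
    stop("ROI box exceeds frame bounds", call. = FALSE)
  }
  crop <- frame[(box$row_min + 1):box$row_max,
                (box$col_min + 1):box$col_max, drop = FALSE]
  if (is_mask) resample_mask(crop, out_size) else resample_frame(crop, out_size)
}

#' Online augmentation parameters
#'
#' Random rotations up to +/-50 degrees, horizontal flips and spatial shifts
#' up to +/-10% of each dimension, sampled uniformly (flip with probability
#' one half), applied online and independently at each training iteration.
#'
#' @param max_rotation_deg Maximum absolute rotation (degrees).
#' @param allow_hflip Allow horizontal flips?
#' @param max_shift_fraction Maximum absolute shift as a fraction of each
#'   dimension, in `[0, 1)`.
#' @param seed Integer seed; together with the draw index it makes every
#'   sampled transform reproducible.
#' @return An object of class `augment_params`.
#' @export
augment_params <- function(max_rotation_deg = 50,
                           allow_hflip = TRUE,
                           max_shift_fraction = 0.10,
                           seed = 1L) {
  stopifnot(max_rotation_deg >= 0,
            max_shift_fraction >= 0, max_shift_fraction < 1)
  structure(list(max_rotation_deg = max_rotation_deg,
                 allow_hflip = allow_hflip,
                 max_shift_fraction = max_shift_fraction,
                 seed = as.integer(seed)),
            class = "augment_params")
}

# Sample the transform for a given (seed, draw_index); a pure function of
# its arguments.
sample_transform <- function(params, draw_index) {
  with_phantom_seed(params$seed + 1000003L * as.integer(draw_index), {
    list(angle = stats::runif(1, -params$max_rotation_deg,
                              params$max_rotation_deg),
         flip = params$allow_hflip && stats::runif(1) < 0.5,
         shift_r = stats::runif(1, -params$max_shift_fraction,
                                params$max_shift_fraction),
         shift_c = stats::runif(1, -params$max_shift_fraction,
                                params$max_shift_fraction))
  })
}

apply_transform <- function(img, tr, is_mask) {
  filt <- if (is_mask) "none" else "bilinear"
  out <- img
  if (tr$flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  if (tr$angle != 0) {
    out <- EBImage::rotate(out, tr$angle, filter = filt,
                           output.dim = dim(img), bg.col = 0)
  }
  dr <- round(tr$shift_r * nrow(img))
  dc <- round(tr$shift_c * ncol(img))
  if (dr != 0 || dc != 0) {
    out <- EBImage::translate(out, c(dr, dc), bg.col = 0)
  }
  m <- matrix(as.numeric(out), nrow(img), ncol(img))
  if (is_mask) matrix(as.numeric(m > 0.5), nrow(img), ncol(img)) else m
}

#' Apply one sampled augmentation to a frame/mask pair
#'
#' The identical transform (rotation, flip, shift) is applied to both; the
#' frame is interpolated bilinearly and the mask with nearest-neighbour so
#' it stays binary. Deterministic given `(params$seed, draw_index)`.
#'
#' @param frame Numeric matrix.
#' @param mask Binary matrix, same shape as `frame`.
#' @param params An [augment_params()].
#' @param draw_index Integer index of the training iteration; distinct
#'   indices give independent draws.
#' @return A list with transformed `frame` and `mask`.
#' @export
augment_pair <- function(frame, mask, params, draw_index = 1L) {
  assert_frame(frame)
  assert_mask(mask)
  stopifnot(all(dim(frame) == dim(mask)), inherits(params, "augment_params"))
  tr <- sample_transform(params, draw_index)
  list(frame = apply_transform(frame, tr, is_mask = FALSE),
       mask = apply_transform(mask, tr, is_mask = TRUE))
}
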