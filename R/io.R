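# Reading and writing the standard formats: PNG (8/16-bit grayscale) and
# NIfTI for frames and masks, CSV/JSON for contours. DICOM input is not
# supported (no reader available in this toolchain); convert to NIfTI or
# PNG upstream.

#' Read a grayscale intensity frame
#'
#' PNG files are read with the png package (values already in `[0, 1]`;
#' RGB input is averaged to one channel). NIfTI files are read with RNifti;
#' for 3-D/4-D volumes the requested slice of the first volume is
#' extracted, and `spacing` is taken from the header's pixel dimensions.
#'
#' @param path File path ending in `.png`, `.nii` or `.nii.gz`.
#' @param slice Slice index for 3-D/4-D NIfTI input.
#' @return A numeric matrix; NIfTI input carries a `spacing` attribute
#'   (mm/px for rows and columns).
#' @export
read_frame <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3) img <- apply(img[, , 1:3, drop = FALSE],
                                            c(1, 2), mean)
    return(img)
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    return(read_nifti_slice(path, 1L))
  }
  stop("unsupported image format: ", path, call. = FALSE)
}

#' @rdname read_frame
#' @export
read_nifti_slice <- function(path, slice = 1L) {
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  m <- if (length(d) == 2) {
    vol[, ]
  } else if (length(d) == 3) {
    vol[, , slice]
  } else {
    vol[, , slice, 1]
  }
  pix <- RNifti::pixdim(vol)
  structure(matrix(as.numeric(m), d[1], d[2]),
            spacing = as.numeric(pix[1:2]))
}

#' Read a binary mask (thresholding any grayscale input at 0.5)
#'
#' @inheritParams read_frame
#' @export
read_mask <- function(path) {
  m <- read_frame(path)
  sp <- attr(m, "spacing")
  out <- matrix(as.numeric(m >= 0.5), nrow(m), ncol(m))
  if (!is.null(sp)) attr(out, "spacing") <- sp
  out
}

#' Write a mask or probability map
#'
#' PNG output quantizes to 8-bit grayscale (adequate for binary masks and
#' display); use NIfTI output for probability maps that must keep full
#' precision.
#'
#' @param x Matrix in `[0, 1]`.
#' @param path Output path (`.png`, `.nii` or `.nii.gz`).
#' @export
write_map <- function(x, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(pmin(pmax(x, 0), 1), path)
    return(invisible(path))
  }
  if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
    return(invisible(path))
  }
  stop("unsupported output format: ", path, call. = FALSE)
}

#' Write a contour as a CSV point list or GeoJSON-like JSON
#'
#' CSV columns are `x`, `y` in 0-based pixel coordinates (x = column,
#' y = row). The JSON form mirrors a GeoJSON polygon: a single ring of
#' `[x, y]` pairs, explicitly closed.
#'
#' @param contour An n x 2 `(row, col)` contour matrix.
#' @param path Output path ending in `.csv` or `.json`.
#' @export
write_contour <- function(contour, path) {
  pts <- contour_points(contour)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    utils::write.csv(data.frame(x = pts[, 2] - 1, y = pts[, 1] - 1),
                     path, row.names = FALSE)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    ring <- lapply(seq_len(nrow(pts)), function(i) {
      c(pts[i, 2] - 1, pts[i, 1] - 1)
    })
    ring[[length(ring) + 1]] <- ring[[1]]
    jsonlite::write_json(
      list(type = "Polygon", coordinates = list(ring)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported contour format: ", path, call. = FALSE)
  }
  invisible(path)
}
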