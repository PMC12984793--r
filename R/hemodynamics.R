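# Aortic distensibility from per-frame segmented cross-sectional areas.
#
# D = (A_max - A_min) / (A_min * CPP) * 10^3, in 10^-3 mmHg^-1, where the
# areas come from the segmented ascending or descending aorta across the
# cardiac cycle and CPP is the central pulse pressure. Cases with
# CPP < 10 mmHg (or failing the validity rules) are excluded.

#' A per-case aortic area measurement
#'
#' @param areas Numeric vector of per-frame cross-sectional areas (mm^2),
#'   length >= 2, all positive.
#' @param cpp Central pulse pressure (mmHg).
#' @param vessel `"ascending"` or `"descending"`.
#' @param smooth Apply a 3-frame running median to the area series before
#'   taking the extrema? Off by default.
#' @return An object of class `aorta_measurement`.
#' @export
aorta_measurement <- function(areas, cpp,
                              vessel = c("ascending", "descending"),
                              smooth = FALSE) {
  vessel <- match.arg(vessel)
  areas <- as.numeric(areas)
  if (length(areas) < 2) stop("area series needs at least 2 frames",
                              call. = FALSE)
  if (any(!is.finite(areas)) || any(areas <= 0)) {
    stop("all areas must be finite and positive", call. = FALSE)
  }
  if (!is.finite(cpp)) stop("CPP must be finite", call. = FALSE)
  if (smooth) areas <- stats::runmed(areas, 3)
  structure(list(areas = areas, cpp = cpp, vessel = vessel),
            class = "aorta_measurement")
}

#' Aortic distensibility of a measurement
#'
#' `D = (A_max - A_min) / (A_min * CPP) * 1e3` in 10^-3 mmHg^-1. A CPP
#' below 10 mmHg raises an exclusion error (the case is dropped from
#' cohort-level analyses with its reason recorded).
#'
#' @param m An [aorta_measurement()].
#' @return Distensibility in 10^-3 mmHg^-1.
#' @examples
#' m <- aorta_measurement(c(1000, 1100, 1200, 1050), cpp = 40)
#' distensibility(m)  # (200/1000)/40 * 1e3 = 5
#' @export
distensibility <- function(m) {
  stopifnot(inherits(m, "aorta_measurement"))
  if (m$cpp < 10) {
    stop(sprintf("case excluded: CPP %.1f mmHg is below the 10 mmHg cutoff",
                 m$cpp), call. = FALSE)
  }
  a_max <- max(m$areas)
  a_min <- min(m$areas)
  (a_max - a_min) / (a_min * m$cpp) * 1e3
}

#' Cohort-level distensibility from tabular area data
#'
#' Takes a long table of per-frame areas and per-case pulse pressures,
#' applies the validity rules (positive areas, at least two frames, finite
#' CPP, CPP >= 10 mmHg) and returns one distensibility per case and
#' vessel; excluded cases are kept in the output with `excluded = TRUE` and
#' the exclusion reason.
#'
#' @param areas A data frame with columns `case`, `frame`, `vessel`,
#'   `area_mm2`.
#' @param cpp A data frame with columns `case`, `cpp_mmhg`.
#' @param smooth Passed to [aorta_measurement()].
#' @return A tibble with `case`, `vessel`, `distensibility`, `excluded`,
#'   `reason`.
#' @export
distensibility_table <- function(areas, cpp, smooth = FALSE) {
  stopifnot(all(c("case", "frame", "vessel", "area_mm2") %in% names(areas)),
            all(c("case", "cpp_mmhg") %in% names(cpp)))
  groups <- dplyr::distinct(areas, .data$case, .data$vessel)
  purrr::pmap_dfr(groups, function(case, vessel) {
    sub <- dplyr::filter(areas, .data$case == !!case,
                         .data$vessel == !!vessel)
    sub <- dplyr::arrange(sub, .data$frame)
    cp <- cpp$cpp_mmhg[match(case, cpp$case)]
    res <- tryCatch({
      m <- aorta_measurement(sub$area_mm2, cp, vessel, smooth = smooth)
      tibble::tibble(case = case, vessel = vessel,
                     distensibility = distensibility(m),
                     excluded = FALSE, reason = NA_character_)
    }, error = function(e) {
      tibble::tibble(case = case, vessel = vessel,
                     distensibility = NA_real_,
                     excluded = TRUE, reason = conditionMessage(e))
    })
    res
  })
}

#' Synthetic pulsatile aortic area series
#'
#' A sinusoidal area waveform over one cardiac cycle, used to exercise the
#' distensibility computation without segmentations.
#'
#' @param n_frames Frames per cycle.
#' @param base_area_mm2 Diastolic (minimum) area.
#' @param pulsatility Fractional area increase at systole.
#' @param noise_sd Additive area noise (mm^2).
#' @param seed Integer seed.
#' @return Numeric vector of areas.
#' @export
synthetic_aorta_areas <- function(n_frames = 20, base_area_mm2 = 1000,
                                  pulsatility = 0.2, noise_sd = 0,
                                  seed = 1L) {
  with_phantom_seed(seed, {
    t <- seq_len(n_frames) - 1
    a <- base_area_mm2 * (1 + pulsatility * (1 - cos(2 * pi * t / n_frames)) / 2)
    if (noise_sd > 0) a <- a + stats::rnorm(n_frames, 0, noise_sd)
    pmax(a, 1)
  })
}
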