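# Active-contour (snake) boundary regularization.
#
# A closed contour initialized from a binary mask evolves by semi-implicit
# gradient descent on the classical energy: internal terms penalizing
# stretching (elasticity) and bending (curvature), plus an external term
# attracting the curve to image edges via the gradient-magnitude map of the
# Gaussian-smoothed image. The evolution is fully deterministic.

#' Snake evolution parameters
#'
#' Defaults: elasticity 0.01, curvature 0.1, step size 0.1, Gaussian
#' smoothing sigma 2 px, 250 iterations, convergence when the mean point
#' displacement per iteration drops below `convergence_tol`.
#'
#' @param elasticity_weight Weight of the first-derivative (stretching)
#'   penalty.
#' @param curvature_weight Weight of the second-derivative (bending)
#'   penalty.
#' @param external_weight Weight of the image-edge attraction force.
#' @param step_size Time step of the semi-implicit update.
#' @param max_iterations Iteration cap.
#' @param gradient_smoothing_sigma Gaussian sigma (pixels) applied to the
#'   image before computing the edge map.
#' @param convergence_tol Mean point displacement (pixels) below which the
#'   evolution stops.
#' @param n_points Number of contour points after arc-length resampling of
#'   the initial boundary.
#' @export
snake_params <- function(elasticity_weight = 0.01, curvature_weight = 0.1,
                         external_weight = 2, step_size = 0.1,
                         max_iterations = 250,
                         gradient_smoothing_sigma = 2,
                         convergence_tol = 0.01, n_points = 100L) {
  stopifnot(elasticity_weight >= 0, curvature_weight >= 0,
            external_weight >= 0, step_size > 0, max_iterations >= 1)
  structure(list(elasticity_weight = elasticity_weight,
                 curvature_weight = curvature_weight,
                 external_weight = external_weight,
                 step_size = step_size,
                 max_iterations = as.integer(max_iterations),
                 gradient_smoothing_sigma = gradient_smoothing_sigma,
                 convergence_tol = convergence_tol,
                 n_points = as.integer(n_points)),
            class = "snake_params")
}

# resample a closed polygon to n points evenly spaced by arc length
resample_closed <- function(pts, n) {
  pts <- rbind(pts, pts[1, , drop = FALSE])
  seg <- sqrt(rowSums(diff(pts)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) return(matrix(pts[1, ], n, 2, byrow = TRUE))
  s <- seq(0, total, length.out = n + 1)[seq_len(n)]
  out <- matrix(0, n, 2)
  for (k in seq_len(n)) {
    i <- findInterval(s[k], cum, rightmost.closed = TRUE)
    i <- min(i, nrow(pts) - 1)
    t <- if (seg[i] == 0) 0 else (s[k] - cum[i]) / seg[i]
    out[k, ] <- (1 - t) * pts[i, ] + t * pts[i + 1, ]
  }
  out
}

# bilinear interpolation of matrix values at real-valued (row, col) points
bilinear_at <- function(m, pts) {
  h <- nrow(m); w <- ncol(m)
  r <- pmin(pmax(pts[, 1], 1), h - 1e-9)
  c <- pmin(pmax(pts[, 2], 1), w - 1e-9)
  r0 <- pmin(floor(r), h - 1); c0 <- pmin(floor(c), w - 1)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0, c0); i10 <- cbind(r0 + 1, c0)
  i01 <- cbind(r0, c0 + 1); i11 <- cbind(r0 + 1, c0 + 1)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# edge-energy map (squared gradient magnitude of the smoothed image,
# normalized to a unit maximum so the force scale is image-independent)
# and its spatial gradient
edge_energy <- function(frame, sigma) {
  sm <- if (sigma > 0) {
    matrix(as.numeric(EBImage::gblur(frame, sigma = sigma)),
           nrow(frame), ncol(frame))
  } else {
    frame
  }
  gr <- central_diff(sm, 1)
  gc <- central_diff(sm, 2)
  E <- gr^2 + gc^2
  if (max(E) > 0) E <- E / max(E)
  list(E = E, Er = central_diff(E, 1), Ec = central_diff(E, 2))
}

central_diff <- function(m, axis) {
  h <- nrow(m); w <- ncol(m)
  d <- matrix(0, h, w)
  if (axis == 1) {
    d[2:(h - 1), ] <- (m[3:h, ] - m[1:(h - 2), ]) / 2
  } else {
    d[, 2:(w - 1)] <- (m[, 3:w] - m[, 1:(w - 2)]) / 2
  }
  d
}

#' Evolve an active contour from an initial mask
#'
#' The initial contour is the traced boundary of the largest connected
#' component of `init_mask`, resampled uniformly by arc length. Each
#' iteration solves the semi-implicit update
#' `(I/step + A) x_new = x/step + w_ext * grad E(x)` where `A` is the
#' pentadiagonal internal-energy matrix (elasticity and curvature terms on
#' a closed curve) and `E` is the squared gradient magnitude of the
#' Gaussian-smoothed frame.
#'
#' @param frame Intensity frame (numeric matrix).
#' @param init_mask Non-empty binary mask providing the initial contour.
#' @param params A [snake_params()].
#' @return The evolved closed contour: an `n_points` x 2 matrix of
#'   `(row, col)` coordinates with attributes `closed = TRUE` and
#'   `iterations`.
#' @export
evolve_contour <- function(frame, init_mask, params = snake_params()) {
  assert_frame(frame)
  assert_mask(init_mask, "init_mask")
  if (sum(init_mask) == 0) {
    stop("cannot initialize a snake from an empty mask", call. = FALSE)
  }
  stopifnot(inherits(params, "snake_params"))
  init <- extract_contour(init_mask)
  x <- resample_closed(contour_points(init), params$n_points)
  n <- nrow(x)
  a <- params$elasticity_weight
  b <- params$curvature_weight
  # pentadiagonal circulant internal-energy matrix on a closed curve
  A <- matrix(0, n, n)
  wrap <- function(i) ((i - 1) %% n) + 1
  for (i in seq_len(n)) {
    A[i, wrap(i - 2)] <- A[i, wrap(i - 2)] + b
    A[i, wrap(i - 1)] <- A[i, wrap(i - 1)] - a - 4 * b
    A[i, i] <- A[i, i] + 2 * a + 6 * b
    A[i, wrap(i + 1)] <- A[i, wrap(i + 1)] - a - 4 * b
    A[i, wrap(i + 2)] <- A[i, wrap(i + 2)] + b
  }
  gamma <- 1 / params$step_size
  M <- solve(A + gamma * diag(n))
  ext <- if (params$external_weight > 0) {
    edge_energy(frame, params$gradient_smoothing_sigma)
  } else {
    NULL
  }
  iter_done <- params$max_iterations
  for (it in seq_len(params$max_iterations)) {
    if (!is.null(ext)) {
      fr <- params$external_weight * bilinear_at(ext$Er, x)
      fc <- params$external_weight * bilinear_at(ext$Ec, x)
    } else {
      fr <- fc <- 0
    }
    xn <- cbind(M %*% (gamma * x[, 1] + fr),
                M %*% (gamma * x[, 2] + fc))
    xn[, 1] <- pmin(pmax(xn[, 1], 1), nrow(frame))
    xn[, 2] <- pmin(pmax(xn[, 2], 1), ncol(frame))
    disp <- mean(sqrt(rowSums((xn - x)^2)))
    x <- xn
    if (disp < params$convergence_tol) {
      iter_done <- it
      break
    }
  }
  colnames(x) <- c("row", "col")
  structure(x, closed = TRUE, iterations = iter_done)
}

# do any two non-adjacent segments of the closed polygon intersect?
polygon_self_intersects <- function(pts) {
  n <- nrow(pts)
  if (n < 4) return(FALSE)
  seg_a <- pts
  seg_b <- pts[c(2:n, 1), , drop = FALSE]
  cross2 <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      d1 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2],
                   seg_a[j, 1], seg_a[j, 2])
      d2 <- cross2(seg_a[i, 1], seg_a[i, 2], seg_b[i, 1], seg_b[i, 2],
                   seg_b[j, 1], seg_b[j, 2])
      d3 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2],
                   seg_a[i, 1], seg_a[i, 2])
      d4 <- cross2(seg_a[j, 1], seg_a[j, 2], seg_b[j, 1], seg_b[j, 2],
                   seg_b[i, 1], seg_b[i, 2])
      if (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
          ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))) {
        return(TRUE)
      }
    }
  }
  FALSE
}

#' Rasterize a closed contour into a binary mask
#'
#' Scanline fill with the even-odd rule over pixel centres. A
#' self-intersecting contour triggers a warning but is still filled.
#'
#' @param contour An n x 2 matrix of `(row, col)` coordinates (closed by
#'   convention).
#' @param shape `(rows, cols)` of the output mask.
#' @return Binary matrix.
#' @export
contour_to_mask <- function(contour, shape) {
  pts <- contour_points(contour)
  h <- shape[1]; w <- shape[2]
  out <- matrix(0, h, w)
  if (nrow(pts) == 1) {
    r <- round(pts[1, 1]); c <- round(pts[1, 2])
    if (r >= 1 && r <= h && c >= 1 && c <= w) out[r, c] <- 1
    return(out)
  }
  if (polygon_self_intersects(pts)) {
    warning("self-intersecting contour; applying even-odd fill anyway",
            call. = FALSE)
  }
  n <- nrow(pts)
  p1 <- pts
  p2 <- pts[c(2:n, 1), , drop = FALSE]
  # draw the boundary itself: scanline fill alone drops the bottom edge of
  # the half-open row rule, and the boundary belongs to the mask
  for (i in seq_len(n)) {
    len <- sqrt(sum((p2[i, ] - p1[i, ])^2))
    ts <- seq(0, 1, length.out = max(2L, ceiling(2 * len)))
    rr <- round(p1[i, 1] + ts * (p2[i, 1] - p1[i, 1]))
    cc <- round(p1[i, 2] + ts * (p2[i, 2] - p1[i, 2]))
    ok <- rr >= 1 & rr <= h & cc >= 1 & cc <= w
    out[cbind(rr[ok], cc[ok])] <- 1
  }
  for (r in seq_len(h)) {
    # half-open rule on the row coordinate avoids double-counting vertices
    lo <- pmin(p1[, 1], p2[, 1])
    hi <- pmax(p1[, 1], p2[, 1])
    active <- which(lo <= r & r < hi)
    if (length(active) == 0) next
    t <- (r - p1[active, 1]) / (p2[active, 1] - p1[active, 1])
    xs <- sort(p1[active, 2] + t * (p2[active, 2] - p1[active, 2]))
    k <- 1
    while (k + 1 <= length(xs)) {
      c0 <- ceiling(xs[k] - 1e-9)
      c1 <- floor(xs[k + 1] + 1e-9)
      if (c1 >= c0) {
        c0 <- max(1, c0); c1 <- min(w, c1)
        if (c1 >= c0) out[r, c0:c1] <- 1
      }
      k <- k + 2
    }
  }
  out
}
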