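# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain double loops / direct enumerations so they
# share no code path with the implementations they check.

# -- fixtures --------------------------------------------------------------

small_phantom_config <- function(seed = 1L, ...) {
  defaults <- list(image_size = 96L, n_frames = 6L,
                   endo_radius_range = c(12, 16),
                   wall_thickness_range = c(5, 7),
                   rv_offset = 30, seed = seed)
  do.call(phantom_config, utils::modifyList(defaults, list(...)))
}

make_disk_mask <- function(n, center, r) {
  rows <- matrix(seq_len(n), n, n)
  cols <- matrix(seq_len(n), n, n, byrow = TRUE)
  matrix(as.numeric((rows - center[1])^2 + (cols - center[2])^2 <= r^2),
         n, n)
}

make_disk_image <- function(n, center, r, bg = 0.1, fg = 0.9) {
  img <- matrix(bg, n, n)
  img[make_disk_mask(n, center, r) == 1] <- fg
  img
}

# -- brute-force morphology (Euclidean disk structuring element) -----------

oracle_disk_offsets <- function(radius) {
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off[off$dr^2 + off$dc^2 <= radius^2, ]
}

oracle_erode <- function(mask, radius) {
  off <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    keep <- 1
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      v <- if (rr < 1 || rr > h || cc < 1 || cc > w) 0 else mask[rr, cc]
      if (v == 0) { keep <- 0; break }
    }
    out[r, c] <- keep
  }
  out
}

oracle_dilate <- function(mask, radius) {
  off <- oracle_disk_offsets(radius)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    hit <- 0
    for (k in seq_len(nrow(off))) {
      rr <- r + off$dr[k]; cc <- c + off$dc[k]
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && mask[rr, cc] == 1) {
        hit <- 1; break
      }
    }
    out[r, c] <- hit
  }
  out
}

# opening (erode, dilate) followed by closing (dilate, erode)
oracle_open_close <- function(mask, radius) {
  opened <- oracle_dilate(oracle_erode(mask, radius), radius)
  oracle_erode(oracle_dilate(opened, radius), radius)
}

# -- brute-force contour distances -----------------------------------------

oracle_mcd <- function(a, b, spacing = 1) {
  d_ab <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    d_ab[i] <- best
  }
  d_ba <- numeric(nrow(b))
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    d_ba[j] <- best
  }
  spacing * 0.5 * (mean(d_ab) + mean(d_ba))
}

oracle_hausdorff <- function(a, b, spacing = 1) {
  dmax <- 0
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    if (best > dmax) dmax <- best
  }
  for (j in seq_len(nrow(b))) {
    best <- Inf
    for (i in seq_len(nrow(a))) {
      d <- sqrt((a[i, 1] - b[j, 1])^2 + (a[i, 2] - b[j, 2])^2)
      if (d < best) best <- d
    }
    if (best > dmax) dmax <- best
  }
  spacing * dmax
}

# -- pairwise-concordance AUC (ties count one half) ------------------------

oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# -- closed-form parameter counter -----------------------------------------

oracle_param_count <- function(layers) {
  # layers: list of c(kind, args): conv(kh, kw, cin, cout) or dense(nin, nout)
  total <- 0
  for (l in layers) {
    if (l$kind == "conv") {
      total <- total + l$kh * l$kw * l$cin * l$cout + l$cout
    } else {
      total <- total + l$nin * l$nout + l$nout
    }
  }
  total
}
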