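# Overlap, boundary and pixel-classification metrics, plus the resampling
# and multiple-comparison machinery used to report them: Dice, confusion
# rates, symmetric mean contour distance (MCD), Hausdorff distance (HD),
# ROC-AUC, percentile bootstrap CIs and Holm-Bonferroni-corrected paired
# t-tests.

#' Dice similarity coefficient between two binary masks
#'
#' `2|P & G| / (|P| + |G|)`. When both masks are empty the coefficient is
#' defined as 1 (perfect agreement) and flagged via the `"both_empty"`
#' attribute.
#'
#' @param p,g Binary matrices of equal shape (prediction, ground truth).
#' @return A number in `[0, 1]`.
#' @export
dsc <- function(p, g) {
  assert_mask(p, "p"); assert_mask(g, "g")
  if (!all(dim(p) == dim(g))) stop("mask shapes differ", call. = FALSE)
  sp <- sum(p); sg <- sum(g)
  if (sp + sg == 0) return(structure(1, both_empty = TRUE))
  2 * sum(p * g) / (sp + sg)
}

#' Pixel-wise confusion counts between prediction and ground truth
#'
#' @inheritParams dsc
#' @return A tibble with one row: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(p, g) {
  assert_mask(p, "p"); assert_mask(g, "g")
  if (!all(dim(p) == dim(g))) stop("mask shapes differ", call. = FALSE)
  tibble::tibble(tp = sum(p == 1 & g == 1),
                 fp = sum(p == 1 & g == 0),
                 tn = sum(p == 0 & g == 0),
                 fn = sum(p == 0 & g == 1))
}

#' Classification rates from confusion counts
#'
#' Precision `TP/(TP+FP)`, recall `TP/(TP+FN)`, F1 and accuracy. A rate
#' whose denominator is zero is returned as `NA` (flagged, never silently
#' zero).
#'
#' @param counts A one-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return A one-row tibble with `precision`, `recall`, `f1`, `accuracy`.
#' @export
rates <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- safe_div(tp, tp + fp)
  recall <- safe_div(tp, tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  accuracy <- safe_div(tp + tn, tp + fp + tn + fn)
  tibble::tibble(precision = precision, recall = recall,
                 f1 = f1, accuracy = accuracy)
}

#' Extract the ordered boundary contour of a binary mask
#'
#' Boundary pixels are foreground pixels 4-adjacent to background (or the
#' image border), traced in order around the largest 8-connected foreground
#' component (Moore neighbourhood tracing). The contour is closed by
#' convention: the successor of the last point is the first.
#'
#' @param mask Non-empty binary matrix.
#' @return A matrix of `(row, col)` pixel coordinates (1-based), with
#'   attribute `closed = TRUE`.
#' @export
extract_contour <- function(mask) {
  assert_mask(mask)
  if (sum(mask) == 0) stop("cannot extract a contour from an empty mask",
                           call. = FALSE)
  comp <- largest_component(mask)
  pts <- trace_boundary(comp)
  structure(pts, closed = TRUE)
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  if (max(lab) <= 1) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep <- which.max(sizes)
  matrix(as.numeric(lab == keep), nrow(mask), ncol(mask))
}

# Moore-neighbour boundary tracing with Jacob's stopping criterion.
trace_boundary <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  pad <- matrix(0, h + 2, w + 2)
  pad[2:(h + 1), 2:(w + 1)] <- mask
  fg <- which(pad == 1, arr.ind = TRUE)
  # start: first foreground pixel in column-major scan
  start <- fg[order(fg[, 2], fg[, 1])[1], ]
  # neighbours clockwise starting from west
  nb <- rbind(c(0, -1), c(-1, -1), c(-1, 0), c(-1, 1),
              c(0, 1), c(1, 1), c(1, 0), c(1, -1))
  if (sum(pad) == 1) {
    return(matrix(start - 1L, ncol = 2,
                  dimnames = list(NULL, c("row", "col"))))
  }
  pts <- list()
  cur <- start
  backtrack <- 1L  # came from the west
  repeat {
    pts[[length(pts) + 1L]] <- cur
    found <- FALSE
    idx <- backtrack
    for (k in 0:7) {
      j <- ((idx - 1L + k) %% 8L) + 1L
      cand <- cur + nb[j, ]
      if (pad[cand[1], cand[2]] == 1) {
        # backtrack points from the new pixel to the last background pixel
        prevj <- ((j - 2L) %% 8L) + 1L
        from <- cur + nb[prevj, ] - cand
        backtrack <- which(nb[, 1] == from[1] & nb[, 2] == from[2])
        cur <- cand
        found <- TRUE
        break
      }
    }
    if (!found) break  # isolated pixel
    if (all(cur == start) && length(pts) > 1) break
    if (length(pts) > 4 * (h * w)) break  # safety
  }
  out <- do.call(rbind, pts) - 1L  # un-pad
  colnames(out) <- c("row", "col")
  unique_consecutive(out)
}

unique_consecutive <- function(pts) {
  if (nrow(pts) <= 1) return(pts)
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 0)
  pts[keep, , drop = FALSE]
}

contour_points <- function(x) {
  if (is.matrix(x)) return(x[, 1:2, drop = FALSE])
  stop("a contour must be a matrix of (row, col) points", call. = FALSE)
}

# all pairwise Euclidean distances between two point sets
cross_dist <- function(a, b) {
  a <- contour_points(a); b <- contour_points(b)
  d2 <- outer(a[, 1], b[, 1], "-")^2 + outer(a[, 2], b[, 2], "-")^2
  sqrt(d2)
}

#' Symmetric mean contour distance (MCD)
#'
#' The average of the two directed mean point-to-set distances between the
#' contours, scaled by the pixel spacing:
#' `0.5 * (mean_x d(x, B) + mean_y d(y, A))`.
#'
#' @param a,b Contour point matrices (`(row, col)` coordinates).
#' @param spacing Pixel spacing in mm per pixel (isotropic; defaults to 1
#'   when no metadata is available).
#' @return Distance in mm.
#' @export
mcd <- function(a, b, spacing = 1) {
  d <- cross_dist(a, b)
  spacing * 0.5 * (mean(apply(d, 1, min)) + mean(apply(d, 2, min)))
}

#' Hausdorff distance between two contours
#'
#' The maximum of the two directed maxima of point-to-set distances,
#' scaled by the pixel spacing.
#'
#' @inheritParams mcd
#' @export
hausdorff <- function(a, b, spacing = 1) {
  d <- cross_dist(a, b)
  spacing * max(max(apply(d, 1, min)), max(apply(d, 2, min)))
}

#' ROC curve and area under it from per-pixel scores
#'
#' Sweeps the decision threshold over all distinct score values (grouping
#' ties), computes recall (TPR) against false-positive rate
#' `FPR = FP/(FP+TN)`, and integrates by the trapezoidal rule.
#'
#' @param scores Numeric vector of predicted probabilities.
#' @param labels Binary vector of the same length (1 = positive).
#' @return A list with `auc` and a tibble `curve` of `(threshold, fpr, tpr)`.
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.numeric(labels)
  if (all(labels == 1) || all(labels == 0)) {
    stop("ROC needs at least one positive and one negative label",
         call. = FALSE)
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # group tied scores
  grp <- cumsum(c(TRUE, diff(s) != 0))
  tp_g <- tapply(y, grp, sum)
  n_g <- tapply(y, grp, length)
  thr <- tapply(s, grp, max)
  tp <- cumsum(tp_g)
  fp <- cumsum(n_g - tp_g)
  P <- sum(y); N <- length(y) - P
  tpr <- c(0, tp / P)
  fpr <- c(0, fp / N)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(auc = auc,
       curve = tibble::tibble(threshold = c(Inf, as.numeric(thr)),
                              fpr = fpr, tpr = tpr))
}

#' Percentile bootstrap confidence interval for a mean
#'
#' Resamples the per-case values with replacement `n_boot` times and
#' returns the percentile interval of the resampled means. Deterministic
#' under `seed`.
#'
#' @param values Numeric vector (one value per case), length >= 2.
#' @param n_boot Number of bootstrap iterations.
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return A tibble with `mean`, `ci_lower`, `ci_upper`, `n`, `n_boot`.
#' @export
bootstrap_ci <- function(values, n_boot = 1000, level = 0.95, seed = 1L) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  means <- with_phantom_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      mean(sample(values, length(values), replace = TRUE))
    }, numeric(1))
  })
  alpha <- 1 - level
  q <- stats::quantile(means, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  tibble::tibble(mean = mean(values), ci_lower = q[1], ci_upper = q[2],
                 n = length(values), n_boot = n_boot)
}

#' Paired t-tests with Holm-Bonferroni correction
#'
#' Runs a two-sided paired t-test for every supplied model pair and applies
#' the Holm step-down procedure at family-wise level `alpha`: p-values are
#' sorted ascending, the k-th smallest is compared against
#' `alpha / (m - k + 1)`, and testing stops at the first failure.
#'
#' @param scores A named list of equal-length numeric vectors (per-case
#'   scores per model), or `NULL` when `p_values` are supplied directly.
#' @param comparisons A list of 2-element character vectors naming the
#'   pairs to compare; default: all pairs.
#' @param p_values Optional named numeric vector of nominal p-values; when
#'   given, only the Holm decision stage is run.
#' @param alpha Family-wise error rate.
#' @return A tibble with one row per comparison: `comparison`, `t`
#'   (`NA` when only p-values were supplied), `p`, `holm_threshold`,
#'   `significant`, ordered by ascending p.
#' @export
paired_t_holm <- function(scores = NULL, comparisons = NULL,
                          p_values = NULL, alpha = 0.05) {
  if (is.null(p_values)) {
    stopifnot(is.list(scores), length(scores) >= 2)
    n <- lengths(scores)
    if (length(unique(n)) != 1 || n[1] < 2) {
      stop("paired scores must be equal-length vectors with >= 2 cases",
           call. = FALSE)
    }
    if (is.null(comparisons)) {
      nm <- names(scores)
      comparisons <- utils::combn(nm, 2, simplify = FALSE)
    }
    res <- purrr::map_dfr(comparisons, function(pair) {
      a <- scores[[pair[1]]]; b <- scores[[pair[2]]]
      if (stats::sd(a - b) == 0) {
        tibble::tibble(comparison = paste(pair, collapse = " vs "),
                       t = NA_real_, p = 1)
      } else {
        tt <- stats::t.test(a, b, paired = TRUE)
        tibble::tibble(comparison = paste(pair, collapse = " vs "),
                       t = unname(tt$statistic), p = tt$p.value)
      }
    })
  } else {
    res <- tibble::tibble(comparison = names(p_values) %||%
                            paste0("comparison_", seq_along(p_values)),
                          t = NA_real_, p = as.numeric(p_values))
  }
  res <- dplyr::arrange(res, .data$p)
  m <- nrow(res)
  res$holm_threshold <- alpha / (m - seq_len(m) + 1)
  pass <- res$p <= res$holm_threshold
  # step-down: stop at the first failure
  first_fail <- which(!pass)[1]
  sig <- if (is.na(first_fail)) rep(TRUE, m) else seq_len(m) < first_fail
  res$significant <- sig
  class(res) <- c("cineseg_holm", class(res))
  res
}

#' Metric report for a set of predicted/reference mask pairs
#'
#' Computes Dice, precision/recall/F1/accuracy, MCD and HD per case, plus
#' pooled ROC-AUC when probability maps are supplied, and percentile
#' bootstrap CIs over cases for each summary metric.
#'
#' @param preds List of binary prediction masks.
#' @param truths List of binary reference masks, same length and shapes.
#' @param probs Optional list of probability maps for ROC-AUC.
#' @param spacing Pixel spacing (mm/px) for the boundary metrics.
#' @param n_boot Bootstrap iterations for the CIs (0 disables).
#' @param seed Seed for the bootstrap.
#' @return A list of class `metric_report` with tibbles `per_case` and
#'   `summary`, and `auc` (or `NA`).
#' @export
metric_report <- function(preds, truths, probs = NULL, spacing = 1,
                          n_boot = 1000, seed = 1L) {
  stopifnot(length(preds) == length(truths))
  per_case <- purrr::map_dfr(seq_along(preds), function(i) {
    p <- preds[[i]]; g <- truths[[i]]
    cm <- confusion(p, g)
    r <- rates(cm)
    bd <- if (sum(p) > 0 && sum(g) > 0) {
      cp <- extract_contour(p); cg <- extract_contour(g)
      c(mcd = mcd(cp, cg, spacing), hd = hausdorff(cp, cg, spacing))
    } else {
      c(mcd = NA_real_, hd = NA_real_)
    }
    dplyr::bind_cols(tibble::tibble(case = i, dice = as.numeric(dsc(p, g))),
                     r, tibble::tibble(mcd_mm = bd[["mcd"]],
                                       hd_mm = bd[["hd"]]))
  })
  auc <- NA_real_
  if (!is.null(probs)) {
    sc <- unlist(lapply(probs, as.numeric))
    lb <- unlist(lapply(truths, as.numeric))
    if (any(lb == 1) && any(lb == 0)) auc <- roc_auc(sc, lb)$auc
  }
  summarize_metric <- function(col) {
    v <- per_case[[col]]
    v <- v[!is.na(v)]
    if (length(v) >= 2 && n_boot > 0) {
      ci <- bootstrap_ci(v, n_boot = n_boot, seed = seed)
      tibble::tibble(metric = col, mean = ci$mean, sd = stats::sd(v),
                     ci_lower = ci$ci_lower, ci_upper = ci$ci_upper)
    } else {
      tibble::tibble(metric = col,
                     mean = if (length(v)) mean(v) else NA_real_,
                     sd = NA_real_, ci_lower = NA_real_, ci_upper = NA_real_)
    }
  }
  summary <- purrr::map_dfr(c("dice", "precision", "recall", "f1",
                              "accuracy", "mcd_mm", "hd_mm"),
                            summarize_metric)
  structure(list(per_case = per_case, summary = summary, auc = auc),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>", nrow(x$per_case), "cases\n")
  print(x$summary)
  if (!is.na(x$auc)) cat(sprintf("pooled ROC-AUC: %.4f\n", x$auc))
  invisible(x)
}
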