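test_that("Dice matches direct counts and handles degenerate masks", {
  m <- make_disk_mask(32, c(16, 16), 6)
  expect_equal(dsc(m, m), 1)
  a <- matrix(0, 8, 8); a[1:2, 1:2] <- 1
  b <- matrix(0, 8, 8); b[5:6, 5:6] <- 1
  expect_equal(dsc(a, b), 0)
  p <- matrix(0, 8, 8); p[1:2, 1:2] <- 1          # |P| = 4
  g <- matrix(0, 8, 8); g[2:3, 1:2] <- 1          # |G| = 4, overlap 2
  expect_equal(dsc(p, g), 0.5)
  both <- dsc(matrix(0, 4, 4), matrix(0, 4, 4))
  expect_equal(as.numeric(both), 1)
  expect_true(attr(both, "both_empty"))
  expect_error(dsc(matrix(0, 4, 4), matrix(0, 5, 5)), "shapes differ")
})

test_that("confusion counts and rates follow their definitions", {
  p <- matrix(0, 4, 4); g <- matrix(0, 4, 4)
  p[1, 1:3] <- 1                      # 3 predicted
  g[1, 1:2] <- 1; g[2, 1:2] <- 1      # 4 true
  cm <- confusion(p, g)
  expect_equal(unlist(cm), c(tp = 2, fp = 1, tn = 11, fn = 2))
  r <- rates(cm)
  expect_equal(r$precision, 2 / 3)
  expect_equal(r$recall, 0.5)
  expect_equal(r$f1, 2 * (2 / 3 * 0.5) / (2 / 3 + 0.5))
  expect_equal(r$accuracy, 13 / 16)
  # dsc/confusion consistency: dice = 2tp / (2tp + fp + fn)
  expect_equal(dsc(p, g), 2 * cm$tp / (2 * cm$tp + cm$fp + cm$fn))
  # degenerate: empty prediction flags precision as NA, recall 0
  r2 <- rates(confusion(matrix(0, 4, 4), g))
  expect_true(is.na(r2$precision))
  expect_equal(r2$recall, 0)
  # perfect agreement
  r3 <- rates(confusion(g, g))
  expect_equal(unlist(r3), c(precision = 1, recall = 1, f1 = 1,
                             accuracy = 1))
})

test_that("contour extraction returns ordered closed boundaries", {
  one <- matrix(0, 5, 5); one[3, 3] <- 1
  ct <- extract_contour(one)
  expect_equal(nrow(ct), 1)
  expect_equal(unname(ct[1, ]), c(3, 3))
  sq <- matrix(0, 14, 14); sq[3:12, 3:12] <- 1
  ct <- extract_contour(sq)
  expect_equal(nrow(ct), 36)  # perimeter pixels of a filled 10x10 square
  # every contour pixel is foreground and touches background (8-adj or edge)
  m <- make_disk_mask(24, c(12, 12), 7)
  ct <- extract_contour(m)
  pad <- matrix(0, 26, 26); pad[2:25, 2:25] <- m
  for (i in seq_len(nrow(ct))) {
    r <- ct[i, 1] + 1; c <- ct[i, 2] + 1
    expect_equal(pad[r, c], 1)
    expect_true(min(pad[(r - 1):(r + 1), (c - 1):(c + 1)]) == 0)
  }
  expect_error(extract_contour(matrix(0, 4, 4)), "empty")
})

test_that("MCD and HD match hand evaluations and brute-force oracles", {
  a <- rbind(c(0, 0)); b <- rbind(c(3, 4))
  expect_equal(mcd(a, b), 5)
  expect_equal(hausdorff(a, b), 5)
  a2 <- rbind(c(0, 0), c(10, 0)); b2 <- rbind(c(0, 0))
  expect_equal(mcd(a2, b2), 2.5)
  expect_equal(hausdorff(a2, b2), 10)
  expect_equal(mcd(a2, b2, spacing = 2), 5)
  set.seed(19)
  for (i in 1:50) {
    n1 <- sample(3:20, 1); n2 <- sample(3:20, 1)
    ca <- cbind(runif(n1, 0, 30), runif(n1, 0, 30))
    cb <- cbind(runif(n2, 0, 30), runif(n2, 0, 30))
    expect_equal(mcd(ca, cb), oracle_mcd(ca, cb), tolerance = 1e-9)
    expect_equal(hausdorff(ca, cb), oracle_hausdorff(ca, cb),
                 tolerance = 1e-9)
    # symmetry and max >= mean
    expect_equal(mcd(ca, cb), mcd(cb, ca))
    expect_equal(hausdorff(ca, cb), hausdorff(cb, ca))
    expect_gte(hausdorff(ca, cb) + 1e-12, mcd(ca, cb))
  }
})

test_that("ROC-AUC handles ties and matches the concordance oracle", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 10), rep(c(0, 1), 5))$auc, 0.5)
  r <- roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 0, 1, 0))
  expect_equal(r$auc, 0.75)
  expect_error(roc_auc(runif(5), rep(1, 5)), "positive and one negative")
  set.seed(23)
  for (i in 1:50) {
    n <- sample(20:200, 1)
    sc <- round(runif(n), 2)  # rounded scores force ties
    lb <- rbinom(n, 1, 0.4)
    if (sum(lb) == 0 || sum(lb) == n) next
    expect_equal(roc_auc(sc, lb)$auc, oracle_auc(sc, lb), tolerance = 1e-9)
  }
})

test_that("ROC-AUC agrees with an established implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  sc <- runif(300); lb <- rbinom(300, 1, 0.35)
  ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, direction = "<",
                                        quiet = TRUE)))
  expect_equal(roc_auc(sc, lb)$auc, ref, tolerance = 1e-9)
})

test_that("bootstrap CIs are seeded percentile intervals with coverage", {
  v <- rep(3.5, 10)
  ci <- bootstrap_ci(v, seed = 1)
  expect_equal(c(ci$ci_lower, ci$ci_upper), c(3.5, 3.5))
  set.seed(77)
  v2 <- rnorm(40)
  ci2 <- bootstrap_ci(v2, seed = 4)
  expect_gte(ci2$ci_lower, min(v2))
  expect_lte(ci2$ci_upper, max(v2))
  expect_identical(bootstrap_ci(v2, seed = 4), bootstrap_ci(v2, seed = 4))
  expect_error(bootstrap_ci(1), "at least 2")
  # coverage of the true mean for Normal(0, 1), n = 75
  set.seed(123)
  hits <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    x <- rnorm(75)
    ci <- bootstrap_ci(x, n_boot = 1000, seed = i)
    if (ci$ci_lower <= 0 && 0 <= ci$ci_upper) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.92)
  expect_lte(hits / reps, 0.98)
})

test_that("Holm step-down matches p.adjust and flags degenerate pairs", {
  scores <- list(a = c(0.5, 0.6, 0.7, 0.4, 0.55),
                 b = c(0.52, 0.61, 0.69, 0.45, 0.5),
                 c = c(0.8, 0.9, 0.85, 0.75, 0.95))
  res <- paired_t_holm(scores)
  expect_equal(nrow(res), 3)
  # decisions agree with stats::p.adjust on the same nominal p-values
  padj <- p.adjust(res$p, method = "holm")
  expect_equal(res$significant, unname(padj <= 0.05))
  # identical vectors: flagged, not significant
  same <- paired_t_holm(list(m1 = 1:5 / 10, m2 = 1:5 / 10))
  expect_equal(same$p, 1)
  expect_false(same$significant)
  # single comparison reduces to the plain alpha test
  one <- paired_t_holm(p_values = c(only = 0.04))
  expect_true(one$significant)
  expect_equal(one$holm_threshold, 0.05)
  set.seed(9)
  for (i in 1:20) {
    pv <- runif(7)^2
    names(pv) <- paste0("c", 1:7)
    res <- paired_t_holm(p_values = pv)
    expect_equal(res$significant,
                 unname(p.adjust(res$p, "holm") <= 0.05))
  }
})

test_that("metric_report aggregates per-case metrics with CIs", {
  set.seed(3)
  truths <- lapply(1:6, function(i) make_disk_mask(48, c(24, 24), 10))
  preds <- lapply(1:6, function(i) make_disk_mask(48, c(24 + i %% 3, 24), 10))
  probs <- lapply(preds, function(p) 0.2 + 0.6 * p)
  rep <- metric_report(preds, truths, probs, n_boot = 200, seed = 1)
  expect_s3_class(rep$per_case, "tbl_df")
  expect_equal(nrow(rep$per_case), 6)
  expect_true(all(rep$per_case$dice >= 0 & rep$per_case$dice <= 1))
  s <- rep$summary
  expect_true(all(s$ci_lower[!is.na(s$ci_lower)] <=
                    s$mean[!is.na(s$ci_lower)] + 1e-12))
  expect_gt(rep$auc, 0.9)
  g <- glance(rep)
  expect_equal(g$n_cases, 6)
  td <- tidy(rep)
  expect_true("dice" %in% td$metric)
})
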