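test_that("per-feature AUC matches brute-force pair counting and known cases", {
  y <- factor(c("baseline", "baseline", "exposed", "exposed"))
  expect_equal(feature_auc(c(1, 4, 3, 5), y, positive = "exposed"), 0.75)
  expect_equal(feature_auc(rep(1, 4), y), 0.5)       # all ties
  expect_equal(feature_auc(c(0, 0, 9, 9), y), 1)     # perfect separation
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(4:40, 1)
    v <- sample(c(rnorm(n), rep(0, 3)))[1:n]  # inject ties
    lab <- factor(sample(c("a", "b"), n, replace = TRUE))
    if (nlevels(droplevels(lab)) < 2) next
    expect_equal(feature_auc(v, lab, positive = "b"),
                 brute_force_auc(v, lab, positive = "b"),
                 tolerance = 1e-12)
  }
  # label-swap antisymmetry
  v <- rnorm(30)
  lab <- factor(rep(c("a", "b"), 15))
  expect_equal(feature_auc(v, lab, positive = "b"),
               1 - feature_auc(v, lab, positive = "a"), tolerance = 1e-12)
  expect_error(feature_auc(1:3, factor(c("a", "a", "a"))), "two classes")
})

test_that("Welch t matches the textbook computation and calibrates under the null", {
  a <- c(5.1, 4.8, 6.2, 5.5, 4.9)
  b <- c(3.9, 4.4, 4.1, 3.7)
  lab <- factor(rep(c("base", "exp"), c(length(b), length(a))))
  got <- welch_t(c(b, a), lab, positive = "exp")
  want <- textbook_welch(a, b)
  expect_equal(unname(got["t"]), unname(want["t"]), tolerance = 1e-10)
  expect_equal(unname(got["p"]), unname(want["p"]), tolerance = 1e-10)
  expect_equal(unname(got["df"]), unname(want["df"]), tolerance = 1e-10)
  # strong shift: p tends to zero
  shifted <- welch_t(c(rnorm(10), rnorm(10) + 50),
                     factor(rep(c("a", "b"), each = 10)))
  expect_lt(shifted["p"], 1e-10)
  expect_error(welch_t(rep(1, 10), factor(rep(c("a", "b"), 5))),
               "zero variance")
  expect_error(welch_t(c(1, 2, 3), factor(c("a", "b", "b"))), "at least 2")
})

test_that("null type-I error of the t gate is close to nominal", {
  set.seed(7)
  n <- 15
  lab <- factor(rep(c("a", "b"), each = n))
  p <- vapply(seq_len(2000), function(i) {
    welch_t(rnorm(2 * n), lab)["p"]
  }, numeric(1))
  expect_gt(mean(p < 0.05), 0.035)
  expect_lt(mean(p < 0.05), 0.065)
})

test_that("classification on strong-marker data is accurate, reproducible and seeded", {
  # non-decaying spike: the benchmark fold-change of 5 holds at the
  # bed-time collection itself
  sc <- make_processed_scenario(seed = 21, n_participants = 30,
                                halflife_h = 1e6)
  ctr <- build_contrast(sc$processed, sc$truth, "garden peas")
  expect_identical(as.vector(table(ctr$labels)), c(30L, 30L))
  cls <- classify_urine_classes(ctr$x, ctr$labels, ntree = 1000, seed = 5)
  expect_gt(cls$metrics$auc, 0.9)
  expect_gt(cls$metrics$accuracy, 0.7)
  expect_gt(cls$metrics$mean_margin, 0)
  expect_true(cls$metrics$oob)
  # proximity is a valid similarity matrix
  pr <- cls$proximity
  expect_equal(pr, t(pr))
  expect_true(all(diag(pr) == 1))
  expect_true(all(pr >= 0 & pr <= 1))
  # same seed, same result
  cls2 <- classify_urine_classes(ctr$x, ctr$labels, ntree = 1000, seed = 5)
  expect_identical(cls$metrics, cls2$metrics)
  expect_error(classify_urine_classes(ctr$x, rep("one", nrow(ctr$x))),
               "two classes")
  expect_error(classify_urine_classes(ctr$x[, 1, drop = FALSE], ctr$labels),
               "2 features")
  expect_error(classify_urine_classes(ctr$x[c(1:3, 31:33), ],
                                      ctr$labels[c(1:3, 31:33)]),
               "at least 5")
})

test_that("permuted labels reduce classification to chance", {
  sc <- make_processed_scenario(seed = 31, n_participants = 10)
  ctr <- build_contrast(sc$processed, sc$truth, "garden peas")
  accs <- vapply(1:10, function(s) {
    set.seed(1000 + s)
    classify_urine_classes(ctr$x, sample(ctr$labels), ntree = 300,
                           seed = s)$metrics$accuracy
  }, numeric(1))
  n_tot <- 10 * length(ctr$labels)
  expect_lt(abs(mean(accs) - 0.5), 3 * sqrt(0.25 / n_tot))
})

test_that("MDS embedding reproduces proximity geometry deterministically", {
  # equidistant points: all pairwise embedded distances equal
  pr <- matrix(0, 4, 4); diag(pr) <- 1
  xy <- mds_embed(pr, dims = 2)
  # two perfect clusters collapse to two coincident point groups
  pr2 <- diag(6) * 0 + 1
  pr2[1:3, 4:6] <- 0; pr2[4:6, 1:3] <- 0
  xy2 <- mds_embed(pr2)
  expect_lt(max(dist(xy2[1:3, ])), 1e-6)
  expect_lt(max(dist(xy2[4:6, ])), 1e-6)
  expect_gt(min(as.matrix(dist(xy2))[1:3, 4:6]), 0.5)
  # sign convention makes the embedding deterministic
  expect_identical(mds_embed(pr2), xy2)
  expect_true(all(apply(xy2, 2, function(cc) cc[which.max(abs(cc))] >= 0)))
  expect_error(mds_embed(matrix(c(1, 0.2, 0.5, 1), 2, 2)), "symmetric")
  # distance ordering is preserved when the proximity has planar geometry
  set.seed(8)
  pts <- matrix(rnorm(40), 20, 2)
  d <- as.matrix(dist(pts))
  pr3 <- 1 - d / (max(d) + 0.1)
  diag(pr3) <- 1
  emb3 <- mds_embed(pr3)
  expect_gt(cor(as.numeric(as.dist(1 - pr3)), as.numeric(dist(emb3)),
                method = "spearman"), 0.8)
  # on a strong-marker contrast the two urine classes separate in the plane
  sc <- make_processed_scenario(seed = 41, n_participants = 15)
  ctr <- build_contrast(sc$processed, sc$truth, "garden peas")
  cls <- classify_urine_classes(ctr$x, ctr$labels, ntree = 500, seed = 2)
  emb <- mds_embed(cls$proximity)
  centb <- colMeans(emb[ctr$labels == "baseline", ])
  cente <- colMeans(emb[ctr$labels == "exposed", ])
  within <- mean(c(dist(emb[ctr$labels == "baseline", ])[1:10],
                   dist(emb[ctr$labels == "exposed", ])[1:10]))
  expect_gt(sqrt(sum((centb - cente)^2)), 0)
  expect_gt(sqrt(sum((centb - cente)^2)) / within, 0.5)
})

test_that("equidistant-point embedding yields equal pairwise distances", {
  pr <- matrix(0, 5, 5); diag(pr) <- 1
  xy <- mds_embed(pr, dims = 4)
  d <- as.numeric(dist(xy))
  expect_lt(max(d) - min(d), 1e-8)
})

test_that("rank aggregation combines the three criteria with FDR gating", {
  stats <- data.frame(
    mz = c(100.005, 200.005, 300.005),
    rf_importance = c(5, 1, 0.5),
    auc = c(0.99, 0.6, 0.45),
    t_statistic = c(12, 2, -1),
    p_value = c(1e-8, 0.04, 0.5))
  out <- select_features(stats, k = 2, fdr_alpha = 0.05)
  # feature ranked 1 by all three criteria: rank sum 3, position 1
  expect_equal(out$rank_sum[1], 3)
  expect_identical(out$mz[1], 100.005)
  expect_identical(out$aggregate_rank, 1:3)
  expect_identical(out$fdr_q, stats::p.adjust(out$p_value, "BH"))
  expect_true(out$selected[1])
  expect_false(out$selected[3])  # fails the BH gate
  # permutation invariance up to the documented tie-break
  out2 <- select_features(stats[c(3, 1, 2), ], k = 2, fdr_alpha = 0.05)
  expect_identical(out2$mz, out$mz)
  expect_identical(out2$selected, out$selected)
  expect_error(select_features(stats, k = 0), "k")
  expect_error(select_features(stats, fdr_alpha = 1.5), "fdr_alpha")
})

test_that("all-null features are almost never selected at the FDR gate", {
  set.seed(11)
  n <- 12
  lab <- factor(rep(c("baseline", "exposed"), each = n))
  x <- matrix(rnorm(2 * n * 400), 2 * n, 400)
  colnames(x) <- format(100 + seq_len(400) / 100, nsmall = 2)
  st <- compute_feature_stats(x, lab, positive = "exposed", ntree = 300,
                              seed = 3)
  out <- select_features(st, k = 25, fdr_alpha = 0.05)
  expect_lte(sum(out$selected), 0.05 * 400)
})

test_that("the spiked bin is recovered at aggregate rank 1", {
  sc <- make_processed_scenario(seed = 51, n_participants = 15,
                                n_noise = 499, ions = "[M-H]1-")
  d <- discover_biomarkers(sc$processed, sc$truth, "garden peas",
                           ntree = 500, seed = 9)
  expect_equal(d$stats$mz[1], sc$marker_mz, tolerance = 1e-9)
  expect_identical(d$stats$aggregate_rank[1], 1L)
  expect_true(d$stats$selected[1])
  expect_equal(d$candidates$mz[1], sc$marker_mz, tolerance = 1e-9)
})
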