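#' Random-forest classification of two urine classes
#'
#' Fits a supervised random forest to distinguish two urine classes (e.g.
#' first morning void vs bed-time urine of the same day) and evaluates it
#' out-of-bag: accuracy, mean margin (mean over samples of the OOB
#' vote-share for the true class minus the vote-share for the other class,
#' after Breiman), and the AUC of the OOB vote shares. The terminal-node
#' co-occupancy proximity matrix is returned for embedding.
#'
#' @param x Numeric matrix, samples x features (>= 2 features).
#' @param labels Factor (or coercible) with exactly two classes, each with
#'   at least 5 samples.
#' @param ntree Number of trees; default 1000.
#' @param seed Optional integer seed for reproducibility.
#' @return List with `metrics` (list: `accuracy`, `mean_margin`, `auc`,
#'   `oob = TRUE`), `proximity` (samples x samples, symmetric, unit
#'   diagonal), `importance` (named mean-decrease-in-Gini vector) and
#'   `votes` (OOB vote-share matrix).
#' @export
classify_urine_classes <- function(x, labels, ntree = 1000, seed = NULL) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("exactly two classes are required, got ", nlevels(labels),
         call. = FALSE)
  }
  if (any(table(labels) < 5)) {
    stop("each class needs at least 5 samples", call. = FALSE)
  }
  if (ncol(x) < 2) stop("at least 2 features are required", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = ntree,
                                   proximity = TRUE, importance = FALSE)
  votes <- rf$votes  # OOB vote fractions
  li <- as.integer(labels)
  margin <- mean(votes[cbind(seq_along(li), li)] -
                   votes[cbind(seq_along(li), 3L - li)])
  acc <- mean(rf$predicted == labels)
  auc <- feature_auc(votes[, 2], labels, positive = levels(labels)[2])
  list(metrics = list(accuracy = acc, mean_margin = margin, auc = auc,
                      oob = TRUE),
       proximity = rf$proximity,
       importance = rf$importance[, 1],
       votes = votes)
}

#' Classical MDS embedding of a random-forest proximity matrix
#'
#' Embeds samples in `dims` dimensions by classical multidimensional
#' scaling of the distance `1 - proximity`. The sign of each axis is fixed
#' so that the largest-magnitude coordinate on it is positive, making the
#' embedding deterministic.
#'
#' @param proximity Symmetric samples x samples matrix in `[0, 1]` with
#'   unit diagonal.
#' @param dims Embedding dimension; default 2.
#' @return Samples x `dims` coordinate matrix.
#' @export
mds_embed <- function(proximity, dims = 2) {
  proximity <- as.matrix(proximity)
  if (nrow(proximity) != ncol(proximity) ||
      max(abs(proximity - t(proximity))) > 1e-8) {
    stop("proximity matrix must be square and symmetric", call. = FALSE)
  }
  if (max(abs(diag(proximity) - 1)) > 1e-8) {
    stop("proximity matrix must have unit diagonal", call. = FALSE)
  }
  d <- 1 - proximity
  coords <- stats::cmdscale(stats::as.dist(d), k = dims)
  if (ncol(coords) < dims) {  # degenerate geometry: pad with zeros
    coords <- cbind(coords, matrix(0, nrow(coords), dims - ncol(coords)))
  }
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (length(i) == 1 && coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  coords
}

#' Per-feature AUC (Mann-Whitney construction)
#'
#' Probability that a randomly chosen sample of the positive (exposed)
#' class exceeds a randomly chosen sample of the other class, counting ties
#' as 1/2; computed from rank sums.
#'
#' @param values Numeric vector, one value per sample.
#' @param labels Two-class factor (or coercible).
#' @param positive Level treated as exposed/positive; defaults to the
#'   second factor level.
#' @return AUC in `[0, 1]`.
#' @examples
#' feature_auc(c(3, 5, 1, 4), factor(c("e", "e", "b", "b")), positive = "e")
#' @export
feature_auc <- function(values, labels, positive = NULL) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("exactly two classes are required", call. = FALSE)
  }
  if (is.null(positive)) positive <- levels(labels)[2]
  pos <- labels == positive
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 == 0 || n2 == 0) {
    stop("both classes must be non-empty", call. = FALSE)
  }
  r <- rank(values)  # average ranks implement the tie = 1/2 convention
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Welch two-sample t-test for one feature
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value, oriented as positive class minus the other. A
#' pooled-variance (classical Student) switch is provided.
#'
#' @inheritParams feature_auc
#' @param pooled Use the pooled-variance test instead of Welch's; default
#'   `FALSE`.
#' @return Named numeric vector `c(t, p, df)`.
#' @export
welch_t <- function(values, labels, positive = NULL, pooled = FALSE) {
  labels <- factor(labels)
  if (nlevels(labels) != 2) {
    stop("exactly two classes are required", call. = FALSE)
  }
  if (is.null(positive)) positive <- levels(labels)[2]
  a <- values[labels == positive]
  b <- values[labels != positive]
  if (length(a) < 2 || length(b) < 2) {
    stop("each class needs at least 2 samples", call. = FALSE)
  }
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    stop("zero variance in both classes", call. = FALSE)
  }
  tt <- stats::t.test(a, b, var.equal = pooled)
  c(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter))
}

#' Per-feature statistics for biomarker feature selection
#'
#' Computes, for every m/z bin, the three selection criteria combined by
#' the discovery stage: random-forest variable importance, per-feature AUC,
#' and the Welch t statistic with its p-value.
#'
#' @param x Samples x features matrix (typically dilution-normalized,
#'   log-transformed intensities).
#' @param labels Two-class factor; `positive` the exposed class.
#' @inheritParams classify_urine_classes
#' @inheritParams welch_t
#' @return `data.frame`: `mz` (from column names when numeric, else the
#'   column index), `rf_importance`, `auc`, `t_statistic`, `p_value`.
#' @export
compute_feature_stats <- function(x, labels, positive = NULL, ntree = 1000,
                                  seed = NULL, pooled = FALSE) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (is.null(positive)) positive <- levels(labels)[2]
  if (!is.null(seed)) set.seed(seed)
  rf <- randomForest::randomForest(x, labels, ntree = ntree)
  imp <- randomForest::importance(rf, type = 2)[, 1]
  auc <- apply(x, 2, feature_auc, labels = labels, positive = positive)
  ts <- apply(x, 2, function(v) welch_t(v, labels, positive, pooled)[1:2])
  mz <- suppressWarnings(as.numeric(colnames(x)))
  if (anyNA(mz)) mz <- seq_len(ncol(x))
  data.frame(mz = mz, rf_importance = unname(imp), auc = unname(auc),
             t_statistic = ts[1, ], p_value = ts[2, ],
             row.names = NULL)
}

#' Combined feature selection by rank aggregation with FDR gating
#'
#' Features are ranked separately by random-forest importance (descending),
#' by `|AUC - 0.5|` (descending) and by `|t|` (descending); the aggregate
#' score is the sum of the three ranks (average ranks on ties, then
#' ascending m/z as the final tie-break, so the ordering is unique).
#' Benjamini-Hochberg q-values are computed from the t-test p-values, and
#' the selected set is the top `k` of the aggregate ordering among features
#' with `q <= fdr_alpha`.
#'
#' @param stats Feature statistics from [compute_feature_stats()].
#' @param k Maximum number of selected features (>= 1); default 25.
#' @param fdr_alpha Benjamini-Hochberg level in (0, 1); default 0.05.
#' @return `stats` reordered by aggregate rank, with added columns
#'   `rank_rf`, `rank_auc`, `rank_t`, `rank_sum`, `aggregate_rank` (unique
#'   1..n), `fdr_q`, and logical `selected`.
#' @export
select_features <- function(stats, k = 25, fdr_alpha = 0.05) {
  if (!is.numeric(k) || k < 1) stop("k must be >= 1", call. = FALSE)
  if (!is.numeric(fdr_alpha) || fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("fdr_alpha must lie in (0, 1)", call. = FALSE)
  }
  required <- c("mz", "rf_importance", "auc", "t_statistic", "p_value")
  missing <- setdiff(required, names(stats))
  if (length(missing) > 0) {
    stop("stats lack column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  stats$rank_rf <- rank(-stats$rf_importance, ties.method = "average")
  stats$rank_auc <- rank(-abs(stats$auc - 0.5), ties.method = "average")
  stats$rank_t <- rank(-abs(stats$t_statistic), ties.method = "average")
  stats$rank_sum <- stats$rank_rf + stats$rank_auc + stats$rank_t
  ord <- order(stats$rank_sum, stats$mz)
  stats <- stats[ord, , drop = FALSE]
  stats$aggregate_rank <- seq_len(nrow(stats))
  stats$fdr_q <- stats::p.adjust(stats$p_value, method = "BH")
  pass <- which(stats$fdr_q <= fdr_alpha)
  stats$selected <- FALSE
  stats$selected[utils::head(pass, k)] <- TRUE
  rownames(stats) <- NULL
  stats
}

#' Extract a baseline/exposed contrast for one food
#'
#' Builds the two urine classes of a discovery contrast from a fingerprint
#' and its exposure truth table: exposed = samples of `exposed_type`
#' (default bed-time urine) on days the participant ate the target food;
#' baseline = samples of `baseline_type` (default first morning void) on
#' those same participant-days.
#'
#' @param fingerprint A processed [fingerprint_matrix()].
#' @param truth Truth table from [simulate_fingerprints()].
#' @param food Target food name.
#' @param baseline_type,exposed_type Urine types for the two classes.
#' @return List with `x` (matrix), `labels` (factor baseline/exposed) and
#'   `sample_id`.
#' @export
build_contrast <- function(fingerprint, truth, food,
                           baseline_type = "FMV", exposed_type = "bed_time") {
  stopifnot(inherits(fingerprint, "fingerprint_matrix"))
  meta <- fingerprint$meta
  tr <- truth[truth$food == food, , drop = FALSE]
  if (nrow(tr) == 0) stop("food '", food, "' absent from truth table",
                          call. = FALSE)
  exposed_ids <- tr$sample_id[tr$exposed]
  exp_rows <- meta$urine_type == exposed_type & meta$sample_id %in% exposed_ids
  exp_days <- unique(meta[exp_rows, c("participant_id", "day_abs")])
  base_rows <- meta$urine_type == baseline_type &
    paste(meta$participant_id, meta$day_abs) %in%
      paste(exp_days$participant_id, exp_days$day_abs)
  keep <- exp_rows | base_rows
  labels <- factor(ifelse(exp_rows[keep], "exposed", "baseline"),
                   levels = c("baseline", "exposed"))
  list(x = fingerprint$intensities[keep, , drop = FALSE],
       labels = labels, sample_id = meta$sample_id[keep])
}

#' One-call biomarker discovery for a single food contrast
#'
#' Convenience wrapper: build the contrast, compute the three per-feature
#' criteria, and return the combined ranking with model-level metrics.
#'
#' @inheritParams build_contrast
#' @inheritParams select_features
#' @param ntree Random-forest trees; default 1000.
#' @param seed Integer seed.
#' @return List with `stats` (ranked feature table), `candidates` (selected
#'   rows only) and `metrics` (from [classify_urine_classes()]).
#' @export
discover_biomarkers <- function(fingerprint, truth, food,
                                baseline_type = "FMV",
                                exposed_type = "bed_time",
                                k = 25, fdr_alpha = 0.05, ntree = 1000,
                                seed = NULL) {
  ctr <- build_contrast(fingerprint, truth, food, baseline_type,
                        exposed_type)
  cls <- classify_urine_classes(ctr$x, ctr$labels, ntree = ntree,
                                seed = seed)
  stats <- compute_feature_stats(ctr$x, ctr$labels, positive = "exposed",
                                 ntree = ntree,
                                 seed = if (is.null(seed)) NULL
                                        else derive_seed(seed, "stats"))
  ranked <- select_features(stats, k = k, fdr_alpha = fdr_alpha)
  list(stats = ranked, candidates = ranked[ranked$selected, , drop = FALSE],
       metrics = cls$metrics)
}
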