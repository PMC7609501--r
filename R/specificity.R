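#' Candidate bins shared across foods of the same group
#'
#' For each food group with at least two member foods among the supplied
#' contrasts, intersects the top-`k` candidate bins of the member foods'
#' discovery rankings, retaining each food's aggregate rank for the shared
#' bins. Groups with fewer than two member contrasts are skipped with a
#' message.
#'
#' @param candidates_by_food Named list (food -> ranked feature table from
#'   [select_features()] or [discover_biomarkers()]`$stats`).
#' @param group_map Named list (group -> character vector of member foods).
#' @param k Top-k depth of each per-food list considered; default 25.
#' @return Named list (group -> `data.frame` with `mz` and one
#'   `rank_<food>` column per member food), empty groups dropped.
#' @export
cross_food_consistency <- function(candidates_by_food, group_map, k = 25) {
  if (length(candidates_by_food) < 2) {
    stop("candidate lists from at least two foods are required",
         call. = FALSE)
  }
  out <- list()
  for (group in names(group_map)) {
    members <- intersect(group_map[[group]], names(candidates_by_food))
    if (length(members) < 2) {
      message("group '", group, "' has fewer than two member contrasts; ",
              "skipped")
      next
    }
    tops <- lapply(members, function(f) {
      s <- candidates_by_food[[f]]
      utils::head(s[order(s$aggregate_rank), ], k)
    })
    shared <- Reduce(intersect, lapply(tops, `[[`, "mz"))
    df <- data.frame(mz = shared)
    for (i in seq_along(members)) {
      df[[paste0("rank_", gsub("[^A-Za-z0-9]+", "_", members[i]))]] <-
        tops[[i]]$aggregate_rank[match(shared, tops[[i]]$mz)]
    }
    out[[group]] <- df
  }
  out
}

#' Cross-food specificity score of a candidate bin
#'
#' AUC (ties 1/2) of the bin's intensity for post-meal samples collected
#' after the target food versus post-meal samples collected after any other
#' food but not the target. 1 means perfectly specific to the target food;
#' 0.5 means no contrast against the rest of the menu — the whole-biobank
#' specificity check that a single-food intervention cannot provide.
#'
#' @param fingerprint A processed [fingerprint_matrix()].
#' @param truth Exposure truth table.
#' @param food Target food.
#' @param mz Candidate bin center (matched to the nearest grid bin within
#'   half a bin).
#' @param post_types Urine types counted as post-meal; default the
#'   post-breakfast/lunch/dinner and bed-time spots.
#' @return Specificity score in `[0, 1]`.
#' @export
specificity_score <- function(fingerprint, truth, food, mz,
                              post_types = c("post_breakfast", "post_lunch",
                                             "post_dinner", "bed_time")) {
  stopifnot(inherits(fingerprint, "fingerprint_matrix"))
  j <- match_bin(fingerprint, mz)
  meta <- fingerprint$meta
  post <- meta$sample_id[meta$urine_type %in% post_types]
  tr <- truth[truth$sample_id %in% post, , drop = FALSE]
  if (!food %in% tr$food) {
    stop("food '", food, "' absent from truth table", call. = FALSE)
  }
  exposed_any <- tapply(tr$exposed, tr$sample_id, any)
  target <- tapply(tr$exposed & tr$food == food, tr$sample_id, any)
  ids <- names(exposed_any)
  target_ids <- ids[target]
  other_ids <- ids[exposed_any & !target]
  if (length(target_ids) == 0 || length(other_ids) == 0) {
    stop("empty comparison set for food '", food, "'", call. = FALSE)
  }
  keep <- c(target_ids, other_ids)
  v <- fingerprint$intensities[match(keep, meta$sample_id), j]
  labels <- factor(rep(c("target", "other"),
                       c(length(target_ids), length(other_ids))),
                   levels = c("other", "target"))
  feature_auc(v, labels, positive = "target")
}

match_bin <- function(fingerprint, mz) {
  j <- which.min(abs(fingerprint$mz - mz))
  w <- if (length(fingerprint$mz) > 1) min(diff(fingerprint$mz)) else Inf
  if (abs(fingerprint$mz[j] - mz) > w / 2 + 1e-9) {
    stop("no fingerprint bin at m/z ", format_mz(mz), call. = FALSE)
  }
  j
}

#' Post-meal elevation window of a biomarker signal
#'
#' Width of the contiguous interval after meal end during which the median
#' signal stays at or above `threshold_fold` times the baseline median,
#' with linear interpolation between sampled times for the crossing points.
#' A signal that is never elevated yields 0 (not an error). The estimate is
#' monotone non-increasing in the threshold.
#'
#' @param times Hours since meal end for the post-exposure measurements
#'   (>= 3 distinct time points required).
#' @param intensities Signal intensities at `times`.
#' @param baseline Baseline (pre-meal) reference intensities; their median
#'   must be positive.
#' @param threshold_fold Elevation threshold as a fold of baseline; default
#'   2.
#' @return Elevation window in hours.
#' @examples
#' t <- 0:16
#' elevation_window(t, 100 * (1 + 4 * 2^(-t / 6)), baseline = 100)  # 12 h
#' @export
elevation_window <- function(times, intensities, baseline,
                             threshold_fold = 2) {
  if (length(baseline) == 0 || all(is.na(baseline))) {
    stop("missing baseline reference", call. = FALSE)
  }
  base <- stats::median(baseline, na.rm = TRUE)
  if (!is.finite(base) || base <= 0) {
    stop("baseline median must be positive", call. = FALSE)
  }
  med <- tapply(intensities, times, stats::median)
  t <- as.numeric(names(med))
  o <- order(t)
  t <- t[o]
  r <- as.numeric(med)[o] / base
  if (length(t) < 3) {
    stop("at least 3 post-exposure time points are required", call. = FALSE)
  }
  up <- r >= threshold_fold
  if (!any(up)) return(0)
  i1 <- which(up)[1]
  i2 <- i1
  while (i2 < length(t) && up[i2 + 1]) i2 <- i2 + 1
  start <- if (i1 == 1) t[1] else {
    t[i1 - 1] + (threshold_fold - r[i1 - 1]) / (r[i1] - r[i1 - 1]) *
      (t[i1] - t[i1 - 1])
  }
  end <- if (i2 == length(t)) t[i2] else {
    t[i2] + (threshold_fold - r[i2]) / (r[i2 + 1] - r[i2]) *
      (t[i2 + 1] - t[i2])
  }
  end - start
}

#' Elevation window of a candidate bin estimated from a simulated study
#'
#' Pools the candidate bin's post-exposure measurements for the target food
#' (times since meal end from the truth table, rounded to the hour so
#' medians are taken over replicate samples), takes the participants'
#' same-day first-morning-void intensities as the baseline reference, and
#' calls [elevation_window()].
#'
#' @inheritParams specificity_score
#' @param threshold_fold Elevation threshold; default 2.
#' @return Elevation window in hours.
#' @export
estimate_elevation_window <- function(fingerprint, truth, food, mz,
                                      threshold_fold = 2) {
  stopifnot(inherits(fingerprint, "fingerprint_matrix"))
  j <- match_bin(fingerprint, mz)
  meta <- fingerprint$meta
  tr <- truth[truth$food == food & truth$exposed, , drop = FALSE]
  if (nrow(tr) == 0) {
    stop("no post-exposure samples for food '", food, "'", call. = FALSE)
  }
  rows <- match(tr$sample_id, meta$sample_id)
  v <- fingerprint$intensities[rows, j]
  times <- round(tr$hours_since)
  exp_days <- unique(meta[rows, c("participant_id", "day_abs")])
  base_rows <- meta$urine_type == "FMV" &
    paste(meta$participant_id, meta$day_abs) %in%
      paste(exp_days$participant_id, exp_days$day_abs)
  if (!any(base_rows)) stop("missing baseline reference", call. = FALSE)
  elevation_window(times, v, fingerprint$intensities[base_rows, j],
                   threshold_fold)
}
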