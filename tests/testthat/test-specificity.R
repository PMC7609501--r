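test_that("specificity score obeys the pair-counting oracle and its extremes", {
  sc <- make_processed_scenario(seed = 61, n_participants = 12)
  # shared legume marker scored for peas with the other legumes in the
  # background: pulled toward 0.5 (it responds to all four foods)
  s_shared <- specificity_score(sc$processed, sc$truth, "garden peas",
                                sc$marker_mz)
  expect_gte(s_shared, 0)
  expect_lte(s_shared, 1)
  expect_lt(s_shared, 0.75)
  # oracle equivalence on the same comparison
  meta <- sc$processed$meta
  tr <- sc$truth[sc$truth$sample_id %in%
                   meta$sample_id[meta$urine_type == "bed_time"], ]
  target <- tapply(tr$exposed & tr$food == "garden peas", tr$sample_id, any)
  other <- tapply(tr$exposed & tr$food != "garden peas", tr$sample_id, any)
  ids <- names(target)[target | other]
  j <- which.min(abs(sc$processed$mz - sc$marker_mz))
  v <- sc$processed$intensities[match(ids, meta$sample_id), j]
  lab <- factor(ifelse(target[ids], "target", "other"))
  expect_equal(s_shared, brute_force_auc(v, lab, "target"),
               tolerance = 1e-12)
  expect_error(specificity_score(sc$processed, sc$truth, "no such food",
                                 sc$marker_mz), "absent")
})

test_that("an exclusive marker is more specific than a group-shared one", {
  # one marker exclusive to peas, one shared across all four legumes
  foods <- c("garden peas", "baked beans", "peanuts", "tofu")
  ids <- sprintf("P%02d", 1:12)
  exposures <- do.call(rbind, lapply(seq_along(foods), function(d) {
    data.frame(participant_id = ids, week = 1L, day = d,
               day_abs = 3L * (d - 1L) + 1L,
               slot = "dinner", food = foods[d], food_group = "legumes",
               fraction = 1, meal_end = 19, stringsAsFactors = FALSE)
  }))
  panel <- data.frame(
    name = c("Shared legume marker", "Pea-exclusive marker"),
    formula = c("C6H6O6S", "C7H7NO2"),
    ionization_products = c("[M-H]1-", "[M+Na]1+"),
    source_foods = c(paste(foods, collapse = ";"), "garden peas"),
    food_group = "legumes", lag_h = 0, halflife_h = 12,
    spike_magnitude = 5, stringsAsFactors = FALSE)
  w <- data.frame(urine_type = c("FMV", "bed_time"), start = c(6.5, 22.5),
                  end = c(7.4, 23.5))
  plan <- merge(unique(exposures[, c("participant_id", "week", "day",
                                     "day_abs")]), w)
  sim <- simulate_fingerprints(exposures, panel = panel, n_noise = 100,
                               sample_plan = plan, seed = 3)
  fp <- transform_log(normalize_dilution(sim$fingerprint))
  shared_mz <- sim$marker_bins$bin_center[
    sim$marker_bins$compound == "Shared legume marker"]
  excl_mz <- sim$marker_bins$bin_center[
    sim$marker_bins$compound == "Pea-exclusive marker"]
  s_shared <- specificity_score(fp, sim$truth, "garden peas", shared_mz)
  s_excl <- specificity_score(fp, sim$truth, "garden peas", excl_mz)
  expect_gt(s_excl, 0.9)
  expect_gt(s_excl, s_shared)
})

test_that("cross-food consistency intersects top candidates within groups", {
  mk <- function(mzs) {
    data.frame(mz = mzs, aggregate_rank = seq_along(mzs))
  }
  cands <- list(peas = mk(c(204.985, 100.005, 101.005)),
                beans = mk(c(100.005, 204.985, 102.005)),
                lentils = mk(c(300.005, 301.005, 302.005)))
  groups <- list(legumes = c("peas", "beans"), curry = "lentils")
  expect_message(res <- cross_food_consistency(cands, groups, k = 3),
                 "curry")
  expect_named(res, "legumes")
  expect_setequal(res$legumes$mz, c(204.985, 100.005))
  expect_identical(res$legumes$rank_peas[res$legumes$mz == 204.985], 1L)
  expect_identical(res$legumes$rank_beans[res$legumes$mz == 204.985], 2L)
  # disjoint lists intersect to nothing
  res2 <- cross_food_consistency(list(a = mk(1:3 + 0.005),
                                      b = mk(7:9 + 0.005)),
                                 list(g = c("a", "b")))
  expect_identical(nrow(res2$g), 0L)
  expect_error(cross_food_consistency(cands["peas"], groups), "two foods")
})

test_that("elevation window matches the first-order decay closed form", {
  # fold 5 with half-life 6 h stays above 2x baseline for exactly
  # halflife * log2(fold - 1) = 12 h
  t <- 0:16
  signal <- 100 * (1 + 4 * 2^(-t / 6))
  expect_equal(elevation_window(t, signal, baseline = 100,
                                threshold_fold = 2), 12, tolerance = 1e-9)
  # flat signal is never elevated
  expect_identical(elevation_window(t, rep(100, 17), baseline = 100), 0)
  # signal at exactly the threshold at two samples: the window is the
  # interval between those samples
  step <- c(100, 200, 200, 100, 100)
  expect_equal(elevation_window(c(0, 1, 2, 3, 4), step, baseline = 100), 1)
  # monotone non-increasing in the threshold
  wins <- vapply(c(1.5, 2, 3, 4), function(f) {
    elevation_window(t, signal, 100, threshold_fold = f)
  }, numeric(1))
  expect_true(all(diff(wins) <= 1e-9))
  expect_error(elevation_window(t, signal, baseline = numeric()), "baseline")
  expect_error(elevation_window(c(0, 1), c(1, 2), baseline = 1),
               "3 post-exposure")
})

test_that("the simulated sweetener-like marker yields a 12 h window, noise-free", {
  # full daily sampling: marker eaten at dinner, collections through the
  # night are approximated by the next day's samples
  ids <- sprintf("P%02d", 1:8)
  exposures <- data.frame(participant_id = rep(ids, each = 1), week = 1L,
                          day = 1L, day_abs = 1L, slot = "dinner",
                          food = "low-calorie beverage",
                          food_group = "low_cal_beverage", fraction = 1,
                          meal_end = 19, stringsAsFactors = FALSE)
  panel <- data.frame(name = "Acesulfame potassium", formula = "C4H4KNO4S",
                      ionization_products = "[M-K]1-",
                      source_foods = "low-calorie beverage",
                      food_group = "low_cal_beverage", lag_h = 0,
                      halflife_h = 6, spike_magnitude = 5,
                      stringsAsFactors = FALSE)
  # dense, noise-free post-meal sampling every hour for 16 h
  times <- seq(0, 16)
  plan <- do.call(rbind, lapply(times, function(h) {
    tt <- 19 + h
    data.frame(participant_id = ids, week = 1L,
               day = 1L + (tt >= 24), day_abs = 1L + (tt >= 24),
               urine_type = if (h == -12) "FMV" else "post_dinner",
               start = tt %% 24, end = tt %% 24, stringsAsFactors = FALSE)
  }))
  fmv <- data.frame(participant_id = ids, week = 1L, day = 1L, day_abs = 1L,
                    urine_type = "FMV", start = 7, end = 7,
                    stringsAsFactors = FALSE)
  sim <- simulate_fingerprints(exposures, panel = panel, n_noise = 20,
                               sample_plan = rbind(fmv, plan),
                               noise_cv = 0, dilution_cv = 0,
                               within_cv = 0, seed = 2)
  mzc <- sim$marker_bins$bin_center[1]
  win <- estimate_elevation_window(sim$fingerprint, sim$truth,
                                   "low-calorie beverage", mzc,
                                   threshold_fold = 2)
  expect_lt(abs(win - 12), 1)
})
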