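test_that("default cohort reproduces the recruitment marginals", {
  cohort <- generate_cohort(seed = 1)
  expect_identical(nrow(cohort), 51L)
  expect_identical(sum(cohort$sex == "F"), 29L)  # 57% by rounding
  expect_true(all(cohort$age >= 19 & cohort$age <= 77))
  expect_equal(cohort$bmi, cohort$weight_kg / (cohort$height_cm / 100)^2)
  one <- generate_cohort(cohort_profile(n = 1), seed = 2)
  expect_identical(nrow(one), 1L)
  # mean age near the profile mean over repeated seeds (3 SE bound with
  # SD 17.5, n = 51 per draw, 20 draws)
  means <- vapply(1:20, function(s) mean(generate_cohort(seed = s)$age),
                  numeric(1))
  se <- 17.5 / sqrt(51 * 20)
  expect_lt(abs(mean(means) - 46.3), 3 * se + 1)  # +1 y truncation shift slack
  expect_error(cohort_profile(age_sd = -1), "positive")
  expect_error(cohort_profile(prop_female = 1.3), "prop_female")
})

test_that("exposure simulation respects menus, compliance and determinism", {
  cohort <- generate_cohort(cohort_profile(n = 6), seed = 3)
  asn <- randomize_study2(cohort$participant_id, seed = 3)
  ev <- simulate_exposures(cohort, asn, seed = 4)
  # one event per participant x week x day x slot
  expect_identical(nrow(ev), 6L * 3L * 3L * 4L)
  expect_true(all(ev$fraction %in% c(0, 0.25, 0.5, 0.75, 1)))
  w <- merge(ev, data.frame(slot = c("breakfast", "lunch", "snack", "dinner"),
                            lo = c(8, 12, 16, 18), hi = c(10, 14, 16.5, 20)))
  expect_true(all(w$meal_end >= w$lo & w$meal_end <= w$hi))
  # default profile clears the >80% compliance bound
  cf <- compliance_fraction(data.frame(
    participant_id = ev$participant_id,
    amount_eaten_percent = ev$fraction * 100))
  expect_gt(cf$overall, 0.80)
  # zero-compliance profile
  ev0 <- simulate_exposures(cohort, asn, seed = 4,
                            compliance = compliance_profile(c(1, 0, 0, 0, 0)))
  expect_true(all(ev0$fraction == 0))
  # determinism
  expect_identical(simulate_exposures(cohort, asn, seed = 4), ev)
  expect_error(simulate_exposures(cohort[1:2, ], asn, seed = 4),
               "not present")
})

test_that("fingerprints place markers on the grid and carry a truth table", {
  sc <- simulate_recovery_scenario(seed = 5, n_participants = 6,
                                   n_noise = 100)
  fp <- sc$fingerprint
  expect_s3_class(fp, "fingerprint_matrix")
  expect_identical(length(fp$mz), 101L)
  expect_false(is.unsorted(fp$mz, strictly = TRUE))
  expect_true(all(fp$intensities >= 0))
  expect_identical(nrow(fp$meta), nrow(fp$intensities))
  # marker bin center within half a bin of the theoretical ion m/z
  rule <- default_ionization_rules()[["[M-H]1-"]]
  expect_lt(abs(sc$marker_mz - ion_mz("C6H6O6S", rule)), 0.005)
  # truth: bed-time samples on pea day are exposed to peas, FMVs are not
  tr <- sc$truth[sc$truth$food == "garden peas", ]
  bed <- grepl("d1_bed_time", tr$sample_id)
  fmv1 <- grepl("d1_FMV", tr$sample_id)
  expect_true(all(tr$exposed[bed]))
  expect_false(any(tr$exposed[fmv1]))
  expect_true(all(tr$hours_since[bed] > 0))
})

test_that("null spike leaves pre/post differing only by dilution and noise", {
  sc <- simulate_recovery_scenario(seed = 6, n_participants = 8,
                                   n_noise = 50, fold = 1,
                                   noise_cv = 0, dilution_cv = 0)
  # with magnitude 1, no noise and unit dilution the marker bin behaves
  # exactly like a background bin: pre and post samples share the
  # participant x sample draw structure, with no systematic elevation
  fp <- sc$fingerprint
  j <- which.min(abs(fp$mz - sc$marker_mz))
  bed <- fp$meta$urine_type == "bed_time" & fp$meta$day == 1
  fmv <- fp$meta$urine_type == "FMV" & fp$meta$day == 1
  ratio <- mean(fp$intensities[bed, j]) / mean(fp$intensities[fmv, j])
  expect_lt(abs(log(ratio)), 0.5)  # no systematic spike
  expect_true(all(fp$meta$dilution == 1))
})

test_that("dilution is exactly invertible when measurement noise is off", {
  sc0 <- simulate_recovery_scenario(seed = 7, n_participants = 5,
                                    n_noise = 40, noise_cv = 0,
                                    dilution_cv = 0)
  sc1 <- simulate_recovery_scenario(seed = 7, n_participants = 5,
                                    n_noise = 40, noise_cv = 0,
                                    dilution_cv = 0.3)
  norm <- normalize_dilution(sc1$fingerprint)
  expect_equal(norm$intensities, sc0$fingerprint$intensities,
               tolerance = 1e-12)
  expect_gt(stats::sd(sc1$fingerprint$meta$dilution), 0)
})

test_that("bin collisions between panel compounds are refused", {
  foods <- "garden peas"
  exposures <- data.frame(participant_id = "P01", week = 1L, day = 1L,
                          day_abs = 1L, slot = "dinner", food = foods,
                          food_group = "legumes", fraction = 1,
                          meal_end = 19)
  panel <- data.frame(
    name = c("A", "B"), formula = c("C6H6O6S", "C6H6O6S"),
    ionization_products = "[M-H]1-", source_foods = foods,
    food_group = "legumes", lag_h = 0, halflife_h = 6, spike_magnitude = 3,
    stringsAsFactors = FALSE)
  expect_error(
    simulate_fingerprints(exposures, panel = panel, n_noise = 10, seed = 1),
    "collision")
})

test_that("with no spiked signal the classifier stays near chance", {
  aucs <- vapply(1:10, function(s) {
    sc <- make_processed_scenario(seed = 100 + s, n_participants = 8,
                                  n_noise = 57, fold = 1)
    ctr <- build_contrast(sc$processed, sc$truth, "garden peas")
    classify_urine_classes(ctr$x, ctr$labels, ntree = 300,
                           seed = s)$metrics$auc
  }, numeric(1))
  expect_lte(mean(aucs), 0.6)
})
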