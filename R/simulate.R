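#' Compliance profile for simulated meal consumption
#'
#' Probabilities over the five-level self-report scale (fraction eaten 0,
#' 0.25, 0.5, 0.75, 1). The default profile is dominated by full
#' consumption, giving an overall compliance fraction above the >80%
#' reported for the intervention.
#'
#' @param probs Numeric length-5 probability vector over the levels
#'   `c(0, 0.25, 0.5, 0.75, 1)`.
#' @return List of class `compliance_profile`.
#' @export
compliance_profile <- function(probs = c(0.02, 0.02, 0.03, 0.08, 0.85)) {
  if (length(probs) != 5 || any(probs < 0) || abs(sum(probs) - 1) > 1e-8) {
    stop("probs must be 5 non-negative values summing to 1", call. = FALSE)
  }
  structure(list(levels = c(0, 0.25, 0.5, 0.75, 1), probs = probs),
            class = "compliance_profile")
}

#' Packaged biomarker panel
#'
#' The spike-in panel used by [simulate_fingerprints()]: compound, elemental
#' formula, ionization products, source foods and group, and first-order
#' appearance/decay kinetics (lag, half-life, multiplicative spike
#' magnitude on baseline intensity).
#'
#' @param path Optional CSV path with the same schema; defaults to the
#'   packaged panel.
#' @return `data.frame`, one row per biomarker.
#' @export
default_biomarker_panel <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_panel.csv",
                        package = "urinebfi", mustWork = TRUE)
  }
  panel <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "formula", "ionization_products", "source_foods",
                "food_group", "lag_h", "halflife_h", "spike_magnitude")
  missing <- setdiff(required, names(panel))
  if (length(missing) > 0) {
    stop("panel lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(panel$lag_h < 0) || any(panel$halflife_h <= 0)) {
    stop("panel kinetics invalid: lag must be >= 0 and halflife > 0",
         call. = FALSE)
  }
  panel
}

#' Simulate menu-plan-driven food exposures
#'
#' Expands each participant's randomized weekly schedules into one exposure
#' event per participant x day x meal slot x food item, with a consumed
#' fraction drawn from the five-level compliance scale and a meal end time
#' drawn uniformly inside the slot's time window.
#'
#' @param cohort Cohort `data.frame` from [generate_cohort()].
#' @param assignments List of `study_assignment`s (ids must be a subset of
#'   the cohort's).
#' @param plans Menu plans, default [menu_plans()].
#' @param compliance A [compliance_profile()].
#' @param seed Integer seed.
#' @return `data.frame`: `participant_id`, `week`, `day` (1-3 within week),
#'   `day_abs` (absolute day index), `slot`, `food`, `food_group`,
#'   `fraction`, `meal_end` (hours of day).
#' @export
simulate_exposures <- function(cohort, assignments, plans = menu_plans(),
                               compliance = compliance_profile(), seed) {
  stopifnot(inherits(compliance, "compliance_profile"))
  ids <- vapply(assignments, `[[`, "", "participant_id")
  if (!all(ids %in% cohort$participant_id)) {
    stop("assignment ids not present in cohort: ",
         paste(setdiff(ids, cohort$participant_id), collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  rows <- list()
  for (a in assignments) {
    weeks <- seq_len(if (a$study == 2L) 3L else 2L)
    for (w in weeks) {
      sched <- build_week_schedule(a, w, plans)
      m <- sched$meals
      m <- m[m$day >= 1, , drop = FALSE]  # experimental days only
      frac <- sample(compliance$levels, nrow(m), replace = TRUE,
                     prob = compliance$probs)
      meal_end <- stats::runif(nrow(m), m$window_start, m$window_end)
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = a$participant_id, week = w, day = m$day,
        day_abs = (w - 1L) * 5L + m$day, slot = m$slot, food = m$food,
        food_group = m$food_group, fraction = frac, meal_end = meal_end,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Nominal collection-time windows (hours of day) for each simulated spot
## urine type. FMV/fasting precede breakfast; bed_time closes the
## post-dinner series.
urine_time_windows <- function() {
  data.frame(
    urine_type = c("FMV", "fasting", "post_breakfast", "post_lunch",
                   "post_dinner", "bed_time"),
    start = c(6.5, 7.5, 10.5, 14.5, 20.5, 22.5),
    end = c(7.4, 7.9, 11.9, 15.9, 21.5, 23.5),
    stringsAsFactors = FALSE)
}

## Default sample plan: every experimental day carries all six spot types;
## the Post day (day 4 of each week) carries FMV and fasting only.
default_sample_plan <- function(exposures) {
  pd <- unique(exposures[, c("participant_id", "week", "day", "day_abs")])
  w <- urine_time_windows()
  exp_days <- merge(pd, w)
  post <- unique(exposures[, c("participant_id", "week")])
  post$day <- 4L
  post$day_abs <- (post$week - 1L) * 5L + 4L
  post <- merge(post, w[w$urine_type %in% c("FMV", "fasting"), ])
  plan <- rbind(exp_days[, c("participant_id", "week", "day", "day_abs",
                             "urine_type", "start", "end")],
                post[, c("participant_id", "week", "day", "day_abs",
                         "urine_type", "start", "end")])
  plan[order(plan$participant_id, plan$day_abs,
             match(plan$urine_type, w$urine_type)), ]
}

#' Simulate spot-urine metabolome fingerprints
#'
#' Generates a samples x m/z-bin intensity matrix with the structure the
#' discovery analysis assumes. Each participant has a log-normal baseline
#' intensity per feature; after every exposure to one of a biomarker's
#' source foods, that biomarker's ion features are elevated by
#' `1 + (magnitude - 1) * fraction * 2^(-(t - lag) / halflife)` for sample
#' times `t >= meal end + lag` (events from earlier days keep decaying, so
#' long-lived markers remain visible in the next morning's void). All
#' intensities are then multiplied by the sample's dilution factor and by
#' log-normal noise. A truth table of per-sample exposure states is emitted
#' alongside.
#'
#' @param exposures Exposure events from [simulate_exposures()].
#' @param panel Biomarker panel, default [default_biomarker_panel()].
#' @param n_noise Number of background (null) m/z bins; default 2000.
#' @param bin_width Fingerprint bin width in Da; default 0.01.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters (per participant x feature).
#' @param within_cv CV of the within-participant, per-sample log-normal
#'   variation of the pre-dilution urine composition; default 0.4. Spot
#'   urines taken hours apart from one person differ substantially (urine
#'   composition turns over quickly — the very property that makes spot
#'   samples track recent intake), so this term keeps same-day samples from
#'   being near-duplicates of each other.
#' @param noise_cv Multiplicative log-normal measurement noise CV; 0
#'   disables noise.
#' @param dilution_cv CV of the log-normal (mean 1) urine dilution factor;
#'   0 fixes all factors at 1.
#' @param sample_plan Optional explicit sample plan (`participant_id`,
#'   `week`, `day`, `day_abs`, `urine_type`, `start`, `end`); by default all
#'   six spot types on each experimental day plus Post-day FMV/fasting.
#' @param rules Ionization rules used to place panel ions on the m/z grid.
#' @param seed Integer seed.
#' @return List with `fingerprint` (a [fingerprint_matrix()]), `truth`
#'   (`data.frame`: `sample_id`, `food`, `food_group`, `exposed`,
#'   `hours_since`), and `marker_bins` (`data.frame` mapping panel
#'   compound/rule to bin centers).
#' @export
simulate_fingerprints <- function(exposures, panel = default_biomarker_panel(),
                                  n_noise = 2000, bin_width = 0.01,
                                  baseline_meanlog = log(1000),
                                  baseline_sdlog = 0.5, within_cv = 0.4,
                                  noise_cv = 0.2, dilution_cv = 0.3,
                                  sample_plan = NULL,
                                  rules = default_ionization_rules(),
                                  seed) {
  set.seed(seed)
  marker_bins <- panel_marker_bins(panel, rules, bin_width)
  ## background bins on the same grid, never colliding with marker bins
  k_range <- seq.int(floor(80 / bin_width), floor(600 / bin_width))
  k_range <- setdiff(k_range, marker_bins$bin_k)
  k_noise <- sort(sample(k_range, n_noise))
  all_k <- sort(unique(c(k_noise, marker_bins$bin_k)))
  mz <- (all_k + 0.5) * bin_width
  n_feat <- length(all_k)

  if (is.null(sample_plan)) sample_plan <- default_sample_plan(exposures)
  sp <- sample_plan
  sp$time_h <- stats::runif(nrow(sp), sp$start, sp$end)
  sp$sample_id <- sprintf("%s_w%d_d%d_%s", sp$participant_id, sp$week,
                          sp$day, sp$urine_type)
  if (anyDuplicated(sp$sample_id)) {  # repeated spot types (dense series)
    sp$sample_id <- make.unique(sp$sample_id, sep = "_")
  }
  sp$dilution <- rlnorm_cv(nrow(sp), dilution_cv)
  n_samp <- nrow(sp)

  participants <- sort(unique(sp$participant_id))
  baseline <- matrix(
    stats::rlnorm(length(participants) * n_feat, baseline_meanlog,
                  baseline_sdlog),
    nrow = length(participants), ncol = n_feat,
    dimnames = list(participants, NULL))

  ## absolute hours for events and samples
  ev <- exposures[exposures$fraction > 0, , drop = FALSE]
  ev$t_abs <- ev$day_abs * 24 + ev$meal_end
  sp$t_abs <- sp$day_abs * 24 + sp$time_h
  ev_by_p <- split(ev, ev$participant_id)

  intens <- baseline[sp$participant_id, , drop = FALSE] *
    matrix(rlnorm_cv(n_samp * n_feat, within_cv), n_samp, n_feat)
  feat_of_bin <- match(marker_bins$bin_k, all_k)
  for (i in seq_len(n_samp)) {
    evs <- ev_by_p[[sp$participant_id[i]]]
    if (is.null(evs)) next
    for (j in seq_len(nrow(marker_bins))) {
      b <- marker_bins[j, ]
      srcs <- strsplit(b$source_foods, ";", fixed = TRUE)[[1]]
      rel <- evs[evs$food %in% srcs, , drop = FALSE]
      if (nrow(rel) == 0) next
      dt <- sp$t_abs[i] - rel$t_abs - b$lag_h
      act <- dt >= 0
      if (!any(act)) next
      excess <- sum((b$spike_magnitude - 1) * rel$fraction[act] *
                      2^(-dt[act] / b$halflife_h))
      intens[i, feat_of_bin[j]] <- intens[i, feat_of_bin[j]] * (1 + excess)
    }
  }
  intens <- intens * sp$dilution * matrix(rlnorm_cv(n_samp * n_feat, noise_cv),
                                          n_samp, n_feat)

  meta <- data.frame(sample_id = sp$sample_id,
                     participant_id = sp$participant_id,
                     week = sp$week, day = sp$day, day_abs = sp$day_abs,
                     urine_type = sp$urine_type, time_h = sp$time_h,
                     dilution = sp$dilution, normalized = FALSE,
                     stringsAsFactors = FALSE)
  fp <- fingerprint_matrix(intens, mz, meta)

  truth <- build_truth_table(sp, ev)
  list(fingerprint = fp, truth = truth, marker_bins = marker_bins)
}

## Map each panel (compound, ionization product) to a bin on the grid and
## refuse grids on which two different compounds collide in one bin.
panel_marker_bins <- function(panel, rules, bin_width) {
  out <- list()
  for (i in seq_len(nrow(panel))) {
    f <- parse_formula(panel$formula[i])
    labels <- strsplit(panel$ionization_products[i], ";", fixed = TRUE)[[1]]
    for (lab in labels) {
      if (!lab %in% names(rules)) {
        stop("unknown ionization product label '", lab, "' in panel row ",
             i, call. = FALSE)
      }
      mz <- ion_mz(f, rules[[lab]])
      out[[length(out) + 1L]] <- data.frame(
        compound = panel$name[i], rule_label = lab, mz = mz,
        bin_k = floor(mz / bin_width),
        source_foods = panel$source_foods[i],
        food_group = panel$food_group[i],
        lag_h = panel$lag_h[i], halflife_h = panel$halflife_h[i],
        spike_magnitude = panel$spike_magnitude[i],
        stringsAsFactors = FALSE)
    }
  }
  mb <- do.call(rbind, out)
  mb$bin_center <- (mb$bin_k + 0.5) * bin_width
  dup <- split(mb$compound, mb$bin_k)
  for (g in dup) {
    if (length(unique(g)) > 1) {
      stop("m/z bin collision between panel compounds: ",
           paste(unique(g), collapse = " and "),
           " share a bin at the configured grid resolution", call. = FALSE)
    }
  }
  ## one compound's multiple rules could share a bin only if two products
  ## coincide in mass; collapse duplicates then
  mb <- mb[!duplicated(mb$bin_k), , drop = FALSE]
  rownames(mb) <- NULL
  mb
}

## Per-sample, per-food exposure state: exposed iff an eaten event for that
## food ended within the 24 h before the sample (the post-dinner series
## runs past midnight, so day boundaries must not cut the window);
## hours_since is time since the most recent such meal (NA when unexposed).
build_truth_table <- function(sp, ev) {
  foods <- unique(ev[, c("food", "food_group")])
  rows <- vector("list", nrow(sp))
  ev_by_p <- split(ev, ev$participant_id)
  for (i in seq_len(nrow(sp))) {
    evs <- ev_by_p[[sp$participant_id[i]]]
    exposed <- rep(FALSE, nrow(foods))
    hours <- rep(NA_real_, nrow(foods))
    if (!is.null(evs)) {
      for (k in seq_len(nrow(foods))) {
        rel <- evs[evs$food == foods$food[k] &
                     evs$t_abs <= sp$t_abs[i] &
                     sp$t_abs[i] - evs$t_abs <= 24, , drop = FALSE]
        if (nrow(rel) > 0) {
          exposed[k] <- TRUE
          hours[k] <- min(sp$t_abs[i] - rel$t_abs)
        }
      }
    }
    rows[[i]] <- data.frame(sample_id = sp$sample_id[i], food = foods$food,
                            food_group = foods$food_group, exposed = exposed,
                            hours_since = hours, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Packaged marker-recovery scenario
#'
#' The benchmark used throughout the test suite: `n_participants`
#' participants each eat one of the four legume foods at dinner on four
#' consecutive days (consumed in full), a single shared pyrogallol-sulfate
#' -like marker bin responds to all four foods, and only first-morning-void
#' (baseline) and bed-time (exposed) urines are collected. With the default
#' 1999 background bins the fingerprint has 2000 features, and each food's
#' contrast has `n_participants` samples per class.
#'
#' @param seed Integer seed.
#' @param n_participants Participants (= samples per class per contrast);
#'   default 30.
#' @param n_noise Background bins; default 1999 (2000 features in total).
#' @param fold Spike magnitude at meal time; default 5.
#' @param halflife_h Marker half-life in hours; default 12.
#' @param noise_cv,dilution_cv Noise levels; defaults 0.2 / 0.3.
#' @param ions Semicolon-separated ionization products carried by the
#'   marker. The default single deprotonated ion makes the 2000-bin
#'   feature-selection benchmark maximally hard (one informative bin); the
#'   classification benchmark instead passes the marker's full three-ion
#'   cluster on a denser 200-bin fingerprint.
#' @return As [simulate_fingerprints()], plus `foods` (the four legume
#'   foods) and `marker_mz` (the shared marker's monoisotopic-ion bin
#'   center).
#' @export
simulate_recovery_scenario <- function(seed, n_participants = 30,
                                       n_noise = 1999, fold = 5,
                                       halflife_h = 12, noise_cv = 0.2,
                                       dilution_cv = 0.3,
                                       ions = "[M-H]1-") {
  foods <- c("garden peas", "baked beans", "peanuts", "tofu")
  ids <- sprintf("P%02d", seq_len(n_participants))
  ## exposure days spaced 3 days apart so residual decay from one legume
  ## dinner is negligible by the next food's baseline void
  exposures <- do.call(rbind, lapply(seq_along(foods), function(d) {
    data.frame(participant_id = ids, week = 1L, day = d,
               day_abs = 3L * (d - 1L) + 1L,
               slot = "dinner", food = foods[d], food_group = "legumes",
               fraction = 1, meal_end = 19, stringsAsFactors = FALSE)
  }))
  panel <- data.frame(
    name = "Pyrogallol sulfate", formula = "C6H6O6S",
    ionization_products = ions,
    source_foods = paste(foods, collapse = ";"),
    food_group = "legumes", lag_h = 0, halflife_h = halflife_h,
    spike_magnitude = fold, stringsAsFactors = FALSE)
  w <- urine_time_windows()
  plan <- merge(unique(exposures[, c("participant_id", "week", "day",
                                     "day_abs")]),
                w[w$urine_type %in% c("FMV", "bed_time"), ])
  sim <- simulate_fingerprints(
    exposures, panel = panel, n_noise = n_noise,
    noise_cv = noise_cv, dilution_cv = dilution_cv,
    sample_plan = plan[, c("participant_id", "week", "day", "day_abs",
                           "urine_type", "start", "end")],
    seed = seed)
  sim$foods <- foods
  sim$marker_mz <- sim$marker_bins$bin_center[1]
  sim
}
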