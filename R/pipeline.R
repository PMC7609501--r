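#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end run: study arm and cohort size,
#' the spike-in biomarker panel, fingerprint grid and noise parameters, the
#' discovery contrast, selection depth and FDR level, the annotation
#' tolerance, and the output directory. Validation happens here so stage
#' errors can name the offending field.
#'
#' @param seed Master seed; every stochastic stage derives its stream from
#'   it.
#' @param study 1 or 2; default 2 (the 3-week discovery study).
#' @param n_participants Cohort size; default 36.
#' @param panel Biomarker panel `data.frame` or CSV path; default the
#'   packaged panel. `NULL` is rejected.
#' @param foods Foods to run discovery contrasts for; default the panel's
#'   legume source foods.
#' @param n_noise,bin_width,noise_cv,dilution_cv Simulator settings (see
#'   [simulate_fingerprints()]).
#' @param baseline_type,exposed_type Contrast classes; defaults FMV /
#'   bed-time urine.
#' @param k,fdr_alpha Selection depth and Benjamini-Hochberg level.
#' @param ppm_tol Annotation tolerance in ppm; default 5.
#' @param ntree Random-forest trees; default 1000.
#' @param out_dir Output directory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, study = 2, n_participants = 36,
                            panel = default_biomarker_panel(),
                            foods = NULL, n_noise = 2000, bin_width = 0.01,
                            noise_cv = 0.2, dilution_cv = 0.3,
                            baseline_type = "FMV", exposed_type = "bed_time",
                            k = 25, fdr_alpha = 0.05, ppm_tol = 5,
                            ntree = 1000, out_dir = tempfile("bfi_run_")) {
  if (missing(seed) || is.null(seed)) {
    stop("config field 'seed' is required", call. = FALSE)
  }
  if (is.null(panel)) stop("config field 'panel' is required", call. = FALSE)
  if (is.character(panel)) panel <- default_biomarker_panel(panel)
  if (!study %in% c(1, 2)) stop("config field 'study' must be 1 or 2",
                                call. = FALSE)
  if (n_participants < 1) {
    stop("config field 'n_participants' must be positive", call. = FALSE)
  }
  if (ppm_tol <= 0) stop("config field 'ppm_tol' must be positive",
                         call. = FALSE)
  if (k < 1) stop("config field 'k' must be >= 1", call. = FALSE)
  if (fdr_alpha <= 0 || fdr_alpha >= 1) {
    stop("config field 'fdr_alpha' must lie in (0, 1)", call. = FALSE)
  }
  if (is.null(foods)) {
    legumes <- panel$source_foods[panel$food_group == "legumes"]
    foods <- unique(unlist(strsplit(legumes, ";", fixed = TRUE)))
    if (length(foods) == 0) {
      foods <- unique(unlist(strsplit(panel$source_foods, ";",
                                      fixed = TRUE)))[1]
    }
  }
  structure(list(seed = as.integer(seed), study = as.integer(study),
                 n_participants = as.integer(n_participants), panel = panel,
                 foods = foods, n_noise = n_noise, bin_width = bin_width,
                 noise_cv = noise_cv, dilution_cv = dilution_cv,
                 baseline_type = baseline_type, exposed_type = exposed_type,
                 k = k, fdr_alpha = fdr_alpha, ppm_tol = ppm_tol,
                 ntree = ntree, out_dir = out_dir),
            class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full discovery pipeline
#'
#' Executes simulate -> process -> discover (one contrast per configured
#' food) -> annotate -> specificity/kinetics, writes every artifact as TSV
#' plus a machine-readable JSON manifest (seed, package version, file MD5
#' hashes — no timestamps), and returns the in-memory report. Identical
#' config and seed give byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the cohort, assignments, fingerprint,
#'   per-food discovery results, shared-marker table, candidate report and
#'   manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)

  cohort <- run_stage("cohort", generate_cohort(
    cohort_profile(n = config$n_participants),
    seed = derive_seed(config$seed, "cohort")))
  assignments <- run_stage("design", {
    if (config$study == 2L) {
      randomize_study2(cohort$participant_id,
                       derive_seed(config$seed, "design"))
    } else {
      randomize_study1(cohort$participant_id,
                       derive_seed(config$seed, "design"))
    }
  })
  exposures <- run_stage("exposures", simulate_exposures(
    cohort, assignments, seed = derive_seed(config$seed, "exposures")))
  sim <- run_stage("fingerprints", simulate_fingerprints(
    exposures, panel = config$panel, n_noise = config$n_noise,
    bin_width = config$bin_width, noise_cv = config$noise_cv,
    dilution_cv = config$dilution_cv,
    seed = derive_seed(config$seed, "fingerprints")))
  processed <- run_stage("process",
                         transform_log(normalize_dilution(sim$fingerprint)))

  discoveries <- list()
  for (food in config$foods) {
    discoveries[[food]] <- run_stage(
      paste0("discover:", food),
      discover_biomarkers(processed, sim$truth, food,
                          baseline_type = config$baseline_type,
                          exposed_type = config$exposed_type,
                          k = config$k, fdr_alpha = config$fdr_alpha,
                          ntree = config$ntree,
                          seed = derive_seed(config$seed,
                                             paste0("discover:", food))))
  }

  srcs <- strsplit(config$panel$source_foods, ";", fixed = TRUE)
  food_groups <- unique(data.frame(
    food = unlist(srcs),
    group = rep(config$panel$food_group, lengths(srcs)),
    stringsAsFactors = FALSE))
  group_map <- split(food_groups$food, food_groups$group)
  shared <- if (length(discoveries) >= 2) {
    run_stage("consistency", cross_food_consistency(
      lapply(discoveries, `[[`, "stats"), group_map, k = config$k))
  } else list()

  report <- run_stage("specificity", {
    rows <- list()
    for (food in names(discoveries)) {
      cand <- discoveries[[food]]$candidates
      for (i in seq_len(min(nrow(cand), 5L))) {
        mz <- cand$mz[i]
        spec <- tryCatch(
          specificity_score(processed, sim$truth, food, mz),
          error = function(e) NA_real_)
        wind <- tryCatch(
          estimate_elevation_window(processed, sim$truth, food, mz),
          error = function(e) NA_real_)
        ann <- annotate_mz(mz, "neg", tol_ppm = config$ppm_tol)
        annp <- annotate_mz(mz, "pos", tol_ppm = config$ppm_tol)
        ann <- rbind(ann, annp)
        rows[[length(rows) + 1L]] <- data.frame(
          food = food, mz = mz, aggregate_rank = cand$aggregate_rank[i],
          specificity = spec, elevation_window_h = wind,
          annotation = if (nrow(ann) > 0) {
            paste0(ann$compound[1], " ", ann$rule_label[1])
          } else NA_character_,
          msi_level = if (nrow(ann) > 0) ann$msi_level[1] else NA_integer_,
          stringsAsFactors = FALSE)
      }
    }
    if (length(rows) == 0) {
      data.frame(food = character(), mz = numeric(),
                 aggregate_rank = integer(), specificity = numeric(),
                 elevation_window_h = numeric(), annotation = character(),
                 msi_level = integer(), stringsAsFactors = FALSE)
    } else {
      do.call(rbind, rows)
    }
  })

  files <- c(cohort = "cohort.tsv", assignments = "assignments.tsv",
             fingerprint = "fingerprint.tsv", meta = "meta.tsv",
             truth = "truth.tsv", candidates = "candidates.tsv")
  write_tsv_table(cohort, file.path(out, files["cohort"]))
  write_assignments(assignments, file.path(out, files["assignments"]))
  write_fingerprint(sim$fingerprint, file.path(out, files["fingerprint"]))
  write_sample_meta(sim$fingerprint$meta, file.path(out, files["meta"]))
  write_truth(sim$truth, file.path(out, files["truth"]))
  write_candidates(report, file.path(out, files["candidates"]))
  for (food in names(discoveries)) {
    fn <- paste0("stats_", gsub("[^A-Za-z0-9]+", "_", food), ".tsv")
    write_tsv_table(discoveries[[food]]$stats, file.path(out, fn))
    files[paste0("stats:", food)] <- fn
  }

  manifest <- list(
    seed = config$seed,
    package_version = as.character(utils::packageVersion("urinebfi")),
    study = config$study, n_participants = config$n_participants,
    foods = config$foods,
    metrics = lapply(discoveries, function(d) {
      d$metrics[c("accuracy", "mean_margin", "auc")]
    }),
    shared_markers = shared,
    file_md5 = as.list(tools::md5sum(file.path(out, unname(files)))))
  names(manifest$file_md5) <- unname(files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(cohort = cohort, assignments = assignments,
                 exposures = exposures, fingerprint = sim$fingerprint,
                 truth = sim$truth, discoveries = discoveries,
                 shared = shared, report = report, manifest = manifest,
                 out_dir = out))
}
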