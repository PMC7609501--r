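#' Assign a Metabolomics Standards Initiative identification level
#'
#' Level 1 requires a full match to an authentic standard (accurate mass,
#' retention time and MSn fragmentation); level 2 a putative match to
#' literature or spectral-library behavior; level 3 a characterized compound
#' class only.
#'
#' @param standard_mass_match,standard_rt_match,msn_match Logical; evidence
#'   against an authentic standard.
#' @param literature_spectral_match Logical; literature / spectral-library
#'   match.
#' @param class_only Logical; compound class characterized only.
#' @return Integer 1, 2 or 3.
#' @examples
#' assign_msi_level(standard_mass_match = TRUE, standard_rt_match = TRUE,
#'                  msn_match = TRUE)
#' @export
assign_msi_level <- function(standard_mass_match = FALSE,
                             standard_rt_match = FALSE,
                             msn_match = FALSE,
                             literature_spectral_match = FALSE,
                             class_only = FALSE) {
  flags <- c(standard_mass_match, standard_rt_match, msn_match,
             literature_spectral_match, class_only)
  if (!any(flags)) {
    stop("no identification evidence supplied; at least one flag must be set",
         call. = FALSE)
  }
  if (standard_mass_match && standard_rt_match && msn_match) return(1L)
  if (literature_spectral_match) return(2L)
  3L
}

#' Read a compound formula database
#'
#' CSV with columns `name`, `formula` (Hill notation), `food_sources`
#' (semicolon-separated), `food_group`, `ionization_products`
#' (semicolon-separated rule labels) and the five MSI evidence flag columns
#' understood by [assign_msi_level()].
#'
#' @param path CSV file path.
#' @return A `data.frame`, one row per compound, with an `msi_level` column
#'   derived from the evidence flags.
#' @export
read_compound_db <- function(path) {
  db <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "formula")
  missing <- setdiff(required, names(db))
  if (length(missing) > 0) {
    stop("compound database lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  validate_compound_db(db)
  flags <- c("standard_mass_match", "standard_rt_match", "msn_match",
             "literature_spectral_match", "class_only")
  if (all(flags %in% names(db))) {
    db$msi_level <- vapply(seq_len(nrow(db)), function(i) {
      assign_msi_level(db$standard_mass_match[i], db$standard_rt_match[i],
                       db$msn_match[i], db$literature_spectral_match[i],
                       db$class_only[i])
    }, integer(1))
  }
  db
}

validate_compound_db <- function(db) {
  for (i in seq_len(nrow(db))) {
    if (is.na(db$name[i]) || !nzchar(db$name[i])) {
      stop("malformed compound database row ", i, ": empty name",
           call. = FALSE)
    }
    ok <- tryCatch({ parse_formula(db$formula[i]); TRUE },
                   error = function(e) FALSE)
    if (!ok) {
      stop("malformed compound database row ", i, " ('", db$name[i],
           "'): bad formula '", db$formula[i], "'", call. = FALSE)
    }
  }
  invisible(db)
}

#' Packaged urinary biomarker compound database
#'
#' Reference set of urinary food-intake biomarker compounds (legume,
#' curry, heated-food, berry/tomato and sweetener markers) with elemental
#' formulas derived from the compound names (sulfate = aglycone + SO3,
#' glucuronide = aglycone + C6H8O6), their observed ionization products and
#' MSI evidence flags.
#'
#' @return A compound database `data.frame` (see [read_compound_db()]).
#' @export
default_compound_db <- function() {
  read_compound_db(system.file("extdata", "compound_db.csv",
                               package = "urinebfi", mustWork = TRUE))
}

#' Annotate an observed m/z against a compound database
#'
#' Enumerates all (compound, ionization rule) pairs of the requested
#' polarity whose theoretical m/z lies within `tol_ppm` of the observed
#' value.
#'
#' @param observed_mz Observed m/z in Da.
#' @param polarity `"neg"` or `"pos"`; rules of the other polarity are
#'   ignored.
#' @param db Compound database `data.frame` with at least `name` and
#'   `formula` columns (see [read_compound_db()]); defaults to the packaged
#'   database.
#' @param rules List of [ionization_rule()] objects; defaults to
#'   [default_ionization_rules()].
#' @param tol_ppm Match tolerance in ppm (> 0); default 5.
#' @return A `data.frame` with columns `compound`, `formula`, `rule_label`,
#'   `theoretical_mz`, `observed_mz`, `ppm_error`, `msi_level`, sorted by
#'   `|ppm_error|` then (compound, rule label). Zero rows if nothing
#'   matches.
#' @examples
#' \donttest{
#' annotate_mz(204.98143, "neg")
#' }
#' @export
annotate_mz <- function(observed_mz, polarity = c("neg", "pos"),
                        db = default_compound_db(),
                        rules = default_ionization_rules(),
                        tol_ppm = 5) {
  polarity <- match.arg(polarity)
  if (!is.numeric(tol_ppm) || tol_ppm <= 0) {
    stop("tol_ppm must be positive", call. = FALSE)
  }
  validate_compound_db(db)
  rules <- rules[vapply(rules, rule_polarity, "") == polarity]
  out <- list()
  for (i in seq_len(nrow(db))) {
    f <- parse_formula(db$formula[i])
    msi <- if ("msi_level" %in% names(db)) db$msi_level[i] else NA_integer_
    for (rule in rules) {
      mz <- tryCatch(ion_mz(f, rule), error = function(e) NA_real_)
      if (is.na(mz)) next  # rule not applicable to this formula
      err <- ppm_error(observed_mz, mz)
      if (abs(err) <= tol_ppm) {
        out[[length(out) + 1L]] <- data.frame(
          compound = db$name[i], formula = db$formula[i],
          rule_label = rule$label, theoretical_mz = mz,
          observed_mz = observed_mz, ppm_error = err, msi_level = msi,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(compound = character(), formula = character(),
                      rule_label = character(), theoretical_mz = numeric(),
                      observed_mz = numeric(), ppm_error = numeric(),
                      msi_level = integer(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(abs(res$ppm_error), res$compound, res$rule_label), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Annotate a vector of peaks and write a results table
#'
#' Convenience wrapper over [annotate_mz()] for a whole peak list; the
#' result is the row-bound annotation table, optionally written as TSV.
#'
#' @inheritParams annotate_mz
#' @param peaks Numeric vector of observed m/z values.
#' @param path Optional TSV output path.
#' @return Annotation `data.frame` (invisibly if `path` given).
#' @export
annotate_peaks <- function(peaks, polarity = c("neg", "pos"),
                           db = default_compound_db(),
                           rules = default_ionization_rules(),
                           tol_ppm = 5, path = NULL) {
  polarity <- match.arg(polarity)
  res <- do.call(rbind, lapply(peaks, annotate_mz, polarity = polarity,
                               db = db, rules = rules, tol_ppm = tol_ppm))
  if (!is.null(path)) {
    write_tsv_table(res, path)
    return(invisible(res))
  }
  res
}
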