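#' Write / read a fingerprint matrix as TSV
#'
#' The fingerprint TSV has a `sample_id` first column and one column per
#' m/z bin, named by the bin center to 5 decimal places. Sample metadata
#' travels in its own TSV (see [write_sample_meta()]).
#'
#' @param x A [fingerprint_matrix()].
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  df <- data.frame(sample_id = x$meta$sample_id, stringsAsFactors = FALSE,
                   check.names = FALSE)
  m <- x$intensities
  for (j in seq_len(ncol(m))) df[[format_mz(x$mz[j])]] <- m[, j]
  write_tsv_table(df, path)
}

#' @rdname write_fingerprint
#' @param meta Optional metadata `data.frame` (e.g. from
#'   [read_sample_meta()]) to attach; must cover all sample ids.
#' @export
read_fingerprint <- function(path, meta = NULL) {
  df <- read_tsv_table(path, required = "sample_id")
  mz <- suppressWarnings(as.numeric(setdiff(names(df), "sample_id")))
  if (anyNA(mz)) {
    stop("file '", path, "': non-numeric m/z column name(s)", call. = FALSE)
  }
  m <- as.matrix(df[, setdiff(names(df), "sample_id"), drop = FALSE])
  if (is.null(meta)) {
    meta <- data.frame(sample_id = df$sample_id, dilution = 1,
                       stringsAsFactors = FALSE)
  } else {
    idx <- match(df$sample_id, meta$sample_id)
    if (anyNA(idx)) {
      stop("metadata lacks sample(s): ",
           paste(df$sample_id[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    meta <- meta[idx, , drop = FALSE]
    rownames(meta) <- NULL
  }
  fingerprint_matrix(m, mz, meta)
}

#' Write / read sample metadata, truth labels and candidate tables
#'
#' Plain TSV round-trip helpers for the pipeline's tabular artifacts; all
#' use a header row, tab separation, '.' decimal point and UTF-8.
#'
#' @param meta,truth,candidates The table to write.
#' @param path File path.
#' @return The table (readers) or `path` invisibly (writers).
#' @export
write_sample_meta <- function(meta, path) write_tsv_table(meta, path)

#' @rdname write_sample_meta
#' @export
read_sample_meta <- function(path) {
  read_tsv_table(path, required = c("sample_id", "participant_id",
                                    "urine_type", "dilution"))
}

#' @rdname write_sample_meta
#' @export
write_truth <- function(truth, path) write_tsv_table(truth, path)

#' @rdname write_sample_meta
#' @export
read_truth <- function(path) {
  read_tsv_table(path, required = c("sample_id", "food", "exposed"))
}

#' @rdname write_sample_meta
#' @export
write_candidates <- function(candidates, path) {
  write_tsv_table(candidates, path)
}

#' @rdname write_sample_meta
#' @export
read_candidates <- function(path) {
  read_tsv_table(path, required = c("mz", "aggregate_rank"))
}

#' Write study assignments as TSV
#'
#' @param assignments List of `study_assignment`s.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_assignments <- function(assignments, path) {
  df <- do.call(rbind, lapply(assignments, function(a) {
    data.frame(
      participant_id = a$participant_id, study = a$study,
      square_index = if (a$study == 2L) a$square_index else NA_integer_,
      dinner_order = if (a$study == 2L) {
        paste(a$dinner_order, collapse = "-")
      } else NA_character_,
      arm = if (a$study == 1L) a$crossover_arm else NA_character_,
      stringsAsFactors = FALSE)
  }))
  write_tsv_table(df, path)
}
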