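#' Construct a fingerprint matrix
#'
#' A fingerprint matrix holds samples x m/z-bin intensities from
#' flow-infusion high-resolution mass spectrometry together with per-sample
#' metadata (participant, day, urine type, collection time, dilution
#' factor).
#'
#' @param intensities Numeric matrix, samples in rows, bins in columns;
#'   no negative values.
#' @param mz Strictly ascending numeric vector of bin centers (Da), one per
#'   column.
#' @param meta `data.frame` with one row per sample; must contain
#'   `sample_id` and `dilution`; a logical `normalized` column is added if
#'   absent.
#' @return Object of class `fingerprint_matrix`.
#' @export
fingerprint_matrix <- function(intensities, mz, meta = NULL) {
  intensities <- as.matrix(intensities)
  if (any(intensities < 0)) {
    stop("negative intensities are not allowed", call. = FALSE)
  }
  if (length(mz) != ncol(intensities)) {
    stop("length(mz) must equal ncol(intensities)", call. = FALSE)
  }
  if (is.unsorted(mz, strictly = TRUE)) {
    stop("mz bin centers must be strictly ascending", call. = FALSE)
  }
  if (is.null(meta)) {
    meta <- data.frame(sample_id = paste0("S", seq_len(nrow(intensities))),
                       dilution = 1, stringsAsFactors = FALSE)
  }
  if (nrow(meta) != nrow(intensities)) {
    stop("meta must have one row per sample", call. = FALSE)
  }
  if (!"sample_id" %in% names(meta)) {
    stop("meta must contain a sample_id column", call. = FALSE)
  }
  if (!"dilution" %in% names(meta)) meta$dilution <- 1
  if (!"normalized" %in% names(meta)) meta$normalized <- FALSE
  rownames(intensities) <- meta$sample_id
  colnames(intensities) <- format_mz(mz)
  structure(list(intensities = intensities, mz = as.numeric(mz),
                 meta = meta),
            class = "fingerprint_matrix")
}

format_mz <- function(mz) sprintf("%.5f", mz)

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat("<fingerprint_matrix> ", nrow(x$intensities), " samples x ",
      ncol(x$intensities), " m/z bins [",
      format_mz(min(x$mz)), ", ", format_mz(max(x$mz)), "] Da; ",
      if (all(x$meta$normalized)) "dilution-normalized" else "raw",
      "\n", sep = "")
  invisible(x)
}

#' @export
dim.fingerprint_matrix <- function(x) dim(x$intensities)

#' Normalize a fingerprint matrix by per-sample dilution factor
#'
#' Divides each sample's intensities by its dilution factor (the stand-in
#' for the refractive-index normalization applied to real urine samples so
#' that all MS measurements share a dynamic range) and flags the matrix as
#' normalized. Normalizing twice is refused.
#'
#' @param x A [fingerprint_matrix()] whose metadata carries positive
#'   `dilution` factors.
#' @return The normalized `fingerprint_matrix`.
#' @export
normalize_dilution <- function(x) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  if (any(x$meta$normalized)) {
    stop("fingerprint matrix is already dilution-normalized", call. = FALSE)
  }
  d <- x$meta$dilution
  bad <- is.na(d) | d <= 0
  if (any(bad)) {
    stop("missing or non-positive dilution factor for sample(s): ",
         paste(x$meta$sample_id[bad], collapse = ", "), call. = FALSE)
  }
  x$intensities <- x$intensities / d
  x$meta$normalized <- TRUE
  x
}

#' Bin peak lists into a fixed-width fingerprint matrix
#'
#' Peaks are summed into half-open bins `[k*w, (k+1)*w)`; a peak exactly on
#' a boundary belongs to the upper bin. Bin centers are reported as
#' `(k + 0.5) * w`. Only occupied bins are kept.
#'
#' @param peaks Named list, one element per sample, each a `data.frame`
#'   with columns `mz` and `intensity` (non-negative).
#' @param bin_width Bin width in Da (> 0), default 0.01.
#' @return A [fingerprint_matrix()] over the union of occupied bins.
#' @examples
#' bin_peaks(list(S1 = data.frame(mz = 204.98143, intensity = 5)), 0.01)
#' @export
bin_peaks <- function(peaks, bin_width = 0.01) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("bin_width must be positive", call. = FALSE)
  }
  if (is.null(names(peaks))) names(peaks) <- paste0("S", seq_along(peaks))
  binned <- lapply(peaks, function(df) {
    stopifnot(all(c("mz", "intensity") %in% names(df)))
    if (any(df$intensity < 0)) {
      stop("negative peak intensity in input", call. = FALSE)
    }
    k <- floor(df$mz / bin_width)
    tapply(df$intensity, k, sum)
  })
  all_k <- sort(unique(as.numeric(unlist(lapply(binned, names)))))
  m <- matrix(0, nrow = length(peaks), ncol = length(all_k))
  for (i in seq_along(binned)) {
    m[i, match(as.numeric(names(binned[[i]])), all_k)] <-
      as.numeric(binned[[i]])
  }
  fingerprint_matrix(m, (all_k + 0.5) * bin_width,
                     data.frame(sample_id = names(peaks), dilution = 1,
                                stringsAsFactors = FALSE))
}

#' Log-transform fingerprint intensities
#'
#' Order-preserving variance stabilization `x -> log(x + offset)` applied
#' before classification.
#'
#' @param x A [fingerprint_matrix()].
#' @param offset Positive shift added before the log; default 1.
#' @return The transformed `fingerprint_matrix` (attribute `log_offset`
#'   records the offset).
#' @export
transform_log <- function(x, offset = 1) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  if (!is.numeric(offset) || offset <= 0) {
    stop("offset must be positive", call. = FALSE)
  }
  x$intensities <- log(x$intensities + offset)
  attr(x, "log_offset") <- offset
  x
}
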