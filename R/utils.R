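## Derive a reproducible sub-seed from a master seed and a stream label, so
## that independent randomization streams (e.g. Latin-square draw vs dinner
## order) do not share state. Kept inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629)
}

## Truncated normal draws by inverse-CDF; deterministic under set.seed.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

## Log-normal multiplicative factors with mean 1 and coefficient of
## variation cv. cv = 0 gives exactly 1 but still consumes n draws, so
## runs that differ only in one cv stay aligned on every other stream.
rlnorm_cv <- function(n, cv) {
  sdlog <- sqrt(log(1 + cv^2))
  exp(-sdlog^2 / 2 + sdlog * stats::rnorm(n))
}

## Write a data.frame as TSV (header, no quoting, '.' decimal, UTF-8).
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv_table <- function(path, required = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!is.null(required)) {
    missing <- setdiff(required, names(df))
    if (length(missing) > 0) {
      stop("file '", path, "': header lacks column(s) ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  df
}
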