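#' Enumerate all Latin squares of a small order
#'
#' Exhaustive, duplicate-free enumeration in lexicographic row order
#' (rows compared as digit sequences, first row most significant). Order 3
#' yields exactly 12 squares — the randomization space used to balance
#' three daily menu plans over three experimental weeks.
#'
#' @param order Square order, 1 to 4 (larger orders are refused: the count
#'   grows combinatorially and is never needed here).
#' @return List of `order x order` integer matrices; each row and column of
#'   each matrix is a permutation of `1:order`.
#' @examples
#' length(enumerate_latin_squares(3))  # 12
#' @export
enumerate_latin_squares <- function(order) {
  if (!is.numeric(order) || length(order) != 1 || order < 1 ||
      order != round(order)) {
    stop("order must be a positive integer", call. = FALSE)
  }
  if (order > 4) {
    stop("orders above 4 are not supported (combinatorial explosion)",
         call. = FALSE)
  }
  order <- as.integer(order)
  rows <- all_permutations(order)
  squares <- list()
  grow <- function(chosen) {
    if (length(chosen) == order) {
      squares[[length(squares) + 1L]] <<- do.call(rbind, chosen)
      return(invisible())
    }
    for (cand in rows) {
      ok <- TRUE
      for (prev in chosen) {
        if (any(prev == cand)) { ok <- FALSE; break }
      }
      if (ok) grow(c(chosen, list(cand)))
    }
  }
  grow(list())
  squares
}

## All permutations of 1:n in lexicographic order.
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    for (p in all_permutations(n - 1L)) {
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

is_latin_square <- function(m) {
  n <- nrow(m)
  if (ncol(m) != n) return(FALSE)
  target <- seq_len(n)
  all(apply(m, 1, function(r) identical(sort(r), target))) &&
    all(apply(m, 2, function(r) identical(sort(r), target)))
}
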