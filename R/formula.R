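## Monoisotopic masses of the principal isotopes (Da), CODATA/AME2020.
## Only elements that occur in the packaged urinary biomarker set are
## supported; unknown symbols are rejected rather than silently dropped.
.element_masses <- c(
  H  = 1.00782503207,
  C  = 12.0,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  S  = 31.9720711744,
  K  = 38.9637064864
)

.electron_mass <- 0.000548579909

## Mass shift m(heavy) - m(light) for the single-substitution isotopologues
## observed in high-resolution urine fingerprints.
.isotope_shifts <- c(
  "13C" = 13.0033548378 - 12.0,
  "34S" = 33.9678670412 - 31.9720711744,
  "41K" = 40.9618252579 - 38.9637064864
)

.isotope_elements <- c("13C" = "C", "34S" = "S", "41K" = "K")

#' Elemental composition of a neutral molecule or ion
#'
#' A `chem_formula` is a named count vector over the supported element set
#' (C, H, N, O, Na, S, K). The empty formula (mass 0) is allowed; negative
#' counts and unknown element symbols are rejected.
#'
#' @param counts Named numeric vector of non-negative integer atom counts,
#'   e.g. `c(C = 6, H = 6, O = 6, S = 1)`.
#' @return An object of class `chem_formula`.
#' @examples
#' chem_formula(c(H = 2, O = 1))
#' @seealso [parse_formula()] for Hill-notation text input.
#' @export
chem_formula <- function(counts = numeric()) {
  if (length(counts) == 0) {
    out <- structure(numeric(), names = character())
    class(out) <- "chem_formula"
    return(out)
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts)))) {
    stop("formula counts must be named by element symbol", call. = FALSE)
  }
  unknown <- setdiff(names(counts), names(.element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("element counts must be non-negative integers", call. = FALSE)
  }
  counts <- counts[counts > 0]
  counts <- counts[order(names(counts))]
  out <- as.numeric(counts)
  names(out) <- names(counts)
  class(out) <- "chem_formula"
  out
}

#' Parse a Hill-notation formula string
#'
#' @param text Formula text such as `"C6H6O6S"` or `"C4H4KNO4S"`. An empty
#'   string yields the empty formula.
#' @return A [chem_formula()].
#' @examples
#' parse_formula("C6H6O6S")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  text <- trimws(text)
  if (!nzchar(text)) return(chem_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text, perl = TRUE)[[1]]
  toks <- regmatches(text, list(m))[[1]]
  if (paste(toks, collapse = "") != text) {
    stop("cannot parse formula text: '", text, "'", call. = FALSE)
  }
  sym <- sub("[0-9]*$", "", toks)
  cnt <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(cnt), as.numeric(cnt), 1)
  counts <- tapply(cnt, sym, sum)
  chem_formula(stats::setNames(as.numeric(counts), names(counts)))
}

#' @export
format.chem_formula <- function(x, ...) {
  if (length(x) == 0) return("(empty)")
  ## Hill order: C, H, then alphabetical
  el <- names(x)
  ord <- order(match(el, c("C", "H"), nomatch = 3L), el)
  paste0(el[ord], ifelse(x[ord] > 1, x[ord], ""), collapse = "")
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format(x), "  (", sprintf("%.5f", monoisotopic_mass(x)),
      " Da)\n", sep = "")
  invisible(x)
}

## Elementwise sum of two formulas.
formula_add <- function(a, b) {
  el <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(el)), el)
  v[names(a)] <- v[names(a)] + as.numeric(a)
  v[names(b)] <- v[names(b)] + as.numeric(b)
  chem_formula(v)
}

## Elementwise difference a - b; caller handles applicability errors.
formula_subtract <- function(a, b) {
  el <- union(names(a), names(b))
  v <- stats::setNames(numeric(length(el)), el)
  v[names(a)] <- v[names(a)] + as.numeric(a)
  v[names(b)] <- v[names(b)] - as.numeric(b)
  if (any(v < 0)) {
    bad <- names(v)[v < 0]
    stop("loss not applicable: formula lacks ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  chem_formula(v)
}

#' Monoisotopic mass of a formula
#'
#' Sum of atom counts times the principal-isotope masses
#' (1H, 12C, 14N, 16O, 23Na, 32S, 39K).
#'
#' @param formula A [chem_formula()] or Hill-notation string.
#' @return Mass in Da; 0 for the empty formula.
#' @examples
#' monoisotopic_mass("H2O")      # 18.010565
#' monoisotopic_mass("C6H6O6S")  # neutral pyrogallol sulfate, 205.98851
#' @export
monoisotopic_mass <- function(formula) {
  formula <- as_chem_formula(formula)
  if (length(formula) == 0) return(0)
  sum(as.numeric(formula) * .element_masses[names(formula)])
}

as_chem_formula <- function(x) {
  if (inherits(x, "chem_formula")) return(x)
  if (is.character(x)) return(parse_formula(x))
  if (is.numeric(x)) return(chem_formula(x))
  stop("cannot interpret object of class '", class(x)[1],
       "' as a chemical formula", call. = FALSE)
}
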