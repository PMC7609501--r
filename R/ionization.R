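#' Define an ionization product rule
#'
#' A rule turns a neutral molecule M into the charged species actually
#' detected: atoms gained and lost, a +/-1 charge, and optionally a single
#' heavy-isotope substitution (13C, 34S or 41K) somewhere in the ion.
#'
#' @param label Display label, e.g. `"[M-H]1-"` or `"[M+K]1+41K"`.
#' @param gains,losses [chem_formula()] (or Hill strings) of atoms added
#'   to / removed from M.
#' @param charge Signed integer, only +1 / -1 in scope.
#' @param isotope One of `"none"`, `"13C"`, `"34S"`, `"41K"`.
#' @return An object of class `ionization_rule`.
#' @examples
#' ionization_rule("[M-H]1-", losses = "H", charge = -1)
#' @export
ionization_rule <- function(label, gains = chem_formula(),
                            losses = chem_formula(), charge,
                            isotope = c("none", "13C", "34S", "41K")) {
  isotope <- match.arg(isotope)
  charge <- as.integer(charge)
  if (length(charge) != 1 || is.na(charge) || charge == 0 ||
      abs(charge) != 1L) {
    stop("charge must be +1 or -1", call. = FALSE)
  }
  structure(
    list(label = label,
         gains = as_chem_formula(gains),
         losses = as_chem_formula(losses),
         charge = charge,
         isotope = isotope),
    class = "ionization_rule")
}

#' @export
print.ionization_rule <- function(x, ...) {
  cat("<ionization_rule> ", x$label, " (charge ", sprintf("%+d", x$charge),
      if (x$isotope != "none") paste0(", ", x$isotope), ")\n", sep = "")
  invisible(x)
}

rule_polarity <- function(rule) if (rule$charge > 0) "pos" else "neg"

## Full elemental composition of the ion formed from `formula` under `rule`;
## errors if a loss or isotope substitution is not satisfiable.
ion_composition <- function(formula, rule) {
  formula <- as_chem_formula(formula)
  comp <- tryCatch(
    formula_subtract(formula_add(formula, rule$gains), rule$losses),
    error = function(e) {
      stop("rule '", rule$label, "' not applicable to ", format(formula),
           ": ", conditionMessage(e), call. = FALSE)
    })
  if (rule$isotope != "none") {
    el <- .isotope_elements[[rule$isotope]]
    if (!el %in% names(comp) || comp[[el]] < 1) {
      stop("rule '", rule$label, "' not applicable to ", format(formula),
           ": no ", el, " atom available for ", rule$isotope,
           " substitution", call. = FALSE)
    }
  }
  comp
}

#' m/z of an ionization product
#'
#' `m/z = (monoisotopic_mass(M + gains - losses) + isotope_shift -
#' charge * m_e) / |charge|`. The electron mass is included, as required to
#' match high-resolution data at the ~1 ppm level.
#'
#' @inheritParams ionization_rule
#' @param formula Neutral molecule as [chem_formula()] or Hill string.
#' @param rule An [ionization_rule()].
#' @return m/z in Da.
#' @examples
#' ion_mz("C6H6O6S", ionization_rule("[M-H]1-", losses = "H", charge = -1))
#' @export
ion_mz <- function(formula, rule) {
  stopifnot(inherits(rule, "ionization_rule"))
  comp <- ion_composition(formula, rule)
  shift <- if (rule$isotope == "none") 0 else .isotope_shifts[[rule$isotope]]
  (monoisotopic_mass(comp) + shift - rule$charge * .electron_mass) /
    abs(rule$charge)
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values in Da; `theoretical` must be > 0.
#' @return `1e6 * (observed - theoretical) / theoretical`.
#' @examples
#' ppm_error(204.98143, 204.98123)  # ~ +0.98
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) {
    stop("theoretical mass must be positive", call. = FALSE)
  }
  1e6 * (observed - theoretical) / theoretical
}

#' Default ionization rule set
#'
#' The adduct and isotopologue labels observed for the packaged urinary
#' biomarkers, split by polarity: deprotonation and potassium loss (with
#' 13C/34S isotopologues) and a glucuronide neutral loss in negative mode;
#' protonation, sodiation and potassiation (with 13C/41K isotopologues) and
#' the mixed-cation [M+2Na-H]/[M+KNa-H] species in positive mode. Additional
#' adducts can be supplied to [annotate_mz()] as extra `ionization_rule`
#' objects.
#'
#' @param polarity `"neg"`, `"pos"`, or `"both"` (default).
#' @return Named list of [ionization_rule()] objects (names = labels).
#' @export
default_ionization_rules <- function(polarity = c("both", "neg", "pos")) {
  polarity <- match.arg(polarity)
  gluc <- "C6H9O6"  # glucuronide moiety plus the proton lost with it
  rules <- list(
    ionization_rule("[M-H]1-", losses = "H", charge = -1),
    ionization_rule("[M-H]1-13C", losses = "H", charge = -1, isotope = "13C"),
    ionization_rule("[M-H]1-34S", losses = "H", charge = -1, isotope = "34S"),
    ionization_rule("[M-H-gluc]1-", losses = gluc, charge = -1),
    ionization_rule("[M-H-gluc]1-13C", losses = gluc, charge = -1,
                    isotope = "13C"),
    ionization_rule("[M-K]1-", losses = "K", charge = -1),
    ionization_rule("[M-K]1-13C", losses = "K", charge = -1, isotope = "13C"),
    ionization_rule("[M-K]1-34S", losses = "K", charge = -1, isotope = "34S"),
    ionization_rule("[M+H]1+", gains = "H", charge = 1),
    ionization_rule("[M+H]1+13C", gains = "H", charge = 1, isotope = "13C"),
    ionization_rule("[M+Na]1+", gains = "Na", charge = 1),
    ionization_rule("[M+Na]1+13C", gains = "Na", charge = 1, isotope = "13C"),
    ionization_rule("[M+K]1+", gains = "K", charge = 1),
    ionization_rule("[M+K]1+13C", gains = "K", charge = 1, isotope = "13C"),
    ionization_rule("[M+K]1+41K", gains = "K", charge = 1, isotope = "41K"),
    ionization_rule("[M+2Na-H]1+", gains = "Na2", losses = "H", charge = 1),
    ionization_rule("[M+KNa-H]1+", gains = "KNa", losses = "H", charge = 1)
  )
  names(rules) <- vapply(rules, `[[`, "", "label")
  if (polarity == "both") return(rules)
  rules[vapply(rules, rule_polarity, "") == polarity]
}
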