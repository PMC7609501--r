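# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# Brute-force pairwise AUC: count wins and half-ties over all cross pairs.
brute_force_auc <- function(values, labels, positive) {
  a <- values[labels == positive]
  b <- values[labels != positive]
  wins <- 0
  for (x in a) for (y in b) {
    wins <- wins + if (x > y) 1 else if (x == y) 0.5 else 0
  }
  wins / (length(a) * length(b))
}

# Atom-by-atom mass summation of an ion's full composition: expand the
# composition into individual atoms and add masses one at a time, swapping
# one atom for its heavy isotope when required.
atomwise_ion_mz <- function(formula_text, rule) {
  masses <- c(H = 1.00782503207, C = 12, N = 14.0030740048,
              O = 15.9949146196, Na = 22.9897692809, S = 31.9720711744,
              K = 38.9637064864)
  heavy <- list("13C" = c("C", 13.0033548378),
                "34S" = c("S", 33.9678670412),
                "41K" = c("K", 40.9618252579))
  electron <- 0.000548579909
  count_atoms <- function(txt) {
    if (!nzchar(txt)) return(character())
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", txt, perl = TRUE)[[1]]
    toks <- regmatches(txt, list(m))[[1]]
    unlist(lapply(toks, function(tk) {
      sym <- sub("[0-9]*$", "", tk)
      n <- sub("^[A-Za-z]+", "", tk)
      rep(sym, if (nzchar(n)) as.integer(n) else 1L)
    }))
  }
  fmt <- function(f) {
    if (length(f) == 0) return("")
    paste0(names(f), ifelse(f > 1, f, ""), collapse = "")
  }
  atoms <- c(count_atoms(formula_text), count_atoms(fmt(rule$gains)))
  for (a in count_atoms(fmt(rule$losses))) {
    i <- match(a, atoms)
    stopifnot(!is.na(i))
    atoms <- atoms[-i]
  }
  total <- 0
  if (rule$isotope != "none") {
    el <- heavy[[rule$isotope]][1]
    i <- match(el, atoms)
    stopifnot(!is.na(i))
    atoms <- atoms[-i]
    total <- total + as.numeric(heavy[[rule$isotope]][2])
  }
  for (a in atoms) total <- total + masses[[a]]
  (total - rule$charge * electron) / abs(rule$charge)
}

# Textbook Welch statistic, written out from the formulas.
textbook_welch <- function(a, b) {
  se2 <- var(a) / length(a) + var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((var(a) / length(a))^2 / (length(a) - 1) +
                   (var(b) / length(b))^2 / (length(b) - 1))
  p <- 2 * pt(-abs(t), df)
  c(t = t, p = p, df = df)
}

# Deterministic small seed from a label, for per-food RF seeding in tests.
derive_seed_for_test <- function(label) sum(utf8ToInt(label))

# Small processed fingerprint + truth for contrast-level tests.
make_processed_scenario <- function(seed, n_participants = 15,
                                    n_noise = 197,
                                    ions = "[M-H]1-;[M-H]1-13C;[M-H]1-34S",
                                    fold = 5, ...) {
  sc <- simulate_recovery_scenario(seed, n_participants = n_participants,
                                   n_noise = n_noise, ions = ions,
                                   fold = fold, ...)
  sc$processed <- transform_log(normalize_dilution(sc$fingerprint))
  sc
}
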