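---
title: "Methods: simulating and recovering urinary biomarkers of food intake"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and recovering urinary biomarkers of food intake}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(urinebfi)
```

## The problem

Self-reported dietary intake is biased and burdensome; urinary metabolites
derived from specific foods offer objective biomarkers of food intake
(BFIs). A realistic discovery design exposes free-living participants to a
comprehensive menu emulating an ordinary national diet — menu plans with a
breakfast, lunch, afternoon snack and dinner — randomized over experimental
weeks, with spot urines (first morning void, fasting, post-breakfast,
post-lunch, the post-dinner series) collected at home. Fingerprints of each
urine (flow-infusion electrospray high-resolution MS: one intensity per
accurate-mass bin) are then mined for m/z signals that discriminate
post-meal urine from the same day's baseline void, and candidate signals
are annotated by accurate mass and tested for specificity against the rest
of the menu.

`urinebfi` implements that pipeline end to end against *simulated* data:
a cohort and exposure generator with known ground truth, so that every
stage — normalization, classification, feature selection, annotation,
specificity, kinetics — can be validated by recovery rather than by faith.

## Study design objects

Six daily menu plans are packaged (`menu_plans()`): plans 1–3 form the
2-week crossover validation study (Study 1), plans 4–6 the 3-week
discovery study (Study 2). Study 2 participants are randomized uniformly
to one of the 12 order-3 Latin squares (`enumerate_latin_squares(3)`
enumerates them exhaustively; rows = weeks, columns = days), so each plan
occurs once per week and once per day position. The order of the three
"Pre"-day dinners is randomized independently, on a sub-seed stream derived
from the master seed, so the two draws are independent yet jointly
reproducible. Whether the original allocation balanced squares across
participants or drew them uniformly is not documented; we draw uniformly.

Compliance is modeled on the five-level self-report scale (0, 25, 50, 75,
100% eaten). The default profile (`compliance_profile()`) puts 85% mass on
full consumption, yielding overall compliance fractions above the >80%
level such interventions achieve; it is a choice of the generator, not an
estimate.

## The synthetic-data generator

`simulate_fingerprints()` composes, per sample:

* **Baseline**: per participant × feature, log-normal
  (`meanlog = log(1000)`, `sdlog = 0.5`) — stable metabolic individuality.
* **Within-person variation**: per sample × feature, log-normal with CV
  0.4. Spot urines hours apart from one person differ substantially (urine
  turns over quickly — the property that makes spot samples informative
  about recent intake); without this term, same-day sample pairs would be
  near-duplicates, which real fingerprints are not.
* **Biomarker spikes**: each panel compound (packaged panel:
  pyrogallol sulfate and trigonelline for legumes, eugenol sulfate for
  curry, 2-furoylglycine for heated foods, acesulfame for low-calorie
  beverages) maps its ionization products to m/z bins; after each eaten
  exposure to a source food the bin intensity is multiplied by
  `1 + (magnitude − 1) · fraction · 2^(−(t − lag)/halflife)` for
  `t ≥ meal end + lag`. Lag-plus-first-order decay is the simplest
  kinetic model consistent with markers remaining elevated for hours;
  magnitude 1 reduces exactly to no spike. Events keep decaying across
  midnight, so long-lived markers are still visible in the next FMV.
* **Dilution**: a per-sample log-normal factor (mean 1, CV 0.3) standing
  in for the refractive-index variation that real pipelines normalize
  away; `normalize_dilution()` inverts it exactly.
* **Measurement noise**: multiplicative log-normal, CV 0.2.

The m/z grid is 0.01 Da wide with half-open `[k·w, (k+1)·w)` bins
(boundary peaks go to the upper bin); 2,000 background bins are the
desk-scale stand-in for a full fingerprint. Two panel compounds colliding
in one bin at the configured resolution is an error, not a silent merge. A
truth table (sample × food, exposed within the trailing 24 h, hours since
the meal) is emitted with every run.

The kinetic defaults were fixed once from the one published anchor — a
sweetener marker elevated for up to 12 h — via the closed form: a spike of
magnitude 5 with half-life 6 h stays above 2× baseline for
`6 · log2(5 − 1) = 12` h. True inter-individual kinetic variance is
unknown; we do not model it.

What the generator does **not** emulate: diurnal rhythms of the background
metabolome, correlated features (adduct/fragment clusters of the same
background compound), batch and carry-over effects, missing samples, or
isotope-pattern intensities. Passing recovery tests therefore show the
statistics behave as designed under the stated model, not that the model
captures every property of real urine.

## Accurate-mass annotation

`ion_mz()` computes `(M + gains − losses + isotope shift − z·mₑ)/|z|` from
principal-isotope masses (¹H, ¹²C, ¹⁴N, ¹⁶O, ²³Na, ³²S, ³⁹K); the electron
mass is included, without which the worked example misses by ~3 ppm. The
default rule set is exactly the adduct/isotopologue labels observed for
the packaged biomarkers — deprotonation, potassium loss and glucuronide
neutral loss with ¹³C/³⁴S isotopologues in negative mode; protonation,
sodiation, potassiation, `[M+2Na−H]⁺`/`[M+KNa−H]⁺` and ¹³C/⁴¹K
isotopologues in positive mode. One heavy-isotope substitution per ion;
multi-isotope species are out of scope. The match tolerance defaults to
5 ppm: the worked example (deprotonated pyrogallol sulfate, theoretical
204.98123 Da vs the observed legume signal 204.98143) sits at ~1 ppm, so
5 ppm accepts it with margin while staying far from promiscuity on a
0.01 Da grid. Identification confidence follows the Metabolomics Standards
Initiative levels: 1 = mass + retention time + MSn against an authentic
standard, 2 = literature/spectral-library match, 3 = compound class only.

The packaged compound table derives elemental formulas from the compound
names (sulfate = aglycone + SO₃, glucuronide = aglycone + C₆H₈O₆); it is a
constructed reference for testing annotation round-trips, not a curated
chemical database.

```{r annotate}
annotate_mz(204.98143, "neg", tol_ppm = 5)[1, ]
```

## Discovery statistics

For a food contrast, the two urine classes follow the intervention's
analysis frame: baseline = first morning void of the exposure day,
exposed = bed-time urine of the same day (other pairings are arguments).
Three per-feature criteria are combined:

* **Random-forest importance** (mean decrease in Gini), from a supervised
  forest with 1,000 trees and √p features per split, evaluated strictly
  out-of-bag: accuracy, mean margin (per Breiman: OOB vote share of the
  true class minus the other class — the margin is named but not defined
  in the source literature, so Breiman's definition is adopted), and the
  AUC of OOB vote shares. The proximity matrix (terminal-node
  co-occupancy) is embedded by classical MDS on `1 − proximity`, with each
  axis's sign fixed so its largest-magnitude coordinate is positive.
* **Per-feature AUC**, the Mann–Whitney probability that an exposed sample
  exceeds a baseline sample, ties counted ½ — implemented from rank sums
  and cross-checked in the tests against brute-force pair counting.
* **"Student's t-test"**, implemented as Welch's unequal-variance variant
  (the robust default; a pooled switch exists), two-sided.

The combination rule is not documented in the source literature, so the
package adopts rank-sum aggregation: rank features by importance, by
|AUC − 0.5| and by |t| (average ranks on ties, ascending m/z as the final
tie-break, making the ordering unique and permutation-invariant), sum the
three ranks, and gate selection by Benjamini–Hochberg FDR on the t-test
p-values (the FDR gate likewise is this package's choice). Selection keeps
the top `k = 25` gated features.

## Specificity and kinetics

`cross_food_consistency()` intersects each food group's top-k candidate
bins across member foods — the shared-marker construction that flags, e.g.,
one bin explanatory for peas, beans, peanuts and soy alike.
`specificity_score()` is deliberately the same AUC construction as the
selection statistic, applied across the whole simulated menu "biobank":
target-food post-meal samples versus post-meal samples after any other
food. A marker attached to a whole group scores near 0.5 for any single
member (shared, not specific); an exclusive marker scores near 1.
`elevation_window()` estimates how long a signal stays at or above a
threshold fold (default 2) of the participant's same-day first-morning-void
baseline: medians per time point, linear interpolation at the crossings,
0 when never elevated. The published "up to 12 h" is an observation, not an
estimator; this interpolated window is our construction.

## Numerical and design choices

* Randomization and simulation are pure functions of (inputs, seed);
  sub-streams are derived from the master seed per stage, so one stage's
  draw count cannot perturb another's. Zero-CV noise paths still consume
  their RNG draws, keeping runs with different noise settings aligned
  elsewhere.
* Sex is assigned by deterministic rounding of the cohort's female
  proportion (29 of 51), then shuffled — the packaged cohort reproduces
  57% female exactly rather than in expectation.
* Masses print at 5 decimals; full double precision is kept internally.
* Log transform before classification defaults to on
  (`log(x + 1)`, arbitrary units ≥ 0); the raw-intensity route is a
  switch away.
* Degenerate inputs error early and by name: unknown elements, infeasible
  losses/substitutions, non-positive dilution factors, double
  normalization, single-class labels, empty comparison sets.

## Benchmark scenarios and problem sizes

Two packaged scenarios (`simulate_recovery_scenario()`) drive the tests:

* **Feature-selection benchmark**: 2,000 bins, one shared legume marker
  bin (its monoisotopic deprotonated ion only), fold 5 with 12 h
  half-life, 30 participants eating each of the four legume foods on days
  spaced three days apart (so carry-over decays to <2% by the next
  baseline), first-morning-void vs bed-time samples — 30 per class per
  contrast. The marker attains aggregate rank 1 in ≥9 of 10 seeds and
  lies in the four-food top-25 intersection.
* **Classification benchmark**: 200 bins with the marker's full three-ion
  cluster (monoisotopic, ¹³C, ³⁴S) and a non-decaying spike, so the
  benchmark fold of 5 holds at the collection itself; out-of-bag AUC
  exceeds 0.9. With only one informative bin among 2,000, a √p-mtry
  forest cannot reliably exceed chance-level voting — feature selection,
  not whole-fingerprint classification, carries the discovery at that
  sparsity, and the within-person sample pairing further biases OOB votes
  toward the paired opposite class. The vote-level metrics are therefore
  benchmarked where the fingerprint carries a realistic ion cluster.

Unit tests use scaled-down sizes (typically 6–15 participants, 60–500
bins, 200–1,000 trees) chosen so the whole suite runs in a couple of
minutes while every assertion still reflects the statistic being tested;
the acceptance checks run the full benchmark sizes above.

## Known limitations

Annotation is database matching only — no formula generation from mass, no
MS² interpretation, no retention-time prediction. The classifier is
strictly two-class. Specificity is an AUC, not a calibrated dose–response;
quantitative intake estimation is out of scope. The generator's defaults
are study-shaped but its variance parameters (within-person CV, baseline
spread, noise CV) are modeling choices where no published values exist.
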