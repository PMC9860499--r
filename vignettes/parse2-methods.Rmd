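---
title: "Methods: window classification of phase-separating disordered regions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: window classification of phase-separating disordered regions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(parse2)
```

# The model and its assumptions

`parse2` classifies protein regions as folded (F), intrinsically
disordered (D), or phase-separating intrinsically disordered (P) from
sequence alone. The underlying assumptions are:

1. **Composition carries the signal.** All three window properties are
   per-residue scale averages; they are invariant under shuffling a
   window. Sequence *order* enters only through the optional
   interaction-potential corrections (`U_q` via SCD) and through which
   residues co-occupy a window.
2. **Intramolecular compaction proxies intermolecular cohesion.** The
   scaling-exponent stand-in `v_model = log(R_h/R_o)/log(N)` measures the
   balance of chain-chain versus chain-solvent interactions for a
   disordered chain; chains that are compact *and* depleted in helix
   propensity pattern with phase-separation-driving IDRs, while expanded,
   helix-rich chains pattern with conventional IDRs.
3. **The hydrodynamic-radius model is for disordered monomeric chains.**
   `R_h = 2.16·N^(0.503 − 0.11·ln f_PPII) + 0.26·|Q_net| − 0.29·√N` (Å)
   was calibrated on monomeric IDPs. Applying it inside folded regions is
   meaningless, which is why the F decision (hydrophobicity) fires before
   the P/D decision ever looks at `v_model`.
4. **A single additive score summarizes a protein.** The summed
   classifier distance over P windows assumes one strong PS region
   suffices to drive condensation of the whole protein, and that several
   moderate regions act cumulatively.

## The four scales

The per-residue constants are frozen in the package (`R/constants.R`),
each with its source:

| role | values | provenance |
|------|--------|------------|
| β-turn propensity | normalized reverse-turn frequencies | Levitt 1978 (AAindex LEVM780103) |
| helix propensity (α) | right-handed helical state occurrence | Rackovsky & Scheraga 1982 (AAindex RACS820102) |
| hydrophobicity (φ) | structure-based interactivity | Bastolla et al. 2005 (AAindex BASU050102) |
| PPII propensity | unfolded-peptide PPII populations | Shi et al. 2005; Gly = 0.500, Pro = 1.000 by the Tomasso et al. 2016 convention |

Two of these assignments deserve comment, because the classifier is
defined by its decision constants *plus* a reference behavior: the
three-way partition of the 20 homopolymers (order-promoting W C F I Y V
L H M; disorder-promoting A R Q P E K D; phase-separation-promoting N S
T G) that the decision rules must reproduce.

* Among the three structure-based "interactivity" hydrophobicity scales
  of Bastolla and co-workers in AAindex, **BASU050102** is the only one
  for which exactly the nine order-promoting residues exceed the F
  cutoff (`φ > 0.08`) as homopolymers; its siblings misplace Ala or His.
* For the helix propensity, an exhaustive scan of all AAindex scales
  shows **RACS820102** is the *unique* scale that, with the PPII values
  above and the fixed boundary `v_model = −0.244·α + 0.789`, sorts the
  eleven non-F homopolymers into the reference D and P groups. Classical
  helix-frequency scales fail for proline (poly-Pro has `v_model ≈ 0.47`,
  so its D assignment requires α(Pro) ≥ 1.30, which only a
  helical-state *occurrence* scale provides). The package therefore
  names this scale by its role (`helix`) and records the accession.

`homopolymerSpace()` recomputes the partition from the frozen constants;
the acceptance suite asserts it exactly.

# Decision rules and numerical choices

* **F cutoff is strict**: `φ > 0.08`, so a window at exactly 0.08 falls
  through to the P/D rule. The difference is measure-zero; the choice is
  recorded here once.
* **Ties on the P/D boundary are labeled D.** The classifier distance is
  0 there from either side, so the label choice has no effect on scores.
* **Classifier distance** is `(φ − 0.08)/(0.1164 − 0.08)` for F windows
  (0.1164 is the folded-set mean φ, i.e. distance 1 = "as deep into F
  territory as the training mean") and, for P/D windows, the Euclidean
  distance in the (α, v_model) plane to the foot of the perpendicular on
  the boundary, divided by 0.019 (the boundary-to-class-mean distance).
  It is continuous through the boundary.
* **Residue labeling**: window *k* labels its central residue *k* + 12;
  the 12 residues at each terminus inherit the first/last window's label.
* **Region calling** (`callRegions`): the ≥ 90 % purity criterion does
  not define maximal regions uniquely, so the package uses a documented
  deterministic construction — seed at every maximal pure run, then
  repeatedly absorb an adjacent run (a mismatching run together with the
  matching run beyond it) on whichever side keeps the higher purity,
  ties to the N-terminal side, while purity stays ≥ 0.9; merge same-label
  candidates whose union still satisfies purity; finally split any
  overlap between adjacent different-label regions evenly, odd residue
  to the N-terminal region, and drop regions shorter than 20 after
  splitting. Candidates satisfy length and purity *before* splitting;
  a trimmed flank can in principle dip a region's purity slightly below
  0.9, which the tests bound at 0.85. The construction is validated
  against an exhaustive interval-enumeration oracle on fixtures.
* **Interaction potentials**: the pair-term divisor in `U_π` is
  `|count₁ − count₂|` (1 when equal). A signed divisor would make a
  potential negative merely because the partner ordering flipped,
  contradicting the cohesion rank order the 3:2:1 weights encode, so the
  absolute value is used. When both corrections are enabled they combine
  additively, `U = U_π + U_q`, and the D→P flip rule compares the
  combined `U` with the original distance; only D windows may flip
  (F windows are never touched). Corrected distances are floored at 0.
* **Fitting**: coefficients are found by grid search maximizing
  |Pearson r| — `a` on `[0, 1]` step 0.01, `(b, c)` on `[−50, 50]` step
  0.2 by default — followed by one ten-fold refinement around the best
  grid point; ties take the smallest coefficient. Grids are arguments,
  so coarser searches can be used where runtime matters (the acceptance
  script uses step 1 for the 2-D search). The signed correlation is
  reported alongside. `a` must be fit on charge-matched variants
  (`filterChargeMatched`), where the charge potential is constant per
  window and cannot confound the π term.
* **Directional agreement** converts each observable into a
  phase-separation direction with a documented sign (`csat` −1, `dg` −1,
  `dh` −1, `ds` +1): e.g. a mutant with lower c_sat phase-separates more
  readily. Zero changes on either axis are excluded from the
  denominator.
* **van't Hoff analysis** fits `ln(c_sat/c_dense)` against `1/T`
  (ordinary least squares): slope·R = Δh°, −intercept·R = Δs°, and
  Δg° = Δh° − T·Δs° reported at 273.15 K. Units are kJ/mol (kJ/mol/K for
  Δs°), R = 8.314 J·mol⁻¹·K⁻¹; condensed-phase concentrations default to
  0.03 M (A1-LCD-like) and 0.01 M (Ddx4-like).
* **One-tail tests** take the tail in the direction of the observed
  difference (so identical samples give p = 0.5), matching how
  class-separation tables are reported against a reference set. The
  Mann-Whitney test uses exact enumeration when min(n) ≤ 8 without ties
  and the tie-corrected normal approximation with continuity correction
  otherwise.
* **Windowed PCA** treats every 25-residue window as a sample (so longer
  domains contribute more windows — window-level weighting), standardizes
  features to zero mean and unit variance, and drops constant features
  with a warning.
* **Recall/AUC** sweeps thresholds over the union of both score sets,
  plots test-set retention against comparison-set retention, and
  integrates by trapezoid; this equals `P(test > comparison) + ½P(tie)`
  and is validated against a pairwise-count oracle.

# The synthetic generators

All tests run offline on generated data (`makeHomopolymers`,
`makeBlockCopolymer`, `makeCompositionSets`, `makeChargeFamily`,
`makeCsatSeries`), each seed-deterministic with its generating
parameters embedded.

`makeCompositionSets` emulates the three curated region classes at the
statistical level: per-sequence compositions are Dirichlet draws around
frozen class profiles, lengths uniform in a class range. The profiles
were calibrated **once** (`scripts/tune_compositions.R`, committed) so
that the class means of `v_model` and β-turn propensity land on the
reference values (0.542/0.558/0.537 and 1.152/1.101/0.971 for the
PS-ID/ID/folded classes) with realistic between-sequence spread, then
frozen; they are not revisited. The generated sets match the class means
closely and the v_model/β-turn spreads approximately (the generator's
v-to-turn variance ratio is somewhat smaller than the curated data's, so
extreme-tail p-values computed on generated sets can overshoot those
implied by the reference moments — which is why the acceptance checks
compare test p-values against moment-matched samples, an exact
construction, and use the generated sets for mean-band checks).

What the generators do **not** emulate: real IDR sequence grammar
(motifs, repeats, low-complexity tracts), length-composition coupling,
phylogenetic redundancy, or curation artifacts. Passing tests therefore
demonstrate the correctness of the computational machinery and the
self-consistency of the model, not predictive performance on biological
data; the latter is asserted only by the acceptance checks that consume
the original datasets when present.

`makeChargeFamily` produces permutation variants of one disordered
sequence: identical composition (hence identical NCPR, f_PPII, v_model)
with the charge arrangement stepped from alternating to fully blocky, so
SCD spans a wide range. Forward-simulated observables on such families
drive the parameter-recovery tests; note that within a single family the
global NCPR is fixed, so identifying the `c` coefficient requires
combining families of different net charge (as the acceptance script
does).

# Problem sizes

The test suite and acceptance script are sized to run comfortably on one
CPU: synthetic sets at the reference sizes (224/121/421 sequences,
lengths ~30-280), property checks over dozens of random sequences of
length ≤ 200, fitting demonstrations on 10-20 variants with ~125 windows
each, a 360-protein synthetic proteome scan, and 60-replicate Monte
Carlo for van't Hoff recovery. The full suite runs in about two minutes;
the acceptance script in under one.

# Known limitations

* The classifier is composition-based; mutations that alter pairwise
  contacts at fixed composition are invisible without the `U_π`/`U_q`
  corrections, and those corrections are linear, window-local
  heuristics.
* `R_h` (and so `v_model`) is undefined in spirit for folded chains and
  short peptides; the window scheme requires N > 25 and
  whole-sequence descriptors require N ≥ 2.
* The (v_model, β-turn) polar visualization (`vizPolar`) conveys
  per-residue-type tendencies around the disordered-class origin
  (0.558, 1.101); it is a display aid, not a decision rule, and the
  package does not reproduce the earlier-generation sector boundaries in
  that plane (see the classifier space for decisions).
* Absolute c_sat prediction and temperature-dependent hydrophobicity are
  out of scope.
* Correlation-objective grid fits have flat optima when a mutant family
  varies few features; report the signed r and the family design along
  with the coefficients.
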