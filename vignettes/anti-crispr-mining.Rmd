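---
title: "Guilt-by-association mining of anti-CRISPR genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guilt-by-association mining of anti-CRISPR genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(acrmine)
```

## The discovery problem

Anti-CRISPR (Acr) proteins are small inhibitors of CRISPR–Cas effectors
encoded on phages, prophages and other mobile genetic elements (MGEs).
They share essentially no sequence or structural signature, which rules
out profile-based prediction. What they do share is genomic context:
*acr* genes cluster in small same-strand cassettes, typically next to an
*acr-associated* (*aca*) gene encoding a helix-turn-helix (HTH) or
AP2-type DNA-binding regulator. The guilt-by-association strategy turns
this into a search procedure: starting from one known Acr family, look
at its genomic neighbors, designate new Aca and Acr candidates by
explicit criteria, validate them, and use the validated families as
markers for the next round — an iterative *search-validation* loop.

`acrmine` implements that computational pipeline end to end, together
with a synthetic-genome simulator that plants ground truth so every
stage can be scored exactly, the distance-based phylogenetics used to
organize homolog families, and the quantification formulas used to
summarize CRISPR-inhibition assays.

## Candidate criteria

A gene is designated an **Aca candidate** when all three hold:

1. it lies directly upstream or downstream of an Acr homolog in the
   same orientation;
2. it carries a predicted DNA-binding domain (HTH or AP2);
3. its family associates with more than two distinct types of Acrs
   corpus-wide.

A gene is an **Acr candidate** when:

1. its protein is small (< 300 amino acids);
2. it lies directly upstream or downstream of an Acr or Aca protein in
   the same orientation;
3. optionally, an Acr–Aca fusion architecture raises its confidence
   tier (`fusion_boosted`) — a booster, never a requirement.

All threshold comparisons are strict exactly as printed: a 300-aa
protein fails, a hit at E-value 0.001 fails, coverage of exactly 70%
fails, and an association with exactly two Acr families fails. Homology
evidence enters as a table of hits (a gene carries family label F iff
it has at least one hit to F with E-value < 0.001 and query coverage >
70%); domain evidence enters as a table of HTH/AP2 calls with a
probability score.

### Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `max_protein_aa` | 300 aa | strict Acr size cutoff |
| `evalue_max` / `coverage_min` | 0.001 / 0.70 | strict homology filters |
| `window_genes` | 1 | "directly" adjacent = one gene per side |
| `max_intergenic_bp` | 1000 bp | adjacency also requires a modest gap |
| `association_threshold` | 2 | Aca families need > 2 distinct Acr partners |
| `domain_prob_min` | 0.5 | floor on the domain-call probability |
| `terminal_fraction` | 0.4 | terminal region for fusion geometry |
| `min_remainder_aa` | 40 aa | minimum Acr remainder of a fusion |

The neighborhood window of one gene per side is the literal reading of
"directly upstream or downstream"; published screens also examined a
broader set of neighboring genes, so a wider `audit_window_genes`
(default 5) is available for enumeration listings. Whether "directly"
tolerates an intervening gene, and the maximum intergenic distance, are
not stated in the published criteria — both are exposed as parameters
rather than guessed. The association criterion counts distinct Acr
*families* (types), not loci; genes without any family label are
treated as singleton families so the criterion is total. The fusion
geometry (an Aca-matching interval confined to the terminal 40% of the
protein, with at least 40 aa of Acr remainder) is this package's
operationalization of a feature originally assessed qualitatively;
both constants are configurable and reported in the output.

## The search-validation loop

`search_validation_loop()` alternates search and validation: label genes
from the current markers, classify Aca then Acr candidates, pass new
candidates to a pluggable validator, and adopt the families of accepted
candidates as new markers. The validator interface is deliberately
abstract because validation is experimental in practice (plasmid
interference screening); tests and the pipeline default use the
simulator's truth ledger, and `validator_accept_all()` /
`validator_reject_all()` / `validator_from_list()` cover audit cases.
The loop never removes markers, so the marker set grows monotonically
and reaches a fixed point in at most as many iterations as there are
families; `max_iterations` (default 20) guards pathological inputs.

Adopted families are typed by the route of adoption, Aca classification
taking precedence within an iteration. One bootstrapping property of
the criteria is worth knowing: the association criterion needs more
than two *marker* Acr families to exist, so a loop seeded with a single
Acr family initially adopts Aca-like genes through the Acr route (they
are small and marker-adjacent); the final candidate ledger, computed
under the full marker set, still reports them as Aca candidates.

Toxic or ambiguous screen outcomes (genes whose validation fails for
reasons without a computational signature) are not modeled: the
validator simply declines them.

## What the simulator plants, and what it does not

`sim_config()` / `generate_genomes()` emulate Streptococcus-like linear
replicons: background genes (80–500 aa, random strands) interleaved
with planted cassettes. Each cassette type is constructed so that its
genes satisfy or violate exactly the intended criteria:

* **operons** — adjacent same-strand acr–aca pairs (order randomized);
  every aca family receives at least three operons with distinct Acr
  families so the association criterion is satisfiable by construction.
* **fusions** — a single ORF whose terminal 40% contains an Aca-family
  segment and whose remainder derives from an Acr family, planted next
  to a partner acr.
* **decoys** — one class per criterion: oversize (>= 300 aa), wrong
  strand, non-adjacent, Aca-like without a domain record, and Aca-like
  with association of one. The no-domain class needs at least two loci
  (with a one-gene window a single locus can contribute at most two
  distinct neighboring families), which the configuration validator
  enforces.

Background genes flanking a cassette are forced onto the opposite
strand, so that candidate signal comes from planted elements only. Note
that Aca-like genes — planted acas and both aca decoy classes — are
legitimately *also* Acr candidates under the printed criteria (they are
small and sit next to Acr markers), exactly as real aca genes were
screened alongside acr candidates; decoy scoring is therefore
per-classifier: an acr-criterion decoy must not appear among Acr
candidates, an aca-criterion decoy must not appear among Aca
candidates.

Evidence tables follow the same logic: planted members draw E-values
log-uniformly from [1e-50, 1e-5], safely inside the strict filter,
while spurious background hits draw from [1e-3, 10] and straddle (but
never pass) it. Protein sequences come from a uniform amino-acid model
— no codon structure, no composition bias, no realistic phage gene
content — because the mining operates purely at protein level. Passing
tests on this material therefore demonstrates the correctness of the
*criteria logic*, not the field performance of the screen on real
genomes, where homology search quality, annotation errors and operon
structure all add noise the simulator does not model. Domain-call
probabilities are likewise trusted inputs, not reproduced predictor
behavior.

## Phylogenetics

Homolog families are organized with distance trees:

* **q** — fraction of identical residues, computed from an optimal
  global alignment (BLOSUM62, affine gaps open 11 / extend 1) over
  residue–residue columns only. Published screens derive identity
  from BLAST pairwise alignments; a global alignment is the closest
  stated-free analogue and is documented as such. Coverage is
  query-relative.
* **Grishin distance** — d solves q = ln(1 + 2d) / (2d), the protein
  distance model accounting for rate variation across sites.
  `grishin_distance()` inverts the model by bracketed root finding with
  Newton polishing to |Δq| ≤ 1e-10; q = 1 returns d = 0 exactly. The
  model diverges as q → 0, so distances are capped at `d_cap = 10`
  substitutions/site and capped pairs flagged; the 0.85
  maximum-difference homolog filter normally keeps pairs well away from
  the cap.
* **fast minimum evolution** — realized as neighbor joining (the
  standard greedy ME heuristic) for the topology plus
  ordinary-least-squares branch lengths; negative OLS estimates are
  clamped to zero and the tree length recomputed. Taxa are sorted
  lexicographically before NJ, making the output invariant to input
  order. `me_exhaustive()` provides an all-topology validation mode for
  up to eight taxa: on additive matrices NJ+OLS provably attains the
  exhaustive minimum, and the test suite checks this on dozens of
  seeded matrices. NJ is a heuristic on non-additive matrices, so any
  length gap against the exhaustive minimum would be reported, not
  hidden.

The homolog filter for tree building retains a hit iff E-value < 0.001,
coverage > 0.70 (both strict) and sequence difference (1 − q) ≤ 0.85 —
the difference bound is inclusive, so a pair at exactly 0.85 is kept.

`simulate_family()` provides the generative counterpart: Poisson
substitution events per site along branches with uniform replacement
over the 19 alternative residues, giving the closed-form expected
identity `1/20 + (19/20) exp(-20t/19)` at path length t used by the
Monte-Carlo checks.

## Assay quantification

* `inhibitory_activity()` — 100 × cfu(matching spacer) / cfu(mismatching
  spacer), the plasmid-interference readout; ratios above 1 (possible
  under sampling noise) are clamped to 100% and flagged.
* `indel_percent()` — 100 × (1 − √(1 − fraction_cleaved)), the T7E1
  mismatch-nuclease conversion, with an exact inverse
  (`indel_to_fraction()`).
* `classify_activity()` — the summary-symbol bands: ≤ 20 "-", (20, 50]
  "+", (50, 80] "++", > 80 "+++", NA → "ND". The printed legend leaves
  the boundary points unassigned; closing the bands on the right gives
  a total, monotone mapping consistent with every printed mean/symbol
  pair.
* `fold_regulation()` — no-inducer efficiency over with-inducer
  efficiency for 4-HT-switchable intein-Acr variants. The source never
  writes this ratio as a formula; this orientation reproduces the
  reported fold values and is documented as this package's
  interpretation.
* `summarize_assays()` — per (Acr, Cas9, assay) mean, SEM and symbol;
  statistics stop at mean ± SEM by design.

`simulate_assay_counts()` draws Poisson colony counts so the estimator
can be checked: at a true activity of 60% and a mean control count of
200 cfu the estimator mean lands within a fraction of a point of truth.
One calibration fact worth knowing: at 200 cfu the per-replicate
activity has a standard deviation near 9 percentage points, so a
three-replicate mean at a true activity of 85% crosses the 80% "+++"
band boundary in only ~85–88% of runs — a property of Poisson counting
noise at this depth, visible in the stochastic summaries the package
reports.

## Numerical and design choices

* Coordinates are 1-based, fully closed intervals throughout (the
  GenBank/GFF3 convention); conversions happen only at parse
  boundaries. "Orientation" is strand-symbol equality; no operon
  prediction is attempted.
* Hit tables are matched by column name, never position, and tolerate
  extra columns; coverage given in percent is normalized to a fraction.
* GenBank records are written and parsed at feature-table level (no
  nucleotide ORIGIN block), which is what annotation round-trips need.
* Determinism: a single integer seed fixes the simulator, and every
  stochastic helper takes its own seed; the pipeline writes a
  provenance block (config hash, seed, versions) sufficient to re-run
  bit-identically.
* Problem sizes in the shipped tests — corpora of roughly 40–50 genes
  for oracle comparisons, 20-replicon simulations for recovery, 6-leaf
  families at 200 aa for tree recovery, 500–1000 Poisson replicates for
  estimator checks — were chosen to make the statistical assertions
  stable at comfortable margins.

## Known limitations

* The simulator does not model real MGE composition, codon usage,
  HHpred probability behavior, self-targeting spacers, or the
  biochemical validation itself; the validator abstraction marks
  exactly where wet-lab information enters.
* Association counting is per-family; if per-locus counting was
  intended in published screens (unstated), thresholds would shift.
* The fusion rule is geometric and will miss fusions whose Aca segment
  straddles the terminal boundary; the terminal fraction is
  configurable.
* NJ+OLS is a heuristic for minimum evolution away from additivity;
  the exhaustive mode is available up to eight taxa for verification.
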