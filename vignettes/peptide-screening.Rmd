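---
title: "Similarity-based peptide screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Similarity-based peptide screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepscreen)
```

## The model

`pepscreen` scores a candidate peptide against every protein of a
restricted proteome with a similarity-based protein–protein interaction
(PPI) scorer. The underlying assumption is instance-based: a validated
interacting pair (P1, P2) is evidence for an interaction between queries
(Q1, Q2) exactly when P1 carries a local region similar to Q1 *and* P2
carries one similar to Q2. The conjunction matters — one-sided similarity
is not evidence — which is why the two sides' evidence weights are
*multiplied*, not added, and both orientations of each unordered database
pair are summed (interactions are undirected):

$$\mathrm{score}(Q_1, Q_2) \;=\; \sum_{\{P_1,P_2\} \in \mathcal{D}}
   \mathrm{ev}(Q_1,P_1)\,\mathrm{ev}(Q_2,P_2) +
   \mathrm{ev}(Q_1,P_2)\,\mathrm{ev}(Q_2,P_1),$$

with self-records (P, P) contributing once. The evidence weight
$\mathrm{ev}(Q, P)$ is computed from substitution-matrix similarity over
sliding windows: every pair of *w*-mers $(a, b)$ with
$\mathrm{sim}(a,b) \ge \tau \cdot \min(\mathrm{sim}(a,a),
\mathrm{sim}(b,b))$ is a hit; hits on one diagonal whose windows overlap
or abut merge into a region; a region's weight is the maximum normalized
similarity among its hits; and $\mathrm{ev}$ is the sum of region
weights. Merging is what prevents a single long similar segment from
being counted ~*w* times over its overlapping windows — a "region of
similarity" is the unit of evidence, not a window.

This scorer is a faithful-in-spirit stand-in for the published
similarity-based predictors (PIPE, SPRINT), whose exact seed/extension
internals are their own; it is not a bit-exact reimplementation of any
released binary, and the test suite verifies it against an exhaustive
in-repo reference, not against external tools.

## Parameters that matter

* **`w` (window length, residues; default 20).** The scale of the local
  similarity that carries evidence — roughly the length of a therapeutic
  peptide, which is precisely why similarity-based methods suit peptide
  queries: their evidence unit *is* a short peptide.
* **`tau` (relative hit threshold; default 0.75).** A window pair must
  reach 75% of the weaker window's self-score. A relative threshold is
  matrix-agnostic; an absolute score cutoff would need retuning per
  matrix. Raising `tau` sharpens specificity of evidence and thins the
  curve's high tail; 1.0 demands near-identity.
* **`matrix` (default PAM120 for scoring; BLOSUM62 for the leakage
  aligner).** PAM120 follows the similarity-predictor tradition; BLOSUM62
  with gap penalties 11/1 reproduces the default blastp scoring scheme
  used for leakage control. Both shipped matrices are diagonally
  dominant, so normalized window similarities lie in (0, 1] and an exact
  self-match scores evidence weight 1.
* **`min_score` (leakage-hit threshold; default 50).** Alignment score
  above which a database protein counts as "similar to the peptide" and
  is purged in the pessimistic scenario. At BLOSUM62/11/1, 50 is far
  above random 30-mer×protein background (tested) yet well below the
  planted-core alignment at a 10% mutation rate (~110+), so the split is
  sharp in both directions.
* **Tie policy and top-1% cutoff.** Tied scores all receive the worst
  rank of their block — the conservative choice when claiming a target
  ranks highly, and the reason an all-zero curve puts every protein at
  rank N rather than rank 1. The top-fraction cutoff is
  `ceiling(fraction · N)` (rank 29 of 2,886 is inside the top 1%, rank 30
  is not); the rounding convention is ours, stated because it changes
  boundary cases.

## The one-to-all curve, elbow and morphology

The curve plots the peptide's score against every proteome protein as a
function of rank. The elbow is detected as the point of maximum
perpendicular distance to the chord joining the curve's endpoints, after
min–max normalizing both axes — this makes the elbow invariant to affine
rescaling of the unbounded scores, which matters because raw evidence
sums have no natural scale. Degenerate inputs are pinned down explicitly:
flat curves return elbow position 1, as do strictly linear descents
(zero distance everywhere, ties break to the smallest rank).

Morphology classification (`no_interaction` / `non_specific` /
`specific`) operationalizes the three qualitative curve shapes with two
thresholds: at most `spec_max = 10` proteins above the elbow for a
"specific" call, and more than `nonspec_frac = 0.05` of the curve above
the elbow for "non-specific". The published descriptions of these shapes
are qualitative; the numeric boundaries here are our own explicit
choices, exposed as arguments and echoed in every call result rather
than hidden.

Rank, not raw score, is the primary readout: a low score may only mean
sparse evidence, but a high rank survives rescaling and is comparable
across peptides. The scan output keeps both. Near a flat zero baseline,
tiny score changes produce huge rank changes — a documented artifact of
rank (exercised by a regression test), not a property of the peptide.

## The glycine scan

For every non-glycine position, the peptide is mutated to Gly and the
entire curve rebuilt with identical parameters; the result records the
change in the target's score and rank. Because a point mutation can only
alter windows that contain it, score changes are provably confined to
positions covered by a similarity-hit window in the original or mutant
peptide — the locality property the acceptance suite verifies against an
exhaustive window enumeration.

## What the synthetic generator emulates — and what it does not

`generate_benchmark()` builds the statistical structure the analysis
relies on: a decoy surfaceome (default 300 proteins including the
receptor), a decoy interaction network (default 200 interactions among
50 database proteins), and one planted ligand→receptor record where the
query peptide is a copy of a 30-residue core of the ligand with 10%
per-residue substitutions — a peptide analog of an endogenous protein.
The ligand is deliberately absent from the surfaceome (it is an
endogenous, non-surface protein), and no decoy interaction touches the
receptor unless confounders are explicitly requested
(`n_confounders > 0` plants additional core-bearing decoys, useful for
provoking non-specific morphologies).

Residues are drawn uniformly over the 20-letter alphabet, which keeps
the null analytically predictable: random window hits at `tau = 0.75`
under PAM120 are vanishingly rare, so every decoy's score is 0 with
overwhelming probability and the planted signal is the only systematic
evidence path. Real proteomes are not uniform: they carry biased
composition, low-complexity and repeat regions, homologous families and
isoforms, and hub-dominated interaction networks. Passing the recovery
tests here therefore shows that the machinery is correct and that the
optimistic/pessimistic contrast behaves as designed — it does not show
that real screens achieve any particular accuracy, which depends
entirely on the coverage of the real interaction database.

One global seed feeds a single pseudo-random stream consumed in a
documented order (database proteins, ligand, core offset, proteome,
decoy network, peptide mutations, confounders); partial regeneration is
impossible by design — simplicity was preferred over resumability. The
generator restores the caller's RNG state on exit.

## Scenario construction and leakage control

The optimistic (+) scenario keeps the full database. The pessimistic (−)
scenario aligns the peptide against every database protein
(Smith–Waterman, affine gaps, one optimal alignment reported with a
deterministic tie-break: highest score, smallest query end, then
smallest subject end) and removes all interactions touching hits. The
in-repo aligner keeps the pipeline free of external binaries; users who
prefer real blastp output can import its 12-column tabular format via
`hits_file`. No E-values are computed — raw scores plus identity are all
the filter needs.

In the planted benchmark the split removes the ligand and with it the
receptor's only evidence: its score drops to exactly 0 and its rank to N
(all-tied baseline). That is the de novo design lesson in miniature —
similarity methods excel when a similar interactor is in the database
and degrade sharply when leakage is removed.

## Numerical and design choices

* Window hits require the smaller window self-score to be positive;
  windows that cannot be thresholded meaningfully never produce hits.
* Evidence weights for sequences shorter than `w` are 0 with a warning,
  not an error, so short mutants degrade gracefully.
* `score_one_vs_all()` prunes database records with zero peptide-side
  evidence before the per-target loop; by bilinearity of the score this
  is exact (tested elementwise against the naive loop), and it is what
  makes a 300-protein screen effectively instantaneous.
* The curation length bound is inclusive (≥ 20): the packaged panel
  lists a 20-mer (bivalirudin), so exclusive reading would contradict
  the table it curates. The panel's 21 peptide–target accession pairs
  are treated independently per (peptide, accession).
* The rank-sum test reports the Mann–Whitney U of the first sample with
  two-sided p-values; exact enumeration is used for `n + m ≤ 12` without
  ties, otherwise a tie- and continuity-corrected normal approximation,
  and the mode used is labeled in every report row. Medians of integer
  ranks use the lower-median convention — an interpolated half-rank
  would be misleading in a report.
* The evaluation applies no multiple-testing correction and no
  effect-size estimate; comparisons are descriptive.

## Problem sizes

The shipped tests verify the scorer against an exhaustive reference on
100 random instances (registries ≤ 10 proteins of ≤ 60 residues,
databases ≤ 10 records, agreement to 1e-9), recover the planted receptor
across 20 seeded benchmarks at the default conditions in both scenarios,
check glycine-scan locality on 50 randomized cases, and validate exact
rank-sum p-values by full enumeration for all sample sizes with
`n + m ≤ 10`. These sizes were chosen as the smallest at which every
property is exercised with real headroom; all thresholds above were
fixed before the suite was written.

## Known limitations

* Scores express evidence strength, never binding affinity or
  thermodynamics; no interaction-probability calibration is attempted.
* The scorer is SPRINT-*like*: faithful to the similarity-evidence
  principle, not bit-compatible with any released implementation.
* No identifier mapping, organism handling, or live database access; the
  stringent-method list shipped for quality filtering is a reviewable
  default, not a canonical standard, and must be supplied explicitly.
* Uniform-background decoys understate the false-positive rate real
  low-complexity sequence would produce; treat real-screen hit lists as
  candidates for validation, not predictions.
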