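# pepscreen

Similarity-based virtual screening of therapeutic peptides in R.

## The problem

Engineering a peptide that binds one intended protein target — and little
else — is hard, and wet-lab validation is expensive. A cheap computational
pre-screen asks: given a candidate peptide, which proteins on the cell
surface does a protein–protein interaction (PPI) predictor expect it to
bind, and does the intended target stand out? `pepscreen` implements this
screen around a *similarity-based* PPI scorer, the family of methods
(PIPE, SPRINT) that works directly from known interactions rather than
from a trained pattern recognizer — the approach best suited to short
peptides, whose evidence lives in short local regions of similarity.

## The scorer

A known interacting pair (P1, P2) supports a query pair (Q1, Q2) when P1
is locally similar to Q1 and P2 to Q2. Similarity is assessed over sliding
windows of *w* residues (default *w* = 20, roughly the length of a
peptide) under a substitution matrix *M* (default PAM120). A window pair
(*a*, *b*) is a **hit** when

    sim(a, b) = Σᵢ M[aᵢ, bᵢ]  ≥  τ · min(sim(a, a), sim(b, b)),

with τ = 0.75 by default — a relative threshold, so it transfers across
matrices. Hits sharing a diagonal merge into **regions**; a region's
weight is its best normalized similarity, and the **evidence weight**
ev(Q, P) is the sum of region weights. The pair score is the exhaustive
sum over database records {P1, P2} of

    ev(Q1,P1)·ev(Q2,P2) + ev(Q1,P2)·ev(Q2,P1),

an unbounded raw evidence sum, never a probability. The screen's primary
readout is the **one-to-all curve**: the peptide's score against every
protein in a restricted proteome (e.g. a surfaceome), plotted against
rank. Its morphology — flat, sigmoidal, or L-shaped with the target above
the elbow — diagnoses whether the peptide is predicted to bind nothing,
everything, or its target specifically.

Two evidence scenarios bracket real use: **optimistic (+)** keeps the
whole database (analog design: an endogenous interactor similar to the
peptide is known), while **pessimistic (−)** removes every interaction
involving a protein with a high-scoring local alignment to the peptide
(de novo design: no similar interactor known). The package also provides
a glycine mutational scan (rebuild the curve for every single-position
Gly mutant) and a Wilcoxon rank-sum comparison of rank distributions.

## Worked example

A seeded synthetic benchmark plants one ligand→receptor interaction in a
decoy network; the query peptide is a mutated copy of a 30-residue core
of the ligand (10% substitutions), the receptor sits in a 300-protein
decoy surfaceome:

```r
library(pepscreen)
params <- scoring_params()                       # w = 20, tau = 0.75, PAM120
b <- generate_benchmark(synthetic_params(seed = 1))

curve <- build_curve(b$peptide, b$proteome, NULL,
                     b$db_optimistic, b$registry, params)
rank_of(curve, b$target_id)                      # 1
in_top_fraction(curve, b$target_id, 0.01)        # TRUE

sp <- derive_pessimistic(b, min_score = 50)      # leakage filter
sp$removed_proteins                              # "LIG"
curve2 <- build_curve(b$peptide, b$proteome, NULL,
                      sp$retained, b$registry, params)
rank_of(curve2, b$target_id)                     # 300
```

In the optimistic scenario the planted receptor ranks **1** of 300 — the
only protein with supporting evidence. After the pessimistic split the
alignment filter removes the ligand (score ≥ 50 against the peptide), the
receptor's evidence vanishes, its score drops to 0 and its rank falls to
**300** (all-tied baseline, worst-rank tie policy): known-interactor
leakage, not generalization, is what makes the optimistic screen succeed.

The packaged FDA-approved peptide panel and its curation rule
(length ≥ 20, standard residues only):

```r
nrow(curate_peptides(fda_peptide_table(), min_length = 20))   # 13
```

A command-line wrapper over the same functions is installed at
`system.file("cli", "pepscreen.R", package = "pepscreen")` with
subcommands `simulate`, `screen`, `scan`, `split`, `evaluate`.

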