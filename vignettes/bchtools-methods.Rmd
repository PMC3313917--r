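---
title: "Distinguishing BCH from CRAL_TRIO domains: models and methods"
author: "bchtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distinguishing BCH from CRAL_TRIO domains: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bchtools)
```

## The scientific problem

The Sec14 superfamily collects protein domains sharing an alpha/beta
fold that encloses a hydrophobic cavity.  Its canonical members carry a
CRAL_TRIO domain and bind small lipophilic ligands (phosphatidylinositol,
tocopherol, retinaldehyde).  The BNIP-2 and Cdc42GAP Homology (BCH)
domain adopts the same overall fold but works differently: it scaffolds
Rho-family GTPases, RhoGAPs and RhoGEFs, and no lipid ligand is known.
Because the two domain types share only ~12% sequence identity with
each other — and BCH domains only ~14% with yeast Sec14p — profile
databases have historically lumped them into one entry and routinely
miss or truncate genuine BCH domains.

`bchtools` implements the sequence-level machinery that separates the
two classes: curation filters for building a clean domain set, percent
identity statistics and their group-wise summary, a bootstrapped
Neighbor-Joining phylogeny with clade collapsing for display,
per-column conservation and sequence-logo information content,
reference-anchored diagnostic residue sets, a degenerate hallmark motif
and a three-way BCH / BCH-like / CRAL_TRIO classifier, and a mapping of
intron positions onto the domain's secondary-structure elements.  A
synthetic family generator with full ground truth makes every stage
testable without any database download.

## Screening

Curation mirrors how such domain datasets are built in practice:

* **Length filter** — sequences shorter than `min_length` (default 100
  residues) are unlikely to fold into a complete ~150–173 residue
  domain and are discarded.
* **Long-gap screen** — alignment rows whose longest *internal* gap run
  spans at least `max_gap_run` columns (default 30) or whose overall
  gap fraction exceeds `max_gap_fraction` (default 0.5) are fragmentary
  or badly aligned and are dropped.  Terminal runs are exempt from the
  run rule because incomplete ends are common and harmless.  The
  literature this emulates never quantifies "long gaps"; the two
  defaults are our operationalization and both are configurable.
* **Redundancy clustering** — greedy clustering at 95% identity in the
  style of CD-hit: sequences are sorted by descending length (ties by
  id) and each joins the first cluster whose representative it matches
  at or above the threshold, else founds a new cluster.  Identity here
  is `matches / length of the shorter sequence` after global alignment,
  the convention of the clustering tool this mirrors.  Word-filtering
  speed heuristics are deliberately not reproduced — at this scale the
  exact greedy pass is fast and simpler to reason about.  Both
  "keep all members" (default; the real dataset retained redundant
  members) and "keep representatives" are supported.

## Pairwise alignment and identity

Global (Needleman–Wunsch) alignment with affine gaps is computed by a
three-state Gotoh dynamic program in compiled code.  A gap run of
length $L$ costs $g_{open} + L \cdot g_{extend}$ (defaults: BLOSUM62,
open 10, extend 0.5).  Traceback ties are broken deterministically —
diagonal, then gap-in-second, then gap-in-first — so the same inputs
always give the same alignment string.  The test suite checks the
score against an independently coded memoized recursion over
(position, position, last-move), itself validated against literal
enumeration of all alignments on tiny instances.

Percent identity from a shared alignment defaults to
**pairwise deletion**: matches over columns where neither row is
gapped.  The original study computed identities with a commercial tool
whose formula is undocumented; pairwise deletion matches the
convention used for tree distances, and the alternative denominators
(shorter ungapped length, full alignment length) are selectable.  On
real data, means will therefore differ slightly from the published
table; the comparison *counts* are exact combinatorics
(`n(n-1)/2` within, `n1*n2` across) and are reproduced exactly from
the published group sizes (68, 30, 33, 41, 13, 16, 69).  `X` never
counts as a match anywhere.

## Phylogeny

Distances are p-distances (1 − identity fraction) computed after
**complete deletion**: every column containing a gap in any row is
removed once, so all pairs use the same column set — the "ignoring
gapped columns" convention.  Neighbor-Joining uses the standard Q
criterion with ties broken by the lexicographically smallest index
pair.  Negative branch-length estimates (possible whenever the matrix
is not additive) are clamped to zero, with the total clamped deficit
recorded on the tree; clamping keeps the branch-length invariant
(lengths ≥ 0) testable and matches common practice in distance tools.
On additive matrices the implementation reproduces the generating
tree's path distances to within 1e-9 (tested over seeded random 4–8
leaf trees) and agrees topologically with `ape::nj`.

Bootstrap supports resample the *retained* (complete-deletion) column
set with replacement — gap columns are removed once, before
resampling, because the tree step itself ignores them.  The support of
an internal split is the percentage of replicate trees containing it.
The conventional 1000 replicates is the default; validation and the
worked examples use 50–100 replicates, which is ample for the
strong-signal synthetic families they run on.

For display, clades whose **mean path length to their descendant
leaves** is strictly below 0.05 are collapsed into a single counted
leaf, applied from the root down so only maximal such clades collapse.
The source material describes the rule both as a branch-length and as
an average-leaf-distance criterion; the mean-distance reading is
implemented (it is the one that produces a scale-free display), and
the threshold is an argument.

## Conservation, logos and signatures

Column frequencies exclude gaps and `X`; occupancy is tracked
separately.  Information content per column is
$IC = \log_2 20 - H$ bits, with letter height = frequency × IC —
identical to the classic sequence-logo construction.  The pseudocount
default is 0 (the published logos are raw frequencies) and the
small-sample correction is off by default; both are switchable.

Two diagnostic signature sets ship as constants:

* **BCH**, anchored to human BNIP-2 (NP_004321): (R/N)165 0.901,
  P176 0.873, (H/N)212 0.890, P221 0.878, (K/R)238 0.928,
  (K/R)239 0.873, N240 0.879, H248 0.983, (K/R)271 0.995.
* **CRAL_TRIO**, anchored to yeast Sec14p (NP_013796): E152 0.841,
  D178 0.942, P206 0.913, P218 0.899, (K/R)239 0.855, P261 0.812,
  G265 0.898, G266 0.970.

Entries like "(R/N)165" are read literally as two-residue allowed
sets.  The two proline positions conserved one alignment column apart
in the two families are kept as two independent reference-anchored
sets, not merged into one column scheme.  Reference positions map to
alignment columns through the reference row's gap structure (1-based
columns, the R convention); when the reference row is absent the
alignment is taken to be in reference coordinates, which holds for the
generator's ungapped output.  Observed conservation is the fraction of
occupied rows carrying an allowed residue; the full table is always
returned, with a flag marking values above the 50% reporting threshold
used in the published table.

## The hallmark motif and the classifier

The hallmark BCH motif `R(R/K)h(R/K)(R/K)NL(R/K)xhhhhHPs` compiles to
16 explicit residue sets; positions 1, 2, 4, 5 and 8 form the
positively charged Arginine/Lysine patch, which is reported as an
annotation of each hit rather than as a second pattern.  The `h`
(large hydrophobic) class is described but never enumerated in the
source material; the default `{L, I, V, F, M, Y, W}` is a modelling
choice, prominently configurable because it changes scan results.
`s` is `{A, T, G, S}` and `x` is any residue.  `X` in a sequence never
matches, not even the wildcard.  In BNIP-2 numbering the invariant N
(pattern position 6) sits at residue 240, placing H at 248 and P at
249.

`classify_domain` scores each sequence against both signature sets
(fraction of mappable positions carrying an allowed residue) and scans
for the hallmark.  The rules:

* **BCH** — hallmark hit within `max_violations`, BCH score ≥ `t_hi`
  (0.6) and CRAL_TRIO score < `t_lo`;
* **CRAL_TRIO** — symmetric on scores, no motif requirement;
* **BCH-like** — both scores in `[t_lo, t_hi)`, the intermediate
  band occupied by the NF1 and RhoGEF relatives;
* **unclassified** otherwise, scores always reported.

Two defaults deserve justification:

* `max_violations = 2`.  Four motif positions coincide with signature
  positions whose published conservation is 87–98%, so a genuine BCH
  domain fails one of those class constraints with probability ≈ 0.30
  and two or more with probability ≈ 0.035.  A tolerance of 1 would
  therefore reject ~3.5% of authentic domains; tolerance 2 reduces
  that to ~0.2% while specificity is preserved by the twelve remaining
  constrained positions (a random sequence window satisfies 14 of 16
  degenerate classes with probability far below 1e-8).
* `t_lo = 0.5`.  The published conservation table reports three
  CRAL_TRIO signature positions conserved *within BCH domains* at over
  90% (P218, K/R239, P261 in Sec14p numbering), so an authentic BCH
  domain is expected to score near 3/8 on the CRAL_TRIO set.  A gate
  at 0.4 sits within one position of that expectation and rejects
  genuine sequences; 0.5 clears it while still separating the
  intermediate band.  A sequence matching exactly half of each set
  still falls in the band and is called BCH-like.

For unaligned input the BCH signature positions are anchored from the
best hallmark hit (pattern position 1 ↔ BNIP-2 residue 235); without a
hit the sequence cannot be anchored and stays unclassified unless a
shared alignment provides the mapping.

## Intron mapping

Intron positions (amino-acid coordinates, with phase recorded but not
used for assignment) are mapped onto an ordered secondary-structure
template of strand / helix / loop elements.  An intron at the last
residue of a non-loop element directly followed by a loop is assigned
to that loop — it falls between structural elements.  Out-of-template
positions are flagged, never dropped.  Strand assignments are
additionally flagged because curated BCH data shows no intron
insertions in beta-strands — the strands form the conserved core of
the domain.  Per-group spectra are fractions of in-span introns per
element kind; the qualitative published pattern (helix insertions in
animals, loop insertions in plants) is a property of the *data*, so
the package only computes assignments and spectra and invents no
centrality statistic.

No experimental structure fixes residue ranges for the BCH template,
so the default template is a synthetic placeholder spanning the
173-residue domain — three alpha-helix/beta-strand pairs flanked by
terminal strands, with contiguous loops — shipped as an editable TSV
(`inst/extdata/bch_ss_template_synthetic.tsv`).  All computation is
template-relative; users analysing real genes supply real ranges.

## The synthetic study and what it does (not) show

The generator defines the study conditions the tests run under:

* **Default dataset** — a BCH family of 175 sequences and a CRAL_TRIO
  family of 69 (the real dataset's sizes), each 297 residues long (the
  trimmed alignment block length of the original analysis), evolved on
  random birth trees (`ape::rtree` topologies, exponential branch
  lengths, mean 0.04 substitutions/site) under a background-resampling
  substitution model: each site substitutes with probability
  $1 - e^{-r \ell}$ per branch and resamples from the background.
  This is deliberately not a named empirical matrix — the statistics
  under test (identities, distances, conservation fractions, motif
  hits) do not depend on realistic exchangeabilities.
* **Planted signal** — the hallmark window (anchored at BNIP-2
  residue 235, BCH family only) is drawn per leaf from the pattern
  classes; signature positions are planted at the published
  conservation rates by *exact count*: `round(rate * n)` randomly
  chosen leaves carry an allowed residue.  The realized conservation
  therefore equals the configured rate up to 1/(2n), which is what a
  generator that *defines* a conservation level should produce; a
  Bernoulli draw would let extreme rates (0.995) stray several
  standard errors in a sizeable fraction of runs.
* **Decoys** — each family also plants the *other* family's signature
  positions at their background expectation (`|allowed| / 20` per
  position).  Without this, ancestral inheritance lets random
  subclades conserve opposite-family residues at levels the published
  table explicitly rules out (every cross-family signature except the
  three prolines/K239 sits below the 50% reporting threshold).
* **Introns** — drawn per gene from the configured element kinds
  (helix for the animal-like policy, loop for the plant-like one),
  strictly inside non-loop elements so the boundary rule cannot
  reassign them; no strand insertions, matching the curated
  observation.
* Evolution is **indel-free**, so the leaf matrix is its own true
  alignment; gap-handling code paths are exercised by a separate
  mutator that injects gap runs into copies.

Everything is reproducible: one seed drives tree, evolution, planting
and intron draws, and emitted datasets are byte-identical per seed.

What passing these tests shows: the statistics, the tree machinery,
the scanner and the classifier do what they claim on data with known
truth at realistic sizes and conservation levels.  What they do not
show: robustness to indels and alignment error, to compositional bias,
to the three cross-family conserved positions the decoy model does not
emulate, or to domains diverged far beyond the planted rates.  On real
data the CRAL_TRIO-score gate in particular deserves attention, since
authentic BCH domains genuinely share part of the CRAL_TRIO signature.

## Numerical choices and degenerate inputs

* Alignment tie-breaks and NJ tie-breaks are deterministic (documented
  above), so every pipeline stage is reproducible bit-for-bit.
* Newick output carries six-decimal branch lengths and integer
  supports as internal node labels.
* Complete deletion of an all-gapped alignment is an error that
  suggests pairwise deletion; a pair with zero shared ungapped columns
  is an error naming the pair.
* A clade-collapse threshold of 0 leaves any tree unchanged (the rule
  is strict `<`); the root never collapses.
* Problem sizes used in validation: random pairs up to length 8
  against the exhaustive alignment oracle (200 cases), random 4–8 leaf
  additive trees (100 cases), random sequences up to length 500
  against the brute-force scanner (100 cases), and the full default
  dataset (244 sequences × 297 columns) for end-to-end recovery.

## Known limitations

* Identity means on real data will differ from the published table
  (undocumented commercial identity formula; trimming choices).
* The default secondary-structure template is a placeholder; intron
  spectra on real genes require real element ranges.
* The greedy clustering reproduces CD-hit's model, not its speed
  heuristics; for datasets orders of magnitude larger than this
  domain family, use the original tool and import its clusters.
* BCH-like (NF1/RhoGEF) families are not simulated; the BCH-like call
  is exercised by construction (band rule) rather than by a dedicated
  generator group.
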