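---
title: "Classifying translational GTPase subfamilies with profile HMMs: methods and design"
author: "trgpipe authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying translational GTPase subfamilies with profile HMMs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trgpipe)
```

## The problem

Translational GTPases (trGTPases) — the IF2/IF5B, EF-Tu/EF1A, EF-G/EF2
and SelB factors and their many paralogues — are among the most
conserved proteins in biology, and their duplications and losses trace
the diversification of translation across the three domains of life and
the organelles. Classifying every trGTPase in a set of proteomes into
its subfamily is a competitive homology-search problem: every sequence
is scored against a collection of subfamily-specific profile hidden
Markov models and assigned to the best-scoring one, subject to a
superfamily significance cutoff, with taxonomic context resolving the
cases (chiefly chloroplast versus cyanobacterial factors) where scores
alone cannot.

`trgpipe` implements that procedure end to end as a reusable, testable
pipeline:

* a **registry** of the 57-subfamily classification, with synonyms,
  compartments, domain architectures, the evolutionary timeline and the
  minimal per-domain repertoires;
* a **profile-HMM engine** (build from alignment, Viterbi and forward
  scoring in compiled code, Gumbel E-value calibration, generative
  sampling);
* **sequence-preparation** stages (gathering at E <= 1e-3, G-domain
  retention checks, analysis-region extraction, gap-column filtering,
  deduplication, fusion flagging, active-site surveys);
* a **clade-delineation** surrogate (p-distance neighbor joining with
  bootstrap supports and label-purity clade extraction);
* the **iterative classifier** (scan, assign at the e-20 cutoff,
  rebuild models from the new members, repeat to convergence) with the
  dual `organellar(bacterial)` notation;
* a **synthetic-proteome generator** that gives every stage a labelled,
  seeded test bed.

## The profile HMM and its scoring model

A model has `L` match states. Each match state emits one of the 20
amino acids; each insert state emits from the background; delete states
emit nothing. Around that core sits a local-alignment shell: a flanking
state `N` before entry and `C` after exit, both emitting background
residues through a self-loop of probability 0.99, entry distributed
uniformly over match states, and a constant early-exit probability of
0.01 from every internal match state (the final one always exits). The
minimal architecture sufficient for local-hit semantics was chosen
deliberately — nothing in the procedure being reproduced depends on a
richer one, and a small architecture is exhaustively checkable (see
below).

Scores are log-odds in bits against a null model that emits every
residue independently from the background (uniform 1/20 by default,
overridable). Because flanks emit the background, their emissions
cancel against the null exactly, so a score measures only the core
alignment. All arithmetic is in log space; underflow cannot occur.
Ambiguity codes (X, B, Z, J, U, O) score at background odds — notably
selenocysteine `U` maps to the background rather than to cysteine — and
a strict mode rejects them instead.

`buildProfile()` turns an alignment into a model: columns with gap
fraction at most 0.5 become match states (the same strictly-greater
rule as the gap-column filter), Henikoff position-based weights correct
for redundant rows, and emissions are weighted counts mixed with one
total pseudocount distributed as the background. Substitution-matrix
pseudocount mixtures are deliberately avoided: with plain
count-plus-background smoothing every number in a model is auditable
from its alignment.

### Why trust the dynamic programming

Forward and Viterbi are verified against an independent brute-force
oracle that enumerates every state path: over all random models with up
to 3 match states on a 4-letter alphabet and all sequences up to length
4, both algorithms agree with enumeration to better than 1e-9 bits (the
observed worst case is ~1e-15, i.e. machine precision). Larger models
are the same recurrences with bigger tables.

### E-values

The procedure's two operating thresholds are E-values: 1e-3 for
candidate gathering and 1e-20 for superfamily membership. Since the
engine is in-package, so is the calibration: `calibrate()` scores
`n >= 100` i.i.d. background random sequences (lengths from a
configurable sampler, by default uniform on 200–500 residues, spanning
one- to two-domain proteins) and fits a Gumbel distribution to the bit
scores by maximum likelihood. Then
`E(s, N) = N * (1 - exp(-exp(-lambda (s - mu))))`. The fit is honest in
the regime the thresholds live in: among fresh random sequences, the
count with `E <= 1` at database size `n` is ~1, and the empirical
median score maps to an upper-tail probability of ~0.5. The database
size used during scans is the number of sequences scanned in the
current run; E-values are linear in it, so any other convention is a
constant factor away.

## Sequence preparation

* **Gathering** keeps sequences whose best E-value against any query
  model is at most 1e-3; it is monotone in the threshold.
* **G-domain retention** re-scores candidates with an in-package
  G-domain model (built from seed alignments; for synthetic data, the
  generator's superfamily root). The retention cutoff defaults to the
  gathering value 1e-3 — the source procedure does not state one, and
  this is recorded as a package choice.
* **Analysis region**: from the G-domain envelope start to the domain
  II envelope end when domain II is predicted, otherwise 100 residues
  (the average domain II length plus margin) past the G-domain end,
  truncated at the sequence boundary. Coordinates are 0-based
  half-open internally; TSV reports are 1-based inclusive and say so in
  a header line.
* **Gap-column filter**: columns with *strictly more than* 50% gaps are
  removed; provenance is kept in `sourceColumns`, making the filter
  idempotent. A column at exactly 0.5 is retained.
* **Deduplication** removes exact-identity duplicates, keeping the
  first occurrence in input order. Whether the original curation meant
  exact or near-identity is unstated; exact identity is implemented as
  the conservative reading.
* **Fusion flagging** automates what was originally manual curation: a
  sequence is flagged when the analysis region covers under half of it
  *and* it is over 1.5x the model consensus length (the CysN–CysC-type
  geometry). Flags are advisory: flagged members are excluded when
  models are rebuilt but retained in classification reports.

## Clade delineation

The original procedure inferred maximum-likelihood trees (RAxML, LG
model) and identified subfamily clades by eye. Tree inference of that
kind is out of scope here; the pipeline needs *cluster delineation*,
not publishable phylogenies, so the surrogate is neighbor joining on
p-distances (mismatch fraction over pairwise-comparable columns), with:

* deterministic tie-breaking (minimum Q, then the lexicographically
  smallest pair of cluster labels, a cluster being labelled by its
  alphabetically first leaf) so results are reproducible;
* negative branch lengths clamped to zero with a warning;
* column-bootstrap supports (percentage of replicate trees containing
  each bipartition of the full-data tree), reproducible under a seed;
* `extractClades()` replacing by-eye inspection: every bipartition side
  is a candidate, and the largest non-overlapping candidates with at
  least `minSize = 3` leaves and dominant-label purity at least
  `minPurity = 0.9` are reported.

On exactly additive matrices NJ provably recovers the generating
topology; the test suite and acceptance script confirm exact topology
and branch-length recovery on 100 random 5–8-leaf trees. Collapsing
bipartitions under 50% support (`collapseWeakNodes()`) is a
presentation option only and is never applied before clade extraction.

## Classification and iteration

For each sequence the hits with `E <= 1e-3` are collected; the model of
minimum E wins. If that E is at most 1e-20 the sequence is classified;
between the two thresholds it is a superfamily non-member; otherwise it
is an unassigned candidate. Ties are broken by bit score, then model
name, and flagged. The e-20 cutoff is applied as a flat constant — the
source procedure prints it as one — and no classified sequence may ever
exceed it (a tested invariant).

"Corrected by taxonomy" is operationalised as annotation, never
relabelling: when a bacterial-taxon sequence is won by an organellar
subfamily whose registry bacterial equivalent also hits, the report
shows `organellar(bacterial)`, e.g. `cEFTu(EF-Tu)`. The E-value winner
always stands. Classification is by model score, not tree monophyly, so
paraphyletic subfamilies are representable by construction.

Iteration alternates scan/assign with model rebuilding: member regions
are re-extracted from the winning model's Viterbi envelope,
deduplicated, fusion-flagged members dropped, the rest profile-aligned
to the current model's match columns (a consistent column set without
any external aligner; an externally aligned FASTA can be substituted
per subfamily), and the model rebuilt and recalibrated. Convergence is
an unchanged sequence-to-label map between consecutive rounds;
`maxRounds = 10` bounds the loop with a warning, so cycling is
impossible. Rebuilt models re-estimate emissions from the member
counts, so absolute bit scores legitimately shift between rounds; the
stability that matters, and the one the tests assert, is that the
assignment map is reproduced.

## The synthetic test bed

The generator emulates the statistical structure the analysis assumes,
so every stage runs with no downloads:

* a root consensus (230 positions: a 140-position G-domain block and a
  90-position domain II block, matching the ~331-residue average
  analysis region) is evolved down a family → subfamily tree, redrawing
  each consensus position with probability 0.45 on family edges and
  0.25 on subfamily edges; emissions put 0.9 on the consensus residue.
  This yields the ordering that real families show — within-subfamily
  p-distance < between-subfamily-within-family < between-family — and
  the generator verifies it empirically in its output record;
* organellar/bacterial pairs (e.g. a cEFTu-like profile evolved from
  the EF-Tu-like one at rate 0.08) reproduce the
  chloroplast-versus-cyanobacteria near-inseparability that motivates
  dual notation;
* members are sampled from their subfamily profile, mutated per site at
  their taxon's divergence level (defaults 0.05 / 0.15 / 0.30) and
  embedded in random flanks of 20–60 residues;
* decoys come in three classes: composition-preserving shuffles of real
  members (the hardest negatives), uniform-random sequences, and
  G-domain-only sequences that emulate GTPases *outside* the
  superfamily — each drawn after redrawing 35% of the root G consensus,
  i.e. roughly 30% identity to any subfamily, the realistic distance of
  a non-trGTPase GTPase — with no domain II block, exercising the
  region-extraction path and the membership boundary;
* seed alignments are emitted from the sampling paths (match-column
  projection), so no aligner is needed;
* everything is byte-identical under an identical spec and seed.

The packaged benchmark is 8 subfamilies in 3 families, 20 members per
subfamily spread over taxa at the three divergence levels, 150 decoys,
seed 20150214. It runs end to end in a few minutes on one CPU; the
test suite and acceptance script use it together with the three
minimal-repertoire fixtures (one member per subfamily of the minimal
bacterial/archaeal/eukaryotic sets, 3/4/6 subfamilies, plus 50 shuffled
decoys). Calibration in those runs uses 150–200 random sequences per
model, a problem size chosen to keep a full run in minutes while
leaving the Gumbel tail accurate at the thresholds used.

What passing these tests shows — and what it does not: the synthetic
data have position-independent emissions, uniform background, no real
indel structure beyond the profile's own, and generator profiles whose
divergence geometry is controlled. Success demonstrates that the
pipeline's logic, thresholds and bookkeeping behave as specified, not
that real proteomes would be classified with the same accuracy; real
trGTPases carry correlated sites, compositional bias and domain gains
and losses that only real alignments exercise.

## The registry and its reconciliation

The registry file (`inst/extdata/trg_registry.json`) transcribes the
57-subfamily classification: one record per subfamily with family
(EF1S/EF2/IF2, midfamily EF1 or SelB within EF1S), domain of life,
compartment, synonyms, origin node on the timeline (LUCA, bLCA,
a+eLCA, aLCA, eLCA, or a post-ancestor lineage), domain architecture
tokens, and for organellar subfamilies the bacterial equivalent used by
dual notation. Slash-joined presence-table cells are split into
separate records. Two reconciliation choices are documented in the
file header and taken as the package's own:

* **lEFG** (the divergent Leptospira EF-G group, the probable spdEFG2
  orthologue) is a distinct record flagged `variant_of = spdEFG2` and
  excluded from default counting, which is what reconciles the record
  total of 57 with the printed 14 bacterial subfamilies;
  `countVariants = TRUE` counts every record.
* **eGTPBP** (protist copies unresolvable into eGTPBP1/eGTPBP2) is a
  distinct, counted record flagged `ambiguous-paralogy`.

Under these choices the registry reproduces 57 records, 14 bacterial,
7 archaeal and 35 eukaryotic counted subfamilies exactly. The
organellar records enumerate to 20; the printed figure of 21
known-or-predicted organellar subfamilies cannot be reconstructed
name-by-name from the available text (and the printed per-domain
counts sum to 56, not 57), so 21 is stored as metadata and the
organellar count check is knowingly left failing rather than forced.
The two printed genome totals (1483 overall; a 103+1274+105 = 1482
breakdown) are likewise both recorded as metadata without resolution.

Timeline complements: LUCA = {EF1, EF2, SelB, IF2} ("at least four");
a+eLCA = {EF2, EF1, IF2g, SelB, GTPBP, IF5B} (six); the eukaryote stem
adds GTPBP2, eRF3, Hbs1, EFL, Ria1 and Snu114 (six cytoplasmic
additions); aLCA adds aSelBL. Minimal repertoires: three factors in
bacteria (EF-Tu, EF-G, IF2), four in archaea (aEF1A, aEF2, aIF2g,
aIF5B), six in eukaryotes (eEF1A, eEF2, eIF2g, eIF5B, eRF3, Ria1).

## Numerical and degenerate-input choices

* Emission/transition distributions must sum to 1 within 1e-9
  (class validity).
* Gumbel fitting solves the standard likelihood equations with
  `uniroot` on a centered sample; degenerate (zero-variance) score sets
  are an error, as is `n < 100`.
* NJ ties break deterministically (above); an all-equal ultrametric
  star resolves arbitrarily but with zero internal branch lengths.
* Empty proteomes scan to empty hit tables; an empty proteome *list*
  is an error. Sequences too short to hit return "no hit", not an
  error.
* A subfamily with no classified members keeps its previous model with
  a warning; a subfamily whose members are all fusion-flagged is an
  error naming it.
* '.' gaps are normalised to '-' on read; alignment rows are
  upper-cased.

## Known limitations

* Maximum-likelihood tree inference is out of scope by design; NJ on
  p-distances delineates clusters but its branch lengths are not
  substitution estimates.
* Multiple sequence alignment construction is consumed, not performed;
  rebuilt models use profile-alignment to the current model, which
  cannot introduce new match columns mid-iteration.
* The E-value calibration assumes the background composition; strongly
  biased real proteomes would warrant the composition override.
* The registry stores the classification schema, not per-genome
  presence/absence calls for real genome sets.
* Apicoplast subfamilies carry an `excluded-from-tree` flag mirroring
  their exclusion from superfamily phylogenies; the flag is annotation
  only.
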