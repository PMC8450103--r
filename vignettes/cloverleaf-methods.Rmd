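---
title: "Models and methods in cloverleaf"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in cloverleaf}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the statistical models, the numerical choices, and
the design decisions behind `cloverleaf`, in the spirit of a methods
section: what is computed, under which assumptions, and what the bundled
synthetic data does and does not demonstrate.

## The profile-SCFG and its guide tree

A seed alignment (rows, a consensus secondary structure, optionally a
marked anticodon) is compiled into a guide tree by the classic
decomposition of a nested structure: unpaired consensus columns become
left- or right-emitting SINGLE nodes, base-paired columns become PAIR
nodes, and a loop enclosing two or more helices introduces BIFURCATION
nodes (a cloverleaf therefore has exactly two below the acceptor stem).
Consensus columns are the alignment columns with gap fraction below 0.5;
the rest are modeled by insert slots.

Parameters, all in bits (base-2 log odds):

* **Single emissions.** `log2(((n_x + α)/(N + 4α)) / q_x)` with Laplace
  pseudocount α = 1 and uniform background `q = 0.25`. IUPAC ambiguity
  codes contribute fractionally (uniformly over their residue sets).
* **Pair emissions.** The analogous 16-cell table. Each pair column also
  carries the two marginal single-column tables derived from the smoothed
  pair probabilities; these serve the structure-free first pass, the
  left/right-only emission states, and the primary/secondary score
  decomposition.
* **Transitions.** Per-node usage probabilities (match/delete for singles;
  match/delete/left-only/right-only for pairs), Laplace-smoothed, stored
  as `log2 p` — they are probabilities, not odds ratios, so they
  normalize per node.
* **Insert slots.** Each node owns up to two geometric insert slots
  (open/extend), placed so that every junction between adjacent consensus
  columns is reachable: `x_l [slot] child` for left singles,
  `child [slot] x_r` for right singles, both sides for pairs and the root,
  one mid slot at each bifurcation, one slot at each END (hairpin loop).
  Slot parameters are trained from the non-consensus columns falling in
  the corresponding inter-column gap; inserted residues emit at the
  background (0 bits). The uniform background (rather than genome
  composition) keeps scores comparable across genomes.

The generative model is properly normalized: emission probabilities sum to
one per column and per pair table, transitions per node, and the insert
geometry integrates to one. `sample_sequence()` draws from exactly this
distribution, which is what makes the implanted fixtures fair test cases
for the scorer.

## Scoring: exact CYK, locality, truncation, ties

`score_sequence()` maximizes the parse score by dynamic programming over
the guide tree (an `O(L²)` table per node, `O(L³)` only at bifurcations).
Two properties are load-bearing and are verified against an independent
exhaustive parse enumeration in the tests:

* the returned score equals the maximum over *all* legal parses, and
* `score == primary + secondary` exactly, where the primary score
  re-scores the identical parse with every pair emission replaced by the
  sum of its two marginals.

*Local* mode means local in the sequence: flanking residues are free, but
the model is traversed in full (the root's insert slots are skipped). This
deliberate choice is why random background almost never reaches the 20-bit
reporting threshold — a high score requires the whole cloverleaf, not a
lucky stem. Model-locality is provided only by the dedicated truncation
layers: when a candidate window touches a sequence boundary, a contiguous
5' (or 3') spine of consensus columns may be deleted free of charge, with
a pair losing one side scored by the marginal of the remaining side.
Parses truncated at *both* ends are not supported; the flags `trunc5` /
`trunc3` are set from the winning layer.

N (and any ambiguity code) emits at 0 bits; a pair with one ambiguous side
scores the marginal of the concrete side. Ties between parses are broken
by a fixed, documented evaluation order (match before delete, smaller
insert counts scanned first), so outputs are deterministic; no secondary
tie-break key is carried through the tables.

Empty input is legal everywhere: the global score of the empty sequence is
the all-delete parse score (finite, very negative), not an error.

## The two-pass scanner

The first pass runs the *marginalized* profile (pair columns released into
their marginals, same insert geometry) as a fully local Smith–Waterman
style DP over both strands. Local entry/exit over the `C(C+1)/2`
begin/end column choices is charged `log2(2/(C(C+1)))` — the standard
profile local-alignment prior — so the 10-bit candidate threshold refers
to a length-corrected score rather than a raw maximum; without this, a
ten-column lucky stretch would fire constantly on megabase backgrounds.
Candidate segments are extended by 60 nt of flanking sequence (matching
the intron-search flank), merged per strand, and rescanned structurally;
hits at or above the 20-bit reporting threshold are kept with the exact
coordinates of the emitted+inserted span.

Two classes of genes are invisible to a structure-free first pass and are
handled by additional candidate windows:

* **boundary-truncated genes** — the two windows touching each sequence
  end are always rescanned with the truncation layers enabled;
* **archaeal genes interrupted by large noncanonical introns** — every
  bulge-helix-bulge (BHB) motif hit seeds a candidate window wide enough
  to hold a whole gene, and in archaeal intron mode the structural pass
  keeps all candidate parses, deferring the 20-bit threshold to the final
  *mature* score (a gene carrying 60+ intron nucleotides can be deeply
  negative before splicing).

`scan_max()` is the exhaustive alternative: overlapping windows (200/150
by default, sized above the longest fixture precursor) are scored
structurally everywhere; its hit set is a superset of the default
pipeline's. When several models scan the same sequence (domain model plus
the separately-folded selenocysteine model, or alternate user models),
the top-scoring hit wins at each overlapping locus, ties broken by model
name then coordinate — deterministically.

## Isotype classification

The anticodon is read from the three marked consensus columns of the
parse; a deletion across them yields `NNN`/`Undet`. The decoding tables
(packaged as data under `inst/extdata/decoding/`, derived from the
standard and vertebrate-mitochondrial genetic codes plus eukaryotic wobble
sparing rules; the eukaryotic table disallows exactly 15 anticodons) map
anticodon to isotype. Independently, the mature sequence is scored
globally against every isotype model; disagreement between the two calls
raises `IPD`. CAU anticodons are resolved by the three subtype models
(iMet/fMet, Met, Ile2) — by design this decision is invariant to whatever
other models are in the registry, and a subtype is reported even when all
three subtype scores are negative.

Isotype models are trained in two rounds: group by anticodon label, align
to the domain model, train intermediates; then regroup every sequence by
its best-scoring intermediate (regardless of anticodon) and retrain. The
second round is what rescues anticodon-mutated genes, but it only works
when groups are large enough that the body-wide signal dominates the
self-similarity a sequence contributes to its own group's intermediate
model — with a handful of sequences per group, Laplace-smoothed
intermediates partially memorize their members. The tests use 30 per
group; real training sets are orders of magnitude larger.

## Introns

*Canonical* introns are insertions of at least 8 nt in the anticodon loop
at the 37/38 junction, read directly off the parse. Because an intron with
random ends can absorb one or two flanking consensus residues into the
alignment, attachment anywhere within two columns of the junction is
accepted; reported bounds are the parse's, so they can slip by the same
one or two nucleotides. Scores of intron-containing genes are re-computed
on the spliced mature sequence.

*Noncanonical* introns are found iteratively: scan the flank-extended
locus with both BHB models, tentatively splice every motif hit of at
least 10 bits and at least 8 nt, accept a splice only if the mature score
strictly improves, and repeat (at most 3 iterations, never letting the
mature length drop below 70 nt). The 10-bit BHB acceptance and the 8-nt
minimum are package defaults validated on the fixtures — the strict
score-improvement rule, not the motif score, is the real gatekeeper. Two
introns in close proximity are recovered across two iterations: the
fixture's nested construction interrupts the second motif with the first
intron, so the second motif only scores after the first splice. A
second-iteration intron is genomically discontiguous (it spans the
already-removed first intron); its reported bounds are the outer genomic
bounds of its span.

## Filters

All thresholds use strict "below"; boundary values are retained.

| stage | rule | constants |
|---|---|---|
| pseudogene | overall < 55 **and** (primary < 10 **or** secondary < 5) | 55/10/5 |
| second | isotype < 70 **or** overall < 50 **or** secondary < 10 | 70/50/10 |
| third | per-anticodon dynamic threshold 71 → 95, rising 1 bit while count > 40 | 71/95/40 |

Consistency annotation (disallowed anticodon, IPD) excludes predictions
from the high-confidence set but reports them with their flags rather than
dropping them. The filter is for eukaryotic predictions; other domains get
a warning. It is deterministic and order-independent.

## Mitochondrial mode

A registry of exactly 22 per-class models (20 isotypes, Leu ×2, Ser ×2;
Ser-GCT built on a D-armless guide tree) scans both strands; overlapping
same-strand hits merge keeping the top model, whose identity becomes the
isotype, with the anticodon cross-checked against the vertebrate
mitochondrial code (`inconsistent_isotype` flag). Evaluation harnesses may
lower the reporting cutoff to 0 bits; the first-pass cutoff follows it
down so that lowering the threshold never removes predictions.

## Virtual genomes and the synthetic fixture set

False-positive behavior is calibrated on fifth-order Markov chains trained
on real(istic) sequence: conditionals from hexamer counts with pseudocount
1 (windows containing N skipped), generation per-sequence to avoid
artificial junction contexts, all randomness through R's seeded RNG.

`make_fixture_set()` generates the entire offline test world: per-isotype
seed alignments (400 rows nuclear, 80 mitochondrial) built around a shared
cloverleaf base consensus with ~25% divergent identity columns per
isotype, loops mutated at 5%, stems substituted *compensatorily* at 25% —
real tRNA stems covary strongly, and this diversity is what gives trained
pair tables their secondary-structure signal; anticodons are never
mutated within a seed. On top of the seeds it trains the domain,
selenocysteine (9/4 fold), BHB, isotype, and mitochondrial registries and
implants sampled genes into uniform-random backgrounds: ~100 kb nuclear
(52 implants: plain, canonical-intron, anticodon-mutated, boundary
truncated, both strands), a small archaeal genome (single-intron,
nested two-intron, and intron-free genes, introns placed in the D-loop
and variable region), and a 16,616 nt mitochondrial genome (one implant
per class). Everything is byte-reproducible from the seed.

What passing on these fixtures shows: the algorithms are internally
consistent (DP equals enumeration), detection and classification recover
what the generative model planted, and thresholds behave exactly as
specified. What it does not show: performance on real genomes — real
tRNA-derived repeats, composition bias, modification-driven identity
elements, and real archaeal intron diversity are all richer than the
generator, and the packaged models are toys trained on synthetic
alignments, not curated databases.

## Problem sizes and numerical notes

The test suite runs the oracle-equivalence sweep at 50 random tiny models
× 200 random sequences (models ≤ 6 columns, sequences ≤ 8 nt — chosen so
exhaustive enumeration stays exact and fast), the recovery and
concordance checks on the 100 kb fixture genome and 200 samples per
isotype, and the false-positive property on 10 × 1 Mb Markov genomes.
Floating-point equality between the DP and the enumeration is asserted at
1e-9 relative; the traceback matches forward values with a 1e-6 epsilon
(option sums are re-derived with a different association order than the
forward recurrences). Model serialization rounds bit scores to 3 decimals
and probabilities to 6; a write/read/write cycle is byte-identical.
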