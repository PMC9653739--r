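---
title: "Inversion archaeology in rearranged plastomes: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inversion archaeology in rearranged plastomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastinv)
```

## The problem

Land-plant plastid genomes (plastomes) are usually structurally conservative:
a quadripartite molecule in which two exact copies of the inverted repeat
(IR) separate the large and small single-copy regions (LSC, SSC). A few
lineages break this pattern spectacularly. In the Lobeliaceae, the most
extensively rearranged plastomes differ from the ancestral, tobacco-like LSC
organization by the loss of *accD* plus five large inversions, and the
inversion endpoints cluster at a recurrent rearrangement hot spot — the
*accD* deletion-site, upstream of *psaI*. `plastinv` implements the
computational core of that analysis as reusable, tested operations:

1. a **signed gene-block algebra** for arrangements, reversal distances and
   exhaustive enumeration of minimal inversion scenarios, with the
   phylogenetic and "common cause" (hot spot) filters that single out the
   historical order of events;
2. **sequence-level detection** of dispersed inverted repeats, hairpins and
   stem-loop-ligation signatures, feeding a mechanistic classification of
   each inversion as *stem-loop* (symmetric: pre-existing flanking repeats
   in inverted orientation recombine) or *disruption-rescue* (asymmetric:
   a foreign-DNA insertion disrupts one endpoint, an unrelated ligation
   rescues an intact molecule at the other);
3. **junction archaeology**: parsimony reconstruction of ancestral
   sequences at the two ends of a phylogenetic interval, classification of
   their differences into events (substitutions, tandem duplications —
   "dupdels" — deletions, transposed insertions, foreign insertions), and
   relative dating of duplicative transpositions from shared derived point
   mutations;
4. a **seeded synthetic-plastome generator** that plants each of these
   event types with known truth, so every detector is exercised against
   planted parameters.

## The inversion algebra

An arrangement is a *linear* signed sequence of blocks (`block_order`).
Linearity is deliberate: all five inversions lie within the LSC, whose
flanks are fixed by the IR boundaries, so circular-symmetry ambiguities
never arise and inverting the whole order is not the identity. Breakpoint
*edges* are 0-based indices between positions; the interval `(i, j)`
reverses the blocks strictly between edges `i` and `j` and flips their
orientation.

`reversal_distance()` is the Hannenhalli–Pevzner formula for sorting signed
permutations by reversals, `d = n + 1 − c + h + f` (breakpoint-graph cycles
`c`, hurdles `h`, fortress indicator `f`), implemented in plain `O(n²)`
which is ample at gene-block scale. The test suite certifies it against a
full breadth-first search of the arrangement space for up to six blocks and
against an independent iterative-deepening search at seven and eight.

`enumerate_minimal_scenarios()` performs a depth-first search restricted to
inversions that strictly reduce the distance to the target. Every prefix of
a minimal scenario lies on a minimal path, so this is exhaustive without
expanding all interval sequences; emitted scenarios are ordered
lexicographically by their per-step edges so output is deterministic.
Scenario identity is the exact sequence of intervals in their per-step
frames: two scenarios with the same inversions in a different temporal
order are distinct hypotheses.

### The packaged fixture and the 67-versus-60 distinction

The packaged encoding of the ancestral and derived LSC uses the minimal
alphabet in which every reconstructed inversion endpoint is a block
boundary — seven blocks
(`psbA | trnK..trnG | trnR..rpoB | trnC..rps4 | trnT..ndhC | trnV..rbcL | psaI`).
No coarser encoding exists: no two blocks remain adjacent and co-oriented
in both arrangements. An eight-block variant adds the ~340-bp `rpoB–trnC`
"C/D" marker segment used to date Inversion 3 against Inversion 4.

On this fixture the two arrangements lie at reversal distance 5, and
exhaustive enumeration finds **67** minimal five-step scenarios. Exactly
**60** of them are temporal orderings of the five reconstructed inversions
— the classical hand count (5!/2 = 60, because one inversion must overlap a
previous one, orderings pairwise coincide after interval remapping). The
remaining 7 scenarios are a genuine finding of machine enumeration: they
reach the same derived arrangement by combining the same six junctions into
interval sets that no comparative reconstruction supports.
`filter_content()` makes the distinction explicit, and the acceptance
checks assert both numbers. Applying the phylogenetic prefix (the first two
inversions are fixed by their phylogenetic intervals) and then the
common-cause filter leaves exactly **one** scenario — whether applied to
the 67 or to the 60 — and its step order is the historical order 1→5.

### Hot-spot tracking and the common-cause criterion

A `breakpoint_locus` is anchored to a block and a side; "upstream of X"
resolves to X's left edge while X is forward and to its right edge when X
is inverted, which is how junctions are read off inverted segments. The
hot-spot locus is anchored upstream of `psaI`. `filter_common_cause()`
keeps scenarios in which *every* step has at least one edge at the tracked
locus. The criterion operates at block resolution: the endpoint of
Inversion 4 is offset from the hot spot by the ~340-bp marker at sequence
resolution but adjacent at block resolution, and the filter is deliberately
insensitive to sub-block offsets.

### Ordering overlapping inversions

`infer_pair_order()` simulates both temporal orders of two inversions given
in the starting frame, remapping the second inversion's breakpoint edges
through the first (edges inside an inverted interval reflect across it).
The call is decided by the final position *and* orientation of a marker
block; when both or neither order reproduces the observation the result is
`indeterminate`. On the marker fixture the 3-before-4 order is the only one
that matches.

## Stem-loop detection

All base pairs of one inverted-repeat stem lie on a single antidiagonal
(`position + partner position` constant). A hit is defined as a chain of
*perfect pairing cores*, each at least `min_stem` bases, bridged across
imperfect stretches of at most `max_gap` positions, subject to a total
substitution budget `floor(max_mismatch_frac × stem_len)`; both hit ends
are matching pairs, arms are gap-free (substitutions only), and only chains
not contained in a longer feasible chain are reported. This definition has
three virtues: it is symmetric under reverse complement (strand-symmetric
detection is a tested property), it admits an exhaustive all-antidiagonal
oracle against which the seed-and-chain implementation is proven equal on
every input up to 2 kb, and it makes "maximality" unambiguous.

Defaults: `min_stem = 6` (the shortest stem implicated in a documented
stem-loop inversion is 7 bp; 6 keeps such stems detectable with one base of
slack and is also the spanning-stem minimum used by
`detect_ligation_signature()`, a configurable choice since no printed
threshold exists for a "compelling" signature), `max_mismatch_frac = 0.1`
(the long dispersed repeat of the reversion case is "imperfect" with no
printed count; 10% keeps arm alignment gap-free and the oracle simple),
`max_gap = 50`. `find_hairpins()` is the same scan restricted to
`max_loop = 50`, the scale at which a separated strand folds back on
itself. Ligation-site scoring (`score_ligation_site()`) counts identities
in the best pair of `window_len = 8` windows over all offsets — the window
length at which the documented insertion site shows a 7-of-8 coincidental
match.

Genome-scale scans should be run per region (`region_seq()`): the two IR
copies are themselves a genome-length inverted repeat and dominate any
whole-genome scan (in `find_transposed_copies()` the IR-versus-IR match is
masked through the annotation instead).

## Junction archaeology

`fitch_reconstruct()` treats the alignment gap as a fifth character state,
so indel columns are reconstructed rather than discarded, and computes for
every internal node and column the full set of states attainable in some
most-parsimonious reconstruction (bottom-up costs plus top-down rest-of-tree
costs; unit changes). A node emits a single state where the set is unique
and the IUPAC ambiguity code otherwise; a set that also admits the gap is
lowercased. Per-column scores are certified against exhaustive assignment
enumeration on small trees.

`interval_diff()` aligns the reconstructions at the start and end of a
phylogenetic interval with an affine-gap global alignment (match 1,
mismatch −1, gap open 4, gap extend 1 — fixed, documented parameters; the
original analysis aligned by eye, the package needs a reproducible
primitive) and classifies each difference segment. An inserted segment
matching the sequence immediately left or right of its insertion point at
≥ 90% identity is a *tandem duplication* — the "dupdel" convention that
most plastome alignment gaps are short tandem duplications rather than bona
fide insertions. An insertion matching a distant region of the supplied
plastome context at ≥ 70% identity over at least half its length is a
*transposed insertion* with its source reported; an insertion matching
nothing is *foreign*, mirroring the convention that foreign DNA is drawn at
its minimum possible extent because plastid-like foreign sequence cannot be
distinguished from plastid DNA. When boundary bases repeat, a global
alignment may slide a gap by a base or two; event lengths are exact, event
start coordinates are exact up to that alignment convention.

Copy dating: `count_shared_derived_mutations()` polarizes copy/source
differences against an explicit ancestral reference (no midpoint or
majority polarization — polarization always comes from the tree-based
reconstruction), and `classify_copy_age()` maps the profile to
`recent_or_concerted` (any shared derived state; the data cannot separate a
very recent transposition from concerted evolution, and the package does
not try), `ancient` (derived states present in the contemporary source but
absent from the copy) or `indeterminate`. `secondary_transposition_order()`
applies the spanning rule: a copy whose source region covers an older
junction with at least `min_flank = 50` bases on each side proves the
junction predates the copy.

## The synthetic generator

`generate_plastome()` emits a deterministic quadripartite genome
(`LSC | IRa | SSC | IRb`, IRb the exact reverse complement of IRa) at GC
0.37 with a nominal gene annotation. Defaults are desk-scale (20-kb LSC,
4-kb IR, 3-kb SSC; the configuration used for the >40-kb-loop case raises
the LSC to 44 kb) — detection is length-scale free, and the methods are
exercised at these sizes; tests state their sizes explicitly.

The planting operations guarantee that planted parameters are exactly
recoverable, which is a property of the *generator*, not leniency in the
detectors: arm-flanking bases are set so they cannot pair, accidental
pairing cores near the planted arms (on the planted antidiagonal) are
broken, planted arm mismatches are spaced so perfect cores stay at least 12
bases, and transposition mutations are spaced at least 18 bases apart and
away from the copy ends. Foreign segments are generated at host GC ± 0.10
around an open reading frame and rejection-sampled to share no 14-mer with
the host on either strand — an operational stand-in for "no detectable
similarity" that makes the plastid/foreign boundary crisp.

What the generator does **not** emulate: nucleotide substitution processes
along a full phylogeny (only the local mutation profiles the detectors
need), realistic gene content or codon structure, IR expansion/contraction,
or sequencing error. Passing the recovery suite therefore demonstrates
correctness of the detectors under the stated event models, not performance
on raw field data, where alignment quality and annotation errors dominate.

## Numerical and design choices

- Coordinates are 1-based inclusive everywhere in user-facing output; BED
  stays 0-based half-open at the file boundary; GFF3 is 1-based inclusive.
- Scenario emission order, hit ordering (`stem_len` desc, `loop_len` asc,
  leftmost) and all seeds make every pipeline output deterministic.
- `enumerate_minimal_scenarios()` refuses distances above `max_len`
  (default 8) rather than attempt an unbounded combinatorial search.
- Degenerate inputs: an empty sequence yields an empty hit table; identical
  sequences yield an empty event list; a locus whose anchor is missing, a
  marker absent from the observed arrangement, and out-of-range intervals
  or junction positions raise typed errors rather than propagate nonsense.
- The command-line surface is the R API plus `scripts/acceptance.R`; the
  package is an analysis library, not a shell tool, so functions, fixtures
  and this vignette are the interface.

## Known limitations

- The inversion algebra excludes translocations and duplications; a
  duplicated segment is not a permutation element but a `TransposedCopy`.
- The stem-loop hit definition requires perfect cores of `min_stem` bases;
  a repeat whose substitutions are denser than one per core length is
  reported in trimmed parts. This matches the planted-event models and
  keeps the oracle exact, but very degraded repeats need lower `min_stem`.
- `interval_diff()` does not call inversions from sequence alone; inversion
  hypotheses enter through the block-order layer.
- Amino-acid-level similarity of foreign ORFs is out of scope, as is
  identifying the extra-plastid source of foreign DNA.
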