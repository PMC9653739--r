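# plastinv

Inversion archaeology for rearranged plastid genomes.

Most land-plant plastomes are structurally conservative; a few lineages are
not. In the Lobeliaceae, the most extensively rearranged plastomes differ
from the ancestral LSC organization by the loss of *accD* plus five large
inversions whose endpoints cluster at a recurrent rearrangement hot spot
(the *accD* deletion-site, upstream of *psaI*). `plastinv` implements the
computational core of that style of analysis for anyone reconstructing
structural evolution in plastomes (or other small genomes):

- **Signed gene-block algebra.** Arrangements are linear signed block
  orders; `reversal_distance(a, b)` is the Hannenhalli–Pevzner distance
  `d = n + 1 − c + h + f` (breakpoint-graph cycles, hurdles, fortress);
  `enumerate_minimal_scenarios()` exhaustively lists every shortest
  inversion scenario by distance-pruned depth-first search.
- **Scenario filters.** `filter_phylo()` fixes a phylogenetically required
  prefix of inversions; `filter_common_cause()` keeps scenarios in which
  every inversion has an endpoint at a tracked hot-spot locus;
  `infer_pair_order()` dates two overlapping inversions from the final
  position and orientation of a marker segment.
- **Stem-loop detection.** `find_inverted_repeats()` / `find_hairpins()`
  report maximal chains of perfect pairing cores bridged under a mismatch
  budget; `score_ligation_site()` and `detect_ligation_signature()` find
  the window-match and expanded-palindrome signatures of stem-loop
  ligation; `classify_mechanism()` calls each inversion *stem-loop* versus
  *disruption-rescue* from endpoint evidence.
- **Junction archaeology.** `fitch_reconstruct()` (parsimony ancestral
  sequences with IUPAC ambiguity codes, gap as a fifth state),
  `interval_diff()` (substitutions, tandem duplications/"dupdels",
  deletions, transposed and foreign insertions),
  `find_transposed_copies()`, `count_shared_derived_mutations()`,
  `classify_copy_age()` and `secondary_transposition_order()`.
- **Synthetic plastomes.** `generate_plastome()` plus planting operations
  (`plant_stem_loop_inversion()`, `plant_disruption_rescue_inversion()`,
  `plant_transposition()`) emit seeded, annotated genomes with truth
  records for every planted event; `load_fixture()` ships the block-order
  encodings of the five-inversion derivation.

## Worked example

```r
library(plastinv)

fx <- load_fixture("five_inversions")
reversal_distance(fx$ancestral, fx$derived)
#> [1] 5

sc <- enumerate_minimal_scenarios(fx$ancestral, fx$derived)
length(sc)                                  # exhaustive enumeration
#> [1] 67
length(filter_content(sc, fx$inversions))   # orderings of the five inversions
#> [1] 60
surv <- filter_common_cause(filter_phylo(sc, fx$phylo), fx$hotspot)
length(surv)
#> [1] 1
surv[[1]]
#> <inversion_scenario> 5 step(s): (1,6) -> (2,6) -> (4,6) -> (3,6) -> (4,6)
```

The two packaged LSC arrangements lie at reversal distance 5. Exhaustive
enumeration finds 67 minimal five-step scenarios; 60 of them are temporal
orderings of the five reconstructed inversions (the classical 5!/2 count),
the other 7 combine the same junctions into interval sets no comparative
evidence supports. Fixing the first two inversions to their phylogenetic
intervals and requiring every inversion to use the hot spot as an endpoint
leaves exactly one scenario — the historical order 1→5.

Dating the two same-interval inversions from the ~340-bp marker segment:

```r
mk <- load_fixture("inv34_marker")
infer_pair_order(mk$order0, mk$invA, mk$invB, mk$marker, mk$observed)
#> [1] "A_first"      # Inversion 3 preceded Inversion 4
```

Planting and recovering a dispersed imperfect inverted repeat:

```r
g <- generate_plastome(plastome_config(seed = 1001))
p <- plant_stem_loop_inversion(g, stem_len = 118, loop_len = 2000, mismatches = 8)
hits <- find_inverted_repeats(region_seq(p$genome, "LSC"))
hits[1, c("stem_len", "loop_len", "mismatches")]
#>   stem_len loop_len mismatches
#> 1      118     2000          8
```

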