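test_that("ancestral reconstruction handles constant and two-state columns", {
  tree <- ape::read.tree(text = "((a:1,b:1)n1:1,(c:1,d:1)n2:1)root;")
  fr <- fitch_reconstruct(c(a = "AA", b = "AC", c = "AA", d = "AA"), tree)
  expect_identical(substr(fr$nodes[["root"]], 1, 1), "A")
  expect_identical(fr$score, c(0L, 1L))
  # two leaves differing: the root is ambiguous with the union code
  tr2 <- ape::read.tree(text = "(a:1,b:1)r;")
  expect_identical(fitch_reconstruct(c(a = "A", b = "C"), tr2)$nodes[["r"]],
                   "M")
  # gap is a fifth state
  expect_identical(fitch_reconstruct(c(a = "-", b = "-"), tr2)$nodes[["r"]],
                   "-")
  expect_error(fitch_reconstruct(c(x = "A", b = "C"), tr2), "tip label")
})

test_that("per-column parsimony scores equal the brute-force minimum", {
  set.seed(555)
  trees <- list(
    ape::read.tree(text = "((a:1,b:1)x:1,(c:1,(d:1,e:1)y:1)z:1)r;"),
    ape::read.tree(text = "(((a:1,b:1)x:1,c:1)y:1,d:1)r;"),
    ape::read.tree(text = "((a:1,b:1)x:1,(c:1,d:1)y:1)r;"))
  for (tree in trees) {
    tips <- tree$tip.label
    for (rep in 1:12) {
      col <- sample(c("A", "C", "G", "T", "-"), length(tips), replace = TRUE)
      names(col) <- tips
      aln <- stats::setNames(col, tips)
      fr <- fitch_reconstruct(aln, tree)
      expect_identical(fr$score, or_fitch_column_score(tree, col))
    }
  }
})

test_that("reconstructed node states are IUPAC codes over most-parsimonious sets", {
  tree <- ape::read.tree(text = "((a:1,b:1)n1:1,(c:1,d:1)n2:1)root;")
  fr <- fitch_reconstruct(c(a = "A", b = "A", c = "C", d = "G"), tree)
  # root can be A, C or G in some most-parsimonious reconstruction
  expect_identical(fr$nodes[["root"]], "V")
  expect_identical(fr$nodes[["n1"]], "A")
})

test_that("interval_diff calls deletions, duplications and substitutions", {
  expect_equal(nrow(interval_diff("ACGTACGT", "ACGTACGT")), 0L)
  set.seed(666)
  anc <- or_rand_dna(900)
  # deletion of 152
  del <- paste0(substr(anc, 1, 400), substr(anc, 553, 900))
  ev <- interval_diff(anc, del)
  expect_identical(ev$type, "deletion")
  expect_identical(ev$length, 152L)
  # alignment may slide the gap by a base when boundary bases coincide
  expect_lte(abs(ev$start - 401L), 2L)
  # tandem duplication of 45
  dup <- paste0(substr(anc, 1, 500), substr(anc, 456, 500), substr(anc, 501, 900))
  ev2 <- interval_diff(anc, dup)
  expect_identical(ev2$type, "tandem_duplication")
  expect_identical(ev2$length, 45L)
  # point substitution
  sub <- anc
  substr(sub, 300, 300) <- setdiff(c("A", "C", "G", "T"),
                                   substr(anc, 300, 300))[1]
  ev3 <- interval_diff(anc, sub)
  expect_identical(ev3$type, "substitution")
  expect_identical(ev3$start, 300L)
  expect_error(interval_diff(anc, or_rand_dna(900)), "identity floor")
})

test_that("insertions are classified foreign vs transposed via the context", {
  set.seed(777)
  context <- or_rand_dna(4000)
  anc <- or_rand_dna(700)
  seg <- substr(context, 2001, 2150)   # a 150-base plastome segment
  ins_t <- paste0(substr(anc, 1, 350), seg, substr(anc, 351, 700))
  ev <- interval_diff(anc, ins_t, plastome_context = context)
  expect_identical(ev$type, "transposed_insertion")
  expect_identical(ev$length, 150L)
  foreign <- or_rand_dna(150)
  ins_f <- paste0(substr(anc, 1, 350), foreign, substr(anc, 351, 700))
  ev2 <- interval_diff(anc, ins_f, plastome_context = context)
  expect_identical(ev2$type, "foreign_insertion")
})

test_that("interval_diff event lengths reconcile the two sequence lengths", {
  set.seed(888)
  for (rep in 1:10) {
    anc <- or_rand_dna(600)
    cur <- anc
    # random edits: one deletion and one tandem duplication
    d0 <- sample(100:200, 1); dl <- sample(20:60, 1)
    cur <- paste0(substr(cur, 1, d0), substr(cur, d0 + dl + 1, nchar(cur)))
    t0 <- sample(350:400, 1); tl <- sample(15:40, 1)
    cur <- paste0(substr(cur, 1, t0), substr(cur, t0 - tl + 1, t0),
                  substr(cur, t0 + 1, nchar(cur)))
    ev <- interval_diff(anc, cur)
    ins_len <- sum(ev$length[ev$type %in% c("tandem_duplication",
                                            "transposed_insertion",
                                            "foreign_insertion")])
    del_len <- sum(ev$length[ev$type == "deletion"])
    expect_identical(nchar(cur) - nchar(anc), ins_len - del_len)
  }
})

test_that("transposed copies are detected at planted coordinates", {
  g <- generate_plastome(plastome_config(seed = 31))
  expect_equal(nrow(find_transposed_copies(g, min_len = 100)), 0L)
  tp <- plant_transposition(g, c(4000, 4299), 11000, "same")
  got <- find_transposed_copies(tp$genome, min_len = 100)
  expect_identical(nrow(got), 1L)
  expect_identical(got$copy_start, tp$event$copy_region[1])
  expect_identical(got$length, 300L)
  expect_identical(got$orientation, "same")
  expect_true(got$polarized)
  # inverted orientation
  tp2 <- plant_transposition(g, c(4000, 4299), 11000, "inverted")
  got2 <- find_transposed_copies(tp2$genome, min_len = 100)
  expect_identical(got2$orientation, "inverted")
  expect_identical(got2$copy_start, tp2$event$copy_region[1])
  # all-pairs oracle on a small sequence: the same-strand pair is the only one
  set.seed(999)
  small <- or_rand_dna(1200)
  seg <- substr(small, 100, 249)
  small2 <- paste0(substr(small, 1, 800), seg, substr(small, 801, 1200))
  fc <- find_transposed_copies(small2, min_len = 100, seed_len = 16)
  expect_identical(nrow(fc), 1L)
  expect_identical(fc$copy_start, 100L)   # unpolarized: leftmost reported first
  expect_identical(fc$source_start, 801L)
  expect_false(fc$polarized)
})

test_that("derived-mutation sharing profiles polarize against the ancestor", {
  anc <- "ACGTACGTACGTACGTACGT"
  expect_identical(count_shared_derived_mutations(anc, anc, anc),
                   c(shared_derived = 0L, copy_only = 0L, source_only = 0L))
  copy <- anc; source <- anc
  substr(copy, 3, 3) <- "T"; substr(source, 3, 3) <- "T"   # shared derived
  substr(copy, 8, 8) <- "G"                                 # copy only
  substr(source, 15, 15) <- "A"                             # source only
  cnt <- count_shared_derived_mutations(copy, source, anc)
  expect_identical(cnt, c(shared_derived = 1L, copy_only = 1L,
                          source_only = 1L))
  # shared count is symmetric in copy/source
  cnt2 <- count_shared_derived_mutations(source, copy, anc)
  expect_identical(cnt2[["shared_derived"]], cnt[["shared_derived"]])
})

test_that("copy age classification separates recent/concerted from ancient", {
  expect_identical(classify_copy_age(c(shared_derived = 5L, copy_only = 0L,
                                       source_only = 1L)),
                   "recent_or_concerted")
  expect_identical(classify_copy_age(c(shared_derived = 0L, copy_only = 0L,
                                       source_only = 4L)),
                   "ancient")
  expect_identical(classify_copy_age(c(shared_derived = 0L, copy_only = 0L,
                                       source_only = 0L)),
                   "indeterminate")
  expect_error(classify_copy_age(c(shared_derived = -1L, copy_only = 0L,
                                   source_only = 0L)), "non-negative")
})

test_that("secondary transpositions date junctions they span", {
  copy <- list(source_start = 1000L, source_end = 1400L)
  expect_identical(secondary_transposition_order(copy, 1200L),
                   "junction_predates_copy")
  expect_identical(secondary_transposition_order(copy, 1020L),
                   "uninformative")  # flank below the minimum
  expect_identical(secondary_transposition_order(copy, 5000L),
                   "uninformative")
  expect_error(secondary_transposition_order(copy, 9000L, genome_len = 8000L),
               "outside")
})
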