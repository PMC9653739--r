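test_that("inverted-repeat scanner matches the exhaustive oracle", {
  set.seed(606)
  for (rep in 1:12) {
    n <- sample(250:700, 1)
    s <- or_rand_dna(n)
    if (rep %% 3 == 0) {
      arm <- or_rand_dna(sample(12:25, 1))
      pos <- sample(40:120, 1)
      s <- paste0(substr(s, 1, pos), arm, or_rand_dna(sample(4:60, 1)),
                  or_revcomp(arm), substr(s, pos + 1, n))
    }
    got <- find_inverted_repeats(s, min_stem = 5, max_loop = Inf,
                                 max_mismatch_frac = 0.1, max_gap = 20)
    exp <- or_inverted_repeats(s, 5, Inf, 0.1, 20)
    expect_equal(nrow(got), nrow(exp))
    if (nrow(exp)) expect_equal(got, exp, tolerance = 1e-12)
  }
})

test_that("sequences without inverted structure yield no hits", {
  expect_equal(nrow(find_inverted_repeats("", min_stem = 6)), 0L)
  expect_equal(nrow(find_hairpins(strrep("A", 300), min_stem = 6)), 0L)
  expect_error(find_inverted_repeats("ACGT", min_stem = 2), "min_stem")
})

test_that("a planted perfect repeat is reported exactly at its coordinates", {
  set.seed(707)
  s <- or_rand_dna(1800)
  arm <- or_rand_dna(20)
  g <- paste0(substr(s, 1, 600), "A", arm, "A",
              or_rand_dna(100), "A", or_revcomp(arm), "A",
              substr(s, 601, 1800))
  hits <- find_inverted_repeats(g, min_stem = 10, max_loop = Inf,
                                max_mismatch_frac = 0)
  top <- hits[1, ]
  expect_identical(top$stem_len, 20L)
  expect_identical(top$left_start, 602L)
  expect_identical(top$loop_len, 102L)
  expect_identical(top$mismatches, 0L)
  # the reported arms really are reverse complements
  larm <- substr(g, top$left_start, top$left_end)
  rarm <- substr(g, top$right_start, top$right_end)
  expect_identical(or_revcomp(larm), rarm)
})

test_that("every reported hit satisfies its own stem invariant", {
  set.seed(808)
  s <- or_rand_dna(1500)
  hits <- find_inverted_repeats(s, min_stem = 5, max_mismatch_frac = 0.1,
                                max_gap = 20)
  for (i in seq_len(nrow(hits))) {
    larm <- substr(s, hits$left_start[i], hits$left_end[i])
    rarm <- substr(s, hits$right_start[i], hits$right_end[i])
    mm <- sum(strsplit(larm, "")[[1]] != strsplit(or_revcomp(rarm), "")[[1]])
    expect_identical(mm, hits$mismatches[i])
    expect_lte(mm, floor(0.1 * hits$stem_len[i]))
    expect_gte(hits$stem_len[i], 5)
  }
})

test_that("detection is strand-symmetric", {
  set.seed(909)
  for (rep in 1:6) {
    s <- or_rand_dna(600)
    arm <- or_rand_dna(14)
    s <- paste0(substr(s, 1, 200), arm, or_rand_dna(30), or_revcomp(arm),
                substr(s, 201, 600))
    n <- nchar(s)
    f <- find_inverted_repeats(s, min_stem = 6, max_gap = 20)
    r <- find_inverted_repeats(or_revcomp(s), min_stem = 6, max_gap = 20)
    mirror <- data.frame(left_start = n - r$right_end + 1L,
                         left_end = n - r$right_start + 1L,
                         right_start = n - r$left_end + 1L,
                         right_end = n - r$left_start + 1L,
                         stem_len = r$stem_len, loop_len = r$loop_len,
                         mismatches = r$mismatches,
                         identity_fraction = r$identity_fraction)
    mirror <- mirror[order(-mirror$stem_len, mirror$loop_len,
                           mirror$left_start), ]
    rownames(mirror) <- NULL
    expect_equal(f, mirror, tolerance = 1e-12)
  }
})

test_that("hairpins are the short-loop subset of inverted repeats", {
  set.seed(111)
  s <- or_rand_dna(500)
  arm <- or_rand_dna(6)
  s <- paste0(substr(s, 1, 100), "A", arm, "TTCT", or_revcomp(arm), "A",
              substr(s, 101, 500))
  hp <- find_hairpins(s, min_stem = 6, max_loop = 4, max_mismatch_frac = 0)
  ir <- find_inverted_repeats(s, min_stem = 6, max_loop = Inf,
                              max_mismatch_frac = 0)
  expect_true(any(hp$stem_len >= 6 & hp$loop_len == 4))
  expect_true(all(hp$loop_len <= 4))
  keys <- function(d) paste(d$left_start, d$right_end)
  expect_true(all(keys(hp) %in% keys(ir)))
})

test_that("ligation-site scoring finds the best window pair", {
  expect_identical(score_ligation_site("GATCCTAG", "GATCCTAG", 8)$matches, 8L)
  fx <- load_fixture("rpl23_primary_transposition")
  sc <- score_ligation_site(fx$donor_flank, fx$acceptor_site, fx$window_len)
  expect_identical(sc$matches, fx$expected_matches)
  expect_identical(sc$window_len, 8L)
  expect_error(score_ligation_site("ACGT", "ACGTACGT", 8), "window_len")
  # chance-level agreement with a brute-force all-offset scan
  set.seed(222)
  for (rep in 1:10) {
    a <- or_rand_dna(sample(10:30, 1)); b <- or_rand_dna(sample(10:30, 1))
    got <- score_ligation_site(a, b, 8)$matches
    ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
    best <- 0L
    for (i in 1:(length(ca) - 7)) for (j in 1:(length(cb) - 7))
      best <- max(best, sum(ca[i:(i + 7)] == cb[j:(j + 7)]))
    expect_identical(got, as.integer(best))
  }
})

test_that("a junction inside an expanded palindrome is a ligation signature", {
  set.seed(333)
  arm <- or_rand_dna(9)
  s <- paste0(or_rand_dna(150), "C", arm, "ATAT", or_revcomp(arm), "C",
              or_rand_dna(150))
  jpos <- 150 + 1 + 9 + 2  # inside the loop: the stem spans it
  res <- detect_ligation_signature(s, jpos, min_stem = 6)
  expect_true(res$detected)
  expect_gte(res$evidence$stem_len[1], 6)
  expect_true(res$evidence$left_start[1] <= jpos &&
              res$evidence$right_end[1] > jpos)
  # no spanning stem in plain sequence
  s2 <- paste0(strrep("ACT", 100))
  expect_false(detect_ligation_signature(s2, 150, min_stem = 6)$detected)
  expect_error(detect_ligation_signature(s2, 300, min_stem = 6), "interior")
})

test_that("mechanism classification follows the endpoint evidence", {
  # matching inverted ancestral flanks at both endpoints: stem-loop
  set.seed(444)
  stem <- or_rand_dna(7)
  flankA <- paste0(or_rand_dna(30), stem, or_rand_dna(10))
  flankB <- paste0(or_rand_dna(12), or_revcomp(stem), or_rand_dna(28))
  cl <- classify_mechanism(ancestral_flanks = list(A = flankA, B = flankB),
                           min_stem = 7)
  expect_identical(cl$mechanism, "stem_loop")
  expect_true("inverted_flanking_repeat" %in% cl$evidence$A)
  # foreign insertion at one endpoint, arbitrary ligation marks at the other
  cl2 <- classify_mechanism("foreign_insertion_at_endpoint",
                            c("deletion_at_endpoint",
                              "tandem_duplication_at_endpoint"))
  expect_identical(cl2$mechanism, "disruption_rescue")
  # nothing detectable: ambiguous
  expect_identical(classify_mechanism()$mechanism, "ambiguous")
  # stem-loop requires the repeat evidence even when other codes are present
  cl3 <- classify_mechanism("arbitrary_ligation", "deletion_at_endpoint")
  expect_identical(cl3$mechanism, "ambiguous")
})
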