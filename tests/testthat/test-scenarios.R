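test_that("enumeration is exhaustive against brute-force expansion", {
  o <- block_order(as.character(1:4))
  expect_length(enumerate_minimal_scenarios(o, o), 1L)
  expect_length(enumerate_minimal_scenarios(o, o)[[1]]$steps, 0L)

  set.seed(404)
  tried <- 0
  while (tried < 12) {
    src <- or_random_order(5)
    tgt <- or_random_order(5, src$ids)
    d <- reversal_distance(src, tgt)
    if (d < 1 || d > 3) next
    tried <- tried + 1
    got <- enumerate_minimal_scenarios(src, tgt)
    p0 <- plastinv:::.relabel_perm(src, tgt)
    tgt0 <- seq_along(p0)
    exp_steps <- or_all_scenarios(p0, tgt0, d)
    key <- function(steps) paste(vapply(steps, paste, "", collapse = ","),
                                 collapse = ";")
    got_keys <- vapply(got, function(sc)
      key(lapply(sc$steps, function(iv) c(iv[[1]], iv[[2]]))), "")
    exp_keys <- vapply(exp_steps, key, "")
    expect_setequal(got_keys, exp_keys)
    expect_false(anyDuplicated(got_keys) > 0)
    # every emitted scenario reproduces the target
    for (sc in got) expect_true(apply_scenario(src, sc) == tgt)
  }
})

test_that("enumeration refuses distances beyond the guard", {
  src <- block_order(as.character(1:6))
  tgt <- apply_scenario(src, list(inversion_interval(0, 3),
                                  inversion_interval(2, 5),
                                  inversion_interval(1, 4)))
  expect_error(enumerate_minimal_scenarios(src, tgt, max_len = 1L),
               "exceeds max_len")
})

test_that("five-inversion fixture: 67 minimal scenarios, 60 orderings of the five inversions", {
  fx <- load_fixture("five_inversions")
  sc <- enumerate_minimal_scenarios(fx$ancestral, fx$derived)
  expect_length(sc, 67L)
  expect_true(all(vapply(sc, function(s) length(s$steps), 1L) == 5L))
  for (s in sc) expect_true(apply_scenario(fx$ancestral, s) == fx$derived)
  # the classical count considers temporal orderings of the five
  # reconstructed inversions (5!/2): exactly 60 of the scenarios
  ord5 <- filter_content(sc, fx$inversions)
  expect_length(ord5, 60L)
})

test_that("common-cause and phylogenetic filters isolate the historical order", {
  fx <- load_fixture("five_inversions")
  sc <- enumerate_minimal_scenarios(fx$ancestral, fx$derived)
  cc <- filter_common_cause(sc, fx$hotspot)
  expect_length(cc, 1L)
  skey <- function(s) paste(vapply(s$steps, paste, "", collapse = ","),
                            collapse = ";")
  expect_true(all(vapply(cc, skey, "") %in% vapply(sc, skey, "")))  # subset
  expect_identical(filter_common_cause(cc, fx$hotspot), cc)  # idempotent
  pre <- filter_phylo(sc, fx$phylo)
  for (s in pre) {
    expect_identical(s$steps[[1]], fx$phylo$fixed_prefix[[1]])
    expect_identical(s$steps[[2]], fx$phylo$fixed_prefix[[2]])
  }
  both <- filter_common_cause(pre, fx$hotspot)
  expect_length(both, 1L)
  # the survivor is the historical order 1 -> 5
  expect_identical(lapply(both[[1]]$steps, as.integer),
                   lapply(fx$scenario$steps, as.integer))
  # empty prefix is the identity filter
  none <- phylo_constraint("none", list())
  expect_identical(filter_phylo(sc, none), sc)
  # unrealisable prefix filters everything out
  bad <- phylo_constraint("bad", list(inversion_interval(0, 1)))
  expect_length(filter_phylo(sc, bad), 0L)
})

test_that("a scenario that never touches the locus is filtered out", {
  o <- block_order(as.character(1:4))
  tgt <- apply_inversion(o, inversion_interval(0, 2))
  sc <- enumerate_minimal_scenarios(o, tgt)
  loc <- breakpoint_locus("L", "4", "downstream")  # edge 4, never used
  expect_length(filter_common_cause(sc, loc), 0L)
})

test_that("marker position and orientation date Inversion 3 before Inversion 4", {
  mk <- load_fixture("inv34_marker")
  expect_identical(
    infer_pair_order(mk$order0, mk$invA, mk$invB, mk$marker, mk$observed),
    "A_first")
  # the reverse claim is rejected: the composite applied 4-then-3 leaves the
  # marker elsewhere
  b_first <- apply_inversion(
    apply_inversion(mk$order0, mk$invB),
    plastinv:::.remap_interval(mk$invA, mk$invB))
  expect_false(b_first == mk$observed)
  expect_identical(
    infer_pair_order(mk$order0, mk$invA, mk$invB, mk$marker, b_first),
    "B_first")
})

test_that("disjoint inversions with an outside marker are order-indeterminate", {
  o <- block_order(as.character(1:6))
  invA <- inversion_interval(1, 2); invB <- inversion_interval(3, 5)
  obs <- apply_inversion(apply_inversion(o, invA), invB)
  expect_identical(infer_pair_order(o, invA, invB, "6", obs), "indeterminate")
  expect_error(infer_pair_order(o, invA, invB, "zz", obs), "marker")
})

test_that("planted pair orders are recovered when the marker is informative", {
  set.seed(505)
  found_a <- 0; found_b <- 0
  for (rep in 1:40) {
    n <- 7
    o <- block_order(as.character(1:n))
    # overlapping intervals; marker inside the overlap of A and B
    a <- sort(sample(0:n, 2)); b <- sort(sample(0:n, 2))
    if (a[1] == a[2] || b[1] == b[2]) next
    invA <- inversion_interval(a[1], a[2]); invB <- inversion_interval(b[1], b[2])
    ov <- intersect((a[1] + 1):a[2], (b[1] + 1):b[2])
    if (!length(ov)) next
    marker <- as.character(sample(ov, 1))
    ab <- apply_inversion(apply_inversion(o, invA),
                          plastinv:::.remap_interval(invB, invA))
    ba <- apply_inversion(apply_inversion(o, invB),
                          plastinv:::.remap_interval(invA, invB))
    res_ab <- infer_pair_order(o, invA, invB, marker, ab)
    res_ba <- infer_pair_order(o, invA, invB, marker, ba)
    ms <- function(ord) {
      p <- match(marker, ord$ids); c(p, ord$signs[p])
    }
    if (!identical(ms(ab), ms(ba))) {
      expect_identical(res_ab, "A_first")
      expect_identical(res_ba, "B_first")
      found_a <- found_a + 1
    } else {
      expect_identical(res_ab, "indeterminate")
      found_b <- found_b + 1
    }
  }
  expect_gt(found_a, 5)  # the discriminating regime was actually exercised
})

test_that("scenario reports carry steps, arrangements and the tracked hot spot", {
  fx <- load_fixture("five_inversions")
  rep_ <- scenario_report(list(fx$scenario), fx$hotspot)
  expect_length(rep_, 1L)
  expect_length(rep_[[1]]$steps, 5L)
  expect_identical(rep_[[1]]$steps[[1]]$hotspot_edge_at_step, 6L)
  final <- rep_[[1]]$steps[[5]]$arrangement_after
  expect_identical(final,
                   paste0(ifelse(fx$derived$signs > 0, "+", "-"),
                          fx$derived$ids))
})
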