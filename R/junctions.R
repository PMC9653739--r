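# Junction archaeology: ancestral reconstruction at rearrangement junctions,
# interval-difference event calling, and transposed-copy detection/dating.

.FIVE_STATES <- c("A", "C", "G", "T", "-")

# IUPAC leaf character -> allowed state set over {A,C,G,T,-}
.iupac_sets <- local({
  m <- list(A = "A", C = "C", G = "G", T = "T", U = "T",
            M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
            S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
            V = c("A", "C", "G"), H = c("A", "C", "T"),
            D = c("A", "G", "T"), B = c("C", "G", "T"),
            N = c("A", "C", "G", "T"), "-" = "-",
            "?" = c("A", "C", "G", "T", "-"))
  m
})

.set_to_code <- local({
  codes <- c(A = "A", C = "C", G = "G", T = "T",
             AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
             ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")
  function(states) {
    has_gap <- "-" %in% states
    bases <- setdiff(states, "-")
    if (!length(bases)) return("-")
    code <- codes[[paste(sort(bases), collapse = "")]]
    # lowercase marks "or an alignment gap"
    if (has_gap) tolower(code) else code
  }
})

#' Parsimony reconstruction of ancestral sequences
#'
#' Reconstructs ancestral sequences on a rooted tree from an aligned set of
#' leaf sequences by unweighted parsimony (Fitch counting over the five
#' states `A, C, G, T, -`; the alignment gap is a fifth state, so indel
#' columns are reconstructed rather than discarded). For every internal node
#' and column, the full set of states attainable in some most-parsimonious
#' reconstruction is computed with a bottom-up/top-down (Sankoff-style)
#' pass; a node emits the single state where that set is unique, and the
#' IUPAC ambiguity code for the set otherwise (lowercased when the set also
#' admits a gap).
#'
#' @param alignment named character vector (or `DNAStringSet`) of equal-length
#'   aligned sequences, names matching the tree's tip labels. IUPAC
#'   ambiguity codes are honoured in the leaves.
#' @param tree a rooted `ape::phylo` tree whose tip labels all occur in the
#'   alignment.
#' @return An object of class `ancestral_alignment`: list with `nodes`
#'   (named character vector of reconstructed node sequences, including one
#'   per internal node; names from `tree$node.label` where present),
#'   `score` (per-column parsimony scores), `tree` and `alignment`.
#' @export
fitch_reconstruct <- function(alignment, tree) {
  if (methods::is(alignment, "XStringSet"))
    alignment <- stats::setNames(as.character(alignment), names(alignment))
  alignment <- toupper(alignment)
  if (is.null(names(alignment)) || !all(tree$tip.label %in% names(alignment)))
    stop("alignment must be named and cover every tip label of the tree")
  if (length(unique(nchar(alignment))) != 1L)
    stop("aligned sequences must have equal length")
  L <- nchar(alignment[[1L]])
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  ntot <- ntip + nnode
  root <- ntip + 1L
  tre <- ape::reorder.phylo(tree, "postorder")
  edge <- tre$edge

  INF <- 1e9
  # down[[v]]: 5 x L matrix of subtree costs given node v in each state
  down <- vector("list", ntot)
  for (i in seq_len(ntip)) {
    chars <- strsplit(alignment[[tree$tip.label[i]]], "", fixed = TRUE)[[1]]
    m <- matrix(INF, 5L, L)
    for (s in seq_along(.FIVE_STATES)) {
      allow <- vapply(chars, function(ch) {
        st <- .iupac_sets[[ch]]
        if (is.null(st)) stop("unsupported alignment character: ", ch)
        .FIVE_STATES[s] %in% st
      }, TRUE)
      m[s, allow] <- 0
    }
    down[[i]] <- m
  }
  kids <- split(edge[, 2L], edge[, 1L])
  for (v in unique(edge[, 1L])) down[[v]] <- matrix(0, 5L, L)
  # postorder guarantees children before parents
  for (r in seq_len(nrow(edge))) {
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    dc <- down[[ch]]
    minc <- do.call(pmin, lapply(1:5, function(s) dc[s, ]))
    contrib <- matrix(0, 5L, L)
    for (s in 1:5) contrib[s, ] <- pmin(dc[s, ], minc + 1)
    down[[p]] <- down[[p]] + contrib
  }
  total <- do.call(pmin, lapply(1:5, function(s) down[[root]][s, ]))

  # up[[v]]: cost of the rest of the tree given node v in each state
  up <- vector("list", ntot)
  up[[root]] <- matrix(0, 5L, L)
  for (r in rev(seq_len(nrow(edge)))) {   # preorder
    p <- edge[r, 1L]; ch <- edge[r, 2L]
    sibs <- setdiff(kids[[as.character(p)]], ch)
    Tp <- up[[p]]
    for (b in sibs) {
      db <- down[[b]]
      minb <- do.call(pmin, lapply(1:5, function(s) db[s, ]))
      add <- matrix(0, 5L, L)
      for (s in 1:5) add[s, ] <- pmin(db[s, ], minb + 1)
      Tp <- Tp + add
    }
    minT <- do.call(pmin, lapply(1:5, function(s) Tp[s, ]))
    u <- matrix(0, 5L, L)
    for (s in 1:5) u[s, ] <- pmin(Tp[s, ], minT + 1)
    up[[ch]] <- u
  }

  node_ids <- (ntip + 1L):ntot
  labs <- if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
    tree$node.label else paste0("node", node_ids)
  nodes <- character(length(node_ids))
  for (t in seq_along(node_ids)) {
    v <- node_ids[t]
    tot_v <- down[[v]] + up[[v]]
    chars <- vapply(seq_len(L), function(col) {
      mpr <- .FIVE_STATES[tot_v[, col] <= total[col] + 1e-9]
      .set_to_code(mpr)
    }, "")
    nodes[t] <- paste(chars, collapse = "")
  }
  names(nodes) <- labs
  structure(list(nodes = nodes, score = as.integer(round(total)),
                 tree = tree, alignment = alignment),
            class = "ancestral_alignment")
}

#' @export
print.ancestral_alignment <- function(x, ...) {
  cat("<ancestral_alignment> ", length(x$nodes), " internal node(s), ",
      nchar(x$alignment[[1L]]), " columns, parsimony score ",
      sum(x$score), "\n", sep = "")
  invisible(x)
}

.pw_sub_matrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE)
}

.global_align <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "global",
    substitutionMatrix = .pw_sub_matrix(), gapOpening = 4, gapExtension = 1)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

.identity_frac <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1]]
  cy <- strsplit(y, "", fixed = TRUE)[[1]]
  both <- cx != "-" & cy != "-"
  if (!sum(both)) return(0)
  sum(cx[both] == cy[both]) / sum(both)
}

#' Event calling between two ancestral reconstructions
#'
#' Aligns the reconstructions of the same region at the start and end of a
#' phylogenetic interval (affine-gap global alignment: match 1, mismatch -1,
#' gap open 4, gap extend 1) and classifies every difference segment as an
#' evolutionary event of that interval. An inserted segment matching the
#' sequence immediately left or right of its insertion point (at
#' `tandem_min_identity`) is a tandem duplication (most plastome 'indels'
#' are such dupdels, not bona fide insertions); an insertion matching a
#' distant region of `plastome_context` (identity >= `transposed_min_identity`
#' over at least half its length) is a transposed insertion; an insertion
#' matching nothing is called foreign, mirroring the convention that foreign
#' DNA is delimited at its minimum possible extent.
#'
#' @param anc_start,anc_end nucleotide sequences (reconstructions at interval
#'   start and end, same region and reading frame).
#' @param plastome_context optional sequence searched for transposition
#'   sources (without it, non-tandem insertions are called foreign).
#' @param tandem_min_identity,transposed_min_identity classification
#'   thresholds (defaults 0.9 and 0.7).
#' @param min_identity_floor alignment sanity floor: an aligned identity
#'   below this raises an error rather than returning nonsense events.
#' @return A data frame of event records: `type` (`substitution`,
#'   `tandem_duplication`, `deletion`, `transposed_insertion`,
#'   `foreign_insertion`), `start`, `end` (1-based in the `anc_start` frame;
#'   insertions anchor at the base before the insertion point), `length`,
#'   `detail`.
#' @export
interval_diff <- function(anc_start, anc_end, plastome_context = NULL,
                          tandem_min_identity = 0.9,
                          transposed_min_identity = 0.7,
                          min_identity_floor = 0.5) {
  sa <- .seq_chr(anc_start); se <- .seq_chr(anc_end)
  empty <- data.frame(type = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      detail = character(0), stringsAsFactors = FALSE)
  if (identical(sa, se)) return(empty)
  al <- .global_align(sa, se)
  if (.identity_frac(al$a, al$b) < min_identity_floor)
    stop("sequences do not align above the identity floor (",
         min_identity_floor, "); not the same region?")
  ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
  cb <- strsplit(al$b, "", fixed = TRUE)[[1]]
  state <- ifelse(ca == "-", "I", ifelse(cb == "-", "D",
                  ifelse(ca == cb, "M", "X")))
  r <- rle(state)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  pos_a <- cumsum(ca != "-")   # coordinate in anc_start per column
  pos_b <- cumsum(cb != "-")   # coordinate in anc_end per column
  ev <- list()
  for (t in seq_along(r$values)) {
    v <- r$values[t]
    if (v == "M") next
    i1 <- starts[t]; i2 <- ends[t]
    if (v == "X") {
      for (col in i1:i2)
        ev[[length(ev) + 1L]] <- data.frame(
          type = "substitution", start = pos_a[col], end = pos_a[col],
          length = 1L,
          detail = paste0(ca[col], ">", cb[col]), stringsAsFactors = FALSE)
    } else if (v == "D") {
      ev[[length(ev) + 1L]] <- data.frame(
        type = "deletion", start = pos_a[i1], end = pos_a[i2],
        length = i2 - i1 + 1L,
        detail = paste0("deleted: ", substr(sa, pos_a[i1], pos_a[i2])),
        stringsAsFactors = FALSE)
    } else {
      len <- i2 - i1 + 1L
      jb1 <- pos_b[i1]; jb2 <- pos_b[i2]
      ins <- substr(se, jb1, jb2)
      anchor <- if (i1 > 1L) pos_a[i1 - 1L] else 0L
      type <- "foreign_insertion"
      detail <- "no plastome match"
      left <- if (jb1 - len >= 1L) substr(se, jb1 - len, jb1 - 1L) else ""
      right <- if (jb2 + len <= nchar(se)) substr(se, jb2 + 1L, jb2 + len) else ""
      if ((nchar(left) == len && .str_identity(ins, left) >= tandem_min_identity) ||
          (nchar(right) == len && .str_identity(ins, right) >= tandem_min_identity)) {
        type <- "tandem_duplication"
        detail <- "insert matches adjacent sequence"
      } else if (!is.null(plastome_context)) {
        src <- .find_insert_source(ins, .seq_chr(plastome_context),
                                   transposed_min_identity)
        if (!is.null(src)) {
          type <- "transposed_insertion"
          detail <- sprintf("source %d-%d (%s strand)", src$start, src$end,
                            src$strand)
        }
      }
      ev[[length(ev) + 1L]] <- data.frame(
        type = type, start = anchor, end = anchor, length = len,
        detail = detail, stringsAsFactors = FALSE)
    }
  }
  if (!length(ev)) return(empty)
  out <- do.call(rbind, ev)
  out <- out[order(out$start, out$type), ]
  rownames(out) <- NULL
  out
}

.str_identity <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- min(length(ca), length(cb))
  if (!n) return(0)
  sum(ca[seq_len(n)] == cb[seq_len(n)]) / n
}

# Best local match of an insert against a context sequence (both strands);
# NULL unless identity and coverage thresholds are met.
.find_insert_source <- function(ins, context, min_identity, min_coverage = 0.5) {
  if (nchar(ins) < 8L || nchar(context) < 8L) return(NULL)
  best <- NULL
  for (strand in c("+", "-")) {
    subj <- if (strand == "+") context else .revcomp_chr(context)
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(ins), Biostrings::DNAString(subj), type = "local",
      substitutionMatrix = .pw_sub_matrix(), gapOpening = 4, gapExtension = 1)
    cov <- Biostrings::nchar(Biostrings::pattern(aln)) / nchar(ins)
    idf <- Biostrings::pid(aln, type = "PID2") / 100
    if (cov >= min_coverage && idf >= min_identity &&
        (is.null(best) || Biostrings::score(aln) > best$score)) {
      st <- Biostrings::start(Biostrings::subject(aln))
      en <- Biostrings::end(Biostrings::subject(aln))
      if (strand == "-") {
        n <- nchar(context)
        tmp <- st; st <- n - en + 1L; en <- n - tmp + 1L
      }
      best <- list(start = st, end = en, strand = strand,
                   score = Biostrings::score(aln))
    }
  }
  best
}

#' Find transposed (duplicated) segments within a plastome
#'
#' Detects all pairs of non-overlapping regions of at least `min_len` bases
#' whose similarity exceeds `min_identity`, in the same or inverted
#' orientation, using the same seed-and-chain machinery as
#' [find_inverted_repeats()] (perfect cores of `seed_len` bases chained
#' across short substitution-only gaps). The genome-scale match between the
#' two copies of the large inverted repeat is masked via the annotation when
#' a [generate_plastome()] object (or feature table) is supplied. The
#' designated copy of a pair is the region overlapping an annotated
#' `transposed_copy` feature when one exists; otherwise the pair is reported
#' unpolarized.
#'
#' @param plastome a `synthetic_plastome`, or a sequence (character /
#'   `DNAString`); in the latter case `features` may supply the annotation.
#' @param min_len minimum copy length (default 100).
#' @param min_identity minimum copy/source identity (default 0.9).
#' @param seed_len length of the exact cores anchoring a match (default 16).
#' @param max_gap maximum bridged imperfect stretch (default 50).
#' @param features optional annotation data frame (`type`, `start`, `end`).
#' @return Data frame with `copy_start, copy_end, source_start, source_end,
#'   orientation, length, mismatches, identity, polarized`.
#' @export
find_transposed_copies <- function(plastome, min_len = 100L,
                                   min_identity = 0.9, seed_len = 16L,
                                   max_gap = 50L, features = NULL) {
  if (inherits(plastome, "synthetic_plastome")) {
    features <- plastome$features
    plastome <- plastome$seq
  }
  s <- .seq_chr(plastome)
  n <- nchar(s)
  code <- .dna_code(s)
  frac <- 1 - min_identity
  k <- as.integer(seed_len)
  out <- list()

  # same-strand pairs: diagonal d = q - p
  seeds <- .kmer_join(s, s, k)
  seeds <- seeds[seeds$j > seeds$i, , drop = FALSE]
  if (nrow(seeds)) {
    d <- seeds$j - seeds$i
    pair_ok <- function(dd, t) {
      u <- t + dd
      u <= n && code[t] >= 0L && code[t] == code[u]
    }
    chains <- .chain_runs(d, seeds$i, k, pair_ok, max_gap, frac,
                          function(dd) n - dd)
    if (nrow(chains)) {
      len <- chains$end - chains$start + 1L
      keep <- len >= min_len & len <= chains$group  # non-overlapping copies
      ch <- chains[keep, , drop = FALSE]
      if (nrow(ch)) out[[length(out) + 1L]] <- data.frame(
        a_start = ch$start, a_end = ch$end,
        b_start = ch$start + ch$group, b_end = ch$end + ch$group,
        orientation = "same", length = ch$end - ch$start + 1L,
        mismatches = ch$mismatches, stringsAsFactors = FALSE)
    }
  }

  # inverted pairs: reuse the antidiagonal scan
  inv <- find_inverted_repeats(s, min_stem = max(k, 4L), max_loop = Inf,
                               max_mismatch_frac = frac, max_gap = max_gap)
  inv <- inv[inv$stem_len >= min_len, , drop = FALSE]
  if (nrow(inv)) out[[length(out) + 1L]] <- data.frame(
    a_start = inv$left_start, a_end = inv$left_end,
    b_start = inv$right_start, b_end = inv$right_end,
    orientation = "inverted", length = inv$stem_len,
    mismatches = inv$mismatches, stringsAsFactors = FALSE)

  if (!length(out))
    return(.empty_copies())
  res <- do.call(rbind, out)

  # mask the trivial IR-vs-IR genome-scale self match
  if (!is.null(features)) {
    ir <- features[features$type == "inverted_repeat", , drop = FALSE]
    if (nrow(ir) == 2L) {
      within <- function(a, b, f) a >= ir$start[f] - 5L & b <= ir$end[f] + 5L
      trivial <- (within(res$a_start, res$a_end, 1L) &
                  within(res$b_start, res$b_end, 2L)) |
                 (within(res$a_start, res$a_end, 2L) &
                  within(res$b_start, res$b_end, 1L))
      res <- res[!trivial, , drop = FALSE]
    }
  }
  if (!nrow(res)) return(.empty_copies())

  # polarize using annotated transposed copies where available
  cp <- if (!is.null(features))
    features[features$type == "transposed_copy", , drop = FALSE]
  else NULL
  pol <- function(a1, a2, b1, b2) {
    if (is.null(cp) || !nrow(cp)) return(0L)
    hit_a <- any(pmin(a2, cp$end) - pmax(a1, cp$start) + 1L > 0.5 * (a2 - a1 + 1L))
    hit_b <- any(pmin(b2, cp$end) - pmax(b1, cp$start) + 1L > 0.5 * (b2 - b1 + 1L))
    if (hit_a && !hit_b) 1L else if (hit_b && !hit_a) 2L else 0L
  }
  rows <- lapply(seq_len(nrow(res)), function(i) {
    w <- pol(res$a_start[i], res$a_end[i], res$b_start[i], res$b_end[i])
    if (w == 2L) {
      data.frame(copy_start = res$b_start[i], copy_end = res$b_end[i],
                 source_start = res$a_start[i], source_end = res$a_end[i],
                 orientation = res$orientation[i], length = res$length[i],
                 mismatches = res$mismatches[i],
                 identity = 1 - res$mismatches[i] / res$length[i],
                 polarized = TRUE, stringsAsFactors = FALSE)
    } else {
      data.frame(copy_start = res$a_start[i], copy_end = res$a_end[i],
                 source_start = res$b_start[i], source_end = res$b_end[i],
                 orientation = res$orientation[i], length = res$length[i],
                 mismatches = res$mismatches[i],
                 identity = 1 - res$mismatches[i] / res$length[i],
                 polarized = w == 1L, stringsAsFactors = FALSE)
    }
  })
  res <- do.call(rbind, rows)
  res <- res[order(-res$length, res$copy_start), ]
  rownames(res) <- NULL
  res
}

.empty_copies <- function() {
  data.frame(copy_start = integer(0), copy_end = integer(0),
             source_start = integer(0), source_end = integer(0),
             orientation = character(0), length = integer(0),
             mismatches = integer(0), identity = numeric(0),
             polarized = logical(0), stringsAsFactors = FALSE)
}

#' Count shared and unique derived point mutations of a transposed copy
#'
#' Polarizes the point differences between a transposed copy and its source
#' region against an explicit ancestral reference (the reconstructed
#' pre-duplication state): a state differing from the reference is derived.
#' Returns the number of positions where copy and source share the same
#' derived state (evidence of very recent duplicative transposition or of
#' concerted evolution), where only the copy is derived, and where only the
#' source is derived (derived states present in the contemporary source but
#' absent from the copy are evidence that the copy is relatively ancient).
#'
#' @param copy,source,ancestral_ref nucleotide sequences; aligned per column
#'   when equal length, otherwise aligned to the reference first.
#' @return Named integer vector `c(shared_derived, copy_only, source_only)`.
#' @export
count_shared_derived_mutations <- function(copy, source, ancestral_ref) {
  sc <- .seq_chr(copy); ss <- .seq_chr(source); sr <- .seq_chr(ancestral_ref)
  if (nchar(sc) != nchar(sr) || nchar(ss) != nchar(sr)) {
    ac <- .global_align(sc, sr); as_ <- .global_align(ss, sr)
    proj <- function(al) {
      ca <- strsplit(al$a, "", fixed = TRUE)[[1]]
      cb <- strsplit(al$b, "", fixed = TRUE)[[1]]
      keep <- cb != "-"
      ca[keep]
    }
    cc <- proj(ac); cs <- proj(as_)
    cr <- strsplit(sr, "", fixed = TRUE)[[1]]
  } else {
    cc <- strsplit(sc, "", fixed = TRUE)[[1]]
    cs <- strsplit(ss, "", fixed = TRUE)[[1]]
    cr <- strsplit(sr, "", fixed = TRUE)[[1]]
  }
  point <- cc != "-" & cs != "-" & cr != "-"
  dc <- point & cc != cr
  ds <- point & cs != cr
  shared <- sum(dc & ds & cc == cs)
  c(shared_derived = as.integer(shared),
    copy_only = as.integer(sum(dc & !ds)),
    source_only = as.integer(sum(ds & !dc)))
}

#' Classify the relative age of a transposed copy
#'
#' @param counts output of [count_shared_derived_mutations()].
#' @return `"recent_or_concerted"` when any derived state is shared (the
#'   data cannot distinguish a very recent transposition from concerted
#'   evolution with the source); `"ancient"` when the copy lacks derived
#'   states now present in the contemporary source; `"indeterminate"` when
#'   there is no polarizable signal.
#' @export
classify_copy_age <- function(counts) {
  if (any(counts < 0)) stop("counts must be non-negative")
  sh <- counts[["shared_derived"]]; so <- counts[["source_only"]]
  if (sh > 0L) "recent_or_concerted"
  else if (so > 0L) "ancient"
  else "indeterminate"
}

#' Date a junction via a secondary transposition
#'
#' A secondary transposed copy whose source region strictly spans an older
#' rearrangement junction preserves evidence of that junction: the junction
#' must predate the copy. Requires at least `min_flank` bases of source
#' region on each side of the junction.
#'
#' @param copy one row of [find_transposed_copies()] output (or any list
#'   with `source_start`, `source_end`), in plastome coordinates.
#' @param junction 1-based plastome coordinate of the junction.
#' @param min_flank minimum flank on each side (default 50).
#' @param genome_len optional total length for bounds checking.
#' @return `"junction_predates_copy"` or `"uninformative"`.
#' @export
secondary_transposition_order <- function(copy, junction, min_flank = 50L,
                                          genome_len = NULL) {
  if (!is.null(genome_len) && (junction < 1L || junction > genome_len))
    stop("junction outside the plastome")
  if (copy$source_start + min_flank <= junction &&
      junction <= copy$source_end - min_flank)
    "junction_predates_copy"
  else
    "uninformative"
}
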