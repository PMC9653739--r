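# Sequence-level detection of inverted repeats, hairpins and
# stem-loop-ligation signatures.
#
# An inverted-repeat hit pairs position p of the left arm with position
# q = c - p of the right arm, where c is constant for a hit (all base pairs
# of one stem lie on a single "antidiagonal"). A hit is a chain of perfect
# pairing cores, each at least min_stem long, bridged across short imperfect
# gaps while the total substitution count stays within the mismatch budget
# floor(max_mismatch_frac * stem_len). Arms are gap-free by construction
# (substitutions only), both hit ends are matching base pairs, and only
# chains not contained in a longer feasible chain are reported.

.DNA_CODE <- c(A = 0L, C = 1L, G = 2L, T = 3L)

.seq_chr <- function(seq) {
  if (methods::is(seq, "XString") || methods::is(seq, "XStringSet"))
    seq <- as.character(seq)
  if (length(seq) != 1L) stop("expected a single sequence")
  toupper(seq)
}

.dna_code <- function(seq) {
  v <- .DNA_CODE[strsplit(seq, "", fixed = TRUE)[[1]]]
  v[is.na(v)] <- -100L  # N and friends never pair and never match
  unname(v)
}

.revcomp_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGTacgtN", "TGCAtgcaN", seq), "",
                     fixed = TRUE)[[1]]), collapse = "")
}

# All seed pairs (i, j) such that the k-mer of `a` at i equals the k-mer of
# `b` at j, via a hash join on the k-mer strings.
.kmer_join <- function(a, b, k) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k)
    return(data.frame(i = integer(0), j = integer(0)))
  ka <- substring(a, 1:(na - k + 1L), k:na)
  kb <- substring(b, 1:(nb - k + 1L), k:nb)
  fa <- split(seq_along(ka), ka)
  fb <- split(seq_along(kb), kb)
  common <- intersect(names(fa), names(fb))
  if (!length(common))
    return(data.frame(i = integer(0), j = integer(0)))
  ii <- jj <- vector("list", length(common))
  for (t in seq_along(common)) {
    u <- fa[[common[t]]]; v <- fb[[common[t]]]
    ii[[t]] <- rep(u, each = length(v))
    jj[[t]] <- rep(v, times = length(u))
  }
  data.frame(i = unlist(ii), j = unlist(jj))
}

# Collapse seed start positions (grouped by diagonal) into maximal runs,
# then chain runs across short gaps under the mismatch budget. `pair_ok`
# reports whether a left-arm position still pairs (boundary extension and
# gap evaluation). Returns a data.frame of chains (left-arm extent + counts).
.chain_runs <- function(groups, starts, k, pair_ok, max_gap,
                        max_mismatch_frac, p_max_of_group) {
  o <- order(groups, starts)
  groups <- groups[o]; starts <- starts[o]
  new_run <- c(TRUE, diff(starts) != 1L | diff(groups) != 0L)
  run_first <- which(new_run)
  run_last <- c(run_first[-1L] - 1L, length(starts))
  a <- starts[run_first]                # run start (left arm)
  b <- starts[run_last] + k - 1L        # run end (left arm, inclusive)
  g <- groups[run_first]
  # boundary extension: runs can grow past seed resolution at sequence ends
  for (r in seq_along(a)) {
    lim <- p_max_of_group(g[r])
    while (a[r] > 1L && pair_ok(g[r], a[r] - 1L)) a[r] <- a[r] - 1L
    while (b[r] < lim && pair_ok(g[r], b[r] + 1L)) b[r] <- b[r] + 1L
  }
  # fast path: groups holding a single run need no chaining
  cnt <- table(g)
  single <- g %in% as.integer(names(cnt)[cnt == 1L])
  out <- list()
  if (any(single))
    out[[1L]] <- data.frame(group = g[single], start = a[single],
                            end = b[single],
                            mismatches = rep(0L, sum(single)))
  for (grp in unique(g[!single])) {
    sel <- which(g == grp)
    aa <- a[sel]; bb <- b[sel]
    ord <- order(aa)
    aa <- aa[ord]; bb <- bb[ord]
    m <- length(aa)
    # mismatches inside each gap between consecutive runs
    gap_mm <- rep(NA_integer_, m)  # gap_mm[t] = mismatches between run t-1 and t
    if (m > 1L) for (t in 2:m) {
      if (aa[t] - bb[t - 1L] - 1L > max_gap) next  # unbridgeable anyway
      gp <- (bb[t - 1L] + 1L):(aa[t] - 1L)
      gap_mm[t] <- sum(!vapply(gp, function(p) pair_ok(grp, p), TRUE))
    }
    # for each start run, the furthest end run forming a feasible chain:
    # all bridged gaps <= max_gap and total mismatches within the budget
    # for the full chain span (an infeasible shorter chain does not block a
    # feasible longer one)
    best_end <- integer(m)
    for (s in seq_len(m)) {
      mm <- 0L; e <- s; t <- s
      while (t < m) {
        gap <- aa[t + 1L] - bb[t] - 1L
        if (gap > max_gap) break
        mm <- mm + gap_mm[t + 1L]
        t <- t + 1L
        if (mm <= floor(max_mismatch_frac * (bb[t] - aa[s] + 1L))) e <- t
      }
      best_end[s] <- e
    }
    # drop chains contained in a feasible chain with an earlier start
    keep <- best_end > c(-1L, cummax(best_end)[-m])
    for (s in which(keep)) {
      e <- best_end[s]
      mm <- if (e > s) sum(gap_mm[(s + 1L):e]) else 0L
      out[[length(out) + 1L]] <- data.frame(
        group = grp, start = aa[s], end = bb[e], mismatches = mm)
    }
  }
  if (!length(out))
    return(data.frame(group = integer(0), start = integer(0),
                      end = integer(0), mismatches = integer(0)))
  do.call(rbind, out)
}

#' Find dispersed inverted repeats (stem-loops)
#'
#' Scans a nucleotide sequence for pairs of segments in inverted orientation
#' (the left arm pairing with the reverse complement of the right arm). Hits
#' are chains of perfect pairing cores of at least `min_stem` bases bridged
#' across gaps of up to `max_gap` substitutions-only positions, subject to a
#' total mismatch budget of `floor(max_mismatch_frac * stem_len)`; both hit
#' ends are matching base pairs and only hits not contained in a longer
#' feasible hit are reported. Coordinates are 1-based inclusive on the
#' forward strand.
#'
#' @param seq a nucleotide sequence (character or `DNAString`) over
#'   `A,C,G,T,N`; `N` never pairs.
#' @param min_stem minimum stem length in bases (and length of the perfect
#'   cores anchoring a hit); must be >= 4.
#' @param max_loop maximum number of bases between the two arms.
#' @param max_mismatch_frac maximum fraction of substitutions within the stem.
#' @param max_gap maximum length of a single imperfect stretch bridged
#'   between two perfect cores.
#' @return A data frame sorted by (stem_len desc, loop_len asc, leftmost)
#'   with columns `left_start, left_end, right_start, right_end, stem_len,
#'   loop_len, mismatches, identity_fraction`.
#' @export
find_inverted_repeats <- function(seq, min_stem = 6L, max_loop = Inf,
                                  max_mismatch_frac = 0.1, max_gap = 50L) {
  s <- .seq_chr(seq)
  n <- nchar(s)
  if (min_stem < 4L) stop("min_stem must be at least 4")
  if (max_mismatch_frac < 0 || max_mismatch_frac >= 1)
    stop("max_mismatch_frac must be in [0, 1)")
  if (max_loop < 0) stop("max_loop must be non-negative")
  empty <- data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      mismatches = integer(0), identity_fraction = numeric(0))
  if (n < 2L * min_stem) return(empty)
  code <- .dna_code(s)
  k <- as.integer(min_stem)
  seeds <- .kmer_join(s, .revcomp_chr(s), k)
  if (!nrow(seeds)) return(empty)
  # seed (i on forward, j on revcomp): right arm starts at q = n - j - k + 2
  p <- seeds$i
  q <- n - seeds$j - k + 2L
  cdiag <- p + q + k - 1L               # antidiagonal: pairs (t, cdiag - t)
  # left arm strictly before right arm, and loop within bounds at seed level
  ok <- p + k - 1L < q
  p <- p[ok]; cdiag <- cdiag[ok]
  if (!length(p)) return(empty)
  dup <- duplicated(paste(cdiag, p))
  p <- p[!dup]; cdiag <- cdiag[!dup]

  pair_ok <- function(cc, t) {
    u <- cc - t
    u >= 1L && u <= n && u > t && (code[t] + code[u] == 3L)
  }
  p_max <- function(cc) as.integer(floor((cc - 1L) / 2L))
  chains <- .chain_runs(cdiag, p, k, pair_ok, max_gap, max_mismatch_frac,
                        p_max)
  if (!nrow(chains)) return(empty)
  left_start <- chains$start
  left_end <- chains$end
  right_start <- chains$group - chains$end
  right_end <- chains$group - chains$start
  stem_len <- left_end - left_start + 1L
  loop_len <- right_start - left_end - 1L
  keep <- stem_len >= min_stem & loop_len >= 0L & loop_len <= max_loop
  out <- data.frame(left_start = left_start, left_end = left_end,
                    right_start = right_start, right_end = right_end,
                    stem_len = stem_len, loop_len = loop_len,
                    mismatches = chains$mismatches,
                    identity_fraction = 1 - chains$mismatches / stem_len)[keep, ]
  out <- out[order(-out$stem_len, out$loop_len, out$left_start), ]
  rownames(out) <- NULL
  out
}

#' Find hairpins (short-loop inverted repeats)
#'
#' [find_inverted_repeats()] restricted to loops of at most `max_loop` bases
#' (default 50): the scale at which the two arms of a separated strand can
#' fold back and pair into a miniature stem-loop structure.
#'
#' @inheritParams find_inverted_repeats
#' @return As [find_inverted_repeats()].
#' @export
find_hairpins <- function(seq, min_stem = 6L, max_loop = 50L,
                          max_mismatch_frac = 0.1, max_gap = 50L) {
  find_inverted_repeats(seq, min_stem = min_stem, max_loop = max_loop,
                        max_mismatch_frac = max_mismatch_frac,
                        max_gap = max_gap)
}

#' Score a candidate ligation site
#'
#' Compares a donor flank against an acceptor insertion site by counting
#' identical nucleotides in the best-matching pair of windows of
#' `window_len` bases over all relative offsets. A near-perfect coincidental
#' match (e.g. 7 of 8) at an insertion site is the signature expected when a
#' stem-loop acted as a molecular jig for the ligation.
#'
#' @param donor_flank,acceptor_site nucleotide sequences, each at least
#'   `window_len` long.
#' @param window_len window size in bases (default 8).
#' @return A list with `window_len`, `matches` (best window identity count),
#'   `offset` (acceptor window start minus donor window start), and the
#'   1-based window starts `donor_start`, `acceptor_start`.
#' @export
score_ligation_site <- function(donor_flank, acceptor_site, window_len = 8L) {
  a <- .dna_code(.seq_chr(donor_flank))
  b <- .dna_code(.seq_chr(acceptor_site))
  w <- as.integer(window_len)
  if (length(a) < w || length(b) < w)
    stop("both sequences must be at least window_len bases")
  best <- list(matches = -1L)
  for (s in (-(length(a) - w)):(length(b) - w)) {
    # windows: donor at i, acceptor at i + s
    i_lo <- max(1L, 1L - s); i_hi <- min(length(a) - w + 1L, length(b) - w + 1L - s)
    if (i_lo > i_hi) next
    m <- rep(NA, length(a))
    valid <- seq_len(length(a))
    valid <- valid[valid + s >= 1L & valid + s <= length(b)]
    m[valid] <- a[valid] == b[valid + s]
    for (i in i_lo:i_hi) {
      cnt <- sum(m[i:(i + w - 1L)], na.rm = TRUE)
      if (cnt > best$matches)
        best <- list(matches = as.integer(cnt), offset = s, donor_start = i,
                     acceptor_start = i + s)
    }
  }
  list(window_len = w, matches = best$matches, offset = best$offset,
       donor_start = best$donor_start, acceptor_start = best$acceptor_start)
}

#' Detect a stem-loop-ligation signature at a junction
#'
#' A rearrangement junction located inside an expanded palindromic sequence
#' (a hairpin whose stem spans the junction) is the signature left behind by
#' stem-loop ligation: the hairpin that held the broken ends in place during
#' repair remains, enlarged, around the new junction.
#'
#' @param junction_seq nucleotide sequence around the junction.
#' @param junction_pos 1-based coordinate of the junction within
#'   `junction_seq` (the junction lies between `junction_pos` and
#'   `junction_pos + 1`); must be interior.
#' @param min_stem minimum spanning-hairpin stem length (default 6).
#' @param max_loop maximum hairpin loop (default 50).
#' @param max_mismatch_frac stem mismatch tolerance.
#' @return A list with `detected` (logical) and `evidence` (the spanning
#'   hairpin row(s), largest stem first; zero rows when not detected).
#' @export
detect_ligation_signature <- function(junction_seq, junction_pos,
                                      min_stem = 6L, max_loop = 50L,
                                      max_mismatch_frac = 0.1) {
  s <- .seq_chr(junction_seq)
  if (junction_pos < 1L || junction_pos >= nchar(s))
    stop("junction_pos must be interior to junction_seq")
  hp <- find_hairpins(s, min_stem = min_stem, max_loop = max_loop,
                      max_mismatch_frac = max_mismatch_frac)
  span <- hp[hp$left_start <= junction_pos & hp$right_end > junction_pos, ]
  rownames(span) <- NULL
  list(detected = nrow(span) > 0L, evidence = span)
}

#' Classify the mechanism behind an inversion's endpoints
#'
#' Weighs endpoint evidence for the two competing models: the symmetrical
#' stem-loop model (the ancestral sequence carried flanking repeats in
#' inverted orientation at the two endpoints, which paired and recombined)
#' and the asymmetrical disruption-rescue model (a foreign-DNA insertion
#' disrupted one endpoint and an unrelated ligation -- with seemingly
#' arbitrary ligation points, deletions or tandem duplications -- rescued an
#' intact molecule at the other).
#'
#' Evidence codes: `inverted_flanking_repeat`, `foreign_insertion_at_endpoint`,
#' `arbitrary_ligation`, `tandem_duplication_at_endpoint`,
#' `deletion_at_endpoint`, `expanded_palindrome_junction`.
#'
#' @param endpointA_evidence,endpointB_evidence character vectors of evidence
#'   codes gathered at the two endpoints (e.g. from
#'   [find_inverted_repeats()] and [interval_diff()] calls).
#' @param ancestral_flanks optional list with elements `A` and `B`: the
#'   ancestral flanking sequences at the two endpoints. When supplied, an
#'   inverted match of at least `min_stem` bases between the two flanks adds
#'   `inverted_flanking_repeat` to both endpoints.
#' @param min_stem minimum flank match treated as a stem (default 6; the
#'   shortest stem implicated in a documented stem-loop inversion is 7 bp).
#' @return A list with `mechanism` (`"stem_loop"`, `"disruption_rescue"` or
#'   `"ambiguous"`) and `evidence` (per-endpoint code lists).
#' @export
classify_mechanism <- function(endpointA_evidence = character(0),
                               endpointB_evidence = character(0),
                               ancestral_flanks = NULL, min_stem = 6L) {
  evA <- unique(as.character(endpointA_evidence))
  evB <- unique(as.character(endpointB_evidence))
  if (!is.null(ancestral_flanks)) {
    m <- .longest_inverted_match(ancestral_flanks$A, ancestral_flanks$B)
    if (m >= min_stem) {
      evA <- union(evA, "inverted_flanking_repeat")
      evB <- union(evB, "inverted_flanking_repeat")
    }
  }
  asym <- c("arbitrary_ligation", "tandem_duplication_at_endpoint",
            "deletion_at_endpoint")
  has <- function(ev, code) code %in% ev
  mech <- "ambiguous"
  if (has(evA, "inverted_flanking_repeat") && has(evB, "inverted_flanking_repeat")) {
    mech <- "stem_loop"
  } else if ((has(evA, "foreign_insertion_at_endpoint") && any(asym %in% evB)) ||
             (has(evB, "foreign_insertion_at_endpoint") && any(asym %in% evA))) {
    mech <- "disruption_rescue"
  }
  list(mechanism = mech, evidence = list(A = evA, B = evB))
}

# Longest exact segment of `a` matching the reverse complement of a segment
# of `b` (simple O(len_a * len_b) run table; flanks are short).
.longest_inverted_match <- function(a, b) {
  if (is.null(a) || is.null(b)) return(0L)
  x <- .dna_code(.seq_chr(a))
  y <- rev(3L - .dna_code(.seq_chr(b)))   # revcomp in code space
  best <- 0L
  prev <- integer(length(y))
  for (i in seq_along(x)) {
    cur <- integer(length(y))
    hit <- which(y == x[i])
    if (length(hit)) {
      cur[hit] <- 1L
      h2 <- hit[hit > 1L]
      cur[h2] <- prev[h2 - 1L] + 1L
      best <- max(best, cur)
    }
    prev <- cur
  }
  as.integer(best)
}
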