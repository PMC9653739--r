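# Seeded generator of annotated synthetic plastomes with planted
# rearrangement events, plus the packaged block-order fixtures.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.rand_dna <- function(n, gc = 0.37) {
  if (n <= 0L) return("")
  paste(sample(c("A", "T", "G", "C"), n, replace = TRUE,
               prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2)),
        collapse = "")
}

#' Synthetic plastome configuration
#'
#' Describes a quadripartite plastome: large single-copy (LSC) and small
#' single-copy (SSC) regions separated by two exact reverse-complement
#' copies of the inverted repeat (IR). Default sizes are desk-scale (a few
#' tens of kilobases) rather than full plastome scale; detection behaviour
#' is length-scale free, so tests run on these smaller replicas.
#'
#' @param lsc_len,ssc_len,ir_len region lengths in bases.
#' @param gc_fraction genomic GC content (plastomes sit near 0.37).
#' @param seed integer seed; the emitted genome is a pure function of the
#'   configuration including this seed.
#' @param genes optional data frame (`gene`, `region`, `rel_pos`, `len`)
#'   overriding the default roster.
#' @return An object of class `plastome_config`.
#' @export
plastome_config <- function(lsc_len = 20000L, ssc_len = 3000L, ir_len = 4000L,
                            gc_fraction = 0.37, seed = 1L, genes = NULL) {
  if (min(lsc_len, ssc_len, ir_len) < 500L)
    stop("regions must be at least 500 bases")
  if (is.null(genes)) genes <- .default_gene_roster()
  structure(list(lsc_len = as.integer(lsc_len), ssc_len = as.integer(ssc_len),
                 ir_len = as.integer(ir_len), gc_fraction = gc_fraction,
                 seed = as.integer(seed), genes = genes),
            class = "plastome_config")
}

# Gene anchors of the ancestral LSC in their canonical order, plus the IR
# genes involved in duplicative transpositions. Positions are fractions of
# their region; lengths are nominal.
.default_gene_roster <- function() {
  data.frame(
    gene = c("psbA", "trnK", "trnG", "trnR", "rpoB", "trnC", "rps4",
             "trnT", "ndhC", "trnV", "rbcL", "psaI",
             "rpl23", "rps12_int1B", "ycf1"),
    region = c(rep("LSC", 12), "IRa", "IRa", "SSC"),
    rel_pos = c(0.02, 0.07, 0.13, 0.16, 0.24, 0.29, 0.44, 0.47, 0.58,
                0.61, 0.72, 0.90, 0.30, 0.60, 0.40),
    len = c(300L, 75L, 75L, 75L, 600L, 75L, 300L, 75L, 300L, 75L, 600L,
            120L, 250L, 230L, 400L),
    strand = c("+", "-", "+", "+", "-", "-", "+", "+", "+", "-", "+", "+",
               "+", "+", "+"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic annotated plastome
#'
#' Emits a deterministic random genome with the quadripartite layout
#' `LSC | IRa | SSC | IRb` (IRb the exact reverse complement of IRa), a
#' gene annotation, and an initially empty truth record of planted events.
#' The same configuration always yields byte-identical output.
#'
#' @param config a [plastome_config()].
#' @return An object of class `synthetic_plastome`: list with `seq`
#'   (character), `features` (data frame: `type, name, start, end, strand`),
#'   `config` and `truth` (list of planted events).
#' @export
generate_plastome <- function(config) {
  stopifnot(inherits(config, "plastome_config"))
  .with_seed(config$seed, {
    lsc <- .rand_dna(config$lsc_len, config$gc_fraction)
    ira <- .rand_dna(config$ir_len, config$gc_fraction)
    ssc <- .rand_dna(config$ssc_len, config$gc_fraction)
  })
  irb <- .revcomp_chr(ira)
  seq <- paste0(lsc, ira, ssc, irb)
  off <- c(LSC = 0L, IRa = config$lsc_len,
           SSC = config$lsc_len + config$ir_len,
           IRb = config$lsc_len + config$ir_len + config$ssc_len)
  len <- c(LSC = config$lsc_len, IRa = config$ir_len, SSC = config$ssc_len,
           IRb = config$ir_len)
  regions <- data.frame(
    type = c("region", "inverted_repeat", "region", "inverted_repeat"),
    name = names(off), start = off + 1L, end = off + len,
    strand = "+", stringsAsFactors = FALSE)
  g <- config$genes
  gstart <- off[g$region] + pmax(1L, as.integer(round(g$rel_pos * len[g$region])))
  genes <- data.frame(type = "gene", name = g$gene, start = gstart,
                      end = gstart + g$len - 1L, strand = g$strand,
                      stringsAsFactors = FALSE)
  # gene lengths are nominal: at small desk scales they are truncated so
  # annotations stay within their region and non-overlapping
  region_end <- off[g$region] + len[g$region]
  ov <- order(genes$start)
  nxt <- c(genes$start[ov][-1L] - 1L, .Machine$integer.max)
  genes$end[ov] <- pmin(genes$end[ov], nxt, region_end[ov])
  if (any(genes$end < genes$start))
    stop("gene roster does not fit the configured regions")
  features <- rbind(regions, genes)
  rownames(features) <- NULL
  structure(list(seq = seq, features = features, config = config,
                 truth = list()), class = "synthetic_plastome")
}

#' @export
print.synthetic_plastome <- function(x, ...) {
  cat("<synthetic_plastome> ", nchar(x$seq), " bp (LSC ", x$config$lsc_len,
      " | IR ", x$config$ir_len, " x2 | SSC ", x$config$ssc_len, "), ",
      length(x$truth), " planted event(s)\n", sep = "")
  invisible(x)
}

# splice `insert` into `seq` after position `at` (0 allowed)
.splice <- function(seq, at, insert) {
  paste0(substr(seq, 1L, at), insert, substr(seq, at + 1L, nchar(seq)))
}

.shift_features <- function(features, at, delta) {
  features$start <- ifelse(features$start > at, features$start + delta,
                           features$start)
  features$end <- ifelse(features$end > at, features$end + delta,
                         features$end)
  features
}

.substr_set <- function(seq, pos, chars) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  v[pos] <- chars
  paste(v, collapse = "")
}

# Break accidental pairing runs on the planted antidiagonal `cc` over
# left-arm positions `window` (which must lie outside the planted arms):
# any run of >= 4 consecutive pairing positions gets its base substituted,
# so no perfect core can extend or bridge into the planted stem.
.break_pairing_runs <- function(seq, cc, window, protect) {
  code <- .dna_code(seq)
  n <- nchar(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  run <- 0L
  for (p in window) {
    q <- cc - p
    if (p < 1L || q < 1L || q > n || q <= p) { run <- 0L; next }
    if (code[p] + code[q] == 3L) {
      run <- run + 1L
      if (run >= 4L && !(p %in% protect) && !(q %in% protect)) {
        v[p] <- chartr("ACGT", "CAAA", v[p])  # breaks the pairing
        code[p] <- .DNA_CODE[v[p]]
        run <- 0L
      }
    } else run <- 0L
  }
  paste(v, collapse = "")
}

#' Plant a stem-loop inversion
#'
#' Inserts an inverted-repeat pair (arms of `stem_len` bases, the right arm
#' carrying `mismatches` substitutions) flanking a stretch of `loop_len`
#' existing bases, then inverts the enclosed segment -- the sequence-level
#' signature of an inversion mediated by flanking repeats in inverted
#' orientation. Flanking bases are adjusted so that the planted repeat is
#' exactly recoverable: immediate neighbours do not pair and accidental
#' pairing cores on the planted antidiagonal near the arms are broken.
#' Mismatches are spread evenly so perfect cores between them stay at least
#' 12 bases (requires `stem_len >= 12 * (mismatches + 1)`).
#'
#' @param genome a `synthetic_plastome`.
#' @param stem_len,loop_len,mismatches planted repeat parameters.
#' @param at 1-based position after which the left arm is inserted (default:
#'   centred in the LSC).
#' @param seed RNG seed for the arm sequence (default derived from the
#'   genome configuration and the number of events already planted).
#' @return List with `genome` (modified) and `event` (truth record with
#'   arm coordinates and the inverted interval).
#' @export
plant_stem_loop_inversion <- function(genome, stem_len, loop_len,
                                      mismatches = 0L, at = NULL,
                                      seed = NULL) {
  stopifnot(inherits(genome, "synthetic_plastome"))
  stem_len <- as.integer(stem_len); loop_len <- as.integer(loop_len)
  if (mismatches > 0L && stem_len < 12L * (mismatches + 1L))
    stop("stem too short to space ", mismatches, " mismatches recoverably")
  lsc <- genome$config$lsc_len
  if (is.null(at)) at <- as.integer(max(200L, floor((lsc - loop_len) / 2)) )
  if (at < 100L || at + loop_len + 2L * stem_len + 100L > lsc)
    stop("not enough room in the LSC to plant the stem-loop inversion")
  if (is.null(seed)) seed <- genome$config$seed * 1009L + length(genome$truth) + 1L
  arm <- .with_seed(seed, .rand_dna(stem_len, genome$config$gc_fraction))
  arm_rc <- .revcomp_chr(arm)
  if (mismatches > 0L) {
    pos <- as.integer(round(seq(7L, stem_len - 6L, length.out = mismatches)))
    v <- strsplit(arm_rc, "", fixed = TRUE)[[1]]
    comp_of <- chartr("ACGT", "TGCA", v[pos])
    # pick a base that neither matches the old base nor pairs with the arm
    v[pos] <- vapply(seq_along(pos), function(i)
      setdiff(c("A", "C", "G", "T"), c(v[pos[i]], comp_of[i]))[1L], "")
    arm_rc <- paste(v, collapse = "")
  }
  seq <- genome$seq
  loop_seq <- substr(seq, at + 1L, at + loop_len)
  new_mid <- paste0(arm, .revcomp_chr(loop_seq), arm_rc)
  seq <- paste0(substr(seq, 1L, at), new_mid,
                substr(seq, at + loop_len + 1L, nchar(seq)))
  left_start <- at + 1L
  left_end <- at + stem_len
  right_start <- at + stem_len + loop_len + 1L
  right_end <- right_start + stem_len - 1L
  cc <- left_start + right_end   # planted antidiagonal
  # guard the immediate outer and inner neighbours, then clean the
  # surrounding antidiagonal so extension/bridging is impossible
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  guard <- function(p, q) {
    if (p >= 1L && q <= length(v) &&
        chartr("ACGT", "TGCA", v[p]) == v[q])
      v[p] <<- setdiff(c("A", "C", "G", "T"),
                       c(v[p], chartr("ACGT", "TGCA", v[q])))[1L]
  }
  guard(left_start - 1L, right_end + 1L)
  guard(left_end + 1L, right_start - 1L)
  seq <- paste(v, collapse = "")
  protect <- c(left_start:left_end)
  seq <- .break_pairing_runs(seq, cc, (left_start - 70L):(left_start - 1L), protect)
  seq <- .break_pairing_runs(seq, cc, (left_end + 1L):(left_end + 70L), protect)
  genome$seq <- seq
  genome$features <- .shift_features(genome$features, at, 2L * stem_len)
  ev <- list(type = "stem_loop_inversion", stem_len = stem_len,
             loop_len = loop_len, mismatches = as.integer(mismatches),
             left_arm = c(left_start, left_end),
             right_arm = c(right_start, right_end),
             inverted_interval = c(left_end + 1L, right_start - 1L))
  genome$truth <- c(genome$truth, list(ev))
  list(genome = genome, event = ev)
}

# Foreign (extra-plastid) segment carrying an ORF, at shifted GC, rejection
# sampled so no 14-mer (either strand) is shared with the host.
.random_foreign <- function(host, foreign_len, orf_len, gc) {
  orf_len <- 3L * max(2L, as.integer(floor(orf_len / 3)))
  k <- 14L
  host_k <- c(substring(host, 1:(nchar(host) - k + 1L), k:nchar(host)))
  rc <- .revcomp_chr(host)
  host_k <- unique(c(host_k, substring(rc, 1:(nchar(rc) - k + 1L), k:nchar(rc))))
  for (try in 1:50) {
    ncod <- orf_len / 3L - 2L
    codons <- character(0)
    if (ncod > 0L) {
      all_cod <- apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                   c("A","C","G","T")), 1, paste, collapse = "")
      ok_cod <- setdiff(all_cod, c("TAA", "TAG", "TGA"))
      codons <- sample(ok_cod, ncod, replace = TRUE)
    }
    orf <- paste0("ATG", paste(codons, collapse = ""), "TAA")
    pad <- foreign_len - nchar(orf)
    if (pad < 0L) stop("orf_len exceeds foreign_len")
    pre <- .rand_dna(floor(pad / 2), gc)
    post <- .rand_dna(pad - floor(pad / 2), gc)
    fr <- paste0(pre, orf, post)
    frk <- substring(fr, 1:(nchar(fr) - k + 1L), k:nchar(fr))
    if (!any(frk %in% host_k)) return(fr)
  }
  stop("could not sample a plastome-dissimilar foreign segment")
}

#' Plant a disruption-rescue inversion
#'
#' Emulates the asymmetric mechanism in which a foreign-DNA insertion
#' disrupts the plastome at one inversion endpoint and an unrelated ligation
#' rescues an intact molecule at the other, with an associated deletion
#' and/or tandem duplication at the rescue endpoint. A segment of the LSC is
#' inverted; a GC-shifted foreign segment carrying an open reading frame is
#' inserted at the disruption junction; `del_len` bases are deleted at the
#' rescue junction and `tandem_dup_len` bases of nearby flank are tandemly
#' duplicated. With all lengths zero the event degenerates to a bare
#' inversion. The truth record carries before/after copies of the collinear
#' rescue-flank window, ready for [interval_diff()], and per-endpoint
#' evidence codes for [classify_mechanism()].
#'
#' @param genome a `synthetic_plastome`.
#' @param foreign_len,orf_len foreign segment and ORF lengths (0 = none).
#' @param del_len,tandem_dup_len rescue-endpoint alteration lengths.
#' @param inv_len length of the inverted segment (default 3000).
#' @param at rescue-junction position (default: centred).
#' @param window rescue-flank window length recorded in the truth (default
#'   1200; must exceed `del_len + tandem_dup_len` with margin).
#' @param seed RNG seed (default derived from the configuration).
#' @return List with `genome` and `event`.
#' @export
plant_disruption_rescue_inversion <- function(genome, foreign_len = 600L,
                                              orf_len = 450L, del_len = 0L,
                                              tandem_dup_len = 0L,
                                              inv_len = 3000L, at = NULL,
                                              window = 1200L, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_plastome"))
  foreign_len <- as.integer(foreign_len); orf_len <- as.integer(orf_len)
  del_len <- as.integer(del_len); tandem_dup_len <- as.integer(tandem_dup_len)
  spacer <- 150L
  if (window < del_len + tandem_dup_len + spacer + 200L)
    stop("window too small for the requested deletion/duplication")
  lsc <- genome$config$lsc_len
  if (is.null(at)) at <- as.integer(floor((lsc - inv_len) / 2))
  j1 <- as.integer(at)                     # rescue junction (after this base)
  j2 <- j1 + as.integer(inv_len)           # disruption junction
  if (j1 < window + 50L || j2 + 100L > lsc)
    stop("not enough room in the LSC for the requested inversion")
  if (is.null(seed)) seed <- genome$config$seed * 2003L + length(genome$truth) + 1L

  seq <- genome$seq
  before_flank <- substr(seq, j1 - window + 1L, j1)
  # rescue flank: delete del_len bases ending at the junction; tandemly
  # duplicate tandem_dup_len bases located `spacer` bases further in
  flank <- substr(before_flank, 1L, window - del_len)
  if (tandem_dup_len > 0L) {
    wl <- nchar(flank)
    dup_end <- wl - spacer
    dup_start <- dup_end - tandem_dup_len + 1L
    dup_seq <- substr(flank, dup_start, dup_end)
    flank <- paste0(substr(flank, 1L, dup_end), dup_seq,
                    substr(flank, dup_end + 1L, wl))
  }
  after_flank <- flank
  foreign <- if (foreign_len > 0L)
    .with_seed(seed, .random_foreign(seq, foreign_len, orf_len,
                                     min(0.9, genome$config$gc_fraction + 0.10)))
  else ""
  mid <- .revcomp_chr(substr(seq, j1 + 1L, j2))
  new_seq <- paste0(substr(seq, 1L, j1 - window), after_flank, mid, foreign,
                    substr(seq, j2 + 1L, nchar(seq)))
  delta <- nchar(new_seq) - nchar(seq)
  genome$seq <- new_seq
  genome$features <- .shift_features(genome$features, j2, delta)
  ev <- list(type = "disruption_rescue_inversion",
             del_len = del_len, tandem_dup_len = tandem_dup_len,
             foreign_len = foreign_len, orf_len = orf_len,
             rescue_junction = j1 - del_len + tandem_dup_len,
             disruption_junction = j2 - del_len + tandem_dup_len,
             inverted_interval = c(j1 + 1L, j2) - del_len + tandem_dup_len,
             foreign_region = if (foreign_len > 0L)
               c(j2 - del_len + tandem_dup_len + 1L,
                 j2 - del_len + tandem_dup_len + foreign_len) else NULL,
             before_rescue_flank = before_flank,
             after_rescue_flank = after_flank,
             evidence_disruption = if (foreign_len > 0L)
               "foreign_insertion_at_endpoint" else character(0),
             evidence_rescue = c(
               if (del_len > 0L) "deletion_at_endpoint",
               if (tandem_dup_len > 0L) "tandem_duplication_at_endpoint",
               if (del_len > 0L || tandem_dup_len > 0L) "arbitrary_ligation"))
  genome$truth <- c(genome$truth, list(ev))
  list(genome = genome, event = ev)
}

#' Plant a duplicative transposition
#'
#' Copies `source_region` to position `dest` (reverse complemented when
#' `orientation = "inverted"`), then applies post-copy point mutations:
#' `shared_derived` substitutions at the same position and to the same new
#' state in both copy and source (as left by a very recent transposition or
#' by concerted evolution), `copy_only` substitutions private to the copy
#' and `source_only` substitutions private to the source. The pre-planting
#' source sequence is recorded as the ancestral reference.
#'
#' @param genome a `synthetic_plastome`.
#' @param source_region length-2 vector (start, end), 1-based inclusive,
#'   within the LSC.
#' @param dest 1-based position after which the copy is inserted; must not
#'   overlap the source.
#' @param orientation `"same"` or `"inverted"`.
#' @param shared_derived,copy_only,source_only mutation counts.
#' @param seed RNG seed (default derived from the configuration).
#' @return List with `genome` and `event` (including `ancestral_ref`,
#'   `copy_seq` and `source_seq`, all in source orientation).
#' @export
plant_transposition <- function(genome, source_region, dest,
                                orientation = c("same", "inverted"),
                                shared_derived = 0L, copy_only = 0L,
                                source_only = 0L, seed = NULL) {
  stopifnot(inherits(genome, "synthetic_plastome"))
  orientation <- match.arg(orientation)
  s1 <- as.integer(source_region[1L]); s2 <- as.integer(source_region[2L])
  dest <- as.integer(dest)
  if (s1 < 1L || s2 <= s1 || s2 > nchar(genome$seq))
    stop("invalid source region")
  if (dest >= s1 - 1L && dest <= s2)
    stop("destination overlaps the source region")
  len <- s2 - s1 + 1L
  ntot <- as.integer(shared_derived + copy_only + source_only)
  # mutations are spaced >= 18 bases apart and away from the copy ends so
  # the planted copy stays exactly recoverable by the seed-and-chain
  # detector at its default core length
  grid <- seq(18L, len - 18L, by = 18L)
  if (ntot > length(grid))
    stop("too many mutations for the region length")
  if (is.null(seed)) seed <- genome$config$seed * 3011L + length(genome$truth) + 1L

  anc <- substr(genome$seq, s1, s2)
  mut <- .with_seed(seed, {
    pos <- if (ntot > 0L) sample(grid, ntot) else integer(0)
    states <- vapply(pos, function(p)
      sample(setdiff(c("A", "C", "G", "T"),
                     substr(anc, p, p)), 1L), "")
    list(pos = pos, states = states)
  })
  idx_shared <- seq_len(shared_derived)
  idx_copy <- shared_derived + seq_len(copy_only)
  idx_source <- shared_derived + copy_only + seq_len(source_only)
  apply_muts <- function(x, which) {
    if (!length(which)) return(x)
    .substr_set(x, mut$pos[which], mut$states[which])
  }
  copy_seq <- apply_muts(apply_muts(anc, idx_shared), idx_copy)
  source_seq <- apply_muts(apply_muts(anc, idx_shared), idx_source)

  seq <- genome$seq
  # rewrite the source in place (no length change)
  seq <- paste0(substr(seq, 1L, s1 - 1L), source_seq,
                substr(seq, s2 + 1L, nchar(seq)))
  insert <- if (orientation == "inverted") .revcomp_chr(copy_seq) else copy_seq
  seq <- .splice(seq, dest, insert)
  shift <- if (dest < s1) len else 0L
  copy_start <- dest + 1L
  # guard the copy flanks: the bases immediately outside the copy must not
  # extend the copy/source match by chance
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  s1s <- s1 + shift; s2s <- s2 + shift
  fix_flank <- function(p, partner, inverted) {
    if (p < 1L || p > length(v) || partner < 1L || partner > length(v)) return()
    bad <- if (inverted) chartr("ACGT", "TGCA", v[partner]) else v[partner]
    if (v[p] == bad)
      v[p] <<- setdiff(c("A", "C", "G", "T"), c(bad, v[p]))[1L]
  }
  if (orientation == "same") {
    fix_flank(copy_start - 1L, s1s - 1L, FALSE)
    fix_flank(copy_start + len, s2s + 1L, FALSE)
  } else {
    fix_flank(copy_start - 1L, s2s + 1L, TRUE)
    fix_flank(copy_start + len, s1s - 1L, TRUE)
  }
  seq <- paste(v, collapse = "")
  genome$seq <- seq
  genome$features <- .shift_features(genome$features, dest, len)
  genome$features <- rbind(genome$features, data.frame(
    type = "transposed_copy", name = paste0("copy_", length(genome$truth) + 1L),
    start = copy_start, end = copy_start + len - 1L,
    strand = if (orientation == "same") "+" else "-",
    stringsAsFactors = FALSE))
  ev <- list(type = "transposition",
             source_region = c(s1 + shift, s2 + shift),
             copy_region = c(copy_start, copy_start + len - 1L),
             orientation = orientation,
             shared_derived = as.integer(shared_derived),
             copy_only = as.integer(copy_only),
             source_only = as.integer(source_only),
             ancestral_ref = anc, copy_seq = copy_seq,
             source_seq = source_seq)
  genome$truth <- c(genome$truth, list(ev))
  list(genome = genome, event = ev)
}

#' Extract one region of a synthetic plastome
#'
#' Dispersed-repeat scans are run on single-copy regions; the two IR copies
#' are themselves a genome-scale inverted repeat and would dominate any
#' whole-genome scan.
#'
#' @param genome a `synthetic_plastome`.
#' @param region `"LSC"`, `"IRa"`, `"SSC"` or `"IRb"`.
#' @return The region sequence (character).
#' @export
region_seq <- function(genome, region = "LSC") {
  stopifnot(inherits(genome, "synthetic_plastome"))
  f <- genome$features
  row <- f[f$name == region & f$type %in% c("region", "inverted_repeat"), ]
  if (nrow(row) != 1L) stop("unknown region: ", region)
  substr(genome$seq, row$start, row$end)
}
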