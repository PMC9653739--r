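# Readers/writers for the standard formats the pipeline touches. Coordinate
# conventions are enforced at the boundary: GFF3 is 1-based inclusive, BED
# is 0-based half-open; all internal coordinates are 1-based inclusive.

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings. Sequences are normalised to upper case on
#' read; writing wraps at 70 columns. Round trips preserve identifiers and
#' sequence.
#'
#' @param path file path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(toupper(as.character(x)), names(x))
}

#' @rdname read_fasta
#' @param seqs named character vector (or `DNAStringSet`).
#' @export
write_fasta <- function(seqs, path) {
  if (!methods::is(seqs, "XStringSet"))
    seqs <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  Biostrings::writeXStringSet(seqs, path, width = 70L)
  invisible(path)
}

.features_to_granges <- function(features, seqname = "plastome") {
  if (methods::is(features, "GRanges")) return(features)
  if (any(features$start < 1L) || any(features$end < features$start))
    stop("invalid 1-based feature coordinates")
  gr <- GenomicRanges::GRanges(
    seqnames = if ("seqid" %in% names(features)) features$seqid else seqname,
    ranges = IRanges::IRanges(features$start, features$end),
    strand = if ("strand" %in% names(features)) features$strand else "*")
  gr$type <- features$type
  if ("name" %in% names(features)) gr$Name <- features$name
  gr
}

#' Read / write GFF3 annotation
#'
#' GFF3 coordinates are 1-based inclusive (a feature covering the first base
#' of the sequence is written with start 1).
#'
#' @param path file path.
#' @return `read_gff3`: a data frame with `seqid, type, start, end, strand,
#'   name` (1-based inclusive).
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  data.frame(seqid = as.character(GenomicRanges::seqnames(gr)),
             type = as.character(gr$type),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             name = if (!is.null(gr$Name)) as.character(gr$Name) else NA_character_,
             stringsAsFactors = FALSE)
}

#' @rdname read_gff3
#' @param features data frame (`type, name, start, end, strand`, optional
#'   `seqid`) or `GRanges`.
#' @param seqname sequence name used when `features` has no `seqid`.
#' @export
write_gff3 <- function(features, path, seqname = "plastome") {
  gr <- .features_to_granges(features, seqname)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write intervals as BED
#'
#' BED is 0-based half-open: a 1-based inclusive interval `[start, end]` is
#' written as `start - 1, end`.
#'
#' @param intervals data frame with 1-based `start`, `end` and optional
#'   `name`, `seqid`, `strand`.
#' @param path file path.
#' @param seqname default sequence name.
#' @export
write_bed <- function(intervals, path, seqname = "plastome") {
  gr <- GenomicRanges::GRanges(
    seqnames = if ("seqid" %in% names(intervals)) intervals$seqid else seqname,
    ranges = IRanges::IRanges(intervals$start, intervals$end),
    strand = if ("strand" %in% names(intervals)) intervals$strand else "*")
  if ("name" %in% names(intervals)) gr$name <- intervals$name
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Stem-loop hits as paired BED intervals
#'
#' Expands [find_inverted_repeats()] output into one row per arm, the name
#' field carrying hit id, arm, stem/loop lengths and mismatch count.
#'
#' @param hits output of [find_inverted_repeats()] / [find_hairpins()].
#' @return A data frame ready for [write_bed()].
#' @export
stemloop_bed <- function(hits) {
  if (!nrow(hits)) return(data.frame(start = integer(0), end = integer(0),
                                     name = character(0)))
  tag <- sprintf("sl%d;stem=%d;loop=%d;mm=%d", seq_len(nrow(hits)),
                 hits$stem_len, hits$loop_len, hits$mismatches)
  data.frame(
    start = c(hits$left_start, hits$right_start),
    end = c(hits$left_end, hits$right_end),
    name = c(paste0(tag, ";arm=left"), paste0(tag, ";arm=right")),
    stringsAsFactors = FALSE)
}

#' Read a phylogeny with named internal nodes
#'
#' @param path newick file; internal node labels (phylogenetic interval
#'   names) are preserved.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Write a JSON report with provenance
#'
#' Every report carries a versioned schema header with the package version,
#' the parameters used and the seed, so any output can be traced back to its
#' configuration.
#'
#' @param obj list to serialise (under `$results`).
#' @param path output file.
#' @param params named list of parameters to echo.
#' @param seed seed to echo.
#' @export
write_report <- function(obj, path, params = list(), seed = NULL) {
  payload <- list(
    schema_version = "1.0",
    package = "plastinv",
    version = as.character(utils::packageVersion("plastinv")),
    params = params,
    seed = seed,
    results = obj)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Write a synthetic plastome to disk
#'
#' Emits FASTA (sequence), GFF3 (annotation) and a truth JSON (planted
#' events) alongside each other.
#'
#' @param genome a `synthetic_plastome`.
#' @param prefix path prefix; files `<prefix>.fasta`, `<prefix>.gff3`,
#'   `<prefix>.truth.json` are written.
#' @return The three paths, invisibly.
#' @export
write_plastome <- function(genome, prefix) {
  stopifnot(inherits(genome, "synthetic_plastome"))
  fa <- paste0(prefix, ".fasta")
  gff <- paste0(prefix, ".gff3")
  js <- paste0(prefix, ".truth.json")
  write_fasta(stats::setNames(genome$seq, "plastome"), fa)
  write_gff3(genome$features, gff)
  write_report(genome$truth, js,
               params = unclass(genome$config)[c("lsc_len", "ssc_len",
                                                 "ir_len", "gc_fraction")],
               seed = genome$config$seed)
  invisible(c(fasta = fa, gff3 = gff, truth = js))
}
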