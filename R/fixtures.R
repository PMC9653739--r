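# Packaged fixtures: the gene-block encodings of the ancestral and derived
# LSC arrangements, the per-inversion before/after orders, the marker-bearing
# arrangement for the inversion-order test, and caption-level feature lengths.

.fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "plastinv")
  if (!nzchar(p)) stop("fixture file not found: ", paste(list(...), collapse = "/"))
  p
}

#' Read / write arrangement files
#'
#' Plain-text arrangement format: a header line `# topology: linear`
#' followed by one row per block, tab-separated: `id  sign  kind`.
#'
#' @param path file path.
#' @return A [block_order()].
#' @export
read_block_order <- function(path) {
  lines <- readLines(path)
  header <- grep("^#\\s*topology:", lines, value = TRUE)
  topo <- if (length(header)) sub("^#\\s*topology:\\s*", "", header[1]) else "linear"
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(parts) != 3L))
    stop("malformed arrangement file: expected 'id<TAB>sign<TAB>kind' rows")
  ids <- vapply(parts, `[[`, "", 1L)
  signs <- vapply(parts, `[[`, "", 2L)
  kinds <- stats::setNames(vapply(parts, `[[`, "", 3L), ids)
  block_order(ids, signs, kinds, topology = trimws(topo))
}

#' @rdname read_block_order
#' @param order a [block_order()] to write.
#' @export
write_block_order <- function(order, path) {
  lines <- c(paste0("# topology: ", order$topology),
             paste(order$ids, ifelse(order$signs > 0, "+", "-"),
                   order$kinds, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Load a packaged fixture
#'
#' Fixtures encode the reconstructed rearrangement history of the most
#' extensively rearranged Lobeliaceae LSC region as signed gene-block
#' arrangements. The block alphabet is the minimal one in which every
#' reconstructed inversion endpoint is a block boundary: the LSC strips
#' between the six junctions (psbA flank | trnK..trnG | trnR..rpoB |
#' trnC..rps4 | trnT..ndhC | trnV..rbcL | psaI flank), plus (in the 8-block
#' marker encoding) the ~340-bp "C/D" intergenic segment of the rpoB-trnC
#' region whose final position and orientation dates Inversion 3 relative to
#' Inversion 4.
#'
#' Available fixtures:
#' \describe{
#'   \item{`five_inversions`}{ancestral/derived orders, the historical
#'     five-step scenario, the hot-spot locus (the accD deletion-site,
#'     upstream of psaI), the two-step phylogenetic prefix, and the content
#'     signature of the five inversions.}
#'   \item{`inversion1` .. `inversion5`}{before/after orders per inversion,
#'     the interval in the before-frame, the inferred mechanism, and
#'     caption-level feature lengths.}
#'   \item{`grammatotheca_reversion`}{the post-Inversion-1 order and the
#'     stem-loop interval (flanked by the inverted 118-bp repeat) whose
#'     application restores the ancestral gene order.}
#'   \item{`inv34_marker`}{8-block encoding: the pre-Inversion-3 order, both
#'     inversions in that frame, the marker block id and the observed
#'     post-Inversion-4 order.}
#'   \item{`rpl23_primary_transposition`}{donor stem-loop flank and acceptor
#'     insertion-site sequences whose best 8-base window match is 7 of 8.}
#'   \item{`feature_lengths`}{table of reconstruction feature lengths.}
#'   \item{`phylogeny`}{the fixed input tree with named phylogenetic
#'     intervals.}
#' }
#'
#' @param name fixture name (see Details).
#' @return A list (contents depend on the fixture).
#' @export
load_fixture <- function(name) {
  ord <- function(f) read_block_order(.fixture_path("fixtures", paste0(f, ".blocks")))
  flen <- function() utils::read.delim(.fixture_path("fixtures", "feature_lengths.tsv"),
                                       stringsAsFactors = FALSE)
  iv <- function(a, b) inversion_interval(a, b)
  steps5 <- list(iv(1, 6), iv(2, 6), iv(4, 6), iv(3, 6), iv(4, 6))
  hotspot <- breakpoint_locus("accD-deletion-site", "psaI", "upstream")
  switch(
    name,
    five_inversions = {
      anc <- ord("ancestral_lsc"); der <- ord("derived_lsc")
      list(ancestral = anc, derived = der,
           scenario = inversion_scenario(steps5, anc, der),
           hotspot = hotspot,
           phylo = phylo_constraint("inv1_interval+inv2_interval",
                                    steps5[1:2]),
           inversions = scenario_content(inversion_scenario(steps5, anc, der)),
           distance = 5L)
    },
    inversion1 = list(before = ord("ancestral_lsc"), after = ord("post_inv1"),
                      interval = iv(1, 6), interval_name = "inv1_interval",
                      mechanism = "disruption_rescue",
                      del_len = 53L, tandem_dup_len = 45L, repeat_stem = 118L,
                      trnC_rpoB_copy = 64L),
    inversion2 = list(before = ord("post_inv1"), after = ord("post_inv2"),
                      interval = iv(2, 6), interval_name = "inv2_interval",
                      mechanism = "disruption_rescue", del_len = 152L),
    inversion3 = list(before = ord("post_inv2"), after = ord("post_inv3"),
                      interval = iv(4, 6), interval_name = "inv34_interval",
                      mechanism = "disruption_rescue",
                      rpl23_remnant = 29L, shared_derived_laxa = 5L),
    inversion4 = list(before = ord("post_inv3"), after = ord("post_inv4"),
                      interval = iv(3, 6), interval_name = "inv34_interval",
                      mechanism = "stem_loop", stem_len = 7L,
                      loop_min = 40000L),
    inversion5 = list(before = ord("post_inv4"), after = ord("derived_lsc"),
                      interval = iv(4, 6), interval_name = "inv5_interval",
                      mechanism = "disruption_rescue",
                      terminal_match = 13L, flank_deletion = 68L,
                      orf_core = 300L, shared_derived_fervens = 4L),
    grammatotheca_reversion = list(order = ord("post_inv1"),
                                   interval = iv(1, 6),
                                   restored = ord("ancestral_lsc"),
                                   repeat_stem = 118L),
    inv34_marker = list(order0 = ord("inv34_order0"),
                        invA = iv(4, 7), invB = iv(3, 5),
                        marker = "rpoB-trnC-CD",
                        observed = ord("inv34_observed")),
    rpl23_primary_transposition = list(
      donor_flank = "ACGTACGGATCCTAGCAATG",
      acceptor_site = "CCTTGGATCGTAGACTGA",
      window_len = 8L, expected_matches = 7L),
    feature_lengths = list(table = flen()),
    phylogeny = list(tree = read_newick(.fixture_path("fixtures",
                                                      "lobeliaceae.nwk"))),
    stop("unknown fixture: ", name)
  )
}
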