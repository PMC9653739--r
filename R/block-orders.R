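#' Signed gene-block arrangements
#'
#' A `block_order` represents one plastome arrangement as an ordered sequence
#' of oriented blocks (genes or intergenic segments). Arrangements used by the
#' inversion algebra are linear: the large single-copy (LSC) region has fixed
#' flanks, so inverting the whole order is not the identity.
#'
#' @param ids character vector of unique block labels, in arrangement order.
#' @param signs integer (+1/-1) or character ("+"/"-") orientations, one per
#'   block. Defaults to all forward.
#' @param kinds named character vector giving the kind of each block id, one of
#'   `"gene"`, `"intergenic"`, `"foreign"`, `"marker"`. Defaults to `"gene"`.
#' @param topology `"linear"` (the only topology the inversion algebra
#'   operates on) or `"circular"` (accepted for completeness of the file
#'   format).
#' @return An object of class `block_order`.
#' @examples
#' anc <- block_order(c("psbA", "trnK-trnG", "trnR-rpoB", "psaI"))
#' apply_inversion(anc, inversion_interval(1, 3))
#' @export
block_order <- function(ids, signs = rep(1L, length(ids)), kinds = NULL,
                        topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  ids <- as.character(ids)
  if (anyDuplicated(ids))
    stop("block ids must be unique within an arrangement")
  if (is.character(signs))
    signs <- ifelse(signs %in% c("+", "1"), 1L, -1L)
  signs <- as.integer(signs)
  if (length(signs) != length(ids) || !all(signs %in% c(-1L, 1L)))
    stop("signs must be +1/-1, one per block")
  if (is.null(kinds)) {
    kinds <- stats::setNames(rep("gene", length(ids)), ids)
  } else {
    if (is.null(names(kinds))) names(kinds) <- ids
    kinds <- kinds[ids]
  }
  bad <- setdiff(unique(kinds), c("gene", "intergenic", "foreign", "marker"))
  if (length(bad))
    stop("unknown block kind(s): ", paste(bad, collapse = ", "))
  structure(list(ids = ids, signs = signs, kinds = kinds, topology = topology),
            class = "block_order")
}

#' @export
print.block_order <- function(x, ...) {
  cat("<block_order> ", x$topology, ", ", length(x$ids), " blocks\n  ",
      paste0(ifelse(x$signs > 0, "+", "-"), x$ids, collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @export
length.block_order <- function(x) length(x$ids)

#' @export
`==.block_order` <- function(e1, e2) {
  identical(e1$ids, e2$ids) && identical(e1$signs, e2$signs) &&
    identical(e1$topology, e2$topology)
}

# canonical string key, used for memoisation and set semantics
.bo_key <- function(order) {
  paste0(ifelse(order$signs > 0, "", "-"), order$ids, collapse = "|")
}

.check_same_alphabet <- function(a, b) {
  if (!setequal(a$ids, b$ids))
    stop("arrangements are over different block alphabets")
  if (!identical(a$topology, b$topology))
    stop("arrangements have different topologies")
  if (a$topology != "linear")
    stop("the inversion algebra operates on linear arrangements only")
  invisible(TRUE)
}

#' Inversion interval between two breakpoint edges
#'
#' Breakpoint edges are 0-based indices between block positions: edge 0
#' precedes the first block, edge `n` follows the last of `n` blocks. The
#' interval `[start_edge, end_edge]` covers the blocks strictly between the
#' two edges and must cover at least one block.
#'
#' @param start_edge,end_edge integer edges with `start_edge < end_edge`.
#' @return An object of class `inversion_interval`.
#' @export
inversion_interval <- function(start_edge, end_edge) {
  start_edge <- as.integer(start_edge); end_edge <- as.integer(end_edge)
  if (is.na(start_edge) || is.na(end_edge) || start_edge < 0L ||
      start_edge >= end_edge)
    stop("invalid inversion interval: need 0 <= start_edge < end_edge")
  structure(c(start_edge = start_edge, end_edge = end_edge),
            class = "inversion_interval")
}

#' @export
print.inversion_interval <- function(x, ...) {
  cat("<inversion_interval> edges (", x[[1]], ", ", x[[2]], ")\n", sep = "")
  invisible(x)
}

.as_interval <- function(x) {
  if (inherits(x, "inversion_interval")) return(x)
  inversion_interval(x[[1]], x[[2]])
}

#' Apply an inversion to an arrangement
#'
#' Standard signed-reversal semantics: blocks inside the interval are reversed
#' in order and flipped in orientation; blocks outside are untouched. The
#' input is not modified. Applying the same interval twice restores the
#' original arrangement.
#'
#' @param order a [block_order()].
#' @param interval an [inversion_interval()] (or length-2 vector of edges).
#' @return The rearranged `block_order`.
#' @export
apply_inversion <- function(order, interval) {
  interval <- .as_interval(interval)
  n <- length(order$ids)
  i <- interval[[1]]; j <- interval[[2]]
  if (j > n)
    stop("inversion interval out of range for an arrangement of ", n, " blocks")
  idx <- (i + 1L):j
  out <- order
  out$ids[idx] <- rev(order$ids[idx])
  out$signs[idx] <- -rev(order$signs[idx])
  out
}

#' Reversal distance between two arrangements
#'
#' Length of the shortest sequence of inversions transforming `a` into `b`,
#' computed with the Hannenhalli-Pevzner breakpoint-graph formula for sorting
#' signed permutations by reversals (cycles, hurdles, fortress). Symmetric in
#' its arguments; zero exactly when the arrangements are equal.
#'
#' @param a,b [block_order()] objects over the same alphabet and topology.
#' @return A non-negative integer.
#' @export
reversal_distance <- function(a, b) {
  .check_same_alphabet(a, b)
  .hp_distance(.relabel_perm(a, b))
}

# Express arrangement `a` as a signed permutation in the frame where `b` is
# the identity 1..n.
.relabel_perm <- function(a, b) {
  pos <- match(a$ids, b$ids)
  as.integer(pos * a$signs * b$signs[pos])
}

#' Breakpoints between two arrangements
#'
#' Sign-aware adjacencies (ordered pairs of oriented blocks) present in `a`
#' but absent from `b` in either reading direction: adjacency `(x, y)` is
#' retained in `b` if `b` contains `x` directly followed by `y`, or `-y`
#' directly followed by `-x`. The two linear ends are included as adjacencies
#' with the virtual caps `"<"` and `">"`, so a flipped terminal block counts
#' as a breakpoint.
#'
#' @param a,b [block_order()] objects over the same alphabet.
#' @return A data frame with columns `left`, `right` (signed block labels) and
#'   `edge` (the 0-based breakpoint edge in `a`); zero rows when `a == b`.
#' @export
breakpoints <- function(a, b) {
  .check_same_alphabet(a, b)
  adj_a <- .adjacencies(a)
  keys_b <- .adjacency_keys(b)
  broken <- !(adj_a$key %in% keys_b)
  out <- adj_a[broken, c("left", "right", "edge")]
  rownames(out) <- NULL
  out
}

.signed_label <- function(ids, signs) paste0(ifelse(signs > 0, "+", "-"), ids)

.adjacencies <- function(order) {
  lab <- c("<", .signed_label(order$ids, order$signs), ">")
  n <- length(lab)
  data.frame(left = lab[-n], right = lab[-1],
             edge = 0:(n - 2L),
             key = paste(lab[-n], lab[-1], sep = " "),
             stringsAsFactors = FALSE)
}

.flip_label <- function(lab) {
  sign <- substr(lab, 1, 1)
  if (lab %in% c("<", ">")) return(lab)
  paste0(if (sign == "+") "-" else "+", substr(lab, 2, nchar(lab)))
}

.adjacency_keys <- function(order) {
  adj <- .adjacencies(order)
  fwd <- adj$key
  rev <- vapply(seq_len(nrow(adj)), function(i)
    paste(.flip_label(adj$right[i]), .flip_label(adj$left[i])), "")
  c(fwd, rev)
}

#' Breakpoint locus anchored to a block
#'
#' A locus names a junction tracked through rearrangements by anchoring it to
#' a block and a side. Following how junctions are read off inverted
#' segments, a locus `upstream` of its anchor maps to the anchor's left edge
#' while the anchor is forward and to its right edge when the anchor is
#' inverted (and conversely for `downstream`).
#'
#' @param name label for the locus (e.g. `"accD-deletion-site"`).
#' @param anchor_block block id the locus is anchored to.
#' @param side `"upstream"` or `"downstream"` of the anchor.
#' @return An object of class `breakpoint_locus`.
#' @export
breakpoint_locus <- function(name, anchor_block, side = c("upstream", "downstream")) {
  side <- match.arg(side)
  structure(list(name = name, anchor_block = anchor_block, side = side),
            class = "breakpoint_locus")
}

#' Resolve a locus to a breakpoint edge
#'
#' @param order a [block_order()].
#' @param locus a [breakpoint_locus()].
#' @return The 0-based edge index of the locus in `order`.
#' @export
locus_edge <- function(order, locus) {
  p <- match(locus$anchor_block, order$ids)
  if (is.na(p))
    stop("locus anchor block '", locus$anchor_block, "' missing from arrangement")
  fwd <- order$signs[p] > 0
  if (locus$side == "upstream") {
    if (fwd) p - 1L else p
  } else {
    if (fwd) p else p - 1L
  }
}

#' Track a locus through an inversion scenario
#'
#' Re-identifies a breakpoint locus step by step while a scenario is applied:
#' for each step the edge index of the locus in the arrangement current at
#' that step (i.e. before the step is applied), plus the final arrangement.
#' The output has `length(steps) + 1` entries.
#'
#' @param order the starting [block_order()].
#' @param locus a [breakpoint_locus()].
#' @param scenario a list of [inversion_interval()]s (each in the coordinate
#'   frame current at its step), or an [inversion_scenario()].
#' @return Integer vector of edge indices, one per visited arrangement.
#' @export
track_locus <- function(order, locus, scenario) {
  steps <- if (inherits(scenario, "inversion_scenario")) scenario$steps else scenario
  edges <- integer(length(steps) + 1L)
  cur <- order
  edges[1L] <- locus_edge(cur, locus)
  for (k in seq_along(steps)) {
    cur <- apply_inversion(cur, steps[[k]])
    edges[k + 1L] <- locus_edge(cur, locus)
  }
  edges
}

#' Project two arrangements onto their shared block alphabet
#'
#' Blocks present in only one arrangement (deleted or inserted segments,
#' which are separate events from inversions) are dropped explicitly before
#' distance or scenario work.
#'
#' @param a,b [block_order()] objects.
#' @return A list with projected elements `a` and `b`.
#' @export
project_shared <- function(a, b) {
  shared <- intersect(a$ids, b$ids)
  keep <- function(o) {
    sel <- o$ids %in% shared
    block_order(o$ids[sel], o$signs[sel], o$kinds[sel], o$topology)
  }
  list(a = keep(a), b = keep(b))
}
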