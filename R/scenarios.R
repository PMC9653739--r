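#' Inversion scenarios
#'
#' An inversion scenario is a temporally ordered list of inversions
#' transforming a source arrangement into a target arrangement. Each step is
#' expressed in the coordinate frame current at that step. Two scenarios with
#' the same steps in a different order are distinct hypotheses.
#'
#' @param steps list of [inversion_interval()]s.
#' @param source,target [block_order()] references.
#' @return An object of class `inversion_scenario`.
#' @export
inversion_scenario <- function(steps, source, target) {
  steps <- lapply(steps, .as_interval)
  structure(list(steps = steps, source = source, target = target),
            class = "inversion_scenario")
}

#' @export
print.inversion_scenario <- function(x, ...) {
  cat("<inversion_scenario> ", length(x$steps), " step(s): ",
      paste(vapply(x$steps, function(s) sprintf("(%d,%d)", s[[1]], s[[2]]), ""),
            collapse = " -> "), "\n", sep = "")
  invisible(x)
}

#' Apply a whole scenario
#'
#' @param order starting [block_order()].
#' @param scenario an [inversion_scenario()] or list of intervals.
#' @return The final `block_order`.
#' @export
apply_scenario <- function(order, scenario) {
  steps <- if (inherits(scenario, "inversion_scenario")) scenario$steps else scenario
  for (s in steps) order <- apply_inversion(order, s)
  order
}

#' Enumerate all minimal inversion scenarios
#'
#' Exhaustively enumerates every shortest sequence of inversions transforming
#' `source` into `target`, by depth-first search restricted to inversions
#' that strictly reduce the reversal distance to the target (every prefix of
#' a minimal scenario lies on a minimal path, so the search is exhaustive
#' without enumerating all interval sequences). Scenarios are emitted in
#' deterministic lexicographic order of their per-step `(start_edge,
#' end_edge)` pairs.
#'
#' Note that the enumeration is over the full inversion algebra: minimal
#' scenarios that reach the target through junction combinations never
#' proposed in a hand reconstruction are still reported. Use
#' [scenario_content()] / [filter_content()] to restrict to scenarios built
#' from a designated set of inversions.
#'
#' @param source,target [block_order()]s over the same alphabet.
#' @param max_len refuse (with an error) to enumerate when the reversal
#'   distance exceeds this guard against combinatorial blow-up.
#' @return A list of [inversion_scenario()]s.
#' @export
enumerate_minimal_scenarios <- function(source, target, max_len = 8L) {
  .check_same_alphabet(source, target)
  n <- length(source)
  d0 <- reversal_distance(source, target)
  if (d0 > max_len)
    stop("reversal distance ", d0, " exceeds max_len = ", max_len)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  dist_to_target <- function(order) {
    k <- .bo_key(order)
    d <- memo[[k]]
    if (is.null(d)) {
      d <- reversal_distance(order, target)
      memo[[k]] <- d
    }
    d
  }
  ivs <- list()
  for (i in 0:(n - 1L)) for (j in (i + 1L):n)
    ivs[[length(ivs) + 1L]] <- inversion_interval(i, j)

  out <- list()
  rec <- function(cur, d, steps) {
    if (d == 0L) {
      out[[length(out) + 1L]] <<- inversion_scenario(steps, source, target)
      return()
    }
    for (iv in ivs) {
      nxt <- apply_inversion(cur, iv)
      if (dist_to_target(nxt) == d - 1L)
        rec(nxt, d - 1L, c(steps, list(iv)))
    }
  }
  rec(source, d0, list())
  out
}

#' Per-step block content of a scenario
#'
#' Identifies each step of a scenario by the (unsigned) set of block ids its
#' interval covers at the time of application. This content signature is
#' frame-independent, so scenarios can be compared with a set of inversions
#' reconstructed from comparative evidence.
#'
#' @param scenario an [inversion_scenario()].
#' @return A list of character vectors (sorted block ids), one per step.
#' @export
scenario_content <- function(scenario) {
  cur <- scenario$source
  out <- vector("list", length(scenario$steps))
  for (k in seq_along(scenario$steps)) {
    iv <- scenario$steps[[k]]
    out[[k]] <- sort(cur$ids[(iv[[1]] + 1L):iv[[2]]])
    cur <- apply_inversion(cur, iv)
  }
  out
}

#' Restrict scenarios to a designated inversion set
#'
#' Retains the scenarios whose step content (see [scenario_content()]) is a
#' permutation of the given inversions' content. This separates temporal
#' re-orderings of a reconstructed set of inversions from minimal scenarios
#' that use altogether different interval combinations.
#'
#' @param scenarios list of [inversion_scenario()]s.
#' @param inversions list of character vectors (block-id sets), or a
#'   reference [inversion_scenario()] whose content defines the set.
#' @return The retained sub-list.
#' @export
filter_content <- function(scenarios, inversions) {
  if (inherits(inversions, "inversion_scenario"))
    inversions <- scenario_content(inversions)
  ref <- sort(vapply(inversions, function(x) paste(sort(x), collapse = "|"), ""))
  Filter(function(sc) {
    got <- sort(vapply(scenario_content(sc),
                       function(x) paste(x, collapse = "|"), ""))
    identical(got, ref)
  }, scenarios)
}

#' Common-cause (hot spot) filter
#'
#' Retains exactly the scenarios in which every step's interval has at least
#' one edge equal to the tracked locus edge at that step (the locus is
#' re-identified from its anchor block with [track_locus()] as the scenario
#' unfolds). This operationalises the criterion that each inversion shares an
#' endpoint at a recurrent rearrangement hot spot. The criterion operates at
#' block resolution: an endpoint offset from the hot spot by less than a
#' block (sub-block sequence offsets) still counts as the hot-spot edge.
#'
#' @param scenarios list of [inversion_scenario()]s.
#' @param locus a [breakpoint_locus()] trackable through every scenario.
#' @return The retained sub-list (a subset of the input; idempotent).
#' @export
filter_common_cause <- function(scenarios, locus) {
  Filter(function(sc) {
    cur <- sc$source
    for (iv in sc$steps) {
      e <- locus_edge(cur, locus)
      if (iv[[1]] != e && iv[[2]] != e) return(FALSE)
      cur <- apply_inversion(cur, iv)
    }
    TRUE
  }, scenarios)
}

#' Phylogenetic constraint on the first scenario steps
#'
#' @param interval_name label of the phylogenetic interval (tree edge) the
#'   constraint is read from.
#' @param fixed_prefix list of [inversion_interval()]s that must occur first,
#'   in order, each in the coordinate frame current at its step.
#' @return An object of class `phylo_constraint`.
#' @export
phylo_constraint <- function(interval_name, fixed_prefix) {
  structure(list(interval_name = interval_name,
                 fixed_prefix = lapply(fixed_prefix, .as_interval)),
            class = "phylo_constraint")
}

#' Filter scenarios by a phylogenetically fixed prefix
#'
#' Retains scenarios whose first steps match the constraint's `fixed_prefix`
#' in order. An empty prefix is the identity filter.
#'
#' @param scenarios list of [inversion_scenario()]s.
#' @param constraint a [phylo_constraint()].
#' @return The retained sub-list.
#' @export
filter_phylo <- function(scenarios, constraint) {
  pre <- constraint$fixed_prefix
  if (!length(pre)) return(scenarios)
  if (length(scenarios) && length(pre) > length(scenarios[[1]]$steps))
    stop("fixed_prefix is longer than the scenarios")
  Filter(function(sc) {
    if (length(sc$steps) < length(pre)) return(FALSE)
    for (k in seq_along(pre)) {
      if (sc$steps[[k]][[1]] != pre[[k]][[1]] ||
          sc$steps[[k]][[2]] != pre[[k]][[2]]) return(FALSE)
    }
    TRUE
  }, scenarios)
}

# Map an edge through an inversion: breakpoint edges inside the inverted
# interval are reflected, edges outside are unchanged.
.remap_edge <- function(edge, interval) {
  a <- interval[[1]]; b <- interval[[2]]
  if (edge > a && edge < b) a + b - edge else edge
}

.remap_interval <- function(interval, through) {
  e1 <- .remap_edge(interval[[1]], through)
  e2 <- .remap_edge(interval[[2]], through)
  inversion_interval(min(e1, e2), max(e1, e2))
}

#' Infer the order of two endpoint-offset inversions
#'
#' Two overlapping inversions applied in different orders can leave a small
#' marker segment in different final positions and orientations. Given both
#' inversions expressed in the starting frame (`order0`), the composite is
#' simulated in both orders, remapping the second inversion's breakpoint
#' edges through the first; the order(s) under which the marker block's final
#' position and orientation match the observed arrangement decide the call.
#'
#' @param order0 the [block_order()] before either inversion.
#' @param invA,invB [inversion_interval()]s in the `order0` frame.
#' @param marker a block id (the diagnostic segment).
#' @param observed the observed [block_order()] after both inversions.
#' @return `"A_first"`, `"B_first"`, or `"indeterminate"` (both or neither
#'   order reproduces the marker's observed placement).
#' @export
infer_pair_order <- function(order0, invA, invB, marker, observed) {
  invA <- .as_interval(invA); invB <- .as_interval(invB)
  if (!marker %in% order0$ids)
    stop("marker block '", marker, "' absent from order0")
  if (!marker %in% observed$ids)
    stop("marker block '", marker, "' absent from observed arrangement")
  compose <- function(first, second) {
    mid <- apply_inversion(order0, first)
    apply_inversion(mid, .remap_interval(second, first))
  }
  marker_state <- function(order) {
    p <- match(marker, order$ids)
    c(p, order$signs[p])
  }
  obs <- marker_state(observed)
  a_ok <- identical(marker_state(compose(invA, invB)), obs)
  b_ok <- identical(marker_state(compose(invB, invA)), obs)
  if (a_ok && !b_ok) "A_first"
  else if (b_ok && !a_ok) "B_first"
  else "indeterminate"
}

#' Scenario report
#'
#' Converts scenarios into a plain-list report (one element per scenario,
#' each step with its edges, the arrangement after the step, and the tracked
#' hot-spot edge) suitable for [write_report()].
#'
#' @param scenarios list of [inversion_scenario()]s.
#' @param locus optional [breakpoint_locus()] to track.
#' @return A list (JSON-ready).
#' @export
scenario_report <- function(scenarios, locus = NULL) {
  lapply(scenarios, function(sc) {
    cur <- sc$source
    steps <- vector("list", length(sc$steps))
    for (k in seq_along(sc$steps)) {
      iv <- sc$steps[[k]]
      hot <- if (!is.null(locus)) locus_edge(cur, locus) else NULL
      cur <- apply_inversion(cur, iv)
      steps[[k]] <- list(
        start_edge = iv[[1]], end_edge = iv[[2]],
        hotspot_edge_at_step = hot,
        arrangement_after = paste0(ifelse(cur$signs > 0, "+", "-"), cur$ids))
    }
    list(n_steps = length(sc$steps), steps = steps)
  })
}
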