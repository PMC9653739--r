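# Independent oracles used by the tests: brute-force reversal on raw signed
# integer vectors, full-space breadth-first search for distances, iterative
# deepening for larger sizes, exhaustive scenario expansion, and a full
# antidiagonal scan for inverted repeats. These deliberately do not share
# code with the package internals they check.

or_apply_rev <- function(p, i, j) {
  idx <- (i + 1):j
  p[idx] <- -rev(p[idx])
  p
}

or_intervals <- function(n) {
  out <- list()
  for (i in 0:(n - 1)) for (j in (i + 1):n) out[[length(out) + 1]] <- c(i, j)
  out
}

# distances from the identity over the whole space of n-block signed orders
or_bfs_table <- function(n) {
  ivs <- or_intervals(n)
  key <- function(p) paste(p, collapse = ",")
  dist <- new.env(hash = TRUE, size = 2^16, parent = emptyenv())
  id <- 1:n
  assign(key(id), 0L, dist)
  frontier <- list(id)
  d <- 0L
  while (length(frontier)) {
    nxt <- list()
    for (p in frontier) {
      for (iv in ivs) {
        q <- or_apply_rev(p, iv[1], iv[2])
        k <- key(q)
        if (is.null(dist[[k]])) {
          dist[[k]] <- d + 1L
          nxt[[length(nxt) + 1]] <- q
        }
      }
    }
    d <- d + 1L
    frontier <- nxt
  }
  dist
}

# express `a` in the frame where `b` is the identity (plain vectors)
or_relabel <- function(a_ids, a_signs, b_ids, b_signs) {
  pos <- match(a_ids, b_ids)
  as.integer(pos * a_signs * b_signs[pos])
}

or_cycle_count <- function(p) {
  n <- length(p)
  dbl <- integer(2 * n + 2)
  k <- 2L
  for (x in p) {
    if (x > 0) { dbl[k] <- 2L * x - 1L; dbl[k + 1] <- 2L * x }
    else { dbl[k] <- -2L * x; dbl[k + 1] <- -2L * x - 1L }
    k <- k + 2L
  }
  dbl[2 * n + 2] <- 2L * n + 1L
  pos <- integer(2 * n + 2); pos[dbl + 1] <- 0:(2 * n + 1)
  seen <- logical(n + 1); nc <- 0L
  for (b in 0:n) {
    if (seen[b + 1]) next
    nc <- nc + 1L; pp <- 2L * b
    repeat {
      bi <- pp %/% 2L
      if (seen[bi + 1]) break
      seen[bi + 1] <- TRUE
      q <- if (pp %% 2L == 0L) pp + 1L else pp - 1L
      v <- dbl[q + 1]
      w <- if (v %% 2L == 0L) v + 1L else v - 1L
      pp <- pos[w + 1]
    }
  }
  nc
}

# exact distance by iterative deepening with the cycle lower bound (each
# reversal changes the cycle count by at most one)
or_iddfs_dist <- function(p) {
  n <- length(p)
  ivs <- or_intervals(n)
  lb0 <- n + 1L - or_cycle_count(p)
  if (lb0 == 0L) return(0L)
  for (lim in lb0:(n + 2L)) {
    found <- FALSE
    rec <- function(q, g) {
      if (found) return()
      lb <- length(q) + 1L - or_cycle_count(q)
      if (lb == 0L) { found <<- TRUE; return() }
      if (g + lb > lim) return()
      for (iv in ivs) {
        rec(or_apply_rev(q, iv[1], iv[2]), g + 1L)
        if (found) return()
      }
    }
    rec(p, 0L)
    if (found) return(lim)
  }
  stop("iddfs failed")
}

# every interval sequence of exactly length d from p that reaches target
or_all_scenarios <- function(p, target, d) {
  ivs <- or_intervals(length(p))
  out <- list()
  rec <- function(q, steps) {
    if (length(steps) == d) {
      if (identical(q, target))
        out[[length(out) + 1]] <<- steps
      return()
    }
    for (iv in ivs) rec(or_apply_rev(q, iv[1], iv[2]), c(steps, list(iv)))
  }
  rec(p, list())
  out
}

or_random_order <- function(n, ids = NULL) {
  if (is.null(ids)) ids <- paste0("b", 1:n)
  block_order(ids[sample(n)], sample(c(-1L, 1L), n, replace = TRUE),
              topology = "linear")
}

or_rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

or_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "", fixed = TRUE)[[1]]),
        collapse = "")
}

# exhaustive inverted-repeat oracle: full antidiagonal scan with the same
# hit definition as the scanner (perfect cores >= min_stem chained across
# gaps <= max_gap under the total mismatch budget; maximal by containment)
or_inverted_repeats <- function(s, min_stem = 6L, max_loop = Inf,
                                frac = 0.1, max_gap = 50L) {
  s <- toupper(s)
  n <- nchar(s)
  code <- c(A = 0L, C = 1L, G = 2L, T = 3L)[strsplit(s, "", fixed = TRUE)[[1]]]
  code[is.na(code)] <- -100L
  hits <- list()
  for (cc in 3:(2 * n - 1)) {
    pm <- floor((cc - 1) / 2)
    ps <- 1:pm
    ps <- ps[cc - ps <= n]
    if (length(ps) < min_stem) next
    mv <- (code[ps] + code[cc - ps]) == 3L
    r <- rle(mv)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    runs <- which(r$values & r$lengths >= min_stem)
    if (!length(runs)) next
    ra <- ps[starts[runs]]; rb <- ps[ends[runs]]
    m <- length(ra)
    feas <- list()
    for (i in 1:m) for (j in i:m) {
      ok <- TRUE; mm <- 0L
      if (j > i) for (t in (i + 1):j) {
        gap <- ra[t] - rb[t - 1] - 1
        if (gap > max_gap) { ok <- FALSE; break }
        if (gap > 0) {
          gp <- (rb[t - 1] + 1):(ra[t] - 1)
          mm <- mm + sum((code[gp] + code[cc - gp]) != 3L)
        }
      }
      if (!ok) next
      L <- rb[j] - ra[i] + 1
      if (mm > floor(frac * L)) next
      feas[[length(feas) + 1]] <- c(ra[i], rb[j], mm)
    }
    if (!length(feas)) next
    fm <- do.call(rbind, feas)
    keep <- rep(TRUE, nrow(fm))
    for (i in seq_len(nrow(fm))) for (j in seq_len(nrow(fm))) {
      if (i != j && fm[j, 1] <= fm[i, 1] && fm[j, 2] >= fm[i, 2] &&
          (fm[j, 1] < fm[i, 1] || fm[j, 2] > fm[i, 2])) keep[i] <- FALSE
    }
    fm <- fm[keep, , drop = FALSE]
    for (i in seq_len(nrow(fm))) {
      a <- fm[i, 1]; b <- fm[i, 2]; mm <- fm[i, 3]
      stem <- b - a + 1; loop <- (cc - b) - b - 1
      if (loop < 0 || loop > max_loop) next
      hits[[length(hits) + 1]] <- data.frame(
        left_start = a, left_end = b, right_start = cc - b,
        right_end = cc - a, stem_len = stem, loop_len = loop,
        mismatches = mm, identity_fraction = 1 - mm / stem)
    }
  }
  if (!length(hits))
    return(data.frame(left_start = integer(0), left_end = integer(0),
                      right_start = integer(0), right_end = integer(0),
                      stem_len = integer(0), loop_len = integer(0),
                      mismatches = integer(0), identity_fraction = numeric(0)))
  out <- do.call(rbind, hits)
  out <- out[order(-out$stem_len, out$loop_len, out$left_start), ]
  rownames(out) <- NULL
  out
}

# minimum parsimony score of one column by exhaustive assignment of the
# five states to all internal nodes
or_fitch_column_score <- function(tree, states) {
  alpha <- c("A", "C", "G", "T", "-")
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  edge <- tree$edge
  leaf_state <- match(states[tree$tip.label], alpha)
  grid <- do.call(expand.grid, rep(list(1:5), nint))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    assign_all <- c(leaf_state, as.integer(grid[r, ]))
    cost <- sum(assign_all[edge[, 1]] != assign_all[edge[, 2]])
    if (cost < best) best <- cost
  }
  best
}
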