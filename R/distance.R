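# Hannenhalli-Pevzner reversal distance for signed permutations
# (linear, fixed ends): d = n + 1 - c + h + f, with c the number of cycles of
# the breakpoint graph, h the number of hurdles and f the fortress indicator.
# O(n^2) throughout, which is ample at gene-block scale.

# Unsigned doubling framed by 0 and 2n+1: +x -> (2x-1, 2x), -x -> (2x, 2x-1).
.hp_double <- function(perm) {
  n <- length(perm)
  out <- integer(2L * n + 2L)
  k <- 2L
  for (x in perm) {
    if (x > 0L) {
      out[k] <- 2L * x - 1L; out[k + 1L] <- 2L * x
    } else {
      out[k] <- -2L * x; out[k + 1L] <- -2L * x - 1L
    }
    k <- k + 2L
  }
  out[2L * n + 2L] <- 2L * n + 1L
  out
}

# Breakpoint-graph structure: cycles and gray edges with spans/orientation.
# Positions are 0-based along the doubled sequence.
.hp_graph <- function(perm) {
  n <- length(perm)
  dbl <- .hp_double(perm)
  pos <- integer(2L * n + 2L)           # pos[value + 1] = 0-based position
  pos[dbl + 1L] <- 0:(2L * n + 1L)

  n_edges <- n + 1L
  # gray edge i (i = 0..n) joins values 2i and 2i+1
  g_lo <- pmin(pos[2L * (0:n) + 1L], pos[2L * (0:n) + 2L])
  g_hi <- pmax(pos[2L * (0:n) + 1L], pos[2L * (0:n) + 2L])
  g_oriented <- ((g_lo + g_hi) %% 2L) == 0L

  # cycle of each gray edge: walk alternating black/gray from each black edge
  # black edge i joins positions 2i and 2i+1
  black_partner <- integer(2L * n + 2L) # by position (1-based index)
  black_partner[2L * (0:n) + 1L] <- 2L * (0:n) + 1L   # pos 2i -> 2i+1
  black_partner[2L * (0:n) + 2L] <- 2L * (0:n)        # pos 2i+1 -> 2i
  gray_partner_val <- integer(2L * n + 2L)  # by value (1-based index)
  gray_partner_val[2L * (0:n) + 1L] <- 2L * (0:n) + 1L  # value 2i -> 2i+1
  gray_partner_val[2L * (0:n) + 2L] <- 2L * (0:n)       # value 2i+1 -> 2i

  cycle_of_gray <- integer(n_edges)
  cycle_len <- integer(0)               # number of black edges per cycle
  seen_black <- logical(n_edges)
  n_cycles <- 0L
  for (b in 0:n) {
    if (seen_black[b + 1L]) next
    n_cycles <- n_cycles + 1L
    len <- 0L
    p <- 2L * b                         # start position of black edge b
    repeat {
      bi <- p %/% 2L                    # black edge index at position p
      if (seen_black[bi + 1L]) break
      seen_black[bi + 1L] <- TRUE
      len <- len + 1L
      q <- black_partner[p + 1L]        # traverse black edge
      v <- dbl[q + 1L]                  # value at far end
      gi <- v %/% 2L                    # gray edge index on that value
      cycle_of_gray[gi + 1L] <- n_cycles
      w <- gray_partner_val[v + 1L]     # traverse gray edge
      p <- pos[w + 1L]
    }
    cycle_len <- c(cycle_len, len)
  }

  list(n = n, n_cycles = n_cycles, cycle_len = cycle_len,
       g_lo = g_lo, g_hi = g_hi, g_oriented = g_oriented,
       cycle_of_gray = cycle_of_gray)
}

# Interleaving components of the breakpoint graph, as cycle groupings.
.hp_components <- function(graph) {
  nc <- graph$n_cycles
  parent <- seq_len(nc)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  union <- function(x, y) { rx <- find(x); ry <- find(y); if (rx != ry) parent[rx] <<- ry }
  ne <- length(graph$g_lo)
  if (ne > 1L) {
    for (i in 1:(ne - 1L)) for (j in (i + 1L):ne) {
      a1 <- graph$g_lo[i]; b1 <- graph$g_hi[i]
      a2 <- graph$g_lo[j]; b2 <- graph$g_hi[j]
      if ((a1 < a2 && a2 < b1 && b1 < b2) || (a2 < a1 && a1 < b2 && b2 < b1))
        union(graph$cycle_of_gray[i], graph$cycle_of_gray[j])
    }
  }
  comp_of_cycle <- vapply(seq_len(nc), find, 1L)
  comp_ids <- unique(comp_of_cycle)
  comps <- lapply(comp_ids, function(cid) {
    cyc <- which(comp_of_cycle == cid)
    gidx <- which(graph$cycle_of_gray %in% cyc)
    list(cycles = cyc,
         lo = min(graph$g_lo[gidx]), hi = max(graph$g_hi[gidx]),
         oriented = any(graph$g_oriented[gidx]),
         trivial = all(graph$cycle_len[cyc] == 1L))
  })
  comps
}

# Hurdle count among unoriented component spans [lo, hi]: a component is a
# hurdle when no other unoriented component lies strictly inside its span, or
# when every other unoriented component does.
.hp_count_hurdles <- function(lo, hi) {
  k <- length(lo)
  if (k == 0L) return(logical(0))
  vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    if (!length(others)) return(TRUE)
    inside <- lo[i] < lo[others] & hi[others] < hi[i]
    all(inside) || !any(inside)
  }, TRUE)
}

.hp_distance <- function(perm) {
  n <- length(perm)
  if (n == 0L) return(0L)
  graph <- .hp_graph(perm)
  comps <- .hp_components(graph)
  unor <- Filter(function(cp) !cp$oriented && !cp$trivial, comps)
  lo <- vapply(unor, `[[`, 1L, "lo"); hi <- vapply(unor, `[[`, 1L, "hi")
  is_hurdle <- .hp_count_hurdles(lo, hi)
  h <- sum(is_hurdle)
  f <- 0L
  if (h >= 3L && h %% 2L == 1L) {
    # fortress: odd number of hurdles, all of them super-hurdles (removing
    # the hurdle promotes a protecting non-hurdle component to hurdle status)
    super <- vapply(which(is_hurdle), function(i) {
      sum(.hp_count_hurdles(lo[-i], hi[-i])) == h
    }, TRUE)
    if (all(super)) f <- 1L
  }
  as.integer(n + 1L - graph$n_cycles + h + f)
}
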