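# Small fixture builders shared across test files. Everything is generated
# in code at test time; no binary fixtures.

# One-hot genotype likelihoods from a hard genotype matrix (sites x ind);
# NA entries become flat (missing) triplets.
gl_from_genotypes <- function(g, chrom = "chr1", spacing = 100L) {
  m <- nrow(g); n <- ncol(g)
  gl <- array(0, c(m, n, 3L))
  for (k in 0:2) gl[, , k + 1L][g == k] <- 1
  flat <- is.na(g)
  for (k in 1:3) gl[, , k][flat] <- 1 / 3
  markers <- data.frame(chrom = chrom, pos = seq_len(m) * spacing,
                        major = "A", minor = "C")
  gl_dataset(markers, gl, sprintf("ind%03d", seq_len(n)))
}

# Random hard-genotype dataset with site frequencies drawn from U(lo, hi).
random_genotype_dataset <- function(m, n, seed, lo = 0.1, hi = 0.5) {
  set.seed(seed)
  p <- runif(m, lo, hi)
  g <- matrix(rbinom(m * n, 2L, p), m, n)
  list(ds = gl_from_genotypes(g), g = g, p = p)
}

# Reference single-source shortest paths by plain O(V^2) Dijkstra over an
# explicit edge list; used as the oracle for least_cost_distance.
dijkstra_oracle <- function(n_nodes, edges, source) {
  dist <- rep(Inf, n_nodes)
  dist[source] <- 0
  done <- rep(FALSE, n_nodes)
  for (step in seq_len(n_nodes)) {
    u <- which(!done & dist == min(dist[!done]))[1L]
    if (!length(u) || is.na(u) || !is.finite(dist[u])) break
    done[u] <- TRUE
    hit <- which(edges$from == u | edges$to == u)
    for (e in hit) {
      v <- if (edges$from[e] == u) edges$to[e] else edges$from[e]
      if (dist[u] + edges$w[e] < dist[v]) dist[v] <- dist[u] + edges$w[e]
    }
  }
  dist
}

# Edge list (8-neighbour moves) of a raster's water cells, for the oracle.
raster_edges <- function(grid, cellsize) {
  nr <- nrow(grid); nc <- ncol(grid)
  water <- which(grid == 0L)
  node <- match(seq_len(nr * nc), water)
  from <- integer(0); to <- integer(0); w <- numeric(0)
  for (cell in water) {
    r <- (cell - 1L) %% nr + 1L
    cc <- (cell - 1L) %/% nr + 1L
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      cell2 <- (c2 - 1L) * nr + r2
      if (is.na(node[cell2]) || cell2 < cell) next
      from <- c(from, node[cell]); to <- c(to, node[cell2])
      w <- c(w, cellsize * sqrt(dr^2 + dc^2))
    }
  }
  data.frame(from = from, to = to, w = w)
}

# Brute-force interval merger: flagged window indices (one chromosome) are
# clustered by scanning, merging neighbours with index gap <= max_gap.
merge_oracle <- function(flagged, max_gap) {
  flagged <- sort(flagged)
  if (!length(flagged)) return(list())
  groups <- list(flagged[1L])
  for (x in flagged[-1L]) {
    last <- groups[[length(groups)]]
    if (x - last[length(last)] <= max_gap)
      groups[[length(groups)]] <- c(last, x)
    else groups[[length(groups) + 1L]] <- x
  }
  groups
}

expect_region_members <- function(regions, windows, expected_groups) {
  got <- lapply(strsplit(regions$windows, ","), as.integer)
  expect_equal(length(got), length(expected_groups))
  for (k in seq_along(expected_groups))
    expect_equal(got[[k]], expected_groups[[k]])
}
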