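#' Per-population allele frequencies with fixed global polarity
#'
#' EM frequencies (as in [estimate_maf_em()]) computed within each group,
#' always counting the dataset's global minor allele (allele2), so that
#' frequencies are comparable across groups without re-folding. The haploid
#' sample size per site and group is twice the number of individuals with
#' data.
#'
#' Frequencies estimated from genotype likelihoods carry more sampling
#' variance than called genotypes would, so alongside the plain haploid
#' count `n = 2 x individuals with data` the effective haploid size
#' `n_eff = p(1-p) x Fisher information` of each site's frequency
#' likelihood is returned; `n_eff` equals `n` for hard genotypes and
#' shrinks as depth drops, and it is what [hudson_fst()] uses for its
#' finite-sample correction.
#'
#' @param ds a [gl_dataset()].
#' @param groups group label per individual.
#' @return object of class `pop_freqs`: list with `p` (sites x groups), `n`
#'   (haploid sizes, sites x groups), `n_eff` (effective haploid sizes),
#'   `groups` (levels), `markers`.
#' @export
pop_allele_freqs <- function(ds, groups) {
  stopifnot(length(groups) == n_individuals(ds))
  levels <- unique(groups)
  miss <- gl_missing(ds)
  p <- matrix(NA_real_, n_markers(ds), length(levels),
              dimnames = list(NULL, levels))
  nmat <- p
  neff <- p
  for (g in seq_along(levels)) {
    cols <- which(groups == levels[g])
    sub <- gl_subset(ds, individuals = cols)
    em <- estimate_maf_em(sub)
    f <- em$f
    p[, g] <- ifelse(em$flagged, NA_real_, f)
    nmat[, g] <- 2 * rowSums(!miss[, cols, drop = FALSE])
    # observed Fisher information (negative curvature of the per-site
    # log-likelihood sum(log l_i(f)) at the EM estimate), with
    # l_i(f) = GL0 (1-f)^2 + GL1 2f(1-f) + GL2 f^2
    l0 <- .gl_slice(sub$gl, 1); l1 <- .gl_slice(sub$gl, 2); l2 <- .gl_slice(sub$gl, 3)
    lik <- l0 * (1 - f)^2 + l1 * 2 * f * (1 - f) + l2 * f^2
    dl <- l0 * (-2 * (1 - f)) + l1 * (2 - 4 * f) + l2 * 2 * f
    d2l <- 2 * l0 - 4 * l1 + 2 * l2
    cur <- -(d2l * lik - dl^2) / pmax(lik^2, 1e-300)
    cur[miss[, cols, drop = FALSE]] <- 0
    info <- rowSums(cur)
    neff[, g] <- pmin(nmat[, g], pmax(f * (1 - f) * info, 0))
  }
  structure(list(p = p, n = nmat, n_eff = neff, groups = levels,
                 markers = ds$markers), class = "pop_freqs")
}

#' Hudson's FST (ratio of averages)
#'
#' Per-site components
#' `N = (p1 - p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `D = p1(1-p2) + p2(1-p1)`; the genome-wide estimate is `sum(N)/sum(D)`,
#' the sample-size-robust ratio-of-averages form. Sites with a haploid size
#' below 2 in either group, or with missing frequencies, are skipped.
#'
#' The haploid sizes entering the correction are the effective sizes of
#' [pop_allele_freqs()] (equal to twice the individuals with data for hard
#' genotypes); this keeps the numerator unbiased when frequencies come from
#' shallow genotype likelihoods rather than called genotypes.
#'
#' @param freqs a [pop_allele_freqs()] result.
#' @param pair length-2 vector of group labels or indices.
#' @return list with `fst`, `n_sites`, and `per_site` (data.frame of
#'   components, aligned to used sites).
#' @export
hudson_fst <- function(freqs, pair) {
  idx <- .pair_index(freqs, pair)
  p1 <- freqs$p[, idx[1L]]; p2 <- freqs$p[, idx[2L]]
  nm <- freqs$n_eff %||% freqs$n
  n1 <- nm[, idx[1L]]; n2 <- nm[, idx[2L]]
  use <- !is.na(p1) & !is.na(p2) & n1 >= 2 & n2 >= 2
  p1 <- p1[use]; p2 <- p2[use]; n1 <- n1[use]; n2 <- n2[use]
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  ok <- den > 0
  list(fst = sum(num[ok]) / sum(den[ok]), n_sites = sum(ok),
       per_site = data.frame(site = which(use)[ok], num = num[ok],
                             den = den[ok]))
}

#' Absolute allele frequency difference (AFD)
#'
#' Mean over sites of `|p1 - p2|` with globally polarized alleles.
#'
#' @inheritParams hudson_fst
#' @return AFD value in [0, 1].
#' @export
afd <- function(freqs, pair) {
  idx <- .pair_index(freqs, pair)
  p1 <- freqs$p[, idx[1L]]; p2 <- freqs$p[, idx[2L]]
  use <- !is.na(p1) & !is.na(p2)
  if (!any(use)) stop("no shared sites between the two groups")
  mean(abs(p1[use] - p2[use]))
}

.pair_index <- function(freqs, pair) {
  stopifnot(length(pair) == 2L)
  idx <- if (is.character(pair)) match(pair, freqs$groups) else as.integer(pair)
  if (anyNA(idx) || any(idx < 1L) || any(idx > length(freqs$groups)))
    stop("unknown group in pair")
  idx
}

#' Linearized FST
#'
#' `f / (1 - f)`, the transform conventionally regressed against geographic
#' distance in isolation-by-distance analyses.
#'
#' @param f FST value(s), each < 1.
#' @return transformed value(s).
#' @export
linearize_fst <- function(f) {
  if (any(f >= 1)) stop("FST must be < 1 to linearize")
  f / (1 - f)
}

#' All pairwise differentiation matrices
#'
#' @param freqs a [pop_allele_freqs()] result.
#' @return list of symmetric matrices `fst`, `linear_fst`, `afd` over groups.
#' @export
pairwise_divergence <- function(freqs) {
  g <- length(freqs$groups)
  fst <- matrix(0, g, g, dimnames = list(freqs$groups, freqs$groups))
  afd_m <- fst
  for (a in seq_len(g - 1L)) for (b in (a + 1L):g) {
    fst[a, b] <- fst[b, a] <- hudson_fst(freqs, c(a, b))$fst
    afd_m[a, b] <- afd_m[b, a] <- afd(freqs, c(a, b))
  }
  lin <- linearize_fst(pmin(fst, 1 - 1e-12))
  diag(lin) <- 0
  list(fst = fst, linear_fst = lin, afd = afd_m)
}

#' Least-cost in-water distances over a habitat raster
#'
#' Dijkstra shortest paths on the graph of water cells with 8-neighbour
#' moves; a step costs one cell size (`sqrt(2)` times that diagonally) and
#' land has infinite resistance. Sample coordinates are raster (row, col)
#' cells and are snapped to the nearest water cell. Disconnected basins give
#' `Inf`.
#'
#' @param raster a `raster_map` from [read_raster()].
#' @param coords data.frame with columns `row`, `col` (one row per sample or
#'   site), optionally `site` for labelling.
#' @return symmetric matrix of distances in km.
#' @export
least_cost_distance <- function(raster, coords) {
  grid <- raster$grid
  nr <- nrow(grid); nc <- ncol(grid)
  if (any(coords$row < 1 | coords$row > nr | coords$col < 1 |
            coords$col > nc))
    stop("coordinate outside the raster grid")
  water <- which(grid == 0L)                      # column-major cell ids
  node <- match(seq_len(nr * nc), water)          # cell -> node or NA
  edges <- integer(0); weights <- numeric(0)
  from <- integer(0); to <- integer(0)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  wr <- (water - 1L) %% nr + 1L
  wc <- (water - 1L) %/% nr + 1L
  for (k in seq_len(nrow(offs))) {
    r2 <- wr + offs$dr[k]; c2 <- wc + offs$dc[k]
    ok <- r2 >= 1L & r2 <= nr & c2 >= 1L & c2 <= nc
    cell2 <- (c2 - 1L) * nr + r2
    ok[ok] <- !is.na(node[cell2[ok]])
    from <- c(from, node[water[ok]])
    to <- c(to, node[cell2[ok]])
    weights <- c(weights, rep(raster$cellsize *
                                sqrt(offs$dr[k]^2 + offs$dc[k]^2), sum(ok)))
  }
  g <- igraph::make_graph(as.vector(rbind(from, to)), n = length(water),
                          directed = FALSE)
  snap <- vapply(seq_len(nrow(coords)), function(i) {
    d2 <- (wr - coords$row[i])^2 + (wc - coords$col[i])^2
    which.min(d2)
  }, 0L)
  d <- igraph::distances(g, v = snap, to = snap, weights = weights,
                         algorithm = "dijkstra")
  dimnames(d) <- list(coords$site %||% NULL, coords$site %||% NULL)
  d
}

#' Mantel test of matrix association
#'
#' Pearson correlation of the lower triangles with significance from
#' simultaneous row/column permutations (one-tailed, greater, with the +1
#' correction); delegated to the community-standard implementation in vegan.
#'
#' @param A,B symmetric matrices of equal dimension.
#' @param permutations number of permutations (default 9999).
#' @param seed integer seed for the permutation stream.
#' @return list with `r`, `p`, `permutations`.
#' @export
mantel_ibd <- function(A, B, permutations = 9999L, seed = 1L) {
  if (!is.matrix(A) || !is.matrix(B) || !identical(dim(A), dim(B)) ||
      nrow(A) != ncol(A))
    stop("A and B must be square matrices of identical dimension")
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8)
    stop("A and B must be symmetric")
  set.seed(seed)
  fit <- vegan::mantel(stats::as.dist(A), stats::as.dist(B),
                       method = "pearson", permutations = permutations)
  list(r = unname(fit$statistic), p = fit$signif,
       permutations = permutations)
}
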