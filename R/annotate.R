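#' Genes overlapping candidate regions
#'
#' Any-overlap intersection of 1-based inclusive intervals with zero flank
#' (a shared boundary bp counts as overlap), computed with GenomicRanges.
#'
#' @param regions region data.frame (`chrom`, `start`, `end`, optional
#'   `label`).
#' @param genes gene table from [read_gff_genes()].
#' @return list of de-duplicated gene-id vectors, one per region (named by
#'   region label when present).
#' @export
overlap_genes <- function(regions, genes) {
  if (!nrow(regions))
    return(setNames(list(), character(0)))
  rg <- GenomicRanges::GRanges(regions$chrom,
                               IRanges::IRanges(regions$start, regions$end))
  if (nrow(genes)) {
    gg <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end))
    hits <- GenomicRanges::findOverlaps(rg, gg)
    from <- S4Vectors::queryHits(hits)
    to <- S4Vectors::subjectHits(hits)
  } else {
    from <- integer(0); to <- integer(0)
  }
  out <- lapply(seq_len(nrow(regions)), function(r)
    unique(genes$gene_id[to[from == r]]))
  names(out) <- regions$label %||% as.character(seq_len(nrow(regions)))
  out
}

#' GO-term enrichment of a gene selection
#'
#' Per GO term with at least `min_size` universe genes: hypergeometric
#' upper-tail probability of drawing at least the observed number of
#' term genes in a selection of size `n` from a universe of size `N`,
#' followed by Benjamini-Hochberg adjustment across tested terms. The
#' gene-to-GO mapping is assumed pre-propagated up the GO graph.
#'
#' @param selected character vector of selected gene ids (must be a subset
#'   of `universe`).
#' @param universe character vector of all gene ids.
#' @param gene2go data.frame from [read_gene2go()].
#' @param alpha significance level on the adjusted p (default 0.05).
#' @param min_size minimum universe genes per tested term (default 2).
#' @return data.frame sorted by adjusted p: `go_id`, `term_size`,
#'   `selected_size`, `p`, `p_adj`, `significant`.
#' @export
go_enrichment <- function(selected, universe, gene2go, alpha = 0.05,
                          min_size = 2L) {
  selected <- unique(selected)
  universe <- unique(universe)
  if (!all(selected %in% universe))
    stop("selection must be a subset of the universe")
  g2g <- gene2go[gene2go$gene_id %in% universe, , drop = FALSE]
  terms <- split(g2g$gene_id, g2g$go_id)
  terms <- terms[lengths(lapply(terms, unique)) >= min_size]
  if (!length(terms))
    return(data.frame(go_id = character(), term_size = integer(),
                      selected_size = integer(), p = numeric(),
                      p_adj = numeric(), significant = logical()))
  N <- length(universe)
  n <- length(selected)
  rows <- lapply(names(terms), function(go) {
    tg <- unique(terms[[go]])
    K <- length(tg)
    k <- sum(selected %in% tg)
    p <- phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
    data.frame(go_id = go, term_size = K, selected_size = k, p = p)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p, method = "BH")
  out$significant <- out$p_adj < alpha
  out[order(out$p_adj, out$p, out$go_id), , drop = FALSE]
}
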