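#' Pairwise linkage disequilibrium within a distance band
#'
#' `r2` is the squared Pearson correlation of posterior-mean dosages across
#' jointly non-missing individuals, for every same-chromosome pair within
#' `max_dist` bp. Pairs with fewer than `min_shared` shared individuals, or
#' with a monomorphic dosage vector among them, are skipped.
#'
#' @param ds a [gl_dataset()], or `NULL` when `dosage` is supplied directly.
#' @param max_dist maximum pair distance in bp.
#' @param min_shared minimum jointly non-missing individuals.
#' @param dosage optional precomputed dosage matrix (sites x individuals,
#'   `NA` = missing); computed with [posterior_dosage()] otherwise.
#' @param markers marker table matching `dosage` (required with `dosage`).
#' @return data.frame with columns `i`, `j` (marker row indices), `dist`,
#'   `r2`.
#' @export
ld_r2 <- function(ds = NULL, max_dist = 200000, min_shared = 10L,
                  dosage = NULL, markers = NULL) {
  if (is.null(dosage)) {
    stopifnot(inherits(ds, "gl_dataset"))
    dosage <- posterior_dosage(ds)
    markers <- ds$markers
  }
  stopifnot(!is.null(markers), nrow(dosage) == nrow(markers))
  chrom_id <- match(markers$chrom, unique(markers$chrom))
  .ld_pairs_band_cpp(dosage, as.integer(markers$pos),
                     as.integer(chrom_id), max_dist, as.integer(min_shared))
}

#' r2 for explicit site pairs
#'
#' @param dosage dosage matrix (sites x individuals, `NA` = missing).
#' @param i,j 1-based site row indices of equal length.
#' @param min_shared minimum jointly non-missing individuals.
#' @return numeric vector of r2 values (`NA` where a pair was skipped).
#' @export
ld_r2_pairs <- function(dosage, i, j, min_shared = 10L) {
  stopifnot(length(i) == length(j))
  .r2_for_pairs_cpp(dosage, as.integer(i), as.integer(j),
                    as.integer(min_shared))
}

#' Greedy LD pruning
#'
#' Repeatedly removes the site with the highest count of pairs violating the
#' r2 threshold until no violating pair remains; ties are broken by removing
#' the lower-MAF site first, then the later position.
#'
#' @param ds a [gl_dataset()].
#' @param r2_threshold maximum tolerated r2 (default 0.075).
#' @param max_dist pair distance cap in bp (default 200 kb).
#' @param pairs optional precomputed [ld_r2()] table.
#' @param maf optional per-site minor-allele frequencies for tie-breaking.
#' @return integer vector of kept marker rows (increasing).
#' @export
ld_prune <- function(ds, r2_threshold = 0.075, max_dist = 200000,
                     pairs = NULL, maf = NULL) {
  m <- n_markers(ds)
  if (is.null(maf)) maf <- estimate_maf_em(ds)$f
  maf <- pmin(maf, 1 - maf)
  if (is.null(pairs)) pairs <- ld_r2(ds, max_dist = max_dist)
  viol <- pairs[pairs$r2 > r2_threshold, c("i", "j"), drop = FALSE]
  removed <- rep(FALSE, m)
  if (nrow(viol)) {
    counts <- tabulate(c(viol$i, viol$j), nbins = m)
    alive_pair <- rep(TRUE, nrow(viol))
    while (TRUE) {
      worst <- max(counts)
      if (worst == 0L) break
      cand <- which(counts == worst)
      if (length(cand) > 1L) cand <- cand[maf[cand] == min(maf[cand])]
      victim <- cand[length(cand)]  # later position among remaining ties
      removed[victim] <- TRUE
      hit <- alive_pair & (viol$i == victim | viol$j == victim)
      partners <- c(viol$j[hit & viol$i == victim],
                    viol$i[hit & viol$j == victim])
      counts[partners] <- counts[partners] - 1L
      counts[victim] <- 0L
      alive_pair[hit] <- FALSE
    }
  }
  which(!removed)
}
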