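#' Karyotype individuals from region PC1 scores by k-means
#'
#' Inversion polymorphisms produce three PC1 clusters in a local PCA of the
#' inverted region: the two arrangement homozygotes at the extremes and the
#' heterokaryotypes between them. Individuals are clustered on PC1 with
#' k = 3 (50 restarts); if any cluster has fewer than 2 members or the mean
#' silhouette falls below 0.3, the clustering is redone with k = 4..6 (best
#' silhouette wins) and the k centers are merged back into three groups by
#' 1-D 3-means on the centers. Groups are ordered by PC1 center: the middle
#' group is `AB`, and the larger extreme group is `AA`.
#'
#' @param pc1 numeric PC1 scores (one per individual).
#' @param k initial cluster count (default 3).
#' @param restarts k-means restarts (default 50).
#' @param seed integer seed.
#' @param min_sil silhouette threshold triggering the fallback.
#' @return object of class `karyotype_calls`: `labels` (AA/AB/BB per
#'   individual), `pc1`, `centers`, `fallback_k` (`NA` when k = 3
#'   sufficed).
#' @export
karyotype_kmeans <- function(pc1, k = 3L, restarts = 50L, seed = 1L,
                             min_sil = 0.3) {
  n <- length(pc1)
  if (n < 6L) stop("need at least 6 individuals to karyotype")
  x <- matrix(pc1, ncol = 1)
  set.seed(substream_seed(seed, "karyotype"))
  fit <- kmeans(x, centers = k, nstart = restarts)
  sil_ok <- function(cl) {
    if (length(unique(cl)) < 2L) return(0)
    mean(cluster::silhouette(cl, dist(x))[, "sil_width"])
  }
  fallback_k <- NA_integer_
  assign3 <- fit$cluster
  centers3 <- as.vector(fit$centers)
  if (min(fit$size) < 2L || sil_ok(fit$cluster) < min_sil) {
    best <- NULL
    for (kk in 4:6) {
      if (kk >= n) break
      f2 <- kmeans(x, centers = kk, nstart = restarts)
      s <- sil_ok(f2$cluster)
      if (is.null(best) || s > best$s) best <- list(fit = f2, s = s, k = kk)
    }
    if (!is.null(best)) {
      fallback_k <- best$k
      cen <- as.vector(best$fit$centers)
      grp_of_center <- kmeans(matrix(cen, ncol = 1), centers = 3L,
                              nstart = restarts)$cluster
      assign3 <- grp_of_center[best$fit$cluster]
      centers3 <- vapply(1:3, function(g) mean(pc1[assign3 == g]), 0)
    }
  }
  ord <- order(centers3)
  pos <- match(assign3, ord)       # 1 = low PC1, 2 = middle, 3 = high
  lab <- c("L", "AB", "H")[pos]
  n_low <- sum(lab == "L"); n_high <- sum(lab == "H")
  labels <- ifelse(lab == "AB", "AB",
                   ifelse(lab == "L",
                          if (n_low >= n_high) "AA" else "BB",
                          if (n_high > n_low) "AA" else "BB"))
  structure(list(labels = labels, pc1 = pc1, centers = sort(centers3),
                 fallback_k = fallback_k), class = "karyotype_calls")
}

#' Heterozygosity contrast between karyotype groups
#'
#' Per-individual heterozygosity over the region's SNPs, compared between
#' groups with one-sided Wilcoxon rank-sum tests: heterokaryotypes (AB) are
#' expected to exceed both homozygote groups because recombination between
#' arrangements is suppressed. The default estimator is the posterior
#' heterozygote probability summed over non-missing sites (the probabilistic
#' analogue of counting SAF = 1 sites); `method = "calls"` counts
#' maximum-posterior heterozygote calls instead, which is noticeably biased
#' at depths near 1x.
#'
#' @param ds a [gl_dataset()].
#' @param region list or one-row data.frame with `chrom`, `start`, `end`.
#' @param calls a [karyotype_kmeans()] result (or character labels).
#' @param method `"expected"` (default) or `"calls"`.
#' @return list with `het` (per individual), `medians` (per label),
#'   `p_ab_aa`, `p_ab_bb` (`NA` with a note when a group is empty).
#' @export
region_het_test <- function(ds, region, calls,
                            method = c("expected", "calls")) {
  method <- match.arg(method)
  labels <- if (inherits(calls, "karyotype_calls")) calls$labels else calls
  stopifnot(length(labels) == n_individuals(ds))
  idx <- which(ds$markers$chrom == region$chrom &
                 ds$markers$pos >= region$start &
                 ds$markers$pos <= region$end)
  if (!length(idx)) stop("region contains no markers")
  sub <- gl_subset(ds, sites = idx)
  if (method == "calls") {
    g <- call_genotypes(sub)
    het <- colSums(g == 1L, na.rm = TRUE) / pmax(colSums(!is.na(g)), 1L)
  } else {
    f <- estimate_maf_em(sub)$f
    p0 <- .gl_slice(sub$gl, 1) * (1 - f)^2
    p1 <- .gl_slice(sub$gl, 2) * 2 * f * (1 - f)
    p2 <- .gl_slice(sub$gl, 3) * f^2
    phet <- p1 / (p0 + p1 + p2)
    obs <- !gl_missing(sub)
    het <- colSums(phet * obs) / pmax(colSums(obs), 1L)
  }
  meds <- tapply(het, labels, median)
  test <- function(a, b) {
    if (!sum(labels == a) || !sum(labels == b)) return(NA_real_)
    suppressWarnings(wilcox.test(het[labels == a], het[labels == b],
                                 alternative = "greater")$p.value)
  }
  list(het = setNames(het, ds$ids), medians = meds,
       p_ab_aa = test("AB", "AA"), p_ab_bb = test("AB", "BB"))
}

#' Z-test of elevated linkage disequilibrium inside a region
#'
#' Mean pairwise r2 among the region's SNPs (pairs subsampled to
#' `max_pairs`) compared with the mean r2 of `n_random` random windows of
#' the same bp length on the same chromosome (uniform starts, windows
#' overlapping the candidate region excluded):
#' `Z = (mean_in - mean(null)) / SD(null)` with a one-tailed upper normal
#' p-value.
#'
#' @param ds a [gl_dataset()].
#' @param region list with `chrom`, `start`, `end`.
#' @param n_random number of random windows (default 1000).
#' @param seed integer seed.
#' @param max_pairs subsample cap for in-region pairs (default 1e5).
#' @param null_pairs subsample cap per random window (default 2000).
#' @param dosage optional precomputed dosage matrix.
#' @return list with `z`, `p`, `mean_in`, `null_mean`, `null_sd`,
#'   `n_windows`, `degenerate` (TRUE when SD(null) = 0).
#' @export
ld_block_test <- function(ds, region, n_random = 1000L, seed = 1L,
                          max_pairs = 100000L, null_pairs = 2000L,
                          dosage = NULL) {
  if (is.null(dosage)) dosage <- posterior_dosage(ds)
  chr_rows <- which(ds$markers$chrom == region$chrom)
  if (!length(chr_rows)) stop("chromosome not in dataset")
  pos <- ds$markers$pos[chr_rows]
  in_region <- chr_rows[pos >= region$start & pos <= region$end]
  if (length(in_region) < 2L) stop("region holds fewer than 2 SNPs")
  set.seed(substream_seed(seed, "ld_block"))
  mean_r2_of <- function(rows, cap) {
    k <- length(rows)
    if (k < 2L) return(NA_real_)
    n_all <- k * (k - 1) / 2
    if (n_all <= cap) {
      pr <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
      ii <- rows[pr[, 1L]]; jj <- rows[pr[, 2L]]
    } else {
      ii <- rows[sample.int(k, cap, replace = TRUE)]
      jj <- rows[sample.int(k, cap, replace = TRUE)]
      keep <- ii != jj
      ii <- ii[keep]; jj <- jj[keep]
    }
    r2 <- ld_r2_pairs(dosage, ii, jj)
    mean(r2, na.rm = TRUE)
  }
  mean_in <- mean_r2_of(in_region, max_pairs)
  span <- region$end - region$start
  chr_len <- max(pos)
  lo <- 1
  hi <- max(chr_len - span, 1)
  null_means <- numeric(0)
  attempts <- 0L
  short <- hi <= lo
  while (length(null_means) < n_random && attempts < 20L * n_random) {
    attempts <- attempts + 1L
    s0 <- runif(1, lo, hi)
    e0 <- s0 + span
    if (s0 <= region$end && e0 >= region$start) next  # overlaps candidate
    rows <- chr_rows[pos >= s0 & pos <= e0]
    m <- mean_r2_of(rows, null_pairs)
    if (!is.na(m)) null_means <- c(null_means, m)
  }
  if (short || length(null_means) < n_random)
    warning("only ", length(null_means),
            " random windows available on this chromosome")
  mu <- mean(null_means)
  sdv <- sd(null_means)
  if (!is.finite(sdv) || sdv == 0)
    return(list(z = NA_real_, p = NA_real_, mean_in = mean_in,
                null_mean = mu, null_sd = sdv,
                n_windows = length(null_means), degenerate = TRUE))
  z <- (mean_in - mu) / sdv
  list(z = z, p = pnorm(z, lower.tail = FALSE), mean_in = mean_in,
       null_mean = mu, null_sd = sdv, n_windows = length(null_means),
       degenerate = FALSE)
}

#' Refine inversion boundaries from tight-linkage counts
#'
#' Using the chromosome-wide distribution of banded pair r2 (pairs within
#' `max_dist`), a SNP is "tightly linked" to another when their r2 exceeds
#' the chromosome's `top_q` quantile. Within the candidate span padded by
#' `pad_frac` on both sides, the refined start is the SNP tightly linked to
#' the most downstream SNPs (ties to the smallest position) and the refined
#' end the SNP tightly linked to the most upstream SNPs (ties to the
#' largest). If no pair clears the threshold or the refined end does not
#' exceed the start, the original span is returned flagged as a fallback.
#'
#' @param ds a [gl_dataset()].
#' @param region list with `chrom`, `start`, `end`.
#' The chromosome-wide r2 quantile is estimated from up to `thr_pairs`
#' randomly drawn banded pairs (seeded); link counts for the padded-region
#' SNPs are exact. Supplying a precomputed `pairs` table instead makes the
#' quantile and the counts exact over that table.
#'
#' @param pad_frac padding around the span as a fraction of its length
#'   (default 0.25).
#' @param top_q chromosome-wide r2 quantile defining tight linkage
#'   (default 0.95).
#' @param max_dist linkage distance cap in bp (default 200 kb).
#' @param dosage optional precomputed dosage matrix.
#' @param pairs optional precomputed [ld_r2()] table for the chromosome
#'   (indices must refer to dataset marker rows).
#' @param thr_pairs pair subsample size for the quantile estimate.
#' @param seed integer seed for the pair subsample.
#' @return list with `start`, `end`, `threshold`, `fallback`.
#' @export
refine_boundaries <- function(ds, region, pad_frac = 0.25, top_q = 0.95,
                              max_dist = 200000, dosage = NULL,
                              pairs = NULL, thr_pairs = 200000L, seed = 1L) {
  chr_rows <- which(ds$markers$chrom == region$chrom)
  if (!length(chr_rows)) stop("chromosome not in dataset")
  fallback <- list(start = region$start, end = region$end,
                   threshold = NA_real_, fallback = TRUE)
  pos <- ds$markers$pos
  pad <- (region$end - region$start) * pad_frac
  in_pad <- chr_rows[pos[chr_rows] >= region$start - pad &
                       pos[chr_rows] <= region$end + pad]
  if (!length(in_pad)) return(fallback)
  if (!is.null(pairs)) {
    if (!nrow(pairs)) return(fallback)
    thr <- unname(quantile(pairs$r2, top_q))
    tight <- pairs[pairs$r2 > thr, , drop = FALSE]
    if (!nrow(tight)) return(fallback)
    down <- tabulate(tight$i, nbins = n_markers(ds))[in_pad]
    up <- tabulate(tight$j, nbins = n_markers(ds))[in_pad]
  } else {
    if (is.null(dosage)) dosage <- posterior_dosage(ds)
    dos <- dosage[chr_rows, , drop = FALSE]
    cpos <- pos[chr_rows]
    set.seed(substream_seed(seed, "refine_thr"))
    ii <- sample.int(length(chr_rows), thr_pairs, replace = TRUE)
    span <- pmax(1, findInterval(cpos[ii] + max_dist, cpos) - ii)
    jj <- ii + ceiling(runif(thr_pairs) * span)
    keep <- jj > ii & jj <= length(chr_rows) &
      (cpos[pmin(jj, length(chr_rows))] - cpos[ii]) <= max_dist
    r2 <- ld_r2_pairs(dos, ii[keep], jj[keep])
    r2 <- r2[!is.na(r2)]
    if (!length(r2)) return(fallback)
    thr <- unname(quantile(r2, top_q))
    counts <- .link_counts_cpp(dos, as.integer(cpos),
                               as.integer(match(in_pad, chr_rows)),
                               max_dist, thr, 10L)
    down <- counts$down
    up <- counts$up
  }
  if (max(down) == 0L || max(up) == 0L) return(fallback)
  start <- min(pos[in_pad[down == max(down)]])
  end <- max(pos[in_pad[up == max(up)]])
  if (end <= start) return(fallback)
  list(start = start, end = end, threshold = thr, fallback = FALSE)
}

#' Region length in kbp
#'
#' `(end - start) / 1000`, reported to one decimal.
#'
#' @param start,end boundary positions in bp, `end > start`.
#' @return length in kbp, rounded to one decimal.
#' @export
region_length_kbp <- function(start, end) {
  if (any(end <= start)) stop("end must exceed start")
  round((end - start) / 1000, 1)
}

#' Karyotype frequencies per sampling site
#'
#' Fractions of AA/AB/BB per site plus the inversion-allele frequency
#' `(n_AB + 2 n_BB) / (2 n)`.
#'
#' @param calls a [karyotype_kmeans()] result or character labels.
#' @param site_labels sampling-site label per individual.
#' @return data.frame with one row per site.
#' @export
karyotype_frequencies <- function(calls, site_labels) {
  labels <- if (inherits(calls, "karyotype_calls")) calls$labels else calls
  stopifnot(length(labels) == length(site_labels))
  out <- lapply(unique(site_labels), function(s) {
    l <- labels[site_labels == s]
    n <- length(l)
    if (!n) return(NULL)
    n_ab <- sum(l == "AB"); n_bb <- sum(l == "BB")
    data.frame(site = s, n = n, freq_aa = sum(l == "AA") / n,
               freq_ab = n_ab / n, freq_bb = n_bb / n,
               allele_freq = (n_ab + 2 * n_bb) / (2 * n))
  })
  do.call(rbind, out)
}
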