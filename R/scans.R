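#' Non-overlapping fixed-count SNP windows
#'
#' Splits each chromosome's ordered markers into consecutive windows of
#' exactly `size` SNPs; the trailing partial window is dropped and
#' chromosomes with fewer than `size` SNPs contribute none (with a
#' warning).
#'
#' @param markers marker table (`chrom`, `pos`).
#' @param size SNPs per window (1000 for scan regions, 100 for local PCA).
#' @return data.frame with `chrom`, `win` (global index), `chrom_win`
#'   (index within chromosome), `first`, `last` (marker rows), `start_bp`,
#'   `end_bp`, `n_snps`.
#' @export
make_snp_windows <- function(markers, size) {
  out <- list()
  win <- 0L
  for (chr in unique(markers$chrom)) {
    rows <- which(markers$chrom == chr)
    k <- length(rows) %/% size
    if (k == 0L) {
      warning("chromosome ", chr, " has fewer than ", size,
              " SNPs; no windows")
      next
    }
    for (w in seq_len(k)) {
      first <- rows[(w - 1L) * size + 1L]
      last <- rows[w * size]
      win <- win + 1L
      out[[win]] <- data.frame(chrom = chr, win = win, chrom_win = w,
                               first = first, last = last,
                               start_bp = markers$pos[first],
                               end_bp = markers$pos[last],
                               n_snps = size)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), win = integer(),
                      chrom_win = integer(), first = integer(),
                      last = integer(), start_bp = numeric(),
                      end_bp = numeric(), n_snps = integer()))
  do.call(rbind, out)
}

# merge flagged window indices (within one chromosome) into clusters when
# consecutive flagged indices differ by at most max_index_gap
.merge_flagged <- function(idx, max_index_gap) {
  if (!length(idx)) return(list())
  idx <- sort(idx)
  breaks <- which(diff(idx) > max_index_gap)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, length(idx))
  lapply(seq_along(starts), function(k) idx[starts[k]:ends[k]])
}

#' Candidate regions from selection-scan outlier windows
#'
#' Per axis: windows with at least `min_outliers` SNPs at `q < q_cutoff`
#' are flagged; flagged windows on the same chromosome separated by fewer
#' than `merge_gap` windows are combined into one candidate region whose
#' span runs from the first to the last member window.
#'
#' @param scan a [fastpca_scan()] result (needs `site`, `axis`, `q`).
#' @param windows a [make_snp_windows()] table (1000-SNP windows).
#' @param min_outliers minimum outlier SNPs per window (default 10).
#' @param merge_gap windows closer than this many indices merge (default
#'   10).
#' @param q_cutoff outlier q-value threshold (default 0.01).
#' @return region data.frame: `chrom`, `start`, `end`, `label`,
#'   `provenance`, `score` (total outlier SNPs), `n_windows`, `windows`
#'   (comma-joined member window indices).
#' @export
call_outlier_regions <- function(scan, windows, min_outliers = 10L,
                                 merge_gap = 10L, q_cutoff = 0.01) {
  out <- list()
  for (ax in sort(unique(scan$axis))) {
    sub <- scan[scan$axis == ax & scan$q < q_cutoff, ]
    counts <- vapply(seq_len(nrow(windows)), function(w)
      sum(sub$site >= windows$first[w] & sub$site <= windows$last[w]), 0L)
    flagged <- which(counts >= min_outliers)
    for (chr in unique(windows$chrom[flagged])) {
      on_chr <- flagged[windows$chrom[flagged] == chr]
      clusters <- .merge_flagged(windows$chrom_win[on_chr], merge_gap)
      for (cl in clusters) {
        members <- on_chr[windows$chrom_win[on_chr] %in% cl]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          start = windows$start_bp[members[1L]],
          end = windows$end_bp[members[length(members)]],
          label = sprintf("scan_PC%d_%s_%d", ax, chr, length(out) + 1L),
          provenance = sprintf("fastpca_PC%d", ax),
          score = sum(counts[members]),
          n_windows = length(members),
          windows = paste(windows$win[members], collapse = ","))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character(),
                      provenance = character(), score = numeric(),
                      n_windows = integer(), windows = character()))
  do.call(rbind, out)
}

#' Local PCA summaries of fixed-SNP windows
#'
#' Per window, the standardized expected-genotype matrix (missing entries
#' imputed at the site mean `2f`) gives an individual x individual
#' covariance; the window summary is the rank-`k` eigen reconstruction
#' scaled to unit Frobenius norm. Comparing summaries in Frobenius norm
#' thus measures how much the leading local relationship structure differs
#' between windows.
#'
#' @param ds a [gl_dataset()].
#' @param windows a [make_snp_windows()] table (100-SNP windows).
#' @param k rank of the summary (default 4).
#' @param f optional per-site frequencies.
#' @return list of class `local_pca`: `summaries` (list of N x N matrices),
#'   `pc1` (list of leading-eigenvector score vectors), `windows`.
#' @export
local_pca_windows <- function(ds, windows, k = 4L, f = NULL) {
  if (is.null(f)) f <- estimate_maf_em(ds)$f
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  e <- posterior_dosage(ds, f, na_missing = FALSE)  # missing -> 2f
  z <- (e - 2 * f) / sqrt(2 * f * (1 - f))
  summaries <- vector("list", nrow(windows))
  pc1 <- vector("list", nrow(windows))
  for (w in seq_len(nrow(windows))) {
    zw <- z[windows$first[w]:windows$last[w], , drop = FALSE]
    C <- crossprod(zw) / nrow(zw)
    dec <- eigen(C, symmetric = TRUE)
    kk <- min(k, ncol(C))
    vals <- pmax(dec$values[seq_len(kk)], 0)
    vecs <- dec$vectors[, seq_len(kk), drop = FALSE]
    S <- vecs %*% (vals * t(vecs))
    nrm <- sqrt(sum(S^2))
    summaries[[w]] <- if (nrm > 0) S / nrm else S
    pc1[[w]] <- vecs[, 1L] * sqrt(vals[1L])
  }
  structure(list(summaries = summaries, pc1 = pc1, windows = windows,
                 k = k), class = "local_pca")
}

#' Distances between local-PCA window summaries
#'
#' Frobenius norm of the difference of the unit-normalized rank-k
#' covariance summaries: symmetric, zero-diagonal and metric by
#' construction.
#'
#' @param lp a [local_pca_windows()] result (or list of summary matrices).
#' @return symmetric distance matrix (windows x windows).
#' @export
window_distances <- function(lp) {
  summaries <- if (inherits(lp, "local_pca")) lp$summaries else lp
  V <- t(vapply(summaries, as.vector,
                numeric(length(summaries[[1L]]))))
  unname(as.matrix(dist(V)))
}

#' Classical multidimensional scaling onto a fixed number of axes
#'
#' Torgerson scaling: double-centre `-D^2/2`, take the top eigenpairs,
#' scale eigenvectors by the square root of positive eigenvalues (axes with
#' non-positive eigenvalues are zero-filled so the output always has
#' `axes` columns), and fix each axis' sign so its largest-magnitude
#' loading is positive.
#'
#' @param D distance matrix.
#' @param axes number of MDS axes (default 5).
#' @return object of class `mds_result`: `points` (windows x axes),
#'   `eig` (all eigenvalues).
#' @export
mds_windows <- function(D, axes = 5L) {
  D <- as.matrix(D)
  n <- nrow(D)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D^2 %*% J
  dec <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pts <- matrix(0, n, axes)
  for (k in seq_len(min(axes, n))) {
    lam <- dec$values[k]
    if (lam > 1e-12) {
      v <- dec$vectors[, k] * sqrt(lam)
      if (v[which.max(abs(v))] < 0) v <- -v
      pts[, k] <- v
    }
  }
  structure(list(points = pts, eig = dec$values), class = "mds_result")
}

#' Outlier-window clusters on MDS axes
#'
#' Per axis independently: windows whose coordinate lies more than
#' `sd_mult` standard deviations from the axis mean (genome-wide) are
#' flagged; flagged windows on the same chromosome within `merge_gap`
#' window indices of each other merge into clusters, and only clusters
#' holding at least `min_windows` flagged windows are kept. Cluster spans
#' run from the first to the last flagged member window.
#'
#' @param mds a [mds_windows()] result.
#' @param windows the [make_snp_windows()] table the distances were built
#'   from.
#' @param sd_mult standard-deviation multiplier (default 3).
#' @param merge_gap maximum window-index gap inside a cluster (default 20).
#' @param min_windows minimum flagged windows per kept cluster (default
#'   10).
#' @return region data.frame as in [call_outlier_regions()] with
#'   provenance `MDS<axis>`.
#' @export
mds_outlier_clusters <- function(mds, windows, sd_mult = 3, merge_gap = 20L,
                                 min_windows = 10L) {
  pts <- mds$points
  stopifnot(nrow(pts) == nrow(windows))
  out <- list()
  for (ax in seq_len(ncol(pts))) {
    x <- pts[, ax]
    if (sd(x) == 0) next
    flagged <- which(abs(x - mean(x)) > sd_mult * sd(x))
    for (chr in unique(windows$chrom[flagged])) {
      on_chr <- flagged[windows$chrom[flagged] == chr]
      clusters <- .merge_flagged(windows$chrom_win[on_chr], merge_gap)
      for (cl in clusters) {
        if (length(cl) < min_windows) next
        members <- on_chr[windows$chrom_win[on_chr] %in% cl]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chr,
          start = windows$start_bp[members[1L]],
          end = windows$end_bp[members[length(members)]],
          label = sprintf("mds%d_%s_%d", ax, chr, length(out) + 1L),
          provenance = sprintf("MDS%d", ax),
          score = max(abs(x[members] - mean(x)) / sd(x)),
          n_windows = length(members),
          windows = paste(windows$win[members], collapse = ","))
      }
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), label = character(),
                      provenance = character(), score = numeric(),
                      n_windows = integer(), windows = character()))
  do.call(rbind, out)
}
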