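#' Per-site folded allele counts for a group
#'
#' Hard genotype calls by maximum posterior on a seeded random subsample of
#' the group (without replacement; groups smaller than the subsample are
#' used whole, with a warning). Per site, the count of the rarer allele
#' among the `2 x called` chromosomes with data.
#'
#' @param ds a [gl_dataset()].
#' @param individuals indices or ids of the group's members.
#' @param subsample subsample size in diploids (default 26).
#' @param seed integer seed for the subsample.
#' @return list with `minor_count`, `alt_count`, `n_chrom` (per site),
#'   `n_sub` (diploids used), `calls` (genotype matrix of the subsample).
#' @export
pop_sfs <- function(ds, individuals, subsample = 26L, seed = 1L) {
  if (is.character(individuals)) individuals <- match(individuals, ds$ids)
  if (length(individuals) < subsample) {
    warning("group smaller than the requested subsample; using all ",
            length(individuals), " individuals")
    pick <- individuals
  } else {
    set.seed(seed)
    pick <- sort(sample(individuals, subsample))
  }
  sub <- gl_subset(ds, individuals = pick)
  calls <- call_genotypes(sub)
  alt <- rowSums(calls, na.rm = TRUE)
  n_chrom <- 2L * rowSums(!is.na(calls))
  minor <- pmin(alt, n_chrom - alt)
  list(minor_count = minor, alt_count = alt, n_chrom = n_chrom,
       n_sub = length(pick), calls = calls)
}

# standard Tajima's D normalization constants for n chromosomes
.tajima_constants <- function(n) {
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Sliding-window Watterson, pi and Tajima's D
#'
#' Per window of `window` bp advanced by `step` bp: with `S` segregating
#' sites among `L` sites with data and nominal chromosome count `n_chrom`,
#' `theta_W = S / a1`, `theta_pi = sum 2 p (1-p) n/(n-1)` over sites (using
#' each site's own chromosome count for the unbiased factor), and Tajima's
#' `D = (theta_pi - theta_W) / sqrt(e1 S + e2 S (S-1))`. Thetas are reported
#' per 1000 sites (divided by `L`, times 1000); windows with fewer than
#' `min_sites` sites are excluded and `D` is `NA` when `S = 0`.
#'
#' @param sfs a [pop_sfs()] result.
#' @param markers marker table aligned to the dataset (`chrom`, `pos`).
#' @param window window size in bp (default 25000).
#' @param step step size in bp (default 5000).
#' @param min_sites minimum sites with data per window (default 1000).
#' @return data.frame with columns `chrom`, `start`, `end`, `n_sites`, `S`,
#'   `theta_w_1000`, `theta_pi_1000`, `tajima_d`.
#' @export
window_thetas <- function(sfs, markers, window = 25000, step = 5000,
                          min_sites = 1000L) {
  n_nom <- 2L * sfs$n_sub
  const <- .tajima_constants(n_nom)
  has_data <- sfs$n_chrom >= 2L
  p_hat <- ifelse(has_data, sfs$alt_count / pmax(sfs$n_chrom, 1L), NA_real_)
  pi_site <- ifelse(has_data,
                    2 * p_hat * (1 - p_hat) * sfs$n_chrom /
                      pmax(sfs$n_chrom - 1L, 1L), 0)
  seg <- has_data & sfs$minor_count > 0L
  out <- list()
  for (chr in unique(markers$chrom)) {
    rows <- which(markers$chrom == chr)
    pos <- markers$pos[rows]
    max_pos <- max(pos)
    starts <- seq(1, max(1, max_pos), by = step)
    for (w0 in starts) {
      w1 <- w0 + window - 1
      if (w0 > max_pos) break
      in_w <- rows[pos >= w0 & pos <= w1]
      in_w <- in_w[has_data[in_w]]
      L <- length(in_w)
      if (L < min_sites) next
      S <- sum(seg[in_w])
      theta_w <- S / const$a1
      theta_pi <- sum(pi_site[in_w])
      d <- if (S > 0) {
        v <- const$e1 * S + const$e2 * S * (S - 1)
        (theta_pi - theta_w) / sqrt(v)
      } else NA_real_
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = w0, end = w1, n_sites = L, S = S,
        theta_w_1000 = theta_w / L * 1000,
        theta_pi_1000 = theta_pi / L * 1000, tajima_d = d)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_sites = integer(), S = integer(),
                      theta_w_1000 = numeric(), theta_pi_1000 = numeric(),
                      tajima_d = numeric()))
  do.call(rbind, out)
}

#' Individual heterozygosity per kb of callable sites
#'
#' The default estimator sums, over the individual's non-missing sites, the
#' posterior probability of the heterozygous genotype under a
#' Hardy-Weinberg prior at the site frequency — the probabilistic analogue
#' of counting sites whose allele count is 1 in a single-individual SFS —
#' and divides by the callable site count in kb (1000 sites = 1 kb of
#' assayed sequence). `method = "calls"` counts maximum-posterior
#' heterozygote calls instead; at depths near 1-2x hard calls undercount
#' heterozygotes noticeably.
#'
#' @param ds a [gl_dataset()].
#' @param individual index or id; `NULL` returns all individuals.
#' @param method `"expected"` (default) or `"calls"`.
#' @return named numeric vector of het-per-kb rates.
#' @export
individual_heterozygosity <- function(ds, individual = NULL,
                                      method = c("expected", "calls")) {
  method <- match.arg(method)
  cols <- if (is.null(individual)) seq_along(ds$ids)
  else if (is.character(individual)) match(individual, ds$ids)
  else individual
  if (method == "calls") {
    calls <- call_genotypes(ds)
    het <- (calls == 1L)
    obs <- !is.na(calls)
    het[!obs] <- FALSE
  } else {
    f <- estimate_maf_em(ds)$f
    p0 <- .gl_slice(ds$gl, 1) * (1 - f)^2
    p1 <- .gl_slice(ds$gl, 2) * 2 * f * (1 - f)
    p2 <- .gl_slice(ds$gl, 3) * f^2
    het <- p1 / (p0 + p1 + p2)
    obs <- !gl_missing(ds)
    het[!obs] <- 0
  }
  out <- vapply(cols, function(i) {
    callable <- sum(obs[, i])
    if (callable == 0L) stop("individual ", ds$ids[i], " has no callable sites")
    sum(het[, i]) / (callable / 1000)
  }, 0)
  setNames(out, ds$ids[cols])
}
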