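#' Site and sample filter configurations
#'
#' Defaults follow the standard low-coverage pipeline thresholds: sites are
#' kept when their minor-allele frequency exceeds 0.05, at least 75% of
#' individuals are covered at 1x or more, and mean depth does not exceed
#' 10x; the excess-heterozygosity (paralog surrogate) test uses a
#' Benjamini-Hochberg alpha of 0.001. Samples are dropped above the 95th
#' missingness percentile; duplicate pairs are flagged at dosage correlation
#' r >= 0.9.
#'
#' @param min_maf minimum minor-allele frequency (exclusive).
#' @param min_cover_frac minimum fraction of individuals covered >= 1x.
#' @param max_mean_depth maximum mean depth across individuals.
#' @param paralog_alpha BH-adjusted alpha of the excess-het filter.
#' @return a list of class `site_filter_config`.
#' @export
site_filter_config <- function(min_maf = 0.05, min_cover_frac = 0.75,
                               max_mean_depth = 10, paralog_alpha = 0.001) {
  stopifnot(min_maf >= 0, min_maf < 0.5, min_cover_frac > 0,
            min_cover_frac <= 1, max_mean_depth > 0,
            paralog_alpha > 0, paralog_alpha < 1)
  structure(list(min_maf = min_maf, min_cover_frac = min_cover_frac,
                 max_mean_depth = max_mean_depth,
                 paralog_alpha = paralog_alpha),
            class = "site_filter_config")
}

#' @rdname site_filter_config
#' @param missing_percentile cohort percentile above which samples are
#'   removed, in (0, 100].
#' @param duplicate_r dosage-correlation threshold flagging duplicates.
#' @export
sample_filter_config <- function(missing_percentile = 95,
                                 duplicate_r = 0.9) {
  stopifnot(missing_percentile > 0, missing_percentile <= 100,
            duplicate_r > 0, duplicate_r <= 1)
  structure(list(missing_percentile = missing_percentile,
                 duplicate_r = duplicate_r), class = "sample_filter_config")
}

#' Site filters: MAF, coverage fraction, mean depth
#'
#' Removes sites whose minor-allele frequency is not above `min_maf`, whose
#' fraction of non-missing individuals is below `min_cover_frac`, or (when a
#' depth sidecar is given) whose mean depth exceeds `max_mean_depth`.
#' Without depths the depth rule is skipped with a warning.
#'
#' @param ds a [gl_dataset()].
#' @param depths optional integer depth matrix aligned to `ds`.
#' @param cfg a [site_filter_config()].
#' @return list with `dataset` (filtered), `report` (per-site pass/fail per
#'   rule) and `kept` (row indices).
#' @export
filter_sites <- function(ds, depths = NULL, cfg = site_filter_config()) {
  if (n_markers(ds) == 0L) stop("empty dataset")
  em <- estimate_maf_em(ds)
  maf <- pmin(em$f, 1 - em$f)
  cover <- rowMeans(!gl_missing(ds))
  pass_maf <- maf > cfg$min_maf & !em$flagged
  pass_cover <- cover >= cfg$min_cover_frac
  if (is.null(depths)) {
    warning("no depth sidecar: mean-depth filter skipped")
    mean_depth <- rep(NA_real_, n_markers(ds))
    pass_depth <- rep(TRUE, n_markers(ds))
  } else {
    stopifnot(nrow(depths) == n_markers(ds))
    mean_depth <- rowMeans(depths)
    pass_depth <- mean_depth <= cfg$max_mean_depth
  }
  keep <- pass_maf & pass_cover & pass_depth
  report <- data.frame(chrom = ds$markers$chrom, pos = ds$markers$pos,
                       maf = maf, cover_frac = cover,
                       mean_depth = mean_depth, pass_maf = pass_maf,
                       pass_cover = pass_cover, pass_depth = pass_depth,
                       kept = keep)
  list(dataset = gl_subset(ds, sites = which(keep)), report = report,
       kept = which(keep))
}

#' Per-sample missingness
#'
#' Fraction of sites with a flat likelihood triplet, per individual.
#' Computed on the dataset as given, so removing one sample never changes
#' another sample's value.
#'
#' @param ds a [gl_dataset()].
#' @return named numeric vector.
#' @export
sample_missingness <- function(ds) {
  setNames(colMeans(gl_missing(ds)), ds$ids)
}

#' Remove high-missingness samples
#'
#' Samples whose missingness exceeds the cohort percentile cutoff (or an
#' explicit absolute cutoff) are removed. Both cutoffs are reported.
#'
#' @param ds a [gl_dataset()].
#' @param cfg a [sample_filter_config()].
#' @param absolute_cutoff optional absolute missingness fraction overriding
#'   the percentile rule.
#' @return list with `dataset`, `removed` (ids), `cutoff` (fraction used)
#'   and `missingness`.
#' @export
filter_samples <- function(ds, cfg = sample_filter_config(),
                           absolute_cutoff = NULL) {
  if (n_individuals(ds) < 2L)
    stop("missingness percentile undefined for fewer than 2 samples")
  miss <- sample_missingness(ds)
  pct_cut <- unname(quantile(miss, cfg$missing_percentile / 100))
  cutoff <- absolute_cutoff %||% pct_cut
  removed <- names(miss)[miss > cutoff]
  keep <- setdiff(ds$ids, removed)
  list(dataset = gl_subset(ds, individuals = keep), removed = removed,
       cutoff = cutoff, percentile_cutoff = pct_cut, missingness = miss)
}

#' Detect putatively duplicated individuals
#'
#' Per pair of individuals, the maximum-likelihood identity coefficient of
#' the two-component model in which, at each site, the pair's genotypes are
#' either independent Hardy-Weinberg draws (weight `1 - r`) or a single
#' shared genotype (weight `r`):
#' `L(r) = prod_s [(1-r) m1 m2 + r sum_g GL1_g GL2_g P(g|f)]`
#' with `m_i = sum_g GL_ig P(g|f)`. Working on the likelihoods directly
#' keeps the estimate unattenuated at low depth (a naive dosage correlation
#' shrinks to ~0.5 at 1.5x): sequencing duplicates score near 1, full sibs
#' near 0.45 and unrelated pairs near 0, so the default threshold of 0.9
#' separates duplicates cleanly. Pairs with `r >= threshold` are flagged
#' and the later-listed member of each pair is marked for removal. Pairs
#' sharing fewer than `min_shared` non-missing sites are skipped with a
#' warning.
#'
#' @param ds a [gl_dataset()].
#' @param threshold identity-coefficient threshold (default 0.9).
#' @param min_shared minimum jointly non-missing sites per pair.
#' @return list with `pairs` (data.frame id1, id2, r, shared; all scored
#'   pairs) and `remove` (ids marked for removal).
#' @export
detect_duplicates <- function(ds, threshold = 0.9, min_shared = 100L) {
  f <- estimate_maf_em(ds)$f
  pg <- cbind((1 - f)^2, 2 * f * (1 - f), f^2)
  n <- n_individuals(ds)
  miss <- gl_missing(ds)
  # per-individual marginal site likelihoods under the HWE prior
  marg <- sapply(seq_len(n), function(i) rowSums(ds$gl[, i, ] * pg))
  out <- data.frame(id1 = character(), id2 = character(), r = numeric(),
                    shared = integer())
  skipped <- 0L
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    k <- !miss[, a] & !miss[, b]
    if (sum(k) < min_shared) { skipped <- skipped + 1L; next }
    A <- marg[k, a] * marg[k, b]
    B <- rowSums(ds$gl[k, a, ] * ds$gl[k, b, ] * pg[k, , drop = FALSE])
    r_hat <- optimize(function(th) -sum(log((1 - th) * A + th * B + 1e-300)),
                      c(0, 1))$minimum
    # optimize() never returns an exact endpoint; snap against the boundary
    if (-sum(log(B + 1e-300)) <= -sum(log((1 - r_hat) * A + r_hat * B + 1e-300)))
      r_hat <- 1
    out <- rbind(out, data.frame(id1 = ds$ids[a], id2 = ds$ids[b],
                                 r = r_hat, shared = sum(k)))
  }
  if (skipped) warning(skipped, " pair(s) skipped with < ", min_shared,
                       " shared sites")
  flagged <- out[out$r >= threshold, , drop = FALSE]
  list(pairs = out, remove = unique(flagged$id2))
}

#' Excess-heterozygosity site filter (paralog surrogate)
#'
#' Mismapped paralogous sites show more heterozygotes than Hardy-Weinberg
#' allows. Per site, genotypes are called by maximum posterior and a
#' one-sided exact binomial test compares the observed heterozygote count
#' with the HWE expectation `2f(1-f)`; Benjamini-Hochberg adjusted p-values
#' below `alpha` flag the site as deviant. Monomorphic or uncalled sites are
#' skipped.
#'
#' @param ds a [gl_dataset()].
#' @param alpha BH-adjusted significance level (default 0.001).
#' @return list with `flagged` (logical per site), `report` (per-site test
#'   table).
#' @export
excess_het_filter <- function(ds, alpha = 0.001) {
  em <- estimate_maf_em(ds)
  f <- em$f
  calls <- call_genotypes(ds, f)
  n_called <- rowSums(!is.na(calls))
  n_het <- rowSums(calls == 1L, na.rm = TRUE)
  maf <- pmin(f, 1 - f)
  testable <- n_called > 0L & maf > 1e-4
  p <- rep(NA_real_, n_markers(ds))
  exp_het <- 2 * f * (1 - f)
  p[testable] <- pbinom(n_het[testable] - 1L, n_called[testable],
                        exp_het[testable], lower.tail = FALSE)
  padj <- rep(NA_real_, length(p))
  padj[testable] <- p.adjust(p[testable], method = "BH")
  flagged <- !is.na(padj) & padj < alpha
  list(flagged = flagged,
       report = data.frame(chrom = ds$markers$chrom, pos = ds$markers$pos,
                           n_called = n_called, n_het = n_het,
                           expected_het = exp_het, p = p, p_adj = padj,
                           flagged = flagged))
}

#' Sample-filtering bookkeeping on a manifest
#'
#' Applies the missingness rule (absolute cutoff) and then the
#' duplicate-removal rule to a sample manifest, in that order, and reports
#' the counts at each step.
#'
#' @param manifest data.frame with columns `id`, `missing_frac` and
#'   optionally `duplicate_of` (empty/NA when not a duplicate).
#' @param missing_cutoff absolute missingness fraction; samples strictly
#'   above it are removed.
#' @return list with `n_input`, `n_high_missing`, `n_duplicates`,
#'   `n_retained` and `retained` ids.
#' @export
qc_bookkeeping <- function(manifest, missing_cutoff = 0.38) {
  stopifnot(all(c("id", "missing_frac") %in% names(manifest)))
  high <- manifest$missing_frac > missing_cutoff
  left <- manifest[!high, , drop = FALSE]
  dup <- if ("duplicate_of" %in% names(left))
    !is.na(left$duplicate_of) & nzchar(left$duplicate_of) &
      left$duplicate_of %in% left$id
  else rep(FALSE, nrow(left))
  list(n_input = nrow(manifest), n_high_missing = sum(high),
       n_duplicates = sum(dup), n_retained = sum(!dup),
       retained = left$id[!dup])
}
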