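#' Configuration for the synthetic genotype-likelihood generator
#'
#' Describes a multi-deme biallelic SNP simulation: demes connected by a drift
#' graph (stepping-stone by default), an optional divergently selected
#' contiguous region, an optional inversion polymorphism, and a low-coverage
#' sequencing model (Poisson read depth, symmetric base error).
#'
#' The per-edge `f` is the target pairwise Hudson FST between the two demes
#' the edge joins. Internally the child deme is drawn from the parent by a
#' Balding-Nichols Beta step with conditional drift `c = 2f`, which makes the
#' expected Hudson FST across the edge equal `f` exactly (the estimator's
#' denominator averages twice the parental heterozygosity while the numerator
#' averages `c` times it). Edge `f` must therefore lie in (0, 0.5).
#'
#' @param n_demes number of demes.
#' @param n_per_deme diploid individuals per deme (recycled to `n_demes`).
#' @param n_snps total SNP count (ignored when `chrom_layout` is given).
#' @param chrom_layout data.frame with columns `chrom`, `length_bp`, `n_snps`;
#'   default one chromosome with 2 kb mean marker spacing.
#' @param deme_graph data.frame with columns `from`, `to`, `f` (per-edge
#'   drift, each in (0, 0.5)); default a 1-D chain with `f = 0.05`.
#' @param deme_coords data.frame with columns `deme`, `row`, `col`: grid cell
#'   of each deme on the habitat raster; default a single row.
#' @param inversion_spec optional list: `chrom`, `start`, `end`,
#'   `freq` (per-deme inversion-allele frequency, recycled), `divergent_frac`
#'   in (0,1], `delta` (allele-frequency divergence between arrangements).
#' @param outlier_region_spec optional list: `chrom`, `start`, `end`,
#'   `shift` (per-deme allele-frequency shift, recycled).
#' @param mean_depth mean sequencing depth lambda (reads/site, Poisson).
#' @param error_rate base error rate epsilon in [0, 0.5).
#' @param maf_floor lower bound of the ancestral frequency draw, so that most
#'   simulated sites survive a 5% MAF filter.
#' @param neutral_sfs_mode when `TRUE`, ancestral frequencies follow the
#'   neutral density proportional to 1/x truncated to
#'   `[1/(2 pop_size), 1 - 1/(2 pop_size)]` instead of
#'   Uniform(`maf_floor`, 0.5).
#' @param pop_size effective size used for the neutral-SFS truncation.
#' @param seed master integer seed; every stage derives a sub-stream from it.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_demes = 2L, n_per_deme = 30L, n_snps = 10000L,
                       chrom_layout = NULL, deme_graph = NULL,
                       deme_coords = NULL, inversion_spec = NULL,
                       outlier_region_spec = NULL, mean_depth = 1.5,
                       error_rate = 0.01, maf_floor = 0.05,
                       neutral_sfs_mode = FALSE, pop_size = 1e4,
                       seed = 1L) {
  n_demes <- as.integer(n_demes)
  stopifnot(n_demes >= 1L, mean_depth >= 0)
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  n_per_deme <- rep_len(as.integer(n_per_deme), n_demes)
  if (is.null(chrom_layout)) {
    chrom_layout <- data.frame(chrom = "chr1",
                               length_bp = as.numeric(n_snps) * 2000,
                               n_snps = as.integer(n_snps))
  }
  stopifnot(all(c("chrom", "length_bp", "n_snps") %in% names(chrom_layout)))
  if (is.null(deme_graph)) {
    deme_graph <- if (n_demes > 1L)
      data.frame(from = seq_len(n_demes - 1L), to = 2:n_demes, f = 0.05)
    else data.frame(from = integer(), to = integer(), f = numeric())
  }
  if (nrow(deme_graph) && (any(deme_graph$f <= 0) || any(deme_graph$f >= 0.5)))
    stop("per-edge drift f must lie in (0, 0.5)")
  if (n_demes > 1L && !.graph_connected(deme_graph, n_demes))
    stop("deme_graph must be connected")
  if (is.null(deme_coords))
    deme_coords <- data.frame(deme = seq_len(n_demes), row = 1L,
                              col = seq_len(n_demes))
  .check_region_spec(inversion_spec, chrom_layout, n_demes, "inversion_spec")
  .check_region_spec(outlier_region_spec, chrom_layout, n_demes,
                     "outlier_region_spec")
  if (!is.null(inversion_spec)) {
    if (is.null(inversion_spec$divergent_frac) ||
        inversion_spec$divergent_frac <= 0 || inversion_spec$divergent_frac > 1)
      stop("inversion divergent_frac must lie in (0, 1]")
    if (inversion_spec$delta < 0 || inversion_spec$delta > 1)
      stop("inversion delta must lie in [0, 1]")
    inversion_spec$freq <- rep_len(inversion_spec$freq, n_demes)
    if (any(inversion_spec$freq < 0 | inversion_spec$freq > 1))
      stop("inversion frequencies must lie in [0, 1]")
  }
  if (!is.null(outlier_region_spec))
    outlier_region_spec$shift <- rep_len(outlier_region_spec$shift, n_demes)
  if (!is.null(inversion_spec) && !is.null(outlier_region_spec) &&
      identical(inversion_spec$chrom, outlier_region_spec$chrom) &&
      inversion_spec$start <= outlier_region_spec$end &&
      outlier_region_spec$start <= inversion_spec$end)
    stop("inversion and outlier-region spans must not overlap")
  structure(list(n_demes = n_demes, n_per_deme = n_per_deme,
                 chrom_layout = chrom_layout, deme_graph = deme_graph,
                 deme_coords = deme_coords, inversion_spec = inversion_spec,
                 outlier_region_spec = outlier_region_spec,
                 mean_depth = mean_depth, error_rate = error_rate,
                 maf_floor = maf_floor, neutral_sfs_mode = neutral_sfs_mode,
                 pop_size = pop_size, seed = as.integer(seed)),
            class = "sim_config")
}

.graph_connected <- function(graph, n) {
  seen <- rep(FALSE, n)
  seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nb <- c(graph$to[graph$from %in% frontier],
            graph$from[graph$to %in% frontier])
    frontier <- unique(nb[!seen[nb]])
    seen[frontier] <- TRUE
  }
  all(seen)
}

.check_region_spec <- function(spec, layout, n_demes, what) {
  if (is.null(spec)) return(invisible(NULL))
  stopifnot(all(c("chrom", "start", "end") %in% names(spec)))
  row <- match(spec$chrom, layout$chrom)
  if (is.na(row)) stop(what, ": unknown chromosome ", spec$chrom)
  if (spec$start < 1 || spec$end > layout$length_bp[row] ||
      spec$start >= spec$end)
    stop(what, ": span must lie within its chromosome")
  invisible(NULL)
}

#' Marker positions implied by a simulation configuration
#'
#' Positions are drawn uniformly (without replacement) along each chromosome
#' and sorted, from the `markers` sub-stream of the master seed.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `chrom`, `pos`, `major`, `minor`.
#' @export
sim_markers <- function(config) {
  set.seed(substream_seed(config$seed, "markers"))
  out <- lapply(seq_len(nrow(config$chrom_layout)), function(i) {
    n <- config$chrom_layout$n_snps[i]
    len <- config$chrom_layout$length_bp[i]
    pos <- sort(sample.int(len, n))
    data.frame(chrom = config$chrom_layout$chrom[i], pos = pos,
               major = "A", minor = "C")
  })
  do.call(rbind, out)
}

#' Balding-Nichols deme allele frequencies
#'
#' Draws ancestral frequencies and propagates them over a breadth-first
#' spanning tree of the deme graph. The root deme carries the ancestral
#' frequencies; each child is drawn from
#' `Beta(p (1-c)/c, (1-p)(1-c)/c)` with conditional drift `c = 2 f_edge`, so
#' the expected pairwise Hudson FST across an edge equals `f_edge`.
#' Frequencies are clamped away from 0 and 1 by `1e-6`. When an outlier
#' region is configured, its per-deme shifts are applied to in-span sites.
#'
#' @param config a [sim_config()].
#' @param markers optional marker table from [sim_markers()] (recomputed
#'   otherwise).
#' @return matrix of per-site frequencies (sites x demes) with attributes
#'   `ancestral` (numeric vector) and `markers`.
#' @export
simulate_deme_frequencies <- function(config, markers = NULL) {
  if (is.null(markers)) markers <- sim_markers(config)
  m <- nrow(markers)
  set.seed(substream_seed(config$seed, "ancestral"))
  p_anc <- if (config$neutral_sfs_mode) {
    a <- 1 / (2 * config$pop_size)
    a * ((1 - a) / a)^runif(m)  # inverse CDF of density proportional to 1/x
  } else {
    runif(m, config$maf_floor, 0.5)
  }
  freqs <- matrix(NA_real_, m, config$n_demes)
  freqs[, 1L] <- p_anc
  set.seed(substream_seed(config$seed, "drift"))
  if (config$n_demes > 1L) {
    edges <- .spanning_tree(config$deme_graph, config$n_demes)
    for (e in seq_len(nrow(edges))) {
      parent <- edges$parent[e]
      child <- edges$child[e]
      cc <- 2 * edges$f[e]
      p <- freqs[, parent]
      freqs[, child] <- rbeta(m, p * (1 - cc) / cc, (1 - p) * (1 - cc) / cc)
    }
  }
  if (!is.null(config$outlier_region_spec)) {
    sp <- config$outlier_region_spec
    idx <- which(markers$chrom == sp$chrom & markers$pos >= sp$start &
                   markers$pos <= sp$end)
    for (d in seq_len(config$n_demes))
      freqs[idx, d] <- freqs[idx, d] + sp$shift[d]
  }
  freqs <- pmin(pmax(freqs, 1e-6), 1 - 1e-6)
  attr(freqs, "ancestral") <- p_anc
  attr(freqs, "markers") <- markers
  freqs
}

# BFS spanning tree rooted at deme 1; rows ordered parent-before-child.
.spanning_tree <- function(graph, n) {
  parent <- integer(0); child <- integer(0); f <- numeric(0)
  seen <- rep(FALSE, n); seen[1L] <- TRUE
  frontier <- 1L
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      hit <- which(graph$from == v | graph$to == v)
      for (e in hit) {
        u <- if (graph$from[e] == v) graph$to[e] else graph$from[e]
        if (!seen[u]) {
          seen[u] <- TRUE
          parent <- c(parent, v); child <- c(child, u); f <- c(f, graph$f[e])
          nxt <- c(nxt, u)
        }
      }
    }
    frontier <- nxt
  }
  data.frame(parent = parent, child = child, f = f)
}

#' Inversion haplogroups and individual karyotypes
#'
#' Inside the configured span, a fraction of SNPs is divergent between the
#' two arrangements A and B with |p_A - p_B| = delta (direction randomized
#' per site); the remaining in-span SNPs share the site's ancestral
#' frequency. Karyotypes (number of B arrangements, 0/1/2) are drawn per
#' individual from Hardy-Weinberg at the deme's inversion frequency.
#'
#' @param config a [sim_config()] with `inversion_spec` set.
#' @param deme_freqs output of [simulate_deme_frequencies()] (for markers and
#'   ancestral frequencies).
#' @return list with `site_idx` (in-span marker rows), `p_a`, `p_b`
#'   (arrangement allele frequencies over those sites), `divergent` (logical),
#'   and `karyotype` (integer per individual, B-arrangement count).
#' @export
simulate_inversion <- function(config, deme_freqs) {
  sp <- config$inversion_spec
  if (is.null(sp)) stop("config has no inversion_spec")
  markers <- attr(deme_freqs, "markers")
  p_anc <- attr(deme_freqs, "ancestral")
  idx <- which(markers$chrom == sp$chrom & markers$pos >= sp$start &
                 markers$pos <= sp$end)
  if (!length(idx)) stop("no markers fall inside the inversion span")
  set.seed(substream_seed(config$seed, "inversion"))
  k <- length(idx)
  divergent <- runif(k) < sp$divergent_frac
  p_a <- p_anc[idx]
  p_b <- p_anc[idx]
  nd <- sum(divergent)
  if (nd) {
    if (sp$delta > 1) stop("delta pushes arrangement frequencies outside [0,1]")
    lo <- runif(nd, 0, 1 - sp$delta)
    hi <- lo + sp$delta
    flip <- runif(nd) < 0.5
    p_a[divergent] <- ifelse(flip, hi, lo)
    p_b[divergent] <- ifelse(flip, lo, hi)
  }
  deme_of <- rep(seq_len(config$n_demes), config$n_per_deme)
  karyotype <- rbinom(length(deme_of), 2L, sp$freq[deme_of])
  list(site_idx = idx, p_a = p_a, p_b = p_b, divergent = divergent,
       karyotype = as.integer(karyotype))
}

#' True genotypes for every individual
#'
#' Outside any inversion span, genotypes are Binomial(2, deme frequency).
#' Inside the span each individual carries two arrangement haplotypes fixed
#' by its karyotype; alleles are drawn per haplotype from the carried
#' arrangement's site frequencies (no recombination between arrangements).
#'
#' @param config a [sim_config()].
#' @param deme_freqs from [simulate_deme_frequencies()].
#' @param inversion optional result of [simulate_inversion()].
#' @return integer matrix, sites x individuals, values in {0, 1, 2} counting
#'   copies of the minor allele.
#' @export
simulate_genotypes <- function(config, deme_freqs, inversion = NULL) {
  m <- nrow(deme_freqs)
  deme_of <- rep(seq_len(config$n_demes), config$n_per_deme)
  n <- length(deme_of)
  set.seed(substream_seed(config$seed, "genotypes"))
  g <- matrix(0L, m, n)
  for (d in seq_len(config$n_demes)) {
    cols <- which(deme_of == d)
    g[, cols] <- rbinom(m * length(cols), 2L, deme_freqs[, d])
  }
  if (!is.null(inversion)) {
    idx <- inversion$site_idx
    k <- length(idx)
    for (i in seq_len(n)) {
      nb <- inversion$karyotype[i]
      h1 <- rbinom(k, 1L, if (nb >= 1L) inversion$p_b else inversion$p_a)
      h2 <- rbinom(k, 1L, if (nb == 2L) inversion$p_b else inversion$p_a)
      g[idx, i] <- h1 + h2
    }
  }
  g
}

#' Genotype likelihoods from a Poisson-depth read model
#'
#' Per site and individual, depth `d ~ Poisson(lambda)`; the alternate-read
#' count is Binomial(d, g/2 (1-eps) + (1-g/2) eps); likelihoods for g in
#' {0,1,2} come from the same binomial model and are normalized to sum to 1.
#' Depth 0 yields the flat triplet (1/3, 1/3, 1/3), the package's missingness
#' encoding.
#'
#' @param genotypes integer matrix from [simulate_genotypes()].
#' @param mean_depth Poisson mean depth.
#' @param error_rate base error rate in [0, 0.5).
#' @param seed integer seed.
#' @return list with `gl` (sites x individuals x 3 array) and `depth`
#'   (integer matrix).
#' @export
simulate_reads_to_gl <- function(genotypes, mean_depth, error_rate, seed) {
  if (error_rate < 0 || error_rate >= 0.5)
    stop("error_rate must lie in [0, 0.5)")
  if (!all(genotypes %in% 0:2)) stop("genotypes must be in {0, 1, 2}")
  m <- nrow(genotypes); n <- ncol(genotypes)
  set.seed(seed)
  depth <- matrix(rpois(m * n, mean_depth), m, n)
  p_read <- genotypes / 2 * (1 - error_rate) + (1 - genotypes / 2) * error_rate
  alt <- matrix(rbinom(m * n, depth, p_read), m, n)
  p_g <- c(error_rate, 0.5, 1 - error_rate)
  gl <- array(NA_real_, c(m, n, 3L))
  ref <- depth - alt
  for (g in 1:3)  # binomial coefficient cancels in the normalization
    gl[, , g] <- p_g[g]^alt * (1 - p_g[g])^ref
  tot <- gl[, , 1] + gl[, , 2] + gl[, , 3]
  for (g in 1:3) gl[, , g] <- gl[, , g] / tot
  flat <- depth == 0L
  for (g in 1:3) gl[, , g][flat] <- 1 / 3
  list(gl = gl, depth = depth)
}

#' Simulate a complete synthetic low-coverage dataset with ground truth
#'
#' Orchestrates [sim_markers()], [simulate_deme_frequencies()],
#' [simulate_inversion()], [simulate_genotypes()] and
#' [simulate_reads_to_gl()], and assembles a truth ledger for recovery tests.
#'
#' @param config a [sim_config()].
#' @return list with `gl` (a [gl_dataset()]), `depth` matrix, `samples`
#'   (sample metadata table), and `truth` (class `truth_ledger`: deme
#'   frequency matrix, expected pairwise FST, genotypes, inversion and
#'   outlier-region truth).
#' @export
simulate_dataset <- function(config) {
  markers <- sim_markers(config)
  freqs <- simulate_deme_frequencies(config, markers)
  inversion <- if (!is.null(config$inversion_spec))
    simulate_inversion(config, freqs) else NULL
  genotypes <- simulate_genotypes(config, freqs, inversion)
  reads <- simulate_reads_to_gl(genotypes, config$mean_depth,
                                config$error_rate,
                                substream_seed(config$seed, "reads"))
  deme_of <- rep(seq_len(config$n_demes), config$n_per_deme)
  ids <- sprintf("d%02d_i%03d", deme_of, seq_along(deme_of))
  ds <- gl_dataset(markers, reads$gl, ids)
  samples <- data.frame(id = ids, site = sprintf("D%02d", deme_of),
                        row = config$deme_coords$row[deme_of],
                        col = config$deme_coords$col[deme_of])
  truth <- structure(list(
    deme_freqs = freqs,
    ancestral = attr(freqs, "ancestral"),
    expected_fst = expected_pairwise_fst(config),
    genotypes = genotypes,
    deme_of = deme_of,
    inversion = if (!is.null(inversion)) list(
      chrom = config$inversion_spec$chrom,
      start = config$inversion_spec$start,
      end = config$inversion_spec$end,
      site_idx = inversion$site_idx,
      divergent = inversion$divergent,
      karyotype = inversion$karyotype) else NULL,
    outlier_region = config$outlier_region_spec,
    config = config), class = "truth_ledger")
  list(gl = ds, depth = reads$depth, samples = samples, truth = truth)
}

#' Expected pairwise Hudson FST implied by the drift graph
#'
#' Conditional drifts `c = 2 f` compose along the spanning-tree path between
#' two demes as `c_tot = c1 + c2 (1 - c1)` (and so on); the expected Hudson
#' FST of the pair is `c_tot / 2`.
#'
#' @param config a [sim_config()].
#' @return symmetric matrix of expected FST values (demes x demes).
#' @export
expected_pairwise_fst <- function(config) {
  n <- config$n_demes
  out <- matrix(0, n, n)
  if (n == 1L) return(out)
  edges <- .spanning_tree(config$deme_graph, n)
  parent <- rep(NA_integer_, n)
  cdrift <- rep(NA_real_, n)
  parent[edges$child] <- edges$parent
  cdrift[edges$child] <- 2 * edges$f
  path_to_root <- function(v) {
    path <- integer(0)
    while (!is.na(parent[v])) { path <- c(path, v); v <- parent[v] }
    c(path, v)
  }
  compose <- function(cs) { tot <- 0; for (cc in cs) tot <- tot + cc * (1 - tot); tot }
  for (a in seq_len(n - 1L)) for (b in (a + 1L):n) {
    pa <- path_to_root(a); pb <- path_to_root(b)
    common <- intersect(pa, pb)
    meet <- pa[min(match(common, pa), na.rm = TRUE)]
    steps <- c(pa[seq_len(match(meet, pa) - 1L)], pb[seq_len(match(meet, pb) - 1L)])
    out[a, b] <- out[b, a] <- compose(cdrift[steps]) / 2
  }
  out
}

#' Write a truth ledger to a key-value text file
#'
#' YAML document holding the simulation configuration scalars, spans,
#' per-deme inversion frequencies, expected pairwise FST, per-individual
#' karyotypes and deme assignments. The full genotype and frequency matrices
#' stay in memory (regenerate them from the seed); `include_freqs` adds the
#' deme frequency matrix for small simulations.
#'
#' @param truth a `truth_ledger`.
#' @param path output file.
#' @param include_freqs also embed the deme frequency matrix.
#' @return `path`, invisibly.
#' @export
write_truth_ledger <- function(truth, path, include_freqs = FALSE) {
  doc <- list(
    n_demes = truth$config$n_demes,
    n_per_deme = as.integer(truth$config$n_per_deme),
    seed = truth$config$seed,
    mean_depth = truth$config$mean_depth,
    error_rate = truth$config$error_rate,
    deme_of = as.integer(truth$deme_of),
    expected_fst = apply(truth$expected_fst, 1, as.numeric, simplify = FALSE),
    inversion = if (!is.null(truth$inversion)) list(
      chrom = truth$inversion$chrom, start = truth$inversion$start,
      end = truth$inversion$end,
      karyotype = as.integer(truth$inversion$karyotype)) else NULL,
    outlier_region = if (!is.null(truth$outlier_region)) list(
      chrom = truth$outlier_region$chrom,
      start = truth$outlier_region$start,
      end = truth$outlier_region$end) else NULL)
  if (include_freqs)
    doc$deme_freqs <- apply(truth$deme_freqs, 2, as.numeric, simplify = FALSE)
  yaml::write_yaml(doc, path, precision = 12L)
  invisible(path)
}

#' Read a truth ledger written by [write_truth_ledger()]
#' @param path ledger file.
#' @return a list mirroring the written keys.
#' @export
read_truth_ledger <- function(path) yaml::read_yaml(path)
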