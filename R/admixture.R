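#' Admixture estimation from genotype likelihoods by EM
#'
#' The model behind likelihood-based admixture estimation for low-coverage
#' data: individual `i`'s allele frequency at site `s` is
#' `h_is = sum_k q_ik f_sk`, genotypes are Binomial(2, h) and the data enter
#' only through genotype likelihoods, so the observed-data likelihood is
#' `prod_is sum_g GL_isg P(g | h_is)`. Q and F are updated by expected
#' cluster-specific allele counts; F is initialized from the per-site MAF
#' perturbed by a seeded Uniform(-0.05, 0.05) and Q from a symmetric
#' Dirichlet(1).
#'
#' @param ds a [gl_dataset()].
#' @param K number of clusters, `1 <= K <= n individuals`.
#' @param seed integer seed for the initialization.
#' @param tol convergence tolerance on the log-likelihood increase.
#' @param maxiter maximum EM iterations (default 2000).
#' @return object of class `admix_fit`: `Q` (individuals x K), `F` (sites x
#'   K), `loglik`, `loglik_trace`, `iterations`, `K`, `seed`, `converged`.
#' @export
admix_em <- function(ds, K, seed = 1L, tol = 1e-5, maxiter = 2000L) {
  n <- n_individuals(ds)
  m <- n_markers(ds)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must lie in [1, n individuals]")
  l0 <- .gl_slice(ds$gl, 1); l1 <- .gl_slice(ds$gl, 2); l2 <- .gl_slice(ds$gl, 3)
  set.seed(seed)
  maf <- estimate_maf_em(ds)$f
  Fmat <- matrix(pmin(pmax(maf + runif(m * K, -0.05, 0.05), 1e-5),
                      1 - 1e-5), m, K)
  Q <- matrix(rexp(n * K), n, K)
  Q <- Q / rowSums(Q)
  trace <- numeric(0)
  prev <- -Inf
  it <- 0L
  converged <- FALSE
  while (it < maxiter) {
    it <- it + 1L
    H <- Fmat %*% t(Q)                       # sites x individuals
    H <- pmin(pmax(H, 1e-9), 1 - 1e-9)
    p0 <- l0 * (1 - H)^2
    p1 <- l1 * 2 * H * (1 - H)
    p2 <- l2 * H^2
    lik <- p0 + p1 + p2
    ll <- sum(log(lik))
    trace <- c(trace, ll)
    eg <- (p1 + 2 * p2) / lik                # expected minor dosage
    w_min <- eg / H                          # weight per minor allele copy
    w_maj <- (2 - eg) / (1 - H)
    Qnew <- matrix(0, n, K)
    Fnew <- matrix(0, m, K)
    for (k in seq_len(K)) {
      a_k <- w_min * outer(Fmat[, k], Q[, k])        # expected minor from k
      b_k <- w_maj * outer(1 - Fmat[, k], Q[, k])    # expected major from k
      Fnew[, k] <- rowSums(a_k) / pmax(rowSums(a_k) + rowSums(b_k), 1e-12)
      Qnew[, k] <- (colSums(a_k) + colSums(b_k)) / (2 * m)
    }
    Fmat <- pmin(pmax(Fnew, 1e-5), 1 - 1e-5)
    Q <- Qnew / rowSums(Qnew)
    if (is.finite(prev) && ll - prev < tol) { converged <- TRUE; break }
    prev <- ll
  }
  rownames(Q) <- ds$ids
  structure(list(Q = Q, F = Fmat, loglik = trace[length(trace)],
                 loglik_trace = trace, iterations = it, K = K,
                 seed = as.integer(seed), converged = converged),
            class = "admix_fit")
}

#' @export
print.admix_fit <- function(x, ...) {
  cat(sprintf("admix_fit: K = %d, logL = %.2f after %d iteration(s)%s\n",
              x$K, x$loglik, x$iterations,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Replicated admixture runs across a K range
#'
#' Fits `reps` independently seeded EM runs for every K; the best-likelihood
#' fit per K is tagged. Replicate seeds derive deterministically from the
#' master seed.
#'
#' @param ds a [gl_dataset()].
#' @param k_range integer vector of K values (default 2:15).
#' @param reps replicates per K (default 50).
#' @param seed master seed.
#' @param tol,maxiter forwarded to [admix_em()].
#' @return list with `fits` (list of `admix_fit`), `summary` (data.frame
#'   K, rep, seed, loglik, best).
#' @export
run_replicates <- function(ds, k_range = 2:15, reps = 50L, seed = 1L,
                           tol = 1e-5, maxiter = 2000L) {
  grid <- expand.grid(rep = seq_len(reps), K = k_range)
  fits <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    s <- substream_seed(seed, sprintf("admix_K%d_rep%d", grid$K[r],
                                      grid$rep[r]))
    fits[[r]] <- admix_em(ds, grid$K[r], seed = s, tol = tol,
                          maxiter = maxiter)
  }
  summary <- data.frame(K = grid$K, rep = grid$rep,
                        seed = vapply(fits, `[[`, 0L, "seed"),
                        loglik = vapply(fits, `[[`, 0, "loglik"))
  summary$best <- FALSE
  for (k in unique(summary$K)) {
    rows <- which(summary$K == k)
    summary$best[rows[which.max(summary$loglik[rows])]] <- TRUE
  }
  list(fits = fits, summary = summary)
}

#' Puechmaille-style estimators of the number of clusters
#'
#' Per fit and sampling site, the mean and the median membership of each
#' cluster are computed; a cluster counts at a threshold when at least one
#' site's mean (resp. median) membership reaches it, giving per-fit MeanK
#' and MedK. Replicates are aggregated by their median (MedMeanK, MedMedK)
#' and maximum (MaxMeanK, MaxMedK); fractional medians are rounded down.
#'
#' @param fits list of [admix_em()] fits (replicates).
#' @param site_labels character vector of sampling-site labels per
#'   individual.
#' @param thresholds membership thresholds (default 0.5, 0.6, 0.7, 0.8).
#' @return data.frame with one row per threshold and columns `MedMedK`,
#'   `MedMeanK`, `MaxMedK`, `MaxMeanK`.
#' @export
puechmaille_k <- function(fits, site_labels,
                          thresholds = c(0.5, 0.6, 0.7, 0.8)) {
  if (inherits(fits, "admix_fit")) fits <- list(fits)
  if (is.null(site_labels)) stop("site labels are required")
  per_fit <- lapply(fits, function(fit) {
    stopifnot(nrow(fit$Q) == length(site_labels))
    sites <- unique(site_labels)
    mean_m <- sapply(sites, function(s)
      colMeans(fit$Q[site_labels == s, , drop = FALSE]))
    med_m <- sapply(sites, function(s)
      apply(fit$Q[site_labels == s, , drop = FALSE], 2, median))
    mean_m <- matrix(mean_m, nrow = fit$K)   # clusters x sites
    med_m <- matrix(med_m, nrow = fit$K)
    list(mean = mean_m, med = med_m)
  })
  out <- lapply(thresholds, function(th) {
    mean_k <- vapply(per_fit, function(x) sum(apply(x$mean >= th, 1, any)), 0L)
    med_k <- vapply(per_fit, function(x) sum(apply(x$med >= th, 1, any)), 0L)
    data.frame(threshold = th,
               MedMedK = floor(median(med_k)),
               MedMeanK = floor(median(mean_k)),
               MaxMedK = max(med_k),
               MaxMeanK = max(mean_k))
  })
  do.call(rbind, out)
}

#' Reassign F0 migrants to their cluster of near-total membership
#'
#' The dominant cluster of a sampling site is the cluster with the highest
#' mean membership there. Individuals with membership strictly above
#' `cutoff` to a different cluster are treated as first-generation migrants
#' and relabelled to that cluster.
#'
#' @param Q membership matrix (individuals x K) or an [admix_em()] fit.
#' @param site_labels sampling-site label per individual.
#' @param cutoff membership threshold (default 0.99, strict).
#' @return list with `groups` (cluster label per individual after
#'   reassignment), `dominant` (per-site dominant cluster) and `moves`
#'   (data.frame of reassignments).
#' @export
reassign_f0_migrants <- function(Q, site_labels, cutoff = 0.99) {
  if (inherits(Q, "admix_fit")) Q <- Q$Q
  stopifnot(nrow(Q) == length(site_labels))
  sites <- unique(site_labels)
  dominant <- vapply(sites, function(s)
    which.max(colMeans(Q[site_labels == s, , drop = FALSE])), 0L)
  groups <- dominant[match(site_labels, sites)]
  qmax <- apply(Q, 1, max)
  amax <- apply(Q, 1, which.max)
  move <- qmax > cutoff & amax != groups
  moves <- data.frame(individual = which(move),
                      id = rownames(Q)[move] %||% as.character(which(move)),
                      site = site_labels[move],
                      from = unname(groups[move]), to = amax[move],
                      q = qmax[move])
  groups[move] <- amax[move]
  list(groups = unname(groups), dominant = dominant, moves = moves)
}

#' Flag putatively admixed individuals
#'
#' @param Q membership matrix or an [admix_em()] fit.
#' @param cutoff individuals with maximum membership strictly below this are
#'   flagged (default 0.8).
#' @return logical vector.
#' @export
flag_admixed <- function(Q, cutoff = 0.8) {
  if (inherits(Q, "admix_fit")) Q <- Q$Q
  apply(Q, 1, max) < cutoff
}

#' Best label permutation between two membership matrices
#'
#' Greedy assignment maximizing column correlation; adequate for the small K
#' used in tests (replicate-mode alignment across runs is out of scope).
#'
#' @param Q reference matrix.
#' @param Q2 matrix to permute.
#' @return `Q2` with columns permuted to best match `Q`.
#' @export
align_clusters <- function(Q, Q2) {
  K <- ncol(Q)
  stopifnot(ncol(Q2) == K)
  cost <- suppressWarnings(cor(Q, Q2))
  cost[!is.finite(cost)] <- 0
  perm <- integer(K)
  used <- logical(K)
  for (k in order(apply(cost, 1, max), decreasing = TRUE)) {
    j <- order(cost[k, ], decreasing = TRUE)
    j <- j[!used[j]][1L]
    perm[k] <- j
    used[j] <- TRUE
  }
  Q2[, perm, drop = FALSE]
}
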