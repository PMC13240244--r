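#' Maximum-likelihood allele frequencies by per-site EM
#'
#' Estimates the minor-allele frequency of every site from genotype
#' likelihoods under a Hardy-Weinberg genotype prior: given the current `f`,
#' the genotype posterior is proportional to `GL * ((1-f)^2, 2f(1-f), f^2)`
#' and `f` is updated from the posterior expected allele counts of the
#' non-missing individuals. Iterated to `tol` or `maxiter`. Sites with no
#' data keep their initialization and are flagged.
#'
#' @param ds a [gl_dataset()] or a sites x individuals x 3 likelihood array.
#' @param tol per-site convergence tolerance on `|delta f|`.
#' @param maxiter iteration cap.
#' @return list with `f` (numeric per site), `flagged` (all-missing sites),
#'   `iterations`.
#' @export
estimate_maf_em <- function(ds, tol = 1e-6, maxiter = 100L) {
  gl <- if (inherits(ds, "gl_dataset")) ds$gl else ds
  miss <- if (inherits(ds, "gl_dataset")) gl_missing(ds) else {
    mx <- pmax(.gl_slice(gl, 1), .gl_slice(gl, 2), .gl_slice(gl, 3))
    mn <- pmin(.gl_slice(gl, 1), .gl_slice(gl, 2), .gl_slice(gl, 3))
    (mx - mn) < 1e-9
  }
  l0 <- .gl_slice(gl, 1); l1 <- .gl_slice(gl, 2); l2 <- .gl_slice(gl, 3)
  dim(miss) <- dim(l0)
  obs <- !miss
  n_obs <- rowSums(obs)
  # initialization: mean dosage under a flat genotype prior
  denom <- l0 + l1 + l2
  e_flat <- (l1 + 2 * l2) / denom
  f <- rowSums(e_flat * obs) / pmax(2 * n_obs, 1)
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  active <- n_obs > 0L
  it <- 0L
  while (it < maxiter && any(active)) {
    it <- it + 1L
    fa <- f[active]
    p0 <- l0[active, , drop = FALSE] * (1 - fa)^2
    p1 <- l1[active, , drop = FALSE] * 2 * fa * (1 - fa)
    p2 <- l2[active, , drop = FALSE] * fa^2
    eg <- (p1 + 2 * p2) / (p0 + p1 + p2)
    fnew <- rowSums(eg * obs[active, , drop = FALSE]) / (2 * n_obs[active])
    moved <- abs(fnew - fa) >= tol
    f[active] <- fnew
    active[active] <- moved
  }
  list(f = f, flagged = n_obs == 0L, iterations = it)
}

#' Posterior-mean genotype dosages
#'
#' Expected minor-allele count per site and individual given the genotype
#' likelihoods and a Hardy-Weinberg prior at the supplied site frequencies.
#'
#' @param ds a [gl_dataset()].
#' @param f per-site frequencies (defaults to [estimate_maf_em()]).
#' @param na_missing return `NA` for missing entries (`TRUE`, default) or the
#'   prior mean `2f` (`FALSE`).
#' @return numeric matrix, sites x individuals.
#' @export
posterior_dosage <- function(ds, f = NULL, na_missing = TRUE) {
  if (is.null(f)) f <- estimate_maf_em(ds)$f
  p0 <- .gl_slice(ds$gl, 1) * (1 - f)^2
  p1 <- .gl_slice(ds$gl, 2) * 2 * f * (1 - f)
  p2 <- .gl_slice(ds$gl, 3) * f^2
  e <- (p1 + 2 * p2) / (p0 + p1 + p2)
  miss <- gl_missing(ds)
  e[miss] <- if (na_missing) NA_real_ else (2 * f)[row(e)[miss]]
  e
}

#' Hard genotype calls by maximum posterior
#'
#' @param ds a [gl_dataset()].
#' @param f per-site frequencies for the Hardy-Weinberg prior.
#' @return integer matrix (0/1/2 minor-allele copies, `NA` where missing).
#' @export
call_genotypes <- function(ds, f = NULL) {
  if (is.null(f)) f <- estimate_maf_em(ds)$f
  p0 <- .gl_slice(ds$gl, 1) * (1 - f)^2
  p1 <- .gl_slice(ds$gl, 2) * 2 * f * (1 - f)
  p2 <- .gl_slice(ds$gl, 3) * f^2
  g <- matrix(max.col(cbind(as.vector(p0), as.vector(p1), as.vector(p2)),
                      ties.method = "first") - 1L,
              nrow(p0), ncol(p0))
  g[gl_missing(ds)] <- NA_integer_
  g
}

#' Iterative individual-allele-frequency PCA from genotype likelihoods
#'
#' The low-coverage PCA model: starting from per-site frequencies `f`,
#' iterate (1) posterior expected genotypes `e` given a Hardy-Weinberg prior
#' at the current individual allele frequencies `pi`; (2) centering by the
#' site means `2f`; (3) a rank-`K` SVD of the centered matrix; (4) the
#' update `pi = (reconstruction + 2f) / 2` truncated to `[1e-4, 1 - 1e-4]`.
#' Iteration stops when the root-mean-square change of `pi` drops below
#' `tol` or after `maxiter` rounds. The final standardized matrix
#' `Z = (e - 2f) / sqrt(2f(1-f))` gives the individual covariance
#' `C = t(Z) Z / M` and its eigen decomposition.
#'
#' @param ds a [gl_dataset()].
#' @param K number of latent axes used for the reconstruction.
#' @param tol RMS convergence tolerance on `pi`.
#' @param maxiter iteration cap.
#' @return object of class `pca_model`: `f`, `pi`, `C`, `values`,
#'   `vectors` (individual scores in columns), `Z` (final standardized
#'   matrix), `K`, `iterations`.
#' @export
pcangsd_fit <- function(ds, K = 2L, tol = 1e-5, maxiter = 100L) {
  n <- n_individuals(ds)
  if (K >= n) stop("K must be smaller than the number of individuals")
  m <- n_markers(ds)
  f <- estimate_maf_em(ds)$f
  f <- pmin(pmax(f, 1e-4), 1 - 1e-4)
  sdv <- sqrt(2 * f * (1 - f))
  l0 <- .gl_slice(ds$gl, 1); l1 <- .gl_slice(ds$gl, 2); l2 <- .gl_slice(ds$gl, 3)
  pi_mat <- matrix(f, m, n)
  expected <- function(pi_mat) {
    p0 <- l0 * (1 - pi_mat)^2
    p1 <- l1 * 2 * pi_mat * (1 - pi_mat)
    p2 <- l2 * pi_mat^2
    (p1 + 2 * p2) / (p0 + p1 + p2)
  }
  it <- 0L
  repeat {
    it <- it + 1L
    e <- expected(pi_mat)
    ec <- e - 2 * f
    sv <- .top_svd(ec, K)
    recon <- sv$u %*% (sv$d * t(sv$v))
    pi_new <- (recon + 2 * f) / 2
    pi_new <- pmin(pmax(pi_new, 1e-4), 1 - 1e-4)
    delta <- sqrt(mean((pi_new - pi_mat)^2))
    pi_mat <- pi_new
    if (delta < tol || it >= maxiter) break
  }
  e <- expected(pi_mat)
  z <- (e - 2 * f) / sdv
  C <- crossprod(z) / m
  dimnames(C) <- list(ds$ids, ds$ids)
  dec <- eigen(C, symmetric = TRUE)
  structure(list(f = f, pi = pi_mat, C = C, values = dec$values,
                 vectors = dec$vectors, Z = z, K = K, iterations = it),
            class = "pca_model")
}

# economy top-K SVD via the small-side eigen problem
.top_svd <- function(z, K) {
  ctc <- crossprod(z)
  dec <- eigen(ctc, symmetric = TRUE)
  d <- sqrt(pmax(dec$values[seq_len(K)], 0))
  v <- dec$vectors[, seq_len(K), drop = FALSE]
  u <- z %*% v
  u <- sweep(u, 2, ifelse(d > 0, d, 1), "/")
  list(u = u, d = d, v = v)
}

#' @export
print.pca_model <- function(x, ...) {
  cat(sprintf("pca_model: %d sites, %d individuals, K = %d (%d iterations)\n",
              nrow(x$pi), ncol(x$pi), x$K, x$iterations))
  invisible(x)
}

#' Choose the number of significant PC axes by an elbow rule
#'
#' Default proxy for a visual scree decision: the axis count maximizing the
#' second difference (curvature) of the eigenvalue curve. An explicit
#' `override` wins; fewer than three eigenvalues give `K* = 1`.
#'
#' @param values eigenvalues, non-increasing.
#' @param override optional integer override.
#' @return integer `K* >= 1`.
#' @export
choose_axes <- function(values, override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  n <- length(values)
  if (n < 3L) return(1L)
  curv <- values[1:(n - 2L)] - 2 * values[2:(n - 1L)] + values[3:n]
  as.integer(which.max(curv))
}

#' PCA-based selection scan with a chi-square(1) null
#'
#' For axis `k` with eigenvector `u_k` and eigenvalue `lambda_k` of the
#' individual covariance, the statistic of SNP `j` is
#' `s_jk = (z_j' u_k)^2 / lambda_k` where `z_j` is the SNP's standardized
#' expected-genotype vector. Under drift alone `s` follows chi-square with
#' 1 d.f.; p-values are its upper tail and q-values are computed per axis.
#'
#' @param model a [pcangsd_fit()] result.
#' @param axes integer axes to scan (defaults to `1:model$K`).
#' @param markers optional marker table for output coordinates.
#' @return object of class `selection_scan`: data.frame with `chrom`, `pos`,
#'   `site`, `axis`, `stat`, `p`, `q`.
#' @export
fastpca_scan <- function(model, axes = NULL, markers = NULL) {
  if (is.null(axes)) axes <- seq_len(model$K)
  if (any(axes > ncol(model$vectors)) || any(axes < 1L))
    stop("requested axis exceeds the fitted decomposition")
  if (any(axes > model$K))
    stop("requested axis exceeds the fitted K")
  m <- nrow(model$Z)
  out <- lapply(axes, function(k) {
    proj <- as.vector(model$Z %*% model$vectors[, k])
    s <- proj^2 / model$values[k]
    p <- pchisq(s, df = 1, lower.tail = FALSE)
    q <- qvalues(pmax(p, .Machine$double.xmin))
    data.frame(site = seq_len(m), axis = k, stat = s, p = p, q = q)
  })
  out <- do.call(rbind, out)
  if (!is.null(markers)) {
    out$chrom <- markers$chrom[out$site]
    out$pos <- markers$pos[out$site]
    out <- out[, c("chrom", "pos", "site", "axis", "stat", "p", "q")]
  }
  class(out) <- c("selection_scan", class(out))
  out
}

#' Storey q-values
#'
#' Estimates the null proportion `pi0` on the lambda grid 0.05..0.95 with a
#' cubic smoothing spline extrapolated at the grid's right end, falling back
#' to `pi0 = 1` (plain Benjamini-Hochberg) when the estimate leaves (0, 1].
#' `q_j` is the running minimum of `pi0 * m * p_(i) / i` over `p_(i) >=
#' p_j`, capped at 1.
#'
#' @param p p-values in (0, 1].
#' @param pi0 optional fixed null proportion.
#' @return q-values in the order of `p`.
#' @export
qvalues <- function(p, pi0 = NULL) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  m <- length(p)
  if (is.null(pi0)) {
    lam <- seq(0.05, 0.95, by = 0.05)
    pi0_hat <- vapply(lam, function(l) mean(p > l) / (1 - l), 0)
    pi0 <- if (m >= 100 && length(unique(pi0_hat)) > 4) {
      fit <- smooth.spline(lam, pi0_hat, df = 3)
      predict(fit, x = max(lam))$y
    } else 1
    if (!is.finite(pi0) || pi0 <= 0 || pi0 > 1) pi0 <- 1
  }
  oi <- order(p)
  q <- pi0 * m * p[oi] / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[oi] <- q
  out
}
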