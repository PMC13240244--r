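fake_windows <- function(n, chrom = "c1", size = 15L) {
  data.frame(chrom = chrom, win = seq_len(n), chrom_win = seq_len(n),
             first = (seq_len(n) - 1L) * size + 1L,
             last = seq_len(n) * size,
             start_bp = (seq_len(n) - 1L) * size * 100 + 1,
             end_bp = seq_len(n) * size * 100, n_snps = size)
}

# scan table giving each window the requested count of q < 0.01 SNPs
scan_with_counts <- function(counts, windows, axis = 1L) {
  rows <- list()
  for (w in seq_along(counts)) {
    sites <- windows$first[w]:windows$last[w]
    q <- rep(0.5, length(sites))
    if (counts[w] > 0) q[seq_len(counts[w])] <- 1e-4
    rows[[w]] <- data.frame(site = sites, axis = axis, stat = 1,
                            p = q, q = q)
  }
  do.call(rbind, rows)
}

test_that("fixed-count windows drop the trailing partial window", {
  markers <- data.frame(chrom = "c1", pos = seq_len(2500) * 10,
                        major = "A", minor = "C")
  w <- make_snp_windows(markers, 1000)
  expect_equal(nrow(w), 2L)
  expect_equal(w$last - w$first + 1L, rep(1000L, 2))
  w2 <- make_snp_windows(data.frame(chrom = "c1", pos = 1:100 * 5,
                                    major = "A", minor = "C"), 100)
  expect_equal(nrow(w2), 1L)
  expect_warning(make_snp_windows(data.frame(chrom = "c1", pos = 1:99,
                                             major = "A", minor = "C"), 100),
                 "fewer")
  # spans are non-overlapping and increasing within a chromosome
  markers3 <- data.frame(chrom = rep(c("a", "b"), each = 500),
                         pos = rep(seq_len(500) * 7, 2),
                         major = "A", minor = "C")
  w3 <- make_snp_windows(markers3, 50)
  for (chr in c("a", "b")) {
    s <- w3[w3$chrom == chr, ]
    expect_true(all(diff(s$start_bp) > 0))
    expect_true(all(s$start_bp[-1] > s$end_bp[-nrow(s)]))
  }
})

test_that("outlier-window merging follows the strict gap rule", {
  w <- fake_windows(12)
  # counts (12, 0 x 8, 11): gap of 8 windows, merged into one region
  s1 <- scan_with_counts(c(12, rep(0, 8), 11, 0, 0), w)
  r1 <- call_outlier_regions(s1, w)
  expect_equal(nrow(r1), 1L)
  expect_equal(r1$n_windows, 2L)
  expect_equal(r1$start, w$start_bp[1])
  expect_equal(r1$end, w$end_bp[10])
  # counts (12, 0 x 10, 11): gap of 10, two regions
  w2 <- fake_windows(14)
  s2 <- scan_with_counts(c(12, rep(0, 10), 11, 0, 0), w2)
  expect_equal(nrow(call_outlier_regions(s2, w2)), 2L)
  # a window with 9 outliers never seeds a region
  s3 <- scan_with_counts(rep(9, 12), w)
  expect_equal(nrow(call_outlier_regions(s3, w)), 0L)
})

test_that("region caller equals a brute-force merging oracle", {
  set.seed(71)
  w <- fake_windows(60)
  for (trial in 1:300) {
    flagged <- sort(sample.int(60, sample.int(12, 1)))
    counts <- integer(60)
    counts[flagged] <- 10L
    scan <- scan_with_counts(counts, w)
    regions <- call_outlier_regions(scan, w, merge_gap = 10)
    expect_region_members(regions, w, merge_oracle(flagged, 10))
  }
})

test_that("MDS cluster caller equals the oracle and applies its minimum", {
  set.seed(72)
  n <- 100  # keep flagged fractions small so 50-sigma spikes stay past 3 SD
  w <- fake_windows(n)
  for (trial in 1:200) {
    flagged <- sort(sample.int(n, sample.int(8, 1)))
    x <- rnorm(n, 0, 0.01)
    x[flagged] <- 50 + rnorm(length(flagged))  # way past 3 SD
    mds <- structure(list(points = cbind(x, matrix(0, n, 4)),
                          eig = rep(1, n)), class = "mds_result")
    regions <- mds_outlier_clusters(mds, w, merge_gap = 20, min_windows = 1)
    oracle <- merge_oracle(flagged, 20)
    expect_region_members(regions, w, oracle)
  }
  # 9 contiguous outliers are dropped at the 10-window minimum
  x <- rnorm(n, 0, 0.01); x[11:19] <- 50
  mds <- structure(list(points = cbind(x, matrix(0, n, 4)),
                        eig = rep(1, n)), class = "mds_result")
  expect_equal(nrow(mds_outlier_clusters(mds, w)), 0L)
  # outliers at indices 10 and 31 (gap 21) form separate clusters
  x <- rnorm(n, 0, 0.01); x[c(10, 31)] <- 50
  mds2 <- structure(list(points = cbind(x, matrix(0, n, 4)),
                         eig = rep(1, n)), class = "mds_result")
  r2 <- mds_outlier_clusters(mds2, w, min_windows = 1)
  expect_equal(nrow(r2), 2L)
})

test_that("local PCA summaries are unit-norm, low-rank and reproducible", {
  fix <- random_genotype_dataset(300, 30, seed = 73)
  w <- make_snp_windows(fix$ds$markers, 100)
  lp <- local_pca_windows(fix$ds, w, k = 4)
  for (s in lp$summaries) {
    expect_equal(sqrt(sum(s^2)), 1, tolerance = 1e-9)
    expect_lte(qr(s)$rank, 4)
    expect_equal(s, t(s), tolerance = 1e-12)
  }
  # identical windows give identical summaries and distance 0
  g2 <- rbind(fix$g[1:100, ], fix$g[1:100, ])
  ds2 <- gl_from_genotypes(g2)
  lp2 <- local_pca_windows(ds2, make_snp_windows(ds2$markers, 100))
  expect_equal(lp2$summaries[[1]], lp2$summaries[[2]], tolerance = 1e-12)
  D <- window_distances(lp2)
  expect_equal(D[1, 2], 0, tolerance = 1e-10)
})

test_that("window distances form a metric", {
  fix <- random_genotype_dataset(1200, 25, seed = 74)
  w <- make_snp_windows(fix$ds$markers, 100)
  D <- window_distances(local_pca_windows(fix$ds, w))
  expect_equal(diag(D), rep(0, nrow(D)))
  expect_equal(D, t(D))
  n <- nrow(D)
  for (i in 1:n) for (j in 1:n) for (k in 1:n)
    expect_lte(D[i, j], D[i, k] + D[k, j] + 1e-12)
})

test_that("classical scaling recovers collinear geometry and pads axes", {
  x <- c(0, 1, 2, 5, 9)
  D <- abs(outer(x, x, "-"))
  mds <- mds_windows(D, axes = 5)
  expect_equal(dim(mds$points), c(5L, 5L))
  # axis 1 recovers the ordering up to sign (sign fixed: max loading > 0)
  expect_equal(cor(mds$points[, 1], x), 1, tolerance = 1e-9)
  # one positive eigenvalue only: remaining axes identically zero
  expect_true(all(abs(mds$points[, 3:5]) < 1e-9))
  # duplicate points map together
  D2 <- as.matrix(dist(c(0, 0, 3, 7)))
  m2 <- mds_windows(D2, axes = 5)
  expect_equal(m2$points[1, ], m2$points[2, ], tolerance = 1e-9)
  # an all-zero distance matrix gives all-zero coordinates
  expect_equal(mds_windows(matrix(0, 4, 4), axes = 5)$points,
               matrix(0, 4, 5))
  # four equidistant points embed as a simplex: 3 positive axes, 2 padded
  D3 <- matrix(1, 4, 4); diag(D3) <- 0
  m3 <- mds_windows(D3, axes = 5)
  expect_true(all(abs(m3$points[, 4:5]) < 1e-9))
  expect_equal(unname(as.matrix(dist(m3$points))), unname(D3),
               tolerance = 1e-9)
})

test_that("windows inside a simulated inversion cluster together", {
  cfg <- sim_config(n_demes = 1, n_per_deme = 40, n_snps = 4000,
                    chrom_layout = data.frame(chrom = "chr1",
                                              length_bp = 4e5, n_snps = 4000),
                    inversion_spec = list(chrom = "chr1", start = 1e5,
                                          end = 2e5, freq = 0.4,
                                          divergent_frac = 0.4, delta = 0.8),
                    mean_depth = 2, seed = 75)
  sim <- simulate_dataset(cfg)
  w <- make_snp_windows(sim$gl$markers, 100)
  D <- window_distances(local_pca_windows(sim$gl, w))
  inside <- which(w$start_bp >= 1e5 & w$end_bp <= 2e5)
  outside <- setdiff(seq_len(nrow(w)), inside)
  within <- mean(D[inside, inside][upper.tri(diag(length(inside)))])
  between <- mean(D[inside, outside])
  expect_lt(within, between)
})
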