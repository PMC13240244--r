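make_pop_freqs <- function(p1, p2, n1 = 1000, n2 = 1000) {
  structure(list(p = cbind(A = p1, B = p2),
                 n = cbind(A = rep(n1, length(p1)), B = rep(n2, length(p1))),
                 n_eff = cbind(A = rep(n1, length(p1)),
                               B = rep(n2, length(p1))),
                 groups = c("A", "B")), class = "pop_freqs")
}

test_that("Hudson FST hits its analytic anchors", {
  # fixed difference
  expect_equal(hudson_fst(make_pop_freqs(0, 1), c("A", "B"))$fst, 1)
  # identical frequencies: small negative from the finite-sample correction
  set.seed(51)
  p <- runif(2000, 0.1, 0.5)
  n <- 60
  g1 <- matrix(rbinom(2000 * 30, 2, p), 2000)
  g2 <- matrix(rbinom(2000 * 30, 2, p), 2000)
  ds <- gl_from_genotypes(cbind(g1, g2))
  pf <- pop_allele_freqs(ds, rep(c("A", "B"), each = 30))
  fst <- hudson_fst(pf, c("A", "B"))$fst
  expect_lte(fst, 0.005)
  expect_lt(abs(fst), 2 / (n - 1))
  # label swap invariance
  expect_equal(hudson_fst(pf, c("B", "A"))$fst, fst)
})

test_that("FST and AFD increase monotonically with simulated drift", {
  vals <- sapply(c(0.01, 0.05, 0.1), function(f_edge) {
    cfg <- sim_config(n_demes = 2, n_per_deme = 30, n_snps = 10000,
                      mean_depth = 2,
                      deme_graph = data.frame(from = 1, to = 2, f = f_edge),
                      seed = 52)
    sim <- simulate_dataset(cfg)
    pf <- pop_allele_freqs(sim$gl, sim$samples$site)
    c(hudson_fst(pf, c(1, 2))$fst, afd(pf, c(1, 2)))
  })
  expect_true(all(diff(vals[1, ]) > 0))
  expect_true(all(diff(vals[2, ]) > 0))
})

test_that("genome-wide FST is the ratio of averages, not an average of ratios", {
  set.seed(53)
  p1 <- runif(500, 0.1, 0.9); p2 <- pmin(p1 + runif(500, 0, 0.2), 0.99)
  n1 <- 1000; n2 <- 1000
  pf <- make_pop_freqs(p1, p2, n1, n2)
  h <- hudson_fst(pf, c("A", "B"))
  # brute-force per-site oracle of the ratio-of-averages estimator
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  expect_equal(h$fst, sum(num) / sum(den), tolerance = 1e-12)
  # the two averaging orders genuinely differ: the ratio of averages
  # weights sites by their denominator (heterozygosity)
  expect_gt(abs(h$fst - mean(num / den)), 1e-4)
})

test_that("AFD is a hand-computable symmetric mean difference", {
  pf <- make_pop_freqs(c(0.1, 0.3), c(0.2, 0.1))
  expect_equal(afd(pf, c("A", "B")), 0.15)
  expect_equal(afd(pf, c("B", "A")), 0.15)
  expect_equal(afd(make_pop_freqs(c(0.4, 0.2), c(0.4, 0.2)), 1:2), 0)
})

test_that("FST linearization matches the printed transform", {
  expect_equal(linearize_fst(0), 0)
  expect_equal(linearize_fst(0.5), 1)
  expect_equal(linearize_fst(0.048), 0.048 / 0.952)
  expect_error(linearize_fst(1), "< 1")
})

test_that("least-cost distances equal an exhaustive Dijkstra oracle", {
  # straight 10-cell corridor, 1 km cells: 9 km end to end
  corridor <- structure(list(grid = matrix(c(rep(0L, 10)), 1), xll = 0,
                             yll = 0, cellsize = 1), class = "raster_map")
  d <- least_cost_distance(corridor, data.frame(row = c(1, 1),
                                                col = c(1, 10)))
  expect_equal(d[1, 2], 9)
  # U-shaped water around a land block: detour forced
  g <- matrix(1L, 7, 9)
  g[2, 2:8] <- 0L        # corridor along the top
  g[2:6, 2] <- 0L        # left arm down
  g[2:6, 8] <- 0L        # right arm down
  u <- structure(list(grid = g, xll = 0, yll = 0, cellsize = 2),
                 class = "raster_map")
  coords <- data.frame(row = c(6, 6), col = c(2, 8))
  d2 <- least_cost_distance(u, coords)
  edges <- raster_edges(g, 2)
  water <- which(g == 0L)
  src <- match((coords$col[1] - 1) * 7 + coords$row[1], water)
  dst <- match((coords$col[2] - 1) * 7 + coords$row[2], water)
  oracle <- dijkstra_oracle(length(water), edges, src)[dst]
  expect_equal(d2[1, 2], oracle)
  expect_gt(d2[1, 2], 2 * 6)  # longer than the blocked straight line
  # disconnected basins are infinite
  g2 <- matrix(1L, 3, 5); g2[2, 1] <- 0L; g2[2, 5] <- 0L
  basins <- structure(list(grid = g2, xll = 0, yll = 0, cellsize = 1),
                      class = "raster_map")
  d3 <- least_cost_distance(basins, data.frame(row = c(2, 2), col = c(1, 5)))
  expect_equal(d3[1, 2], Inf)
  expect_error(least_cost_distance(basins,
                                   data.frame(row = 9, col = 1)), "outside")
})

test_that("Mantel detects affine association and validates input", {
  set.seed(54)
  x <- matrix(rnorm(64), 8); A <- as.matrix(dist(x))
  B <- 2 * A + 3; diag(B) <- 0
  mt <- mantel_ibd(A, B, permutations = 999, seed = 1)
  expect_equal(mt$r, 1, tolerance = 1e-10)
  expect_lt(mt$p, 0.01)
  expect_error(mantel_ibd(A, B[1:7, 1:7]), "square")
  A2 <- A; A2[1, 2] <- 99
  expect_error(mantel_ibd(A2, B), "symmetric")
})

test_that("Mantel p-values are calibrated under independence", {
  set.seed(55)
  ps <- replicate(60, {
    a <- as.matrix(dist(rnorm(8))); b <- as.matrix(dist(rnorm(8)))
    mantel_ibd(a, b, permutations = 199, seed = sample.int(1e6, 1))$p
  })
  expect_gt(mean(ps > 0.05), 0.8)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.001)
})
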