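test_that("pairwise Pearson matches hand-computed coefficients", {
  states <- cbind(a = c(1, 1, 0, 0), b = c(1, 0, 1, 0), c = c(0, 0, 1, 1),
                  d = c(1, 1, 0, 0))
  g <- pairwise_pearson(binary_raster(states, fps = 15))
  expect_equal(g$matrix["a", "b"], 0)
  expect_equal(g$matrix["a", "c"], -1)
  expect_equal(g$matrix["a", "d"], 1)
  expect_true(isSymmetric(g$matrix))
  expect_error(pairwise_pearson(binary_raster(cbind(c(0, 1)), fps = 15)),
               "at least 2")
})

test_that("constant columns yield NA entries excluded from statistics", {
  states <- cbind(c(1, 0, 1, 0), c(0, 0, 0, 0), c(1, 0, 1, 0))
  g <- pairwise_pearson(binary_raster(states, fps = 15))
  expect_true(is.na(g$matrix[1, 2]))
  expect_equal(g$n_undefined, 2)
  expect_equal(mean_correlation_above(g, 0.5), 1)  # only the defined pair
  expect_equal(unname(network_degree(g, 0)), 1)    # 1 defined pair, above 0
})

test_that("mean correlation above a threshold selects strictly greater pairs", {
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.4
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  expect_equal(mean_correlation_above(g, 0.3), 0.4)
  expect_equal(mean_correlation_above(g, 0.05), mean(c(0.1, 0.2, 0.4)))
  expect_true(is.na(mean_correlation_above(g, 1)))
  expect_error(mean_correlation_above(g, 2), "\\[-1, 1\\]")
})

test_that("network degree sweeps the grid and is non-increasing", {
  m <- diag(3); m[1, 2] <- m[2, 1] <- 0.1; m[1, 3] <- m[3, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.4
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  expect_equal(unname(network_degree(g, c(0, 0.15, 0.3))), c(1, 2 / 3, 1 / 3))
  deg <- network_degree(g)
  expect_true(all(diff(unname(deg)) <= 0))
  expect_equal(unname(network_degree(g, -1)), 1)
})

test_that("strong threshold applies the mean-percentile-then-round rule", {
  const_graph <- function(r, n = 5) {
    m <- matrix(r, n, n); diag(m) <- 1
    structure(list(matrix = m, method = "spike",
                   threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
              class = "correlation_graph")
  }
  expect_equal(strong_threshold(const_graph(0.28)), 0.30)
  expect_equal(strong_threshold(list(const_graph(0.22), const_graph(0.24))),
               0.25)
  expect_equal(strong_threshold(const_graph(0)), 0)
  # half-way values round up
  expect_equal(strong_threshold(const_graph(0.225)), 0.25)
  # percentile uses linear interpolation between order statistics
  set.seed(4)
  m <- matrix(0, 6, 6)
  vals <- runif(15)
  m[upper.tri(m)] <- vals
  m <- m + t(m); diag(m) <- 1
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  want <- 0.05 * floor(quantile(vals, 0.95, type = 7) / 0.05 + 0.5 + 1e-12)
  expect_equal(strong_threshold(g), unname(want))
  expect_error(strong_threshold(list()), "at least one")
})

test_that("connectivity reports percent of partners above threshold", {
  # star: neuron 1 linked to all, others only to neuron 1
  m <- diag(4)
  m[1, 2:4] <- m[2:4, 1] <- 0.5
  m[2, 3] <- m[3, 2] <- m[2, 4] <- m[4, 2] <- m[3, 4] <- m[4, 3] <- 0.1
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  expect_equal(unname(connectivity(g, 0.3)), c(100, 100 / 3, 100 / 3, 100 / 3))
  expect_equal(unname(connectivity(g, 0.9)), c(0, 0, 0, 0))
  expect_equal(unname(connectivity(g, 0)), rep(100, 4))
})

test_that("clustering links pairs above the 80th percentile into components", {
  # 4 neurons, six distinct coefficients; the top ~1 edge survives the cut
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.9
  m[3, 4] <- m[4, 3] <- 0.8
  m[1, 3] <- m[3, 1] <- 0.1; m[1, 4] <- m[4, 1] <- 0.2
  m[2, 3] <- m[3, 2] <- 0.3; m[2, 4] <- m[4, 2] <- 0.15
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  a <- cluster_assign(g)
  cut <- quantile(c(0.9, 0.8, 0.1, 0.2, 0.3, 0.15), 0.8, type = 7)
  expect_equal(unname(attr(a, "cut")), unname(cut))
  # the 80th percentile is exactly 0.8, so only the 0.9 edge strictly
  # exceeds it: one 2-member cluster, neurons 3 and 4 unclustered
  expect_equal(unname(a[1]), unname(a[2]))
  expect_true(is.na(a[3]) && is.na(a[4]))

  # all-equal coefficients: nothing strictly exceeds the percentile
  m2 <- matrix(0.5, 4, 4); diag(m2) <- 1
  g2 <- structure(list(matrix = m2, method = "spike",
                       threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                  class = "correlation_graph")
  expect_true(all(is.na(cluster_assign(g2))))
})

test_that("cluster membership is invariant to neuron relabeling", {
  set.seed(12)
  ras <- random_raster(120, 8)
  g <- pairwise_pearson(ras)
  a <- cluster_assign(g)
  perm <- sample(8)
  g_p <- pairwise_pearson(binary_raster(unclass(ras)[, perm], fps = 15,
                                        neuron_ids = attr(ras, "neuron_ids")[perm]))
  a_p <- cluster_assign(g_p)
  same <- function(asg, i, j) !is.na(asg[i]) && !is.na(asg[j]) && asg[i] == asg[j]
  for (i in 1:7) for (j in (i + 1):8) {
    expect_equal(same(a, i, j),
                 same(a_p, which(perm == i), which(perm == j)))
  }
})

test_that("intra/intercluster means follow the construction", {
  m <- diag(4)
  m[1, 2] <- m[2, 1] <- 0.8
  m[lower.tri(m) & m == 0] <- 0.1
  m[upper.tri(m) & m == 0] <- 0.1
  g <- structure(list(matrix = m, method = "spike",
                      threshold_grid = seq(0, 0.3, 0.05), n_undefined = 0),
                 class = "correlation_graph")
  a <- c(1L, 1L, NA, NA); names(a) <- rownames(m) <- colnames(m) <- paste0("n", 1:4)
  res <- intra_inter_cluster(g, a)
  expect_equal(res$intra, 0.8)
  expect_equal(res$inter, 0.1)
  # single all-member cluster has no outside pairs
  a_all <- rep(1L, 4)
  res2 <- intra_inter_cluster(g, a_all)
  expect_true(is.na(res2$inter))
  # nothing clustered gives an empty frame
  expect_equal(nrow(intra_inter_cluster(g, rep(NA_integer_, 4))), 0)
})

test_that("intra exceeds inter for percentile-rule clusters", {
  set.seed(71)
  for (k in 1:20) {
    ras <- random_raster(150, 9)
    g <- pairwise_pearson(ras)
    if (length(offdiag <- g$matrix[upper.tri(g$matrix)]) == 0) next
    a <- cluster_assign(g)
    res <- intra_inter_cluster(g, a)
    if (nrow(res) == 0) next
    ok <- !is.na(res$inter)
    expect_true(all(res$intra[ok] >= res$inter[ok]))
  }
})

test_that("correlation statistics equal brute-force oracles on small instances", {
  set.seed(99)
  for (k in 1:40) {
    ras <- random_raster(sample(50:200, 1), sample(3:10, 1))
    g <- pairwise_pearson(ras)
    want <- oracle_pearson(unclass(ras))
    expect_equal(unname(g$matrix), want, tolerance = 1e-12)
    if (length(oracle_offdiag(want)) == 0) next
    # counting oracles take the computed matrix so strict thresholds are not
    # flipped by last-bit differences between the two Pearson formulas
    m <- unname(g$matrix)
    for (t in c(0.05, 0.1, 0.3)) {
      expect_equal(unname(network_degree(g, t)), oracle_degree(m, t))
      expect_equal(unname(connectivity(g, t)), oracle_connectivity(m, t))
    }
    a <- cluster_assign(g)
    oc <- oracle_clusters(m)
    same <- function(v, i, j) !is.na(v[i]) && !is.na(v[j]) && v[i] == v[j]
    n <- ncol(ras)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      expect_equal(same(a, i, j), same(oc, i, j))
    }
  }
})

test_that("binarized correlation grows with the planted sharing fraction", {
  r_at <- function(f, seed) {
    cfg <- sim_config(n_neurons = 6, rate_per_min = 3, duration_s = 300,
                      noise_sd = 0.05, coupled_pairs = list(c(1, 2, f)),
                      seed = seed)
    rec <- simulate_recording(cfg)
    pairwise_pearson(binarize(rec$traces, "spike"))$matrix[1, 2]
  }
  rs <- vapply(c(0, 0.25, 0.5, 1),
               function(f) mean(vapply(1:4, function(s) r_at(f, 40 + s),
                                       numeric(1))), numeric(1))
  expect_true(all(diff(rs) > 0))
  expect_lt(abs(rs[1]), 0.1)  # uncoupled pairs near zero
  expect_gt(rs[4], 0.8)
})
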