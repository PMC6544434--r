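# clustering module: Ward over-clustering, homogeneity, pruning,
# re-aggregation, explained variance, type fractions.

# three well-separated archetype profiles plus per-cell noise
archetype_profiles <- function(n_per = 12, noise = 0.05, seed = 1) {
  set.seed(seed)
  t <- seq(0, 1, length.out = 60)
  arch <- rbind(sin(pi * t), exp(-8 * t), as.numeric(t > 0.5))
  X <- arch[rep(1:3, each = n_per), ] +
    matrix(rnorm(3 * n_per * 60, sd = noise), 3 * n_per)
  list(X = X, truth = rep(c("a", "b", "c"), each = n_per))
}

test_that("well-separated archetypes yield pure clusters", {
  ap <- archetype_profiles()
  m <- cluster_profiles(ap$X, n_over = 10)
  purity <- sapply(split(ap$truth, m$labels), function(g) max(table(g)) / length(g))
  expect_true(all(purity == 1))
  expect_s3_class(m, "ClusterModel")
  # every neuron is labelled; centroids are member means
  expect_true(all(m$labels > 0))
  k <- m$labels[1]
  expect_equal(m$centroids[as.character(k), ],
               colMeans(ap$X[m$labels == k, , drop = FALSE]))
})

test_that("degenerate cuts and bad inputs behave per contract", {
  ap <- archetype_profiles(n_per = 4)
  m <- cluster_profiles(ap$X, n_over = nrow(ap$X))  # singletons
  expect_true(all(m$homogeneity == 1))
  expect_equal(m$explained_variance_pct$total, 100)
  bad <- ap$X; bad[3, 5] <- NaN
  expect_error(cluster_profiles(bad, 3), "3", class = "xmv1_bad_profiles")
  expect_error(cluster_profiles(ap$X, n_over = 1000), class = "xmv1_bad_argument")
})

test_that("duplicating every profile leaves the centroid set unchanged", {
  ap <- archetype_profiles(n_per = 6)
  m1 <- cluster_profiles(ap$X, 3)
  m2 <- cluster_profiles(rbind(ap$X, ap$X), 3)
  s1 <- m1$centroids[order(m1$centroids[, 1]), ]
  s2 <- m2$centroids[order(m2$centroids[, 1]), ]
  expect_equal(unname(s1), unname(s2), tolerance = 1e-12)
})

test_that("homogeneity matches its definition", {
  X <- rbind(c(1, 2, 3, 4), c(2, 4, 6, 8), c(1, 2, 3, 4))
  expect_equal(unname(homogeneity(X, rep(1L, 3))), 1)
  orth <- rbind(c(1, -1, 1, -1), c(1, 1, -1, -1))
  expect_equal(unname(homogeneity(orth, rep(1L, 2))), 0)
  # iid-noise profiles: homogeneity ~ 0
  set.seed(5)
  Z <- matrix(rnorm(50 * 80), 50)
  expect_lt(abs(homogeneity(Z, rep(1L, 50))), 0.1)
  # zero-variance member contributes 0 with a warning
  zv <- rbind(c(1, 2, 3, 4), c(5, 5, 5, 5))
  expect_warning(h <- homogeneity(zv, rep(1L, 2)), "zero-variance")
  expect_equal(unname(h), 0)
})

test_that("pruning keeps only homogeneous clusters and is monotone", {
  ap <- archetype_profiles(n_per = 10, noise = 0.03)
  set.seed(6)
  # iid-noise cells sharing a common offset: they form one spatially compact
  # cluster whose member profiles are mutually uncorrelated
  noise_cells <- 3 + matrix(rnorm(10 * 60, sd = 0.3), 10)
  X <- rbind(ap$X, noise_cells)
  m <- cluster_profiles(X, 4)
  pr <- prune_clusters(m, X, 0.4)
  # the iid-noise cells land in the pool, the archetype cells stay clustered
  expect_true(all(pr$labels[31:40] == 0))
  expect_true(all(pr$labels[1:30] > 0))
  # all-homogeneous model: nothing pruned
  m3 <- cluster_profiles(ap$X, 3)
  expect_length(prune_clusters(m3, ap$X, 0.4)$pruned, 0)
  # threshold 1.0 prunes everything (homogeneity <= 1 always)
  expect_true(all(prune_clusters(m3, ap$X, 1.0)$labels == 0))
  # raising the threshold never increases the number of kept clusters
  kept <- sapply(c(0, 0.2, 0.4, 0.6, 0.8, 1),
                 function(th) nrow(prune_clusters(m, X, th)$centroids))
  expect_true(all(diff(kept) <= 0))
})

test_that("re-aggregation rescues matching neurons and leaves others pooled", {
  ap <- archetype_profiles(n_per = 8, noise = 0.03)
  m <- cluster_profiles(ap$X, 3)
  # a pooled neuron identical to a centroid joins that cluster
  X <- rbind(ap$X, m$centroids[1, ], rep(c(1, -1), 30))
  m$labels <- c(m$labels, 0L, 0L)
  m2 <- reaggregate(m, X, 0.4)
  expect_equal(unname(m2$labels[25]), as.integer(rownames(m$centroids)[1]))
  # near-orthogonal neuron stays pooled
  expect_equal(unname(m2$labels[26]), 0L)
  expect_equal(m2$n_reaggregated, 1L)
})

test_that("re-aggregation barely moves centroids on default synthetic data", {
  X <- small_profiles()
  m <- cluster_pipeline(X, n_over = 15)
  new_ctr <- t(sapply(rownames(m$centroids), function(k) {
    colMeans(X[m$labels == as.integer(k), , drop = FALSE])
  }))
  rel <- sqrt(rowSums((new_ctr - m$centroids)^2) / rowSums(m$centroids^2))
  expect_true(all(rel < 0.05))
})

test_that("explained variance follows its definition and invariances", {
  ap <- archetype_profiles(n_per = 6, noise = 0.05)
  m <- cluster_profiles(ap$X, 3)
  # all neurons equal to their centroid -> 100%
  X_eq <- m$centroids[as.character(m$labels), ]
  expect_equal(explained_variance(X_eq, m$labels, m$centroids), 100)
  ev <- explained_variance(ap$X, m$labels, m$centroids)
  # shuffled assignment explains less than the fitted one
  set.seed(7)
  ev_shuf <- explained_variance(ap$X, sample(m$labels), m$centroids)
  expect_gt(ev, ev_shuf)
  # invariant to a global positive rescaling
  expect_equal(explained_variance(3.7 * ap$X, m$labels, 3.7 * m$centroids), ev,
               tolerance = 1e-12)
})

test_that("type fractions normalise over clustered neurons", {
  labels <- c(1L, 1L, 2L, 0L, 2L, 2L)
  tm <- c(`1` = "loud_ON", `2` = "quiet_ON")
  fr <- type_fractions(labels, tm)
  expect_equal(sum(fr), 1, tolerance = 1e-12)
  expect_equal(unname(fr["loud_ON"]), 2 / 5)
  expect_equal(unname(type_fractions(rep(1L, 4), tm[1])), 1)
  expect_error(type_fractions(labels, tm[1]), class = "xmv1_unmapped_cluster")
})

test_that("cluster labelling recovers the injected archetypes end to end", {
  ds <- small_dataset()
  pp <- small_preprocessed()
  X <- small_profiles()
  m <- cluster_pipeline(X, n_over = 15)
  mt <- match_to_truth(m$labels, ds$truth_labels[pp$kept])
  expect_gt(mt$accuracy, 0.85)
  tm <- label_clusters(m, ds$templates, attr(X, "stimuli"))
  # the rule-based archetype labels agree with the ground-truth majority map
  expect_gt(mean(tm == mt$mapping), 0.9)
})
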