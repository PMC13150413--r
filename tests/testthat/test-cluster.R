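test_that("DBSCAN frame statistics follow the outlier conventions", {
  cell <- cubic_cell(30)
  # one tight 5-atom clump
  clump <- md_frame(matrix(c(5, 5, 5, 6, 5, 5, 5, 6, 5, 5, 5, 6, 6, 6, 5),
                           5, 3, byrow = TRUE), rep("Pt", 5))
  cf <- cluster_frame(clump, cell, select_all(), eps = 2, min_samples = 2)
  expect_equal(cf$n_clusters, 1)
  expect_equal(cf$avg_size_excl_outliers, 5)
  expect_equal(cf$n_outliers, 0)

  # pair + distant singleton: the singleton is an outlier, not a cluster
  pair <- md_frame(matrix(c(5, 5, 5, 6.5, 5, 5, 20, 20, 20), 3, 3,
                          byrow = TRUE), rep("Pt", 3))
  cp <- cluster_frame(pair, cell, select_all(), eps = 2, min_samples = 2)
  expect_equal(cp$n_clusters, 1)
  expect_equal(cp$avg_size_excl_outliers, 2.0)
  expect_equal(cp$avg_size_incl_outliers, 1.5)
  expect_equal(cp$n_outliers, 1)
  expect_equal(cp$labels, c(1L, 1L, 0L))
})

test_that("min_samples = 2 equals the eps-graph component oracle", {
  for (s in 1:3) {
    set.seed(s)
    cell <- cubic_cell(14)
    n <- 120
    pos <- matrix(runif(3 * n, 0, 14), ncol = 3)
    fr <- md_frame(pos, rep("Pt", n))
    for (eps in c(1.2, 2.0)) {
      got <- cluster_frame(fr, cell, select_all(), eps = eps,
                           min_samples = 2)$labels
      want <- oracle_cluster_components(fr, cell, eps)
      # both sides label clusters by first appearance, so the full label
      # vectors must agree exactly
      expect_equal(got, as.integer(want))
    }
  }
})

test_that("standard DBSCAN core/border semantics hold for min_samples = 3", {
  # chain: A-B-C with 1.0 spacing plus distant D; B is core (3 within eps),
  # A and C are border points, D is an outlier
  fr <- md_frame(rbind(c(5, 5, 5), c(6, 5, 5), c(7, 5, 5), c(15, 15, 15)),
                 rep("Pt", 4))
  cf <- cluster_frame(fr, cubic_cell(30), select_all(), eps = 1.1,
                      min_samples = 3)
  expect_equal(cf$labels, c(1L, 1L, 1L, 0L))
  expect_equal(cf$sizes, 3L)
})

test_that("clusters straddling the periodic boundary stay intact", {
  centered <- make_clustered_points(k = 1, n_per = 12, spread = 0.6,
                                    sep = 8, seed = 6)
  cell <- attr(centered, "cell")
  L <- cell$vectors[1, 1]
  straddle <- md_frame(wrap_positions(centered$positions +
                                        matrix(c(L - 8, 0, 0), 12, 3,
                                               byrow = TRUE), cell),
                       centered$elements)
  c1 <- cluster_frame(centered, cell, select_all(), eps = 2.5)
  c2 <- cluster_frame(straddle, cell, select_all(), eps = 2.5)
  expect_equal(c1$n_clusters, 1)
  expect_equal(c2$n_clusters, 1)
  expect_equal(c2$sizes, c1$sizes)
})

test_that("statistics are invariant under atom relabeling", {
  fr <- make_clustered_points(k = 3, n_per = 8, spread = 0.5, sep = 9,
                              seed = 2)
  cell <- attr(fr, "cell")
  perm <- sample(nrow(fr$positions))
  fr2 <- md_frame(fr$positions[perm, ], fr$elements[perm])
  a <- cluster_frame(fr, cell, select_all(), eps = 2.5)
  b <- cluster_frame(fr2, cell, select_all(), eps = 2.5)
  expect_equal(a$n_clusters, b$n_clusters)
  expect_equal(sort(a$sizes), sort(b$sizes))
  expect_equal(a$n_outliers, b$n_outliers)
  # the partitions coincide once mapped through the permutation
  for (cl in setdiff(unique(a$labels), 0)) {
    members <- which(a$labels == cl)          # original atom ids
    expect_length(unique(b$labels[match(members, perm)]), 1)
  }
})

test_that("growing eps only merges clusters, never splits them", {
  fr <- make_clustered_points(k = 3, n_per = 8, spread = 0.6, sep = 7,
                              seed = 9)
  cell <- attr(fr, "cell")
  l1 <- cluster_frame(fr, cell, select_all(), eps = 2.0)$labels
  l2 <- cluster_frame(fr, cell, select_all(), eps = 4.0)$labels
  for (cl in setdiff(unique(l1), 0)) {
    members <- which(l1 == cl)
    expect_length(unique(l2[members]), 1)
  }
})

test_that("cluster time series reproduce hand-enumerated dynamics", {
  cell <- cubic_cell(30)
  intact <- md_frame(matrix(c(5, 5, 5, 6.5, 5, 5, 5, 6.5, 5, 6.5, 6.5, 5,
                              5.8, 5.8, 6.2), 5, 3, byrow = TRUE),
                     rep("Pt", 5))
  split4 <- md_frame(rbind(intact$positions[1:4, ], c(20, 20, 20)),
                     rep("Pt", 5))
  tr <- md_trajectory(list(intact, split4, intact, split4), cell)
  cs <- cluster_timeseries(tr, select_all(), eps = 2.2, min_samples = 2)
  expect_equal(cs$per_frame$n_clusters, rep(1, 4))
  expect_equal(cs$mean_n_clusters, 1.0)
  expect_equal(cs$mean_size_excl, 4.5)    # (5 + 4) / 2
  expect_equal(cs$per_frame$avg_size_incl, rep(c(5, 2.5), 2))
  expect_equal(length(cs$fragmented_frames), 0)

  # enlarging eps reconnects the split atom
  cs2 <- cluster_timeseries(tr, select_all(), eps = 30, min_samples = 2)
  expect_equal(cs2$mean_size_excl, 5.0)

  # a genuine fragmentation event is flagged
  two <- md_frame(rbind(intact$positions[1:3, ], c(20, 20, 20),
                        c(21.5, 20, 20)), rep("Pt", 5))
  tr3 <- md_trajectory(list(intact, intact, two), cell)
  cs3 <- cluster_timeseries(tr3, select_all(), eps = 2.2)
  expect_equal(cs3$modal_n_clusters, 1)
  expect_equal(cs3$fragmented_frames, 3)
})
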