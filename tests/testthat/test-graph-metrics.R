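test_that("degree homogeneity matches direct arithmetic on known degree sequences", {
  expect_equal(degree_homogeneity(complete(7)), 1)
  expect_equal(degree_homogeneity(cycle(5)), 1)  # regular
  # star: degrees (6, 1 x 6)
  expect_equal(degree_homogeneity(star7()),
               ((sqrt(6) + 6) / 7)^2 / (12 / 7), tolerance = 1e-12)
  # path P3: degrees (1, 2, 1)
  expect_equal(degree_homogeneity(path_graph(3)),
               ((2 + sqrt(2)) / 3)^2 / (4 / 3), tolerance = 1e-12)
  expect_equal(degree_homogeneity(path_graph(3)), 0.9714, tolerance = 1e-4)
})

test_that("degree homogeneity is at most 1, with equality exactly for regular graphs", {
  for (M in 2:6) {
    for (g in enumerate_connected_graphs(M)) {
      hd <- degree_homogeneity(g)
      expect_lte(hd, 1 + 1e-12)
      if (length(unique(degree(g))) == 1L) expect_equal(hd, 1)
      else expect_lt(hd, 1)
    }
  }
})

test_that("mean path length matches brute-force Floyd-Warshall", {
  expect_equal(mean_path_length(complete(5)), 1)
  expect_equal(mean_path_length(path_graph(7)), 56 / 21)
  expect_equal(mean_path_length(star7()), 36 / 21)
  for (M in 3:5) {
    for (g in enumerate_connected_graphs(M)) {
      expect_equal(mean_path_length(g), fw_mean_path(g), tolerance = 1e-12)
    }
  }
})

test_that("habitat assortativity hits the exact limits and hand-computed values", {
  # alternating labels on an even cycle: every edge joins unlike habitats
  expect_equal(habitat_assortativity(cycle(6), rep(c(-0.5, 0.5), 3)), -1)
  # all edges within-type: two triangles joined by one edge, then labels by triangle
  g <- as_spatial_graph(rbind(c(1, 2), c(2, 3), c(1, 3),
                              c(4, 5), c(5, 6), c(4, 6), c(3, 4)))
  lab <- c(-0.5, -0.5, -0.5, 0.5, 0.5, 0.5)
  expect_equal(habitat_assortativity(g, lab), assortativity_oracle(g, lab),
               tolerance = 1e-12)
  g2 <- as_spatial_graph(rbind(c(1, 2), c(2, 3), c(3, 4)))
  expect_error(habitat_assortativity(g2, rep(0.5, 4)), "identical")
  # perfectly assortative: both endpoint sets split exactly by cluster
  # (approached as r -> 1; with a single bridging edge r stays below 1)
  expect_lt(habitat_assortativity(g, lab), 1)
  expect_gt(habitat_assortativity(g, lab), 0)
})

test_that("Pearson and edge-proportion forms agree on edge-balanced two-type labelings", {
  # the identity requires the two types to hold equal shares of the directed
  # edge endpoints, i.e. equal degree sums -- the graph analogue of the
  # "habitats equally distributed" mean-field assumption
  checked <- 0L
  for (M in c(4L, 6L)) {
    for (g in enumerate_connected_graphs(M)) {
      k <- degree(g)
      for (lab in balanced_labelings(M)) {
        if (sum(k[lab > 0]) != sum(k[lab < 0])) next
        r1 <- tryCatch(habitat_assortativity(g, lab), error = function(e) NA_real_)
        if (is.na(r1)) next
        expect_equal(r1, assortativity_edge_proportions(g, lab), tolerance = 1e-12)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 100L)
})

test_that("assortativity is symmetric under swapping the habitat types", {
  set.seed(42)
  for (rep in 1:20) {
    M <- sample(4:7, 1)
    g <- enumerate_connected_graphs(M)[[sample(length(enumerate_connected_graphs(M)), 1)]]
    lab <- sample(c(-0.5, 0.5), M, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(habitat_assortativity(g, lab), habitat_assortativity(g, -lab),
                 tolerance = 1e-12)
  }
})

test_that("metric table carries the full metric set", {
  gs <- list(star7(), complete(4))
  labs <- list(c(-0.5, rep(0.5, 6)), c(-0.5, -0.5, 0.5, 0.5))
  tab <- graph_metrics_table(gs, labs)
  expect_named(tab, c("graph_id", "M", "edges", "mean_path_length", "h_d", "r_theta"))
  expect_equal(tab$M, c(7L, 4L))
  expect_true(all(is.finite(tab$r_theta)))
})
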