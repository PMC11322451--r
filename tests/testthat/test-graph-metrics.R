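path3 <- function() {           # 1 - 2 - 3 chain, unit weights
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- W[2, 3] <- W[3, 2] <- 1
  W
}
complete_graph <- function(n) {
  W <- matrix(1, n, n); diag(W) <- 0; W
}

test_that("to_lengths is the reciprocal convention", {
  expect_equal(to_lengths(1), 1)
  expect_equal(to_lengths(2), 0.5)
  expect_equal(to_lengths(0), Inf)
  W <- path3()
  L <- to_lengths(W)
  expect_equal(L[1, 3], Inf)
  expect_equal(diag(L), rep(0, 3))
})

test_that("nodal strength sums incident weights", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 0.5
  expect_equal(nodal_strength(star)[1], 1.5, ignore_attr = TRUE)
  tri <- complete_graph(3)
  expect_equal(unname(nodal_strength(tri)), rep(2, 3))
  iso <- matrix(0, 2, 2)
  expect_equal(unname(nodal_strength(iso)), c(0, 0))
})

test_that("betweenness matches enumeration on canonical graphs", {
  expect_equal(unname(betweenness_w(path3())), c(0, 1, 0))
  expect_equal(unname(betweenness_w(complete_graph(5))), rep(0, 5))
  cyc <- matrix(0, 4, 4)
  for (k in 1:4) {
    j <- k %% 4 + 1
    cyc[k, j] <- cyc[j, k] <- 1
  }
  expect_equal(unname(betweenness_w(cyc)), rep(1 / 6, 4))
  expect_equal(unname(betweenness_w(cyc, normalized = FALSE)), rep(0.5, 4))
})

test_that("Onnela clustering matches hand values and brute force", {
  expect_equal(unname(clustering_onnela(complete_graph(3))), rep(1, 3))
  expect_equal(unname(clustering_onnela(path3())), rep(0, 3))
  tri <- matrix(0, 3, 3)
  tri[1, 2] <- tri[2, 1] <- 1
  tri[1, 3] <- tri[3, 1] <- 1
  tri[2, 3] <- tri[3, 2] <- 0.125
  expect_equal(clustering_onnela(tri), oracle_clustering(tri),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(clustering_onnela(tri)[[1]], 0.125^(1 / 3))
})

test_that("local efficiency follows the neighbor-subgraph definition", {
  W <- complete_graph(4)                       # neighbors fully connected
  expect_equal(unname(local_efficiency(W)), rep(1, 4))
  expect_equal(unname(local_efficiency(path3())), c(0, 0, 0))
  # middle of the path: two non-adjacent neighbors -> efficiency 0
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(unname(local_efficiency(star)), rep(0, 4))
})

test_that("CPL and GE match the all-pairs oracle", {
  W <- path3()
  expect_equal(char_path_length(W), 4 / 3)
  expect_equal(global_efficiency(W), 5 / 6)
  K <- complete_graph(4)
  expect_equal(char_path_length(K), 1)
  expect_equal(global_efficiency(K), 1)
  dyads <- matrix(0, 4, 4)
  dyads[1, 2] <- dyads[2, 1] <- dyads[3, 4] <- dyads[4, 3] <- 1
  expect_warning(cpl <- char_path_length(dyads), "disconnected")
  expect_equal(cpl, 1)
  expect_equal(global_efficiency(dyads), 1 / 3)
})

test_that("all metrics agree with brute-force oracles on random graphs", {
  set.seed(20)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    W <- random_test_graph(n)
    expect_equal(unname(betweenness_w(W)), oracle_betweenness(W),
                 tolerance = 1e-9)
    expect_equal(unname(clustering_onnela(W)), oracle_clustering(W),
                 tolerance = 1e-9)
    expect_equal(unname(local_efficiency(W)), oracle_local_eff(W),
                 tolerance = 1e-9)
    expect_equal(global_efficiency(W), oracle_global_eff(W),
                 tolerance = 1e-9)
    D <- oracle_distances(W)
    off <- D[row(D) != col(D)]
    if (any(is.finite(off)))
      expect_equal(suppressWarnings(char_path_length(W)), oracle_cpl(W),
                   tolerance = 1e-9)
  }
})

test_that("metrics transform correctly under weight scaling and relabeling", {
  set.seed(30)
  for (rep in 1:10) {
    W <- random_test_graph(5, p_edge = 0.8)
    c0 <- 3.7
    expect_equal(clustering_onnela(c0 * W), clustering_onnela(W))
    expect_equal(betweenness_w(c0 * W), betweenness_w(W))
    expect_equal(nodal_strength(c0 * W), c0 * nodal_strength(W))
    expect_equal(global_efficiency(c0 * W), c0 * global_efficiency(W))
    expect_equal(suppressWarnings(char_path_length(c0 * W)),
                 suppressWarnings(char_path_length(W)) / c0)
    # permutation equivariance
    pm <- sample(5)
    Wp <- W[pm, pm]
    expect_equal(unname(betweenness_w(Wp)), unname(betweenness_w(W))[pm])
    expect_equal(unname(clustering_onnela(Wp)),
                 unname(clustering_onnela(W))[pm])
    expect_equal(unname(local_efficiency(Wp)),
                 unname(local_efficiency(W))[pm])
  }
})

test_that("small-worldness handles canonical and degenerate cases", {
  K <- complete_graph(6)                 # rewiring-invariant: sigma = 1
  expect_equal(small_worldness(K, n_null = 5, seed = 1), 1)
  set.seed(9)
  W <- random_test_graph(10, p_edge = 0.9)
  s1 <- small_worldness(W, n_null = 20, seed = 3)
  s2 <- small_worldness(W, n_null = 20, seed = 3)
  expect_identical(s1, s2)               # seeded determinism
  expect_gt(s1, 0.5)                     # dense random graph: sigma near 1
  expect_lt(s1, 2)
  dis <- matrix(0, 4, 4)
  dis[1, 2] <- dis[2, 1] <- 1
  expect_error(small_worldness(dis), "connected")
  expect_error(small_worldness(complete_graph(3)), "4 nodes")
})

test_that("subnetwork scoping selects the documented node sets", {
  cfg <- synthetic_config(seed = 8)
  p <- generate_parcellation(cfg)
  m <- named_matrix(1, p$labels$name); diag(m) <- 0
  expect_equal(nrow(subnetwork(m, p, "whole_brain")), 41)
  expect_equal(nrow(subnetwork(m, p, "ipsilateral")), 20)
  expect_equal(nrow(subnetwork(m, p, "contralateral")), 20)
  ci <- subnetwork(m, p, "contralateral_insular")
  expect_equal(nrow(ci), 6)
  expect_true(all(grepl("^L", rownames(ci))))   # canonical focus = right
  # retained-label intersection
  expect_equal(nrow(subnetwork(m, p, "whole_brain",
                               retained_labels = p$labels$name[1:5])), 5)
})

test_that("node_metrics and global_metrics assemble coherent tables", {
  set.seed(12)
  W <- random_test_graph(6, p_edge = 0.9)
  rownames(W) <- colnames(W) <- sprintf("N%d", 1:6)
  nm <- node_metrics(W)
  expect_equal(nm$nodal_strength, unname(nodal_strength(W)))
  expect_equal(nm$clustering_coefficient, unname(clustering_onnela(W)))
  gm <- global_metrics(W, n_null = 5, seed = 2)
  expect_equal(unname(gm["average_nodal_strength"]), mean(nodal_strength(W)))
  expect_equal(unname(gm["global_efficiency"]), global_efficiency(W))
  expect_named(gm, c("characteristic_path_length", "global_efficiency",
                     "small_worldness", "average_betweenness_centrality",
                     "average_clustering_coefficient",
                     "average_nodal_strength"))
})
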