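# Binarization, nodal/global metrics and the degree-preserving null model,
# validated on hand-countable graphs and against igraph where it implements
# the same primitive independently of this package's code path.

graph_from_edges <- function(n, edges) {
  adj <- matrix(0L, n, n)
  for (e in edges) { adj[e[1], e[2]] <- 1L; adj[e[2], e[1]] <- 1L }
  restlat:::binarize_graph_from_adjacency(adj, threshold = 0.1)
}

test_that("binarization thresholds the back-transformed correlation", {
  z_small <- atanh(matrix(0.03, 4, 4)); diag(z_small) <- NA
  expect_equal(binarize_fc(z_small, 0.05)$density, 0)
  z_big <- atanh(matrix(0.9, 4, 4)); diag(z_big) <- NA
  g <- binarize_fc(z_big, 0.3)
  expect_equal(g$density, 1)
  expect_equal(diag(g$adjacency), rep(0L, 4))

  set.seed(5)
  for (i in 1:100) {
    r <- matrix(stats::runif(36, -1, 1), 6, 6)
    r <- (r + t(r)) / 2; diag(r) <- NA
    z <- atanh(pmin(pmax(r, -0.99), 0.99))
    expect_gte(binarize_fc(z, 0.05)$density, binarize_fc(z, 0.30)$density)
  }
})

test_that("nodal metrics are exact on the complete graph and the path graph", {
  k4 <- graph_from_edges(4, list(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4)))
  nm <- nodal_metrics(k4)
  expect_equal(nm$degree, rep(3, 4))
  expect_equal(nm$shortest_path_length, rep(1, 4))
  expect_equal(nm$global_efficiency, rep(1, 4))
  expect_equal(nm$clustering_coefficient, rep(1, 4))

  path <- graph_from_edges(4, list(c(1,2), c(2,3), c(3,4)))
  nmp <- nodal_metrics(path)
  expect_equal(nmp$degree, c(1, 2, 2, 1))
  expect_equal(nmp$shortest_path_length[1], (1 + 2 + 3) / 3)
})

test_that("triangle-plus-pendant clustering and transitivity match hand counts", {
  g <- graph_from_edges(4, list(c(1,2), c(2,3), c(1,3), c(3,4)))
  nm <- nodal_metrics(g)
  expect_equal(nm$clustering_coefficient, c(1, 1, 1/3, 0))
  gm <- global_metrics(g, n_null = 0)
  expect_equal(unname(gm["transitivity"]), 0.6)   # 3 triangles / 5 triples
  orc <- graph_oracle(g$adjacency)
  expect_equal(unname(gm["transitivity"]), orc$transitivity)
})

test_that("a star graph is perfectly disassortative and K4 fully transitive", {
  star <- graph_from_edges(6, lapply(2:6, function(i) c(1, i)))
  gm <- global_metrics(star, n_null = 0)
  expect_equal(unname(gm["assortativity"]), -1)
  k4 <- graph_from_edges(4, list(c(1,2), c(1,3), c(1,4), c(2,3), c(2,4), c(3,4)))
  gm4 <- global_metrics(k4, n_null = 0)
  expect_equal(unname(gm4["transitivity"]), 1)
  expect_equal(unname(gm4["clustering_coefficient"]), 1)
  expect_equal(unname(gm4["shortest_path_length"]), 1)
})

test_that("complete graphs close every connected triple", {
  for (n in 3:6) {
    kn <- restlat:::binarize_graph_from_adjacency(
      matrix(1L, n, n) - diag(1L, n), threshold = 0.1)
    expect_equal(unname(global_metrics(kn, n_null = 0)["transitivity"]), 1)
  }
})

test_that("rewiring preserves the degree multiset and leaves K3 unchanged", {
  set.seed(8)
  for (i in 1:20) {
    g <- restlat:::binarize_graph_from_adjacency(random_graph_adj(10, 0.3), 0.1)
    rg <- random_reference(g, seed = i)
    expect_equal(sort(rowSums(rg$adjacency)), sort(rowSums(g$adjacency)))
    expect_equal(diag(rg$adjacency), rep(0L, 10))
    expect_identical(rg$adjacency, t(rg$adjacency))
  }
  k3 <- graph_from_edges(3, list(c(1,2), c(2,3), c(1,3)))
  expect_identical(random_reference(k3, seed = 1)$adjacency, k3$adjacency)
})

test_that("ring-lattice clustering always exceeds its rewired null", {
  n <- 50
  edges <- c(lapply(1:n, function(i) c(i, i %% n + 1)),
             lapply(1:n, function(i) c(i, (i + 1) %% n + 1)))
  ring <- graph_from_edges(n, edges)
  C_ring <- mean(nodal_metrics(ring)$clustering_coefficient)
  expect_equal(C_ring, 0.5)     # k=4 ring lattice closed form
  null_C <- vapply(1:100, function(b) {
    mean(restlat:::clustering_from_adjacency(random_reference(ring, seed = b)$adjacency))
  }, numeric(1))
  expect_true(all(null_C < C_ring))
})

test_that("Erdos-Renyi graphs are their own small-world null (sigma near 1)", {
  set.seed(12)
  sigmas <- vapply(1:20, function(i) {
    g <- restlat:::binarize_graph_from_adjacency(random_graph_adj(60, 0.2), 0.1)
    unname(global_metrics(g, n_null = 10, seed = 100 * i)["small_worldness"])
  }, numeric(1))
  expect_gt(mean(sigmas), 0.8)
  expect_lt(mean(sigmas), 1.2)
})

test_that("edge additions never reduce degrees nor lengthen characteristic paths", {
  set.seed(21)
  for (i in 1:20) {
    adj <- random_graph_adj(8, 0.35)
    off <- which(upper.tri(adj) & adj == 0L)
    if (!length(off)) next
    pick <- sample(off, 1)
    adj2 <- adj
    adj2[pick] <- 1L
    adj2 <- matrix(pmax(adj2, t(adj2)), 8, 8)
    g1 <- restlat:::binarize_graph_from_adjacency(adj, 0.1)
    g2 <- restlat:::binarize_graph_from_adjacency(adj2, 0.1)
    expect_true(all(rowSums(g2$adjacency) >= rowSums(g1$adjacency)))
    L1 <- restlat:::characteristic_path_length(g1)
    L2 <- restlat:::characteristic_path_length(g2)
    # compare over pairs reachable in both (adding an edge can connect new,
    # distant pairs); on connected graphs L must not increase
    if (all(is.finite(restlat:::hop_distances(adj)[upper.tri(adj)])))
      expect_lte(L2, L1)
  }
})

test_that("hop distances and betweenness agree with igraph", {
  set.seed(31)
  for (i in 1:10) {
    adj <- random_graph_adj(9, 0.3)
    g <- restlat:::binarize_graph_from_adjacency(adj, 0.1)
    ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    expect_equal(restlat:::hop_distances(adj), igraph::distances(ig),
                 ignore_attr = TRUE)
    expect_equal(nodal_metrics(g)$betweenness,
                 as.numeric(igraph::betweenness(ig, normalized = TRUE)))
  }
})

test_that("the feature block emits complete, unique, stable names", {
  set.seed(3)
  Y <- matrix(stats::rnorm(50 * 12), 50)
  colnames(Y) <- sprintf("ROI%03d", 1:12)
  z <- fc_matrix(structure(list(data = Y, roi_ids = 1:12, tr = 2.5),
                           class = "roi_timeseries"))
  blk <- network_feature_block(z, n_null = 2, seed = 5)
  expect_length(blk$global, 66)
  expect_length(blk$nodal, 12 * 6 * 6)
  expect_false(anyDuplicated(c(names(blk$global), names(blk$nodal))) > 0)
  blk2 <- network_feature_block(z, n_null = 2, seed = 5)
  expect_identical(blk, blk2)
  expect_true("gamma@0.25" %in% names(blk$global))
  expect_true("clustering_coefficient@0.10@ROI007" %in% names(blk$nodal))
})
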