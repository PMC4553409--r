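#' Graph-theoretic network metrics on binarized connectivity
#'
#' Fisher-z matrices are back-transformed to correlations and thresholded at
#' six levels (0.05-0.30) into simple undirected graphs. Six nodal metrics
#' (degree, shortest path length, global efficiency, local efficiency,
#' clustering coefficient, betweenness) and eleven global metrics (the six
#' nodal means plus assortativity, transitivity, gamma, lambda and
#' small-worldness sigma = gamma / lambda against degree-preserving rewired
#' null graphs) are computed per threshold, giving 66 global and `R * 36`
#' nodal candidate features.
#'
#' @name graph_metrics
NULL

#' Binarize a connectivity matrix
#'
#' An edge joins regions i and j when the back-transformed correlation
#' `r = tanh(z)` exceeds `threshold` (signed: negative correlations never
#' form edges). Self-loops are removed; NA entries never form edges.
#'
#' @param z symmetric Fisher-z matrix.
#' @param threshold correlation threshold (>= 0).
#' @return An object of class `binary_graph`: 0/1 `adjacency` matrix with the
#'   `threshold` and edge `density`.
#' @export
binarize_fc <- function(z, threshold) {
  stopifnot(threshold >= 0, nrow(z) == ncol(z))
  r <- tanh(z)
  adj <- (!is.na(r)) & r > threshold
  adj <- adj | t(adj)   # guard against asymmetric NA patterns
  diag(adj) <- FALSE
  adj <- matrix(as.integer(adj), nrow(z), ncol(z))
  n <- nrow(adj)
  structure(list(adjacency = adj, threshold = threshold,
                 density = sum(adj) / (n * (n - 1))),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (density %.3f) at r > %.2f\n",
              nrow(x$adjacency), sum(x$adjacency) / 2, x$density, x$threshold))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected", diag = FALSE)
}

# All-pairs BFS hop distances via Floyd-Warshall on the 0/1 adjacency
# (vectorized over the inner two loops; fine for the network sizes here).
hop_distances <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  D[adj == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) {
    via <- outer(D[, k], D[k, ], `+`)
    upd <- via < D
    if (any(upd)) D[upd] <- via[upd]
  }
  D
}

# Mean inverse distance over ordered pairs j != i (1/Inf = 0): the nodal
# global efficiency; also reused for local efficiency on neighbour subgraphs.
efficiency_from_distances <- function(D) {
  n <- nrow(D)
  if (n < 2) return(rep(0, n))
  inv <- 1 / D
  diag(inv) <- 0
  inv[!is.finite(inv)] <- 0
  rowSums(inv) / (n - 1)
}

# Per-node triangle counts and clustering from the adjacency alone.
triangle_counts <- function(adj) rowSums((adj %*% adj) * adj) / 2

clustering_from_adjacency <- function(adj) {
  deg <- rowSums(adj)
  ifelse(deg >= 2, 2 * triangle_counts(adj) / (deg * (deg - 1)), 0)
}

#' Nodal graph metrics
#'
#' Per node: degree; shortest path length (mean BFS hop distance over
#' reachable nodes, 0 for isolated nodes); global efficiency (mean inverse
#' distance over all other nodes, unreachable contributing 0); clustering
#' coefficient `2 t_i / (k_i (k_i - 1))` with `t_i` the edges among
#' neighbours (0 when degree < 2); local efficiency (global efficiency of the
#' subgraph induced by the node's neighbours, 0 when degree < 2); and
#' normalized betweenness centrality.
#'
#' @param g a [binarize_fc()] result.
#' @return data.frame with one row per node and columns `degree`,
#'   `shortest_path_length`, `global_efficiency`, `local_efficiency`,
#'   `clustering_coefficient`, `betweenness`.
#' @export
nodal_metrics <- function(g) {
  stopifnot(inherits(g, "binary_graph"))
  adj <- g$adjacency
  n <- nrow(adj)
  D <- hop_distances(adj)
  deg <- rowSums(adj)

  spl <- vapply(seq_len(n), function(i) {
    d <- D[i, -i]
    d <- d[is.finite(d)]
    if (length(d)) mean(d) else 0
  }, numeric(1))

  geff <- efficiency_from_distances(D)
  clust <- clustering_from_adjacency(adj)

  leff <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1L)
    if (length(nb) < 2) return(0)
    mean(efficiency_from_distances(hop_distances(adj[nb, nb, drop = FALSE])))
  }, numeric(1))

  btw <- if (n > 2) igraph::betweenness(as_igraph(g), normalized = TRUE)
         else rep(0, n)

  data.frame(degree = deg, shortest_path_length = spl,
             global_efficiency = geff, local_efficiency = leff,
             clustering_coefficient = clust, betweenness = as.numeric(btw))
}

binarize_graph_from_adjacency <- function(adj, threshold = 0) {
  n <- nrow(adj)
  structure(list(adjacency = adj, threshold = threshold,
                 density = if (n > 1) sum(adj) / (n * (n - 1)) else 0),
            class = "binary_graph")
}

# Characteristic path length: mean BFS distance over reachable ordered pairs.
characteristic_path_length <- function(g) {
  D <- hop_distances(g$adjacency)
  d <- D[row(D) != col(D)]
  d <- d[is.finite(d)]
  if (length(d)) mean(d) else NA_real_
}

# Degree-preserving double-edge swaps on an adjacency matrix: pick two edges
# a-b, c-d and replace them with a-d, c-b when that creates neither a
# self-loop nor a multi-edge. Caller manages the RNG state.
double_edge_swap <- function(adj, n_attempts) {
  edges <- which(upper.tri(adj) & adj == 1L, arr.ind = TRUE)
  m <- nrow(edges)
  if (m < 2) return(adj)
  pick1 <- sample.int(m, n_attempts, replace = TRUE)
  pick2 <- sample.int(m, n_attempts, replace = TRUE)
  flip <- stats::runif(n_attempts) < 0.5
  for (it in seq_len(n_attempts)) {
    if (pick1[it] == pick2[it]) next
    a <- edges[pick1[it], 1]; b <- edges[pick1[it], 2]
    c_ <- edges[pick2[it], 1]; d <- edges[pick2[it], 2]
    if (flip[it]) { tmp <- c_; c_ <- d; d <- tmp }
    # propose a-d and c-b
    if (a == d || c_ == b) next
    if (adj[a, d] == 1L || adj[c_, b] == 1L) next
    adj[a, b] <- adj[b, a] <- 0L
    adj[c_, d] <- adj[d, c_] <- 0L
    adj[a, d] <- adj[d, a] <- 1L
    adj[c_, b] <- adj[b, c_] <- 1L
    edges[pick1[it], ] <- c(min(a, d), max(a, d))
    edges[pick2[it], ] <- c(min(c_, b), max(c_, b))
  }
  adj
}

#' Degree-preserving random reference graph
#'
#' Rewires the graph with double-edge swaps, which preserve every node's
#' degree exactly and keep the graph simple. Used as the null model for
#' gamma/lambda/small-worldness. If no valid swap exists (e.g. a triangle),
#' the graph comes back unchanged.
#'
#' @param g a `binary_graph`.
#' @param n_rewires_per_edge attempted swaps per edge.
#' @param seed integer seed.
#' @return A rewired `binary_graph` with the same degree sequence.
#' @export
random_reference <- function(g, n_rewires_per_edge = 10, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  n_edges <- sum(g$adjacency) / 2
  if (n_edges < 2) {
    warning("fewer than 2 edges: returning the graph unchanged")
    return(g)
  }
  adj <- withr_seed(seed,
    double_edge_swap(g$adjacency, ceiling(n_rewires_per_edge * n_edges)))
  binarize_graph_from_adjacency(adj, g$threshold)
}

#' Global graph metrics
#'
#' The network means of the six nodal metrics plus: assortativity (Pearson
#' correlation of end-node degrees over edges, Newman's r), transitivity
#' (3 x triangles / connected triples), and the small-world triple gamma =
#' C / <C_null>, lambda = L / <L_null>, sigma = gamma / lambda, where C is the
#' network mean clustering coefficient, L the characteristic path length, and
#' the nulls are degree-preserving rewired graphs. Metrics that are undefined
#' on degenerate graphs (no edges, no triples, constant degree) are NA.
#'
#' @param g a `binary_graph`.
#' @param n_null number of rewired null graphs.
#' @param seed integer seed for the null ensemble.
#' @return Named numeric vector of the 11 global metrics.
#' @export
global_metrics <- function(g, n_null = 100, seed = 1L) {
  stopifnot(inherits(g, "binary_graph"))
  nm <- nodal_metrics(g)
  out <- colMeans(nm)
  ig <- as_igraph(g)
  n_edges <- sum(g$adjacency) / 2

  assort <- if (n_edges >= 1) suppressWarnings(igraph::assortativity_degree(ig))
            else NA_real_
  trans <- suppressWarnings(igraph::transitivity(ig, type = "global"))
  if (is.nan(assort)) assort <- NA_real_
  if (is.nan(trans)) trans <- NA_real_

  gamma <- lambda <- sigma <- NA_real_
  if (n_edges >= 2 && n_null >= 1) {
    C <- out[["clustering_coefficient"]]
    L <- characteristic_path_length(g)
    null_C <- null_L <- numeric(n_null)
    for (b in seq_len(n_null)) {
      adj_rg <- random_reference(g, seed = seed + b)$adjacency
      null_C[b] <- mean(clustering_from_adjacency(adj_rg))
      Drg <- hop_distances(adj_rg)
      drg <- Drg[row(Drg) != col(Drg)]
      drg <- drg[is.finite(drg)]
      null_L[b] <- if (length(drg)) mean(drg) else NA_real_
    }
    mC <- mean(null_C); mL <- mean(null_L, na.rm = TRUE)
    if (is.finite(mC) && mC > 0) gamma <- C / mC
    if (is.finite(L) && is.finite(mL) && mL > 0) lambda <- L / mL
    if (is.finite(gamma) && is.finite(lambda) && lambda > 0) sigma <- gamma / lambda
  }

  c(out, assortativity = assort, transitivity = trans,
    gamma = gamma, lambda = lambda, small_worldness = sigma)
}

nodal_metric_names <- function() {
  c("degree", "shortest_path_length", "global_efficiency",
    "local_efficiency", "clustering_coefficient", "betweenness")
}

global_metric_names <- function() {
  c(nodal_metric_names(), "assortativity", "transitivity",
    "gamma", "lambda", "small_worldness")
}

format_threshold <- function(thr) formatC(thr, format = "f", digits = 2)

#' Network feature block for one subject
#'
#' Binarizes the z matrix at each threshold and emits every global and nodal
#' metric under a canonical, stable name: `metric@threshold` for global
#' metrics and `metric@threshold@region` for nodal ones. With R regions and
#' 6 thresholds this is 66 global and `R * 36` nodal features (4176 at
#' R = 116).
#'
#' @param z Fisher-z connectivity matrix.
#' @param thresholds correlation thresholds.
#' @param n_null null graphs per threshold for the small-world metrics.
#' @param seed integer seed.
#' @param region_names names for the nodes (defaults to ROI001...).
#' @return list with named numeric vectors `global` and `nodal`.
#' @export
network_feature_block <- function(z, thresholds = seq(0.05, 0.30, by = 0.05),
                                  n_null = 100, seed = 1L, region_names = NULL) {
  R <- nrow(z)
  if (is.null(region_names)) region_names <- sprintf("ROI%03d", seq_len(R))
  stopifnot(length(region_names) == R)
  glob <- numeric(0)
  nod <- numeric(0)
  for (i in seq_along(thresholds)) {
    thr <- thresholds[i]
    tag <- format_threshold(thr)
    g <- binarize_fc(z, thr)
    gm <- global_metrics(g, n_null = n_null, seed = seed + i * 1000L)
    names(gm) <- sprintf("%s@%s", global_metric_names(), tag)
    glob <- c(glob, gm)
    nm <- nodal_metrics(g)
    v <- as.vector(as.matrix(nm))
    names(v) <- as.vector(outer(region_names, nodal_metric_names(),
                                function(roi, met) sprintf("%s@%s@%s", met, tag, roi)))
    nod <- c(nod, v)
  }
  list(global = glob, nodal = nod)
}
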