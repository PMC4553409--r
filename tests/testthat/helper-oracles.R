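# Independent brute-force oracles used to validate the package's
# implementations, plus small fixture builders. Everything here is
# deliberately written the slow, obvious way.

# --- OLS oracles -----------------------------------------------------------

ols_detrend_oracle <- function(ts) {
  t_idx <- seq_along(ts)
  unname(stats::residuals(stats::lm(ts ~ t_idx)))
}

ols_residual_oracle <- function(Y, X) {
  # explicit normal equations
  beta <- solve(t(X) %*% X, t(X) %*% Y)
  Y - X %*% beta
}

# --- spectral oracle -------------------------------------------------------

# per-bin amplitude by explicit DFT sums; returns in-band amplitude sum
dft_alff_oracle <- function(ts, tr, band = c(0.01, 0.08)) {
  n <- length(ts)
  total <- 0
  for (k in seq_len(n %/% 2)) {
    f <- k / (n * tr)
    if (f < band[1] || f > band[2]) next
    re <- sum(ts * cos(-2 * pi * k * (0:(n - 1)) / n))
    im <- sum(ts * sin(-2 * pi * k * (0:(n - 1)) / n))
    total <- total + sqrt(re^2 + im^2)
  }
  total
}

# --- Kendall's W oracle ----------------------------------------------------

# series in columns (one per voxel); direct rank-sum computation
kcc_oracle <- function(series) {
  K <- ncol(series)
  T_ <- nrow(series)
  R <- apply(series, 2, rank)
  rs <- rowSums(R)
  rbar <- K * (T_ + 1) / 2
  12 * sum((rs - rbar)^2) / (K^2 * (T_^3 - T_))
}

# --- graph oracles ---------------------------------------------------------

fw_distances_oracle <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (i in seq_len(n)) for (j in seq_len(n))
    if (i != j && adj[i, j] == 1) D[i, j] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  D
}

# number of shortest paths between every ordered pair, by dynamic programming
# over the distance matrix
path_counts_oracle <- function(adj, D) {
  n <- nrow(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  for (s in seq_len(n)) {
    finite <- sort(unique(D[s, is.finite(D[s, ]) & D[s, ] > 0]))
    for (d in finite) {
      for (t_ in which(D[s, ] == d)) {
        pred <- which(adj[, t_] == 1 & D[s, ] == d - 1)
        sigma[s, t_] <- sum(sigma[s, pred])
      }
    }
  }
  sigma
}

graph_oracle <- function(adj) {
  n <- nrow(adj)
  D <- fw_distances_oracle(adj)
  deg <- rowSums(adj)

  spl <- numeric(n); geff <- numeric(n)
  for (i in seq_len(n)) {
    d <- D[i, -i]
    reach <- d[is.finite(d)]
    spl[i] <- if (length(reach)) mean(reach) else 0
    geff[i] <- sum(1 / d[is.finite(d)]) / (n - 1)
  }

  tri <- numeric(n)
  for (i in seq_len(n)) for (j in seq_len(n)) for (k in seq_len(n))
    if (i < j && j < k && adj[i, j] && adj[j, k] && adj[i, k]) {
      tri[i] <- tri[i] + 1; tri[j] <- tri[j] + 1; tri[k] <- tri[k] + 1
    }
  clust <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)

  leff <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) next
    Ds <- fw_distances_oracle(adj[nb, nb, drop = FALSE])
    m <- length(nb)
    acc <- 0
    for (a in seq_len(m)) for (b in seq_len(m))
      if (a != b && is.finite(Ds[a, b])) acc <- acc + 1 / Ds[a, b]
    leff[i] <- acc / (m * (m - 1))
  }

  sigma <- path_counts_oracle(adj, D)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n)) for (t_ in seq_len(n)) {
      if (s >= t_ || s == v || t_ == v) next
      if (!is.finite(D[s, t_]) || sigma[s, t_] == 0) next
      if (is.finite(D[s, v]) && is.finite(D[v, t_]) &&
          D[s, v] + D[v, t_] == D[s, t_])
        acc <- acc + sigma[s, v] * sigma[v, t_] / sigma[s, t_]
    }
    btw[v] <- acc / ((n - 1) * (n - 2) / 2)
  }

  triples <- 0
  for (i in seq_len(n)) triples <- triples + deg[i] * (deg[i] - 1) / 2
  transitivity <- if (triples > 0) sum(tri) / triples else NA_real_

  list(degree = deg, shortest_path_length = spl, global_efficiency = geff,
       local_efficiency = leff, clustering_coefficient = clust,
       betweenness = btw, transitivity = transitivity)
}

random_graph_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(stats::runif(length(up)) < p)
  adj + t(adj)
}

adjacency_to_graph <- function(adj, threshold = 0.1) {
  r <- matrix(0, nrow(adj), ncol(adj))
  r[adj == 1L] <- 0.5
  binarize_fc(atanh(r), threshold)
}

# --- Mann-Whitney exact oracle ---------------------------------------------

mw_exact_p_oracle <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(pooled), n1)
  u_obs <- sum(rank(pooled)[seq_len(n1)]) - n1 * (n1 + 1) / 2
  us <- apply(idx, 2, function(ii)
    sum(rank(pooled)[ii]) - n1 * (n1 + 1) / 2)
  # the null distribution of U is symmetric about its mean, so the two-sided
  # p is the mass at least as far from the mean as observed
  mu <- n1 * length(b) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# --- small fixtures --------------------------------------------------------

tiny_cohort_spec <- function(n_left = 3, n_right = 3, n_regions = 6,
                             grid = c(6, 6, 8), effect = NULL, seed = 1,
                             n_timepoints = 60, noise_sd = 1) {
  cohort_spec(n_left = n_left, n_right = n_right, grid = grid,
              n_timepoints = n_timepoints, tr = 2.5, n_regions = n_regions,
              effect = effect, noise_sd = noise_sd, seed = seed)
}

# a bold_image wrapping an arbitrary T x V matrix laid out on a small grid
bold_from_matrix <- function(ts_matrix, grid, tr = 2.5, mask = NULL) {
  tp <- nrow(ts_matrix)
  stopifnot(ncol(ts_matrix) == prod(grid))
  if (is.null(mask)) mask <- array(TRUE, grid)
  bold_image(array(t(ts_matrix), c(grid, tp)), mask, tr)
}

# a feature table with one planted discriminative feature per request
synthetic_feature_table <- function(n_per_class = 8, n_noise = 60,
                                    planted = c(ALFF = 1), effect_size = 3,
                                    seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    labels <- rep(c("L", "R"), each = n_per_class)
    subcats <- rep(restlat:::FEATURE_SUBCATEGORIES, length.out = n_noise)
    X <- matrix(stats::rnorm(n * n_noise), n, n_noise)
    colnames(X) <- sprintf("noise%03d", seq_len(n_noise))
    for (i in seq_along(planted)) {
      f <- stats::rnorm(n) + effect_size * (labels == "L")
      X <- cbind(X, f)
      colnames(X)[ncol(X)] <- paste0("planted", i)
      subcats <- c(subcats, names(planted)[i])
    }
    feature_table(X, subcats, labels)
  })
}
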