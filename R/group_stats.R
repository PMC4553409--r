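#' Nonparametric group comparison with cluster-extent correction
#'
#' Two-group differences are tested feature-wise (and voxelwise) with the
#' Mann-Whitney U-test; voxelwise significance maps are corrected for
#' multiple comparisons by keeping only 6-connected clusters of at least a
#' minimum extent (default 16 voxels at p < 0.01), with a Monte Carlo
#' routine available to derive the extent threshold for other grids.
#'
#' @name group_stats
NULL

#' Mann-Whitney U-test for one feature
#'
#' Two-sided; the exact null distribution is used when `n1 + n2 < 50` and
#' there are no ties (the `stats::wilcox.test` rule), the normal
#' approximation with tie correction otherwise. Identical values across both
#' groups give p = 1.
#'
#' @param a,b numeric value vectors for the two groups (each nonempty).
#' @return list with `U` (the statistic for group `a`) and `p`.
#' @export
mann_whitney_feature <- function(a, b) {
  stopifnot(length(a) >= 1, length(b) >= 1)
  if (length(unique(c(a, b))) == 1L)
    return(list(U = length(a) * length(b) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
  p <- wt$p.value
  if (!is.finite(p)) p <- 1
  list(U = unname(wt$statistic), p = p)
}

#' Voxelwise Mann-Whitney p-map
#'
#' @param maps_a,maps_b lists of 3D maps (one per subject in each group).
#' @param mask 3D logical array; tests run only inside it.
#' @return 3D array of two-sided p values (1 outside the mask).
#' @export
mann_whitney_map <- function(maps_a, maps_b, mask) {
  vox <- which(mask)
  A <- vapply(maps_a, function(m) m[vox], numeric(length(vox)))
  B <- vapply(maps_b, function(m) m[vox], numeric(length(vox)))
  p <- array(1, dim(mask))
  p[vox] <- vapply(seq_along(vox), function(i)
    mann_whitney_feature(A[i, ], B[i, ])$p, numeric(1))
  p
}

connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  switch(as.character(connectivity),
         "6"  = g[rowSums(abs(g)) == 1, , drop = FALSE],
         "18" = g[rowSums(abs(g)) <= 2, , drop = FALSE],
         "26" = g,
         stop("connectivity must be 6, 18 or 26"))
}

# Label connected components of a binary 3D mask by flood fill.
label_components <- function(mask, connectivity = 6) {
  d <- dim(mask)
  offs <- connectivity_offsets(connectivity)
  labels <- array(0L, d)
  idx <- which(mask, arr.ind = TRUE)
  in_mask <- array(FALSE, d)
  in_mask[mask] <- TRUE
  current <- 0L
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    if (labels[v[1], v[2], v[3]] != 0L) next
    current <- current + 1L
    queue <- matrix(v, ncol = 3)
    labels[v[1], v[2], v[3]] <- current
    while (nrow(queue)) {
      head <- queue[1, ]
      queue <- queue[-1, , drop = FALSE]
      for (o in seq_len(nrow(offs))) {
        w <- head + offs[o, ]
        if (any(w < 1) || any(w > d)) next
        if (in_mask[w[1], w[2], w[3]] && labels[w[1], w[2], w[3]] == 0L) {
          labels[w[1], w[2], w[3]] <- current
          queue <- rbind(queue, w)
        }
      }
    }
  }
  labels
}

#' Cluster-extent filter of a significance mask
#'
#' Finds connected components of the binary mask under face adjacency
#' (6-connectivity by default) and discards components smaller than
#' `min_size` voxels.
#'
#' @param sig_mask binary/logical 3D array.
#' @param connectivity 6 (faces), 18 or 26.
#' @param min_size minimum cluster extent in voxels.
#' @param stat_map optional 3D array used to locate each cluster's peak; the
#'   first voxel in array order is reported otherwise.
#' @return An object of class `cluster_report`: list of clusters (each with a
#'   `voxels` index matrix, `size` and `peak` coordinate), plus the settings.
#' @export
cluster_filter <- function(sig_mask, connectivity = 6, min_size = 16,
                           stat_map = NULL) {
  mask <- array(as.logical(sig_mask), dim(sig_mask))
  labels <- label_components(mask, connectivity)
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  clusters <- list()
  for (id in ids) {
    vox <- which(labels == id, arr.ind = TRUE)
    if (nrow(vox) < min_size) next
    peak <- if (is.null(stat_map)) vox[1, ]
            else vox[which.max(abs(stat_map[labels == id])), ]
    clusters[[length(clusters) + 1L]] <-
      list(voxels = vox, size = nrow(vox), peak = as.integer(peak))
  }
  structure(list(clusters = clusters, connectivity = connectivity,
                 min_size = min_size),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d cluster(s) of >= %d voxels (%d-connectivity)\n",
              length(x$clusters), x$min_size, x$connectivity))
  for (i in seq_along(x$clusters))
    cat(sprintf("  cluster %d: %d voxels, peak (%s)\n", i, x$clusters[[i]]$size,
                paste(x$clusters[[i]]$peak, collapse = ", ")))
  invisible(x)
}

#' Monte Carlo cluster-extent threshold (AlphaSim-style)
#'
#' Simulates smooth Gaussian noise volumes, standardizes them over the mask,
#' thresholds at the voxelwise level `voxel_p` (upper tail) and records the
#' largest surviving cluster per iteration. The returned extent is the
#' `1 - family_alpha` quantile of that maximum-cluster-size distribution
#' (at least 1 voxel).
#'
#' @param volume_shape integer length-3 grid dimensions.
#' @param mask optional 3D logical array (defaults to the full volume).
#' @param fwhm_mm smoothing applied to each noise volume (0 = none).
#' @param voxel_size voxel edge length, mm.
#' @param voxel_p voxelwise threshold.
#' @param family_alpha target family-wise error rate.
#' @param n_iter Monte Carlo iterations (>= 100).
#' @param seed integer seed.
#' @param connectivity cluster connectivity (6, 18, 26).
#' @return Minimum cluster size in voxels.
#' @export
alphasim_min_cluster <- function(volume_shape, mask = NULL, fwhm_mm = 0,
                                 voxel_size = 1, voxel_p = 0.01,
                                 family_alpha = 0.05, n_iter = 1000, seed = 1L,
                                 connectivity = 6) {
  stopifnot(n_iter >= 100, voxel_p > 0, voxel_p < 1)
  volume_shape <- as.integer(volume_shape)
  if (is.null(mask)) mask <- array(TRUE, volume_shape)
  zthr <- stats::qnorm(1 - voxel_p)
  max_sizes <- withr_seed(seed, vapply(seq_len(n_iter), function(i) {
    noise <- array(stats::rnorm(prod(volume_shape)), volume_shape)
    if (fwhm_mm > 0)
      noise <- gaussian_smooth(noise, fwhm = fwhm_mm, voxel_size = voxel_size)
    v <- noise[mask]
    noise[mask] <- (v - mean(v)) / stats::sd(v)
    sig <- array(FALSE, volume_shape)
    sig[mask] <- noise[mask] > zthr
    if (!any(sig)) return(0)
    labels <- label_components(sig, connectivity)
    max(tabulate(labels[labels > 0L]))
  }, numeric(1)))
  max(1, as.numeric(stats::quantile(max_sizes, 1 - family_alpha, type = 1)))
}
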