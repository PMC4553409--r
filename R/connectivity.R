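#' Inter-regional functional connectivity
#'
#' Region-mean time courses are extracted from the parcellation, nuisance
#' covariates (six motion parameters plus global/WM/CSF mean signals) are
#' regressed out, and pairwise Pearson correlations are Fisher z transformed
#' into a symmetric connectivity matrix. A one-sample t-test across training
#' subjects screens which connections enter the candidate feature set.
#'
#' @name connectivity
NULL

#' Extract region-mean time courses
#'
#' @param bold a [bold_image].
#' @param parcellation a [make_atlas()] result (or compatible list with an
#'   integer `labels` volume and `region_names`).
#' @return An object of class `roi_timeseries`: `data` is a T x R matrix (one
#'   column per region, named), `roi_ids`, and `tr`. Regions without any
#'   in-mask voxel yield an all-NA column, recorded in attribute `missing`.
#' @export
extract_roi_timeseries <- function(bold, parcellation) {
  stopifnot(inherits(bold, "bold_image"))
  if (!all(dim(bold$mask) == dim(parcellation$labels)))
    stop("bold image and parcellation grids differ")
  tp <- dim(bold$data)[4]
  flat <- matrix(bold$data, ncol = tp)
  lab <- as.vector(parcellation$labels)
  lab[!as.vector(bold$mask)] <- 0L
  ids <- parcellation$region_ids
  if (!any(lab %in% ids))
    stop("no atlas label overlaps the brain mask")
  data <- vapply(ids, function(r) {
    vox <- which(lab == r)
    if (!length(vox)) return(rep(NA_real_, tp))
    colMeans(flat[vox, , drop = FALSE])
  }, numeric(tp))
  colnames(data) <- parcellation$region_names
  out <- structure(list(data = data, roi_ids = ids, tr = bold$tr),
                   class = "roi_timeseries")
  attr(out, "missing") <- parcellation$region_names[colSums(is.na(data)) > 0]
  out
}

#' Regress nuisance covariates out of ROI time courses
#'
#' Each region's series is replaced by its OLS residual against the confound
#' matrix (an intercept is appended if absent). Collinear confound columns
#' are dropped with a warning.
#'
#' @param ts a [extract_roi_timeseries()] result.
#' @param confounds T x C numeric matrix.
#' @return A `roi_timeseries` of residuals, orthogonal to every retained
#'   confound column.
#' @export
regress_nuisance <- function(ts, confounds) {
  stopifnot(inherits(ts, "roi_timeseries"))
  confounds <- as.matrix(confounds)
  tp <- nrow(ts$data)
  if (nrow(confounds) != tp) stop("confounds and time series lengths differ")
  has_intercept <- any(apply(confounds, 2, function(x) stats::sd(x) == 0 & x[1] != 0))
  X <- if (has_intercept) confounds else cbind(intercept = 1, confounds)
  if (ncol(X) >= tp) stop("more confound columns than timepoints")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop_idx <- qx$pivot[(qx$rank + 1L):ncol(X)]
    warning(sprintf("dropping %d collinear confound column(s): %s",
                    length(drop_idx),
                    paste(colnames(X)[drop_idx], collapse = ", ")))
    X <- X[, -drop_idx, drop = FALSE]
    qx <- qr(X)
  }
  res <- ts
  ok <- colSums(is.na(ts$data)) == 0
  res$data[, ok] <- qr.resid(qx, ts$data[, ok, drop = FALSE])
  res
}

#' Fisher-z connectivity matrix
#'
#' Pearson correlations between all pairs of region time courses, clipped to
#' `|r| <= 1 - 1e-7` and Fisher z transformed (`atanh`), so every off-diagonal
#' entry is finite. Zero-variance or missing columns give NA rows/columns.
#'
#' @param ts a `roi_timeseries` (usually nuisance-regressed).
#' @return R x R symmetric numeric matrix of z values with NA diagonal.
#' @export
fc_matrix <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  m <- ts$data
  if (nrow(m) < 3) stop("need at least 3 timepoints for correlation")
  bad <- colSums(is.na(m)) > 0 | apply(m, 2, stats::sd, na.rm = TRUE) == 0
  r <- suppressWarnings(stats::cor(m))
  r[bad, ] <- NA
  r[, bad] <- NA
  clip <- 1 - 1e-7
  z <- atanh(pmin(pmax(r, -clip), clip))
  diag(z) <- NA
  z
}

# Vectorized two-sided one-sample t-test against 0, one test per column.
# Degenerate columns follow the candidate-filter contract: zero variance with
# nonzero mean is significant (p = 0), zero variance with zero mean is not
# (p = 1).
one_sample_t_pvalues <- function(values) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (n < 3) stop("need at least 3 subjects for the one-sample t filter")
  m <- colMeans(values)
  s <- col_sds(values)
  p <- rep(1, length(m))
  nz <- s > 0
  tstat <- m[nz] / (s[nz] / sqrt(n))
  p[nz] <- 2 * stats::pt(-abs(tstat), df = n - 1)
  p[!nz] <- ifelse(m[!nz] != 0, 0, 1)
  p
}

#' Candidate connectivity filter
#'
#' For every region pair, a two-sided one-sample t-test of the training
#' subjects' z values against 0; pairs with `p < alpha` survive as candidate
#' bivariate features. Applied per cross-validation fold (training subjects
#' only) so the held-out subject never influences the mask.
#'
#' @param z_list list of [fc_matrix()] results (the training subjects).
#' @param alpha two-sided significance level.
#' @return Symmetric logical R x R matrix (FALSE diagonal); `TRUE` marks
#'   surviving candidate connections.
#' @export
candidate_fc_filter <- function(z_list, alpha = 0.05) {
  stopifnot(length(z_list) >= 3)
  R <- nrow(z_list[[1]])
  ut <- upper.tri(matrix(0, R, R))
  values <- vapply(z_list, function(z) z[ut], numeric(sum(ut)))  # pairs x n
  p <- one_sample_t_pvalues(t(values))
  mask <- matrix(FALSE, R, R)
  mask[ut] <- p < alpha & !is.na(p)
  mask | t(mask)
}

#' Canonical names for the upper-triangle connectivity features
#'
#' @param region_names character vector of region names.
#' @return `"fc@A__B"` for every pair A < B, in column-major upper-triangle
#'   order (the order used when flattening an [fc_matrix()]).
#' @export
fc_feature_names <- function(region_names) {
  R <- length(region_names)
  ut <- which(upper.tri(matrix(0, R, R)), arr.ind = TRUE)
  ut <- ut[order(ut[, 2], ut[, 1]), , drop = FALSE]
  sprintf("fc@%s__%s", region_names[ut[, 1]], region_names[ut[, 2]])
}
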