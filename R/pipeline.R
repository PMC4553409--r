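#' End-to-end pipeline
#'
#' Composition of the stages: simulate (or load) a cohort, compute voxelwise
#' maps and the connectivity/network feature blocks into one feature table,
#' run the nested leave-one-out classification, and score feature importance.
#' Group comparison (Mann-Whitney with cluster-extent correction) is run on
#' the voxelwise maps as the univariate reference. Fully deterministic given
#' the seeds in the configuration.
#'
#' @name pipeline
NULL

#' Pipeline configuration
#'
#' Defaults are the analysis settings the pipeline is built around: the
#' 0.01-0.08 Hz band, 4 mm FWHM smoothing, six binarization thresholds
#' 0.05-0.30, a 0.05 candidate-filter alpha, 50-repetition random-forest
#' ranking with top-50 pooling, and a linear SVM with C = 1.
#'
#' @param band low/high frequency bounds, Hz.
#' @param fwhm_mm smoothing kernel FWHM, mm.
#' @param voxel_size_mm voxel edge length, mm.
#' @param thresholds binarization thresholds, strictly increasing in (0, 1).
#' @param candidate_alpha FC candidate-filter alpha.
#' @param rf list: `n_trees`, `n_reps` (ranking repetitions), `top_k`.
#' @param n_null rewired null graphs per threshold.
#' @param svm_c SVM cost.
#' @param scale_features z-score features per fold before the SVM.
#' @param seed master seed.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(band = c(0.01, 0.08), fwhm_mm = 4, voxel_size_mm = 1,
                            thresholds = seq(0.05, 0.30, by = 0.05),
                            candidate_alpha = 0.05,
                            rf = list(n_trees = 500, n_reps = 50, top_k = 50),
                            n_null = 100, svm_c = 1, scale_features = TRUE,
                            seed = 1L) {
  stopifnot(length(band) == 2, band[1] >= 0, band[1] < band[2])
  if (any(diff(thresholds) <= 0) || any(thresholds <= 0) || any(thresholds >= 1))
    stop("thresholds must be strictly increasing within (0, 1)")
  stopifnot(all(c("n_trees", "n_reps", "top_k") %in% names(rf)),
            candidate_alpha > 0, candidate_alpha < 1, svm_c > 0)
  structure(list(band = band, fwhm_mm = fwhm_mm, voxel_size_mm = voxel_size_mm,
                 thresholds = thresholds, candidate_alpha = candidate_alpha,
                 rf = rf, n_null = n_null, svm_c = svm_c,
                 scale_features = scale_features, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Scaled-down configuration for demonstrations and simulation studies
#'
#' Same analysis structure as [pipeline_config()] with smaller ensembles
#' (100-tree forests, 3 ranking repetitions, top-10 pooling, 20 null graphs)
#' so a 12-subject cohort runs in seconds.
#'
#' @param seed master seed.
#' @param ... overrides passed to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
demo_config <- function(seed = 1L, ...) {
  pipeline_config(rf = list(n_trees = 100, n_reps = 3, top_k = 10),
                  n_null = 20, seed = seed, ...)
}

#' Demonstration cohort specification
#'
#' A 12-region cohort on a 6 x 6 x 14 grid (about 36 voxels per region, so
#' full ReHo neighbourhoods fit) with the acquisition the analysis assumes:
#' 135 volumes at TR 2.5 s. When `effects = TRUE`, the left group carries
#' strong lateralized effects in all three feature families: doubled
#' low-frequency amplitude in regions 1-2, 0.8 neighbourhood-coherence mixing
#' in regions 3-4, and 0.6 latent coupling between regions 5-6 and 7-8.
#'
#' @param n_left,n_right group sizes.
#' @param effects plant the lateralized effects (FALSE gives a null cohort).
#' @param seed master seed.
#' @param ... overrides passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
demo_cohort_spec <- function(n_left = 7, n_right = 5, effects = TRUE, seed = 1L,
                             ...) {
  eff <- if (effects) {
    effect_spec(alff = data.frame(roi = 1:2, factor = 2.0),
                reho = data.frame(roi = 3:4, weight = 0.8),
                fc = data.frame(roi_i = c(5, 7), roi_j = c(6, 8), delta = 0.6),
                target_group = "L")
  } else NULL
  cohort_spec(n_left = n_left, n_right = n_right, grid = c(6L, 6L, 14L),
              n_regions = 12L, effect = eff, noise_sd = 1, seed = seed, ...)
}

voxel_feature_names <- function(mask, prefix) {
  idx <- which(mask, arr.ind = TRUE) - 1L   # 0-based array indices
  sprintf("%s@%d_%d_%d", prefix, idx[, 1], idx[, 2], idx[, 3])
}

#' Build the full feature table for a cohort
#'
#' Per subject: standardized ALFF/fALFF/ReHo maps (one feature per in-mask
#' voxel, named by 0-based voxel index), the upper triangle of the
#' nuisance-regressed Fisher-z connectivity matrix, and the global and nodal
#' network metric blocks at each threshold.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param config a [pipeline_config()].
#' @return A [feature_table()].
#' @export
build_feature_table <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "pipeline_config"))
  atlas <- cohort$atlas
  mask <- atlas$brain_mask
  ut <- upper.tri(matrix(0, atlas$n_regions, atlas$n_regions))
  fc_names <- fc_feature_names(atlas$region_names)

  rows <- lapply(seq_along(cohort$subjects), function(i) {
    s <- cohort$subjects[[i]]
    maps <- voxel_feature_maps(s$bold, band = config$band, fwhm = config$fwhm_mm,
                               voxel_size = config$voxel_size_mm)
    ts <- extract_roi_timeseries(s$bold, atlas)
    ts <- regress_nuisance(ts, s$confounds)
    z <- fc_matrix(ts)
    net <- network_feature_block(z, thresholds = config$thresholds,
                                 n_null = config$n_null,
                                 seed = config$seed + i,
                                 region_names = atlas$region_names)
    c(stats::setNames(maps$alff[mask], voxel_feature_names(mask, "alff")),
      stats::setNames(maps$falff[mask], voxel_feature_names(mask, "falff")),
      stats::setNames(maps$reho[mask], voxel_feature_names(mask, "reho")),
      stats::setNames(z[ut], fc_names),
      net$global, net$nodal)
  })
  values <- do.call(rbind, rows)
  nv <- sum(mask)
  subcat <- c(rep("ALFF", nv), rep("fALFF", nv), rep("ReHo", nv),
              rep("FC", length(fc_names)),
              rep("NMglobal", length(config$thresholds) * length(global_metric_names())),
              rep("NMnodal",
                  length(config$thresholds) * atlas$n_regions * length(nodal_metric_names())))
  # network metrics can be NA on degenerate graphs; such columns cannot feed
  # the forests, so impute them to the column mean (NA-only columns to 0)
  values[, ] <- apply(values, 2, function(v) {
    if (anyNA(v)) {
      m <- mean(v, na.rm = TRUE)
      v[is.na(v)] <- if (is.finite(m)) m else 0
    }
    v
  })
  feature_table(values, subcat, vapply(cohort$subjects, `[[`, "", "label"),
                vapply(cohort$subjects, `[[`, "", "subject_id"))
}

group_stats_stage <- function(cohort, config) {
  mask <- cohort$atlas$brain_mask
  maps <- lapply(cohort$subjects, function(s)
    voxel_feature_maps(s$bold, band = config$band, fwhm = config$fwhm_mm,
                       voxel_size = config$voxel_size_mm))
  labels <- vapply(cohort$subjects, `[[`, "", "label")
  out <- list()
  for (kind in c("alff", "falff", "reho")) {
    a <- lapply(maps[labels == "L"], `[[`, kind)
    b <- lapply(maps[labels == "R"], `[[`, kind)
    p <- mann_whitney_map(a, b, mask)
    out[[kind]] <- cluster_filter(p < 0.01 & mask, connectivity = 6, min_size = 16)
  }
  out
}

#' Run the full pipeline on a (simulated) cohort
#'
#' @param spec a [cohort_spec()] (e.g. [demo_cohort_spec()]).
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; stage artifacts (feature table, fold
#'   records, importance report, cluster reports, summary YAML) are written
#'   there as TSV/YAML.
#' @param group_stats also run the voxelwise group comparison stage.
#' @return list of class `pipeline_result`: the cohort, feature table,
#'   `loocv` result, `importance` report and (optionally) `clusters`.
#' @export
run_pipeline <- function(spec, config = pipeline_config(), out_dir = NULL,
                         group_stats = FALSE) {
  cohort <- simulate_cohort(spec)
  table <- build_feature_table(cohort, config)
  cv <- loocv(table, candidate_alpha = config$candidate_alpha, rf = config$rf,
              svm_c = config$svm_c, scale_features = config$scale_features,
              seed = config$seed)
  imp <- importance_from_loocv(cv, table)
  clusters <- if (group_stats) group_stats_stage(cohort, config) else NULL
  res <- structure(list(cohort = cohort, table = table, loocv = cv,
                        importance = imp, clusters = clusters, config = config),
                   class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_artifacts(res, out_dir)
  res
}

#' @export
print.pipeline_result <- function(x, ...) {
  print(x$cohort)
  print(x$loocv)
  print(x$importance)
  invisible(x)
}

write_pipeline_artifacts <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  tb <- res$table
  utils::write.table(
    data.frame(subject_id = tb$subject_ids, label = tb$labels, tb$values,
               check.names = FALSE),
    file.path(out_dir, "feature_table.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  folds <- do.call(rbind, lapply(res$loocv$folds, function(f)
    data.frame(subject_id = f$subject_id, truth = f$truth,
               predicted = f$predicted,
               n_selected = length(f$selection$selected),
               selected = paste(f$selection$selected, collapse = ","))))
  utils::write.table(folds, file.path(out_dir, "loocv_folds.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  imp <- res$importance
  utils::write.table(
    data.frame(feature = names(imp$feature_scores),
               subcategory = unname(imp$feature_subcategory),
               score = unname(imp$feature_scores)),
    file.path(out_dir, "importance.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  s <- res$loocv$summary
  yaml::write_yaml(list(
    seed = res$config$seed,
    n_subjects = length(res$loocv$folds),
    correct_rate = s$correct_rate, sensitivity = s$sensitivity,
    specificity = s$specificity,
    features_per_fold = vapply(res$loocv$folds,
                               function(f) length(f$selection$selected), numeric(1)),
    subcategory_percent = as.list(imp$subcategory_percent)
  ), file.path(out_dir, "summary.yaml"))
  if (!is.null(res$clusters)) {
    cl <- do.call(rbind, lapply(names(res$clusters), function(kind) {
      rep_ <- res$clusters[[kind]]
      if (!length(rep_$clusters)) return(NULL)
      do.call(rbind, lapply(seq_along(rep_$clusters), function(i)
        data.frame(map = kind, cluster = i, size = rep_$clusters[[i]]$size,
                   peak = paste(rep_$clusters[[i]]$peak, collapse = ","))))
    }))
    if (is.null(cl)) cl <- data.frame(map = character(), cluster = integer(),
                                      size = integer(), peak = character())
    utils::write.table(cl, file.path(out_dir, "clusters.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(out_dir)
}
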