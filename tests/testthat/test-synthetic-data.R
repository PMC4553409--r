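# Cohort generator: atlas geometry, reproducibility, and the statistical
# structure of planted effects.

test_that("block atlas partitions the grid into contiguous regions of >= 27 voxels", {
  atlas <- make_atlas(c(12, 12, 12), 12, seed = 3)
  sizes <- tabulate(atlas$labels[atlas$labels > 0], nbins = 12)
  expect_length(sizes, 12)
  expect_true(all(sizes >= 27))
  # every region is one 6-connected component
  for (r in 1:12) {
    comp <- restlat:::label_components(atlas$labels == r, connectivity = 6)
    expect_equal(max(comp), 1L)
  }
  # ROIs, WM and CSF are disjoint and labels cover exactly the brain mask
  expect_false(any(atlas$wm_mask & atlas$brain_mask))
  expect_false(any(atlas$csf_mask & atlas$brain_mask))
  expect_true(all((atlas$labels > 0) == atlas$brain_mask))
})

test_that("atlas construction is deterministic and rejects undersized grids", {
  expect_identical(make_atlas(c(10, 10, 10), 8, seed = 7),
                   make_atlas(c(10, 10, 10), 8, seed = 7))
  expect_error(make_atlas(c(2, 2, 2), 12), "too small")
})

test_that("cohorts have the requested composition and are byte-reproducible", {
  spec <- tiny_cohort_spec(n_left = 7, n_right = 5)
  cohort <- simulate_cohort(spec)
  labels <- vapply(cohort$subjects, `[[`, "", "label")
  expect_length(cohort$subjects, 12)
  expect_equal(sum(labels == "L"), 7)
  expect_identical(simulate_cohort(spec), cohort)
  expect_error(cohort_spec(n_left = 0, n_right = 5), "at least one")
})

test_that("uncoupled regions have near-zero expected correlation", {
  spec <- tiny_cohort_spec(n_left = 1, n_right = 1, n_timepoints = 80)
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  rs <- vapply(1:50, function(i) {
    s <- simulate_subject(spec, "L", subject_seed = 100 + i, atlas = atlas)
    ts <- extract_roi_timeseries(s$bold, atlas)
    stats::cor(ts$data[, 1], ts$data[, 2])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("full coherence mixing drives regional homogeneity to 1", {
  eff <- effect_spec(reho = data.frame(roi = 2, weight = 1.0), target_group = "L")
  spec <- tiny_cohort_spec(effect = eff)
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  s <- simulate_subject(spec, "L", subject_seed = 11, atlas = atlas)
  flat <- matrix(s$bold$data, ncol = spec$n_timepoints)
  vox <- which(as.vector(atlas$labels) == 2)
  # all voxel series in the region are identical, so Kendall's W is exactly 1
  expect_equal(max(abs(sweep(flat[vox, ], 2, flat[vox[1], ]))), 0)
  bp <- bandpass_filter(t(flat), tr = spec$tr)
  w <- compute_reho(bold_image(array(t(bp), dim(s$bold$data)), atlas$brain_mask, spec$tr))
  # W = 1 exactly where the whole 3x3x3 neighbourhood lies inside the region
  # (neighbourhoods of boundary voxels mix in other regions' series)
  interior <- array(FALSE, spec$grid)
  idx <- which(atlas$labels == 2, arr.ind = TRUE)
  for (k in seq_len(nrow(idx))) {
    v <- idx[k, ]
    nb <- expand.grid(v[1] + (-1:1), v[2] + (-1:1), v[3] + (-1:1))
    if (all(nb >= 1) && all(t(t(nb) <= spec$grid)) &&
        all(atlas$labels[as.matrix(nb)] == 2))
      interior[v[1], v[2], v[3]] <- TRUE
  }
  expect_gt(sum(interior), 0)
  expect_true(all(abs(w[interior] - 1) < 1e-12))
})

test_that("a 2x amplitude effect doubles the group-mean ALFF in the target region", {
  eff <- effect_spec(alff = data.frame(roi = 1, factor = 2.0), target_group = "L")
  spec <- tiny_cohort_spec(n_left = 20, n_right = 20, effect = eff,
                           n_timepoints = 135, noise_sd = 0.2)
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  # group-mean in-band amplitude over the target region's voxels
  region_amp <- function(label, seed_off) {
    vapply(1:20, function(i) {
      s <- simulate_subject(spec, label, subject_seed = seed_off + i, atlas = atlas)
      flat <- matrix(s$bold$data, ncol = spec$n_timepoints)
      vox <- which(as.vector(atlas$labels) == 1)
      d <- linear_detrend(t(flat[vox, , drop = FALSE]))
      amp <- Mod(stats::mvfft(d))
      k <- seq_len(spec$n_timepoints %/% 2)
      f <- k / (spec$n_timepoints * spec$tr)
      mean(colSums(amp[k + 1, , drop = FALSE][f >= 0.01 & f <= 0.08, , drop = FALSE]))
    }, numeric(1))
  }
  ratio <- mean(region_amp("L", 1000)) / mean(region_amp("R", 2000))
  expect_gt(ratio, 1.6)
  expect_lt(ratio, 2.4)
})

test_that("raising the noise level never increases planted group separation", {
  eff <- effect_spec(alff = data.frame(roi = 1, factor = 2.0), target_group = "L")
  separation <- function(noise_sd) {
    spec <- tiny_cohort_spec(n_left = 12, n_right = 12, effect = eff,
                             noise_sd = noise_sd, seed = 5)
    cohort <- simulate_cohort(spec)
    vals <- vapply(cohort$subjects, function(s) {
      flat <- matrix(s$bold$data, ncol = spec$n_timepoints)
      vox <- which(as.vector(cohort$atlas$labels) == 1)
      mean(apply(flat[vox, , drop = FALSE], 1, stats::sd))
    }, numeric(1))
    labels <- vapply(cohort$subjects, `[[`, "", "label")
    abs(mean(vals[labels == "L"]) - mean(vals[labels == "R"])) /
      stats::sd(vals)
  }
  expect_gt(separation(0.5), separation(4))
})

test_that("written cohorts round-trip through NIfTI and TSV", {
  spec <- tiny_cohort_spec(n_left = 2, n_right = 2, n_timepoints = 20)
  cohort <- simulate_cohort(spec)
  dir <- withr::local_tempdir()
  write_cohort(cohort, dir)
  expect_true(file.exists(file.path(dir, "atlas.nii.gz")))
  expect_true(file.exists(file.path(dir, "cohort_spec.yaml")))
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"))
  expect_equal(subj$label, c("L", "L", "R", "R"))
  img <- RNifti::readNifti(file.path(dir, "sub01_bold.nii.gz"))
  expect_equal(as.array(img), cohort$subjects[[1]]$bold$data,
               ignore_attr = TRUE, tolerance = 1e-6)

  back <- read_cohort(dir)
  expect_equal(back$spec, cohort$spec)
  expect_identical(back$atlas$labels, cohort$atlas$labels)
  expect_equal(back$subjects[[3]]$bold$data, cohort$subjects[[3]]$bold$data,
               tolerance = 1e-6)
  expect_equal(back$subjects[[3]]$label, cohort$subjects[[3]]$label)
  file.remove(file.path(dir, "atlas.nii.gz"))
  expect_error(read_cohort(dir), "atlas.nii.gz")
})
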