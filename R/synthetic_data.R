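#' Synthetic resting-state cohorts with planted lateralized effects
#'
#' The generator produces 4D BOLD-like images whose statistical structure
#' matches what the downstream analysis assumes: every region shares a latent
#' band-limited (0.01-0.08 Hz) signal mixed into its voxels on top of white
#' noise, and group differences can be planted in local amplitude (ALFF),
#' local coherence (ReHo) and inter-regional coupling (FC). No hemodynamic
#' response or physiological noise is modelled.
#'
#' @name synthetic_data
NULL

#' BOLD image container
#'
#' @param data 4D numeric array (x, y, z, t).
#' @param mask 3D logical array marking in-brain voxels.
#' @param tr repetition time in seconds.
#' @return An object of class `bold_image`.
#' @export
bold_image <- function(data, mask, tr) {
  stopifnot(length(dim(data)) == 4, length(dim(mask)) == 3)
  if (!all(dim(data)[1:3] == dim(mask)))
    stop("bold data and mask grids differ")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("tr must be a positive scalar (seconds)")
  structure(list(data = data, mask = array(as.logical(mask), dim(mask)),
                 tr = tr),
            class = "bold_image")
}

#' @export
print.bold_image <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_image> grid %dx%dx%d, %d volumes, TR %.3g s, %d in-mask voxels\n",
              d[1], d[2], d[3], d[4], x$tr, sum(x$mask)))
  invisible(x)
}

# Recursive bisection of a box (1-based inclusive bounds) into k axis-aligned
# sub-boxes with near-equal voxel counts. Returns a list of integer vectors
# c(x0, x1, y0, y1, z0, z1).
split_box <- function(box, k) {
  if (k == 1L) return(list(box))
  len <- c(box[2] - box[1], box[4] - box[3], box[6] - box[5]) + 1L
  ax <- which.max(len)
  if (len[ax] < 2L)
    stop("grid too small: cannot split a unit-length box")
  k1 <- k %/% 2L
  k2 <- k - k1
  n1 <- max(1L, min(len[ax] - 1L, round(len[ax] * k1 / k)))
  lo <- box[c(1, 3, 5)[ax]]
  b1 <- box; b2 <- box
  b1[c(2, 4, 6)[ax]] <- lo + n1 - 1L
  b2[c(1, 3, 5)[ax]] <- lo + n1
  c(split_box(b1, k1), split_box(b2, k2))
}

box_volume <- function(b) prod(b[c(2, 4, 6)] - b[c(1, 3, 5)] + 1)

fill_box <- function(arr, b, value) {
  arr[b[1]:b[2], b[3]:b[4], b[5]:b[6]] <- value
  arr
}

#' Build a toy block parcellation
#'
#' Partitions the grid into `n_regions` spatially contiguous axis-aligned
#' blocks (the ROIs) plus two reserved non-ROI blocks used as white-matter and
#' CSF nuisance masks. Regions are crude stand-ins for an anatomical atlas:
#' contiguity and a minimum size of 27 voxels (so a full 3x3x3 ReHo
#' neighbourhood fits) are the only properties downstream code relies on.
#'
#' @param grid integer length-3 voxel dimensions.
#' @param n_regions number of ROI labels (1..n_regions).
#' @param seed integer; permutes which block receives which ROI id.
#' @return An object of class `parcellation`: integer label volume (0 =
#'   non-ROI), region ids/names, brain mask (union of ROIs) and WM/CSF masks.
#' @export
make_atlas <- function(grid, n_regions, seed = 1L) {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3, all(grid >= 1), n_regions >= 1)
  n_blocks <- n_regions + 2L  # + WM and CSF nuisance blocks
  if (prod(grid) < 27 * n_blocks)
    stop(sprintf("grid too small: %d voxels cannot host %d regions of >= 27 voxels (plus WM/CSF blocks)",
                 prod(grid), n_regions))
  boxes <- split_box(c(1L, grid[1], 1L, grid[2], 1L, grid[3]), n_blocks)
  sizes <- vapply(boxes, box_volume, numeric(1))
  if (any(sizes < 27))
    stop("grid too small: recursive split produced a region under 27 voxels")
  roi_boxes <- boxes[seq_len(n_regions)]
  wm_box <- boxes[[n_regions + 1L]]
  csf_box <- boxes[[n_regions + 2L]]

  # seed only permutes the id -> block assignment
  perm <- withr_seed(seed, sample.int(n_regions))
  labels <- array(0L, grid)
  for (i in seq_len(n_regions))
    labels <- fill_box(labels, roi_boxes[[i]], perm[i])
  wm_mask <- fill_box(array(FALSE, grid), wm_box, TRUE)
  csf_mask <- fill_box(array(FALSE, grid), csf_box, TRUE)

  structure(list(
    labels = labels,
    n_regions = as.integer(n_regions),
    region_ids = seq_len(n_regions),
    region_names = sprintf("ROI%03d", seq_len(n_regions)),
    brain_mask = labels > 0L,
    wm_mask = wm_mask,
    csf_mask = csf_mask,
    grid = grid
  ), class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> grid %s, %d regions (%d-%d voxels), WM %d / CSF %d voxels\n",
              paste(x$grid, collapse = "x"), x$n_regions,
              min(tabulate(x$labels[x$labels > 0])),
              max(tabulate(x$labels[x$labels > 0])),
              sum(x$wm_mask), sum(x$csf_mask)))
  invisible(x)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Planted group-effect specification
#'
#' Describes which regions/pairs carry lateralized effects and for which
#' group. `alff` rows multiply the latent amplitude of a region, `reho` rows
#' mix a shared noise source into a region's voxels (weight 1 makes all voxel
#' time courses identical), and `fc` rows couple two regions' latents so
#' their expected correlation increases by roughly `delta`.
#'
#' @param alff data.frame with columns `roi`, `factor` (or NULL).
#' @param reho data.frame with columns `roi`, `weight` in \[0, 1\] (or NULL).
#' @param fc data.frame with columns `roi_i`, `roi_j`, `delta` in \[0, 1) (or NULL).
#' @param target_group `"L"` or `"R"`; the group carrying every effect.
#' @return An object of class `effect_spec`.
#' @export
effect_spec <- function(alff = NULL, reho = NULL, fc = NULL, target_group = "L") {
  stopifnot(target_group %in% c("L", "R"))
  if (!is.null(alff)) {
    alff <- as.data.frame(alff)
    stopifnot(all(c("roi", "factor") %in% names(alff)), all(alff$factor > 0))
  }
  if (!is.null(reho)) {
    reho <- as.data.frame(reho)
    stopifnot(all(c("roi", "weight") %in% names(reho)))
    if (any(reho$weight < 0 | reho$weight > 1))
      stop("reho mixing weights must lie in [0, 1]")
  }
  if (!is.null(fc)) {
    fc <- as.data.frame(fc)
    stopifnot(all(c("roi_i", "roi_j", "delta") %in% names(fc)))
    if (any(fc$delta < 0 | fc$delta >= 1))
      stop("fc coupling deltas must lie in [0, 1) so correlations stay below 1")
  }
  structure(list(alff = alff, reho = reho, fc = fc,
                 target_group = target_group),
            class = "effect_spec")
}

#' Cohort specification
#'
#' Defaults follow the acquisition the analysis expects: 135 retained volumes
#' at TR 2.5 s and a 116-region parcellation. `n_regions` can be reduced
#' (down to 12) with a correspondingly smaller grid for fast tests.
#'
#' @param n_left,n_right group sizes (each >= 1).
#' @param grid voxel dimensions, length 3.
#' @param n_timepoints number of volumes (>= 16).
#' @param tr repetition time, seconds.
#' @param n_regions number of atlas regions.
#' @param effect an [effect_spec()] (NULL = no planted effect).
#' @param noise_sd white-noise standard deviation, signal units.
#' @param seed integer master seed; per-subject seeds are derived from it.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_left, n_right, grid = c(16L, 16L, 16L),
                        n_timepoints = 135L, tr = 2.5, n_regions = 116L,
                        effect = NULL, noise_sd = 1, seed = 1L) {
  if (n_left < 1 || n_right < 1)
    stop("each group needs at least one subject")
  if (n_timepoints < 16)
    stop("n_timepoints must be >= 16")
  if (is.null(effect)) effect <- effect_spec()
  stopifnot(inherits(effect, "effect_spec"), noise_sd >= 0)
  rois <- c(effect$alff$roi, effect$reho$roi, effect$fc$roi_i, effect$fc$roi_j)
  if (length(rois) && any(rois < 1 | rois > n_regions))
    stop("effect ROI ids outside 1..n_regions")
  structure(list(n_left = as.integer(n_left), n_right = as.integer(n_right),
                 grid = as.integer(grid), n_timepoints = as.integer(n_timepoints),
                 tr = tr, n_regions = as.integer(n_regions), effect = effect,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cohort_spec")
}

# Deterministic per-subject seed: a 32-bit multiplicative mix of the master
# seed and the subject index, kept below 2^31.
subject_seed <- function(seed, idx) {
  as.integer((abs(as.numeric(seed)) * 48271 + as.numeric(idx) * 2654435) %% 2147483647)
}

# A unit-variance latent confined to the analysis band: white noise run
# through the ideal FFT bandpass so planted effects live in 0.01-0.08 Hz.
band_limited_latent <- function(n_timepoints, tr, band = c(0.01, 0.08)) {
  x <- bandpass_filter(stats::rnorm(n_timepoints), tr = tr,
                       low = band[1], high = band[2])
  s <- stats::sd(x)
  if (s < .Machine$double.eps) x else x / s
}

#' Simulate one subject
#'
#' @param spec a [cohort_spec()].
#' @param label `"L"` or `"R"`.
#' @param subject_seed integer seed for this subject's randomness.
#' @param atlas optional pre-built [make_atlas()] parcellation (rebuilt from
#'   `spec` when omitted).
#' @return list with elements `bold` ([bold_image]), `confounds` (T x 9 matrix:
#'   six motion random walks plus global/WM/CSF mean signals) and `label`.
#' @export
simulate_subject <- function(spec, label, subject_seed,
                             atlas = make_atlas(spec$grid, spec$n_regions, spec$seed)) {
  stopifnot(inherits(spec, "cohort_spec"), label %in% c("L", "R"))
  tp <- spec$n_timepoints
  eff <- spec$effect
  carries <- identical(label, eff$target_group)

  withr_seed(subject_seed, {
    # region latents, then couple pairs for the target group:
    # l' = sqrt(1-d) l + sqrt(d) c gives E[cor] ~ d between pure latents
    latents <- vapply(seq_len(spec$n_regions),
                      function(i) band_limited_latent(tp, spec$tr),
                      numeric(tp))
    if (carries && !is.null(eff$fc)) {
      for (k in seq_len(nrow(eff$fc))) {
        i <- eff$fc$roi_i[k]; j <- eff$fc$roi_j[k]; d <- eff$fc$delta[k]
        shared <- band_limited_latent(tp, spec$tr)
        latents[, i] <- sqrt(1 - d) * latents[, i] + sqrt(d) * shared
        latents[, j] <- sqrt(1 - d) * latents[, j] + sqrt(d) * shared
      }
    }

    amp <- rep(1, spec$n_regions)
    if (carries && !is.null(eff$alff))
      amp[eff$alff$roi] <- amp[eff$alff$roi] * eff$alff$factor
    mix <- rep(0, spec$n_regions)
    if (carries && !is.null(eff$reho))
      mix[eff$reho$roi] <- eff$reho$weight

    data <- array(0, c(spec$grid, tp))
    flat <- matrix(data, nrow = prod(spec$grid), ncol = tp)
    lab_vec <- as.vector(atlas$labels)
    for (r in seq_len(spec$n_regions)) {
      vox <- which(lab_vec == r)
      nv <- length(vox)
      shared_noise <- stats::rnorm(tp)              # ReHo mixing source
      eps <- matrix(stats::rnorm(nv * tp), nv, tp)  # independent voxel noise
      noise <- (1 - mix[r]) * eps +
        mix[r] * matrix(shared_noise, nv, tp, byrow = TRUE)
      flat[vox, ] <- matrix(amp[r] * latents[, r], nv, tp, byrow = TRUE) +
        spec$noise_sd * noise
    }
    for (m in list(atlas$wm_mask, atlas$csf_mask)) {
      vox <- which(as.vector(m))
      lat <- band_limited_latent(tp, spec$tr)
      flat[vox, ] <- matrix(lat, length(vox), tp, byrow = TRUE) +
        spec$noise_sd * matrix(stats::rnorm(length(vox) * tp), length(vox), tp)
    }
    data <- array(flat, c(spec$grid, tp))

    motion <- vapply(seq_len(6), function(i) cumsum(stats::rnorm(tp, sd = 0.02)),
                     numeric(tp))
    colnames(motion) <- c("mot_tx", "mot_ty", "mot_tz", "mot_rx", "mot_ry", "mot_rz")
    confounds <- cbind(
      motion,
      global = colMeans(flat[as.vector(atlas$brain_mask), , drop = FALSE]),
      wm = colMeans(flat[as.vector(atlas$wm_mask), , drop = FALSE]),
      csf = colMeans(flat[as.vector(atlas$csf_mask), , drop = FALSE])
    )

    list(bold = bold_image(data, atlas$brain_mask, spec$tr),
         confounds = confounds, label = label)
  })
}

#' Simulate a full cohort
#'
#' Subjects get seeds derived deterministically from `spec$seed`, so the
#' cohort is reproducible while subjects remain independent.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `cohort`: list of subjects (each as returned by
#'   [simulate_subject()], plus a `subject_id`), the shared atlas, and the spec.
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  labels <- c(rep("L", spec$n_left), rep("R", spec$n_right))
  subjects <- lapply(seq_along(labels), function(i) {
    s <- simulate_subject(spec, labels[i], subject_seed(spec$seed, i), atlas)
    s$subject_id <- sprintf("sub%02d", i)
    s
  })
  structure(list(subjects = subjects, atlas = atlas, spec = spec),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort> %d subjects (%d L / %d R), grid %s, %d regions, T=%d, TR=%.3g s\n",
              length(x$subjects), x$spec$n_left, x$spec$n_right,
              paste(x$spec$grid, collapse = "x"), x$spec$n_regions,
              x$spec$n_timepoints, x$spec$tr))
  invisible(x)
}

#' Write a cohort to disk
#'
#' Per-subject 4D NIfTI plus confound TSVs, the atlas NIfTI, a subject table
#' and the cohort specification as YAML.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(cohort$atlas$labels, file.path(dir, "atlas.nii.gz"))
  subj <- data.frame(
    subject_id = vapply(cohort$subjects, `[[`, "", "subject_id"),
    label = vapply(cohort$subjects, `[[`, "", "label")
  )
  utils::write.table(subj, file.path(dir, "subjects.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (s in cohort$subjects) {
    RNifti::writeNifti(s$bold$data,
                       file.path(dir, paste0(s$subject_id, "_bold.nii.gz")))
    utils::write.table(as.data.frame(s$confounds),
                       file.path(dir, paste0(s$subject_id, "_confounds.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  sp <- cohort$spec
  yaml::write_yaml(list(
    n_left = sp$n_left, n_right = sp$n_right, grid = sp$grid,
    n_timepoints = sp$n_timepoints, tr = sp$tr, n_regions = sp$n_regions,
    noise_sd = sp$noise_sd, seed = sp$seed,
    effect = list(target_group = sp$effect$target_group,
                  alff = sp$effect$alff, reho = sp$effect$reho, fc = sp$effect$fc)
  ), file.path(dir, "cohort_spec.yaml"))
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir directory containing `atlas.nii.gz`, `subjects.tsv`,
#'   `cohort_spec.yaml` and the per-subject BOLD/confound files.
#' @return A `cohort` object equivalent to the one written.
#' @export
read_cohort <- function(dir) {
  need <- c("atlas.nii.gz", "subjects.tsv", "cohort_spec.yaml")
  for (f in need) {
    path <- file.path(dir, f)
    if (!file.exists(path)) stop("missing cohort file: ", path)
  }
  sp <- yaml::read_yaml(file.path(dir, "cohort_spec.yaml"))
  as_df <- function(x) if (is.null(x)) NULL else as.data.frame(lapply(x, unlist))
  spec <- cohort_spec(
    n_left = sp$n_left, n_right = sp$n_right, grid = unlist(sp$grid),
    n_timepoints = sp$n_timepoints, tr = sp$tr, n_regions = sp$n_regions,
    effect = effect_spec(alff = as_df(sp$effect$alff),
                         reho = as_df(sp$effect$reho),
                         fc = as_df(sp$effect$fc),
                         target_group = sp$effect$target_group),
    noise_sd = sp$noise_sd, seed = sp$seed)
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  stored <- array(as.integer(RNifti::readNifti(file.path(dir, "atlas.nii.gz"))),
                  spec$grid)
  if (!identical(stored, atlas$labels))
    stop("stored atlas does not match the cohort specification in ", dir)
  subj <- utils::read.delim(file.path(dir, "subjects.tsv"),
                            colClasses = "character")
  subjects <- lapply(seq_len(nrow(subj)), function(i) {
    id <- subj$subject_id[i]
    bold_path <- file.path(dir, paste0(id, "_bold.nii.gz"))
    conf_path <- file.path(dir, paste0(id, "_confounds.tsv"))
    for (p in c(bold_path, conf_path))
      if (!file.exists(p)) stop("missing cohort file: ", p)
    data <- array(as.numeric(RNifti::readNifti(bold_path)),
                  c(spec$grid, spec$n_timepoints))
    conf <- as.matrix(utils::read.delim(conf_path))
    list(bold = bold_image(data, atlas$brain_mask, spec$tr),
         confounds = conf, label = subj$label[i], subject_id = id)
  })
  structure(list(subjects = subjects, atlas = atlas, spec = spec),
            class = "cohort")
}
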