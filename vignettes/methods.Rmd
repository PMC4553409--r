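---
title: "Lateralizing temporal lobe epilepsy from resting-state connectivity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralizing temporal lobe epilepsy from resting-state connectivity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

In drug-resistant temporal lobe epilepsy (TLE), surgery is the treatment of
choice, and knowing whether the seizure focus sits in the left or the right
temporal lobe is a precondition for planning it. `restlat` implements a
machine-learning lateralization pipeline driven entirely by resting-state
fMRI: connectivity-derived features are extracted at three spatial scales,
features are selected by a nested random-forest procedure, and a linear
support vector machine predicts laterality for each held-out patient under
leave-one-patient-out cross-validation (LOOCV).

The package also ships a synthetic-cohort generator. Resting-state datasets
of presurgical TLE patients are small and rarely shareable, so every stage
here is built to be exercised, tested and calibrated on simulated cohorts
with known, planted lateralized effects.

## Feature space

Six sub-categories of features are computed per subject from a 4D BOLD image,
a parcellation into $R$ regions, and nuisance regressors.

**Voxelwise (univariate) features.** For each in-mask voxel:

* **ALFF** — the amplitude of low-frequency fluctuation: the sum of DFT
  amplitudes $\sqrt{P_k}$ over frequency bins $f_k \in [0.01, 0.08]$ Hz,
  DC excluded.
* **fALFF** — the same in-band amplitude sum divided by the amplitude sum
  over the entire detectable range, a ratio in $[0,1]$ that is less
  sensitive to broadband physiological noise.
* **ReHo** — regional homogeneity: Kendall's coefficient of concordance
  $W = \frac{12 \sum_t (R_t - \bar R)^2}{K^2 (T^3 - T)}$
  over the ranked time courses of the $K \le 27$ in-mask voxels of the
  3×3×3 neighbourhood.

The processing order is fixed: linear detrend first; ALFF and fALFF are
computed on smoothed but *unfiltered* data (their numerator is the band
itself, so pre-filtering would be circular); ReHo is computed on bandpassed
but *unsmoothed* data (smoothing would manufacture neighbourhood concordance)
and the resulting $W$ map is smoothed afterwards. Each map is divided by its
subject-specific in-mask global mean, so values are dimensionless ratios with
in-mask mean 1.

Two deliberate numerical choices: spectral amplitude is defined as the square
root of per-bin periodogram power summed over bins, and tied ranks in the KCC
receive average ranks with *no* tie-correction term — at $T = 135$ continuous
samples ties are rare and the plain formula is used. Whether the spectral
features should see smoothed or unsmoothed input is genuinely
underdetermined; smoothing-first is the default and
`voxel_feature_maps(smooth_before_spectral = FALSE)` gives the alternative.

**Inter-regional (bivariate) features.** Region-mean time courses are
residualized against six motion parameters plus global, white-matter and CSF
mean signals (OLS, intercept included, collinear columns dropped with a
warning), then all pairwise Pearson correlations are Fisher-z transformed:
$z_{ij} = \operatorname{atanh}(r_{ij})$, with $|r|$ clipped at $1 - 10^{-7}$
so downstream learners never see infinities. A candidate filter keeps only
pairs whose $z$ values differ from zero by a two-sided one-sample t-test at
$\alpha = 0.05$ across the *training* subjects of the current fold. Running
the filter inside each fold costs a little power but cannot leak the held-out
subject into feature definition; the filter alpha is a configuration knob.

**Network (multivariate) features.** The z-matrix is back-transformed and
binarized at six correlation thresholds $0.05, 0.10, \ldots, 0.30$ (signed:
negative correlations never form edges; thresholds apply to $r$, not to a
target density — both conventions exist, and a density-targeting variant can
be built from `binarize_fc` directly). Per threshold the package computes six
nodal metrics — degree, shortest path length (mean hop distance over
*reachable* nodes), global efficiency (mean inverse distance, $1/\infty = 0$),
local efficiency (global efficiency of the neighbour-induced subgraph),
clustering coefficient, and normalized betweenness centrality — and eleven
global metrics: the six nodal means plus assortativity, transitivity,
$\gamma = C/\langle C_{\text{null}}\rangle$,
$\lambda = L/\langle L_{\text{null}}\rangle$ and small-worldness
$\sigma = \gamma/\lambda$. Null graphs preserve the degree sequence exactly
via double-edge swaps (10 attempted swaps per edge, 100 nulls by default).
With $R = 116$ regions this yields exactly 66 global and 4176 nodal
candidate features. The sixth nodal metric and eleventh global metric are
a design choice (betweenness and its network mean) consistent with those
printed counts; disconnected node pairs contribute nothing to path lengths
and zeros to efficiencies, and metrics that are undefined on a degenerate
graph (no edges, no triples, constant degree) are recorded as missing and
mean-imputed before model fitting.

## Feature selection and classification

Within each LOOCV fold, using the training subjects only:

1. **Per-sub-category ranking.** Gini importance (total decrease in Gini
   impurity over all splits) is averaged over `n_reps` random forests with
   distinct seeds (`seed+1 … seed+n_reps` for auditability), separately per
   sub-category; the top `top_k` features of each survive. Defaults: 50
   repetitions, top 50, 500 trees, $\sqrt F$ candidates per split, bootstrap
   sampling with replacement — conventional forest settings at small $n$.
   Zero-variance training features are dropped first.
2. **Pooling and re-ranking.** The six top lists (up to 300 features) are
   pooled and re-ranked by the same repeated-forest importance. Repetition is
   used here too, for symmetry with stage 1; a single forest is the cheaper
   alternative.
3. **Incremental OOB minimization.** Forests are grown on prefixes of the
   pooled ranking, adding one feature at a time; the *shortest* prefix
   attaining the global minimum out-of-bag error is the selected set
   ("minimum feature set" read literally — ties break toward fewer
   features).
4. **Classification.** Selected features are z-scored with training-fold
   statistics (the feature space mixes counts, ratios and z-values, so a
   linear margin needs a common scale; `scale_features = FALSE` disables it)
   and a linear SVM with cost $C = 1$ predicts the held-out subject. No
   class weighting is applied to the 7-vs-5 imbalance.

Performance is reported as correct rate, sensitivity and specificity with
left-sided TLE as the positive class. Because selection, the candidate
filter and the scaling statistics are all fold-internal, perturbing a
held-out subject provably cannot change that fold's selected features — the
test suite asserts this mutation property.

## Importance scoring

In each run the $m$ selected features receive raw scores $m, m-1, \ldots, 1$
from most to least important (the ranks come from the pooled importance
ordering, which by construction is also the selection order), normalized by
the run total $m(m+1)/2$ so each run contributes mass exactly 1. Feature and
sub-category importance is the plain sum of normalized scores over runs — no
fold weighting — so the total mass always equals the number of runs and
sub-category percentages are comparable across experiments. A feature that is
the only selection of a run therefore scores exactly 1 from that run.

## Group comparison reference

As a univariate reference alongside the classifier, feature-wise and
voxelwise group differences use the Mann–Whitney U-test (exact null
distribution at these sample sizes, normal approximation with tie correction
for larger ones), with voxelwise maps corrected by cluster extent: only
6-connected clusters of at least 16 voxels at $p < 0.01$ survive, the
printed convention for the 3 mm grid this analysis targets.
`alphasim_min_cluster()` re-derives the extent threshold for other grids by
Monte Carlo: smooth Gaussian null volumes are standardized over the mask,
thresholded voxelwise, and the $1-\alpha$ quantile of the maximum cluster
size is returned.

## The synthetic cohort generator

`simulate_cohort()` emulates the acquisition the analysis assumes: 135
volumes at TR = 2.5 s, a parcellation of contiguous regions each large
enough (≥ 27 voxels) to contain full ReHo neighbourhoods, plus designated
non-ROI white-matter and CSF blocks so nuisance regression can be exercised
end-to-end. Every region carries a latent signal built by bandpassing white
noise to 0.01–0.08 Hz — planted effects therefore live exactly in the
analysis band — mixed into its voxels over white noise of standard deviation
`noise_sd`. Three effect families mirror the three feature scales:

* an **amplitude factor** multiplies a region's latent for one group only
  (targets ALFF/fALFF),
* a **coherence weight** $w \in [0,1]$ replaces a fraction of each voxel's
  independent noise with a region-shared source; $w = 1$ makes all voxel
  time courses identical and drives Kendall's $W$ to 1 (targets ReHo),
* a **coupling delta** $d \in [0,1)$ mixes a shared latent into two regions'
  latents as $\sqrt{1-d}\,\ell + \sqrt{d}\,c$, raising their expected
  correlation by about $d$ (targets FC and, indirectly, the graph metrics).

Subject seeds are derived deterministically from the cohort seed, so cohorts
are byte-reproducible while subjects stay independent. Confounds are six
smooth random-walk motion traces plus the mean signals over the brain, WM
and CSF masks.

What the generator does *not* model: hemodynamic response shape, cardiac and
respiratory cycles, scanner drift beyond a linear trend, anatomically shaped
regions, or spatial autocorrelation beyond region membership. Passing
recovery tests on these cohorts therefore demonstrates that the pipeline's
statistics and plumbing are correct and leakage-free — not that its accuracy
on real patients is any particular number.

## Simulation study scale

The default configuration reflects the full-size analysis (116 regions,
50-repetition ranking, 500-tree forests, 100 null graphs). The simulation
studies in the test suite use `demo_cohort_spec()` / `demo_config()`: 12
regions on a 6×6×14 grid (~36 voxels per region), 100-tree forests, 3
ranking repetitions, top-10 pooling and 20 null graphs. These sizes are the
package's chosen demonstration scale: large enough that every stage runs on
real data structures with hundreds of candidate features per sub-category,
small enough that a hundred replicate cohorts are practical. The planted
demonstration effects (amplitude ×2.0, coherence 0.8, coupling 0.6, all on
the left group) were fixed a priori as "strong" on the reasoning that a
doubling of band-limited amplitude and a near-unity coherence mixing are at
the upper end of what patient studies report as group differences; with them
the 12-subject LOOCV recovers laterality in ≥ 10/12 subjects in the large
majority of replicate cohorts, while cohorts with no planted effect stay at
chance on average.

## Known limitations

* The toy atlas is axis-aligned blocks; nothing anatomical is implied by
  region identities.
* ReHo neighbourhoods truncate at mask and volume borders ($K$ adapts), so
  boundary voxels have systematically different null expectations than
  interior ones; the acceptance checks use interior voxels.
* The graph thresholds apply to signed correlations; strongly negative
  connectivity is invisible to the network features by design.
* Exact Mann–Whitney p-values require tie-free data; with heavy ties the
  normal approximation with tie correction is used automatically.
* With 12 subjects a LOOCV accuracy estimate has a standard error of roughly
  0.1–0.14; single-cohort accuracies should be read accordingly.
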