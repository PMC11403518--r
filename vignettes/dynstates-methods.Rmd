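---
title: "Dynamic brain-state analysis with dynstates: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic brain-state analysis with dynstates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynstates)
```

## The analysis

`dynstates` implements a sliding-window dynamic functional-connectivity
analysis of denoised ROI time series, together with the structural
network-composite statistics that usually accompany it in clinical
resting-state studies, and a synthetic-cohort generator used to validate every
stage against planted ground truth.

The pipeline, per subject and run:

1. **Windows.** Each run is sliced into overlapping windows (default width 80
   frames = 60 s at TR 0.72 s, advanced by 1 frame). Windows never span run
   boundaries — runs are separate acquisitions. A window containing at least
   one motion-outlier frame is a *motion window*.
2. **Connectivity and strength.** The Pearson correlation matrix over the
   window's frames is reduced to per-ROI *positive strength*
   $s_i = \sum_{j \ne i} \max(r_{ij}, 0)$. Negative edges are discarded, not
   absolute-valued. *Global strength* is the ROI mean of $s$.
3. **Control-referenced z-scores.** Each ROI's strength column is standardised
   by the mean and population SD (divisor $N$) of the control group's windows,
   applied to all windows of both groups. Without this step, highly connected
   ROIs dominate the clustering; with it, every ROI's fluctuations contribute
   comparably.
4. **Data reduction by stationary modules.** Modularity maximisation (Louvain
   restarts at resolution $\gamma = 1$, best modularity Q kept across 1000
   seeded restarts, positive edges only) on the control group's mean scrubbed
   correlation matrix yields the module partition; window z-scores are averaged
   within modules, giving one feature per module per window.
5. **States.** Ward minimum-variance clustering of the module-averaged
   features, with the number of clusters chosen by Sarle's cubic clustering
   criterion (CCC): the observed $R^2(k)$ of the Ward cuts is compared against
   a uniform-hypercube null and the highest positive CCC peak selects $k$.
6. **Motion bookkeeping.** A cluster averaging strictly more than 2
   motion-outlier frames per window is a *motion cluster* and is dropped
   wholesale; remaining states are analysed over non-motion windows only.
   Subjects with strictly fewer usable windows than a threshold (1200 for
   2 x 726-window runs, scaled proportionally for other run lengths) are
   excluded. Per subject, dwell + motion-window + motion-cluster-window counts
   always equal the total window count.
7. **Characterisation.** Dwell time of a state in a subject = number of
   usable windows assigned to it (windows overlap, so frames are counted by
   several windows; the definition is deliberately not normalised). Per state,
   the population mean strength profile defines *hubs*: ROIs strictly above the
   state's own 90th percentile (linear interpolation). Per subject and state,
   the *representative window* minimises the representation index (mean
   Euclidean distance between upper-triangle-vectorised window correlation
   matrices); its correlation matrix yields global, within-network, and
   hub/non-hub cross strengths.
8. **Inference.** Two-tailed Welch t-tests compare groups per state (dwell
   time, global and network strengths) over the subjects expressing the state;
   ROI-wise representative-window strengths are compared with
   Benjamini-Hochberg FDR per state (both corrected and uncorrected sets are
   reported). Directional hypotheses (atrophy: negative; hyperconnectivity:
   positive) use one-tailed tie-corrected Kendall tau-b, with the side declared
   per association family in configuration, never inferred from data.
   Volumetrics averages ROI-level Jacobian-determinant values over nested
   network tiers and applies the same Welch/Kendall/FDR layer.

```{r example, eval = FALSE}
cohort <- simulateCohort(synthConfig(seed = 1))
res <- runPipeline(cohort, pipelineConfig(), outputDir = "dynstates-out")
subjectSummary(res$assignment)
res$stats$stateTable
```

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| window width | 80 frames (60 s) | connectivity estimation window; robust strength with visible fluctuation |
| window step | 1 frame | maximal overlap; dwell counts are in overlapping-window units |
| $\gamma$, restarts | 1, 1000 | modularity resolution and number of seeded Louvain restarts |
| hub percentile | 90 | hubs are strictly above this percentile of the state's profile |
| motion-cluster threshold | 2 outliers/window | strict inequality |
| exclusion threshold | 1200 of 1452 windows | scaled proportionally to the cohort's windows per subject |
| FDR level q | 0.05 | per-state ROI family; per-table association family |

One printed-parameter discrepancy is worth noting: with 833 acquired frames,
28 discarded for T1 equilibration, width 80 and step 1, the closed form gives
805 − 80 + 1 = 726 windows per run, not the 729 sometimes quoted for this
design; the package uses the closed form everywhere.

## What the synthetic cohort emulates

`synthConfig()` describes a cohort of 28 subjects (14 controls, 14 cases — the
scale of a single-site clinical study), 50 ROIs in 6 modules, 2 runs of 800
usable frames at TR 0.72 s. Latent brain states are covariance regimes: each
state couples one distinct pair of modules (correlation 0.42 between them, 0.6
within modules at baseline, 0.02 between) and raises the coupled modules'
internal correlation, so states are separable by module-averaged strength by
construction. A sticky Markov chain (self-transition 0.995, mean segment
about 200 frames = 2.4 min) switches states; innovations are smoothed by a
variance-preserving AR(1) filter (coefficient 0.25) standing in for the
band-pass filtering the pipeline assumes has already happened upstream. Run
initial states cycle round-robin across the cohort so every state is expressed
in finite cohorts.

Motion is injected as bursts of up to 8 consecutive outlier frames (1% of
frames per run), with a global additive spike of 1.5 signal-SD and an elevated
framewise-displacement series — head motion contaminates stretches of frames,
which is also why window-level exclusion is more aggressive than frame
scrubbing. The "case" group carries the planted overshooting state: its last
state's coupled blocks are scaled by 1.3 and its self-transition is multiplied
by `dwellBias` (capped at 0.9999), yielding dwell times several-fold longer in
cases, the qualitative pattern of a hyperconnected, longer-dwelling state
confined to one group. Volume tables plant a case-group decrement (0.04 at
composite SD 0.03) on the coupled-module ROI set, and a symptom score is
negatively coupled to that composite (latent correlation 0.45, Kendall tau
near −0.3).

Things real data have that the generator does not: hemodynamics and
physiological noise, spatially graded (non-block) connectivity, gradual state
transitions, distance-dependent motion artifacts, site/scanner effects.
Passing recovery tests therefore demonstrates the pipeline's correctness and
calibration under the stated statistical structure, not clinical validity on
any particular dataset.

### Calibration choices (and why)

* **Stickiness 0.995.** Dwell times land in the tens-to-hundreds of
  overlapping windows per subject and state, the order of magnitude such
  sliding-window analyses report; segments (~200 frames) are long against the
  window width (80), so most windows sample a single state. Much shorter
  segments make most windows state mixtures and no clustering method can
  label them cleanly.
* **Burst motion.** Independent per-frame outliers at 1% would make almost
  half of all width-80 windows motion windows and the proportional exclusion
  rule would remove every subject; bursts reproduce the empirical situation
  where a feasible share of windows is motion-affected.
* **Spike amplitude 1.5 SD.** Strong enough that motion windows form their own
  high-strength clusters (exercising the motion-cluster rule), not so strong
  that the motion/no-motion split dominates the cluster geometry entirely.
* **28 subjects.** Group tests at 14 per group have realistic clinical power;
  the planted dwell effect is detectable in most replicates while non-boosted
  states stay at their nominal false-positive rate.

## Numerical and algorithmic choices

* Ward linkage is the Lance-Williams `ward.D2` form on Euclidean distances via
  `stats::hclust`; labels are canonicalised to first-appearance order for
  determinism. At the default cohort scale (28,840 windows) the linkage is
  computed on an evenly spaced subsample of at most 6000 windows and every
  window is assigned to the nearest cluster centroid — a dissimilarity matrix
  over all windows would need gigabytes and changes labels only at cluster
  boundaries. The cap is configurable.
* CCC follows Sarle's formulation: feature covariance eigenvalues define the
  hyperbox null, $p^*$ is the largest dimension count below $k$ whose
  normalised edge is at least 1, and
  $\mathrm{CCC} = \ln\frac{1 - E(R^2)}{1 - R^2}\sqrt{np^*/2}\,(0.001 + E(R^2))^{-1.2}$.
  When no positive peak exists the largest local maximum is used, else a
  configured fallback; both are reported.
* Zero-variance ROIs within a window get correlation 0 (logged) so downstream
  strengths stay finite; zero control-group strength SD is a hard error naming
  the ROI.
* State covariances failing positive definiteness are repaired by eigenvalue
  clipping followed by rescaling to unit diagonal, and flagged.
* Kendall tau-b uses the tie-corrected normal approximation at n >= 8 and
  exact permutation enumeration below; BH adjustment is the step-up rule via
  `stats::p.adjust`.
* Euclidean window distances use upper-triangle vectorisation (the diagonal is
  constant); full-matrix vectorisation would scale all distances by sqrt(2)
  and leave every argmin unchanged.
* Hub profiles use raw (not z-scored) strength; the strict ">" against the
  linearly interpolated percentile means a constant profile has no hubs.
* Frames and windows are 1-based with closed intervals, the R convention.

## Validation design

The test suite validates each operation against an independent oracle
(brute-force double loops, exhaustive pair enumeration, hand-evaluated closed
forms) and the whole pipeline against planted truth:

* **State recovery.** On a 20-subject default cohort the pipeline's non-motion
  window labels, mapped to planted states by majority vote, reach an adjusted
  Rand index of at least 0.8. CCC typically selects more clusters than the 5
  planted states (transition and motion windows form their own clusters, as in
  real analyses where a sizable share of clusters are motion clusters);
  majority-vote mapping absorbs this oversplitting, which is why the mapped
  index is the right recovery score.
* **Calibration replicates.** Re-running the full BOLD pipeline hundreds of
  times is not informative per CPU-hour; the dwell-test calibration instead
  simulates the latent chains and motion masks only, labels windows by their
  centre frame, and applies the package's exact bookkeeping and Welch layer —
  isolating the inferential claim (type-I error, power, selectivity) from
  clustering noise, which the recovery experiment covers separately. The
  connectivity side of the planted effect samples one window of BOLD per
  subject and state from the true covariance regime. The overshooting flag is
  the conjunction the analysis targets: significantly longer dwell *and*
  significantly higher planted-network strength in cases. A plain two-sided
  flag cannot be selective: lengthening one state's dwell necessarily shortens
  the others' occupancy, a real effect a two-sided test will eventually find.
* **Problem sizes.** The recovery experiment uses 20 subjects x 2 x 721
  windows; calibration uses 200 replicates of 28-subject cohorts; CCC model
  selection uses 25 replicates of 2000 x 6 features. These sizes were chosen
  as the package's own validation design.

## Known limitations

* The dwell-time definition counts overlapping windows; values are not
  directly comparable across different window steps.
* The resolution-limit of modularity at gamma = 1 binds for small modules
  (8 ROIs here, versus hundreds of ROIs in full-brain analyses); heavily
  imbalanced state occupancy can bridge coupled modules. The generator's
  round-robin initial states keep cohort occupancy balanced.
* CCC assumes roughly hyperspherical clusters; on manifold-like feature
  clouds (strong state mixing) its curve can be monotone, in which case the
  documented fallback applies.
* One-tailed Kendall sides must be declared a priori per association family;
  the package never infers direction from the data.
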