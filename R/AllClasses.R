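#' @include AllGenerics.R
NULL

# ---------------------------------------------------------------------------
# SynthConfig
# ---------------------------------------------------------------------------

#' Synthetic-cohort configuration
#'
#' Parameters of the latent state-switching cohort generator. ROI signals are
#' drawn from one covariance matrix per latent state (block structure over
#' modules; states differ by which module pairs are coupled), switched by a
#' sticky Markov chain, temporally smoothed with an AR(1) filter, and
#' contaminated with sparse global motion spikes. The "case" group can carry a
#' longer dwell time (via \code{dwellBias} on the boosted state's
#' self-transition) and a connectivity boost (via \code{boostFactor} on that
#' state's coupled blocks), emulating an overshooting hyperconnectivity state.
#'
#' @slot nRois number of ROIs
#' @slot nModules number of connectivity modules
#' @slot nStates number of latent states
#' @slot nSubjectsPerGroup subjects per group (two groups: control, case)
#' @slot nRuns runs (independent acquisitions) per subject
#' @slot framesPerRun usable frames per run
#' @slot trSeconds repetition time in seconds
#' @slot transitionStickiness Markov self-transition probability, in (0,1)
#' @slot withinModuleCorr within-module correlation, in (0,1)
#' @slot betweenModuleCorr baseline between-module correlation
#' @slot coupledCorr correlation planted in a state's coupled module pair
#' @slot boostState index of the state boosted in the case group
#' @slot boostFactor multiplier (>= 1) on the boosted state's coupled blocks
#'   for case subjects
#' @slot dwellBias multiplier (>= 1) on the boosted state's self-transition
#'   probability for case subjects (capped below 1)
#' @slot outlierRate per-frame probability of a motion-outlier frame
#' @slot outlierAmplitude spike amplitude in signal-SD units
#' @slot arCoefficient AR(1) smoothing coefficient, in (0,1)
#' @slot volumeMean control-group mean of per-ROI volume (Jacobian) values
#' @slot volumeSd between-subject SD of ROI volume values
#' @slot volumeDecrement case-group decrement on the planted atrophy ROI set
#' @slot behaviorCoupling latent correlation between the (negated) planted
#'   network composite and the symptom score, in [0,1)
#' @slot seed master seed; per-subject streams are derived by fixed offsets
#' @export
setClass("SynthConfig",
  representation(
    nRois = "integer", nModules = "integer", nStates = "integer",
    nSubjectsPerGroup = "integer", nRuns = "integer", framesPerRun = "integer",
    trSeconds = "numeric", transitionStickiness = "numeric",
    withinModuleCorr = "numeric", betweenModuleCorr = "numeric",
    coupledCorr = "numeric", boostState = "integer", boostFactor = "numeric",
    dwellBias = "numeric", outlierRate = "numeric",
    outlierAmplitude = "numeric", arCoefficient = "numeric",
    volumeMean = "numeric", volumeSd = "numeric", volumeDecrement = "numeric",
    behaviorCoupling = "numeric", seed = "integer"
  )
)

setValidity("SynthConfig", function(object) {
  msg <- character()
  chk <- function(cond, m) if (!cond) msg <<- c(msg, m)
  chk(object@nRois >= object@nModules, "nRois must be >= nModules")
  chk(object@nModules >= 1L, "nModules must be >= 1")
  chk(object@nStates >= 1L, "nStates must be >= 1")
  chk(object@nStates <= choose(object@nModules, 2),
      "nStates must not exceed the number of distinct module pairs")
  chk(object@nSubjectsPerGroup >= 1L, "nSubjectsPerGroup must be >= 1")
  chk(object@nRuns >= 1L, "nRuns must be >= 1")
  chk(object@framesPerRun >= 2L, "framesPerRun must be >= 2")
  chk(object@trSeconds > 0, "trSeconds must be positive")
  chk(object@transitionStickiness > 0 && object@transitionStickiness < 1,
      "transitionStickiness must be in (0,1)")
  chk(object@withinModuleCorr > 0 && object@withinModuleCorr < 1,
      "withinModuleCorr must be in (0,1)")
  chk(object@boostState >= 1L && object@boostState <= object@nStates,
      "boostState must index a state")
  chk(object@boostFactor >= 1, "boostFactor must be >= 1")
  chk(object@dwellBias >= 1, "dwellBias must be >= 1")
  chk(object@outlierRate >= 0 && object@outlierRate < 1,
      "outlierRate must be in [0,1)")
  chk(object@outlierAmplitude > 0, "outlierAmplitude must be positive")
  chk(object@arCoefficient > 0 && object@arCoefficient < 1,
      "arCoefficient must be in (0,1)")
  chk(object@behaviorCoupling >= 0 && object@behaviorCoupling < 1,
      "behaviorCoupling must be in [0,1)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RoiTimeSeries
# ---------------------------------------------------------------------------

#' One subject's denoised ROI time series
#'
#' Frames x ROIs signal matrix with run boundaries, a per-frame motion-outlier
#' mask and a framewise-displacement (mm) series. Runs are separate
#' acquisitions: they are disjoint, ordered and cover all frames; sliding
#' windows never span a run boundary.
#'
#' @slot subject subject identifier
#' @slot group group label ("control" or "case")
#' @slot signal numeric matrix, frames x ROIs, column names = ROI ids
#' @slot runBoundaries data.frame with columns run, start, end (1-based,
#'   inclusive)
#' @slot outlierMask logical per frame
#' @slot fwd framewise displacement in mm per frame
#' @export
setClass("RoiTimeSeries",
  representation(
    subject = "character", group = "character", signal = "matrix",
    runBoundaries = "data.frame", outlierMask = "logical", fwd = "numeric"
  )
)

setValidity("RoiTimeSeries", function(object) {
  n <- nrow(object@signal)
  rb <- object@runBoundaries
  msg <- character()
  if (!all(c("run", "start", "end") %in% names(rb)))
    msg <- c(msg, "runBoundaries needs columns run, start, end")
  else {
    if (nrow(rb) && rb$start[1] != 1L) msg <- c(msg, "first run must start at frame 1")
    if (nrow(rb) && rb$end[nrow(rb)] != n) msg <- c(msg, "last run must end at the last frame")
    if (nrow(rb) > 1 && any(rb$start[-1] != rb$end[-nrow(rb)] + 1L))
      msg <- c(msg, "runs must be disjoint, ordered and cover all frames")
  }
  if (length(object@outlierMask) != n) msg <- c(msg, "outlierMask length != frame count")
  if (length(object@fwd) != n) msg <- c(msg, "fwd length != frame count")
  if (anyNA(object@signal)) msg <- c(msg, "signal contains missing values")
  if (is.null(colnames(object@signal))) msg <- c(msg, "signal must carry ROI ids as colnames")
  if (length(msg)) msg else TRUE
})

#' @describeIn RoiTimeSeries ROI identifiers
#' @param object a RoiTimeSeries
#' @export
setMethod("roiIds", "RoiTimeSeries", function(object, ...) colnames(object@signal))

setMethod("show", "RoiTimeSeries", function(object) {
  cat("RoiTimeSeries: subject", object@subject, sprintf("(%s)", object@group), "\n",
      " ", nrow(object@signal), "frames x", ncol(object@signal), "ROIs in",
      nrow(object@runBoundaries), "run(s);",
      sum(object@outlierMask), "outlier frames\n")
})

# ---------------------------------------------------------------------------
# WindowSet
# ---------------------------------------------------------------------------

#' Sliding-window correlation matrices with motion annotations
#'
#' One correlation matrix per sliding window plus per-window metadata
#' (subject, run, start frame, motion-outlier frame count, motion-window flag,
#' mean framewise displacement). A window is a motion window iff it contains
#' at least one motion-outlier frame.
#'
#' @slot meta data.frame, one row per window: subject, group, run, start,
#'   outlierFrames, isMotionWindow, meanFwd
#' @slot corr numeric array ROIs x ROIs x windows
#' @slot roiIds ROI identifiers
#' @slot width window width in frames
#' @export
setClass("WindowSet",
  representation(meta = "data.frame", corr = "array", roiIds = "character",
                 width = "integer")
)

setValidity("WindowSet", function(object) {
  msg <- character()
  need <- c("subject", "group", "run", "start", "outlierFrames",
            "isMotionWindow", "meanFwd")
  if (!all(need %in% names(object@meta)))
    msg <- c(msg, paste("meta needs columns:", paste(need, collapse = ", ")))
  if (length(dim(object@corr)) != 3L ||
      dim(object@corr)[3] != nrow(object@meta))
    msg <- c(msg, "corr must be ROIs x ROIs x nrow(meta)")
  if (dim(object@corr)[1] != length(object@roiIds))
    msg <- c(msg, "corr dimension does not match roiIds")
  if (all(c("outlierFrames", "isMotionWindow") %in% names(object@meta)) &&
      nrow(object@meta) &&
      !identical(object@meta$isMotionWindow, object@meta$outlierFrames >= 1L))
    msg <- c(msg, "isMotionWindow must equal (outlierFrames >= 1)")
  if (length(msg)) msg else TRUE
})

#' @describeIn WindowSet per-window metadata
#' @param object a WindowSet
#' @export
setMethod("windowMeta", "WindowSet", function(object, ...) object@meta)

#' @describeIn WindowSet ROI identifiers
#' @export
setMethod("roiIds", "WindowSet", function(object, ...) object@roiIds)

setMethod("show", "WindowSet", function(object) {
  cat("WindowSet:", nrow(object@meta), "windows of width", object@width,
      "frames,", length(object@roiIds), "ROIs\n",
      " motion windows:", sum(object@meta$isMotionWindow), "\n")
})

# ---------------------------------------------------------------------------
# StrengthTable
# ---------------------------------------------------------------------------

#' Windows x ROIs positive-strength table
#'
#' Raw positive node strength per window and ROI, and its control-referenced
#' z-scored variant: each ROI column is standardised by the mean and
#' (population, divisor N) SD of that ROI's strength over the control-group
#' windows, applied to all windows of both groups.
#'
#' @slot meta per-window metadata (as in \linkS4class{WindowSet})
#' @slot raw windows x ROIs matrix of positive strengths
#' @slot z control-referenced z-scores (same shape; may be empty before
#'   \code{\link{zscoreStrengths}})
#' @slot refStats data.frame roi, mean, sd over the control reference windows
#' @export
setClass("StrengthTable",
  representation(meta = "data.frame", raw = "matrix", z = "matrix",
                 refStats = "data.frame")
)

setValidity("StrengthTable", function(object) {
  msg <- character()
  if (nrow(object@raw) != nrow(object@meta))
    msg <- c(msg, "raw rows must match meta rows")
  if (any(object@raw < 0)) msg <- c(msg, "raw strengths must be >= 0")
  if (nrow(object@z) && !identical(dim(object@z), dim(object@raw)))
    msg <- c(msg, "z must have the shape of raw")
  if (length(msg)) msg else TRUE
})

#' @describeIn StrengthTable per-window metadata
#' @param object a StrengthTable
#' @export
setMethod("windowMeta", "StrengthTable", function(object, ...) object@meta)

#' @describeIn StrengthTable raw positive strengths
#' @export
setMethod("strengthRaw", "StrengthTable", function(object, ...) object@raw)

#' @describeIn StrengthTable control-referenced z-scores
#' @export
setMethod("strengthZ", "StrengthTable", function(object, ...) {
  if (!nrow(object@z)) stop("z-scores not computed yet; run zscoreStrengths()")
  object@z
})

#' @describeIn StrengthTable per-ROI reference mean/SD over control windows
#' @export
setMethod("referenceStats", "StrengthTable", function(object, ...) object@refStats)

#' @describeIn StrengthTable ROI identifiers
#' @export
setMethod("roiIds", "StrengthTable", function(object, ...) colnames(object@raw))

setMethod("show", "StrengthTable", function(object) {
  cat("StrengthTable:", nrow(object@raw), "windows x", ncol(object@raw),
      "ROIs;", if (nrow(object@z)) "z-scored" else "raw only", "\n")
})

# ---------------------------------------------------------------------------
# ModulePartition
# ---------------------------------------------------------------------------

#' Modularity partition of the ROI graph
#'
#' ROI -> module assignment from modularity maximisation on the positive part
#' of a (mean) correlation matrix, with the modularity Q of the best restart.
#'
#' @slot membership named integer vector, ROI id -> module (1..K)
#' @slot Q modularity of the returned partition
#' @slot gamma resolution parameter
#' @slot nIter number of randomized restarts evaluated
#' @export
setClass("ModulePartition",
  representation(membership = "integer", Q = "numeric", gamma = "numeric",
                 nIter = "integer")
)

setValidity("ModulePartition", function(object) {
  m <- object@membership
  if (is.null(names(m))) return("membership must be named by ROI id")
  if (anyNA(m) || any(m < 1L)) return("module labels must be positive integers")
  if (!setequal(unique(m), seq_len(max(m)))) return("module labels must be 1..K")
  TRUE
})

#' @describeIn ModulePartition ROI -> module assignment
#' @param object a ModulePartition
#' @export
setMethod("membership", "ModulePartition", function(object, ...) object@membership)

setMethod("show", "ModulePartition", function(object) {
  cat("ModulePartition:", max(object@membership), "modules over",
      length(object@membership), "ROIs; Q =", format(object@Q, digits = 4),
      sprintf("(gamma = %g, %d restarts)\n", object@gamma, object@nIter))
})

# ---------------------------------------------------------------------------
# StateAssignment
# ---------------------------------------------------------------------------

#' Window-to-state assignment with motion bookkeeping
#'
#' Per-window state labels from Ward clustering of module-averaged z-scores,
#' cluster-level motion classification (a cluster averaging more than 2
#' motion-outlier frames per window is a motion cluster and is dropped
#' wholesale), and per-subject usable-window accounting with the exclusion
#' flag (fewer usable windows than the threshold).
#'
#' @slot meta per-window metadata plus a \code{state} column
#' @slot clusterSummary data.frame: state, nWindows, meanOutliers, meanFwd,
#'   isMotionCluster
#' @slot subjectSummary data.frame: subject, group, totalWindows,
#'   motionClusterWindows, motionWindows, usableWindows, excluded
#' @slot k number of clusters the dendrogram was cut at
#' @slot details list with clustering internals (CCC curve, subsample size,
#'   centroids) for audit
#' @export
setClass("StateAssignment",
  representation(meta = "data.frame", clusterSummary = "data.frame",
                 subjectSummary = "data.frame", k = "integer",
                 details = "list")
)

setValidity("StateAssignment", function(object) {
  msg <- character()
  if (!"state" %in% names(object@meta)) msg <- c(msg, "meta needs a state column")
  else if (nrow(object@meta) &&
           (any(object@meta$state < 1L) || any(object@meta$state > object@k)))
    msg <- c(msg, "state labels must lie in 1..k")
  if (length(msg)) msg else TRUE
})

#' @describeIn StateAssignment per-window metadata with state labels
#' @param object a StateAssignment
#' @export
setMethod("windowMeta", "StateAssignment", function(object, ...) object@meta)

#' @describeIn StateAssignment per-window state labels
#' @export
setMethod("stateLabels", "StateAssignment", function(object, ...) object@meta$state)

#' @describeIn StateAssignment per-state window counts and motion summary
#' @export
setMethod("clusterSummary", "StateAssignment", function(object, ...) object@clusterSummary)

#' @describeIn StateAssignment per-subject usable windows and exclusion flags
#' @export
setMethod("subjectSummary", "StateAssignment", function(object, ...) object@subjectSummary)

setMethod("show", "StateAssignment", function(object) {
  cs <- object@clusterSummary
  cat("StateAssignment:", nrow(object@meta), "windows in", object@k, "states;",
      sum(cs$isMotionCluster), "motion cluster(s);",
      sum(object@subjectSummary$excluded), "subject(s) excluded\n")
})
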