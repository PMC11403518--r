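#' @include AllClasses.R
NULL

#' Ward hierarchical clustering of window features
#'
#' Agglomerative Ward (minimum-variance) linkage on Euclidean distances,
#' cut to k clusters. Labels are returned in first-appearance order so that
#' repeated runs on the same data are deterministic.
#'
#' @param features windows x K numeric matrix (no missing values)
#' @param k number of clusters, 1 <= k <= nrow(features)
#' @return integer vector of cluster labels in 1..k
#' @export
wardCluster <- function(features, k) {
  features <- as.matrix(features)
  if (anyNA(features)) stop("features contain missing values")
  k <- as.integer(k)
  if (k < 1L || k > nrow(features)) stop("k must be in 1..n_windows")
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  canonicalLabels(stats::cutree(hc, k = k))
}

# R^2 (between-cluster share of total sum of squares) for a labeling.
clusterR2 <- function(features, labels) {
  tot <- sum(scale(features, scale = FALSE)^2)
  if (tot == 0) stop("features have zero total variance")
  within <- 0
  for (g in unique(labels)) {
    xg <- features[labels == g, , drop = FALSE]
    within <- within + sum(scale(xg, scale = FALSE)^2)
  }
  1 - within / tot
}

# Sarle's cubic clustering criterion for one (n, q, R^2) against the
# uniform-hypercube null. `sv` are the singular-value-based SDs (sqrt of
# covariance eigenvalues) of the feature matrix, zero eigenvalues removed.
cccStatistic <- function(n, sv, q, r2) {
  p <- length(sv)
  pstar <- 1L
  cstar <- sv[1] / q
  for (j in seq.int(min(p, q - 1L), 1L)) {
    cj <- (prod(sv[seq_len(j)]) / q)^(1 / j)
    if (sv[j] / cj >= 1) { pstar <- j; cstar <- cj; break }
  }
  u <- sv / cstar
  num <- sum(1 / (n + u[seq_len(pstar)]))
  if (pstar < p) num <- num + sum(u[(pstar + 1L):p]^2 / (n + u[(pstar + 1L):p]))
  er2 <- 1 - (num / sum(u^2)) * ((n - q)^2 / n) * (1 + 4 / n)
  if (r2 >= 1 || er2 >= 1) return(-Inf)
  log((1 - er2) / (1 - r2)) * sqrt(n * pstar / 2) / ((0.001 + er2)^1.2)
}

#' Choose the number of states by the cubic clustering criterion
#'
#' Computes Ward linkage once, evaluates Sarle's cubic clustering criterion
#' (observed R-squared against the uniform-hypercube null) at every k of the
#' range, and returns the k at the highest positive CCC peak. When no positive
#' peak exists, the largest local maximum of the curve is used; failing that,
#' \code{fallbackK} (logged via a message in both fallback cases).
#'
#' @param features windows x K numeric matrix
#' @param kRange candidate cluster counts (within 2..n-1)
#' @param fallbackK k to use when the curve is monotone with no local maximum
#' @return list with elements \code{k}, \code{curve} (data.frame k, r2, ccc)
#'   and \code{fallback} (logical)
#' @export
chooseKCCC <- function(features, kRange = 2:15, fallbackK = min(kRange)) {
  features <- as.matrix(features)
  n <- nrow(features)
  kRange <- sort(unique(as.integer(kRange)))
  if (min(kRange) < 2L || max(kRange) > n - 1L)
    stop("kRange must lie within [2, n_windows - 1]")
  ev <- eigen(stats::cov(features), symmetric = TRUE, only.values = TRUE)$values
  ev <- ev[ev > max(ev) * 1e-12]
  if (!length(ev)) stop("features have zero variance")
  sv <- sqrt(ev)
  hc <- stats::hclust(stats::dist(features), method = "ward.D2")
  cuts <- stats::cutree(hc, k = kRange)
  if (length(kRange) == 1L) cuts <- matrix(cuts, ncol = 1L)
  r2 <- vapply(seq_along(kRange), function(i)
    clusterR2(features, cuts[, i]), numeric(1))
  ccc <- vapply(seq_along(kRange), function(i)
    cccStatistic(n, sv, kRange[i], r2[i]), numeric(1))
  curve <- data.frame(k = kRange, r2 = r2, ccc = ccc)
  # local maxima (boundary points count with one-sided comparison)
  left <- c(-Inf, ccc[-length(ccc)])
  right <- c(ccc[-1], -Inf)
  peaks <- which(ccc > left & ccc > right)
  fallback <- FALSE
  if (length(peaks) && any(ccc[peaks] > 0)) {
    pos <- peaks[ccc[peaks] > 0]
    k <- kRange[pos[which.max(ccc[pos])]]
  } else if (length(peaks)) {
    k <- kRange[max(peaks)]
    fallback <- TRUE
    message("no positive CCC peak; using largest local maximum k = ", k)
  } else {
    k <- fallbackK
    fallback <- TRUE
    message("CCC curve is monotone; falling back to k = ", k)
  }
  list(k = k, curve = curve, fallback = fallback)
}

#' Cluster all windows into states
#'
#' State identification on the pooled (all-subjects) feature matrix. For
#' tractability the Ward linkage is computed on at most
#' \code{maxLinkageWindows} windows (an evenly spaced deterministic
#' subsample); every window is then assigned to the nearest cluster centroid.
#' With fewer windows than the cap, labels come directly from the dendrogram
#' cut. k is chosen by \code{\link{chooseKCCC}} unless given.
#'
#' @param meta per-window metadata (as from \code{\link{windowMeta}})
#' @param features pooled windows x K module-averaged z-score matrix
#' @param k fixed number of states, or NULL to select via CCC
#' @param kRange candidate k for CCC selection
#' @param maxLinkageWindows cap on the linkage problem size
#' @return a \linkS4class{StateAssignment} (motion clusters and exclusions not
#'   yet applied; see \code{\link{classifyMotionClusters}} and
#'   \code{\link{applySubjectExclusion}})
#' @export
clusterWindows <- function(meta, features, k = NULL, kRange = 2:15,
                           maxLinkageWindows = 6000L) {
  features <- as.matrix(features)
  n <- nrow(features)
  stopifnot(nrow(meta) == n)
  sub <- if (n > maxLinkageWindows)
    unique(round(seq(1, n, length.out = maxLinkageWindows))) else seq_len(n)
  fsub <- features[sub, , drop = FALSE]
  cccOut <- NULL
  if (is.null(k)) {
    cccOut <- chooseKCCC(fsub, kRange = kRange)
    k <- cccOut$k
  }
  subLabels <- wardCluster(fsub, k)
  centroids <- vapply(seq_len(k), function(g)
    colMeans(fsub[subLabels == g, , drop = FALSE]), numeric(ncol(features)))
  centroids <- t(centroids)
  if (length(sub) < n) {
    d2 <- outer(rowSums(features^2), rowSums(centroids^2), "+") -
      2 * features %*% t(centroids)
    labels <- max.col(-d2, ties.method = "first")
  } else labels <- subLabels
  labels <- canonicalLabels(labels)
  k <- max(labels)
  meta$state <- labels
  cs <- clusterStats(meta)
  methods::new("StateAssignment", meta = meta, clusterSummary = cs,
               subjectSummary = data.frame(), k = as.integer(k),
               details = list(ccc = cccOut, subsample = sub,
                              centroids = centroids))
}

# per-state window counts and motion summaries
clusterStats <- function(meta) {
  ag <- function(v) tapply(v, meta$state, mean)
  states <- sort(unique(meta$state))
  data.frame(state = states,
             nWindows = as.integer(table(factor(meta$state, levels = states))),
             meanOutliers = as.numeric(ag(meta$outlierFrames)),
             meanFwd = as.numeric(ag(meta$meanFwd)),
             isMotionCluster = FALSE,
             row.names = NULL)
}

#' Flag motion clusters
#'
#' A cluster averaging strictly more than \code{threshold} motion-outlier
#' frames per window is a motion cluster; its windows are removed from all
#' downstream analysis.
#'
#' @param assignment a \linkS4class{StateAssignment}
#' @param threshold mean outlier frames per window above which a cluster is a
#'   motion cluster (strict inequality; default 2)
#' @return the assignment with cluster flags and per-subject usable-window
#'   accounting filled in
#' @export
classifyMotionClusters <- function(assignment, threshold = 2) {
  cs <- clusterStats(assignment@meta)
  cs$isMotionCluster <- cs$meanOutliers > threshold
  assignment@clusterSummary <- cs
  meta <- assignment@meta
  inMotionCluster <- meta$state %in% cs$state[cs$isMotionCluster]
  subjects <- unique(meta$subject)
  ss <- do.call(rbind, lapply(subjects, function(s) {
    i <- meta$subject == s
    mc <- sum(i & inMotionCluster)
    mw <- sum(i & !inMotionCluster & meta$isMotionWindow)
    data.frame(subject = s, group = meta$group[i][1],
               totalWindows = sum(i), motionClusterWindows = mc,
               motionWindows = mw, usableWindows = sum(i) - mc - mw,
               excluded = FALSE, stringsAsFactors = FALSE)
  }))
  assignment@subjectSummary <- ss
  assignment
}

#' Exclude subjects with too few usable windows
#'
#' A subject with strictly fewer usable (non-motion-window, non-motion-cluster)
#' windows than \code{minWindows} is marked excluded. The reference threshold
#' of 1200 corresponds to runs of ~726 windows x 2; for other run lengths use
#' \code{proportionalMinWindows}.
#'
#' @param assignment a \linkS4class{StateAssignment} after
#'   \code{\link{classifyMotionClusters}}
#' @param minWindows exclusion threshold (strict "fewer than")
#' @return the assignment with exclusion flags set
#' @export
applySubjectExclusion <- function(assignment, minWindows = 1200L) {
  ss <- assignment@subjectSummary
  if (!nrow(ss)) stop("run classifyMotionClusters() first")
  ss$excluded <- ss$usableWindows < minWindows
  if (all(ss$excluded)) stop("all subjects excluded at minWindows = ", minWindows)
  assignment@subjectSummary <- ss
  assignment
}

#' Proportional subject-exclusion threshold
#'
#' Scales the reference threshold (1200 usable windows out of 2 x 726) to a
#' cohort's actual per-subject window count.
#'
#' @param totalWindowsPerSubject windows per subject before any exclusion
#' @return integer threshold
#' @export
proportionalMinWindows <- function(totalWindowsPerSubject) {
  as.integer(round(1200 / (2 * 726) * totalWindowsPerSubject))
}

#' Per-subject state dwell times
#'
#' Dwell time of a state in a subject = number of that subject's non-motion
#' windows (in non-motion clusters) assigned to the state. Because windows
#' overlap (step 1), frames are counted by several windows; this is the
#' standard sliding-window dwell definition and is kept un-normalised.
#'
#' @param assignment a \linkS4class{StateAssignment} after
#'   \code{\link{classifyMotionClusters}}
#' @return list with \code{dwell} (long data.frame subject, group, state,
#'   dwell; all subject x non-motion-state combinations present) and
#'   \code{subjectsWithState} (named list: state -> subjects with dwell > 0)
#' @export
dwellTimes <- function(assignment) {
  if (!nrow(assignment@subjectSummary)) stop("run classifyMotionClusters() first")
  meta <- assignment@meta
  cs <- assignment@clusterSummary
  keepStates <- cs$state[!cs$isMotionCluster]
  use <- !meta$isMotionWindow & meta$state %in% keepStates
  subjects <- unique(meta$subject)
  grp <- stats::setNames(assignment@subjectSummary$group,
                         assignment@subjectSummary$subject)
  tab <- table(factor(meta$subject[use], levels = subjects),
               factor(meta$state[use], levels = keepStates))
  dwell <- data.frame(
    subject = rep(subjects, times = length(keepStates)),
    group = grp[rep(subjects, times = length(keepStates))],
    state = rep(keepStates, each = length(subjects)),
    dwell = as.integer(tab),
    row.names = NULL, stringsAsFactors = FALSE)
  sws <- lapply(stats::setNames(keepStates, paste0("state", keepStates)),
                function(s) dwell$subject[dwell$state == s & dwell$dwell > 0])
  list(dwell = dwell, subjectsWithState = sws)
}
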