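#' @include AllClasses.R
NULL

#' Population state profiles and hub ROIs
#'
#' For each retained (non-motion) state: the per-ROI mean raw positive
#' strength over the state's non-motion windows pooled across subjects, and
#' the hub set — ROIs strictly above the state's own linearly interpolated
#' strength percentile (default 90th, i.e. roughly the top 10% of ROIs).
#'
#' @param st a \linkS4class{StrengthTable} (raw strengths are used)
#' @param assignment a \linkS4class{StateAssignment} after
#'   \code{\link{classifyMotionClusters}}
#' @param percentile hub threshold percentile in [0, 100)
#' @return named list (state<s>) of lists with elements \code{profile} (named
#'   per-ROI mean strength), \code{threshold} and \code{hubs}
#' @export
stateProfileAndHubs <- function(st, assignment, percentile = 90) {
  stopifnot(nrow(st@meta) == nrow(assignment@meta))
  cs <- assignment@clusterSummary
  keepStates <- cs$state[!cs$isMotionCluster]
  meta <- assignment@meta
  usable <- vapply(keepStates, function(s)
    any(meta$state == s & !meta$isMotionWindow), logical(1))
  if (any(!usable))
    message("state(s) ", paste(keepStates[!usable], collapse = ", "),
            " have no non-motion windows and are not profiled")
  keepStates <- keepStates[usable]
  out <- lapply(keepStates, function(s) {
    idx <- meta$state == s & !meta$isMotionWindow
    profile <- colMeans(st@raw[idx, , drop = FALSE])
    thr <- as.numeric(stats::quantile(profile, percentile / 100, type = 7))
    list(profile = profile, threshold = thr,
         hubs = names(profile)[profile > thr])
  })
  stats::setNames(out, paste0("state", keepStates))
}

#' Representation index of same-state windows
#'
#' For one subject's windows assigned to one state: Euclidean distance between
#' the upper-triangle-vectorised correlation matrices of every window pair;
#' the representation index RI of a window is its mean distance to all other
#' windows. The minimum-RI window best represents the state in that subject
#' (a single window gets RI 0; ties go to the earliest window).
#'
#' @param corrMats list of ROI x ROI correlation matrices (>= 1)
#' @return list with \code{ri} (numeric per window) and \code{best} (index of
#'   the representative window)
#' @export
representationIndex <- function(corrMats) {
  n <- length(corrMats)
  if (n < 1L) stop("at least one window required")
  if (n == 1L) return(list(ri = 0, best = 1L))
  v <- t(vapply(corrMats, upperTriVec, numeric(length(upperTriVec(corrMats[[1]])))))
  d <- as.matrix(stats::dist(v))
  ri <- unname(rowSums(d) / (n - 1))
  list(ri = ri, best = which.min(ri))
}

#' Representative window per subject and state
#'
#' Applies \code{\link{representationIndex}} to every (subject, state) pair
#' over the subject's non-motion windows of that (non-motion-cluster) state;
#' excluded subjects are skipped.
#'
#' @param assignment a \linkS4class{StateAssignment} after
#'   \code{\link{classifyMotionClusters}} (and, typically,
#'   \code{\link{applySubjectExclusion}})
#' @param windowSets named list of \linkS4class{WindowSet}, one per subject,
#'   whose window order matches the assignment's metadata
#' @return data.frame subject, group, state, window (row index into the
#'   subject's WindowSet), ri
#' @export
representativeWindows <- function(assignment, windowSets) {
  meta <- assignment@meta
  cs <- assignment@clusterSummary
  ss <- assignment@subjectSummary
  keepStates <- cs$state[!cs$isMotionCluster]
  keepSubjects <- ss$subject[!(ss$excluded %||% FALSE)]
  rows <- list()
  for (s in keepSubjects) {
    ws <- windowSets[[s]]
    if (is.null(ws)) stop("no WindowSet for subject ", s)
    subIdx <- which(meta$subject == s)
    if (length(subIdx) != nrow(ws@meta) ||
        !identical(meta$start[subIdx], ws@meta$start))
      stop("window order mismatch between assignment and WindowSet of ", s)
    for (st in keepStates) {
      local <- which(meta$state[subIdx] == st & !meta$isMotionWindow[subIdx])
      if (!length(local)) next
      riOut <- representationIndex(lapply(local, windowCorrMatrix, ws = ws))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, group = meta$group[subIdx][1], state = st,
        window = local[riOut$best], ri = riOut$ri[riOut$best],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Connectivity metrics of one representative window
#'
#' Global strength, within-network positive strength for each (nested) network
#' tier, and — when a significant-ROI set is supplied — the cross-set strength
#' between those ROIs (hubs removed) and the state's hub set.
#'
#' @param corr the representative window's ROI x ROI correlation matrix
#' @param networks list with a \code{tiers} element: named list of ROI id sets
#' @param hubSet the state's hub ROI ids (optional, needed for the cross term)
#' @param sigSet ROIs with significant group differences (optional)
#' @return one-row data.frame: global, within.<tier>..., and hubCross when
#'   computable
#' @export
subjectStateConnectivity <- function(corr, networks, hubSet = NULL,
                                     sigSet = NULL) {
  out <- data.frame(global = globalStrength(corr))
  for (tier in names(networks$tiers))
    out[[paste0("within.", tier)]] <- withinSetStrength(corr, networks$tiers[[tier]])
  if (!is.null(sigSet) && !is.null(hubSet)) {
    nonHub <- setdiff(sigSet, hubSet)
    if (!length(nonHub))
      stop("significant set is contained in the hub set; cross-set strength undefined")
    out$hubCross <- crossSetStrength(corr, nonHub, hubSet)
  }
  out
}
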