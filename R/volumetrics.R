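#' @include AllClasses.R
NULL

#' Network volume composites
#'
#' Per-subject unweighted mean of ROI-level Jacobian-determinant values over
#' each nested network tier (e.g. brainstem; brainstem+forebrain;
#' brainstem+forebrain+cortical).
#'
#' @param volumes subject x ROI numeric matrix (ROI ids as colnames)
#' @param networks list with a \code{tiers} element: named list of ROI id sets
#' @return data.frame with subject and one composite column per tier
#' @export
networkComposites <- function(volumes, networks) {
  out <- data.frame(subject = rownames(volumes), stringsAsFactors = FALSE)
  for (tier in names(networks$tiers)) {
    set <- networks$tiers[[tier]]
    miss <- setdiff(set, colnames(volumes))
    if (length(miss))
      stop("network tier '", tier, "' has ROI(s) missing from the volume table: ",
           paste(miss, collapse = ", "))
    out[[tier]] <- rowMeans(volumes[, set, drop = FALSE])
  }
  out
}

#' Volumetric group comparisons and associations
#'
#' Two-tailed Welch tests on every network composite (case vs control);
#' one-tailed (negative direction, atrophy hypothesis) Kendall tau-b of each
#' composite against each behavioral measure, BH-FDR corrected per table; and
#' one-tailed (negative) Kendall tau-b of each composite against per-state
#' dwell times. Associations with a constant variable are flagged
#' not-testable rather than computed.
#'
#' @param composites data.frame from \code{\link{networkComposites}}
#' @param groups named group vector (subject -> "control"/"case")
#' @param behavior data.frame with subject plus numeric measure columns
#' @param dwell optional long dwell data.frame (subject, state, dwell)
#' @param q FDR level for the association table
#' @return list: \code{groupTests} (per-composite Welch), \code{associations}
#'   (composite x measure tau/p with FDR), \code{dwellAssociations} (composite
#'   x state) or NULL
#' @export
volumetricAnalysis <- function(composites, groups, behavior, dwell = NULL,
                               q = 0.05) {
  tiers <- setdiff(names(composites), "subject")
  subj <- composites$subject
  if (!all(subj %in% names(groups))) stop("composites/groups subjects misaligned")
  g <- groups[subj]
  groupTests <- do.call(rbind, lapply(tiers, function(tier) {
    w <- welchTest(composites[[tier]][g == "control"],
                   composites[[tier]][g == "case"], tails = "two")
    cbind(data.frame(composite = tier, stringsAsFactors = FALSE), w)
  }))

  if (!all(subj %in% behavior$subject)) stop("behavior subjects misaligned")
  bidx <- match(subj, behavior$subject)
  measures <- names(behavior)[vapply(behavior, is.numeric, logical(1))]
  assoc <- list()
  for (m in measures) for (tier in tiers) {
    res <- tryCatch(
      kendallTauB(composites[[tier]], behavior[[m]][bidx], side = "less"),
      error = function(e) NULL)
    assoc[[length(assoc) + 1L]] <- data.frame(
      measure = m, composite = tier,
      tau = if (is.null(res)) NA_real_ else res$tau,
      p = if (is.null(res)) NA_real_ else res$p,
      testable = !is.null(res), stringsAsFactors = FALSE)
  }
  associations <- do.call(rbind, assoc)
  ok <- associations$testable
  if (any(ok)) {
    fdr <- bhFdr(associations$p[ok], q = q)
    associations$pAdjusted <- NA_real_
    associations$pAdjusted[ok] <- fdr$adjusted
    associations$sigFdr <- FALSE
    associations$sigFdr[ok] <- fdr$reject
  }

  dwellAssociations <- NULL
  if (!is.null(dwell)) {
    rows <- list()
    for (s in sort(unique(dwell$state))) {
      ds <- dwell[dwell$state == s, ]
      didx <- match(subj, ds$subject)
      for (tier in tiers) {
        res <- tryCatch(
          kendallTauB(composites[[tier]], ds$dwell[didx], side = "less"),
          error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          state = s, composite = tier,
          tau = if (is.null(res)) NA_real_ else res$tau,
          p = if (is.null(res)) NA_real_ else res$p,
          testable = !is.null(res), stringsAsFactors = FALSE)
      }
    }
    dwellAssociations <- do.call(rbind, rows)
  }
  list(groupTests = groupTests, associations = associations,
       dwellAssociations = dwellAssociations)
}
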