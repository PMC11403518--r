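#' @include AllClasses.R
NULL

checkCorrMatrix <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("correlation matrix must be square")
  if (max(abs(corr - t(corr))) > 1e-8) stop("correlation matrix must be symmetric")
  invisible(corr)
}

#' Positive node strength
#'
#' Per-ROI sum of positive off-diagonal correlations; negative edges are
#' discarded (not absolute-valued).
#'
#' @param corr symmetric ROI x ROI correlation matrix with unit diagonal
#' @return numeric vector, one non-negative strength per ROI
#' @examples
#' m <- matrix(c(1, .5, -.3, .5, 1, .2, -.3, .2, 1), 3, 3)
#' positiveStrength(m)  # 0.5 0.7 0.2
#' @export
positiveStrength <- function(corr) {
  checkCorrMatrix(corr)
  pos <- pmax(corr, 0)
  diag(pos) <- 0
  rowSums(pos)
}

#' Global strength
#'
#' Mean positive strength over all ROIs of one window's correlation matrix.
#'
#' @inheritParams positiveStrength
#' @return numeric scalar
#' @export
globalStrength <- function(corr) mean(positiveStrength(corr))

#' Positive-strength table of a window set
#'
#' @param ws a \linkS4class{WindowSet}
#' @return a \linkS4class{StrengthTable} with the raw slot filled
#' @export
strengthTable <- function(ws) {
  n <- dim(ws@corr)[3]
  pos <- pmax(ws@corr, 0)
  for (j in seq_len(dim(pos)[1])) pos[j, j, ] <- 0
  raw <- t(apply(pos, 3, rowSums))
  if (n == 1L) raw <- matrix(raw, nrow = 1L)
  colnames(raw) <- ws@roiIds
  methods::new("StrengthTable", meta = ws@meta, raw = raw,
               z = matrix(numeric(0), 0, 0), refStats = data.frame())
}

#' Concatenate strength tables across subjects
#'
#' @param tables list of \linkS4class{StrengthTable} with identical ROI columns
#' @return one \linkS4class{StrengthTable}
#' @export
concatStrengthTables <- function(tables) {
  stopifnot(length(tables) >= 1L)
  ids <- colnames(tables[[1]]@raw)
  for (t in tables)
    if (!identical(colnames(t@raw), ids)) stop("ROI columns differ across tables")
  methods::new("StrengthTable",
               meta = do.call(rbind, lapply(tables, function(t) t@meta)),
               raw = do.call(rbind, lapply(tables, function(t) t@raw)),
               z = matrix(numeric(0), 0, 0), refStats = data.frame())
}

#' Control-referenced z-scoring of strengths
#'
#' Standardises every ROI column of the raw strength table by the mean and
#' population SD (divisor N) of that ROI's strength over the control-group
#' reference windows; the transform is applied to all windows of both groups.
#'
#' @param st a \linkS4class{StrengthTable}
#' @param controlIdx logical or integer index of the reference windows;
#'   defaults to all windows whose group is "control"
#' @return the table with the z slot and reference stats filled
#' @export
zscoreStrengths <- function(st, controlIdx = st@meta$group == "control") {
  ref <- st@raw[controlIdx, , drop = FALSE]
  if (!nrow(ref)) stop("control reference window set is empty")
  mu <- colMeans(ref)
  n <- nrow(ref)
  sdv <- sqrt(colSums(sweep(ref, 2, mu)^2) / n)
  if (any(sdv == 0))
    stop("zero control SD for ROI(s): ",
         paste(colnames(st@raw)[sdv == 0], collapse = ", "))
  z <- sweep(sweep(st@raw, 2, mu), 2, sdv, "/")
  st@z <- z
  st@refStats <- data.frame(roi = colnames(st@raw), mean = mu, sd = sdv,
                            row.names = NULL, stringsAsFactors = FALSE)
  st
}

#' Modularity partition of the mean connectivity graph
#'
#' Modularity maximisation on the positive part of a (mean) correlation
#' matrix: \code{nIter} randomized Louvain restarts at resolution \code{gamma}
#' under the Newman null model; the partition with the highest Q is returned
#' (ties broken toward the lexicographically smallest first-appearance
#' labeling, for determinism).
#'
#' @param meanCorr symmetric ROI x ROI matrix; negative entries are dropped
#' @param gamma resolution parameter (1 = standard modularity)
#' @param nIter number of randomized restarts
#' @param seed RNG seed for the restart streams
#' @return a \linkS4class{ModulePartition}
#' @export
modularityPartition <- function(meanCorr, gamma = 1, nIter = 1000L, seed = 1L) {
  checkCorrMatrix(meanCorr)
  ids <- colnames(meanCorr) %||% sprintf("roi%03d", seq_len(ncol(meanCorr)))
  w <- pmax(meanCorr, 0)
  diag(w) <- 0
  if (all(w == 0)) stop("positive-weight graph is empty")
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE)
  bestQ <- -Inf; bestLab <- NULL
  for (i in seq_len(nIter)) {
    set.seed(deriveSeed(seed, i))
    cl <- igraph::cluster_louvain(g, resolution = gamma)
    memb <- igraph::membership(cl)
    q <- igraph::modularity(g, memb, resolution = gamma)
    lab <- canonicalLabels(as.integer(memb))
    if (q > bestQ + 1e-12 ||
        (abs(q - bestQ) <= 1e-12 && !is.null(bestLab) &&
         isTRUE(vecLess(lab, bestLab)))) {
      bestQ <- q; bestLab <- lab
    }
  }
  methods::new("ModulePartition",
               membership = stats::setNames(as.integer(bestLab), ids),
               Q = bestQ, gamma = gamma, nIter = as.integer(nIter))
}

# lexicographic comparison of equal-length integer vectors
vecLess <- function(a, b) {
  d <- a - b
  i <- which(d != 0)
  length(i) > 0 && d[i[1]] < 0
}

#' Modularity Q of a given partition
#'
#' Newman modularity with resolution \code{gamma} on the positive part of the
#' matrix; used for audits and exhaustive-search cross-checks.
#'
#' @inheritParams modularityPartition
#' @param labels module label per ROI
#' @return numeric scalar
#' @export
modularityQ <- function(meanCorr, labels, gamma = 1) {
  w <- pmax(meanCorr, 0)
  diag(w) <- 0
  k <- rowSums(w)
  m2 <- sum(w)
  if (m2 == 0) stop("positive-weight graph is empty")
  same <- outer(labels, labels, "==")
  sum((w - gamma * tcrossprod(k) / m2) * same) / m2
}

#' Module-averaged features
#'
#' Averages z-scored ROI strengths over each module's ROIs, per window: the
#' data-reduction step ahead of state clustering.
#'
#' @param st a z-scored \linkS4class{StrengthTable} (or a plain windows x ROIs
#'   matrix)
#' @param partition a \linkS4class{ModulePartition} covering all ROI columns
#' @return windows x K numeric matrix, columns named module1..K
#' @export
moduleAverage <- function(st, partition) {
  z <- if (methods::is(st, "StrengthTable")) strengthZ(st) else as.matrix(st)
  memb <- membership(partition)
  if (!all(colnames(z) %in% names(memb)))
    stop("partition does not cover all ROI columns")
  memb <- memb[colnames(z)]
  k <- max(memb)
  out <- vapply(seq_len(k), function(m)
    rowMeans(z[, memb == m, drop = FALSE]), numeric(nrow(z)))
  if (nrow(z) == 1L) out <- matrix(out, nrow = 1L)
  colnames(out) <- paste0("module", seq_len(k))
  out
}

#' Within-network positive strength
#'
#' For each node of the ROI set, sum of positive correlations to the other
#' nodes of the set; returns the mean over the set. With the full ROI set this
#' equals \code{\link{globalStrength}}.
#'
#' @param corr ROI x ROI correlation matrix with ROI ids as dimnames
#' @param roiSet character vector of at least 2 ROI ids
#' @return numeric scalar
#' @export
withinSetStrength <- function(corr, roiSet) {
  if (length(roiSet) < 2L) stop("roiSet must contain at least 2 ROIs")
  miss <- setdiff(roiSet, rownames(corr))
  if (length(miss)) stop("unknown ROI id(s): ", paste(miss, collapse = ", "))
  sub <- corr[roiSet, roiSet, drop = FALSE]
  mean(positiveStrength(sub))
}

#' Cross-set positive strength
#'
#' For each node of set A, sum of positive correlations to the nodes of set B;
#' returns the mean over set A. ROIs present in both sets are removed from set
#' A first (so the pairs are disjoint); an empty set A after removal is an
#' error.
#'
#' @param corr ROI x ROI correlation matrix with ROI ids as dimnames
#' @param setA,setB character vectors of ROI ids
#' @return numeric scalar
#' @export
crossSetStrength <- function(corr, setA, setB) {
  miss <- setdiff(c(setA, setB), rownames(corr))
  if (length(miss)) stop("unknown ROI id(s): ", paste(miss, collapse = ", "))
  overlap <- intersect(setA, setB)
  if (length(overlap)) {
    message("removing ", length(overlap), " overlapping ROI(s) from set A")
    setA <- setdiff(setA, overlap)
  }
  if (!length(setA)) stop("set A is empty after overlap removal")
  if (!length(setB)) stop("set B is empty")
  sub <- pmax(corr[setA, setB, drop = FALSE], 0)
  mean(rowSums(sub))
}

#' Scrubbed stationary correlation matrix of one subject
#'
#' Pearson correlation over all non-outlier frames (runs pooled); the
#' per-subject input to the stationary module-detection step.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @return ROI x ROI correlation matrix
#' @export
scrubbedCorrelation <- function(ts) {
  keep <- !ts@outlierMask
  if (sum(keep) < 3L) stop("fewer than 3 non-outlier frames")
  stats::cor(ts@signal[keep, , drop = FALSE])
}
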