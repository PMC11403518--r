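#' @include AllClasses.R
NULL

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie adjusted Rand index; 1 for identical partitions (up to label
#' permutation), ~0 for independent ones.
#'
#' @param a,b label vectors of equal length
#' @return numeric scalar
#' @export
adjustedRandIndex <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  tab <- table(a, b)
  sn <- sum(choose(tab, 2))
  sa <- sum(choose(rowSums(tab), 2))
  sb <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(a), 2)
  expected <- sa * sb / n2
  denom <- (sa + sb) / 2 - expected
  if (denom == 0) return(1)
  (sn - expected) / denom
}

# Nearest-SPD repair by eigenvalue clipping, rescaled back to unit diagonal.
# Returns the matrix with attribute "repaired" = TRUE when clipping occurred.
nearestSPD <- function(m, epsEig = 1e-8) {
  e <- eigen(m, symmetric = TRUE)
  repaired <- FALSE
  if (min(e$values) <= epsEig) {
    vals <- pmax(e$values, epsEig)
    m <- e$vectors %*% (vals * t(e$vectors))
    m <- stats::cov2cor(m)
    m <- (m + t(m)) / 2
    repaired <- TRUE
    if (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("covariance not positive definite after nearest-SPD repair")
  }
  attr(m, "repaired") <- repaired
  m
}

# Upper-triangle (no diagonal) vectorisation used for window distances.
upperTriVec <- function(m) m[upper.tri(m)]

# Relabel integer labels to first-appearance order (1,2,...): deterministic
# canonical form used after clustering.
canonicalLabels <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

# Derive a per-subject seed from the master seed by a fixed offset, kept
# within 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 7919 + offset * 104729) %% 2147483647)
}

# Assign ROIs to nModules near-equal contiguous blocks.
moduleLayout <- function(nRois, nModules) {
  sizes <- diff(round(seq(0, nRois, length.out = nModules + 1)))
  rep(seq_len(nModules), times = sizes)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
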