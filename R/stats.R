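#' @include AllClasses.R
NULL

#' Welch t-test from group summaries
#'
#' Welch's unequal-variance t statistic with Welch-Satterthwaite degrees of
#' freedom, from group sizes, means and SDs.
#'
#' @param n1,m1,s1 size, mean, SD of group 1
#' @param n2,m2,s2 size, mean, SD of group 2
#' @param tails "two" (default) or "one" (tail on the observed side)
#' @return data.frame t, df, p, tails, n1, m1, s1, n2, m2, s2
#' @examples
#' welchFromSummary(15, 41.7, 13.0, 13, 44.6, 11.5)  # t ~ -0.626, df ~ 26
#' @export
welchFromSummary <- function(n1, m1, s1, n2, m2, s2,
                             tails = c("two", "one")) {
  tails <- match.arg(tails)
  stopifnot(n1 >= 2, n2 >= 2)
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) {
    if (m1 == m2) {
      message("both group SDs are zero and means equal; p = 1 by convention")
      return(data.frame(t = 0, df = NA_real_, p = 1, tails = tails,
                        n1 = n1, m1 = m1, s1 = s1, n2 = n2, m2 = m2, s2 = s2))
    }
    stop("both group SDs are zero with unequal means")
  }
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  p <- if (tails == "two") 2 * stats::pt(-abs(t), df) else stats::pt(-abs(t), df)
  data.frame(t = t, df = df, p = p, tails = tails,
             n1 = n1, m1 = m1, s1 = s1, n2 = n2, m2 = m2, s2 = s2)
}

#' Welch t-test from samples
#'
#' @param x,y numeric samples (n >= 2 each)
#' @inheritParams welchFromSummary
#' @return as \code{\link{welchFromSummary}}
#' @export
welchTest <- function(x, y, tails = c("two", "one")) {
  tails <- match.arg(tails)
  welchFromSummary(length(x), mean(x), stats::sd(x),
                   length(y), mean(y), stats::sd(y), tails = tails)
}

# concordance statistic S and tie counts for tau-b
kendallS <- function(x, y) {
  dx <- sign(outer(x, x, "-"))
  dy <- sign(outer(y, y, "-"))
  sum(dx[upper.tri(dx)] * dy[upper.tri(dy)])
}

#' Kendall tau-b with one-sided inference
#'
#' Tie-corrected Kendall rank correlation: tau-b = S / sqrt((n0 - T_x)(n0 -
#' T_y)) with S the concordant-minus-discordant pair count. The p-value uses
#' the tie-adjusted normal approximation for n >= \code{exactBelow}, and exact
#' enumeration of all permutations of y below that (default 8, i.e. up to
#' 5040 permutations). The test side is declared a priori ("greater" for
#' hyperconnectivity-type, "less" for atrophy-type associations).
#'
#' @param x,y paired numeric vectors, n >= 3
#' @param side "greater", "less" or "two"
#' @param exactBelow sample size below which the exact permutation null is
#'   enumerated
#' @return data.frame tau, S, p, side, n, method
#' @export
kendallTauB <- function(x, y, side = c("greater", "less", "two"),
                        exactBelow = 8L) {
  side <- match.arg(side)
  n <- length(x)
  stopifnot(n == length(y), n >= 3)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("tau-b undefined: a variable is constant (all tied)")
  S <- kendallS(x, y)
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  Tx <- sum(tx * (tx - 1) / 2); Ty <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - Tx) * (n0 - Ty))
  if (n < exactBelow) {
    perms <- permuteAll(n)
    Sp <- apply(perms, 1, function(idx) kendallS(x, y[idx]))
    p <- switch(side,
      greater = mean(Sp >= S),
      less = mean(Sp <= S),
      two = mean(abs(Sp) >= abs(S)))
    method <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    varS <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(varS)
    p <- switch(side,
      greater = stats::pnorm(z, lower.tail = FALSE),
      less = stats::pnorm(z),
      two = 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  data.frame(tau = tau, S = S, p = p, side = side, n = n, method = method,
             stringsAsFactors = FALSE)
}

# all permutations of 1..n (n <= 8)
permuteAll <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- permuteAll(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  r <- 0L
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq.int(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out[r + seq_len(nrow(sub)), ] <- as.matrix(block)
    r <- r + nrow(sub)
  }
  out
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up FDR control: adjusted p-values by monotone cumulative minimum and
#' the rejection mask at level q.
#'
#' @param p raw p-values in [0,1]
#' @param q FDR level (default 0.05)
#' @return list with \code{raw}, \code{adjusted} and logical \code{reject}
#' @export
bhFdr <- function(p, q = 0.05) {
  stopifnot(all(p >= 0 & p <= 1))
  adj <- stats::p.adjust(p, method = "BH")
  list(raw = p, adjusted = adj, reject = adj <= q)
}

#' Per-state group comparisons
#'
#' Mirrors the state summary layout: for every retained state, two-tailed
#' Welch comparisons of dwell time, global strength and each network-tier
#' strength between groups, over the subjects expressing the state (dwell >
#' 0); states expressed by fewer than 2 subjects per group are flagged
#' not-testable. Optionally, per-state ROI-wise comparisons of
#' representative-window strengths with BH-FDR, returning both the
#' FDR-surviving and the uncorrected-significant ROI sets.
#'
#' @param metrics data.frame from the pipeline: subject, group, state, dwell,
#'   global and within.<tier> columns
#' @param roiStrengths optional named list (state<s>) with elements
#'   \code{strengths} (subjects x ROIs representative-window strengths) and
#'   \code{group} (per-subject group labels)
#' @param q FDR level for the ROI-wise family (one family per state)
#' @param alpha uncorrected significance level
#' @return list: \code{stateTable} (long data.frame state, measure, t, df, p,
#'   testable, group means/SDs), \code{roiResults} (per state: sigFdr,
#'   sigUncorrected, table)
#' @export
stateGroupAnalysis <- function(metrics, roiStrengths = NULL, q = 0.05,
                               alpha = 0.05) {
  measures <- setdiff(names(metrics),
                      c("subject", "group", "state", "window", "ri"))
  states <- sort(unique(metrics$state))
  rows <- list()
  for (s in states) {
    ms <- metrics[metrics$state == s & metrics$dwell > 0, , drop = FALSE]
    nCon <- sum(ms$group == "control"); nCase <- sum(ms$group == "case")
    for (m in measures) {
      if (nCon >= 2 && nCase >= 2) {
        w <- welchTest(ms[[m]][ms$group == "control"],
                       ms[[m]][ms$group == "case"], tails = "two")
        rows[[length(rows) + 1L]] <- data.frame(
          state = s, measure = m, testable = TRUE, t = w$t, df = w$df, p = w$p,
          nControl = nCon, meanControl = w$m1, sdControl = w$s1,
          nCase = nCase, meanCase = w$m2, sdCase = w$s2,
          stringsAsFactors = FALSE)
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          state = s, measure = m, testable = FALSE, t = NA_real_,
          df = NA_real_, p = NA_real_, nControl = nCon, meanControl = NA_real_,
          sdControl = NA_real_, nCase = nCase, meanCase = NA_real_,
          sdCase = NA_real_, stringsAsFactors = FALSE)
      }
    }
  }
  stateTable <- do.call(rbind, rows)
  roiResults <- NULL
  if (!is.null(roiStrengths)) {
    roiResults <- lapply(roiStrengths, function(rs) {
      grp <- rs$group
      if (sum(grp == "control") < 2 || sum(grp == "case") < 2)
        return(list(sigFdr = character(0), sigUncorrected = character(0),
                    table = NULL, testable = FALSE))
      pv <- apply(rs$strengths, 2, function(v)
        welchTest(v[grp == "control"], v[grp == "case"], tails = "two")$p)
      fdr <- bhFdr(pv, q = q)
      list(sigFdr = colnames(rs$strengths)[fdr$reject],
           sigUncorrected = colnames(rs$strengths)[pv < alpha],
           table = data.frame(roi = colnames(rs$strengths), p = pv,
                              pAdjusted = fdr$adjusted,
                              stringsAsFactors = FALSE),
           testable = TRUE)
    })
  }
  list(stateTable = stateTable, roiResults = roiResults)
}
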