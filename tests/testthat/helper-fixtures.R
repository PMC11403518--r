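# shared fixture builders

# random symmetric correlation-like matrix with unit diagonal
randomCorr <- function(p, n = 4 * p) {
  x <- matrix(rnorm(n * p), n, p)
  r <- cor(x)
  dimnames(r) <- list(sprintf("roi%03d", 1:p), sprintf("roi%03d", 1:p))
  r
}

# minimal RoiTimeSeries around a signal matrix
makeTs <- function(signal, runs = 1L, subject = "subA", group = "control",
                   outlier = rep(FALSE, nrow(signal)),
                   fwd = rep(0.05, nrow(signal))) {
  n <- nrow(signal)
  colnames(signal) <- sprintf("roi%03d", seq_len(ncol(signal)))
  per <- n %/% runs
  rb <- data.frame(run = seq_len(runs),
                   start = (seq_len(runs) - 1L) * per + 1L,
                   end = c((seq_len(runs - 1)) * per, n)[seq_len(runs)])
  if (runs == 1L) rb <- data.frame(run = 1L, start = 1L, end = n)
  new("RoiTimeSeries", subject = subject, group = group, signal = signal,
      runBoundaries = rb, outlierMask = outlier, fwd = fwd)
}

# brute-force positive strength (double loop)
bfPositiveStrength <- function(corr) {
  p <- nrow(corr)
  s <- numeric(p)
  for (i in 1:p) for (j in 1:p)
    if (i != j && corr[i, j] > 0) s[i] <- s[i] + corr[i, j]
  s
}

# brute-force Kendall tau-b by pair enumeration
bfKendall <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    s <- sign(x[i] - x[j]) * sign(y[i] - y[j])
    if (s > 0) conc <- conc + 1 else if (s < 0) disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x); ty <- table(y)
  (conc - disc) / sqrt((n0 - sum(tx * (tx - 1) / 2)) * (n0 - sum(ty * (ty - 1) / 2)))
}

# brute-force BH step-up rejection set
bfBH <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= (1:m) * q / m)
  reject <- rep(FALSE, m)
  if (length(k)) reject[o[1:max(k)]] <- TRUE
  reject
}

# majority-vote mapping of recovered labels onto planted labels
mapLabels <- function(rec, truth) {
  map <- vapply(split(truth, rec),
                function(v) as.integer(names(which.max(table(v)))), integer(1))
  map[as.character(rec)]
}
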