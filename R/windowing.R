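#' @include AllClasses.R
NULL

#' Sliding-window specification
#'
#' @param width window width in frames (default 80 frames; 60 s at TR 0.72 s)
#' @param step advance in frames between consecutive windows (default 1 TR)
#' @return list with elements width, step
#' @export
windowSpec <- function(width = 80L, step = 1L) {
  width <- as.integer(width); step <- as.integer(step)
  stopifnot(width >= 1L, step >= 1L, step <= width)
  list(width = width, step = step)
}

#' Window start frames for one run
#'
#' Starts are 1, 1+step, 1+2*step, ... while start+width-1 <= runLength, so the
#' window count is floor((runLength - width)/step) + 1.
#'
#' @param runLength run length in frames
#' @param spec a \code{\link{windowSpec}}
#' @return integer vector of start frames (empty, with a warning, if the run
#'   is shorter than the window)
#' @export
makeWindowStarts <- function(runLength, spec = windowSpec()) {
  if (runLength < spec$width) {
    warning("run of ", runLength, " frames is shorter than window width ",
            spec$width, "; no windows produced")
    return(integer(0))
  }
  as.integer(seq.int(1L, runLength - spec$width + 1L, by = spec$step))
}

#' Framewise displacement from rigid-body motion parameters
#'
#' Power-style framewise displacement: sum of absolute frame-to-frame changes
#' of the three translations (mm) plus the three rotations (radians) converted
#' to arc length on a 50 mm sphere. The first frame has no predecessor and is
#' assigned 0.
#'
#' @param motionParams numeric matrix, frames x 6 (3 translations in mm, then
#'   3 rotations in radians)
#' @param radiusMm rotation-to-displacement radius (default 50 mm)
#' @return numeric vector, mm per frame
#' @export
framewiseDisplacement <- function(motionParams, radiusMm = 50) {
  motionParams <- as.matrix(motionParams)
  if (ncol(motionParams) != 6L)
    stop("motionParams must have 6 columns (3 translations, 3 rotations)")
  d <- abs(diff(motionParams))
  c(0, rowSums(d[, 1:3, drop = FALSE]) +
      radiusMm * rowSums(d[, 4:6, drop = FALSE]))
}

# Sliding Pearson correlation matrices for one run, by incremental rank
# updates of the cross-product matrix. Zero-variance ROIs within a window get
# correlation 0 to every other ROI (diagonal stays 1); occurrences counted.
slidingCorr <- function(x, starts, width) {
  p <- ncol(x)
  out <- array(NA_real_, c(p, p, length(starts)))
  zeroVar <- 0L
  S <- crossprod(x[starts[1]:(starts[1] + width - 1L), , drop = FALSE])
  cs <- colSums(x[starts[1]:(starts[1] + width - 1L), , drop = FALSE])
  for (i in seq_along(starts)) {
    if (i > 1L) {
      drop <- starts[i - 1L]:(starts[i] - 1L)
      add <- (starts[i - 1L] + width):(starts[i] + width - 1L)
      xd <- x[drop, , drop = FALSE]; xa <- x[add, , drop = FALSE]
      S <- S - crossprod(xd) + crossprod(xa)
      cs <- cs - colSums(xd) + colSums(xa)
    }
    cv <- (S - tcrossprod(cs) / width) / (width - 1)
    v <- diag(cv)
    bad <- v < 1e-12
    sd <- sqrt(pmax(v, 1e-12))
    r <- cv / tcrossprod(sd)
    if (any(bad)) {
      zeroVar <- zeroVar + sum(bad)
      r[bad, ] <- 0; r[, bad] <- 0
    }
    r[r > 1] <- 1; r[r < -1] <- -1
    diag(r) <- 1
    out[, , i] <- (r + t(r)) / 2
  }
  attr(out, "zeroVarEvents") <- zeroVar
  out
}

#' Per-window correlation matrices with motion annotations
#'
#' Slices each run into sliding windows (never spanning run boundaries),
#' computes the Pearson correlation matrix over each window's frames, and
#' annotates every window with its motion-outlier frame count, motion-window
#' flag (>= 1 outlier frame) and mean framewise displacement. Runs shorter
#' than the window width are skipped with a warning. Windows containing a
#' zero-variance ROI get that ROI's correlations set to 0; the number of such
#' events is reported via a message.
#'
#' @param ts a \linkS4class{RoiTimeSeries}
#' @param spec a \code{\link{windowSpec}}
#' @return a \linkS4class{WindowSet}
#' @export
windowCorrelations <- function(ts, spec = windowSpec()) {
  rb <- ts@runBoundaries
  p <- ncol(ts@signal)
  metas <- list(); corrs <- list(); zeroVar <- 0L
  for (r in seq_len(nrow(rb))) {
    lo <- rb$start[r]; hi <- rb$end[r]
    starts <- makeWindowStarts(hi - lo + 1L, spec)
    if (!length(starts)) next
    x <- ts@signal[lo:hi, , drop = FALSE]
    cr <- slidingCorr(x, starts, spec$width)
    zeroVar <- zeroVar + attr(cr, "zeroVarEvents")
    oc <- vapply(starts, function(s)
      sum(ts@outlierMask[(lo + s - 1L):(lo + s + spec$width - 2L)]), integer(1))
    mf <- vapply(starts, function(s)
      mean(ts@fwd[(lo + s - 1L):(lo + s + spec$width - 2L)]), numeric(1))
    metas[[length(metas) + 1L]] <- data.frame(
      subject = ts@subject, group = ts@group, run = rb$run[r], start = starts,
      outlierFrames = oc, isMotionWindow = oc >= 1L, meanFwd = mf,
      stringsAsFactors = FALSE)
    corrs[[length(corrs) + 1L]] <- cr
  }
  if (!length(metas))
    stop("no run of subject ", ts@subject, " is long enough for width ",
         spec$width)
  if (zeroVar > 0)
    message(zeroVar, " zero-variance ROI-window event(s); correlations set to 0")
  meta <- do.call(rbind, metas)
  corr <- array(unlist(corrs, use.names = FALSE), c(p, p, nrow(meta)),
                dimnames = list(roiIds(ts), roiIds(ts), NULL))
  methods::new("WindowSet", meta = meta, corr = corr, roiIds = roiIds(ts),
               width = spec$width)
}

#' Extract one window's correlation matrix
#'
#' @param ws a \linkS4class{WindowSet}
#' @param i window index (row of \code{windowMeta(ws)})
#' @return ROI x ROI correlation matrix
#' @export
windowCorrMatrix <- function(ws, i) {
  stopifnot(i >= 1L, i <= dim(ws@corr)[3])
  m <- ws@corr[, , i]
  dimnames(m) <- list(ws@roiIds, ws@roiIds)
  m
}
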