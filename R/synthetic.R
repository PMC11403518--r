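#' @include utils.R
NULL

#' Create a synthetic-cohort configuration
#'
#' Defaults describe the reference validation cohort: 28 subjects (14 per
#' group, the scale of a typical single-site clinical study), 50 ROIs in 6
#' modules, 5 latent connectivity states, 2 runs of 800 usable frames at TR
#' 0.72 s, band-limited-like AR(1) smoothing, 1% motion outlier frames
#' arranged in bursts, and a "case" group whose last state is boosted both in
#' connectivity (boostFactor) and dwell time (dwellBias). Volume and behavior
#' parameters plant a case-group network-composite decrement coupled to a
#' symptom score.
#'
#' @param nRois,nModules,nStates,nSubjectsPerGroup,nRuns,framesPerRun see
#'   \linkS4class{SynthConfig}
#' @param trSeconds repetition time (s)
#' @param transitionStickiness Markov self-transition probability; 0.995 gives
#'   mean state segments of ~200 frames, long against the 80-frame window, so
#'   that windows are mostly state-pure and per-subject dwell times land in
#'   the tens-to-hundreds-of-windows range typical of sliding-window analyses
#' @param withinModuleCorr,betweenModuleCorr,coupledCorr correlation levels of
#'   the block covariance structure
#' @param boostState,boostFactor,dwellBias planted case-group effect
#' @param outlierRate,outlierAmplitude motion contamination
#' @param arCoefficient AR(1) smoothing coefficient
#' @param volumeMean,volumeSd,volumeDecrement volumetric table parameters
#' @param behaviorCoupling latent correlation magnitude between the planted
#'   composite and the symptom score (0.45 yields Kendall tau around -0.3)
#' @param seed master seed
#' @return a validated \linkS4class{SynthConfig}
#' @examples
#' cfg <- synthConfig(nRois = 12, nModules = 3, nStates = 2,
#'                    nSubjectsPerGroup = 2, framesPerRun = 120, seed = 1)
#' @export
synthConfig <- function(nRois = 50, nModules = 6, nStates = 5,
                        nSubjectsPerGroup = 14, nRuns = 2, framesPerRun = 800,
                        trSeconds = 0.72, transitionStickiness = 0.995,
                        withinModuleCorr = 0.6, betweenModuleCorr = 0.02,
                        coupledCorr = 0.42, boostState = nStates,
                        boostFactor = 1.3, dwellBias = 1.005,
                        outlierRate = 0.01, outlierAmplitude = 1.5,
                        arCoefficient = 0.25, volumeMean = 0.73,
                        volumeSd = 0.03, volumeDecrement = 0.04,
                        behaviorCoupling = 0.45, seed = 1L) {
  methods::new("SynthConfig",
    nRois = as.integer(nRois), nModules = as.integer(nModules),
    nStates = as.integer(nStates),
    nSubjectsPerGroup = as.integer(nSubjectsPerGroup),
    nRuns = as.integer(nRuns), framesPerRun = as.integer(framesPerRun),
    trSeconds = trSeconds, transitionStickiness = transitionStickiness,
    withinModuleCorr = withinModuleCorr, betweenModuleCorr = betweenModuleCorr,
    coupledCorr = coupledCorr, boostState = as.integer(boostState),
    boostFactor = boostFactor, dwellBias = dwellBias,
    outlierRate = outlierRate, outlierAmplitude = outlierAmplitude,
    arCoefficient = arCoefficient, volumeMean = volumeMean,
    volumeSd = volumeSd, volumeDecrement = volumeDecrement,
    behaviorCoupling = behaviorCoupling, seed = as.integer(seed))
}

# ROI ids are zero-padded so lexicographic order equals numeric order.
synthRoiIds <- function(nRois) sprintf("roi%03d", seq_len(nRois))

#' Planted module layout of a synthetic configuration
#'
#' @param config a \linkS4class{SynthConfig}
#' @return named integer vector, ROI id -> planted module
#' @export
synthRoiModules <- function(config) {
  stats::setNames(moduleLayout(config@nRois, config@nModules),
                  synthRoiIds(config@nRois))
}

#' Module-pair couplings that identify each state
#'
#' Each latent state couples one distinct pair of modules; pairs are spread
#' over the set of all module pairs so the states' module-averaged profiles
#' are maximally distinct.
#'
#' @param config a \linkS4class{SynthConfig}
#' @return integer matrix, 2 x nStates; column s holds the coupled module pair
#'   of state s
#' @export
statePairs <- function(config) {
  pairs <- utils::combn(config@nModules, 2)
  idx <- unique(round(seq(1, ncol(pairs), length.out = config@nStates)))
  # if rounding collapsed indices (few pairs), fall back to the first nStates
  if (length(idx) < config@nStates) idx <- seq_len(config@nStates)
  pairs[, idx, drop = FALSE]
}

#' Per-state ROI covariance matrices
#'
#' Builds one correlation (unit-variance covariance) matrix per latent state:
#' within-module blocks at \code{withinModuleCorr}, baseline between-module
#' correlation at \code{betweenModuleCorr}, and the state's coupled module
#' pair raised to \code{coupledCorr}; the coupled modules are also denser
#' internally (their within-module correlation rises by half the coupling
#' contrast), making each state's module-strength profile distinctive. For
#' the case-group variant the boosted
#' state's coupled blocks are scaled by \code{boostFactor} (capped at 0.95).
#' Matrices failing positive definiteness are repaired by eigenvalue clipping
#' (and flagged via the "repaired" attribute); a matrix that cannot be
#' repaired raises an error.
#'
#' @param config a \linkS4class{SynthConfig}
#' @param group "control" or "case"
#' @return list of nStates SPD matrices with ROI ids as dimnames
#' @export
makeStateCovariances <- function(config, group = c("control", "case")) {
  group <- match.arg(group)
  mod <- moduleLayout(config@nRois, config@nModules)
  ids <- synthRoiIds(config@nRois)
  pairs <- statePairs(config)
  same <- outer(mod, mod, "==")
  base <- matrix(config@betweenModuleCorr, config@nRois, config@nRois)
  base[same] <- config@withinModuleCorr
  diag(base) <- 1
  lapply(seq_len(config@nStates), function(s) {
    m <- base
    cc <- config@coupledCorr
    if (group == "case" && s == config@boostState)
      cc <- min(cc * config@boostFactor, 0.95)
    a <- pairs[1, s]; b <- pairs[2, s]
    blk <- (mod == a) %o% (mod == b)
    m[blk | t(blk)] <- cc
    # the coupled modules are hyperconnected internally as well: their
    # within-module correlation rises by half the coupling contrast
    wcUp <- min(config@withinModuleCorr +
                  (cc - config@betweenModuleCorr) / 2, 0.9)
    for (mm in c(a, b)) {
      inside <- outer(mod == mm, mod == mm, "&")
      diag(inside) <- FALSE
      m[inside] <- wcUp
    }
    m <- nearestSPD(m)
    dimnames(m) <- list(ids, ids)
    m
  })
}

#' State-transition matrix of the latent Markov chain
#'
#' Sticky chain: self-transition \code{transitionStickiness}, remaining mass
#' spread uniformly. For case subjects the boosted state's self-transition is
#' multiplied by \code{dwellBias} (capped at 0.9999), lengthening its dwell
#' segments.
#'
#' @param config a \linkS4class{SynthConfig}
#' @param group "control" or "case"
#' @return row-stochastic nStates x nStates matrix
#' @export
transitionMatrix <- function(config, group = c("control", "case")) {
  group <- match.arg(group)
  k <- config@nStates
  p <- config@transitionStickiness
  if (k == 1L) return(matrix(1, 1, 1))
  tm <- matrix((1 - p) / (k - 1), k, k)
  diag(tm) <- p
  if (group == "case" && config@dwellBias > 1) {
    pb <- min(p * config@dwellBias, 0.9999)
    tm[config@boostState, ] <- (1 - pb) / (k - 1)
    tm[config@boostState, config@boostState] <- pb
  }
  tm
}

# Simulate one run's latent state sequence. The initial state can be fixed
# (runs across a cohort cycle through the states round-robin so that every
# state is well represented in finite cohorts); default is uniform random.
simulateChain <- function(tm, nFrames, init = NULL) {
  k <- nrow(tm)
  s <- integer(nFrames)
  s[1] <- if (is.null(init)) sample.int(k, 1) else as.integer(init)
  if (nFrames > 1) {
    u <- stats::runif(nFrames - 1)
    cum <- t(apply(tm, 1, cumsum))
    for (t in 2:nFrames)
      s[t] <- sum(u[t - 1] > cum[s[t - 1], ]) + 1L
  }
  s
}

#' Simulate one subject's ROI time series
#'
#' Per run, a sticky Markov chain over latent states drives which state
#' covariance the multivariate-normal innovations are drawn from; the
#' innovation stream is smoothed with an AR(1) filter (variance-preserving, so
#' long same-state segments carry that state's correlation structure). Motion
#' outlier frames are injected at \code{outlierRate} as additive spikes of
#' \code{outlierAmplitude} signal-SDs, global across ROIs (emulating how
#' frame-censoring routines flag whole frames), with a matching elevated
#' framewise-displacement series. Runs are independent chains.
#'
#' @param config a \linkS4class{SynthConfig}
#' @param group "control" or "case"
#' @param subjectSeed integer seed for this subject's stream
#' @param subject subject id string
#' @param initStates optional integer vector (one entry per run) fixing each
#'   run's initial latent state; cohorts cycle initial states round-robin so
#'   every state is expressed in finite cohorts
#' @return list with elements \code{ts} (a \linkS4class{RoiTimeSeries}) and
#'   \code{truth} (list: per-frame \code{stateLabels}, \code{outlierFrames},
#'   \code{runBoundaries})
#' @export
simulateSubject <- function(config, group = c("control", "case"),
                            subjectSeed = config@seed, subject = "sub01",
                            initStates = NULL) {
  group <- match.arg(group)
  set.seed(subjectSeed)
  covs <- makeStateCovariances(config, group)
  chols <- lapply(covs, chol)
  tm <- transitionMatrix(config, group)
  nR <- config@nRuns; nF <- config@framesPerRun; p <- config@nRois
  ar <- config@arCoefficient
  allSig <- vector("list", nR); allLab <- vector("list", nR)
  for (r in seq_len(nR)) {
    lab <- simulateChain(tm, nF,
                         init = if (is.null(initStates)) NULL else initStates[r])
    e <- matrix(0, nF, p)
    for (s in unique(lab)) {
      idx <- which(lab == s)
      z <- matrix(stats::rnorm(length(idx) * p), length(idx), p)
      e[idx, ] <- z %*% chols[[s]]
    }
    x <- apply(sqrt(1 - ar^2) * e, 2, stats::filter,
               filter = ar, method = "recursive")
    x[1, ] <- e[1, ]   # initialise at stationary scale
    allSig[[r]] <- x
    allLab[[r]] <- lab
  }
  signal <- do.call(rbind, allSig)
  n <- nR * nF
  # motion comes in episodes: round(rate * frames) outlier frames per run,
  # arranged in bursts of up to 8 consecutive frames at random non-adjacent
  # positions (head motion contaminates stretches of frames, not isolated ones)
  outlier <- logical(n)
  for (r in seq_len(nR)) {
    nOut <- round(config@outlierRate * nF)
    off <- (r - 1L) * nF
    while (nOut > 0L) {
      len <- min(8L, nOut)
      for (try in 1:100) {
        s <- sample.int(nF - len + 1L, 1)
        idx <- off + s:(s + len - 1L)
        if (!any(outlier[pmax(off + 1L, idx[1] - 1L):
                         pmin(off + nF, idx[len] + 1L)])) break
      }
      outlier[idx] <- TRUE
      nOut <- nOut - len
    }
  }
  fwd <- abs(stats::rnorm(n, 0.08, 0.04))
  if (any(outlier)) {
    spikes <- config@outlierAmplitude *
      sample(c(-1, 1), sum(outlier), replace = TRUE)
    signal[outlier, ] <- signal[outlier, ] + spikes
    fwd[outlier] <- fwd[outlier] + stats::runif(sum(outlier), 0.5, 2)
  }
  colnames(signal) <- synthRoiIds(p)
  rb <- data.frame(run = seq_len(nR),
                   start = (seq_len(nR) - 1L) * nF + 1L,
                   end = seq_len(nR) * nF)
  ts <- methods::new("RoiTimeSeries", subject = subject, group = group,
                     signal = signal, runBoundaries = rb,
                     outlierMask = outlier, fwd = fwd)
  list(ts = ts,
       truth = list(stateLabels = unlist(allLab, use.names = FALSE),
                    outlierFrames = which(outlier),
                    runBoundaries = rb))
}

#' Simulate a full cohort with ground truth
#'
#' Simulates \code{2 * nSubjectsPerGroup} subjects (controls first), a volume
#' table (subject x ROI Jacobian-determinant-like values, with a case-group
#' decrement planted on the boosted state's coupled-module ROIs), and a
#' behavior table whose symptom score is negatively coupled to the planted
#' network composite. Deterministic given \code{config@seed}: per-subject
#' streams are derived from the master seed by fixed offsets.
#'
#' @param config a \linkS4class{SynthConfig}
#' @return list with \code{timeSeries} (list of \linkS4class{RoiTimeSeries}),
#'   \code{groundTruth} (per-subject latent labels and outlier frames, group
#'   labels, true covariances, module layout, state module-pairs, atrophy ROI
#'   set), \code{volumes} (subject x ROI matrix), \code{behavior} (data.frame
#'   subject, group, symptom), \code{networks} (nested tiered ROI sets of the
#'   planted network, see \code{\link{networkComposites}}), and \code{roiMeta}
#'   (data.frame roi, module).
#' @export
simulateCohort <- function(config) {
  groups <- rep(c("control", "case"), each = config@nSubjectsPerGroup)
  nSub <- length(groups)
  subjects <- sprintf("sub%02d", seq_len(nSub))
  sims <- vector("list", nSub)
  for (i in seq_len(nSub)) {
    init <- ((i - 1L) * config@nRuns + seq_len(config@nRuns) - 1L) %%
      config@nStates + 1L
    sims[[i]] <- simulateSubject(config, groups[i],
                                 subjectSeed = deriveSeed(config@seed, i),
                                 subject = subjects[i], initStates = init)
  }
  ts <- lapply(sims, `[[`, "ts")
  names(ts) <- subjects
  mod <- moduleLayout(config@nRois, config@nModules)
  ids <- synthRoiIds(config@nRois)
  pairs <- statePairs(config)
  bp <- pairs[, config@boostState]
  tierMods <- list(bp[1:2], bp, c(bp, setdiff(seq_len(config@nModules), bp)[1]))
  networks <- list(
    name = "planted",
    tiers = list(
      brainstem = ids[mod %in% tierMods[[1]]],
      `brainstem+forebrain` = ids[mod %in% tierMods[[2]]],
      `brainstem+forebrain+cortical` = ids[mod %in% tierMods[[3]]]
    ))
  atrophyRois <- networks$tiers[["brainstem+forebrain"]]

  vb <- simulateVolumeBehavior(config, groups, subjects, ids, atrophyRois,
                               seed = deriveSeed(config@seed, 900001L))
  volumes <- vb$volumes
  behavior <- vb$behavior

  groundTruth <- list(
    stateLabels = stats::setNames(lapply(sims, function(s) s$truth$stateLabels),
                                  subjects),
    outlierFrames = stats::setNames(lapply(sims, function(s) s$truth$outlierFrames),
                                    subjects),
    groups = stats::setNames(groups, subjects),
    covariances = list(control = makeStateCovariances(config, "control"),
                       case = makeStateCovariances(config, "case")),
    modules = stats::setNames(mod, ids),
    statePairs = pairs,
    boostState = config@boostState,
    atrophyRois = atrophyRois)
  list(timeSeries = ts, groundTruth = groundTruth, volumes = volumes,
       behavior = behavior, networks = networks,
       roiMeta = data.frame(roi = ids, module = mod, stringsAsFactors = FALSE))
}

# Volume (Jacobian-determinant-like) and behavior tables with planted effects.
# Subject-level shared variation dominates the composite's between-subject SD;
# per-ROI noise mostly averages out in composites. The symptom score is
# negatively coupled (latent correlation behaviorCoupling) to the atrophy
# composite.
simulateVolumeBehavior <- function(config, groups, subjects, ids, atrophyRois,
                                   seed) {
  set.seed(seed)
  nSub <- length(groups)
  subjEff <- stats::rnorm(nSub, 0, config@volumeSd)
  volumes <- matrix(config@volumeMean + rep(subjEff, config@nRois) +
                      stats::rnorm(nSub * config@nRois, 0, config@volumeSd),
                    nSub, config@nRois, dimnames = list(subjects, ids))
  volumes[groups == "case", atrophyRois] <-
    volumes[groups == "case", atrophyRois] - config@volumeDecrement
  comp <- rowMeans(volumes[, atrophyRois, drop = FALSE])
  zc <- if (stats::sd(comp) > 0) as.numeric(scale(comp)) else numeric(nSub)
  rho <- config@behaviorCoupling
  lat <- -rho * zc + sqrt(1 - rho^2) * stats::rnorm(nSub)
  behavior <- data.frame(subject = subjects, group = groups,
                         symptom = 10 + 6 * lat, stringsAsFactors = FALSE)
  list(volumes = volumes, behavior = behavior)
}

#' Latent-chain dwell-time replicate
#'
#' Fast calibration utility: simulates the cohort's latent state chains and
#' motion masks only (no BOLD sampling) and returns the per-subject dwell
#' table that the pipeline's bookkeeping would produce for perfectly recovered
#' states — windows are labeled by their centre frame's latent state and
#' motion windows (>= 1 outlier frame) are excluded. Used to calibrate the
#' dwell-time inference layer over many replicates; state recovery itself is
#' validated separately.
#'
#' @param config a \linkS4class{SynthConfig}
#' @param seed replicate seed
#' @param spec a \code{\link{windowSpec}}
#' @return long data.frame subject, group, state, dwell
#' @export
simulateLatentDwell <- function(config, seed, spec = windowSpec()) {
  set.seed(seed)
  k <- config@nStates
  nF <- config@framesPerRun
  groups <- rep(c("control", "case"), each = config@nSubjectsPerGroup)
  nSub <- length(groups)
  starts <- makeWindowStarts(nF, spec)
  centre <- starts + spec$width %/% 2L
  nOut <- round(config@outlierRate * nF)
  runIdx <- 0L
  dwell <- matrix(0L, nSub, k)
  for (i in seq_len(nSub)) {
    tm <- transitionMatrix(config, groups[i])
    for (r in seq_len(config@nRuns)) {
      init <- runIdx %% k + 1L
      runIdx <- runIdx + 1L
      # segment-based chain (geometric sojourns)
      lab <- integer(nF); t <- 0L; s <- init
      while (t < nF) {
        stay <- min(1L + stats::rgeom(1, 1 - tm[s, s]), nF - t)
        lab[(t + 1L):(t + stay)] <- s
        t <- t + stay
        if (t < nF) {
          others <- setdiff(seq_len(k), s)
          pr <- tm[s, others]
          s <- others[sample.int(length(others), 1, prob = pr)]
        }
      }
      # burst motion mask as in simulateSubject
      mask <- logical(nF); left <- nOut
      while (left > 0L) {
        len <- min(8L, left)
        st <- sample.int(nF - len + 1L, 1)
        mask[st:(st + len - 1L)] <- TRUE
        left <- left - len
      }
      cs <- c(0L, cumsum(mask))
      hasOut <- (cs[starts + spec$width] - cs[starts]) > 0L
      wl <- lab[centre]
      for (s2 in seq_len(k))
        dwell[i, s2] <- dwell[i, s2] + sum(wl == s2 & !hasOut)
    }
  }
  subjects <- sprintf("sub%02d", seq_len(nSub))
  data.frame(subject = rep(subjects, k),
             group = rep(groups, k),
             state = rep(seq_len(k), each = nSub),
             dwell = as.integer(dwell),
             stringsAsFactors = FALSE)
}

#' Single-window state connectivity replicate
#'
#' Fast calibration utility for the planted connectivity effect: for every
#' subject and state, samples one window of AR(1)-smoothed frames from that
#' state's (group-appropriate) covariance, computes the window correlation
#' matrix, and returns global strength and the within-strength of the planted
#' network tier. Emulates each subject's representative window of the state
#' under perfect state recovery.
#'
#' @param config a \linkS4class{SynthConfig}
#' @param seed replicate seed
#' @param width window width in frames
#' @return data.frame subject, group, state, global, within
#' @export
simulateStateWindows <- function(config, seed, width = 80L) {
  set.seed(seed)
  groups <- rep(c("control", "case"), each = config@nSubjectsPerGroup)
  nSub <- length(groups)
  chols <- list(control = lapply(makeStateCovariances(config, "control"), chol),
                case = lapply(makeStateCovariances(config, "case"), chol))
  mod <- moduleLayout(config@nRois, config@nModules)
  ids <- synthRoiIds(config@nRois)
  bp <- statePairs(config)[, config@boostState]
  tier <- ids[mod %in% bp]
  ar <- config@arCoefficient
  rows <- list()
  for (i in seq_len(nSub)) for (s in seq_len(config@nStates)) {
    e <- matrix(stats::rnorm(width * config@nRois), width) %*%
      chols[[groups[i]]][[s]]
    x <- apply(sqrt(1 - ar^2) * e, 2, stats::filter,
               filter = ar, method = "recursive")
    x[1, ] <- e[1, ]
    r <- stats::cor(x)
    dimnames(r) <- list(ids, ids)
    rows[[length(rows) + 1L]] <- data.frame(
      subject = sprintf("sub%02d", i), group = groups[i], state = s,
      global = globalStrength(r), within = withinSetStrength(r, tier),
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Planted state label per sliding window
#'
#' Maps a per-frame latent state sequence to per-window labels: each window is
#' labeled with the modal latent state over its frames (ties broken toward the
#' earlier state in the window). Used to score recovery of planted states.
#'
#' @param frameLabels integer latent state per frame (all runs concatenated)
#' @param runBoundaries data.frame run/start/end as in
#'   \linkS4class{RoiTimeSeries}
#' @param spec a \code{\link{windowSpec}}
#' @return data.frame run, start, plantedState
#' @export
windowPlantedLabels <- function(frameLabels, runBoundaries, spec = windowSpec()) {
  out <- lapply(seq_len(nrow(runBoundaries)), function(r) {
    lo <- runBoundaries$start[r]; hi <- runBoundaries$end[r]
    starts <- makeWindowStarts(hi - lo + 1L, spec)
    if (!length(starts)) return(NULL)
    lab <- vapply(starts, function(s) {
      fr <- frameLabels[(lo + s - 1L):(lo + s + spec$width - 2L)]
      tab <- table(fr)
      cand <- as.integer(names(tab)[tab == max(tab)])
      as.integer(if (length(cand) > 1L) fr[fr %in% cand][1] else cand)
    }, integer(1))
    data.frame(run = runBoundaries$run[r], start = starts, plantedState = lab)
  })
  do.call(rbind, out)
}
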