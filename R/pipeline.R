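#' @include AllClasses.R
NULL

#' Pipeline configuration
#'
#' Defaults follow the standard analysis settings: 80-frame windows advanced
#' by 1 TR, modularity resolution 1 with 1000 restarts, 90th-percentile hubs,
#' motion-cluster threshold 2 outlier frames/window, FDR q = 0.05. The
#' subject-exclusion threshold defaults to "auto": the reference value of 1200
#' usable windows (for 2 x 726-window runs) scaled proportionally to the
#' cohort's per-subject window count.
#'
#' @param width,step sliding-window parameters (frames)
#' @param gamma,nIter modularity resolution and restart count
#' @param percentile hub percentile
#' @param motionThreshold motion-cluster threshold (mean outlier frames/window)
#' @param minWindows subject-exclusion threshold, or "auto"
#' @param k fixed state count; NULL selects k by the cubic clustering criterion
#' @param kRange candidate k for CCC selection
#' @param maxLinkageWindows cap on the Ward linkage problem size
#' @param q FDR level
#' @param alpha uncorrected significance level for ROI-wise sets
#' @param seed master seed for modularity restarts
#' @return validated configuration list
#' @export
pipelineConfig <- function(width = 80L, step = 1L, gamma = 1, nIter = 1000L,
                           percentile = 90, motionThreshold = 2,
                           minWindows = "auto", k = NULL, kRange = 2:20,
                           maxLinkageWindows = 6000L, q = 0.05, alpha = 0.05,
                           seed = 1L) {
  cfg <- list(width = as.integer(width), step = as.integer(step),
              gamma = gamma, nIter = as.integer(nIter),
              percentile = percentile, motionThreshold = motionThreshold,
              minWindows = minWindows, k = k, kRange = as.integer(kRange),
              maxLinkageWindows = as.integer(maxLinkageWindows), q = q,
              alpha = alpha, seed = as.integer(seed))
  stopifnot(cfg$width >= 1L, cfg$step >= 1L, cfg$step <= cfg$width,
            cfg$gamma > 0, cfg$nIter >= 1L,
            cfg$percentile >= 0, cfg$percentile < 100,
            cfg$motionThreshold >= 0, cfg$q > 0, cfg$q < 1)
  if (!identical(cfg$minWindows, "auto")) stopifnot(cfg$minWindows >= 0)
  cfg
}

#' Run the full dynamic-connectivity analysis
#'
#' Executes the stage sequence window correlation -> positive strength ->
#' control-referenced z-scores -> module detection on the controls' scrubbed
#' stationary correlations -> module-averaged features -> Ward clustering
#' (CCC-selected k unless fixed) -> motion-cluster classification and subject
#' exclusion -> dwell times, state profiles/hubs, representative windows,
#' per-subject state connectivity -> group statistics and volumetrics.
#' Deterministic given the cohort and config.
#'
#' @param cohort a cohort list (\code{\link{simulateCohort}} /
#'   \code{\link{readCohort}}) or a cohort directory path
#' @param config a \code{\link{pipelineConfig}}
#' @param outputDir optional directory for TSV/JSON artifacts and the run
#'   manifest
#' @param characterize logical; FALSE stops after dwell-time bookkeeping
#'   (skipping representative windows, per-subject metrics, group statistics
#'   and volumetrics) — useful for state-recovery experiments
#' @return list with partition, strength table, features, assignment, dwell,
#'   profiles, representative windows, metrics, stats, volumetrics and config
#' @export
runPipeline <- function(cohort, config = pipelineConfig(), outputDir = NULL,
                        characterize = TRUE) {
  if (is.character(cohort)) cohort <- readCohort(cohort)
  spec <- windowSpec(config$width, config$step)
  tsList <- cohort$timeSeries
  groups <- vapply(tsList, function(t) t@group, character(1))

  # stage: stationary module detection on controls
  conTs <- tsList[groups == "control"]
  if (!length(conTs)) stop("stage stationary: no control subjects")
  meanCorr <- Reduce(`+`, lapply(conTs, scrubbedCorrelation)) / length(conTs)
  partition <- modularityPartition(meanCorr, gamma = config$gamma,
                                   nIter = config$nIter, seed = config$seed)

  # stage: windows + strengths
  windowSets <- lapply(tsList, windowCorrelations, spec = spec)
  st <- concatStrengthTables(lapply(windowSets, strengthTable))
  st <- zscoreStrengths(st)
  features <- moduleAverage(st, partition)

  # stage: state clustering and motion bookkeeping
  assignment <- clusterWindows(st@meta, features, k = config$k,
                               kRange = config$kRange,
                               maxLinkageWindows = config$maxLinkageWindows)
  assignment <- classifyMotionClusters(assignment, config$motionThreshold)
  minW <- if (identical(config$minWindows, "auto"))
    proportionalMinWindows(max(assignment@subjectSummary$totalWindows))
  else config$minWindows
  assignment <- applySubjectExclusion(assignment, minWindows = minW)

  # stage: characterization
  dw <- dwellTimes(assignment)
  if (!characterize) {
    return(invisible(list(partition = partition, strength = st,
                          features = features, assignment = assignment,
                          dwell = dw, config = config, minWindows = minW,
                          windowSets = windowSets)))
  }
  profiles <- stateProfileAndHubs(st, assignment, percentile = config$percentile)
  repWin <- representativeWindows(assignment, windowSets)
  if (is.null(repWin) || !nrow(repWin)) stop("stage characterization: no representative windows")

  metricRows <- lapply(seq_len(nrow(repWin)), function(i) {
    r <- repWin[i, ]
    corr <- windowCorrMatrix(windowSets[[r$subject]], r$window)
    cbind(r[, c("subject", "group", "state", "window", "ri")],
          subjectStateConnectivity(corr, cohort$networks))
  })
  metrics <- do.call(rbind, metricRows)
  metrics <- merge(metrics, dw$dwell[, c("subject", "state", "dwell")],
                   by = c("subject", "state"), sort = TRUE)

  # ROI-wise representative-window strengths per state
  states <- sort(unique(repWin$state))
  roiStrengths <- lapply(stats::setNames(states, paste0("state", states)),
    function(s) {
      rw <- repWin[repWin$state == s, ]
      m <- t(vapply(seq_len(nrow(rw)), function(i)
        positiveStrength(windowCorrMatrix(windowSets[[rw$subject[i]]],
                                          rw$window[i])),
        numeric(length(st@refStats$roi))))
      rownames(m) <- rw$subject
      colnames(m) <- colnames(st@raw)
      list(strengths = m, group = rw$group)
    })

  statsOut <- stateGroupAnalysis(metrics, roiStrengths = roiStrengths,
                                 q = config$q, alpha = config$alpha)

  # hub/non-hub cross connectivity for states with significant ROIs
  hubCross <- list()
  for (s in states) {
    rr <- statsOut$roiResults[[paste0("state", s)]]
    hubs <- profiles[[paste0("state", s)]]$hubs
    if (is.null(rr) || !isTRUE(rr$testable)) next
    sig <- rr$sigUncorrected
    nonHub <- setdiff(sig, hubs)
    if (!length(nonHub)) next
    rw <- repWin[repWin$state == s, ]
    vals <- vapply(seq_len(nrow(rw)), function(i)
      crossSetStrength(windowCorrMatrix(windowSets[[rw$subject[i]]],
                                        rw$window[i]), nonHub, hubs),
      numeric(1))
    grp <- rw$group
    hubCross[[paste0("state", s)]] <- list(
      values = data.frame(subject = rw$subject, group = grp, value = vals,
                          stringsAsFactors = FALSE),
      test = if (sum(grp == "control") >= 2 && sum(grp == "case") >= 2)
        welchTest(vals[grp == "control"], vals[grp == "case"]) else NULL)
  }

  # stage: volumetrics
  volOut <- NULL
  if (!is.null(cohort$volumes)) {
    composites <- networkComposites(cohort$volumes, cohort$networks)
    volOut <- volumetricAnalysis(composites,
                                 stats::setNames(groups, names(tsList)),
                                 cohort$behavior, dwell = dw$dwell,
                                 q = config$q)
    volOut$composites <- composites
  }

  result <- list(partition = partition, strength = st, features = features,
                 assignment = assignment, dwell = dw, profiles = profiles,
                 representativeWindows = repWin, metrics = metrics,
                 stats = statsOut, hubCross = hubCross,
                 volumetrics = volOut, config = config, minWindows = minW)
  if (!is.null(outputDir)) writePipelineOutputs(result, outputDir)
  invisible(result)
}

# write the standard TSV/JSON artifact set plus a run manifest
writePipelineOutputs <- function(result, outputDir) {
  dir.create(outputDir, recursive = TRUE, showWarnings = FALSE)
  o <- function(f) file.path(outputDir, f)
  memb <- membership(result$partition)
  writeTsv(data.frame(roi = names(memb), module = as.integer(memb)),
           o("partition.tsv"))
  writeTsv(windowMeta(result$assignment), o("window_annotations.tsv"))
  writeTsv(clusterSummary(result$assignment), o("cluster_summary.tsv"))
  writeTsv(subjectSummary(result$assignment), o("subject_summary.tsv"))
  writeTsv(result$dwell$dwell, o("dwell.tsv"))
  prof <- do.call(rbind, lapply(names(result$profiles), function(nm) {
    p <- result$profiles[[nm]]
    data.frame(state = nm, roi = names(p$profile), meanStrength = p$profile,
               isHub = names(p$profile) %in% p$hubs, row.names = NULL)
  }))
  writeTsv(prof, o("state_profiles.tsv"))
  writeTsv(result$representativeWindows, o("representative_windows.tsv"))
  writeTsv(result$metrics, o("state_metrics.tsv"))
  writeTsv(result$stats$stateTable, o("state_tests.tsv"))
  roiTab <- do.call(rbind, lapply(names(result$stats$roiResults), function(nm) {
    t <- result$stats$roiResults[[nm]]$table
    if (is.null(t)) return(NULL)
    cbind(data.frame(state = nm), t)
  }))
  if (!is.null(roiTab)) writeTsv(roiTab, o("roi_tests.tsv"))
  if (!is.null(result$volumetrics)) {
    writeTsv(result$volumetrics$composites, o("composites.tsv"))
    writeTsv(result$volumetrics$groupTests, o("volume_tests.tsv"))
    writeTsv(result$volumetrics$associations, o("volume_associations.tsv"))
    if (!is.null(result$volumetrics$dwellAssociations))
      writeTsv(result$volumetrics$dwellAssociations, o("dwell_associations.tsv"))
  }
  cfgJson <- jsonlite::toJSON(result$config, auto_unbox = TRUE, digits = NA,
                              null = "null")
  tmp <- tempfile(); writeLines(cfgJson, tmp)
  manifest <- list(config = result$config,
                   configHash = unname(tools::md5sum(tmp)),
                   k = result$assignment@k, minWindows = result$minWindows,
                   package = as.character(utils::packageVersion("dynstates")))
  unlink(tmp)
  jsonlite::write_json(manifest, o("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(outputDir)
}

#' Validate a cohort input directory
#'
#' Checks the manifest, per-subject TSV shapes, ROI-id consistency against the
#' ROI metadata, motion-file lengths and duplicate subject ids. Problems are
#' reported per file, not raised.
#'
#' @param dir cohort directory
#' @return data.frame file, check, ok, message; attribute "ok" = all checks
#'   passed
#' @export
validateInputs <- function(dir) {
  rows <- list()
  add <- function(file, check, ok, message = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      file = file, check = check, ok = ok, message = message,
      stringsAsFactors = FALSE)
  }
  manPath <- file.path(dir, "manifest.json")
  if (!file.exists(manPath)) {
    add("manifest.json", "exists", FALSE, "missing manifest")
    out <- do.call(rbind, rows); attr(out, "ok") <- FALSE; return(out)
  }
  manifest <- tryCatch(jsonlite::read_json(manPath), error = function(e) NULL)
  add("manifest.json", "parses", !is.null(manifest))
  roiMetaPath <- file.path(dir, "roi_meta.tsv")
  roiMeta <- NULL
  if (file.exists(roiMetaPath)) {
    roiMeta <- readTsv(roiMetaPath)
    add("roi_meta.tsv", "has roi column", "roi" %in% names(roiMeta),
        if (!"roi" %in% names(roiMeta)) "column 'roi' missing" else "")
  } else add("roi_meta.tsv", "exists", FALSE, "missing ROI metadata")
  if (!is.null(manifest)) {
    ids <- vapply(manifest$subjects, function(s) s$subject, character(1))
    add("manifest.json", "unique subjects", !anyDuplicated(ids),
        if (anyDuplicated(ids)) "duplicate subject ids" else "")
    for (entry in manifest$subjects) {
      s <- entry$subject
      sigPath <- file.path(dir, paste0(s, "_signal.tsv"))
      motPath <- file.path(dir, paste0(s, "_motion.tsv"))
      if (!file.exists(sigPath)) { add(basename(sigPath), "exists", FALSE); next }
      sig <- readTsv(sigPath)
      nFrames <- max(vapply(entry$runs, function(r) r$end, numeric(1)))
      add(basename(sigPath), "frame count matches runs", nrow(sig) == nFrames,
          sprintf("%d frames vs %d expected", nrow(sig), nFrames))
      if (!is.null(roiMeta) && "roi" %in% names(roiMeta))
        add(basename(sigPath), "ROI ids match metadata",
            identical(names(sig), roiMeta$roi),
            if (!identical(names(sig), roiMeta$roi)) "ROI columns differ" else "")
      if (!file.exists(motPath)) { add(basename(motPath), "exists", FALSE); next }
      mot <- readTsv(motPath)
      add(basename(motPath), "has required columns",
          all(c("frame", "is_outlier", "fwd_mm") %in% names(mot)))
      add(basename(motPath), "length matches signal", nrow(mot) == nrow(sig),
          sprintf("%d rows vs %d frames", nrow(mot), nrow(sig)))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "ok") <- all(out$ok)
  out
}

#' Planted-state recovery experiment
#'
#' Simulates a synthetic cohort, runs the pipeline through state clustering,
#' and scores recovery of the planted states: recovered non-motion window
#' labels (motion clusters removed) are mapped to planted window labels by
#' majority vote and compared by the adjusted Rand index. Also reports whether
#' the stationary modularity step recovered the planted module layout.
#'
#' @param seed cohort seed
#' @param nSubjectsPerGroup cohort size per group (20 subjects by default)
#' @param config pipeline configuration
#' @return list: ari (mapped adjusted Rand index), k, moduleAri, nMotionClusters
#' @export
stateRecoveryExperiment <- function(seed, nSubjectsPerGroup = 10,
                                    config = pipelineConfig()) {
  scfg <- synthConfig(nSubjectsPerGroup = nSubjectsPerGroup, seed = seed)
  co <- simulateCohort(scfg)
  res <- runPipeline(co, config, characterize = FALSE)
  spec <- windowSpec(config$width, config$step)
  planted <- do.call(rbind, lapply(names(co$timeSeries), function(s)
    windowPlantedLabels(co$groundTruth$stateLabels[[s]],
                        co$timeSeries[[s]]@runBoundaries, spec)))
  meta <- windowMeta(res$assignment)
  cs <- clusterSummary(res$assignment)
  keep <- !meta$isMotionWindow &
    !(meta$state %in% cs$state[cs$isMotionCluster])
  rec <- meta$state[keep]
  truth <- planted$plantedState[keep]
  map <- vapply(split(truth, rec),
                function(v) as.integer(names(which.max(table(v)))), integer(1))
  list(ari = adjustedRandIndex(map[as.character(rec)], truth),
       k = res$assignment@k,
       moduleAri = adjustedRandIndex(
         membership(res$partition)[names(co$groundTruth$modules)],
         co$groundTruth$modules),
       nMotionClusters = sum(cs$isMotionCluster))
}
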