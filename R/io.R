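#' @include AllClasses.R
NULL

writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path, ...) {
  utils::read.delim(path, sep = "\t", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write a cohort to disk
#'
#' Writes per-subject signal TSVs (frames x ROIs, header = ROI ids),
#' per-subject motion TSVs (frame, is_outlier, fwd_mm), a cohort manifest JSON
#' (subject ids, groups, run boundaries, network tiers), ROI metadata TSV,
#' volume and behavior TSVs, and (for synthetic cohorts) a ground-truth JSON.
#'
#' @param cohort a cohort list as returned by \code{\link{simulateCohort}}
#' @param dir output directory (created if needed)
#' @return dir, invisibly
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- names(cohort$timeSeries)
  manifest <- list(subjects = lapply(subjects, function(s) {
    ts <- cohort$timeSeries[[s]]
    list(subject = s, group = ts@group,
         runs = lapply(seq_len(nrow(ts@runBoundaries)), function(r)
           as.list(ts@runBoundaries[r, c("run", "start", "end")])))
  }), networks = cohort$networks)
  for (s in subjects) {
    ts <- cohort$timeSeries[[s]]
    writeTsv(as.data.frame(ts@signal), file.path(dir, paste0(s, "_signal.tsv")))
    writeTsv(data.frame(frame = seq_along(ts@outlierMask),
                        is_outlier = as.integer(ts@outlierMask),
                        fwd_mm = ts@fwd),
             file.path(dir, paste0(s, "_motion.tsv")))
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  writeTsv(cohort$roiMeta, file.path(dir, "roi_meta.tsv"))
  writeTsv(cbind(data.frame(subject = rownames(cohort$volumes)),
                 as.data.frame(cohort$volumes)),
           file.path(dir, "volumes.tsv"))
  writeTsv(cohort$behavior, file.path(dir, "behavior.tsv"))
  if (!is.null(cohort$groundTruth)) {
    gt <- cohort$groundTruth
    jsonlite::write_json(
      list(stateLabels = gt$stateLabels, outlierFrames = gt$outlierFrames,
           groups = as.list(gt$groups), modules = as.list(gt$modules),
           boostState = gt$boostState, atrophyRois = gt$atrophyRois),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

#' Read a cohort from disk
#'
#' Inverse of \code{\link{writeCohort}} (the ground-truth covariances are not
#' round-tripped; labels, masks and tables are).
#'
#' @param dir cohort directory
#' @return cohort list (timeSeries, volumes, behavior, networks, roiMeta, and
#'   groundTruth when present)
#' @export
readCohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  ts <- list()
  for (entry in manifest$subjects) {
    s <- entry$subject
    sig <- as.matrix(readTsv(file.path(dir, paste0(s, "_signal.tsv"))))
    mot <- readTsv(file.path(dir, paste0(s, "_motion.tsv")))
    rb <- do.call(rbind, lapply(entry$runs, function(r)
      data.frame(run = r$run, start = r$start, end = r$end)))
    ts[[s]] <- methods::new("RoiTimeSeries", subject = s, group = entry$group,
                            signal = sig, runBoundaries = rb,
                            outlierMask = mot$is_outlier == 1,
                            fwd = mot$fwd_mm)
  }
  networks <- manifest$networks
  networks$tiers <- lapply(networks$tiers, function(t) unlist(t))
  vol <- readTsv(file.path(dir, "volumes.tsv"))
  volumes <- as.matrix(vol[, -1, drop = FALSE])
  rownames(volumes) <- vol$subject
  out <- list(timeSeries = ts, volumes = volumes,
              behavior = readTsv(file.path(dir, "behavior.tsv")),
              networks = networks,
              roiMeta = readTsv(file.path(dir, "roi_meta.tsv")))
  gtPath <- file.path(dir, "ground_truth.json")
  if (file.exists(gtPath)) {
    gt <- jsonlite::read_json(gtPath)
    out$groundTruth <- list(
      stateLabels = lapply(gt$stateLabels, function(x) unlist(x)),
      outlierFrames = lapply(gt$outlierFrames, function(x) unlist(x)),
      groups = unlist(gt$groups),
      modules = unlist(gt$modules),
      boostState = gt$boostState,
      atrophyRois = unlist(gt$atrophyRois))
  }
  out
}

#' Load network definitions from YAML
#'
#' Reads tiered network definitions (increments per tier) and returns them
#' with cumulative tier ROI sets, matching the nested-tier convention of
#' \code{\link{networkComposites}}. A default file with the emotional
#' modulatory and emotional motor networks ships with the package:
#' \code{system.file("extdata", "networks_emotional.yaml", package =
#' "dynstates")}.
#'
#' @param path YAML file with a \code{networks} list (name, tiers)
#' @return named list of networks, each with \code{name} and cumulative
#'   \code{tiers}
#' @export
readNetworks <- function(path) {
  y <- yaml::read_yaml(path)
  nets <- lapply(y$networks, function(nw) {
    acc <- character(0)
    tiers <- list()
    prevName <- NULL
    for (tn in names(nw$tiers)) {
      acc <- union(acc, unlist(nw$tiers[[tn]]))
      cumName <- if (is.null(prevName)) tn else paste0(prevName, "+", tn)
      tiers[[cumName]] <- acc
      prevName <- cumName
    }
    list(name = nw$name, tiers = tiers)
  })
  stats::setNames(nets, vapply(nets, `[[`, character(1), "name"))
}
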