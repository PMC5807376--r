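# End-to-end orchestration: simulate (or read) -> preprocess -> PCA ->
# control variables -> cross-validation -> group statistics, with a results
# manifest for reproducibility.

#' Assemble a pipeline run configuration
#'
#' Defaults follow the standard analysis chain: 240 Hz / 80 s trials,
#' 7 Hz Butterworth cutoff, order-50 FIR differentiator (5/7 Hz bands),
#' 9 retained components, 15 degree robustness threshold, alpha = 0.05.
#'
#' @param synthetic a \linkS4class{SyntheticConfig}, or NULL when reading
#'   marker CSV files from \code{inputDir}.
#' @param inputDir directory of marker CSV files (used when
#'   \code{synthetic} is NULL).
#' @param outDir output directory for result artifacts (default: a fresh
#'   temporary directory).
#' @param settings a \linkS4class{KinematicsSettings}.
#' @param r number of components retained for reporting.
#' @param crossvalThreshold robustness threshold in degrees.
#' @param alpha significance level.
#' @param seed integer seed recorded in the manifest and used for the
#'   synthetic stage.
#' @param writeCohort also write the raw marker CSVs (large; default FALSE).
#' @return a named list of class \code{pmRunConfig}.
#' @export
runConfig <- function(synthetic = syntheticConfig(), inputDir = NULL,
                      outDir = NULL, settings = kinematicsSettings(),
                      r = 9, crossvalThreshold = 15, alpha = 0.05,
                      seed = 1L, writeCohort = FALSE) {
  .stopIf(is.null(synthetic) && is.null(inputDir),
          "either a synthetic config or an input directory is required")
  .stopIf(!is.null(inputDir) && !dir.exists(inputDir),
          "input directory does not exist: %s", inputDir)
  if (!is.null(synthetic)) synthetic@seed <- as.numeric(seed)
  structure(list(synthetic = synthetic, inputDir = inputDir, outDir = outDir,
                 settings = settings, r = r,
                 crossvalThreshold = crossvalThreshold, alpha = alpha,
                 seed = as.integer(seed), writeCohort = isTRUE(writeCohort)),
            class = "pmRunConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the \code{\link{runConfig}} arguments; the
#' \code{synthetic} and \code{settings} blocks mirror
#' \code{\link{syntheticConfig}} and \code{\link{kinematicsSettings}}.
#' Group effects are given as a list of \code{\{group, mode, amplitude,
#' frequency, jitter\}} entries.
#'
#' @param path YAML file path.
#' @return a \code{pmRunConfig}.
#' @export
readRunConfig <- function(path) {
  .stopIf(!file.exists(path), "config file not found: %s", path)
  y <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(y$synthetic)) {
    sy <- y$synthetic
    if (!is.null(sy$nSubjectsPerCell)) sy$nSubjectsPerCell <- unlist(sy$nSubjectsPerCell)
    syn <- do.call(syntheticConfig, sy)
  }
  st <- if (!is.null(y$settings)) do.call(kinematicsSettings, y$settings)
        else kinematicsSettings()
  args <- y[setdiff(names(y), c("synthetic", "settings"))]
  do.call(runConfig, c(list(synthetic = syn, settings = st), args))
}

# preprocess one raw trajectory into a PostureMatrix
.preprocessOne <- function(traj, policy, segmentMap, gapRank = 10L) {
  if (any(traj@missingMask)) traj <- fillGaps(traj, rank = gapRank)
  traj <- selectMarkers(traj, policy)
  if (traj@frontFoot == "left") traj <- mirrorLeftFront(traj)
  normalizeAndWeight(traj, segmentWeights(traj@markerLabels, segmentMap))
}

#' Run the full principal-movement analysis pipeline
#'
#' Executes all stages in order — cohort simulation (or CSV input), gap
#' filling, marker selection, mirroring, normalization and weighting, pooled
#' PCA, per-subject scores and relative amplitudes, posture-space kinematics
#' and control variables, leave-one-out eigenvector cross-validation, and the
#' group-statistics report — writing each result table as CSV into the output
#' directory together with a JSON manifest (inputs, seed, file checksums).
#' Runs are idempotent: the same config and seed give identical artifacts.
#'
#' @param config a \code{pmRunConfig} from \code{\link{runConfig}} /
#'   \code{\link{readRunConfig}}.
#' @return (invisibly) a list with the in-memory results: \code{model},
#'   \code{scores}, \code{rstd}, \code{control}, \code{crossval},
#'   \code{stats}, \code{meta}, \code{truth} (synthetic runs), and
#'   \code{manifest}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pmRunConfig"))
  outDir <- config$outDir
  if (is.null(outDir)) outDir <- tempfile("pmrun")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)

  truth <- NULL
  if (!is.null(config$synthetic)) {
    cohort <- generateCohort(config$synthetic)
    rawSubjects <- cohort$subjects
    truth <- cohort$truth
    segmentMap <- makeBasePosture(config$synthetic@nMarkers,
                                  seed = config$synthetic@seed)$segmentMap
  } else {
    files <- sort(list.files(config$inputDir, pattern = "\\.csv$",
                             full.names = TRUE))
    .stopIf(!length(files), "no CSV marker files in %s", config$inputDir)
    rawSubjects <- lapply(files, readMarkers)
    names(rawSubjects) <- vapply(rawSubjects, subjectId, "")
    segmentMap <- makeBasePosture(37)$segmentMap
  }
  policy <- defaultMarkerPolicy()
  policy$drop <- intersect(policy$drop, rawSubjects[[1]]@markerLabels)
  if (!length(policy$drop)) policy <- list(keep = rawSubjects[[1]]@markerLabels)

  postures <- lapply(rawSubjects, .preprocessOne, policy = policy,
                     segmentMap = segmentMap)
  meta <- do.call(rbind, lapply(rawSubjects, function(s)
    data.frame(subject_id = s@subjectId, age_group = s@ageGroup,
               gender = s@gender, height = s@height, mass = s@mass)))
  rownames(meta) <- NULL

  pooled <- concatenateSubjects(postures)
  r <- min(config$r, ncol(pooled@coords))
  model <- fitPCA(pooled, r = r)
  r <- ncol(model@rotation)

  scoresList <- lapply(postures, projectSubject, model = model)
  rstd <- do.call(rbind, lapply(scoresList, relativeStd))
  rownames(rstd) <- NULL
  control <- cohortControlVariables(scoresList, config$settings, rstd)
  crossval <- looCrossval(postures, r = r,
                          threshold = config$crossvalThreshold)
  stats <- fullReport(control, meta, r = r, alpha = config$alpha)

  evTab <- data.frame(k = seq_len(r), eigenvalue = model@eigenvalues,
                      explained_pct = model@explainedPct)
  files <- list(
    eigenvalues = "eigenvalues.csv", rstd = "rstd.csv",
    control = "control.csv", crossval = "crossval.csv",
    anova = "anova.csv", subjects = "subjects.csv"
  )
  write.csv(evTab, file.path(outDir, files$eigenvalues), row.names = FALSE)
  write.csv(rstd, file.path(outDir, files$rstd), row.names = FALSE)
  write.csv(control, file.path(outDir, files$control), row.names = FALSE)
  cvOut <- crossval; attributes(cvOut)[c("n_folds", "threshold")] <- NULL
  write.csv(cvOut, file.path(outDir, files$crossval), row.names = FALSE)
  write.csv(stats$anova, file.path(outDir, files$anova), row.names = FALSE)
  write.csv(meta, file.path(outDir, files$subjects), row.names = FALSE)
  if (!is.null(stats$posthoc)) {
    files$posthoc <- "posthoc.csv"
    write.csv(stats$posthoc, file.path(outDir, files$posthoc), row.names = FALSE)
  }
  if (config$writeCohort) {
    cohortDir <- file.path(outDir, "cohort")
    dir.create(cohortDir, showWarnings = FALSE)
    for (s in rawSubjects)
      writeMarkers(s, file.path(cohortDir, paste0(s@subjectId, ".csv")))
  }
  sums <- tools::md5sum(file.path(outDir, unlist(files)))
  manifest <- list(
    seed = config$seed,
    n_subjects = length(rawSubjects),
    n_components = r,
    crossval_threshold = config$crossvalThreshold,
    alpha = config$alpha,
    settings = list(
      butterworth_order = config$settings@butterworthOrder,
      cutoff_hz = config$settings@cutoffHz,
      fir_order = config$settings@firOrder,
      pass_hz = config$settings@passHz, stop_hz = config$settings@stopHz,
      edge_trim_s = config$settings@edgeTrimS),
    files = as.list(setNames(unname(sums), unlist(files)))
  )
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(model = model, scores = scoresList, rstd = rstd,
                 control = control, crossval = crossval, stats = stats,
                 meta = meta, truth = truth, manifest = manifest,
                 outDir = outDir))
}
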