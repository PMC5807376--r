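#' @rdname accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))

#' @rdname accessors
#' @export
setGeneric("markerLabels", function(x) standardGeneric("markerLabels"))

#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))

#' @rdname accessors
#' @export
setGeneric("markerPositions", function(x) standardGeneric("markerPositions"))

#' @rdname accessors
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname accessors
#' @export
setGeneric("postureCoords", function(x) standardGeneric("postureCoords"))

#' @rdname accessors
#' @export
setGeneric("markerWeights", function(x) standardGeneric("markerWeights"))

#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(x) standardGeneric("eigenvectors"))

#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(x) standardGeneric("eigenvalues"))

#' @rdname accessors
#' @export
setGeneric("explainedVariance", function(x) standardGeneric("explainedVariance"))

#' @rdname accessors
#' @export
setGeneric("scores", function(x) standardGeneric("scores"))

#' @rdname accessors
#' @export
setGeneric("accelerations", function(x) standardGeneric("accelerations"))

#' @rdname accessors
#' @export
setGeneric("velocities", function(x) standardGeneric("velocities"))

#' @rdname accessors
#' @export
setGeneric("validRange", function(x) standardGeneric("validRange"))

#' Accessors for posturePM objects
#'
#' Small read-only accessors for the S4 containers; user code should use
#' these rather than reaching into slots.
#'
#' @param x a posturePM object.
#' @return The corresponding slot value.
#' @name accessors
NULL

#' @rdname accessors
setMethod("subjectId", "MarkerTrajectorySet", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "PostureMatrix", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "SubjectScores", function(x) x@subjectId)
#' @rdname accessors
setMethod("subjectId", "PMKinematics", function(x) x@subjectId)

#' @rdname accessors
setMethod("markerLabels", "MarkerTrajectorySet", function(x) x@markerLabels)
#' @rdname accessors
setMethod("markerLabels", "PostureMatrix", function(x) x@markerLabels)
#' @rdname accessors
setMethod("markerLabels", "PooledPostures", function(x) x@markerLabels)
#' @rdname accessors
setMethod("markerLabels", "PCAModel", function(x) x@markerLabels)

#' @rdname accessors
setMethod("sampleRate", "MarkerTrajectorySet", function(x) x@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "PostureMatrix", function(x) x@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "SubjectScores", function(x) x@sampleRate)
#' @rdname accessors
setMethod("sampleRate", "PMKinematics", function(x) x@sampleRate)

#' @rdname accessors
setMethod("markerPositions", "MarkerTrajectorySet", function(x) x@positions)
#' @rdname accessors
setMethod("missingMask", "MarkerTrajectorySet", function(x) x@missingMask)

#' @rdname accessors
setMethod("postureCoords", "PostureMatrix", function(x) x@coords)
#' @rdname accessors
setMethod("postureCoords", "PooledPostures", function(x) x@coords)

#' @rdname accessors
setMethod("markerWeights", "PostureMatrix", function(x) x@weights)
#' @rdname accessors
setMethod("markerWeights", "PooledPostures", function(x) x@weights)

#' @rdname accessors
setMethod("eigenvectors", "PCAModel", function(x) x@rotation)
#' @rdname accessors
setMethod("eigenvalues", "PCAModel", function(x) x@eigenvalues)
#' @rdname accessors
setMethod("explainedVariance", "PCAModel", function(x) x@explainedPct)

#' @rdname accessors
setMethod("scores", "SubjectScores", function(x) x@scores)
#' @rdname accessors
setMethod("scores", "PMKinematics", function(x) x@position)
#' @rdname accessors
setMethod("velocities", "PMKinematics", function(x) x@velocity)
#' @rdname accessors
setMethod("accelerations", "PMKinematics", function(x) x@acceleration)
#' @rdname accessors
setMethod("validRange", "PMKinematics", function(x) x@validRange)

setMethod("show", "MarkerTrajectorySet", function(object) {
  d <- dim(object@positions)
  cat("MarkerTrajectorySet '", object@subjectId, "'\n", sep = "")
  cat(sprintf("  %d frames x %d markers @ %g Hz (%.1f s)\n",
              d[1], d[2], object@sampleRate, d[1] / object@sampleRate))
  cat(sprintf("  %s / %s, height %.2f m, front foot %s, %.2f%% samples missing\n",
              object@ageGroup, object@gender, object@height, object@frontFoot,
              100 * mean(object@missingMask)))
})

setMethod("show", "PostureMatrix", function(object) {
  cat("PostureMatrix '", object@subjectId, "'\n", sep = "")
  cat(sprintf("  %d frames x %d coordinates (%d markers), centered/normalized/weighted\n",
              nrow(object@coords), ncol(object@coords), length(object@markerLabels)))
})

setMethod("show", "PooledPostures", function(object) {
  cat(sprintf("PooledPostures: %d frames x %d coordinates, %d subjects\n",
              nrow(object@coords), ncol(object@coords),
              length(unique(object@index$subject_id))))
})

setMethod("show", "PCAModel", function(object) {
  r <- ncol(object@rotation)
  cat(sprintf("PCAModel: %d principal movements in %d-dimensional posture space\n",
              r, nrow(object@rotation)))
  k <- seq_len(min(r, 9L))
  cat("  EV% :", paste(sprintf("%.2f", object@explainedPct[k]), collapse = " "), "\n")
  cat(sprintf("  fitted on %d subjects, %d pooled frames\n",
              length(object@subjects), object@nObs))
})

setMethod("show", "SubjectScores", function(object) {
  cat(sprintf("SubjectScores '%s': %d frames x %d components @ %g Hz\n",
              object@subjectId, nrow(object@scores), ncol(object@scores),
              object@sampleRate))
})

setMethod("show", "PMKinematics", function(object) {
  vr <- object@validRange
  cat(sprintf("PMKinematics '%s': %d frames x %d components, valid window [%d, %d] (%.2f s)\n",
              object@subjectId, nrow(object@position), ncol(object@position),
              vr[1], vr[2], (vr[2] - vr[1] + 1) / object@sampleRate))
})

setMethod("show", "KinematicsSettings", function(object) {
  cat(sprintf(
    "KinematicsSettings: Butterworth order %d @ %g Hz (zero-phase); FIR differentiator order %d, pass %g / stop %g Hz; edge trim %g s\n",
    object@butterworthOrder, object@cutoffHz, object@firOrder,
    object@passHz, object@stopHz, object@edgeTrimS))
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig:\n")
  cat(sprintf("  %s subjects (young F/M, old F/M), %g s @ %g Hz, %d markers\n",
              paste(object@nSubjectsPerCell[c("young_female", "young_male",
                                              "old_female", "old_male")],
                    collapse = "/"),
              object@duration, object@sampleRate, as.integer(object@nMarkers)))
  cat(sprintf("  %d modes; amplitudes %s; frequencies %s Hz; jitter %s\n",
              as.integer(object@nModes),
              paste(signif(object@modeAmplitudes, 3), collapse = ", "),
              paste(object@modeFrequencies, collapse = ", "),
              paste(object@frequencyJitter, collapse = ", ")))
  cat(sprintf("  noise SD %g m, gap fraction %g, %d group effect(s), seed %d\n",
              object@measurementNoiseSD, object@gapFraction,
              length(object@groupEffects), as.integer(object@seed)))
})
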