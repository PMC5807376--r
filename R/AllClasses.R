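#' @import methods
NULL

#' One subject's raw marker trajectories
#'
#' Container for a single subject's 3D marker time series and the subject
#' metadata needed by the preprocessing chain. Coordinates are in meters in
#' the laboratory frame (x anterior, y leftward, z up). Samples flagged in
#' \code{missingMask} are occlusion gaps; their coordinates are \code{NA}.
#'
#' @slot subjectId character scalar.
#' @slot markerLabels character vector, one unique label per marker.
#' @slot positions numeric array, frames x markers x 3, meters.
#' @slot missingMask logical matrix, frames x markers.
#' @slot sampleRate sampling rate in Hz.
#' @slot height subject height in meters.
#' @slot mass subject mass in kg.
#' @slot ageGroup \code{"young"} or \code{"old"}.
#' @slot gender \code{"female"} or \code{"male"}.
#' @slot frontFoot foot placed in front in the tandem stance, \code{"left"}
#'   or \code{"right"}.
#'
#' @exportClass MarkerTrajectorySet
setClass("MarkerTrajectorySet",
  representation(
    subjectId = "character",
    markerLabels = "character",
    positions = "array",
    missingMask = "matrix",
    sampleRate = "numeric",
    height = "numeric",
    mass = "numeric",
    ageGroup = "character",
    gender = "character",
    frontFoot = "character"
  )
)

setValidity("MarkerTrajectorySet", function(object) {
  msg <- character()
  d <- dim(object@positions)
  M <- length(object@markerLabels)
  if (length(d) != 3L || d[3] != 3L)
    msg <- c(msg, "'positions' must be a frames x markers x 3 array")
  else {
    if (d[2] != M)
      msg <- c(msg, "marker dimension of 'positions' must match 'markerLabels'")
    if (!identical(dim(object@missingMask), d[1:2]))
      msg <- c(msg, "'missingMask' must be frames x markers")
    else {
      obs <- object@positions[!array(object@missingMask, dim = d)]
      if (anyNA(obs) || any(!is.finite(obs)))
        msg <- c(msg, "positions must be finite wherever missingMask is FALSE")
    }
  }
  if (anyDuplicated(object@markerLabels))
    msg <- c(msg, "marker labels must be unique")
  if (length(object@sampleRate) != 1L || object@sampleRate <= 0)
    msg <- c(msg, "'sampleRate' must be a positive scalar")
  if (length(object@height) != 1L || object@height <= 0)
    msg <- c(msg, "'height' must be a positive scalar")
  if (!object@ageGroup %in% c("young", "old"))
    msg <- c(msg, "'ageGroup' must be \"young\" or \"old\"")
  if (!object@gender %in% c("female", "male"))
    msg <- c(msg, "'gender' must be \"female\" or \"male\"")
  if (!object@frontFoot %in% c("left", "right"))
    msg <- c(msg, "'frontFoot' must be \"left\" or \"right\"")
  if (length(msg)) msg else TRUE
})

#' Centered, normalized, mass-weighted posture vectors of one subject
#'
#' Rows are frames, columns the marker coordinates in marker-major order
#' (x, y, z per marker). Values are dimensionless: each frame's marker vector
#' has the subject's mean posture subtracted, is divided by the subject's
#' height, and each marker's three coordinates are multiplied by the marker's
#' relative segment-mass weight. \code{meanPosture} is stored in the same
#' normalization but before weighting.
#'
#' @slot subjectId character scalar.
#' @slot coords frames x (3 M) numeric matrix.
#' @slot meanPosture length-3M numeric vector (height-normalized, unweighted).
#' @slot markerLabels selected marker labels (length M).
#' @slot weights named per-marker mass weights, summing to 1 over the labels.
#' @slot height,sampleRate subject height (m) and sampling rate (Hz).
#' @slot ageGroup,gender,mass subject metadata carried through the pipeline.
#'
#' @exportClass PostureMatrix
setClass("PostureMatrix",
  representation(
    subjectId = "character",
    coords = "matrix",
    meanPosture = "numeric",
    markerLabels = "character",
    weights = "numeric",
    height = "numeric",
    sampleRate = "numeric",
    ageGroup = "character",
    gender = "character",
    mass = "numeric"
  )
)

setValidity("PostureMatrix", function(object) {
  msg <- character()
  M <- length(object@markerLabels)
  if (ncol(object@coords) != 3L * M)
    msg <- c(msg, "'coords' must have 3 columns per marker")
  if (length(object@meanPosture) != 3L * M)
    msg <- c(msg, "'meanPosture' must have length 3 * n_markers")
  if (length(object@weights) != M || any(object@weights <= 0))
    msg <- c(msg, "'weights' must be positive, one per marker")
  if (nrow(object@coords) > 0 &&
      max(abs(colMeans(object@coords))) > 1e-10)
    msg <- c(msg, "columns of 'coords' must have zero mean (subject-wise centering)")
  if (length(msg)) msg else TRUE
})

#' Pooled posture matrix across subjects
#'
#' Row-wise concatenation of subjects' \linkS4class{PostureMatrix} coordinate
#' matrices, with an index mapping every row back to its (subject, frame).
#'
#' @slot coords pooled frames x (3 M) matrix.
#' @slot index data.frame with columns \code{subject_id}, \code{frame}.
#' @slot markerLabels shared marker labels.
#' @slot weights shared per-marker weights.
#'
#' @exportClass PooledPostures
setClass("PooledPostures",
  representation(
    coords = "matrix",
    index = "data.frame",
    markerLabels = "character",
    weights = "numeric"
  )
)

setValidity("PooledPostures", function(object) {
  msg <- character()
  if (nrow(object@index) != nrow(object@coords))
    msg <- c(msg, "'index' must have one row per pooled frame")
  if (!all(c("subject_id", "frame") %in% names(object@index)))
    msg <- c(msg, "'index' needs columns subject_id, frame")
  if (ncol(object@coords) != 3L * length(object@markerLabels))
    msg <- c(msg, "'coords' must have 3 columns per marker")
  if (length(msg)) msg else TRUE
})

#' Principal movement basis fitted on pooled posture vectors
#'
#' Eigenvectors (principal movement directions \code{PC_k}) of the pooled
#' posture matrix, their eigenvalues \code{EV_k} (pooled variance along each
#' component, population convention) in non-increasing order, and the percent
#' of total variance each explains.
#'
#' @slot rotation (3 M) x r matrix of orthonormal eigenvector columns.
#' @slot eigenvalues length-r non-increasing variances.
#' @slot explainedPct eigenvalues as percent of the total variance (all
#'   components, not just the retained r).
#' @slot totalVariance total pooled variance (sum over all components).
#' @slot markerLabels coordinate-space marker labels.
#' @slot subjects subject ids the model was fitted on.
#' @slot nObs number of pooled frames.
#'
#' @exportClass PCAModel
setClass("PCAModel",
  representation(
    rotation = "matrix",
    eigenvalues = "numeric",
    explainedPct = "numeric",
    totalVariance = "numeric",
    markerLabels = "character",
    subjects = "character",
    nObs = "integer"
  )
)

setValidity("PCAModel", function(object) {
  msg <- character()
  r <- ncol(object@rotation)
  if (length(object@eigenvalues) != r)
    msg <- c(msg, "one eigenvalue per eigenvector required")
  if (r > 1 && any(diff(object@eigenvalues) > 1e-8 * max(object@eigenvalues, 1e-300)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (r > 0) {
    g <- crossprod(object@rotation)
    if (max(abs(g - diag(r))) > 1e-8)
      msg <- c(msg, "eigenvectors must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' Principal position score series of one subject
#'
#' The principal positions \code{PP_k(t)}: projections of a subject's
#' normalized posture vectors onto the principal movement basis.
#'
#' @slot subjectId character scalar.
#' @slot scores frames x r matrix of principal positions (dimensionless).
#' @slot sampleRate Hz.
#'
#' @exportClass SubjectScores
setClass("SubjectScores",
  representation(
    subjectId = "character",
    scores = "matrix",
    sampleRate = "numeric"
  )
)

#' Filtering and differentiation settings for posture-space kinematics
#'
#' Defaults follow the standard analysis chain for 240 Hz postural data:
#' a 5th-order Butterworth lowpass at 7 Hz applied zero-phase to the score
#' series, and an order-50 linear-phase FIR lowpass differentiator with
#' 5 Hz passband edge and 7 Hz stopband edge applied twice to obtain
#' accelerations, with 0.5 s trimmed from both ends of the trial to discard
#' filter transients.
#'
#' @slot butterworthOrder integer, Butterworth order (default 5).
#' @slot cutoffHz Butterworth cutoff in Hz (default 7).
#' @slot firOrder FIR differentiator order, even (default 50).
#' @slot passHz,stopHz differentiator band edges in Hz (defaults 5, 7).
#' @slot edgeTrimS seconds trimmed from each end of the trial (default 0.5).
#'
#' @exportClass KinematicsSettings
setClass("KinematicsSettings",
  representation(
    butterworthOrder = "numeric",
    cutoffHz = "numeric",
    firOrder = "numeric",
    passHz = "numeric",
    stopHz = "numeric",
    edgeTrimS = "numeric"
  ),
  prototype(
    butterworthOrder = 5, cutoffHz = 7, firOrder = 50,
    passHz = 5, stopHz = 7, edgeTrimS = 0.5
  )
)

setValidity("KinematicsSettings", function(object) {
  msg <- character()
  if (object@passHz >= object@stopHz)
    msg <- c(msg, "'passHz' must be smaller than 'stopHz'")
  if (object@butterworthOrder < 1 || object@cutoffHz <= 0)
    msg <- c(msg, "Butterworth order and cutoff must be positive")
  if (object@firOrder < 2 || object@firOrder %% 2 != 0)
    msg <- c(msg, "'firOrder' must be a positive even integer (type III design)")
  if (object@edgeTrimS < 0)
    msg <- c(msg, "'edgeTrimS' must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Posture-space kinematics of one subject
#'
#' Filtered principal positions and their first and second derivatives
#' (principal velocities \code{PV_k} and accelerations \code{PA_k}).
#' Derivative edges carry \code{NA} over the FIR group delay; analyses use
#' the \code{validRange} window, which also excludes \code{edgeTrimS}
#' seconds at both ends.
#'
#' @slot subjectId character scalar.
#' @slot position,velocity,acceleration frames x r matrices.
#' @slot sampleRate Hz.
#' @slot validRange integer first and last valid sample index.
#' @slot settings the \linkS4class{KinematicsSettings} used.
#'
#' @exportClass PMKinematics
setClass("PMKinematics",
  representation(
    subjectId = "character",
    position = "matrix",
    velocity = "matrix",
    acceleration = "matrix",
    sampleRate = "numeric",
    validRange = "integer",
    settings = "KinematicsSettings"
  )
)

setValidity("PMKinematics", function(object) {
  msg <- character()
  n <- nrow(object@position)
  if (nrow(object@velocity) != n || nrow(object@acceleration) != n)
    msg <- c(msg, "position, velocity and acceleration must have equal length")
  if (length(object@validRange) != 2L ||
      object@validRange[1] < 1L || object@validRange[2] > n ||
      object@validRange[1] > object@validRange[2])
    msg <- c(msg, "'validRange' must lie inside the trial")
  if (length(msg)) msg else TRUE
})

#' Configuration of the synthetic motion-capture cohort generator
#'
#' See \code{\link{syntheticConfig}} for the user constructor and defaults.
#'
#' @slot nSubjectsPerCell named integer vector, subjects per
#'   (age group x gender) cell: \code{young_female}, \code{young_male},
#'   \code{old_female}, \code{old_male}.
#' @slot duration trial duration in seconds.
#' @slot sampleRate Hz.
#' @slot nMarkers number of markers (>= 4).
#' @slot nModes number K of planted movement modes.
#' @slot modeAmplitudes strictly decreasing positive amplitudes
#'   (normalized-posture units).
#' @slot modeFrequencies dominant frequencies in Hz.
#' @slot frequencyJitter per-mode relative SD of the instantaneous
#'   half-cycle period (control irregularity).
#' @slot groupEffects list of multiplicative modifiers, each a list with
#'   elements \code{group}, \code{mode} and any of \code{amplitude},
#'   \code{frequency}, \code{jitter}.
#' @slot measurementNoiseSD marker noise SD in meters.
#' @slot gapFraction fraction of samples lost to occlusion gaps per marker.
#' @slot heights range (min, max) of uniformly drawn subject heights, meters.
#' @slot subjectAmpCV,subjectFreqCV between-subject log-normal coefficients
#'   of variation of mode amplitude and frequency.
#' @slot seed integer RNG seed.
#'
#' @exportClass SyntheticConfig
setClass("SyntheticConfig",
  representation(
    nSubjectsPerCell = "numeric",
    duration = "numeric",
    sampleRate = "numeric",
    nMarkers = "numeric",
    nModes = "numeric",
    modeAmplitudes = "numeric",
    modeFrequencies = "numeric",
    frequencyJitter = "numeric",
    groupEffects = "list",
    measurementNoiseSD = "numeric",
    gapFraction = "numeric",
    heights = "numeric",
    subjectAmpCV = "numeric",
    subjectFreqCV = "numeric",
    seed = "numeric"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  K <- object@nModes
  if (object@nMarkers < 4)
    msg <- c(msg, "'nMarkers' must be at least 4")
  if (length(object@modeAmplitudes) != K ||
      length(object@modeFrequencies) != K ||
      length(object@frequencyJitter) != K)
    msg <- c(msg, "amplitudes, frequencies and jitter must have one entry per mode")
  if (any(object@modeAmplitudes < 0))
    msg <- c(msg, "mode amplitudes must be non-negative")
  if (K > 1 && any(diff(object@modeAmplitudes) >= 0))
    msg <- c(msg, "mode amplitudes must be strictly decreasing (identifiable ordering)")
  if (any(object@modeFrequencies <= 0) ||
      any(object@modeFrequencies >= object@sampleRate / 2))
    msg <- c(msg, "mode frequencies must lie in (0, sampleRate/2)")
  if (any(object@frequencyJitter < 0))
    msg <- c(msg, "'frequencyJitter' must be non-negative")
  if (object@gapFraction < 0 || object@gapFraction >= 0.5)
    msg <- c(msg, "'gapFraction' must lie in [0, 0.5)")
  if (K > 3 * object@nMarkers)
    msg <- c(msg, "cannot plant more modes than posture-space dimensions")
  if (!all(c("young_female", "young_male", "old_female", "old_male") %in%
           names(object@nSubjectsPerCell)))
    msg <- c(msg, "'nSubjectsPerCell' must name all four age x gender cells")
  if (any(object@nSubjectsPerCell < 0))
    msg <- c(msg, "cell sizes must be non-negative")
  if (object@duration <= 0 || object@sampleRate <= 0)
    msg <- c(msg, "'duration' and 'sampleRate' must be positive")
  if (length(object@heights) != 2L || any(object@heights <= 0) ||
      object@heights[1] > object@heights[2])
    msg <- c(msg, "'heights' must be a positive (min, max) range")
  if (length(msg)) msg else TRUE
})
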