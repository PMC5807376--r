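# Synthetic motion-capture cohort with planted movement modes.
#
# The generator inverts the preprocessing chain: orthonormal modes are planted
# in the centered/height-normalized/mass-weighted posture space, per-subject
# score series drive them, and the result is mapped back to lab coordinates
# (un-weight, un-normalize, add the mean posture) before measurement noise and
# occlusion gaps are applied. Every planted quantity is returned as ground
# truth so downstream stages can be tested by parameter recovery.

# full-body template: 15 bilateral pairs + 7 midline markers = 37
.pairRoots <- c("FHD", "BHD", "SHO", "ELB", "FRM", "WRA", "WRB", "ASI", "PSI",
                "THI", "KNE", "TIB", "ANK", "HEE", "TOE")
.midlineLabels <- c("HDTP", "C7", "CLAV", "STRN", "T10", "RBAK", "SACR")

# template coordinates for a 1.72 m standing subject (x anterior, y left, z up)
.templateXYZ <- list(
  HDTP = c(0.00, 0.00, 1.72), C7 = c(-0.07, 0.00, 1.50),
  CLAV = c(0.06, 0.00, 1.47), STRN = c(0.09, 0.00, 1.32),
  T10 = c(-0.10, 0.00, 1.28), RBAK = c(-0.11, -0.09, 1.40),
  SACR = c(-0.13, 0.00, 1.05),
  FHD = c(0.09, 0.06, 1.65), BHD = c(-0.07, 0.07, 1.64),
  SHO = c(0.00, 0.19, 1.45), ELB = c(0.00, 0.24, 1.14),
  FRM = c(0.02, 0.25, 1.03), WRA = c(0.03, 0.27, 0.93),
  WRB = c(0.01, 0.29, 0.93), ASI = c(0.09, 0.12, 1.02),
  PSI = c(-0.12, 0.05, 1.04), THI = c(0.04, 0.16, 0.76),
  KNE = c(0.02, 0.12, 0.50), TIB = c(0.02, 0.14, 0.30),
  ANK = c(0.00, 0.11, 0.08), HEE = c(-0.06, 0.10, 0.03),
  TOE = c(0.12, 0.10, 0.02)
)

.segmentOfRoot <- c(
  HDTP = "head", FHD = "head", BHD = "head",
  C7 = "trunk", CLAV = "trunk", STRN = "trunk", T10 = "trunk",
  RBAK = "trunk", SACR = "trunk", SHO = "trunk", ASI = "trunk", PSI = "trunk",
  ELB = "upper_arm", FRM = "forearm_hand", WRA = "forearm_hand",
  WRB = "forearm_hand", THI = "thigh", KNE = "thigh",
  TIB = "shank", ANK = "shank", HEE = "foot", TOE = "foot"
)

#' Build a plausible standing base posture
#'
#' Returns a fixed, anatomically plausible standing posture of \code{nMarkers}
#' labeled points for a 1.72 m template subject, together with a marker-to-body
#' segment map. With 37 markers this is a full-body set of 15 bilateral
#' left/right pairs plus 7 midline markers (including the asymmetric
#' mid-segment marker \code{RBAK} on the right scapula). Smaller sets keep
#' bilateral pairs plus one or two midline markers. The seed adds a small
#' (\eqn{\le} 3 mm) deterministic anatomical perturbation.
#'
#' @param nMarkers number of markers, between 4 and 37.
#' @param seed integer seed for the perturbation.
#' @return list with \code{meanPosture} (nMarkers x 3 matrix, meters, rows
#'   named by label), \code{markerLabels}, and \code{segmentMap} (named
#'   character vector label -> segment).
#' @export
makeBasePosture <- function(nMarkers, seed = 1L) {
  .stopIf(nMarkers < 4, "invalid config: need at least 4 markers, got %d", nMarkers)
  .stopIf(nMarkers > 37, "invalid config: the marker template supports at most 37 markers")
  nMarkers <- as.integer(nMarkers)
  if (nMarkers == 37L) {
    mids <- .midlineLabels
    roots <- .pairRoots
  } else {
    nMid <- 2L - nMarkers %% 2L
    mids <- c("SACR", "C7")[seq_len(nMid)]
    nPairs <- (nMarkers - nMid) %/% 2L
    roots <- c("ASI", "KNE", "ANK", "SHO", "HEE", "TOE", "ELB", "WRA", "FHD",
               "PSI", "THI", "TIB", "FRM", "WRB", "BHD")[seq_len(nPairs)]
  }
  labels <- c(mids, as.vector(rbind(paste0("L", roots), paste0("R", roots))))
  xyz <- matrix(0, length(labels), 3, dimnames = list(labels, c("x", "y", "z")))
  for (m in mids) xyz[m, ] <- .templateXYZ[[m]]
  for (r in roots) {
    p <- .templateXYZ[[r]]
    xyz[paste0("L", r), ] <- p
    xyz[paste0("R", r), ] <- p * c(1, -1, 1)
  }
  xyz <- .withSeed(seed, xyz + matrix(runif(3 * length(labels), -0.003, 0.003),
                                      ncol = 3))
  segRoot <- sub("^[LR](?=..)", "", labels, perl = TRUE)
  segRoot[labels %in% c(mids)] <- labels[labels %in% mids]
  side <- ifelse(labels %in% mids, "",
                 ifelse(startsWith(labels, "L"), "_L", "_R"))
  seg <- .segmentOfRoot[segRoot]
  # bilateral limbs get per-side segments; head/trunk are shared
  segmentMap <- ifelse(seg %in% c("head", "trunk"), seg, paste0(seg, side))
  names(segmentMap) <- labels
  list(meanPosture = xyz, markerLabels = labels, segmentMap = segmentMap)
}

#' Planted orthonormal movement modes
#'
#' Gram-Schmidt orthonormalization of seeded Gaussian vectors; the columns
#' play the role of the eigenvectors the decomposition stage should recover.
#'
#' @param dim posture-space dimension (3 x number of markers).
#' @param nModes number of modes (columns), at most \code{dim}.
#' @param seed integer seed.
#' @return dim x nModes matrix with orthonormal columns.
#' @export
makeModes <- function(dim, nModes, seed = 1L) {
  .stopIf(nModes > dim, "invalid config: cannot plant %d modes in %d dimensions",
          nModes, dim)
  .withSeed(seed, {
    A <- matrix(rnorm(dim * nModes), dim, nModes)
    Q <- matrix(0, dim, nModes)
    for (k in seq_len(nModes)) {
      v <- A[, k]
      for (pass in 1:2) if (k > 1)  # two passes for orthogonality to ~1e-15
        v <- v - Q[, 1:(k - 1), drop = FALSE] %*% crossprod(Q[, 1:(k - 1), drop = FALSE], v)
      Q[, k] <- v / sqrt(sum(v^2))
    }
    Q
  })
}

#' Oscillatory score series with controllable regularity
#'
#' Generates \eqn{s(t) = A \sin\phi(t)} where the phase advances by \eqn{\pi}
#' over each half-cycle and the half-cycle durations are drawn from a
#' mean-preserving log-normal distribution with mean \eqn{1/(2f)} and relative
#' standard deviation \code{jitter}. With \code{jitter = 0} the series is a
#' pure sinusoid, so the acceleration of the series crosses zero
#' \eqn{2 f T} times over a trial of length \eqn{T}; increasing jitter
#' directly increases the spread of the crossing intervals, which is what the
#' crossing-interval SD endpoint measures.
#'
#' @param amplitude non-negative amplitude (normalized-posture units).
#' @param frequency nominal frequency in Hz, below Nyquist.
#' @param jitter relative SD of the instantaneous half-cycle period (>= 0).
#' @param duration trial length in seconds.
#' @param sampleRate Hz.
#' @param seed integer seed, or NULL to draw from the current RNG stream.
#' @return numeric vector of length \code{round(duration * sampleRate)}.
#' @export
makeScoreSeries <- function(amplitude, frequency, jitter, duration,
                            sampleRate, seed = NULL) {
  .stopIf(jitter < 0, "invalid config: negative jitter")
  .stopIf(amplitude < 0, "invalid config: negative amplitude")
  .stopIf(frequency <= 0 || frequency >= sampleRate / 2,
          "invalid config: frequency must lie in (0, sampleRate/2)")
  n <- round(duration * sampleRate)
  t <- (seq_len(n) - 1) / sampleRate
  if (amplitude == 0) return(numeric(n))
  .withSeed(seed, {
    phase0 <- runif(1, 0, 2 * pi)  # arbitrary sway phase at trial start
    if (jitter == 0) return(amplitude * sin(2 * pi * frequency * t + phase0))
    m <- 1 / (2 * frequency)
    s2 <- log(1 + jitter^2)
    mu <- log(m) - s2 / 2
    nHalf <- ceiling(duration / m * (1 + 6 * jitter)) + 8L
    d <- rlnorm(nHalf, mu, sqrt(s2))
    while (sum(d) < duration) d <- c(d, rlnorm(nHalf, mu, sqrt(s2)))
    breaks <- c(0, cumsum(d))
    phi <- approx(breaks, pi * (seq_along(breaks) - 1), xout = t)$y
    amplitude * sin(phi + phase0)
  })
}

#' Synthetic cohort configuration
#'
#' Constructor with defaults emulating a tandem-stance cohort: 50 subjects
#' (17 women / 8 men in each of two age groups), 80 s trials at 240 Hz,
#' 37 markers, five planted modes whose amplitudes follow the square roots of
#' a realistic eigenvalue spectrum and whose dominant frequencies lie in the
#' 2-3 Hz band, 1 mm measurement noise, and a default age effect on mode 2
#' (older group: frequency x 0.9, jitter x 1.15).
#'
#' @param nSubjectsPerCell single integer (all four cells equal) or named
#'   vector with entries \code{young_female}, \code{young_male},
#'   \code{old_female}, \code{old_male}.
#' @param duration,sampleRate trial length (s) and sampling rate (Hz).
#' @param nMarkers,nModes marker count and number K of planted modes.
#' @param modeAmplitudes strictly decreasing positive amplitudes, length K.
#' @param modeFrequencies dominant frequencies (Hz), length K.
#' @param frequencyJitter per-mode relative SD of the half-cycle period.
#' @param groupEffects list of effects, each
#'   \code{list(group =, mode =, amplitude =, frequency =, jitter =)} with
#'   multiplicative modifiers (missing modifiers default to 1); \code{group}
#'   matches an age group, a gender, or an \code{age_gender} cell.
#' @param measurementNoiseSD marker noise SD in meters.
#' @param gapFraction fraction of samples per marker lost to occlusion runs.
#' @param heights (min, max) of uniform subject heights in meters.
#' @param subjectAmpCV,subjectFreqCV between-subject log-normal CVs of
#'   amplitude and frequency.
#' @param seed integer seed.
#' @return a validated \linkS4class{SyntheticConfig}.
#' @export
syntheticConfig <- function(nSubjectsPerCell = c(young_female = 17, young_male = 8,
                                                 old_female = 17, old_male = 8),
                            duration = 80, sampleRate = 240,
                            nMarkers = 37, nModes = 5,
                            modeAmplitudes = NULL,
                            modeFrequencies = NULL,
                            frequencyJitter = NULL,
                            groupEffects = list(list(group = "old", mode = 2,
                                                     frequency = 0.9, jitter = 1.15)),
                            measurementNoiseSD = 0.001,
                            gapFraction = 0,
                            heights = c(1.55, 1.90),
                            subjectAmpCV = 0.10,
                            subjectFreqCV = 0.05,
                            seed = 1L) {
  if (length(nSubjectsPerCell) == 1L && is.null(names(nSubjectsPerCell)))
    nSubjectsPerCell <- c(young_female = nSubjectsPerCell, young_male = nSubjectsPerCell,
                          old_female = nSubjectsPerCell, old_male = nSubjectsPerCell)
  K <- nModes
  if (is.null(modeAmplitudes))
    modeAmplitudes <- if (K == 5) c(0.0200, 0.0137, 0.0090, 0.0048, 0.0040)
                      else 0.02 * 0.7^(seq_len(K) - 1)
  if (is.null(modeFrequencies))
    modeFrequencies <- if (K == 5) c(2.2, 2.6, 2.0, 2.9, 2.4)
                       else seq(2, 2.9, length.out = K)
  if (is.null(frequencyJitter)) frequencyJitter <- rep(0.1, K)
  new("SyntheticConfig",
      nSubjectsPerCell = nSubjectsPerCell, duration = duration,
      sampleRate = sampleRate, nMarkers = nMarkers, nModes = nModes,
      modeAmplitudes = modeAmplitudes, modeFrequencies = modeFrequencies,
      frequencyJitter = frequencyJitter, groupEffects = groupEffects,
      measurementNoiseSD = measurementNoiseSD, gapFraction = gapFraction,
      heights = heights, subjectAmpCV = subjectAmpCV,
      subjectFreqCV = subjectFreqCV, seed = seed)
}

# multiplicative (amplitude, frequency, jitter) modifiers for one subject/mode
.effectMultipliers <- function(ageGroup, gender, mode, effects) {
  out <- c(amplitude = 1, frequency = 1, jitter = 1)
  for (e in effects) {
    if (e$mode != mode) next
    if (!(e$group %in% c(ageGroup, gender, paste(ageGroup, gender, sep = "_")))) next
    for (f in c("amplitude", "frequency", "jitter"))
      if (!is.null(e[[f]])) out[f] <- out[f] * e[[f]]
  }
  out
}

# mirror raw marker data: negate y, swap bilateral labels (in-place reorder)
.mirrorRaw <- function(positions, labels) {
  out <- positions
  out[, , 2] <- -out[, , 2]
  swapped <- ifelse(startsWith(labels, "L"), sub("^L", "R", labels),
                    ifelse(startsWith(labels, "R"), sub("^R", "L", labels), labels))
  has <- swapped %in% labels
  src <- ifelse(has, match(swapped, labels), seq_along(labels))
  out[, seq_along(labels), ] <- out[, src, , drop = FALSE]
  out
}

#' Generate a synthetic multi-subject marker cohort with ground truth
#'
#' For each subject, planted score series drive orthonormal modes in the
#' weighted, height-normalized posture space; the trajectory is mapped back to
#' lab coordinates, measurement noise and occlusion gaps are added, and
#' left-foot-front subjects are stored mirrored (as they would be recorded).
#' Modes are planted only on the markers retained by the default selection
#' policy, so the preprocessing chain recovers them exactly.
#'
#' @param config a \linkS4class{SyntheticConfig}.
#' @return list with \code{subjects} (list of
#'   \linkS4class{MarkerTrajectorySet}) and \code{truth}, a list holding the
#'   planted \code{modeMatrix} (selected weighted posture space),
#'   \code{fullModeMatrix} (all markers, zero rows on non-selected ones),
#'   \code{markerLabels} (selected), per-subject metadata and per-subject,
#'   per-mode amplitude/frequency/jitter and expected crossing counts
#'   (\code{2 f T}), the canonical score series, and the config.
#' @export
generateCohort <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  validObject(config)
  fs <- config@sampleRate
  Tn <- round(config@duration * fs)
  K <- as.integer(config@nModes)
  base <- makeBasePosture(config@nMarkers, seed = config@seed)
  labels <- base$markerLabels
  policy <- defaultMarkerPolicy()
  selLabels <- setdiff(labels, policy$drop)
  selIdx <- match(selLabels, labels)
  weights <- segmentWeights(selLabels, base$segmentMap)
  D <- 3L * length(selLabels)
  modeSel <- makeModes(D, K, seed = config@seed + 1L)
  fullMode <- matrix(0, 3L * length(labels), K)
  fullRows <- as.vector(outer(1:3, (selIdx - 1L) * 3L, `+`))  # marker-major
  fullMode[fullRows, ] <- modeSel

  cells <- c("young_female", "young_male", "old_female", "old_male")
  nPerCell <- config@nSubjectsPerCell[cells]
  wCoord <- .perCoord(weights[selLabels])

  subjects <- list()
  meta <- list(); modeTab <- list(); scoreList <- list()
  .withSeed(config@seed, {
    sidx <- 0L
    for (cell in cells) {
      ag <- sub("_.*", "", cell)
      gd <- sub(".*_", "", cell)
      for (i in seq_len(nPerCell[cell])) {
        sidx <- sidx + 1L
        sid <- sprintf("S%03d", sidx)
        height <- runif(1, config@heights[1], config@heights[2])
        mass <- min(max(rnorm(1, 72, 12), 45), 110)
        frontFoot <- if (runif(1) < 0.5) "left" else "right"
        S <- matrix(0, Tn, K)
        rows <- list()
        for (k in seq_len(K)) {
          mult <- .effectMultipliers(ag, gd, k, config@groupEffects)
          A <- config@modeAmplitudes[k] * mult["amplitude"] *
            exp(rnorm(1, 0, config@subjectAmpCV))
          f <- config@modeFrequencies[k] * mult["frequency"] *
            exp(rnorm(1, 0, config@subjectFreqCV))
          j <- config@frequencyJitter[k] * mult["jitter"]
          S[, k] <- makeScoreSeries(A, f, j, config@duration, fs, seed = NULL)
          rows[[k]] <- data.frame(subject_id = sid, mode = k, amplitude = A,
                                  frequency = f, jitter = j,
                                  expected_n = 2 * f * config@duration)
        }
        # normalized-weighted space -> lab space
        Xw <- S %*% t(modeSel)
        pos <- array(0, dim = c(Tn, length(labels), 3))
        baseSubj <- base$meanPosture * (height / 1.72)
        for (m in seq_along(labels)) {
          pos[, m, ] <- matrix(baseSubj[m, ], Tn, 3, byrow = TRUE)
        }
        for (mi in seq_along(selIdx)) {
          cols <- (mi - 1L) * 3L + 1:3
          pos[, selIdx[mi], ] <- pos[, selIdx[mi], ] +
            height * Xw[, cols] / weights[selLabels[mi]]
        }
        if (config@measurementNoiseSD > 0)
          pos <- pos + array(rnorm(length(pos), 0, config@measurementNoiseSD),
                             dim = dim(pos))
        if (frontFoot == "left") pos <- .mirrorRaw(pos, labels)
        mask <- matrix(FALSE, Tn, length(labels))
        if (config@gapFraction > 0) {
          meanLen <- max(1, 0.25 * fs)
          for (m in seq_along(labels)) {
            target <- config@gapFraction * Tn
            while (sum(mask[, m]) < target) {
              st <- sample.int(Tn, 1L)
              len <- rgeom(1L, 1 / meanLen) + 1L
              mask[st:min(Tn, st + len - 1L), m] <- TRUE
            }
          }
          for (m in seq_along(labels)) pos[, m, ][mask[, m]] <- NA_real_
        }
        subjects[[sid]] <- new("MarkerTrajectorySet",
          subjectId = sid, markerLabels = labels, positions = pos,
          missingMask = mask, sampleRate = fs, height = height, mass = mass,
          ageGroup = ag, gender = gd, frontFoot = frontFoot)
        meta[[sid]] <- data.frame(subject_id = sid, age_group = ag, gender = gd,
                                  front_foot = frontFoot, height = height,
                                  mass = mass)
        modeTab[[sid]] <- do.call(rbind, rows)
        scoreList[[sid]] <- S
      }
    }
  })
  truth <- list(
    modeMatrix = modeSel, fullModeMatrix = fullMode, markerLabels = selLabels,
    weights = weights, subjects = do.call(rbind, c(meta, make.row.names = FALSE)),
    modes = do.call(rbind, c(modeTab, make.row.names = FALSE)),
    scoreSeries = scoreList, config = config)
  list(subjects = subjects, truth = truth)
}
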