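# Preprocessing: marker IO, gap filling, mirroring, marker selection, and the
# centered / height-normalized / segment-mass-weighted posture matrix.

# Winter-style body segment mass fractions (share of total body mass)
.segmentMassFractions <- c(
  head = 0.081, trunk = 0.497,
  upper_arm_L = 0.028, upper_arm_R = 0.028,
  forearm_hand_L = 0.022, forearm_hand_R = 0.022,
  thigh_L = 0.100, thigh_R = 0.100,
  shank_L = 0.0465, shank_R = 0.0465,
  foot_L = 0.0145, foot_R = 0.0145
)

#' Default marker-selection policy
#'
#' Keeps all bilaterally symmetric marker pairs and the symmetric midline
#' markers, and drops the asymmetric mid-segment markers (\code{RBAK}, the
#' single scapula marker of the full-body set), which have no contralateral
#' partner and would break the mirroring step.
#'
#' @return list with element \code{drop} (labels to omit).
#' @export
defaultMarkerPolicy <- function() list(drop = "RBAK")

#' Relative mass weights per marker
#'
#' Distributes each body segment's Winter-style mass fraction equally among
#' that segment's markers present in \code{markerLabels}, then renormalizes so
#' the weights over the given marker set sum to exactly 1.
#'
#' @param markerLabels labels of the selected markers.
#' @param segmentMap named character vector mapping every label to a segment
#'   (as returned by \code{\link{makeBasePosture}}).
#' @return named numeric vector of weights summing to 1.
#' @export
segmentWeights <- function(markerLabels, segmentMap) {
  .stopIf(!all(markerLabels %in% names(segmentMap)),
          "segment map is missing labels: %s",
          paste(setdiff(markerLabels, names(segmentMap)), collapse = ", "))
  seg <- segmentMap[markerLabels]
  frac <- .segmentMassFractions[seg]
  frac[is.na(frac)] <- min(.segmentMassFractions)  # unknown segments: small weight
  w <- frac / as.vector(table(seg)[seg])
  w <- w / sum(w)
  names(w) <- markerLabels
  w
}

#' Write marker trajectories as long CSV
#'
#' Dialect: comment header lines \code{# key: value} carrying the subject
#' metadata, then \code{frame,label,x,y,z} with coordinates in meters and
#' missing samples as empty cells.
#'
#' @param traj a \linkS4class{MarkerTrajectorySet}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeMarkers <- function(traj, path) {
  stopifnot(is(traj, "MarkerTrajectorySet"))
  d <- dim(traj@positions)
  meta <- c(subject_id = traj@subjectId, sample_rate = traj@sampleRate,
            height = traj@height, mass = traj@mass, age_group = traj@ageGroup,
            gender = traj@gender, front_foot = traj@frontFoot, units = "m")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s: %s", names(meta), meta), con)
  df <- data.frame(
    frame = rep(seq_len(d[1]), times = d[2]),
    label = rep(traj@markerLabels, each = d[1]),
    x = as.vector(traj@positions[, , 1]),
    y = as.vector(traj@positions[, , 2]),
    z = as.vector(traj@positions[, , 3])
  )
  write.csv(df, con, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read marker trajectories from long CSV
#'
#' Reads the dialect written by \code{\link{writeMarkers}}. Cells that are
#' empty or NaN are flagged in the missing mask. A \code{units: mm} metadata
#' line triggers conversion to meters. Frames must form one uniform sequence
#' per marker and labels must be unique per frame.
#'
#' @param path file path.
#' @param format currently only \code{"csv"}.
#' @return a \linkS4class{MarkerTrajectorySet}.
#' @export
readMarkers <- function(path, format = c("csv")) {
  format <- match.arg(format)
  .stopIf(!file.exists(path), "file not found: %s", path)
  hdr <- readLines(path, n = 50L)
  metaLines <- grep("^#", hdr, value = TRUE)
  meta <- list()
  for (ln in metaLines) {
    kv <- regmatches(ln, regexec("^#\\s*([^:]+):\\s*(.*)$", ln))[[1]]
    if (length(kv) == 3) meta[[trimws(kv[2])]] <- trimws(kv[3])
  }
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  .stopIf(!all(c("frame", "label", "x", "y", "z") %in% names(df)),
          "format error: CSV must have columns frame,label,x,y,z")
  labels <- unique(df$label)
  frames <- sort(unique(df$frame))
  Tn <- length(frames)
  .stopIf(Tn > 1 && any(abs(diff(frames) - 1) > 1e-9),
          "format error: non-uniform frame sampling")
  .stopIf(anyDuplicated(df[, c("frame", "label")]) > 0,
          "format error: duplicate marker labels within a frame")
  .stopIf(nrow(df) != Tn * length(labels),
          "format error: markers do not share a common frame range")
  scale <- if (identical(meta$units, "mm")) 1e-3 else 1
  pos <- array(NA_real_, dim = c(Tn, length(labels), 3))
  fi <- match(df$frame, frames)
  mi <- match(df$label, labels)
  for (c in 1:3) {
    v <- df[[c("x", "y", "z")[c]]] * scale
    pos[cbind(fi, mi, c)] <- v
  }
  pos[is.nan(pos)] <- NA_real_
  mask <- is.na(pos[, , 1, drop = FALSE]) | is.na(pos[, , 2, drop = FALSE]) |
    is.na(pos[, , 3, drop = FALSE])
  mask <- matrix(mask, Tn, length(labels))
  for (c in 1:3) { sl <- pos[, , c]; sl[mask] <- NA_real_; pos[, , c] <- sl }
  num <- function(key, default) if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else default
  chr <- function(key, default) if (!is.null(meta[[key]])) meta[[key]] else default
  new("MarkerTrajectorySet",
      subjectId = chr("subject_id", basename(path)),
      markerLabels = labels, positions = pos, missingMask = mask,
      sampleRate = num("sample_rate", 240), height = num("height", 1.70),
      mass = num("mass", 70), ageGroup = chr("age_group", "young"),
      gender = chr("gender", "female"), frontFoot = chr("front_foot", "right"))
}

#' Fill occlusion gaps by iterative low-rank reconstruction
#'
#' Missing entries are initialized by linear interpolation per coordinate,
#' then refined by iterating: center columns, compute the rank-\code{rank}
#' principal subspace of the frames x coordinates matrix, and replace the
#' missing entries by their low-rank reconstruction, until the RMS change of
#' the imputed entries drops below \code{tol} (meters) or \code{maxIter} is
#' reached. Observed samples are never altered.
#'
#' @param traj a \linkS4class{MarkerTrajectorySet}.
#' @param rank reconstruction rank (default 10).
#' @param maxIter iteration cap (default 100).
#' @param tol RMS convergence tolerance in meters (default 1e-8).
#' @return the trajectory with gaps filled and the missing mask cleared.
#' @export
fillGaps <- function(traj, rank = 10L, maxIter = 100L, tol = 1e-8) {
  stopifnot(is(traj, "MarkerTrajectorySet"))
  if (!any(traj@missingMask)) return(traj)
  d <- dim(traj@positions)
  full <- colSums(!traj@missingMask) == 0
  .stopIf(any(full), "unrecoverable gap: marker(s) fully missing: %s",
          paste(traj@markerLabels[full], collapse = ", "))
  X <- matrix(traj@positions, d[1], d[2] * 3L)  # frames x (all x, all y, all z)
  miss <- is.na(X)
  t0 <- seq_len(d[1])
  for (j in which(colSums(miss) > 0)) {
    obs <- !miss[, j]
    X[miss[, j], j] <- approx(t0[obs], X[obs, j], xout = t0[miss[, j]],
                              rule = 2)$y
  }
  rank <- min(rank, d[1] - 1L, ncol(X))
  converged <- FALSE
  for (it in seq_len(maxIter)) {
    mu <- colMeans(X)
    Xc <- sweep(X, 2, mu)
    sv <- svd(Xc, nu = 0, nv = rank)
    V <- sv$v
    recon <- sweep(Xc %*% V %*% t(V), 2, mu, `+`)
    delta <- recon[miss] - X[miss]
    X[miss] <- recon[miss]
    if (sqrt(mean(delta^2)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("gap filling did not converge within ", maxIter,
            " iterations; returning best iterate")
  pos <- array(X, dim = d)
  initialize(traj, positions = pos,
             missingMask = matrix(FALSE, d[1], d[2]))
}

#' Mirror a left-foot-front trial into the right-foot-front convention
#'
#' Negates the lateral (y) coordinate of every marker and swaps left/right
#' marker labels so the dataset describes a tandem stance with the right foot
#' in front. Midline labels are unchanged. Errors if the trial already has the
#' right foot in front or if a lateral label has no contralateral partner.
#'
#' @param traj a \linkS4class{MarkerTrajectorySet} with \code{frontFoot == "left"}.
#' @return the mirrored trajectory with \code{frontFoot == "right"}.
#' @export
mirrorLeftFront <- function(traj) {
  stopifnot(is(traj, "MarkerTrajectorySet"))
  .stopIf(traj@frontFoot != "left",
          "precondition: trial already has the right foot in front")
  labels <- traj@markerLabels
  lateral <- grepl("^[LR].", labels)
  partner <- ifelse(startsWith(labels, "L"), sub("^L", "R", labels),
                    sub("^R", "L", labels))
  bad <- lateral & !(partner %in% labels)
  .stopIf(any(bad), "labeling error: unpaired lateral label(s): %s",
          paste(labels[bad], collapse = ", "))
  src <- ifelse(lateral, match(partner, labels), seq_along(labels))
  pos <- traj@positions
  pos[, , 2] <- -pos[, , 2]
  pos <- pos[, src, , drop = FALSE]
  mask <- traj@missingMask[, src, drop = FALSE]
  initialize(traj, positions = pos, missingMask = mask, frontFoot = "right")
}

#' Select the analysis marker set
#'
#' Returns the subset of markers retained by the policy (default: drop the
#' asymmetric mid-segment markers), in the original, deterministic order.
#'
#' @param traj a \linkS4class{MarkerTrajectorySet}.
#' @param policy list with element \code{drop} (labels to omit) and/or
#'   \code{keep} (explicit labels to retain).
#' @return the reduced trajectory set.
#' @export
selectMarkers <- function(traj, policy = defaultMarkerPolicy()) {
  stopifnot(is(traj, "MarkerTrajectorySet"))
  labels <- traj@markerLabels
  named <- c(policy$drop, policy$keep)
  absent <- setdiff(named, labels)
  .stopIf(length(absent) > 0, "selection error: policy names absent label(s): %s",
          paste(absent, collapse = ", "))
  keep <- if (!is.null(policy$keep)) labels[labels %in% policy$keep]
          else setdiff(labels, policy$drop)
  .stopIf(length(keep) == 0, "selection error: policy selects no markers")
  idx <- match(keep, labels)
  initialize(traj, markerLabels = labels[idx],
             positions = traj@positions[, idx, , drop = FALSE],
             missingMask = traj@missingMask[, idx, drop = FALSE])
}

#' Centered, height-normalized, mass-weighted posture matrix
#'
#' For each frame, the posture vector is the subject's marker coordinates with
#' the subject's mean posture subtracted, divided by the subject's height, and
#' each marker's three coordinates multiplied by that marker's relative
#' segment-mass weight:
#' \eqn{v(t) = w \odot (m(t) - \bar m) / h}.
#'
#' @param traj a gap-free \linkS4class{MarkerTrajectorySet} (selected markers).
#' @param weights named per-marker weights (default: Winter-style segment
#'   fractions via \code{\link{segmentWeights}} on the full-body template map);
#'   must cover all markers of \code{traj}.
#' @param segmentMap optional marker-to-segment map used when \code{weights}
#'   is NULL.
#' @return a \linkS4class{PostureMatrix}.
#' @export
normalizeAndWeight <- function(traj, weights = NULL, segmentMap = NULL) {
  stopifnot(is(traj, "MarkerTrajectorySet"))
  .stopIf(any(traj@missingMask),
          "must-fill-gaps-first: trajectory contains missing samples")
  labels <- traj@markerLabels
  if (is.null(weights)) {
    if (is.null(segmentMap))
      segmentMap <- makeBasePosture(37)$segmentMap
    weights <- segmentWeights(labels, segmentMap)
  }
  .stopIf(!all(labels %in% names(weights)),
          "weights missing for marker(s): %s",
          paste(setdiff(labels, names(weights)), collapse = ", "))
  w <- weights[labels]
  d <- dim(traj@positions)
  X <- matrix(aperm(traj@positions, c(1, 3, 2)), d[1], 3L * d[2])  # marker-major
  mu <- colMeans(X)
  Xn <- sweep(X, 2, mu) / traj@height
  Xw <- sweep(Xn, 2, .perCoord(w), `*`)
  Xw <- sweep(Xw, 2, colMeans(Xw))  # exact zero column means
  colnames(Xw) <- .coordNames(labels)
  new("PostureMatrix",
      subjectId = traj@subjectId, coords = Xw, meanPosture = mu / traj@height,
      markerLabels = labels, weights = w, height = traj@height,
      sampleRate = traj@sampleRate, ageGroup = traj@ageGroup,
      gender = traj@gender, mass = traj@mass)
}

#' Concatenate subjects' posture matrices for the pooled PCA
#'
#' Row-wise stack of the subjects' centered, normalized, weighted coordinate
#' matrices, preserving subject order, with an index mapping every pooled row
#' back to its (subject, frame).
#'
#' @param subjects list of \linkS4class{PostureMatrix} with identical marker
#'   sets and column order.
#' @return a \linkS4class{PooledPostures}.
#' @export
concatenateSubjects <- function(subjects) {
  stopifnot(length(subjects) >= 1, all(vapply(subjects, is, TRUE, "PostureMatrix")))
  ref <- subjects[[1]]@markerLabels
  for (s in subjects)
    .stopIf(!identical(s@markerLabels, ref),
            "incompatible subjects: marker sets or column order differ ('%s')",
            s@subjectId)
  coords <- do.call(rbind, lapply(subjects, function(s) s@coords))
  index <- do.call(rbind, lapply(subjects, function(s)
    data.frame(subject_id = s@subjectId, frame = seq_len(nrow(s@coords)))))
  rownames(index) <- NULL
  new("PooledPostures", coords = coords, index = index,
      markerLabels = ref, weights = subjects[[1]]@weights)
}
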