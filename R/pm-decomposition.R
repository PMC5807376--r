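# Principal movement decomposition: pooled PCA of posture vectors, per-subject
# score series, relative sway amplitudes, and reconstruction of amplified
# extreme postures.

#' Fit the principal movement basis on pooled posture vectors
#'
#' Singular value decomposition of the pooled (already subject-wise centered)
#' posture matrix; no additional centering is applied. Eigenvalues use the
#' population convention \eqn{EV_k = d_k^2 / N}. A deterministic sign
#' convention is applied: the largest-magnitude coefficient of every
#' eigenvector is made positive.
#'
#' @param pooled a \linkS4class{PooledPostures} (or bare numeric matrix).
#' @param r number of components to retain (default: all).
#' @return a \linkS4class{PCAModel}; if the matrix has rank below \code{r},
#'   only the nonzero components are retained, with a warning.
#' @export
fitPCA <- function(pooled, r = NULL) {
  X <- if (is(pooled, "PooledPostures")) pooled@coords else as.matrix(pooled)
  .stopIf(anyNA(X) || any(!is.finite(X)), "pooled matrix must be finite")
  maxR <- min(dim(X))
  if (is.null(r)) r <- ncol(X)
  .stopIf(r < 1 || r > maxR, "r must lie in [1, min(rows, cols)]")
  sv <- svd(X, nu = 0)
  ev <- sv$d^2 / nrow(X)
  total <- sum(ev)
  nz <- sum(sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1])
  if (nz < r) {
    warning(sprintf("pooled matrix has rank %d < r = %d; retaining %d components",
                    nz, r, nz))
    r <- nz
  }
  V <- sv$v[, seq_len(r), drop = FALSE]
  V <- .applySignConvention(V)
  labs <- if (is(pooled, "PooledPostures")) pooled@markerLabels else character()
  subj <- if (is(pooled, "PooledPostures")) unique(pooled@index$subject_id) else character()
  new("PCAModel", rotation = V, eigenvalues = ev[seq_len(r)],
      explainedPct = 100 * ev[seq_len(r)] / total, totalVariance = total,
      markerLabels = labs, subjects = subj, nObs = nrow(X))
}

# flip each column so its largest-|coefficient| entry is positive
.applySignConvention <- function(V) {
  for (k in seq_len(ncol(V))) {
    i <- which.max(abs(V[, k]))
    if (V[i, k] < 0) V[, k] <- -V[, k]
  }
  V
}

#' Project a subject onto the principal movement basis
#'
#' The principal positions are \eqn{PP = X V}: the subject's centered,
#' normalized, weighted posture vectors expressed in the pooled eigenvector
#' basis. Over a complete basis the inverse transform \eqn{PP V^T} reproduces
#' the posture matrix.
#'
#' @param subject a \linkS4class{PostureMatrix}.
#' @param model a \linkS4class{PCAModel} fitted in the same coordinate space.
#' @return a \linkS4class{SubjectScores}.
#' @export
projectSubject <- function(subject, model) {
  stopifnot(is(subject, "PostureMatrix"), is(model, "PCAModel"))
  .stopIf(ncol(subject@coords) != nrow(model@rotation),
          "dimension mismatch: subject has %d coordinates, model %d",
          ncol(subject@coords), nrow(model@rotation))
  PP <- subject@coords %*% model@rotation
  colnames(PP) <- paste0("PM", seq_len(ncol(PP)))
  new("SubjectScores", subjectId = subject@subjectId, scores = PP,
      sampleRate = subject@sampleRate)
}

#' Relative standard deviations of the principal positions
#'
#' \eqn{rSTD_k = 100\, \sigma(PP_k) / \sum_{j=1}^{r} \sigma(PP_j)} with the
#' population standard deviation over the trial: the percentage of the
#' subject's overall postural motion explained by each component. The
#' denominator spans the retained basis \code{r}, so the values sum to 100
#' over those components.
#'
#' @param scores a \linkS4class{SubjectScores}.
#' @param r number of components over which to normalize (default: all in
#'   \code{scores}).
#' @return data.frame with columns \code{subject_id}, \code{k}, \code{rSTD}.
#' @export
relativeStd <- function(scores, r = ncol(scores@scores)) {
  stopifnot(is(scores, "SubjectScores"))
  .stopIf(r < 1 || r > ncol(scores@scores), "r out of range")
  sds <- apply(scores@scores[, seq_len(r), drop = FALSE], 2, .sdPop)
  tot <- sum(sds)
  if (tot == 0) {
    warning("all-zero scores: rSTD undefined")
    vals <- rep(NaN, r)
  } else vals <- 100 * sds / tot
  data.frame(subject_id = scores@subjectId, k = seq_len(r), rSTD = vals,
             row.names = NULL)
}

#' Amplified extreme postures of one principal movement
#'
#' Reconstructs the two lab-space postures at \eqn{\pm a \max_t |PP_k(t)|}
#' along component \code{k} for visualization: the score excursion is mapped
#' through the eigenvector, un-weighted (divided by the marker mass weights),
#' un-normalized (multiplied by the subject's height), and added to the
#' subject's mean posture.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param scores the subject's \linkS4class{SubjectScores}.
#' @param k component index.
#' @param amplification amplification factor (e.g. 10, 15, 20).
#' @param posture the subject's \linkS4class{PostureMatrix} (supplies weights,
#'   height and mean posture).
#' @return list with \code{plus} and \code{minus}, each an M x 3 matrix of
#'   marker coordinates in meters (rows named by label).
#' @export
pmExtremePostures <- function(model, scores, k, amplification, posture) {
  stopifnot(is(model, "PCAModel"), is(scores, "SubjectScores"),
            is(posture, "PostureMatrix"))
  .stopIf(k < 1 || k > ncol(model@rotation), "component %d not in model", k)
  amp <- amplification * max(abs(scores@scores[, k]))
  wC <- .perCoord(posture@weights)
  # meanPosture is height-normalized: scale back to meters
  toLabM <- function(s) {
    v <- posture@height * (posture@meanPosture + (s * model@rotation[, k]) / wC)
    matrix(v, ncol = 3, byrow = TRUE,
           dimnames = list(posture@markerLabels, c("x", "y", "z")))
  }
  list(plus = toLabM(amp), minus = toLabM(-amp))
}
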