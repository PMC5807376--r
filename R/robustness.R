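# Leave-one-subject-out cross-validation of eigenvector stability.

#' Sign-invariant angle between two direction vectors
#'
#' \eqn{\arccos(|u \cdot v| / (\|u\| \|v\|))} in degrees. Sign-invariant
#' because the sign of a PCA eigenvector is arbitrary; the result lies in
#' [0, 90].
#'
#' @param u,v non-zero numeric vectors of equal length.
#' @return angle in degrees.
#' @export
vectorAngle <- function(u, v) {
  .stopIf(length(u) != length(v), "vectors must have equal length")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  .stopIf(nu == 0 || nv == 0, "zero vector has no direction")
  acos(min(1, abs(sum(u * v)) / (nu * nv))) * 180 / pi
}

# eigen-decomposition of a (downdated) cross-product matrix -> PCA basis;
# numerically equivalent to the SVD route used by fitPCA (tested), but lets
# each LOO fold reuse precomputed per-subject cross-products
.pcaFromCrossprod <- function(C, nObs, r) {
  e <- eigen(C / nObs, symmetric = TRUE)
  list(rotation = .applySignConvention(e$vectors[, seq_len(r), drop = FALSE]),
       eigenvalues = pmax(e$values, 0)[seq_len(r)])
}

#' Leave-one-subject-out cross-validation of the principal movements
#'
#' Refits the pooled PCA with each subject left out and records, for every
#' component \eqn{k \le r}, the orientation change (sign-invariant angle)
#' between the fold's eigenvector and the full-data eigenvector. Components
#' are matched by eigenvalue rank (no re-pairing by similarity), so
#' eigenvalue degeneracy surfaces as large angles — which is the diagnostic
#' intent. A component is robust when its worst-case (maximum) angle across
#' folds does not exceed the threshold.
#'
#' @param subjects list of \linkS4class{PostureMatrix} (at least 3).
#' @param r number of components to evaluate.
#' @param threshold robustness threshold in degrees (default 15).
#' @return data.frame with columns \code{k}, \code{max_deg}, \code{mean_deg},
#'   \code{robust}; attributes \code{n_folds} and \code{threshold}.
#' @export
looCrossval <- function(subjects, r, threshold = 15) {
  .stopIf(length(subjects) < 3, "need at least 3 subjects for cross-validation")
  D <- ncol(subjects[[1]]@coords)
  .stopIf(r < 1 || r > D, "r out of range")
  cps <- lapply(subjects, function(s) crossprod(s@coords))
  ns <- vapply(subjects, function(s) nrow(s@coords), 0)
  Ctot <- Reduce(`+`, cps)
  full <- .pcaFromCrossprod(Ctot, sum(ns), r)
  nF <- length(subjects)
  ang <- matrix(NA_real_, nF, r)
  rankWarned <- FALSE
  for (i in seq_len(nF)) {
    fold <- .pcaFromCrossprod(Ctot - cps[[i]], sum(ns) - ns[i], r)
    tol <- max(fold$eigenvalues) * 1e-12
    for (k in seq_len(r)) {
      if (fold$eigenvalues[k] <= tol) {
        ang[i, k] <- 90
        rankWarned <- TRUE
      } else {
        ang[i, k] <- vectorAngle(fold$rotation[, k], full$rotation[, k])
      }
    }
  }
  if (rankWarned)
    warning("some folds had rank below r; missing components reported as 90 degrees")
  out <- data.frame(
    k = seq_len(r),
    max_deg = apply(ang, 2, max),
    mean_deg = colMeans(ang),
    robust = apply(ang, 2, max) <= threshold
  )
  attr(out, "n_folds") <- nF
  attr(out, "threshold") <- threshold
  out
}
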