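# Control variables of the principal movements: posture-space kinematics,
# zero-crossing counts N_k of the principal accelerations, and the SD of the
# time between zero crossings sigma_k.

#' Posture-space kinematics of a subject's score series
#'
#' Applies the analysis chain: zero-phase Butterworth lowpass on every
#' principal position series, then the FIR lowpass differentiator twice
#' (positions -> velocities -> accelerations). The valid analysis window
#' excludes \code{edgeTrimS} seconds at both ends (filter transients and the
#' differentiator's incomplete edges).
#'
#' @param scoresObj a \linkS4class{SubjectScores}.
#' @param settings a \linkS4class{KinematicsSettings}.
#' @return a \linkS4class{PMKinematics}.
#' @export
computeKinematics <- function(scoresObj, settings = kinematicsSettings()) {
  stopifnot(is(scoresObj, "SubjectScores"), is(settings, "KinematicsSettings"))
  fs <- scoresObj@sampleRate
  PP <- scoresObj@scores
  n <- nrow(PP)
  trim <- round(settings@edgeTrimS * fs)
  firEdge <- settings@firOrder  # two passes, order/2 NA samples each end per pass
  lo <- max(trim + 1L, firEdge + 1L)
  hi <- min(n - trim, n - firEdge)
  .stopIf(lo > hi, "trial too short for the requested edge trim and filters")
  PPf <- PV <- PA <- matrix(NA_real_, n, ncol(PP), dimnames = dimnames(PP))
  for (k in seq_len(ncol(PP))) {
    PPf[, k] <- butterLowpass(PP[, k], fs, settings)
    PV[, k] <- differentiateSeries(PPf[, k], fs, settings)
    pv <- PV[, k]
    pv[is.na(pv)] <- 0  # NA edges lie outside the valid window
    PA[, k] <- differentiateSeries(pv, fs, settings)
  }
  new("PMKinematics", subjectId = scoresObj@subjectId, position = PPf,
      velocity = PV, acceleration = PA, sampleRate = fs,
      validRange = c(as.integer(lo), as.integer(hi)), settings = settings)
}

#' Zero crossings of a series
#'
#' A crossing is a sign change between consecutive non-zero samples. Runs of
#' exact zeros bracketed by opposite signs collapse to a single crossing at
#' the run center; zero runs bracketed by equal signs are not crossings.
#' Crossing times are estimated by linear interpolation between the bracketing
#' samples and reported in seconds from the start of the series.
#'
#' @param x numeric series (the valid window of an acceleration series).
#' @param sampleRate Hz.
#' @return list with \code{times} (seconds) and \code{n} (count).
#' @export
zeroCrossings <- function(x, sampleRate) {
  .stopIf(length(x) == 0 || anyNA(x), "valid window must be non-empty and NA-free")
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) < 2) return(list(times = numeric(0), n = 0L))
  ch <- which(s[nz[-1]] != s[nz[-length(nz)]])
  if (!length(ch)) return(list(times = numeric(0), n = 0L))
  i <- nz[ch]        # last non-zero sample before the crossing
  j <- nz[ch + 1L]   # first non-zero sample after
  times <- ifelse(j == i + 1L,
                  (i - 1 + x[i] / (x[i] - x[j])) / sampleRate,
                  ((i + j) / 2 - 1) / sampleRate)
  list(times = as.numeric(times), n = length(times))
}

#' Standard deviation of the time between zero crossings
#'
#' Sample (n-1 denominator) standard deviation of the successive differences
#' of the crossing times. Needs at least 3 crossings (2 intervals); otherwise
#' \code{NaN} with a warning.
#'
#' @param times crossing times in seconds (from \code{\link{zeroCrossings}}).
#' @return sigma in seconds.
#' @export
crossingIntervalSD <- function(times) {
  if (length(times) < 3) {
    warning("fewer than 3 zero crossings: sigma undefined")
    return(NaN)
  }
  sd(diff(times))
}

#' Control variables per component for one subject
#'
#' Assembles the per-component table of the control endpoints: crossing count
#' \code{N} of the principal acceleration over the valid window, the
#' crossing-interval SD \code{sigma} (seconds), the relative sway amplitude
#' \code{rSTD} (percent, if supplied), and the window duration used.
#'
#' @param kin a \linkS4class{PMKinematics}.
#' @param rstd optional data.frame from \code{\link{relativeStd}} for the same
#'   subject.
#' @return data.frame with columns \code{subject_id}, \code{k}, \code{rSTD},
#'   \code{N}, \code{sigma}, \code{window_s}.
#' @export
controlVariables <- function(kin, rstd = NULL) {
  stopifnot(is(kin, "PMKinematics"))
  vr <- kin@validRange
  win <- (vr[2] - vr[1] + 1) / kin@sampleRate
  r <- ncol(kin@acceleration)
  out <- lapply(seq_len(r), function(k) {
    pa <- kin@acceleration[vr[1]:vr[2], k]
    zc <- zeroCrossings(pa, kin@sampleRate)
    sig <- if (zc$n >= 3) crossingIntervalSD(zc$times) else {
      if (zc$n > 0) warning("component ", k, ": fewer than 3 zero crossings")
      NaN
    }
    data.frame(subject_id = kin@subjectId, k = k, N = zc$n, sigma = sig,
               window_s = win)
  })
  out <- do.call(rbind, out)
  if (!is.null(rstd)) {
    .stopIf(!all(rstd$subject_id == kin@subjectId),
            "rSTD table belongs to a different subject")
    out <- merge(out, rstd[, c("k", "rSTD")], by = "k", all.x = TRUE)
  } else out$rSTD <- NA_real_
  out[order(out$k), c("subject_id", "k", "rSTD", "N", "sigma", "window_s")]
}

#' Control variables for a list of subjects
#'
#' Convenience wrapper running \code{\link{computeKinematics}} and
#' \code{\link{controlVariables}} over a cohort of score series.
#'
#' @param scoresList list of \linkS4class{SubjectScores}.
#' @param settings a \linkS4class{KinematicsSettings}.
#' @param rstdTable optional combined rSTD table (rows for all subjects).
#' @return combined data.frame, one row per subject x component.
#' @export
cohortControlVariables <- function(scoresList, settings = kinematicsSettings(),
                                   rstdTable = NULL) {
  rows <- lapply(scoresList, function(sc) {
    kin <- computeKinematics(sc, settings)
    rs <- if (!is.null(rstdTable))
      rstdTable[rstdTable$subject_id == sc@subjectId, , drop = FALSE] else NULL
    controlVariables(kin, rs)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Filter-sensitivity sweep
#'
#' Recomputes the control variables and their age/gender ANOVA p-values for
#' every filter setting in a grid, to inspect how stable the group effects are
#' against the filtering choices. Invalid grid rows (non-increasing bands,
#' cutoff at or above Nyquist) are skipped with a warning.
#'
#' @param scoresList list of \linkS4class{SubjectScores} for the cohort.
#' @param grid data.frame with columns \code{cutoff_hz}, \code{pass_hz},
#'   \code{stop_hz} (one row per setting).
#' @param meta data.frame with \code{subject_id}, \code{age_group},
#'   \code{gender}.
#' @param components component indices to analyze (default: all).
#' @param baseSettings settings supplying the non-swept parameters.
#' @return tidy data.frame: setting, cutoff_hz, pass_hz, stop_hz, variable,
#'   k, effect, F, p.
#' @export
filterSensitivitySweep <- function(scoresList, grid, meta,
                                   components = NULL,
                                   baseSettings = kinematicsSettings()) {
  .stopIf(is.null(grid) || nrow(grid) == 0, "empty filter grid")
  fs <- scoresList[[1]]@sampleRate
  out <- list()
  for (g in seq_len(nrow(grid))) {
    cu <- grid$cutoff_hz[g]; pb <- grid$pass_hz[g]; sb <- grid$stop_hz[g]
    if (!(pb < sb) || cu >= fs / 2 || sb > fs / 2) {
      warning(sprintf("skipping invalid grid row %d (cutoff %g, pass %g, stop %g)",
                      g, cu, pb, sb))
      next
    }
    st <- kinematicsSettings(butterworthOrder = baseSettings@butterworthOrder,
                             cutoffHz = cu, firOrder = baseSettings@firOrder,
                             passHz = pb, stopHz = sb,
                             edgeTrimS = baseSettings@edgeTrimS)
    cv <- cohortControlVariables(scoresList, st)
    tab <- merge(cv, meta, by = "subject_id")
    ks <- if (is.null(components)) sort(unique(tab$k)) else components
    for (k in ks) for (v in c("N", "sigma")) {
      sub <- tab[tab$k == k, ]
      sub$value <- sub[[v]]
      sub <- sub[is.finite(sub$value), ]
      if (length(unique(sub$age_group)) < 2 || length(unique(sub$gender)) < 2)
        next
      an <- twoWayAnova(sub)
      out[[length(out) + 1L]] <- data.frame(
        setting = g, cutoff_hz = cu, pass_hz = pb, stop_hz = sb,
        variable = v, k = k, effect = an$effect, F = an$F, p = an$p)
    }
  }
  .stopIf(!length(out), "no valid grid settings")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
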