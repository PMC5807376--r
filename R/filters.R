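# Filtering and numerical differentiation of principal position series.

#' Kinematics settings constructor
#'
#' @param butterworthOrder Butterworth lowpass order (default 5).
#' @param cutoffHz Butterworth cutoff frequency in Hz (default 7).
#' @param firOrder FIR differentiator order, even (default 50).
#' @param passHz differentiator passband edge in Hz (default 5).
#' @param stopHz differentiator stopband edge in Hz (default 7).
#' @param edgeTrimS seconds trimmed from both trial ends (default 0.5).
#' @return a validated \linkS4class{KinematicsSettings}.
#' @export
kinematicsSettings <- function(butterworthOrder = 5, cutoffHz = 7,
                               firOrder = 50, passHz = 5, stopHz = 7,
                               edgeTrimS = 0.5) {
  new("KinematicsSettings", butterworthOrder = butterworthOrder,
      cutoffHz = cutoffHz, firOrder = firOrder, passHz = passHz,
      stopHz = stopHz, edgeTrimS = edgeTrimS)
}

#' Welch power spectral density estimate
#'
#' Averaged periodogram over Hann-windowed segments with 50% overlap.
#'
#' @param x numeric series (at least 2 s of data).
#' @param sampleRate Hz.
#' @param segLength segment length in samples (default: about an eighth of
#'   the series, at least 256 samples, at most the series length).
#' @return data.frame with columns \code{freq} (Hz) and \code{power}.
#' @export
welchPsd <- function(x, sampleRate, segLength = NULL) {
  n <- length(x)
  .stopIf(n < 2 * sampleRate, "series too short: need at least 2 s of data")
  if (is.null(segLength)) segLength <- min(n, max(256L, 2^floor(log2(n / 8))))
  segLength <- min(segLength, n)
  hop <- max(1L, floor(segLength / 2))
  starts <- seq(1L, n - segLength + 1L, by = hop)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(segLength) / (segLength + 1))
  U <- sum(w^2)
  nf <- floor(segLength / 2) + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segLength - 1L)]
    seg <- (seg - mean(seg)) * w
    P <- abs(fft(seg))^2 / (U * sampleRate)
    acc <- acc + P[seq_len(nf)]
  }
  pw <- acc / length(starts)
  pw[2:(nf - 1L)] <- 2 * pw[2:(nf - 1L)]  # one-sided
  data.frame(freq = (seq_len(nf) - 1) * sampleRate / segLength, power = pw)
}

# forward pass of an IIR filter with odd-reflection padding and DC anchoring
.padFilter <- function(b, a, x, npad) {
  n <- length(x)
  npad <- min(npad, n - 1L)
  pre <- 2 * x[1] - x[(npad + 1L):2L]
  post <- 2 * x[n] - x[(n - 1L):(n - npad)]
  y <- signal::filter(b, a, c(pre, x, post))
  y[(npad + 1L):(npad + n)]
}

#' Zero-phase Butterworth lowpass
#'
#' Applies the Butterworth design forward and backward (zero net phase, DC
#' gain exactly 1). Edge transients are suppressed by odd-reflection padding
#' and by removing the endpoint offset before filtering, so a constant series
#' passes through unchanged.
#'
#' @param x numeric series.
#' @param sampleRate Hz.
#' @param settings a \linkS4class{KinematicsSettings}.
#' @return filtered series, same length.
#' @export
butterLowpass <- function(x, sampleRate, settings = kinematicsSettings()) {
  stopifnot(is(settings, "KinematicsSettings"))
  .stopIf(settings@cutoffHz >= sampleRate / 2,
          "unstable design: cutoff must be below the Nyquist frequency")
  bf <- signal::butter(settings@butterworthOrder,
                       settings@cutoffHz / (sampleRate / 2), type = "low")
  npad <- min(length(x) - 1L, ceiling(2 * sampleRate))
  x0 <- x[1]
  y <- .padFilter(bf$b, bf$a, x - x0, npad) + x0
  y1 <- y[length(y)]
  rev(.padFilter(bf$b, bf$a, rev(y) - y1, npad) + y1)
}

#' Linear-phase FIR lowpass differentiator coefficients
#'
#' Weighted least-squares design of a type III (even order, antisymmetric)
#' FIR differentiator: the amplitude response approximates \eqn{\omega} on
#' \code{[0, passHz]} and 0 on \code{[stopHz, Nyquist]}, with the transition
#' band unconstrained. The impulse response has exact linear phase with group
#' delay \code{order/2} samples.
#'
#' @param order even filter order (number of taps minus one).
#' @param passHz,stopHz band edges in Hz.
#' @param sampleRate Hz.
#' @return numeric vector of \code{order + 1} coefficients. The discrete
#'   response approximates the derivative in units of rad/sample; multiply
#'   convolved output by \code{sampleRate} for derivatives per second.
#' @export
.firCache <- new.env(parent = emptyenv())

firDifferentiator <- function(order = 50, passHz = 5, stopHz = 7,
                              sampleRate = 240) {
  key <- paste(order, passHz, stopHz, sampleRate)
  hit <- get0(key, envir = .firCache, inherits = FALSE)
  if (!is.null(hit)) return(hit)
  .stopIf(order < 2 || order %% 2 != 0, "order must be a positive even integer")
  .stopIf(passHz >= stopHz, "passHz must be below stopHz")
  .stopIf(stopHz > sampleRate / 2, "stopHz must not exceed the Nyquist frequency")
  M <- order / 2
  wp <- 2 * pi * passHz / sampleRate
  ws <- 2 * pi * stopHz / sampleRate
  gp <- seq(wp / 1024, wp, length.out = 1024L)
  gs <- seq(ws, pi, length.out = 2048L)
  grid <- c(gp, gs)
  des <- c(gp, rep(0, 2048L))
  # relative-error weighting: 1/w^4 in the passband keeps the *percent* error
  # of the derivative flat across 1-5 Hz; 1/w^2 in the stopband concentrates
  # suppression just above the transition where residual signal power sits
  wgt <- sqrt(c(1 / gp^4, 1 / gs^2))
  S <- outer(grid, seq_len(M), function(w, n) sin(n * w))
  cf <- qr.solve(S * wgt, des * wgt)  # weighted least squares
  h <- numeric(order + 1)
  h[M + 1 + seq_len(M)] <- -cf / 2
  h[M + 1 - seq_len(M)] <- cf / 2
  assign(key, h, envir = .firCache)
  h
}

#' Differentiate a series with the FIR lowpass differentiator
#'
#' Convolves with the linear-phase differentiator and shifts by the group
#' delay (\code{order/2} samples) so the derivative is time-aligned with the
#' input. The \code{order/2} samples at each end, where the filter window is
#' incomplete, are returned as \code{NA}; downstream analyses exclude them via
#' the edge trim.
#'
#' @param x numeric series, longer than the filter.
#' @param sampleRate Hz.
#' @param settings a \linkS4class{KinematicsSettings}.
#' @return derivative series in units of \code{x} per second, same length.
#' @export
differentiateSeries <- function(x, sampleRate, settings = kinematicsSettings()) {
  stopifnot(is(settings, "KinematicsSettings"))
  .stopIf(length(x) <= settings@firOrder + 1,
          "series shorter than the differentiator filter")
  h <- firDifferentiator(settings@firOrder, settings@passHz, settings@stopHz,
                         sampleRate)
  y <- stats::filter(x, h, method = "convolution", sides = 2)
  as.numeric(y) * sampleRate
}
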