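fs <- 240

test_that("Welch PSD locates dominant frequencies", {
  t <- (0:(20 * fs - 1)) / fs
  psd <- welchPsd(sin(2 * pi * 2 * t), fs)
  expect_equal(psd$freq[which.max(psd$power)], 2, tolerance = 0.2)
  # white noise: spectrum flat within sampling error across octave bands
  set.seed(8)
  psdN <- welchPsd(rnorm(20 * fs), fs)
  b1 <- mean(psdN$power[psdN$freq > 10 & psdN$freq < 50])
  b2 <- mean(psdN$power[psdN$freq > 60 & psdN$freq < 110])
  expect_lt(abs(log(b1 / b2)), log(1.25))
  # a generated mode at 2.5 Hz concentrates its power in the 2-3 Hz band
  s <- makeScoreSeries(1, 2.5, 0.1, 20, fs, seed = 2)
  psdS <- welchPsd(s, fs)
  inBand <- sum(psdS$power[psdS$freq >= 2 & psdS$freq <= 3])
  expect_gt(inBand / sum(psdS$power), 0.5)
  expect_error(welchPsd(rnorm(100), fs), "too short")
})

test_that("zero-phase Butterworth: DC exact, passband flat, stopband killed", {
  st <- kinematicsSettings()
  expect_equal(butterLowpass(rep(3.2, 1000), fs, st), rep(3.2, 1000),
               tolerance = 1e-9)
  t <- (0:(10 * fs - 1)) / fs
  inner <- 500:1900
  y1 <- butterLowpass(sin(2 * pi * 1 * t), fs, st)
  expect_equal(max(abs(y1[inner])), 1, tolerance = 0.01)
  y20 <- butterLowpass(sin(2 * pi * 20 * t), fs, st)
  expect_lt(max(abs(y20[inner])), 0.05)  # > 95% attenuation
  # zero phase: cross-correlation with the input peaks at lag 0
  cc <- ccf(y1[inner], sin(2 * pi * 1 * t)[inner], lag.max = 30, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(butterLowpass(t, fs, kinematicsSettings(cutoffHz = 130)),
               "Nyquist")
})

test_that("FIR differentiator matches analytic derivatives", {
  t <- (0:(10 * fs - 1)) / fs
  inner <- 200:(length(t) - 200)
  for (f in c(1, 2, 3)) {
    y <- differentiateSeries(sin(2 * pi * f * t), fs)
    truth <- 2 * pi * f * cos(2 * pi * f * t)
    relErr <- sqrt(mean((y[inner] - truth[inner])^2)) / sqrt(mean(truth[inner]^2))
    expect_lt(relErr, 0.01)
  }
  # constant -> zero; ramp -> slope
  yc <- differentiateSeries(rep(5, 1000), fs)
  expect_lt(max(abs(yc[100:900])), 1e-10 * 5)
  yr <- differentiateSeries(3.7 * t, fs)
  expect_lt(max(abs(yr[inner] - 3.7)) / 3.7, 0.001)
  expect_error(differentiateSeries(rnorm(40), fs), "shorter")
})

test_that("kinematics chain reproduces the analytic second derivative", {
  t <- (0:(20 * fs - 1)) / fs
  sc <- new("SubjectScores", subjectId = "s",
            scores = cbind(sin(2 * pi * 2 * t)), sampleRate = fs)
  kin <- computeKinematics(sc)
  vr <- validRange(kin)
  idx <- vr[1]:vr[2]
  pa <- accelerations(kin)[idx, 1]
  truth <- -(4 * pi)^2 * sin(2 * pi * 2 * t)[idx]
  expect_lt(sqrt(mean((pa - truth)^2)) / sqrt(mean(truth^2)), 0.02)
  # zero scores give zero accelerations
  scz <- new("SubjectScores", subjectId = "s",
             scores = cbind(0 * t), sampleRate = fs)
  expect_lt(max(abs(accelerations(computeKinematics(scz))[idx, 1])), 1e-12)
})

test_that("the valid window arithmetic matches the trim", {
  t <- (0:(80 * fs - 1)) / fs
  sc <- new("SubjectScores", subjectId = "s",
            scores = cbind(sin(2 * pi * 2 * t)), sampleRate = fs)
  vr <- validRange(computeKinematics(sc))
  expect_equal(vr[2] - vr[1] + 1, 18960)  # 79 s at 240 Hz
})

test_that("zero crossings: sign changes, zero runs, interpolation, invariances", {
  # sinusoid second derivative crosses 2 f T times
  t <- (0:(10 * fs - 1)) / fs
  pa <- -sin(2 * pi * 2 * t)
  zc <- zeroCrossings(pa, fs)
  expect_lte(abs(zc$n - 2 * 2 * 10), 2)
  # crossing times fall on half-period gridpoints
  expect_lt(max(abs(diff(zc$times) - 0.25)), 1e-3)
  expect_equal(zeroCrossings(abs(pa) + 1, fs)$n, 0)
  # tie rule: a zero run bracketed by opposite signs is one crossing at its center
  z1 <- zeroCrossings(c(1, 0, -1), fs)
  expect_equal(z1$n, 1)
  expect_equal(z1$times, 1 / fs)
  expect_equal(zeroCrossings(c(1, 0, 0, 1), fs)$n, 0)
  expect_equal(zeroCrossings(c(1, 0, 0, -1, 1), fs)$n, 2)
  # N is invariant under positive rescaling
  expect_equal(zeroCrossings(0.003 * pa, fs)$n, zc$n)
  # sigma is invariant under time shift of the series
  s1 <- crossingIntervalSD(zeroCrossings(pa[1:2000], fs)$times)
  s2 <- crossingIntervalSD(zeroCrossings(pa[241:2240], fs)$times)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("crossing-interval SD follows the sample convention", {
  expect_equal(crossingIntervalSD(seq(0, 10, by = 0.25)), 0)
  # alternating 0.4 / 0.6 s intervals, equal counts
  n <- 40
  times <- cumsum(c(0, rep(c(0.4, 0.6), n / 2)))
  expect_equal(crossingIntervalSD(times), 0.1 * sqrt(n / (n - 1)),
               tolerance = 1e-9)
  expect_warning(s <- crossingIntervalSD(c(0, 1)), "fewer than 3")
  expect_true(is.nan(s))
  # interpolated crossings of a pure sinusoid acceleration: sigma < 2 ms
  t <- (0:(20 * fs - 1)) / fs
  sc <- new("SubjectScores", subjectId = "s",
            scores = cbind(sin(2 * pi * 2 * t)), sampleRate = fs)
  kin <- computeKinematics(sc)
  vr <- validRange(kin)
  sig <- crossingIntervalSD(zeroCrossings(accelerations(kin)[vr[1]:vr[2], 1], fs)$times)
  expect_lt(sig, 0.002)
})

test_that("control variables table: counts, NaN for dead components, rSTD merge", {
  t <- (0:(20 * fs - 1)) / fs
  sc <- new("SubjectScores", subjectId = "s",
            scores = cbind(PM1 = sin(2 * pi * 2 * t), PM2 = 0 * t),
            sampleRate = fs)
  kin <- computeKinematics(sc)
  rs <- suppressWarnings(relativeStd(sc))
  cv <- suppressWarnings(controlVariables(kin, rs))
  win <- cv$window_s[1]
  expect_lte(abs(cv$N[1] - 2 * 2 * win), 2)
  expect_equal(cv$N[2], 0)
  expect_true(is.nan(cv$sigma[2]))
  expect_equal(cv$rSTD, rs$rSTD)
  expect_identical(names(cv), c("subject_id", "k", "rSTD", "N", "sigma", "window_s"))
})

test_that("planted jitter raises the mean crossing-interval SD", {
  sigMean <- function(jit, n = 20) {
    mean(vapply(seq_len(n), function(i) {
      s <- makeScoreSeries(1, 2, jit, 20, fs, seed = 1000 + 31 * i + round(1e4 * jit))
      sc <- new("SubjectScores", subjectId = "s", scores = cbind(s), sampleRate = fs)
      kin <- computeKinematics(sc)
      vr <- validRange(kin)
      crossingIntervalSD(zeroCrossings(accelerations(kin)[vr[1]:vr[2], 1], fs)$times)
    }, 0))
  }
  m0 <- sigMean(0); m1 <- sigMean(0.1); m2 <- sigMean(0.2)
  expect_lt(m0, m1)
  expect_lt(m1, m2)
})

test_that("filter sweep: single default setting reproduces the single run", {
  co <- generateCohort(effectConfig(101))
  ps <- preprocessCohort(co, nMarkers = 8, seed = 101)
  m <- fitPCA(concatenateSubjects(ps), r = 3)
  sc <- lapply(ps, projectSubject, model = m)
  meta <- co$truth$subjects[, c("subject_id", "age_group", "gender")]
  grid <- data.frame(cutoff_hz = 7, pass_hz = 5, stop_hz = 7)
  sw <- filterSensitivitySweep(sc, grid, meta, components = 2)
  # independent single run
  cv <- cohortControlVariables(sc)
  tab <- merge(cv[cv$k == 2, ], meta, by = "subject_id")
  tab$value <- tab$N
  an <- twoWayAnova(tab)
  expect_equal(sw$p[sw$variable == "N" & sw$effect == "age"],
               an$p[an$effect == "age"], tolerance = 1e-12)
  # invalid rows skipped with warning; empty grid errors
  gridBad <- data.frame(cutoff_hz = c(7, 300), pass_hz = c(5, 9), stop_hz = c(7, 7))
  expect_warning(sw2 <- filterSensitivitySweep(sc, gridBad, meta, components = 2),
                 "skipping invalid")
  expect_identical(unique(sw2$setting), 1L)
  expect_error(filterSensitivitySweep(sc, data.frame(), meta), "empty")
})
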