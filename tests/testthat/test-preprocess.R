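makeTinyTraj <- function(nFrames = 48, nMarkers = 6, seed = 2, frontFoot = "right") {
  cfg <- syntheticConfig(nSubjectsPerCell = 1, duration = nFrames / 240,
                         nMarkers = nMarkers, nModes = 2,
                         measurementNoiseSD = 0, gapFraction = 0, seed = seed)
  co <- generateCohort(cfg)
  tr <- co$subjects[[1]]
  tr@frontFoot <- frontFoot
  tr
}

test_that("marker CSV write/read round trip preserves data and metadata", {
  tr <- makeTinyTraj()
  path <- withr::local_tempfile(fileext = ".csv")
  writeMarkers(tr, path)
  tr2 <- readMarkers(path)
  expect_identical(markerLabels(tr2), markerLabels(tr))
  expect_lt(max(abs(markerPositions(tr2) - markerPositions(tr))), 1e-9)
  expect_equal(sampleRate(tr2), sampleRate(tr))
  expect_equal(tr2@height, tr@height)
  expect_identical(tr2@ageGroup, tr@ageGroup)
  expect_identical(tr2@frontFoot, tr@frontFoot)
})

test_that("CSV reader flags missing cells and honors millimeter units", {
  df <- data.frame(frame = rep(1:4, each = 2), label = rep(c("C7", "SACR"), 4),
                   x = 1:8, y = 1:8, z = 1:8)
  df$x[3] <- NA
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("# units: mm", path)
  suppressWarnings(write.table(df, path, append = TRUE, sep = ",",
                               row.names = FALSE, quote = FALSE, na = ""))
  tr <- readMarkers(path)
  expect_true(missingMask(tr)[2, 1])   # frame 2, marker C7
  expect_equal(sum(missingMask(tr)), 1)
  expect_equal(markerPositions(tr)[1, 1, 1], 1e-3)  # mm -> m
})

test_that("CSV reader rejects malformed files", {
  path <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame = c(1, 1, 3), label = c("A", "B", "A"),
                   x = 1:3, y = 1:3, z = 1:3)
  write.csv(df, path, row.names = FALSE)
  expect_error(readMarkers(path), "format error")
  expect_error(readMarkers("no/such/file.csv"), "not found")
})

test_that("gap filling recovers low-rank structure and never touches observed data", {
  cfg <- syntheticConfig(nSubjectsPerCell = 1, duration = 4, nMarkers = 12,
                         nModes = 3, measurementNoiseSD = 0, gapFraction = 0,
                         seed = 13)
  co <- generateCohort(cfg)
  tr <- co$subjects[[1]]
  expect_identical(fillGaps(tr), tr)  # no gaps: identity

  d <- dim(tr@positions)
  set.seed(4)
  mask <- matrix(runif(d[1] * d[2]) < 0.05, d[1], d[2])
  mask[1, ] <- FALSE; mask[d[1], ] <- FALSE
  holed <- tr
  for (c in 1:3) { sl <- holed@positions[, , c]; sl[mask] <- NA; holed@positions[, , c] <- sl }
  holed@missingMask <- mask
  filled <- fillGaps(holed, rank = 3, maxIter = 500, tol = 1e-9)
  expect_false(any(missingMask(filled)))
  # imputed entries match ground truth
  err <- (markerPositions(filled) - markerPositions(tr))[array(mask, d)]
  expect_lt(sqrt(mean(err^2)), 1e-6)
  # observed entries bit-exact
  obs <- !array(mask, d)
  expect_identical(markerPositions(filled)[obs], markerPositions(tr)[obs])
})

test_that("a single missing sample on linear motion is interpolation-accurate", {
  tr <- makeTinyTraj(nFrames = 60, nMarkers = 6)
  # overwrite one marker with exactly linear motion
  d <- dim(tr@positions)
  tr@positions[, 2, 1] <- seq(0, 1, length.out = d[1])
  tr@positions[30, 2, 1] <- NA
  tr@missingMask[30, 2] <- TRUE
  filled <- fillGaps(tr, rank = 5)
  expect_lt(abs(markerPositions(filled)[30, 2, 1] - 29 / (d[1] - 1)), 1e-6)
})

test_that("gap filling refuses a fully missing marker", {
  tr <- makeTinyTraj()
  tr@missingMask[, 3] <- TRUE
  for (c in 1:3) tr@positions[, 3, c] <- NA
  expect_error(fillGaps(tr), "unrecoverable gap")
})

test_that("mirroring reflects y, swaps lateral labels, and is an involution", {
  tr <- makeTinyTraj(frontFoot = "left")
  m <- mirrorLeftFront(tr)
  expect_identical(m@frontFoot, "right")
  labs <- markerLabels(tr)
  iL <- which(labs == "LASI"); iR <- which(labs == "RASI")
  expect_equal(markerPositions(m)[, iR, ],
               markerPositions(tr)[, iL, ] %*% diag(c(1, -1, 1)))
  # midline markers only flip sign of y
  iC <- which(labs == "C7")
  expect_equal(markerPositions(m)[, iC, 2], -markerPositions(tr)[, iC, 2])
  # involution
  m@frontFoot <- "left"
  back <- mirrorLeftFront(m)
  expect_equal(markerPositions(back), markerPositions(tr))
  # guard: right-foot-front input rejected
  expect_error(mirrorLeftFront(makeTinyTraj(frontFoot = "right")), "precondition")
})

test_that("mirroring rejects unpaired lateral labels", {
  tr <- makeTinyTraj(frontFoot = "left")
  tr@markerLabels[markerLabels(tr) == "RASI"] <- "RBAK"
  expect_error(mirrorLeftFront(tr), "unpaired")
})

test_that("marker selection drops asymmetric markers and validates the policy", {
  cfg <- syntheticConfig(nSubjectsPerCell = 1, duration = 1, nMarkers = 37,
                         nModes = 1, seed = 1)
  tr <- generateCohort(cfg)$subjects[[1]]
  sel <- selectMarkers(tr)
  expect_length(markerLabels(sel), 36)
  expect_false("RBAK" %in% markerLabels(sel))
  expect_identical(markerLabels(selectMarkers(tr, list(keep = markerLabels(tr)))),
                   markerLabels(tr))
  expect_error(selectMarkers(tr, list(drop = "NOPE")), "absent label")
  expect_error(selectMarkers(tr, list(keep = character())), "selects no markers")
})

test_that("segment weights are positive and sum to one over the marker set", {
  b <- makeBasePosture(37)
  for (labs in list(b$markerLabels, setdiff(b$markerLabels, "RBAK"))) {
    w <- segmentWeights(labs, b$segmentMap)
    expect_true(all(w > 0))
    expect_equal(sum(w), 1, tolerance = 1e-9)
  }
})

test_that("normalization centers, scales by height, weights by segment mass", {
  tr <- makeTinyTraj(nFrames = 48, nMarkers = 6)
  segMap <- makeBasePosture(6, seed = 2)$segmentMap
  w <- segmentWeights(markerLabels(tr), segMap)
  pm <- normalizeAndWeight(tr, w)
  expect_lt(max(abs(colMeans(postureCoords(pm)))), 1e-10)

  # static subject -> all-zero matrix
  trS <- tr
  for (c in 1:3) trS@positions[, , c] <- matrix(tr@positions[1, , c],
                                                nrow(tr@positions[, , c]),
                                                ncol(tr@positions[, , c]),
                                                byrow = TRUE)
  expect_lt(max(abs(postureCoords(normalizeAndWeight(trS, w)))), 1e-12)

  # joint rescaling of positions and height leaves the matrix unchanged
  trC <- tr
  trC@positions <- tr@positions * 2
  trC@height <- tr@height * 2
  expect_equal(postureCoords(normalizeAndWeight(trC, w)), postureCoords(pm),
               tolerance = 1e-12)

  # missing samples must be filled first
  trM <- tr
  trM@missingMask[5, 2] <- TRUE
  trM@positions[5, 2, 1] <- NA
  expect_error(normalizeAndWeight(trM, w), "must-fill-gaps-first")
})

test_that("a single-mode noise-free subject yields an exact rank-1 posture matrix", {
  cfg <- syntheticConfig(nSubjectsPerCell = 1, duration = 2, nMarkers = 8,
                         nModes = 1, measurementNoiseSD = 0, gapFraction = 0,
                         seed = 31)
  co <- generateCohort(cfg)
  pm <- preprocessCohort(co, nMarkers = 8, seed = 31)[[1]]
  sv <- svd(postureCoords(pm))$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("concatenation stacks subjects in order with a frame index", {
  cfg <- syntheticConfig(nSubjectsPerCell = 1, duration = 1, nMarkers = 6,
                         nModes = 2, seed = 17)
  ps <- preprocessCohort(generateCohort(cfg), nMarkers = 6, seed = 17)
  pooled <- concatenateSubjects(ps)
  expect_equal(nrow(postureCoords(pooled)),
               sum(vapply(ps, function(p) nrow(postureCoords(p)), 0)))
  expect_identical(unique(pooled@index$subject_id), names(ps))
  one <- concatenateSubjects(ps[1])
  expect_identical(postureCoords(one), postureCoords(ps[[1]]))

  bad <- ps[[2]]
  bad@markerLabels <- rev(bad@markerLabels)
  expect_error(concatenateSubjects(list(ps[[1]], bad)), "incompatible")
})
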