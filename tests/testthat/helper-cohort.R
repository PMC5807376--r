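# Shared fixtures and independent oracles, built in code at test time.

# preprocess a raw trajectory exactly as the pipeline does
preprocessTraj <- function(traj, segmentMap, policy = defaultMarkerPolicy()) {
  policy$drop <- intersect(policy$drop, traj@markerLabels)
  if (length(policy$drop)) traj <- selectMarkers(traj, policy)
  if (traj@frontFoot == "left") traj <- mirrorLeftFront(traj)
  normalizeAndWeight(traj, segmentWeights(traj@markerLabels, segmentMap))
}

preprocessCohort <- function(cohort, nMarkers, seed) {
  segMap <- makeBasePosture(nMarkers, seed = seed)$segmentMap
  lapply(cohort$subjects, preprocessTraj, segmentMap = segMap)
}

# clean validation cohort for basis-recovery checks: pure (jitter-free)
# oscillatory modes at well-separated frequencies, no between-subject
# parameter scatter
recoveryConfig <- function(noise = 0, seed = 11, nPerCell = 5, duration = 20) {
  syntheticConfig(
    nSubjectsPerCell = nPerCell, duration = duration, nMarkers = 37, nModes = 5,
    modeAmplitudes = 0.02 * 1.5^-(0:4),
    modeFrequencies = c(1.2, 2.9, 2.0, 2.55, 1.6),
    frequencyJitter = rep(0, 5), subjectAmpCV = 0, subjectFreqCV = 0,
    measurementNoiseSD = noise, gapFraction = 0, groupEffects = list(),
    seed = seed)
}

# small fast cohort for end-to-end group-effect simulations
effectConfig <- function(seed, effects = list(list(group = "old", mode = 2,
                                                  frequency = 0.9, jitter = 1.15))) {
  syntheticConfig(
    nSubjectsPerCell = c(young_female = 17, young_male = 8,
                         old_female = 17, old_male = 8),
    duration = 20, nMarkers = 8, nModes = 3,
    modeAmplitudes = c(0.020, 0.013, 0.008),
    modeFrequencies = c(2.2, 2.6, 2.0), frequencyJitter = rep(0.1, 3),
    groupEffects = effects, measurementNoiseSD = 0.001, gapFraction = 0,
    seed = seed)
}

# one end-to-end replicate: cohort -> preprocess -> PCA -> N_k -> ANOVA;
# returns the age-effect p-value for every component
ageEffectPvalues <- function(seed, effects, variable = "N") {
  cfg <- effectConfig(seed, effects)
  co <- generateCohort(cfg)
  ps <- preprocessCohort(co, nMarkers = 8, seed = seed)
  model <- fitPCA(concatenateSubjects(ps), r = 3)
  sc <- lapply(ps, projectSubject, model = model)
  cv <- cohortControlVariables(sc)
  tab <- merge(cv, co$truth$subjects[, c("subject_id", "age_group", "gender")],
               by = "subject_id")
  vapply(sort(unique(tab$k)), function(k) {
    sub <- tab[tab$k == k, ]
    sub$value <- sub[[variable]]
    an <- twoWayAnova(sub)
    an$p[an$effect == "age"]
  }, 0)
}

# independent brute-force type III ANOVA oracle: effect-coded design matrix,
# full vs drop-one-term least-squares fits compared by residual sums of squares
bruteForceAnova <- function(data) {
  data <- data[is.finite(data$value), ]
  a <- ifelse(data$age_group == "young", 1, -1)
  g <- ifelse(data$gender == "female", 1, -1)
  X <- cbind(1, a, g, a * g)
  y <- data$value
  rss <- function(M) {
    fit <- qr(M)
    sum((y - M %*% qr.coef(fit, y))^2)
  }
  rssFull <- rss(X)
  n <- length(y)
  dfErr <- n - 4L
  out <- lapply(2:4, function(j) {
    rssRed <- rss(X[, -j, drop = FALSE])
    ss <- rssRed - rssFull
    F <- (ss / 1) / (rssFull / dfErr)
    data.frame(effect = c("age", "gender", "age:gender")[j - 1], F = F,
               p = pf(F, 1, dfErr, lower.tail = FALSE),
               eta_p2 = ss / (ss + rssFull))
  })
  do.call(rbind, out)
}

# random subject table for ANOVA oracle comparisons
randomAnovaTable <- function(seed, cells = NULL) {
  set.seed(seed)
  if (is.null(cells))
    cells <- c(young_female = sample(3:17, 1), young_male = sample(3:17, 1),
               old_female = sample(3:17, 1), old_male = sample(3:17, 1))
  rows <- lapply(names(cells), function(cl) {
    data.frame(age_group = sub("_.*", "", cl), gender = sub(".*_", "", cl),
               value = rnorm(cells[[cl]], mean = runif(1, -2, 2),
                             sd = runif(1, 0.5, 2)))
  })
  do.call(rbind, rows)
}
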