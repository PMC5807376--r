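test_that("normality tests accept Gaussian and reject skewed samples", {
  accept <- vapply(1:40, function(i) {
    set.seed(100 + i)
    nt <- normalityTests(rnorm(200), rep("a", 200))
    nt$shapiro_p > 0.05 && nt$ks_p > 0.05
  }, TRUE)
  expect_gte(mean(accept), 0.80)
  reject <- vapply(1:40, function(i) {
    set.seed(200 + i)
    nt <- normalityTests(exp(rnorm(50)), rep("a", 50))
    nt$shapiro_p < 0.05
  }, TRUE)
  expect_gte(mean(reject), 0.90)
  expect_warning(nt <- normalityTests(rep(1, 10), rep("a", 10)), "degenerate")
  expect_true(is.nan(nt$shapiro_p))
})

test_that("Levene check detects variance heterogeneity at the right rate", {
  # equal variances: rejection rate near the nominal 5%
  rej <- vapply(1:200, function(i) {
    set.seed(i)
    cell <- rep(c("a", "b", "c", "d"), each = 50)
    leveneCheck(rnorm(200), cell)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.11)
  # a 10x SD cell is flagged
  pow <- vapply(1:40, function(i) {
    set.seed(1000 + i)
    cell <- rep(c("a", "b"), each = 30)
    leveneCheck(c(rnorm(30), rnorm(30, sd = 10)), cell)$p < 0.05
  }, TRUE)
  expect_gte(mean(pow), 0.9)
  # two identical cells: statistic exactly zero
  v <- rnorm(20)
  expect_equal(leveneCheck(c(v, v), rep(c("a", "b"), each = 20))$statistic, 0,
               tolerance = 1e-12)
  expect_error(leveneCheck(rnorm(3), c("a", "a", "b")), "degenerate")
})

test_that("type III ANOVA matches the brute-force least-squares oracle", {
  for (i in 1:25) {
    tab <- randomAnovaTable(i)
    mine <- twoWayAnova(tab)
    oracle <- bruteForceAnova(tab)
    expect_equal(mine$F, oracle$F, tolerance = 1e-8)
    expect_equal(mine$p, oracle$p, tolerance = 1e-8)
    expect_equal(mine$eta_p2, oracle$eta_p2, tolerance = 1e-8)
  }
  # the unbalanced 17 F / 8 M split of a 50-subject cohort
  tab <- randomAnovaTable(99, cells = c(young_female = 17, young_male = 8,
                                        old_female = 17, old_male = 8))
  mine <- twoWayAnova(tab)
  expect_equal(mine$df2, rep(46, 3))
  expect_equal(mine$F, bruteForceAnova(tab)$F, tolerance = 1e-8)
})

test_that("a pure additive effect without noise has zero interaction", {
  tab <- expand.grid(age_group = c("young", "old"),
                     gender = c("female", "male"), rep = 1:3)
  # cell means exactly additive; within-cell spread makes the error SS nonzero
  tab$value <- 10 + 2 * (tab$age_group == "old") + rep(c(-1, 0, 1), each = 4)
  an <- twoWayAnova(tab)
  expect_lt(an$F[an$effect == "age:gender"], 1e-20)
  expect_gt(an$F[an$effect == "age"], 1)
})

test_that("balanced designs decompose the total sum of squares", {
  set.seed(7)
  tab <- expand.grid(age_group = c("young", "old"),
                     gender = c("female", "male"), rep = 1:12)
  tab$value <- rnorm(nrow(tab))
  an <- twoWayAnova(tab)
  ssTot <- sum((tab$value - mean(tab$value))^2)
  expect_equal(sum(an$ss) + attr(an, "ss_error"), ssTot, tolerance = 1e-10 * ssTot)
})

test_that("observed power follows the noncentral F convention", {
  an <- twoWayAnova(randomAnovaTable(3))
  # recompute from the definition
  for (i in 1:3) {
    lambda <- an$F[i] * an$df1[i]
    expect_equal(an$power[i],
                 1 - pf(qf(0.95, an$df1[i], an$df2[i]), an$df1[i], an$df2[i],
                        ncp = lambda), tolerance = 1e-12)
  }
  expect_gt(posturePM:::.observedPower(1000, 1, 46), 0.999999)
  expect_lt(posturePM:::.observedPower(0.01, 1, 46), 0.06)
})

test_that("Sidak adjustment: closed forms and monotonicity", {
  expect_equal(sidakAdjust(0.05, 1), 0.05)
  expect_equal(sidakAdjust(0.01, 3), 0.029701, tolerance = 1e-9)
  expect_equal(sidakAdjust(1, 5), 1)
  expect_equal(sidakAdjust(0, 10), 0)
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(sidakAdjust(p, 4)) >= 0))
  expect_true(all(sidakAdjust(0.2, 1:10) >= 0.2 - 1e-12))
  expect_true(all(diff(sidakAdjust(0.2, 1:10)) >= 0))
  expect_error(sidakAdjust(1.2, 2), "lie in")
})

test_that("percent change uses the reference-group-as-100% convention", {
  expect_equal(percentChange(10, 9.08), -9.2)
  expect_equal(percentChange(7.3, 7.3), 0)
  expect_equal(percentChange(10, 14.6), 46)
  expect_error(percentChange(0, 1), "reference mean is zero")
})

test_that("simple-effects post-hoc agrees with emmeans and Sidak-corrects", {
  skip_if_not_installed("emmeans")
  tab <- randomAnovaTable(11, cells = c(young_female = 17, young_male = 8,
                                        old_female = 17, old_male = 8))
  ph <- posturePM:::.simpleEffects(tab)
  expect_equal(nrow(ph), 4)
  expect_true(all(ph$p_sidak >= ph$p_raw))
  expect_equal(ph$p_sidak, sidakAdjust(ph$p_raw, 4))

  tab$age_group <- factor(tab$age_group, levels = c("young", "old"))
  tab$gender <- factor(tab$gender, levels = c("female", "male"))
  fit <- lm(value ~ age_group * gender, data = tab)
  emm <- emmeans::emmeans(fit, ~ age_group | gender)
  emmAge <- as.data.frame(emmeans::contrast(emm, "revpairwise", adjust = "none"))
  # old-vs-young within female / male
  expect_equal(ph$mean_diff[1:2], emmAge$estimate, tolerance = 1e-10)
  expect_equal(ph$p_raw[1:2], emmAge$p.value, tolerance = 1e-10)
  emm2 <- emmeans::emmeans(fit, ~ gender | age_group)
  emmGen <- as.data.frame(emmeans::contrast(emm2, "revpairwise", adjust = "none"))
  expect_equal(abs(ph$mean_diff[3:4]), abs(emmGen$estimate), tolerance = 1e-10)
  expect_equal(ph$p_raw[3:4], emmGen$p.value, tolerance = 1e-10)
})

test_that("full report covers variables x components with correct df and exclusions", {
  set.seed(5)
  subj <- data.frame(subject_id = sprintf("S%02d", 1:50),
                     age_group = rep(c("young", "old"), each = 25),
                     gender = rep(c(rep("female", 17), rep("male", 8)), 2))
  control <- do.call(rbind, lapply(1:3, function(k)
    data.frame(subject_id = subj$subject_id, k = k,
               rSTD = runif(50, 5, 40), N = rpois(50, 90 - 10 * k),
               sigma = runif(50, 0.02, 0.06))))
  rep1 <- suppressMessages(fullReport(control, subj, r = 3))
  expect_equal(nrow(rep1$anova), 3 * 3 * 3)  # variables x components x effects
  expect_true(all(rep1$anova$df2 == 46))
  expect_true(all(is.finite(rep1$anova$p)))
  expect_equal(sum(rep1$excluded$excluded), 0)

  # casewise exclusion: one NaN sigma drops one subject for that variable only
  control$sigma[control$subject_id == "S01" & control$k == 2] <- NaN
  rep2 <- suppressMessages(fullReport(control, subj, r = 3))
  expect_equal(rep2$excluded$excluded[rep2$excluded$variable == "sigma" &
                                      rep2$excluded$k == 2], 1)
  expect_true(all(rep2$anova$df2[rep2$anova$variable == "sigma" &
                                 rep2$anova$k == 2] == 45))
})
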