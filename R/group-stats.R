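# Group statistics: assumption checks, type III two-way ANOVA with partial
# eta squared and observed power, Sidak-corrected post-hoc simple effects,
# and percent-change reporting.

#' Normality tests per design cell
#'
#' Lilliefors-corrected Kolmogorov-Smirnov and Shapiro-Wilk tests per cell.
#' Cells with fewer than 3 values (or zero variance) yield \code{NaN} with a
#' warning.
#'
#' @param values numeric vector.
#' @param cell factor/character of the same length identifying the cells.
#' @return data.frame: cell, n, ks_stat, ks_p, shapiro_stat, shapiro_p.
#' @export
normalityTests <- function(values, cell) {
  stopifnot(length(values) == length(cell))
  out <- lapply(split(values, cell), function(v) {
    v <- v[is.finite(v)]
    if (length(v) < 4 || .sdPop(v) == 0) {
      # lillie.test needs n >= 4; constant samples are degenerate for both tests
      warning("cell too small or degenerate for normality testing")
      return(data.frame(n = length(v), ks_stat = NaN, ks_p = NaN,
                        shapiro_stat = NaN, shapiro_p = NaN))
    }
    ks <- nortest::lillie.test(v)
    sw <- shapiro.test(v)
    data.frame(n = length(v), ks_stat = unname(ks$statistic),
               ks_p = ks$p.value, shapiro_stat = unname(sw$statistic),
               shapiro_p = sw$p.value)
  })
  cbind(data.frame(cell = names(out)), do.call(rbind, c(out, make.row.names = FALSE)))
}

#' Levene's test of variance homogeneity
#'
#' Mean-centered Levene test (the classical form) across cells.
#'
#' @param values numeric vector.
#' @param cell factor/character of cells (>= 2 cells, >= 2 values each).
#' @return list with \code{statistic}, \code{df1}, \code{df2}, \code{p}.
#' @export
leveneCheck <- function(values, cell) {
  keep <- is.finite(values)
  values <- values[keep]; cell <- factor(cell[keep])
  .stopIf(nlevels(cell) < 2 || any(table(cell) < 2),
          "degenerate cells: Levene needs >= 2 cells with >= 2 values each")
  lt <- car::leveneTest(values ~ cell, center = mean)
  list(statistic = lt[1, "F value"], df1 = lt[1, "Df"], df2 = lt[2, "Df"],
       p = lt[1, "Pr(>F)"])
}

#' Sidak multiplicity correction
#'
#' \eqn{p_{adj} = 1 - (1 - p)^m}, clipped to [0, 1].
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m number of comparisons in the family (>= 1).
#' @return adjusted p-value(s).
#' @export
sidakAdjust <- function(p, m) {
  .stopIf(any(p < 0 | p > 1, na.rm = TRUE), "p-values must lie in [0, 1]")
  .stopIf(any(m < 1), "m must be >= 1")
  pmin(1, pmax(0, 1 - (1 - p)^m))
}

#' Percent change of a group mean relative to a reference group
#'
#' \eqn{100 (\bar x_{cmp} - \bar x_{ref}) / \bar x_{ref}}; the reference
#' group (younger or male) is 100%.
#'
#' @param reference reference-group mean (non-zero).
#' @param comparison comparison-group mean.
#' @return percent change.
#' @export
percentChange <- function(reference, comparison) {
  .stopIf(any(reference == 0), "undefined: reference mean is zero")
  100 * (comparison - reference) / reference
}

# observed power of an F test at alpha, using the noncentral F with
# noncentrality lambda = F * df1 (the convention of common GLM software)
.observedPower <- function(F, df1, df2, alpha = 0.05) {
  crit <- qf(1 - alpha, df1, df2)
  1 - pf(crit, df1, df2, ncp = F * df1)
}

#' Type III two-way ANOVA with effect sizes and observed power
#'
#' Fits \code{value ~ age_group * gender} with sum-to-zero effect coding and
#' type III sums of squares (valid for the unbalanced gender cells), and
#' reports per effect: F, degrees of freedom, p, partial eta squared
#' \eqn{SS_e / (SS_e + SS_{err})}, and observed power from the noncentral F
#' distribution with \eqn{\lambda = F \cdot df_1} at \code{alpha}.
#'
#' @param data data.frame with columns \code{value}, \code{age_group}
#'   (young/old), \code{gender} (female/male); rows with non-finite values
#'   are dropped (casewise deletion).
#' @param alpha significance level for the power computation (default 0.05).
#' @return data.frame with one row per effect (\code{age}, \code{gender},
#'   \code{age:gender}) plus columns F, df1, df2, p, ss, eta_p2, power;
#'   attribute \code{ss_error}.
#' @export
twoWayAnova <- function(data, alpha = 0.05) {
  stopifnot(all(c("value", "age_group", "gender") %in% names(data)))
  data <- data[is.finite(data$value), , drop = FALSE]
  data$age_group <- factor(data$age_group, levels = c("young", "old"))
  data$gender <- factor(data$gender, levels = c("female", "male"))
  cellN <- table(data$age_group, data$gender)
  .stopIf(any(cellN < 2) || any(dim(cellN) != 2),
          "each of the four age x gender cells needs at least 2 subjects")
  fit <- lm(value ~ age_group * gender, data = data,
            contrasts = list(age_group = "contr.sum", gender = "contr.sum"))
  an <- car::Anova(fit, type = 3)
  eff <- c("age_group", "gender", "age_group:gender")
  ssErr <- an["Residuals", "Sum Sq"]
  dfErr <- an["Residuals", "Df"]
  rows <- lapply(eff, function(e) {
    ss <- an[e, "Sum Sq"]; df1 <- an[e, "Df"]
    F <- an[e, "F value"]; p <- an[e, "Pr(>F)"]
    data.frame(effect = sub("age_group", "age", e), F = F, df1 = df1,
               df2 = dfErr, p = p, ss = ss, eta_p2 = ss / (ss + ssErr),
               power = .observedPower(F, df1, dfErr, alpha))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "ss_error") <- ssErr
  attr(out, "n") <- nrow(data)
  out
}

# the four pairwise simple-effects comparisons of the 2x2 design, from cell
# means and the pooled error variance; Sidak family size m = 4
.simpleEffects <- function(data, alpha = 0.05) {
  data <- data[is.finite(data$value), , drop = FALSE]
  data$age_group <- factor(data$age_group, levels = c("young", "old"))
  data$gender <- factor(data$gender, levels = c("female", "male"))
  ag <- aggregate(value ~ age_group + gender, data, mean)
  nn <- aggregate(value ~ age_group + gender, data, length)
  fit <- lm(value ~ age_group * gender, data = data,
            contrasts = list(age_group = "contr.sum", gender = "contr.sum"))
  mse <- sum(residuals(fit)^2) / df.residual(fit)
  cm <- function(a, g) ag$value[ag$age_group == a & ag$gender == g]
  cn <- function(a, g) nn$value[nn$age_group == a & nn$gender == g]
  fam <- list(
    list(lab = "old-vs-young within female", ref = cm("young", "female"),
         cmp = cm("old", "female"), n1 = cn("young", "female"), n2 = cn("old", "female")),
    list(lab = "old-vs-young within male", ref = cm("young", "male"),
         cmp = cm("old", "male"), n1 = cn("young", "male"), n2 = cn("old", "male")),
    list(lab = "male-vs-female within young", ref = cm("young", "female"),
         cmp = cm("young", "male"), n1 = cn("young", "female"), n2 = cn("young", "male")),
    list(lab = "male-vs-female within old", ref = cm("old", "female"),
         cmp = cm("old", "male"), n1 = cn("old", "female"), n2 = cn("old", "male"))
  )
  m <- length(fam)
  rows <- lapply(fam, function(f) {
    diff <- f$cmp - f$ref
    se <- sqrt(mse * (1 / f$n1 + 1 / f$n2))
    tv <- diff / se
    praw <- 2 * pt(-abs(tv), df.residual(fit))
    data.frame(contrast = f$lab, mean_diff = diff, se = se, t = tv,
               df = df.residual(fit), p_raw = praw,
               p_sidak = sidakAdjust(praw, m), m = m,
               pct_change = if (f$ref != 0) percentChange(f$ref, f$cmp) else NaN)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full group-statistics report over variables and components
#'
#' For every dependent variable (\code{rSTD}, \code{N}, \code{sigma}) and
#' every component \eqn{k \le r}: assumption checks (per-cell normality,
#' Levene), the type III two-way age x gender ANOVA with partial eta squared
#' and observed power, percent changes of the group means (younger and male
#' groups = 100%), and — when the interaction is significant at \code{alpha} —
#' the four Sidak-corrected pairwise simple-effects comparisons.
#'
#' @param control combined control-variable table
#'   (\code{\link{cohortControlVariables}}), columns subject_id, k, rSTD, N,
#'   sigma.
#' @param meta data.frame with subject_id, age_group, gender.
#' @param r components to analyze (default: all present).
#' @param alpha significance level (default 0.05).
#' @return list with data.frames \code{anova}, \code{posthoc},
#'   \code{assumptions}, and \code{excluded} (casewise-deletion counts).
#' @export
fullReport <- function(control, meta, r = max(control$k), alpha = 0.05) {
  stopifnot(all(c("subject_id", "k") %in% names(control)),
            all(c("subject_id", "age_group", "gender") %in% names(meta)))
  tab <- merge(control, meta, by = "subject_id")
  vars <- intersect(c("rSTD", "N", "sigma"), names(control))
  anovaRows <- list(); phRows <- list(); asRows <- list(); exRows <- list()
  for (v in vars) for (k in seq_len(r)) {
    sub <- tab[tab$k == k, , drop = FALSE]
    sub$value <- sub[[v]]
    nMiss <- sum(!is.finite(sub$value))
    sub <- sub[is.finite(sub$value), , drop = FALSE]
    exRows[[length(exRows) + 1L]] <- data.frame(variable = v, k = k,
                                                excluded = nMiss)
    if (nMiss > 0)
      message(sprintf("%s, PM%d: %d subject(s) excluded casewise", v, k, nMiss))
    cellLab <- interaction(sub$age_group, sub$gender, sep = "_")
    nt <- suppressWarnings(normalityTests(sub$value, cellLab))
    lv <- leveneCheck(sub$value, cellLab)
    asRows[[length(asRows) + 1L]] <- cbind(data.frame(variable = v, k = k),
                                           nt, levene_p = lv$p)
    an <- twoWayAnova(sub, alpha)
    mAge <- tapply(sub$value, sub$age_group, mean)
    mGen <- tapply(sub$value, sub$gender, mean)
    an$pct_change <- c(percentChange(mAge["young"], mAge["old"]),
                       percentChange(mGen["male"], mGen["female"]),
                       NA_real_)
    anovaRows[[length(anovaRows) + 1L]] <- cbind(data.frame(variable = v, k = k), an)
    int_p <- an$p[an$effect == "age:gender"]
    if (is.finite(int_p) && int_p < alpha) {
      ph <- .simpleEffects(sub, alpha)
      phRows[[length(phRows) + 1L]] <- cbind(data.frame(variable = v, k = k), ph)
    }
  }
  list(
    anova = do.call(rbind, c(anovaRows, make.row.names = FALSE)),
    posthoc = if (length(phRows)) do.call(rbind, c(phRows, make.row.names = FALSE)) else NULL,
    assumptions = do.call(rbind, c(asRows, make.row.names = FALSE)),
    excluded = do.call(rbind, c(exRows, make.row.names = FALSE))
  )
}
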