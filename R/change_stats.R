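#' Reliable change index
#'
#' `rci = (after - before) / sem_d`, the individual difference score scaled
#' by the standard error of measurement of the difference. A positive RCI
#' indicates an increase from the first to the second time point.
#'
#' @param before,after numeric score vectors (same length).
#' @param sem_d standard error of measurement of the difference (> 0),
#'   scalar or per-subject vector.
#' @param subject optional subject labels.
#' @return data frame with `subject`, `d` (after - before), `sem_d`, `rci`.
#' @export
reliable_change <- function(before, after, sem_d, subject = NULL) {
  if (length(before) != length(after)) {
    stop("`before` and `after` must have equal length", call. = FALSE)
  }
  if (any(sem_d <= 0)) stop("`sem_d` must be > 0", call. = FALSE)
  if (is.null(subject)) subject <- seq_along(before)
  d <- after - before
  data.frame(subject = subject, d = d, sem_d = sem_d, rci = d / sem_d)
}

#' Standard error of measurement of a difference score
#'
#' Jacobson-Truax family estimator: `sem_d = sd_baseline * sqrt(2) *
#' sqrt(1 - reliability)`, i.e. the SE of a difference of two measurements
#' whose shared reliability is `reliability`.
#'
#' @param sd_baseline baseline SD of the measure (> 0).
#' @param reliability test-retest reliability in \[0, 1).
#' @return `sem_d`, same units as the measure.
#' @export
estimate_sem_d <- function(sd_baseline, reliability) {
  if (any(sd_baseline <= 0)) stop("`sd_baseline` must be > 0", call. = FALSE)
  if (any(reliability < 0 | reliability >= 1)) {
    stop("`reliability` must be in [0, 1)", call. = FALSE)
  }
  sd_baseline * sqrt(2) * sqrt(1 - reliability)
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' Equal-variance t with `df = n1 + n2 - 2` and two-sided p, computed from
#' group means, SDs and sizes (as printed in demographic tables).
#'
#' @param m1,sd1,n1 mean, SD, size of group 1.
#' @param m2,sd2,n2 mean, SD, size of group 2.
#' @return list with `statistic`, `df`, `p`, `estimate` (m1 - m2), `se`.
#' @export
pooled_two_sample_t <- function(m1, sd1, n1, m2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  list(statistic = t, df = df, p = 2 * pt(-abs(t), df),
       estimate = m1 - m2, se = se)
}

#' Pearson chi-square test of a 2 x 2 table
#'
#' Classic Pearson statistic without continuity correction, df = 1.
#'
#' @param a,b,c,d cell counts: rows are groups, columns categories
#'   (`a`,`b` = group 1; `c`,`d` = group 2).
#' @return list with `statistic`, `df`, `p`.
#' @export
chi_square_2x2 <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (any(counts < 0) || sum(counts) == 0) {
    stop("counts must be non-negative with a positive total", call. = FALSE)
  }
  tab <- matrix(counts, 2, 2, byrow = TRUE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  n <- sum(tab)
  E <- outer(rowSums(tab), colSums(tab)) / n
  stat <- sum((tab - E)^2 / E)
  list(statistic = stat, df = 1, p = pchisq(stat, 1, lower.tail = FALSE))
}

#' Linear-regression group comparison
#'
#' OLS of a score on a two-level group indicator, optionally adjusting for
#' a covariate; the group coefficient is tested. Without a covariate this
#' is numerically identical to the pooled two-sample t test.
#'
#' @param scores numeric outcome vector.
#' @param group two-level factor/character/logical of the same length.
#' @param covariate optional numeric covariate.
#' @return list with `estimate`, `se`, `statistic`, `df`, `p` for the group
#'   term.
#' @export
group_model <- function(scores, group, covariate = NULL) {
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("`group` must have two levels", call. = FALSE)
  if (min(table(group)) < 3) stop("need >= 3 subjects per group", call. = FALSE)
  dat <- data.frame(y = scores, g = group)
  if (is.null(covariate)) {
    fit <- lm(y ~ g, data = dat)
  } else {
    if (var(covariate) == 0) {
      stop("constant covariate: design is singular", call. = FALSE)
    }
    dat$x <- covariate
    fit <- lm(y ~ g + x, data = dat)
  }
  sm <- summary(fit)$coefficients
  row <- grep("^g", rownames(sm))[1]
  list(estimate = sm[row, 1], se = sm[row, 2], statistic = sm[row, 3],
       df = fit$df.residual, p = sm[row, 4])
}

#' Pre/post mixed model (random subject intercept)
#'
#' Random-intercept model of score on time point fitted with `lme4`; with
#' two complete, balanced time points the time effect is numerically the
#' paired t test on the differences (estimate = mean difference,
#' SE = sd(differences)/sqrt(n), df = n - 1), which is how the p-value is
#' computed.
#'
#' @param before,after paired score vectors.
#' @param subject subject ids (defaults to sequence).
#' @return list with `estimate`, `se`, `statistic`, `df`, `p` for the time
#'   effect.
#' @export
prepost_model <- function(before, after, subject = seq_along(before)) {
  if (length(before) != length(after) || anyNA(before) || anyNA(after)) {
    stop("paired complete data required", call. = FALSE)
  }
  n <- length(before)
  dat <- data.frame(y = c(before, after),
                    time = rep(c(0, 1), each = n),
                    subject = factor(rep(subject, 2)))
  fit <- suppressMessages(
    lme4::lmer(y ~ time + (1 | subject), data = dat,
               control = lme4::lmerControl(check.conv.singular = "ignore",
                                           calc.derivs = FALSE))
  )
  est <- lme4::fixef(fit)[["time"]]
  se <- unname(sqrt(diag(as.matrix(stats::vcov(fit))))[2])
  t <- est / se
  df <- n - 1
  list(estimate = unname(est), se = unname(se), statistic = unname(t),
       df = df, p = 2 * pt(-abs(t), df))
}

#' Benjamini-Hochberg q-values with significance flags
#'
#' Step-up FDR q-values; entries with `q < q_threshold` are flagged.
#'
#' @param pvals p-values in \[0, 1\].
#' @param q_threshold flag threshold (default 0.1).
#' @return data frame with `p`, `q`, `flag`.
#' @export
bh_fdr <- function(pvals, q_threshold = 0.1) {
  if (any(pvals < 0 | pvals > 1)) stop("p-values must be in [0, 1]", call. = FALSE)
  q <- p.adjust(pvals, method = "BH")
  data.frame(p = pvals, q = q, flag = q < q_threshold)
}
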