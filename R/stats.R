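# Cohort validation statistics: contingency tests, rank tests,
# Kaplan-Meier / log-rank, and Cox regression (plain and L1-penalised).
# Standard procedures are delegated to base R, survival and glmnet behind
# this module's interface.

#' Pearson chi-square test on a contingency table
#'
#' All-zero rows and columns are dropped before testing (expected counts
#' of an empty category are undefined). The Yates continuity correction
#' `(|O - E| - 0.5)^2 / E` is applied only for 2x2 tables, matching the
#' usual convention for sparse 2x2 comparisons; larger tables always use
#' the uncorrected statistic.
#'
#' @param counts r x c matrix of nonnegative integer counts.
#' @param yates apply the continuity correction (2x2 tables only).
#' @return List with `statistic`, `df`, `p.value`, and `dropped`
#'   (indices of removed all-zero rows/columns).
#' @export
pearson_chi2 <- function(counts, yates = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) == 0) {
    gs_error("counts must be nonnegative with positive total", "degenerate_table_error")
  }
  zr <- which(rowSums(counts) == 0)
  zc <- which(colSums(counts) == 0)
  if (length(zr)) counts <- counts[-zr, , drop = FALSE]
  if (length(zc)) counts <- counts[, -zc, drop = FALSE]
  if (nrow(counts) < 2 || ncol(counts) < 2) {
    gs_error("table degenerate after dropping empty categories",
             "degenerate_table_error")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = yates))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, dropped = list(rows = zr, cols = zc))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value summing hypergeometric probabilities of tables at
#' most as probable as the observed one.
#'
#' @param counts 2x2 matrix of nonnegative integers.
#' @return The p-value.
#' @export
fisher_exact <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2))) gs_error("fisher_exact requires a 2x2 table",
                                             "degenerate_table_error")
  stats::fisher.test(counts)$p.value
}

#' Mann-Whitney U test
#'
#' Two-sided test by normal approximation with tie correction and
#' continuity correction. Returns the U statistic for the first sample
#' (number of pairs `x_i > y_j` counting ties as one half). Two groups
#' that are completely tied give p = 1.
#'
#' @param x,y numeric samples.
#' @return List with `U` and `p.value`.
#' @export
mann_whitney <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1) {
    return(list(U = length(x) * length(y) / 2, p.value = 1))
  }
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE, correct = TRUE))
  p <- if (is.finite(ht$p.value)) ht$p.value else 1
  list(U = unname(ht$statistic), p.value = p)
}

#' Kaplan-Meier curve
#'
#' Product-limit estimate of the survival function. With no censoring it
#' equals the empirical survival function exactly.
#'
#' @param times observed times.
#' @param events event indicators (0/1).
#' @return An object of class `km_curve`: `times` (sorted unique observed
#'   times), `survival`, `at_risk`, `events`.
#' @export
km_fit <- function(times, events) {
  sf <- survival::survfit(survival::Surv(times, as.numeric(events)) ~ 1)
  structure(list(times = sf$time, survival = sf$surv, at_risk = sf$n.risk,
                 events = sf$n.event), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> %d time points, S from 1 to %.3f\n",
              length(x$times), min(x$survival)))
  invisible(x)
}

#' @export
plot.km_curve <- function(x, ...) {
  plot(stats::stepfun(x$times, c(1, x$survival)), do.points = FALSE,
       xlab = "months", ylab = "survival probability", main = "", ...)
  invisible(x)
}

#' Two-group log-rank test
#'
#' Chi-square statistic `(sum(O - E))^2 / sum(V)` with the hypergeometric
#' variance at each event time; symmetric in the group labels.
#'
#' @param times_a,events_a first group.
#' @param times_b,events_b second group.
#' @return List with `statistic` (chi-square, 1 df) and `p.value`.
#' @export
logrank_test <- function(times_a, events_a, times_b, events_b) {
  if (sum(events_a) + sum(events_b) == 0) {
    gs_error("log-rank test undefined without events", "no_events_error")
  }
  time <- c(times_a, times_b)
  event <- as.numeric(c(events_a, events_b))
  grp <- rep(c("a", "b"), c(length(times_a), length(times_b)))
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  list(statistic = unname(sd$chisq),
       p.value = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Cox proportional hazards regression
#'
#' Unpenalised fits maximise the Breslow partial likelihood by
#' Newton-Raphson (tolerance 1e-8, at most 100 iterations) and report
#' hazard ratios `exp(coef)` with Wald 95% confidence intervals
#' `exp(coef +- 1.96 SE)` from the inverse observed information.
#' Non-convergence is flagged, not thrown; a monotone partial likelihood
#' (perfect separation) is flagged and the diverging coefficient capped
#' at +-20. With `l1_penalty > 0` an L1-penalised (lasso) fit is returned
#' instead: coefficients at the requested penalty plus the whole
#' regularisation path, without standard errors.
#'
#' @param times observed times.
#' @param events event indicators (0/1).
#' @param covariates numeric matrix or data frame of covariates.
#' @param l1_penalty lasso penalty (0 = plain Cox).
#' @return An object of class `cox_fit`: data frame `coefficients`
#'   (`term`, `coef`, `hr`, `ci_lower`, `ci_upper`, `se`, `p.value`),
#'   flags `converged` and `monotone`, and for penalised fits `path`
#'   (lambda grid and coefficient matrix).
#' @export
cox_fit <- function(times, events, covariates, l1_penalty = 0) {
  x <- as.matrix(covariates)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  if (sum(events) < 1) gs_error("Cox fit needs at least one event",
                                "no_events_error")
  if (l1_penalty > 0) {
    lam <- sort(unique(c(l1_penalty, exp(seq(log(max(l1_penalty * 20, 1)),
                                             log(l1_penalty / 20), length.out = 30)))),
                decreasing = TRUE)
    fit <- glmnet::glmnet(x, survival::Surv(times, as.numeric(events)),
                          family = "cox", alpha = 1, lambda = lam,
                          standardize = FALSE)
    cf <- as.matrix(stats::coef(fit, s = l1_penalty))[, 1]
    res <- data.frame(term = colnames(x), coef = unname(cf),
                      hr = exp(unname(cf)), ci_lower = NA_real_,
                      ci_upper = NA_real_, se = NA_real_, p.value = NA_real_,
                      stringsAsFactors = FALSE)
    return(structure(list(coefficients = res, converged = TRUE,
                          monotone = FALSE, l1_penalty = l1_penalty,
                          path = list(lambda = fit$lambda,
                                      beta = as.matrix(fit$beta))),
                     class = "cox_fit"))
  }
  if (any(apply(x, 2, function(v) length(unique(v)) == 1))) {
    gs_error("constant covariate in unpenalised Cox fit", "configuration_error")
  }
  warned <- FALSE
  fit <- withCallingHandlers(
    survival::coxph(survival::Surv(times, as.numeric(events)) ~ x,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-8, iter.max = 100)),
    warning = function(w) {
      warned <<- TRUE
      invokeRestart("muffleWarning")
    })
  cf <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  monotone <- any(abs(cf) > 20) || (warned && any(abs(cf) > 10))
  cf_capped <- pmin(pmax(cf, -20), 20)
  res <- data.frame(term = colnames(x), coef = cf_capped, hr = exp(cf_capped),
                    ci_lower = exp(cf_capped - 1.96 * se),
                    ci_upper = exp(cf_capped + 1.96 * se), se = se,
                    p.value = 2 * stats::pnorm(-abs(cf / se)),
                    stringsAsFactors = FALSE)
  structure(list(coefficients = res,
                 converged = !warned || monotone,
                 monotone = monotone, l1_penalty = 0),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  if (x$l1_penalty > 0) {
    cat(sprintf("<cox_fit> lasso, lambda = %g\n", x$l1_penalty))
  } else {
    cat(sprintf("<cox_fit> Breslow partial likelihood%s\n",
                if (x$monotone) " [monotone likelihood, coefficients capped]" else ""))
  }
  df <- x$coefficients
  df$hr <- round(df$hr, 3); df$coef <- round(df$coef, 4)
  print(df[, c("term", "coef", "hr", "ci_lower", "ci_upper", "p.value")],
        row.names = FALSE)
  invisible(x)
}

#' Group-comparison table (cohort characteristics by risk group)
#'
#' Builds the standard baseline-characteristics comparison: for each
#' categorical variable, counts per group with a Pearson chi-square
#' p-value (Yates-corrected when 2x2) or Fisher's exact test on request;
#' for each continuous variable, median (range) per group with a
#' Mann-Whitney p-value.
#'
#' @param data data frame of patient-level variables.
#' @param group name of the two-level grouping column.
#' @param categorical,continuous character vectors of column names.
#' @param fisher character vector of categorical variables to test with
#'   Fisher's exact test instead.
#' @return Data frame with `variable`, `type`, `p.value` and per-group
#'   summaries.
#' @export
group_comparison_table <- function(data, group, categorical = character(),
                                   continuous = character(),
                                   fisher = character()) {
  g <- factor(data[[group]])
  stopifnot(nlevels(g) == 2)
  rows <- NULL
  for (v in categorical) {
    tab <- table(g, factor(data[[v]]))
    p <- if (v %in% fisher) fisher_exact(tab) else
      pearson_chi2(tab, yates = all(dim(tab) == 2))$p.value
    rows <- rbind(rows, data.frame(
      variable = v, type = "categorical",
      group1 = paste(sprintf("%s:%d", colnames(tab), tab[1, ]), collapse = " "),
      group2 = paste(sprintf("%s:%d", colnames(tab), tab[2, ]), collapse = " "),
      p.value = p, stringsAsFactors = FALSE))
  }
  for (v in continuous) {
    x1 <- data[[v]][g == levels(g)[1]]
    x2 <- data[[v]][g == levels(g)[2]]
    p <- mann_whitney(x1, x2)$p.value
    fmt <- function(x) sprintf("%.2f (%.2f-%.2f)", median(x), min(x), max(x))
    rows <- rbind(rows, data.frame(variable = v, type = "continuous",
                                   group1 = fmt(x1), group2 = fmt(x2),
                                   p.value = p, stringsAsFactors = FALSE))
  }
  rows
}

#' Univariable and multivariable Cox summary table
#'
#' For each variable, a univariable Cox fit; variables in `multivariable`
#' additionally enter one joint model. Hazard ratios are reported with
#' 95% confidence intervals and Wald p-values.
#'
#' @param data patient-level data frame.
#' @param time,event column names of the outcome.
#' @param variables character vector of covariates (numeric or two-level).
#' @param multivariable subset of `variables` for the joint model.
#' @return Data frame with `variable`, `analysis` (`"univariable"` /
#'   `"multivariable"`), `hr`, `ci_lower`, `ci_upper`, `p.value`.
#' @export
cox_table <- function(data, time, event, variables,
                      multivariable = variables) {
  enc <- function(v) {
    x <- data[[v]]
    if (is.numeric(x)) x else as.numeric(factor(x)) - 1
  }
  rows <- NULL
  for (v in variables) {
    f <- cox_fit(data[[time]], data[[event]], matrix(enc(v), ncol = 1,
                                                     dimnames = list(NULL, v)))
    cf <- f$coefficients
    rows <- rbind(rows, data.frame(variable = v, analysis = "univariable",
                                   hr = cf$hr, ci_lower = cf$ci_lower,
                                   ci_upper = cf$ci_upper, p.value = cf$p.value,
                                   stringsAsFactors = FALSE))
  }
  if (length(multivariable) >= 1) {
    xm <- sapply(multivariable, enc)
    f <- cox_fit(data[[time]], data[[event]], xm)
    cf <- f$coefficients
    rows <- rbind(rows, data.frame(variable = multivariable,
                                   analysis = "multivariable",
                                   hr = cf$hr, ci_lower = cf$ci_lower,
                                   ci_upper = cf$ci_upper, p.value = cf$p.value,
                                   stringsAsFactors = FALSE))
  }
  rows
}
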