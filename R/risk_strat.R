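#' Patient-level risk score
#'
#' A patient with several slides receives the maximum slide-level risk
#' score as their patient-specific score.
#'
#' @param scores_by_slide named numeric vector of slide scores.
#' @param slides_of_patient character vector of the patient's slide ids.
#' @return The maximum score.
#' @export
patient_risk <- function(scores_by_slide, slides_of_patient) {
  sc <- scores_by_slide[as.character(slides_of_patient)]
  if (length(sc) == 0 || anyNA(sc)) {
    gs_error("patient has no scored slides", "configuration_error")
  }
  max(sc)
}

#' Breslow baseline survival estimator
#'
#' Step-function estimate of the cumulative baseline hazard under the
#' Cox model, given fitted risk scores on the training set:
#' `H0(t) = sum_{event times t_i <= t} d_i / sum_{j: t_j >= t_i} exp(score_j)`
#' with `d_i` the number of events at `t_i`. The baseline survival is
#' `S0(t) = exp(-H0(t))`, right-continuous, nonincreasing, `S0(0) = 1`.
#' With all scores zero this reduces exactly to the Nelson-Aalen
#' estimator.
#'
#' @param scores fitted risk scores (linear predictors).
#' @param times observed times (months).
#' @param events event indicators (0/1).
#' @return An object of class `breslow_baseline` with `event_times`
#'   (sorted distinct times with at least one event) and `cum_hazard`.
#' @export
breslow_baseline <- function(scores, times, events) {
  events <- as.logical(events)
  stopifnot(length(scores) == length(times), length(times) == length(events))
  if (!any(events)) gs_error("baseline hazard undefined without events",
                             "no_events_error")
  et <- sort(unique(times[events]))
  inc <- vapply(et, function(t) {
    sum(events & times == t) / sum(exp(scores[times >= t]))
  }, numeric(1))
  structure(list(event_times = et, cum_hazard = cumsum(inc)),
            class = "breslow_baseline")
}

#' @export
print.breslow_baseline <- function(x, ...) {
  cat(sprintf("<breslow_baseline> %d event times, H0 range [0, %.4f]\n",
              length(x$event_times), max(x$cum_hazard)))
  invisible(x)
}

# H0(t), right-continuous step function (vectorised over t)
cumulative_hazard <- function(base, t) {
  idx <- findInterval(t, base$event_times)
  ifelse(idx == 0, 0, base$cum_hazard[pmax(idx, 1)])
}

#' Predicted survival probability at a horizon
#'
#' `S(t | risk) = S0(t)^exp(risk)` with `S0` from [breslow_baseline()].
#' Before the first event time the probability is exactly 1. Monotone
#' decreasing in the risk score.
#'
#' @param risk risk score(s), vectorised.
#' @param base a [breslow_baseline()].
#' @param horizon time (months) at which to evaluate; 18 months is the
#'   1.5-year horizon used for stratification.
#' @return Survival probabilities in `(0, 1]`.
#' @export
survival_probability <- function(risk, base, horizon = 18) {
  stopifnot(horizon >= 0)
  exp(-cumulative_hazard(base, horizon) * exp(risk))
}

#' Threshold risk stratification
#'
#' Assigns each patient to the high-risk group iff their predicted
#' survival probability at the horizon is strictly below the threshold
#' (a probability exactly equal to the threshold is low-risk). The
#' threshold is deliberately exposed: no universal value exists, and it
#' must be chosen for any deployment; 0.9 at the 18-month horizon is the
#' package default.
#'
#' @param probabilities named numeric vector (patient id to probability
#'   in `(0, 1]`).
#' @param threshold stratification threshold in (0, 1).
#' @param horizon the horizon the probabilities refer to (stored).
#' @return An object of class `risk_stratification`: data frame
#'   `patients` (`patient_id`, `probability`, `group`), `threshold`,
#'   `horizon`.
#' @export
stratify <- function(probabilities, threshold = 0.9, horizon = 18) {
  stopifnot(threshold > 0, threshold < 1,
            all(probabilities > 0), all(probabilities <= 1))
  grp <- ifelse(probabilities < threshold, "high", "low")
  structure(list(patients = data.frame(
    patient_id = if (is.null(names(probabilities)))
      as.character(seq_along(probabilities)) else names(probabilities),
    probability = unname(probabilities),
    group = unname(grp), stringsAsFactors = FALSE),
    threshold = threshold, horizon = horizon),
    class = "risk_stratification")
}

#' @export
print.risk_stratification <- function(x, ...) {
  tb <- table(factor(x$patients$group, levels = c("high", "low")))
  cat(sprintf("<risk_stratification> S(%g mo) < %g: %d high-risk / %d low-risk\n",
              x$horizon, x$threshold, tb["high"], tb["low"]))
  invisible(x)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk scores order their
#' survival times correctly. A pair (i, j) is comparable when i has an
#' event and `t_i < t_j`; it counts 1 when `risk_i > risk_j`, 0.5 on a
#' risk tie. Invariant under strictly monotone transforms of the risks.
#'
#' @param risks predicted risk scores.
#' @param times observed times.
#' @param events event indicators (0/1).
#' @return Concordance in `[0, 1]`.
#' @export
concordance_index <- function(risks, times, events) {
  n <- length(risks)
  stopifnot(n >= 2, length(times) == n, length(events) == n)
  events <- as.logical(events)
  conc <- 0; comp <- 0
  for (i in which(events)) {
    later <- times > times[i]
    comp <- comp + sum(later)
    conc <- conc + sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (comp == 0) gs_error("no comparable pairs; concordance undefined",
                          "undefined_result_error")
  conc / comp
}

#' Patient-level cross-validation of the joint model
#'
#' Shuffles patient ids with the run seed and deals them round-robin into
#' `n_folds` folds (sizes differing by at most one); all slides of a
#' patient always share a fold. Each round trains on the other folds,
#' scores the held-out patients (maximum over their slides), estimates
#' the Breslow baseline on the training patients and records the
#' held-out 18-month survival probabilities and the held-out concordance
#' index. Folds whose test set has no comparable pairs get an undefined
#' C-index, which is excluded from the mean with a warning.
#'
#' @param graphs list of `slide_graph` objects.
#' @param survival per-slide survival table (see [gnnsurv()]).
#' @param backbone a [backbone_config()].
#' @param training a [train_config()]; fold f trains with seed
#'   `training$seed + f`.
#' @param n_folds number of patient-level folds.
#' @param seed seed for the fold shuffle.
#' @param threshold,horizon stratification settings (see [stratify()]).
#' @param verbose print per-fold progress.
#' @return An object of class `gnnsurv_cv`: `fold_cindex`, `mean_cindex`,
#'   `folds` (patient id to fold), `patients` (risk, probability, group
#'   per patient, each scored as a test case exactly once), `threshold`,
#'   `horizon`.
#' @export
cross_validate <- function(graphs, survival, backbone = backbone_config(),
                           training = train_config(), n_folds = 4L, seed = 1L,
                           threshold = 0.9, horizon = 18, verbose = FALSE) {
  survival <- check_survival_table(survival)
  sid <- vapply(graphs, function(g) g$slide_id, character(1))
  survival <- survival[match(sid, survival$slide_id), ]
  if (anyNA(survival$slide_id)) {
    gs_error("every graph needs a row in the survival table", "configuration_error")
  }
  pids <- unique(survival$patient_id)
  if (length(pids) < n_folds) gs_error("need at least n_folds patients",
                                       "configuration_error")
  folds <- with_preserved_seed(seed, {
    setNames(rep(seq_len(n_folds), length.out = length(pids)), sample(pids))
  })
  fold_ci <- rep(NA_real_, n_folds)
  rows <- NULL
  for (f in seq_len(n_folds)) {
    test_p <- names(folds)[folds == f]
    train_rows <- survival$patient_id %in% names(folds)[folds != f]
    gtrain <- graphs[train_rows]
    ttrain <- survival[train_rows, ]
    if (sum(unique(ttrain[, c("patient_id", "event")])$event) < 1) {
      gs_error(sprintf("fold %d training split has no events", f),
               "configuration_error")
    }
    tc <- training
    tc$seed <- training$seed + f
    fit <- gnnsurv(gtrain, ttrain, backbone, tc)
    gtest <- graphs[survival$patient_id %in% test_p]
    ptest <- predict(fit, gtest, aggregate = "patient",
                     mapping = survival[survival$patient_id %in% test_p, ])
    info <- unique(survival[survival$patient_id %in% test_p,
                            c("patient_id", "time_months", "event")])
    r <- ptest[info$patient_id]
    ci <- tryCatch(concordance_index(r, info$time_months, info$event),
                   gnnsurv_error = function(e) NA_real_)
    if (is.na(ci)) warning(sprintf("fold %d C-index undefined (no comparable test pairs); excluded from mean", f),
                           call. = FALSE)
    fold_ci[f] <- ci
    prob <- survival_probability(r, fit$baseline, horizon)
    rows <- rbind(rows, data.frame(patient_id = info$patient_id, fold = f,
                                   risk = unname(r), probability = unname(prob),
                                   time_months = info$time_months,
                                   event = info$event, stringsAsFactors = FALSE))
    if (verbose) message(sprintf("fold %d/%d: test C-index %s", f, n_folds,
                                 format(round(ci, 4))))
  }
  rows$group <- ifelse(rows$probability < threshold, "high", "low")
  structure(list(fold_cindex = fold_ci,
                 mean_cindex = mean(fold_ci, na.rm = TRUE),
                 folds = folds, patients = rows,
                 threshold = threshold, horizon = horizon,
                 backbone = backbone, training = training),
            class = "gnnsurv_cv")
}

#' @export
print.gnnsurv_cv <- function(x, ...) {
  cat(sprintf("%d-fold patient-level CV (%s + %s)\n", length(x$fold_cindex),
              toupper(x$backbone$arch), x$backbone$pooling))
  cat("  per-fold C-index:", paste(format(round(x$fold_cindex, 4)), collapse = ", "), "\n")
  cat(sprintf("  mean C-index: %.4f\n", x$mean_cindex))
  tb <- table(factor(x$patients$group, levels = c("high", "low")))
  cat(sprintf("  stratification at S(%g mo) < %g: %d high / %d low\n",
              x$horizon, x$threshold, tb["high"], tb["low"]))
  invisible(x)
}
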