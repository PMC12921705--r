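#' Backbone configuration
#'
#' Architecture of the graph neural network that maps a patch graph to a
#' compact 64-dimensional graph-level embedding: a message-passing
#' backbone (graph convolution or graph attention), a node-level linear
#' map to the embedding dimension, and one of four graph poolings.
#'
#' @param arch `"gcn"` or `"gat"`.
#' @param hidden_dims widths of the message-passing layers.
#' @param embed_dim graph embedding dimension (64).
#' @param gat_heads attention heads for `"gat"` (must divide the hidden
#'   widths).
#' @param dropout dropout probability on hidden node activations.
#' @param pooling `"kde"`, `"attention"`, `"max"` or `"mean"`.
#' @param kde_grid KDE evaluation points per embedding dimension.
#' @param kde_bandwidth fixed KDE bandwidth; `NULL` for Scott's rule.
#' @return An object of class `backbone_config`.
#' @export
backbone_config <- function(arch = c("gcn", "gat"), hidden_dims = c(256L, 128L),
                            embed_dim = 64L, gat_heads = 4L, dropout = 0.25,
                            pooling = c("kde", "attention", "max", "mean"),
                            kde_grid = 16L, kde_bandwidth = NULL) {
  arch <- match.arg(arch)
  pooling <- match.arg(pooling)
  stopifnot(length(hidden_dims) >= 1, embed_dim >= 1,
            dropout >= 0, dropout < 1)
  if (arch == "gat" && any(hidden_dims %% gat_heads != 0)) {
    gs_error("gat_heads must divide every hidden width", "configuration_error")
  }
  structure(list(arch = arch, hidden_dims = as.integer(hidden_dims),
                 embed_dim = as.integer(embed_dim), gat_heads = as.integer(gat_heads),
                 dropout = dropout, pooling = pooling,
                 kde_grid = as.integer(kde_grid), kde_bandwidth = kde_bandwidth),
            class = "backbone_config")
}

#' Training configuration
#'
#' Full-batch Adam settings for the joint optimisation of the backbone
#' and the Cox head. The cohort sizes this model targets are small and
#' the partial likelihood couples all samples through shared risk sets,
#' so every epoch uses the whole training set. The seed fully determines
#' initialisation and dropout, making training runs reproducible.
#'
#' @param epochs number of full-batch epochs.
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 penalty added to weight (not bias) gradients.
#' @param seed RNG seed for initialisation and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 120L, learning_rate = 1e-3,
                         weight_decay = 1e-2, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 weight_decay = weight_decay, seed = as.integer(seed),
                 optimizer = "adam"),
            class = "train_config")
}

#' Fit a joint graph-neural-network Cox survival model
#'
#' Trains the backbone, pooling and Cox regression coefficients jointly
#' by minimising the negative Cox partial log-likelihood
#' ([cox_partial_nll()], Breslow ties) of the per-slide risk scores.
#' Every slide is a training sample carrying its patient's observed time
#' and event status; the per-patient maximum aggregation is applied at
#' inference. After training, a Breslow baseline survival function is
#' estimated from the patient-level training risk scores so the fitted
#' object can predict absolute survival probabilities.
#'
#' @param graphs list of [build_knn_graph()] `slide_graph` objects.
#' @param survival data frame with columns `patient_id`, `slide_id`,
#'   `time_months`, `event` (one row per slide; slides of a patient share
#'   time and event).
#' @param backbone a [backbone_config()].
#' @param training a [train_config()].
#' @param verbose print the loss every 20 epochs.
#' @return An object of class `gnnsurv` with components `params`,
#'   `backbone`, `training`, `loss_trajectory`, `slide_risks`,
#'   `patient_risks`, `baseline` (a [breslow_baseline()]) and `cindex`
#'   (training concordance).
#' @seealso [predict.gnnsurv()], [cross_validate()], [explain_graph()]
#' @examples
#' cohort <- simulate_cohort(cohort_sim_config(n_patients = 12,
#'   nodes_per_graph = c(6, 10), seed = 7))
#' fit <- gnnsurv(cohort$graphs, cohort$survival,
#'                backbone_config("gcn", hidden_dims = 16, pooling = "mean"),
#'                train_config(epochs = 15))
#' fit
#' @export
gnnsurv <- function(graphs, survival, backbone = backbone_config(),
                    training = train_config(), verbose = FALSE) {
  stopifnot(inherits(backbone, "backbone_config"),
            inherits(training, "train_config"))
  survival <- check_survival_table(survival)
  sid <- vapply(graphs, function(g) g$slide_id, character(1))
  if (!all(survival$slide_id %in% sid)) {
    gs_error("survival table references slide_ids with no graph",
             "configuration_error")
  }
  survival <- survival[match(sid, survival$slide_id), ]
  if (anyNA(survival$slide_id)) {
    gs_error("every graph needs a row in the survival table", "configuration_error")
  }
  if (length(unique(survival$patient_id)) < 2 || sum(survival$event) < 1) {
    gs_error("need at least 2 patients and 1 event to train", "configuration_error")
  }
  times <- survival$time_months
  events <- survival$event
  gps <- lapply(graphs, prep_graph)
  input_dim <- ncol(graphs[[1]]$features)

  set.seed(training$seed)
  params <- init_params(backbone, input_dim)
  ng <- length(gps)
  trained <- train_model(params, backbone, gps, times, events, training,
                         verbose = verbose)
  params <- trained$params
  loss_tr <- trained$loss_trajectory

  slide_risks <- vapply(seq_len(ng), function(i)
    model_forward(params, backbone, gps[[i]])$risk, numeric(1))
  names(slide_risks) <- sid
  pat <- unique(survival[, c("patient_id", "time_months", "event")])
  pat$risk <- vapply(pat$patient_id, function(pid)
    patient_risk(slide_risks, survival$slide_id[survival$patient_id == pid]),
    numeric(1))
  baseline <- breslow_baseline(pat$risk, pat$time_months, pat$event)
  ci <- tryCatch(concordance_index(pat$risk, pat$time_months, pat$event),
                 gnnsurv_error = function(e) NA_real_)
  structure(list(params = params, backbone = backbone, training = training,
                 loss_trajectory = loss_tr, slide_risks = slide_risks,
                 patient_risks = pat, baseline = baseline, cindex = ci,
                 input_dim = input_dim, call = match.call()),
            class = "gnnsurv")
}

check_survival_table <- function(survival) {
  need <- c("patient_id", "slide_id", "time_months", "event")
  miss <- setdiff(need, names(survival))
  if (length(miss)) gs_error(paste("survival table missing columns:",
                                   paste(miss, collapse = ", ")),
                             "configuration_error")
  if (any(survival$time_months <= 0)) gs_error("times must be positive",
                                               "configuration_error")
  if (!all(survival$event %in% c(0, 1))) gs_error("event must be 0/1",
                                                  "configuration_error")
  survival$patient_id <- as.character(survival$patient_id)
  survival$slide_id <- as.character(survival$slide_id)
  survival
}

#' @export
print.gnnsurv <- function(x, ...) {
  cat(sprintf("Joint GNN-Cox survival model (%s + %s pooling)\n",
              toupper(x$backbone$arch), x$backbone$pooling))
  cat(sprintf("  %d slides, %d patients (%d events)\n",
              length(x$slide_risks), nrow(x$patient_risks),
              sum(x$patient_risks$event)))
  cat(sprintf("  final loss %.4f (from %.4f), training C-index %.3f\n",
              utils::tail(x$loss_trajectory, 1), x$loss_trajectory[1], x$cindex))
  invisible(x)
}

#' @export
summary.gnnsurv <- function(object, ...) {
  out <- list(
    arch = object$backbone$arch, pooling = object$backbone$pooling,
    n_slides = length(object$slide_risks),
    n_patients = nrow(object$patient_risks),
    n_events = sum(object$patient_risks$event),
    epochs = object$training$epochs,
    initial_loss = object$loss_trajectory[1],
    final_loss = utils::tail(object$loss_trajectory, 1),
    train_cindex = object$cindex,
    beta_norm = sqrt(sum(object$params$beta^2))
  )
  class(out) <- "summary.gnnsurv"
  out
}

#' @export
print.summary.gnnsurv <- function(x, ...) {
  cat(sprintf("GNN-Cox model: %s + %s pooling\n", toupper(x$arch), x$pooling))
  cat(sprintf("  samples: %d slides / %d patients / %d events\n",
              x$n_slides, x$n_patients, x$n_events))
  cat(sprintf("  loss: %.4f -> %.4f over %d epochs\n",
              x$initial_loss, x$final_loss, x$epochs))
  cat(sprintf("  training C-index: %.4f; |cox beta| = %.3f\n",
              x$train_cindex, x$beta_norm))
  invisible(x)
}

#' @export
coef.gnnsurv <- function(object, ...) object$params$beta

#' Predict risk scores or survival probabilities
#'
#' Computes per-slide risk scores for new graphs; with `aggregate =
#' "patient"` a `mapping` of slides to patients is required and each
#' patient gets the maximum score over their slides. `type = "survival"`
#' additionally converts scores to `S0(horizon)^exp(risk)` using the
#' Breslow baseline estimated on the training set.
#'
#' @param object a fitted [gnnsurv()] model.
#' @param graphs list of `slide_graph` objects.
#' @param type `"risk"` (linear predictor) or `"survival"`.
#' @param aggregate `"slide"` or `"patient"`.
#' @param mapping data frame with `patient_id`, `slide_id` (needed for
#'   patient aggregation).
#' @param horizon months at which survival is evaluated (18 = 1.5 years).
#' @param ... unused.
#' @return Named numeric vector (slide or patient ids).
#' @export
predict.gnnsurv <- function(object, graphs, type = c("risk", "survival"),
                            aggregate = c("slide", "patient"), mapping = NULL,
                            horizon = 18, ...) {
  type <- match.arg(type)
  aggregate <- match.arg(aggregate)
  risks <- vapply(graphs, function(g)
    model_forward(object$params, object$backbone, prep_graph(g))$risk, numeric(1))
  names(risks) <- vapply(graphs, function(g) g$slide_id, character(1))
  if (aggregate == "patient") {
    if (is.null(mapping)) gs_error("patient aggregation needs a mapping",
                                   "configuration_error")
    mapping$patient_id <- as.character(mapping$patient_id)
    pids <- unique(mapping$patient_id[mapping$slide_id %in% names(risks)])
    risks <- vapply(pids, function(pid)
      patient_risk(risks, mapping$slide_id[mapping$patient_id == pid]),
      numeric(1))
    names(risks) <- pids
  }
  if (type == "survival") {
    risks <- survival_probability(risks, object$baseline, horizon)
  }
  risks
}

#' @export
plot.gnnsurv <- function(x, ...) {
  plot(seq_along(x$loss_trajectory), x$loss_trajectory, type = "l",
       xlab = "epoch", ylab = "negative partial log-likelihood",
       main = "training loss", ...)
  invisible(x)
}

#' @export
residuals.gnnsurv <- function(object, ...) {
  # martingale residuals on the training patients
  pat <- object$patient_risks
  h0 <- cumulative_hazard(object$baseline, pat$time_months)
  res <- pat$event - h0 * exp(pat$risk)
  names(res) <- pat$patient_id
  res
}
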