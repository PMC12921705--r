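#' Negative Cox partial log-likelihood
#'
#' The training loss of the joint model:
#' `-sum_{i: event} [ s_i - log sum_{j: t_j >= t_i} exp(s_j) ]`
#' with the Breslow convention for tied event times (events at a time are
#' counted in their own risk set). The loss is invariant to shifting all
#' scores by a constant, which is why the Cox head carries no intercept
#' (it is absorbed by the baseline hazard). Computed with log-sum-exp
#' stabilisation; the analytic gradient is returned on request.
#'
#' @param scores numeric vector of risk scores (one per sample).
#' @param times observed times (months), same length.
#' @param events event indicators (1/TRUE = event, 0/FALSE = censored).
#' @param return_gradient if `TRUE`, attach the gradient with respect to
#'   `scores` as attribute `"gradient"`.
#' @return The loss (a scalar), optionally with a `"gradient"` attribute.
#' @export
cox_partial_nll <- function(scores, times, events, return_gradient = FALSE) {
  n <- length(scores)
  stopifnot(length(times) == n, length(events) == n, n >= 2)
  events <- as.logical(events)
  if (!any(events)) gs_error("partial likelihood undefined without events",
                             "no_events_error")
  ord <- order(times)
  s <- scores[ord]; t <- times[ord]; e <- events[ord]
  m <- max(s)
  es <- exp(s - m)
  # risk-set sums: for position i, sum over j with t_j >= t_i (ties included)
  rev_cum <- rev(cumsum(rev(es)))
  first_of_tie <- match(t, t)             # index of first position with this time
  risk_sum <- rev_cum[first_of_tie]
  log_risk <- log(risk_sum) + m
  nll <- -(sum(s[e]) - sum(log_risk[e]))
  if (return_gradient) {
    # d nll / d s_j = -delta_j + exp(s_j) * sum_{events i: t_i <= t_j} 1 / R_i
    inv_r <- ifelse(e, 1 / risk_sum, 0)
    # accumulate per tie-group so every member of a tie group gets the full sum
    cum_inv <- cumsum(inv_r)
    last_of_tie <- n + 1L - match(t, rev(t))   # last index of the tie group
    g <- -as.numeric(e) + es * cum_inv[last_of_tie]
    grad <- numeric(n)
    grad[ord] <- g
    attr(nll, "gradient") <- grad
  }
  nll
}
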