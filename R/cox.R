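#' Negative Cox log partial likelihood (Breslow ties)
#'
#' Evaluates
#' \deqn{L = -\sum_{i: E_i = 1}\Big[h_i - \log \sum_{j: T_j \ge T_i} e^{h_j}\Big]}
#' over the observed events, with Breslow's convention for tied event
#' times (tied events share the full risk set at their common time). The
#' loss is invariant to adding a constant to all log-risks; internally the
#' risks are centered before exponentiation for numerical stability.
#'
#' @param risks Numeric vector of per-subject log-risks h(x).
#' @param times Positive observed times (days).
#' @param events 0/1 event indicators (1 = death observed).
#' @return A single non-negative number.
#' @export
cox_partial_loss <- function(risks, times, events) {
  check_survival_args(risks, times, events)
  if (sum(events) == 0) {
    stop_memsurv("partial likelihood undefined: no observed events",
                 "memsurv_undefined_loss_error")
  }
  h <- risks - max(risks)
  ord <- order(times, decreasing = TRUE)
  eh <- exp(h[ord])
  cs <- cumsum(eh)
  # Breslow: all subjects tied at T_i belong to the risk set of T_i.
  denom <- stats::ave(cs, times[ord], FUN = max)
  ev <- events[ord] == 1
  -sum(h[ord][ev] - log(denom[ev]))
}

# Gradient of cox_partial_loss with respect to the log-risks, computed in
# O(n log n) with the same Breslow convention. Used by the trainer.
cox_partial_gradient <- function(risks, times, events) {
  h <- risks - max(risks)
  n <- length(h)
  ord <- order(times, decreasing = TRUE)
  eh <- exp(h[ord])
  denom <- stats::ave(cumsum(eh), times[ord], FUN = max)
  ev <- events[ord] == 1
  inv <- ifelse(ev, 1 / denom, 0)
  # S_k = sum over events i with T_i <= T_k of 1/denom_i: reverse cumsum in
  # descending-time order, ties sharing the inclusive value.
  s <- rev(cumsum(rev(inv)))
  s <- stats::ave(s, times[ord], FUN = max)
  g_sorted <- eh * s - as.numeric(ev)
  g <- numeric(n)
  g[ord] <- g_sorted
  g
}

check_survival_args <- function(risks, times, events) {
  n <- length(risks)
  if (length(times) != n || length(events) != n) {
    stop_memsurv("risks, times and events must have equal length",
                 "memsurv_shape_error")
  }
  if (any(!is.finite(risks))) {
    stop_memsurv("risks must be finite", "memsurv_numeric_error")
  }
  if (any(times <= 0)) {
    stop_memsurv("times must be strictly positive", "memsurv_parameter_error")
  }
  if (!all(events %in% c(0, 1))) {
    stop_memsurv("events must be 0/1", "memsurv_parameter_error")
  }
  invisible(NULL)
}

#' Harrell's concordance index
#'
#' Fraction of permissible subject pairs whose predicted risk ordering
#' agrees with the observed survival ordering. A pair is permissible when
#' the earlier observed time carries an event; the pair is credited 1 if
#' the earlier-event subject has the higher risk, 0.5 if the risks are
#' tied, 0 otherwise. C = 1 is a perfect ranking, C = 0.5 is random.
#'
#' Implemented by aggregating over event subjects with vectorized
#' comparisons (O(events x n)); agrees with exhaustive pair enumeration.
#'
#' @inheritParams cox_partial_loss
#' @return Concordance index in \[0, 1\].
#' @export
concordance_index <- function(risks, times, events) {
  check_survival_args(risks, times, events)
  n <- length(risks)
  permissible <- 0
  credited <- 0
  for (i in which(events == 1)) {
    later <- times > times[i] | (times == times[i] & events == 0)
    later[i] <- FALSE
    m <- sum(later)
    if (m == 0) next
    permissible <- permissible + m
    credited <- credited +
      sum(risks[i] > risks[later]) + 0.5 * sum(risks[i] == risks[later])
  }
  if (permissible == 0) {
    stop_memsurv("concordance undefined: no permissible pairs",
                 "memsurv_undefined_cindex_error")
  }
  credited / permissible
}
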