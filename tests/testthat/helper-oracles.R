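# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: the partial likelihood is written out explicitly
# and maximized by one-dimensional search, the product-limit estimator is
# computed by hand, and AUC by exhaustive pair counting.

# Explicit Cox partial log-likelihood for a single coefficient, no ties
# (fixtures keep event times distinct): sum over event times of
# beta*x_i - log(sum_{j in risk set} exp(beta*x_j)).
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# grid + golden-section maximization of the explicit partial likelihood
oracle_cox_loghr <- function(time, event, x, lower = -8, upper = 8) {
  stats::optimize(function(b) oracle_cox_loglik(b, time, event, x),
                  c(lower, upper), maximum = TRUE, tol = 1e-9)$maximum
}

# hand product-limit estimator: returns S(t) at each distinct event time
oracle_km <- function(time, event) {
  tt <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (k in seq_along(tt)) {
    n_risk <- sum(time >= tt[k])
    d <- sum(time == tt[k] & event == 1)
    s <- s * (1 - d / n_risk)
    out[k] <- s
  }
  data.frame(time = tt, surv = out)
}

# exhaustive pair-counting AUC (ties count 1/2)
oracle_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ct <- scores[labels == 0]
  tot <- 0
  for (a in cs) tot <- tot + sum(a > ct) + 0.5 * sum(a == ct)
  tot / (length(cs) * length(ct))
}

# exhaustive Youden scan over observed thresholds and both directions
oracle_youden_j <- function(marker, event) {
  thr <- sort(unique(marker))
  n1 <- sum(event == 1); n0 <- sum(event == 0)
  j <- vapply(thr, function(ct) {
    sum(marker >= ct & event == 1) / n1 +
      sum(marker < ct & event == 0) / n0 - 1
  }, 0)
  max(abs(j))
}

# Closed-form categorical NRI for risks generated as plogis(z) with z
# normal given the class.  The net movement of a class depends only on the
# marginal exceedance probabilities (P(up) - P(down) telescopes), so the
# population NRI is exact whatever the old/new dependence:
#   nri_event    = P(new >= thr | event)    - P(old >= thr | event)
#   nri_nonevent = P(old >= thr | nonevent) - P(new >= thr | nonevent)
oracle_logitnormal_nri <- function(mu_old_event, mu_new_event,
                                   mu_old_non, mu_new_non,
                                   sd = 1, threshold) {
  ct <- stats::qlogis(threshold)
  exceed <- function(mu) stats::pnorm(ct, mu, sd, lower.tail = FALSE)
  e <- exceed(mu_new_event) - exceed(mu_old_event)
  v <- exceed(mu_old_non) - exceed(mu_new_non)
  list(event = e, nonevent = v, overall = e + v)
}
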