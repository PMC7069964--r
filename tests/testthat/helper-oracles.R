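# Independent brute-force oracles used to validate the fast implementations.

# Exhaustive step-fit search: minimum SSE over all splits of the sorted
# vector, ties toward the smallest split index.
oracle_step <- function(values) {
  v <- sort(values)
  n <- length(v)
  best <- list(sse = Inf, k = NA_integer_)
  tol <- 1e-9 * max(1, sum(v^2))
  for (k in 1:(n - 1)) {
    low <- v[1:k]
    high <- v[(k + 1):n]
    sse <- sum((low - mean(low))^2) + sum((high - mean(high))^2)
    if (sse < best$sse - tol) best <- list(sse = sse, k = k)
  }
  best$threshold <- (mean(v[1:best$k]) + mean(v[(best$k + 1):n])) / 2
  best
}

# Pairwise-concordance (Mann-Whitney) AUC with ties counted one half.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Brute-force Youden maximizer over all observed scores as cutoffs, with
# the rule "predict death when score >= cutoff" and ties toward the
# smallest cutoff.
oracle_youden <- function(scores, labels) {
  cuts <- sort(unique(scores))
  best <- list(j = -Inf, cutoff = NA_real_)
  for (ct in cuts) {
    pred <- as.integer(scores >= ct)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    j <- sens + spec - 1
    if (j > best$j + 1e-12) best <- list(j = j, cutoff = ct)
  }
  best
}

# Breslow partial log-likelihood for a single binary covariate.
oracle_cox_loglik <- function(beta, g, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- time >= time[i]
    ll <- ll + beta * g[i] - log(sum(exp(beta * g[risk])))
  }
  ll
}

# Grid-search maximizer of the Breslow partial likelihood (coarse pass,
# then a fine pass around the coarse optimum).
oracle_cox_loghr <- function(g, time, event, lo = -5, hi = 5) {
  coarse <- seq(lo, hi, by = 0.01)
  ll <- vapply(coarse, oracle_cox_loglik, numeric(1), g = g,
               time = time, event = event)
  c0 <- coarse[which.max(ll)]
  fine <- seq(c0 - 0.02, c0 + 0.02, by = 1e-4)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), g = g,
                time = time, event = event)
  fine[which.max(llf)]
}

# Hand product-limit estimator (events before censorings at ties).
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}
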