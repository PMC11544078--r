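# Independent oracles used to check the package's implementations.
# Each is a deliberately naive or closed-form computation that shares no
# code with the functions under test.

# brute-force tie-corrected Mann-Whitney AUC: mean over all (pos, neg) pairs
oracle_auc_pairwise <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (n in neg) tot <- tot + (p > n) + 0.5 * (p == n)
  tot / (length(pos) * length(neg))
}

# exhaustive closest-topleft search over a threshold set
oracle_topleft <- function(scores, labels, thresholds) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  d <- vapply(thresholds, function(ct) {
    (1 - mean(pos > ct))^2 + (1 - mean(neg <= ct))^2
  }, numeric(1))
  thresholds[which(d == min(d))[1]]
}

# independent Newton-Raphson logistic MLE (no glm, no IRLS reuse)
oracle_logistic_newton <- function(x, y, tol = 1e-12, maxit = 200) {
  beta <- c(0, 0)
  X <- cbind(1, x)
  for (it in seq_len(maxit)) {
    p <- 1 / (1 + exp(-(X %*% beta)))
    grad <- t(X) %*% (y - p)
    W <- as.numeric(p * (1 - p))
    H <- t(X) %*% (X * W)
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

# hand DeLong variance via the placement-value definition
oracle_delong_var <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- sapply(pos, function(xi) mean(sapply(neg, function(yj) psi(xi, yj))))
  v01 <- sapply(neg, function(yj) mean(sapply(pos, function(xi) psi(xi, yj))))
  var(v10) / length(pos) + var(v01) / length(neg)
}

# closed-form OLS via the normal equations
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  yhat <- intercept + slope * x
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(slope = slope, intercept = intercept, r_squared = r2)
}

# small analytic wind-field fixtures shared across tests (kept tiny for speed)
tiny_uniform_field <- function(u0 = 10, v0 = 0, T0 = 20, lapse = 0,
                               lat_range = c(20, 45), lon_range = c(105, 140),
                               n_times = 41, ...) {
  gen_wind_field(wind_field_spec("uniform", u0 = u0, v0 = v0, T0 = T0,
                                 lapse = lapse, lat_range = lat_range,
                                 lon_range = lon_range, n_times = n_times,
                                 ...))
}

# reduced ensembles keep integration tests inside the time budget
small_params <- function(...) {
  flight_params(start_heights = c(500, 1000), ...)
}
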