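# Independent oracles used across the suite. Each recomputes a quantity by a
# route different from the implementation under test.

# Direct evaluation of the accumulated losses: sum_k a_k(t) l(f_{i,k}, y_k),
# with the coefficient written out literally per variant.
brute_accumulated_loss <- function(advice, y, loss, variant,
                                   lambda = NULL, tea_exponent = "k_minus_1",
                                   rho = NULL) {
  t_end <- length(y)
  coef_at <- function(k) {
    switch(variant,
           standard = 1,
           tea = if (tea_exponent == "k") lambda^k else lambda^(k - 1),
           cz = rho^(t_end - k - 1))
  }
  sapply(seq_len(nrow(advice)), function(i) {
    sum(sapply(seq_len(t_end), function(k)
      coef_at(k) * loss_eval(loss, advice[i, k], y[k])))
  })
}

# Numeric minimisation of the two-term regret bound over eta (independent of
# the closed forms under test); searched on the log scale so that minima many
# orders of magnitude apart are all located accurately.
numeric_bound_min <- function(N, t, epsilon, S) {
  f <- function(leta) {
    eta <- exp(leta)
    log(N) / eta + eta * epsilon^2 * S / 8
  }
  opt <- stats::optimize(f, c(log(1e-12), log(1e6)), tol = 1e-12)
  list(eta = exp(opt$minimum), bound = opt$objective)
}

coef_sq_sum_direct <- function(variant, t, lambda = NULL, rho = NULL) {
  k <- seq_len(t)
  switch(variant,
         standard = t,
         tea = sum(lambda^(2 * (k - 1))),
         cz = sum(rho^(2 * (t - k - 1))))
}

# Exact-tail brute force: smallest c with P(X >= c+1) <= alpha/2 under
# Binomial(n, 1/2), by direct summation of dbinom.
brute_thresholds <- function(n, alpha = 0.05) {
  upper_tail <- rev(cumsum(rev(stats::dbinom(0:n, n, 0.5))))  # P(X >= c)
  upper <- min(which(c(upper_tail[-1], 0) <= alpha / 2)) - 1L  # index c = 0..n
  list(lower = n - upper, upper = upper)
}

# Mixture CDF by adaptive numeric integration of the density.
integrated_cdf <- function(mix, u) {
  lo <- min(mix$centers) - 12 * mix$sigma
  stats::integrate(function(x) mixture_density(mix, x), lo, u,
                   rel.tol = 1e-12, abs.tol = 1e-12)$value
}

random_mixture <- function(max_k = 10) {
  k <- sample(seq_len(max_k), 1)
  mixture_prediction(stats::rnorm(k, 0, 5), stats::rexp(k),
                     sigma = stats::runif(1, 0.05, 2))
}

# Random online prediction instance with losses inside [0, 1].
random_instance <- function(N, t_end) {
  list(advice = matrix(stats::runif(N * t_end), N),
       y = stats::runif(t_end))
}

q_levels7 <- c(0.975, 0.875, 0.75, 0.65, 0.6, 0.55, 0.525)
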