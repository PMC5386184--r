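# Regret, bound-optimal learning rates, and the optimal upper bounds of the
# three weighting schemes.
#
# All bounds descend from the Hoeffding two-term form
#   bound(eta) = ln(N)/eta + eta * epsilon^2 / 8 * S,   S = sum_k a_k(t)^2,
# minimised at eta* = sqrt(8 ln N / (epsilon^2 S)) with minimum
#   B* = epsilon * sqrt(S * ln N / 2).
# For the temporal scheme (a_k = lambda^{k-1}) S = (lambda^{2t}-1)/(lambda^2-1);
# for the standard scheme S = t, recovering epsilon*sqrt((t/2) ln N); for the
# discounted scheme (a_k = rho^{t-k-1}) S = rho^{-2}(1-rho^{2t})/(1-rho^2).

# log of S = sum of squared coefficients, computed without overflow.
# Under the a_k = lambda^k convention every coefficient gains a factor
# lambda, so S gains lambda^2.
log_coef_sq_sum <- function(variant, t, lambda = NULL, rho = NULL,
                            tea_exponent = "k_minus_1") {
  t <- as.integer(t)
  if (t < 1L) stop("'t' must be a positive integer")
  switch(variant,
         standard = log(t),
         tea = {
           if (is.null(lambda)) stop("tea requires 'lambda'")
           if (lambda < 1) stop("'lambda' must be >= 1")
           shift <- if (tea_exponent == "k") 2 * log(lambda) else 0
           if (lambda == 1) log(t)
           else shift + log_expm1(2 * t * log(lambda)) -
                log_expm1(2 * log(lambda))
         },
         cz = {
           if (is.null(rho)) stop("cz requires 'rho'")
           if (rho <= 0 || rho >= 1) stop("'rho' must lie in (0, 1)")
           -2 * log(rho) + log1p(-rho^(2 * t)) - log1p(-rho^2)
         },
         stop("unknown variant '", variant, "'"))
}

#' Bound-optimal learning rate
#'
#' The learning rate minimising the scheme's regret upper bound
#' \eqn{\ln(N)/\eta + \eta \epsilon^2 S / 8} with \eqn{S} the sum of squared
#' loss coefficients, i.e. \eqn{\eta^* = \sqrt{8 \ln N / (\epsilon^2 S)}}.
#' With \eqn{\lambda \to 1} (or the standard variant) this is the familiar
#' \eqn{\sqrt{8 \ln N / t}} at \eqn{\epsilon = 1}.
#'
#' @param N number of experts (>= 2 for a nonzero bound; N = 1 gives Inf).
#' @param t number of time steps.
#' @param epsilon loss bound (see [loss_spec()]).
#' @param variant `"standard"`, `"tea"` or `"cz"`.
#' @param lambda temporal decay rate (tea), >= 1.
#' @param rho discount rate in (0, 1) (cz).
#' @param tea_exponent coefficient convention for the temporal scheme, as in
#'   [weight_scheme()].
#' @return The optimal learning rate \eqn{\eta^*}.
#' @examples
#' optimal_eta(N = 10, t = 50, variant = "standard")
#' @export
optimal_eta <- function(N, t, epsilon = 1,
                        variant = c("standard", "tea", "cz"),
                        lambda = NULL, rho = NULL,
                        tea_exponent = c("k_minus_1", "k")) {
  variant <- match.arg(variant)
  tea_exponent <- match.arg(tea_exponent)
  if (N < 1) stop("'N' must be >= 1")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (N == 1) return(Inf)  # single expert: any eta; bound is 0
  logS <- log_coef_sq_sum(variant, t, lambda, rho, tea_exponent)
  exp(0.5 * (log(8 * log(N)) - logS) - log(epsilon))
}

#' Optimal regret upper bound
#'
#' The minimised upper bound \eqn{B^* = \epsilon \sqrt{S \ln N / 2}} on the
#' scheme's regret (defined through its own accumulated-loss weighting), where
#' \eqn{S} is the scheme's sum of squared loss coefficients. For the temporal
#' scheme this grows like \eqn{\lambda^t}; that is an artefact of the
#' exponential accumulated-loss scale and is made comparable across schemes by
#' [normalized_tea_bound()].
#'
#' @inheritParams optimal_eta
#' @return The optimal upper bound.
#' @examples
#' optimal_bound(N = 2, t = 2, variant = "standard")  # sqrt(ln 2)
#' @export
optimal_bound <- function(N, t, epsilon = 1,
                          variant = c("standard", "tea", "cz"),
                          lambda = NULL, rho = NULL,
                          tea_exponent = c("k_minus_1", "k")) {
  variant <- match.arg(variant)
  tea_exponent <- match.arg(tea_exponent)
  if (N < 1) stop("'N' must be >= 1")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  if (N == 1) return(0)
  logS <- log_coef_sq_sum(variant, t, lambda, rho, tea_exponent)
  epsilon * exp(0.5 * (logS + log(log(N) / 2)))
}

#' Normalised optimal upper bound of temporal expert advice
#'
#' Multiplies the temporal optimal bound (with \eqn{\lambda = \rho^{-1}}) by
#' \eqn{\rho^{t-1}}, bringing it onto the discounted-loss scale so that it can
#' be compared with the Chernov--Zhdanov bound. The product simplifies to
#' \eqn{\epsilon \sqrt{(1-\rho^{2t}) \ln N / (2 (1-\rho^2))}}, which equals
#' \eqn{\rho} times the CZ optimal bound and is therefore strictly smaller
#' whenever \eqn{0 < \rho < 1}.
#'
#' @inheritParams optimal_eta
#' @param lambda optional; if supplied it must satisfy `lambda * rho == 1`.
#' @return The normalised optimal bound.
#' @export
normalized_tea_bound <- function(N, t, epsilon = 1, rho, lambda = NULL) {
  if (!is.null(lambda) && abs(lambda * rho - 1) > 1e-12)
    stop("normalisation requires lambda = 1/rho")
  if (rho <= 0 || rho > 1) stop("'rho' must lie in (0, 1]")
  if (N == 1) return(0)
  if (rho == 1) return(optimal_bound(N, t, epsilon, "standard"))
  logB <- log(epsilon) +
    0.5 * (log_coef_sq_sum("tea", t, lambda = 1 / rho) + log(log(N) / 2))
  exp((t - 1) * log(rho) + logB)
}

#' Compare the normalised temporal bound with the discounted bound
#'
#' @inheritParams normalized_tea_bound
#' @return A list with `tea_normalized`, `cz` and the logical `tea_leq_cz`.
#' @export
bound_comparison <- function(N, t, epsilon = 1, rho) {
  if (rho <= 0 || rho >= 1) stop("'rho' must lie in (0, 1)")
  tea_n <- normalized_tea_bound(N, t, epsilon, rho)
  cz <- optimal_bound(N, t, epsilon, "cz", rho = rho)
  list(tea_normalized = tea_n, cz = cz, tea_leq_cz = tea_n <= cz + 1e-12)
}

#' Regret of a forecaster run
#'
#' The forecaster's accumulated loss minus the best expert's accumulated
#' loss, both under the scheme's own loss weighting (the "exponential"
#' accumulated losses for the temporal scheme, the discounted ones for CZ,
#' the plain sums for the standard forecaster).
#'
#' @param x a `"forecast_state"`, an `"ewa_run"` or a [tea()] fit.
#' @return The regret as a single number.
#' @export
regret_of <- function(x) {
  state <- if (inherits(x, "forecast_state")) x
           else if (!is.null(x$state)) x$state
           else stop("cannot extract a forecast state from 'x'")
  state$predictor_loss - min(state$expert_losses)
}

#' Regret report for a completed run
#'
#' Packages the observed regret, the matched optimal upper bound, the
#' learning rate actually used, and whether the bound held. The bound is
#' guaranteed only when the run used `eta = "auto"` (the bound-optimal rate)
#' and losses stayed within `[0, epsilon]`.
#'
#' @param fit an `"ewa_run"` or [tea()] fit.
#' @return A list with `regret`, `bound`, `eta_used`, `satisfied`.
#' @export
regret_report <- function(fit) {
  if (!inherits(fit, c("ewa_run", "tea_fit")))
    stop("'fit' must come from run_online() or tea()")
  sc <- fit$scheme
  t <- fit$state$t
  N <- fit$state$n_experts
  bound <- optimal_bound(N, t, fit$loss$epsilon, sc$variant,
                         lambda = sc$lambda, rho = sc$rho,
                         tea_exponent = sc$tea_exponent)
  reg <- regret_of(fit)
  list(regret = reg, bound = bound, eta_used = sc$eta,
       satisfied = reg <= bound + 1e-9)
}
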