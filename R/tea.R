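#' Fit an expert-advice forecaster to a target series
#'
#' Runs prediction with expert advice online over a target series: at each
#' step the forecaster emits a one-step-ahead prediction as the weighted
#' average of the experts' advice, then updates the weights from the revealed
#' loss. The temporal variant (`variant = "tea"`) multiplies the step-k loss
#' by \eqn{\lambda^{k-1}} (or \eqn{\lambda^k}) so that agreement with the
#' recent past dominates the weighting — the behaviour wanted for unstable
#' dynamics such as chaotic series or rising tumour-marker levels.
#'
#' @param target observed series: a [timeseries()] or numeric vector.
#' @param experts an [expert_panel()] whose columns align with the target's
#'   steps.
#' @param variant `"tea"`, `"standard"` or `"cz"`.
#' @param lambda temporal decay rate (tea; default \eqn{1/0.9}).
#' @param tea_exponent `"k_minus_1"` or `"k"`; see [weight_scheme()].
#' @param rho discount rate in (0, 1) (cz).
#' @param eta learning rate, or `"auto"` for the bound-optimal rate.
#' @param loss `"absolute"` or `"squared"`.
#' @param epsilon loss bound for the regret machinery (default 1).
#' @param burn_in initial steps excluded from evaluation summaries.
#' @param warn_epsilon warn if losses exceed `epsilon`.
#' @return An object of class `"tea_fit"` with components of [run_online()]
#'   plus the panel and the matched call. Supports `print`, `summary`,
#'   `coef` (final weights), `fitted`, `residuals`, `predict`, `plot` and
#'   `simulate`.
#' @examples
#' y <- sin(1:30 / 2)
#' panel <- expert_panel(rbind(good = sin(1:40 / 2), bad = cos(1:40)))
#' fit <- tea(y, panel, lambda = 1.2)
#' coef(fit)
#' predict(fit, q = 1)
#' @seealso [run_online()], [regret_report()], [mixture_predict()]
#' @export
tea <- function(target, experts, variant = c("tea", "standard", "cz"),
                lambda = 1 / 0.9, tea_exponent = c("k_minus_1", "k"),
                rho = NULL, eta = "auto",
                loss = c("absolute", "squared"), epsilon = 1,
                burn_in = 0L, warn_epsilon = TRUE) {
  variant <- match.arg(variant)
  tea_exponent <- match.arg(tea_exponent)
  if (is.character(loss)) loss <- loss_spec(match.arg(loss), epsilon)
  scheme <- weight_scheme(variant,
                          lambda = if (variant == "tea") lambda else NULL,
                          tea_exponent = tea_exponent,
                          rho = rho, eta = eta)
  target <- if (inherits(target, "timeseries")) target
            else timeseries(ts_values(target))
  run <- run_online(experts, target, scheme, loss, burn_in = burn_in,
                    warn_epsilon = warn_epsilon)
  run$panel <- experts
  run$times <- target$times[seq_along(run$y)]
  run$call <- match.call()
  class(run) <- c("tea_fit", "ewa_run")
  run
}

#' @export
print.tea_fit <- function(x, ...) {
  cat("Online expert-advice forecast (", x$scheme$variant, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n", sep = "")
  cat(sprintf("%d experts, %d steps, eta = %.4g\n",
              x$state$n_experts, x$state$t, x$scheme$eta))
  keep <- seq_along(x$y) > x$burn_in
  cat(sprintf("Mean %s error after burn-in: %.4g\n", x$loss$kind,
              mean(loss_eval(x$loss, x$predictions[keep], x$y[keep]))))
  invisible(x)
}

#' @export
summary.tea_fit <- function(object, ...) {
  w <- coef(object)
  rep_ <- regret_report(object)
  keep <- seq_along(object$y) > object$burn_in
  out <- list(call = object$call, variant = object$scheme$variant,
              n_experts = object$state$n_experts, steps = object$state$t,
              eta = object$scheme$eta, lambda = object$scheme$lambda,
              rho = object$scheme$rho,
              mean_loss = mean(loss_eval(object$loss,
                                         object$predictions[keep],
                                         object$y[keep])),
              regret = rep_$regret, bound = rep_$bound,
              bound_satisfied = rep_$satisfied,
              top_weights = sort(w, decreasing = TRUE)[seq_len(min(5, length(w)))])
  class(out) <- "summary.tea_fit"
  out
}

#' @export
print.summary.tea_fit <- function(x, ...) {
  cat("Online expert-advice forecast (", x$variant, ")\n", sep = "")
  cat("Call: ", deparse(x$call), "\n\n", sep = "")
  cat(sprintf("Experts: %d   Steps: %d   eta: %.4g", x$n_experts, x$steps, x$eta))
  if (!is.null(x$lambda)) cat(sprintf("   lambda: %.4g", x$lambda))
  if (!is.null(x$rho)) cat(sprintf("   rho: %.4g", x$rho))
  cat("\n")
  cat(sprintf("Mean loss after burn-in: %.4g\n", x$mean_loss))
  cat(sprintf("Regret: %.4g   optimal upper bound: %.4g   within bound: %s\n",
              x$regret, x$bound, x$bound_satisfied))
  cat("Largest final weights:\n")
  print(round(x$top_weights, 4))
  invisible(x)
}

#' @export
coef.tea_fit <- function(object, ...) {
  w <- state_weights(object$state)
  names(w) <- object$panel$ids
  w
}

#' @export
fitted.tea_fit <- function(object, ...) object$predictions

#' @export
residuals.tea_fit <- function(object, ...) object$y - object$predictions

#' Predict from a fitted expert-advice forecaster
#'
#' @param object a [tea()] fit.
#' @param q horizon in steps beyond the last observed step.
#' @param type `"point"` for the weighted-average point prediction,
#'   `"quantile"` for quantiles of the Gaussian-mixture predictive
#'   distribution, `"mixture"` for the mixture object itself.
#' @param sigma mixture component standard deviation; if `NULL`, estimated
#'   from the final learning point via [estimate_sigma()].
#' @param probs quantile levels for `type = "quantile"`.
#' @param ... unused.
#' @return A number, a named vector of quantiles, or a
#'   `"mixture_prediction"`.
#' @export
predict.tea_fit <- function(object, q = 1L,
                            type = c("point", "quantile", "mixture"),
                            sigma = NULL,
                            probs = c(0.525, 0.55, 0.6, 0.65, 0.75, 0.875, 0.975),
                            ...) {
  type <- match.arg(type)
  if (type == "point") return(point_predict(object$state, object$panel, q))
  if (is.null(sigma)) sigma <- estimate_sigma(object, "final_point")
  mix <- mixture_predict(object, sigma = sigma, q = q)
  if (type == "mixture") return(mix)
  quantile(mix, probs)
}

#' Simulate observations from the predictive distribution
#'
#' Draws from the weighted Gaussian mixture centred on the experts'
#' `q`-steps-ahead advice.
#'
#' @param object a [tea()] fit.
#' @param nsim number of draws.
#' @param seed optional seed, restored after use.
#' @param q horizon in steps.
#' @param sigma mixture standard deviation; `NULL` to estimate.
#' @param ... unused.
#' @return Numeric vector of `nsim` draws.
#' @export
simulate.tea_fit <- function(object, nsim = 1, seed = NULL, q = 1L,
                             sigma = NULL, ...) {
  if (is.null(sigma)) sigma <- estimate_sigma(object, "final_point")
  mix <- mixture_predict(object, sigma = sigma, q = q)
  with_seed(seed, mixture_draw(mix, nsim))
}

#' Plot a fitted expert-advice forecaster
#'
#' Observations and one-step-ahead predictions over the fitted steps.
#'
#' @param x a [tea()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.tea_fit <- function(x, ...) {
  tt <- x$times
  graphics::plot(tt, x$y, type = "b", lty = 3, pch = 1,
                 xlab = "time", ylab = "value", ...)
  graphics::lines(tt, x$predictions, col = 2, lwd = 1.5)
  graphics::points(tt, x$predictions, col = 2, pch = 3)
  if (x$burn_in > 0) graphics::abline(v = tt[x$burn_in] + 0.5, col = "grey", lty = 2)
  graphics::legend("topleft", bty = "n",
                   legend = c("observed", "predicted"),
                   col = c(1, 2), pch = c(1, 3), lty = c(3, 1))
  invisible(x)
}
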