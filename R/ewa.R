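#' Loss coefficient of a weighting scheme
#'
#' The coefficient \eqn{a_k(t)} multiplying the step-\eqn{k} loss inside the
#' accumulated losses at time \eqn{t}: \eqn{\lambda^{k-1}} or \eqn{\lambda^k}
#' for temporal expert advice, 1 for the standard forecaster, and
#' \eqn{\rho^{t-k-1}} for the Chernov--Zhdanov discount.
#'
#' @param scheme a [weight_scheme()].
#' @param k loss step, `1 <= k <= t`.
#' @param t current time step.
#' @return The coefficient as a single number.
#' @examples
#' loss_coefficient(weight_scheme("tea", lambda = 2), k = 3, t = 5)  # 4
#' @export
loss_coefficient <- function(scheme, k, t) {
  stopifnot(inherits(scheme, "weight_scheme"))
  k <- as.integer(k); t <- as.integer(t)
  if (k < 1L || k > t) stop("'k' must satisfy 1 <= k <= t")
  switch(scheme$variant,
         standard = 1,
         tea = if (scheme$tea_exponent == "k") scheme$lambda^k
               else scheme$lambda^(k - 1L),
         cz = scheme$rho^(t - k - 1L))
}

#' Initial forecast state
#'
#' Starts the online forecaster at \eqn{t = 0} with all accumulated losses
#' zero (\eqn{L_0 = L_{i,0} = 0}) and uniform weights \eqn{1/N}.
#'
#' @param panel an [expert_panel()].
#' @return An object of class `"forecast_state"` with elements `t`,
#'   `expert_losses`, `predictor_loss` and `log_weights` (normalised, so the
#'   weights are `exp(log_weights)`).
#' @export
init_state <- function(panel) {
  stopifnot(inherits(panel, "expert_panel"))
  N <- n_experts(panel)
  structure(list(t = 0L,
                 expert_losses = numeric(N),
                 predictor_loss = 0,
                 log_weights = rep(-log(N), N),
                 n_experts = N),
            class = "forecast_state")
}

#' @export
print.forecast_state <- function(x, ...) {
  cat("<forecast_state> t = ", x$t, ", ", x$n_experts, " experts, regret = ",
      format(x$predictor_loss - min(x$expert_losses)), "\n", sep = "")
  invisible(x)
}

#' Weights of a forecast state
#'
#' @param state a `"forecast_state"`.
#' @return Normalised nonnegative weights summing to one.
#' @export
state_weights <- function(state) {
  stopifnot(inherits(state, "forecast_state"))
  exp(state$log_weights)
}

#' One online update of the forecaster
#'
#' Reveals the observation for step `state$t + 1`, accumulates each expert's
#' (and the forecaster's own) loss with the scheme's coefficient, and
#' recomputes the weights as \eqn{w_{i,t} \propto \exp(-\eta L_{i,t})}.
#' Weights are computed in the log domain after subtracting the minimum
#' accumulated loss, so only loss differences enter the exponentials.
#'
#' For the temporal scheme the increment at step \eqn{t} is
#' \eqn{\lambda^{t-1} l} (or \eqn{\lambda^t l}); for the discounted scheme
#' the whole accumulation is refreshed through the recursion
#' \eqn{L \leftarrow \rho L + \rho^{-1} l_t}, algebraically equal to
#' \eqn{\sum_k \rho^{t-k-1} l_k}. Experts whose horizon has passed (advice
#' `NA`) keep their accumulated loss frozen.
#'
#' @param state a `"forecast_state"` at time \eqn{t-1}.
#' @param advice_col advice of all experts for step \eqn{t} (`NA` beyond an
#'   expert's horizon).
#' @param y the revealed observation \eqn{y_t}.
#' @param loss a [loss_spec()].
#' @param scheme a [weight_scheme()] with a numeric `eta`.
#' @param prediction the forecaster's own output for step \eqn{t}, made
#'   before seeing `y`.
#' @param warn_epsilon warn when a loss exceeds `loss$epsilon`.
#' @return The updated `"forecast_state"` at time \eqn{t}.
#' @export
update_state <- function(state, advice_col, y, loss, scheme, prediction,
                         warn_epsilon = TRUE) {
  stopifnot(inherits(state, "forecast_state"),
            inherits(loss, "loss_spec"),
            inherits(scheme, "weight_scheme"))
  if (is.character(scheme$eta))
    stop("update_state() needs a numeric 'eta'; resolve \"auto\" first ",
         "(see run_online() or optimal_eta())")
  t <- state$t + 1L
  N <- state$n_experts
  if (length(advice_col) != N) stop("'advice_col' must have one entry per expert")
  if (!is.finite(y)) stop("non-finite observation at step ", t)
  active <- !is.na(advice_col)
  if (!all(is.finite(advice_col[active])))
    stop("non-finite advice at step ", t)
  if (!is.finite(prediction)) stop("non-finite prediction at step ", t)

  l_exp <- rep(0, N)
  l_exp[active] <- loss_eval(loss, advice_col[active], y)
  l_pred <- loss_eval(loss, prediction, y)
  if (warn_epsilon && any(c(l_exp[active], l_pred) > loss$epsilon))
    warning("loss exceeded epsilon = ", loss$epsilon, " at step ", t,
            "; regret bounds assume losses within [0, epsilon]")

  L <- state$expert_losses
  if (scheme$variant == "cz") {
    rho <- scheme$rho
    L[active] <- rho * L[active] + l_exp[active] / rho
    Lp <- rho * state$predictor_loss + l_pred / rho
  } else {
    a <- loss_coefficient(scheme, t, t)
    if (!is.finite(a))
      stop("coefficient lambda^", t - 1L, " overflowed at step ", t,
           "; shorten the horizon or reduce lambda")
    L[active] <- L[active] + a * l_exp[active]
    Lp <- state$predictor_loss + a * l_pred
  }
  if (!all(is.finite(L)) || !is.finite(Lp))
    stop("accumulated loss overflowed at step ", t,
         "; shorten the horizon or reduce lambda")

  d <- L - min(L)
  lw <- -scheme$eta * d
  lw[d == 0] <- 0  # keeps eta = Inf (single expert / degenerate) well defined
  lw <- lw - logsumexp(lw)
  structure(list(t = t, expert_losses = L, predictor_loss = Lp,
                 log_weights = lw, n_experts = N),
            class = "forecast_state")
}

#' Point prediction by weighted averaging of expert advice
#'
#' Returns \eqn{\sum_i w_{i,t} f_{i,t+q}} for the `q`-steps-ahead advice.
#' Experts whose horizon ends before \eqn{t+q} are excluded and the weights
#' renormalised over the survivors, preserving the convex-combination
#' contract; it is an error if no expert survives.
#'
#' @param state a `"forecast_state"` at time \eqn{t}.
#' @param panel the [expert_panel()] the state was trained on.
#' @param q prediction horizon in steps (default 1).
#' @return The point prediction as a single number.
#' @export
point_predict <- function(state, panel, q = 1L) {
  stopifnot(inherits(state, "forecast_state"), inherits(panel, "expert_panel"))
  q <- as.integer(q)
  if (q < 1L) stop("'q' must be a positive integer")
  col <- state$t + q
  if (col > ncol(panel$advice))
    stop("panel has no advice at step ", col)
  alive <- panel$horizon >= col & !is.na(panel$advice[, col])
  if (!any(alive)) stop("no expert has advice at step ", col)
  lw <- state$log_weights[alive]
  w <- exp(lw - logsumexp(lw))
  sum(w * panel$advice[alive, col])
}

#' Run the forecaster online over a target series
#'
#' Repeats the weight-update and prediction steps iteratively: at each step a
#' one-step-ahead prediction is emitted before the observation is revealed,
#' then the weights are updated from the revealed loss. The first `burn_in`
#' steps still update the weights (the learning part) but are conventionally
#' excluded from downstream evaluation.
#'
#' @param panel an [expert_panel()].
#' @param target the observed series: a [timeseries()] or numeric vector.
#' @param scheme a [weight_scheme()]; `eta = "auto"` is resolved to the
#'   bound-optimal rate for the run length.
#' @param loss a [loss_spec()].
#' @param burn_in number of initial steps excluded from evaluation.
#' @param steps number of online steps; defaults to the shorter of the target
#'   and the panel.
#' @param trace_weights keep the full T x N weight trace (needed for
#'   per-step distribution predictions).
#' @param warn_epsilon warn (once) if any loss exceeded `loss$epsilon`.
#' @return An object of class `"ewa_run"`: list with `predictions` (one-step
#'   predictions aligned with the observations), `y`, final `state`, the
#'   weight trace `weights` (row t = weights after the step-t update),
#'   per-step predictor losses `pred_losses`, the resolved `scheme`, `loss`
#'   and `burn_in`.
#' @export
run_online <- function(panel, target, scheme, loss = loss_spec(),
                       burn_in = 0L, steps = NULL, trace_weights = TRUE,
                       warn_epsilon = TRUE) {
  stopifnot(inherits(panel, "expert_panel"), inherits(scheme, "weight_scheme"))
  y <- ts_values(target)
  T_run <- if (is.null(steps)) min(length(y), ncol(panel$advice))
           else min(as.integer(steps), length(y), ncol(panel$advice))
  burn_in <- as.integer(burn_in)
  if (length(y) < burn_in + 1L)
    stop("target shorter than burn_in + 1")
  if (T_run < 1L) stop("nothing to predict")
  schedule <- identical(scheme$eta, "auto_t")
  scheme <- resolve_eta(scheme, N = n_experts(panel), t = T_run,
                        epsilon = loss$epsilon)
  state <- init_state(panel)
  N <- n_experts(panel)
  preds <- rep(NA_real_, T_run)
  pred_losses <- numeric(T_run)
  W <- if (trace_weights) matrix(NA_real_, T_run, N) else NULL
  step_scheme <- scheme
  for (t in seq_len(T_run)) {
    preds[t] <- point_predict(state, panel, q = 1L)
    if (schedule)
      step_scheme$eta <- optimal_eta(N, t, loss$epsilon, scheme$variant,
                                     lambda = scheme$lambda,
                                     rho = scheme$rho,
                                     tea_exponent = scheme$tea_exponent)
    state <- update_state(state, panel$advice[, t], y[t], loss, step_scheme,
                          preds[t], warn_epsilon = FALSE)
    pred_losses[t] <- loss_eval(loss, preds[t], y[t])
    if (trace_weights) W[t, ] <- state_weights(state)
  }
  if (schedule) {
    scheme$eta <- step_scheme$eta
    scheme$eta_schedule <- "auto_t"
  }
  if (warn_epsilon && any(pred_losses > loss$epsilon))
    warning("some losses exceeded epsilon = ", loss$epsilon,
            "; regret bounds assume losses within [0, epsilon]")
  structure(list(predictions = preds, y = y[seq_len(T_run)], state = state,
                 weights = W, pred_losses = pred_losses, scheme = scheme,
                 loss = loss, burn_in = burn_in),
            class = "ewa_run")
}

# Resolve eta = "auto"/"auto_t" to the bound-optimal learning rate (for
# "auto_t" this seeds the schedule; run_online re-resolves per step).
resolve_eta <- function(scheme, N, t, epsilon) {
  if (!is.character(scheme$eta)) return(scheme)
  scheme$eta <- optimal_eta(N = N, t = t, epsilon = epsilon,
                            variant = scheme$variant,
                            lambda = scheme$lambda, rho = scheme$rho,
                            tea_exponent = scheme$tea_exponent)
  scheme
}
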