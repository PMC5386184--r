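#' Ordered scalar time series
#'
#' Container for an observed scalar series \eqn{y_k} at strictly increasing
#' measurement times \eqn{t_k}. Times may be integer step indices (the default)
#' or arbitrary real sampling times such as irregular clinical visit dates.
#'
#' @param values numeric vector of finite observations.
#' @param times numeric vector of strictly increasing timestamps; defaults to
#'   the 1-based step index.
#' @return An object of class `"timeseries"`: a list with elements `times`
#'   and `values`.
#' @examples
#' ts <- timeseries(c(3.1, 2.9, 3.4))
#' length(ts$values)
#' @export
timeseries <- function(values, times = seq_along(values)) {
  values <- as.numeric(values)
  times <- as.numeric(times)
  if (length(times) != length(values))
    stop("'times' and 'values' must have equal length")
  if (length(values) == 0L) stop("empty time series")
  if (!all(is.finite(values))) stop("all values must be finite")
  if (!all(is.finite(times))) stop("all times must be finite")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("'times' must be strictly increasing")
  structure(list(times = times, values = values), class = "timeseries")
}

#' @export
print.timeseries <- function(x, ...) {
  cat("<timeseries> ", length(x$values), " observations, t in [",
      x$times[1L], ", ", x$times[length(x$times)], "]\n", sep = "")
  invisible(x)
}

#' @rdname timeseries
#' @param x object to coerce: a `timeseries`, a numeric vector, or a
#'   data frame with columns `time` and `value`.
#' @export
as_timeseries <- function(x) {
  if (inherits(x, "timeseries")) return(x)
  if (is.data.frame(x)) {
    if (!all(c("time", "value") %in% names(x)))
      stop("data frame must have columns 'time' and 'value'")
    return(timeseries(x$value, x$time))
  }
  timeseries(as.numeric(x))
}

ts_values <- function(x) {
  if (inherits(x, "timeseries")) x$values else as.numeric(x)
}

#' Panel of expert advice
#'
#' An expert panel holds the advice \eqn{f_{i,t}} of \eqn{N} experts over
#' \eqn{T} time steps. Experts built from finite windows stop advising early;
#' their per-expert horizon records the last valid step, and advice beyond the
#' horizon is `NA`.
#'
#' @param advice numeric matrix, one row per expert, one column per time step.
#' @param horizon integer vector of last valid step per expert; defaults to
#'   the last non-`NA` column of each row.
#' @param ids optional character vector of expert identifiers.
#' @return An object of class `"expert_panel"`.
#' @examples
#' p <- expert_panel(rbind(a = c(1, 2, 3), b = c(0, 0, 0)))
#' n_experts(p)
#' @export
expert_panel <- function(advice, horizon = NULL, ids = NULL) {
  advice <- as.matrix(advice)
  storage.mode(advice) <- "double"
  N <- nrow(advice)
  if (N < 1L) stop("panel must contain at least one expert")
  if (is.null(horizon)) {
    horizon <- apply(advice, 1L, function(r) {
      ok <- which(!is.na(r))
      if (length(ok) == 0L) 0L else max(ok)
    })
  }
  horizon <- as.integer(horizon)
  if (length(horizon) != N) stop("'horizon' must have one entry per expert")
  if (any(horizon < 1L)) stop("every expert needs at least one valid step")
  for (i in seq_len(N)) {
    seg <- advice[i, seq_len(horizon[i])]
    if (!all(is.finite(seg)))
      stop("non-finite advice within horizon for expert ", i)
  }
  if (is.null(ids)) ids <- rownames(advice)
  if (is.null(ids)) ids <- paste0("expert", seq_len(N))
  rownames(advice) <- ids
  structure(list(advice = advice, horizon = horizon, ids = ids),
            class = "expert_panel")
}

#' @rdname expert_panel
#' @param panel an `expert_panel`.
#' @export
n_experts <- function(panel) nrow(panel$advice)

#' @export
print.expert_panel <- function(x, ...) {
  cat("<expert_panel> ", n_experts(x), " experts x ", ncol(x$advice),
      " steps (horizons ", min(x$horizon), "..", max(x$horizon), ")\n",
      sep = "")
  invisible(x)
}

#' Loss specification
#'
#' The convex per-step loss \eqn{l(x, y)} and the bound \eqn{\epsilon} on its
#' magnitude assumed by the regret machinery. \eqn{\epsilon} is a configured
#' value (default 1), not estimated from data; losses exceeding it trigger a
#' warning, not an error, since e.g. PSA errors are unbounded in principle.
#'
#' @param kind `"absolute"` (\eqn{|x-y|}) or `"squared"` (\eqn{(x-y)^2}).
#' @param epsilon positive bound on the loss used by the regret bounds.
#' @return An object of class `"loss_spec"`.
#' @export
loss_spec <- function(kind = c("absolute", "squared"), epsilon = 1) {
  kind <- match.arg(kind)
  stop_if_not_scalar(epsilon, "epsilon")
  if (epsilon <= 0) stop("'epsilon' must be positive")
  structure(list(kind = kind, epsilon = epsilon), class = "loss_spec")
}

#' @rdname loss_spec
#' @param loss a `loss_spec`.
#' @param x,y prediction(s) and outcome; vectorised.
#' @export
loss_eval <- function(loss, x, y) {
  switch(loss$kind,
         absolute = abs(x - y),
         squared  = (x - y)^2)
}

#' Weighting scheme for prediction with expert advice
#'
#' Selects the forecaster variant and its decay/learning parameters:
#' * `"standard"`: the exponentially weighted average forecaster, coefficient
#'   \eqn{a_k(t) = 1}.
#' * `"tea"`: temporal expert advice, coefficient \eqn{a_k(t) = \lambda^{k-1}}
#'   or \eqn{\lambda^k} with \eqn{\lambda > 1}, so recent losses dominate.
#'   \eqn{\lambda = 1} is allowed and reduces exactly to the standard scheme.
#' * `"cz"`: the Chernov--Zhdanov discounted forecaster, coefficient
#'   \eqn{a_k(t) = \rho^{t-k-1}} with \eqn{0 < \rho < 1}.
#'
#' @param variant one of `"standard"`, `"tea"`, `"cz"`.
#' @param lambda decay rate \eqn{\lambda \ge 1} (tea only).
#' @param tea_exponent `"k_minus_1"` for \eqn{a_k = \lambda^{k-1}} (used in
#'   the regret bound chain and the chaotic-map experiments) or `"k"` for
#'   \eqn{a_k = \lambda^k} (used when the learning series is very short, as
#'   in the PSA application).
#' @param rho discount rate in (0, 1) (cz only).
#' @param eta positive learning rate; `"auto"` for the bound-optimal constant
#'   rate [optimal_eta()] resolved at run time from (N, T, epsilon); or
#'   `"auto_t"` for the bound-optimal schedule re-evaluated at every step t
#'   (useful when the forecaster must discriminate from the first steps).
#' @return An object of class `"weight_scheme"`.
#' @examples
#' weight_scheme("tea", lambda = 1/0.9)
#' @export
weight_scheme <- function(variant = c("standard", "tea", "cz"),
                          lambda = NULL,
                          tea_exponent = c("k_minus_1", "k"),
                          rho = NULL, eta = "auto") {
  variant <- match.arg(variant)
  tea_exponent <- match.arg(tea_exponent)
  if (variant == "tea") {
    if (is.null(lambda)) stop("tea scheme requires 'lambda'")
    stop_if_not_scalar(lambda, "lambda")
    if (lambda < 1) stop("'lambda' must be >= 1")
  }
  if (variant == "cz") {
    if (is.null(rho)) stop("cz scheme requires 'rho'")
    stop_if_not_scalar(rho, "rho")
    if (rho <= 0 || rho >= 1) stop("'rho' must lie in (0, 1)")
  }
  if (!identical(eta, "auto") && !identical(eta, "auto_t")) {
    stop_if_not_scalar(eta, "eta")
    if (eta < 0) stop("'eta' must be nonnegative")
  }
  structure(list(variant = variant, lambda = lambda,
                 tea_exponent = tea_exponent, rho = rho, eta = eta),
            class = "weight_scheme")
}

#' @export
print.weight_scheme <- function(x, ...) {
  extra <- switch(x$variant,
                  standard = "",
                  tea = paste0(", lambda = ", format(x$lambda),
                               " (a_k = lambda^",
                               if (x$tea_exponent == "k") "k" else "(k-1)", ")"),
                  cz = paste0(", rho = ", format(x$rho)))
  cat("<weight_scheme> ", x$variant, extra, ", eta = ",
      if (identical(x$eta, "auto")) "auto" else format(x$eta), "\n", sep = "")
  invisible(x)
}
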