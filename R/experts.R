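#' Database of reference time series
#'
#' @param series list of numeric vectors (or a matrix, one series per row):
#'   past recordings from which windowed experts are cut.
#' @param ids optional identifiers.
#' @return An object of class `"series_database"`.
#' @export
series_database <- function(series, ids = NULL) {
  if (is.matrix(series)) series <- lapply(seq_len(nrow(series)), function(i) series[i, ])
  if (!is.list(series) || length(series) == 0L)
    stop("'series' must be a nonempty list of numeric vectors")
  series <- lapply(series, as.numeric)
  if (!all(vapply(series, function(s) all(is.finite(s)), logical(1))))
    stop("all series values must be finite")
  if (is.null(ids)) ids <- paste0("s", seq_along(series))
  structure(list(series = series, ids = ids), class = "series_database")
}

#' @export
print.series_database <- function(x, ...) {
  cat("<series_database> ", length(x$series), " series, lengths ",
      min(lengths(x$series)), "..", max(lengths(x$series)), "\n", sep = "")
  invisible(x)
}

#' Sliding-window experts from a series database
#'
#' Every length-`P` contiguous window of every database series becomes one
#' expert: for the `j`th series the `i`th window supplies advice
#' \eqn{f_{(L-P+1)(j-1)+i,\,k} = x_{j,\,i+k-1}} for \eqn{k = 1..P}. Each
#' expert's horizon is `P`.
#'
#' @param db a [series_database()].
#' @param P window length, `1 <= P <= length of each series`.
#' @return An [expert_panel()] with \eqn{\sum_j (L_j - P + 1)} experts.
#' @examples
#' db <- series_database(list(c(10, 20, 30, 40, 50)))
#' windowed_experts(db, P = 3)$advice
#' @export
windowed_experts <- function(db, P) {
  stopifnot(inherits(db, "series_database"))
  P <- as.integer(P)
  if (P < 1L) stop("'P' must be >= 1")
  if (any(lengths(db$series) < P))
    stop("'P' exceeds the length of at least one series")
  rows <- list(); ids <- character(0)
  for (j in seq_along(db$series)) {
    x <- db$series[[j]]
    L <- length(x)
    for (i in seq_len(L - P + 1L)) {
      rows[[length(rows) + 1L]] <- x[seq(i, i + P - 1L)]
      ids <- c(ids, paste0(db$ids[j], ".w", i))
    }
  }
  expert_panel(do.call(rbind, rows), horizon = rep(P, length(rows)), ids = ids)
}

# Penalty keeping fitted states in the physical (nonnegative) region:
# h(x) = 1e15 * (1 - x) for x < 0, 0 otherwise; summed over entries.
state_penalty <- function(x) {
  neg <- x < 0
  if (!any(neg)) return(0)
  sum(1e15 * (1 - x[neg]))
}

#' Fit initial model states to a short PSA series
#'
#' Given one patient's rate parameters, finds the initial cell-state
#' `(x1, x2, x3)` whose simulated PSA best matches the first `K`
#' observations, by minimising the summed absolute discrepancy plus the
#' penalty \eqn{h(x) = 10^{15}(1 - x)} for each negative state entry
#' (evaluated at every observation time and at the initial state). At least
#' three points are required because the model has three state dimensions.
#'
#' Optimisation is derivative-free simplex search from `n_starts` starting
#' points drawn uniformly from `[0, y_1]^3` (the first observation bounds the
#' plausible state mass); the huge penalty makes nonnegativity effectively a
#' hard constraint. The propagators \eqn{e^{A t_k}} are precomputed once, so
#' each cost evaluation is a single small matrix product.
#'
#' @param params an [ias_params()].
#' @param times observation times (days); only the first `K` are used.
#' @param values observed PSA; only the first `K` are used.
#' @param K number of learning points (>= 3).
#' @param phase `"off"` (default; follow-up after initial treatment) or
#'   `"on"`.
#' @param n_starts number of multi-start draws.
#' @param seed optional seed for the starts, restored afterwards.
#' @return A list with `initial_state`, `cost` (penalty-free at the
#'   solution), and `fitted_psa` at the learning times.
#' @export
fit_initial_state <- function(params, times, values, K = length(values),
                              phase = "off", n_starts = 20L, seed = NULL) {
  stopifnot(inherits(params, "ias_params"))
  K <- as.integer(K)
  if (K < 3L) stop("'K' must be at least 3 (model has three state dimensions)")
  if (length(times) < K || length(values) < K)
    stop("need at least K observation points")
  tt <- times[seq_len(K)] - times[1L]
  y <- values[seq_len(K)]
  A <- ias_matrix(params, phase)
  props <- lapply(tt, function(d) expm3(A * d))
  Mstack <- do.call(rbind, props)             # (3K x 3) propagator stack
  psa_row <- rep(seq_len(K), each = 3L)

  cost_fn <- function(s) {
    states <- Mstack %*% s                    # all states, all times
    if (!all(is.finite(states))) return(1e300)
    psa <- rowsum(as.numeric(states), psa_row)
    sum(abs(y - psa)) + state_penalty(states) + state_penalty(s)
  }

  # PSA at the learning times is linear in the initial state, so the
  # least-squares solution (clipped to the feasible orthant) is a cheap,
  # deterministic warm start: exact whenever a perfect fit exists
  P <- t(vapply(props, colSums, numeric(3)))
  ls_start <- tryCatch(pmax(qr.solve(P, y), 0),
                       error = function(e) rep(y[1L] / 3, 3))
  starts <- with_seed(seed, {
    rand <- matrix(stats::runif(3L * n_starts, 0, max(y[1L], 1e-6)),
                   ncol = 3L)
    rbind(ls_start, rep(y[1L] / 3, 3), rand)[seq_len(n_starts), , drop = FALSE]
  })
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    opt <- stats::optim(starts[i, ], cost_fn, method = "Nelder-Mead",
                        control = list(maxit = 2000L, reltol = 1e-12))
    # the simplex stalls easily on the kinks of the absolute-error cost;
    # restart it from its own solution until it stops improving
    for (restart in 1:6) {
      re <- stats::optim(opt$par, cost_fn, method = "Nelder-Mead",
                         control = list(maxit = 2000L, reltol = 1e-12))
      if (re$value >= opt$value - 1e-12) { opt <- re; break }
      opt <- re
    }
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (best$value >= 1e14)
    stop("no feasible nonnegative initial state found (all starts penalised)")
  s <- pmax(best$par, 0)  # clip sub-tolerance negatives from the simplex
  states <- Mstack %*% s
  psa <- rowsum(as.numeric(states), psa_row)
  list(initial_state = s, cost = sum(abs(y - psa)),
       fitted_psa = as.numeric(psa))
}

#' Build model-based experts from a parameter table
#'
#' One expert per parameter set: the initial state is fitted to the target's
#' first `K` observations with [fit_initial_state()], the model is then run
#' forward from that state, and the simulated PSA at the requested horizon
#' times is the expert's advice. Parameter sets whose fit fails are skipped
#' with a warning, shrinking the panel rather than aborting.
#'
#' @param param_table data frame with columns `id, d1..d6, e1..e4`, one row
#'   per previous patient.
#' @param times,values the target patient's observation times and PSA values.
#' @param K number of learning points used for the fits (>= 3).
#' @param horizon_times times (same clock as `times`) at which experts
#'   advise; defaults to all target times.
#' @param phase treatment phase, `"off"` by default.
#' @param n_starts,seed passed to [fit_initial_state()].
#' @return An [expert_panel()] with attribute `"fits"`: a data frame of ids,
#'   fitted initial states and costs.
#' @export
model_experts <- function(param_table, times, values, K,
                          horizon_times = times, phase = "off",
                          n_starts = 20L, seed = NULL) {
  check_param_table(param_table)
  if (nrow(param_table) == 0L) stop("empty parameter table")
  advice <- list(); ids <- character(0); fits <- list()
  for (r in seq_len(nrow(param_table))) {
    pr <- param_table[r, ]
    params <- ias_params(d = as.numeric(pr[paste0("d", 1:6)]),
                         e = as.numeric(pr[paste0("e", 1:4)]))
    fit <- tryCatch(
      fit_initial_state(params, times, values, K, phase = phase,
                        n_starts = n_starts,
                        seed = if (is.null(seed)) NULL else seed + r),
      error = function(e) e)
    if (inherits(fit, "error")) {
      warning("skipping parameter set '", pr$id, "': ",
              conditionMessage(fit))
      next
    }
    sim <- tryCatch(
      ias_simulate(params, fit$initial_state, phase,
                   eval_times = horizon_times - times[1L]),
      error = function(e) e)
    if (inherits(sim, "error")) {
      warning("skipping parameter set '", pr$id, "': ",
              conditionMessage(sim))
      next
    }
    advice[[length(advice) + 1L]] <- sim$psa
    ids <- c(ids, as.character(pr$id))
    fits[[length(fits) + 1L]] <-
      data.frame(id = as.character(pr$id), cost = fit$cost,
                 x1 = fit$initial_state[1L], x2 = fit$initial_state[2L],
                 x3 = fit$initial_state[3L])
  }
  if (length(advice) == 0L) stop("every parameter set failed to fit")
  panel <- expert_panel(do.call(rbind, advice),
                        horizon = rep(length(horizon_times), length(advice)),
                        ids = ids)
  attr(panel, "fits") <- do.call(rbind, fits)
  panel
}

check_param_table <- function(tab) {
  need <- c("id", paste0("d", 1:6), paste0("e", 1:4))
  if (!is.data.frame(tab) || !all(need %in% names(tab)))
    stop("parameter table needs columns ", paste(need, collapse = ", "))
  invisible(tab)
}
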