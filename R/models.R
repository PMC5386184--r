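# Dynamical systems used as targets and expert generators: two chaotic maps
# observed through x + y, and a piecewise-linear three-compartment model of
# prostate cancer cell populations observed through PSA = x1 + x2 + x3.

henon_step <- function(x, y, a, b) {
  list(x = 1 - a * x^2 + y, y = b * x)
}

ikeda_step <- function(x, y, u) {
  tau <- 0.4 - 6 / (1 + x^2 + y^2)
  list(x = 1 + u * (x * cos(tau) - y * sin(tau)),
       y = u * (x * sin(tau) + y * cos(tau)))
}

# Iterate a 2-d map, vectorised over orbits; returns n x m matrix of x + y
# after discarding `transient` steps. Non-finite or exploding orbits yield
# NA columns (the caller decides whether to redraw).
map_orbit <- function(step, x, y, pars, n, transient, blowup = 1e6) {
  m <- length(x)
  out <- matrix(NA_real_, n, m)
  for (i in seq_len(transient + n)) {
    s <- do.call(step, c(list(x = x, y = y), pars))
    x <- s$x; y <- s$y
    bad <- !is.finite(x) | !is.finite(y) | abs(x) > blowup | abs(y) > blowup
    x[bad] <- NA_real_; y[bad] <- NA_real_
    if (i > transient) out[i - transient, ] <- x + y
  }
  out
}

#' Henon map series
#'
#' Iterates the Henon map \eqn{x' = 1 - a x^2 + y}, \eqn{y' = b x} and
#' records the observable \eqn{x + y} after discarding a transient. The
#' parameter set \eqn{a = 1.35, b = 0.15} produces deterministic chaos.
#'
#' @param a,b map parameters.
#' @param x0,y0 initial condition.
#' @param n number of recorded steps.
#' @param transient discarded leading steps (default 1000).
#' @return A [timeseries()] of \eqn{x + y} at steps `1..n`.
#' @examples
#' henon_series(n = 5, transient = 0, x0 = 1, y0 = 0)
#' @export
henon_series <- function(a = 1.35, b = 0.15, x0 = 0, y0 = 0, n,
                         transient = 1000L) {
  obs <- map_orbit(henon_step, x0, y0, list(a = a, b = b), n, transient)[, 1L]
  if (anyNA(obs)) stop("Henon orbit diverged to non-finite values")
  timeseries(obs)
}

#' Ikeda map series
#'
#' Iterates the Ikeda map \eqn{x' = 1 + u (x \cos\tau - y \sin\tau)},
#' \eqn{y' = u (x \sin\tau + y \cos\tau)} with phase
#' \eqn{\tau = 0.4 - 6 / (1 + x^2 + y^2)}, recording \eqn{x + y}.
#'
#' @param u map parameter (chaotic around 0.9; orbit bounded for u < 1).
#' @inheritParams henon_series
#' @return A [timeseries()] of \eqn{x + y}.
#' @export
ikeda_series <- function(u = 0.9, x0 = 0, y0 = 0, n, transient = 1000L) {
  obs <- map_orbit(ikeda_step, x0, y0, list(u = u), n, transient)[, 1L]
  if (anyNA(obs)) stop("Ikeda orbit diverged to non-finite values")
  timeseries(obs)
}

#' Parameters of the intermittent androgen suppression model
#'
#' The piecewise-linear three-compartment model of prostate cancer cell
#' dynamics: androgen-dependent cells \eqn{x_1}, reversibly
#' androgen-independent cells \eqn{x_2}, and irreversibly independent cells
#' \eqn{x_3}; a PSA measurement is \eqn{x_1 + x_2 + x_3}. During hormone
#' therapy (on-treatment) \eqn{x_1} may convert to \eqn{x_2} or \eqn{x_3}
#' (six rate coefficients `d1..d6`); off treatment \eqn{x_2} may revert to
#' \eqn{x_1} while \eqn{x_3} cannot revert (four coefficients `e1..e4`):
#' \deqn{on:\ \dot x_1 = d_1 x_1,\ \dot x_2 = d_2 x_1 + d_3 x_2,\
#'       \dot x_3 = d_4 x_1 + d_5 x_2 + d_6 x_3}
#' \deqn{off:\ \dot x_1 = e_1 x_1 + e_2 x_2,\ \dot x_2 = e_3 x_2,\
#'       \dot x_3 = e_4 x_3}
#'
#' @param d numeric length 6, on-treatment rates (per day).
#' @param e numeric length 4, off-treatment rates (per day).
#' @return An object of class `"ias_params"`.
#' @export
ias_params <- function(d = numeric(6), e = numeric(4)) {
  d <- as.numeric(d); e <- as.numeric(e)
  if (length(d) != 6L || length(e) != 4L)
    stop("need 6 on-treatment and 4 off-treatment rates")
  if (!all(is.finite(c(d, e)))) stop("rates must be finite")
  structure(list(d = d, e = e), class = "ias_params")
}

ias_matrix <- function(params, phase = c("off", "on")) {
  phase <- match.arg(phase)
  if (phase == "on") {
    d <- params$d
    rbind(c(d[1], 0,    0),
          c(d[2], d[3], 0),
          c(d[4], d[5], d[6]))
  } else {
    e <- params$e
    rbind(c(e[1], e[2], 0),
          c(0,    e[3], 0),
          c(0,    0,    e[4]))
  }
}

#' Simulate the intermittent androgen suppression model
#'
#' Integrates the piecewise-linear system over a treatment schedule by matrix
#' exponential per linear piece (exact for linear dynamics). Time is
#' continuous, in days; evaluation times are arbitrary reals within the
#' schedule span.
#'
#' @param params an [ias_params()].
#' @param initial nonnegative initial state `(x1, x2, x3)` at time 0.
#' @param schedule either a single phase string (`"off"` or `"on"`, one
#'   segment spanning all `eval_times`) or a data frame with columns
#'   `duration` (days) and `phase`.
#' @param eval_times times at which states are returned.
#' @return A list with `times`, `states` (length x 3 matrix) and
#'   `psa = x1 + x2 + x3`.
#' @examples
#' p <- ias_params(e = c(-0.05, 0.02, 0.01, 0.03))
#' ias_simulate(p, c(2, 1, 0.5), "off", eval_times = c(0, 10, 20))$psa
#' @export
ias_simulate <- function(params, initial, schedule = "off", eval_times) {
  stopifnot(inherits(params, "ias_params"))
  initial <- as.numeric(initial)
  if (length(initial) != 3L || !all(is.finite(initial)))
    stop("'initial' must be 3 finite state values")
  if (any(initial < 0)) stop("'initial' must be nonnegative")
  if (is.character(schedule))
    schedule <- data.frame(duration = max(eval_times, 0) + 1e-9,
                           phase = schedule)
  if (!all(c("duration", "phase") %in% names(schedule)))
    stop("'schedule' needs columns 'duration' and 'phase'")
  bounds <- c(0, cumsum(schedule$duration))
  if (any(eval_times < 0) || any(eval_times > bounds[length(bounds)] + 1e-9))
    stop("'eval_times' must lie within the schedule span")

  # state at the start of each segment
  seg_state <- vector("list", nrow(schedule) + 1L)
  seg_state[[1L]] <- initial
  mats <- lapply(seq_len(nrow(schedule)),
                 function(j) ias_matrix(params, schedule$phase[j]))
  for (j in seq_len(nrow(schedule)))
    seg_state[[j + 1L]] <- drop(expm3(mats[[j]] * schedule$duration[j]) %*%
                                  seg_state[[j]])
  states <- t(vapply(eval_times, function(tt) {
    j <- max(1L, findInterval(tt, bounds, rightmost.closed = TRUE))
    j <- min(j, nrow(schedule))
    drop(expm3(mats[[j]] * (tt - bounds[j])) %*% seg_state[[j]])
  }, numeric(3)))
  if (!all(is.finite(states)))
    stop("state overflowed to non-finite values; check the rates")
  colnames(states) <- c("x1", "x2", "x3")
  list(times = eval_times, states = states, psa = rowSums(states))
}
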