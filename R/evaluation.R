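# Baseline predictors, the pairwise win-count tournament used in the
# real-data protocol, exact binomial significance thresholds, and
# loss-accumulation curves.

#' Persistence baseline
#'
#' Forecasts the next value as the current value.
#'
#' @param target a [timeseries()] or numeric vector with >= 2 points.
#' @return Predictions aligned with the observations (`NA` at step 1, for
#'   which no prediction exists).
#' @export
persistence_predict <- function(target) {
  y <- ts_values(target)
  if (length(y) < 2L) stop("need at least 2 observations")
  c(NA_real_, y[-length(y)])
}

#' Running-mean baseline
#'
#' The "average prediction": forecasts the next value as the mean of all
#' observations so far (a running mean — the minimal stateless reading of an
#' average baseline).
#'
#' @inheritParams persistence_predict
#' @return Predictions aligned with the observations (`NA` at step 1).
#' @export
average_predict <- function(target) {
  y <- ts_values(target)
  if (length(y) < 2L) stop("need at least 2 observations")
  n <- length(y)
  c(NA_real_, cumsum(y)[-n] / seq_len(n - 1L))
}

#' Pairwise win count between two prediction traces
#'
#' Counts, over the points after the burn-in, how often each method's
#' prediction is strictly better (smaller loss) than the other's. A method
#' wins the target if it is superior at more than half of the compared
#' points; point ties count toward neither, and a target with no strict
#' majority has no winner.
#'
#' @param pred_a,pred_b prediction traces aligned with the observations.
#' @param target the observed series.
#' @param burn_in initial points excluded (default 10, since no learning
#'   part can be prepared for them).
#' @param loss a [loss_spec()]; the per-point comparator (default absolute).
#' @return A list with `points_a`, `points_b`, `ties`, `n_compared` and
#'   `winner` (`"A"`, `"B"` or `NA`).
#' @export
pairwise_wins <- function(pred_a, pred_b, target, burn_in = 10L,
                          loss = loss_spec("absolute")) {
  y <- ts_values(target)
  if (length(pred_a) != length(y) || length(pred_b) != length(y))
    stop("prediction traces must align with the target")
  idx <- seq_along(y) > burn_in & !is.na(pred_a) & !is.na(pred_b)
  if (!any(idx)) stop("no compared points after burn_in")
  la <- loss_eval(loss, pred_a[idx], y[idx])
  lb <- loss_eval(loss, pred_b[idx], y[idx])
  pa <- sum(la < lb); pb <- sum(lb < la)
  n <- sum(idx)
  winner <- if (pa > n / 2) "A" else if (pb > n / 2) "B" else NA_character_
  list(points_a = pa, points_b = pb, ties = n - pa - pb,
       n_compared = n, winner = winner)
}

#' Win-count tournament across methods and targets
#'
#' For every pair of methods and every target, decides the pairwise winner
#' with [pairwise_wins()] and accumulates a method-by-method win matrix:
#' `wins[A, B]` is the number of targets on which A beat B.
#'
#' @param predictions named list (one element per method) of lists of
#'   prediction traces, one per target, each aligned with its target.
#' @param targets list of observed series.
#' @param burn_in initial points excluded from every comparison.
#' @param loss a [loss_spec()].
#' @return An object of class `"tournament"`: list with the `wins` matrix,
#'   `pair_ties` matrix (targets with no strict majority), `n_targets` and
#'   `methods`.
#' @export
prediction_tournament <- function(predictions, targets, burn_in = 10L,
                                  loss = loss_spec("absolute")) {
  methods <- names(predictions)
  if (is.null(methods) || length(methods) < 2L)
    stop("need a named list of at least two methods")
  n_targets <- length(targets)
  if (n_targets < 1L) stop("need at least one target")
  wins <- matrix(0L, length(methods), length(methods),
                 dimnames = list(methods, methods))
  ties <- wins
  for (a in seq_along(methods)) for (b in seq_along(methods)) {
    if (a >= b) next
    for (g in seq_len(n_targets)) {
      res <- pairwise_wins(predictions[[a]][[g]], predictions[[b]][[g]],
                           targets[[g]], burn_in, loss)
      if (identical(res$winner, "A")) wins[a, b] <- wins[a, b] + 1L
      else if (identical(res$winner, "B")) wins[b, a] <- wins[b, a] + 1L
      else { ties[a, b] <- ties[a, b] + 1L; ties[b, a] <- ties[b, a] + 1L }
    }
  }
  structure(list(wins = wins, pair_ties = ties, n_targets = n_targets,
                 methods = methods, burn_in = burn_in),
            class = "tournament")
}

#' @export
print.tournament <- function(x, ...) {
  cat("Pairwise win counts over", x$n_targets, "targets (row beats column):\n")
  print(x$wins)
  invisible(x)
}

#' Exact binomial significance thresholds for win counts
#'
#' Two-sided test of the fair-coin null at level `alpha`: a method is
#' significantly superior if its wins over `n` targets exceed `upper`, and
#' significantly inferior if below `lower`. `upper` is the smallest integer
#' c with \eqn{P(X \ge c + 1) \le \alpha/2} under Binomial(n, 1/2) (exact
#' tail), and `lower = n - upper` by symmetry. For `n = 1000` at
#' \eqn{\alpha = 0.05} these are 531 and 469; for `n = 120`, 71 and 49.
#'
#' @param n number of trials (targets).
#' @param alpha two-sided significance level.
#' @return An object of class `"threshold_pair"`: list with `n`, `alpha`,
#'   `lower`, `upper`.
#' @examples
#' binomial_thresholds(1000)
#' @export
binomial_thresholds <- function(n, alpha = 0.05) {
  n <- as.integer(n)
  if (n < 1L) stop("'n' must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  upper <- as.integer(stats::qbinom(1 - alpha / 2, n, 0.5))
  structure(list(n = n, alpha = alpha, lower = n - upper, upper = upper),
            class = "threshold_pair")
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(paste0("Binomial(n = %d, 1/2), two-sided alpha = %g:\n",
                     "  superior if wins > %d, inferior if wins < %d\n"),
              x$n, x$alpha, x$upper, x$lower))
  invisible(x)
}

#' Accumulated-loss curves versus panel size
#'
#' Runs each weighting scheme online over the target once per panel and
#' reports the predictor's exponential accumulated loss
#' \eqn{\sum_k \lambda^{k-1} l_k} (a common reference decay so the curves
#' are comparable across schemes) and the standard accumulated loss
#' \eqn{\sum_k l_k}, per panel size.
#'
#' @param panels named list of [expert_panel()]s of increasing size.
#' @param target the observed series.
#' @param schemes named list of [weight_scheme()]s.
#' @param loss a [loss_spec()].
#' @param burn_in steps excluded from the accumulations.
#' @param coef_lambda reference decay for the exponential accumulation;
#'   defaults to the first temporal scheme's lambda, else 1.
#' @return A data frame with columns `n_experts`, `method`, `exponential`,
#'   `standard`.
#' @export
loss_curves <- function(panels, target, schemes, loss = loss_spec(),
                        burn_in = 0L, coef_lambda = NULL) {
  if (is.null(coef_lambda)) {
    lams <- vapply(schemes, function(s)
      if (s$variant == "tea") s$lambda else NA_real_, numeric(1))
    coef_lambda <- if (all(is.na(lams))) 1 else lams[!is.na(lams)][1L]
  }
  out <- list()
  for (p in seq_along(panels)) for (m in seq_along(schemes)) {
    run <- run_online(panels[[p]], target, schemes[[m]], loss,
                      burn_in = burn_in, trace_weights = FALSE,
                      warn_epsilon = FALSE)
    keep <- seq_along(run$pred_losses) > burn_in
    l <- run$pred_losses[keep]
    a <- coef_lambda^(which(keep) - 1)
    out[[length(out) + 1L]] <- data.frame(
      n_experts = n_experts(panels[[p]]),
      method = names(schemes)[m],
      exponential = sum(a * l),
      standard = sum(l))
  }
  do.call(rbind, out)
}

#' Coverage of predictive quantile bands
#'
#' For each quantile level `Q`, the fraction of subjects whose next
#' observation lies below the predicted \eqn{u(Q)}; a well-calibrated
#' forecaster yields fractions close to `Q`. With a `groups` factor (e.g.
#' the number of learning points used) proportions are reported per group.
#'
#' @param mixtures list of `"mixture_prediction"`s, one next-point
#'   predictive distribution per subject.
#' @param observations the subjects' next observed values.
#' @param q_levels quantile levels.
#' @param groups optional grouping factor of the same length.
#' @return A named vector of proportions, or a groups x levels matrix.
#' @export
coverage_table <- function(mixtures, observations,
                           q_levels = c(0.975, 0.875, 0.75, 0.65, 0.6,
                                        0.55, 0.525),
                           groups = NULL) {
  if (length(mixtures) != length(observations))
    stop("one observation per predictive distribution is required")
  if (length(mixtures) == 0L) stop("empty subject set")
  below <- t(vapply(seq_along(mixtures), function(i) {
    u <- quantile(mixtures[[i]], q_levels)
    as.numeric(observations[i] < u)
  }, numeric(length(q_levels))))
  colnames(below) <- paste0(format(100 * q_levels, trim = TRUE), "%")
  if (is.null(groups)) return(colMeans(below))
  rowsum(below, groups) / as.vector(table(groups))
}
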