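abs_loss <- loss_spec("absolute")

test_that("baseline predictors follow their definitions", {
  expect_equal(persistence_predict(c(1, 3, 2)), c(NA, 1, 3))
  expect_equal(persistence_predict(rep(4, 5))[-1], rep(4, 4))
  alt <- rep(c(0, 1), 10)
  expect_true(all(abs(persistence_predict(alt)[-1] - alt[-1]) == 1))
  expect_equal(average_predict(c(0, 2, 7))[2:3], c(0, 1))
  expect_equal(average_predict(rep(3, 6))[-1], rep(3, 5))
  expect_error(persistence_predict(1), "at least 2")
})

test_that("pairwise wins count strictly better points with tie handling", {
  y <- c(0, 0, 0, 0, 0, 0, 0)
  perfect <- rep(0, 7)
  off <- rep(1, 7)
  res <- pairwise_wins(perfect, off, y, burn_in = 2)
  expect_equal(res$points_a, 5)
  expect_equal(res$winner, "A")
  # 5 compared points, A better at 3 -> A wins
  pa <- c(NA, 0, 0, 0, 1, 1)
  pb <- c(NA, 1, 1, 1, 0, 0)
  res2 <- pairwise_wins(pa, pb, rep(0, 6), burn_in = 1)
  expect_equal(res2$points_a, 3)
  expect_equal(res2$winner, "A")
  # identical predictions: all ties, no winner
  res3 <- pairwise_wins(off, off, y, burn_in = 0)
  expect_equal(res3$ties, 7)
  expect_true(is.na(res3$winner))
  expect_error(pairwise_wins(perfect[-1], off, y), "align")
})

test_that("the tournament fills a Table-1-shaped win matrix", {
  targets <- lapply(1:3, function(i) c(0, 0, 0, 0, 0))
  preds <- list(A = lapply(targets, function(y) rep(0, 5)),
                B = lapply(targets, function(y) rep(1, 5)))
  tour <- prediction_tournament(preds, targets, burn_in = 1)
  expect_equal(tour$wins["A", "B"], 3L)
  expect_equal(tour$wins["B", "A"], 0L)
  # single target: entries in {0, 1}
  tour1 <- prediction_tournament(lapply(preds, `[`, 1), targets[1],
                                 burn_in = 1)
  expect_true(all(tour1$wins %in% 0:1))
  expect_error(prediction_tournament(preds["A"], targets), "two methods")
})

test_that("tournament wins and pair ties add up to the target count", {
  set.seed(22)
  targets <- lapply(1:6, function(i) stats::runif(20))
  mk <- function() lapply(targets, function(y)
    c(NA, y[-20] + stats::rnorm(19, 0, 0.3)))
  preds <- list(A = mk(), B = mk(), C = mk())
  tour <- prediction_tournament(preds, targets, burn_in = 5)
  for (a in 1:3) for (b in 1:3) {
    if (a == b) next
    expect_equal(tour$wins[a, b] + tour$wins[b, a] + tour$pair_ties[a, b], 6)
  }
})

test_that("persistence beats the running mean on increasing targets", {
  y <- cumsum(stats::runif(30, 0.5, 1.5))
  res <- pairwise_wins(persistence_predict(y), average_predict(y), y,
                       burn_in = 10)
  expect_equal(res$points_a, res$n_compared)
  expect_equal(res$winner, "A")
})

test_that("binomial thresholds match the exact tails", {
  th <- binomial_thresholds(1000)
  expect_equal(th$upper, 531L)
  expect_equal(th$lower, 469L)
  th2 <- binomial_thresholds(120)
  expect_equal(th2$upper, 71L)
  expect_equal(th2$lower, 49L)
  # brute-force exact-tail summation across a spread of n <= 2000
  for (n in c(1, 2, 7, 33, 120, 525, 1000, 1999, 2000)) {
    bt <- brute_thresholds(n)
    th <- binomial_thresholds(n)
    expect_equal(th$upper, bt$upper)
    expect_equal(th$lower, bt$lower)
    expect_equal(th$lower + th$upper, n)
    # strictness: exceeding upper is significant, hitting it is not
    expect_lte(stats::pbinom(th$upper, n, 0.5, lower.tail = FALSE), 0.025)
    expect_gt(stats::pbinom(th$upper - 1L, n, 0.5, lower.tail = FALSE), 0.025)
  }
  expect_error(binomial_thresholds(10, alpha = 0), "alpha")
})

test_that("loss curves accumulate exponentially and plainly", {
  set.seed(23)
  y <- stats::runif(12)
  pan_small <- expert_panel(rbind(y, matrix(stats::runif(24), 2)))
  pan_big <- expert_panel(rbind(y, matrix(stats::runif(60), 5)))
  schemes <- list(tea = weight_scheme("tea", lambda = 1.2, eta = 1),
                  standard = weight_scheme("standard", eta = 1))
  curves <- loss_curves(list(pan_small, pan_big), y, schemes)
  expect_equal(nrow(curves), 4L)
  expect_true(all(curves$exponential >= curves$standard))
  # a zero-error method: panel containing only the target
  perfect <- loss_curves(list(expert_panel(matrix(y, 1))), y,
                         schemes["standard"])
  expect_equal(perfect$exponential, 0)
  expect_equal(perfect$standard, 0)
  # reference decay 1: both accumulations coincide
  c1 <- loss_curves(list(pan_small), y, schemes["standard"], coef_lambda = 1)
  expect_equal(c1$exponential, c1$standard)
})

test_that("coverage proportions count observations under the bands", {
  mixes <- lapply(c(0, 5), function(c) mixture_prediction(c, 1, sigma = 1))
  # observations far below every band
  expect_equal(unname(coverage_table(mixes, c(-50, -50), q_levels7)),
               rep(1, 7))
  # single subject: proportions are 0 or 1
  cov1 <- coverage_table(mixes[1], 0.1, q_levels7)
  expect_true(all(cov1 %in% c(0, 1)))
  # grouping splits the proportions by group
  covg <- coverage_table(mixes, c(-50, 50), q_levels7,
                         groups = c("K3", "K4"))
  expect_equal(unname(covg["K3", ]), rep(1, 7))
  expect_equal(unname(covg["K4", ]), rep(0, 7))
  expect_error(coverage_table(mixes, 1), "one observation per")
  expect_error(coverage_table(list(), numeric(0)), "empty")
})
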