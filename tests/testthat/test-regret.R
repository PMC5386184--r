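abs_loss <- loss_spec("absolute")

test_that("regret is predictor loss minus the best expert's loss", {
  st <- structure(list(t = 3L, expert_losses = c(2, 7), predictor_loss = 5,
                       log_weights = c(log(0.5), log(0.5)), n_experts = 2L),
                  class = "forecast_state")
  expect_equal(regret_of(st), 3)
  # perfect best expert and perfect predictor (single perfect expert)
  y <- c(0.2, 0.4, 0.6)
  p <- expert_panel(matrix(y, 1))
  run <- run_online(p, y, weight_scheme("tea", lambda = 1.5, eta = 1),
                    abs_loss)
  expect_equal(regret_of(run), 0)
  # random instance equals brute-force recomputation
  set.seed(7)
  inst <- random_instance(N = 3, t_end = 12)
  run <- run_online(expert_panel(inst$advice), inst$y,
                    weight_scheme("tea", lambda = 1.3, eta = 1), abs_loss)
  L <- brute_accumulated_loss(inst$advice, inst$y, abs_loss, "tea",
                              lambda = 1.3)
  Lp <- sum(1.3^(seq_len(12) - 1) *
              abs(run$predictions - inst$y))
  expect_equal(regret_of(run), Lp - min(L), tolerance = 1e-10)
})

test_that("closed-form optimal eta and bound match numeric minimisation", {
  grid <- expand.grid(N = c(2, 10, 100), t = c(1, 2, 5, 20),
                      eps = c(0.5, 1, 2), lambda = c(1, 1.11, 1.5, 2))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    S <- coef_sq_sum_direct("tea", g$t, lambda = g$lambda)
    num <- numeric_bound_min(g$N, g$t, g$eps, S)
    expect_equal(optimal_eta(g$N, g$t, g$eps, "tea", lambda = g$lambda),
                 num$eta, tolerance = 1e-4)
    expect_equal(optimal_bound(g$N, g$t, g$eps, "tea", lambda = g$lambda),
                 num$bound, tolerance = 1e-6)
  }
  # discounted variant against its own coefficient sum
  S_cz <- coef_sq_sum_direct("cz", 15, rho = 0.9)
  num <- numeric_bound_min(10, 15, 1, S_cz)
  expect_equal(optimal_bound(10, 15, 1, "cz", rho = 0.9), num$bound,
               tolerance = 1e-6)
})

test_that("optimal eta scales as 1/epsilon and recovers the standard limit", {
  e1 <- optimal_eta(5, 10, 1, "tea", lambda = 1.2)
  e2 <- optimal_eta(5, 10, 2, "tea", lambda = 1.2)
  expect_equal(e1 / e2, 2, tolerance = 1e-12)
  expect_equal(optimal_eta(5, 10, 1, "tea", lambda = 1),
               optimal_eta(5, 10, 1, "standard"), tolerance = 1e-12)
  expect_equal(optimal_eta(5, 10, 1, "standard"), sqrt(8 * log(5) / 10),
               tolerance = 1e-12)
})

test_that("optimal bounds reproduce the worked values and the lambda->1 limit", {
  expect_equal(optimal_bound(2, 2, 1, "standard"), sqrt(log(2)),
               tolerance = 1e-12)
  expect_equal(optimal_bound(2, 2, 1, "tea", lambda = 2),
               sqrt(5 * log(2) / 2), tolerance = 1e-12)
  for (t in c(1, 2, 5, 10, 50, 100)) for (N in c(2, 10, 100, 1000)) {
    expect_equal(optimal_bound(N, t, 1, "tea", lambda = 1 + 1e-10),
                 sqrt((t / 2) * log(N)), tolerance = 1e-6)
  }
})

test_that("optimal bound is monotone in t, N, epsilon and lambda", {
  b <- function(N = 10, t = 10, eps = 1, lam = 1.2)
    optimal_bound(N, t, eps, "tea", lambda = lam)
  expect_true(all(diff(sapply(c(2, 5, 10, 40), function(t) b(t = t))) > 0))
  expect_true(all(diff(sapply(c(2, 10, 100), function(N) b(N = N))) > 0))
  expect_true(all(diff(sapply(c(0.5, 1, 2), function(e) b(eps = e))) > 0))
  expect_true(all(diff(sapply(c(1, 1.1, 1.5, 2), function(l) b(lam = l))) >= 0))
})

test_that("normalised temporal bound multiplies by rho^(t-1) and beats CZ", {
  # rho = 1 limit: the standard bound
  expect_equal(normalized_tea_bound(100, 10, 1, rho = 1),
               optimal_bound(100, 10, 1, "standard"), tolerance = 1e-12)
  # t = 1: multiplier is rho^0 = 1
  expect_equal(normalized_tea_bound(5, 1, 1, rho = 0.9),
               optimal_bound(5, 1, 1, "tea", lambda = 1 / 0.9),
               tolerance = 1e-12)
  # definitional route: rho^{t-1} * temporal bound
  for (rho in c(0.5, 0.9, 0.99)) for (t in c(2, 10, 50)) {
    expect_equal(normalized_tea_bound(100, t, 1, rho = rho),
                 rho^(t - 1) * optimal_bound(100, t, 1, "tea", lambda = 1 / rho),
                 tolerance = 1e-10)
  }
  expect_lte(normalized_tea_bound(100, 10, 1, rho = 0.9),
             optimal_bound(100, 10, 1, "cz", rho = 0.9))
  expect_error(normalized_tea_bound(10, 5, 1, rho = 0.9, lambda = 2),
               "lambda = 1/rho")
})

test_that("bound comparison holds on the grid and random sweeps", {
  for (rho in c(0.5, 0.9, 0.99)) for (t in c(2, 10, 50))
    for (N in c(2, 100)) {
      rep <- bound_comparison(N, t, 1, rho)
      expect_true(rep$tea_leq_cz)
      expect_lte(rep$tea_normalized, rep$cz + 1e-12)
    }
  set.seed(8)
  for (i in 1:1000) {
    rep <- bound_comparison(N = sample(2:500, 1), t = sample(1:200, 1),
                            epsilon = stats::runif(1, 0.1, 5),
                            rho = stats::runif(1, 0.01, 0.999))
    expect_true(rep$tea_leq_cz)
  }
  # rho -> 1: the two bounds converge toward equality
  r <- bound_comparison(100, 20, 1, rho = 1 - 1e-9)
  expect_equal(r$tea_normalized / r$cz, 1, tolerance = 1e-6)
})

test_that("simulated regret stays within the optimal bound at eta*", {
  set.seed(9)
  for (i in 1:30) {
    N <- sample(2:20, 1); t_end <- sample(3:30, 1)
    lambda <- sample(c(1.05, 1.11, 1.5), 1)
    inst <- random_instance(N, t_end)
    run <- run_online(expert_panel(inst$advice), inst$y,
                      weight_scheme("tea", lambda = lambda, eta = "auto"),
                      abs_loss)
    rep <- regret_report(run)
    expect_true(rep$satisfied)
    expect_lte(rep$regret, optimal_bound(N, t_end, 1, "tea", lambda = lambda) + 1e-9)
  }
})
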