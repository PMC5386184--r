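abs_loss <- loss_spec("absolute")

test_that("initial state has zero losses and uniform weights", {
  p4 <- expert_panel(matrix(0, 4, 2))
  st <- init_state(p4)
  expect_equal(state_weights(st), rep(0.25, 4))
  expect_equal(st$t, 0L)
  st1 <- init_state(expert_panel(matrix(0, 1, 2)))
  expect_equal(state_weights(st1), 1)
  st2 <- init_state(expert_panel(matrix(0, 2, 2)))
  expect_equal(st2$expert_losses, c(0, 0))
  expect_equal(st2$predictor_loss, 0)
  expect_error(expert_panel(matrix(0, 0, 2)), "at least one expert")
})

test_that("loss coefficients follow each variant's definition", {
  tea2 <- weight_scheme("tea", lambda = 2)
  expect_equal(loss_coefficient(tea2, 1, 5), 1)
  expect_equal(loss_coefficient(tea2, 3, 5), 4)
  tea_k <- weight_scheme("tea", lambda = 2, tea_exponent = "k")
  expect_equal(loss_coefficient(tea_k, 3, 5), 8)
  cz <- weight_scheme("cz", rho = 0.9)
  expect_equal(loss_coefficient(cz, 7, 7), 1 / 0.9)
  expect_equal(loss_coefficient(weight_scheme("standard"), 2, 9), 1)
  expect_error(loss_coefficient(tea2, 0, 5), "1 <= k <= t")
  expect_error(loss_coefficient(tea2, 6, 5), "1 <= k <= t")
})

test_that("updates reproduce the hand-evaluated two-expert trace", {
  p <- expert_panel(rbind(c(0, 0), c(1, 1)))
  sc <- weight_scheme("tea", lambda = 2, eta = 1)
  st <- update_state(init_state(p), c(0, 1), y = 0, abs_loss, sc,
                     prediction = 0.5)
  expect_equal(st$expert_losses, c(0, 1))
  expect_equal(state_weights(st), c(1, exp(-1)) / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(state_weights(st), c(0.7311, 0.2689), tolerance = 1e-4)

  st2 <- update_state(st, c(0, 1), y = 0, abs_loss, sc, prediction = 0.2,
                      warn_epsilon = FALSE)
  expect_equal(st2$expert_losses, c(0, 3))  # increment lambda^1 * 1 = 2
  expect_equal(state_weights(st2), c(0.9526, 0.0474), tolerance = 1e-4)
})

test_that("update rejects unresolved eta and non-finite inputs", {
  p <- expert_panel(rbind(c(0, 0), c(1, 1)))
  st <- init_state(p)
  expect_error(update_state(st, c(0, 1), 0, abs_loss,
                            weight_scheme("standard"), 0.5), "numeric 'eta'")
  sc <- weight_scheme("standard", eta = 1)
  expect_error(update_state(st, c(0, 1), NaN, abs_loss, sc, 0.5),
               "non-finite observation")
  expect_warning(update_state(st, c(0, 5), 0, abs_loss, sc, 0.5),
                 "exceeded epsilon")
})

test_that("temporal scheme with lambda = 1 is bit-identical to standard", {
  set.seed(1)
  inst <- random_instance(N = 6, t_end = 15)
  p <- expert_panel(inst$advice)
  f1 <- tea(inst$y, p, variant = "tea", lambda = 1, eta = 0.7)
  f0 <- tea(inst$y, p, variant = "standard", eta = 0.7)
  expect_identical(f1$weights, f0$weights)
  expect_identical(f1$predictions, f0$predictions)
  expect_identical(f1$state$expert_losses, f0$state$expert_losses)
})

test_that("point prediction is a convex combination honouring horizons", {
  p <- expert_panel(matrix(5, 3, 4))
  st <- init_state(p)
  expect_equal(point_predict(st, p, 1), 5)
  # hand-weighted average
  p2 <- expert_panel(rbind(c(0, 0), c(1, 1)))
  st2 <- update_state(init_state(p2), c(0, 1), 0, abs_loss,
                      weight_scheme("tea", lambda = 2, eta = 1), 0.5)
  expect_equal(point_predict(st2, p2, 1), exp(-1) / (1 + exp(-1)),
               tolerance = 1e-12)
  # single expert
  p1 <- expert_panel(matrix(c(7, 9), 1))
  expect_equal(point_predict(init_state(p1), p1, 2), 9)
  # expired expert excluded, survivors renormalised
  p3 <- expert_panel(rbind(c(1, 1, 1), c(3, 3, NA)))
  st3 <- init_state(p3)
  expect_equal(point_predict(st3, p3, 2), 2)    # both alive
  expect_equal(point_predict(st3, p3, 3), 1)    # only first survives
  p4 <- expert_panel(rbind(c(1, NA), c(3, NA)))
  expect_error(point_predict(init_state(p4), p4, 2), "no expert")
})

test_that("online run matches a step-by-step hand trace", {
  # 2 experts, 3 steps, absolute loss, eta = 1, lambda = 2 (a_k = 2^{k-1})
  adv <- rbind(c(1.0, 0.5, 0.2), c(0.0, 1.0, 1.0))
  y <- c(0.5, 0.9, 0.1)
  p <- expert_panel(adv)
  run <- run_online(p, y, weight_scheme("tea", lambda = 2, eta = 1),
                    abs_loss, warn_epsilon = FALSE)
  # hand application: L_{i,t} = sum_k 2^{k-1} |f_{i,k} - y_k|
  L <- brute_accumulated_loss(adv, y, abs_loss, "tea", lambda = 2)
  expect_equal(run$state$expert_losses, L, tolerance = 1e-12)
  w1 <- exp(-1 * abs(adv[, 1] - y[1])); w1 <- w1 / sum(w1)
  expect_equal(run$weights[1, ], w1, tolerance = 1e-12)
  expect_equal(run$predictions[1], mean(adv[, 1]))  # uniform at t = 1
  expect_equal(run$predictions[2], sum(w1 * adv[, 2]), tolerance = 1e-12)
  L2 <- abs(adv[, 1] - y[1]) + 2 * abs(adv[, 2] - y[2])
  w2 <- exp(-L2) / sum(exp(-L2))
  expect_equal(run$predictions[3], sum(w2 * adv[, 3]), tolerance = 1e-12)
})

test_that("a perfect expert dominates and eta = 0 freezes uniform weights", {
  set.seed(2)
  y <- stats::runif(12)
  adv <- rbind(y, matrix(stats::runif(36), 3))
  p <- expert_panel(adv)
  run <- run_online(p, y, weight_scheme("tea", lambda = 1.3, eta = 1),
                    abs_loss, warn_epsilon = FALSE)
  expect_true(all(apply(run$weights, 1, which.max) == 1L))
  expect_equal(min(run$state$expert_losses), 0)

  run0 <- run_online(p, y, weight_scheme("standard", eta = 0), abs_loss)
  expect_equal(run0$predictions, colMeans(adv), tolerance = 1e-12)
})

test_that("weights stay normalised and respect loss dominance", {
  set.seed(3)
  for (variant in c("standard", "tea", "cz")) {
    inst <- random_instance(N = 8, t_end = 20)
    p <- expert_panel(inst$advice)
    sc <- weight_scheme(variant,
                        lambda = if (variant == "tea") 1.4 else NULL,
                        rho = if (variant == "cz") 0.9 else NULL,
                        eta = 0.8)
    run <- run_online(p, inst$y, sc, abs_loss, warn_epsilon = FALSE)
    expect_true(all(abs(rowSums(run$weights) - 1) < 1e-12))
  }
  # monotone dominance: expert 1 never worse, strictly better somewhere
  adv <- rbind(c(0.1, 0.0, 0.2), c(0.3, 0.0, 0.5))
  y <- c(0, 0, 0)
  for (variant in c("standard", "tea", "cz")) {
    sc <- weight_scheme(variant,
                        lambda = if (variant == "tea") 1.5 else NULL,
                        rho = if (variant == "cz") 0.8 else NULL,
                        eta = 0.5)
    run <- run_online(expert_panel(adv), y, sc, abs_loss)
    w <- state_weights(run$state)
    expect_gt(w[1], w[2])
  }
})

test_that("permuting panel rows permutes weights identically", {
  set.seed(4)
  inst <- random_instance(N = 5, t_end = 10)
  perm <- sample(5)
  sc <- weight_scheme("tea", lambda = 1.2, eta = 1)
  r1 <- run_online(expert_panel(inst$advice), inst$y, sc, abs_loss)
  r2 <- run_online(expert_panel(inst$advice[perm, ]), inst$y, sc, abs_loss)
  expect_equal(state_weights(r2$state), state_weights(r1$state)[perm],
               tolerance = 1e-14)
})

test_that("discounted recursion equals the direct discounted sum", {
  set.seed(5)
  inst <- random_instance(N = 4, t_end = 17)
  run <- run_online(expert_panel(inst$advice), inst$y,
                    weight_scheme("cz", rho = 0.85, eta = 1), abs_loss)
  direct <- brute_accumulated_loss(inst$advice, inst$y, abs_loss, "cz",
                                   rho = 0.85)
  expect_equal(run$state$expert_losses, direct, tolerance = 1e-10)
})

test_that("temporal and discounted weights obey the power relation", {
  # with lambda = 1/rho and a_k = lambda^k, discounted losses are
  # rho^{t-1} times the temporal ones, so TEA weights equal CZ weights
  # raised to rho^{-(t-1)} and renormalised
  set.seed(6)
  for (rep in 1:5) {
    rho <- stats::runif(1, 0.7, 0.95)
    inst <- random_instance(N = 6, t_end = 10)
    p <- expert_panel(inst$advice)
    f_tea <- run_online(p, inst$y,
                        weight_scheme("tea", lambda = 1 / rho,
                                      tea_exponent = "k", eta = 0.4),
                        abs_loss, warn_epsilon = FALSE)
    f_cz <- run_online(p, inst$y, weight_scheme("cz", rho = rho, eta = 0.4),
                       abs_loss, warn_epsilon = FALSE)
    w_cz <- state_weights(f_cz$state)
    w_pow <- w_cz^(rho^(-(10 - 1)))
    expect_equal(state_weights(f_tea$state), w_pow / sum(w_pow),
                 tolerance = 1e-9)
  }
})

test_that("run_online validates burn-in and reports overflow", {
  p <- expert_panel(matrix(0, 2, 3))
  expect_error(run_online(p, c(1, 2), weight_scheme("standard", eta = 1),
                          abs_loss, burn_in = 5), "burn_in")
  huge <- expert_panel(matrix(0, 2, 600))
  expect_error(
    run_online(huge, rep(1, 600), weight_scheme("tea", lambda = 10, eta = 1),
               abs_loss, warn_epsilon = FALSE),
    "overflow")
})
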