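# Seed-controlled synthetic data generators. These stand in for the study's
# unavailable recordings: chaotic-map expert databases built over parameter
# grids, and synthetic PSA cohorts simulated from the piecewise-linear cell
# model with irregular short sampling. They are synthetic by construction and
# do not imitate the statistical fine structure of any real recording.

#' Chaotic-map expert database
#'
#' Generates `M` parameter sets x `S` initial conditions, iterates each orbit
#' past the transient, and records the observable `x + y` for `n` steps. The
#' defaults follow the chaotic-map study conditions: Henon parameters drawn
#' uniformly from a in \[1.3, 1.4\] and b in \[0.1, 0.2\], initial conditions
#' from \[-0.02, 0.02\]^2, transient 1000. Diverging orbits are discarded and
#' redrawn with a warning. Deterministic given `seed`.
#'
#' @param map `"henon"` or `"ikeda"`.
#' @param M number of parameter sets.
#' @param S initial conditions per set.
#' @param n recorded length of each series.
#' @param a_range,b_range Henon parameter ranges.
#' @param u_range Ikeda parameter range.
#' @param ic_range half-width of the initial-condition box.
#' @param transient discarded leading steps.
#' @param seed optional seed, restored afterwards.
#' @return A list with `db` (a [series_database()]), `panel` (an
#'   [expert_panel()] whose experts are the series themselves, horizon `n`)
#'   and `params` (the drawn parameters).
#' @export
toy_database <- function(map = c("henon", "ikeda"), M = 100L, S = 1000L, n,
                         a_range = c(1.3, 1.4), b_range = c(0.1, 0.2),
                         u_range = c(0.85, 0.95), ic_range = 0.02,
                         transient = 1000L, seed = NULL) {
  map <- match.arg(map)
  M <- as.integer(M); S <- as.integer(S)
  if (M < 1L || S < 1L) stop("'M' and 'S' must be >= 1")
  with_seed(seed, {
    m <- M * S
    if (map == "henon") {
      a <- rep(stats::runif(M, a_range[1L], a_range[2L]), each = S)
      b <- rep(stats::runif(M, b_range[1L], b_range[2L]), each = S)
      pars <- list(a = a, b = b)
      step <- henon_step
      params <- data.frame(a = a, b = b)
    } else {
      u <- rep(stats::runif(M, u_range[1L], u_range[2L]), each = S)
      pars <- list(u = u)
      step <- ikeda_step
      params <- data.frame(u = u)
    }
    x0 <- stats::runif(m, -ic_range, ic_range)
    y0 <- stats::runif(m, -ic_range, ic_range)
    obs <- map_orbit(step, x0, y0, pars, n, transient)
    for (attempt in 1:50) {
      bad <- which(apply(obs, 2L, anyNA))
      if (length(bad) == 0L) break
      if (attempt == 1L)
        warning(length(bad), " diverging orbit(s) discarded and redrawn")
      x0b <- stats::runif(length(bad), -ic_range, ic_range)
      y0b <- stats::runif(length(bad), -ic_range, ic_range)
      parsb <- lapply(pars, function(p) p[bad])
      obs[, bad] <- map_orbit(step, x0b, y0b, parsb, n, transient)
    }
    if (anyNA(obs)) stop("orbits kept diverging after 50 redraws")
    series <- lapply(seq_len(m), function(i) obs[, i])
    db <- series_database(series)
    list(db = db,
         panel = expert_panel(t(obs), horizon = rep(n, m), ids = db$ids),
         params = params)
  })
}

#' Synthetic PSA cohort from the cell-population model
#'
#' Emulates a cohort of post-treatment (off-therapy) prostate cancer
#' patients: each patient gets sampled model rates, a sampled nonnegative
#' initial cell state, an irregular visit schedule, and PSA observations
#' simulated from the piecewise-linear model with additive Gaussian noise
#' clipped at zero. Off-treatment rates are drawn from `e_range` per day with
#' at least one positive growth mode per patient, giving the clinically
#' interesting mix of rising and falling PSA; on-treatment rates are also
#' drawn (self-rates negative, conversions small positive) so the table has
#' the full 10 columns, though only the off phase is simulated here.
#'
#' @param n_patients cohort size (default 72, the size of the reference
#'   parameter table).
#' @param K learning points per patient.
#' @param n_followup additional follow-up points.
#' @param e_range range of the off-treatment rates (per day).
#' @param gap_range range of the uniform inter-visit gaps (days).
#' @param initial_range range of each initial state component.
#' @param noise_sd observation noise standard deviation (PSA units).
#' @param seed optional seed, restored afterwards.
#' @return A list with `params` (data frame `id, d1..d6, e1..e4`) and
#'   `patients`: per patient a list with `times`, `truth`, `observed`,
#'   `initial_state` and `row` (its row in the table).
#' @export
synthetic_cohort <- function(n_patients = 72L, K = 6L, n_followup = 4L,
                             e_range = c(-0.1, 0.1), gap_range = c(2, 6),
                             initial_range = c(0.5, 5), noise_sd = 0.1,
                             seed = NULL) {
  n_patients <- as.integer(n_patients)
  if (n_patients < 1L) stop("'n_patients' must be >= 1")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (e_range[2L] <= 0)
    stop("'e_range' must allow a positive growth rate")
  with_seed(seed, {
    params <- data.frame(id = paste0("p", seq_len(n_patients)))
    for (j in 1:6)
      params[[paste0("d", j)]] <- if (j %in% c(1, 3, 6))
        stats::runif(n_patients, -0.2, -0.01)
      else stats::runif(n_patients, 0, 0.05)
    # self-rates (e1, e3, e4) may have either sign; the x2 -> x1 reversion
    # coupling e2 is a transfer rate and must be nonnegative, which keeps
    # the nonnegative orthant invariant (Metzler structure)
    for (j in c(1, 3, 4))
      params[[paste0("e", j)]] <- stats::runif(n_patients, e_range[1L], e_range[2L])
    params$e2 <- stats::runif(n_patients, 0, e_range[2L])
    params <- params[, c("id", paste0("d", 1:6), paste0("e", 1:4))]
    # ensure at least one positive growth mode (self-rates e1, e3, e4)
    for (i in seq_len(n_patients)) {
      while (max(params$e1[i], params$e3[i], params$e4[i]) <= 0) {
        j <- sample(c("e1", "e3", "e4"), 1L)
        params[[j]][i] <- stats::runif(1L, 0, e_range[2L])
      }
    }
    patients <- lapply(seq_len(n_patients), function(i) {
      pr <- params[i, ]
      p <- ias_params(d = as.numeric(pr[paste0("d", 1:6)]),
                      e = as.numeric(pr[paste0("e", 1:4)]))
      n_pts <- K + n_followup
      gaps <- stats::runif(n_pts - 1L, gap_range[1L], gap_range[2L])
      times <- c(0, cumsum(gaps))
      s0 <- stats::runif(3L, initial_range[1L], initial_range[2L])
      truth <- ias_simulate(p, s0, "off", eval_times = times)$psa
      observed <- if (noise_sd > 0)
        pmax(truth + stats::rnorm(n_pts, 0, noise_sd), 0)
      else truth
      list(times = times, truth = truth, observed = observed,
           initial_state = s0, row = i)
    })
    list(params = params, patients = patients)
  })
}
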