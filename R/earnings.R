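# Reward-earnings simulations for pure-MBCA agents, standardized against
# guessing and oracle baselines.

#' Per-trial guessing and oracle baseline earnings
#'
#' For each trial, the expected total reward (points) of each offered person
#' is the sum of their two outcomes' block-level reward probabilities. The
#' guessing baseline earns the mean of the two offers' expected totals, the
#' oracle baseline the maximum.
#'
#' @param session A `cm_session` (plan or simulated; only the offers and
#'   reward probabilities are used).
#' @return A data frame with per-trial `guessing` and `oracle` expected
#'   points.
#' @export
baseline_earnings <- function(session) {
  tr <- session$trials
  pref <- session$task_map$pref
  ev_person <- function(p) session$reward_probs[cbind(tr$block, pref[p, 1])] +
    session$reward_probs[cbind(tr$block, pref[p, 2])]
  evl <- ev_person(tr$left)
  evr <- ev_person(tr$right)
  data.frame(guessing = (evl + evr) / 2, oracle = pmax(evl, evr))
}

#' Standardized earnings of a simulated session
#'
#' The ratio of how much more the agent earned per trial (realized coins)
#' than the guessing baseline to how much more the oracle earned than the
#' guessing baseline, with baselines as expected points on the same trials.
#' The oracle policy scores 1 and uniform-random choice about 0.
#'
#' @param session A simulated `cm_session` (choices and rewards filled).
#' @return A scalar.
#' @export
standardized_earnings <- function(session) {
  tr <- session$trials
  if (anyNA(tr$chosen)) stop("session has unfilled choices")
  base <- baseline_earnings(session)
  points <- mean(tr$reward1 + tr$reward2)
  (points - mean(base$guessing)) / (mean(base$oracle) - mean(base$guessing))
}

pure_mb_params <- function(c_mb, f_mb) {
  param_vector(c_mf = 0, f_mf = 0, c_mb = c_mb, f_mb = f_mb, pr = 0, f_p = 0)
}

#' Earnings of format-yoked pure-MB agents
#'
#' For each participant's full-model fit, builds three pure-MB agents by
#' copying the fitted MBCA gains of one presentation format (S, PI, or RI)
#' across all three formats, keeping the fitted MB forgetting rate and
#' ablating MFCA and perseveration. All agents of all participants play the
#' same `n_sessions` fresh session plans; standardized earnings are averaged
#' across agents within each format regime per session, giving `n_sessions`
#' group-level measurements per regime.
#'
#' @param fits List of full-model `cm_fit` objects.
#' @param n_sessions Number of shared synthetic sessions.
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @return A list: `summary` (data frame with per-regime mean and SEM over
#'   sessions) and `per_session` (an `n_sessions` x 3 matrix of group-mean
#'   standardized earnings).
#' @export
yoked_format_agents <- function(fits, n_sessions = 1000L,
                                config = session_config(), seed = NULL) {
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, 2L * n_sessions)
  regimes <- c(S = "S", PI = "PI", RI = "RI")
  agent_params <- lapply(fits, function(f) lapply(regimes, function(fm) {
    g <- f$params[paste0("c_mb_", fm, 1:2)]
    pure_mb_params(rep(g, 3L), f$params[["f_mb"]])
  }))
  per_session <- matrix(NA_real_, n_sessions, 3L,
                        dimnames = list(NULL, regimes))
  for (s in seq_len(n_sessions)) {
    map <- build_task_map(seed = seeds[2L * s - 1L])
    plan <- generate_session_plan(map, config, seed = seeds[2L * s - 1L])
    sim_seeds <- derive_seeds(seeds[2L * s], length(fits) * 3L)
    for (r in 1:3) {
      vals <- vapply(seq_along(fits), function(i) standardized_earnings(
        simulate_session(agent_params[[i]][[r]], plan,
                         seed = sim_seeds[(i - 1L) * 3L + r])),
        numeric(1))
      per_session[s, r] <- mean(vals)
    }
  }
  summary <- data.frame(regime = regimes,
                        mean = colMeans(per_session),
                        sem = apply(per_session, 2, sd) / sqrt(n_sessions),
                        row.names = NULL)
  list(summary = summary, per_session = per_session)
}

#' Earnings surface over total MBCA and its position allocation
#'
#' Simulates pure-MB agents on a grid: at total MBCA `t` and allocation
#' fraction `p`, the standard- and prospective-format gains are `t / 2` for
#' both positions, and the retrospective-inference gains are `p * t` for the
#' first (inferred) outcome and `(1 - p) * t` for the second (seen) outcome.
#' Session plans are shared across all grid cells (common random numbers),
#' so comparisons across fractions are paired.
#'
#' @param total_grid Total retrospective MBCA values.
#' @param fraction_grid Allocation fractions for the first outcome.
#' @param f_mb MB forgetting rate for all agents (e.g. a group-mean fitted
#'   value).
#' @param n_sims Simulated sessions per grid cell.
#' @param config A [session_config()].
#' @param seed Integer seed.
#' @param keep_draws Keep the per-session earnings array (needed by
#'   [argmax_fraction()]).
#' @return An object of class `cm_earnings_grid`: `surface` (data frame
#'   with `total`, `fraction`, `mean`, `sem`, `n_sims`) and, if requested,
#'   `draws` (an `n_sims` x cells matrix).
#' @export
grid_earnings <- function(total_grid = seq(0.3, 3, by = 0.3),
                          fraction_grid = seq(0, 1, by = 0.05),
                          f_mb = 0.2, n_sims = 10000L,
                          config = session_config(), seed = NULL,
                          keep_draws = TRUE) {
  stopifnot(length(total_grid) >= 1L, length(fraction_grid) >= 1L)
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, 2L * n_sims)
  cells <- expand.grid(fraction = fraction_grid, total = total_grid)
  draws <- matrix(NA_real_, n_sims, nrow(cells))
  for (s in seq_len(n_sims)) {
    map <- build_task_map(seed = seeds[2L * s - 1L])
    plan <- generate_session_plan(map, config, seed = seeds[2L * s - 1L])
    # one choice/reward stream per session, shared by every cell, so the
    # comparison across grid cells is paired
    for (j in seq_len(nrow(cells))) {
      t_ <- cells$total[j]
      p_ <- cells$fraction[j]
      theta <- pure_mb_params(
        c(t_ / 2, t_ / 2, t_ / 2, t_ / 2, p_ * t_, (1 - p_) * t_), f_mb)
      draws[s, j] <- standardized_earnings(
        simulate_session(theta, plan, seed = seeds[2L * s]))
    }
  }
  surface <- cbind(cells[, c("total", "fraction")],
                   mean = colMeans(draws),
                   sem = apply(draws, 2, sd) / sqrt(n_sims),
                   n_sims = n_sims)
  structure(list(surface = surface,
                 draws = if (keep_draws) draws else NULL,
                 f_mb = f_mb, seed = seed),
            class = "cm_earnings_grid")
}

#' @export
print.cm_earnings_grid <- function(x, ...) {
  cat("<cm_earnings_grid> ", length(unique(x$surface$total)), " totals x ",
      length(unique(x$surface$fraction)), " fractions, ",
      x$surface$n_sims[1], " sims/cell\n", sep = "")
  invisible(x)
}

#' Earnings-maximizing allocation fraction at one total MBCA
#'
#' Returns the grid fraction maximizing mean standardized earnings. Ties
#' within Monte-Carlo error are resolved by taking all fractions whose
#' paired earnings deficit relative to the best cell is within two standard
#' errors (of the paired difference, using the shared session plans) and
#' reporting the central one, i.e. the plateau's midpoint on the grid.
#'
#' @param grid A [grid_earnings()] result with `keep_draws = TRUE`.
#' @param total Which total MBCA level to use (defaults to the grid's
#'   only/first level).
#' @return The selected fraction (scalar).
#' @export
argmax_fraction <- function(grid, total = NULL) {
  stopifnot(inherits(grid, "cm_earnings_grid"))
  if (is.null(grid$draws)) stop("grid was built with keep_draws = FALSE")
  total <- total %||% grid$surface$total[1]
  sel <- which(grid$surface$total == total)
  if (!length(sel)) stop("total ", total, " not on the grid")
  draws <- grid$draws[, sel, drop = FALSE]
  fractions <- grid$surface$fraction[sel]
  means <- colMeans(draws)
  best <- which.max(means)
  tied <- vapply(seq_along(sel), function(j) {
    if (j == best) return(TRUE)
    d <- draws[, best] - draws[, j]
    mean(d) <= 2 * sd(d) / sqrt(nrow(draws))
  }, logical(1))
  cand <- sort(fractions[tied])
  cand[ceiling(length(cand) / 2)]
}

#' Robust regression of earnings on MBCA level and asymmetry
#'
#' Regresses one standardized-earnings value per participant on (1) their
#' overall MBCA level (mean of the six full-model MBCA gains) and (2) their
#' MBCA position asymmetry (mean over formats of the absolute first/second
#' gain difference), using iteratively reweighted robust M-estimation.
#'
#' @param fits List of full-model `cm_fit` objects.
#' @param earnings Numeric vector of standardized earnings, one per fit.
#' @return A list with `coefficients` (estimate, SE, t, df, p per term),
#'   `model` (the [MASS::rlm()] fit), and `data`.
#' @export
earnings_regression <- function(fits, earnings) {
  if (length(fits) != length(earnings))
    stop("one earnings value per fit required")
  if (length(fits) < 3L) stop("need at least 3 participants")
  dat <- do.call(rbind, lapply(fits, function(f) {
    mb <- f$params[.mb_names]
    data.frame(overall = mean(mb),
               asymmetry = mean(abs(mb[c(1, 3, 5)] - mb[c(2, 4, 6)])))
  }))
  dat$earnings <- earnings
  fit <- MASS::rlm(earnings ~ overall + asymmetry, data = dat, maxit = 100)
  cf <- summary(fit)$coefficients
  df <- length(earnings) - nrow(cf)
  out <- data.frame(term = rownames(cf), estimate = cf[, "Value"],
                    se = cf[, "Std. Error"], t = cf[, "t value"], df = df,
                    p = 2 * pt(-abs(cf[, "t value"]), df), row.names = NULL)
  list(coefficients = out, model = fit, data = dat)
}
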