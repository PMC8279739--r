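# Baseline earnings, standardization, the earnings surface, and the
# earnings regression.

test_that("guessing and oracle baselines obey their identities", {
  map <- build_task_map(seed = 80)
  plan <- generate_session_plan(map, tiny_config(), seed = 81)
  base <- baseline_earnings(plan)
  tr <- plan$trials
  ev <- function(p, b) sum(plan$reward_probs[b, map$pref[p, ]])
  evl <- mapply(ev, tr$left, tr$block)
  evr <- mapply(ev, tr$right, tr$block)
  # oracle >= guessing everywhere; the gap is half the absolute difference
  expect_true(all(base$oracle >= base$guessing))
  expect_equal(base$oracle - base$guessing, abs(evl - evr) / 2)

  # equal expected sums: guessing equals oracle
  plan$reward_probs[] <- 0.4
  base_eq <- baseline_earnings(plan)
  expect_equal(base_eq$guessing, base_eq$oracle)
  expect_equal(base_eq$guessing, rep(0.8, nrow(tr)))

  # worked arithmetic: offered persons share one outcome, so set the shared
  # outcome to 0.5 and the unique outcomes to 0.9 / 0.1, giving expected
  # sums 1.4 vs 0.6: guessing (1.4 + 0.6) / 2 = 1.0, oracle max = 1.4
  p1 <- tr$left[1]
  p2 <- tr$right[1]
  shared <- intersect(map$pref[p1, ], map$pref[p2, ])
  plan$reward_probs[tr$block[1], shared] <- 0.5
  plan$reward_probs[tr$block[1], setdiff(map$pref[p1, ], shared)] <- 0.9
  plan$reward_probs[tr$block[1], setdiff(map$pref[p2, ], shared)] <- 0.1
  base1 <- baseline_earnings(plan)
  expect_equal(base1$guessing[1], 1.0)
  expect_equal(base1$oracle[1], 1.4)
})

test_that("oracle play standardizes to 1 and random play to about 0", {
  set.seed(82)
  n_sessions <- 150L
  std <- vapply(seq_len(n_sessions), function(s) {
    map <- build_task_map(seed = 8200 + s)
    plan <- generate_session_plan(map, session_config(n_blocks = 4L),
                                  seed = 8200 + s)
    tr <- plan$trials
    ev <- function(p, b) sum(plan$reward_probs[b, map$pref[p, ]])
    evl <- mapply(ev, tr$left, tr$block)
    evr <- mapply(ev, tr$right, tr$block)
    fill <- function(chosen) {
      plan$trials$chosen <- chosen
      o <- ifelse(plan$trials$animal_first, 1L, 2L)
      plan$trials$outcome1 <- plan$task_map$pref[cbind(chosen, o)]
      plan$trials$outcome2 <- plan$task_map$pref[cbind(chosen, 3L - o)]
      p1 <- plan$reward_probs[cbind(tr$block, plan$trials$outcome1)]
      p2 <- plan$reward_probs[cbind(tr$block, plan$trials$outcome2)]
      plan$trials$reward1 <- rbinom(nrow(tr), 1L, p1)
      plan$trials$reward2 <- rbinom(nrow(tr), 1L, p2)
      plan
    }
    oracle_chosen <- ifelse(evl >= evr, tr$left, tr$right)
    random_chosen <- ifelse(runif(nrow(tr)) < 0.5, tr$left, tr$right)
    c(standardized_earnings(fill(oracle_chosen)),
      standardized_earnings(fill(random_chosen)))
  }, numeric(2))
  expect_lt(abs(mean(std[1, ]) - 1), 0.05)
  expect_lt(abs(mean(std[2, ])), 0.05)
})

test_that("the earnings surface is flat at zero MBCA and grows with total", {
  grid <- grid_earnings(total_grid = c(0, 1.5), fraction_grid = c(0.25, 0.5),
                        f_mb = 0.2, n_sims = 120L,
                        config = session_config(n_blocks = 4L), seed = 83)
  s <- grid$surface
  expect_true(all(abs(s$mean[s$total == 0]) < 4 * s$sem[s$total == 0]))
  expect_gt(min(s$mean[s$total == 1.5]), max(s$mean[s$total == 0]) + 0.1)
  expect_equal(nrow(grid$draws), 120L)
})

test_that("argmax selection resolves plateaus to their center", {
  grid <- structure(list(
    surface = data.frame(total = 1.5, fraction = seq(0, 1, 0.25)),
    draws = NULL), class = "cm_earnings_grid")
  # construct draws with a flat region around 0.5 and clearly worse edges
  set.seed(84)
  means <- c(0.2, 0.5, 0.5, 0.5, 0.2)
  grid$draws <- sapply(means, function(m) rnorm(400, m, 0.05))
  expect_equal(argmax_fraction(grid), 0.5)
})

test_that("yoked format agents rank regimes by their generating gains", {
  # synthetic "fits" with S > PI > RI MBCA must earn in that order
  fits <- lapply(1:4, function(i) structure(
    list(params = param_vector(c_mb = c(1.2, 1.2, 0.6, 0.6, 0.25, 0.25),
                               f_mb = 0.2)), class = "cm_fit"))
  yk <- yoked_format_agents(fits, n_sessions = 60L,
                            config = session_config(n_blocks = 4L),
                            seed = 85)
  m <- yk$summary$mean
  expect_equal(yk$summary$regime, c("S", "PI", "RI"))
  expect_gt(m[1], m[2])
  expect_gt(m[2], m[3])
})

test_that("earnings regression separates level from asymmetry", {
  set.seed(86)
  fits <- lapply(1:20, function(i) {
    lvl <- runif(1, 0.1, 0.6)
    mb <- rep(lvl, 6)
    mb[c(2, 4, 6)] <- mb[c(2, 4, 6)] + runif(3, -0.2, 0.2)
    structure(list(params = param_vector(c_mb = mb, f_mb = 0.2)),
              class = "cm_fit")
  })
  overall <- vapply(fits, function(f) mean(f$params[3:8]), numeric(1))
  earnings <- 0.2 + 0.5 * overall + rnorm(20, 0, 0.01)
  res <- earnings_regression(fits, earnings)
  cf <- res$coefficients
  expect_lt(abs(cf$estimate[cf$term == "overall"] - 0.5), 0.1)
  # no asymmetry in the generator: its coefficient is indistinguishable from 0
  expect_gt(cf$p[cf$term == "asymmetry"], 0.05)

  # duplicating every participant leaves the coefficients unchanged
  res2 <- earnings_regression(c(fits, fits), c(earnings, earnings))
  expect_equal(res2$coefficients$estimate, cf$estimate, tolerance = 1e-6)
})
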