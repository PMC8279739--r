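# Value computation, learning updates, likelihood, and simulation.

test_that("MB person values add the two outcome values and generalize", {
  map <- build_task_map(seed = 4)
  state <- init_state()
  for (p in 1:4) expect_equal(mb_person_value(state, map, p), 0)

  state$q_mb[map$pref[1, 1]] <- 0.3
  state$q_mb[map$pref[1, 2]] <- 0.1
  expect_equal(mb_person_value(state, map, 1), 0.4)

  # raising a shared outcome raises both sharers' values by the same amount
  o <- map$pref[1, 1]
  sharers <- outcome_persons(map, o)
  expect_length(sharers, 2L)
  before <- vapply(sharers, function(p) mb_person_value(state, map, p),
                   numeric(1))
  state$q_mb[o] <- state$q_mb[o] + 0.25
  after <- vapply(sharers, function(p) mb_person_value(state, map, p),
                  numeric(1))
  expect_equal(unname(after - before), c(0.25, 0.25))

  expect_error(mb_person_value(state, map, 9), "unknown person")
})

test_that("choice probabilities are a softmax of net values", {
  map <- build_task_map(seed = 4)
  pair <- map$valid_pairs[1, ]
  state <- init_state()
  expect_equal(unname(choice_probability(state, map, pair)), c(0.5, 0.5))

  d <- 0.7
  state$q_mf[pair[1]] <- d
  p <- choice_probability(state, map, pair)
  expect_equal(unname(p[1]), 1 / (1 + exp(-d)))

  # shift invariance
  state$q_mf[pair] <- state$q_mf[pair] + 3.2
  expect_equal(unname(choice_probability(state, map, pair)), unname(p))
})

test_that("learning updates follow the MF/MB/perseveration rules", {
  map <- build_task_map(seed = 4)
  theta <- param_vector(c_mf = 0.4, f_mf = 0, c_mb = 0.2, f_mb = 1,
                        pr = 0.3, f_p = 0.1)
  trial <- list(format = "S", chosen = 1L, outcome1 = map$pref[1, 1],
                outcome2 = map$pref[1, 2], reward1 = 1L, reward2 = 1L)
  state <- init_state()
  state$q_mb[] <- 0.5
  out <- update_state(state, theta, trial, map)
  # f_mf = 0, both outcomes rewarded: chosen person gains 2 * c_mf
  expect_equal(out$q_mf[1], 2 * 0.4)
  expect_equal(out$q_mf[2:4], rep(0, 3))
  # f_mb = 1: unrelated outcomes are wiped, related ones keep only the gain
  unrelated <- setdiff(1:4, map$pref[1, ])
  expect_equal(out$q_mb[unrelated], rep(0, 2))
  expect_equal(out$q_mb[map$pref[1, ]], rep(0.2, 2))
  # perseveration: decay everywhere plus the chosen-person bump
  expect_equal(out$pers[1], 0.3)

  # a missing choice triggers no update
  skip_trial <- list(format = "S", chosen = NA_integer_)
  expect_identical(update_state(state, theta, skip_trial, map), state)
})

test_that("zero credit assignment makes every choice a coin flip", {
  s <- sim_test_session(param_vector(), seed = 6, config = tiny_config())
  n <- sum(!is.na(s$trials$chosen))
  expect_equal(session_loglik(param_vector(), s), n * log(0.5))
})

test_that("likelihood is invariant to expressing a model through its spec", {
  s <- sim_test_session(seed = 7, config = tiny_config())
  free_sub <- c(c_mf = 0.35, f_mf = 0.15, pr = 0.25, f_p = 0.6)
  sub <- model_spec("pure_MF")
  expect_equal(session_loglik(free_sub, s, spec = sub),
               session_loglik(sub$expand(free_sub), s))

  # the full model is the cross-credit model with zero cross gains
  full_theta <- theta_hybrid()
  expect_equal(session_loglik(full_theta, s),
               session_loglik(unclass(full_theta), s,
                              spec = model_spec("RI_cross_CA")))
  # with nonzero cross gains the compiled likelihood still matches the
  # step-by-step R recursion (which implements the cross update separately)
  th_cross <- unclass(full_theta)
  th_cross[c("c_cross_12", "c_cross_21")] <- c(0.3, -0.2)
  expect_equal(session_loglik(th_cross, s),
               sum(loglik_trace(th_cross, s)$ll), tolerance = 1e-12)
})

test_that("equal-across-everything MBCA makes the MBCA sub-models agree", {
  s <- sim_test_session(seed = 8, config = tiny_config())
  base <- c(c_mf = 0.3, f_mf = 0.2)
  tail <- c(f_mb = 0.15, pr = 0.2, f_p = 0.5)
  cmb <- 0.27
  lls <- c(
    session_loglik(c(base, c_mb = rep(cmb, 6), tail), s,
                   spec = model_spec("full")),
    session_loglik(c(base, c_mb = cmb, tail), s,
                   spec = model_spec("no_presentation_MBCA")),
    session_loglik(c(base, c_mb = rep(cmb, 3), tail), s,
                   spec = model_spec("no_position_MBCA")),
    session_loglik(c(base, c_mb = rep(cmb, 2), tail), s,
                   spec = model_spec("no_format_MBCA")),
    session_loglik(c(base, c_mb = rep(cmb, 3), c_mb_pos2 = 0, tail), s,
                   spec = model_spec("additive_MBCA")),
    session_loglik(c(base, c_mb = rep(cmb, 2), tail), s,
                   spec = model_spec("flipped_functional")))
  expect_equal(lls, rep(lls[1], 6))
})

test_that("session log-likelihood matches a straight-line transcription", {
  # independent oracle: the update and choice equations written out plainly,
  # with no shared code with the package implementation
  map <- build_task_map(seed = 10)
  plan <- generate_session_plan(map, tiny_config(n_blocks = 2L,
                                                 trials_per_block = 12L),
                                seed = 11)
  s <- simulate_session(theta_hybrid(), plan, seed = 12)
  th <- unclass(theta_hybrid())
  tr <- s$trials

  oracle <- 0
  for (b in unique(tr$block)) {
    qmf <- rep(0, 4); qmb <- rep(0, 4); pers <- rep(0, 4)
    for (i in which(tr$block == b)) {
      l <- tr$left[i]; r <- tr$right[i]; c <- tr$chosen[i]
      qn <- function(p) qmf[p] + qmb[map$pref[p, 1]] + qmb[map$pref[p, 2]] +
        pers[p]
      pc <- exp(qn(c)) / (exp(qn(l)) + exp(qn(r)))
      oracle <- oracle + log(pc)
      r1 <- 2 * tr$reward1[i] - 1; r2 <- 2 * tr$reward2[i] - 1
      o1 <- tr$outcome1[i]; o2 <- tr$outcome2[i]
      # MF update
      qmf <- (1 - th["f_mf"]) * qmf
      qmf[c] <- qmf[c] + th["c_mf"] * (r1 + r2)
      # MB update with format x position gain
      g <- th[paste0("c_mb_", tr$format[i], 1:2)]
      qmb <- (1 - th["f_mb"]) * qmb
      qmb[o1] <- qmb[o1] + g[1] * r1
      qmb[o2] <- qmb[o2] + g[2] * r2
      # perseveration
      pers <- (1 - th["f_p"]) * pers
      pers[c] <- pers[c] + th["pr"]
    }
  }
  expect_equal(session_loglik(theta_hybrid(), s), oracle, tolerance = 1e-12)
  expect_equal(sum(loglik_trace(theta_hybrid(), s)$ll), oracle,
               tolerance = 1e-12)
})

test_that("the analytic gradient matches central differences", {
  s <- sim_test_session(seed = 13, config = tiny_config())
  th <- unclass(theta_hybrid())
  th[c("c_cross_12", "c_cross_21")] <- c(0.2, -0.1)
  g <- attr(session_loglik(th, s, gradient = TRUE), "gradient")
  num <- vapply(seq_along(th), function(k) {
    e <- th; e[k] <- e[k] + 1e-6
    e2 <- th; e2[k] <- e2[k] - 1e-6
    (session_loglik(e, s) - session_loglik(e2, s)) / 2e-6
  }, numeric(1))
  expect_equal(unname(g), num, tolerance = 1e-5)
})

test_that("simulation is reproducible and missing data never generated", {
  plan <- generate_session_plan(build_task_map(seed = 1), tiny_config(),
                                seed = 2)
  s1 <- simulate_session(theta_hybrid(), plan, seed = 3)
  s2 <- simulate_session(theta_hybrid(), plan, seed = 3)
  expect_identical(s1$trials, s2$trials)
  s3 <- simulate_session(theta_hybrid(), plan, seed = 4)
  expect_false(identical(s1$trials$chosen, s3$trials$chosen))
  expect_false(anyNA(s1$trials$chosen))
  expect_true(all(s1$trials$reward1 %in% 0:1))
})

test_that("a pure-MF agent is blind to the presentation format", {
  # MF learning uses persons and total reward only, so reshuffling which
  # trials are inference trials must not change the simulated choices
  plan <- generate_session_plan(build_task_map(seed = 15), tiny_config(),
                                seed = 16)
  plan2 <- plan
  plan2$trials$format <- rev(plan$trials$format)
  s1 <- simulate_session(theta_pure_mf(), plan, seed = 17)
  s2 <- simulate_session(theta_pure_mf(), plan2, seed = 17)
  expect_identical(s1$trials$chosen, s2$trials$chosen)
})
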