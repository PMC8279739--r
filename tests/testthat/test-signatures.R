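# Transition selectors, design coding, and the mixed-effects analyses.

test_that("every valid trial pair is a repetition or a generalization", {
  s <- sim_test_session(seed = 60)
  rep_tab <- repetition_transitions(s)
  gen_tab <- generalization_transitions(s)
  tr <- s$trials
  i <- seq_len(nrow(tr) - 1L)
  n_pairs <- sum(tr$block[i] == tr$block[i + 1L] & !is.na(tr$chosen[i]) &
                   !is.na(tr$chosen[i + 1L]))
  expect_equal(nrow(rep_tab) + nrow(gen_tab), n_pairs)
  expect_gt(nrow(rep_tab), 0L)
  expect_gt(nrow(gen_tab), 0L)
})

test_that("exactly one offered person shares an outcome on exclusion trials", {
  # exhaustive over maps: for any valid pair excluding person c, exactly one
  # of the offered persons shares exactly one outcome with c
  for (seed in 1:10) {
    map <- build_task_map(seed = seed)
    for (c in 1:4) {
      vp <- map$valid_pairs
      excl <- vp[vp[, 1] != c & vp[, 2] != c, , drop = FALSE]
      for (k in seq_len(nrow(excl))) {
        shares <- !is.na(c(shared_outcome(map, c, excl[k, 1]),
                           shared_outcome(map, c, excl[k, 2])))
        expect_equal(sum(shares), 1L)
      }
    }
  }
})

test_that("regressors take only their declared values", {
  s <- sim_test_session(seed = 61)
  rep_tab <- repetition_transitions(s)
  gen_tab <- generalization_transitions(s)
  expect_true(all(rep_tab$COMMON %in% c(-0.5, 0.5)))
  expect_true(all(rep_tab$POSITION %in% c(-0.5, 0.5)))
  expect_true(all(rep_tab$REPEAT %in% 0:1))
  expect_true(all(rep_tab$PROSPECTIVE %in% 0:1 &
                    rep_tab$RETROSPECTIVE %in% 0:1))
  expect_true(all(rep_tab$PROSPECTIVE + rep_tab$RETROSPECTIVE <= 1))
  expect_true(all(gen_tab$NON_COMMON %in% c(-0.5, 0.5)))

  full_tab <- full_transition_design(s)
  mf_cols <- grep("MF_REW", names(full_tab), value = TRUE)
  expect_length(mf_cols, 6L)
  expect_true(all(as.matrix(full_tab[mf_cols]) %in% c(-0.5, 0, 0.5)))
  expect_true(all(full_tab$PERS %in% c(-1, 0, 1)))
  expect_true(all(full_tab$MB_REW %in% c(-0.5, 0.5)))
})

test_that("MF regressors are zeroed outside their format and offer", {
  s <- sim_test_session(seed = 62)
  full_tab <- full_transition_design(s)
  mf <- as.matrix(full_tab[grep("MF_REW", names(full_tab))])
  # at most one format pair of MF regressors is nonzero per row
  active_pairs <- (mf[, 1] != 0 | mf[, 2] != 0) +
    (mf[, 3] != 0 | mf[, 4] != 0) + (mf[, 5] != 0 | mf[, 6] != 0)
  expect_true(all(active_pairs <= 1))
  # when the previous choice is not offered, everything MF-related is 0
  off <- full_tab$PERS == 0
  expect_true(all(mf[off, ] == 0))
  # the active pair matches the previous trial's format
  fmt_col <- c(S = 1L, PI = 3L, RI = 5L)[full_tab$format]
  on <- which(!off)
  expect_true(all(mf[cbind(on, fmt_col[on])] != 0))
})

test_that("mirroring the display sides flips the side-coded regressors", {
  s <- sim_test_session(seed = 63)
  flipped <- s
  flipped$trials[, c("left", "right")] <- s$trials[, c("right", "left")]
  a <- full_transition_design(s)
  b <- full_transition_design(flipped)
  expect_equal(b$MB_REW, -a$MB_REW)
  expect_equal(b$PERS, -a$PERS)
  expect_equal(b$CHOOSE_R, 1 - a$CHOOSE_R)
  # format, position, and the response-independent structure are unchanged
  expect_equal(b$POSITION, a$POSITION)
  mf_cols <- grep("MF_REW", names(a), value = TRUE)
  expect_equal(as.matrix(b[mf_cols]), -as.matrix(a[mf_cols]))
})

test_that("cross-credit selection keeps only RI trials at the right position", {
  s <- sim_test_session(seed = 64)
  ct2 <- cross_ca_transitions(s, common_position = 2L)
  expect_true(all(ct2$format == "RI"))
  expect_true(all(ct2$common_pos == 2L))
  ct1 <- cross_ca_transitions(s, common_position = 1L)
  expect_true(all(ct1$common_pos == 1L))
  gen_ri <- generalization_transitions(s)
  gen_ri <- gen_ri[gen_ri$format == "RI", ]
  expect_equal(nrow(ct1) + nrow(ct2), nrow(gen_ri))
})

test_that("reward-effect table has six bounded effects per participant", {
  cohort <- sim_point_cohort(theta_hybrid(), 3L, seed = 65)
  eff <- reward_effect_table(
    generalization_transitions(lapply(cohort, `[[`, "session")),
    "GENERALIZE")
  expect_equal(nrow(eff), 3L * 6L)
  ok <- is.finite(eff$effect)
  expect_true(all(abs(eff$effect[ok]) <= 1))
  expect_equal(sort(unique(eff$common_pos)), 1:2)
})

test_that("reward-effect model finds no structure in flat effects and
          recovers a seeded position-by-format pattern", {
  set.seed(71)
  mk_effects <- function(gen) {
    eff <- expand.grid(PART = sprintf("S%02d", 1:14),
                       format = c("S", "PI", "RI"), common_pos = 1:2,
                       stringsAsFactors = FALSE)
    eff$POSITION <- ifelse(eff$common_pos == 1L, 0.5, -0.5)
    eff$PROSPECTIVE <- as.numeric(eff$format == "PI")
    eff$RETROSPECTIVE <- as.numeric(eff$format == "RI")
    eff$effect <- gen(eff) + rnorm(nrow(eff), 0, 0.02)
    eff
  }
  # flat generator: all coefficients except the intercept are near 0
  flat <- reward_effect_model(mk_effects(function(e) 0.3),
                              re = c("intercept"))
  ct <- flat$contrasts
  expect_true(all(ct$p[ct$contrast != "intercept"] > 0.01))
  expect_lt(abs(ct$estimate[ct$contrast == "position_main"]), 0.05)
  # impair the RI second position only: position x RI interaction appears
  imp <- reward_effect_model(
    mk_effects(function(e) 0.3 - 0.2 * (e$format == "RI" &
                                          e$common_pos == 2L)),
    re = c("intercept"))
  cti <- imp$contrasts
  expect_lt(cti$p[cti$contrast == "position_x_RI_vs_S"], 0.001)
  expect_gt(cti$estimate[cti$contrast == "position_x_RI_vs_S"], 0.1)
})

test_that("mixed logistic model fits and exposes the contrast battery", {
  cohort <- sim_point_cohort(theta_hybrid(), 6L, seed = 66)
  sessions <- lapply(cohort, `[[`, "session")
  fit <- fit_mixed_logistic(generalization_transitions(sessions),
                            "GENERALIZE", re = c("intercept"))
  expect_s3_class(fit, "cm_sig_fit")
  expect_true(all(c("common_main", "common_x_format_x_position",
                    "second_outcome_RI_vs_S") %in% fit$contrasts$contrast))
  expect_true(all(fit$contrasts$p >= 0 & fit$contrasts$p <= 1,
                  na.rm = TRUE))
  # single participant: the model collapses to ordinary logistic regression
  single <- fit_mixed_logistic(repetition_transitions(sessions[[1]]),
                               "REPEAT", re = "none")
  expect_s3_class(single$model, "glm")
})

test_that("parameter-level model recovers a seeded position asymmetry", {
  # build synthetic "fits" whose RI second-position gain is lowered by delta
  set.seed(67)
  delta <- 0.3
  fits <- lapply(1:12, function(i) {
    base <- runif(1, 0.2, 0.5)
    mb <- rep(base, 6) + rnorm(6, 0, 0.02)
    mb[6] <- mb[6] - delta
    structure(list(params = param_vector(c_mf = 0.3, c_mb = mb,
                                         f_mb = 0.1, pr = 0.1, f_p = 0.1)),
              class = "cm_fit")
  })
  pm <- mbca_parameter_model(fits, re = c("intercept"))
  ct <- pm$contrasts
  # lowering RI2 only creates a positive RI x position interaction
  est <- ct$estimate[ct$contrast == "position_x_RI_vs_S"]
  expect_gt(est, 0.1)
  expect_lt(ct$p[ct$contrast == "format_x_position"], 0.05)
  # and a negative second-outcome RI-vs-S contrast of about -delta
  expect_lt(ct$estimate[ct$contrast == "second_outcome_RI_vs_S"], -0.15)

  # impairment of a parameter against itself correlates perfectly
  imp <- pm$impairment
  expect_equal(cor(imp$table$imp1, imp$table$imp1), 1)

  # the functional recoding swaps the RI gains
  pf <- mbca_parameter_model(fits, functional = TRUE, re = c("intercept"))
  tab_t <- pm$table
  tab_f <- pf$table
  expect_equal(tab_f$CA[tab_f$format == "RI" & tab_f$position == 1],
               tab_t$CA[tab_t$format == "RI" & tab_t$position == 2])
})

test_that("RT analysis filters trials and recovers an injected slowdown", {
  set.seed(68)
  cohort <- sim_point_cohort(theta_hybrid(), 8L, seed = 68)
  sessions <- lapply(cohort, function(p) {
    s <- p$session
    tr <- s$trials
    prev_same <- c(FALSE, pmin(tr$left, tr$right)[-1] ==
                     pmin(tr$left, tr$right)[-nrow(tr)] &
                     pmax(tr$left, tr$right)[-1] ==
                     pmax(tr$left, tr$right)[-nrow(tr)])
    new_trial <- !prev_same
    s$trials$rt_ms <- 600 + 120 * new_trial + rnorm(nrow(tr), 0, 30)
    s$trials$rt_ms[3] <- 100  # below the fast-guess cutoff
    s
  })
  rt <- rt_analysis(sessions, re = c("intercept"))
  expect_true(all(rt$table$MRT >= 250))
  ct <- rt$contrasts
  est <- ct$estimate[ct$contrast == "type_main"]
  expect_gt(est, 90)
  expect_lt(est, 150)
  expect_lt(ct$p[ct$contrast == "type_main"], 0.001)

  # the first trial of a block never contributes
  one <- sessions[[1]]
  one$trials$rt_ms[one$trials$trial == 1L] <- 1e6
  rt1 <- rt_analysis(one, re = "none")
  expect_true(all(rt1$table$MRT < 1e5))
})

test_that("bootstrap power is a proportion and handles tiny n_boot", {
  cohort <- sim_point_cohort(theta_hybrid(), 5L, seed = 69)
  sessions <- lapply(cohort, `[[`, "session")
  bp <- bootstrap_power(sessions, "generalization", n_boot = 2L,
                        alpha = 0.05, seed = 70)
  expect_true(bp$power %in% c(0, 0.5, 1))
  expect_length(bp$p_values, 2L)
  expect_error(bootstrap_power(sessions, "mbca_parameters", n_boot = 1L),
               "needs full-model fits")
  expect_error(credmap:::focal_p("nope", sessions, NULL), "unknown analysis")
})
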