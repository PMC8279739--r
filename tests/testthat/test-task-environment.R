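# Task map structure and session-plan statistics.

test_that("task maps satisfy the bipartite sharing structure for any seed", {
  for (seed in 1:25) {
    map <- build_task_map(seed = seed)
    # every outcome favored by exactly two persons
    counts <- tabulate(as.vector(map$pref), nbins = 4L)
    expect_equal(counts, rep(2L, 4L))
    # preference pairs are unique (injective over combos)
    expect_equal(nrow(unique(map$pref)), 4L)
    # exactly 4 pairs share exactly one outcome, 2 share none
    pairs <- t(combn(4L, 2L))
    n_shared <- apply(pairs, 1L, function(pq)
      length(intersect(map$pref[pq[1], ], map$pref[pq[2], ])))
    expect_equal(sum(n_shared == 1L), 4L)
    expect_equal(sum(n_shared == 0L), 2L)
    expect_equal(nrow(map$valid_pairs), 4L)
  }
})

test_that("task map construction is deterministic under a fixed seed", {
  expect_identical(build_task_map(seed = 7), build_task_map(seed = 7))
  maps <- vapply(1:50, function(s)
    paste(build_task_map(seed = s)$pref, collapse = ","), character(1))
  expect_gt(length(unique(maps)), 1L)  # the randomization actually varies
})

test_that("session plans allocate pairs exactly equally within blocks", {
  map <- build_task_map(seed = 3)
  plan <- generate_session_plan(map, session_config(), seed = 11)
  expect_equal(nrow(plan$trials), 360L)
  key <- paste(pmin(plan$trials$left, plan$trials$right),
               pmax(plan$trials$left, plan$trials$right))
  tab <- table(plan$trials$block, key)
  expect_true(all(tab == 9L))
  expect_equal(ncol(tab), 4L)

  # minimal allocation: each pair exactly once per block
  plan4 <- generate_session_plan(map, tiny_config(trials_per_block = 4L),
                                 seed = 12)
  tab4 <- table(plan4$trials$block,
                paste(pmin(plan4$trials$left, plan4$trials$right),
                      pmax(plan4$trials$left, plan4$trials$right)))
  expect_true(all(tab4 == 1L))
})

test_that("invalid configurations are rejected", {
  expect_error(session_config(trials_per_block = 10), "divisible by 4")
  expect_error(session_config(format_probs = c(0.5, 0.5, 0.5)), "sum to 1")
})

test_that("format frequencies match the format probabilities", {
  map <- build_task_map(seed = 5)
  counts <- c(S = 0, PI = 0, RI = 0)
  n_sessions <- 100L
  for (s in seq_len(n_sessions)) {
    plan <- generate_session_plan(map, tiny_config(), seed = 1000 + s)
    tb <- table(factor(plan$trials$format, levels = c("S", "PI", "RI")))
    counts <- counts + as.numeric(tb)
  }
  gof <- chisq.test(counts, p = rep(1 / 3, 3))
  expect_gt(gof$p.value, 0.001)
})

test_that("reward probabilities are uniform on the range and independent", {
  probs <- vapply(1:200, function(s) {
    plan <- generate_session_plan(build_task_map(seed = s),
                                  tiny_config(), seed = s)
    plan$reward_probs[1, 1:2]
  }, numeric(2))
  expect_true(all(probs >= 0.2 & probs <= 0.8))
  expect_lt(abs(cor(probs[1, ], probs[2, ])), 0.2)
})

test_that("rewards are realized from the block's outcome probabilities", {
  map <- build_task_map(seed = 2)
  plan <- generate_session_plan(map, tiny_config(), seed = 9)

  plan$reward_probs[] <- 1
  r <- realize_rewards(plan, plan$trials$left[1], 1L)
  expect_equal(c(r$reward1, r$reward2), c(1L, 1L))
  plan$reward_probs[] <- 0
  r <- realize_rewards(plan, plan$trials$left[1], 1L)
  expect_equal(c(r$reward1, r$reward2), c(0L, 0L))

  plan$reward_probs[] <- 0.3
  set.seed(42)
  draws <- replicate(10000, realize_rewards(plan, plan$trials$left[1],
                                            1L)$reward1)
  expect_lt(abs(mean(draws) - 0.3), 0.02)

  not_offered <- setdiff(1:4, c(plan$trials$left[1], plan$trials$right[1]))
  expect_error(realize_rewards(plan, not_offered[1], 1L), "not offered")
})

test_that("synthetic cohorts record their generating parameters", {
  cohort <- sim_point_cohort(theta_hybrid(), 3L, seed = 21,
                             config = tiny_config())
  expect_length(cohort, 3L)
  for (p in cohort) {
    expect_s3_class(p$session, "cm_session")
    expect_identical(unclass(p$params), unclass(theta_hybrid()))
    expect_false(anyNA(p$session$trials$chosen))
  }
  # participants get distinct maps/plans but the same seed reproduces all
  cohort2 <- sim_point_cohort(theta_hybrid(), 3L, seed = 21,
                              config = tiny_config())
  expect_identical(cohort[[2]]$session$trials, cohort2[[2]]$session$trials)
  expect_false(identical(cohort[[1]]$session$trials$left,
                         cohort[[2]]$session$trials$left) &&
                 identical(cohort[[1]]$session$task_map$pref,
                           cohort[[2]]$session$task_map$pref))
})
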