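# Session plans, reward realization, and synthetic cohorts.

#' Session configuration
#'
#' Defaults reproduce the experimental schedule: 10 blocks of 36 bandit
#' trials, the four valid person pairs each offered 9 times per block in
#' random order, the three presentation formats (S, PI, RI) interleaved with
#' equal probability, and block-wise constant outcome reward probabilities
#' drawn independently and uniformly from `[0.2, 0.8]`.
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block; must be divisible by 4 so the
#'   four valid pairs can be offered equally often.
#' @param reward_prob_low,reward_prob_high Bounds of the uniform distribution
#'   of per-block outcome reward probabilities.
#' @param format_probs Probabilities of the S, PI, and RI presentation
#'   formats; must sum to 1.
#' @param choice_deadline Response deadline in seconds (metadata only).
#' @param rng_seed Optional default seed used by [generate_session_plan()].
#' @return An object of class `cm_session_config`.
#' @export
session_config <- function(n_blocks = 10L, trials_per_block = 36L,
                           reward_prob_low = 0.2, reward_prob_high = 0.8,
                           format_probs = c(S = 1, PI = 1, RI = 1) / 3,
                           choice_deadline = 2.0, rng_seed = NULL) {
  n_blocks <- as.integer(n_blocks)
  trials_per_block <- as.integer(trials_per_block)
  if (n_blocks < 1L || trials_per_block < 4L)
    stop("need at least 1 block and 4 trials per block")
  if (trials_per_block %% 4L != 0L)
    stop("trials_per_block must be divisible by 4 (equal allocation to the ",
         "4 valid pairs)")
  stopifnot(length(format_probs) == 3L, all(format_probs >= 0))
  if (abs(sum(format_probs) - 1) > 1e-8)
    stop("format_probs must sum to 1")
  stopifnot(reward_prob_low >= 0, reward_prob_high <= 1,
            reward_prob_low <= reward_prob_high)
  structure(list(n_blocks = n_blocks, trials_per_block = trials_per_block,
                 reward_prob_low = reward_prob_low,
                 reward_prob_high = reward_prob_high,
                 format_probs = setNames(as.numeric(format_probs),
                                         c("S", "PI", "RI")),
                 choice_deadline = choice_deadline, rng_seed = rng_seed),
            class = "cm_session_config")
}

cm_formats <- c("S", "PI", "RI")

#' Generate a session plan (choices and rewards unfilled)
#'
#' Lays out one synthetic session: per block, each of the four valid person
#' pairs is offered exactly `trials_per_block / 4` times in random order with
#' uniformly randomized display sides; each trial's presentation format is
#' drawn iid from `config$format_probs`; the temporal order of the chosen
#' person's two outcomes is uniform per trial; and each block draws fresh
#' iid-uniform reward probabilities for the four outcomes.
#'
#' The session seed deterministically derives separate sub-streams for pair
#' order, display sides, formats, outcome order, and reward probabilities.
#'
#' @param map A [build_task_map()] object.
#' @param config A [session_config()] object.
#' @param seed Integer seed (defaults to `config$rng_seed`, or a random seed).
#' @param participant Participant label stored with the session.
#' @return An object of class `cm_session`: a list with `task_map`, `config`,
#'   `participant`, `seed`, `reward_probs` (an `n_blocks` x 4 matrix), and
#'   `trials`, a data frame with one row per trial and columns `block`,
#'   `trial` (1-based within block), `left`, `right` (person ids), `format`
#'   ("S"/"PI"/"RI"), `animal_first` (planned temporal outcome order),
#'   `chosen`, `outcome1`, `outcome2`, `reward1`, `reward2`, `rt_ms` (all
#'   `NA` until filled by [simulate_session()] or a data loader).
#' @export
generate_session_plan <- function(map, config = session_config(),
                                  seed = NULL, participant = "synthetic") {
  stopifnot(inherits(map, "cm_task_map"), inherits(config, "cm_session_config"))
  seed <- seed %||% config$rng_seed %||% draw_seed()
  sub <- derive_seeds(seed, 5L)
  nb <- config$n_blocks
  tpb <- config$trials_per_block
  n <- nb * tpb
  vp <- map$valid_pairs

  pair_idx <- with_seed(sub[1], unlist(lapply(seq_len(nb), function(b)
    sample(rep(seq_len(4L), tpb / 4L)))))
  left_first <- with_seed(sub[2], runif(n) < 0.5)
  format <- cm_formats[with_seed(sub[3],
    sample.int(3L, n, replace = TRUE, prob = config$format_probs))]
  animal_first <- with_seed(sub[4], runif(n) < 0.5)
  reward_probs <- with_seed(sub[5], matrix(
    runif(nb * 4L, config$reward_prob_low, config$reward_prob_high),
    nrow = nb, dimnames = list(NULL, c("A1", "A2", "V1", "V2"))))

  left <- ifelse(left_first, vp[pair_idx, 1], vp[pair_idx, 2])
  right <- ifelse(left_first, vp[pair_idx, 2], vp[pair_idx, 1])
  trials <- data.frame(
    block = rep(seq_len(nb), each = tpb),
    trial = rep(seq_len(tpb), nb),
    left = as.integer(left), right = as.integer(right),
    format = format, animal_first = animal_first,
    chosen = NA_integer_, outcome1 = NA_integer_, outcome2 = NA_integer_,
    reward1 = NA_integer_, reward2 = NA_integer_, rt_ms = NA_real_
  )
  structure(list(task_map = map, config = config, participant = participant,
                 seed = seed, reward_probs = reward_probs, trials = trials),
            class = "cm_session")
}

#' @export
print.cm_session <- function(x, ...) {
  n <- nrow(x$trials)
  filled <- sum(!is.na(x$trials$chosen))
  cat("<cm_session> participant ", x$participant, ": ", x$config$n_blocks,
      " blocks x ", x$config$trials_per_block, " trials (", n, " total, ",
      filled, " with choices)\n", sep = "")
  invisible(x)
}

#' Realize the two outcome rewards for a chosen person on one trial
#'
#' Each reward is an independent Bernoulli draw with the trial's block-level
#' probability for the corresponding outcome, bound to the trial's planned
#' temporal outcome order. Draws come from the current RNG stream.
#'
#' @param session A `cm_session`.
#' @param chosen Person id; must be one of the trial's offered pair.
#' @param trial_idx Row index into `session$trials`.
#' @return A list with `outcome1`, `outcome2` (outcome ids in temporal
#'   order) and `reward1`, `reward2` (0/1).
#' @export
realize_rewards <- function(session, chosen, trial_idx) {
  tr <- session$trials[trial_idx, ]
  if (!chosen %in% c(tr$left, tr$right))
    stop("chosen person ", chosen, " is not offered on trial ", trial_idx)
  pref <- session$task_map$pref
  oa <- pref[chosen, 1]
  ov <- pref[chosen, 2]
  o1 <- if (tr$animal_first) oa else ov
  o2 <- if (tr$animal_first) ov else oa
  p <- session$reward_probs[tr$block, ]
  list(outcome1 = as.integer(o1), outcome2 = as.integer(o2),
       reward1 = rbinom(1L, 1L, p[o1]), reward2 = rbinom(1L, 1L, p[o2]))
}

#' Simulate choices and rewards on a session plan
#'
#' Plays the hybrid model forward through the plan: on every trial the choice
#' is sampled from the softmax over the two offered persons' net values,
#' rewards are realized from the block's outcome probabilities, and the
#' latent values are updated (with a reset at each block boundary).
#'
#' @param params Either a full `cm_params` vector or a free-parameter vector
#'   for `spec`.
#' @param plan A `cm_session` plan from [generate_session_plan()].
#' @param spec A [model_spec()]; only used to expand `params` when a free
#'   vector is given. The cross-credit gains in the expanded vector fully
#'   determine the update rule, so the same simulator serves all model
#'   variants.
#' @param seed Optional seed for the choice/reward draws.
#' @return The plan with `chosen`, `outcome1/2`, and `reward1/2` filled.
#' @export
simulate_session <- function(params, plan, spec = NULL, seed = NULL) {
  stopifnot(inherits(plan, "cm_session"))
  theta <- resolve_params(params, spec)
  tr <- plan$trials
  sim <- with_seed(seed, cm_simulate_cpp(
    unclass(theta), tr$block, tr$left, tr$right,
    match(tr$format, cm_formats), tr$animal_first,
    plan$task_map$pref, plan$reward_probs))
  tr$chosen <- sim$chosen
  tr$outcome1 <- sim$outcome1
  tr$outcome2 <- sim$outcome2
  tr$reward1 <- sim$reward1
  tr$reward2 <- sim$reward2
  plan$trials <- tr
  plan
}

resolve_params <- function(params, spec = NULL) {
  if (inherits(params, "cm_params")) return(params)
  if (is.numeric(params) && length(params) == 13L)
    return(as_param_vector(params))
  if (is.null(spec))
    stop("params is not a full 13-entry vector; supply its model spec")
  validate_params(spec$expand(params))
}

#' Sample plausible generating parameters for synthetic participants
#'
#' Draws one full parameter vector per participant from distributions chosen
#' to resemble fitted human behavior on this task: MBCA gains normal with
#' mean 0.2 and across-participant standard deviation 0.22 (the group-level
#' gain estimates on this task are about 0.1-0.3 with an implied
#' between-participant SD of about 0.22; occasional negative gains occur,
#' which is why the exclusion rule exists), a moderate positive MFCA gain,
#' mild-to-moderate forgetting, and a weak perseveration tendency. Used as
#' the default generator for recovery studies and synthetic cohorts; see the
#' methods vignette for the derivation.
#'
#' @param n Number of parameter vectors.
#' @return A list of `cm_params` vectors.
#' @export
sample_plausible_params <- function(n) {
  lapply(seq_len(n), function(i) param_vector(
    c_mf = stats::rnorm(1, 0.3, 0.2),
    f_mf = runif(1, 0.05, 0.5),
    c_mb = stats::rnorm(6, 0.2, 0.22),
    f_mb = runif(1, 0.05, 0.5),
    pr = runif(1, 0, 0.4),
    f_p = runif(1, 0.2, 0.8)
  ))
}

#' Generate a synthetic cohort with recorded generating parameters
#'
#' One full session per synthetic participant: a fresh task map (the
#' person-outcome mapping is randomized anew per participant), a fresh
#' session plan, and choices/rewards simulated from parameters drawn by
#' `param_sampler`.
#'
#' @param n_participants Cohort size.
#' @param param_sampler Function of `n` returning a list of parameter
#'   vectors (full `cm_params`, or free vectors for `spec`). Defaults to
#'   [sample_plausible_params()].
#' @param config A [session_config()].
#' @param seed Master seed; participant-level seeds are derived from it.
#' @param spec Optional [model_spec()] used to expand free vectors.
#' @return A list with one element per participant, each a list of
#'   `session` (a simulated `cm_session`) and `params` (the generating
#'   `cm_params`).
#' @export
generate_synthetic_cohort <- function(n_participants,
                                      param_sampler = sample_plausible_params,
                                      config = session_config(),
                                      seed = NULL, spec = NULL) {
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, 2L * n_participants + 1L)
  params <- with_seed(seeds[1], param_sampler(n_participants))
  lapply(seq_len(n_participants), function(i) {
    theta <- resolve_params(params[[i]], spec)
    map <- build_task_map(seed = seeds[2L * i])
    plan <- generate_session_plan(map, config, seed = seeds[2L * i],
                                  participant = sprintf("S%03d", i))
    session <- simulate_session(theta, plan, seed = seeds[2L * i + 1L])
    list(session = session, params = theta)
  })
}
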