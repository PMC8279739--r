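# Latent state, choice rule, learning updates, and session log-likelihood.
#
# The per-trial R functions below (init_state, mb_person_value,
# choice_probability, update_state) define the model one step at a time and
# are used for inspection, traces, and simulation-free analyses. The session
# log-likelihood used by the fitting routines runs the same recursion in
# compiled code with an analytic gradient.

#' Fresh latent state
#'
#' All person-level MF values, outcome-level MB values, and perseveration
#' values start at 0; the state is reset at the beginning of every block.
#'
#' @return A list with numeric vectors `q_mf` (4 persons), `q_mb`
#'   (4 outcomes), `pers` (4 persons).
#' @export
init_state <- function() {
  list(q_mf = numeric(4L), q_mb = numeric(4L), pers = numeric(4L))
}

#' Model-based value of a person
#'
#' The on-demand MB valuation: the sum of the MB values of the person's two
#' preferred outcomes. Because outcomes are shared, an update to a shared
#' outcome moves both sharers' values equally.
#'
#' @param state A latent state, see [init_state()].
#' @param map A [build_task_map()] object.
#' @param person Person id (1:4).
#' @return Numeric value.
#' @export
mb_person_value <- function(state, map, person) {
  if (!(is.numeric(person) && length(person) == 1L && person %in% 1:4))
    stop("unknown person: ", person)
  sum(state$q_mb[map$pref[person, ]])
}

q_net <- function(state, map, person) {
  state$q_mf[person] + mb_person_value(state, map, person) +
    state$pers[person]
}

#' Softmax choice probabilities for an offered pair
#'
#' The net value of each offered person is the sum of their MF, MB, and
#' perseveration values; choice probabilities are the softmax of the two net
#' values. There is no inverse-temperature parameter; the choice scale is
#' absorbed by the credit-assignment gains.
#'
#' @inheritParams mb_person_value
#' @param pair Integer vector of the two offered persons.
#' @return Named numeric vector of the two choice probabilities (sums to 1).
#' @export
choice_probability <- function(state, map, pair) {
  stopifnot(length(pair) == 2L)
  q <- vapply(pair, function(p) q_net(state, map, p), numeric(1))
  z <- q - max(q)  # log-sum-exp guard
  p <- exp(z) / sum(exp(z))
  setNames(p, map$persons[pair])
}

#' Apply one trial's learning update to the latent state
#'
#' Implements the three value-update rules after a completed trial:
#' * MF: the chosen person's value decays by `1 - f_mf` and is reinforced by
#'   `c_mf` times the total signed reward (each reward coded +1/-1); the
#'   three non-chosen persons only decay.
#' * MB: each of the chosen person's two outcomes decays by `1 - f_mb` and is
#'   reinforced by its own signed reward times the MBCA gain for the trial's
#'   format and the outcome's temporal position; the two unrelated outcomes
#'   only decay. On retrospective-inference trials, nonzero cross-credit
#'   gains additionally let each reward reinforce the other outcome.
#' * Perseveration: all four persons decay by `1 - f_p` and the chosen
#'   person gains `pr`.
#'
#' Trials without a recorded choice trigger no update.
#'
#' @inheritParams mb_person_value
#' @param params A full `cm_params` vector.
#' @param trial One row of a session's `trials` data frame (or any list with
#'   fields `format`, `chosen`, `outcome1`, `outcome2`, `reward1`,
#'   `reward2`; rewards binary 0/1).
#' @return The updated state.
#' @export
update_state <- function(state, params, trial, map) {
  params <- as_param_vector(params)
  if (is.na(trial$chosen)) return(state)
  chosen <- trial$chosen
  r1 <- 2 * trial$reward1 - 1
  r2 <- 2 * trial$reward2 - 1

  q_mf <- (1 - params["f_mf"]) * state$q_mf
  q_mf[chosen] <- q_mf[chosen] + params["c_mf"] * (r1 + r2)

  q_mb <- (1 - params["f_mb"]) * state$q_mb
  o1 <- trial$outcome1
  o2 <- trial$outcome2
  if (trial$format == "RI") {
    q_mb[o1] <- q_mb[o1] + params["c_mb_RI1"] * r1 + params["c_cross_21"] * r2
    q_mb[o2] <- q_mb[o2] + params["c_mb_RI2"] * r2 + params["c_cross_12"] * r1
  } else {
    g <- paste0("c_mb_", trial$format, 1:2)
    q_mb[o1] <- q_mb[o1] + params[g[1]] * r1
    q_mb[o2] <- q_mb[o2] + params[g[2]] * r2
  }

  pers <- (1 - params["f_p"]) * state$pers
  pers[chosen] <- pers[chosen] + params["pr"]

  list(q_mf = unname(q_mf), q_mb = unname(q_mb), pers = unname(pers))
}

session_arrays <- function(session) {
  tr <- session$trials
  has_choice <- !is.na(tr$chosen)
  list(
    block = tr$block,
    left = tr$left, right = tr$right,
    chosen = ifelse(has_choice, tr$chosen, 0L),
    fmt = match(tr$format, cm_formats),
    o1 = ifelse(has_choice, tr$outcome1, 1L),
    o2 = ifelse(has_choice, tr$outcome2, 1L),
    r1 = ifelse(has_choice, 2 * tr$reward1 - 1, 0),
    r2 = ifelse(has_choice, 2 * tr$reward2 - 1, 0)
  )
}

#' Session log-likelihood of observed choices
#'
#' Sums the log softmax probability of every observed choice, applying the
#' learning update after each trial and resetting the latent state at block
#' boundaries. Trials with missing choices contribute nothing and trigger no
#' update. Deterministic in its inputs.
#'
#' @param params A full `cm_params` vector, or a free vector for `spec`.
#' @param session A `cm_session` with choices and rewards filled.
#' @param spec Optional [model_spec()] used to expand a free vector.
#' @param gradient If `TRUE`, also return the analytic gradient with respect
#'   to the 13 canonical parameters.
#' @return The log-likelihood (a scalar), with attribute `"gradient"` when
#'   requested.
#' @export
session_loglik <- function(params, session, spec = NULL, gradient = FALSE) {
  theta <- resolve_params(params, spec)
  a <- session_arrays(session)
  out <- cm_loglik_cpp(unclass(theta), a$block, a$left, a$right, a$chosen,
                       a$fmt, a$o1, a$o2, a$r1, a$r2, session$task_map$pref,
                       gradient)
  ll <- out$loglik
  if (gradient)
    attr(ll, "gradient") <- setNames(out$gradient, cm_param_names)
  ll
}

#' Per-trial likelihood trace
#'
#' Replays a session through the step-by-step R implementation and records,
#' for every trial, the offered persons' net values, the probability of the
#' observed choice, and its log-likelihood contribution. Intended for
#' debugging and audit; the summed trace equals [session_loglik()].
#'
#' @inheritParams session_loglik
#' @return A data frame with one row per trial.
#' @export
loglik_trace <- function(params, session, spec = NULL) {
  theta <- resolve_params(params, spec)
  tr <- session$trials
  map <- session$task_map
  state <- init_state()
  last_block <- -1L
  rows <- lapply(seq_len(nrow(tr)), function(i) {
    t1 <- tr[i, ]
    if (t1$block != last_block) {
      state <<- init_state()
      last_block <<- t1$block
    }
    q <- vapply(c(t1$left, t1$right), function(p) q_net(state, map, p),
                numeric(1))
    if (!is.na(t1$chosen)) {
      pc <- choice_probability(state, map, c(t1$left, t1$right))
      p_obs <- unname(pc[which(c(t1$left, t1$right) == t1$chosen)])
      state <<- update_state(state, theta, t1, map)
    } else {
      p_obs <- NA_real_
    }
    data.frame(block = t1$block, trial = t1$trial, q_left = q[1],
               q_right = q[2], p_chosen = p_obs,
               ll = ifelse(is.na(p_obs), 0, log(p_obs)))
  })
  do.call(rbind, rows)
}
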