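# Model-agnostic trial-transition datasets: choice repetition, choice
# generalization, the full-transition design, and the cross-credit subset.
#
# Coding conventions follow the original analyses: reward regressors are
# +0.5 (reward) / -0.5 (non-reward); PROSPECTIVE/RETROSPECTIVE are 0/1
# dummies with the standard format as reference. The serial-position coding
# differs by analysis (+0.5 = first in the repetition/generalization and
# parameter analyses; -0.5 = first in the full-transition design); tables
# store the temporal position and apply the per-analysis coding when built.
# Transitions never cross block boundaries (values reset between blocks).

as_session_list <- function(sessions) {
  if (inherits(sessions, "cm_session")) list(sessions) else sessions
}

# All consecutive within-block trial pairs with valid choices on both.
session_transitions <- function(session) {
  tr <- session$trials
  n <- nrow(tr)
  i <- seq_len(n - 1L)
  ok <- tr$block[i] == tr$block[i + 1L] & !is.na(tr$chosen[i]) &
    !is.na(tr$chosen[i + 1L])
  i <- i[ok]
  data.frame(
    PART = session$participant,
    prev_format = tr$format[i], prev_chosen = tr$chosen[i],
    prev_o1 = tr$outcome1[i], prev_o2 = tr$outcome2[i],
    prev_r1 = tr$reward1[i], prev_r2 = tr$reward2[i],
    next_left = tr$left[i + 1L], next_right = tr$right[i + 1L],
    next_chosen = tr$chosen[i + 1L]
  )
}

format_dummies <- function(format) {
  data.frame(PROSPECTIVE = as.numeric(format == "PI"),
             RETROSPECTIVE = as.numeric(format == "RI"))
}

#' Choice-repetition transitions (MFCA signature)
#'
#' Keeps trial pairs (n, n+1) where trial n+1 offers the person chosen on
#' trial n. The two offered persons share exactly one outcome (the common
#' outcome); its trial-n reward defines `COMMON`. Because a common-outcome
#' reward raises both offered persons' MB values equally, it cancels from MB
#' choice tendencies, so a positive `COMMON` effect on `REPEAT` isolates
#' model-free credit assignment.
#'
#' @param sessions A `cm_session` or list of them.
#' @return A data frame with columns `PART`, `REPEAT` (0/1), `COMMON`
#'   (+/-0.5), `POSITION` (+0.5 = common outcome first on trial n, -0.5 =
#'   second), `PROSPECTIVE`, `RETROSPECTIVE` (trial-n format dummies), and
#'   bookkeeping columns `format` and `common_pos`.
#' @export
repetition_transitions <- function(sessions) {
  sessions <- as_session_list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    tt <- session_transitions(s)
    keep <- tt$prev_chosen == tt$next_left | tt$prev_chosen == tt$next_right
    tt <- tt[keep, , drop = FALSE]
    if (!nrow(tt)) return(NULL)
    other <- tt$next_left + tt$next_right - tt$prev_chosen
    common <- mapply(shared_outcome, list(s$task_map), tt$prev_chosen, other)
    first <- common == tt$prev_o1
    r_common <- ifelse(first, tt$prev_r1, tt$prev_r2)
    cbind(data.frame(
      PART = tt$PART,
      REPEAT = as.numeric(tt$next_chosen == tt$prev_chosen),
      COMMON = r_common - 0.5,
      POSITION = ifelse(first, 0.5, -0.5),
      format = tt$prev_format, common_pos = ifelse(first, 1L, 2L)
    ), format_dummies(tt$prev_format))
  }))
}

#' Choice-generalization transitions (MBCA signature)
#'
#' Keeps trial pairs where trial n+1 excludes the person chosen on trial n.
#' By the task's structure, exactly one offered person (the generalization
#' person) then shares exactly one outcome with the previous choice; its
#' trial-n reward defines `COMMON`. Only model-based credit assignment
#' propagates that reward to the generalization person, so a positive
#' `COMMON` effect on `GENERALIZE` isolates MBCA.
#'
#' @inheritParams repetition_transitions
#' @return As [repetition_transitions()], with response `GENERALIZE` and an
#'   additional column `NON_COMMON` (+/-0.5): the trial-n reward of the
#'   previous choice's *other* outcome, used by the cross-credit analysis.
#' @export
generalization_transitions <- function(sessions) {
  sessions <- as_session_list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    tt <- session_transitions(s)
    keep <- tt$prev_chosen != tt$next_left & tt$prev_chosen != tt$next_right
    tt <- tt[keep, , drop = FALSE]
    if (!nrow(tt)) return(NULL)
    shared_l <- mapply(shared_outcome, list(s$task_map), tt$prev_chosen,
                       tt$next_left)
    shared_r <- mapply(shared_outcome, list(s$task_map), tt$prev_chosen,
                       tt$next_right)
    gen_is_left <- !is.na(shared_l)
    gen <- ifelse(gen_is_left, tt$next_left, tt$next_right)
    common <- ifelse(gen_is_left, shared_l, shared_r)
    first <- common == tt$prev_o1
    r_common <- ifelse(first, tt$prev_r1, tt$prev_r2)
    r_noncommon <- ifelse(first, tt$prev_r2, tt$prev_r1)
    cbind(data.frame(
      PART = tt$PART,
      GENERALIZE = as.numeric(tt$next_chosen == gen),
      COMMON = r_common - 0.5,
      NON_COMMON = r_noncommon - 0.5,
      POSITION = ifelse(first, 0.5, -0.5),
      format = tt$prev_format, common_pos = ifelse(first, 1L, 2L)
    ), format_dummies(tt$prev_format))
  }))
}

#' Full-transition design (joint MBCA and MFCA regressors)
#'
#' Uses every valid consecutive trial pair. Exactly one of the two trial-n
#' outcomes (the unique outcome) relates to exactly one of the two persons
#' offered on trial n+1; `MB_REW` codes whether its trial-n reward favors
#' the right-side person (+0.5) or the left-side person (-0.5). Six
#' format-by-position model-free reward regressors code the trial-n rewards
#' when the previously chosen person is offered again (sign-flipped when
#' that person sits on the left), and are all 0 otherwise. `PERS` codes the
#' previously chosen person's display side (1 = right, -1 = left, 0 = not
#' offered). The response `CHOOSE_R` is 1 when the right-side person is
#' chosen.
#'
#' @inheritParams repetition_transitions
#' @return A data frame with columns `PART`, `CHOOSE_R`, `MB_REW`,
#'   `POSITION` (-0.5 = unique outcome first on trial n, +0.5 = second),
#'   `PROSPECTIVE`, `RETROSPECTIVE`, `MF_REW1`, `MF_REW2`,
#'   `PROSPECTIVE_MF_REW1`, `PROSPECTIVE_MF_REW2`, `RETROSPECTIVE_MF_REW1`,
#'   `RETROSPECTIVE_MF_REW2`, `PERS`.
#' @export
full_transition_design <- function(sessions) {
  sessions <- as_session_list(sessions)
  do.call(rbind, lapply(sessions, function(s) {
    tt <- session_transitions(s)
    if (!nrow(tt)) return(NULL)
    pref <- s$task_map$pref
    relates <- function(o, p) pref[p, 1] == o | pref[p, 2] == o
    n_rel_o1 <- mapply(function(o, l, r) relates(o, l) + relates(o, r),
                       tt$prev_o1, tt$next_left, tt$next_right)
    unique_is_o1 <- n_rel_o1 == 1L
    u <- ifelse(unique_is_o1, tt$prev_o1, tt$prev_o2)
    ur <- ifelse(unique_is_o1, tt$prev_r1, tt$prev_r2)
    rel_right <- mapply(relates, u, tt$next_right)
    mb_rew <- ifelse((rel_right & ur == 1L) | (!rel_right & ur == 0L),
                     0.5, -0.5)

    offered <- tt$prev_chosen == tt$next_left |
      tt$prev_chosen == tt$next_right
    side <- ifelse(tt$prev_chosen == tt$next_right, 1, -1)
    side[!offered] <- 0
    mf <- matrix(0, nrow(tt), 6L,
                 dimnames = list(NULL, c(
                   "MF_REW1", "MF_REW2", "PROSPECTIVE_MF_REW1",
                   "PROSPECTIVE_MF_REW2", "RETROSPECTIVE_MF_REW1",
                   "RETROSPECTIVE_MF_REW2")))
    col1 <- c(S = 1L, PI = 3L, RI = 5L)[tt$prev_format]
    idx <- which(offered)
    mf[cbind(idx, col1[idx])] <- side[idx] * (tt$prev_r1[idx] - 0.5)
    mf[cbind(idx, col1[idx] + 1L)] <- side[idx] * (tt$prev_r2[idx] - 0.5)

    cbind(data.frame(
      PART = tt$PART,
      CHOOSE_R = as.numeric(tt$next_chosen == tt$next_right),
      MB_REW = mb_rew,
      POSITION = ifelse(unique_is_o1, -0.5, 0.5),
      format = tt$prev_format
    ), format_dummies(tt$prev_format), as.data.frame(mf),
    data.frame(PERS = side))
  }))
}

#' Cross-credit transitions on retrospective-inference trials
#'
#' Restricts the generalization transitions to pairs whose trial n was in
#' the retrospective-inference format with the (n+1)-common outcome at the
#' requested temporal position. With `common_position = 2` (the main
#' analysis) the common outcome was seen and the non-common outcome hidden;
#' a positive effect of the hidden outcome's reward (`NON_COMMON`) on
#' generalization would indicate credit leaking across outcomes, as
#' predicted by online belief-state credit assignment.
#'
#' @inheritParams repetition_transitions
#' @param common_position Temporal position (1 or 2) of the common outcome
#'   on trial n.
#' @return The filtered generalization table.
#' @export
cross_ca_transitions <- function(sessions, common_position = 2L) {
  stopifnot(common_position %in% 1:2)
  gt <- generalization_transitions(sessions)
  gt[gt$format == "RI" & gt$common_pos == common_position, , drop = FALSE]
}

#' Per-participant common-reward effect table
#'
#' For each participant, presentation format, and common-outcome serial
#' position, the difference in response probability between common-reward
#' and common-non-reward transitions (each participant contributes 6
#' effects, all in `[-1, 1]`).
#'
#' @param table A [repetition_transitions()] or
#'   [generalization_transitions()] table.
#' @param response Response column name (`"REPEAT"` or `"GENERALIZE"`).
#' @return A data frame with `PART`, `format`, `common_pos`, `POSITION`
#'   (+0.5 first / -0.5 second), `PROSPECTIVE`, `RETROSPECTIVE`, `effect`,
#'   and the cell counts `n_reward`, `n_nonreward`. Cells with no
#'   observations yield `NA` effects.
#' @export
reward_effect_table <- function(table, response = "GENERALIZE") {
  stopifnot(response %in% names(table))
  cells <- expand.grid(PART = unique(table$PART), format = cm_formats,
                       common_pos = 1:2, stringsAsFactors = FALSE)
  eff <- mapply(function(pt, fm, cp) {
    sub <- table[table$PART == pt & table$format == fm &
                   table$common_pos == cp, ]
    rew <- sub[[response]][sub$COMMON > 0]
    non <- sub[[response]][sub$COMMON < 0]
    c(effect = mean(rew) - mean(non), n_reward = length(rew),
      n_nonreward = length(non))
  }, cells$PART, cells$format, cells$common_pos)
  out <- cbind(cells, t(eff))
  out$POSITION <- ifelse(out$common_pos == 1L, 0.5, -0.5)
  cbind(out, format_dummies(out$format))
}
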