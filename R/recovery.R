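# Parameter recovery and estimation-error trade-offs for the full model.

#' Parameter recovery study
#'
#' For every participant in a synthetic cohort and every repetition,
#' simulates a fresh dataset (new session plan, same task map and
#' configuration) from the participant's generating parameters under the
#' full model, refits the full model, and summarizes recovery: the Pearson
#' correlation between generating and recovered values for each of the six
#' MBCA gains (across all participant x repetition datasets), and the
#' trade-off matrix of Pearson correlations between pairs of estimation
#' errors (generating minus recovered).
#'
#' @param cohort A list of `list(session, params)` as produced by
#'   [generate_synthetic_cohort()]; only `session`'s plan structure and
#'   `params` are used.
#' @param n_reps Synthetic datasets per participant.
#' @param n_starts Random starts per refit.
#' @param seed Integer seed.
#' @return A list of class `cm_recovery`: `recovery_r` (named length-6
#'   vector; `NA` when a generating parameter has degenerate variance),
#'   `error_cor` (6 x 6 matrix), and `table` (one row per dataset with
#'   generating and recovered parameters).
#' @export
parameter_recovery <- function(cohort, n_reps = 1L, n_starts = 20L,
                               seed = NULL) {
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, length(cohort) * n_reps * 2L)
  full <- model_spec("full")
  rows <- list()
  k <- 0L
  for (i in seq_along(cohort)) {
    gen <- as_param_vector(cohort[[i]]$params)
    sess <- cohort[[i]]$session
    for (r in seq_len(n_reps)) {
      k <- k + 1L
      plan <- generate_session_plan(sess$task_map, sess$config,
                                    seed = seeds[2L * k - 1L],
                                    participant = sess$participant)
      sim <- simulate_session(gen, plan, seed = seeds[2L * k - 1L])
      fit <- fit_participant(sim, full, n_starts = n_starts,
                             seed = seeds[2L * k])
      rows[[k]] <- data.frame(
        participant = i, rep = r,
        t(setNames(gen[.mb_names], paste0("gen_", .mb_names))),
        t(setNames(fit$params[.mb_names], paste0("rec_", .mb_names))),
        gen_c_mf = unname(gen["c_mf"]), rec_c_mf = unname(fit$params["c_mf"]))
    }
  }
  tab <- do.call(rbind, rows)
  recovery_r <- vapply(.mb_names, function(nm) {
    g <- tab[[paste0("gen_", nm)]]
    r <- tab[[paste0("rec_", nm)]]
    if (sd(g) < 1e-12 || sd(r) < 1e-12) NA_real_ else cor(g, r)
  }, numeric(1))
  errs <- vapply(.mb_names, function(nm)
    tab[[paste0("gen_", nm)]] - tab[[paste0("rec_", nm)]],
    numeric(nrow(tab)))
  error_cor <- suppressWarnings(cor(errs))
  structure(list(recovery_r = recovery_r, error_cor = error_cor,
                 table = tab, seed = seed),
            class = "cm_recovery")
}

#' @export
print.cm_recovery <- function(x, ...) {
  cat("<cm_recovery> ", nrow(x$table), " datasets\n", sep = "")
  cat("MBCA recovery r:\n")
  print(round(x$recovery_r, 3))
  invisible(x)
}
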