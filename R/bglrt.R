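# Bootstrapped generalized likelihood-ratio testing (BGLRT), group
# aggregation, and model-recovery power.

#' Participant-level bootstrapped generalized likelihood-ratio test
#'
#' Tests a nested sub-model (the null) against a super-model. Both models
#' are fit to the session; the empirical statistic is twice the
#' log-likelihood improvement of the super-model. The null distribution is
#' built by parametric bootstrap: `n_boot` synthetic sessions are simulated
#' from the sub-model at its ML parameters on fresh trial plans generated
#' exactly as the original session (same task map and configuration, new
#' randomization), and both models are refit to each. The p value is the
#' proportion of bootstrap statistics at least as large as the empirical
#' one (no continuity correction).
#'
#' Super-model fits are warm-started from the (expanded) sub-model ML
#' parameters of the same dataset, identically for the empirical and every
#' bootstrap dataset, so the statistic is computed by one exchangeable
#' pipeline. Negative statistics (optimizer noise) are clamped to 0 with a
#' warning.
#'
#' @param session A `cm_session` with choices filled.
#' @param sub,super [model_spec()] objects; `sub` must be nested in `super`.
#' @param n_boot Number of bootstrap datasets (1001 matches the original
#'   protocol; 99 is a practical scaled-down value).
#' @param n_starts Random starts per fit (both empirical and bootstrap).
#' @param seed Integer seed controlling fits and bootstrap simulation.
#' @return An object of class `cm_bglrt`: list with `participant`,
#'   `sub`/`super` names, `statistic`, `null_stats` (length `n_boot`), `p`,
#'   `fit_sub`, `fit_super`, `n_boot`, `seed`.
#' @export
bglrt_participant <- function(session, sub, super = model_spec("full"),
                              n_boot = 1001L, n_starts = 20L, seed = NULL) {
  stopifnot(inherits(sub, "cm_spec"), inherits(super, "cm_spec"))
  if (!is_nested(sub, super))
    stop("'", sub$name, "' is not nested in '", super$name, "'")
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, 2L * n_boot + 2L)

  pair_stat <- function(sess, fit_seed_1, fit_seed_2) {
    f_sub <- fit_participant(sess, sub, n_starts = n_starts,
                             seed = fit_seed_1)
    warm <- list(free_from_full(super, f_sub$params))
    f_super <- fit_participant(sess, super, n_starts = n_starts,
                               seed = fit_seed_2, init = warm)
    list(stat = clamp_stat(2 * (f_super$loglik - f_sub$loglik)),
         f_sub = f_sub, f_super = f_super)
  }

  emp <- pair_stat(session, seeds[1], seeds[2])
  null_stats <- vapply(seq_len(n_boot), function(b) {
    plan <- generate_session_plan(session$task_map, session$config,
                                  seed = seeds[2L * b + 1L],
                                  participant = session$participant)
    boot <- simulate_session(emp$f_sub$params, plan,
                             seed = seeds[2L * b + 1L])
    pair_stat(boot, seeds[2L * b + 2L], seeds[2L * b + 1L])$stat
  }, numeric(1))

  structure(list(participant = session$participant, sub = sub$name,
                 super = super$name, statistic = emp$stat,
                 null_stats = null_stats,
                 p = mean(null_stats >= emp$stat),
                 fit_sub = emp$f_sub, fit_super = emp$f_super,
                 n_boot = n_boot, seed = seed),
            class = "cm_bglrt")
}

clamp_stat <- function(stat) {
  if (stat < 0) {
    if (stat < -1e-3)
      warning("negative likelihood-ratio statistic (", signif(stat, 3),
              ") clamped to 0; consider more starts")
    stat <- 0
  }
  stat
}

# Free-parameter vector of `spec` whose expansion best matches a full
# parameter vector; exact when the full vector satisfies the constraints.
free_from_full <- function(spec, params) {
  params <- as_param_vector(params)
  direct <- intersect(spec$free, cm_param_names)
  free <- setNames(numeric(length(spec$free)), spec$free)
  free[direct] <- params[direct]
  synth <- setdiff(spec$free, cm_param_names)
  if (length(synth)) {
    mb <- params[.mb_names]
    free[synth] <- switch(spec$name,
      no_presentation_MBCA = mean(mb),
      no_position_MBCA = c(mean(mb[1:2]), mean(mb[3:4]), mean(mb[5:6])),
      no_format_MBCA = c(mean(mb[c(1, 3, 5)]), mean(mb[c(2, 4, 6)])),
      additive_MBCA = {
        pos2 <- mean(mb[c(2, 4, 6)] - mb[c(1, 3, 5)])
        c(mb[1], mb[3], mb[5], pos2)
      },
      flipped_functional = c(mean(mb[c(1, 3, 6)]), mean(mb[c(2, 4, 5)])),
      stop("cannot reduce parameters to spec '", spec$name, "'")
    )
  }
  free
}

#' @export
print.cm_bglrt <- function(x, ...) {
  cat("<cm_bglrt> ", x$super, " vs ", x$sub, ": 2*dLL = ",
      round(x$statistic, 3), ", p = ", signif(x$p, 3), " (", x$n_boot,
      " bootstraps)\n", sep = "")
  invisible(x)
}

#' Group-level BGLRT by resampled null sums
#'
#' The group statistic is the sum of the participant statistics. Its null
#' distribution is built by repeatedly drawing, for each participant, one of
#' their bootstrap statistics uniformly at random and summing; the group p
#' value is the proportion of null sums at least as large as the empirical
#' sum.
#'
#' @param results List of `cm_bglrt` objects (one per participant, same
#'   sub/super pair).
#' @param n_resample Number of resampled null sums (10000 matches the
#'   original protocol).
#' @param seed Integer seed.
#' @return A list of class `cm_bglrt_group` with `sub`, `super`,
#'   `statistic`, `null_sums`, `p`, `n_resample`.
#' @export
bglrt_group <- function(results, n_resample = 10000L, seed = NULL) {
  if (!length(results)) stop("no participant results supplied")
  subs <- unique(vapply(results, `[[`, character(1), "sub"))
  if (length(subs) != 1L)
    stop("participant results mix sub-models: ", paste(subs, collapse = ", "))
  stat <- sum(vapply(results, `[[`, numeric(1), "statistic"))
  null_sums <- with_seed(seed, {
    draws <- lapply(results, function(r)
      r$null_stats[sample.int(length(r$null_stats), n_resample,
                              replace = TRUE)])
    Reduce(`+`, draws)
  })
  structure(list(sub = subs, super = results[[1]]$super, statistic = stat,
                 null_sums = null_sums, p = mean(null_sums >= stat),
                 n_resample = n_resample),
            class = "cm_bglrt_group")
}

#' @export
print.cm_bglrt_group <- function(x, ...) {
  cat("<cm_bglrt_group> ", x$super, " vs ", x$sub, ": sum 2*dLL = ",
      round(x$statistic, 3), ", group p = ", signif(x$p, 3), "\n", sep = "")
  invisible(x)
}

#' Model-recovery rates: type-I error and power of the group BGLRT
#'
#' Simulates cohorts from a generating model and records how often the group
#' BGLRT rejects each tested sub-model at level `alpha`. With the generating
#' model equal to the tested sub-model this estimates the type-I error
#' (nominally `alpha`); with the full model generating heterogeneous MBCA it
#' estimates power.
#'
#' @param cohort_params List of generating `cm_params` (one per participant;
#'   cohort size is its length).
#' @param generating_spec [model_spec()] the data are simulated from (the
#'   parameters must satisfy its constraints).
#' @param subs List of sub-model [model_spec()]s to test against `super`.
#' @param super Super-model [model_spec()].
#' @param n_sims Number of simulated cohorts.
#' @param alpha Nominal level.
#' @param config [session_config()] for the simulated sessions.
#' @param n_boot,n_starts,n_resample BGLRT settings per cohort.
#' @param seed Integer seed.
#' @return A data frame with one row per tested sub-model: rejection
#'   frequency, `n_sims`, `alpha`; attribute `"p_values"` holds the matrix
#'   of group p values (cohorts x subs).
#' @export
model_recovery_power <- function(cohort_params, generating_spec,
                                 subs, super = model_spec("full"),
                                 n_sims = 100L, alpha = 0.05,
                                 config = session_config(),
                                 n_boot = 99L, n_starts = 5L,
                                 n_resample = 2000L, seed = NULL) {
  if (inherits(subs, "cm_spec")) subs <- list(subs)
  seed <- seed %||% draw_seed()
  seeds <- derive_seeds(seed, n_sims)
  pmat <- matrix(NA_real_, n_sims, length(subs),
                 dimnames = list(NULL, vapply(subs, `[[`, character(1),
                                              "name")))
  for (s in seq_len(n_sims)) {
    cohort <- generate_synthetic_cohort(
      length(cohort_params), param_sampler = function(n) cohort_params,
      config = config, seed = seeds[s], spec = generating_spec)
    sub_seeds <- derive_seeds(seeds[s], length(subs) * length(cohort) + 1L)
    for (j in seq_along(subs)) {
      res <- lapply(seq_along(cohort), function(i)
        bglrt_participant(cohort[[i]]$session, subs[[j]], super,
                          n_boot = n_boot, n_starts = n_starts,
                          seed = sub_seeds[(j - 1L) * length(cohort) + i]))
      grp <- bglrt_group(res, n_resample = n_resample,
                         seed = sub_seeds[length(sub_seeds)])
      pmat[s, j] <- grp$p
    }
  }
  out <- data.frame(sub = colnames(pmat),
                    rejection_rate = colMeans(pmat < alpha),
                    n_sims = n_sims, alpha = alpha, row.names = NULL)
  attr(out, "p_values") <- pmat
  out
}
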