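# Multi-start maximum-likelihood fitting and the participant-exclusion rule.

#' Fit a model to one participant's session by maximum likelihood
#'
#' Runs `n_starts` bounded quasi-Newton (L-BFGS-B) optimizations of the
#' session log-likelihood from starting points drawn uniformly over the
#' parameter box (forgetting rates in `[0, 1]`, credit-assignment and
#' perseveration gains in the spec's box, `[-5, 5]` by default), using the
#' analytic gradient. The best start wins; ties are broken by the first
#' start found. Deterministic given `seed`: the start stream is laid out
#' up-front, so increasing `n_starts` extends, never reshuffles, the starts.
#'
#' @param session A `cm_session` with at least one valid choice trial.
#' @param spec A [model_spec()].
#' @param n_starts Number of random starts (200 matches the original fitting
#'   protocol; 20 is a practical fast mode).
#' @param seed Integer seed for the starting points.
#' @param init Optional list of extra free-parameter vectors prepended as
#'   warm starts (they count toward neither `n_starts` nor the random
#'   stream).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `cm_fit`: list with `spec`, `free` (best free
#'   parameters), `params` (expanded `cm_params`), `loglik`, `start_logliks`,
#'   `convergence` (per-start optim codes), `n_starts`, `seed`.
#' @export
fit_participant <- function(session, spec, n_starts = 200L, seed = NULL,
                            init = NULL, reltol = 1e-6) {
  stopifnot(inherits(session, "cm_session"), inherits(spec, "cm_spec"))
  if (!any(!is.na(session$trials$chosen)))
    stop("session has no valid choice trials")
  a <- session_arrays(session)
  pref <- session$task_map$pref
  k <- length(spec$free)

  # expand() is linear with a constant Jacobian, so inside the optimizer the
  # expansion is a matrix product and the chain rule is J^T g; the whole
  # multi-start L-BFGS-B loop runs in compiled code
  jac <- expand_jacobian(spec)

  seed <- seed %||% draw_seed()
  # one start per RNG block, so a larger n_starts extends the same stream
  starts <- with_seed(seed, t(vapply(seq_len(n_starts), function(i)
    runif(k, spec$lower, spec$upper), numeric(k))))
  if (!is.null(init)) {
    init <- lapply(init, function(x) pmin(pmax(as.numeric(x), spec$lower),
                                          spec$upper))
    starts <- rbind(do.call(rbind, init), starts)
  }

  out <- cm_fit_cpp(starts, spec$lower, spec$upper, jac, a$block, a$left,
                    a$right, a$chosen, a$fmt, a$o1, a$o2, a$r1, a$r2, pref,
                    500L, reltol / .Machine$double.eps, reltol)
  if (!is.finite(out$loglik))
    stop("all ", nrow(starts), " starts failed for spec '", spec$name,
         "' (convergence codes: ",
         paste(unique(out$convergence), collapse = ", "), ")")
  lls <- out$start_logliks
  conv <- out$convergence
  free <- setNames(out$free, spec$free)
  structure(list(spec = spec, free = free, params = spec$expand(free),
                 loglik = out$loglik, start_logliks = lls,
                 convergence = conv,
                 n_starts = n_starts, seed = seed),
            class = "cm_fit")
}

# Constant Jacobian d(full 13-vector)/d(free vector) of spec$expand.
expand_jacobian <- function(spec) {
  k <- length(spec$free)
  base <- spec$expand(numeric(k))
  jac <- matrix(0, nrow = 13L, ncol = k,
                dimnames = list(cm_param_names, spec$free))
  for (j in seq_len(k)) {
    e <- numeric(k)
    e[j] <- 1
    jac[, j] <- spec$expand(e) - base
  }
  jac
}

#' @export
print.cm_fit <- function(x, ...) {
  cat("<cm_fit> ", x$spec$name, ": loglik ", round(x$loglik, 3), " (",
      x$n_starts, " starts)\n", sep = "")
  print(round(x$free, 4))
  invisible(x)
}

#' Participant exclusion rule
#'
#' A participant is excluded if and only if all seven credit-assignment
#' parameters of their full-model fit (the MFCA gain and the six MBCA gains)
#' are strictly negative, indicating no incentive to earn rewards.
#'
#' @param fits A list of full-model `cm_fit` objects.
#' @return A list with integer index vectors `kept` and `excluded`.
#' @export
exclude_participants <- function(fits) {
  all_neg <- vapply(fits, function(f) all(f$params[.ca_names] < 0),
                    logical(1))
  list(kept = which(!all_neg), excluded = which(all_neg))
}
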