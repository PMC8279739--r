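# Mixed-effects models over transition tables, Wald contrast tests, the
# parameter-level and RT analyses, and bootstrap power estimation.

re_formula <- function(terms, re) {
  switch(re,
    full = sprintf("(%s | PART)", terms),
    slopes = "(COMMON | PART)",
    intercept = "(1 | PART)",
    none = NULL,
    stop("unknown random-effects structure: ", re))
}

# Fit a (generalized) linear mixed model with a graded fallback over
# random-effects structures; returns the first fit that converges without a
# singular covariance. The structure actually used is recorded.
fit_with_fallback <- function(data, response, fixed_terms, re_chain,
                              logistic = TRUE, weights = NULL) {
  last_err <- NULL
  for (j in seq_along(re_chain)) {
    re <- re_chain[j]
    ref <- re_formula(fixed_terms, re)
    fml <- as.formula(paste(response, "~", fixed_terms,
                            if (!is.null(ref)) paste("+", ref)))
    fit <- tryCatch(withCallingHandlers({
      if (is.null(ref)) {
        if (logistic) stats::glm(fml, data = data, family = binomial())
        else stats::lm(fml, data = data)
      } else if (logistic) {
        lme4::glmer(fml, data = data, family = binomial(), nAGQ = 0L,
                    control = lme4::glmerControl(calc.derivs = FALSE))
      } else {
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(calc.derivs = FALSE,
                                               check.conv.singular =
                                                 lme4::.makeCC("ignore",
                                                               tol = 1e-4)))
      }
    }, warning = function(w) invokeRestart("muffleWarning")),
    error = function(e) {
      last_err <<- e
      NULL
    })
    if (is.null(fit)) next
    # singular covariance: keep falling back while simpler structures remain
    if (!is.null(ref) && lme4::isSingular(fit, tol = 1e-4) &&
        j < length(re_chain)) next
    return(list(model = fit, re = re))
  }
  stop("no mixed-model structure converged: ",
       conditionMessage(last_err %||% simpleError("singular fits")))
}

fixed_stats <- function(model) {
  if (inherits(model, "merMod")) {
    b <- lme4::fixef(model)
    V <- as.matrix(vcov(model))
    n <- stats::nobs(model)
  } else {
    b <- coef(model)
    V <- vcov(model)
    n <- stats::nobs(model)
  }
  list(b = b, V = V, df = max(n - length(b), 1L))
}

# Wald test of one linear contrast (named weight vector) or a joint test
# that several coefficients are simultaneously 0. F statistics use the
# residual-style denominator df recorded on the fit (backend default).
contrast_test <- function(stats, weights = NULL, joint = NULL,
                          label = "contrast") {
  b <- stats$b
  V <- stats$V
  if (!is.null(weights)) {
    w <- setNames(numeric(length(b)), names(b))
    missing <- setdiff(names(weights), names(b))
    if (length(missing))
      stop("contrast refers to absent coefficients: ",
           paste(missing, collapse = ", "))
    w[names(weights)] <- weights
    est <- sum(w * b)
    se <- sqrt(drop(t(w) %*% V %*% w))
    fstat <- (est / se)^2
    data.frame(contrast = label, estimate = est, se = se, df1 = 1,
               df2 = stats$df, statistic = fstat,
               p = pf(fstat, 1, stats$df, lower.tail = FALSE))
  } else {
    idx <- match(joint, names(b))
    if (anyNA(idx))
      stop("joint test refers to absent coefficients: ",
           paste(joint[is.na(idx)], collapse = ", "))
    bb <- b[idx]
    VV <- V[idx, idx, drop = FALSE]
    q <- length(idx)
    fstat <- drop(t(bb) %*% solve(VV) %*% bb) / q
    data.frame(contrast = label, estimate = NA_real_, se = NA_real_,
               df1 = q, df2 = stats$df, statistic = fstat,
               p = pf(fstat, q, stats$df, lower.tail = FALSE))
  }
}

signature_contrasts <- function(stats, prefix = "COMMON") {
  p <- prefix
  rbind(
    contrast_test(stats, weights = setNames(c(1, 1 / 3, 1 / 3),
      c(p, paste0(p, ":PROSPECTIVE"), paste0(p, ":RETROSPECTIVE"))),
      label = "common_main"),
    contrast_test(stats, joint = paste0(p, c(":PROSPECTIVE",
      ":RETROSPECTIVE")), label = "common_x_format"),
    contrast_test(stats, weights = setNames(c(1, 1 / 3, 1 / 3),
      c(paste0(p, ":POSITION"), paste0(p, ":PROSPECTIVE:POSITION"),
        paste0(p, ":RETROSPECTIVE:POSITION"))),
      label = "common_x_position"),
    contrast_test(stats, joint = paste0(p, c(":PROSPECTIVE:POSITION",
      ":RETROSPECTIVE:POSITION")), label = "common_x_format_x_position"),
    contrast_test(stats, weights = setNames(1,
      paste0(p, ":PROSPECTIVE:POSITION")), label = "position_x_PI_vs_S"),
    contrast_test(stats, weights = setNames(1,
      paste0(p, ":RETROSPECTIVE:POSITION")), label = "position_x_RI_vs_S"),
    contrast_test(stats, weights = setNames(c(1, -1),
      paste0(p, c(":RETROSPECTIVE:POSITION", ":PROSPECTIVE:POSITION"))),
      label = "position_x_RI_vs_PI"),
    contrast_test(stats, weights = setNames(c(1, 0.5),
      paste0(p, c(":RETROSPECTIVE", ":RETROSPECTIVE:POSITION"))),
      label = "first_outcome_RI_vs_S"),
    contrast_test(stats, weights = setNames(c(1, -0.5),
      paste0(p, c(":RETROSPECTIVE", ":RETROSPECTIVE:POSITION"))),
      label = "second_outcome_RI_vs_S")
  )
}

#' Fit the mixed-effects logistic model for a transition analysis
#'
#' Fits `response ~ COMMON * (PROSPECTIVE + RETROSPECTIVE) * POSITION` with
#' per-participant random effects, and exposes the standard battery of Wald
#' contrast tests: the composite common-reward main effect
#' `(3 b_COMMON + b_COMMON:PI + b_COMMON:RI) / 3` (and its POSITION
#' analogue), joint F tests of the format and format-by-position
#' interactions, the per-format-pair interaction contrasts, and the
#' per-position standard-vs-retrospective contrasts.
#'
#' The random-effects structure starts from the full free-covariance
#' structure and falls back to simpler structures (`COMMON` slope, random
#' intercept, plain logistic regression) if a fit fails or is singular —
#' small cohorts are often degenerate under the full structure. The
#' structure used is recorded in the result.
#'
#' @param table A [repetition_transitions()] or
#'   [generalization_transitions()] table.
#' @param response Response column: `"REPEAT"` or `"GENERALIZE"`.
#' @param re Random-effects chain to try, in order.
#' @return An object of class `cm_sig_fit`: list with `model`, `re`
#'   (structure used), `coefficients` (fixed effects), `contrasts` (a data
#'   frame of contrast tests), `n_obs`, `df`.
#' @export
fit_mixed_logistic <- function(table,
                               response = c("GENERALIZE", "REPEAT"),
                               re = c("full", "slopes", "intercept",
                                      "none")) {
  response <- match.arg(response)
  fx <- "COMMON * (PROSPECTIVE + RETROSPECTIVE) * POSITION"
  ft <- fit_with_fallback(table, response, fx, re, logistic = TRUE)
  st <- fixed_stats(ft$model)
  structure(list(model = ft$model, re = ft$re, coefficients = st$b,
                 vcov = st$V, contrasts = signature_contrasts(st),
                 n_obs = nrow(table), df = st$df, response = response),
            class = "cm_sig_fit")
}

#' @export
print.cm_sig_fit <- function(x, ...) {
  cat("<cm_sig_fit> ", x$response, " ~ COMMON*(PI+RI)*POSITION, RE = ",
      x$re, ", n = ", x$n_obs, "\n", sep = "")
  print(x$contrasts[, c("contrast", "estimate", "statistic", "df1", "df2",
                        "p")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Mixed logistic model for the cross-credit analysis
#'
#' Regresses choice generalization on the non-common (hidden) outcome's
#' reward over the retrospective-inference transitions selected by
#' [cross_ca_transitions()]: `GENERALIZE ~ NON_COMMON` with participant
#' random effects. A positive `NON_COMMON` effect indicates credit from the
#' first, hidden outcome's reward leaking to the second, seen outcome, the
#' signature of online belief-state credit assignment.
#'
#' @param table A [cross_ca_transitions()] table.
#' @param re Random-effects chain (the slope structure is the analysis's
#'   free-covariance default).
#' @return A `cm_sig_fit`-like object whose single contrast is the
#'   `NON_COMMON` fixed effect.
#' @export
fit_cross_ca_model <- function(table, re = c("noncommon_slope",
                                             "intercept", "none")) {
  re_fml <- c(noncommon_slope = "(NON_COMMON | PART)",
              intercept = "(1 | PART)")
  last_err <- NULL
  for (j in seq_along(re)) {
    fml <- if (re[j] == "none") GENERALIZE ~ NON_COMMON else
      as.formula(paste("GENERALIZE ~ NON_COMMON +", re_fml[re[j]]))
    fit <- tryCatch(withCallingHandlers(
      if (re[j] == "none") stats::glm(fml, data = table,
                                      family = binomial())
      else lme4::glmer(fml, data = table, family = binomial(), nAGQ = 0L,
                       control = lme4::glmerControl(calc.derivs = FALSE)),
      warning = function(w) invokeRestart("muffleWarning")),
      error = function(e) { last_err <<- e; NULL })
    if (is.null(fit)) next
    if (re[j] != "none" && lme4::isSingular(fit, tol = 1e-4) &&
        j < length(re)) next
    st <- fixed_stats(fit)
    return(structure(list(
      model = fit, re = re[j], coefficients = st$b, vcov = st$V,
      contrasts = contrast_test(st, weights = c(NON_COMMON = 1),
                                label = "non_common"),
      n_obs = nrow(table), df = st$df, response = "GENERALIZE"),
      class = "cm_sig_fit"))
  }
  stop("cross-credit model failed to fit: ",
       conditionMessage(last_err %||% simpleError("singular fits")))
}

#' Mixed model of per-participant common-reward effects
#'
#' Regresses the 6 per-participant common-reward effects (format x serial
#' position, from [reward_effect_table()]) on position and format dummies
#' with participant random effects. Participants with missing cells are
#' dropped with a warning.
#'
#' @param effects A [reward_effect_table()].
#' @param re Random-effects chain.
#' @return A `cm_sig_fit`-like object with position/format contrasts.
#' @export
reward_effect_model <- function(effects,
                                re = c("full", "intercept", "none")) {
  bad <- unique(effects$PART[!is.finite(effects$effect)])
  if (length(bad)) {
    warning("dropping participants with empty effect cells: ",
            paste(bad, collapse = ", "))
    effects <- effects[!effects$PART %in% bad, ]
  }
  fx <- "POSITION * (PROSPECTIVE + RETROSPECTIVE)"
  ft <- fit_with_fallback(effects, "effect", fx, re, logistic = FALSE)
  st <- fixed_stats(ft$model)
  contrasts <- rbind(
    contrast_test(st, weights = setNames(c(1, 1 / 3, 1 / 3),
      c("POSITION", "POSITION:PROSPECTIVE", "POSITION:RETROSPECTIVE")),
      label = "position_main"),
    contrast_test(st, joint = c("POSITION:PROSPECTIVE",
                                "POSITION:RETROSPECTIVE"),
                  label = "position_x_format"),
    contrast_test(st, weights = setNames(1, "POSITION:RETROSPECTIVE"),
                  label = "position_x_RI_vs_S"))
  structure(list(model = ft$model, re = ft$re, coefficients = st$b,
                 vcov = st$V, contrasts = contrasts,
                 n_obs = nrow(effects), df = st$df,
                 response = "effect"), class = "cm_sig_fit")
}

#' Mixed model of fitted MBCA parameters
#'
#' Regresses participants' six full-model MBCA gains on presentation format
#' and outcome serial position (`CA ~ (PI + RI) * POSITION` with
#' participant random effects; position coded +0.5 first, -0.5 second).
#' With `functional = TRUE` the two retrospective-inference gains swap
#' positions first, so `POSITION` indexes the *functional* credit-assignment
#' order instead of the temporal one.
#'
#' Also returns the retrospective-impairment analysis: per participant and
#' position, the standard-minus-retrospective MBCA difference; the Pearson
#' correlation between the two positions' impairments; and the regression
#' of the second-position impairment on the first (a positive intercept
#' indicates a baseline shift sparing the hidden outcome).
#'
#' @param fits List of full-model `cm_fit` objects (>= 3 participants).
#' @param functional Use functional instead of temporal position for the
#'   retrospective-inference gains.
#' @param re Random-effects chain.
#' @return A list of class `cm_param_model`: `model`, `re`, `coefficients`,
#'   `contrasts`, `table` (the long CA table), and `impairment` (list with
#'   `table`, `correlation` [cor.test result], `regression` [lm coefficient
#'   matrix]).
#' @export
mbca_parameter_model <- function(fits, functional = FALSE,
                                 re = c("full", "intercept", "none")) {
  if (length(fits) < 3L) stop("need at least 3 participants")
  tab <- do.call(rbind, lapply(seq_along(fits), function(i) {
    mb <- fits[[i]]$params[.mb_names]
    if (functional) mb[c("c_mb_RI1", "c_mb_RI2")] <-
        mb[c("c_mb_RI2", "c_mb_RI1")]
    data.frame(PART = sprintf("S%03d", i),
               format = rep(cm_formats, each = 2L),
               position = rep(1:2, 3L), CA = unname(mb))
  }))
  tab$POSITION <- ifelse(tab$position == 1L, 0.5, -0.5)
  tab <- cbind(tab, format_dummies(tab$format))
  fx <- "(PROSPECTIVE + RETROSPECTIVE) * POSITION"
  ft <- fit_with_fallback(tab, "CA", fx, re, logistic = FALSE)
  st <- fixed_stats(ft$model)
  contrasts <- rbind(
    contrast_test(st, joint = c("PROSPECTIVE:POSITION",
                                "RETROSPECTIVE:POSITION"),
                  label = "format_x_position"),
    contrast_test(st, weights = setNames(1, "RETROSPECTIVE:POSITION"),
                  label = "position_x_RI_vs_S"),
    contrast_test(st, weights = setNames(1, "PROSPECTIVE:POSITION"),
                  label = "position_x_PI_vs_S"),
    contrast_test(st, weights = setNames(c(1, 0.5),
      c("RETROSPECTIVE", "RETROSPECTIVE:POSITION")),
      label = "first_outcome_RI_vs_S"),
    contrast_test(st, weights = setNames(c(1, -0.5),
      c("RETROSPECTIVE", "RETROSPECTIVE:POSITION")),
      label = "second_outcome_RI_vs_S"))

  wide <- do.call(rbind, lapply(fits, function(f)
    as.data.frame(t(f$params[.mb_names]))))
  imp <- data.frame(imp1 = wide$c_mb_S1 - wide$c_mb_RI1,
                    imp2 = wide$c_mb_S2 - wide$c_mb_RI2)
  impairment <- list(
    table = imp,
    correlation = stats::cor.test(imp$imp1, imp$imp2),
    regression = summary(lm(imp2 ~ imp1, data = imp))$coefficients)

  structure(list(model = ft$model, re = ft$re, coefficients = st$b,
                 vcov = st$V, contrasts = contrasts, table = tab,
                 impairment = impairment, functional = functional),
            class = "cm_param_model")
}

#' @export
print.cm_param_model <- function(x, ...) {
  cat("<cm_param_model> CA ~ (PI+RI)*POSITION (",
      if (x$functional) "functional" else "temporal", " position), RE = ",
      x$re, "\n", sep = "")
  print(x$contrasts[, c("contrast", "estimate", "statistic", "df1", "df2",
                        "p")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Reaction-time analysis by previous-trial format and trial type
#'
#' Removes trials faster than 250 ms and the first trial of each block,
#' classifies each remaining trial as a replica (same two persons offered
#' as the previous trial) or new trial, computes each participant's mean RT
#' per previous-trial format and type, and fits
#' `MRT ~ TYPE * (PI + RI)` (TYPE: replica -0.5, new +0.5) with participant
#' random effects.
#'
#' @param sessions A `cm_session` or list of them (with `rt_ms` present).
#' @param min_rt Lower RT cutoff in milliseconds.
#' @param re Random-effects chain.
#' @return A list of class `cm_rt_fit`: `table` (the mean-RT cells),
#'   `model`, `re`, `coefficients`, `contrasts`.
#' @export
rt_analysis <- function(sessions, min_rt = 250,
                        re = c("full", "intercept", "none")) {
  sessions <- as_session_list(sessions)
  cells <- do.call(rbind, lapply(sessions, function(s) {
    tr <- s$trials
    n <- nrow(tr)
    i <- which(tr$trial > 1L)  # first trial of each block never contributes
    keep <- i[!is.na(tr$rt_ms[i]) & tr$rt_ms[i] >= min_rt &
                !is.na(tr$chosen[i])]
    if (!length(keep)) return(NULL)
    replica <- (pmin(tr$left, tr$right)[keep] ==
                  pmin(tr$left, tr$right)[keep - 1L]) &
      (pmax(tr$left, tr$right)[keep] == pmax(tr$left, tr$right)[keep - 1L])
    df <- data.frame(PART = s$participant,
                     prev_format = tr$format[keep - 1L],
                     type = ifelse(replica, "replica", "new"),
                     rt = tr$rt_ms[keep])
    aggregate(rt ~ PART + prev_format + type, df, mean)
  }))
  names(cells)[names(cells) == "rt"] <- "MRT"
  cells$TYPE <- ifelse(cells$type == "new", 0.5, -0.5)
  cells <- cbind(cells, format_dummies(cells$prev_format))
  fx <- "TYPE * (PROSPECTIVE + RETROSPECTIVE)"
  ft <- fit_with_fallback(cells, "MRT", fx, re, logistic = FALSE)
  st <- fixed_stats(ft$model)
  contrasts <- rbind(
    contrast_test(st, weights = setNames(c(1, 1 / 3, 1 / 3),
      c("TYPE", "TYPE:PROSPECTIVE", "TYPE:RETROSPECTIVE")),
      label = "type_main"),
    contrast_test(st, joint = c("TYPE:PROSPECTIVE", "TYPE:RETROSPECTIVE"),
                  label = "type_x_format"),
    contrast_test(st, weights = setNames(1, "TYPE:RETROSPECTIVE"),
                  label = "type_x_RI_vs_S"),
    contrast_test(st, weights = setNames(c(1, 0.5),
      c("RETROSPECTIVE", "TYPE:RETROSPECTIVE")),
      label = "new_trials_RI_vs_S"),
    contrast_test(st, weights = setNames(c(1, -0.5),
      c("RETROSPECTIVE", "TYPE:RETROSPECTIVE")),
      label = "replica_trials_RI_vs_S"))
  structure(list(table = cells, model = ft$model, re = ft$re,
                 coefficients = st$b, vcov = st$V, contrasts = contrasts),
            class = "cm_rt_fit")
}

#' @export
print.cm_rt_fit <- function(x, ...) {
  cat("<cm_rt_fit> MRT ~ TYPE*(PI+RI), RE = ", x$re, "\n", sep = "")
  print(x$contrasts[, c("contrast", "estimate", "statistic", "df1", "df2",
                        "p")], digits = 3, row.names = FALSE)
  invisible(x)
}

focal_p <- function(analysis, sessions, fits) {
  switch(analysis,
    generalization = {
      ct <- fit_mixed_logistic(generalization_transitions(sessions),
                               "GENERALIZE")$contrasts
      ct$p[ct$contrast == "common_x_format_x_position"]
    },
    repetition = {
      ct <- fit_mixed_logistic(repetition_transitions(sessions),
                               "REPEAT")$contrasts
      ct$p[ct$contrast == "common_x_format_x_position"]
    },
    mbca_parameters = {
      ct <- mbca_parameter_model(fits)$contrasts
      ct$p[ct$contrast == "format_x_position"]
    },
    rt = {
      ct <- rt_analysis(sessions)$contrasts
      ct$p[ct$contrast == "type_x_format"]
    },
    stop("unknown analysis: ", analysis))
}

#' Bootstrap power of a focal interaction
#'
#' Resamples participants with replacement (optionally up-sampling to a
#' larger target cohort), reruns the named analysis on each bootstrap
#' cohort, and returns the proportion of resamples in which the focal
#' high-order interaction is significant at `alpha`. Focal effects:
#' the common-reward x format x position interaction for the
#' repetition/generalization analyses, the format x position interaction
#' for the parameter analysis, and the type x format interaction for the RT
#' analysis.
#'
#' @param sessions List of `cm_session`s (one per participant).
#' @param analysis One of `"generalization"`, `"repetition"`,
#'   `"mbca_parameters"`, `"rt"`.
#' @param n_boot Number of bootstrap cohorts.
#' @param alpha Significance level.
#' @param seed Integer seed.
#' @param target_n Bootstrap cohort size (defaults to the observed size).
#' @param fits Full-model fits, required for `analysis =
#'   "mbca_parameters"` (same order as `sessions`).
#' @return A list with `power`, `p_values`, `n_boot`, `alpha`, `target_n`.
#' @export
bootstrap_power <- function(sessions, analysis, n_boot = 1000L,
                            alpha = 0.05, seed = NULL, target_n = NULL,
                            fits = NULL) {
  sessions <- as_session_list(sessions)
  if (analysis == "mbca_parameters" && is.null(fits))
    stop("analysis 'mbca_parameters' needs full-model fits")
  n <- length(sessions)
  target_n <- target_n %||% n
  idx_mat <- with_seed(seed, matrix(
    sample.int(n, n_boot * target_n, replace = TRUE), nrow = n_boot))
  p_values <- vapply(seq_len(n_boot), function(b) {
    idx <- idx_mat[b, ]
    boot_sessions <- lapply(seq_along(idx), function(j) {
      s <- sessions[[idx[j]]]
      s$participant <- sprintf("B%04d", j)  # duplicates become distinct
      s
    })
    boot_fits <- if (!is.null(fits)) fits[idx]
    tryCatch(focal_p(analysis, boot_sessions, boot_fits),
             error = function(e) NA_real_)
  }, numeric(1))
  list(power = mean(p_values < alpha, na.rm = TRUE), p_values = p_values,
       n_boot = n_boot, alpha = alpha, target_n = target_n)
}
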