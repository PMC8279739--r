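# Session serialization (tidy CSV + JSON sidecar) and the pipeline driver.

#' Write sessions to a directory
#'
#' One tidy CSV per participant (one row per trial, columns `participant`,
#' `block`, `trial`, `left_person`, `right_person`, `format`,
#' `first_outcome`, `second_outcome`, `chosen_person`, `reward1`, `reward2`,
#' `rt_ms`, plus `animal_first` so unfilled plans round-trip) and one JSON
#' sidecar per participant carrying the task map, per-block reward
#' probabilities, configuration, and seed. Persons and outcomes are written
#' as labels; trials are 1-based.
#'
#' @param sessions A `cm_session` or list of them.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the CSV paths.
#' @export
write_sessions <- function(sessions, dir) {
  sessions <- as_session_list(sessions)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sessions, function(s) {
    tr <- s$trials
    map <- s$task_map
    lab <- function(ids, labels) ifelse(is.na(ids), NA_character_,
                                        labels[ids])
    out <- data.frame(
      participant = s$participant, block = tr$block, trial = tr$trial,
      left_person = lab(tr$left, map$persons),
      right_person = lab(tr$right, map$persons),
      format = tr$format,
      first_outcome = lab(tr$outcome1, map$outcomes),
      second_outcome = lab(tr$outcome2, map$outcomes),
      chosen_person = lab(tr$chosen, map$persons),
      reward1 = tr$reward1, reward2 = tr$reward2, rt_ms = tr$rt_ms,
      animal_first = tr$animal_first)
    csv <- file.path(dir, paste0(s$participant, ".csv"))
    write.csv(out, csv, row.names = FALSE, na = "")
    meta <- list(
      participant = s$participant, seed = s$seed,
      config = unclass(s$config),
      preference = setNames(lapply(1:4, function(p)
        map$outcomes[map$pref[p, ]]), map$persons),
      reward_probs = apply(s$reward_probs, 1, as.list))
    jsonlite::write_json(meta, file.path(dir, paste0(s$participant,
                                                     ".json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    csv
  }, character(1))
  invisible(paths)
}

required_cols <- c("participant", "block", "trial", "left_person",
                   "right_person", "format", "chosen_person", "reward1",
                   "reward2")

#' Read sessions from a directory
#'
#' Reads the CSV/JSON pairs written by [write_sessions()], validating the
#' schema and the task invariants. Malformed rows are reported with their
#' row numbers; a missing `rt_ms` column is accepted (reaction times marked
#' missing), as are rows without a recorded choice (missed deadlines).
#'
#' @param dir Directory holding `<participant>.csv` / `<participant>.json`
#'   pairs.
#' @return A list of `cm_session` objects.
#' @export
read_sessions <- function(dir) {
  csvs <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(csvs)) stop("no session CSV files in ", dir)
  lapply(csvs, read_one_session)
}

read_one_session <- function(csv) {
  raw <- read.csv(csv, stringsAsFactors = FALSE, na.strings = "")
  missing_cols <- setdiff(required_cols, names(raw))
  if (length(missing_cols))
    stop(csv, ": missing required columns: ",
         paste(missing_cols, collapse = ", "))
  json <- sub("\\.csv$", ".json", csv)
  if (!file.exists(json)) stop("missing sidecar metadata: ", json)
  meta <- jsonlite::read_json(json, simplifyVector = TRUE)

  cfg_args <- meta$config[names(meta$config) %in%
                            names(formals(session_config))]
  config <- do.call(session_config, cfg_args)

  # rebuild the task map from the serialized preferences
  persons <- names(meta$preference)
  outcomes <- c("A1", "A2", "V1", "V2")
  pref <- t(vapply(meta$preference, function(o) match(o, outcomes),
                   integer(2)))
  dimnames(pref) <- list(persons, c("animal", "vegetable"))
  map <- structure(list(persons = persons, outcomes = outcomes,
                        pref = pref,
                        valid_pairs = valid_pairs_from_pref(pref),
                        seed = meta$seed),
                   class = "cm_task_map")

  rp <- meta$reward_probs
  rewp <- if (is.data.frame(rp)) as.matrix(rp[, outcomes])
    else do.call(rbind, lapply(rp, function(r) unlist(r)[outcomes]))
  dimnames(rewp) <- list(NULL, outcomes)

  to_id <- function(x, labels, col) {
    id <- match(x, labels)
    bad <- which(!is.na(x) & is.na(id))
    if (length(bad))
      stop(csv, ": unknown ", col, " at rows ",
           paste(utils::head(bad, 5), collapse = ", "))
    id
  }
  trials <- data.frame(
    block = as.integer(raw$block), trial = as.integer(raw$trial),
    left = to_id(raw$left_person, persons, "left_person"),
    right = to_id(raw$right_person, persons, "right_person"),
    format = raw$format,
    animal_first = if ("animal_first" %in% names(raw))
      as.logical(raw$animal_first) else NA,
    chosen = to_id(raw$chosen_person, persons, "chosen_person"),
    outcome1 = if ("first_outcome" %in% names(raw))
      to_id(raw$first_outcome, outcomes, "first_outcome") else NA_integer_,
    outcome2 = if ("second_outcome" %in% names(raw))
      to_id(raw$second_outcome, outcomes, "second_outcome")
      else NA_integer_,
    reward1 = as.integer(raw$reward1), reward2 = as.integer(raw$reward2),
    rt_ms = if ("rt_ms" %in% names(raw)) as.numeric(raw$rt_ms)
      else NA_real_)

  bad_fmt <- which(!trials$format %in% cm_formats)
  if (length(bad_fmt))
    stop(csv, ": invalid format at rows ",
         paste(utils::head(bad_fmt, 5), collapse = ", "))
  bad_choice <- which(!is.na(trials$chosen) &
                        trials$chosen != trials$left &
                        trials$chosen != trials$right)
  if (length(bad_choice))
    stop(csv, ": chosen person not in the offered pair at rows ",
         paste(utils::head(bad_choice, 5), collapse = ", "))
  bad_rew <- which(!is.na(trials$chosen) &
                     (is.na(trials$reward1) | is.na(trials$reward2) |
                        is.na(trials$outcome1) | is.na(trials$outcome2)))
  if (length(bad_rew))
    stop(csv, ": chosen trials must carry outcomes and rewards; offending ",
         "rows ", paste(utils::head(bad_rew, 5), collapse = ", "))

  structure(list(task_map = map, config = config,
                 participant = as.character(raw$participant[1]),
                 seed = meta$seed, reward_probs = rewp, trials = trials),
            class = "cm_session")
}

#' Run the full synthetic pipeline
#'
#' Convenience driver: simulate a cohort, fit the full model, apply the
#' exclusion rule, optionally run a BGLRT against one sub-model, the
#' model-agnostic signature analyses, a parameter-recovery study, and the
#' yoked-earnings simulation. Every stage receives a seed derived from the
#' master seed, so reruns with the same configuration are identical.
#'
#' @param n_participants Cohort size.
#' @param config A [session_config()].
#' @param seed Master seed.
#' @param n_starts Random starts for the full-model fits.
#' @param bglrt_sub Optional sub-model name to test against the full model.
#' @param n_boot,bglrt_n_starts BGLRT settings.
#' @param stages Character vector choosing among `"signatures"`,
#'   `"recovery"`, `"earnings"` (fits and exclusion always run).
#' @param out_dir Optional directory; when given, sessions and a JSON
#'   results summary (with seed and configuration) are written there.
#' @return A list bundling the cohort, fits, exclusion, and stage results,
#'   plus the seeds used.
#' @export
run_pipeline <- function(n_participants = 10L, config = session_config(),
                         seed = 1L, n_starts = 20L, bglrt_sub = NULL,
                         n_boot = 99L, bglrt_n_starts = 5L,
                         stages = c("signatures", "earnings"),
                         out_dir = NULL) {
  if (!is.null(bglrt_sub) && !bglrt_sub %in% model_names())
    stop("unknown model name: ", bglrt_sub)
  bad <- setdiff(stages, c("signatures", "recovery", "earnings"))
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  seeds <- derive_seeds(seed, 6L)
  full <- model_spec("full")

  cohort <- generate_synthetic_cohort(n_participants, config = config,
                                      seed = seeds[1])
  sessions <- lapply(cohort, `[[`, "session")
  fit_seeds <- derive_seeds(seeds[2], n_participants)
  fits <- lapply(seq_along(sessions), function(i)
    fit_participant(sessions[[i]], full, n_starts = n_starts,
                    seed = fit_seeds[i]))
  exclusion <- exclude_participants(fits)

  result <- list(seed = seed, stage_seeds = seeds, config = config,
                 cohort = cohort, fits = fits, exclusion = exclusion)

  if (!is.null(bglrt_sub)) {
    sub <- model_spec(bglrt_sub)
    bg_seeds <- derive_seeds(seeds[3], n_participants)
    per_part <- lapply(seq_along(sessions), function(i)
      bglrt_participant(sessions[[i]], sub, full, n_boot = n_boot,
                        n_starts = bglrt_n_starts, seed = bg_seeds[i]))
    result$bglrt <- list(participants = per_part,
                         group = bglrt_group(per_part, seed = seeds[3]))
  }
  if ("signatures" %in% stages) {
    result$signatures <- list(
      repetition = fit_mixed_logistic(repetition_transitions(sessions),
                                      "REPEAT"),
      generalization = fit_mixed_logistic(
        generalization_transitions(sessions), "GENERALIZE"),
      parameters = mbca_parameter_model(fits))
  }
  if ("recovery" %in% stages) {
    result$recovery <- parameter_recovery(cohort, n_reps = 1L,
                                          n_starts = n_starts,
                                          seed = seeds[4])
  }
  if ("earnings" %in% stages) {
    result$earnings <- yoked_format_agents(fits, n_sessions = 100L,
                                           config = config,
                                           seed = seeds[5])
  }

  if (!is.null(out_dir)) {
    write_sessions(sessions, file.path(out_dir, "sessions"))
    summary <- list(
      seed = seed, n_participants = n_participants,
      config = unclass(config),
      excluded = exclusion$excluded,
      loglik = vapply(fits, `[[`, numeric(1), "loglik"),
      params = lapply(fits, function(f) as.list(unclass(f$params))))
    if (!is.null(result$bglrt))
      summary$bglrt_group_p <- result$bglrt$group$p
    jsonlite::write_json(summary, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}
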