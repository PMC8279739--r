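# The bipartite person <-> outcome structure ("cognitive map").

#' Build a randomized task map
#'
#' Four persons are each assigned a unique (animal, vegetable) preference
#' pair, drawn from two animals and two vegetables, so that every outcome is
#' favored by exactly two persons. Consequently exactly four unordered person
#' pairs share exactly one outcome (the valid choice pairs) and the remaining
#' two pairs share none. The assignment of preference pairs to persons is
#' randomized, mirroring the per-participant randomization of the task.
#'
#' Outcomes are indexed 1:4 in the order animal 1, animal 2, vegetable 1,
#' vegetable 2.
#'
#' @param seed Optional integer seed; the map is a deterministic function of
#'   it. With `NULL` the current RNG stream is used.
#' @return An object of class `cm_task_map`: a list with `persons` and
#'   `outcomes` (labels), `pref` (a 4 x 2 integer matrix; row p holds person
#'   p's animal and vegetable outcome ids), and `valid_pairs` (a 4 x 2 matrix
#'   of the person pairs sharing exactly one outcome).
#' @examples
#' map <- build_task_map(seed = 1)
#' map$pref
#' @export
build_task_map <- function(seed = NULL) {
  combos <- as.matrix(expand.grid(animal = 1:2, vegetable = 3:4))
  assignment <- with_seed(seed, sample.int(4L))
  pref <- combos[assignment, , drop = FALSE]
  dimnames(pref) <- list(paste0("P", 1:4), c("animal", "vegetable"))
  vp <- valid_pairs_from_pref(pref)
  structure(list(
    persons = paste0("P", 1:4),
    outcomes = c("A1", "A2", "V1", "V2"),
    pref = pref,
    valid_pairs = vp,
    seed = seed
  ), class = "cm_task_map")
}

valid_pairs_from_pref <- function(pref) {
  pairs <- t(utils::combn(4L, 2L))
  shared <- apply(pairs, 1L, function(pq)
    length(intersect(pref[pq[1], ], pref[pq[2], ])))
  vp <- pairs[shared == 1L, , drop = FALSE]
  colnames(vp) <- c("p1", "p2")
  vp
}

#' @export
print.cm_task_map <- function(x, ...) {
  cat("<cm_task_map>\n")
  prefs <- apply(x$pref, 1L, function(o)
    paste(x$outcomes[o], collapse = " + "))
  for (p in 1:4) cat(" ", x$persons[p], "->", prefs[p], "\n")
  invisible(x)
}

#' Outcome shared by two persons
#'
#' @param map A [build_task_map()] object.
#' @param p1,p2 Person indices (1:4).
#' @return The shared outcome id, or `NA_integer_` if the persons share no
#'   outcome (an invalid choice pair).
#' @export
shared_outcome <- function(map, p1, p2) {
  s <- intersect(map$pref[p1, ], map$pref[p2, ])
  if (length(s) == 1L) as.integer(s) else NA_integer_
}

#' Persons related to an outcome
#'
#' @param map A [build_task_map()] object.
#' @param outcome Outcome id (1:4).
#' @return Integer vector of the two persons whose preference pair contains
#'   the outcome.
#' @export
outcome_persons <- function(map, outcome) {
  which(map$pref[, 1] == outcome | map$pref[, 2] == outcome)
}
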