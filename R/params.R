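# Parameter vectors and model specifications for the hybrid MB/MF model.

#' Canonical model-parameter names
#'
#' The full parameter vector has 13 entries, always stored in this order:
#' `c_mf` (MFCA gain), `f_mf` (MF forgetting), the six MBCA gains
#' `c_mb_S1, c_mb_S2, c_mb_PI1, c_mb_PI2, c_mb_RI1, c_mb_RI2` (format x
#' temporal position), `f_mb` (MB forgetting), `pr` (perseveration gain),
#' `f_p` (perseveration forgetting), and the two cross-credit gains
#' `c_cross_12`, `c_cross_21` (retrospective-inference trials only; the
#' temporally i-th reward reinforcing the other outcome j). In the plain
#' hybrid model both cross gains are 0.
#'
#' @format A character vector of length 13.
#' @export
cm_param_names <- c(
  "c_mf", "f_mf",
  "c_mb_S1", "c_mb_S2", "c_mb_PI1", "c_mb_PI2", "c_mb_RI1", "c_mb_RI2",
  "f_mb", "pr", "f_p", "c_cross_12", "c_cross_21"
)

.ca_names <- c("c_mf", "c_mb_S1", "c_mb_S2", "c_mb_PI1", "c_mb_PI2",
               "c_mb_RI1", "c_mb_RI2")
.forget_names <- c("f_mf", "f_mb", "f_p")
.mb_names <- cm_param_names[3:8]

#' Construct a full model-parameter vector
#'
#' @param c_mf Model-free credit-assignment gain.
#' @param f_mf Model-free forgetting rate, in `[0, 1]`.
#' @param c_mb Six model-based credit-assignment gains, in the canonical
#'   order S1, S2, PI1, PI2, RI1, RI2 (format x temporal outcome position).
#'   A single value is recycled.
#' @param f_mb Model-based forgetting rate, in `[0, 1]`.
#' @param pr Perseveration gain.
#' @param f_p Perseveration forgetting rate, in `[0, 1]`.
#' @param c_cross_12,c_cross_21 Cross-credit gains on retrospective-inference
#'   trials (reward at position i reinforcing the outcome at position j).
#'   Zero under the plain hybrid model.
#' @return A named numeric vector of length 13 with class `cm_params`.
#' @examples
#' param_vector(c_mf = 0.3, c_mb = c(.25, .25, .2, .2, .15, .1), f_mb = 0.2)
#' @export
param_vector <- function(c_mf = 0, f_mf = 0, c_mb = 0, f_mb = 0,
                         pr = 0, f_p = 0, c_cross_12 = 0, c_cross_21 = 0) {
  if (length(c_mb) == 1L) c_mb <- rep(c_mb, 6L)
  stopifnot(length(c_mb) == 6L)
  x <- c(c_mf, f_mf, c_mb, f_mb, pr, f_p, c_cross_12, c_cross_21)
  names(x) <- cm_param_names
  validate_params(x)
  structure(x, class = "cm_params")
}

validate_params <- function(x) {
  stopifnot(length(x) == 13L, all(is.finite(x)))
  fr <- x[.forget_names]
  if (any(fr < 0 | fr > 1))
    stop("forgetting rates (f_mf, f_mb, f_p) must lie in [0, 1]")
  invisible(x)
}

as_param_vector <- function(x) {
  if (inherits(x, "cm_params")) return(x)
  stopifnot(is.numeric(x), length(x) == 13L)
  structure(setNames(as.numeric(x), cm_param_names), class = "cm_params")
}

#' @export
print.cm_params <- function(x, ...) {
  cat("<cm_params>\n")
  print(round(unclass(x), 4))
  invisible(x)
}

.spec_names <- c("full", "pure_MB", "pure_MF", "no_presentation_MBCA",
                 "no_position_MBCA", "no_format_MBCA", "additive_MBCA",
                 "flipped_functional", "RI_cross_CA")

#' Model specifications: the full hybrid model and its nested variants
#'
#' Returns a specification object mapping a reduced free-parameter vector to
#' the full 13-entry parameter vector (see [cm_param_names]). The family
#' comprises the full hybrid model, seven nested sub-models obtained by
#' constraining it, and one extension in which the full model is itself
#' nested:
#'
#' * `full`: all 11 plain parameters free (cross gains fixed at 0).
#' * `pure_MB`: no MFCA (`c_mf = f_mf = 0`).
#' * `pure_MF`: no MBCA (all `c_mb = 0`, `f_mb = 0`).
#' * `no_presentation_MBCA`: one common MBCA gain across formats and
#'   positions.
#' * `no_position_MBCA`: per-format MBCA gains, equal across positions.
#' * `no_format_MBCA`: per-position MBCA gains, equal across formats.
#' * `additive_MBCA`: MBCA gain = format effect + a common second-position
#'   offset (no interaction).
#' * `flipped_functional`: two MBCA gains indexed by *functional* position,
#'   i.e. the order in which credit assignment can operate; on
#'   retrospective-inference trials the temporal order is flipped, so
#'   `S1 = PI1 = RI2` and `S2 = PI2 = RI1`.
#' * `RI_cross_CA`: the full model plus the two cross-credit gains on
#'   retrospective-inference trials.
#'
#' @param name One of the model names above.
#' @param box_ca Bounds for credit-assignment and perseveration gains used by
#'   the fitting routines (forgetting rates are always bounded in `[0, 1]`).
#' @return An object of class `cm_spec`: a list with elements `name`, `free`
#'   (free-parameter names), `lower`/`upper` (the optimization box), and
#'   `expand(free)` mapping a free vector to a full `cm_params` vector.
#' @examples
#' spec <- model_spec("no_position_MBCA")
#' spec$expand(c(c_mf = .3, f_mf = .1, c_mb_S = .2, c_mb_PI = .2,
#'               c_mb_RI = .1, f_mb = .2, pr = .2, f_p = .5))
#' @export
model_spec <- function(name = .spec_names, box_ca = c(-5, 5)) {
  name <- match.arg(name)
  full_free <- cm_param_names[1:11]
  free <- switch(name,
    full = full_free,
    pure_MB = setdiff(full_free, c("c_mf", "f_mf")),
    pure_MF = c("c_mf", "f_mf", "pr", "f_p"),
    no_presentation_MBCA = c("c_mf", "f_mf", "c_mb", "f_mb", "pr", "f_p"),
    no_position_MBCA = c("c_mf", "f_mf", "c_mb_S", "c_mb_PI", "c_mb_RI",
                         "f_mb", "pr", "f_p"),
    no_format_MBCA = c("c_mf", "f_mf", "c_mb_1", "c_mb_2", "f_mb", "pr",
                       "f_p"),
    additive_MBCA = c("c_mf", "f_mf", "c_mb_S", "c_mb_PI", "c_mb_RI",
                      "c_mb_pos2", "f_mb", "pr", "f_p"),
    flipped_functional = c("c_mf", "f_mf", "c_mb_fun1", "c_mb_fun2", "f_mb",
                           "pr", "f_p"),
    RI_cross_CA = cm_param_names
  )
  is_forget <- free %in% .forget_names
  lower <- ifelse(is_forget, 0, box_ca[1])
  upper <- ifelse(is_forget, 1, box_ca[2])
  expand <- function(theta) {
    stopifnot(length(theta) == length(free))
    theta <- setNames(as.numeric(theta), free)
    full <- setNames(numeric(13L), cm_param_names)
    mb <- switch(name,
      pure_MF = numeric(6L),
      no_presentation_MBCA = rep(theta[["c_mb"]], 6L),
      no_position_MBCA = rep(theta[c("c_mb_S", "c_mb_PI", "c_mb_RI")],
                             each = 2L),
      no_format_MBCA = rep(theta[c("c_mb_1", "c_mb_2")], 3L),
      additive_MBCA = rep(theta[c("c_mb_S", "c_mb_PI", "c_mb_RI")],
                          each = 2L) + theta[["c_mb_pos2"]] * rep(0:1, 3L),
      flipped_functional = theta[c("c_mb_fun1", "c_mb_fun2", "c_mb_fun1",
                                   "c_mb_fun2", "c_mb_fun2", "c_mb_fun1")],
      # full, pure_MB, RI_cross_CA carry the six gains directly
      theta[.mb_names]
    )
    full[.mb_names] <- mb
    direct <- intersect(free, cm_param_names)
    full[direct] <- theta[direct]
    if (name == "pure_MF") full["f_mb"] <- 0
    structure(full, class = "cm_params")
  }
  structure(list(name = name, free = free, lower = setNames(lower, free),
                 upper = setNames(upper, free), expand = expand),
            class = "cm_spec")
}

#' @export
print.cm_spec <- function(x, ...) {
  cat("<cm_spec> ", x$name, " (", length(x$free), " free parameters)\n",
      sep = "")
  cat("  free:", paste(x$free, collapse = ", "), "\n")
  invisible(x)
}

#' Is one model specification nested in another?
#'
#' Every sub-model is nested in `full`, and `full` is nested in
#' `RI_cross_CA` (obtained by fixing both cross gains at 0).
#'
#' @param sub,super `cm_spec` objects or model names.
#' @return Logical.
#' @export
is_nested <- function(sub, super) {
  sub <- if (inherits(sub, "cm_spec")) sub$name else sub
  super <- if (inherits(super, "cm_spec")) super$name else super
  stopifnot(sub %in% .spec_names, super %in% .spec_names)
  if (sub == super) return(FALSE)
  if (super == "RI_cross_CA") return(TRUE)
  super == "full" && sub != "RI_cross_CA"
}

#' Names of the available model specifications
#' @return Character vector.
#' @export
model_names <- function() .spec_names
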