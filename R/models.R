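#' Choice-based learning model identifiers
#'
#' The package implements seven models of two-alternative preference
#' judgment. Five belong to Study-style set 1: a frequency-ratio
#' `control` model with no free parameters and four choice-based learning
#' (CBL) variants differing in which item values a choice updates
#' (`cbl_c`: chosen only, `cbl_r`: rejected only, `cbl_cr`: both with a
#' shared learning rate, `cbl_c_r`: both with separate rates). Two are
#' extensions of `cbl_cr`: `tbeta_cbl` replaces the constant inverse
#' temperature with one that grows with stimulus experience, and `f_cbl`
#' adds exponential forgetting of unpresented items' values.
#'
#' @return Character vector of the seven canonical model identifiers, in
#'   canonical order (used for tie-breaking in model comparison).
#' @export
#' @examples
#' cbl_models()
cbl_models <- function() {
  c("control", "cbl_c", "cbl_r", "cbl_cr", "cbl_c_r", "tbeta_cbl", "f_cbl")
}

.check_model <- function(model) {
  if (!is.character(model) || length(model) != 1L || !model %in% cbl_models()) {
    stop("unknown model id: ", paste(model, collapse = ", "),
         " (see cbl_models())", call. = FALSE)
  }
  model
}

#' Number of free parameters of a model
#'
#' @param model A model identifier from [cbl_models()].
#' @return Integer count `k` used in the AIC penalty.
#' @export
model_k <- function(model) {
  .check_model(model)
  c(control = 0L, cbl_c = 2L, cbl_r = 2L, cbl_cr = 2L, cbl_c_r = 3L,
    tbeta_cbl = 2L, f_cbl = 3L)[[model]]
}

#' Parameter names of a model, in canonical order
#'
#' @inheritParams model_k
#' @return Character vector of active parameter names (empty for the
#'   control model).
#' @export
model_params <- function(model) {
  .check_model(model)
  switch(model,
    control   = character(0),
    cbl_c     = c("alpha_c", "beta"),
    cbl_r     = c("alpha_r", "beta"),
    cbl_cr    = c("alpha_cr", "beta"),
    cbl_c_r   = c("alpha_c", "alpha_r", "beta"),
    tbeta_cbl = c("alpha_cr", "c"),
    f_cbl     = c("alpha_cr", "beta", "alpha_F")
  )
}

#' Parameter bounds and free-parameter count
#'
#' Learning rates (`alpha_c`, `alpha_r`, `alpha_cr`, `alpha_F`) are
#' bounded in \[0, 1\]; the inverse temperature `beta` in \[0,
#' `beta_max`\]; the experience exponent `c` of `tbeta_cbl` in \[0, 9\].
#' The same bounds are used for simulation priors and for the bounded
#' likelihood search.
#'
#' @inheritParams model_k
#' @param beta_max Upper bound of the inverse-temperature search range.
#'   20 for simulation work; 100 is the wider range for behavioral fits.
#' @return A list with named numeric vectors `lower` and `upper` and the
#'   integer `k`.
#' @export
#' @examples
#' param_space("cbl_c_r", beta_max = 20)
param_space <- function(model, beta_max = 20) {
  .check_model(model)
  stopifnot(is.numeric(beta_max), length(beta_max) == 1L, beta_max > 0)
  nm <- model_params(model)
  lower <- stats::setNames(rep(0, length(nm)), nm)
  upper <- stats::setNames(rep(1, length(nm)), nm)
  if ("beta" %in% nm) upper[["beta"]] <- beta_max
  if ("c" %in% nm) upper[["c"]] <- 9
  list(lower = lower, upper = upper, k = model_k(model))
}

.check_params <- function(model, params, beta_max = Inf) {
  nm <- model_params(model)
  if (length(nm) == 0L) return(stats::setNames(numeric(0), character(0)))
  if (is.null(names(params)) || !all(nm %in% names(params))) {
    stop("model '", model, "' needs named parameters: ",
         paste(nm, collapse = ", "), call. = FALSE)
  }
  p <- params[nm]
  if (any(!is.finite(p))) stop("non-finite parameter value", call. = FALSE)
  sp <- param_space(model, beta_max = if (is.finite(beta_max)) beta_max else 1e6)
  rate <- setdiff(nm, "beta")
  if (any(p[rate] < sp$lower[rate] - 1e-12) || any(p[rate] > sp$upper[rate] + 1e-12))
    stop("parameter out of bounds for model '", model, "'", call. = FALSE)
  if ("beta" %in% nm && p[["beta"]] < 0)
    stop("beta must be non-negative", call. = FALSE)
  p
}

#' Initialize the latent value state
#'
#' CBL-family models start every item at value 0.5 (novel stimuli assumed
#' equally preferred a priori); the control model starts at 0 because its
#' value is a chosen/presented count ratio, defined as 0 before the first
#' presentation. Presentation and choice counters start at zero.
#'
#' @inheritParams model_k
#' @param n_items Number of stimuli (>= 2).
#' @return An object of class `cbl_state`: a list with numeric `values`
#'   and integer `presented` and `chosen` counters, one element per item.
#' @export
#' @examples
#' init_state("cbl_cr", 15)$values[1:3]
init_state <- function(model, n_items) {
  .check_model(model)
  if (!is.numeric(n_items) || length(n_items) != 1L || n_items < 2)
    stop("invalid design: n_items must be >= 2", call. = FALSE)
  n_items <- as.integer(n_items)
  v0 <- if (model == "control") 0 else 0.5
  structure(
    list(values = rep(v0, n_items),
         presented = integer(n_items),
         chosen = integer(n_items)),
    class = "cbl_state", model = model)
}

.check_pair <- function(state, pair) {
  n <- length(state$values)
  if (length(pair) != 2L || anyNA(pair) || pair[1] == pair[2] ||
      any(pair < 1) || any(pair > n))
    stop("pair must be two distinct item indices in 1..n_items",
         call. = FALSE)
  as.integer(pair)
}

#' Effective softmax inverse temperature for a trial
#'
#' Constant-`beta` models return `params["beta"]` unchanged. For
#' `tbeta_cbl` the inverse temperature grows with experience:
#' `((N_L + N_R) / 2 * 1/10) ^ c`, where `N_L`, `N_R` are the
#' presentation counts of the on-screen pair *inclusive of the current
#' trial* — callers replaying a trial before updating counters must pass
#' a state whose counters already include the current presentation (the
#' internal replay engine adds 1 to each pair member's count).
#'
#' @inheritParams model_k
#' @param params Named numeric parameter vector (see [model_params()]).
#' @param state A `cbl_state` whose presentation counters include the
#'   current trial for the pair items.
#' @param pair Integer vector of the two on-screen item indices.
#' @return Non-negative scalar inverse temperature.
#' @export
effective_beta <- function(model, params, state, pair) {
  .check_model(model)
  if (model == "control")
    stop("unsupported model: the control model has no softmax", call. = FALSE)
  p <- .check_params(model, params)
  pair <- .check_pair(state, pair)
  if (model == "tbeta_cbl") {
    base <- mean(state$presented[pair]) / 10
    base ^ p[["c"]]
  } else {
    p[["beta"]]
  }
}

#' Probability a model assigns to choosing one pair member
#'
#' CBL-family models use a logistic (softmax) rule on the value
#' difference, `1 / (1 + exp(-beta * (V_candidate - V_other)))`, with the
#' effective inverse temperature of [effective_beta()]. The control model
#' uses the Laplace-smoothed frequency-ratio rule
#' `(V_candidate + 1) / (V_candidate + V_other + 2)` on its count-ratio
#' values. Probabilities of the two pair members sum to 1 and are
#' strictly inside (0, 1).
#'
#' @inheritParams effective_beta
#' @param candidate Item index whose choice probability is requested;
#'   must be a member of `pair`.
#' @return Probability in (0, 1).
#' @export
#' @examples
#' s <- init_state("cbl_cr", 3)
#' choice_probability("cbl_cr", c(alpha_cr = .5, beta = 5), s, c(1, 2), 1)
choice_probability <- function(model, params, state, pair, candidate) {
  .check_model(model)
  pair <- .check_pair(state, pair)
  if (length(candidate) != 1L || !candidate %in% pair)
    stop("candidate must be a member of pair", call. = FALSE)
  other <- pair[pair != candidate]
  v_c <- state$values[candidate]
  v_o <- state$values[other]
  if (model == "control") {
    (v_c + 1) / (v_c + v_o + 2)
  } else {
    b <- effective_beta(model, params, state, pair)
    1 / (1 + exp(-b * (v_c - v_o)))
  }
}

#' Apply one trial's outcome to the value state
#'
#' Increments the presentation counter of both pair members and the
#' choice counter of the chosen one, then updates values:
#' * CBL family: chosen value moves toward 1 by its learning rate,
#'   rejected value toward 0 by its rate — `(alpha_chosen,
#'   alpha_rejected)` is `(alpha_c, 0)` for `cbl_c`, `(0, alpha_r)` for
#'   `cbl_r`, `(alpha_cr, alpha_cr)` for `cbl_cr`/`tbeta_cbl`/`f_cbl`,
#'   and `(alpha_c, alpha_r)` for `cbl_c_r`.
#' * `f_cbl` additionally decays every *unpresented* item's value by the
#'   factor `(1 - alpha_F)`.
#' * control: values are recomputed as the count ratio chosen/presented
#'   (0 for never-presented items), so they never drift.
#' Unpresented items are untouched in all non-forgetting models.
#'
#' @inheritParams effective_beta
#' @param chosen Item index actually chosen; must be a member of `pair`.
#' @return The updated `cbl_state`.
#' @export
update_state <- function(model, params, state, pair, chosen) {
  .check_model(model)
  pair <- .check_pair(state, pair)
  if (length(chosen) != 1L || !chosen %in% pair)
    stop("chosen must be a member of pair", call. = FALSE)
  p <- .check_params(model, params)
  rejected <- pair[pair != chosen]
  state$presented[pair] <- state$presented[pair] + 1L
  state$chosen[chosen] <- state$chosen[chosen] + 1L
  if (model == "control") {
    seen <- state$presented > 0L
    state$values[seen] <- state$chosen[seen] / state$presented[seen]
    return(state)
  }
  a <- switch(model,
    cbl_c     = c(p[["alpha_c"]], 0),
    cbl_r     = c(0, p[["alpha_r"]]),
    cbl_cr    = rep(p[["alpha_cr"]], 2),
    tbeta_cbl = rep(p[["alpha_cr"]], 2),
    f_cbl     = rep(p[["alpha_cr"]], 2),
    cbl_c_r   = c(p[["alpha_c"]], p[["alpha_r"]]))
  state$values[chosen] <- state$values[chosen] + a[1] * (1 - state$values[chosen])
  state$values[rejected] <- state$values[rejected] + a[2] * (0 - state$values[rejected])
  if (model == "f_cbl") {
    idx <- setdiff(seq_along(state$values), pair)
    state$values[idx] <- (1 - p[["alpha_F"]]) * state$values[idx]
  }
  state
}
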