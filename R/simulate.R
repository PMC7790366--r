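#' Draw generating parameters from the simulation priors
#'
#' Each active parameter of `model` is drawn independently and uniformly
#' over its bounds: learning rates over \[0, 1\], the inverse temperature
#' over \[0, `beta_max`\] and the experience exponent `c` over \[0, 9\].
#' The control model has no parameters and returns an empty vector.
#'
#' @inheritParams param_space
#' @param seed Optional integer seed.
#' @return Named numeric vector of generating parameter values.
#' @export
sample_params <- function(model, beta_max = 20, seed = NULL) {
  sp <- param_space(model, beta_max)
  if (!is.null(seed)) set.seed(seed)
  if (sp$k == 0L) return(stats::setNames(numeric(0), character(0)))
  stats::setNames(stats::runif(length(sp$lower), sp$lower, sp$upper),
                  names(sp$lower))
}

# One-trial view of the state for probability evaluation: presentation
# counts must include the current trial for the experience-dependent
# inverse temperature (harmless for every other model, which reads only
# pre-trial values).
.prob_state <- function(state, pair) {
  state$presented[pair] <- state$presented[pair] + 1L
  state
}

#' Simulate a choice dataset from a model
#'
#' Walks the trial schedule: at each trial the model's choice probability
#' for the left item is computed from the current latent values, a choice
#' is sampled, and the value state is updated exactly as during
#' likelihood evaluation. Deterministic given (`params`, `schedule`,
#' `seed`).
#'
#' @inheritParams effective_beta
#' @param schedule A `cbl_schedule` from [build_schedule()].
#' @param seed Optional integer seed.
#' @param participant Participant identifier stored in the output.
#' @return A data frame of class `cbl_data` with columns `participant`,
#'   `trial`, `block`, `left`, `right`, `chosen`, `rt` (NA here),
#'   attribute `n_items`, and a `provenance` attribute recording the
#'   ground truth (`model`, `params`, `seed`).
#' @export
#' @examples
#' sch <- build_schedule(15, 21, seed = 1)
#' d <- simulate_dataset("cbl_cr", c(alpha_cr = .6, beta = 5), sch, seed = 2)
#' head(d)
simulate_dataset <- function(model, params, schedule, seed = NULL,
                             participant = "sim1") {
  .check_model(model)
  n_items <- attr(schedule, "n_items")
  if (is.null(n_items)) n_items <- max(schedule$left, schedule$right)
  params <- .check_params(model, params)
  if (!is.null(seed)) set.seed(seed)
  state <- init_state(model, n_items)
  n <- nrow(schedule)
  chosen <- integer(n)
  u <- stats::runif(n)
  for (t in seq_len(n)) {
    pair <- c(schedule$left[t], schedule$right[t])
    p_left <- choice_probability(model, params, .prob_state(state, pair),
                                 pair, pair[1])
    chosen[t] <- if (u[t] < p_left) pair[1] else pair[2]
    state <- update_state(model, params, state, pair, chosen[t])
  }
  out <- data.frame(participant = participant,
                    trial = schedule$trial,
                    block = schedule$block,
                    left = schedule$left,
                    right = schedule$right,
                    chosen = chosen,
                    rt = NA_real_)
  attr(out, "n_items") <- n_items
  attr(out, "provenance") <- list(model = model, params = params, seed = seed)
  class(out) <- c("cbl_data", "data.frame")
  out
}

#' Simulate a batch of datasets with freshly drawn parameters
#'
#' Each dataset draws its own generating parameters from the uniform
#' priors of [sample_params()] and, under the default `"fresh"` schedule
#' policy, its own randomized trial schedule (mirroring per-participant
#' randomization); `"shared"` reuses one schedule for the whole batch.
#'
#' @inheritParams sample_params
#' @param n_datasets Number of datasets to generate.
#' @param n_items,block_size Design passed to [build_schedule()].
#' @param schedule_policy `"fresh"` (default) or `"shared"`.
#' @param seed Integer master seed; every dataset is reproducible from
#'   it.
#' @return List of `cbl_data` objects, each carrying its provenance.
#' @export
simulate_batch <- function(model, n_datasets, beta_max = 20, n_items = 15,
                           block_size = 21,
                           schedule_policy = c("fresh", "shared"),
                           seed = NULL) {
  .check_model(model)
  stopifnot(n_datasets >= 1)
  schedule_policy <- match.arg(schedule_policy)
  if (!is.null(seed)) set.seed(seed)
  shared <- if (schedule_policy == "shared")
    build_schedule(n_items, block_size) else NULL
  lapply(seq_len(n_datasets), function(i) {
    params <- sample_params(model, beta_max)
    sch <- if (is.null(shared)) build_schedule(n_items, block_size) else shared
    simulate_dataset(model, params, sch,
                     participant = sprintf("%s_%03d", model, i))
  })
}

#' Generate a synthetic RT + rating cohort fixture
#'
#' A fixture generator for exercising the reaction-time conflict and
#' rating-consistency analyses; it is not one of the learning models.
#' Choices follow a logistic rule on fixed latent preferences. Mean RT
#' decreases linearly with the absolute latent-preference difference of
#' the on-screen pair (the injected conflict effect) with Gaussian noise,
#' floored at `rt_floor`. Ratings are a noisy monotone 5-point
#' discretization of latent preference; `rating_noise` decouples them
#' from choices as it grows.
#'
#' @param latent_preferences Numeric vector of per-item preference
#'   strengths (finite).
#' @param schedule A `cbl_schedule` over the same items.
#' @param choice_beta Logistic slope for choices on preference
#'   differences.
#' @param rt_base Mean RT (seconds) at zero preference difference.
#' @param conflict_gain Seconds of RT decrease per unit absolute
#'   preference difference.
#' @param rt_sd RT noise SD in seconds.
#' @param rt_floor Minimum RT in seconds.
#' @param rating_noise SD of Gaussian noise added to the scaled latent
#'   preference before discretizing to 1..5.
#' @param seed Optional integer seed.
#' @param participant Identifier for the generated participant.
#' @return A list with `data` (a `cbl_data` with `rt` filled in) and
#'   `ratings` (data frame `participant`, `item`, `rating`).
#' @export
simulate_rt_ratings <- function(latent_preferences, schedule,
                                choice_beta = 5, rt_base = 1.2,
                                conflict_gain = 0.4, rt_sd = 0.25,
                                rt_floor = 0.25, rating_noise = 0.25,
                                seed = NULL, participant = "sim1") {
  stopifnot(all(is.finite(latent_preferences)))
  n_items <- length(latent_preferences)
  if (!is.null(seed)) set.seed(seed)
  L <- schedule$left
  R <- schedule$right
  d <- latent_preferences[L] - latent_preferences[R]
  p_left <- 1 / (1 + exp(-choice_beta * d))
  take_left <- stats::runif(nrow(schedule)) < p_left
  chosen <- ifelse(take_left, L, R)
  rt <- pmax(rt_floor,
             stats::rnorm(nrow(schedule),
                          mean = rt_base - conflict_gain * abs(d),
                          sd = rt_sd))
  rng <- range(latent_preferences)
  z <- if (diff(rng) > 0)
    (latent_preferences - rng[1]) / diff(rng) else rep(0.5, n_items)
  rating <- pmin(5L, pmax(1L, as.integer(round(
    1 + 4 * z + stats::rnorm(n_items, sd = rating_noise)))))
  data <- data.frame(participant = participant,
                     trial = schedule$trial,
                     block = schedule$block,
                     left = L, right = R,
                     chosen = as.integer(chosen),
                     rt = rt)
  attr(data, "n_items") <- n_items
  class(data) <- c("cbl_data", "data.frame")
  list(data = data,
       ratings = data.frame(participant = participant,
                            item = seq_len(n_items),
                            rating = rating))
}
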