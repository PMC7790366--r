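.model_code <- function(model) {
  match(model, cbl_models()) - 1L
}

.check_data <- function(data) {
  need <- c("left", "right", "chosen")
  if (!all(need %in% names(data)))
    stop("dataset needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("empty dataset", call. = FALSE)
  if (any(data$chosen != data$left & data$chosen != data$right))
    stop("chosen item not a member of its pair", call. = FALSE)
  n_items <- attr(data, "n_items")
  if (is.null(n_items)) n_items <- max(data$left, data$right)
  as.integer(n_items)
}

#' Log-likelihood of a dataset under a model
#'
#' Replays the observed choices deterministically: per trial the
#' probability of the item actually chosen is computed from the current
#' latent values, then the state is updated — the identical state
#' evolution used when simulating. Probabilities are floored at
#' `prob_floor` inside the log to guard against underflow at extreme
#' inverse temperatures. The sum over trials of log probabilities is
#' returned.
#'
#' Two engines compute the same quantity: `"cpp"` (default, used by the
#' optimizer) and `"r"`, a plain-R replay through the exported step
#' functions, retained as an independent cross-check.
#'
#' @inheritParams effective_beta
#' @param data A `cbl_data` (or data frame with columns `left`, `right`,
#'   `chosen`).
#' @param prob_floor Lower bound applied to per-trial probabilities.
#' @param engine `"cpp"` or `"r"`.
#' @return Non-positive scalar log-likelihood.
#' @export
#' @examples
#' sch <- build_schedule(15, seed = 1)
#' d <- simulate_dataset("cbl_cr", c(alpha_cr = .5, beta = 0), sch, seed = 2)
#' log_likelihood("cbl_cr", c(alpha_cr = .5, beta = 0), d)  # 105 * log(0.5)
log_likelihood <- function(model, params, data, prob_floor = 1e-12,
                           engine = c("cpp", "r")) {
  .check_model(model)
  engine <- match.arg(engine)
  n_items <- .check_data(data)
  p <- .check_params(model, params)
  if (engine == "cpp") {
    return(cbl_loglik_cpp(.model_code(model), as.numeric(p),
                          as.integer(data$left), as.integer(data$right),
                          as.integer(data$chosen), n_items, prob_floor))
  }
  state <- init_state(model, n_items)
  ll <- 0
  for (t in seq_len(nrow(data))) {
    pair <- c(data$left[t], data$right[t])
    pr <- choice_probability(model, p, .prob_state(state, pair), pair,
                             data$chosen[t])
    ll <- ll + log(max(pr, prob_floor))
    state <- update_state(model, p, state, pair, data$chosen[t])
  }
  ll
}

#' Normalized likelihood
#'
#' `exp(LL / T)`: the geometric-mean per-trial probability the model
#' assigns to the observed choices. 0.5 is the chance anchor for binary
#' choice.
#'
#' @param log_lik Total log-likelihood.
#' @param n_trials Number of trials `T`.
#' @return Value in (0, 1\].
#' @export
normalized_likelihood <- function(log_lik, n_trials) {
  exp(log_lik / n_trials)
}

#' Fit one model to a dataset by bounded maximum likelihood
#'
#' Models with free parameters are fitted by bounded local maximization
#' of [log_likelihood()] (`stats::optim`, L-BFGS-B) from `n_restarts`
#' random interior starting points plus the midpoint of the box, keeping
#' the best solution; objective and step tolerances are on the order of
#' `tol`. The likelihood surfaces of these models can be multimodal,
#' hence the multi-start. The control model has nothing to optimize and
#' is evaluated directly.
#'
#' @inheritParams log_likelihood
#' @inheritParams param_space
#' @param n_restarts Number of random starting points.
#' @param tol Convergence tolerance on objective and step.
#' @return A list of class `cbl_fit`: `model`, `params_hat`,
#'   `log_likelihood`, `aic` (`-2 LL + 2k`), `normalized_likelihood`
#'   (`exp(LL/T)`), `n_trials`, `k`, `n_restarts_used`, `converged`.
#' @export
fit_model <- function(model, data, beta_max = 20, n_restarts = 10,
                      tol = 1e-8, prob_floor = 1e-12) {
  .check_model(model)
  n_items <- .check_data(data)
  sp <- param_space(model, beta_max)
  T_ <- nrow(data)
  left <- as.integer(data$left); right <- as.integer(data$right)
  ch <- as.integer(data$chosen); code <- .model_code(model)

  finish <- function(par, ll, restarts, converged) {
    structure(list(
      model = model,
      params_hat = par,
      log_likelihood = ll,
      aic = -2 * ll + 2 * sp$k,
      normalized_likelihood = normalized_likelihood(ll, T_),
      n_trials = T_, k = sp$k,
      n_restarts_used = restarts,
      converged = converged), class = "cbl_fit")
  }

  if (sp$k == 0L) {
    ll <- cbl_loglik_cpp(code, numeric(0), left, right, ch, n_items,
                         prob_floor)
    return(finish(stats::setNames(numeric(0), character(0)), ll, 0L, TRUE))
  }

  negll <- function(par)
    -cbl_loglik_cpp(code, par, left, right, ch, n_items, prob_floor)
  width <- sp$upper - sp$lower
  # deterministic coarse lattice pre-scan; its two best points seed the
  # local optimizer alongside the random restarts, so the multi-start is
  # anchored near the global basin even on multimodal surfaces
  axes <- rep(list(seq(0.02, 0.98, length.out = 8)), sp$k)
  lattice <- as.matrix(expand.grid(axes))
  lat_val <- apply(lattice, 1L, function(u) negll(sp$lower + u * width))
  lat_best <- lattice[order(lat_val)[1:2], , drop = FALSE]
  starts <- rbind(
    matrix(stats::runif(n_restarts * sp$k), ncol = sp$k) * 0.9 + 0.05,
    rep(0.5, sp$k),
    lat_best)
  best <- NULL
  any_conv <- FALSE
  for (i in seq_len(nrow(starts))) {
    st <- sp$lower + starts[i, ] * width
    res <- tryCatch(
      stats::optim(st, negll, method = "L-BFGS-B",
                   lower = sp$lower, upper = sp$upper,
                   control = list(factr = tol / .Machine$double.eps,
                                  pgtol = tol, maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (res$convergence == 0L) any_conv <- TRUE
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    # every restart errored: fall back to the best evaluated start
    vals <- apply(starts, 1L, function(u) negll(sp$lower + u * width))
    j <- which.min(vals)
    par <- stats::setNames(sp$lower + starts[j, ] * width, names(sp$lower))
    return(finish(par, -vals[j], nrow(starts), FALSE))
  }
  finish(stats::setNames(best$par, names(sp$lower)), -best$value,
         nrow(starts), any_conv)
}

#' @export
print.cbl_fit <- function(x, ...) {
  cat(sprintf("CBL fit: %s  (k = %d, T = %d)\n", x$model, x$k, x$n_trials))
  if (length(x$params_hat))
    cat("  params:", paste(sprintf("%s = %.4f", names(x$params_hat),
                                   x$params_hat), collapse = ", "), "\n")
  cat(sprintf("  LL = %.3f, AIC = %.2f, normalized likelihood = %.4f\n",
              x$log_likelihood, x$aic, x$normalized_likelihood))
  invisible(x)
}

#' Fit several models to one dataset and rank them by AIC
#'
#' The best model is the AIC minimizer; exact ties are broken toward
#' fewer free parameters, then canonical model order ([cbl_models()]).
#'
#' @inheritParams fit_model
#' @param models Character vector of model identifiers.
#' @return Data frame with one row per model (`model`, `k`, `log_lik`,
#'   `aic`, `zL`, `converged`, `best`), ordered as given; the full
#'   `cbl_fit` objects are in attribute `fits`, the winner's id in
#'   attribute `best_model`.
#' @export
fit_all_models <- function(data, models = cbl_models(), beta_max = 20,
                           n_restarts = 10, tol = 1e-8,
                           prob_floor = 1e-12) {
  stopifnot(length(models) >= 1L)
  fits <- lapply(models, fit_model, data = data, beta_max = beta_max,
                 n_restarts = n_restarts, tol = tol,
                 prob_floor = prob_floor)
  names(fits) <- models
  tab <- data.frame(
    model = models,
    k = vapply(fits, `[[`, integer(1), "k"),
    log_lik = vapply(fits, `[[`, numeric(1), "log_likelihood"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    zL = vapply(fits, `[[`, numeric(1), "normalized_likelihood"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    row.names = NULL)
  ord <- order(tab$aic, tab$k, match(tab$model, cbl_models()))
  best <- tab$model[ord[1L]]
  tab$best <- tab$model == best
  attr(tab, "fits") <- fits
  attr(tab, "best_model") <- best
  tab
}

#' Paired model comparison of AIC with Holm correction
#'
#' Paired two-sided t-tests on per-participant AIC for every model pair,
#' with Holm step-down adjustment across all pairs, per-model mean AIC
#' with standard errors, and the proportion of participants best fit by
#' each model (AIC minimum with the [fit_all_models()] tie-break).
#'
#' @param aic_matrix Numeric matrix, participants in rows, models in
#'   columns (column names are model ids).
#' @return A list with `pairs` (data frame: `model_a`, `model_b`,
#'   `mean_diff`, `t`, `df`, `p_raw`, `p_holm`, `degenerate`), `models`
#'   (data frame: `model`, `mean_aic`, `se_aic`, `best_fit_prop`) and
#'   `n_participants`. Pairs with identically zero AIC differences are
#'   undefined under the t-test and reported as p = 1 with
#'   `degenerate = TRUE`.
#' @export
compare_models_holm <- function(aic_matrix) {
  aic_matrix <- as.matrix(aic_matrix)
  n <- nrow(aic_matrix); m <- ncol(aic_matrix)
  if (m < 2L) stop("need at least 2 models", call. = FALSE)
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  ids <- colnames(aic_matrix)
  if (is.null(ids)) ids <- paste0("model", seq_len(m))
  cmb <- utils::combn(m, 2)
  pairs <- data.frame(model_a = ids[cmb[1, ]], model_b = ids[cmb[2, ]],
                      mean_diff = NA_real_, t = NA_real_, df = n - 1L,
                      p_raw = NA_real_, degenerate = FALSE)
  for (j in seq_len(ncol(cmb))) {
    d <- aic_matrix[, cmb[1, j]] - aic_matrix[, cmb[2, j]]
    pairs$mean_diff[j] <- mean(d)
    if (stats::sd(d) == 0) {
      pairs$t[j] <- if (mean(d) == 0) 0 else Inf
      pairs$p_raw[j] <- 1
      pairs$degenerate[j] <- TRUE
    } else {
      tt <- stats::t.test(aic_matrix[, cmb[1, j]], aic_matrix[, cmb[2, j]],
                          paired = TRUE)
      pairs$t[j] <- unname(tt$statistic)
      pairs$p_raw[j] <- tt$p.value
    }
  }
  pairs$p_holm <- stats::p.adjust(pairs$p_raw, method = "holm")
  pairs <- pairs[c("model_a", "model_b", "mean_diff", "t", "df",
                   "p_raw", "p_holm", "degenerate")]
  ord <- match(ids, cbl_models())
  winners <- apply(aic_matrix, 1L, function(a) {
    k <- vapply(ids, function(id)
      if (id %in% cbl_models()) model_k(id) else NA_integer_, integer(1))
    ids[order(a, k, ord)[1L]]
  })
  models <- data.frame(
    model = ids,
    mean_aic = colMeans(aic_matrix),
    se_aic = apply(aic_matrix, 2L, stats::sd) / sqrt(n),
    best_fit_prop = vapply(ids, function(id) mean(winners == id),
                           numeric(1)),
    row.names = NULL)
  list(pairs = pairs, models = models, n_participants = n)
}
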