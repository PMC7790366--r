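#' Parameter-recovery experiment for one model
#'
#' For each replicate: draw generating parameters from the uniform
#' priors, simulate a dataset on a freshly randomized schedule, refit the
#' generating model by bounded maximum likelihood, and record generating
#' vs recovered values. Recovery quality is summarized as the Pearson
#' correlation per parameter across replicates. Deterministic given
#' `seed`.
#'
#' @inheritParams simulate_batch
#' @inheritParams fit_model
#' @param n_sims Number of replicates (100 in the reference design).
#' @param schedule_policy `"fresh"` (default): each replicate simulates
#'   on its own randomized schedule, mirroring per-participant
#'   randomization; `"shared"`: one schedule for all replicates.
#' @param seed Integer master seed.
#' @return A list of class `cbl_recovery`: `model`, `n_sims`, `pairs`
#'   (data frame `sim`, `param`, `generating`, `recovered`),
#'   `correlations` (named vector; `NA` if a parameter has zero variance
#'   across replicates), `n_converged`, and the settings used.
#' @export
parameter_recovery <- function(model, n_sims = 100, beta_max = 20,
                               n_items = 15, block_size = 21,
                               n_restarts = 10,
                               schedule_policy = c("fresh", "shared"),
                               seed = NULL) {
  .check_model(model)
  schedule_policy <- match.arg(schedule_policy)
  if (model_k(model) < 1L)
    stop("parameter recovery needs a model with free parameters",
         call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  shared <- if (schedule_policy == "shared")
    build_schedule(n_items, block_size) else NULL
  nm <- model_params(model)
  gen <- matrix(NA_real_, n_sims, length(nm), dimnames = list(NULL, nm))
  rec <- gen
  n_conv <- 0L
  for (i in seq_len(n_sims)) {
    params <- sample_params(model, beta_max)
    sch <- if (is.null(shared)) build_schedule(n_items, block_size) else shared
    d <- simulate_dataset(model, params, sch,
                          participant = sprintf("%s_%03d", model, i))
    fit <- fit_model(model, d, beta_max = beta_max, n_restarts = n_restarts)
    gen[i, ] <- params[nm]
    rec[i, ] <- fit$params_hat[nm]
    if (fit$converged) n_conv <- n_conv + 1L
  }
  correlations <- vapply(nm, function(p) {
    if (stats::sd(gen[, p]) == 0 || stats::sd(rec[, p]) == 0)
      return(NA_real_)
    stats::cor(gen[, p], rec[, p])
  }, numeric(1))
  pairs <- data.frame(
    sim = rep(seq_len(n_sims), times = length(nm)),
    param = rep(nm, each = n_sims),
    generating = as.vector(gen),
    recovered = as.vector(rec))
  structure(list(model = model, n_sims = n_sims, pairs = pairs,
                 correlations = correlations, n_converged = n_conv,
                 settings = list(beta_max = beta_max, n_items = n_items,
                                 block_size = block_size,
                                 n_restarts = n_restarts, seed = seed)),
            class = "cbl_recovery")
}

#' @export
print.cbl_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery: %s (%d replicates, %d converged)\n",
              x$model, x$n_sims, x$n_converged))
  for (p in names(x$correlations))
    cat(sprintf("  r(%s) = %.3f\n", p, x$correlations[[p]]))
  invisible(x)
}

#' Model-recovery experiment (confusion matrix)
#'
#' For each generating model, simulates `n_sims_per_model` datasets with
#' parameters drawn from the uniform priors, fits every model in
#' `fitting_models` to each dataset, and declares the AIC minimizer the
#' winner (ties toward fewer parameters, then canonical order). Returns
#' the row-normalized confusion matrix plus the full per-dataset record
#' — generating parameters, all AICs, and winner — for conditional
#' summaries.
#'
#' @inheritParams parameter_recovery
#' @param generating_models,fitting_models Character vectors of model
#'   ids.
#' @param n_sims_per_model Datasets per generating model (500 in the
#'   reference design; reduced counts are usual at desk scale).
#' @return A list of class `cbl_model_recovery`: `confusion` (matrix,
#'   generating rows x fitted columns, rows summing to 1) and `records`
#'   (data frame with `generating_model`, `sim`, generating parameter
#'   columns `gen_*`, one `aic_*` column per fitted model, and `winner`).
#' @export
model_recovery <- function(generating_models, fitting_models = generating_models,
                           n_sims_per_model = 500, beta_max = 20,
                           n_items = 15, block_size = 21, n_restarts = 10,
                           seed = NULL) {
  stopifnot(length(generating_models) >= 1L, length(fitting_models) >= 1L)
  for (m in c(generating_models, fitting_models)) .check_model(m)
  if (!is.null(seed)) set.seed(seed)
  all_par <- unique(unlist(lapply(generating_models, model_params)))
  rows <- vector("list", length(generating_models) * n_sims_per_model)
  r <- 0L
  for (g in generating_models) {
    for (i in seq_len(n_sims_per_model)) {
      params <- sample_params(g, beta_max)
      sch <- build_schedule(n_items, block_size)
      d <- simulate_dataset(g, params, sch,
                            participant = sprintf("%s_%03d", g, i))
      tab <- fit_all_models(d, models = fitting_models,
                            beta_max = beta_max, n_restarts = n_restarts)
      rec <- as.list(stats::setNames(tab$aic, paste0("aic_", tab$model)))
      gp <- stats::setNames(rep(NA_real_, length(all_par)),
                            paste0("gen_", all_par))
      if (length(params))
        gp[paste0("gen_", names(params))] <- params
      r <- r + 1L
      rows[[r]] <- c(list(generating_model = g, sim = i), as.list(gp),
                     rec, list(winner = attr(tab, "best_model")))
    }
  }
  records <- do.call(rbind, lapply(rows, function(x)
    as.data.frame(x, stringsAsFactors = FALSE)))
  confusion <- matrix(0, length(generating_models), length(fitting_models),
                      dimnames = list(generating = generating_models,
                                      fitted = fitting_models))
  for (g in generating_models) {
    w <- records$winner[records$generating_model == g]
    for (f in fitting_models) confusion[g, f] <- mean(w == f)
  }
  structure(list(confusion = confusion, records = records,
                 settings = list(n_sims_per_model = n_sims_per_model,
                                 beta_max = beta_max, n_items = n_items,
                                 n_restarts = n_restarts, seed = seed)),
            class = "cbl_model_recovery")
}

#' @export
print.cbl_model_recovery <- function(x, ...) {
  cat("Model recovery confusion matrix (rows: generating; cols: best fit)\n")
  print(round(x$confusion, 3))
  invisible(x)
}

#' Conditional summary of generating learning rates by winning model
#'
#' For datasets generated by the separate-rates model (`cbl_c_r`),
#' groups the per-dataset records by which model won the AIC comparison
#' and summarizes the generating learning rates within each group: the
#' proportion of datasets with `alpha_c > alpha_r` and the means of the
#' generating `alpha_c` and `alpha_r`. Datasets won by `cbl_c` should be
#' dominated by `alpha_c`, `cbl_r` wins by `alpha_r`, and `cbl_cr` wins
#' by near-equal rates.
#'
#' @param records Per-dataset records from [model_recovery()].
#' @param generating_model Generating model to condition on (default
#'   `"cbl_c_r"`; it must have `gen_alpha_c`/`gen_alpha_r` stored).
#' @param winners Winning models to summarize (rows); groups with no
#'   datasets are omitted with a note in attribute `empty_groups`.
#' @return Data frame with columns `winner`, `n`, `prop_alpha_c_gt_r`,
#'   `mean_alpha_c`, `mean_alpha_r`.
#' @export
conditional_param_summary <- function(records,
                                      generating_model = "cbl_c_r",
                                      winners = c("cbl_c", "cbl_r", "cbl_cr")) {
  sub <- records[records$generating_model == generating_model, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no records generated by ", generating_model, call. = FALSE)
  if (!all(c("gen_alpha_c", "gen_alpha_r") %in% names(sub)))
    stop("records lack generating alpha_c/alpha_r columns", call. = FALSE)
  out <- lapply(winners, function(w) {
    g <- sub[sub$winner == w, , drop = FALSE]
    if (nrow(g) == 0L) return(NULL)
    data.frame(winner = w, n = nrow(g),
               prop_alpha_c_gt_r = mean(g$gen_alpha_c > g$gen_alpha_r),
               mean_alpha_c = mean(g$gen_alpha_c),
               mean_alpha_r = mean(g$gen_alpha_r))
  })
  empty <- winners[vapply(out, is.null, logical(1))]
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(winner = character(0), n = integer(0),
                      prop_alpha_c_gt_r = numeric(0),
                      mean_alpha_c = numeric(0), mean_alpha_r = numeric(0))
  attr(res, "empty_groups") <- empty
  res
}
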