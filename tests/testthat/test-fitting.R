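test_that("the two likelihood engines agree across models and datasets", {
  sch <- std_schedule(13)
  set.seed(13)
  for (m in cbl_models()) {
    p <- sample_params(m)
    d <- simulate_dataset(m, p, sch)
    expect_equal(log_likelihood(m, p, d, engine = "cpp"),
                 log_likelihood(m, p, d, engine = "r"),
                 tolerance = 1e-12, info = m)
  }
})

test_that("log-likelihood matches an independent scalar replay", {
  sch <- build_schedule(6, 5, seed = 21)
  d <- simulate_dataset("cbl_cr", c(alpha_cr = .7, beta = 9), sch, seed = 22)
  d10 <- d[1:10, ]
  attr(d10, "n_items") <- 6L
  expect_equal(log_likelihood("cbl_cr", c(alpha_cr = .7, beta = 9), d10),
               oracle_loglik_cbl(.7, .7, 9, d10, 6), tolerance = 1e-12)
  expect_equal(log_likelihood("cbl_c_r", c(alpha_c = .3, alpha_r = .6,
                                           beta = 4), d10),
               oracle_loglik_cbl(.3, .6, 4, d10, 6), tolerance = 1e-12)
})

test_that("chance-level probabilities give LL = T log(1/2) and zL = 0.5", {
  sch <- std_schedule(2)
  d <- simulate_dataset("cbl_cr", c(alpha_cr = .5, beta = 0), sch, seed = 1)
  ll <- log_likelihood("cbl_cr", c(alpha_cr = .5, beta = 0), d)
  expect_equal(ll, 105 * log(0.5), tolerance = 1e-12)
  expect_equal(normalized_likelihood(ll, 105), 0.5, tolerance = 1e-12)
  # control model, single first-presentation trial
  d1 <- fixed_winner_data()[1, ]
  attr(d1, "n_items") <- 3L
  expect_equal(log_likelihood("control", numeric(0), d1), log(0.5))
})

test_that("fit results satisfy the AIC and normalized-likelihood identities", {
  sch <- std_schedule(31)
  set.seed(31)
  d <- simulate_dataset("cbl_cr", c(alpha_cr = .6, beta = 8), sch)
  f <- fit_model("cbl_cr", d)
  expect_identical(f$aic, -2 * f$log_likelihood + 2 * f$k)
  expect_identical(f$normalized_likelihood,
                   exp(f$log_likelihood / f$n_trials))
  expect_true(all(f$params_hat >= param_space("cbl_cr")$lower))
  expect_true(all(f$params_hat <= param_space("cbl_cr")$upper))
  expect_true(f$converged)
  fc <- fit_model("control", d)
  expect_equal(fc$k, 0L)
  expect_identical(fc$aic, -2 * fc$log_likelihood)
})

test_that("fitting a flat likelihood recovers the chance-level optimum", {
  sch <- std_schedule(41)
  d <- simulate_dataset("cbl_cr", c(alpha_cr = .5, beta = 0), sch, seed = 41)
  set.seed(42)
  f <- fit_model("cbl_cr", d)
  # no structure to exploit: the maximum can be no better than slightly
  # above chance on 105 binary trials
  expect_gte(f$log_likelihood, 105 * log(0.5) - 1e-6)
  expect_lt(f$normalized_likelihood, 0.58)
})

test_that("multi-start optimizer is at least as good as an exhaustive grid", {
  set.seed(51)
  for (i in 1:5) {
    p <- sample_params("cbl_cr")
    sch <- build_schedule(15, 21)
    d <- simulate_dataset("cbl_cr", p, sch)
    f <- fit_model("cbl_cr", d)
    grid_a <- seq(0, 1, length.out = 41)
    grid_b <- seq(0, 20, length.out = 41)
    grid_ll <- max(vapply(grid_a, function(a)
      max(vapply(grid_b, function(b)
        log_likelihood("cbl_cr", c(alpha_cr = a, beta = b), d),
        numeric(1))), numeric(1)))
    expect_gte(f$log_likelihood, grid_ll - 1e-6)
  }
})

test_that("maximized likelihood respects model nesting", {
  set.seed(61)
  for (i in 1:5) {
    g <- sample(c("cbl_c", "cbl_r", "cbl_cr", "cbl_c_r"), 1)
    d <- simulate_dataset(g, sample_params(g), build_schedule(15, 21))
    lls <- vapply(c("cbl_c", "cbl_r", "cbl_cr", "cbl_c_r", "f_cbl"),
                  function(m) fit_model(m, d)$log_likelihood, numeric(1))
    expect_gte(lls[["cbl_c_r"]], lls[["cbl_c"]] - 1e-6)
    expect_gte(lls[["cbl_c_r"]], lls[["cbl_r"]] - 1e-6)
    expect_gte(lls[["cbl_c_r"]], lls[["cbl_cr"]] - 1e-6)
    expect_gte(lls[["f_cbl"]], lls[["cbl_cr"]] - 1e-6)
  }
})

test_that("fit_all_models ranks by AIC with the parsimony tie-break", {
  sch <- std_schedule(71)
  d <- simulate_dataset("cbl_cr", c(alpha_cr = .7, beta = 10), sch, seed = 71)
  set.seed(72)
  tab <- fit_all_models(d, models = c("control", "cbl_cr", "cbl_c_r"))
  expect_equal(nrow(tab), 3L)
  expect_equal(sum(tab$best), 1L)
  expect_equal(attr(tab, "best_model"), tab$model[tab$best])
  expect_equal(tab$aic, -2 * tab$log_lik + 2 * tab$k)
  # equal LL between nested models: fewer parameters must win
  expect_true(tab$aic[tab$model == "cbl_cr"] <
                tab$aic[tab$model == "cbl_c_r"] + 2 + 1e-9 ||
              attr(tab, "best_model") != "cbl_c_r")
})

test_that("Holm-corrected pairwise AIC comparison matches hand computation", {
  # identical columns -> degenerate pair reported with p = 1
  set.seed(81)
  aic <- cbind(a = rnorm(10, 100), b = rnorm(10, 120))
  aic <- cbind(aic, c = aic[, "a"])
  rep <- compare_models_holm(aic)
  dg <- rep$pairs[rep$pairs$model_a == "a" & rep$pairs$model_b == "c", ]
  expect_true(dg$degenerate)
  expect_equal(dg$p_holm, 1)
  expect_true(all(rep$pairs$df == 9))
  # Holm step-down on raw p = (.01, .02, .04) -> (.03, .04, .04)
  expect_equal(p.adjust(c(.01, .02, .04), method = "holm"),
               c(.03, .04, .04))
  # mean AIC / SE / best-fit proportions
  expect_equal(rep$models$mean_aic, unname(colMeans(aic)))
  expect_equal(rep$models$se_aic,
               unname(apply(aic, 2, sd) / sqrt(10)))
  expect_equal(sum(rep$models$best_fit_prop), 1)
  expect_error(compare_models_holm(aic[1:2, ]), "participants")
})
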