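test_that("model registry exposes seven models with fixed parameter counts", {
  ids <- cbl_models()
  expect_length(ids, 7L)
  expect_false(anyDuplicated(ids) > 0)
  k <- vapply(ids, model_k, integer(1))
  expect_identical(unname(k), c(0L, 2L, 2L, 2L, 3L, 2L, 3L))
  expect_error(model_k("softmax"), "unknown model")
})

test_that("initialization gives 0.5 values to CBL models and 0 to control", {
  s <- init_state("cbl_cr", 15)
  expect_equal(s$values, rep(0.5, 15))
  expect_equal(s$presented, integer(15))
  expect_equal(s$chosen, integer(15))
  expect_equal(init_state("control", 15)$values, rep(0, 15))
  expect_equal(init_state("f_cbl", 2)$values, c(0.5, 0.5))
  expect_error(init_state("cbl_cr", 1), "n_items")
})

test_that("parameter spaces match the declared bounds and counts", {
  sp <- param_space("cbl_c_r", 20)
  expect_equal(sp$lower, c(alpha_c = 0, alpha_r = 0, beta = 0))
  expect_equal(sp$upper, c(alpha_c = 1, alpha_r = 1, beta = 20))
  expect_equal(sp$k, 3L)
  expect_equal(param_space("control")$k, 0L)
  expect_length(param_space("control")$lower, 0L)
  sp2 <- param_space("tbeta_cbl")
  expect_equal(sp2$upper[["c"]], 9)
  expect_equal(sp2$k, 2L)
  sp3 <- param_space("cbl_cr", beta_max = 100)
  expect_equal(sp3$upper[["beta"]], 100)
})

test_that("effective beta follows the experience rule for tbeta_cbl", {
  s <- init_state("tbeta_cbl", 15)
  # counts are inclusive of the current trial's presentation
  s$presented[1:2] <- 10L
  expect_equal(effective_beta("tbeta_cbl", c(alpha_cr = .5, c = 3.7),
                              s, c(1, 2)), 1)
  s$presented[1:2] <- c(4L, 7L)
  expect_equal(effective_beta("tbeta_cbl", c(alpha_cr = .5, c = 0),
                              s, c(1, 2)), 1)
  s$presented[1:2] <- 1L
  expect_equal(effective_beta("tbeta_cbl", c(alpha_cr = .5, c = 2),
                              s, c(1, 2)), 0.01)
  expect_equal(effective_beta("cbl_cr", c(alpha_cr = .5, beta = 7.3),
                              s, c(1, 2)), 7.3)
  expect_error(effective_beta("control", numeric(0), s, c(1, 2)),
               "unsupported")
})

test_that("choice probabilities are normalized, interior, and match closed forms", {
  s <- init_state("cbl_cr", 3)
  p <- c(alpha_cr = .5, beta = 10)
  expect_equal(choice_probability("cbl_cr", p, s, c(1, 2), 1), 0.5)
  s$values <- c(0.6, 0.5, 0.5)
  expect_equal(choice_probability("cbl_cr", p, s, c(1, 2), 1),
               1 / (1 + exp(-1)), tolerance = 1e-12)
  sc <- init_state("control", 3)
  expect_equal(choice_probability("control", numeric(0), sc, c(1, 2), 1), 0.5)
  expect_error(choice_probability("cbl_cr", p, s, c(1, 2), 3), "member")

  # normalization and interiority across models and random states
  set.seed(42)
  for (m in setdiff(cbl_models(), "control")) {
    for (rep in 1:20) {
      st <- init_state(m, 5)
      st$values <- runif(5)
      st$presented <- sample.int(10, 5, replace = TRUE)
      pp <- sample_params(m)
      p1 <- choice_probability(m, pp, st, c(2, 4), 2)
      p2 <- choice_probability(m, pp, st, c(2, 4), 4)
      expect_equal(p1 + p2, 1, tolerance = 1e-12)
      expect_gt(p1, 0); expect_lt(p1, 1)
    }
  }
  # beta = 0 forces 0.5 whatever the values
  s$values <- c(0.9, 0.1, 0.4)
  expect_equal(choice_probability("cbl_cr", c(alpha_cr = .5, beta = 0),
                                  s, c(1, 2), 1), 0.5)
})

test_that("value updates follow the chosen/rejected learning-rate table", {
  s <- init_state("cbl_cr", 3)
  s2 <- update_state("cbl_cr", c(alpha_cr = .5, beta = 1), s, c(1, 2), 1)
  expect_equal(s2$values[1:2], c(0.75, 0.25))
  expect_equal(s2$presented, c(1L, 1L, 0L))
  expect_equal(s2$chosen, c(1L, 0L, 0L))

  s3 <- update_state("cbl_c", c(alpha_c = .4, beta = 1), s, c(1, 2), 1)
  expect_equal(s3$values[1:2], c(0.7, 0.5))  # rejected untouched
  s4 <- update_state("cbl_r", c(alpha_r = .4, beta = 1), s, c(1, 2), 1)
  expect_equal(s4$values[1:2], c(0.5, 0.3))  # chosen untouched

  # f_cbl decays only unpresented items
  sf <- init_state("f_cbl", 4)
  sf2 <- update_state("f_cbl", c(alpha_cr = .5, beta = 1, alpha_F = .2),
                      sf, c(1, 2), 1)
  expect_equal(sf2$values, c(0.75, 0.25, 0.4, 0.4))
  # alpha_F = 0 leaves unpresented values identical to cbl_cr
  sf3 <- update_state("f_cbl", c(alpha_cr = .5, beta = 1, alpha_F = 0),
                      sf, c(1, 2), 1)
  expect_equal(sf3$values[3:4], c(0.5, 0.5))

  expect_error(update_state("cbl_cr", c(alpha_cr = .5, beta = 1),
                            s, c(1, 2), 3), "member")
})

test_that("control model values are chosen/presented count ratios", {
  s <- init_state("control", 3)
  # item 1 chosen 3 of 4 presentations against alternating opponents
  for (tr in list(c(1, 2, 1), c(1, 3, 1), c(1, 2, 2), c(1, 3, 1)))
    s <- update_state("control", numeric(0), s, tr[1:2], tr[3])
  expect_equal(s$values[1], 0.75)
  expect_equal(s$presented[1], 4L)
  expect_equal(s$chosen[1], 3L)
})

test_that("CBL values stay in [0,1] under any random update sequence", {
  set.seed(7)
  for (m in c("cbl_c", "cbl_r", "cbl_cr", "cbl_c_r", "tbeta_cbl", "f_cbl")) {
    pp <- sample_params(m)
    s <- init_state(m, 6)
    for (t in 1:200) {
      pair <- sample.int(6, 2)
      s <- update_state(m, pp, s, pair, sample(pair, 1))
      expect_true(all(s$values >= 0 & s$values <= 1))
      expect_true(all(s$chosen <= s$presented))
    }
  }
})

test_that("nested models reduce to each other on identical inputs", {
  sch <- std_schedule(3)
  d <- simulate_dataset("cbl_c_r", c(alpha_c = .4, alpha_r = .4, beta = 6),
                        sch, seed = 9)
  a <- 0.37; b <- 4.2
  expect_equal(
    log_likelihood("cbl_c_r", c(alpha_c = a, alpha_r = a, beta = b), d),
    log_likelihood("cbl_cr", c(alpha_cr = a, beta = b), d))
  expect_equal(
    log_likelihood("cbl_c_r", c(alpha_c = a, alpha_r = 0, beta = b), d),
    log_likelihood("cbl_c", c(alpha_c = a, beta = b), d))
  expect_equal(
    log_likelihood("cbl_c_r", c(alpha_c = 0, alpha_r = a, beta = b), d),
    log_likelihood("cbl_r", c(alpha_r = a, beta = b), d))
  expect_equal(
    log_likelihood("f_cbl", c(alpha_cr = a, beta = b, alpha_F = 0), d),
    log_likelihood("cbl_cr", c(alpha_cr = a, beta = b), d))
  expect_equal(
    log_likelihood("tbeta_cbl", c(alpha_cr = a, c = 0), d),
    log_likelihood("cbl_cr", c(alpha_cr = a, beta = 1), d))
})
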