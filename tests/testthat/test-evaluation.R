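test_that("degenerate-prevalence columns are dropped by name", {
  X <- cbind(all1 = rep(1, 10), all0 = rep(0, 10),
             rare = c(1, rep(0, 9)))
  r <- drop_degenerate_columns(X)
  expect_setequal(r$dropped, c("all1", "all0"))
  expect_identical(colnames(r$design), "rare")
  r0 <- drop_degenerate_columns(X[, 0])
  expect_equal(ncol(r0$design), 0L)
  expect_length(r0$dropped, 0L)
})

test_that("logistic fits match closed-form maximum likelihood", {
  # 2x2 table: x=1 -> 10 events / 40 non-events; x=0 -> 5 / 45
  x <- c(rep(1, 50), rep(0, 50))
  y <- c(rep(1, 10), rep(0, 40), rep(1, 5), rep(0, 45))
  f <- fit_logistic(cbind(x = x), y)
  expect_equal(unname(f$coefficients["x"]), log((10 * 45) / (40 * 5)),
               tolerance = 1e-6)

  f0 <- fit_logistic(matrix(nrow = 100, ncol = 0),
                     c(rep(1, 30), rep(0, 70)))
  expect_equal(unname(f0$coefficients["(Intercept)"]), log(30 / 70),
               tolerance = 1e-8)
  expect_equal(f0$n_parameters, 0L)

  expect_error(fit_logistic(cbind(x = x), rep(0, 100)),
               "degenerate outcome")
})

test_that("complete separation is flagged", {
  y <- c(rep(0, 20), rep(1, 20))
  f <- fit_logistic(cbind(x = y), y)
  expect_true(f$separation)
})

test_that("G2 is zero for identical or redundant nested models", {
  set.seed(2)
  x <- rnorm(80); y <- rbinom(80, 1, plogis(x))
  base <- fit_logistic(cbind(x = x), y)
  expect_equal(g2_statistic(base, base)$g2, 0)
  expect_equal(g2_statistic(base, base)$p, 1)
  dup <- fit_logistic(cbind(x = x, x2 = x), y)
  g <- g2_statistic(dup, base)
  expect_lt(abs(g$g2), 1e-6)
  expect_equal(g$df_diff, 0L)  # aliased copy estimates no extra parameter
})

test_that("G2 matches an independent likelihood-maximization oracle", {
  set.seed(33)
  for (rep in 1:50) {
    n <- 60
    p <- sample(1:3, 1)
    X <- matrix(rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("v", seq_len(p))))
    y <- rbinom(n, 1, plogis(0.3 * X[, 1]))
    if (length(unique(y)) < 2) next
    base <- fit_logistic(X[, 1, drop = FALSE], y)
    full <- fit_logistic(X, y)
    g <- g2_statistic(full, base)
    oracle <- 2 * (direct_loglik(X, y) - direct_loglik(X[, 1, drop = FALSE], y))
    expect_equal(g$g2, oracle, tolerance = 1e-6)
    expect_equal(g$df_diff, p - 1L)
    expect_equal(g$df_total, p)
  }
})

test_that("non-nested fits are rejected", {
  set.seed(4)
  x <- rnorm(50); z <- rnorm(50); y <- rbinom(50, 1, 0.4)
  fx <- fit_logistic(cbind(a = x), y)
  fz <- fit_logistic(cbind(b = z), y)
  expect_error(g2_statistic(fx, fz), "not nested")
  f30 <- fit_logistic(cbind(a = x[1:30]), y[1:30])
  expect_error(g2_statistic(fx, f30), "different numbers of rows")
})

test_that("c-statistic anchors: chance is 0.5, perfect separation is 1", {
  y <- rep(c(1, 0), 25)
  expect_equal(c_statistic(rep(0.3, 50), y), 0.5)
  expect_equal(c_statistic(ifelse(y == 1, 2, 1), y), 1)
  expect_equal(c_statistic(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  expect_error(c_statistic(1:4, rep(1, 4)), "single class")
})

test_that("c-statistic equals brute-force pair enumeration everywhere", {
  set.seed(9)
  for (rep in 1:300) {
    n <- sample(4:12, 1)
    scores <- sample(seq(0, 1, 0.1), n, replace = TRUE)  # many ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    expect_equal(c_statistic(scores, y), brute_force_c(scores, y))
  }
})

test_that("c-statistic is invariant under strictly increasing transforms", {
  set.seed(10)
  scores <- rnorm(60); y <- rbinom(60, 1, 0.4)
  c0 <- c_statistic(scores, y)
  expect_equal(c_statistic(exp(scores), y), c0)
  expect_equal(c_statistic(rank(scores), y), c0)
})

test_that("the bootstrap CI is seeded and degenerates correctly", {
  set.seed(14)
  X <- cbind(x = rnorm(100))
  y <- rbinom(100, 1, plogis(X[, 1]))
  b1 <- bootstrap_c_ci(X, y, n_reps = 50, seed = 7)
  b2 <- bootstrap_c_ci(X, y, n_reps = 50, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_lte(b1$ci_low, b1$ci_high)

  # perfectly separable toy data: every replicate has c = 1
  ys <- c(rep(0, 30), rep(1, 30))
  bs <- bootstrap_c_ci(cbind(x = ys), ys, n_reps = 30, seed = 3)
  expect_equal(unname(c(bs$ci_low, bs$ci_high)), c(1, 1))
})

test_that("the percentile CI attains near-nominal coverage", {
  # scaled-down Monte Carlo: logistic truth, large-sample c from n = 1e5
  set.seed(123)
  beta <- 1
  big_x <- rnorm(100000)
  big_y <- rbinom(100000, 1, plogis(beta * big_x))
  true_c <- c_statistic(big_x, big_y)
  cover <- 0; runs <- 60
  for (r in seq_len(runs)) {
    x <- rnorm(400)
    y <- rbinom(400, 1, plogis(beta * x))
    if (length(unique(y)) < 2) next
    b <- bootstrap_c_ci(cbind(x = x), y, n_reps = 100, seed = r)
    cover <- cover + (b$ci_low <= true_c && true_c <= b$ci_high)
  }
  expect_gte(cover / runs, 0.85)
})

test_that("paired comparison: identical designs tie, signal beats noise", {
  set.seed(55)
  x <- rnorm(300); y <- rbinom(300, 1, plogis(x))
  same <- paired_bootstrap_compare(cbind(a = x), cbind(a = x), y,
                                   n_reps = 40, seed = 2)
  expect_equal(same$win_frac_a, 0)
  expect_equal(same$ties, 1)

  # adding a pure-noise column to B gives A no systematic advantage
  z <- rnorm(1000); yy <- rbinom(1000, 1, plogis(z))
  noise <- paired_bootstrap_compare(cbind(s = z),
                                    cbind(s = z, noise = rnorm(1000)), yy,
                                    n_reps = 200, seed = 3)
  expect_gt(noise$win_frac_a, 0.2)
  expect_lt(noise$win_frac_a, 0.8)

  # outcome generated from covariates only A observes
  n <- 1500
  X <- matrix(rbinom(n * 3, 1, 0.3), n, 3,
              dimnames = list(NULL, paste0("c", 1:3)))
  yd <- rbinom(n, 1, plogis(-1.5 + X %*% c(1.2, 1, 0.8)))
  dom <- paired_bootstrap_compare(X, cbind(junk = rnorm(n)), yd,
                                  n_reps = 100, seed = 4)
  expect_gte(dom$win_frac_a, 0.95)
})

test_that("comorbidity_model wires fits, G2 and bootstrap together", {
  sim <- simulate_population(load_scenario("ami", n_patients = 800,
                                           seed = 19))
  cohort <- build_cohort(sim$dataset, disease_definition("AMI"))
  fit <- comorbidity_model(cohort, sim$dataset, outcome = "one_year",
                           method = "charlson_romano",
                           period = "index_plus_prior",
                           n_bootstrap = 25, seed = 6)
  expect_s3_class(fit, "comorbidity_model")
  expect_gte(fit$g2$g2, 0)
  expect_equal(fit$g2$df_total, fit$fit$n_parameters)
  expect_equal(fit$g2$df_diff, fit$fit$n_parameters - 4L)
  expect_true(fit$c_statistic > 0.5 && fit$c_statistic < 1)
  expect_lte(fit$ci[1], fit$ci[2])
  expect_equal(length(coef(fit)), fit$fit$n_parameters + 1L +
                 sum(is.na(coef(fit))))
  expect_output(print(fit), "c-statistic")
  s <- summary(fit)
  expect_s3_class(s, "summary.comorbidity_model")
  pr <- predict(fit)
  expect_equal(unname(c_statistic(pr, fit$y)), fit$c_statistic)
})
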