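# closed-form checks, parameter-recovery oracles and invariances for the
# statistics layer

test_that("the power-law MLE matches its closed form", {
  # all mass at e * x_min makes sum(log(x/x_min)) = n, so mu-hat = 2 exactly
  x <- rep(exp(1), 10)
  fit <- fit_power_law(x, x_min = 1)
  expect_equal(fit$parameter, 2)
  expect_equal(fit$aic, 2 - 2 * fit$log_likelihood)
  expect_error(fit_power_law(c(2, 3, 4), 1), "fewer than 5")
  expect_error(fit_power_law(rep(1, 10), 1), "undefined")
  expect_error(fit_power_law(c(0.5, rep(2, 6)), 1), ">= x_min")
})

test_that("the shifted-exponential MLE matches its closed form", {
  x <- 1 + c(2, 4, 6, 4, 4)    # mean(x - x_min) = 4
  fit <- fit_exponential(x, x_min = 1)
  expect_equal(fit$parameter, 0.25)
  expect_error(fit_exponential(rep(1, 10), 1), "undefined")
})

test_that("both MLEs recover generating parameters within 2% at n = 10^4", {
  n <- 1e4
  set.seed(123)
  for (mu in c(1.3, 1.63, 2.0)) {
    x <- runif(n)^(-1 / (mu - 1))        # inverse-CDF Pareto sample, x_min = 1
    fit <- fit_power_law(x, x_min = 1)
    expect_lt(abs(fit$parameter - mu) / mu, 0.02)
  }
  for (lambda in c(0.1, 0.29, 1.0)) {
    x <- 1 + rexp(n, rate = lambda)
    fit <- fit_exponential(x, x_min = 1)
    expect_lt(abs(fit$parameter - lambda) / lambda, 0.02)
  }
})

test_that("Akaike weights are symmetric, normalised and shift-invariant", {
  x <- c(1, 1, 2, 3, 8, 1, 2, 1, 5, 1)
  pl <- fit_power_law(x)
  ex <- fit_exponential(x)
  w <- akaike_weights(list(pl, ex))
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0 & w <= 1))
  # equal AICs split evenly
  w_eq <- akaike_weights(list(pl, pl))
  expect_equal(unname(w_eq), c(0.5, 0.5))
  # a common AIC shift changes nothing
  pl2 <- pl; ex2 <- ex
  pl2$aic <- pl$aic + 123.4
  ex2$aic <- ex$aic + 123.4
  expect_equal(akaike_weights(list(pl2, ex2)), w)
  # a 10-unit AIC gap
  ex3 <- ex; ex3$aic <- pl$aic + 10
  w10 <- akaike_weights(list(pl, ex3))
  expect_equal(unname(w10), c(0.99330714907572, 0.00669285092428), tolerance = 1e-10)
  # mismatched samples are refused
  ex4 <- ex; ex4$n_obs <- ex$n_obs + 1
  expect_error(akaike_weights(list(pl, ex4)), "different numbers")
})

test_that("the G statistic matches hand evaluation and vanishes iff O = E", {
  expect_equal(g_statistic(c(50, 30, 20), c(40, 40, 20)),
               2 * (50 * log(50 / 40) + 30 * log(30 / 40)))
  expect_equal(g_statistic(c(50, 30, 20), c(40, 40, 20)), 5.0534,
               tolerance = 1e-4)
  expect_equal(g_statistic(c(7, 3, 9), c(7, 3, 9)), 0)
  expect_gt(g_statistic(c(8, 3, 9), c(7, 4, 9)), 0)
})

test_that("the binned G-test accepts well-specified samples and has sane df", {
  set.seed(7)
  x <- runif(400)^(-1 / 0.8)           # Pareto, mu = 1.8
  fit <- fit_power_law(x, 1)
  gof <- g_test_gof(x, fit)
  expect_gte(gof$df, 1)
  expect_gt(gof$p_value, 0.05)
  expect_false(gof$significant)
  # too narrow a spread leaves too few bins to test
  expect_error(g_test_gof(c(1, 1.1, 1.2, 1.3, 1.05), fit_power_law(c(1, 1.1, 1.2, 1.3, 1.05))),
               "fewer than 3 bins")
})

test_that("i.i.d. intervals scale as a random walk, constants not at all", {
  set.seed(11)
  fr <- fluctuation_function(rexp(1e4))
  expect_gt(fr$alpha, 0.45)
  expect_lt(fr$alpha, 0.55)
  const <- fluctuation_function(rep(4, 100))
  expect_true(const$degenerate)
  expect_true(all(const$f_values == 0))
  expect_true(is.na(const$alpha))
})

test_that("the fluctuation function ignores a constant interval offset", {
  set.seed(13)
  dt <- rpois(500, 10)
  a <- fluctuation_function(dt)
  b <- fluctuation_function(dt + 1000)
  expect_equal(a$f_values, b$f_values)
  expect_equal(a$alpha, b$alpha)
})

test_that("model comparison pools magnitudes, drops zeros and picks a winner", {
  set.seed(5)
  inc <- c(0, 0, diff(round(1 + runif(400)^(-1 / 0.7))))
  mc <- compare_increment_models(inc)
  expect_identical(mc$n_obs, sum(abs(inc) > 0))
  expect_equal(sum(mc$akaike_weights), 1)
  expect_true(mc$preferred %in% c("power_law", "exponential"))
  expect_identical(names(mc$akaike_weights)[which.max(mc$akaike_weights)],
                   mc$preferred)
})
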