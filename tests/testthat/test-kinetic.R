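# Verhulst logistic growth with the Pirt-type respiration split.

test_that("verhulst_weight matches the closed form at its landmarks", {
  p <- logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
  expect_equal(verhulst_weight(0, p), 1)
  expect_equal(verhulst_weight(200, p), 100, tolerance = 1e-9)
  # midpoint: X = Xmax/2 exactly at t = ln((Xmax-X0)/X0)/mu
  expect_equal(verhulst_weight(log(99) / 0.5, p), 50, tolerance = 1e-12)
  # strictly increasing, bounded
  tt <- seq(0, 40, by = 0.5)
  xx <- verhulst_weight(tt, p)
  expect_true(all(diff(xx) > 0))
  expect_true(all(xx >= 1 & xx <= 100))
  expect_error(verhulst_weight(-1, p), ">= 0")
  expect_error(verhulst_weight(NaN, p), "finite")
})

test_that("kinetic growth rate is the logistic rate, zero at both ends", {
  p <- logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
  expect_equal(kinetic_growth_rate(50, p), 12.5)
  expect_equal(kinetic_growth_rate(0, p), 0)
  expect_equal(kinetic_growth_rate(100, p), 0)
  expect_error(kinetic_growth_rate(101, p), "0, Xmax")
})

test_that("respiration splits into growth-associated and maintenance terms", {
  q <- pirt_params(Y = 0.44, m = 0.08)
  expect_equal(kinetic_respiration_rate(0, 10, q), 0.8)
  expect_equal(kinetic_respiration_rate(1, 0, q), 0.44)
  expect_equal(kinetic_respiration_rate(2.0, 25, q), 2.88)
  expect_error(kinetic_respiration_rate(-1, 5, q), ">= 0")
  # non-negative and increasing in each argument and coefficient
  base <- kinetic_respiration_rate(1, 10, q)
  expect_gt(kinetic_respiration_rate(2, 10, q), base)
  expect_gt(kinetic_respiration_rate(1, 20, q), base)
  expect_gt(kinetic_respiration_rate(1, 10, pirt_params(0.6, 0.08)), base)
  expect_gt(kinetic_respiration_rate(1, 10, pirt_params(0.44, 0.1)), base)
})

test_that("assimilation is growth plus respiration; m = 0 gives the 1/(1+Y) identity", {
  expect_equal(kinetic_assimilation_rate(0, 0), 0)
  expect_equal(kinetic_assimilation_rate(12.5, 2.88), 15.38)
  q0 <- pirt_params(Y = 0.44, m = 0)
  p <- logistic_params(0.5, 1, 100)
  for (X in c(5, 30, 60, 95)) {
    r_X <- kinetic_growth_rate(X, p)
    r_A <- kinetic_assimilation_rate(r_X, kinetic_respiration_rate(r_X, X, q0))
    expect_equal(r_X / r_A, 1 / 1.44, tolerance = 1e-12)
  }
})

test_that("closed-form curve agrees with explicit integration of the rate", {
  p <- logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
  # explicit fixed-step RK4 at dt = 1e-3 d over [0, 30]
  dt <- 1e-3
  tt <- seq(0, 30, by = dt)
  x <- p$X0
  num <- numeric(length(tt)); num[1] <- x
  f <- function(x) p$mu * x * (1 - x / p$Xmax)
  for (i in 2:length(tt)) {
    k1 <- f(x); k2 <- f(x + dt / 2 * k1)
    k3 <- f(x + dt / 2 * k2); k4 <- f(x + dt * k3)
    x <- x + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    num[i] <- x
  }
  expect_lt(max(abs(num - verhulst_weight(tt, p)) / verhulst_weight(tt, p)),
            1e-5)
})

test_that("fit_verhulst recovers generating parameters from noiseless data", {
  p <- logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
  tt <- 0:20
  fit <- fit_verhulst(tt, verhulst_weight(tt, p))
  expect_true(fit$converged)
  expect_equal(fit$params$mu, 0.5, tolerance = 1e-4)
  expect_equal(fit$params$X0, 1, tolerance = 1e-4)
  expect_equal(fit$params$Xmax, 100, tolerance = 1e-4)
  expect_true(is.finite(fit$rss))
})

test_that("fit_verhulst flags degenerate and insufficient series", {
  expect_error(fit_verhulst(c(0, 1, 2), c(1, 2, 3)), "insufficient")
  flat <- fit_verhulst(0:10, rep(5, 11))
  expect_false(flat$converged)
  expect_true(flat$degenerate)
})

test_that("fit_verhulst tolerates multiplicative noise (20 seeds)", {
  p <- logistic_params(mu = 0.5, X0 = 1, Xmax = 100)
  tt <- 0:20
  clean <- verhulst_weight(tt, p)
  rel_err_mu <- vapply(1:20, function(s) {
    set.seed(s)
    sdlog <- sqrt(log(1 + 0.05^2))
    x <- clean * rlnorm(length(tt), -sdlog^2 / 2, sdlog)
    fit <- fit_verhulst(tt, x, seed = s)
    abs(fit$params$mu - 0.5) / 0.5
  }, 0.0)
  expect_lte(median(rel_err_mu), 0.10)
  # bias statistically indistinguishable from zero at this noise level
  set.seed(99)
  signed <- vapply(21:40, function(s) {
    set.seed(s)
    sdlog <- sqrt(log(1 + 0.05^2))
    x <- clean * rlnorm(length(tt), -sdlog^2 / 2, sdlog)
    fit_verhulst(tt, x, seed = s)$params$mu - 0.5
  }, 0.0)
  expect_gt(t.test(signed)$p.value, 0.01)
})
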