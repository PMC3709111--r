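test_that("invalid configurations fail before any sampling", {
  expect_error(sim_config(n = 1), ">= 2")
  expect_error(sim_config(t = -1), "positive")
  expect_error(sim_config(sigma_t = 0), "positive")
  expect_error(sim_config(tau = -3), "positive")
  expect_error(simulate_gaussian(sim_config()), "seed")
  expect_error(null_config(var_alpha = -1), ">= 0")
  expect_error(null_config(rho = 1.2), "rho")
  expect_error(simulate_null(null_config()), "seed")
})

test_that("identical seeds give bit-identical communities", {
  cfg <- sim_config(n = 20, m = 30, t = 1, seed = 11)
  s1 <- simulate_gaussian(cfg); s2 <- simulate_gaussian(cfg)
  expect_identical(s1$data$Y, s2$data$Y)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_gaussian(sim_config(n = 20, m = 30, t = 1, seed = 12))
  expect_false(identical(s1$data$Y, s3$data$Y))

  ncfg <- null_config(n = 20, m = 30, seed = 5)
  expect_identical(simulate_null(ncfg)$data$Y, simulate_null(ncfg)$data$Y)
})

test_that("the response curve peaks at the optimum with height plogis(a)", {
  a <- c(-1, 0, 2); u <- c(-0.5, 0, 1.5); t <- c(0.5, 1, 4)
  expect_equal(gaussian_logistic(u, a, u, t), plogis(a))
  # strictly below the peak away from the optimum
  expect_true(all(gaussian_logistic(u + 0.3, a, u, t) < plogis(a)))
})

test_that("simulated dimensions and occupancy match the generating curve", {
  sim <- simulate_gaussian(sim_config(n = 50, m = 100, t = 1, tau = 3,
                                      seed = 3))
  expect_identical(dim(sim$data$Y), c(50L, 100L))
  expect_true(all(sim$data$Y %in% 0:1))
  expect_identical(sim$truth$t, rep(1, 100))

  # law of large numbers: occupancy within 3 SE of the analytic mean
  big <- simulate_gaussian(sim_config(n = 5000, m = 8, t = 1, seed = 7))
  p <- sapply(seq_len(8), function(j) {
    gaussian_logistic(big$truth$x, big$truth$a[j], big$truth$u[j],
                      big$truth$t[j])
  })
  occ <- colMeans(big$data$Y)
  se <- sqrt(colSums(p * (1 - p))) / 5000
  expect_true(all(abs(occ - colMeans(p)) < 3 * se))
})

test_that("lognormal-tolerance and normal-gradient variants draw as documented", {
  sim <- simulate_gaussian(sim_config(n = 30, m = 2000, sigma_t = 0.5,
                                      seed = 9))
  lt <- log(sim$truth$t)
  expect_equal(median(sim$truth$t), 1, tolerance = 0.1)
  expect_equal(sd(lt), 0.5, tolerance = 0.05)

  nsim <- simulate_gaussian(sim_config(n = 2000, m = 5, t = 2,
                                       distribution = "normal", seed = 9))
  expect_equal(sd(nsim$truth$x), 1, tolerance = 0.1)
  expect_equal(sd(nsim$truth$u), 2, tolerance = 0.5)
})

test_that("null simulation respects its degenerate and correlation contracts", {
  # all variances zero: every species follows one logistic curve in x
  cfg <- null_config(n = 2000, m = 4, var_alpha = 0, var_beta = 0,
                     var_gamma = 0, fixed_intercept = 0.5, fixed_slope = 1,
                     seed = 21)
  sim <- simulate_null(cfg)
  pooled <- glm(y ~ x, family = binomial(), data = to_long(sim$data))
  expect_equal(unname(coef(pooled)), c(0.5, 1), tolerance = 0.12)

  # rho = 0: drawn intercepts and slopes uncorrelated
  big <- simulate_null(null_config(n = 2, m = 10000, rho = 0, seed = 22))
  expect_lt(abs(cor(big$truth$alpha, big$truth$beta)), 3 / sqrt(10000))
  # rho = 0.8 is recovered in the draws
  cor8 <- simulate_null(null_config(n = 2, m = 10000, rho = 0.8, seed = 23))
  expect_equal(cor(cor8$truth$alpha, cor8$truth$beta), 0.8, tolerance = 0.03)
})

test_that("series grids reproduce the three example designs", {
  s1 <- series_grid(1)
  expect_equal(sapply(s1, `[[`, "t"), c(0.5, 1, 4))
  expect_equal(sapply(s1, `[[`, "tau"), 2 + c(0.5, 1, 4))
  expect_true(all(sapply(s1, `[[`, "n") == 50))
  expect_true(all(sapply(s1, `[[`, "m") == 100))

  s2 <- series_grid(2)
  expect_equal(sapply(s2, `[[`, "sigma_t"), c(0.25, 0.5, 1))

  s3 <- series_grid(3, seed = 5)
  expect_equal(sapply(s3, `[[`, "m"), c(10, 50, 100))
  expect_true(all(sapply(s3, `[[`, "t") == 1))
  expect_equal(sapply(s3, `[[`, "seed"), c(5L, 6L, 7L))
  expect_true(all(sapply(c(s1, s2, s3), inherits, "sim_config")))
  expect_error(series_grid(4), "must be 1, 2 or 3")
})

test_that("the quadratic expansion of the Gaussian curve is exact", {
  set.seed(1)
  for (r in 1:20) {
    a <- rnorm(1); u <- runif(1, -3, 3); t <- runif(1, 0.2, 4)
    x <- runif(7, -2, 2)
    b <- gaussian_to_quadratic(a, u, t)
    expect_equal(gaussian_logit(x, a, u, t),
                 b[["b0"]] + b[["b1"]] * x + b[["b2"]] * x^2,
                 tolerance = 1e-12)
  }
})

test_that("narrower tolerance means emptier sites, on average", {
  mean_S <- sapply(c(0.5, 1, 4), function(t) {
    mean(sapply(1:10, function(s) {
      mean(site_totals(simulate_gaussian(
        sim_config(n = 50, m = 100, t = t, seed = 30 + s))$data))
    }))
  })
  expect_true(all(diff(mean_S) > 0))
})

test_that("replicates advance the seed and keep the configuration", {
  sims <- simulate_replicates(sim_config(n = 10, m = 10, t = 1, seed = 100),
                              reps = 3)
  expect_length(sims, 3)
  expect_identical(sapply(sims, function(s) s$truth$seed), c(100L, 101L, 102L))
  expect_false(identical(sims[[1]]$data$Y, sims[[2]]$data$Y))
})
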