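test_that("an exact quadratic signal is recovered perfectly", {
  x <- c(-2, -1, 0, 1, 2, 1.5)
  g <- -x^2
  # residuals are exactly zero, so lm's "perfect fit" warning is expected
  expect_message(suppressWarnings(tt <- unimodality_test(g, x, S = rep(7, 6))),
                 "collinear")
  expect_true(tt$dropped_S)
  expect_equal(tt$coef[["x2"]], -1, tolerance = 1e-10)
  expect_lt(tt$p_x2, 1e-10)
  expect_identical(tt$curvature_sign, "n-shaped")
  expect_equal(tt$implied_t, 1 / sqrt(2), tolerance = 1e-10)
})

test_that("a constant site-effect vector is flagged flat, not significant", {
  x <- c(-2, -1, 0, 1, 2)
  tt <- unimodality_test(rep(0.3, 5), x, S = c(3, 4, 5, 4, 3))
  expect_true(tt$degenerate)
  expect_identical(tt$curvature_sign, "flat")
  expect_equal(tt$coef[["x2"]], 0)
  expect_equal(tt$p_x2, 1)
})

test_that("coefficients match the normal-equations solution on a hand dataset", {
  x <- c(-1.5, -0.7, 0.1, 0.6, 1.2, 1.9)
  g <- c(-2.1, -0.4, 0.3, 0.2, -0.8, -3.0)
  S <- c(4, 7, 9, 8, 6, 3)
  tt <- unimodality_test(g, x, S)
  X <- cbind(1, x, x^2, S)
  beta <- solve(crossprod(X), crossprod(X, g))
  expect_equal(unname(tt$coef), unname(drop(beta)), tolerance = 1e-10)
  # standard error from first principles
  rss <- sum((g - X %*% beta)^2)
  se <- sqrt(rss / (6 - 4) * solve(crossprod(X))[3, 3])
  expect_equal(tt$se_x2, se, tolerance = 1e-10)
})

test_that("the F test of the added squared term equals the squared z ratio", {
  set.seed(99)
  for (r in 1:20) {
    n <- sample(8:40, 1)
    x <- runif(n, -2, 2)
    S <- rpois(n, 10)
    g <- 0.3 * x - 0.2 * x^2 + 0.05 * S + rnorm(n, 0, 0.3)
    tt <- unimodality_test(g, x, S)
    # independent F test via the two nested linear models
    f0 <- lm(g ~ x + S); f1 <- lm(g ~ x + I(x^2) + S)
    Ftab <- anova(f0, f1)
    expect_equal(tt$z_x2^2, Ftab$F[2], tolerance = 1e-10)
    expect_equal(tt$p_anova, Ftab$`Pr(>F)`[2], tolerance = 1e-10)
    expect_equal(tt$p_x2, tt$p_anova, tolerance = 1e-10)
  }
})

test_that("the squared-term p-value is invariant to affine changes of x", {
  set.seed(5)
  x <- runif(20, -2, 2); S <- rpois(20, 12)
  g <- -0.4 * x^2 + 0.1 * x + rnorm(20, 0, 0.5)
  t1 <- unimodality_test(g, x, S)
  t2 <- unimodality_test(g, 2 * x + 3, S)
  expect_equal(t1$p_x2, t2$p_x2, tolerance = 1e-8)
  expect_equal(abs(t1$z_x2), abs(t2$z_x2), tolerance = 1e-8)
})

test_that("collinear designs are refused with an informative message", {
  # x with two distinct values: x^2 lies in span{1, x}
  x <- c(0, 0, 1, 1, 0, 1)
  expect_error(unimodality_test(rnorm(6), x, S = c(1, 2, 3, 4, 5, 6)),
               "x\\^2 is a linear combination")
  # S constructed as x^2 - x: rank deficiency involving all three
  set.seed(2)
  x <- runif(8, -2, 2)
  expect_error(unimodality_test(rnorm(8), x, S = x^2 - x),
               "linearly dependent")
  expect_error(unimodality_test(rnorm(5), rep(1, 5), S = 1:5), "constant")
  expect_error(unimodality_test(rnorm(4), 1:4, S = 1:4), "at least 5")
})

test_that("one-sided n-shaped alternative halves the two-sided p when negative", {
  set.seed(7)
  x <- runif(30, -2, 2); S <- rpois(30, 10)
  g <- -0.5 * x^2 + rnorm(30, 0, 0.4)
  two <- unimodality_test(g, x, S)
  one <- unimodality_test(g, x, S, alternative = "n.shaped")
  expect_lt(two$coef[["x2"]], 0)
  expect_equal(one$p_x2, two$p_x2 / 2, tolerance = 1e-12)
})

test_that("the quantile correlation summarizes normality as expected", {
  n <- 1000
  q <- qnorm(ppoints(n))
  expect_equal(qq_site_effects(q)$correlation, 1, tolerance = 1e-12)
  set.seed(3)
  r_norm <- qq_site_effects(rnorm(n))$correlation
  expect_gt(r_norm, 0.995)
  r_heavy <- qq_site_effects(rt(n, df = 2))$correlation
  expect_lt(r_heavy, r_norm - 0.02)
})

test_that("the diagnostic plot writes a file whose curve matches the fit", {
  set.seed(11)
  x <- runif(25, -2, 2); S <- rpois(25, 10)
  g <- -0.6 * x^2 + 0.2 * x + 0.03 * S + rnorm(25, 0, 0.3)
  tt <- unimodality_test(g, x, S)
  tmp <- withr::local_tempfile(fileext = ".svg")
  ov <- site_effect_plot(g, x, tt, out_path = tmp)
  expect_true(file.exists(tmp) && file.size(tmp) > 0)
  cs <- tt$coef
  expect_equal(ov$y,
               cs[["intercept"]] + cs[["x"]] * ov$x + cs[["x2"]] * ov$x^2 +
                 cs[["S"]] * mean(S),
               tolerance = 1e-12)
  qtmp <- withr::local_tempfile(fileext = ".pdf")
  qq_site_effects(g, out_path = qtmp)
  expect_true(file.exists(qtmp) && file.size(qtmp) > 0)
})

test_that("serialization writes the verdict in both formats", {
  set.seed(12)
  x <- runif(12, -2, 2); S <- rpois(12, 8)
  tt <- unimodality_test(-x^2 + rnorm(12, 0, 0.2), x, S)
  jp <- withr::local_tempfile(fileext = ".json")
  tp <- withr::local_tempfile(fileext = ".tsv")
  write_unimodal_result(tt, json_path = jp, tsv_path = tp)
  back <- jsonlite::read_json(jp)
  expect_equal(back$p_x2, tt$p_x2, tolerance = 1e-12)
  expect_identical(back$curvature_sign, tt$curvature_sign)
  tsv <- read.delim(tp)
  expect_equal(tsv$coef_x2, tt$coef[["x2"]], tolerance = 1e-12)
})

test_that("the pipeline detects unimodal response and ignores column order", {
  sim <- simulate_gaussian(sim_config(n = 50, m = 40, t = 1, seed = 18))
  res <- suppressWarnings(run_unimodal_pipeline(sim$data))
  expect_identical(res$test$curvature_sign, "n-shaped")
  expect_lt(res$test$p_x2, 0.001)
  expect_false(res$boundary_site_variance)

  d <- sim$data
  set.seed(2); pj <- sample(ncol(d$Y))
  dp <- community_data(d$Y[, pj], d$x, site_ids = d$site_ids,
                       species_ids = d$species_ids[pj])
  res2 <- suppressWarnings(run_unimodal_pipeline(dp))
  expect_equal(res2$test$p_x2, res$test$p_x2, tolerance = 1e-8)
})
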