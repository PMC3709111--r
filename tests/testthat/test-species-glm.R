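test_that("closed-form parameter conversions are exact both ways", {
  b <- gaussian_to_quadratic(a = 0, u = 0, t = 1)
  expect_equal(unname(b), c(0, 0, -0.5))
  g <- quadratic_to_gaussian(1, 2, -1)
  expect_equal(g$u, 1)
  expect_equal(g$t, 1 / sqrt(2))
  expect_equal(g$a, 2)

  set.seed(6)
  for (r in 1:10) {
    a <- rnorm(1); u <- runif(1, -3, 3); t <- runif(1, 0.3, 4)
    b <- gaussian_to_quadratic(a, u, t)
    g <- quadratic_to_gaussian(b[["b0"]], b[["b1"]], b[["b2"]])
    expect_equal(c(g$a, g$u, g$t), c(a, u, t), tolerance = 1e-12)
    b2 <- gaussian_to_quadratic(g$a, g$u, g$t)
    expect_equal(unname(b2), unname(b), tolerance = 1e-10)
  }

  expect_error(quadratic_to_gaussian(0, 1, 0.2), "no interior optimum")
  expect_error(quadratic_to_gaussian(0, 1, 0), "no interior optimum")
})

test_that("the quadratic logistic fit matches direct likelihood maximization", {
  set.seed(17)
  x <- runif(60, -2, 2)
  p <- plogis(1 - (x - 0.4)^2 / (2 * 0.8^2))
  y <- rbinom(60, 1, p)
  fit <- fit_species_glm(y, x, "sp1")
  nll <- function(b) -sum(y * (b[1] + b[2] * x + b[3] * x^2) -
                            log1p(exp(b[1] + b[2] * x + b[3] * x^2)))
  opt <- optim(c(0, 0, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14, maxit = 2000))
  expect_equal(c(fit$b0, fit$b1, fit$b2), opt$par, tolerance = 1e-6)
  expect_true(fit$converged)
  expect_false(fit$separation)
})

test_that("data built from a concave curve yields a concave fit", {
  # deterministic: y = 1 exactly where the curve exceeds one half
  x <- seq(-2, 2, length.out = 41)
  eta <- 2 - (x - 0)^2 / (2 * 0.7^2)
  y <- as.integer(plogis(eta) > 0.5)
  fit <- suppressWarnings(fit_species_glm(y, x))
  expect_lt(fit$b2, 0)
  g <- to_gaussian(fit)
  expect_lt(abs(g$u), 0.3)
})

test_that("under a permutation null the curvature z has no systematic sign", {
  set.seed(41)
  x <- runif(40, -2, 2)
  zs <- replicate(60, {
    y <- rbinom(40, 1, 0.5)  # independent of x by construction
    suppressWarnings(fit_species_glm(y, x))$z_b2
  })
  zs <- zs[is.finite(zs)]
  expect_lt(abs(mean(zs)), 3 * sd(zs) / sqrt(length(zs)))
})

test_that("separation and degenerate species are flagged, not raised", {
  x <- seq(-2, 2, length.out = 20)
  sep <- fit_species_glm(as.integer(x > 0), x)
  expect_true(sep$separation)
  allzero <- fit_species_glm(rep(0L, 20), x)
  expect_true(allzero$degenerate)
  expect_true(allzero$separation)
  expect_true(is.na(allzero$b2))
  expect_error(to_gaussian(allzero), "degenerate")
  expect_error(fit_species_glm(c(0, 2, 1, 0), x[1:4]), "binary")
  expect_error(fit_species_glm(c(0, 1, 0), c(1, 2, 3)), "at least 4")
})

test_that("screening keeps species by sign and strength of curvature", {
  mk <- function(id, b2, z) {
    structure(list(species_id = id, b0 = 0, b1 = 0, b2 = b2, se_b2 = 1,
                   z_b2 = z, converged = TRUE, separation = FALSE,
                   degenerate = FALSE), class = "species_glm")
  }
  fits <- list(strong = mk("strong", -0.5, -3),
               weak = mk("weak", -0.1, -0.5),
               convex = mk("convex", 0.2, 2),
               undef = mk("undef", NA, NA))
  expect_identical(screen_optima(fits), "strong")
  expect_identical(sort(screen_optima(fits, z_threshold = 0)),
                   c("strong", "weak"))
})

test_that("fits over a community tabulate with Gaussian columns where defined", {
  sim <- simulate_gaussian(sim_config(n = 50, m = 20, t = 1, seed = 27))
  fits <- suppressWarnings(fit_species_glms(sim$data))
  expect_length(fits, 20)
  expect_named(fits, sim$data$species_ids)
  tab <- species_glm_table(fits)
  expect_identical(nrow(tab), 20L)
  conc <- !is.na(tab$b2) & tab$b2 < 0
  expect_true(all(is.na(tab$t[!conc])))
  expect_true(all(tab$t[conc] > 0))
  # recovered optima of well-determined species correlate with truth
  keep <- screen_optima(fits)
  keep <- keep[!vapply(fits[keep], `[[`, logical(1), "separation")]
  expect_gte(length(keep), 5)
  est_u <- tab$u[match(keep, tab$species_id)]
  true_u <- sim$truth$u[match(keep, sim$data$species_ids)]
  expect_gt(cor(est_u, true_u), 0.8)
})

test_that("the common-tolerance transform inverts the quadratic mixed model", {
  # hand-built fit: fixed beta2 = -0.5 gives t = 1, so u_j equals the slope
  fx <- matrix(c(0.2, 0.4, -0.5, 0.1, 0.1, 0.1), 3, 2,
               dimnames = list(c("(Intercept)", "x", "xx"), c("est", "se")))
  fit <- structure(list(
    fixed = fx,
    species_modes = data.frame(species_id = c("a", "b"),
                               `(Intercept)` = c(0.3, -0.3), x = c(1, -1),
                               check.names = FALSE),
    gamma = c(s1 = 0.1, s2 = -0.2),
    x = c(1, 2),
    spec = glmm_spec(fixed = c("intercept", "x", "x2"))),
    class = "glmm_fit")
  ct <- common_tolerance_transform(fit)
  expect_equal(ct$t, 1)
  expect_equal(ct$params$slope, c(1.4, -0.6))
  expect_equal(ct$params$u, c(1.4, -0.6))
  expect_equal(ct$params$alpha, c(0.5, -0.1))
  expect_equal(ct$params$a, c(0.5 + 1.4^2 / 2, -0.1 + 0.6^2 / 2))
  expect_equal(unname(ct$gamma_adj), c(0.1 + 0.5, -0.2 + 2))

  # guard rails
  fit_pos <- fit; fit_pos$fixed["xx", 1] <- 0.1
  expect_error(common_tolerance_transform(fit_pos), "not negative")
  fit_nox2 <- fit; fit_nox2$spec <- glmm_spec()
  expect_error(common_tolerance_transform(fit_nox2), "fixed x\\^2")
})

test_that("the transform reproduces the fitted linear predictor exactly", {
  sim <- simulate_gaussian(sim_config(n = 40, m = 25, t = 1, seed = 33))
  fit <- suppressWarnings(
    fit_glmm(sim$data, glmm_spec(fixed = c("intercept", "x", "x2"))))
  ct <- common_tolerance_transform(fit)
  # Gaussian form a_j - (x_i - u_j)^2 / (2 t^2) + adjusted site effect must
  # equal the quadratic form evaluated from the same coefficients
  x <- fit$x
  for (j in c(1, 5, 25)) {
    quad <- ct$params$alpha[j] + ct$params$slope[j] * x +
      fit$fixed["xx", 1] * x^2 + fit$gamma
    gauss <- ct$params$a[j] - (x - ct$params$u[j])^2 / (2 * ct$t^2) +
      ct$gamma_adj - x^2 / (2 * ct$t^2)
    expect_equal(unname(gauss), unname(quad), tolerance = 1e-10)
  }
  # common tolerance estimated near the generating value of 1
  expect_gt(ct$t, 0.5)
  expect_lt(ct$t, 2)
})

test_that("slope-versus-optimum agreement is computed on the screened join", {
  sim <- simulate_gaussian(sim_config(n = 50, m = 40, t = 1, seed = 52))
  gfit <- suppressWarnings(fit_glmm(sim$data))
  fits <- suppressWarnings(fit_species_glms(sim$data))
  so <- slope_vs_optimum(gfit, fits)
  expect_s3_class(so, "slope_optimum")
  expect_true(all(so$table$species_id %in% screen_optima(fits)))
  # hand-recompute the correlation from the returned table
  expect_equal(so$correlation,
               cor(so$table$glmm_slope, so$table$glm_optimum),
               tolerance = 1e-12)
  expect_gt(so$correlation, 0.5)

  tmp <- withr::local_tempfile(fileext = ".png")
  slope_vs_optimum(gfit, fits, out_path = tmp)
  expect_true(file.exists(tmp) && file.size(tmp) > 0)

  # impossible screening threshold leaves nothing
  expect_error(slope_vs_optimum(gfit, fits, z_threshold = -1e6),
               "no species left")
})

test_that("the species table serializes to CSV and reloads", {
  sim <- simulate_gaussian(sim_config(n = 30, m = 10, t = 1, seed = 61))
  fits <- suppressWarnings(fit_species_glms(sim$data))
  tmp <- withr::local_tempfile(fileext = ".csv")
  tab <- write_species_glms(fits, tmp)
  back <- read.csv(tmp)
  expect_equal(back$b2, tab$b2, tolerance = 1e-12)
  expect_identical(back$species_id, tab$species_id)
})
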