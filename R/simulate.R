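#' Gaussian logistic response curve
#'
#' The occurrence probability of a species with maximum-logit coefficient
#' \code{a}, optimum \code{u} and tolerance \code{t} at gradient value
#' \code{x} is \code{plogis(a - (x - u)^2 / (2 t^2))}: it peaks at
#' \code{x = u} with height \code{plogis(a)} and decays symmetrically with
#' niche width \code{t}.
#'
#' @param x numeric vector of gradient values.
#' @param a,u,t scalars (or vectors recycled against \code{x}): maximum
#'   coefficient, optimum and tolerance (\code{t > 0}).
#' @return \code{gaussian_logit} returns the linear predictor (logit scale);
#'   \code{gaussian_logistic} the probability.
#' @export
gaussian_logit <- function(x, a, u, t) {
  stopifnot(all(t > 0))
  a - (x - u)^2 / (2 * t^2)
}

#' @rdname gaussian_logit
#' @export
gaussian_logistic <- function(x, a, u, t) {
  stats::plogis(gaussian_logit(x, a, u, t))
}

#' Configuration for a Gaussian-logistic community simulation
#'
#' Captures the generating conditions for one simulated presence-absence
#' community: site and species counts, the tolerance regime (a single common
#' tolerance \code{t}, or species tolerances drawn lognormally with scale
#' \code{sigma_t} and median 1), the half-range \code{tau} of the species
#' optima, the sampling distribution of gradient and optima, and the seed.
#'
#' By default \code{tau = 2 + t} (or \code{2 + 1} under lognormal
#' tolerances), which places part of the optima outside the sampled gradient
#' range so that some species are seen only on one flank of their niche.
#'
#' @param n number of sites (>= 2).
#' @param m number of species (>= 1).
#' @param t common tolerance (> 0); ignored when \code{sigma_t} is given.
#' @param sigma_t lognormal scale of per-species tolerances (median 1), or
#'   \code{NULL} for a common tolerance.
#' @param tau half-range of the optima; defaults to \code{2 + t} (or 3 under
#'   lognormal tolerances).
#' @param distribution \code{"uniform"}: gradient \code{x ~ U(-2, 2)} and
#'   optima \code{u ~ U(-tau, tau)}; \code{"normal"}: \code{x ~ N(0, 1)} and
#'   \code{u ~ N(0, t^2)}.
#' @param seed integer seed; must be set before simulating.
#' @return an object of class \code{"sim_config"}.
#' @seealso \code{\link{simulate_gaussian}}, \code{\link{series_grid}}
#' @export
sim_config <- function(n = 50, m = 100, t = 1, sigma_t = NULL,
                       tau = NULL,
                       distribution = c("uniform", "normal"),
                       seed = NA_integer_) {
  distribution <- match.arg(distribution)
  if (!is.null(sigma_t)) {
    if (!is.numeric(sigma_t) || length(sigma_t) != 1L || sigma_t <= 0) {
      stop("'sigma_t' must be a positive scalar", call. = FALSE)
    }
    t <- NULL
    if (is.null(tau)) tau <- 2 + 1  # median tolerance is 1
  } else {
    if (!is.numeric(t) || length(t) != 1L || t <= 0) {
      stop("'t' must be a positive scalar", call. = FALSE)
    }
    if (is.null(tau)) tau <- 2 + t
  }
  if (!is.numeric(n) || length(n) != 1L || n < 2) {
    stop("'n' must be >= 2", call. = FALSE)
  }
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("'m' must be >= 1", call. = FALSE)
  }
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0) {
    stop("'tau' must be a positive scalar", call. = FALSE)
  }
  structure(list(n = as.integer(n), m = as.integer(m), t = t,
                 sigma_t = sigma_t, tau = tau,
                 distribution = distribution,
                 seed = if (is.na(seed)) NA_integer_ else as.integer(seed)),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  tol <- if (is.null(x$sigma_t)) sprintf("t = %g", x$t) else
    sprintf("t ~ LogN(0, %g)", x$sigma_t)
  cat(sprintf("sim_config: n = %d sites, m = %d species, %s, tau = %g, %s, seed = %s\n",
              x$n, x$m, tol, x$tau, x$distribution,
              ifelse(is.na(x$seed), "<unset>", x$seed)))
  invisible(x)
}

#' Simulate a Gaussian-logistic presence-absence community
#'
#' Generates one community data set from unimodal species response curves.
#' Draws are made in the fixed order gradient \code{x}, optima \code{u},
#' maxima \code{a}, tolerances \code{t}, then presences \code{y}, from a
#' single stream seeded by \code{config$seed}, so identical configurations
#' reproduce bit-identical data.
#'
#' The recipe: \code{x_i ~ U(-2, 2)} (or \code{N(0, 1)}),
#' \code{u_j ~ U(-tau, tau)} (or \code{N(0, t^2)}), \code{a_j ~ N(0, 1)},
#' tolerances either all equal to \code{t} or \code{t_j ~ LogN(0, sigma_t)};
#' then \code{p_ij = plogis(a_j - (x_i - u_j)^2 / (2 t_j^2))} and
#' \code{y_ij ~ Bernoulli(p_ij)}.
#'
#' @param config a \code{\link{sim_config}} with a set seed.
#' @return list with elements \code{data}, a \code{\link{community_data}},
#'   and \code{truth}, a \code{"sim_truth"} record of the generating
#'   \code{x}, \code{u}, \code{a}, \code{t} and seed.
#' @export
simulate_gaussian <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.na(config$seed)) {
    stop("config$seed must be set before simulating", call. = FALSE)
  }
  n <- config$n; m <- config$m
  set.seed(config$seed)
  if (config$distribution == "uniform") {
    x <- stats::runif(n, -2, 2)
    u <- stats::runif(m, -config$tau, config$tau)
  } else {
    x <- stats::rnorm(n, 0, 1)
    u <- stats::rnorm(m, 0, if (is.null(config$sigma_t)) config$t else 1)
  }
  a <- stats::rnorm(m)
  tj <- if (is.null(config$sigma_t)) rep(config$t, m) else
    stats::rlnorm(m, 0, config$sigma_t)
  eta <- matrix(a, n, m, byrow = TRUE) -
    sweep(outer(x, u, "-")^2, 2L, 2 * tj^2, "/")
  p <- stats::plogis(eta)
  y <- matrix(stats::rbinom(n * m, 1L, p), n, m)
  data <- community_data(y, x)
  truth <- structure(list(x = x, u = u, a = a, t = tj, seed = config$seed),
                     class = "sim_truth")
  list(data = data, truth = truth)
}

#' Configuration for a null mixed-model community simulation
#'
#' Describes the generating process of the null model against which the
#' unimodality test should not reject: species intercepts and slopes drawn
#' jointly normal with correlation \code{rho}, site effects drawn
#' independent normal (in particular, independent of the gradient), and
#' presences Bernoulli from the logit-linear predictor.
#'
#' @param n,m site and species counts.
#' @param var_alpha,var_beta,var_gamma variances (>= 0) of species
#'   intercepts, species slopes and site effects.
#' @param rho correlation between species intercepts and slopes, in
#'   \code{[-1, 1]}.
#' @param fixed_intercept,fixed_slope the common fixed effects; the strict
#'   null model has zero-mean random coefficients and no fixed terms, so
#'   both default to 0.
#' @param distribution distribution of the gradient: \code{"uniform"} for
#'   \code{U(-2, 2)} or \code{"normal"} for \code{N(0, 1)}.
#' @param seed integer seed.
#' @return an object of class \code{"null_config"}.
#' @seealso \code{\link{simulate_null}}
#' @export
null_config <- function(n = 50, m = 100, var_alpha = 1, var_beta = 1,
                        var_gamma = 1, rho = 0,
                        fixed_intercept = 0, fixed_slope = 0,
                        distribution = c("uniform", "normal"),
                        seed = NA_integer_) {
  distribution <- match.arg(distribution)
  if (any(c(var_alpha, var_beta, var_gamma) < 0)) {
    stop("variances must be >= 0", call. = FALSE)
  }
  if (abs(rho) > 1) {
    stop("'rho' must lie in [-1, 1]", call. = FALSE)
  }
  if (n < 2 || m < 1) stop("need n >= 2 and m >= 1", call. = FALSE)
  structure(list(n = as.integer(n), m = as.integer(m),
                 var_alpha = var_alpha, var_beta = var_beta,
                 var_gamma = var_gamma, rho = rho,
                 fixed_intercept = fixed_intercept,
                 fixed_slope = fixed_slope,
                 distribution = distribution,
                 seed = if (is.na(seed)) NA_integer_ else as.integer(seed)),
            class = "null_config")
}

#' Simulate a community under the null mixed model
#'
#' Generates presence-absence data whose site effects are genuinely
#' independent normal, matching the distributional assumptions of the
#' random-intercept random-slope site-effect model.  Used to study the
#' type-I error of the unimodality test.  Draw order: gradient \code{x},
#' species intercept/slope pairs, site effects, presences.
#'
#' @param config a \code{\link{null_config}} with a set seed.
#' @return list with elements \code{data} (a
#'   \code{\link{community_data}}) and \code{truth} (drawn \code{alpha},
#'   \code{beta}, \code{gamma}, the gradient \code{x} and the seed).
#' @export
simulate_null <- function(config) {
  stopifnot(inherits(config, "null_config"))
  if (is.na(config$seed)) {
    stop("config$seed must be set before simulating", call. = FALSE)
  }
  n <- config$n; m <- config$m
  set.seed(config$seed)
  x <- if (config$distribution == "uniform") stats::runif(n, -2, 2) else
    stats::rnorm(n)
  # bivariate normal (alpha_j, beta_j) via its Cholesky factor
  z1 <- stats::rnorm(m); z2 <- stats::rnorm(m)
  sa <- sqrt(config$var_alpha); sb <- sqrt(config$var_beta)
  alpha <- sa * z1
  beta <- sb * (config$rho * z1 + sqrt(1 - config$rho^2) * z2)
  gamma <- stats::rnorm(n, 0, sqrt(config$var_gamma))
  eta <- config$fixed_intercept +
    matrix(alpha, n, m, byrow = TRUE) +
    outer(x, config$fixed_slope + beta) +
    matrix(gamma, n, m)
  y <- matrix(stats::rbinom(n * m, 1L, stats::plogis(eta)), n, m)
  data <- community_data(y, x)
  truth <- structure(list(x = x, alpha = alpha, beta = beta, gamma = gamma,
                          seed = config$seed),
                     class = "sim_truth")
  list(data = data, truth = truth)
}

#' Standard simulation series
#'
#' The three example series used throughout the package's validation:
#' series 1 varies the common tolerance (\code{t = 0.5, 1, 4}, with
#' \code{tau = 2 + t}); series 2 draws species tolerances lognormally
#' (\code{sigma_t = 0.25, 0.5, 1}, median tolerance 1); series 3 varies the
#' species count (\code{m = 10, 50, 100}) at \code{t = 1}.  All use
#' \code{n = 50} sites and, except series 3, \code{m = 100} species.
#'
#' @param series 1, 2 or 3.
#' @param seed optional integer; when given, the k-th returned config gets
#'   seed \code{seed + k - 1}.
#' @return list of \code{\link{sim_config}} objects.
#' @export
series_grid <- function(series, seed = NA_integer_) {
  if (!series %in% 1:3) stop("'series' must be 1, 2 or 3", call. = FALSE)
  cfgs <- switch(as.character(series),
    "1" = lapply(c(0.5, 1, 4), function(t) sim_config(n = 50, m = 100, t = t)),
    "2" = lapply(c(0.25, 0.5, 1),
                 function(s) sim_config(n = 50, m = 100, sigma_t = s)),
    "3" = lapply(c(10, 50, 100),
                 function(m) sim_config(n = 50, m = m, t = 1)))
  if (!is.na(seed)) {
    for (k in seq_along(cfgs)) cfgs[[k]]$seed <- as.integer(seed + k - 1L)
  }
  cfgs
}

#' Replicated simulations from one configuration
#'
#' Runs \code{\link{simulate_gaussian}} (or \code{\link{simulate_null}} for
#' a \code{null_config}) \code{reps} times with seeds
#' \code{config$seed + 0:(reps - 1)}.
#'
#' @param config a \code{\link{sim_config}} or \code{\link{null_config}}
#'   with a set seed (the seed of the first replicate).
#' @param reps number of replicates (default 10).
#' @return list of simulation results.
#' @export
simulate_replicates <- function(config, reps = 10) {
  if (is.na(config$seed)) {
    stop("config$seed must be set (seed of the first replicate)",
         call. = FALSE)
  }
  fun <- if (inherits(config, "null_config")) simulate_null else
    simulate_gaussian
  lapply(seq_len(reps) - 1L, function(k) {
    cfg <- config
    cfg$seed <- config$seed + k
    fun(cfg)
  })
}

#' Write a simulated data set with its truth sidecars
#'
#' Writes the community matrix and site table (per
#' \code{\link{write_community}}) plus two truth sidecars: a species CSV
#' (\code{species_id, u, a, t} or the null model's \code{alpha, beta}) and a
#' site CSV (\code{site_id, x}, plus \code{gamma} for null simulations).
#'
#' @param sim a result of \code{\link{simulate_gaussian}} or
#'   \code{\link{simulate_null}}.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix (default \code{"sim"}).
#' @return invisibly, the vector of written paths.
#' @export
write_simulation <- function(sim, dir, prefix = "sim") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  data <- sim$data; truth <- sim$truth
  p_mat <- file.path(dir, paste0(prefix, "_matrix.csv"))
  p_env <- file.path(dir, paste0(prefix, "_env.csv"))
  write_community(data, p_mat, p_env)
  p_sp <- file.path(dir, paste0(prefix, "_truth_species.csv"))
  p_si <- file.path(dir, paste0(prefix, "_truth_sites.csv"))
  if (!is.null(truth$u)) {
    sp <- data.frame(species_id = data$species_ids, u = truth$u,
                     a = truth$a, t = truth$t)
    si <- data.frame(site_id = data$site_ids, x = truth$x)
  } else {
    sp <- data.frame(species_id = data$species_ids, alpha = truth$alpha,
                     beta = truth$beta)
    si <- data.frame(site_id = data$site_ids, x = truth$x,
                     gamma = truth$gamma)
  }
  utils::write.csv(sp, p_sp, row.names = FALSE, quote = FALSE)
  utils::write.csv(si, p_si, row.names = FALSE, quote = FALSE)
  invisible(c(p_mat, p_env, p_sp, p_si))
}
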