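#' Specify a binomial-logit mixed model for community data
#'
#' Describes which terms of \code{1, x, x^2} enter as fixed effects, which
#' enter as correlated random effects varying by species, and whether a
#' random site intercept (the site effect) is included.  The default is the
#' package's workhorse: random species intercepts and slopes with an
#' unstructured 2x2 covariance, plus random site effects,
#' i.e. \code{y ~ 1 + x + (1 + x | species) + (1 | site)}.
#'
#' @param fixed character subset of \code{c("intercept", "x", "x2")};
#'   must contain \code{"intercept"}.
#' @param species_random character subset of \code{c("intercept", "x",
#'   "x2")}; all included terms share a full covariance matrix.
#' @param site_random logical: include a random site intercept.
#' @return an object of class \code{"glmm_spec"}.
#' @export
glmm_spec <- function(fixed = c("intercept", "x"),
                      species_random = c("intercept", "x"),
                      site_random = TRUE) {
  all_terms <- c("intercept", "x", "x2")
  fixed <- match.arg(fixed, all_terms, several.ok = TRUE)
  if (!"intercept" %in% fixed) {
    stop("'fixed' must contain \"intercept\"", call. = FALSE)
  }
  if (length(species_random)) {
    species_random <- match.arg(species_random, all_terms, several.ok = TRUE)
  } else {
    species_random <- character(0)
  }
  structure(list(fixed = all_terms[all_terms %in% fixed],
                 species_random = all_terms[all_terms %in% species_random],
                 site_random = isTRUE(site_random)),
            class = "glmm_spec")
}

#' @export
print.glmm_spec <- function(x, ...) {
  cat("glmm_spec:", spec_formula_string(x), "\n")
  invisible(x)
}

# term name -> model-column label used in formulas and coefficient tables
term_cols <- function(terms) {
  c(intercept = "1", x = "x", x2 = "xx")[terms]
}

spec_formula_string <- function(spec) {
  fx <- paste(term_cols(spec$fixed), collapse = " + ")
  parts <- fx
  if (length(spec$species_random)) {
    parts <- c(parts, sprintf("(%s | species)",
      paste(c(if ("intercept" %in% spec$species_random) "1",
              term_cols(setdiff(spec$species_random, "intercept"))),
            collapse = " + ")))
  }
  if (spec$site_random) parts <- c(parts, "(1 | site)")
  paste("y ~", paste(parts, collapse = " + "))
}

# long-format model frame with site/species factors and xx = x^2
model_frame <- function(data) {
  long <- to_long(data)
  long$site <- factor(long$site_id, levels = data$site_ids)
  long$species <- factor(long$species_id, levels = data$species_ids)
  long$xx <- long$x^2
  long
}

# is spec `a` nested in spec `b`?
spec_nested <- function(a, b) {
  all(a$fixed %in% b$fixed) &&
    all(a$species_random %in% b$species_random) &&
    (!a$site_random || b$site_random)
}

n_var_params <- function(spec) {
  k <- length(spec$species_random)
  k * (k + 1) / 2 + as.integer(spec$site_random)
}

#' Fit the community mixed model
#'
#' Fits the binomial-logit mixed model described by \code{spec} to the
#' community data by maximum likelihood with the Laplace approximation
#' (via \code{\link[lme4]{glmer}}; Laplace is the standard — and for crossed
#' species-by-site random effects the only practical — approximation).
#' Returns fixed-effect estimates, variance components and the conditional
#' modes (BLUPs) of all random effects.
#'
#' When \code{spec} contains no random terms the model degenerates to an
#' ordinary pooled logistic regression, fitted with \code{\link[stats]{glm}}.
#'
#' Species observed in no site or in every site are retained: shrinkage of
#' the random effects handles the resulting quasi-separation, and
#' \code{\link{species_flags}} identifies them.
#'
#' @param data a \code{\link{community_data}}; needs >= 2 sites, >= 2
#'   species and a non-constant gradient.
#' @param spec a \code{\link{glmm_spec}} (default: random species
#'   intercept/slope plus random site effect).
#' @param control a \code{\link[lme4]{glmerControl}}; the default uses the
#'   bobyqa optimizer without the post-fit derivative check, which on binary
#'   community matrices is fast and avoids spurious convergence flags.
#' @return an object of class \code{"glmm_fit"}: a list with components
#'   \code{fixed} (matrix of estimates and standard errors),
#'   \code{var_species} (covariance matrix of the species random terms),
#'   \code{var_alpha}, \code{var_beta}, \code{rho}, \code{var_gamma},
#'   \code{species_modes} (data.frame of per-species conditional modes),
#'   \code{gamma} (named vector of site-effect conditional modes),
#'   \code{loglik}, \code{n_params}, \code{converged}, \code{iterations},
#'   \code{S} (site totals), \code{site_score} (per-site sums of response
#'   residuals, the direction the site-effect modes shrink along as their
#'   variance tends to zero), plus the underlying model object.
#' @seealso \code{\link{site_effects}}, \code{\link{species_slopes}},
#'   \code{\link{compare_fits}}, \code{\link{run_unimodal_pipeline}}
#' @export
fit_glmm <- function(data, spec = glmm_spec(), control = NULL) {
  stopifnot(inherits(data, "community_data"), inherits(spec, "glmm_spec"))
  if (nrow(data$Y) < 2L || ncol(data$Y) < 2L) {
    stop("need at least 2 sites and 2 species", call. = FALSE)
  }
  if (diff(range(data$x)) == 0) {
    stop("the environmental variable x is constant", call. = FALSE)
  }
  long <- model_frame(data)
  fixed_cols <- term_cols(spec$fixed)
  has_random <- length(spec$species_random) > 0L || spec$site_random

  if (!has_random) {
    fml <- stats::as.formula(paste("y ~", paste(fixed_cols, collapse = " + ")))
    fit <- stats::glm(fml, family = stats::binomial(), data = long)
    cf <- summary(fit)$coefficients
    out <- list(fixed = cf[, 1:2, drop = FALSE],
                var_species = NULL, var_alpha = NA_real_,
                var_beta = NA_real_, rho = NA_real_, var_gamma = NA_real_,
                species_modes = NULL, gamma = NULL,
                loglik = as.numeric(stats::logLik(fit)),
                n_params = attr(stats::logLik(fit), "df"),
                converged = fit$converged, iterations = fit$iter,
                spec = spec, model = fit,
                S = site_totals(data), x = data$x,
                site_ids = data$site_ids, species_ids = data$species_ids)
    class(out) <- "glmm_fit"
    return(out)
  }

  if (is.null(control)) {
    control <- lme4::glmerControl(optimizer = "bobyqa", calc.derivs = FALSE)
  }
  fml <- stats::as.formula(spec_formula_string(spec))
  fit <- lme4::glmer(fml, family = stats::binomial(), data = long,
                     control = control)
  cf <- summary(fit)$coefficients
  fixed <- cf[, 1:2, drop = FALSE]

  vc <- lme4::VarCorr(fit)
  var_species <- NULL; var_alpha <- NA_real_; var_beta <- NA_real_
  rho <- NA_real_
  if (length(spec$species_random)) {
    var_species <- matrix(as.numeric(vc$species), nrow = nrow(vc$species),
                          dimnames = dimnames(vc$species))
    nm <- rownames(var_species)
    if ("(Intercept)" %in% nm) var_alpha <- var_species["(Intercept)", "(Intercept)"]
    if ("x" %in% nm) var_beta <- var_species["x", "x"]
    if (all(c("(Intercept)", "x") %in% nm)) {
      denom <- sqrt(var_alpha * var_beta)
      rho <- if (denom > 0) var_species["(Intercept)", "x"] / denom else 0
    }
  }
  var_gamma <- if (spec$site_random) as.numeric(vc$site[1, 1]) else NA_real_

  # per-site sum of response residuals: the direction of the site-effect
  # conditional modes in the limit of vanishing site variance
  site_score <- NULL
  if (spec$site_random) {
    r <- stats::residuals(fit, type = "response")
    site_score <- tapply(r, long$site, sum)
    site_score <- stats::setNames(as.numeric(site_score), data$site_ids)
  }

  re <- lme4::ranef(fit)
  species_modes <- NULL
  if (length(spec$species_random)) {
    sm <- re$species
    species_modes <- data.frame(species_id = rownames(sm), sm,
                                check.names = FALSE,
                                stringsAsFactors = FALSE, row.names = NULL)
  }
  gamma <- NULL
  if (spec$site_random) {
    gamma <- stats::setNames(re$site[, 1], rownames(re$site))
    gamma <- gamma[data$site_ids]
  }

  conv_ok <- fit@optinfo$conv$opt == 0
  if (!conv_ok) {
    warning("mixed-model optimizer did not report convergence; inspect the fit",
            call. = FALSE)
  }
  out <- list(fixed = fixed, var_species = var_species,
              var_alpha = var_alpha, var_beta = var_beta, rho = rho,
              var_gamma = var_gamma,
              species_modes = species_modes, gamma = gamma,
              site_score = site_score,
              loglik = as.numeric(stats::logLik(fit)),
              n_params = attr(stats::logLik(fit), "df"),
              converged = conv_ok,
              iterations = as.integer(fit@optinfo$feval),
              spec = spec, model = fit,
              S = site_totals(data), x = data$x,
              site_ids = data$site_ids, species_ids = data$species_ids)
  class(out) <- "glmm_fit"
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Binomial-logit mixed model fit\n")
  cat("  formula:", spec_formula_string(x$spec), "\n")
  cat(sprintf("  logLik %.2f on %d parameters; %s after %d evaluations\n",
              x$loglik, as.integer(x$n_params),
              if (x$converged) "converged" else "NOT converged",
              as.integer(x$iterations)))
  cat("  fixed effects:\n")
  print(round(x$fixed, 4))
  if (!is.na(x$var_alpha) || !is.na(x$var_gamma)) {
    cat(sprintf("  variance components: var_alpha = %.3f, var_beta = %.3f, rho = %.3f, var_gamma = %.3f\n",
                x$var_alpha, x$var_beta, x$rho, x$var_gamma))
  }
  invisible(x)
}

#' Extract the site-effect conditional modes
#'
#' Returns the conditional modes (BLUPs) of the random site effects in site
#' order — the quantities that are plotted against the gradient and fed to
#' \code{\link{unimodality_test}}.
#'
#' @param fit a \code{\link{fit_glmm}} result whose spec includes the random
#'   site intercept.
#' @return data.frame with columns \code{site_id}, \code{gamma}.
#' @export
site_effects <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!fit$spec$site_random) {
    stop("the fitted model has no random site effect", call. = FALSE)
  }
  data.frame(site_id = fit$site_ids,
             gamma = as.numeric(fit$gamma),
             stringsAsFactors = FALSE)
}

#' Extract total per-species slopes
#'
#' The total slope of species j is the fixed slope plus the species'
#' conditional-mode deviation.  Under equal-tolerance unimodal response the
#' slopes are proportional to the species optima (slope = optimum /
#' tolerance^2), so plotting them against independently estimated optima is
#' a key diagnostic.
#'
#' @param fit a \code{\link{fit_glmm}} result whose spec includes a random
#'   species slope on \code{x}.
#' @return data.frame with columns \code{species_id}, \code{slope}.
#' @export
species_slopes <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!"x" %in% fit$spec$species_random) {
    stop("the fitted model has no random species slope on x", call. = FALSE)
  }
  fx <- if ("x" %in% rownames(fit$fixed)) fit$fixed["x", 1] else 0
  data.frame(species_id = fit$species_modes$species_id,
             slope = fx + fit$species_modes[["x"]],
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio comparison of two nested mixed-model fits
#'
#' Computes the likelihood-ratio statistic \code{2 * (logLik_alt -
#' logLik_null)} with a chi-square reference on the parameter-count
#' difference.  When the extra parameters are variance components the null
#' value lies on the boundary of the parameter space, so the chi-square
#' reference is only a rough guide — for small tolerances the test is
#' anti-conservative (inflated type-I error); the returned object carries
#' this caveat.
#'
#' @param null_fit,alt_fit \code{\link{fit_glmm}} results; the null spec
#'   must be nested in the alternative spec and both must have converged.
#' @return list with \code{statistic}, \code{df}, \code{p} and
#'   \code{caveat}.
#' @export
compare_fits <- function(null_fit, alt_fit) {
  stopifnot(inherits(null_fit, "glmm_fit"), inherits(alt_fit, "glmm_fit"))
  if (!spec_nested(null_fit$spec, alt_fit$spec)) {
    stop("null model is not nested in the alternative model", call. = FALSE)
  }
  if (!null_fit$converged || !alt_fit$converged) {
    stop("both fits must have converged", call. = FALSE)
  }
  stat <- 2 * (alt_fit$loglik - null_fit$loglik)
  df <- alt_fit$n_params - null_fit$n_params
  p <- if (stat <= 0) 1 else if (df == 0) 0 else
    stats::pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p = p,
       caveat = paste("chi-square reference; boundary variance-component",
                      "tests can be anti-conservative"))
}

#' Joint conditional modes at fixed variance components
#'
#' Maximizes the joint penalized binomial log-likelihood over the random
#' effects (and, optionally, the fixed effects) with the variance components
#' held at supplied values: the inner problem of the Laplace approximation,
#' solved by damped Newton iteration on the dense joint system.  Useful for
#' profiling, for verification against the full fitter, and for degenerate
#' models — a block whose variance is zero is dropped (its modes are exactly
#' zero), and with all variances zero the procedure reduces to ordinary
#' logistic regression.
#'
#' The penalized objective is the Bernoulli log-likelihood of the linear
#' predictor minus \code{b' V^{-1} b / 2} summed over random-effect blocks.
#' Newton steps are halved until the objective does not decrease, so the
#' accepted path is monotone.
#'
#' @param data a \code{\link{community_data}}.
#' @param spec a \code{\link{glmm_spec}}.
#' @param species_vcov covariance matrix of the species random terms
#'   (dimension = number of species random terms); a zero matrix (or
#'   \code{NULL} with no species terms) drops the block.  Must otherwise be
#'   positive definite.
#' @param site_var variance of the random site effect; 0 drops the block.
#' @param fixed named numeric vector of fixed-effect values to hold fixed
#'   (names as in the fit's coefficient table), or \code{NULL} to estimate
#'   the fixed effects jointly with the modes.
#' @param max_iter,tol Newton iteration cap and gradient-norm tolerance.
#' @return list with \code{fixed}, \code{species_modes} (matrix m x k),
#'   \code{gamma}, \code{objective} (the final penalized log-likelihood),
#'   \code{trace} (objective per accepted iteration), \code{iterations},
#'   \code{converged}.
#' @export
conditional_modes_fixed <- function(data, spec = glmm_spec(),
                                    species_vcov = NULL, site_var = 0,
                                    fixed = NULL,
                                    max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(data, "community_data"), inherits(spec, "glmm_spec"))
  long <- model_frame(data)
  N <- nrow(long)
  n <- nrow(data$Y); m <- ncol(data$Y)
  y <- long$y

  cols <- function(terms) {
    out <- matrix(1, N, 0)
    for (tm in terms) {
      out <- cbind(out, switch(tm, intercept = rep(1, N), x = long$x,
                               x2 = long$xx))
    }
    colnames(out) <- c(intercept = "(Intercept)", x = "x",
                       x2 = "xx")[terms]
    out
  }

  X <- cols(spec$fixed)
  k <- length(spec$species_random)
  use_species <- k > 0L && !is.null(species_vcov) && any(species_vcov != 0)
  use_site <- spec$site_random && site_var > 0
  if (k > 0L && use_species) {
    species_vcov <- as.matrix(species_vcov)
    if (!all(dim(species_vcov) == k)) {
      stop("species_vcov must be ", k, " x ", k, call. = FALSE)
    }
    ev <- eigen(species_vcov, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) {
      stop("species_vcov must be positive definite (or all zero)",
           call. = FALSE)
    }
  }
  estimate_fixed <- is.null(fixed)
  if (!estimate_fixed) {
    if (is.null(names(fixed)) || !all(colnames(X) %in% names(fixed))) {
      stop("'fixed' must be named with: ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    }
    offset_fixed <- drop(X %*% fixed[colnames(X)])
  }

  # assemble the joint (dense) design and penalty
  blocks <- list()
  if (estimate_fixed) blocks$fixed <- X
  ji <- as.integer(long$species); si <- as.integer(long$site)
  if (use_species) {
    Zs_cols <- cols(spec$species_random)
    Z <- matrix(0, N, m * k)
    for (c0 in seq_len(k)) {
      Z[cbind(seq_len(N), (ji - 1L) * k + c0)] <- Zs_cols[, c0]
    }
    blocks$species <- Z
  }
  if (use_site) {
    G <- matrix(0, N, n)
    G[cbind(seq_len(N), si)] <- 1
    blocks$site <- G
  }
  D <- do.call(cbind, blocks)
  p_fx <- if (estimate_fixed) ncol(X) else 0L
  d <- ncol(D)
  P <- matrix(0, d, d)
  if (use_species) {
    Sinv <- solve(species_vcov)
    idx <- p_fx + seq_len(m * k)
    P[idx, idx] <- kronecker(diag(m), Sinv)
  }
  if (use_site) {
    idx <- p_fx + (if (use_species) m * k else 0L) + seq_len(n)
    diag(P)[idx] <- 1 / site_var
  }

  obj <- function(theta) {
    eta <- drop(D %*% theta) + (if (estimate_fixed) 0 else offset_fixed)
    sum(y * eta - log1p(exp(eta))) - 0.5 * drop(theta %*% P %*% theta)
  }
  theta <- rep(0, d)
  f <- obj(theta)
  trace <- f
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    eta <- drop(D %*% theta) + (if (estimate_fixed) 0 else offset_fixed)
    mu <- stats::plogis(eta)
    g <- drop(crossprod(D, y - mu)) - drop(P %*% theta)
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; it <- it - 1L; break }
    W <- mu * (1 - mu)
    H <- crossprod(D, D * W) + P
    step <- solve(H, g)
    # damped: halve until the penalized objective does not decrease
    lam <- 1
    repeat {
      f_new <- obj(theta + lam * step)
      if (f_new >= f - 1e-12 || lam < 1e-8) break
      lam <- lam / 2
    }
    theta <- theta + lam * step
    if (abs(f_new - f) < tol * (abs(f) + 1)) converged <- TRUE
    f <- f_new
    trace <- c(trace, f)
    if (converged) break
  }

  fixed_out <- if (estimate_fixed) {
    stats::setNames(theta[seq_len(p_fx)], colnames(X))
  } else fixed
  sm <- NULL
  if (use_species) {
    sm <- matrix(theta[p_fx + seq_len(m * k)], nrow = m, ncol = k,
                 byrow = TRUE,
                 dimnames = list(data$species_ids,
                                 colnames(cols(spec$species_random))))
  } else if (k > 0L) {
    sm <- matrix(0, m, k, dimnames = list(data$species_ids, NULL))
  }
  gam <- if (use_site) {
    stats::setNames(theta[p_fx + (if (use_species) m * k else 0L) +
                            seq_len(n)], data$site_ids)
  } else if (spec$site_random) {
    stats::setNames(rep(0, n), data$site_ids)
  } else NULL
  list(fixed = fixed_out, species_modes = sm, gamma = gam,
       objective = f, trace = trace, iterations = it,
       converged = converged)
}

#' Serialize a mixed-model fit
#'
#' Writes a JSON summary (fixed effects, variance components, likelihood,
#' convergence) and two CSVs of conditional modes (per species and per
#' site).
#'
#' @param fit a \code{\link{fit_glmm}} result.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return invisibly, the written paths.
#' @export
write_glmm_fit <- function(fit, dir, prefix = "glmm") {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p_json <- file.path(dir, paste0(prefix, "_summary.json"))
  summ <- list(
    formula = spec_formula_string(fit$spec),
    fixed = apply(fit$fixed, 1, function(r)
      list(estimate = r[[1]], se = r[[2]])),
    var_alpha = fit$var_alpha, var_beta = fit$var_beta, rho = fit$rho,
    var_gamma = fit$var_gamma,
    loglik = fit$loglik, n_params = fit$n_params,
    converged = fit$converged, iterations = fit$iterations)
  jsonlite::write_json(summ, p_json, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- p_json
  if (!is.null(fit$species_modes)) {
    p_sp <- file.path(dir, paste0(prefix, "_species_modes.csv"))
    utils::write.csv(fit$species_modes, p_sp, row.names = FALSE)
    paths <- c(paths, p_sp)
  }
  if (!is.null(fit$gamma)) {
    p_si <- file.path(dir, paste0(prefix, "_site_effects.csv"))
    utils::write.csv(site_effects(fit), p_si, row.names = FALSE)
    paths <- c(paths, p_si)
  }
  invisible(paths)
}
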