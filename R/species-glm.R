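#' Convert between Gaussian and quadratic-logit parameterizations
#'
#' The Gaussian logistic curve \code{logit(p) = a - (x - u)^2 / (2 t^2)}
#' expands to the quadratic predictor \code{b0 + b1 x + b2 x^2} with
#' \code{b0 = a - u^2/(2 t^2)}, \code{b1 = u / t^2}, \code{b2 = -1/(2 t^2)}.
#' The inverse is defined only for negative curvature (\code{b2 < 0}):
#' \code{t = 1/sqrt(-2 b2)}, \code{u = -b1 / (2 b2)},
#' \code{a = b0 - b1^2 / (4 b2)}.
#'
#' @param a,u,t Gaussian parameters (tolerance \code{t > 0}); vectors are
#'   accepted and recycled.
#' @return \code{gaussian_to_quadratic}: matrix (or named vector for scalar
#'   input) with columns \code{b0}, \code{b1}, \code{b2};
#'   \code{quadratic_to_gaussian}: an object of class
#'   \code{"gaussian_params"} with fields \code{a}, \code{u}, \code{t}.
#' @export
gaussian_to_quadratic <- function(a, u, t) {
  stopifnot(all(t > 0))
  out <- cbind(b0 = a - u^2 / (2 * t^2), b1 = u / t^2, b2 = -1 / (2 * t^2))
  if (nrow(out) == 1L) out[1L, ] else out
}

#' @rdname gaussian_to_quadratic
#' @param b0,b1,b2 quadratic logit coefficients; \code{b2} must be negative.
#' @export
quadratic_to_gaussian <- function(b0, b1, b2) {
  if (any(b2 >= 0)) {
    stop("no interior optimum: the x^2 coefficient must be negative",
         call. = FALSE)
  }
  structure(list(a = b0 - b1^2 / (4 * b2),
                 u = -b1 / (2 * b2),
                 t = 1 / sqrt(-2 * b2)),
            class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Gaussian logistic parameters (%d species)\n", length(x$u)))
  print(data.frame(a = x$a, u = x$u, t = x$t))
  invisible(x)
}

#' Per-species Gaussian logistic fit by quadratic logistic regression
#'
#' Fits the logistic regression of one species' presences on \code{x} and
#' \code{x^2} by maximum likelihood (IRLS, via \code{\link[stats]{glm}}).
#' A negative fitted \code{x^2} coefficient means the estimated response is
#' unimodal within-range; \code{\link{to_gaussian}} then yields the optimum
#' and tolerance.  Complete or quasi-complete separation — coefficients
#' diverging because a threshold on \code{x} splits the 0s and 1s — is
#' flagged, not raised; species with constant response (never or always
#' present) get an undefined fit with both flags set.
#'
#' @param y binary 0/1 vector (one species' presences).
#' @param x gradient values, same length (>= 4).
#' @param species_id identifier carried through to tables.
#' @return object of class \code{"species_glm"}: list with \code{species_id},
#'   coefficients \code{b0}, \code{b1}, \code{b2}, \code{se_b2},
#'   \code{z_b2}, \code{converged}, \code{separation}, \code{degenerate}.
#' @export
fit_species_glm <- function(y, x, species_id = "sp") {
  y <- as.numeric(y); x <- as.numeric(x)
  if (length(y) != length(x)) stop("y and x differ in length", call. = FALSE)
  if (length(y) < 4L) stop("need at least 4 observations", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1", call. = FALSE)
  if (all(y == y[1L])) {
    out <- list(species_id = species_id, b0 = NA_real_, b1 = NA_real_,
                b2 = NA_real_, se_b2 = NA_real_, z_b2 = NA_real_,
                converged = FALSE, separation = TRUE, degenerate = TRUE)
    class(out) <- "species_glm"
    return(out)
  }
  separation <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x + I(x^2), family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("algorithm did not converge", conditionMessage(w))) {
        separation <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  cf <- summary(fit)$coefficients
  out <- list(species_id = species_id,
              b0 = cf[1, 1], b1 = cf[2, 1], b2 = cf[3, 1],
              se_b2 = cf[3, 2], z_b2 = cf[3, 1] / cf[3, 2],
              converged = fit$converged,
              separation = separation || !fit$converged,
              degenerate = FALSE)
  class(out) <- "species_glm"
  out
}

#' @export
print.species_glm <- function(x, ...) {
  cat(sprintf("species_glm [%s]: b = (%.3g, %.3g, %.3g), z[x^2] = %.2f%s\n",
              x$species_id, x$b0, x$b1, x$b2, x$z_b2,
              if (x$separation) " (separation)" else ""))
  invisible(x)
}

#' Fit the quadratic logistic GLM to every species
#'
#' @param data a \code{\link{community_data}}.
#' @return list of \code{\link{fit_species_glm}} results, one per species,
#'   named by species id.
#' @export
fit_species_glms <- function(data) {
  stopifnot(inherits(data, "community_data"))
  fits <- lapply(seq_len(ncol(data$Y)), function(j) {
    fit_species_glm(data$Y[, j], data$x, species_id = data$species_ids[j])
  })
  names(fits) <- data$species_ids
  fits
}

#' Tabulate per-species fits with their Gaussian parameters
#'
#' @param fits list of \code{\link{fit_species_glm}} results.
#' @return data.frame with columns \code{species_id}, \code{b0}, \code{b1},
#'   \code{b2}, \code{se_b2}, \code{z_b2}, \code{a}, \code{u}, \code{t}
#'   (\code{NA} unless \code{b2 < 0}), \code{converged}, \code{separation}.
#' @export
species_glm_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    g <- if (!is.na(f$b2) && f$b2 < 0) {
      quadratic_to_gaussian(f$b0, f$b1, f$b2)
    } else list(a = NA_real_, u = NA_real_, t = NA_real_)
    data.frame(species_id = f$species_id, b0 = f$b0, b1 = f$b1, b2 = f$b2,
               se_b2 = f$se_b2, z_b2 = f$z_b2,
               a = g$a, u = g$u, t = g$t,
               converged = f$converged, separation = f$separation,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gaussian parameters of a fitted species curve
#'
#' @param fit a \code{\link{fit_species_glm}} result with \code{b2 < 0}.
#' @return a \code{"gaussian_params"} object (fields \code{a}, \code{u},
#'   \code{t}).
#' @export
to_gaussian <- function(fit) {
  stopifnot(inherits(fit, "species_glm"))
  if (is.na(fit$b2)) stop("undefined fit (degenerate species)", call. = FALSE)
  quadratic_to_gaussian(fit$b0, fit$b1, fit$b2)
}

#' Screen species for a well-defined optimum
#'
#' Retains species whose quadratic-logit fit is concave (\code{b2 < 0}) and
#' whose squared-term z-ratio falls below \code{z_threshold}.  The default
#' threshold of -1 asks for at least mild evidence of curvature; for very
#' small data sets a threshold of 0 (sign only) may be preferred.
#'
#' @param fits list of \code{\link{fit_species_glm}} results.
#' @param z_threshold keep species with \code{z_b2 < z_threshold} (default
#'   -1).
#' @return character vector of retained species ids.
#' @export
screen_optima <- function(fits, z_threshold = -1) {
  keep <- vapply(fits, function(f) {
    !is.na(f$b2) && !is.na(f$z_b2) && f$b2 < 0 && f$z_b2 < z_threshold
  }, logical(1))
  unname(vapply(fits[keep], `[[`, character(1), "species_id"))
}

#' Recover equal-tolerance Gaussian parameters from the quadratic mixed model
#'
#' When the mixed model carries an explicit fixed \code{x^2} term (with
#' random species intercepts and slopes and random site effects), its
#' coefficients map onto a constant-tolerance Gaussian logistic model: the
#' common tolerance is \code{t = 1/sqrt(-2 beta2)} from the fixed curvature
#' \code{beta2}, each species' optimum is \code{u_j = t^2 * beta_1j} (its
#' total slope), its maximum coefficient is \code{a_j = alpha_j + u_j^2 /
#' (2 t^2)} (from its total intercept), and the adjusted site effects are
#' \code{gamma_i + x_i^2 / (2 t^2)}.  The adjusted site effects should look
#' like independent normal noise when the quadratic adequately captures the
#' unimodality — check with \code{\link{qq_site_effects}}.
#'
#' @param fit a \code{\link{fit_glmm}} result whose spec has fixed terms
#'   \code{intercept, x, x2}, species random \code{intercept, x} and the
#'   random site effect, with a negative fitted \code{x^2} coefficient.
#' @return list with \code{t} (common tolerance), \code{beta2},
#'   \code{params} (data.frame \code{species_id}, \code{u}, \code{a},
#'   \code{alpha}, \code{slope}) and \code{gamma_adj} (named vector of
#'   adjusted site effects).
#' @export
common_tolerance_transform <- function(fit) {
  stopifnot(inherits(fit, "glmm_fit"))
  if (!"x2" %in% fit$spec$fixed) {
    stop("fit must include the fixed x^2 term", call. = FALSE)
  }
  if (!all(c("intercept", "x") %in% fit$spec$species_random) ||
      !fit$spec$site_random) {
    stop("fit must have random species intercept and slope and random site effects",
         call. = FALSE)
  }
  beta2 <- fit$fixed["xx", 1]
  if (beta2 >= 0) {
    stop("no common curvature: the fixed x^2 coefficient is not negative",
         call. = FALSE)
  }
  t <- 1 / sqrt(-2 * beta2)
  alpha <- fit$fixed["(Intercept)", 1] + fit$species_modes[["(Intercept)"]]
  slope <- fit$fixed["x", 1] + fit$species_modes[["x"]]
  u <- t^2 * slope
  a <- alpha + u^2 / (2 * t^2)
  gamma_adj <- fit$gamma + fit$x^2 / (2 * t^2)
  list(t = t, beta2 = beta2,
       params = data.frame(species_id = fit$species_modes$species_id,
                           u = u, a = a, alpha = alpha, slope = slope,
                           stringsAsFactors = FALSE),
       gamma_adj = gamma_adj)
}

#' Compare mixed-model slopes with independently fitted optima
#'
#' Under equal-tolerance unimodal response the mixed-model species slope is
#' proportional to the species optimum (slope = u / t^2), so the two should
#' line up when plotted.  This joins the per-species slopes from the mixed
#' model with the optima from the explicit per-species Gaussian fits
#' (screened by \code{\link{screen_optima}}; separation-flagged species are
#' excluded by default) and reports their Pearson correlation.
#'
#' @param glmm_fit a \code{\link{fit_glmm}} result with random species
#'   slopes.
#' @param fits list of \code{\link{fit_species_glm}} results on the same
#'   data.
#' @param z_threshold screening threshold (see \code{\link{screen_optima}}).
#' @param exclude_separation drop separation-flagged species (default TRUE).
#' @param out_path optional scatter-plot file (svg, pdf or png).
#' @return object of class \code{"slope_optimum"}: list with \code{table}
#'   (data.frame \code{species_id}, \code{glmm_slope}, \code{glm_optimum})
#'   and \code{correlation}.
#' @export
slope_vs_optimum <- function(glmm_fit, fits, z_threshold = -1,
                             exclude_separation = TRUE, out_path = NULL) {
  slopes <- species_slopes(glmm_fit)
  keep <- screen_optima(fits, z_threshold = z_threshold)
  if (exclude_separation) {
    sep <- vapply(fits, `[[`, logical(1), "separation")
    keep <- setdiff(keep, names(fits)[sep])
  }
  keep <- intersect(keep, slopes$species_id)
  if (!length(keep)) {
    stop("no species left after screening", call. = FALSE)
  }
  opt <- vapply(fits[keep], function(f) to_gaussian(f)$u, numeric(1))
  tab <- data.frame(species_id = keep,
                    glmm_slope = slopes$slope[match(keep, slopes$species_id)],
                    glm_optimum = as.numeric(opt),
                    stringsAsFactors = FALSE)
  r <- if (nrow(tab) >= 3L) stats::cor(tab$glmm_slope, tab$glm_optimum)
       else NA_real_
  if (!is.null(out_path)) {
    open_device(out_path)
    on.exit(grDevices::dev.off())
    graphics::plot(tab$glm_optimum, tab$glmm_slope,
                   xlab = "optimum (per-species Gaussian fit)",
                   ylab = "mixed-model species slope",
                   main = sprintf("r = %.3f (%d species)", r, nrow(tab)))
  }
  structure(list(table = tab, correlation = r), class = "slope_optimum")
}

#' @export
print.slope_optimum <- function(x, ...) {
  cat(sprintf("slope vs optimum: %d species, Pearson r = %.3f\n",
              nrow(x$table), x$correlation))
  invisible(x)
}

#' Write the per-species fit table as CSV
#'
#' @param fits list of \code{\link{fit_species_glm}} results.
#' @param path output path.
#' @return invisibly, the table.
#' @export
write_species_glms <- function(fits, path) {
  tab <- species_glm_table(fits)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
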