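#' Site totals (per-site species richness)
#'
#' The site total S_i is the number of species observed at site i, the row
#' sum of the presence-absence matrix.  It proxies overall site
#' favourability and enters the unimodality regression as a covariate.
#'
#' @param data a \code{\link{community_data}}.
#' @return integer vector of length n, named by site id.
#' @export
site_totals <- function(data) {
  stopifnot(inherits(data, "community_data"))
  rowSums(data$Y)
}

#' Whittaker's beta diversity
#'
#' Computes beta_w = T / S_bar - 1, where T is the number of species
#' observed in at least one site and S_bar the mean site total.  Zero means
#' every species occurs everywhere (no turnover); larger values indicate
#' stronger species turnover along the gradient.  All sites, including empty
#' ones, enter the mean; species never observed do not enter T.
#'
#' @param data a \code{\link{community_data}} with at least one occurrence.
#' @return object of class \code{"diversity_summary"}: list with \code{S_i},
#'   \code{T}, \code{S_bar}, \code{beta_w}.
#' @export
whittaker_beta <- function(data) {
  stopifnot(inherits(data, "community_data"))
  S_i <- site_totals(data)
  T_obs <- sum(colSums(data$Y) > 0)
  if (T_obs == 0L) {
    stop("all-zero community matrix: beta diversity undefined", call. = FALSE)
  }
  S_bar <- mean(S_i)
  structure(list(S_i = S_i, T = T_obs, S_bar = S_bar,
                 beta_w = T_obs / S_bar - 1),
            class = "diversity_summary")
}

#' @export
print.diversity_summary <- function(x, ...) {
  cat(sprintf("diversity: T = %d species, mean site total = %.2f, beta_w = %.3f\n",
              x$T, x$S_bar, x$beta_w))
  invisible(x)
}

#' Serialize a diversity summary
#'
#' Writes T, S_bar and beta_w as JSON and the site totals as CSV.
#'
#' @param summary a \code{\link{whittaker_beta}} result.
#' @param json_path,csv_path output paths (either may be \code{NULL}).
#' @return invisibly, \code{summary}.
#' @export
write_diversity <- function(summary, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(summary, "diversity_summary"))
  if (!is.null(json_path)) {
    jsonlite::write_json(list(T = summary$T, S_bar = summary$S_bar,
                              beta_w = summary$beta_w),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(data.frame(site_id = names(summary$S_i),
                                S = as.integer(summary$S_i)),
                     csv_path, row.names = FALSE)
  }
  invisible(summary)
}
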