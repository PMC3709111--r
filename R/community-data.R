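#' Construct a presence-absence community data object
#'
#' Bundles a binary sites-by-species matrix with one quantitative
#' environmental variable per site.  This is the universal input of the
#' package: the mixed-model fitters, the unimodality test pipeline and the
#' diversity descriptors all consume it.
#'
#' @param Y integer or logical matrix, \code{n} sites (rows) by \code{m}
#'   species (columns), entries 0/1.  Dimnames, when present, seed the
#'   default ids.
#' @param x numeric vector of length \code{n}: the environmental variable,
#'   one value per site, no missing values.
#' @param site_ids character vector of unique site identifiers (default:
#'   rownames of \code{Y}, else \code{"site1"..."siten"}).
#' @param species_ids character vector of unique species identifiers
#'   (default: colnames of \code{Y}, else \code{"sp1"..."spm"}).
#'
#' @return An object of class \code{"community_data"}: a list with elements
#'   \code{Y} (integer matrix with dimnames), \code{x}, \code{site_ids},
#'   \code{species_ids}.
#'
#' @details Missing values in \code{x} are an error, never silently dropped:
#'   remove such sites yourself before constructing the object.  All-zero
#'   sites are legitimate (they still inform the site effects), as are
#'   species observed in no or all sites; the latter are reported by
#'   \code{\link{species_flags}}.
#'
#' @seealso \code{\link{read_community}}, \code{\link{to_long}}
#' @export
#' @examples
#' d <- community_data(rbind(c(1, 1, 0), c(0, 1, 1)), x = c(-1, 1))
#' d
community_data <- function(Y, x, site_ids = NULL, species_ids = NULL) {
  if (!is.matrix(Y)) Y <- as.matrix(Y)
  if (is.logical(Y)) storage.mode(Y) <- "integer"
  if (!is.numeric(Y)) {
    stop("'Y' must be a numeric 0/1 matrix", call. = FALSE)
  }
  bad <- which(!(Y %in% c(0L, 1L)) | is.na(Y))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(Y))
    stop(sprintf(
      "'Y' must contain only 0 or 1; first offending cell at row %d, column %d (value %s)",
      i[1L], i[2L], format(Y[bad[1L]])), call. = FALSE)
  }
  storage.mode(Y) <- "integer"
  n <- nrow(Y); m <- ncol(Y)
  if (is.null(site_ids)) {
    site_ids <- rownames(Y)
    if (is.null(site_ids)) site_ids <- paste0("site", seq_len(n))
  }
  if (is.null(species_ids)) {
    species_ids <- colnames(Y)
    if (is.null(species_ids)) species_ids <- paste0("sp", seq_len(m))
  }
  site_ids <- as.character(site_ids)
  species_ids <- as.character(species_ids)
  x <- as.numeric(x)
  if (length(x) != n) {
    stop(sprintf("length(x) is %d but Y has %d rows", length(x), n),
         call. = FALSE)
  }
  if (anyNA(x)) {
    stop("'x' contains missing values; drop or impute those sites explicitly",
         call. = FALSE)
  }
  if (length(site_ids) != n || length(species_ids) != m) {
    stop("id vectors must match the matrix dimensions", call. = FALSE)
  }
  if (anyDuplicated(site_ids)) {
    stop("duplicate site ids: ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(species_ids)) {
    stop("duplicate species ids: ",
         paste(unique(species_ids[duplicated(species_ids)]), collapse = ", "),
         call. = FALSE)
  }
  dimnames(Y) <- list(site_ids, species_ids)
  structure(list(Y = Y, x = x, site_ids = site_ids,
                 species_ids = species_ids),
            class = "community_data")
}

#' @export
print.community_data <- function(x, ...) {
  cat(sprintf("community_data: %d sites x %d species\n",
              nrow(x$Y), ncol(x$Y)))
  cat(sprintf("  occupancy: %.1f%% of cells are presences\n",
              100 * mean(x$Y)))
  cat(sprintf("  gradient x: range [%.3g, %.3g]\n",
              min(x$x), max(x$x)))
  invisible(x)
}

#' @export
dim.community_data <- function(x) dim(x$Y)

#' Flag degenerate species columns
#'
#' Species observed in zero sites or in every site carry no information about
#' the gradient; they are kept in the matrix (the mixed model shrinks their
#' effects) but can be identified with this helper.
#'
#' @param data a \code{\link{community_data}} object.
#' @return data.frame with columns \code{species_id}, \code{n_occ},
#'   \code{all_zero}, \code{all_one}.
#' @export
species_flags <- function(data) {
  stopifnot(inherits(data, "community_data"))
  occ <- colSums(data$Y)
  data.frame(species_id = data$species_ids,
             n_occ = as.integer(occ),
             all_zero = occ == 0L,
             all_one = occ == nrow(data$Y),
             stringsAsFactors = FALSE)
}

#' Convert a community matrix to long (vectorized) records
#'
#' One row per (site, species) cell, in site-major order: all species of the
#' first site, then all species of the second site, and so on.  Each row
#' repeats the site's gradient value.  This is the layout the mixed-model
#' fitters consume.
#'
#' @param data a \code{\link{community_data}} object.
#' @return data.frame with columns \code{site_id}, \code{species_id},
#'   \code{y} (integer 0/1), \code{x} (numeric), \code{n * m} rows.
#' @seealso \code{\link{from_long}} for the lossless inverse.
#' @export
to_long <- function(data) {
  stopifnot(inherits(data, "community_data"))
  n <- nrow(data$Y); m <- ncol(data$Y)
  data.frame(
    site_id = rep(data$site_ids, each = m),
    species_id = rep(data$species_ids, times = n),
    y = as.integer(t(data$Y)),
    x = rep(data$x, each = m),
    stringsAsFactors = FALSE)
}

#' Rebuild a community object from long records
#'
#' Inverse of \code{\link{to_long}}.  Site and species order follow first
#' appearance in the records; every (site, species) pair must occur exactly
#' once, and the per-site \code{x} must be consistent across that site's
#' rows.
#'
#' @param records data.frame with columns \code{site_id}, \code{species_id},
#'   \code{y}, \code{x}.
#' @return a \code{\link{community_data}} object.
#' @export
from_long <- function(records) {
  need <- c("site_id", "species_id", "y", "x")
  miss <- setdiff(need, names(records))
  if (length(miss)) {
    stop("long records lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  sites <- unique(as.character(records$site_id))
  species <- unique(as.character(records$species_id))
  n <- length(sites); m <- length(species)
  if (nrow(records) != n * m) {
    stop(sprintf(
      "expected one row per (site, species) pair: %d x %d = %d rows, got %d",
      n, m, n * m, nrow(records)), call. = FALSE)
  }
  i <- match(as.character(records$site_id), sites)
  j <- match(as.character(records$species_id), species)
  if (anyDuplicated(cbind(i, j))) {
    stop("duplicate (site, species) pairs in long records", call. = FALSE)
  }
  Y <- matrix(NA_integer_, n, m)
  Y[cbind(i, j)] <- as.integer(records$y)
  xs <- rep(NA_real_, n)
  xs[i] <- as.numeric(records$x)
  # consistency of x within each site
  agg <- tapply(as.numeric(records$x), i, function(v) diff(range(v)))
  if (any(agg > 0)) {
    stop("inconsistent x values within site(s): ",
         paste(sites[as.integer(names(agg))[agg > 0]], collapse = ", "),
         call. = FALSE)
  }
  community_data(Y, xs, site_ids = sites, species_ids = species)
}
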