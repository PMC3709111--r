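#' @keywords internal
#' Sniff the delimiter of a delimited text file: comma or tab.
detect_sep <- function(path) {
  header <- readLines(path, n = 1L)
  n_tab <- lengths(regmatches(header, gregexpr("\t", header)))
  n_com <- lengths(regmatches(header, gregexpr(",", header)))
  if (n_tab == 0L && n_com == 0L) {
    stop("cannot detect delimiter (no comma or tab) in header of ", path,
         call. = FALSE)
  }
  if (n_tab >= n_com) "\t" else ","
}

read_table_auto <- function(path) {
  sep <- detect_sep(path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "\"")
}

#' Read community data from delimited text files
#'
#' Reads a wide sites-by-species matrix (header row of species ids, first
#' column of site ids) and a site table holding the environmental variable,
#' and assembles a \code{\link{community_data}} object.  The delimiter
#' (comma or tab) is auto-detected per file from the header line.
#'
#' Abundance values are binarized on read by the rule \code{value > 0 -> 1},
#' with a warning when any cell exceeded 1: the method is defined for
#' presence-absence data.  Sites in the environment table are matched to
#' matrix rows by id, not by position, so row order of the two files may
#' differ.
#'
#' @param path_matrix path to the community matrix file.
#' @param path_env path to the site table; must contain a \code{site_id}
#'   column and the column named by \code{env_column}.
#' @param env_column name of the environmental variable column in
#'   \code{path_env}.
#' @return a \code{\link{community_data}} object.
#' @seealso \code{\link{write_community}}
#' @export
read_community <- function(path_matrix, path_env, env_column = "x") {
  mat <- read_table_auto(path_matrix)
  if (ncol(mat) < 2L) {
    stop("community matrix needs a site-id column plus at least one species",
         call. = FALSE)
  }
  site_ids <- as.character(mat[[1L]])
  vals <- mat[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf(
        "non-numeric cell in community matrix at site '%s', species '%s'",
        site_ids[i], names(vals)[j]), call. = FALSE)
    }
    vals[[j]] <- v
  }
  Y <- as.matrix(vals)
  if (any(Y > 1)) {
    warning("abundances > 1 found; binarizing at value > 0", call. = FALSE)
  }
  Y <- (Y > 0) + 0L

  env <- read_table_auto(path_env)
  if (!"site_id" %in% names(env)) {
    stop("environment table lacks a 'site_id' column", call. = FALSE)
  }
  if (!env_column %in% names(env)) {
    stop(sprintf("environment table lacks column '%s' (has: %s)",
                 env_column, paste(names(env), collapse = ", ")),
         call. = FALSE)
  }
  env_ids <- as.character(env$site_id)
  if (anyDuplicated(env_ids)) {
    stop("duplicate site ids in environment table: ",
         paste(unique(env_ids[duplicated(env_ids)]), collapse = ", "),
         call. = FALSE)
  }
  idx <- match(site_ids, env_ids)
  if (anyNA(idx)) {
    stop("site ids missing from environment table: ",
         paste(site_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  x <- as.numeric(env[[env_column]])[idx]
  if (anyNA(x)) {
    stop("missing values in environment column '", env_column, "' for sites: ",
         paste(site_ids[is.na(x)], collapse = ", "), call. = FALSE)
  }
  community_data(Y, x, site_ids = site_ids,
                 species_ids = colnames(Y))
}

#' Write community data to delimited text files
#'
#' Writes the wide matrix (first column \code{site_id}) and the site table
#' (\code{site_id} plus the environmental column) as CSV, the format
#' \code{\link{read_community}} reads back losslessly.
#'
#' @param data a \code{\link{community_data}} object.
#' @param path_matrix,path_env output paths.
#' @param env_column column name to use for \code{x} in the site table.
#' @return invisibly, \code{data}.
#' @export
write_community <- function(data, path_matrix, path_env, env_column = "x") {
  stopifnot(inherits(data, "community_data"))
  mat <- data.frame(site_id = data$site_ids, data$Y,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(mat, path_matrix, row.names = FALSE, quote = FALSE)
  env <- data.frame(site_id = data$site_ids, x = data$x,
                    stringsAsFactors = FALSE)
  names(env)[2L] <- env_column
  utils::write.csv(env, path_env, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' Read/write the long (vectorized) form
#'
#' The long form is a CSV with columns \code{site_id}, \code{species_id},
#' \code{y}, \code{x}, one row per cell of the community matrix.
#'
#' @param data a \code{\link{community_data}} object.
#' @param path file path.
#' @return \code{read_community_long} returns a \code{community_data};
#'   \code{write_community_long} invisibly returns \code{data}.
#' @export
write_community_long <- function(data, path) {
  utils::write.csv(to_long(data), path, row.names = FALSE, quote = FALSE)
  invisible(data)
}

#' @rdname write_community_long
#' @export
read_community_long <- function(path) {
  from_long(read_table_auto(path))
}
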