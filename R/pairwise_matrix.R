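#' Labeled symmetric pairwise matrix over sites
#'
#' Shared container for pairwise genetic distances (FST, linFST, Dps),
#' landscape resistances, and Euclidean distances: a symmetric numeric
#' matrix with a zero diagonal, site labels, and a metric tag.
#'
#' @param values square numeric matrix (or lower triangle to symmetrize)
#' @param sites site labels
#' @param metric one of `"fst"`, `"linfst"`, `"dps"`, `"resistance"`,
#'   `"euclid"`, `"other"`
#' @param p optional matching matrix of p-values
#' @return object of class `pairwise_matrix`
#' @export
pairwise_matrix <- function(values, sites = rownames(values),
                            metric = "other", p = NULL) {
  values <- as.matrix(values)
  k <- nrow(values)
  stopifnot(ncol(values) == k, k >= 2)
  if (is.null(sites)) sites <- as.character(seq_len(k))
  # symmetrize from whichever triangle is filled
  low <- values[lower.tri(values)]
  up <- t(values)[lower.tri(values)]
  if (all(is.na(up))) up <- low
  if (all(is.na(low))) low <- up
  if (any(abs(low - up) > 1e-8, na.rm = TRUE))
    stop("matrix is not symmetric")
  values[lower.tri(values)] <- low
  values <- t(values)
  values[lower.tri(values)] <- low
  diag(values) <- 0
  dimnames(values) <- list(sites, sites)
  structure(list(values = values, sites = as.character(sites),
                 metric = metric, p = p),
            class = "pairwise_matrix")
}

#' @export
print.pairwise_matrix <- function(x, ...) {
  cat("pairwise_matrix (", x$metric, ") over ", length(x$sites),
      " sites\n", sep = "")
  print(round(x$values, 4))
  invisible(x)
}

#' Lower-triangle vector of a pairwise matrix
#' @param m a [pairwise_matrix()] or square matrix
#' @return numeric vector, column-major lower triangle
#' @export
lower_tri <- function(m) {
  v <- if (inherits(m, "pairwise_matrix")) m$values else as.matrix(m)
  v[lower.tri(v)]
}

#' Write a pairwise matrix as labeled CSV
#' @param m a [pairwise_matrix()]
#' @param path output path
#' @return `path` invisibly
#' @export
write_pairwise_csv <- function(m, path) {
  df <- as.data.frame(m$values)
  write.csv(cbind(site = m$sites, df), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a labeled square CSV as a pairwise matrix
#' @param path CSV written by [write_pairwise_csv()] (first column = site)
#' @param metric metric tag
#' @return a [pairwise_matrix()]
#' @export
read_pairwise_csv <- function(path, metric = "other") {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  sites <- as.character(df[[1]])
  v <- as.matrix(df[, -1, drop = FALSE])
  pairwise_matrix(v, sites, metric)
}

#' Euclidean distance matrix from site coordinates
#' @param sites data frame with `site`, `x`, `y`
#' @return a [pairwise_matrix()] with metric `"euclid"`
#' @export
euclid_matrix <- function(sites) {
  d <- as.matrix(dist(sites[, c("x", "y")]))
  pairwise_matrix(d, sites$site, "euclid")
}

#' @importFrom stats dist
NULL
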