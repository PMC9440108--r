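#' Bray-Curtis dissimilarity between two abundance vectors
#'
#' \eqn{d(x, y) = \sum_i |x_i - y_i| / \sum_i (x_i + y_i)}, bounded in
#' [0, 1] for non-negative input; 0 for identical assemblages, 1 for
#' assemblages sharing no taxa.
#'
#' @param x,y non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return a single dissimilarity in [0, 1].
#' @export
bray_curtis <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  tot <- sum(x) + sum(y)
  if (tot <= 0) stop("Bray-Curtis undefined for two all-zero assemblages")
  sum(abs(x - y)) / tot
}

#' Squared-chord distance between two percentage vectors
#'
#' \eqn{d(x, y) = \sum_i (\sqrt{x_i} - \sqrt{y_i})^2}, the community
#' standard analogue metric for percentage data (maximum 200 when both
#' rows sum to 100).
#'
#' @param x,y non-negative numeric vectors of equal length.
#' @return a single distance \eqn{\ge 0}.
#' @export
squared_chord <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (any(x < 0) || any(y < 0)) stop("abundances must be non-negative")
  sum((sqrt(x) - sqrt(y))^2)
}

#' Pairwise dissimilarity matrix of a site-by-taxon table
#'
#' Bray-Curtis distances are computed with \code{vegan::vegdist};
#' squared-chord distances as squared Euclidean distances of the
#' square-root matrix.
#'
#' @param table a \code{\link{taxon_table}} or non-negative matrix.
#' @param metric "bray" or "sqchord".
#' @return an object of class \code{dissimilarity_matrix}: a symmetric
#'   zero-diagonal matrix with site ids as dimnames and the metric as an
#'   attribute.
#' @export
dissimilarity_matrix <- function(table, metric = c("bray", "sqchord")) {
  metric <- match.arg(metric)
  m <- if (inherits(table, "taxon_table")) table$values else as.matrix(table)
  if (any(m < 0)) stop("abundances must be non-negative")
  d <- switch(metric,
    bray = as.matrix(vegan::vegdist(m, method = "bray")),
    sqchord = as.matrix(dist(sqrt(m)))^2
  )
  dimnames(d) <- list(rownames(m), rownames(m))
  as_dissimilarity(d, metric)
}

as_dissimilarity <- function(d, metric) {
  d <- as.matrix(d)
  if (nrow(d) != ncol(d)) stop("dissimilarity matrix must be square")
  if (max(abs(d - t(d))) > 1e-10) stop("dissimilarity matrix must be symmetric")
  if (any(diag(d) > 1e-10)) stop("dissimilarity matrix must have a zero diagonal")
  if (any(d < 0)) stop("dissimilarities must be non-negative")
  if (metric == "bray" && any(d > 1 + 1e-10)) {
    stop("Bray-Curtis dissimilarities must lie in [0, 1]")
  }
  diag(d) <- 0
  d <- (d + t(d)) / 2
  structure(d, metric = metric, class = c("dissimilarity_matrix", "matrix", "array"))
}

#' @export
print.dissimilarity_matrix <- function(x, ...) {
  cat(sprintf("dissimilarity_matrix (%s): %d sites\n", attr(x, "metric"), nrow(x)))
  invisible(x)
}

#' Cross dissimilarities between two tables sharing a taxonomy
#'
#' One row per query (e.g. fossil) sample, one column per reference
#' (training) site. Taxa are matched by id; taxa absent from either side
#' contribute their abundance to the distance exactly as a disjoint taxon
#' would.
#'
#' @param query,reference \code{\link{taxon_table}}s or matrices with
#'   taxon ids as colnames.
#' @param metric "bray" or "sqchord".
#' @return numeric matrix (n_query x n_reference).
#' @export
cross_dissimilarity <- function(query, reference, metric = c("bray", "sqchord")) {
  metric <- match.arg(metric)
  q <- if (inherits(query, "taxon_table")) query$values else as.matrix(query)
  r <- if (inherits(reference, "taxon_table")) reference$values else as.matrix(reference)
  taxa <- union(colnames(q), colnames(r))
  pad <- function(m) {
    out <- matrix(0, nrow(m), length(taxa), dimnames = list(rownames(m), taxa))
    out[, colnames(m)] <- m
    out
  }
  q <- pad(q); r <- pad(r)
  if (metric == "sqchord") {
    sq <- sqrt(q); sr <- sqrt(r)
    # squared Euclidean cross-distances of the sqrt-transformed rows
    d <- outer(rowSums(sq^2), rep(1, nrow(sr))) +
      outer(rep(1, nrow(sq)), rowSums(sr^2)) - 2 * tcrossprod(sq, sr)
    d[d < 0] <- 0
  } else {
    d <- matrix(0, nrow(q), nrow(r))
    rs <- rowSums(r)
    for (i in seq_len(nrow(q))) {
      num <- colSums(abs(t(r) - q[i, ]))
      d[i, ] <- num / (sum(q[i, ]) + rs)
    }
  }
  dimnames(d) <- list(rownames(q), rownames(r))
  d
}

#' @rdname dissimilarity_matrix
#' @param d a \code{dissimilarity_matrix} to write.
#' @param path file path for a square CSV with site ids as header/index.
#' @export
write_dissimilarity_csv <- function(d, path) {
  stopifnot(inherits(d, "dissimilarity_matrix"))
  df <- cbind(data.frame(site = rownames(d), stringsAsFactors = FALSE),
              as.data.frame(unclass(d), check.names = FALSE))
  utils::write.table(df, path, row.names = FALSE, sep = ",",
                     fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' @rdname dissimilarity_matrix
#' @export
read_dissimilarity_csv <- function(path, metric = c("bray", "sqchord")) {
  metric <- match.arg(metric)
  df <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  as_dissimilarity(m, metric)
}
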