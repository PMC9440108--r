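#' Site-by-taxon abundance table
#'
#' The central data container: a dense numeric matrix of non-negative
#' abundances with sites as rows and taxa as columns, either raw counts
#' or percentages. Fossil tables additionally carry a calibrated age
#' (cal yr BP, larger = older) per site; ages must be strictly ordered
#' along the sequence so that row order matches depth order.
#'
#' Percentage tables are validated to have row sums of 100: rows summing
#' to 100 within 0.5 (tolerating rounding in published tables) are
#' renormalised exactly; anything further off is rejected.
#'
#' @param values numeric matrix (sites x taxa), non-negative.
#' @param site_ids character site identifiers; default rownames.
#' @param taxon_ids character taxon identifiers; default colnames.
#' @param kind "counts" or "percent".
#' @param ages optional numeric vector of calibrated ages (cal yr BP),
#'   strictly monotone along the rows.
#' @param metadata optional named list of free-form annotations (e.g. how
#'   fossil percentages were computed).
#' @return an object of class \code{taxon_table}.
#' @export
taxon_table <- function(values, site_ids = rownames(values),
                        taxon_ids = colnames(values),
                        kind = c("counts", "percent"),
                        ages = NULL, metadata = list()) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  n <- nrow(values)
  if (is.null(site_ids)) site_ids <- paste0("site_", seq_len(n))
  if (is.null(taxon_ids)) taxon_ids <- paste0("taxon_", seq_len(ncol(values)))
  site_ids <- as.character(site_ids)
  taxon_ids <- as.character(taxon_ids)
  if (length(site_ids) != n) stop("site_ids length does not match rows")
  if (length(taxon_ids) != ncol(values)) stop("taxon_ids length does not match columns")
  if (anyDuplicated(site_ids)) {
    stop("duplicate site id(s): ",
         paste(unique(site_ids[duplicated(site_ids)]), collapse = ", "))
  }
  if (anyDuplicated(taxon_ids)) {
    stop("duplicate taxon id(s): ",
         paste(unique(taxon_ids[duplicated(taxon_ids)]), collapse = ", "))
  }
  if (anyNA(values) || !all(is.finite(values))) stop("abundances must be finite")
  if (any(values < 0)) stop("abundances must be non-negative")
  if (kind == "percent") {
    rs <- rowSums(values)
    bad <- abs(rs - 100) > 0.5
    if (any(bad)) {
      stop("percent rows not summing to 100 (beyond rounding tolerance 0.5): ",
           paste(site_ids[bad], collapse = ", "))
    }
    values <- values / rs * 100
  }
  if (!is.null(ages)) {
    ages <- as.numeric(ages)
    if (length(ages) != n) stop("ages length does not match rows")
    if (anyNA(ages)) stop("ages must not contain NA")
    d <- diff(ages)
    if (length(d) && !(all(d > 0) || all(d < 0))) {
      stop("ages must be strictly monotone along the sequence")
    }
  }
  dimnames(values) <- list(site_ids, taxon_ids)
  structure(list(values = values, site_ids = site_ids, taxon_ids = taxon_ids,
                 kind = kind, ages = ages, metadata = metadata),
            class = "taxon_table")
}

#' @export
print.taxon_table <- function(x, ...) {
  cat(sprintf("taxon_table (%s): %d sites x %d taxa%s\n", x$kind,
              nrow(x$values), ncol(x$values),
              if (!is.null(x$ages)) sprintf(", ages %s-%s cal yr BP",
                                            format(min(x$ages)), format(max(x$ages)))
              else ""))
  invisible(x)
}

#' @export
dim.taxon_table <- function(x) dim(x$values)

#' Per-site environmental table
#'
#' Numeric per-site environmental variables (seasonal temperatures in
#' degrees C, mean annual temperature, precipitation, ...) aligned
#' one-to-one with a \code{\link{taxon_table}} by site id.
#'
#' @param values numeric matrix (sites x variables) with no missing values.
#' @param site_ids character site identifiers; default rownames.
#' @param var_names character variable names; default colnames.
#' @return an object of class \code{env_table}.
#' @export
env_table <- function(values, site_ids = rownames(values),
                      var_names = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(site_ids)) stop("site_ids required")
  site_ids <- as.character(site_ids)
  var_names <- as.character(var_names)
  if (anyDuplicated(site_ids)) stop("duplicate site id(s)")
  if (anyDuplicated(var_names)) stop("duplicate variable name(s)")
  if (length(site_ids) != nrow(values)) stop("site_ids length mismatch")
  if (length(var_names) != ncol(values)) stop("var_names length mismatch")
  if (anyNA(values) || !all(is.finite(values))) {
    stop("environmental values must be finite with no missing entries")
  }
  dimnames(values) <- list(site_ids, var_names)
  structure(list(values = values, site_ids = site_ids, var_names = var_names),
            class = "env_table")
}

#' @export
print.env_table <- function(x, ...) {
  cat(sprintf("env_table: %d sites x %d variables (%s)\n", nrow(x$values),
              ncol(x$values), paste(head(x$var_names, 8), collapse = ", ")))
  invisible(x)
}

# Check that an env_table aligns with a taxon_table site-for-site.
check_aligned <- function(taxa, env) {
  if (!identical(taxa$site_ids, env$site_ids)) {
    stop("taxon_table and env_table site ids are not aligned")
  }
  invisible(TRUE)
}

#' Convert a count table to percentages
#'
#' Scales every row to sum to 100. Rows with no individuals are rejected.
#' Idempotent on percentage tables.
#'
#' @param table a \code{\link{taxon_table}}.
#' @return a \code{taxon_table} with \code{kind = "percent"}.
#' @export
to_percentages <- function(table) {
  stopifnot(inherits(table, "taxon_table"))
  rs <- rowSums(table$values)
  if (any(rs <= 0)) {
    stop("all-zero row(s): ", paste(table$site_ids[rs <= 0], collapse = ", "))
  }
  taxon_table(table$values / rs * 100, table$site_ids, table$taxon_ids,
              kind = "percent", ages = table$ages, metadata = table$metadata)
}

#' Square-root transform a percentage table
#'
#' Returns the element-wise square root of the percentage matrix, the
#' standard variance-stabilising transform applied before ordination of
#' community percentage data.
#'
#' @param table a percent \code{\link{taxon_table}} or a non-negative matrix.
#' @return a plain numeric matrix.
#' @export
sqrt_transform <- function(table) {
  m <- if (inherits(table, "taxon_table")) {
    if (table$kind != "percent") stop("sqrt_transform expects a percent table")
    table$values
  } else {
    as.matrix(table)
  }
  if (any(m < 0)) stop("negative abundances")
  sqrt(m)
}

#' Read / write site-by-taxon CSV files
#'
#' The on-disk dialect is UTF-8 CSV with a header row of taxon names,
#' the first column holding the site id, and an optional age column
#' (\code{age_col}) of calibrated ages. \code{write_taxon_csv} is the
#' exact inverse of \code{read_taxon_csv}.
#'
#' @param path file path.
#' @param kind "counts" or "percent".
#' @param age_col name of the age column, if present.
#' @param sep,dec field and decimal separators ("," + "." by default; a
#'   ";" + "," locale is supported).
#' @return a \code{\link{taxon_table}}.
#' @export
read_taxon_csv <- function(path, kind = c("counts", "percent"),
                           age_col = "age_calBP", sep = ",", dec = ".") {
  kind <- match.arg(kind)
  df <- read.csv(path, check.names = FALSE, sep = sep, dec = dec,
                 colClasses = "character", fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("taxon CSV needs a site-id column plus taxa: ", path)
  site_ids <- df[[1]]
  df <- df[, -1, drop = FALSE]
  ages <- NULL
  if (age_col %in% names(df)) {
    ages <- suppressWarnings(as.numeric(df[[age_col]]))
    if (anyNA(ages)) stop("non-numeric age cell in column '", age_col, "'")
    df <- df[, setdiff(names(df), age_col), drop = FALSE]
  }
  num <- suppressWarnings(vapply(df, as.numeric, numeric(nrow(df))))
  num <- matrix(num, nrow = nrow(df),
                dimnames = list(site_ids, names(df)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                 site_ids[bad[1]], colnames(num)[bad[2]], path))
  }
  taxon_table(num, kind = kind, ages = ages)
}

#' @rdname read_taxon_csv
#' @param table a \code{\link{taxon_table}} to write.
#' @export
write_taxon_csv <- function(table, path, age_col = "age_calBP",
                            sep = ",", dec = ".") {
  stopifnot(inherits(table, "taxon_table"))
  df <- data.frame(site = table$site_ids, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(table$ages)) df[[age_col]] <- table$ages
  df <- cbind(df, as.data.frame(table$values, check.names = FALSE))
  utils::write.table(df, path, row.names = FALSE, sep = sep, dec = dec,
                     qmethod = "double", fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}

#' Read / write per-site environmental CSV files
#'
#' First column: site id; remaining columns: numeric variables.
#'
#' @inheritParams read_taxon_csv
#' @return an \code{\link{env_table}}.
#' @export
read_env_csv <- function(path, sep = ",", dec = ".") {
  df <- read.csv(path, check.names = FALSE, sep = sep, dec = dec,
                 fileEncoding = "UTF-8")
  if (ncol(df) < 2) stop("environment CSV needs a site-id column plus variables")
  site_ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- site_ids
  env_table(m)
}

#' @rdname read_env_csv
#' @param env an \code{\link{env_table}} to write.
#' @export
write_env_csv <- function(env, path, sep = ",", dec = ".") {
  stopifnot(inherits(env, "env_table"))
  df <- cbind(data.frame(site = env$site_ids, stringsAsFactors = FALSE),
              as.data.frame(env$values, check.names = FALSE))
  utils::write.table(df, path, row.names = FALSE, sep = sep, dec = dec,
                     qmethod = "double", fileEncoding = "UTF-8", quote = TRUE)
  invisible(path)
}
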