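# Analogue goodness-of-fit classification and the random-reconstruction
# significance test.

#' Analogue-quality thresholds from a training set
#'
#' Empirical 5th and 10th percentiles (linear-interpolation quantiles,
#' type 7; class boundaries depend on the convention, so it is fixed
#' here) of the distribution of all pairwise dissimilarities between
#' training-set samples (strict upper triangle). Fossil data never enter
#' the threshold computation.
#'
#' @param d a \code{\link{dissimilarity_matrix}} of the training set.
#' @return named numeric vector \code{c(q5 = ..., q10 = ...)}.
#' @export
analogue_thresholds <- function(d) {
  m <- as.matrix(d)
  if (nrow(m) < 2) stop("need at least 2 training sites")
  vals <- m[upper.tri(m)]
  stats::setNames(quantile(vals, c(0.05, 0.10), names = FALSE, type = 7),
                  c("q5", "q10"))
}

#' Classify fossil samples by analogue quality
#'
#' Each fossil sample's minimum dissimilarity to the training set is
#' compared against the training-set percentile thresholds: below the
#' 5th percentile = "good" analogue; above the 10th percentile =
#' "no-analogue"; between the two = "fair".
#'
#' @param fossil fossil \code{\link{taxon_table}} (percentages).
#' @param training modern \code{\link{taxon_table}} (percentages).
#' @param metric "sqchord" (default) or "bray".
#' @return an \code{analogue_classification}: data.frame with columns
#'   \code{sample}, \code{min_dissim}, \code{class}; thresholds attached
#'   as attribute \code{"thresholds"}.
#' @export
classify_analogues <- function(fossil, training, metric = c("sqchord", "bray")) {
  metric <- match.arg(metric)
  yf <- as_abund(fossil)
  if (any(rowSums(yf) <= 0)) {
    stop("empty fossil sample(s): ",
         paste((rownames(yf) %||% seq_len(nrow(yf)))[rowSums(yf) <= 0],
               collapse = ", "))
  }
  thr <- analogue_thresholds(dissimilarity_matrix(training, metric))
  mind <- apply(cross_dissimilarity(yf, training, metric), 1, min)
  cls <- ifelse(mind < thr["q5"], "good",
                ifelse(mind > thr["q10"], "no-analogue", "fair"))
  out <- data.frame(sample = rownames(yf) %||% seq_len(nrow(yf)),
                    min_dissim = mind, class = cls, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(out, thresholds = thr, metric = metric,
            class = c("analogue_classification", "data.frame"))
}

#' Random-reconstruction significance test
#'
#' Tests whether a reconstruction explains more of the fossil
#' assemblage variance than reconstructions trained on random
#' environmental variables. The observed statistic is the fraction of
#' variance of the (square-root-transformed, column-centred) fossil
#' percentage matrix explained - via single-predictor redundancy
#' analysis - by the reconstruction from the real training variable.
#' Each of \code{n_random} trials draws an i.i.d. uniform variable over
#' the observed range of the real one, trains the same method, and
#' reconstructs; the p-value is
#' \eqn{(1 + \#\{random \ge observed\}) / (n_{random} + 1)}.
#'
#' @param training modern \code{\link{taxon_table}} (percentages).
#' @param env an \code{\link{env_table}}.
#' @param target name of the environmental variable under test.
#' @param fossil fossil \code{\link{taxon_table}} (percentages).
#' @param spec a \code{\link{method_spec}} (fixed before testing).
#' @param n_random number of random reconstructions (999 conventional).
#' @param seed integer seed; deterministic given it.
#' @return a \code{significance_result}: observed explained fraction,
#'   vector of random fractions, p-value, and the proportion of random
#'   reconstructions the observed one exceeds.
#' @export
significance_test <- function(training, env, target, fossil,
                              spec = method_spec("WAPLS"), n_random = 999,
                              seed = 1) {
  check_aligned(training, env)
  if (n_random < 99) warning("n_random < 99 gives a coarse p-value resolution")
  x <- env$values[, target]
  ytrain <- as_abund(training)
  yfoss <- as_abund(fossil)
  shared <- intersect(colnames(ytrain), colnames(yfoss))
  yfoss <- yfoss[, shared, drop = FALSE]
  response <- scale(sqrt(yfoss), center = TRUE, scale = FALSE)
  observed_recon <- fit_predict(spec, ytrain, x, yfoss)
  observed <- rda_explained_variance(response, observed_recon)
  rng <- range(x)
  fractions <- with_seed(seed, {
    vapply(seq_len(n_random), function(b) {
      xr <- runif(length(x), rng[1], rng[2])
      rec <- fit_predict(spec, ytrain, xr, yfoss)
      if (sd(rec) < 1e-12) return(0)
      rda_explained_variance(response, rec)
    }, numeric(1))
  })
  p <- (1 + sum(fractions >= observed - 1e-12)) / (n_random + 1)
  structure(list(target = target, observed = observed,
                 random_fractions = fractions,
                 p_value = p, proportion_exceeded = mean(observed > fractions),
                 n_random = as.integer(n_random), seed = seed,
                 spec = spec),
            class = "significance_result")
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("significance test (%s): observed fraction = %.3f, exceeds %.1f%% of %d random reconstructions, p = %.4g\n",
              x$target, x$observed, 100 * x$proportion_exceeded, x$n_random,
              x$p_value))
  invisible(x)
}
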