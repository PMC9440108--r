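# Bootstrap cross-validation of calibration models and component
# selection for the WA-PLS family.

#' Bootstrap validation of a calibration method
#'
#' Each cycle resamples training sites with replacement, fits the method
#' on the bag and predicts the out-of-bag sites. Performance statistics:
#' \itemize{
#'   \item RMSEP: square root of the mean (over sites) of each site's
#'     mean squared out-of-bag prediction error;
#'   \item R2: squared correlation between observed values and the mean
#'     out-of-bag prediction;
#'   \item average bias: mean of (mean out-of-bag prediction - observed);
#'   \item maximum bias: largest absolute mean residual over 10
#'     equal-width segments of the environmental gradient.
#' }
#' When fossil samples are supplied, each cycle's model also predicts
#' them; the sample-specific reconstruction error is
#' \eqn{\sqrt{s_1^2 + s_2^2}} with \eqn{s_1} the standard deviation of a
#' sample's bootstrap predictions and \eqn{s_2} the model RMSEP.
#'
#' For WA-PLS the statistics are computed for every component count from
#' 1 to \code{spec$n_components} (the per-component table used by
#' \code{\link{select_n_components}}).
#'
#' @param spec a \code{\link{method_spec}}.
#' @param training site-by-taxon table or matrix (percentages).
#' @param x numeric environmental values per training site.
#' @param n_boot bootstrap cycles (>= 100 recommended, default 1000).
#' @param seed integer seed; results are bit-identical given it.
#' @param fossil optional fossil table for sample-specific errors.
#' @return a \code{crossval_stats} object.
#' @export
bootstrap_validate <- function(spec, training, x, n_boot = 1000, seed = 1,
                               fossil = NULL) {
  y <- as_abund(training)
  x <- as.numeric(x)
  n <- nrow(y)
  stopifnot(length(x) == n, n_boot >= 1)
  is_wapls <- spec$method == "WAPLS"
  nc <- if (is_wapls) min(spec$n_components, min(ncol(y), n - 1L)) else 1L
  sse <- matrix(0, n, nc)
  sum_pred <- matrix(0, n, nc)
  n_oob <- integer(n)
  yf <- if (!is.null(fossil)) as_abund(fossil)
  if (!is.null(yf)) {
    f_sum <- matrix(0, nrow(yf), 1)
    f_sumsq <- matrix(0, nrow(yf), 1)
    f_n <- 0L
  }
  n_skipped <- 0L
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), unique(idx))
      if (!length(oob)) next
      preds <- tryCatch({
        if (is_wapls) {
          yb <- if (isTRUE(spec$sqrt_abundance)) sqrt(y[idx, , drop = FALSE])
                else y[idx, , drop = FALSE]
          ncb <- min(nc, min(sum(colSums(yb) > 0), length(unique(idx)) - 1L))
          fitb <- suppressWarnings(wapls_fit(yb, x[idx], n_components = ncb))
          yo <- if (isTRUE(spec$sqrt_abundance)) sqrt(y[oob, , drop = FALSE])
                else y[oob, , drop = FALSE]
          po <- suppressWarnings(predict(fitb, yo))
          if (ncb < nc) po <- cbind(po, po[, rep(ncb, nc - ncb), drop = FALSE])
          pf <- if (!is.null(yf)) {
            yfp <- if (isTRUE(spec$sqrt_abundance)) sqrt(yf) else yf
            suppressWarnings(predict(fitb, yfp, n_components = min(nc, ncb)))
          }
          list(oob = po, fossil = pf)
        } else {
          po <- suppressWarnings(
            fit_predict(spec, y[idx, , drop = FALSE], x[idx],
                        y[oob, , drop = FALSE]))
          pf <- if (!is.null(yf)) {
            suppressWarnings(fit_predict(spec, y[idx, , drop = FALSE], x[idx], yf))
          }
          list(oob = matrix(po, ncol = 1), fossil = pf)
        }
      }, error = function(e) NULL)
      if (is.null(preds) || anyNA(preds$oob)) {
        n_skipped <- n_skipped + 1L
        next
      }
      sse[oob, ] <- sse[oob, , drop = FALSE] + (preds$oob - x[oob])^2
      sum_pred[oob, ] <- sum_pred[oob, , drop = FALSE] + preds$oob
      n_oob[oob] <- n_oob[oob] + 1L
      if (!is.null(yf) && !is.null(preds$fossil) && !anyNA(preds$fossil)) {
        f_sum <- f_sum + preds$fossil
        f_sumsq <- f_sumsq + preds$fossil^2
        f_n <- f_n + 1L
      }
    }
  })
  seen <- n_oob > 0
  if (!all(seen)) {
    warning(sum(!seen), " site(s) never out-of-bag; increase n_boot")
  }
  stat_for <- function(j) {
    msqe <- sse[seen, j] / n_oob[seen]
    mp <- sum_pred[seen, j] / n_oob[seen]
    obs <- x[seen]
    resid <- mp - obs
    segs <- cut(obs, breaks = seq(min(obs), max(obs), length.out = 11),
                include.lowest = TRUE)
    seg_bias <- tapply(resid, segs, mean)
    c(rmsep = sqrt(mean(msqe)), r2 = cor(obs, mp)^2, avg_bias = mean(resid),
      max_bias = max(abs(seg_bias), na.rm = TRUE))
  }
  per_comp <- t(vapply(seq_len(nc), stat_for, numeric(4)))
  per_component <- data.frame(component = seq_len(nc), per_comp)
  final <- per_comp[nc, ]
  fossil_df <- NULL
  if (!is.null(yf)) {
    if (f_n < 2) {
      warning("too few successful bootstrap cycles for fossil errors")
    } else {
      s1 <- sqrt(pmax(0, (f_sumsq[, 1] - f_sum[, 1]^2 / f_n) / (f_n - 1)))
      fossil_df <- data.frame(sample = rownames(yf) %||% seq_len(nrow(yf)),
                              boot_mean = f_sum[, 1] / f_n, s1 = s1,
                              error = sqrt(s1^2 + final["rmsep"]^2),
                              stringsAsFactors = FALSE)
    }
  }
  structure(list(method = spec, rmsep = unname(final["rmsep"]),
                 r2 = unname(final["r2"]), avg_bias = unname(final["avg_bias"]),
                 max_bias = unname(final["max_bias"]), n_boot = n_boot,
                 per_component = per_component,
                 site_predicted = data.frame(
                   site = (rownames(y) %||% seq_len(n))[seen],
                   observed = x[seen],
                   predicted = sum_pred[seen, nc] / n_oob[seen],
                   stringsAsFactors = FALSE),
                 fossil = fossil_df, n_skipped = n_skipped, seed = seed),
            class = "crossval_stats")
}

#' @export
print.crossval_stats <- function(x, ...) {
  cat(sprintf("bootstrap validation (%s, %d cycles): RMSEP = %.3f, R2 = %.3f, avg bias = %.3f, max bias = %.3f\n",
              x$method$method, x$n_boot, x$rmsep, x$r2, x$avg_bias, x$max_bias))
  invisible(x)
}

#' Choose the number of WA-PLS components
#'
#' Default rule: the smallest component count whose cross-validated
#' RMSEP lies within 5 percent of the global minimum RMSEP (parsimony
#' over marginal gains).
#'
#' @param per_component data.frame with columns \code{component} and
#'   \code{rmsep} (as returned in \code{crossval_stats$per_component}),
#'   or a \code{crossval_stats} object.
#' @param tolerance relative slack on the minimum RMSEP (default 0.05).
#' @return an integer component count.
#' @export
select_n_components <- function(per_component, tolerance = 0.05) {
  if (inherits(per_component, "crossval_stats")) {
    per_component <- per_component$per_component
  }
  rmsep <- per_component$rmsep
  comp <- per_component$component %||% seq_along(rmsep)
  as.integer(comp[which(rmsep <= (1 + tolerance) * min(rmsep))[1]])
}

#' Compare calibration methods by bootstrap validation
#'
#' Convenience wrapper producing one row of performance statistics per
#' method (the model-comparison table of a transfer-function study).
#'
#' @param specs a list of \code{\link{method_spec}}s.
#' @param training,x training table and environmental values.
#' @param n_boot,seed passed to \code{\link{bootstrap_validate}}; each
#'   method derives its own child seed.
#' @return data.frame with columns method, rmsep, r2, avg_bias, max_bias.
#' @export
compare_models <- function(specs, training, x, n_boot = 500, seed = 1) {
  rows <- lapply(specs, function(sp) {
    cv <- bootstrap_validate(sp, training, x, n_boot = n_boot,
                             seed = derive_seed(seed, sp$method))
    data.frame(method = sp$method, rmsep = cv$rmsep, r2 = cv$r2,
               avg_bias = cv$avg_bias, max_bias = cv$max_bias,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
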