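# Transfer-function calibration: weighted averaging (WA), weighted-
# averaging partial least squares (WA-PLS, ter Braak & Juggins
# algorithm), the modern analogue technique (MAT), and locally-weighted
# variants fitting the base model on each sample's nearest analogues.
#
# Calibration operates on raw percentage abundances by default (the
# square-root transform is an ordination convention here); a sqrt flag
# is available on the method specification.

as_abund <- function(y) {
  m <- if (inherits(y, "taxon_table")) y$values else as.matrix(y)
  if (is.null(colnames(m))) colnames(m) <- paste0("taxon_", seq_len(ncol(m)))
  m
}

drop_absent_taxa <- function(y, quiet = FALSE) {
  cs <- colSums(y)
  if (any(cs <= 0)) {
    if (!quiet) {
      warning("taxa absent from all training sites excluded: ",
              paste(colnames(y)[cs <= 0], collapse = ", "))
    }
    y <- y[, cs > 0, drop = FALSE]
  }
  y
}

#' Fit a weighted-averaging (WA) transfer function
#'
#' Taxon optima are abundance-weighted means of the environmental
#' variable, \eqn{\hat u_k = \sum_i y_{ik} x_i / \sum_i y_{ik}}; the raw
#' site prediction is the abundance-weighted mean of the optima,
#' \eqn{\hat x_i = \sum_k y_{ik}\hat u_k / \sum_k y_{ik}}. A deshrinking
#' regression (weighted by site abundance totals; with percentage data
#' all weights are equal) corrects the variance compression: "inverse"
#' regresses x on the raw predictions, "classical" regresses the raw
#' predictions on x and inverts.
#'
#' @param training site-by-taxon \code{\link{taxon_table}} or matrix
#'   (percentages).
#' @param x numeric environmental values, one per training site.
#' @param deshrink "inverse" (default) or "classical".
#' @param target name of the environmental variable (for reporting).
#' @return a \code{wa_model} (also \code{calibration_model}).
#' @export
wa_fit <- function(training, x, deshrink = c("inverse", "classical"),
                   target = "x") {
  deshrink <- match.arg(deshrink)
  y <- drop_absent_taxa(as_abund(training))
  x <- as.numeric(x)
  stopifnot(nrow(y) == length(x))
  u <- as.numeric(crossprod(y, x)) / colSums(y)
  names(u) <- colnames(y)
  r <- rowSums(y)
  raw <- as.numeric(y %*% u) / r
  if (stats::weighted.mean((raw - wmean(raw, r))^2, r) < 1e-20) {
    stop("deshrinking degenerate: raw WA predictions are constant ",
         "(constant environmental variable?)")
  }
  co <- if (deshrink == "inverse") {
    coef(lm(x ~ raw, weights = r))
  } else {
    cc <- coef(lm(raw ~ x, weights = r))
    # invert raw = a0 + a1 * x  =>  x = (raw - a0) / a1
    c(-cc[1] / cc[2], 1 / cc[2])
  }
  structure(list(method = "WA", target = target, optima = u,
                 deshrink = deshrink, coef = unname(co),
                 taxon_ids = colnames(y), n_sites = nrow(y)),
            class = c("wa_model", "calibration_model"))
}

# Raw weighted-average prediction of new samples from taxon scores `u`,
# renormalising over the matched taxa.
wa_raw_predict <- function(u, newdata) {
  y <- as_abund(newdata)
  common <- intersect(names(u), colnames(y))
  if (!length(common)) stop("no taxa shared with the training set")
  ym <- y[, common, drop = FALSE]
  r <- rowSums(ym)
  out <- rep(NA_real_, nrow(y))
  ok <- r > 0
  out[ok] <- as.numeric(ym[ok, , drop = FALSE] %*% u[common]) / r[ok]
  if (any(!ok)) warning("sample(s) with no matched taxa predicted as NA")
  out
}

#' @export
predict.wa_model <- function(object, newdata, ...) {
  raw <- wa_raw_predict(object$optima, newdata)
  object$coef[1] + object$coef[2] * raw
}

#' @export
print.wa_model <- function(x, ...) {
  cat(sprintf("WA transfer function (%s deshrinking): %d taxa, %d sites, target %s\n",
              x$deshrink, length(x$optima), x$n_sites, x$target))
  invisible(x)
}

#' Fit a WA-PLS transfer function
#'
#' Weighted-averaging partial least squares (the ter Braak-Juggins
#' algorithm): successive components are built by weighted averaging of
#' the residual environmental signal, each new component's site scores
#' orthogonalised (with site-total weights) against the previous ones,
#' standardised, and used in a weighted regression of the environmental
#' variable. Component 1 with inverse deshrinking is algebraically
#' identical to \code{\link{wa_fit}}.
#'
#' @param training site-by-taxon table or matrix (percentages).
#' @param x numeric environmental values per site.
#' @param n_components number of components, between 1 and
#'   \code{min(n_taxa, n_sites - 1)}.
#' @param target variable name for reporting.
#' @return a \code{wapls_model} (also \code{calibration_model});
#'   \code{predict()} returns a matrix with one column per component
#'   count (cumulative model with 1..n components).
#' @export
wapls_fit <- function(training, x, n_components = 2, target = "x") {
  y <- drop_absent_taxa(as_abund(training))
  x <- as.numeric(x)
  n <- nrow(y); m <- ncol(y)
  stopifnot(n == length(x))
  limit <- min(m, n - 1L)
  if (n_components < 1 || n_components > limit) {
    stop(sprintf("n_components must be in [1, %d] (min(n_taxa, n_sites - 1))", limit))
  }
  r <- rowSums(y); s <- colSums(y); tot <- sum(y)
  xbar <- sum(r * x) / tot
  e <- x - xbar
  comps <- vector("list", n_components)
  P <- matrix(0, n, n_components)
  alpha <- numeric(n_components)
  fitted <- matrix(0, n, n_components)
  for (a in seq_len(n_components)) {
    u <- as.numeric(crossprod(y, e)) / s
    p <- as.numeric(y %*% u) / r
    orth <- numeric(0)
    if (a > 1) {
      orth <- numeric(a - 1)
      for (b in seq_len(a - 1)) {
        orth[b] <- sum(r * p * P[, b]) / sum(r * P[, b]^2)
        p <- p - orth[b] * P[, b]
      }
    }
    mu <- sum(r * p) / tot
    p <- p - mu
    sdev <- sqrt(sum(r * p^2) / tot)
    if (sdev < 1e-12) {
      stop(sprintf("WA-PLS component %d is degenerate (no residual structure)", a))
    }
    p <- p / sdev
    P[, a] <- p
    alpha[a] <- sum(r * x * p) / tot
    comps[[a]] <- list(u = stats::setNames(u, colnames(y)), orth = orth,
                       mu = mu, sd = sdev)
    fitted[, a] <- xbar + P[, seq_len(a), drop = FALSE] %*% alpha[seq_len(a)]
    e <- x - fitted[, a]
  }
  colnames(fitted) <- paste0("comp", seq_len(n_components))
  structure(list(method = "WAPLS", target = target, n_components = n_components,
                 xbar = xbar, alpha = alpha, components = comps,
                 taxon_ids = colnames(y), n_sites = n, fitted = fitted),
            class = c("wapls_model", "calibration_model"))
}

#' @export
predict.wapls_model <- function(object, newdata, n_components = NULL, ...) {
  y <- as_abund(newdata)
  nc <- object$n_components
  Pn <- matrix(NA_real_, nrow(y), nc)
  for (a in seq_len(nc)) {
    cmp <- object$components[[a]]
    p <- wa_raw_predict(cmp$u, y)
    if (a > 1) {
      for (b in seq_len(a - 1)) p <- p - cmp$orth[b] * Pn[, b]
    }
    Pn[, a] <- (p - cmp$mu) / cmp$sd
  }
  # cumulative predictions: pred_a = xbar + sum_{b<=a} alpha_b * Pn[, b]
  contrib <- sweep(Pn, 2, object$alpha, "*")
  preds <- if (nc == 1) matrix(contrib + object$xbar, ncol = 1)
           else object$xbar + t(apply(contrib, 1, cumsum))
  colnames(preds) <- paste0("comp", seq_len(nc))
  rownames(preds) <- rownames(y)
  if (!is.null(n_components)) preds[, min(n_components, nc)] else preds
}

#' @export
print.wapls_model <- function(x, ...) {
  cat(sprintf("WA-PLS transfer function: %d component(s), %d taxa, %d sites, target %s\n",
              x$n_components, length(x$taxon_ids), x$n_sites, x$target))
  invisible(x)
}

#' Modern analogue technique (MAT) prediction
#'
#' Predicts each sample's environment as the dissimilarity-weighted
#' (weights 1/d) mean of its k most similar training sites. A
#' zero-distance analogue short-circuits the weighting: the prediction
#' is that analogue's value exactly (averaged over ties). The minimum
#' dissimilarity is returned for analogue-quality assessment.
#'
#' @param training site-by-taxon table or matrix (percentages).
#' @param x numeric environmental values per training site.
#' @param samples table or matrix of samples to predict.
#' @param k number of analogues (\code{k <= n_sites}).
#' @param metric "sqchord" (default) or "bray".
#' @return data.frame with columns \code{sample}, \code{pred},
#'   \code{min_dissim}; the analogue site ids per sample are attached as
#'   attribute \code{"analogues"}.
#' @export
mat_predict <- function(training, x, samples, k = 10,
                        metric = c("sqchord", "bray")) {
  metric <- match.arg(metric)
  y <- as_abund(training)
  x <- as.numeric(x)
  stopifnot(nrow(y) == length(x), k >= 1, k <= nrow(y))
  d <- cross_dissimilarity(samples, y, metric)
  ids <- rownames(y) %||% as.character(seq_len(nrow(y)))
  pred <- numeric(nrow(d)); mind <- numeric(nrow(d))
  analogues <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    ord <- stable_order(d[i, ], ids)
    nn <- ord[seq_len(k)]
    di <- d[i, nn]
    mind[i] <- di[1]
    zero <- di < 1e-12
    pred[i] <- if (any(zero)) mean(x[nn[zero]]) else sum(x[nn] / di) / sum(1 / di)
    analogues[[i]] <- ids[nn]
  }
  out <- data.frame(sample = rownames(d) %||% seq_len(nrow(d)),
                    pred = pred, min_dissim = mind, stringsAsFactors = FALSE)
  attr(out, "analogues") <- analogues
  out
}

#' Locally-weighted transfer-function predictions (LW-WA, LW-WAPLS)
#'
#' For each sample, the m_local most similar training sites are selected
#' (ties broken stably by site id) and the base model (WA or WA-PLS) is
#' fitted on that local subset only before predicting the sample. With
#' \code{m_local = n_sites} this reduces exactly to the global base
#' model. A local subset with fewer than 2 distinct environmental values
#' cannot support a calibration; such samples fall back to MAT and are
#' flagged.
#'
#' @param training site-by-taxon table or matrix (percentages).
#' @param x numeric environmental values per training site.
#' @param samples table or matrix of samples to predict.
#' @param base "WAPLS" or "WA".
#' @param m_local local neighbourhood size; default
#'   \code{min(100, ceiling(0.3 * n_sites))}.
#' @param n_components WA-PLS components for the local fits.
#' @param deshrink deshrinking for WA local fits.
#' @param metric locality metric, "sqchord" (default) or "bray".
#' @param k_fallback MAT analogues used when a local fit is impossible.
#' @return data.frame with columns \code{sample}, \code{pred},
#'   \code{min_dissim}, \code{fallback}; local training subsets per
#'   sample attached as attribute \code{"local_sites"}.
#' @export
lw_predict <- function(training, x, samples, base = c("WAPLS", "WA"),
                       m_local = NULL, n_components = 2,
                       deshrink = "inverse", metric = c("sqchord", "bray"),
                       k_fallback = 5) {
  base <- match.arg(base)
  metric <- match.arg(metric)
  y <- as_abund(training)
  x <- as.numeric(x)
  n <- nrow(y)
  if (is.null(m_local)) m_local <- min(100L, ceiling(0.3 * n))
  stopifnot(m_local >= 2, m_local <= n)
  d <- cross_dissimilarity(samples, y, metric)
  ids <- rownames(y) %||% as.character(seq_len(n))
  ysamp <- as_abund(samples)
  pred <- numeric(nrow(d)); fallback <- logical(nrow(d))
  local_sites <- vector("list", nrow(d))
  for (i in seq_len(nrow(d))) {
    sel <- stable_order(d[i, ], ids)[seq_len(m_local)]
    local_sites[[i]] <- ids[sel]
    ysub <- y[sel, , drop = FALSE]
    xsub <- x[sel]
    row_i <- ysamp[i, , drop = FALSE]
    if (length(unique(xsub)) < 2) {
      pred[i] <- mat_predict(ysub, xsub, row_i,
                             k = min(k_fallback, m_local), metric = metric)$pred
      fallback[i] <- TRUE
    } else if (base == "WA") {
      pred[i] <- suppressWarnings(
        predict(wa_fit(ysub, xsub, deshrink = deshrink), row_i))
    } else {
      nc <- min(n_components, min(sum(colSums(ysub) > 0), m_local - 1L))
      pred[i] <- suppressWarnings(
        predict(wapls_fit(ysub, xsub, n_components = nc), row_i,
                n_components = nc))
    }
  }
  out <- data.frame(sample = rownames(d) %||% seq_len(nrow(d)), pred = pred,
                    min_dissim = apply(d, 1, min), fallback = fallback,
                    stringsAsFactors = FALSE)
  attr(out, "local_sites") <- local_sites
  out
}

#' Specify a calibration method
#'
#' A compact description of a transfer-function method and its
#' hyperparameters, consumed by \code{\link{bootstrap_validate}},
#' \code{\link{reconstruct}} and \code{\link{significance_test}}.
#'
#' @param method one of "WAPLS", "WA", "MAT", "LW-WA", "LW-WAPLS".
#' @param n_components WA-PLS components (WAPLS family).
#' @param deshrink deshrinking variant for the WA family.
#' @param k MAT analogue count.
#' @param metric analogue/locality metric ("sqchord" or "bray").
#' @param m_local locally-weighted neighbourhood size (NULL = default).
#' @param sqrt_abundance transform abundances with a square root before
#'   calibration (off by default; calibration uses raw percentages).
#' @return a \code{method_spec} list.
#' @export
method_spec <- function(method = c("WAPLS", "WA", "MAT", "LW-WA", "LW-WAPLS"),
                        n_components = 2, deshrink = "inverse", k = 10,
                        metric = "sqchord", m_local = NULL,
                        sqrt_abundance = FALSE) {
  method <- match.arg(method)
  structure(list(method = method, n_components = n_components,
                 deshrink = deshrink, k = k, metric = metric,
                 m_local = m_local, sqrt_abundance = sqrt_abundance),
            class = "method_spec")
}

#' @export
print.method_spec <- function(x, ...) {
  cat("method_spec:", x$method,
      if (x$method %in% c("WAPLS", "LW-WAPLS")) sprintf("(%d comp)", x$n_components),
      "\n")
  invisible(x)
}

# Fit the specified method on (y, x) and predict new samples.
# Returns a numeric vector (the chosen model's predictions).
fit_predict <- function(spec, training, x, samples) {
  y <- as_abund(training)
  ys <- as_abund(samples)
  if (isTRUE(spec$sqrt_abundance)) {
    y <- sqrt(y); ys <- sqrt(ys)
  }
  switch(spec$method,
    WA = predict(wa_fit(y, x, deshrink = spec$deshrink), ys),
    WAPLS = {
      nc <- min(spec$n_components, min(ncol(y), nrow(y) - 1L))
      predict(wapls_fit(y, x, n_components = nc), ys, n_components = nc)
    },
    MAT = mat_predict(y, x, ys, k = min(spec$k, nrow(y)), metric = spec$metric)$pred,
    `LW-WA` = lw_predict(y, x, ys, base = "WA", m_local = spec$m_local,
                         deshrink = spec$deshrink, metric = spec$metric)$pred,
    `LW-WAPLS` = lw_predict(y, x, ys, base = "WAPLS", m_local = spec$m_local,
                            n_components = spec$n_components,
                            metric = spec$metric)$pred
  )
}
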