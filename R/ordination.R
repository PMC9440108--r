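# Ordination screening of calibration sets and fossil-modern overlap.
# Standard engines (eigen-decomposition, correspondence analysis, NMDS)
# are delegated to stats/vegan; this module defines the surface the rest
# of the pipeline uses and the statistics built on top of them.

ordination_result <- function(method, site_scores, species_scores = NULL,
                              biplot_scores = NULL, eigenvalues = NULL,
                              stress = NULL, explained = NULL, extra = list()) {
  structure(list(method = method, site_scores = site_scores,
                 species_scores = species_scores, biplot_scores = biplot_scores,
                 eigenvalues = eigenvalues, stress = stress,
                 explained = explained, extra = extra),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(sprintf("ordination_result: %s, %d sites x %d axes", x$method,
              nrow(x$site_scores), ncol(x$site_scores)))
  if (!is.null(x$explained)) cat(sprintf(", explained = %.1f%%", 100 * x$explained))
  if (!is.null(x$stress)) cat(sprintf(", stress = %.4f", x$stress))
  cat("\n")
  invisible(x)
}

#' Principal coordinates analysis
#'
#' Classical scaling of a dissimilarity matrix: eigen-decomposition of the
#' double-centred squared-distance matrix. Because Bray-Curtis
#' dissimilarities are generally non-Euclidean, the Cailliez additive
#' correction is applied automatically whenever a meaningfully negative
#' eigenvalue appears (below \code{-1e-8} times the largest); Euclidean
#' inputs are decomposed as-is.
#'
#' @param d a \code{\link{dissimilarity_matrix}} (or symmetric matrix).
#' @param n_axes number of axes to return; truncated with a warning if it
#'   exceeds the number of positive eigenvalues.
#' @return an \code{ordination_result} with site scores and eigenvalues.
#' @export
pcoa <- function(d, n_axes = 2) {
  m <- as.matrix(d)
  n <- nrow(m)
  kmax <- n - 1L
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = kmax, eig = TRUE))
  eig <- fit$eig
  corrected <- FALSE
  if (any(eig < -1e-8 * max(abs(eig), 1e-12))) {
    fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = kmax,
                                            eig = TRUE, add = TRUE))
    eig <- fit$eig
    corrected <- TRUE
  }
  npos <- sum(eig > 1e-8 * max(abs(eig), 1e-12))
  if (n_axes > npos) {
    warning(sprintf("n_axes = %d exceeds %d positive eigenvalue(s); truncating",
                    n_axes, npos))
    n_axes <- npos
  }
  scores <- if (n_axes > 0) fit$points[, seq_len(n_axes), drop = FALSE]
            else matrix(0, n, max(1L, 0L))[, 0, drop = FALSE]
  if (npos == 0) scores <- matrix(0, n, 0, dimnames = list(rownames(m), NULL))
  rownames(scores) <- rownames(m)
  if (ncol(scores)) colnames(scores) <- paste0("PCoA", seq_len(ncol(scores)))
  ordination_result("PCoA", scores, eigenvalues = eig,
                    extra = list(cailliez = corrected, n_positive = npos))
}

#' DCA gradient length in standard-deviation units
#'
#' Length of the first detrended-correspondence-analysis axis
#' (detrending by segments with nonlinear rescaling, the Hill & Gauch
#' procedure with its standard 26 segments) in SD units of compositional
#' turnover. A gradient longer than ~2 SD indicates enough species
#' turnover for unimodal (CCA/WA) methods.
#'
#' @param species non-negative site-by-taxon matrix (or
#'   \code{\link{taxon_table}}), no empty rows or columns.
#' @param downweight logical: downweight rare species (off by default).
#' @return gradient length (SD units), a single non-negative number.
#' @export
dca_gradient_length <- function(species, downweight = FALSE) {
  m <- if (inherits(species, "taxon_table")) species$values else as.matrix(species)
  if (nrow(m) < 2 || ncol(m) < 2) {
    stop("degenerate input: need at least 2 sites and 2 taxa")
  }
  rs <- rowSums(m)
  if (any(rs <= 0) || any(colSums(m) <= 0)) stop("empty row(s)/column(s)")
  prof <- m / rs
  if (max(abs(sweep(prof, 2, prof[1, ], "-"))) < 1e-12) {
    return(0) # all sites compositionally identical: no turnover
  }
  dec <- vegan::decorana(m, iweigh = as.integer(downweight))
  sc <- vegan::scores(dec, display = "sites", choices = 1)
  as.numeric(diff(range(sc)))
}

#' Canonical correspondence analysis
#'
#' Constrains community variation to the part explained by the chosen
#' environmental variables. The explained-variance fraction is the sum of
#' constrained eigenvalues over the total correspondence-analysis inertia.
#'
#' @param species site-by-taxon matrix (typically square-root-transformed
#'   percentages) or \code{\link{taxon_table}}.
#' @param env an \code{\link{env_table}} aligned with \code{species}.
#' @param variables character vector of env variables to constrain on.
#' @return an \code{ordination_result} with site/species/biplot scores,
#'   constrained eigenvalues and the explained fraction.
#' @export
cca_fit <- function(species, env, variables = env$var_names) {
  m <- if (inherits(species, "taxon_table")) species$values else as.matrix(species)
  x <- env$values[, variables, drop = FALSE]
  if (nrow(m) != nrow(x)) stop("species and environment tables are not aligned")
  mm <- cbind(1, scale(x))
  qr_rank <- qr(mm)$rank
  if (qr_rank < ncol(mm)) {
    # name a variable whose removal restores full rank
    for (v in rev(variables)) {
      mm2 <- cbind(1, scale(x[, setdiff(variables, v), drop = FALSE]))
      if (qr(mm2)$rank == ncol(mm2)) {
        stop("predictor set is collinear to singularity; offending variable: ", v)
      }
    }
    stop("predictor set is collinear to singularity")
  }
  cc <- vegan::cca(m, x)
  n_axes <- length(cc$CCA$eig)
  ordination_result(
    "CCA",
    site_scores = vegan::scores(cc, display = "lc", choices = seq_len(n_axes),
                                scaling = "sites"),
    species_scores = vegan::scores(cc, display = "species",
                                   choices = seq_len(n_axes), scaling = "sites"),
    biplot_scores = vegan::scores(cc, display = "bp", choices = seq_len(n_axes),
                                  scaling = "sites"),
    eigenvalues = cc$CCA$eig,
    explained = cc$CCA$tot.chi / cc$tot.chi,
    extra = list(total_inertia = cc$tot.chi, fit = cc)
  )
}

#' Iterative variance-inflation-factor filtering
#'
#' Drops, one at a time, the candidate variable with the highest VIF
#' (1 / (1 - R^2) of that variable regressed on the others) until all
#' VIFs fall at or below the threshold. Ties and order are deterministic
#' (first candidate wins).
#'
#' @param env an \code{\link{env_table}}.
#' @param candidates character vector (>= 2) of variable names.
#' @param threshold VIF threshold (default 20).
#' @return character vector of retained variables, with the final VIFs as
#'   attribute \code{"vifs"} and the drop order as attribute
#'   \code{"dropped"}.
#' @export
vif_filter <- function(env, candidates = env$var_names, threshold = 20) {
  stopifnot(length(candidates) >= 2)
  x <- env$values[, candidates, drop = FALSE]
  keep <- candidates
  dropped <- character(0)
  vifs_of <- function(vars) {
    vapply(vars, function(v) {
      others <- setdiff(vars, v)
      if (!length(others)) return(1)
      # exact linear combinations give "perfect fit" warnings by design
      r2 <- suppressWarnings(
        summary(lm(x[, v] ~ x[, others, drop = FALSE]))$r.squared)
      if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
    }, numeric(1))
  }
  repeat {
    v <- vifs_of(keep)
    if (max(v) <= threshold || length(keep) <= 1) break
    worst <- keep[which.max(v)]
    dropped <- c(dropped, worst)
    keep <- setdiff(keep, worst)
  }
  if (length(keep) < 2) warning("fewer than 2 variables survive VIF filtering")
  structure(keep, vifs = vifs_of(keep), dropped = dropped)
}

# Constrained-inertia fraction of species by x given optional conditioning
# matrix z (the statistic permuted in the Monte Carlo tests).
cca_inertia_fraction <- function(species, x, z = NULL) {
  cc <- if (is.null(z)) vegan::cca(species, x) else vegan::cca(species, x, z)
  cc$CCA$tot.chi / cc$tot.chi
}

#' Monte Carlo permutation test for a constrained ordination
#'
#' Tests whether an environmental variable explains more community
#' inertia (CCA constrained fraction) than expected by chance.
#' \code{mode = "single"} permutes the variable itself;
#' \code{mode = "forward-conditional"} tests the variable's additional
#' contribution given already-selected variables by permuting its
#' residuals on the conditioning set. The p-value is
#' \eqn{(1 + \#\{permuted \ge observed\}) / (n_{perm} + 1)}.
#'
#' @param species site-by-taxon matrix (transformed as desired).
#' @param x numeric environmental variable (aligned with rows).
#' @param n_perm number of permutations (999 is conventional; < 99 warns).
#' @param seed integer seed; the test is deterministic given it.
#' @param mode "single" or "forward-conditional".
#' @param conditioning optional matrix of already-selected variables.
#' @param variable label for reporting.
#' @return a \code{permutation_test_result} with the observed statistic,
#'   permutation count and p-value.
#' @export
permutation_test <- function(species, x, n_perm = 999, seed = 1,
                             mode = c("single", "forward-conditional"),
                             conditioning = NULL, variable = "x") {
  mode <- match.arg(mode)
  m <- if (inherits(species, "taxon_table")) species$values else as.matrix(species)
  x <- as.numeric(x)
  if (n_perm < 99) warning("n_perm < 99 gives a coarse p-value resolution")
  z <- if (!is.null(conditioning)) as.matrix(conditioning)
  if (mode == "forward-conditional" && !is.null(z)) {
    x_base <- residuals(lm(x ~ z))
  } else {
    x_base <- x
  }
  observed <- cca_inertia_fraction(m, x, z)
  hits <- 0L
  with_seed(seed, {
    for (b in seq_len(n_perm)) {
      xp <- x_base[sample.int(length(x_base))]
      stat <- cca_inertia_fraction(m, xp, z)
      if (stat >= observed - 1e-12) hits <- hits + 1L
    }
  })
  structure(list(variable = variable, statistic = observed,
                 n_perm = as.integer(n_perm),
                 p_value = (1 + hits) / (n_perm + 1)),
            class = "permutation_test_result")
}

#' @export
print.permutation_test_result <- function(x, ...) {
  cat(sprintf("permutation test: %s, explained fraction = %.4f, p = %.4g (%d perms)\n",
              x$variable, x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' Forward selection of constraining variables
#'
#' Greedy forward selection for CCA: at each step the candidate adding
#' the most constrained inertia (given the variables already selected)
#' enters if its conditional permutation p-value is at or below
#' \code{alpha}; selection stops at the first failure.
#'
#' @param species site-by-taxon matrix.
#' @param env an \code{\link{env_table}}.
#' @param candidates candidate variable names.
#' @param alpha entry threshold on the conditional p-value.
#' @param n_perm permutations per entry test.
#' @param seed master seed; each step derives a child seed.
#' @return data.frame with the selection order, added inertia fraction
#'   and conditional p-value of each selected variable.
#' @export
forward_select <- function(species, env, candidates = env$var_names,
                           alpha = 0.05, n_perm = 999, seed = 1) {
  m <- if (inherits(species, "taxon_table")) species$values else as.matrix(species)
  selected <- character(0)
  rows <- list()
  remaining <- candidates
  while (length(remaining)) {
    z <- if (length(selected)) env$values[, selected, drop = FALSE]
    base <- if (length(selected)) cca_inertia_fraction(m, z) else 0
    # additional constrained inertia of each candidate given the selected
    # set; exact duplicates add none (vegan treats them as aliased)
    gains <- vapply(remaining, function(v) {
      joint <- suppressMessages(suppressWarnings(
        cca_inertia_fraction(m, cbind(z, env$values[, v, drop = FALSE]))))
      joint - base
    }, numeric(1))
    best <- remaining[which.max(gains)]
    if (max(gains) <= 1e-10) break # no additional inertia available
    pt <- permutation_test(m, env$values[, best], n_perm = n_perm,
                           seed = derive_seed(seed, paste0("fwd:", best)),
                           mode = "forward-conditional", conditioning = z,
                           variable = best)
    if (pt$p_value > alpha) break
    selected <- c(selected, best)
    rows[[best]] <- data.frame(variable = best, order = length(selected),
                               added_fraction = max(gains), p_value = pt$p_value,
                               stringsAsFactors = FALSE)
    remaining <- setdiff(remaining, best)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), order = integer(0),
               added_fraction = numeric(0), p_value = numeric(0))
  rownames(out) <- NULL
  out
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation (isotonic regression, via
#' \code{vegan::metaMDS}/\code{monoMDS}) from multiple random starts.
#'
#' @param d a \code{\link{dissimilarity_matrix}}.
#' @param k number of dimensions.
#' @param n_starts random starts; the best (lowest-stress) converged
#'   solution is returned, or the best found with a warning flag if no
#'   start converged.
#' @param seed integer seed.
#' @return an \code{ordination_result} with configuration and stress
#'   (stress-1, a fraction in [0, 1]).
#' @export
nmds <- function(d, k = 2, n_starts = 50, seed = 1) {
  dd <- stats::as.dist(as.matrix(d))
  fit <- with_seed(seed, suppressMessages(suppressWarnings(
    vegan::metaMDS(dd, k = k, try = n_starts, trymax = n_starts,
                   autotransform = FALSE, wascores = FALSE, trace = 0)
  )))
  pts <- fit$points
  rownames(pts) <- attr(dd, "Labels") %||% rownames(as.matrix(d))
  if (!isTRUE(fit$converged) && fit$stress > 1e-4) {
    warning("NMDS did not converge in any start; returning best configuration")
  }
  ordination_result("NMDS", pts, stress = fit$stress,
                    extra = list(converged = isTRUE(fit$converged), k = k,
                                 fit = fit))
}

#' Passive placement of new samples into an NMDS configuration
#'
#' Places each new (e.g. fossil) sample into a fixed modern-only NMDS
#' space by least-squares matching of its dissimilarities to the modern
#' sites, without altering the modern configuration.
#'
#' @param ordination an NMDS \code{ordination_result}.
#' @param cross numeric matrix of dissimilarities, one row per new sample,
#'   columns aligned with the ordination's sites.
#' @return matrix of coordinates (n_new x k).
#' @export
nmds_project <- function(ordination, cross) {
  stopifnot(ordination$method == "NMDS")
  conf <- ordination$site_scores
  k <- ncol(conf)
  out <- matrix(NA_real_, nrow(cross), k,
                dimnames = list(rownames(cross), colnames(conf)))
  for (i in seq_len(nrow(cross))) {
    target <- cross[i, ]
    # the NMDS configuration carries an arbitrary scale relative to the
    # dissimilarities; fit the scale factor in closed form per evaluation
    obj <- function(p) {
      dd <- sqrt(colSums((t(conf) - p)^2))
      b <- sum(dd * target) / max(sum(target^2), 1e-300)
      sum((dd - b * target)^2)
    }
    nn <- stable_order(target, colnames(cross) %||% seq_along(target))
    starts <- rbind(conf[nn[1], ], conf[nn[min(2, length(nn))], ],
                    colMeans(conf[nn[seq_len(min(3, length(nn)))], , drop = FALSE]))
    fits <- apply(starts, 1, function(s) optim(s, obj, method = "BFGS"))
    out[i, ] <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]$par
  }
  out
}

#' Explained-variance fraction of a single-predictor redundancy analysis
#'
#' Fraction of the total variance of a (column-centred) multivariate
#' response captured by least-squares regression on one predictor - the
#' statistic used by the random-reconstruction significance test.
#'
#' @param response numeric matrix (observations x variables).
#' @param predictor numeric vector, non-constant.
#' @return a fraction in [0, 1].
#' @export
rda_explained_variance <- function(response, predictor) {
  y <- scale(as.matrix(response), center = TRUE, scale = FALSE)
  x <- as.numeric(predictor)
  if (length(x) != nrow(y)) stop("predictor length does not match response rows")
  x <- x - mean(x)
  ssx <- sum(x^2)
  if (ssx <= 1e-24) stop("constant predictor")
  tot <- sum(y^2)
  if (tot <= 0) return(0)
  sum((crossprod(y, x))^2) / ssx / tot
}
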