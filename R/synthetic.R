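# Synthetic calibration sets, temperature histories and fossil
# sequences with the statistical structure the analysis assumes:
# unimodal (Gaussian) species responses along correlated seasonal
# temperature gradients, multinomial counting noise, and a glacial-to-
# interglacial temperature history with an early-to-mid-Holocene warm
# plateau. Every generator is deterministic under its seed and returns
# its full generative truth for parameter-recovery tests.

default_season_ranges <- function() {
  # coldest and warmest season spans follow the calibration-set gradient
  # (~ -23..5.9 degC winter, ~10.9..27.9 degC summer); spring/autumn are
  # intermediate
  list(T_spring = c(-2, 18), T_summer = c(10.9, 27.9),
       T_autumn = c(0, 20), T_winter = c(-23, 5.9))
}

#' Configuration of a synthetic calibration study
#'
#' @param n_sites modern training sites (default 382, the size of the
#'   modern surface-soil calibration set being emulated).
#' @param n_species species in the pool (default 40).
#' @param count_depth individuals counted per sample (>= 50; default 500).
#' @param correlation inter-season temperature correlation (scalar
#'   equicorrelation, default 0.8, or a 4x4 positive semi-definite
#'   matrix) - mid-latitude seasonal temperatures covary strongly.
#' @param season_ranges named list of c(min, max) per season, degC.
#' @param resolution fossil sampling resolution, yr/sample (default 250,
#'   emulating ~200-300 yr per sample).
#' @param seed integer seed.
#' @return a \code{sim_config}.
#' @export
sim_config <- function(n_sites = 382, n_species = 40, count_depth = 500,
                       correlation = 0.8, season_ranges = default_season_ranges(),
                       resolution = 250, seed = 42) {
  if (count_depth < 50) stop("count_depth must be >= 50")
  R <- if (is.matrix(correlation)) correlation else {
    r <- matrix(correlation, 4, 4); diag(r) <- 1; r
  }
  if (any(eigen(R, symmetric = TRUE, only.values = TRUE)$values < -1e-10)) {
    stop("inter-season correlation matrix must be positive semi-definite")
  }
  stopifnot(setequal(names(season_ranges), SEASONS))
  structure(list(n_sites = n_sites, n_species = n_species,
                 count_depth = count_depth, correlation = R,
                 season_ranges = season_ranges[SEASONS],
                 resolution = resolution, seed = seed),
            class = "sim_config")
}

#' Gaussian species response parameters
#'
#' Each species responds unimodally to one designated driver season
#' (optimum \code{u}, tolerance \code{tol}, peak abundance \code{peak})
#' with a weaker secondary Gaussian term in mean annual temperature -
#' giving realistic collinearity between seasonal gradients while
#' keeping the generative truth recoverable. Drivers cycle through the
#' four seasons; optima are spread evenly (with jitter) over each
#' driver's range.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param tolerance_range c(min, max) driver tolerances, degC.
#' @param mat_tolerance_factor secondary (MAT) tolerance as a multiple
#'   of the driver tolerance (default 3: a weak broad modifier).
#' @return a \code{species_responses} data.frame with columns
#'   \code{species}, \code{driver}, \code{u}, \code{tol}, \code{peak},
#'   \code{u_mat}, \code{tol_mat}.
#' @export
species_responses <- function(cfg, tolerance_range = c(2.5, 5),
                              mat_tolerance_factor = 3) {
  n <- cfg$n_species
  ranges <- cfg$season_ranges
  mat_range <- c(mean(vapply(ranges, `[`, numeric(1), 1)),
                 mean(vapply(ranges, `[`, numeric(1), 2)))
  with_seed(derive_seed(cfg$seed, "responses"), {
    driver <- rep(SEASONS, length.out = n)
    u <- numeric(n); rel <- numeric(n)
    for (s in SEASONS) {
      k <- which(driver == s)
      rng <- ranges[[s]]
      # even coverage of the gradient with jitter
      rel[k] <- (seq_along(k) - 0.5) / length(k) +
        runif(length(k), -0.3, 0.3) / length(k)
      rel[k] <- pmin(pmax(rel[k], 0.02), 0.98)
      u[k] <- rng[1] + rel[k] * diff(rng)
    }
    tol <- runif(n, tolerance_range[1], tolerance_range[2])
    peak <- exp(rnorm(n, 0, 0.5))
    structure(data.frame(
      species = sprintf("sp%02d", seq_len(n)), driver = driver, u = u,
      tol = tol, peak = peak,
      u_mat = mat_range[1] + rel * diff(mat_range),
      tol_mat = tol * mat_tolerance_factor,
      stringsAsFactors = FALSE),
      class = c("species_responses", "data.frame"))
  })
}

# Expected (unnormalised) abundance of every species at every site.
expected_abundance <- function(responses, env_mat) {
  n <- nrow(env_mat); m <- nrow(responses)
  lam <- matrix(0, n, m, dimnames = list(rownames(env_mat), responses$species))
  mat <- env_mat[, "MAT"]
  for (k in seq_len(m)) {
    xk <- env_mat[, responses$driver[k]]
    lam[, k] <- responses$peak[k] *
      exp(-(xk - responses$u[k])^2 / (2 * responses$tol[k]^2)) *
      exp(-(mat - responses$u_mat[k])^2 / (2 * responses$tol_mat[k]^2))
  }
  lam
}

#' Simulate a modern calibration set
#'
#' Site environments are drawn with the configured inter-season
#' correlations over the configured ranges (Gaussian copula, uniform
#' margins); MAT is the arithmetic four-season mean, and a correlated
#' annual-precipitation nuisance variable is included. Assemblage
#' counts are multinomial with the configured depth over the Gaussian
#' response expectations; sites whose expected abundances are all
#' (numerically) zero are re-drawn, with a bounded number of retries.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param responses optional \code{\link{species_responses}} (generated
#'   from \code{cfg} if omitted).
#' @return a list: \code{taxa} (percent \code{\link{taxon_table}}),
#'   \code{counts} (count table), \code{env} (\code{\link{env_table}}
#'   with the four seasons, MAT, MAP), \code{responses}, \code{config}.
#' @export
simulate_training_set <- function(cfg, responses = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(responses)) responses <- species_responses(cfg)
  n <- cfg$n_sites
  ranges <- cfg$season_ranges
  L <- chol(cfg$correlation)
  draw_env <- function(nn) {
    z <- matrix(rnorm(nn * 4), nn, 4) %*% L
    u <- pnorm(z)
    env <- vapply(seq_along(SEASONS), function(j) {
      rng <- ranges[[j]]
      rng[1] + u[, j] * diff(rng)
    }, numeric(nn))
    colnames(env) <- SEASONS
    env
  }
  with_seed(derive_seed(cfg$seed, "training"), {
    env <- draw_env(n)
    lam <- expected_abundance(responses,
                              cbind(env, MAT = rowMeans(env)))
    retries <- 0L
    repeat {
      bad <- which(rowSums(lam) < 1e-8)
      if (!length(bad) || retries >= 50L) break
      env[bad, ] <- draw_env(length(bad))
      lam[bad, ] <- expected_abundance(
        responses, cbind(env[bad, , drop = FALSE],
                         MAT = rowMeans(env[bad, , drop = FALSE])))
      retries <- retries + 1L
    }
    if (any(rowSums(lam) < 1e-8)) stop("could not populate all sites")
    mat <- rowMeans(env)
    map <- 200 + 15 * (env[, "T_summer"] - mean(ranges$T_summer)) +
      rnorm(n, 0, 40)
    counts <- t(vapply(seq_len(n), function(i) {
      drop(rmultinom(1, cfg$count_depth, lam[i, ] / sum(lam[i, ])))
    }, numeric(nrow(responses))))
    ids <- sprintf("site%03d", seq_len(n))
    dimnames(counts) <- list(ids, responses$species)
    env_full <- cbind(env, MAT = mat, MAP = map)
    rownames(env_full) <- ids
    ct <- taxon_table(counts, kind = "counts")
    list(taxa = to_percentages(ct), counts = ct, env = env_table(env_full),
         responses = responses, config = cfg)
  })
}

#' Parameters of a synthetic glacial-to-Holocene temperature history
#'
#' A piecewise-smooth shape per season: a cold glacial state, a smooth
#' deglacial ramp, a warm plateau (the Holocene thermal maximum,
#' default 9-4 ka), then a linear late-Holocene cooling, plus additive
#' stationary AR(1) noise. The winter amplitude default (5.5 degC
#' deglaciation-to-plateau warming) is the largest, followed by spring,
#' autumn and summer.
#'
#' @param age_max oldest age, cal yr BP (default 20000).
#' @param grid_step dense grid step, yr (default 25).
#' @param ramp c(start, end) ages of the deglacial warming ramp.
#' @param plateau c(start, end) ages of the warm plateau; must satisfy
#'   age_max >= ramp[1] > ramp[2] >= plateau[1] > plateau[2] >= 0.
#' @param late_cooling_frac fraction of the amplitude lost between the
#'   plateau end and the present (default 0.3).
#' @param base named glacial baseline temperatures, degC.
#' @param amplitude named deglacial warming amplitudes, degC.
#' @param noise_sd stationary SD of the AR(1) noise, degC.
#' @param noise_ar AR(1) coefficient.
#' @return a \code{history_params} list.
#' @export
history_params <- function(age_max = 20000, grid_step = 25,
                           ramp = c(15000, 9000), plateau = c(9000, 4000),
                           late_cooling_frac = 0.3,
                           base = c(T_spring = 2, T_summer = 14,
                                    T_autumn = 3, T_winter = -12),
                           amplitude = c(T_spring = 4.5, T_summer = 3,
                                         T_autumn = 3.5, T_winter = 5.5),
                           noise_sd = 0.3, noise_ar = 0.6) {
  ok <- age_max >= ramp[1] && ramp[1] > ramp[2] && ramp[2] >= plateau[1] &&
    plateau[1] > plateau[2] && plateau[2] >= 0
  if (!ok) stop("inconsistent ramp/plateau intervals")
  stopifnot(all(SEASONS %in% names(base)), all(SEASONS %in% names(amplitude)))
  structure(list(age_max = age_max, grid_step = grid_step, ramp = ramp,
                 plateau = plateau, late_cooling_frac = late_cooling_frac,
                 base = base[SEASONS], amplitude = amplitude[SEASONS],
                 noise_sd = noise_sd, noise_ar = noise_ar),
            class = "history_params")
}

#' Simulate a seasonal temperature history
#'
#' @param params a \code{\link{history_params}}.
#' @param seed integer seed.
#' @return a \code{\link{seasonal_series}} on the dense grid (ages
#'   ascending from 0 to \code{age_max}), with MAT, the noise-free truth
#'   attached as attribute \code{"smooth"} and the parameters as
#'   attribute \code{"params"}.
#' @export
simulate_temperature_history <- function(params = history_params(), seed = 1) {
  stopifnot(inherits(params, "history_params"))
  ages <- seq(0, params$age_max, by = params$grid_step)
  w <- warm_index(ages, params)
  ar1 <- function(n, sd, phi) {
    if (sd <= 0) return(numeric(n))
    e <- numeric(n)
    e[1] <- rnorm(1, 0, sd)
    innov <- rnorm(n - 1, 0, sd * sqrt(1 - phi^2))
    for (t in seq_len(n - 1)) e[t + 1] <- phi * e[t] + innov[t]
    e
  }
  smooth <- vapply(SEASONS, function(s) {
    params$base[[s]] + params$amplitude[[s]] * w
  }, numeric(length(ages)))
  noisy <- with_seed(derive_seed(seed, "history"), {
    smooth + vapply(SEASONS, function(s) {
      ar1(length(ages), params$noise_sd, params$noise_ar)
    }, numeric(length(ages)))
  })
  if (any(noisy[, "T_winter"] > noisy[, "T_summer"])) {
    stop("generated history violates winter <= summer; adjust base/amplitude")
  }
  out <- seasonal_series(ages, noisy[, "T_spring"], noisy[, "T_summer"],
                         noisy[, "T_autumn"], noisy[, "T_winter"],
                         MAT = rowMeans(noisy))
  attr(out, "smooth") <- data.frame(age = ages, smooth, MAT = rowMeans(smooth))
  attr(out, "params") <- params
  attr(out, "seed") <- seed
  out
}

# Warming index in [0, 1]: 0 at the glacial state, 1 on the plateau,
# declining linearly after the plateau end.
warm_index <- function(ages, params) {
  w <- numeric(length(ages))
  r1 <- params$ramp[1]; r2 <- params$ramp[2]
  p2 <- params$plateau[2]
  ramping <- ages < r1 & ages >= r2
  w[ramping] <- 0.5 * (1 + cos(pi * (ages[ramping] - r2) / (r1 - r2)))
  w[ages < r2 & ages >= p2] <- 1
  late <- ages < p2
  w[late] <- 1 - params$late_cooling_frac * (p2 - ages[late]) / p2
  w
}

#' Simulate a fossil assemblage sequence from a temperature history
#'
#' Samples the history at the stated resolution, evaluates the Gaussian
#' response model at the true seasonal temperatures of each sample age,
#' and draws multinomial counts. Ages are attached to the table
#' (ascending, youngest first - matching depth order).
#'
#' @param history a series from \code{\link{simulate_temperature_history}}.
#' @param responses a \code{\link{species_responses}}.
#' @param resolution yr per sample; must be >= the history grid step.
#' @param count_depth individuals per sample.
#' @param seed integer seed.
#' @return a list: \code{taxa} (percent \code{\link{taxon_table}} with
#'   ages), \code{counts}, and \code{truth} (data.frame of the true
#'   seasonal temperatures and MAT at the sample ages).
#' @export
simulate_fossil_sequence <- function(history, responses, resolution = 250,
                                     count_depth = 500, seed = 1) {
  grid_step <- min(diff(history$age))
  if (resolution < grid_step) stop("resolution must be >= history grid spacing")
  ages <- seq(min(history$age), max(history$age), by = resolution)
  env <- vapply(SEASONS, function(s) {
    approx(history$age, history[[s]], xout = ages)$y
  }, numeric(length(ages)))
  env <- cbind(env, MAT = rowMeans(env))
  ids <- sprintf("f%05d", ages)
  rownames(env) <- ids
  lam <- expected_abundance(responses, env)
  counts <- with_seed(derive_seed(seed, "fossil"), {
    t(vapply(seq_along(ages), function(i) {
      if (sum(lam[i, ]) < 1e-8) stop("sample with vanishing expected abundance at age ", ages[i])
      drop(rmultinom(1, count_depth, lam[i, ] / sum(lam[i, ])))
    }, numeric(nrow(responses))))
  })
  dimnames(counts) <- list(ids, responses$species)
  ct <- taxon_table(counts, kind = "counts", ages = ages)
  list(taxa = to_percentages(ct), counts = ct,
       truth = data.frame(age = ages, env))
}

#' Inject no-analogue samples into a fossil sequence
#'
#' Replaces a fraction of samples with compositions outside the modern
#' training cloud: either a novel taxon absent from the training set
#' takes 80 percent of the assemblage ("novel_taxon"), or the full
#' assemblage is concentrated into the single rarest taxon
#' ("extreme_mixture").
#'
#' @param fossil percent \code{\link{taxon_table}}.
#' @param fraction fraction of samples to alter, in (0, 1).
#' @param mode "novel_taxon" (default) or "extreme_mixture".
#' @param seed integer seed.
#' @return a list: \code{table} (altered \code{taxon_table}) and
#'   \code{altered} (manifest of altered site ids).
#' @export
inject_no_analogue <- function(fossil, fraction, mode = c("novel_taxon",
                                                          "extreme_mixture"),
                               seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(fossil, "taxon_table"), fraction > 0, fraction < 1)
  n <- nrow(fossil$values)
  n_alter <- round(fraction * n)
  pick <- with_seed(derive_seed(seed, "inject"), sort(sample.int(n, n_alter)))
  v <- fossil$values
  if (mode == "novel_taxon") {
    v <- cbind(v, novel_taxon = 0)
    v[pick, ] <- v[pick, ] * 0.2 # percent rows: existing taxa scaled to 20
    v[pick, "novel_taxon"] <- 80
  } else {
    rare <- colnames(v)[which.min(colSums(v))]
    v[pick, ] <- 0
    v[pick, rare] <- 100
  }
  out <- taxon_table(v, kind = "percent", ages = fossil$ages,
                     metadata = c(fossil$metadata,
                                  list(injected = fossil$site_ids[pick],
                                       inject_mode = mode)))
  list(table = out, altered = fossil$site_ids[pick], mode = mode)
}
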