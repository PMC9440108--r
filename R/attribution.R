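# Seasonal variance attribution: the contribution of each season's
# temperature variability to mean-annual-temperature variability,
# computed from sliding 1000-yr windows on a uniform 100-yr grid.

SEASONS <- c("T_spring", "T_summer", "T_autumn", "T_winter")

#' A seasonal temperature series
#'
#' Per-sample age (cal yr BP, strictly monotone) with the four seasonal
#' temperatures and, optionally, mean annual temperature (MAT). A grid
#' flag records whether the series sits on a uniform 100-yr (or other
#' \code{dt}) grid.
#'
#' @param ages numeric, cal yr BP, strictly monotone.
#' @param T_spring,T_summer,T_autumn,T_winter seasonal temperatures, degC.
#' @param MAT optional mean annual temperature, degC.
#' @param uniform logical grid flag; when TRUE the spacing must be
#'   exactly \code{dt}.
#' @param dt grid spacing in years (only checked when uniform).
#' @return a \code{seasonal_series} (a data.frame).
#' @export
seasonal_series <- function(ages, T_spring, T_summer, T_autumn, T_winter,
                            MAT = NULL, uniform = FALSE, dt = 100) {
  ages <- as.numeric(ages)
  d <- diff(ages)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop("ages must be strictly monotone")
  }
  cols <- list(T_spring, T_summer, T_autumn, T_winter)
  if (any(vapply(cols, function(v) length(v) != length(ages) || anyNA(v),
                 logical(1)))) {
    stop("all four seasons must be present (no NA) at every sample")
  }
  out <- data.frame(age = ages, T_spring = T_spring, T_summer = T_summer,
                    T_autumn = T_autumn, T_winter = T_winter)
  if (!is.null(MAT)) out$MAT <- MAT
  if (uniform && length(d) && max(abs(abs(d) - dt)) > 1e-9) {
    stop("uniform series must have spacing exactly dt = ", dt, " yr")
  }
  structure(out, uniform = uniform, dt = if (uniform) dt,
            class = c("seasonal_series", "data.frame"))
}

#' Mean annual temperature from the four seasons
#'
#' MAT is the arithmetic average of the four seasonal temperatures,
#' computed per sample. Samples with any missing season are rejected.
#'
#' @param s a \code{\link{seasonal_series}} (or data.frame with the four
#'   season columns).
#' @return numeric vector of MAT values, one per sample.
#' @export
mat_from_seasons <- function(s) {
  if (!all(SEASONS %in% names(s))) stop("all four season columns required")
  m <- as.matrix(s[, SEASONS])
  if (anyNA(m)) {
    stop("sample(s) with a missing season rejected: rows ",
         paste(which(rowSums(is.na(m)) > 0), collapse = ", "))
  }
  unname(rowMeans(m))
}

#' Interpolate a seasonal series onto a uniform time grid
#'
#' Linear interpolation of every season (and MAT, if present) onto a
#' grid from \code{ceil(min age)} to \code{floor(max age)} in \code{dt}
#' steps (no extrapolation beyond the data). Linear interpolation is
#' used because it cannot overshoot the data - the standard choice for
#' palaeo series.
#'
#' @param s a \code{\link{seasonal_series}} with >= 2 samples and
#'   monotone ages.
#' @param dt grid step in years (default 100).
#' @return a uniform \code{seasonal_series}.
#' @export
interpolate_uniform <- function(s, dt = 100) {
  if (nrow(s) < 2) stop("need at least 2 samples")
  ages <- s$age
  if (anyDuplicated(ages)) stop("duplicate ages")
  grid <- seq(ceiling(min(ages) / dt) * dt, floor(max(ages) / dt) * dt, by = dt)
  if (!length(grid)) stop("series too short for one grid point at dt = ", dt)
  interp <- function(v) approx(ages, v, xout = grid, method = "linear")$y
  seasonal_series(grid, interp(s$T_spring), interp(s$T_summer),
                  interp(s$T_autumn), interp(s$T_winter),
                  MAT = if ("MAT" %in% names(s)) interp(s$MAT),
                  uniform = TRUE, dt = dt)
}

#' Seasonal variances within one time window
#'
#' For the window [center - halfwidth, center + halfwidth] (inclusive
#' bounds), computes per season the sample variance
#' \eqn{V_i = \frac{1}{n-1}\sum_1^n (T_i - T_m)^2} where \eqn{T_i} are
#' the season's temperatures of the n samples in the window and
#' \eqn{T_m} their mean. At least 2 samples are required; otherwise the
#' window is flagged undefined (never zero-filled).
#'
#' @param s a uniform \code{\link{seasonal_series}}.
#' @param center window centre age (cal yr BP).
#' @param halfwidth half window width in years (default 500, i.e. a
#'   1000-yr window).
#' @return a one-row data.frame: \code{center}, \code{n},
#'   \code{partial} (window truncated by the series edge), per-season
#'   mean \code{<season>_Tm} and variance \code{<season>_Vi}, and
#'   \code{defined}.
#' @export
window_variance <- function(s, center, halfwidth = 500) {
  idx <- which(s$age >= center - halfwidth & s$age <= center + halfwidth)
  n <- length(idx)
  partial <- (center - halfwidth) < min(s$age) - 1e-9 ||
             (center + halfwidth) > max(s$age) + 1e-9
  out <- data.frame(center = center, n = n, partial = partial,
                    defined = n >= 2)
  for (season in SEASONS) {
    v <- s[[season]][idx]
    out[[paste0(season, "_Tm")]] <- if (n >= 1) mean(v) else NA_real_
    out[[paste0(season, "_Vi")]] <- if (n >= 2) var(v) else NA_real_
  }
  out
}

#' Percentage contribution of each season in a window
#'
#' Divides each season's variance by the sum of the four seasonal
#' variances: \eqn{c_i = 100 V_i / \sum_j V_j}. If all four variances
#' are zero (or the window was undefined), the record is flagged null
#' rather than zero-filled.
#'
#' @param w a one-row data.frame from \code{\link{window_variance}}.
#' @return a one-row data.frame: \code{center}, per-season
#'   \code{<season>_pct}, \code{defined}, \code{partial}.
#' @export
contribution_percent <- function(w) {
  vi <- as.numeric(w[paste0(SEASONS, "_Vi")])
  out <- data.frame(center = w$center, partial = w$partial)
  if (!isTRUE(w$defined) || anyNA(vi) || sum(vi) <= 0) {
    out[paste0(SEASONS, "_pct")] <- NA_real_
    out$defined <- FALSE
  } else {
    out[paste0(SEASONS, "_pct")] <- as.list(100 * vi / sum(vi))
    out$defined <- TRUE
  }
  out
}

#' Sliding-window seasonal contributions
#'
#' Computes the percentage contribution of each season for every
#' \code{step} years along a uniform series, using windows of
#' \code{window} years (inclusive bounds, centred on each grid point).
#' Windows truncated by the series edges use the available points and
#' are flagged partial; windows with fewer than 2 points or zero total
#' variance are flagged undefined with null contributions.
#'
#' @param s a uniform \code{\link{seasonal_series}}.
#' @param step sliding step in years (default 100).
#' @param window full window width in years (default 1000).
#' @return a \code{contribution_record} data.frame, one row per window
#'   centre, with \code{center}, \code{<season>_pct} columns,
#'   \code{partial} and \code{defined} flags.
#' @export
sliding_contributions <- function(s, step = 100, window = 1000) {
  if (!isTRUE(attr(s, "uniform"))) stop("sliding_contributions needs a uniform grid")
  span <- diff(range(s$age))
  if (span < window) stop("series shorter than one window")
  centers <- seq(min(s$age), max(s$age), by = step)
  half <- window / 2
  rows <- lapply(centers, function(ct) {
    contribution_percent(window_variance(s, ct, halfwidth = half))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, step = step, window = window,
            class = c("contribution_record", "data.frame"))
}

#' Frequency distribution of seasonal contributions
#'
#' Counts defined contribution records in bins covering [0, 100] percent
#' for each season.
#'
#' @param records a \code{contribution_record} data.frame.
#' @param bin_width bin width in percent (default 5).
#' @return data.frame with bin bounds and one count column per season.
#' @export
contribution_histogram <- function(records, bin_width = 5) {
  def <- records[which(records$defined), , drop = FALSE]
  if (!nrow(def)) stop("no defined contribution records")
  breaks <- seq(0, 100, by = bin_width)
  if (max(breaks) < 100) breaks <- c(breaks, 100)
  out <- data.frame(bin_low = head(breaks, -1), bin_high = breaks[-1])
  for (season in SEASONS) {
    cuts <- cut(def[[paste0(season, "_pct")]], breaks = breaks,
                include.lowest = TRUE, right = FALSE)
    # right-open bins except the last, so 100% lands in the top bin
    cuts[def[[paste0(season, "_pct")]] >= 100 - 1e-9] <- levels(cuts)[nlevels(cuts)]
    out[[season]] <- as.integer(table(cuts))
  }
  out
}

#' LOWESS smoothing of a time series
#'
#' Locally weighted linear regression with tricube weights
#' (\code{stats::lowess}), with configurable robustifying iterations.
#' Used for the smoothed trend curves over reconstructions and
#' contribution series.
#'
#' @param x,y numeric vectors (>= 4 points).
#' @param span smoother span: the fraction of points used per local fit.
#' @param iter robustifying iterations (default 3; 0 = plain fit).
#' @return smoothed y at the input x, in input order.
#' @export
lowess_smooth <- function(x, y, span = 0.1, iter = 3) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4) stop("need at least 4 points")
  if (span * n < 2) stop("span too small: fewer than 2 points per local fit")
  ord <- order(x)
  fit <- lowess(x[ord], y[ord], f = span, iter = iter)
  out <- numeric(n)
  out[ord] <- fit$y
  out
}
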