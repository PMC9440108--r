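# Seasonal variance attribution: MAT, interpolation, window variances,
# contributions, histograms, LOWESS.

make_series <- function(ages, sp, su, au, wi, ...) {
  seasonal_series(ages, sp, su, au, wi, ...)
}

test_that("MAT is the arithmetic mean of the four seasons", {
  s <- make_series(c(100, 200, 300),
                   c(0, 5, -10), c(10, 5, 25), c(20, 5, 10), c(10, 5, -5))
  expect_equal(mat_from_seasons(s), c(10, 5, 5))
  s$T_summer[2] <- NA
  expect_error(mat_from_seasons(s), "missing season")
})

test_that("uniform interpolation is linear, exact at data ages, no extrapolation", {
  s <- make_series(c(1000, 1200), c(10, 14), c(20, 24), c(8, 12), c(-5, -1))
  g <- interpolate_uniform(s, dt = 100)
  expect_equal(g$age, c(1000, 1100, 1200))
  expect_equal(g$T_spring, c(10, 12, 14))
  expect_equal(g$T_winter[2], -3)
  expect_true(attr(g, "uniform"))
  # grid endpoints inside the data range only
  s2 <- make_series(c(950, 1210, 1500), c(1, 2, 3), c(4, 5, 6), c(7, 8, 9),
                    c(0, 1, 2))
  g2 <- interpolate_uniform(s2, dt = 100)
  expect_equal(range(g2$age), c(1000, 1500))
  expect_error(interpolate_uniform(make_series(c(1, 1, 2), 1:3, 1:3, 1:3, 1:3)),
               "monotone")
})

test_that("interpolation error of a smooth series obeys the curvature bound", {
  ages <- sort(withr::with_seed(50, runif(300, 0, 20000)))
  period <- 6000
  f <- function(a) 5 * sin(2 * pi * a / period)
  s <- make_series(ages, f(ages), f(ages) + 15, f(ages) + 5, f(ages) - 15)
  g <- interpolate_uniform(s, dt = 100)
  truth <- f(g$age)
  # linear interpolation error <= max|f''| h^2 / 8 per gap of width h
  gaps <- diff(ages)
  h <- max(gaps)
  bound <- 5 * (2 * pi / period)^2 * h^2 / 8
  expect_lt(max(abs(g$T_spring - truth)), bound + 1e-9)
})

test_that("window variance matches the (n-1) formula and its invariances", {
  s <- make_series(seq(0, 200, by = 100), c(1, 2, 3), c(4, 4, 4), c(0, 2, 4),
                   c(-1, -2, -3), uniform = TRUE, dt = 100)
  w <- window_variance(s, center = 100, halfwidth = 500)
  expect_equal(w$n, 3)
  expect_equal(w$T_spring_Vi, 1) # ((-1)^2 + 0 + 1^2) / 2
  expect_equal(w$T_summer_Vi, 0) # constant window
  expect_equal(w$T_winter_Vi, 1)
  # constant offset leaves Vi unchanged; scaling anomalies by a scales Vi by a^2
  s2 <- s; s2$T_spring <- s$T_spring + 7
  expect_equal(window_variance(s2, 100, 500)$T_spring_Vi, 1)
  s3 <- s; s3$T_spring <- mean(s$T_spring) + 3 * (s$T_spring - mean(s$T_spring))
  expect_equal(window_variance(s3, 100, 500)$T_spring_Vi, 9)
  # single-point window undefined
  w1 <- window_variance(s, center = -1000, halfwidth = 500)
  expect_false(w1$defined)
  expect_true(is.na(w1$T_spring_Vi))
})

test_that("contribution percentages are ratios of window variances", {
  w <- data.frame(center = 0, partial = FALSE, defined = TRUE,
                  T_spring_Vi = 2, T_summer_Vi = 1, T_autumn_Vi = 1,
                  T_winter_Vi = 0)
  cp <- contribution_percent(w)
  expect_equal(as.numeric(cp[paste0(paleoseason:::SEASONS, "_pct")]),
               c(50, 25, 25, 0))
  w$T_spring_Vi <- w$T_summer_Vi <- w$T_autumn_Vi <- 0
  w$T_winter_Vi <- 0.3
  expect_equal(as.numeric(contribution_percent(w)[paste0(paleoseason:::SEASONS, "_pct")]),
               c(0, 0, 0, 100))
  # all-zero variances: flagged null, never zero-filled
  w$T_winter_Vi <- 0
  cp0 <- contribution_percent(w)
  expect_false(cp0$defined)
  expect_true(all(is.na(cp0[paste0(paleoseason:::SEASONS, "_pct")])))
})

test_that("sliding contributions sum to 100 and reverse cleanly with time", {
  withr::with_seed(51, {
    ages <- seq(0, 10000, by = 100)
    s <- make_series(ages, rnorm(101, 5, 2), rnorm(101, 20, 1),
                     rnorm(101, 10, 1.5), rnorm(101, -8, 3),
                     uniform = TRUE, dt = 100)
    rec <- sliding_contributions(s)
    def <- rec[rec$defined, ]
    sums <- rowSums(def[, paste0(paleoseason:::SEASONS, "_pct")])
    expect_true(all(abs(sums - 100) < 1e-9))
    expect_equal(nrow(rec), 101) # one record per grid centre
    expect_true(any(rec$partial) && any(!rec$partial))
    # reversing the time axis reverses record order, not values
    srev <- make_series(ages, rev(s$T_spring), rev(s$T_summer),
                        rev(s$T_autumn), rev(s$T_winter),
                        uniform = TRUE, dt = 100)
    rec2 <- sliding_contributions(srev)
    expect_equal(rev(rec2$T_winter_pct), rec$T_winter_pct, tolerance = 1e-9)
  })
  expect_error(sliding_contributions(
    make_series(c(0, 100), 1:2, 1:2, 1:2, 1:2, uniform = TRUE, dt = 100)),
    "shorter than one window")
})

test_that("a season with 10x the variance contributes ~10/13 on average", {
  withr::with_seed(52, {
    n <- 4001
    ages <- seq(0, 400000, by = 100)
    s <- make_series(ages, rnorm(n, 0, sqrt(10)), rnorm(n, 20, 1),
                     rnorm(n, 10, 1), rnorm(n, -10, 1),
                     uniform = TRUE, dt = 100)
    rec <- sliding_contributions(s)
    mean_spring <- mean(rec$T_spring_pct[rec$defined])
    expect_equal(mean_spring, 100 * 10 / 13, tolerance = 3)
  })
})

test_that("contribution histograms conserve counts over [0, 100] bins", {
  withr::with_seed(53, {
    ages <- seq(0, 20000, by = 100)
    n <- length(ages)
    s <- make_series(ages, rnorm(n), rnorm(n), rnorm(n), rnorm(n),
                     uniform = TRUE, dt = 100)
    rec <- sliding_contributions(s)
    h <- contribution_histogram(rec, bin_width = 5)
    n_def <- sum(rec$defined)
    expect_equal(sum(h[paleoseason:::SEASONS]), 4 * n_def)
    expect_equal(h$bin_low[1], 0)
    expect_equal(h$bin_high[nrow(h)], 100)
    # identical records occupy a single bin
    rec1 <- rec[rep(which(rec$defined)[1], 5), ]
    h1 <- contribution_histogram(rec1, bin_width = 5)
    expect_true(all(colSums(h1[paleoseason:::SEASONS] > 0) == 1))
  })
})

test_that("LOWESS is exact on linear series and denoises a sine", {
  x <- seq(0, 100, by = 2)
  expect_equal(lowess_smooth(x, rep(3, 51), span = 0.3), rep(3, 51))
  y_lin <- 2 + 0.5 * x
  for (span in c(0.1, 0.3, 0.7)) {
    expect_equal(lowess_smooth(x, y_lin, span = span), y_lin, tolerance = 1e-8)
  }
  withr::with_seed(54, {
    xs <- seq(0, 1, length.out = 400)
    truth <- sin(2 * pi * xs)
    noisy <- truth + rnorm(400, 0, 0.3)
    sm <- lowess_smooth(xs, noisy, span = 0.2)
    expect_lt(sqrt(mean((sm - truth)^2)), 0.3)
  })
  expect_error(lowess_smooth(1:3, 1:3), "at least 4")
  expect_error(lowess_smooth(1:10, 1:10, span = 0.05), "span too small")
})

test_that("MAT computation commutes with linear interpolation", {
  withr::with_seed(55, {
    ages <- sort(runif(40, 0, 8000))
    s <- make_series(ages, rnorm(40, 5, 3), rnorm(40, 20, 2), rnorm(40, 10, 2),
                     rnorm(40, -5, 4))
    s$MAT <- mat_from_seasons(s)
    g <- interpolate_uniform(s, dt = 100)
    expect_equal(g$MAT, mat_from_seasons(g), tolerance = 1e-10)
  })
})
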