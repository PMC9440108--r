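# Synthetic calibration sets, temperature histories, fossil sequences.

small_cfg <- function(seed = 3, ...) {
  sim_config(n_sites = 80, n_species = 20, count_depth = 300, seed = seed, ...)
}

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_training_set(small_cfg())
  b <- simulate_training_set(small_cfg())
  expect_identical(a$taxa$values, b$taxa$values)
  expect_identical(a$env$values, b$env$values)
  h1 <- simulate_temperature_history(seed = 5)
  h2 <- simulate_temperature_history(seed = 5)
  expect_identical(h1$T_winter, h2$T_winter)
  f1 <- simulate_fossil_sequence(h1, a$responses, seed = 9)
  f2 <- simulate_fossil_sequence(h2, a$responses, seed = 9)
  expect_identical(f1$taxa$values, f2$taxa$values)
})

test_that("training environments respect ranges and inter-season correlation", {
  tr <- simulate_training_set(sim_config(n_sites = 400, seed = 11))
  env <- tr$env$values
  rng <- paleoseason:::default_season_ranges()
  for (s in paleoseason:::SEASONS) {
    expect_gte(min(env[, s]), rng[[s]][1] - 1e-9)
    expect_lte(max(env[, s]), rng[[s]][2] + 1e-9)
  }
  cors <- cor(env[, paleoseason:::SEASONS])
  off <- cors[upper.tri(cors)]
  expect_true(all(off > 0.6 & off < 0.95)) # target equicorrelation 0.8
  expect_equal(env[, "MAT"], rowMeans(env[, paleoseason:::SEASONS]))
})

test_that("percentages converge to expected relative abundances at large depth", {
  cfg <- sim_config(n_sites = 30, n_species = 15, count_depth = 1e5, seed = 13)
  tr <- simulate_training_set(cfg)
  # independent expectation straight from the Gaussian response parameters
  rs <- tr$responses
  env <- tr$env$values
  lam <- sapply(seq_len(nrow(rs)), function(k) {
    rs$peak[k] *
      exp(-(env[, rs$driver[k]] - rs$u[k])^2 / (2 * rs$tol[k]^2)) *
      exp(-(env[, "MAT"] - rs$u_mat[k])^2 / (2 * rs$tol_mat[k]^2))
  })
  expected_pct <- lam / rowSums(lam) * 100
  expect_lt(max(abs(tr$taxa$values - expected_pct)), 1)
})

test_that("flat species responses erase the compositional gradient", {
  cfg <- small_cfg(seed = 17)
  rs <- species_responses(cfg)
  rs$tol <- rep(1e6, nrow(rs))
  rs$tol_mat <- rep(1e6, nrow(rs))
  tr <- simulate_training_set(cfg, responses = rs)
  expect_lt(dca_gradient_length(tr$taxa), 0.5)
  # while the default unimodal responses give a long gradient
  tr2 <- simulate_training_set(cfg)
  expect_gt(dca_gradient_length(tr2$taxa), 2)
})

test_that("temperature history has the prescribed plateau and amplitudes", {
  h <- simulate_temperature_history(seed = 21)
  p <- attr(h, "params")
  smooth <- attr(h, "smooth")
  # the smoothed MAT maximum falls inside the plateau interval
  peak_age <- smooth$age[which.max(smooth$MAT)]
  expect_gte(peak_age, p$plateau[2])
  expect_lte(peak_age, p$plateau[1])
  # winter LGM-to-plateau warming equals the 5.5 degC amplitude (+/- noise)
  lgm <- mean(h$T_winter[h$age >= p$ramp[1]])
  htm <- mean(h$T_winter[h$age <= p$plateau[1] & h$age >= p$plateau[2]])
  expect_equal(htm - lgm, 5.5, tolerance = 0.15)
  expect_true(all(h$T_winter <= h$T_summer))
  # zero noise, zero amplitude, zero cooling: constant curves
  hp <- history_params(amplitude = c(T_spring = 0, T_summer = 0,
                                     T_autumn = 0, T_winter = 0),
                       late_cooling_frac = 0, noise_sd = 0)
  h0 <- simulate_temperature_history(hp, seed = 1)
  expect_equal(diff(range(h0$T_summer)), 0)
  expect_error(history_params(ramp = c(9000, 15000)), "inconsistent")
})

test_that("fossil sequences sample the history at the stated resolution", {
  cfg <- small_cfg(seed = 23)
  tr <- simulate_training_set(cfg)
  h <- simulate_temperature_history(seed = 23)
  f <- simulate_fossil_sequence(h, tr$responses, resolution = 250, seed = 2)
  expect_equal(nrow(f$taxa$values), 81) # 0..20000 by 250
  expect_equal(f$taxa$ages, seq(0, 20000, by = 250))
  expect_equal(f$truth$age, f$taxa$ages)
  expect_error(simulate_fossil_sequence(h, tr$responses, resolution = 10),
               "resolution")
})

test_that("a constant-climate fossil sequence is indistinguishable from
          same-temperature modern sites", {
  cfg <- small_cfg(seed = 29)
  tr <- simulate_training_set(cfg)
  hp <- history_params(base = c(T_spring = 8, T_summer = 20, T_autumn = 10,
                                T_winter = -8),
                       amplitude = c(T_spring = 0, T_summer = 0, T_autumn = 0,
                                     T_winter = 0),
                       late_cooling_frac = 0, noise_sd = 0)
  h <- simulate_temperature_history(hp, seed = 3)
  f <- simulate_fossil_sequence(h, tr$responses, resolution = 500,
                                count_depth = 300, seed = 4)
  # nearest-training-analogue distances of the fossil samples should look
  # like those of the modern sites closest to the same climate
  target <- c(8, 20, 10, -8)
  env_dist <- sqrt(colSums((t(tr$env$values[, paleoseason:::SEASONS]) - target)^2))
  close <- which(rank(env_dist, ties.method = "first") <= 15)
  d_fossil <- apply(cross_dissimilarity(f$taxa, tr$taxa, "sqchord"), 1, min)
  d_modern <- sapply(close, function(i) {
    min(cross_dissimilarity(tr$taxa$values[i, , drop = FALSE],
                            tr$taxa$values[-i, ], "sqchord"))
  })
  # two-sample rank test at alpha = 0.01: same dissimilarity population
  expect_gt(wilcox.test(d_fossil, d_modern, exact = FALSE)$p.value, 0.01)
})

test_that("no-analogue injection alters exactly the requested fraction", {
  cfg <- small_cfg(seed = 31)
  tr <- simulate_training_set(cfg)
  h <- simulate_temperature_history(seed = 31)
  f <- simulate_fossil_sequence(h, tr$responses, resolution = 250, seed = 5)
  inj <- inject_no_analogue(f$taxa, fraction = 0.1, seed = 6)
  expect_equal(length(inj$altered), round(0.1 * 81))
  expect_true(all(rowSums(inj$table$values) - 100 < 1e-9))
  # unaltered samples keep their original composition (novel taxon at 0)
  keep <- setdiff(f$taxa$site_ids, inj$altered)
  expect_equal(inj$table$values[keep, colnames(f$taxa$values)],
               f$taxa$values[keep, ])
  expect_true(all(inj$table$values[inj$altered, "novel_taxon"] == 80))
})
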