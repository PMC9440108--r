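# WA, WA-PLS, MAT and locally-weighted transfer functions.

test_that("WA optima and raw predictions follow the weighted-mean algebra", {
  y <- matrix(c(100, 0, 0, 100), 2, 2, byrow = TRUE,
              dimnames = list(c("cold", "warm"), c("t1", "t2")))
  m <- wa_fit(y, c(10, 20))
  expect_equal(unname(m$optima), c(10, 20)) # monospecific sites
  mixed <- matrix(c(50, 50), 1, dimnames = list("f", c("t1", "t2")))
  raw <- paleoseason:::wa_raw_predict(m$optima, mixed)
  expect_equal(raw, 15) # 50/50 mixture sits midway before deshrinking
  expect_equal(unname(predict(m, mixed)), 15, tolerance = 1e-10)
})

test_that("WA on a noise-free single-gradient system is an identity map", {
  ls <- linear_system()
  for (ds in c("inverse", "classical")) {
    m <- wa_fit(ls$taxa, ls$x, deshrink = ds)
    expect_equal(unname(predict(m, ls$taxa)), ls$x, tolerance = 1e-8)
  }
  # a fossil sample identical to a training site gets that site's value
  m <- wa_fit(ls$taxa, ls$x)
  expect_equal(unname(predict(m, ls$taxa$values[3, , drop = FALSE])),
               ls$x[3], tolerance = 1e-8)
})

test_that("constant environment makes WA deshrinking degenerate", {
  tt <- toy_percent(8, 4, seed = 13)
  expect_error(wa_fit(tt, rep(5, 8)), "degenerate")
})

test_that("WA-PLS component 1 with inverse deshrinking equals WA exactly", {
  withr::with_seed(17, {
    for (rep in 1:5) {
      tt <- toy_percent(15, 6, seed = 100 + rep)
      x <- rnorm(15, 10, 4)
      wa <- predict(wa_fit(tt, x, deshrink = "inverse"), tt)
      wp <- predict(wapls_fit(tt, x, n_components = 2), tt)
      expect_lt(max(abs(wa - wp[, 1])), 1e-10)
    }
  })
})

test_that("WA-PLS training error is non-increasing in components", {
  ug <- unimodal_gradient(n_sites = 30, n_species = 10, tol = 15, span = 60,
                          seed = 18)
  x <- ug$gradient
  m <- wapls_fit(ug$taxa, x, n_components = 4)
  rmse <- sqrt(colMeans((m$fitted - x)^2))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("WA-PLS matches an independent step-by-step implementation", {
  withr::with_seed(19, {
    Y <- matrix(rexp(15), 5, 3, dimnames = list(paste0("s", 1:5), paste0("t", 1:3)))
    Y <- Y / rowSums(Y) * 100
    x <- c(3, 9, 5, 12, 7)
    fit <- wapls_fit(Y, x, n_components = 2)
    oracle <- naive_wapls_fitted(Y, x, 2)
    expect_equal(unname(fit$fitted), oracle, tolerance = 1e-10)
    # larger random case, component 3
    Y2 <- toy_percent(20, 8, seed = 20)$values
    x2 <- rnorm(20, 0, 2)
    fit2 <- wapls_fit(Y2, x2, n_components = 3)
    expect_equal(unname(fit2$fitted), naive_wapls_fitted(Y2, x2, 3),
                 tolerance = 1e-10)
  })
})

test_that("WA-PLS component limit is enforced", {
  tt <- toy_percent(5, 3, seed = 1)
  expect_error(wapls_fit(tt, rnorm(5), n_components = 4), "n_components")
  expect_error(wapls_fit(tt, rnorm(5), n_components = 0), "n_components")
})

test_that("MAT predictions are inverse-distance weighted means of analogues", {
  # exact worked case: squared-chord distances 0.1 and 0.3, env 10 and 20
  train <- rbind(assemblage_at_sqchord(0.1), assemblage_at_sqchord(0.3))
  dimnames(train) <- list(c("near", "far"), c("t1", "t2"))
  sample <- matrix(c(100, 0), 1, dimnames = list("f", c("t1", "t2")))
  res <- mat_predict(train, c(10, 20), sample, k = 2)
  expect_equal(res$pred, (10 / 0.1 + 20 / 0.3) / (1 / 0.1 + 1 / 0.3),
               tolerance = 1e-9) # = 12.5
  expect_equal(res$pred, 12.5, tolerance = 1e-9)
  expect_equal(res$min_dissim, 0.1, tolerance = 1e-9)
})

test_that("MAT handles zero-distance analogues and uniform weights", {
  tt <- toy_percent(6, 4, seed = 22)
  x <- seq(2, 12, by = 2)
  # sample equal to a training site with k = 1: exact value
  res <- mat_predict(tt, x, tt$values[2, , drop = FALSE], k = 1)
  expect_equal(res$pred, x[2])
  expect_equal(res$min_dissim, 0)
  # all distances equal (k = n): arithmetic mean
  train_eq <- rbind(c(100, 0, 0), c(0, 100, 0), c(0, 0, 100))
  colnames(train_eq) <- c("a", "b", "c")
  rownames(train_eq) <- paste0("s", 1:3)
  smp <- matrix(c(100, 0, 0, 0), 1,
                dimnames = list("f", c("d", "a", "b", "c")))
  res2 <- mat_predict(train_eq, c(1, 2, 3), smp, k = 3)
  expect_equal(res2$pred, 2)
})

test_that("locally-weighted models with a full neighbourhood equal the global fit", {
  tt <- toy_percent(20, 8, seed = 23)
  x <- withr::with_seed(23, rnorm(20, 8, 3))
  foss <- toy_percent(6, 8, seed = 24)
  for (base in c("WA", "WAPLS")) {
    lw <- lw_predict(tt, x, foss, base = base, m_local = 20, n_components = 2)
    glob <- if (base == "WA") unname(predict(wa_fit(tt, x), foss))
            else unname(predict(wapls_fit(tt, x, 2), foss, n_components = 2))
    expect_equal(lw$pred, glob, tolerance = 1e-10)
    expect_false(any(lw$fallback))
  }
})

test_that("locally-weighted fits use only the local cluster", {
  # two compositionally disjoint climate regimes
  withr::with_seed(25, {
    cold <- matrix(rexp(10 * 3), 10, 3)
    warm <- matrix(rexp(10 * 3), 10, 3)
    m <- cbind(rbind(cold, matrix(0, 10, 3)), rbind(matrix(0, 10, 3), warm))
    m <- m / rowSums(m) * 100
    dimnames(m) <- list(c(paste0("cold", 1:10), paste0("warm", 1:10)),
                        paste0("t", 1:6))
    x <- c(rnorm(10, 0, 1), rnorm(10, 20, 1))
    foss <- m[15, , drop = FALSE] # a warm-regime assemblage
    rownames(foss) <- "f"
    lw <- lw_predict(m, x, foss, base = "WA", m_local = 8)
    expect_true(all(grepl("^warm", attr(lw, "local_sites")[[1]])))
    expect_gt(lw$pred, 15)
  })
})

test_that("a duplicated fossil sample is recovered by the local model", {
  ug <- unimodal_gradient(n_sites = 40, n_species = 15, tol = 10, span = 80,
                          seed = 26)
  foss <- ug$taxa$values[12, , drop = FALSE]
  lw <- lw_predict(ug$taxa, ug$gradient, foss, base = "WAPLS", m_local = 10,
                   n_components = 2)
  expect_equal(lw$pred, ug$gradient[12], tolerance = 0.5)
})

test_that("degenerate local neighbourhoods fall back to MAT with a flag", {
  m <- rbind(c(100, 0), c(99, 1), c(98, 2), c(0, 100))
  dimnames(m) <- list(paste0("s", 1:4), c("t1", "t2"))
  x <- c(5, 5, 5, 30) # the 3 nearest sites share one env value
  foss <- matrix(c(100, 0), 1, dimnames = list("f", c("t1", "t2")))
  lw <- lw_predict(m, x, foss, base = "WA", m_local = 3)
  expect_true(lw$fallback)
  expect_equal(lw$pred, 5)
})
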