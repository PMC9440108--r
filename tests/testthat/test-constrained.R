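# Constrained ordination, VIF filtering, permutation tests, forward
# selection and the RDA explained-variance statistic.

make_constrained_fixture <- function(seed = 21) {
  withr::with_seed(seed, {
    ug <- unimodal_gradient(n_sites = 40, n_species = 12, tol = 20, span = 100)
    env <- env_table(cbind(grad = ug$gradient,
                           noise1 = rnorm(40), noise2 = rnorm(40),
                           grad_copy = ug$gradient),
                     site_ids = ug$taxa$site_ids)
    list(taxa = ug$taxa, env = env)
  })
}

test_that("CCA constrained by the CA axis reproduces the CA eigenvalue", {
  tt <- toy_percent(15, 8, seed = 14)
  ca <- vegan::cca(tt$values)
  ax1 <- vegan::scores(ca, display = "sites", choices = 1, scaling = "sites")[, 1]
  env <- env_table(cbind(ca1 = ax1), site_ids = tt$site_ids)
  res <- cca_fit(tt$values, env, "ca1")
  expect_equal(unname(res$eigenvalues[1]), unname(ca$CA$eig[1]), tolerance = 1e-8)
})

test_that("CCA explained fraction: strong driver >> pure noise, and joint
          relabeling of sites leaves eigenvalues unchanged", {
  fx <- make_constrained_fixture()
  strong <- cca_fit(fx$taxa$values, fx$env, "grad")$explained
  noise <- cca_fit(fx$taxa$values, fx$env, "noise1")$explained
  expect_gt(strong, 5 * noise)
  expect_lt(noise, 0.1)
  perm <- sample(nrow(fx$taxa$values))
  env_p <- env_table(fx$env$values[perm, , drop = FALSE])
  res_p <- cca_fit(fx$taxa$values[perm, ], env_p, c("grad", "noise1"))
  res_o <- cca_fit(fx$taxa$values, fx$env, c("grad", "noise1"))
  expect_equal(res_p$eigenvalues, res_o$eigenvalues, tolerance = 1e-10)
})

test_that("CCA explained fraction is monotone in added variables", {
  fx <- make_constrained_fixture()
  vars <- c("grad", "noise1", "noise2")
  fr <- vapply(seq_along(vars), function(k) {
    cca_fit(fx$taxa$values, fx$env, vars[1:k])$explained
  }, numeric(1))
  expect_true(all(diff(fr) >= -1e-12))
  expect_true(all(fr >= 0 & fr <= 1))
})

test_that("singular predictor sets are rejected with the variable named", {
  fx <- make_constrained_fixture()
  env2 <- env_table(cbind(a = fx$env$values[, "grad"],
                          b = fx$env$values[, "grad"]),
                    site_ids = fx$taxa$site_ids)
  expect_error(cca_fit(fx$taxa$values, env2, c("a", "b")), "collinear")
})

test_that("VIF filtering drops exact and near-exact collinearity", {
  withr::with_seed(30, {
    x <- rnorm(50); y <- rnorm(50)
    env <- env_table(cbind(x = x, y = y, xy = x + y + rnorm(50, 0, 0.01),
                           dup = x),
                     site_ids = paste0("s", 1:50))
    # identical pair: one survives (with a "fewer than 2" warning)
    expect_warning(keep <- vif_filter(env, c("x", "dup")), "fewer than 2")
    expect_length(keep, 1)
    keep2 <- vif_filter(env, c("x", "y", "xy"), threshold = 20)
    expect_length(keep2, 2)
    expect_true(all(attr(keep2, "vifs") <= 20))
    # orthogonal-ish variables all retained with VIF near 1
    keep3 <- vif_filter(env, c("x", "y"), threshold = 20)
    expect_length(keep3, 2)
    expect_true(all(attr(keep3, "vifs") < 1.2))
  })
})

test_that("permutation p-value hits the attainable minimum for the true driver
          and respects the 1/(n_perm+1) floor", {
  fx <- make_constrained_fixture()
  pt <- permutation_test(sqrt(fx$taxa$values / 100), fx$env$values[, "grad"],
                         n_perm = 999, seed = 5, variable = "grad")
  expect_equal(pt$p_value, 1 / 1000)
  pt2 <- permutation_test(sqrt(fx$taxa$values / 100), fx$env$values[, "noise1"],
                          n_perm = 199, seed = 6)
  expect_gte(pt2$p_value, 1 / 200)
  expect_lte(pt2$p_value, 1)
  expect_warning(permutation_test(fx$taxa$values, fx$env$values[, "noise1"],
                                  n_perm = 9, seed = 1), "n_perm")
})

test_that("permutation tests are deterministic under a fixed seed", {
  fx <- make_constrained_fixture()
  a <- permutation_test(fx$taxa$values, fx$env$values[, "noise1"],
                        n_perm = 99, seed = 77)
  b <- permutation_test(fx$taxa$values, fx$env$values[, "noise1"],
                        n_perm = 99, seed = 77)
  expect_identical(a$p_value, b$p_value)
})

test_that("forward selection finds the true driver first and ignores duplicates", {
  fx <- make_constrained_fixture()
  sel <- forward_select(fx$taxa$values, fx$env,
                        candidates = c("noise1", "grad", "noise2"),
                        alpha = 0.05, n_perm = 99, seed = 9)
  expect_equal(sel$variable[1], "grad")
  # an exact duplicate of the selected driver adds no inertia
  sel2 <- forward_select(fx$taxa$values, fx$env,
                         candidates = c("grad", "grad_copy"),
                         alpha = 1, n_perm = 99, seed = 9)
  expect_false("grad_copy" %in% sel2$variable)
})

test_that("with alpha = 1 all contributing candidates enter in decreasing
          marginal-gain order", {
  fx <- make_constrained_fixture()
  sel <- forward_select(fx$taxa$values, fx$env,
                        candidates = c("noise1", "grad", "noise2"),
                        alpha = 1, n_perm = 99, seed = 10)
  expect_setequal(sel$variable, c("grad", "noise1", "noise2"))
  expect_equal(sel$variable[1], "grad")
  expect_equal(sel$order, seq_len(nrow(sel)))
})

test_that("RDA explained variance matches trivial cases and the projection oracle", {
  withr::with_seed(40, {
    x <- rnorm(6)
    loadings <- c(2, -1, 0.5)
    exact <- outer(x, loadings)
    expect_equal(rda_explained_variance(exact, x), 1)
    # orthogonal predictor explains nothing
    y <- matrix(rnorm(12), 6, 2)
    y <- qr.resid(qr(cbind(1, x)), y)
    expect_equal(rda_explained_variance(y, x), 0, tolerance = 1e-12)
    expect_error(rda_explained_variance(y, rep(1, 6)), "constant")
    # 5 x 3 toy against brute-force least-squares projection
    Y <- matrix(rnorm(15), 5, 3)
    p <- rnorm(5)
    Yc <- scale(Y, scale = FALSE)
    pc <- p - mean(p)
    H <- pc %*% t(pc) / sum(pc^2)
    oracle <- sum((H %*% Yc)^2) / sum(Yc^2)
    expect_equal(rda_explained_variance(Y, p), oracle, tolerance = 1e-10)
    # and against the independent vegan implementation
    rd <- vegan::rda(Y, p)
    expect_equal(rda_explained_variance(Y, p),
                 unname(rd$CCA$tot.chi / rd$tot.chi), tolerance = 1e-10)
  })
})
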