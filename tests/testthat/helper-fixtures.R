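# Fixtures and independent oracles, built in code.

# Random percent table with named sites/taxa.
toy_percent <- function(n_sites, n_taxa, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rexp(n_sites * n_taxa), n_sites, n_taxa)
    m <- m / rowSums(m) * 100
    dimnames(m) <- list(sprintf("s%02d", seq_len(n_sites)),
                        sprintf("t%02d", seq_len(n_taxa)))
    taxon_table(m, kind = "percent")
  })
}

# Noise-free two-taxon system whose percentages are exactly linear in x:
# p1 = x, p2 = 100 - x. WA with inverse deshrinking recovers x exactly.
linear_system <- function(x = seq(20, 80, by = 5)) {
  m <- cbind(t1 = x, t2 = 100 - x)
  rownames(m) <- sprintf("s%02d", seq_along(x))
  list(taxa = taxon_table(m, kind = "percent"), x = x)
}

# Unimodal (Gaussian) community along a single long gradient; the
# gradient spans `span_tol` tolerance units of species turnover.
unimodal_gradient <- function(n_sites = 60, n_species = 25, tol = 5,
                              span = 100, seed = 1) {
  withr::with_seed(seed, {
    grad <- seq(0, span, length.out = n_sites)
    opt <- seq(0, span, length.out = n_species)
    lam <- outer(grad, opt, function(g, o) exp(-(g - o)^2 / (2 * tol^2)))
    m <- lam / rowSums(lam) * 100
    dimnames(m) <- list(sprintf("s%02d", seq_len(n_sites)),
                        sprintf("t%02d", seq_len(n_species)))
    list(taxa = taxon_table(m, kind = "percent"), gradient = grad)
  })
}

# Independent step-by-step WA-PLS oracle: plain loops, joint weighted
# least squares at every component (no reliance on component
# orthogonality), entirely separate from the package's vectorised path.
# Returns the matrix of training fitted values per component count.
naive_wapls_fitted <- function(Y, x, ncomp) {
  n <- nrow(Y); m <- ncol(Y)
  r <- rowSums(Y); s <- colSums(Y); tot <- sum(Y)
  xbar <- sum(r * x) / tot
  e <- x - xbar
  P <- matrix(0, n, 0)
  fitted <- matrix(0, n, ncomp)
  for (a in seq_len(ncomp)) {
    u <- numeric(m)
    for (k in seq_len(m)) u[k] <- sum(Y[, k] * e) / s[k]
    p <- numeric(n)
    for (i in seq_len(n)) p[i] <- sum(Y[i, ] * u) / r[i]
    if (a > 1) {
      for (b in seq_len(a - 1)) {
        p <- p - sum(r * p * P[, b]) / sum(r * P[, b]^2) * P[, b]
      }
    }
    p <- p - sum(r * p) / tot
    p <- p / sqrt(sum(r * p^2) / tot)
    P <- cbind(P, p)
    X <- cbind(1, P)
    W <- diag(r)
    beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% x)
    fitted[, a] <- X %*% beta
    e <- x - fitted[, a]
  }
  fitted
}

# Two-taxon percent assemblage at an exact squared-chord distance `d`
# from the monospecific assemblage (100, 0); used to plant exact
# analogue distances.
assemblage_at_sqchord <- function(d) {
  a <- (200 - d) / 20
  c(a^2, 100 - a^2)
}
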