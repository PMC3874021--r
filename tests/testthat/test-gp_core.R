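test_that("squared-exponential covariance has the stated entries and is PSD", {
  q <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  W <- se_covariance(q, q, tau2 = 2.5, lam = 0.015)
  expect_equal(diag(W), rep(2.5, 5))
  expect_equal(W[1, 2], 2.5 * exp(-0.01^2 / (2 * 0.015^2)))
  expect_equal(W, t(W))
  # unit-lengthscale distance gives tau2 * exp(-1/2)
  expect_equal(se_covariance(0, 0.015, 2.5, 0.015)[1, 1], 2.5 * exp(-0.5))
  expect_true(all(eigen(W, symmetric = TRUE, only.values = TRUE)$values >=
                    -1e-10 * 2.5))
})

test_that("log marginal likelihood matches dense-algebra oracles", {
  # single point at the prior mean: a 1-D normal at its mode
  p1 <- scatter_profile(0.02, 8.5, 0.4, N = 5)
  th <- list(mean = list(A = 8.5), sigma = 1.2, tau2 = 0.7, lam = 0.01)
  v <- 0.7 + 1.2 * 0.4^2 / 5
  expect_equal(log_marginal_likelihood(p1, th, kind = "flat"),
               -0.5 * log(2 * pi * v), tolerance = 1e-12)

  # M = 3: explicit dense inverse and determinant
  p3 <- scatter_profile(c(0.01, 0.02, 0.03), c(10, 9, 8), c(0.5, 0.4, 0.6),
                        N = 5)
  th3 <- list(mean = list(A = 8.5), sigma = 1.3, tau2 = 2.0, lam = 0.015)
  Om <- se_covariance(p3$q, p3$q, 2.0, 0.015) + diag(1.3 * p3$s^2 / 5)
  r <- p3$I - 8.5
  oracle <- -0.5 * (3 * log(2 * pi) + log(det(Om)) +
                      drop(t(r) %*% solve(Om) %*% r))
  expect_equal(log_marginal_likelihood(p3, th3, kind = "flat"), oracle,
               tolerance = 1e-12)

  # invariant under joint permutation of the data rows
  perm <- c(3, 1, 2)
  p3p <- scatter_profile(p3$q[perm], p3$I[perm], p3$s[perm], N = 5)
  expect_equal(log_marginal_likelihood(p3p, th3, kind = "flat"), oracle,
               tolerance = 1e-12)

  # monotone decrease as the residual grows, all else fixed
  lls <- vapply(c(0, 1, 2, 4), function(off) {
    pp <- scatter_profile(p3$q, p3$I + off, p3$s, N = 5)
    log_marginal_likelihood(pp, th3, kind = "flat")
  }, 0)
  expect_true(all(diff(lls) < 0))
})

test_that("posterior conditioning matches the hand-derived 2x2 formulas", {
  p2 <- scatter_profile(c(0.01, 0.03), c(10, 8), c(0.5, 0.4), N = 4)
  fit <- fit_ml2(p2, "flat", config = gp_config(
    fixed = list(A = 9, sigma = 1, tau2 = 4, lam = 0.02)))
  w <- function(a, b) 4 * exp(-(a - b)^2 / (2 * 0.02^2))
  Om <- matrix(c(w(0.01, 0.01) + 0.25 / 4, w(0.01, 0.03),
                 w(0.01, 0.03), w(0.03, 0.03) + 0.16 / 4), 2, 2)
  det2 <- Om[1, 1] * Om[2, 2] - Om[1, 2] * Om[2, 1]
  Oinv <- matrix(c(Om[2, 2], -Om[1, 2], -Om[2, 1], Om[1, 1]), 2, 2) / det2
  r <- c(1, -1)
  for (qs in c(0.015, 0.02, 0.05)) {
    kv <- c(w(qs, 0.01), w(qs, 0.03))
    expect_equal(posterior_mean(fit, qs), 9 + sum(kv * (Oinv %*% r)),
                 tolerance = 1e-12)
    expect_equal(posterior_var(fit, qs), 4 - drop(t(kv) %*% Oinv %*% kv),
                 tolerance = 1e-12)
  }
  # far from all data the posterior reverts to the prior
  expect_equal(posterior_mean(fit, 0.8), 9, tolerance = 1e-10)
  expect_equal(posterior_var(fit, 0.8), 4, tolerance = 1e-10)
})

test_that("posterior variance at data sites is bounded by the noise level", {
  set.seed(12)
  for (rep in 1:10) {
    M <- sample(10:30, 1)
    q <- sort(runif(M, 0.01, 0.3))
    I <- rnorm(M, 50, 5)
    s <- runif(M, 0.5, 2)
    p <- scatter_profile(q, I, s, N = 10)
    fit <- quiet_fit(p, "flat")
    jit <- 1e-6 * mean(fit$theta$tau2 + fit$theta$sigma * s^2 / 10)
    expect_true(all(posterior_var(fit, q) <=
                      fit$theta$sigma * s^2 / 10 + jit + 1e-8))
  }
})

test_that("posterior covariance is symmetric and near-interpolates noise-free data", {
  q <- seq(0.01, 0.1, length.out = 12)
  truth <- 5 + 40 * exp(-q^2 * 15^2 / 3)
  p <- scatter_profile(q, truth, s = rep(1e-5, 12), N = 10)
  # short lengthscale keeps the kernel matrix well conditioned in the
  # near-noiseless limit
  fit <- quiet_fit(p, "guinier", fixed = list(A = 5, G = 40, Rg = 15,
                                              sigma = 1, tau2 = 100,
                                              lam = 0.008))
  expect_equal(posterior_mean(fit, q), truth, tolerance = 1e-6)
  qa <- c(0.02, 0.05); qb <- c(0.03, 0.08, 0.11)
  C1 <- posterior_cov(fit, qa, qb)
  C2 <- posterior_cov(fit, qb, qa)
  expect_lt(max(abs(C1 - t(C2))), 1e-10 * fit$theta$tau2 + 1e-12)
})

test_that("functional deviates are reproducible and Monte-Carlo consistent", {
  p <- make_guinier_profile(seed = 9, noise = 0.02, n = 40)
  fit <- quiet_fit(p, "guinier")
  grid <- seq(0.01, 0.05, length.out = 5)
  d1 <- sample_deviates(fit, grid, k = 100, seed = 7)
  d2 <- sample_deviates(fit, grid, k = 100, seed = 7)
  expect_identical(d1, d2)
  expect_equal(dim(d1), c(100L, 5L))

  dd <- sample_deviates(fit, grid, k = 1e4, seed = 11)
  mu <- posterior_mean(fit, grid)
  C <- posterior_cov(fit, grid)
  se <- sqrt(diag(C) / 1e4)
  expect_true(all(abs(colMeans(dd) - mu) <= 4 * se))
  Chat <- cov(dd)
  expect_lt(max(abs(Chat - C)) / max(abs(C)), 0.1)
})

test_that("hyperparameter averaging obeys the law of total variance", {
  set.seed(21)
  worse <- 0; total <- 0
  for (rep in 1:8) {
    p <- make_wiggly_profile(seed = 60 + rep)
    fit <- quiet_fit(p, "guinier")
    av <- averaged_posterior(fit)
    grid <- seq(0.006, 0.059, length.out = 40)
    v_plug <- posterior_var(fit, grid)
    v_avg <- diag(posterior_cov(av, grid))
    # the law of total variance holds up to the sigma-point quadrature error
    tol <- 0.01 * v_plug + 1e-12
    worse <- worse + sum(v_avg < v_plug - tol)
    total <- total + length(grid)
    # averaged mean stays close to the plug-in mean
    expect_equal(posterior_mean(av, grid), posterior_mean(fit, grid),
                 tolerance = 0.05)
  }
  expect_lte(worse / total, 0.05)
})

test_that("sigma-point and Monte-Carlo hyperparameter averages agree", {
  p <- make_wiggly_profile(seed = 14)
  fit <- quiet_fit(p, "guinier")
  av <- averaged_posterior(fit)
  grid <- c(0.01, 0.02, 0.04)
  # Monte-Carlo average over the Laplace Gaussian
  set.seed(99)
  free <- fit$tab[fit$tab$free, ]
  L <- t(chol(fit$Hinv))
  x_star <- vapply(free$name, function(n)
    c(fit$theta$mean, sigma = fit$theta$sigma, tau2 = fit$theta$tau2,
      lam = fit$theta$lam)[[n]], 0)
  ndraw <- 400
  mus <- matrix(0, ndraw, length(grid))
  kept <- 0
  for (i in seq_len(ndraw)) {
    x <- x_star + drop(L %*% rnorm(length(x_star)))
    x <- pmin(pmax(x, free$lo * (1 + 1e-9) + 1e-300), free$hi * (1 - 1e-9))
    th <- list(mean = as.list(x[setdiff(free$name, c("sigma", "tau2", "lam"))]),
               sigma = x[["sigma"]], tau2 = x[["tau2"]], lam = x[["lam"]])
    f2 <- fit_ml2(p, "guinier", config = gp_config(fixed = th$mean |>
      c(list(sigma = th$sigma, tau2 = th$tau2, lam = th$lam))))
    kept <- kept + 1
    mus[kept, ] <- posterior_mean(f2, grid)
  }
  mc_mean <- colMeans(mus[seq_len(kept), ])
  mc_se <- apply(mus[seq_len(kept), ], 2, sd) / sqrt(kept)
  # deterministic quadrature vs Monte Carlo of a (mildly) nonlinear map:
  # agreement to MC error plus a small nonlinearity allowance
  expect_true(all(abs(posterior_mean(av, grid) - mc_mean) <=
                    3 * mc_se + 0.005 * abs(mc_mean)))
})

test_that("a degenerate Laplace covariance leaves the averaged posterior at the plug-in", {
  p <- make_guinier_profile(seed = 3, noise = 0.02, n = 40)
  fit <- quiet_fit(p, "guinier")
  fit$Hinv <- fit$Hinv * 0
  av <- averaged_posterior(fit)
  grid <- seq(0.01, 0.05, length.out = 9)
  expect_equal(posterior_mean(av, grid), posterior_mean(fit, grid),
               tolerance = 1e-9)
  expect_equal(diag(posterior_cov(av, grid)), posterior_var(fit, grid),
               tolerance = 1e-9)
})

test_that("model comparison ranks by evidence with a zero self Bayes factor", {
  p <- make_guinier_profile(seed = 22, noise = 0.01, A = 10)
  cmp <- suppressWarnings(compare_models(p, c("flat", "guinier"),
                                         config = gp_config(restarts = 2,
                                                            seed = 1)))
  expect_equal(diag(cmp$log_bayes_factors), c(0, 0), ignore_attr = TRUE)
  expect_equal(cmp$log_bayes_factors, -t(cmp$log_bayes_factors))
  expect_equal(cmp$best, cmp$table$kind[1])
  expect_setequal(names(cmp$fits), c("flat", "guinier"))
  expect_equal(cmp$table$log_evidence,
               sort(cmp$table$log_evidence, decreasing = TRUE))
  expect_equal(cmp$log_bayes_factors["guinier", "flat"],
               cmp$fits$guinier$log_evidence - cmp$fits$flat$log_evidence)
})

test_that("ML-II recovers hyperparameters on benchmark synthetic data", {
  ok_rg <- 0; ok_sig <- 0
  for (seed in 1:12) {
    p <- make_guinier_profile(seed = 700 + seed)
    fit <- quiet_fit(p, "guinier")
    if (abs(fit$theta$mean$Rg - 20) / 20 < 0.05) ok_rg <- ok_rg + 1
    if (fit$theta$sigma >= 0.5 && fit$theta$sigma <= 2) ok_sig <- ok_sig + 1
  }
  expect_gte(ok_rg, 11)
  expect_gte(ok_sig, 10)
})
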