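test_that("welch test reduces to the textbook cases", {
  # identical means: t = 0, p = 1, compatible
  w <- welch_test(5, 1, 10, 5, 1, 10)
  expect_equal(w$t, 0)
  expect_equal(w$p, 1)
  expect_false(w$incompatible)
  # equal per-sample variance and size: Satterthwaite df = 2(N-1)
  w2 <- welch_test(1, 2, 10, 0, 2, 10)
  expect_equal(w2$nu, 18)
  # vectorized, and df uses each side's N - 1
  w3 <- welch_test(c(1, 2), c(1, 1), 10, c(0, 0), c(4, 4), 5)
  expect_equal(w3$nu,
               rep((1 / 10 + 4 / 5)^2 / ((1 / 10)^2 / 9 + (4 / 5)^2 / 4), 2),
               tolerance = 1e-12)
  expect_error(welch_test(1, 0, 10, 0, 1, 10), "positive variances")
  expect_error(welch_test(1, 1, 1, 0, 1, 10), "N >= 2")
})

test_that("verdicts are monotone in alpha: the incompatible set only grows", {
  set.seed(33)
  mu1 <- rnorm(200); mu2 <- rnorm(200)
  w05 <- welch_test(mu1, 1, 10, mu2, 1, 10, alpha = 0.05)
  w20 <- welch_test(mu1, 1, 10, mu2, 1, 10, alpha = 0.20)
  expect_true(all(which(w05$incompatible) %in% which(w20$incompatible)))
})

test_that("ranking orders by concentration proxy and is stable", {
  spec <- synthetic_spec(guinier_truth(), q_ranges = c(0.008, 0.15),
                         n_points = 60, gammas = c(1, 1), noise = 0.02,
                         N = 10, seed = 12)
  gen <- generate_profiles(spec)
  p1 <- gen$profiles[[1]]
  # same errors, ten-fold intensity: the x1 profile must rank first
  p10 <- scatter_profile(p1$q, 10 * p1$I, p1$s, N = 10, label = "x10")
  ord <- rank_profiles(list(p10, p1))
  expect_equal(as.integer(ord), c(2L, 1L))
  st <- attr(ord, "stats")
  expect_gt(st$snr[1], st$snr[2] * 5)
  # profiles already in rank order stay in order; a single profile is rank 1
  expect_equal(as.integer(rank_profiles(list(p1, p10))), c(1L, 2L))
  expect_equal(as.integer(rank_profiles(list(p1))), 1L)
})

test_that("a single profile yields an all-compatible map with one segment", {
  p <- make_guinier_profile(seed = 2, noise = 0.02, n = 30)
  fit <- quiet_fit(p, "guinier")
  map <- classify_profiles(list(p), list(fit))
  expect_equal(unique(map$verdicts[[1]]), "compatible")
  expect_equal(nrow(map$segments), 1L)
  expect_equal(map$segments$lo, min(p$q))
  expect_equal(map$segments$hi, max(p$q))
})

test_that("points beyond the reference range are handed off as new segments", {
  spec <- synthetic_spec(guinier_truth(),
                         q_ranges = list(c(0.01, 0.1), c(0.01, 0.25)),
                         n_points = c(40, 70), gammas = c(1, 1),
                         noise = 0.02, N = 10, seed = 71)
  gen <- generate_profiles(spec)
  f1 <- quiet_fit(gen$profiles[[1]], "guinier")
  f2 <- quiet_fit(gen$profiles[[2]], "guinier")
  map <- classify_profiles(gen$profiles, list(f1, f2),
                           rank_order = c(1L, 2L))
  v2 <- map$verdicts[[2]]
  ext <- gen$profiles[[2]]$q > 0.1
  expect_true(all(v2[ext] == "untested"))
  expect_true(all(v2[!ext] %in% c("compatible", "incompatible")))
  expect_equal(nrow(map$segments), 2L)
  expect_equal(map$segments$owner, c(1L, 2L))
  expect_gte(map$segments$lo[2], 0.1)
  # full q coverage: every retained point lies inside some segment
  for (i in 1:2) {
    q <- gen$profiles[[i]]$q
    inside <- vapply(q, function(qq)
      any(map$segments$lo <= qq & qq <= map$segments$hi), TRUE)
    expect_true(all(inside))
  }
  # segments are disjoint and ordered
  s <- map$segments
  expect_true(all(diff(s$lo) > 0))
  expect_true(all(s$hi[-nrow(s)] <= s$lo[-1]))
})

test_that("an injected bump is flagged locally while the rest survives", {
  flagged_bump <- 0; n_bump <- 0; flagged_rest <- 0; n_rest <- 0
  for (seed in 1:8) {
    spec <- synthetic_spec(guinier_truth(),
                           q_ranges = list(c(0.008, 0.15), c(0.008, 0.15)),
                           n_points = c(70, 70), gammas = c(1, 1),
                           noise = 0.02, N = 10, seed = 800 + seed,
                           gp_draw = list(tau2 = 13, lam = 0.02),
                           perturbations = list(
                             list(profile = 2, q = c(0.05, 0.07),
                                  amplitude = 0.10)))
    gen <- generate_profiles(spec)
    f1 <- quiet_fit(gen$profiles[[1]], "guinier")
    f2 <- quiet_fit(gen$profiles[[2]], "guinier")
    map <- classify_profiles(gen$profiles, list(f1, f2),
                             rank_order = c(1L, 2L))
    m <- gen$truth$masks[[2]]
    v <- map$verdicts[[2]]
    flagged_bump <- flagged_bump + sum(v[m] == "incompatible")
    n_bump <- n_bump + sum(m)
    flagged_rest <- flagged_rest + sum(v[!m] == "incompatible")
    n_rest <- n_rest + sum(!m)
  }
  expect_gte(flagged_bump / n_bump, 0.8)
  expect_lte(flagged_rest / n_rest, 0.1)
})
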