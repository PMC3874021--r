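test_that("disjoint compatible profiles pool with full conservation", {
  spec <- synthetic_spec(guinier_truth(),
                         q_ranges = list(c(0.01, 0.1), c(0.102, 0.2)),
                         n_points = c(30, 30), gammas = c(1, 1),
                         noise = 0.02, N = 10, seed = 41,
                         gp_draw = list(tau2 = 13, lam = 0.02))
  gen <- generate_profiles(spec)
  f1 <- quiet_fit(gen$profiles[[1]], "guinier")
  f2 <- quiet_fit(gen$profiles[[2]], "guinier")
  map <- classify_profiles(gen$profiles, list(f1, f2),
                           rank_order = c(1L, 2L))
  merged <- suppressWarnings(merge_profiles(map, gen$profiles,
    mean = "guinier", config = gp_config(restarts = 2, seed = 1)))
  expect_equal(nrow(merged$points), 60L)
  expect_setequal(unique(merged$points$origin),
                  c("synthetic-1", "synthetic-2"))
  # retention accounting sums to the input counts
  r <- merged$retention
  expect_equal(r$cleaned_out + r$incompatible +
                 (r$kept - r$extension) + r$extension, r$input)
})

test_that("duplicate q keeps the smallest-sd point, earlier rank on ties", {
  set.seed(1)
  q <- seq(0.01, 0.12, length.out = 12)
  I <- rnorm(12, 50, 0.5)
  s1 <- rep(1, 12); s1[1] <- 2          # q[1]: profile b wins on sd
  s2 <- rep(1, 12); s2[3] <- 2          # q[3]: profile a wins on sd
  p1 <- scatter_profile(q, I, s1, N = 10, label = "a")
  p2 <- scatter_profile(q, I + 0.1, s2, N = 10, label = "b")
  map <- structure(list(
    verdicts = list(rep("compatible", 12), rep("compatible", 12)),
    segments = data.frame(lo = 0.01, hi = 0.12, owner = 1L, label = "a"),
    tests = list(NULL, NULL), alpha = 0.05, order = c(1L, 2L),
    labels = c("a", "b")), class = "compatibility_map")
  merged <- suppressWarnings(merge_profiles(map, list(p1, p2),
    mean = "flat", config = gp_config(restarts = 2, seed = 1)))
  expect_equal(nrow(merged$points), 12L)
  # q[1]: b has smaller sd; q[3]: a; everywhere else ties -> earlier rank (a)
  expect_equal(merged$points$origin,
               c("b", rep("a", 11)))
  expect_equal(attr(merged$retention, "duplicates_dropped"), 12L)
  # disabling duplicate discarding keeps all 24 points
  merged2 <- suppressWarnings(merge_profiles(map, list(p1, p2),
    mean = "flat", keep_duplicates = TRUE,
    config = gp_config(restarts = 2, seed = 1)))
  expect_equal(nrow(merged2$points), 24L)
})

test_that("merging a duplicated profile reproduces the single-profile fit", {
  p <- make_guinier_profile(seed = 6, noise = 0.02, n = 40, A = 10)
  fit <- quiet_fit(p, "guinier")
  p2 <- p; p2$label <- "copy"
  map <- structure(list(
    verdicts = list(rep("compatible", 40), rep("compatible", 40)),
    segments = data.frame(lo = min(p$q), hi = max(p$q), owner = 1L,
                          label = p$label),
    tests = list(NULL, NULL), alpha = 0.05, order = c(1L, 2L),
    labels = c(p$label, "copy")), class = "compatibility_map")
  merged <- suppressWarnings(merge_profiles(map, list(p, p2),
    mean = "guinier", config = gp_config(restarts = 2, seed = 1)))
  expect_equal(nrow(merged$points), 40L)   # duplicates dropped
  grid <- seq(0.006, 0.059, length.out = 50)
  expect_equal(posterior_mean(merged$posterior, grid),
               posterior_mean(fit, grid), tolerance = 1e-6)
})

test_that("pooling compatible data never inflates the posterior variance much", {
  spec <- synthetic_spec(guinier_truth(),
                         q_ranges = list(c(0.01, 0.2), c(0.01, 0.2)),
                         n_points = c(50, 50), gammas = c(1, 1),
                         noise = 0.02, N = 10, seed = 52,
                         gp_draw = list(tau2 = 13, lam = 0.02))
  gen <- generate_profiles(spec)
  f1 <- quiet_fit(gen$profiles[[1]], "guinier")
  f2 <- quiet_fit(gen$profiles[[2]], "guinier")
  map <- classify_profiles(gen$profiles, list(f1, f2),
                           rank_order = c(1L, 2L))
  merged <- suppressWarnings(merge_profiles(map, gen$profiles,
    mean = "guinier", config = gp_config(restarts = 2, seed = 1)))
  grid <- seq(0.02, 0.19, length.out = 30)
  v_merged <- posterior_var(merged$posterior, grid)
  # at shared hyperparameters, conditioning on the pooled data can only
  # shrink the predictive variance relative to either single profile
  th <- c(merged$posterior$theta$mean,
          list(sigma = merged$posterior$theta$sigma,
               tau2 = merged$posterior$theta$tau2,
               lam = merged$posterior$theta$lam))
  f1f <- quiet_fit(gen$profiles[[1]], "guinier", fixed = th)
  f2f <- quiet_fit(gen$profiles[[2]], "guinier", fixed = th)
  v_single <- pmin(posterior_var(f1f, grid), posterior_var(f2f, grid))
  expect_true(all(v_merged <= v_single * (1 + 1e-6) + 1e-12))
})

test_that("the report marks missing estimates and accounts for every point", {
  p <- scatter_profile(seq(0.01, 0.1, length.out = 30),
                       rnorm(30, 50, 0.5), rep(0.5, 30), N = 10,
                       label = "flat-ish")
  fit <- quiet_fit(p, "flat")
  map <- structure(list(
    verdicts = list(rep("compatible", 30)),
    segments = data.frame(lo = 0.01, hi = 0.1, owner = 1L,
                          label = "flat-ish"),
    tests = list(NULL), alpha = 0.05, order = 1L, labels = "flat-ish"),
    class = "compatibility_map")
  merged <- suppressWarnings(merge_profiles(map, list(p), mean = "flat",
    config = gp_config(restarts = 2, seed = 1)))
  rep <- report_estimates(merged)
  expect_identical(rep$Rg, "not estimable")
  expect_identical(rep$d, "not estimable")
  out <- capture.output(print(rep))
  expect_true(any(grepl("not estimable", out)))

  # with a Guinier mean the Rg estimate and its Laplace error are reported
  p2 <- make_guinier_profile(seed = 13, noise = 0.01)
  fit2 <- quiet_fit(p2, "guinier")
  map2 <- structure(list(
    verdicts = list(rep("compatible", 80)),
    segments = data.frame(lo = min(p2$q), hi = max(p2$q), owner = 1L,
                          label = p2$label),
    tests = list(NULL), alpha = 0.05, order = 1L, labels = p2$label),
    class = "compatibility_map")
  merged2 <- suppressWarnings(merge_profiles(map2, list(p2),
    mean = "guinier", config = gp_config(restarts = 2, seed = 1)))
  rep2 <- report_estimates(merged2)
  expect_true(is.numeric(rep2$Rg))
  expect_gt(rep2$Rg_se, 0)
  expect_lt(abs(rep2$Rg - 20) / 20, 0.05)
})
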