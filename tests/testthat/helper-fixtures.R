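# Shared fixtures: everything is generated in code, nothing read from disk.

quiet_fit <- function(profile, model = "guinier", restarts = 2, fixed = list(),
                      bounds = NULL) {
  suppressWarnings(fit_ml2(profile, model, bounds = bounds,
                           config = gp_config(restarts = restarts, seed = 1,
                                              fixed = fixed)))
}

guinier_truth <- function(A = 20, G = 100, Rg = 20)
  mean_model("guinier", list(A = A, G = G, Rg = Rg))

# one noisy Guinier profile on [0.005, 0.06], the recovery-benchmark layout
make_guinier_profile <- function(seed, noise = 0.01, n = 80, N = 10,
                                 A = 0, G = 100, Rg = 20) {
  spec <- synthetic_spec(guinier_truth(A, G, Rg),
                         q_ranges = c(0.005, 0.06), n_points = n,
                         gammas = 1, noise = noise, N = N, seed = seed)
  generate_profiles(spec)$profiles[[1]]
}

# profile with genuine non-parametric structure on top of the Guinier part:
# the ML-II optimum is interior (healthy Laplace hessian)
make_wiggly_profile <- function(seed, noise = 0.03, n = 50) {
  spec <- synthetic_spec(guinier_truth(A = 10, G = 100, Rg = 20),
                         q_ranges = c(0.005, 0.06), n_points = n,
                         gammas = 1, noise = noise, N = 10, seed = seed,
                         gp_draw = list(tau2 = 10, lam = 0.008))
  generate_profiles(spec)$profiles[[1]]
}

# delta-like "posterior" with known mean/variance curves, for closed-form
# rescaling identities in the noiseless limit
mock_posterior <- function(q, mean_fn, var_fn = function(q) rep(0, length(q)),
                           label = "mock") {
  structure(list(averaged = TRUE, label = label, data = list(q = q),
                 avg_mean = function(qq) mean_fn(qq),
                 avg_cov = function(qq, qp = qq) {
                   C <- matrix(0, length(qq), length(qp))
                   if (length(qq) == length(qp) && all(qq == qp))
                     diag(C) <- var_fn(qq)
                   C
                 }),
            class = "gp_posterior")
}

# study conditions of the three-profile merging demonstration
e2e_spec <- function(seed) {
  synthetic_spec(guinier_truth(),
                 q_ranges = list(c(0.008, 0.12), c(0.008, 0.25),
                                 c(0.008, 0.4)),
                 n_points = c(60, 90, 120), gammas = c(1, 2, 4),
                 noise = 0.03, N = 10, seed = seed,
                 gp_draw = list(tau2 = 13, lam = 0.02),
                 perturbations = list(list(profile = 3, q = c(0.008, 0.015),
                                           amplitude = -0.08)))
}

e2e_config <- function(run_seed) {
  run_config(mean = "guinier", gp = gp_config(restarts = 2, seed = 1),
             seed = run_seed, reference = 1)
}

# map a cleaned profile's points back to the generator's perturbation mask
mask_on_cleaned <- function(cleaned, spec, gen, i) {
  qorig <- seq(spec$q_ranges[[i]][1], spec$q_ranges[[i]][2],
               length.out = spec$n_points[i])
  gen$truth$masks[[i]][match(cleaned$q, qorig)]
}
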