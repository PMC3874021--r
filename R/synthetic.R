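#' Specification of a synthetic scattering experiment
#'
#' Describes a set of scattering profiles drawn from a known ground-truth
#' curve, with heteroscedastic repetition noise, known per-profile scale
#' factors, and optional localized incompatibility perturbations (a low-`q`
#' perturbation emulates interparticle interference at high concentration; a
#' perturbation at arbitrary `q` emulates radiation damage). All tests and
#' simulations in the package draw their data from this generator, so the
#' ground truth is always known.
#'
#' The per-repetition noise standard deviation at a point with (scaled) true
#' intensity `I` is
#' `noise * I_pk * (noise_floor + (1 - noise_floor) * sqrt(max(I, 0)/I_pk))`,
#' where `I_pk` is the profile's peak true intensity: a constant floor plus a
#' component growing with the square root of the signal
#' (counting-statistics behaviour). `noise` is the relative noise level at
#' the peak and the default floor fraction of 0.5 keeps the standard
#' deviations nearly constant across the curve, as observed in real
#' reductions. An optional `edge_factor` inflates the noise quadratically
#' towards both ends of the `q` window, emulating the diverging standard
#' deviations seen at extreme `q`.
#'
#' @param truth a [mean_model()] ground-truth curve.
#' @param q_ranges list (one per profile) of `c(lo, hi)` momentum-transfer
#'   windows, or a single `c(lo, hi)` recycled.
#' @param n_points integer vector of points per profile (recycled).
#' @param gammas per-profile true scale factors.
#' @param noise relative per-repetition noise level at the peak intensity
#'   (default 0.04; 0 gives noiseless profiles with `s = 0`).
#' @param noise_floor signal-independent fraction of the noise level, in
#'   `[0, 1]` (default 0.5).
#' @param edge_factor extra relative noise at the window edges (default 0).
#' @param perturbations list of `list(profile =, q = c(lo, hi), amplitude =)`
#'   entries; the true curve is multiplied by `1 + amplitude` inside the
#'   interval for that profile only.
#' @param N repetition count (default 10).
#' @param seed RNG seed used by [generate_profiles()] (default 1).
#' @param gp_draw optional `list(tau2 =, lam =)`: adds one shared
#'   squared-exponential Gaussian-process draw on top of the parametric truth.
#' @param sd_floor lower bound applied to the reported `s` (default 0; set
#'   positive when a downstream step requires `s > 0` on noiseless data).
#' @return a `synthetic_spec` list.
#' @export
synthetic_spec <- function(truth, q_ranges = c(0.008, 0.4), n_points = 100L,
                           gammas = 1, noise = 0.04, noise_floor = 0.5,
                           edge_factor = 0, perturbations = list(),
                           N = 10L, seed = 1L, gp_draw = NULL, sd_floor = 0) {
  stopifnot(inherits(truth, "mean_model"), noise >= 0, N >= 1,
            noise_floor >= 0, noise_floor <= 1)
  np <- length(gammas)
  if (!is.list(q_ranges)) q_ranges <- rep(list(q_ranges), np)
  if (length(q_ranges) != np) q_ranges <- rep(q_ranges, length.out = np)
  n_points <- rep(as.integer(n_points), length.out = np)
  for (pert in perturbations)
    stopifnot(pert$profile >= 1, pert$profile <= np, length(pert$q) == 2L)
  structure(list(truth = truth, q_ranges = q_ranges, n_points = n_points,
                 gammas = gammas, noise = noise, noise_floor = noise_floor,
                 edge_factor = edge_factor, perturbations = perturbations,
                 N = as.integer(N), seed = seed, gp_draw = gp_draw,
                 sd_floor = sd_floor),
            class = "synthetic_spec")
}

#' Generate synthetic scattering profiles
#'
#' For each profile: evaluates the truth curve on its `q` grid, applies the
#' profile's scale factor and any perturbations, simulates `N` repetitions of
#' Gaussian noise, and reports their mean as `I` and their sample standard
#' deviation as `s` — exactly the summary statistics a reduction pipeline
#' would report. Reproducible under a fixed seed.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `profiles` (list of [scatter_profile()]) and `truth`
#'   (ground-truth record: the model, a `curve(q, profile)` function giving
#'   the full unperturbed truth — parametric part plus any shared GP draw —
#'   on the scale of `profile`, the perturbation masks, and the per-point
#'   true noise standard deviations).
#' @export
generate_profiles <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  np <- length(spec$gammas)
  profiles <- vector("list", np)
  masks <- vector("list", np)
  true_sd <- vector("list", np)

  gp_fn <- NULL
  if (!is.null(spec$gp_draw)) {
    # one shared smooth deviation, drawn on a fine grid and interpolated
    qq <- seq(min(vapply(spec$q_ranges, min, 0)),
              max(vapply(spec$q_ranges, max, 0)), length.out = 400L)
    C <- se_covariance(qq, qq, spec$gp_draw$tau2, spec$gp_draw$lam)
    cf <- chol_jitter(C + diag(1e-10 * spec$gp_draw$tau2, length(qq)))
    dev <- drop(crossprod(cf$R, stats::rnorm(length(qq))))
    gp_fn <- stats::approxfun(qq, dev, rule = 2)
  }

  for (j in seq_len(np)) {
    rg <- spec$q_ranges[[j]]
    q <- seq(rg[1], rg[2], length.out = spec$n_points[j])
    truth <- model_evaluate(spec$truth, q)
    if (!is.null(gp_fn)) truth <- truth + gp_fn(q)
    mask <- rep(FALSE, length(q))
    for (pert in spec$perturbations) {
      if (pert$profile != j) next
      inside <- q >= pert$q[1] & q <= pert$q[2]
      truth[inside] <- truth[inside] * (1 + pert$amplitude)
      mask <- mask | inside
    }
    scaled <- spec$gammas[j] * truth
    pk <- max(scaled)
    sd_rep <- spec$noise * pk *
      (spec$noise_floor + (1 - spec$noise_floor) * sqrt(pmax(scaled, 0) / pk))
    if (spec$edge_factor > 0) {
      mid <- mean(rg)
      half <- diff(rg) / 2
      sd_rep <- sd_rep * (1 + spec$edge_factor * ((q - mid) / half)^2)
    }
    if (all(sd_rep == 0)) {
      I <- scaled
      s <- rep(spec$sd_floor, length(q))
    } else {
      reps <- matrix(stats::rnorm(spec$N * length(q), mean = rep(scaled,
                                                                 each = spec$N),
                                  sd = rep(sd_rep, each = spec$N)),
                     nrow = spec$N)
      I <- colMeans(reps)
      s <- apply(reps, 2, stats::sd)
      s <- pmax(s, spec$sd_floor)
    }
    profiles[[j]] <- scatter_profile(q, I, s, N = spec$N,
                                     label = sprintf("synthetic-%d", j))
    masks[[j]] <- mask
    true_sd[[j]] <- sd_rep
  }
  base_fn <- function(q) {
    out <- model_evaluate(spec$truth, q)
    if (!is.null(gp_fn)) out <- out + gp_fn(q)
    out
  }
  list(profiles = profiles,
       truth = list(model = spec$truth, gammas = spec$gammas,
                    masks = masks, sd = true_sd, gp_deviation = gp_fn,
                    curve = function(q, profile = np)
                      spec$gammas[profile] * base_fn(q)))
}
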