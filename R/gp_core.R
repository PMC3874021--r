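#' Squared-exponential covariance function
#'
#' The prior covariance of the Gaussian process over the scattering curve:
#' \deqn{w(q, q') = \tau^2 \exp\{-(q - q')^2 / (2\lambda^2)\},}
#' where `tau2` is the variance the process assigns far from any data point
#' and `lam` is the persistence length of the profile, in units of `q`.
#' This kernel yields continuous, infinitely differentiable curves, so the
#' machinery is only appropriate for smooth scattering profiles.
#'
#' @param q,qp numeric vectors of momentum-transfer values.
#' @param tau2 prior variance, positive.
#' @param lam persistence length, positive, in `q` units.
#' @return `length(q) x length(qp)` covariance matrix.
#' @export
se_covariance <- function(q, qp = q, tau2, lam) {
  stopifnot(tau2 > 0, lam > 0)
  d <- outer(q, qp, "-")
  tau2 * exp(-d^2 / (2 * lam^2))
}

#' Hyperparameter container
#'
#' Collects the mean-model parameters together with the noise scale `sigma`
#' (multiplying the reported empirical variances: the noise covariance is
#' `sigma * diag(s^2) / N`), the prior variance `tau2` and the persistence
#' length `lam` of the squared-exponential kernel.
#'
#' @param mean named list/vector of mean-model parameters.
#' @param sigma positive noise proportionality constant.
#' @param tau2 positive kernel variance.
#' @param lam positive kernel persistence length.
#' @return a plain list with class `gp_hyperparameters`.
#' @export
gp_hyperparameters <- function(mean, sigma, tau2, lam) {
  stopifnot(sigma > 0, tau2 > 0, lam > 0)
  structure(list(mean = as.list(mean), sigma = sigma, tau2 = tau2, lam = lam),
            class = "gp_hyperparameters")
}

#' Fitting configuration for the Gaussian process
#'
#' @param restarts number of optimizer starts: one heuristic start plus
#'   Latin-hypercube draws over the prior box (default 5).
#' @param seed optional seed for the restart draws.
#' @param fixed named list of hyperparameters to hold fixed (excluded from
#'   optimization and from the Laplace parameter count), e.g.
#'   `list(tau2 = 0.1, lam = 0.05)`.
#' @param jitter_start,jitter_max relative jitter added to the data covariance
#'   when a Cholesky factorization fails; escalates by factors of 10 from
#'   `jitter_start` to `jitter_max` before a conditioning error is raised.
#' @param average use the hyperparameter-averaged posterior downstream?
#'   Default `FALSE` (plug-in posterior).
#' @param maxit optimizer iteration cap per restart.
#' @return a `gp_config` list.
#' @export
gp_config <- function(restarts = 5L, seed = NULL, fixed = list(),
                      jitter_start = 1e-10, jitter_max = 1e-6,
                      average = FALSE, maxit = 200L) {
  structure(list(restarts = as.integer(restarts), seed = seed, fixed = fixed,
                 jitter_start = jitter_start, jitter_max = jitter_max,
                 average = isTRUE(average), maxit = as.integer(maxit)),
            class = "gp_config")
}

#' Default hyperprior bounds for a profile
#'
#' Finite bounds are required so that the uniform hyperpriors are normalized
#' (the evidence would otherwise be improper). Defaults scale with the data:
#' `sigma` in `[1e-3, 1e3]` (Jeffreys), `tau2` in `[1e-6, 1e6] * var(I)`,
#' `lam` between the median `q` spacing and the `q` range, `A` within
#' `±10 max|I|`, `G` in `[1e-4, 10] * max(I)`, `Rg` in `[1/q_max, 10/q_min]`,
#' the Porod exponent `d` in `[0.05, 8]`, and for the full generalized
#' Guinier-Porod model `s` in `[0, 2.9]` with `delta = d - s` in `[0.05, 8]`
#' (the box on `(s, delta)` keeps `d > s` by construction).
#'
#' @param profile a [scatter_profile()].
#' @return named list of `c(lo, hi)` bounds.
#' @export
default_bounds <- function(profile) {
  q <- profile$q; I <- profile$I
  maxI <- max(abs(I))
  vI <- if (length(I) >= 2) stats::var(I) else max(profile$s^2, maxI^2 * 1e-4)
  vI <- max(vI, .Machine$double.eps * maxI^2, .Machine$double.xmin)
  qr <- max(q) - min(q)
  dq <- if (length(q) >= 2) stats::median(diff(q)) else qr
  list(A = c(-10 * maxI, 10 * maxI),
       G = c(1e-4 * maxI, 10 * maxI),
       Rg = c(1 / max(q), 10 / min(q)),
       d = c(0.05, 8),
       delta = c(0.05, 8),
       s = c(0, 2.9),
       sigma = c(1e-3, 1e3),
       tau2 = c(1e-6 * vI, 1e6 * vI),
       lam = c(max(min(dq, qr / 2), 1e-6 * qr), qr))
}

# ---- internal parameter bookkeeping -----------------------------------------
# Free hyperparameters are optimized in transformed coordinates: log scale for
# the positive scale parameters, natural scale for A, d/delta, s. The full GGP
# model is parameterized internally as (s, delta = d - s) so the constraint
# d > s is a box constraint.

.log_scaled <- c("G", "Rg", "sigma", "tau2", "lam")

param_table <- function(kind, bounds, fixed = list()) {
  mp <- model_param_names(kind)
  if (kind == "guinier-porod") mp[mp == "d"] <- "delta"
  nm <- c(mp, "sigma", "tau2", "lam")
  fixed_here <- intersect(names(fixed), nm)
  tab <- data.frame(name = nm,
                    lo = vapply(nm, function(n) bounds[[n]][1], 0),
                    hi = vapply(nm, function(n) bounds[[n]][2], 0),
                    log = nm %in% .log_scaled,
                    free = !(nm %in% fixed_here),
                    value = NA_real_, stringsAsFactors = FALSE)
  for (n in fixed_here) tab$value[tab$name == n] <- fixed[[n]]
  if (any(tab$lo >= tab$hi)) stop("invalid hyperprior bounds (lo >= hi)")
  tab
}

# natural free vector -> full named natural vector
tab_full <- function(tab, x_free) {
  v <- tab$value
  v[tab$free] <- x_free
  names(v) <- tab$name
  v
}

theta_from_tab <- function(kind, v) {
  mp <- model_param_names(kind)
  mean <- as.list(v[setdiff(names(v), c("sigma", "tau2", "lam"))])
  if (kind == "guinier-porod") {
    mean$d <- mean$s + mean$delta
    mean$delta <- NULL
  }
  list(mean = mean[mp], sigma = unname(v[["sigma"]]),
       tau2 = unname(v[["tau2"]]), lam = unname(v[["lam"]]))
}

to_u <- function(tab, x) {
  lg <- tab$log[tab$free]
  x[lg] <- log(x[lg])
  x
}
from_u <- function(tab, u) {
  lg <- tab$log[tab$free]
  u[lg] <- exp(u[lg])
  u
}
bounds_u <- function(free) {
  lo <- free$lo; hi <- free$hi
  lo[free$log] <- log(lo[free$log])
  hi[free$log] <- log(hi[free$log])
  list(lo = lo, hi = hi)
}

# log hyperprior over the free parameters (normalized): Jeffreys 1/sigma on
# its interval, uniform on the natural scale for everything else.
log_hyperprior <- function(tab, v) {
  lp <- 0
  for (i in which(tab$free)) {
    n <- tab$name[i]
    if (v[[n]] < tab$lo[i] || v[[n]] > tab$hi[i]) return(-Inf)
    lp <- lp + if (n == "sigma")
      -log(v[[n]]) - log(log(tab$hi[i] / tab$lo[i]))
    else
      -log(tab$hi[i] - tab$lo[i])
  }
  lp
}

# Cholesky with escalating relative jitter; returns list(R, jitter).
chol_jitter <- function(Omega, jitter_start = 1e-10, jitter_max = 1e-6) {
  sc <- mean(diag(Omega))
  R <- tryCatch(chol(Omega), error = function(e) NULL)
  if (!is.null(R)) return(list(R = R, jitter = 0))
  eps <- jitter_start
  while (eps <= jitter_max) {
    R <- tryCatch(chol(Omega + diag(eps * sc, nrow(Omega))),
                  error = function(e) NULL)
    if (!is.null(R)) return(list(R = R, jitter = eps * sc))
    eps <- eps * 10
  }
  stop("covariance factorization failed after maximum jitter; ",
       "reciprocal condition estimate ", format(rcond(Omega), digits = 3))
}

.gp_data <- function(profile) {
  list(q = profile$q, I = profile$I, s = profile$s,
       s2N = profile$s^2 / profile_N(profile))
}

# log marginal likelihood and its gradient w.r.t. the natural parameters of
# `tab` (value only when grad = FALSE).
logml_core <- function(dat, kind, v, grad = TRUE,
                       jitter_start = 1e-10, jitter_max = 1e-6) {
  th <- theta_from_tab(kind, v)
  model <- mean_model(kind, th$mean)
  q <- dat$q
  m <- model_evaluate(model, q)
  r <- dat$I - m
  W <- se_covariance(q, q, th$tau2, th$lam)
  Omega <- W + diag(th$sigma * dat$s2N, length(q))
  cf <- chol_jitter(Omega, jitter_start, jitter_max)
  R <- cf$R
  a <- backsolve(R, forwardsolve(t(R), r))
  logml <- -0.5 * length(q) * log(2 * pi) - sum(log(diag(R))) -
    0.5 * sum(r * a)
  if (!grad) return(list(value = logml, theta = th, model = model))

  Oinv <- chol2inv(R)
  gl <- list()
  J <- model_gradient(model, q)           # columns named by natural params
  gm <- drop(crossprod(J, a))
  names(gm) <- colnames(J)
  if (kind == "guinier-porod") {
    # chain rule to the internal (s, delta) coordinates
    gm2 <- c(gm[c("A", "G", "Rg")],
             delta = unname(gm["d"]),
             s = unname(gm["s"] + gm["d"]))
    gm <- gm2
  }
  dsq <- outer(q, q, "-")^2
  quad <- function(P) 0.5 * (drop(crossprod(a, P %*% a)) - sum(Oinv * P))
  gl[["tau2"]] <- quad(W / th$tau2)
  gl[["lam"]] <- quad(W * dsq / th$lam^3)
  gl[["sigma"]] <- 0.5 * (sum(a^2 * dat$s2N) - sum(diag(Oinv) * dat$s2N))
  grad_nat <- c(gm, unlist(gl))
  list(value = logml, grad = grad_nat, theta = th, model = model,
       R = R, Oinv = Oinv, alpha = a, mean = m, jitter = cf$jitter)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log marginal likelihood of a profile under the Gaussian-process model
#'
#' The latent curve integrates out analytically: the intensities are jointly
#' multivariate normal with mean `m(q)` (the parametric mean model) and
#' covariance `Omega = W + sigma * diag(s^2)/N`, where `W` is the
#' squared-exponential kernel matrix on the data sites. Computed via a
#' Cholesky factorization for numerical stability.
#'
#' @param profile a cleaned [scatter_profile()].
#' @param theta a [gp_hyperparameters()] (or plain list with elements `mean`,
#'   `sigma`, `tau2`, `lam`).
#' @param model a [mean_model()]; if `NULL`, built from `theta$mean` with the
#'   kind of `kind`.
#' @param kind mean-model kind used when `model` is `NULL`.
#' @return the log marginal likelihood (scalar).
#' @export
log_marginal_likelihood <- function(profile, theta, model = NULL,
                                    kind = NULL) {
  if (!is.null(model)) kind <- model$kind
  if (is.null(kind)) stop("supply either `model` or `kind`")
  mean <- if (!is.null(model)) model$params else theta$mean
  v <- unlist(c(mean, sigma = theta$sigma, tau2 = theta$tau2,
                lam = theta$lam))
  if (kind == "guinier-porod") {
    v[["delta"]] <- v[["d"]] - v[["s"]]
    v <- v[setdiff(names(v), "d")]
  }
  dat <- .gp_data(profile)
  logml_core(dat, kind, v, grad = FALSE)$value
}

# central finite-difference hessian of the *analytic gradient* of the log
# posterior, in the natural coordinates of the free parameters.
fd_hessian <- function(fun_grad, x, rel = 1e-5) {
  k <- length(x)
  H <- matrix(0, k, k)
  for (j in seq_len(k)) {
    h <- rel * max(abs(x[j]), 1e-8)
    xp <- x; xp[j] <- xp[j] + h
    xm <- x; xm[j] <- xm[j] - h
    H[, j] <- (fun_grad(xp) - fun_grad(xm)) / (2 * h)
  }
  (H + t(H)) / 2
}

#' Fit a profile by type-II maximum likelihood
#'
#' Maximizes the log marginal likelihood plus the log hyperprior (Jeffreys on
#' `sigma`, uniform within bounds on everything else) over the
#' hyperparameters, using L-BFGS-B with analytic gradients in transformed
#' coordinates, from one heuristic start plus Latin-hypercube restarts over
#' the prior box. Returns the plug-in posterior predictive at the optimum
#' together with the Laplace-approximated log evidence
#' \deqn{\log P(D|\mathcal{M}) \approx \log P(D|\Theta^*) + \log P(\Theta^*)
#'   + (k/2)\log 2\pi - \tfrac12 \log\det H,}
#' with `H` the negative hessian of the log posterior at the optimum and `k`
#' the number of free hyperparameters.
#'
#' @param profile a cleaned [scatter_profile()] with at least `k + 3` points.
#' @param model a [mean_model()] kind (character) or `mean_model` object
#'   whose kind selects the mean family.
#' @param bounds optional named list overriding entries of
#'   [default_bounds()].
#' @param config a [gp_config()].
#' @return a `gp_posterior` object with elements `theta`, `model`,
#'   `log_evidence`, `log_posterior`, `H`, `Hinv`, `k`, `evidence_reliable`,
#'   `averaged`, and callable accessors via [posterior_mean()],
#'   [posterior_cov()], [posterior_var()].
#' @export
fit_ml2 <- function(profile, model = "guinier", bounds = NULL,
                    config = gp_config()) {
  kind <- if (inherits(model, "mean_model")) model$kind else model
  b <- default_bounds(profile)
  for (n in names(bounds)) b[[n]] <- bounds[[n]]
  tab <- param_table(kind, b, config$fixed)
  free <- tab[tab$free, , drop = FALSE]
  k <- nrow(free)
  dat <- .gp_data(profile)
  if (k > 0L && length(dat$q) < length(model_param_names(kind)) + 3)
    stop("profile '", profile$label, "' has too few points (", length(dat$q),
         ") to fit the ", kind, " mean model")

  neg_obj <- function(u) {
    x <- from_u(free, u)
    v <- tab_full(tab, x)
    lp <- log_hyperprior(tab, v)
    if (!is.finite(lp)) return(1e10)
    res <- tryCatch(logml_core(dat, kind, v, grad = FALSE,
                               config$jitter_start, config$jitter_max),
                    error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) return(1e10)
    -(res$value + lp)
  }
  neg_grad <- function(u) {
    x <- from_u(free, u)
    v <- tab_full(tab, x)
    res <- tryCatch(logml_core(dat, kind, v, grad = TRUE,
                               config$jitter_start, config$jitter_max),
                    error = function(e) NULL)
    if (is.null(res)) return(rep(0, k))
    g <- res$grad[free$name]
    g[free$name == "sigma"] <- g[free$name == "sigma"] - 1 / x[free$name == "sigma"]
    gu <- ifelse(free$log, g * x, g)      # chain rule for log coordinates
    -gu
  }

  if (k == 0L) {
    # nothing to optimize: the "fit" is the fixed hyperparameter set
    res <- logml_core(dat, kind, tab_full(tab, numeric(0)), grad = TRUE,
                      config$jitter_start, config$jitter_max)
    post <- structure(
      list(theta = res$theta, model = res$model, data = dat,
           label = profile$label, N = profile$N,
           log_posterior = res$value, log_evidence = res$value,
           H = matrix(0, 0, 0), Hinv = matrix(0, 0, 0), k = 0L,
           tab = tab, kind = kind, evidence_reliable = TRUE,
           averaged = FALSE, Oinv = res$Oinv, alpha = res$alpha,
           convergence = 0L),
      class = "gp_posterior")
    return(post)
  }

  starts <- fit_starts(dat, kind, tab, config)
  bu <- bounds_u(free)
  lo_u <- bu$lo; hi_u <- bu$hi
  best <- NULL
  fails <- character(0)
  for (st in starts) {
    u0 <- pmin(pmax(to_u(free, st), lo_u + 1e-10), hi_u - 1e-10)
    fit <- tryCatch(
      stats::optim(u0, neg_obj, neg_grad, method = "L-BFGS-B",
                   lower = lo_u, upper = hi_u,
                   control = list(maxit = config$maxit)),
      error = function(e) {fails <<- c(fails, conditionMessage(e)); NULL})
    if (is.null(fit) || !is.finite(fit$value) || fit$value >= 1e10) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best))
    stop("hyperparameter optimization failed on all restarts",
         if (length(fails)) paste0(": ", paste(unique(fails), collapse = "; ")))

  x_star <- from_u(free, best$par)
  v_star <- tab_full(tab, x_star)
  logpost <- -best$value

  # Laplace evidence in natural coordinates
  grad_nat <- function(x) {
    x <- pmin(pmax(x, free$lo), free$hi)   # FD probes stay in the prior box
    v <- tab_full(tab, x)
    res <- logml_core(dat, kind, v, grad = TRUE,
                      config$jitter_start, config$jitter_max)
    g <- res$grad[free$name]
    g[free$name == "sigma"] <- g[free$name == "sigma"] - 1 / x[free$name == "sigma"]
    g
  }
  reliable <- TRUE
  H <- -fd_hessian(grad_nat, x_star)
  ch <- tryCatch(chol(H), error = function(e) NULL)
  if (is.null(ch)) {
    reliable <- FALSE
    warning("log-posterior hessian not positive definite at the optimum; ",
            "projecting to the nearest PD matrix, evidence flagged unreliable")
    ev <- eigen(H, symmetric = TRUE)
    lam_min <- max(abs(ev$values)) * 1e-8
    H <- ev$vectors %*% diag(pmax(ev$values, lam_min), nrow(H)) %*% t(ev$vectors)
    ch <- chol(H)
  }
  logdetH <- 2 * sum(log(diag(ch)))
  Hinv <- chol2inv(ch)
  dimnames(H) <- dimnames(Hinv) <- list(free$name, free$name)
  log_evidence <- logpost + 0.5 * k * log(2 * pi) - 0.5 * logdetH

  res <- logml_core(dat, kind, v_star, grad = TRUE,
                    config$jitter_start, config$jitter_max)
  post <- structure(
    list(theta = res$theta, model = res$model, data = dat,
         label = profile$label, N = profile$N,
         log_posterior = logpost, log_evidence = log_evidence,
         H = H, Hinv = Hinv, k = k, tab = tab, kind = kind,
         evidence_reliable = reliable, averaged = FALSE,
         Oinv = res$Oinv, alpha = res$alpha,
         convergence = best$convergence),
    class = "gp_posterior")
  if (config$average) averaged_posterior(post) else post
}

# Heuristic first start plus Latin-hypercube draws over the prior box.
fit_starts <- function(dat, kind, tab, config) {
  free <- tab[tab$free, , drop = FALSE]
  clamp <- function(x, i) pmin(pmax(x, free$lo[i] * (1 + 1e-9) + 1e-300),
                               free$hi[i] * (1 - 1e-9))
  q <- dat$q; I <- dat$I
  init <- numeric(nrow(free))
  # Guinier regression on the low-q third for G and Rg
  G0 <- max(I); Rg0 <- 1.3 / stats::median(q)
  nlo <- max(5L, ceiling(length(q) / 3))
  sel <- seq_len(min(nlo, length(q)))
  pos <- sel[I[sel] > 0]
  if (length(pos) >= 3) {
    fit <- stats::lm(log(I[pos]) ~ I(q[pos]^2))
    sl <- stats::coef(fit)
    if (is.finite(sl[2]) && sl[2] < 0) {
      G0 <- exp(sl[1]); Rg0 <- sqrt(-3 * sl[2])
    }
  }
  m0 <- NULL
  for (i in seq_len(nrow(free))) {
    init[i] <- switch(free$name[i],
                      A = 0, G = G0, Rg = Rg0, d = 4, delta = 3.8, s = 0.2,
                      sigma = 1,
                      tau2 = max(stats::var(I) * 0.1, free$lo[free$name == "tau2"]),
                      lam = (max(q) - min(q)) / 5)
    init[i] <- clamp(init[i], i)
  }
  starts <- list(init)
  nr <- max(config$restarts - 1L, 0L)
  if (nr > 0) {
    if (!is.null(config$seed)) set.seed(config$seed)
    bu <- bounds_u(free)
    lo_u <- bu$lo; hi_u <- bu$hi
    Lh <- lhs::randomLHS(nr, nrow(free))
    for (r in seq_len(nr)) {
      u <- lo_u + Lh[r, ] * (hi_u - lo_u)
      starts[[r + 1L]] <- from_u(free, u)
    }
  }
  starts
}

#' @export
print.gp_posterior <- function(x, ...) {
  cat(sprintf("<gp_posterior '%s'>  mean model: %s%s\n", x$label,
              x$model$kind, if (x$averaged) " (hyperparameter-averaged)" else ""))
  th <- unlist(x$theta$mean)
  cat("  mean params:", paste(sprintf("%s=%.4g", names(th), th),
                              collapse = " "), "\n")
  cat(sprintf("  sigma=%.4g tau2=%.4g lambda=%.4g\n",
              x$theta$sigma, x$theta$tau2, x$theta$lam))
  cat(sprintf("  log evidence (Laplace): %.4f  [k=%d free hyperparameters]\n",
              x$log_evidence, x$k))
  invisible(x)
}

#' Posterior predictive mean
#'
#' `m_hat(q) = m(q) + w(q, Q) Omega^{-1} (I - m(Q))`: the prior mean corrected
#' by the kernel-weighted residuals at the data sites.
#'
#' @param post a `gp_posterior` from [fit_ml2()] (or its averaged version).
#' @param q evaluation points.
#' @return posterior mean intensities.
#' @export
posterior_mean <- function(post, q) {
  if (post$averaged) return(post$avg_mean(q))
  Kq <- se_covariance(q, post$data$q, post$theta$tau2, post$theta$lam)
  model_evaluate(post$model, q) + drop(Kq %*% post$alpha)
}

#' Posterior predictive covariance
#'
#' `w_hat(q, q') = w(q, q') - w(q, Q) Omega^{-1} w(Q, q')`.
#'
#' @inheritParams posterior_mean
#' @param qp second set of evaluation points (defaults to `q`).
#' @return covariance matrix of the posterior curve between `q` and `qp`.
#' @export
posterior_cov <- function(post, q, qp = q) {
  if (post$averaged) return(post$avg_cov(q, qp))
  th <- post$theta
  Kq <- se_covariance(q, post$data$q, th$tau2, th$lam)
  Kp <- se_covariance(qp, post$data$q, th$tau2, th$lam)
  se_covariance(q, qp, th$tau2, th$lam) - Kq %*% post$Oinv %*% t(Kp)
}

#' Pointwise posterior predictive variance
#' @inheritParams posterior_mean
#' @return vector of `w_hat(q, q)` values.
#' @export
posterior_var <- function(post, q) {
  if (post$averaged) return(diag(post$avg_cov(q, q)))
  th <- post$theta
  Kq <- se_covariance(q, post$data$q, th$tau2, th$lam)
  pmax(th$tau2 - rowSums((Kq %*% post$Oinv) * Kq), 0)
}

#' Hyperparameter-averaged posterior
#'
#' Averages the posterior predictive over the Laplace Gaussian on the
#' hyperparameters using a deterministic sigma-point set: the `2k` points
#' `Theta* +/- sqrt(k) L_i` (with `L L' = H^{-1}`), equally weighted, which
#' reproduce the Laplace mean and covariance exactly. The averaged covariance
#' adds the between-sigma-point dispersion of the means (law of total
#' variance), so it is never smaller than any systematic plug-in optimism.
#' Sigma points are clipped into the hyperprior box.
#'
#' @param post a plug-in `gp_posterior`.
#' @return a `gp_posterior` with `averaged = TRUE`.
#' @export
averaged_posterior <- function(post) {
  if (post$averaged) return(post)
  free <- post$tab[post$tab$free, , drop = FALSE]
  k <- post$k
  x_star <- vapply(free$name, function(n) {
    v <- c(post$theta$mean, sigma = post$theta$sigma,
           tau2 = post$theta$tau2, lam = post$theta$lam)
    if (n == "delta") v$d - v$s else v[[n]]
  }, 0)
  L <- tryCatch(t(chol(post$Hinv)), error = function(e) {
    ev <- eigen(post$Hinv, symmetric = TRUE)
    ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), k)
  })
  pts <- list()
  for (i in seq_len(k)) {
    pts[[2 * i - 1]] <- x_star + sqrt(k) * L[, i]
    pts[[2 * i]] <- x_star - sqrt(k) * L[, i]
  }
  clamp <- function(x) pmin(pmax(x, free$lo * (1 + 1e-9) + 1e-300),
                            free$hi * (1 - 1e-9))
  comps <- lapply(pts, function(x) {
    v <- tab_full(post$tab, clamp(x))
    res <- logml_core(post$data, post$kind, v, grad = TRUE)
    list(theta = res$theta, model = res$model, Oinv = res$Oinv,
         alpha = res$alpha)
  })
  wgt <- rep(1 / (2 * k), 2 * k)
  comp_mean <- function(cp, q) {
    Kq <- se_covariance(q, post$data$q, cp$theta$tau2, cp$theta$lam)
    model_evaluate(cp$model, q) + drop(Kq %*% cp$alpha)
  }
  comp_cov <- function(cp, q, qp) {
    th <- cp$theta
    Kq <- se_covariance(q, post$data$q, th$tau2, th$lam)
    Kp <- se_covariance(qp, post$data$q, th$tau2, th$lam)
    se_covariance(q, qp, th$tau2, th$lam) - Kq %*% cp$Oinv %*% t(Kp)
  }
  avg <- post
  avg$averaged <- TRUE
  avg$avg_mean <- function(q) {
    mus <- vapply(comps, comp_mean, numeric(length(q)), q = q)
    drop(as.matrix(mus) %*% wgt)
  }
  avg$avg_cov <- function(q, qp = q) {
    mus_q <- vapply(comps, comp_mean, numeric(length(q)), q = q)
    mus_p <- vapply(comps, comp_mean, numeric(length(qp)), q = qp)
    mbar_q <- drop(as.matrix(mus_q) %*% wgt)
    mbar_p <- drop(as.matrix(mus_p) %*% wgt)
    C <- matrix(0, length(q), length(qp))
    for (j in seq_along(comps)) {
      C <- C + wgt[j] * (comp_cov(comps[[j]], q, qp) +
                           tcrossprod(mus_q[, j] - mbar_q, mus_p[, j] - mbar_p))
    }
    C
  }
  avg
}

#' Draw functional deviates from the posterior predictive
#'
#' Samples whole curves from the multivariate normal with mean
#' `posterior_mean(post, q_grid)` and covariance
#' `posterior_cov(post, q_grid)`.
#'
#' @param post a `gp_posterior`.
#' @param q_grid evaluation grid.
#' @param k number of draws.
#' @param seed optional seed for reproducible draws.
#' @return a `k x length(q_grid)` matrix, one curve per row.
#' @export
sample_deviates <- function(post, q_grid, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mu <- posterior_mean(post, q_grid)
  C <- posterior_cov(post, q_grid)
  cf <- chol_jitter(C + diag(1e-12 * max(diag(C), 1e-300), length(q_grid)))
  Z <- matrix(stats::rnorm(k * length(q_grid)), k, length(q_grid))
  sweep(Z %*% cf$R, 2, mu, "+")
}

#' Compare candidate mean models by Bayes factors
#'
#' Fits each candidate mean family and ranks them by the
#' Laplace-approximated log evidence. The log Bayes factor between two models
#' is the difference of their log evidences (equal prior model
#' probabilities); the selected model is the evidence argmax. Richer models
#' pay an Occam penalty through the prior normalization and the Laplace
#' determinant, so they win only when the data support the extra structure.
#'
#' @param profile a cleaned [scatter_profile()].
#' @param models character vector of candidate kinds (>= 2).
#' @param bounds,config forwarded to [fit_ml2()].
#' @return a `gp_model_comparison` with `fits`, a ranked `table`, the
#'   pairwise `log_bayes_factors` matrix, `best` (kind) and `best_fit`.
#' @export
compare_models <- function(profile,
                           models = c("flat", "guinier", "guinier-porod-s0",
                                      "guinier-porod"),
                           bounds = NULL, config = gp_config()) {
  if (length(models) < 2L) stop("need at least two candidate models")
  fits <- list(); errs <- character(0)
  for (kind in models) {
    f <- tryCatch(fit_ml2(profile, kind, bounds, config),
                  error = function(e) {
                    errs <<- c(errs, paste0(kind, ": ", conditionMessage(e)))
                    NULL
                  })
    if (!is.null(f)) fits[[kind]] <- f
  }
  if (length(fits) == 0L)
    stop("all candidate models failed to fit: ", paste(errs, collapse = "; "))
  if (length(fits) == 1L)
    warning("only one candidate model fitted successfully (",
            names(fits), "); selecting it without comparison")
  ev <- vapply(fits, function(f) f$log_evidence, 0)
  ord <- order(ev, decreasing = TRUE)
  tabl <- data.frame(kind = names(fits)[ord],
                     k = vapply(fits, function(f) f$k, 0L)[ord],
                     log_evidence = ev[ord], row.names = NULL,
                     stringsAsFactors = FALSE)
  bf <- outer(ev, ev, "-")
  dimnames(bf) <- list(names(fits), names(fits))
  structure(list(fits = fits, table = tabl, log_bayes_factors = bf,
                 best = tabl$kind[1L], best_fit = fits[[tabl$kind[1L]]],
                 errors = errs),
            class = "gp_model_comparison")
}

#' @export
print.gp_model_comparison <- function(x, ...) {
  cat("<gp_model_comparison>  best mean model:", x$best, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
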