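#' Parametric prior-mean models for scattering curves
#'
#' Constructs a member of the nested family of parametric mean functions used
#' as the prior mean of the Gaussian process:
#'
#' * `"flat"` — constant `A` (1 parameter);
#' * `"guinier"` — `A + G exp(-q^2 Rg^2 / 3)`, the Guinier law with a constant
#'   offset (3 parameters);
#' * `"guinier-porod-s0"` — Hammouda's generalized Guinier-Porod form with the
#'   low-`q` power-law exponent fixed at `s = 0`, plus offset (4 parameters);
#' * `"guinier-porod"` — the full generalized Guinier-Porod form, plus offset
#'   (5 parameters).
#'
#' The generalized Guinier-Porod form joins a (power-law-modified) Guinier
#' regime `G q^{-s} exp(-q^2 Rg^2 / (3 - s))` for `q <= q1` to a Porod regime
#' `D q^{-d}` for `q > q1`, where the transition point
#' `q1 = sqrt((d - s)(3 - s)/2) / Rg` and prefactor
#' `D = G q1^{d-s} exp(-(d - s)/2)` are determined by continuity of the value
#' and the first derivative; they are never free parameters. Each simpler
#' model is a constrained case of the richer ones.
#'
#' @param kind one of `"flat"`, `"guinier"`, `"guinier-porod-s0"`,
#'   `"guinier-porod"`.
#' @param params named numeric vector/list with the active parameters among
#'   `A` (offset), `G > 0` (Guinier prefactor), `Rg > 0` (radius of gyration,
#'   in inverse `q` units), `d` (Porod exponent) and `s` (low-`q` exponent),
#'   with `d > s >= 0` and `s < 3`.
#' @return a `mean_model` object.
#' @export
mean_model <- function(kind = c("flat", "guinier", "guinier-porod-s0",
                                "guinier-porod"),
                       params) {
  kind <- match.arg(kind)
  need <- model_param_names(kind)
  params <- as.list(params)
  if (!all(need %in% names(params)))
    stop("model '", kind, "' needs parameters: ", paste(need, collapse = ", "))
  p <- lapply(params[need], as.numeric)
  validate_mean_params(kind, p)
  structure(list(kind = kind, params = p), class = "mean_model")
}

#' Active parameter names of a mean-model kind
#' @param kind model kind, as in [mean_model()].
#' @return character vector of parameter names.
#' @export
model_param_names <- function(kind) {
  switch(kind,
         "flat" = "A",
         "guinier" = c("A", "G", "Rg"),
         "guinier-porod-s0" = c("A", "G", "Rg", "d"),
         "guinier-porod" = c("A", "G", "Rg", "d", "s"),
         stop("unknown mean model kind: ", kind))
}

validate_mean_params <- function(kind, p) {
  if (kind == "flat") return(invisible(TRUE))
  if (p$G <= 0) stop("G must be positive")
  if (p$Rg <= 0) stop("Rg must be positive")
  if (kind %in% c("guinier-porod-s0", "guinier-porod")) {
    s <- if (kind == "guinier-porod") p$s else 0
    if (s < 0 || s >= 3) stop("s must satisfy 0 <= s < 3")
    if (p$d <= s) stop("d must exceed s")
  }
  invisible(TRUE)
}

# Transition point and Porod prefactor of the generalized Guinier-Porod form.
ggp_transition <- function(G, Rg, d, s) {
  q1 <- sqrt((d - s) * (3 - s) / 2) / Rg
  D <- G * q1^(d - s) * exp(-(d - s) / 2)   # uses q1^2 Rg^2 = (d-s)(3-s)/2
  list(q1 = q1, D = D)
}

# Value, gradient and log-hessian pieces of the GGP form (without offset A),
# for parameters (G, Rg, d, s). Returns value f, gradient of log f (per q,
# 4 columns) and second derivatives of log f (per q, 4x4), from which
# grad f = f * dlog and hess f = f * (dlog dlog' + d2log).
ggp_pieces <- function(q, G, Rg, d, s) {
  tr <- ggp_transition(G, Rg, d, s)
  lo <- q <= tr$q1
  n <- length(q)
  f <- numeric(n)
  dl <- matrix(0, n, 4, dimnames = list(NULL, c("G", "Rg", "d", "s")))
  d2 <- array(0, c(n, 4, 4), dimnames = list(NULL, colnames(dl), colnames(dl)))

  if (any(lo)) {
    ql <- q[lo]
    f[lo] <- G * ql^(-s) * exp(-ql^2 * Rg^2 / (3 - s))
    dl[lo, "G"] <- 1 / G
    dl[lo, "Rg"] <- -2 * ql^2 * Rg / (3 - s)
    dl[lo, "s"] <- -log(ql) - ql^2 * Rg^2 / (3 - s)^2
    d2[lo, "G", "G"] <- -1 / G^2
    d2[lo, "Rg", "Rg"] <- -2 * ql^2 / (3 - s)
    d2[lo, "Rg", "s"] <- d2[lo, "s", "Rg"] <- -2 * ql^2 * Rg / (3 - s)^2
    d2[lo, "s", "s"] <- -2 * ql^2 * Rg^2 / (3 - s)^3
  }
  if (any(!lo)) {
    qh <- q[!lo]
    f[!lo] <- tr$D * qh^(-d)
    dl[!lo, "G"] <- 1 / G
    dl[!lo, "Rg"] <- -(d - s) / Rg
    dl[!lo, "d"] <- log(tr$q1 / qh)
    dl[!lo, "s"] <- -log(tr$q1) - (d - s) / (2 * (3 - s))
    d2[!lo, "G", "G"] <- -1 / G^2
    d2[!lo, "Rg", "Rg"] <- (d - s) / Rg^2
    d2[!lo, "Rg", "d"] <- d2[!lo, "d", "Rg"] <- -1 / Rg
    d2[!lo, "Rg", "s"] <- d2[!lo, "s", "Rg"] <- 1 / Rg
    d2[!lo, "d", "d"] <- 1 / (2 * (d - s))
    d2[!lo, "d", "s"] <- d2[!lo, "s", "d"] <-
      -1 / (2 * (d - s)) - 1 / (2 * (3 - s))
    d2[!lo, "s", "s"] <- 1 / (2 * (d - s)) + 1 / (2 * (3 - s)) +
      (3 - d) / (2 * (3 - s)^2)
  }
  list(f = f, dlog = dl, d2log = d2)
}

#' Evaluate a mean model
#'
#' @param model a [mean_model()].
#' @param q positive momentum-transfer vector.
#' @return intensity vector `m(q)`.
#' @export
model_evaluate <- function(model, q) {
  stopifnot(inherits(model, "mean_model"))
  if (any(q <= 0)) stop("q must be positive")
  p <- model$params
  validate_mean_params(model$kind, p)
  switch(model$kind,
         "flat" = rep(p$A, length(q)),
         "guinier" = p$A + p$G * exp(-q^2 * p$Rg^2 / 3),
         "guinier-porod-s0" =
           p$A + ggp_pieces(q, p$G, p$Rg, p$d, 0)$f,
         "guinier-porod" =
           p$A + ggp_pieces(q, p$G, p$Rg, p$d, p$s)$f)
}

#' Gradient of a mean model with respect to its parameters
#'
#' @inheritParams model_evaluate
#' @return matrix with `length(q)` rows and one named column per active
#'   parameter, `d m(q) / d theta`.
#' @export
model_gradient <- function(model, q) {
  stopifnot(inherits(model, "mean_model"))
  if (any(q <= 0)) stop("q must be positive")
  p <- model$params
  validate_mean_params(model$kind, p)
  nm <- model_param_names(model$kind)
  out <- matrix(0, length(q), length(nm), dimnames = list(NULL, nm))
  out[, "A"] <- 1
  if (model$kind == "guinier") {
    E <- exp(-q^2 * p$Rg^2 / 3)
    out[, "G"] <- E
    out[, "Rg"] <- -p$G * E * 2 * q^2 * p$Rg / 3
  } else if (model$kind != "flat") {
    s <- if (model$kind == "guinier-porod") p$s else 0
    pc <- ggp_pieces(q, p$G, p$Rg, p$d, s)
    g <- pc$f * pc$dlog
    for (v in intersect(colnames(g), nm)) out[, v] <- g[, v]
  }
  out
}

#' Hessian of a mean model with respect to its parameters
#'
#' @inheritParams model_evaluate
#' @return array of dimension `length(q) x k x k` (named), the elementwise
#'   second derivatives `d^2 m(q) / d theta d theta'`.
#' @export
model_hessian <- function(model, q) {
  stopifnot(inherits(model, "mean_model"))
  if (any(q <= 0)) stop("q must be positive")
  p <- model$params
  validate_mean_params(model$kind, p)
  nm <- model_param_names(model$kind)
  H <- array(0, c(length(q), length(nm), length(nm)),
             dimnames = list(NULL, nm, nm))
  if (model$kind == "guinier") {
    f <- p$G * exp(-q^2 * p$Rg^2 / 3)
    lG <- 1 / p$G
    lR <- -2 * q^2 * p$Rg / 3
    H[, "G", "G"] <- f * (lG^2 - 1 / p$G^2)         # = 0 exactly
    H[, "G", "Rg"] <- H[, "Rg", "G"] <- f * lG * lR
    H[, "Rg", "Rg"] <- f * (lR^2 - 2 * q^2 / 3)
  } else if (model$kind != "flat") {
    s <- if (model$kind == "guinier-porod") p$s else 0
    pc <- ggp_pieces(q, p$G, p$Rg, p$d, s)
    keep <- intersect(colnames(pc$dlog), nm)
    for (a in keep) for (b in keep)
      H[, a, b] <- pc$f * (pc$dlog[, a] * pc$dlog[, b] + pc$d2log[, a, b])
  }
  H
}
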