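#' Rank profiles by expected concentration / dose
#'
#' Computes, for each profile, the forward scattering `I(0)` from a Guinier
#' fit of the low-`q` region and the median of the reported standard
#' deviations, and ranks the profiles by ascending `I(0) / median(s)`. This
#' signal-to-noise ratio grows with either concentration or X-ray dose, so
#' the first-ranked profile is the one least affected by interparticle
#' interference and radiation damage; it holds initial reference status in
#' classification. The Guinier region is taken as `q <= 1.3 / Rg` after one
#' round of iterated fitting (standard Guinier practice). When the Guinier
#' fit fails the ranking falls back to the median error alone, with a
#' warning.
#'
#' Ranking is performed on the profiles' original (pre-rescaling) scale,
#' where the statistic still discriminates concentrations.
#'
#' @param profiles list of cleaned [scatter_profile()] objects.
#' @param statistic `"snr"` (default) or `"median-error"` (fall-back only).
#' @return integer vector of profile indices in rank order, with the per
#'   profile statistics in `attr(, "stats")`. Ties keep input order (stable).
#' @export
rank_profiles <- function(profiles, statistic = c("snr", "median-error")) {
  statistic <- match.arg(statistic)
  stats_df <- do.call(rbind, lapply(profiles, function(p) {
    med <- stats::median(p$s)
    gf <- guinier_quick_fit(p)
    data.frame(label = p$label, I0 = gf$I0, Rg = gf$Rg, median_s = med,
               snr = if (is.na(gf$I0)) NA_real_ else gf$I0 / med,
               stringsAsFactors = FALSE)
  }))
  key <- if (statistic == "snr") stats_df$snr else stats_df$median_s
  if (statistic == "snr" && anyNA(key)) {
    warning("Guinier fit failed for profile(s) ",
            paste(stats_df$label[is.na(key)], collapse = ", "),
            "; ranking by median error only")
    key <- stats_df$median_s
  }
  ord <- order(key)                       # radix: stable for ties
  structure(ord, stats = stats_df)
}

# One-round iterated Guinier regression: fit log I ~ q^2 on the low-q third,
# then refit restricted to q <= 1.3/Rg. Returns I0 = exp(intercept) and Rg,
# or NAs when no usable region exists.
guinier_quick_fit <- function(profile) {
  q <- profile$q; I <- profile$I
  fit_on <- function(idx) {
    idx <- idx[I[idx] > 0]
    if (length(idx) < 3) return(NULL)
    co <- stats::coef(stats::lm(log(I[idx]) ~ I(q[idx]^2)))
    if (!all(is.finite(co)) || co[2] >= 0) return(NULL)
    list(I0 = exp(co[[1]]), Rg = sqrt(-3 * co[[2]]))
  }
  f1 <- fit_on(seq_len(max(5L, ceiling(length(q) / 3))))
  if (is.null(f1)) return(list(I0 = NA_real_, Rg = NA_real_))
  f2 <- fit_on(which(q <= 1.3 / f1$Rg))
  if (is.null(f2)) f2 <- f1
  f2
}

#' Welch's two-sample t-test from summary statistics
#'
#' Two-sided unequal-variance test of `mu1 = mu2` with the Satterthwaite
#' degrees-of-freedom approximation:
#' \deqn{t = (\mu_1 - \mu_2)/\sqrt{v_1/N_1 + v_2/N_2},}
#' \deqn{\nu = (v_1/N_1 + v_2/N_2)^2 /
#'   [(v_1/N_1)^2/(N_1-1) + (v_2/N_2)^2/(N_2-1)].}
#' All arguments are vectorized.
#'
#' @param mu1,mu2 sample means.
#' @param var1,var2 sample variances (positive).
#' @param N1,N2 sample sizes (>= 2).
#' @param alpha significance level for the verdict (default 0.05).
#' @return data frame with columns `t`, `nu`, `p` and logical
#'   `incompatible` (`p < alpha`).
#' @export
welch_test <- function(mu1, var1, N1, mu2, var2, N2, alpha = 0.05) {
  if (any(var1 <= 0) || any(var2 <= 0))
    stop("welch_test requires positive variances")
  if (any(N1 < 2) || any(N2 < 2)) stop("welch_test requires N >= 2")
  se1 <- var1 / N1; se2 <- var2 / N2
  t <- (mu1 - mu2) / sqrt(se1 + se2)
  nu <- (se1 + se2)^2 / (se1^2 / (N1 - 1) + se2^2 / (N2 - 1))
  p <- 2 * stats::pt(abs(t), df = nu, lower.tail = FALSE)
  data.frame(t = t, nu = nu, p = p, incompatible = p < alpha)
}

#' Detect incompatible regions across ranked profiles
#'
#' Walks the profiles in rank order. The first profile holds reference status
#' over its whole retained range. Each subsequent candidate point is
#' Welch-tested against the posterior of whichever profile holds reference
#' status at that `q` (candidate side: its mean, sample variance and `N`;
#' reference side: the fitted posterior mean and pointwise variance,
#' converted to a per-observation variance through the owner's repetition
#' count). Points with `p < alpha` are flagged incompatible. Candidate `q`
#' regions not covered by any reference segment are untested, marked valid,
#' and become reference segments owned by the candidate — this is how a
#' wider-range profile hands its tail over as the new reference.
#'
#' Profiles and posteriors must already be on the common (rescaled) scale.
#' No multiple-testing correction is applied here; `alpha` is per point.
#'
#' @param profiles list of cleaned, rescaled [scatter_profile()] objects.
#' @param posteriors list of matching (rescaled) `gp_posterior` objects.
#' @param rank_order integer vector from [rank_profiles()]; defaults to input
#'   order.
#' @param alpha per-point significance level (default 0.05).
#' @return a `compatibility_map`: per-profile `verdicts` (character vectors
#'   over each profile's points: `"compatible"`, `"incompatible"` or
#'   `"untested"` for extension points), `segments` (data frame `lo`, `hi`,
#'   `owner`, `label`, ordered and disjoint in `q`), per-profile `tests`
#'   (Welch statistics), plus `alpha` and `order`.
#' @export
classify_profiles <- function(profiles, posteriors, rank_order = NULL,
                              alpha = 0.05) {
  np <- length(profiles)
  stopifnot(np >= 1L, length(posteriors) == np)
  if (is.null(rank_order)) rank_order <- seq_len(np)
  verdicts <- vector("list", np)
  tests <- vector("list", np)
  labs <- vapply(profiles, function(p) p$label, "")

  first <- rank_order[1L]
  segments <- data.frame(lo = min(profiles[[first]]$q),
                         hi = max(profiles[[first]]$q),
                         owner = first, label = labs[first],
                         stringsAsFactors = FALSE)
  verdicts[[first]] <- rep("compatible", n_points(profiles[[first]]))

  for (ci in rank_order[-1L]) {
    p <- profiles[[ci]]
    Np <- profile_N(p)
    v <- rep("untested", n_points(p))
    tt <- data.frame(t = rep(NA_real_, n_points(p)), nu = NA_real_,
                     p = NA_real_)
    seg_of <- vapply(p$q, function(qi) {
      w <- which(segments$lo <= qi & qi <= segments$hi)
      if (length(w)) w[1L] else NA_integer_
    }, 0L)
    tested <- !is.na(seg_of)
    if (any(tested)) {
      owner <- segments$owner[seg_of[tested]]
      mu_ref <- numeric(sum(tested)); var_ref <- numeric(sum(tested))
      N_ref <- numeric(sum(tested))
      qi <- p$q[tested]
      for (ow in unique(owner)) {
        sel <- owner == ow
        mu_ref[sel] <- posterior_mean(posteriors[[ow]], qi[sel])
        var_ref[sel] <- pmax(posterior_var(posteriors[[ow]], qi[sel]), 0)
        N_ref[sel] <- if (length(profiles[[ow]]$N) == 1L)
          profiles[[ow]]$N else round(stats::median(profiles[[ow]]$N))
      }
      # per-observation variance so that var/N equals the posterior variance
      var_obs <- pmax(N_ref * var_ref, 1e-12 * pmax(mu_ref^2, 1e-300))
      wt <- welch_test(p$I[tested], p$s[tested]^2, Np[tested],
                       mu_ref, var_obs, N_ref, alpha)
      v[tested] <- ifelse(wt$incompatible, "incompatible", "compatible")
      tt$t[tested] <- wt$t; tt$nu[tested] <- wt$nu; tt$p[tested] <- wt$p
    }
    # uncovered q runs become new reference segments owned by the candidate
    if (any(!tested)) {
      runs <- split(which(!tested), cumsum(c(1, diff(which(!tested)) != 1)))
      for (r in runs) {
        segments <- rbind(segments,
                          data.frame(lo = p$q[r[1L]], hi = p$q[r[length(r)]],
                                     owner = ci, label = labs[ci],
                                     stringsAsFactors = FALSE))
      }
      segments <- segments[order(segments$lo), , drop = FALSE]
      rownames(segments) <- NULL
    }
    verdicts[[ci]] <- v
    tests[[ci]] <- tt
  }
  if (!any(unlist(verdicts) == "compatible") &&
      !any(unlist(verdicts) == "untested"))
    stop("no compatible points anywhere; manual inspection advised")
  structure(list(verdicts = verdicts, segments = segments, tests = tests,
                 alpha = alpha, order = rank_order, labels = labs),
            class = "compatibility_map")
}

#' @export
print.compatibility_map <- function(x, ...) {
  cat("<compatibility_map>\n  reference segments:\n")
  for (i in seq_len(nrow(x$segments)))
    cat(sprintf("    [%g, %g] -> %s\n", x$segments$lo[i], x$segments$hi[i],
                x$segments$label[i]))
  for (i in seq_along(x$verdicts)) {
    tb <- table(factor(x$verdicts[[i]],
                       levels = c("compatible", "incompatible", "untested")))
    cat(sprintf("  %s: %d compatible, %d incompatible, %d untested\n",
                x$labels[i], tb[1L], tb[2L], tb[3L]))
  }
  invisible(x)
}
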