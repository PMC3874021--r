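#' Clean-up configuration
#'
#' Settings for the first pipeline step, which removes points whose expected
#' intensity is not significantly different from zero together with points
#' having degenerate or outlying standard deviations.
#'
#' @param alpha_total family-wise type-I error for the Bonferroni-corrected
#'   one-sample t-tests (default 0.05).
#' @param sd_outlier_factor multiplier on the median standard deviation above
#'   which points are discarded (default 2). Standard deviations are nearly
#'   constant across a scattering curve except at extreme `q`, where they
#'   diverge; such points are experimental artefacts.
#' @param drop_noisy apply the sd-outlier filter? Default `TRUE`.
#' @param drop_zero_sd discard points with zero (or missing) standard
#'   deviation? Default `TRUE`; such points must go before any t-test.
#' @return a `cleanup_config` list.
#' @export
cleanup_config <- function(alpha_total = 0.05, sd_outlier_factor = 2,
                           drop_noisy = TRUE, drop_zero_sd = TRUE) {
  stopifnot(alpha_total > 0, alpha_total < 1, sd_outlier_factor > 1)
  structure(list(alpha_total = alpha_total,
                 sd_outlier_factor = sd_outlier_factor,
                 drop_noisy = isTRUE(drop_noisy),
                 drop_zero_sd = isTRUE(drop_zero_sd)),
            class = "cleanup_config")
}

#' One-sample t statistic for a profile point
#'
#' Under the null hypothesis that a point is pure noise, the mean of `N`
#' repetitions divided by its standard error follows a Student-t distribution
#' with `N - 1` degrees of freedom:
#' \deqn{t = I \sqrt{N} / s.}
#'
#' @param I mean intensity (vectorized).
#' @param s standard deviation of a single repetition; must be positive.
#' @param N repetition count, at least 2 (the variance must be estimable).
#' @return the t statistic(s); reference distribution is `pt(.., df = N - 1)`.
#' @export
t_statistic <- function(I, s, N) {
  if (any(s <= 0)) stop("t_statistic requires s > 0 (filter zero-sd points first)")
  if (any(N < 2)) stop("t_statistic requires N >= 2")
  I * sqrt(N) / s
}

#' Clean a scattering profile
#'
#' Applies, in order: (1) removal of zero/missing-sd points, (2) the optional
#' sd-outlier filter discarding points with `s > sd_outlier_factor *
#' median(s)` (median over positive pre-filter `s`), and (3) a one-sided
#' one-sample t-test per point against zero intensity at the
#' Bonferroni-corrected level `alpha = alpha_total / M`, retaining a point iff
#' its one-sided p-value `P(T >= t)` is below `alpha`. `M` is the number of
#' points in the profile *before* any filtering (overridable via `m_total`),
#' so repeated cleaning with the original divisor is idempotent.
#'
#' @param profile a [scatter_profile()] with `N >= 2`.
#' @param config a [cleanup_config()].
#' @param m_total Bonferroni divisor override; defaults to the current point
#'   count of `profile`.
#' @return the cleaned [scatter_profile()]; removed points are recorded in
#'   `$removed` with flags `cleaned-out:zero-sd`, `cleaned-out:sd-outlier`
#'   or `cleaned-out:t-test`.
#' @export
clean_profile <- function(profile, config = cleanup_config(), m_total = NULL) {
  stopifnot(inherits(profile, "scatter_profile"))
  if (any(profile$N < 2)) stop("clean-up requires N >= 2")
  M <- if (is.null(m_total)) length(profile$q) else m_total
  alpha <- config$alpha_total / M
  N <- profile_N(profile)

  flag <- rep(NA_character_, length(profile$q))
  zero_sd <- !is.finite(profile$s) | profile$s <= 0
  if (config$drop_zero_sd) flag[zero_sd] <- "cleaned-out:zero-sd"

  s_ok <- profile$s[!zero_sd]
  if (config$drop_noisy && length(s_ok)) {
    med <- stats::median(s_ok)
    noisy <- is.na(flag) & !zero_sd &
      profile$s > config$sd_outlier_factor * med
    flag[noisy] <- "cleaned-out:sd-outlier"
  }

  testable <- is.na(flag) & !zero_sd
  if (any(testable)) {
    t <- t_statistic(profile$I[testable], profile$s[testable], N[testable])
    p <- stats::pt(t, df = N[testable] - 1, lower.tail = FALSE)
    drop <- testable
    drop[testable] <- p >= alpha
    flag[drop] <- "cleaned-out:t-test"
  } else if (config$drop_zero_sd) {
    # nothing testable: everything already flagged by the sd filters
  }

  keep <- is.na(flag)
  if (!any(keep)) {
    tab <- sort(table(flag), decreasing = TRUE)
    stop("empty profile after clean-up of '", profile$label,
         "' (dominant filter: ", names(tab)[1L], ")")
  }
  removed <- rbind(profile$removed,
                   data.frame(q = profile$q[!keep], I = profile$I[!keep],
                              s = profile$s[!keep], flag = flag[!keep],
                              stringsAsFactors = FALSE))
  scatter_profile(q = profile$q[keep], I = profile$I[keep],
                  s = profile$s[keep],
                  N = if (length(profile$N) == 1L) profile$N else N[keep],
                  label = profile$label, flags = profile$flags[keep],
                  removed = removed, sort = FALSE)
}
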