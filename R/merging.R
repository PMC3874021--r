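#' Merge compatible points and refit the Gaussian process
#'
#' Pools every point judged compatible (or valid-by-extension) by the
#' classification step, keeping track of each point's origin and repetition
#' count. When two pooled points share a `q` value (within a relative
#' tolerance, since rescaling breaks exact float equality) the one with the
#' smaller standard deviation is kept, ties broken in favour of the earlier
#' rank; this duplicate discarding can be disabled. The Gaussian process is
#' then refitted on the pooled data — with mean-model comparison when
#' `mean = "auto"` — using per-point noise variances `sigma * s_i^2 / N_i`,
#' so profiles with different repetition counts mix correctly.
#'
#' @param map a `compatibility_map` from [classify_profiles()].
#' @param profiles the rescaled profiles that were classified.
#' @param mean mean-model kind for the final fit, or `"auto"` for Bayes-factor
#'   selection across the whole nested family.
#' @param keep_duplicates keep duplicate `q` points? Default `FALSE`.
#' @param dup_tol relative duplicate tolerance: two points are duplicates when
#'   `|q_i - q_j| < dup_tol * (q range)` (default 1e-8).
#' @param bounds,config forwarded to the final [fit_ml2()] /
#'   [compare_models()].
#' @return a `merged_dataset` with `points` (data frame `q, I, s, origin, N,
#'   flag`), `posterior` (the final `gp_posterior`), `comparison` (when
#'   `mean = "auto"`), `estimates` (see [report_estimates()]) and
#'   `retention` (per-profile point accounting).
#' @export
merge_profiles <- function(map, profiles, mean = "auto",
                           keep_duplicates = FALSE, dup_tol = 1e-8,
                           bounds = NULL, config = gp_config()) {
  stopifnot(inherits(map, "compatibility_map"))
  rank_of <- match(seq_along(profiles), map$order)
  rows <- list()
  for (i in seq_along(profiles)) {
    p <- profiles[[i]]
    v <- map$verdicts[[i]]
    ok <- v %in% c("compatible", "untested")
    if (!any(ok)) next
    rows[[length(rows) + 1L]] <-
      data.frame(q = p$q[ok], I = p$I[ok], s = p$s[ok],
                 origin = p$label, N = profile_N(p)[ok],
                 flag = ifelse(v[ok] == "untested", "merged:extension",
                               "merged"),
                 rank = rank_of[i], stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no compatible points to merge")
  pool <- do.call(rbind, rows)
  pool <- pool[order(pool$q), , drop = FALSE]
  rownames(pool) <- NULL

  dup_dropped <- 0L
  if (!keep_duplicates && nrow(pool) > 1L) {
    tol <- dup_tol * (max(pool$q) - min(pool$q))
    grp <- cumsum(c(TRUE, diff(pool$q) >= tol))
    keep <- unlist(lapply(split(seq_len(nrow(pool)), grp), function(idx) {
      if (length(idx) == 1L) return(idx)
      o <- idx[order(pool$s[idx], pool$rank[idx])]
      o[1L]
    }), use.names = FALSE)
    dup_dropped <- nrow(pool) - length(keep)
    dropped <- setdiff(seq_len(nrow(pool)), keep)
    pool$flag[dropped] <- "duplicate"
    kept_pool <- pool[sort(keep), , drop = FALSE]
  } else {
    kept_pool <- pool
  }

  merged_profile <- scatter_profile(
    q = kept_pool$q, I = kept_pool$I, s = kept_pool$s, N = kept_pool$N,
    label = "merged", sort = FALSE)

  comparison <- NULL
  if (identical(mean, "auto")) {
    comparison <- compare_models(merged_profile, bounds = bounds,
                                 config = config)
    posterior <- comparison$best_fit
  } else {
    posterior <- fit_ml2(merged_profile, mean, bounds, config)
  }

  retention <- retention_stats(map, profiles, dup_dropped)
  out <- structure(list(points = kept_pool[, c("q", "I", "s", "origin",
                                               "N", "flag")],
                        all_points = pool,
                        posterior = posterior, comparison = comparison,
                        retention = retention),
                   class = "merged_dataset")
  out$estimates <- laplace_estimates(posterior)
  out
}

# Per-profile accounting: kept / cleaned-out / incompatible / extension.
retention_stats <- function(map, profiles, dup_dropped) {
  df <- do.call(rbind, lapply(seq_along(profiles), function(i) {
    p <- profiles[[i]]
    v <- map$verdicts[[i]]
    data.frame(label = p$label,
               input = length(p$q) + nrow(p$removed),
               cleaned_out = nrow(p$removed),
               incompatible = sum(v == "incompatible"),
               extension = sum(v == "untested"),
               kept = sum(v %in% c("compatible", "untested")),
               stringsAsFactors = FALSE)
  }))
  attr(df, "duplicates_dropped") <- dup_dropped
  df
}

# Rg and Porod-exponent estimates with Laplace standard errors from the
# inverse hessian of the log posterior (delta rule for d = s + delta).
laplace_estimates <- function(post) {
  est <- list(model = post$model$kind)
  nm <- rownames(post$Hinv)
  se_of <- function(name) {
    if (!(name %in% nm)) return(NA_real_)
    sqrt(max(post$Hinv[name, name], 0))
  }
  if ("Rg" %in% names(post$model$params)) {
    est$Rg <- post$model$params$Rg
    est$Rg_se <- se_of("Rg")
  }
  if ("d" %in% names(post$model$params)) {
    est$d <- post$model$params$d
    if (post$kind == "guinier-porod" && all(c("s", "delta") %in% nm)) {
      v <- post$Hinv["s", "s"] + post$Hinv["delta", "delta"] +
        2 * post$Hinv["s", "delta"]
      est$d_se <- sqrt(max(v, 0))
    } else {
      est$d_se <- se_of("d")
    }
  }
  est
}

#' Summarize a merged dataset
#'
#' Reports the selected mean model, the radius-of-gyration and
#' Porod-exponent estimates with their Laplace standard errors (explicitly
#' marked not estimable when the selected mean model lacks them), and the
#' per-profile retention accounting.
#'
#' @param merged a `merged_dataset`.
#' @return a `merge_report` list (also printed nicely).
#' @export
report_estimates <- function(merged) {
  stopifnot(inherits(merged, "merged_dataset"))
  est <- merged$estimates
  rep <- list(
    model = est$model,
    Rg = if (!is.null(est$Rg)) est$Rg else "not estimable",
    Rg_se = if (!is.null(est$Rg)) est$Rg_se else NA_real_,
    d = if (!is.null(est$d)) est$d else "not estimable",
    d_se = if (!is.null(est$d)) est$d_se else NA_real_,
    log_evidence = merged$posterior$log_evidence,
    retention = merged$retention,
    duplicates_dropped = attr(merged$retention, "duplicates_dropped"))
  class(rep) <- "merge_report"
  rep
}

#' @export
print.merge_report <- function(x, ...) {
  cat("Merged profile summary\n")
  cat("  selected mean model:", x$model, "\n")
  if (is.character(x$Rg)) cat("  Rg: not estimable\n")
  else cat(sprintf("  Rg: %.4g +- %.3g\n", x$Rg, x$Rg_se))
  if (is.character(x$d)) cat("  Porod exponent d: not estimable\n")
  else cat(sprintf("  Porod exponent d: %.4g +- %.3g\n", x$d, x$d_se))
  cat(sprintf("  log evidence: %.3f\n", x$log_evidence))
  cat(sprintf("  duplicates dropped: %d\n", x$duplicates_dropped))
  cat("  retention by profile:\n")
  print(x$retention, row.names = FALSE)
  invisible(x)
}

#' @export
print.merged_dataset <- function(x, ...) {
  cat(sprintf("<merged_dataset>  %d pooled points from %d profile(s)\n",
              nrow(x$points), length(unique(x$points$origin))))
  print(report_estimates(x))
  invisible(x)
}
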