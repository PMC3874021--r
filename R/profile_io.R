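#' Scattering profile container
#'
#' A `scatter_profile` holds one experiment's buffer-subtracted scattering
#' curve as parallel vectors of momentum transfer `q` (inverse length units),
#' mean intensity `I` (arbitrary units) and standard deviation `s` (same units
#' as `I`), together with the repetition count `N` used to form the means.
#' Points removed by later pipeline steps are moved to the `removed` record so
#' that the active vectors always describe the points still in play.
#'
#' @param q numeric vector of momentum transfer values, all positive.
#' @param I numeric vector of mean intensities.
#' @param s numeric vector of standard deviations (of a single repetition).
#' @param N repetition count; a single positive integer, or a vector with one
#'   entry per point (merged pools mix profiles with different `N`).
#' @param label free-text identifier for the profile's origin.
#' @param flags optional character vector of per-point status flags; defaults
#'   to `"raw"`.
#' @param removed optional data frame of previously removed points with
#'   columns `q`, `I`, `s`, `flag`.
#' @param sort sort rows by ascending `q` (stable)? Default `TRUE`.
#' @return an object of class `scatter_profile`.
#' @export
scatter_profile <- function(q, I, s, N = 10L, label = "profile",
                            flags = NULL, removed = NULL, sort = TRUE) {
  q <- as.numeric(q); I <- as.numeric(I); s <- as.numeric(s)
  M <- length(q)
  if (M < 1L) stop("a scatter profile needs at least one point")
  if (length(I) != M || length(s) != M)
    stop("q, I and s must have equal length")
  if (!all(is.finite(q)) || !all(is.finite(I)) || !all(is.finite(s)))
    stop("non-finite values in profile data")
  if (any(q <= 0)) stop("all q values must be positive")
  if (!(length(N) %in% c(1L, M)) || any(N < 1) || any(N != round(N)))
    stop("N must be a positive integer (scalar or one per point)")
  if (is.null(flags)) flags <- rep("raw", M)
  if (length(flags) != M) stop("flags must have one entry per point")
  if (sort) {
    o <- order(q)                       # radix order: stable for ties
    q <- q[o]; I <- I[o]; s <- s[o]; flags <- flags[o]
    if (length(N) == M) N <- N[o]
  } else if (is.unsorted(q)) {
    stop("q must be non-decreasing (or use sort = TRUE)")
  }
  if (is.null(removed))
    removed <- data.frame(q = numeric(0), I = numeric(0), s = numeric(0),
                          flag = character(0), stringsAsFactors = FALSE)
  structure(list(q = q, I = I, s = s, N = N, label = label,
                 flags = flags, removed = removed),
            class = "scatter_profile")
}

#' @export
print.scatter_profile <- function(x, ...) {
  cat(sprintf("<scatter_profile '%s'>  %d points, q in [%g, %g], N = %s\n",
              x$label, length(x$q), min(x$q), max(x$q),
              paste(unique(x$N), collapse = "/")))
  if (nrow(x$removed) > 0L)
    cat(sprintf("  %d removed point(s): %s\n", nrow(x$removed),
                paste(names(table(x$removed$flag)), table(x$removed$flag),
                      sep = "=", collapse = ", ")))
  invisible(x)
}

#' Number of active points in a profile
#' @param profile a [scatter_profile()].
#' @return integer count of points currently retained.
#' @export
n_points <- function(profile) length(profile$q)

# Per-point repetition counts as a full-length vector.
profile_N <- function(profile) {
  if (length(profile$N) == 1L) rep(profile$N, length(profile$q)) else profile$N
}

#' Read a three-column scattering profile
#'
#' Parses the plain-text exchange format used by most beamline reduction
#' software: one data point per line, columns `q`, intensity, standard
#' deviation, whitespace- or comma-delimited. Lines starting with `#` and
#' blank lines are skipped. Rows are returned sorted by ascending `q`
#' (stable). Extra columns beyond the third are ignored with a warning.
#'
#' The three-column format does not carry the repetition count, so `N` must be
#' supplied; if it is not, a default of 10 is used with a warning.
#'
#' @param path path to the profile file.
#' @param N repetition count for this profile (positive integer, >= 2 for the
#'   clean-up t-tests).
#' @param label profile label; defaults to the file name.
#' @return a [scatter_profile()].
#' @export
read_profile <- function(path, N = NULL, label = basename(path)) {
  if (!file.exists(path)) stop("cannot read profile file: ", path)
  if (is.null(N)) {
    warning("repetition count N not supplied for '", path,
            "'; defaulting to N = 10")
    N <- 10L
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) stop("no data rows in ", path)

  parse_with <- function(split) {
    lapply(lines, function(l) {
      toks <- strsplit(trimws(l), split)[[1]]
      toks[nzchar(toks)]
    })
  }
  parses <- function(tk) all(vapply(tk, length, 1L) >= 3L) &&
    !anyNA(suppressWarnings(as.numeric(unlist(lapply(tk, `[`, 1:3)))))
  toks <- parse_with("[[:space:]]+")
  if (!parses(toks)) {
    toks_c <- parse_with("[[:space:]]*,[[:space:]]*")
    # fall back to comma-delimited only when that actually parses; otherwise
    # report errors against the primary whitespace interpretation
    if (parses(toks_c)) toks <- toks_c
  }

  nfield <- vapply(toks, length, 1L)
  if (any(nfield < 3L))
    stop("line ", lineno[which(nfield < 3L)[1L]], " of ", path,
         ": fewer than 3 numeric fields")
  if (any(nfield > 3L))
    warning("extra columns in ", path, " ignored (first three used)")
  vals <- suppressWarnings(
    vapply(toks, function(tk) as.numeric(tk[1:3]), numeric(3)))
  bad <- which(!is.finite(vals), arr.ind = TRUE)
  if (length(bad))
    stop("line ", lineno[bad[1L, 2L]], " of ", path,
         ": non-numeric or non-finite value")
  scatter_profile(q = vals[1L, ], I = vals[2L, ], s = vals[3L, ],
                  N = N, label = label)
}

#' Write a profile in three-column format
#'
#' @param profile a [scatter_profile()].
#' @param path output path.
#' @param digits significant digits to print (default 12, enough for a
#'   lossless round trip at double precision for typical magnitudes).
#' @export
write_profile <- function(profile, path, digits = 12L) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("# %s  (N = %s)", profile$label,
                     paste(unique(profile$N), collapse = "/")), con)
  writeLines(sprintf(paste0("%.", digits, "g %.", digits, "g %.", digits, "g"),
                     profile$q, profile$I, profile$s), con)
  invisible(path)
}

#' Write an annotated merged profile
#'
#' Writes (a) the retained experimental points with their origin labels and
#' status flags and (b) the posterior mean curve with its pointwise standard
#' deviation on a `q` grid. Header lines (prefixed `#`) record the selected
#' mean model, the fitted hyperparameters, and the radius-of-gyration and
#' Porod-exponent estimates when available.
#'
#' @param merged a `merged_dataset` from [merge_profiles()].
#' @param path output path.
#' @param grid optional numeric vector of `q` values for the posterior curve.
#' @param grid_n number of grid points when `grid` is not given (default 200,
#'   evenly spaced over the merged `q` range).
#' @export
write_merged <- function(merged, path, grid = NULL, grid_n = 200L) {
  post <- merged$posterior
  pts <- merged$points
  if (is.null(grid))
    grid <- seq(min(pts$q), max(pts$q), length.out = grid_n)
  mu <- posterior_mean(post, grid)
  sd <- sqrt(pmax(posterior_var(post, grid), 0))
  est <- merged$estimates

  con <- file(path, "w"); on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# saxsgp merged profile")
  w("# mean model: %s", post$model$kind)
  th <- unlist(post$theta$mean)
  w("# mean parameters: %s",
    paste(sprintf("%s=%.10g", names(th), th), collapse = " "))
  w("# gp parameters: sigma=%.10g tau2=%.10g lambda=%.10g",
    post$theta$sigma, post$theta$tau2, post$theta$lam)
  w("# log evidence: %.10g", post$log_evidence)
  if (!is.null(est$Rg))
    w("# Rg: %.10g +- %.4g", est$Rg, est$Rg_se)
  else
    w("# Rg: not estimable (mean model '%s')", post$model$kind)
  if (!is.null(est$d))
    w("# Porod exponent d: %.10g +- %.4g", est$d, est$d_se)
  else
    w("# Porod exponent d: not estimable (mean model '%s')", post$model$kind)
  w("# data points: %d", nrow(pts))
  w("# columns: q I s origin flag")
  writeLines(sprintf("%.12g\t%.12g\t%.12g\t%s\t%s",
                     pts$q, pts$I, pts$s, pts$origin, pts$flag), con)
  w("# posterior grid: %d", length(grid))
  w("# columns: q mean sd")
  writeLines(sprintf("%.12g\t%.12g\t%.12g", grid, mu, sd), con)
  invisible(path)
}
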