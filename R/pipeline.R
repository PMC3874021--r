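#' Pipeline configuration
#'
#' Bundles every module's settings for an end-to-end run. All elements are
#' plain values, so the resolved configuration can be serialized alongside a
#' run's outputs.
#'
#' @param cleanup a [cleanup_config()].
#' @param gp a [gp_config()].
#' @param mean mean-model kind for the per-profile fits and the final merged
#'   fit, or `"auto"` for Bayes-factor selection.
#' @param rescale_model loss model for rescaling: `"normal"`,
#'   `"normal-offset"` or `"lognormal"`.
#' @param reference rescaling reference override (label or index); `NULL`
#'   uses the last profile.
#' @param alpha per-point significance level for classification.
#' @param keep_duplicates,dup_tol duplicate handling at the merge step.
#' @param grid_n posterior-curve grid size for written output.
#' @param seed seed set at the start of a run (restart draws, deviates).
#' @param output_dir optional directory for written outputs.
#' @param verbose print per-step progress? Default `FALSE`.
#' @return a `run_config` list.
#' @export
run_config <- function(cleanup = cleanup_config(), gp = gp_config(),
                       mean = "auto", rescale_model = "normal",
                       reference = NULL, alpha = 0.05,
                       keep_duplicates = FALSE, dup_tol = 1e-8,
                       grid_n = 200L, seed = 1L, output_dir = NULL,
                       verbose = FALSE) {
  structure(list(cleanup = cleanup, gp = gp, mean = mean,
                 rescale_model = rescale_model, reference = reference,
                 alpha = alpha, keep_duplicates = keep_duplicates,
                 dup_tol = dup_tol, grid_n = as.integer(grid_n),
                 seed = seed, output_dir = output_dir,
                 verbose = isTRUE(verbose)),
            class = "run_config")
}

#' Run the full merging pipeline
#'
#' Executes the five sequential steps: (i) clean-up, (ii) per-profile
#' Gaussian-process fitting, (iii) rescaling to a common reference, (iv)
#' ranking and classification of incompatible regions, and (v) merging with a
#' final fit. The first three steps run separately on every input profile.
#'
#' @param profiles list of [scatter_profile()] objects, or a character vector
#'   of file paths (read with [read_profile()]; supply `N` per file then).
#' @param config a [run_config()].
#' @param N repetition count(s) used when `profiles` are file paths.
#' @return a `pipeline_result` with the per-step artifacts: `cleaned`,
#'   `fits`, `rescales`, `rescaled_profiles`, `rescaled_posteriors`,
#'   `rank_order`, `map`, `merged`, `report` and the resolved `config`.
#' @export
run_pipeline <- function(profiles, config = run_config(), N = NULL) {
  step <- function(...) if (config$verbose) message(sprintf(...))
  if (is.character(profiles)) {
    paths <- profiles
    if (is.null(N)) N <- rep(list(NULL), length(paths))
    if (!is.list(N)) N <- as.list(rep(N, length.out = length(paths)))
    profiles <- mapply(read_profile, paths, N, SIMPLIFY = FALSE)
  }
  stopifnot(length(profiles) >= 1L)
  if (!is.null(config$seed)) set.seed(config$seed)

  step("step (i): clean-up of %d profile(s)", length(profiles))
  cleaned <- lapply(profiles, clean_profile, config = config$cleanup)

  step("step (ii): Gaussian-process fitting")
  fit_one <- function(p) {
    if (identical(config$mean, "auto"))
      compare_models(p, config = config$gp)$best_fit
    else
      fit_ml2(p, config$mean, config = config$gp)
  }
  fits <- lapply(cleaned, fit_one)
  if (config$gp$average) fits <- lapply(fits, averaged_posterior)

  step("step (iii): rescaling to the common reference")
  ref <- choose_reference(cleaned, config$reference)
  rescales <- vector("list", length(cleaned))
  for (i in seq_along(cleaned)) {
    rescales[[i]] <- if (i == ref)
      structure(list(gamma = 1, offset = 0, model = config$rescale_model,
                     reference_label = cleaned[[ref]]$label),
                class = "rescale_result")
    else
      rescale_to_reference(fits[[i]], fits[[ref]],
                           model = config$rescale_model)
  }
  rescaled_profiles <- mapply(apply_rescale, cleaned, rescales,
                              SIMPLIFY = FALSE)
  rescaled_posteriors <- mapply(scale_posterior, fits, rescales,
                                SIMPLIFY = FALSE)

  step("step (iv): ranking and classification")
  rank_order <- rank_profiles(cleaned)
  map <- classify_profiles(rescaled_profiles, rescaled_posteriors,
                           rank_order = rank_order, alpha = config$alpha)

  step("step (v): merging and final fit")
  merged <- merge_profiles(map, rescaled_profiles, mean = config$mean,
                           keep_duplicates = config$keep_duplicates,
                           dup_tol = config$dup_tol, config = config$gp)
  report <- report_estimates(merged)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    write_merged(merged, file.path(config$output_dir, "merged.dat"),
                 grid_n = config$grid_n)
  }

  structure(list(cleaned = cleaned, fits = fits, rescales = rescales,
                 rescaled_profiles = rescaled_profiles,
                 rescaled_posteriors = rescaled_posteriors,
                 rank_order = rank_order, map = map, merged = merged,
                 report = report, reference = ref, config = config),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result>  %d profile(s), reference '%s'\n",
              length(x$cleaned), x$cleaned[[x$reference]]$label))
  gammas <- vapply(x$rescales, function(r) r$gamma, 0)
  cat("  scale factors:",
      paste(sprintf("%s=%.4g",
                    vapply(x$cleaned, function(p) p$label, ""), gammas),
            collapse = " "), "\n")
  print(x$report)
  invisible(x)
}
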