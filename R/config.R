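#' Analysis configuration
#'
#' Bundles the tuning parameters shared by the 2D-TPP, SPP and melting-curve
#' pipelines. Defaults follow the published analysis: a fold-change gate of
#' `h = 1.5`, a 1% FDR cutoff and 100 permutations.
#'
#' @param h Fold-change gate (> 1). A temperature window (2D-TPP) or dose
#'   profile (SPP) only contributes evidence when its extreme fold change
#'   exceeds `h` (stabilization/solubilization) or falls below `1/h`
#'   (destabilization/loss of solubility).
#' @param fdr_cutoff FDR threshold for hit calling, in (0, 1).
#' @param n_permutations Number of permutations `B` for the FDR estimate.
#' @param min_points_per_fit Minimum number of (dose, fold change) points
#'   required before a sigmoid is fitted.
#' @param seed Integer master seed for the permutation scheme.
#' @param comelt_cutoff Profile-distance cutoff below which two melting
#'   profiles are called "in proximity" (co-melting).
#' @param insoluble_ratio SDS/NP40 vehicle-intensity ratio at or above which a
#'   protein is classified as part of the insoluble proteome.
#' @param include_vehicle_point Include the vehicle measurement (at a
#'   pseudo-dose two decades below the lowest tested dose) in dose-response
#'   fits.
#' @param allow_negative_log_terms If `TRUE`, the combined 2D-TPP score sums
#'   `ln(F)` terms below zero as printed in the score definition; the default
#'   floors each term at zero so windows with `F < 1` carry no evidence.
#' @param comelt_metric `"mean_sq"` (average squared per-temperature
#'   deviation, the default on which the 0.02 cutoff is calibrated) or
#'   `"rss"` (root-sum-square) for co-melting distances.
#' @param fit_on_log If `TRUE`, SPP dose-response fits use log2 fold changes
#'   instead of raw ratios.
#' @param verbose Log per-stage protein counts via `message()`.
#'
#' @return A list of class `"thermsol_config"`.
#' @examples
#' cfg <- analysis_config(seed = 1)
#' cfg$h
#' @export
analysis_config <- function(h = 1.5,
                            fdr_cutoff = 0.01,
                            n_permutations = 100,
                            min_points_per_fit = 5,
                            seed = 1L,
                            comelt_cutoff = 0.02,
                            insoluble_ratio = 1.5,
                            include_vehicle_point = TRUE,
                            allow_negative_log_terms = FALSE,
                            comelt_metric = c("mean_sq", "rss"),
                            fit_on_log = FALSE,
                            verbose = FALSE) {
  if (h <= 1) stopf("h must be > 1 (got %g)", h)
  if (fdr_cutoff <= 0 || fdr_cutoff >= 1) stopf("fdr_cutoff must be in (0,1)")
  if (n_permutations < 1) stopf("n_permutations must be >= 1")
  if (min_points_per_fit < 4) stopf("min_points_per_fit must be >= 4")
  cfg <- list(
    h = h, fdr_cutoff = fdr_cutoff, n_permutations = as.integer(n_permutations),
    min_points_per_fit = as.integer(min_points_per_fit), seed = as.integer(seed),
    comelt_cutoff = comelt_cutoff, insoluble_ratio = insoluble_ratio,
    include_vehicle_point = isTRUE(include_vehicle_point),
    allow_negative_log_terms = isTRUE(allow_negative_log_terms),
    comelt_metric = match.arg(comelt_metric),
    fit_on_log = isTRUE(fit_on_log), verbose = isTRUE(verbose)
  )
  class(cfg) <- "thermsol_config"
  cfg
}

#' Read an analysis configuration from a YAML or JSON file
#'
#' Unknown keys are rejected so typos do not silently fall back to defaults.
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file whose keys match
#'   the arguments of [analysis_config()].
#' @return A `"thermsol_config"` list.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(analysis_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stopf("unknown config keys: %s", paste(bad, collapse = ", "))
  do.call(analysis_config, vals)
}

#' @export
print.thermsol_config <- function(x, ...) {
  cat("thermsol analysis configuration\n")
  cat(sprintf("  fold-change gate h: %g (destabilization 1/h = %.3g)\n", x$h, 1 / x$h))
  cat(sprintf("  FDR cutoff: %g  permutations B: %d  seed: %d\n",
              x$fdr_cutoff, x$n_permutations, x$seed))
  cat(sprintf("  min points per fit: %d  insoluble ratio: %g  co-melt cutoff: %g\n",
              x$min_points_per_fit, x$insoluble_ratio, x$comelt_cutoff))
  invisible(x)
}
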