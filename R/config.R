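#' Pipeline configuration with the study's filtering thresholds
#'
#' Bundles every numeric threshold used across the pipeline. Defaults are
#' the published filtering rules: interactions with a Bayesian FDR of at
#' least `bfdr_max` are dropped; preys detected in at least `crapome_freq_max`
#' of contaminant-repository experiments are dropped unless their
#' spectral-count fold change over the repository average exceeds
#' `crapome_fc_min`; prey-prey association edges require a correlation above
#' `corr_r_min` at a Benjamini-Hochberg q-value below `corr_q_max`;
#' phosphosites need a localization probability of at least `loc_prob_min`;
#' protein complexes are called at subunit coverage of at least
#' `complex_coverage_min`; co-association clusters need at least
#' `cluster_min_size` members.
#'
#' @param bfdr_max Drop scored pairs with BFDR at or above this value.
#' @param crapome_freq_max Contaminant detection-fraction threshold; preys at
#'   or above it are dropped unless rescued by fold change.
#' @param crapome_fc_min Fold-change rescue threshold (strictly greater-than).
#' @param corr_q_max Prey-prey correlation q-value threshold (strictly below).
#' @param corr_r_min Prey-prey Pearson r threshold (strictly above, signed).
#' @param loc_prob_min Minimum phosphosite localization probability (kept at
#'   or above).
#' @param complex_coverage_min Minimum fraction of complex subunits identified.
#' @param cluster_min_size Minimum proteins per co-association cluster.
#' @param null_iterations Iterations for the random-topology null model.
#' @param enrichment_q_max Significance threshold for enrichment q-values.
#' @param min_baits Minimum non-zero bait profile entries for a prey to enter
#'   the correlation analysis.
#' @param prior_true Prior probability that an observed pair is a true
#'   interaction, used by the spectral-count scorer.
#' @param pseudo_rate Poisson rate floor (pseudo-count) for control means and
#'   the fold-change denominator.
#' @param rng_seed Integer seed recorded alongside results.
#'
#' @return A named list with class `rtk_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(bfdr_max = 0.01)
#' cfg$bfdr_max
pipeline_config <- function(bfdr_max = 0.05,
                            crapome_freq_max = 0.20,
                            crapome_fc_min = 3.0,
                            corr_q_max = 0.01,
                            corr_r_min = 0.70,
                            loc_prob_min = 0.75,
                            complex_coverage_min = 0.60,
                            cluster_min_size = 3L,
                            null_iterations = 100000L,
                            enrichment_q_max = 0.05,
                            min_baits = 3L,
                            prior_true = 0.05,
                            pseudo_rate = 0.1,
                            rng_seed = 1L) {
  cfg <- list(
    bfdr_max = bfdr_max,
    crapome_freq_max = crapome_freq_max,
    crapome_fc_min = crapome_fc_min,
    corr_q_max = corr_q_max,
    corr_r_min = corr_r_min,
    loc_prob_min = loc_prob_min,
    complex_coverage_min = complex_coverage_min,
    cluster_min_size = as.integer(cluster_min_size),
    null_iterations = as.integer(null_iterations),
    enrichment_q_max = enrichment_q_max,
    min_baits = as.integer(min_baits),
    prior_true = prior_true,
    pseudo_rate = pseudo_rate,
    rng_seed = as.integer(rng_seed)
  )
  probs <- c("bfdr_max", "crapome_freq_max", "corr_q_max", "loc_prob_min",
             "complex_coverage_min", "enrichment_q_max", "prior_true")
  for (p in probs) {
    v <- cfg[[p]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop_rtk(sprintf("`%s` must be a single value in [0, 1], got %s",
                       p, format(v)), class = "rtkscape_config_error")
    }
  }
  if (cfg$null_iterations < 1L) {
    stop_rtk("`null_iterations` must be at least 1",
             class = "rtkscape_config_error")
  }
  if (cfg$crapome_fc_min < 0 || cfg$pseudo_rate <= 0) {
    stop_rtk("`crapome_fc_min` must be >= 0 and `pseudo_rate` > 0",
             class = "rtkscape_config_error")
  }
  if (abs(cfg$corr_r_min) > 1) {
    stop_rtk("`corr_r_min` must lie in [-1, 1]",
             class = "rtkscape_config_error")
  }
  structure(cfg, class = "rtk_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Unknown keys are rejected so typos in config files surface immediately;
#' missing keys fall back to the [pipeline_config()] defaults.
#'
#' @param path Path to a YAML file whose top-level keys are
#'   [pipeline_config()] arguments.
#' @return An `rtk_config` list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    stop_rtk(sprintf("config file not found: %s", path),
             class = "rtkscape_io_error")
  }
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  known <- names(formals(pipeline_config))
  extra <- setdiff(names(vals), known)
  if (length(extra)) {
    stop_rtk(sprintf("unknown config keys: %s", paste(extra, collapse = ", ")),
             class = "rtkscape_config_error")
  }
  do.call(pipeline_config, vals)
}

#' @export
print.rtk_config <- function(x, ...) {
  cat("<rtk_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
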