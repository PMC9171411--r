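#' @name rtk-scoring
#' @title Spectral-count interaction scoring and the compound HCI filter
#'
#' @description Bait-prey pairs are scored from replicate spectral counts
#' with an explicit two-component Poisson model: under the background
#' hypothesis a prey's counts follow its GFP-control rate, under the
#' interaction hypothesis they follow the (higher) bait-specific rate. The
#' per-pair posterior probability of a true interaction is converted into a
#' Bayesian false discovery rate (BFDR) by cumulative averaging along the
#' posterior-descending ranking, the convention of spectral-count
#' interaction scorers. The compound high-confidence-interactor (HCI) filter
#' then drops pairs with BFDR >= 0.05 and pairs whose prey is a frequent
#' contaminant (detected in >= 20% of contaminant-repository runs) unless
#' the spectral-count fold change over the repository average exceeds 3.
NULL

#' Score bait-prey pairs from replicate spectral counts
#'
#' For each prey, the background rate is `lambda0 = max(mean GFP-control
#' count, pseudo_rate)`; for each (bait, method, condition) group the
#' interaction rate is `lambda1 = max(mean bait count, lambda0)`. Replicate
#' Poisson likelihoods under `lambda1` versus `lambda0` are combined with
#' `prior_true` into a posterior probability of interaction, pairs are
#' ranked by descending posterior within each group, and
#' `bfdr(k) = mean(1 - posterior)` over the top `k` pairs. Control means are
#' computed per method (GFP runs are condition-agnostic); missing replicate
#' observations count as zeros against the replicates present for that
#' bait run. Tables imported from pre-scored SAINT-style files are refused.
#'
#' @param counts A validated spectral-count tibble containing at least one
#'   control run (bait tag [control_tag()]).
#' @param prior_true Prior probability of a true interaction.
#' @param pseudo_rate Poisson rate floor for control means.
#' @return A tibble of scored pairs: `bait`, `prey`, `method`, `condition`,
#'   `n_replicates`, `avg_count`, `lambda0`, `posterior_true`, `bfdr`,
#'   ordered by group and descending posterior.
#' @export
#' @examples
#' tr <- simulate_interactome(n_baits = 4, n_subfamilies = 2, n_preys = 150,
#'                            edges_per_bait = 8, seed = 2)
#' sc <- score_interactions(simulate_counts(tr, seed = 2))
#' head(sc)
score_interactions <- function(counts, prior_true = 0.05,
                               pseudo_rate = 0.1) {
  if (isTRUE(attr(counts, "pre_scored"))) {
    stop_rtk(paste0(
      "this table was imported from a pre-scored SAINT-style file without ",
      "replicate structure; use its imported BFDRs instead of re-scoring"),
      class = "rtkscape_config_error")
  }
  counts <- validate_counts(counts)
  if (prior_true <= 0 || prior_true >= 1) {
    stop_rtk("prior_true must lie strictly within (0, 1)",
             class = "rtkscape_config_error")
  }
  ctrl <- counts[counts$is_control, ]
  if (nrow(ctrl) == 0) {
    stop_rtk("no control runs found (reserved bait tag missing): the scorer needs GFP controls",
             class = "rtkscape_config_error")
  }
  bait_rows <- counts[!counts$is_control, ]
  if (nrow(bait_rows) == 0) {
    return(tibble(bait = character(), prey = character(),
                  method = character(), condition = character(),
                  n_replicates = integer(), avg_count = numeric(),
                  lambda0 = numeric(), posterior_true = numeric(),
                  bfdr = numeric()))
  }

  ctrl_runs <- ctrl |>
    distinct(.data$method, .data$condition, .data$replicate) |>
    count(.data$method, name = "n_ctrl_runs")
  ctrl_mean <- ctrl |>
    group_by(.data$method, .data$prey) |>
    summarise(ctrl_total = sum(.data$spectral_count), .groups = "drop") |>
    left_join(ctrl_runs, by = "method") |>
    mutate(ctrl_mean = .data$ctrl_total / .data$n_ctrl_runs)

  n_rep <- bait_rows |>
    distinct(.data$bait, .data$method, .data$condition, .data$replicate) |>
    count(.data$bait, .data$method, .data$condition, name = "n_replicates")

  scored <- bait_rows |>
    group_by(.data$bait, .data$method, .data$condition, .data$prey) |>
    summarise(total = sum(.data$spectral_count), .groups = "drop") |>
    left_join(n_rep, by = c("bait", "method", "condition")) |>
    left_join(ctrl_mean[, c("method", "prey", "ctrl_mean")],
              by = c("method", "prey")) |>
    mutate(
      ctrl_mean = tidyr::replace_na(.data$ctrl_mean, 0),
      avg_count = .data$total / .data$n_replicates,
      lambda0 = pmax(.data$ctrl_mean, pseudo_rate),
      lambda1 = pmax(.data$avg_count, .data$lambda0),
      # log likelihood ratio summed over replicates:
      # sum(x) * log(l1/l0) - n * (l1 - l0)
      llr = .data$total * log(.data$lambda1 / .data$lambda0) -
        .data$n_replicates * (.data$lambda1 - .data$lambda0),
      posterior_true =
        1 / (1 + ((1 - prior_true) / prior_true) * exp(-.data$llr))
    ) |>
    group_by(.data$bait, .data$method, .data$condition) |>
    arrange(desc(.data$posterior_true), .data$prey, .by_group = TRUE) |>
    mutate(bfdr = bfdr_from_posterior(.data$posterior_true)) |>
    ungroup() |>
    select("bait", "prey", "method", "condition", "n_replicates",
           "avg_count", "lambda0", "posterior_true", "bfdr")
  scored
}

#' Compute the cumulative-mean Bayesian FDR from posterior probabilities
#'
#' Given posteriors ranked in scoring order, `bfdr(k)` is the mean of
#' `1 - posterior` over the top `k` entries. Exposed separately so the
#' ranking convention can be tested in isolation.
#'
#' @param posterior Numeric vector of posterior probabilities, already in
#'   descending rank order.
#' @return Numeric vector of BFDRs, same length.
#' @export
#' @examples
#' bfdr_from_posterior(c(0.99, 0.90, 0.50))
bfdr_from_posterior <- function(posterior) {
  if (any(posterior < 0 | posterior > 1, na.rm = TRUE)) {
    stop_rtk("posteriors must lie in [0, 1]",
             class = "rtkscape_validation_error")
  }
  cumsum(1 - posterior) / seq_along(posterior)
}

#' Apply the compound high-confidence-interactor filter
#'
#' Retains a scored pair iff `bfdr < bfdr_max` *and* (contaminant detection
#' fraction `< crapome_freq_max` *or* spectral-count fold change
#' `> crapome_fc_min`). The fold change is the pair's average spectral count
#' divided by the contaminant-repository average for the prey, floored at
#' `config$pseudo_rate` so preys absent from the repository (treated as
#' frequency 0) never divide by zero. Boundary semantics are strict as
#' published: a pair at exactly `bfdr = bfdr_max` is dropped, a prey at
#' exactly `crapome_freq_max` needs the fold-change rescue, and a fold
#' change exactly at `crapome_fc_min` does not rescue.
#'
#' @param scored Scored-pair tibble from [score_interactions()] (or any
#'   table with `bait`, `prey`, `avg_count`, `bfdr`).
#' @param crapome Contaminant-frequency tibble (`prey`,
#'   `detection_fraction`, `mean_spectral_count`); preys missing from it get
#'   frequency 0.
#' @param config An [pipeline_config()] list.
#' @param keep_all If `TRUE`, return every input row with a logical
#'   `retained` column instead of only the retained rows.
#' @return The retained rows (or all rows when `keep_all`), with
#'   `crapome_frequency`, `crapome_fold_change` and (if `keep_all`)
#'   `retained` appended.
#' @export
apply_hci_filter <- function(scored, crapome, config = pipeline_config(),
                             keep_all = FALSE) {
  out <- as_tibble(scored) |>
    left_join(crapome |>
                select(crapome_frequency = "detection_fraction",
                       crapome_mean = "mean_spectral_count", "prey"),
              by = "prey") |>
    mutate(
      crapome_frequency = tidyr::replace_na(.data$crapome_frequency, 0),
      crapome_mean = tidyr::replace_na(.data$crapome_mean, 0),
      crapome_fold_change =
        .data$avg_count / pmax(.data$crapome_mean, config$pseudo_rate),
      retained = .data$bfdr < config$bfdr_max &
        (.data$crapome_frequency < config$crapome_freq_max |
           .data$crapome_fold_change > config$crapome_fc_min)
    ) |>
    select(-"crapome_mean")
  if (keep_all) out else select(filter(out, .data$retained), -"retained")
}

#' Merge AP-MS and BioID high-confidence interactors
#'
#' Pairs surviving the filter in both strata are labeled `BOTH`; the three
#' detection classes partition the merged set. Each merged record is flagged
#' against the known-interaction database (canonical undirected lookup) and
#' carries the supporting source names.
#'
#' @param apms_hcis,bioid_hcis Filtered scored tibbles for each stratum.
#' @param known_db Canonical known-interaction tibble (see
#'   [read_known_db()]); `NULL` marks everything novel.
#' @return An HCI tibble: `bait`, `prey`, `detection`, `avg_count_apms`,
#'   `avg_count_bioid`, `bfdr_apms`, `bfdr_bioid`, `known`, `known_sources`
#'   (list), `n_known_sources`.
#' @export
merge_strata <- function(apms_hcis, bioid_hcis, known_db = NULL) {
  pick <- function(x, suffix) {
    x |>
      select("bait", "prey", "avg_count", "bfdr") |>
      rename(!!paste0("avg_count_", suffix) := "avg_count",
             !!paste0("bfdr_", suffix) := "bfdr")
  }
  merged <- full_join(pick(apms_hcis, "apms"), pick(bioid_hcis, "bioid"),
                      by = c("bait", "prey")) |>
    mutate(detection = dplyr::case_when(
      !is.na(.data$avg_count_apms) & !is.na(.data$avg_count_bioid) ~ "BOTH",
      !is.na(.data$avg_count_apms) ~ "APMS_ONLY",
      TRUE ~ "BIOID_ONLY"
    ))
  merged <- annotate_known(merged, known_db)
  merged |>
    select("bait", "prey", "detection", "avg_count_apms", "avg_count_bioid",
           "bfdr_apms", "bfdr_bioid", "known", "known_sources",
           "n_known_sources") |>
    arrange(.data$bait, .data$prey)
}

annotate_known <- function(pairs, known_db) {
  if (is.null(known_db) || nrow(known_db) == 0) {
    return(mutate(pairs, known = FALSE,
                  known_sources = purrr::map(seq_len(dplyr::n()),
                                             ~ character()),
                  n_known_sources = 0L))
  }
  cp <- canonical_pair(pairs$bait, pairs$prey)
  key <- paste(cp$a, cp$b, sep = "\r")
  db_key <- paste(known_db$a, known_db$b, sep = "\r")
  i <- match(key, db_key)
  pairs$known <- !is.na(i)
  pairs$known_sources <- purrr::map(i, function(j) {
    if (is.na(j)) character() else known_db$sources[[j]]
  })
  pairs$n_known_sources <- purrr::map_int(pairs$known_sources, length)
  pairs
}

#' Compare the interactomes of two conditions
#'
#' Splits two filtered interaction tables (same baits, e.g. pervanadate
#' versus ligand activation) into shared and condition-specific pairs and
#' computes the Pearson product-moment correlation of per-pair average
#' spectral counts over the shared pairs. With fewer than 3 shared pairs the
#' correlation is undefined and reported as `NA`.
#'
#' @param hcis_a,hcis_b Tibbles with `bait`, `prey`, `avg_count`.
#' @param label_a,label_b Condition labels used in the output.
#' @return A list of class `rtk_condition_comparison`: `shared` (tibble with
#'   both average counts), `a_only`, `b_only`, `r`, `labels`.
#' @export
compare_conditions <- function(hcis_a, hcis_b, label_a = "A", label_b = "B") {
  a <- distinct(as_tibble(hcis_a)[, c("bait", "prey", "avg_count")])
  b <- distinct(as_tibble(hcis_b)[, c("bait", "prey", "avg_count")])
  shared <- inner_join(a, b, by = c("bait", "prey"),
                       suffix = c("_a", "_b"))
  a_only <- anti_join(a, b, by = c("bait", "prey"))
  b_only <- anti_join(b, a, by = c("bait", "prey"))
  r <- if (nrow(shared) < 3) {
    inform("fewer than 3 shared pairs: correlation undefined, reported as NA")
    NA_real_
  } else if (sd(shared$avg_count_a) == 0 || sd(shared$avg_count_b) == 0) {
    NA_real_
  } else {
    cor(shared$avg_count_a, shared$avg_count_b, method = "pearson")
  }
  structure(list(shared = shared, a_only = a_only, b_only = b_only, r = r,
                 labels = c(label_a, label_b)),
            class = "rtk_condition_comparison")
}

#' @export
print.rtk_condition_comparison <- function(x, ...) {
  cat(sprintf(
    "<rtk_condition_comparison> %s vs %s: %d shared, %d %s-only, %d %s-only, Pearson r = %s\n",
    x$labels[1], x$labels[2], nrow(x$shared), nrow(x$a_only), x$labels[1],
    nrow(x$b_only), x$labels[2],
    ifelse(is.na(x$r), "NA", format(round(x$r, 3)))))
  invisible(x)
}

#' @export
glance.rtk_condition_comparison <- function(x, ...) {
  tibble(n_shared = nrow(x$shared), n_a_only = nrow(x$a_only),
         n_b_only = nrow(x$b_only), pearson_r = x$r)
}
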