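#' @name rtk-pipeline
#' @title End-to-end synthetic-study pipeline
NULL

#' Run the full analysis chain on a simulated study
#'
#' Generates a synthetic study (planted interactome, WT and KD spectral
#' counts, contaminant frequencies, known-interaction database, annotations
#' and phosphosites), then runs scoring, the compound HCI filter, stratum
#' merging, network statistics with the random-topology null, prey-prey
#' correlation clustering with complex calls, annotation enrichment, KD/WT
#' comparison and the phosphosite analyses. Identical `config` and `seed`
#' give identical results; with `out_dir` set, all stage outputs are written
#' as pipeline-dialect TSVs plus a JSON run report whose counts equal the
#' written row counts.
#'
#' @param config A [pipeline_config()] list; `config$rng_seed` seeds the
#'   whole run.
#' @param stages Subset of
#'   `c("interactome", "network", "coassociation", "enrichment", "phospho")`
#'   to execute. Stages needing a missing upstream stage raise an error
#'   before anything runs.
#' @param sim Named list of overrides forwarded to [simulate_study()].
#' @param out_dir Optional output directory for TSV/JSON exports.
#' @return An object of class `rtk_report`; see `print()` and `glance()`.
#' @export
run_rtk_pipeline <- function(config = pipeline_config(),
                             stages = c("interactome", "network",
                                        "coassociation", "enrichment",
                                        "phospho"),
                             sim = list(), out_dir = NULL) {
  stages <- match.arg(stages, several.ok = TRUE)
  needs_interactome <- c("network", "coassociation", "enrichment")
  if (any(needs_interactome %in% stages) && !"interactome" %in% stages) {
    stop_rtk(sprintf(
      "stage(s) %s require the interactome stage",
      paste(intersect(needs_interactome, stages), collapse = ", ")),
      class = "rtkscape_config_error")
  }
  seed <- config$rng_seed
  bundle <- do.call(simulate_study,
                    modifyList(list(seed = seed, kd = TRUE), sim))
  res <- list(config = config, seed = seed, truth = bundle$truth)

  if ("interactome" %in% stages) {
    scored <- score_interactions(bundle$counts_wt,
                                 prior_true = config$prior_true,
                                 pseudo_rate = config$pseudo_rate)
    hci <- apply_hci_filter(scored, bundle$crapome, config)
    merged <- merge_strata(hci[hci$method == "APMS", ],
                           hci[hci$method == "BIOID", ],
                           bundle$known_db)
    scored_kd <- score_interactions(bundle$counts_kd,
                                    prior_true = config$prior_true,
                                    pseudo_rate = config$pseudo_rate)
    hci_kd <- apply_hci_filter(scored_kd, bundle$crapome, config)
    res$scored <- scored
    res$hcis <- merged
    res$hcis_kd <- hci_kd
    pair_avg <- function(x) {
      x |>
        group_by(.data$bait, .data$prey) |>
        summarise(avg_count = mean(.data$avg_count), .groups = "drop")
    }
    res$kd_wt <- compare_conditions(pair_avg(hci), pair_avg(hci_kd),
                                    label_a = "WT", label_b = "KD")
  }

  if ("network" %in% stages) {
    network <- build_interactome(res$hcis,
                                 prey_universe = unique(res$scored$prey),
                                 bait_set = bundle$truth$baits)
    res$network <- network
    res$known_histogram <- known_source_histogram(network, bundle$known_db)
    res$null <- random_topology_null(network, bundle$known_db,
                                     n_iterations = config$null_iterations,
                                     seed = seed)
    res$rtk_rtk <- extract_rtk_rtk(network)
    res$sharing <- subfamily_sharing(network, bundle$truth$subfamilies)
    first_bait <- bundle$truth$baits[1]
    res$kd_term_fc <- kd_wt_term_foldchange(
      res$hcis_kd[res$hcis_kd$bait == first_bait, ],
      res$hcis[res$hcis$bait == first_bait, ],
      bundle$annotations$terms)
  }

  if ("coassociation" %in% stages) {
    assoc <- purrr::map(c(APMS = "APMS", BIOID = "BIOID"), function(s) {
      mat <- prey_profile_matrix(res$hcis, bundle$counts_wt, stratum = s,
                                 min_baits = config$min_baits)
      if (nrow(mat) < 2) {
        return(list(edges = tibble(prey_a = character(),
                                   prey_b = character(), r = numeric(),
                                   p = numeric(), q = numeric(),
                                   stratum = character()),
                    clusters = extract_clusters(
                      tibble(prey_a = character(), prey_b = character(),
                             stratum = character()),
                      config$cluster_min_size)))
      }
      edges <- correlate_preys(mat, config, stratum = s)
      list(edges = edges,
           clusters = extract_clusters(edges, config$cluster_min_size))
    })
    res$assoc_edges <- bind_rows(purrr::map(assoc, "edges"))
    res$clusters <- bind_rows(purrr::map(assoc, "clusters"))
    cluster_members <- unique(unlist(res$clusters$members))
    res$complex_calls <- complex_coverage(cluster_members,
                                          bundle$annotations$complexes,
                                          config)
  }

  if ("enrichment" %in% stages) {
    background <- unique(res$scored$prey)
    query <- intersect(unique(res$hcis$prey), background)
    res$enrichment <- fisher_enrichment(query, background,
                                        bundle$annotations$terms, config)
    res$domains <- domain_count_summary(res$hcis, bundle$annotations$terms)
  }

  if ("phospho" %in% stages) {
    ph <- bundle$phospho
    filtered <- filter_sites(ph$sites, ph$control_sites, config)
    res$phospho_sites <- filtered
    res$phospho_tab <- tabulate_relations(filtered)
    res$motif_profile <- site_motif_profile(filtered, ph$motifs)
    res$dendrogram <- cluster_substrate_profiles(filtered)
  }

  report <- build_report(res, stages)
  res$report <- report
  out <- structure(res, class = "rtk_report")
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

build_report <- function(res, stages) {
  rep <- list(seed = res$seed, stages = stages,
              thresholds = unclass(res$config),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(res$hcis)) {
    det <- count(res$hcis, .data$detection)
    rep$n_scored <- nrow(res$scored)
    rep$n_hcis <- nrow(res$hcis)
    rep$detection_counts <- setNames(as.integer(det$n), det$detection)
  }
  if (!is.null(res$null)) {
    rep$null_mean <- res$null$mean
    rep$null_expected <- res$null$expected
    rep$known_observed <- res$null$observed
    rep$null_empirical_p <- res$null$empirical_p
    rep$n_rtk_rtk_edges <- nrow(res$rtk_rtk)
    rep$sharing_counts <- setNames(as.integer(res$sharing$counts$n),
                                   res$sharing$counts$class)
  }
  if (!is.null(res$clusters)) {
    rep$n_assoc_edges <- nrow(res$assoc_edges)
    rep$n_clusters <- nrow(res$clusters)
    rep$n_complex_calls <- nrow(res$complex_calls)
  }
  if (!is.null(res$enrichment)) {
    rep$n_enriched_terms <- sum(res$enrichment$significant)
  }
  if (!is.null(res$phospho_tab)) {
    rep$phospho <- res$phospho_tab[c("n_unique_sites", "n_pairs",
                                     "n_relations")]
  }
  rep
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(x, name) {
    if (!is.null(x) && is.data.frame(x)) {
      write_rtk_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  w(res$scored, "scored_interactions")
  w(res$hcis, "hcis")
  w(res$rtk_rtk, "rtk_rtk_edges")
  w(res$assoc_edges, "association_edges")
  w(res$clusters, "clusters")
  w(res$complex_calls, "complex_calls")
  w(res$enrichment, "enrichment")
  w(res$phospho_sites, "phosphosites_filtered")
  if (!is.null(res$dendrogram)) {
    writeLines(res$dendrogram$newick,
               file.path(out_dir, "kinase_dendrogram.nwk"))
  }
  report <- res$report
  report$timestamp <- NULL  # byte-identical outputs under a fixed seed
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}

#' @export
print.rtk_report <- function(x, ...) {
  r <- x$report
  cat(sprintf("<rtk_report> seed %d; stages: %s\n", r$seed,
              paste(r$stages, collapse = ", ")))
  if (!is.null(r$n_hcis)) {
    cat(sprintf("  scored pairs: %d; HCIs: %d (%s)\n", r$n_scored, r$n_hcis,
                paste(sprintf("%s %d", names(r$detection_counts),
                              r$detection_counts), collapse = ", ")))
  }
  if (!is.null(r$null_mean)) {
    cat(sprintf(
      "  known HCI pairs: %d observed vs null mean %.2f (p = %.2g); RTK-RTK edges: %d\n",
      r$known_observed, r$null_mean, r$null_empirical_p, r$n_rtk_rtk_edges))
  }
  if (!is.null(r$n_clusters)) {
    cat(sprintf("  association edges: %d; clusters: %d; complex calls: %d\n",
                r$n_assoc_edges, r$n_clusters, r$n_complex_calls))
  }
  if (!is.null(r$n_enriched_terms)) {
    cat(sprintf("  enriched terms (q < %.2g): %d\n",
                x$config$enrichment_q_max, r$n_enriched_terms))
  }
  if (!is.null(r$phospho)) {
    cat(sprintf(
      "  phospho: %d unique sites, %d kinase-substrate pairs, %d site relations\n",
      r$phospho$n_unique_sites, r$phospho$n_pairs, r$phospho$n_relations))
  }
  invisible(x)
}

#' @export
glance.rtk_report <- function(x, ...) {
  r <- x$report
  tibble(
    seed = r$seed,
    n_scored = r$n_scored %||% NA_integer_,
    n_hcis = r$n_hcis %||% NA_integer_,
    known_observed = r$known_observed %||% NA_integer_,
    null_mean = r$null_mean %||% NA_real_,
    n_rtk_rtk_edges = r$n_rtk_rtk_edges %||% NA_integer_,
    n_clusters = r$n_clusters %||% NA_integer_,
    n_enriched_terms = r$n_enriched_terms %||% NA_integer_,
    n_unique_phosphosites = r$phospho$n_unique_sites %||% NA_integer_
  )
}
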