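#' @name rtk-network
#' @title Interactome construction, known-interaction mapping and the
#'   random-topology null
NULL

#' Build an interactome object from merged HCI records
#'
#' @param hcis Merged HCI tibble (see [merge_strata()]).
#' @param prey_universe Character vector of all proteins identified *before*
#'   any filtering; this is the background set for enrichment and the
#'   sampling pool of the random-network null.
#' @param bait_set Baits in the design; defaults to the baits present in
#'   `hcis`.
#' @return A list of class `rtk_interactome`: `hcis`, `bait_set`,
#'   `prey_universe`, `degrees` (tibble bait/degree).
#' @export
build_interactome <- function(hcis, prey_universe, bait_set = NULL) {
  hcis <- as_tibble(hcis)
  if (is.null(bait_set)) bait_set <- sort(unique(hcis$bait))
  if (!all(hcis$bait %in% bait_set)) {
    stop_rtk("every HCI bait must belong to bait_set",
             class = "rtkscape_validation_error")
  }
  if (!length(prey_universe)) {
    stop_rtk("prey_universe must be non-empty",
             class = "rtkscape_validation_error")
  }
  degrees <- hcis |>
    distinct(.data$bait, .data$prey) |>
    count(.data$bait, name = "degree")
  structure(list(hcis = hcis, bait_set = bait_set,
                 prey_universe = unique(prey_universe), degrees = degrees),
            class = "rtk_interactome")
}

#' @export
print.rtk_interactome <- function(x, ...) {
  cat(sprintf(
    "<rtk_interactome> %d HCIs over %d baits; background universe of %d proteins\n",
    nrow(x$hcis), length(x$bait_set), length(x$prey_universe)))
  invisible(x)
}

#' Histogram of HCIs by number of supporting known-interaction sources
#'
#' Bin 0 counts novel interactions; bins 1..`max_sources` count pairs by how
#' many of the merged source databases report them.
#'
#' @param network An `rtk_interactome` (or an HCI tibble).
#' @param known_db Canonical known-interaction tibble.
#' @param max_sources Highest bin to report (default 6 sources).
#' @return A tibble with `n_sources` (0..max) and `n_hcis`; bins partition
#'   the HCI set.
#' @export
known_source_histogram <- function(network, known_db, max_sources = 6L) {
  hcis <- if (inherits(network, "rtk_interactome")) network$hcis
          else as_tibble(network)
  ann <- annotate_known(hcis[, c("bait", "prey")], known_db)
  top <- max(max_sources, ann$n_known_sources)
  tibble(n_sources = 0:top) |>
    left_join(count(ann, n_sources = .data$n_known_sources, name = "n_hcis"),
              by = "n_sources") |>
    mutate(n_hcis = as.integer(tidyr::replace_na(.data$n_hcis, 0L)))
}

#' Topology-preserving random-network null for known-interaction counts
#'
#' Each iteration keeps every bait's degree and redraws its preys uniformly
#' without replacement from the pre-filter background universe; the
#' iteration statistic is the number of redrawn bait-prey pairs present in
#' the known-interaction database (prey-prey coincidences are not counted).
#' For one bait the number of hits among `d_b` uniform draws without
#' replacement from a universe containing `K_b` known partners is exactly
#' hypergeometric, so iterations are drawn with [stats::rhyper()] per bait --
#' distributionally identical to redrawing prey identities and far faster at
#' the published scale of 100,000 iterations. The empirical p-value for the
#' observed known count uses the add-one estimator `(r + 1) / (n + 1)`.
#'
#' @param network An `rtk_interactome`.
#' @param known_db Canonical known-interaction tibble.
#' @param n_iterations Number of random networks.
#' @param seed Integer seed.
#' @return An object of class `rtk_null`: `counts` (integer vector),
#'   `mean`, `observed`, `expected` (analytic mean), `empirical_p`,
#'   `n_iterations`, `seed`.
#' @export
random_topology_null <- function(network, known_db,
                                 n_iterations = 100000L, seed = 1L) {
  stopifnot(inherits(network, "rtk_interactome"))
  if (n_iterations < 1L) {
    stop_rtk("n_iterations must be at least 1",
             class = "rtkscape_config_error")
  }
  universe <- network$prey_universe
  n_univ <- length(universe)
  if (any(network$degrees$degree > n_univ)) {
    stop_rtk("a bait's degree exceeds the background universe size",
             class = "rtkscape_config_error")
  }
  set.seed(seed)

  # Known partners of each bait within the universe.
  kdb <- known_db
  partners_of <- function(bait) {
    p <- c(kdb$b[kdb$a == bait], kdb$a[kdb$b == bait])
    sum(unique(p) %in% universe)
  }
  deg <- network$degrees
  deg$k_known <- purrr::map_int(deg$bait, partners_of)

  counts <- integer(n_iterations)
  for (i in seq_len(nrow(deg))) {
    counts <- counts + rhyper(n_iterations, deg$k_known[i],
                              n_univ - deg$k_known[i], deg$degree[i])
  }

  obs_pairs <- distinct(network$hcis[, c("bait", "prey")])
  observed <- sum(annotate_known(obs_pairs, known_db)$known)
  expected <- sum(deg$degree * deg$k_known) / n_univ

  structure(list(
    counts = counts,
    mean = mean(counts),
    observed = observed,
    expected = expected,
    empirical_p = (sum(counts >= observed) + 1) / (n_iterations + 1),
    n_iterations = as.integer(n_iterations),
    seed = as.integer(seed)
  ), class = "rtk_null")
}

#' @export
print.rtk_null <- function(x, ...) {
  cat(sprintf(
    "<rtk_null> %d iterations: mean known pairs %.3f (analytic %.3f); observed %d, empirical p = %.3g\n",
    x$n_iterations, x$mean, x$expected, x$observed, x$empirical_p))
  invisible(x)
}

#' @export
tidy.rtk_null <- function(x, ...) {
  tibble(iteration = seq_along(x$counts), known_pairs = x$counts)
}

#' @export
glance.rtk_null <- function(x, ...) {
  tibble(n_iterations = x$n_iterations, mean = x$mean,
         expected = x$expected, observed = x$observed,
         empirical_p = x$empirical_p)
}

detection_strata <- function(detection) {
  purrr::map(detection, function(d) {
    switch(d,
           APMS_ONLY = "APMS",
           BIOID_ONLY = "BIOID",
           BOTH = c("APMS", "BIOID"),
           stop_rtk(sprintf("unknown detection label '%s'", d),
                    class = "rtkscape_validation_error"))
  })
}

#' Extract the undirected bait-bait (RTK-RTK) subnetwork
#'
#' Keeps HCIs whose prey is itself a bait, merges the two directions of each
#' pair into one undirected edge and recomputes the detection label on the
#' union of the merged records' strata (a pair seen AP-MS-only in one
#' direction and BioID-only in the other is labeled `BOTH`).
#'
#' @param network An `rtk_interactome` or HCI tibble.
#' @param bait_set Baits defining the subnetwork; defaults to the network's.
#' @return A tibble of undirected edges: `a`, `b`, `detection`.
#' @export
extract_rtk_rtk <- function(network, bait_set = NULL) {
  hcis <- if (inherits(network, "rtk_interactome")) network$hcis
          else as_tibble(network)
  if (is.null(bait_set)) {
    bait_set <- if (inherits(network, "rtk_interactome")) network$bait_set
                else sort(unique(hcis$bait))
  }
  bb <- hcis[hcis$prey %in% bait_set, , drop = FALSE]
  if (nrow(bb) == 0) {
    return(tibble(a = character(), b = character(), detection = character()))
  }
  cp <- canonical_pair(bb$bait, bb$prey)
  bb$a <- cp$a
  bb$b <- cp$b
  bb$strata <- detection_strata(bb$detection)
  bb |>
    group_by(.data$a, .data$b) |>
    summarise(strata = list(sort(unique(unlist(.data$strata)))),
              .groups = "drop") |>
    mutate(detection = purrr::map_chr(.data$strata, function(s) {
      if (length(s) == 2) "BOTH"
      else if (s == "APMS") "APMS_ONLY"
      else "BIOID_ONLY"
    })) |>
    select("a", "b", "detection") |>
    arrange(.data$a, .data$b)
}

#' Partition preys by subfamily sharing
#'
#' A prey seen with exactly one bait is `unique`; a prey whose two or more
#' baits all belong to one subfamily is `shared_within`; a prey whose baits
#' span two or more subfamilies is `shared_across`. The three classes
#' partition the distinct preys.
#'
#' @param network An `rtk_interactome` or HCI tibble.
#' @param subfamily_map Tibble with `rtk`, `subfamily`, total over the baits.
#' @return A list with `per_prey` (tibble prey/n_baits/n_subfamilies/class)
#'   and `counts` (tibble class/n).
#' @export
subfamily_sharing <- function(network, subfamily_map) {
  hcis <- if (inherits(network, "rtk_interactome")) network$hcis
          else as_tibble(network)
  missing_baits <- setdiff(unique(hcis$bait), subfamily_map$rtk)
  if (length(missing_baits)) {
    stop_rtk(sprintf("baits missing from subfamily map: %s",
                     paste(missing_baits, collapse = ", ")),
             class = "rtkscape_validation_error")
  }
  per_prey <- hcis |>
    distinct(.data$bait, .data$prey) |>
    left_join(subfamily_map, by = c(bait = "rtk")) |>
    group_by(.data$prey) |>
    summarise(n_baits = dplyr::n_distinct(.data$bait),
              n_subfamilies = dplyr::n_distinct(.data$subfamily),
              .groups = "drop") |>
    mutate(class = dplyr::case_when(
      .data$n_baits == 1L ~ "unique",
      .data$n_subfamilies == 1L ~ "shared_within",
      TRUE ~ "shared_across"
    ))
  counts <- per_prey |>
    count(.data$class, name = "n") |>
    tidyr::complete(class = c("unique", "shared_within", "shared_across"),
                    fill = list(n = 0L))
  list(per_prey = per_prey, counts = counts)
}

#' Per-term log2 fold change of a kinase-dead versus wild-type interactome
#'
#' For each annotation term, compares the proportion of term-annotated
#' interactors in the KD interactome against the WT interactome of the same
#' bait: `log2(((k_KD + pseudo) / (n_KD + pseudo)) /
#' ((k_WT + pseudo) / (n_WT + pseudo)))`, where `k` counts annotated
#' interactors and `n` the interactome size. The WT interactome is the
#' background set.
#'
#' @param kd_hcis,wt_hcis Tibbles with a `prey` column (HCIs of one bait in
#'   the two conditions).
#' @param annotations Annotation collection tibble (see [read_gmt()]).
#' @param pseudo Pseudo-count guarding empty terms.
#' @return A tibble: `term_id`, `name`, `k_kd`, `n_kd`, `k_wt`, `n_wt`,
#'   `log2_fc`, sorted by descending absolute fold change.
#' @export
kd_wt_term_foldchange <- function(kd_hcis, wt_hcis, annotations,
                                  pseudo = 1) {
  wt <- unique(as_tibble(wt_hcis)$prey)
  kd <- unique(as_tibble(kd_hcis)$prey)
  if (!length(wt)) {
    stop_rtk("WT interactome is empty: fold change undefined",
             class = "rtkscape_validation_error")
  }
  n_kd <- length(kd)
  n_wt <- length(wt)
  annotations |>
    mutate(k_kd = purrr::map_int(.data$members, ~ sum(kd %in% .x)),
           k_wt = purrr::map_int(.data$members, ~ sum(wt %in% .x)),
           n_kd = n_kd, n_wt = n_wt,
           log2_fc = log2(((.data$k_kd + pseudo) / (n_kd + pseudo)) /
                            ((.data$k_wt + pseudo) / (n_wt + pseudo)))) |>
    select("term_id", "name", "k_kd", "n_kd", "k_wt", "n_wt", "log2_fc") |>
    arrange(desc(abs(.data$log2_fc)), .data$term_id)
}
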