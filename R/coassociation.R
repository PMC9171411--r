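#' @name rtk-coassociation
#' @title Prey-prey co-purification correlation network and complex calling
#'
#' @description Preys that are parts of the same complex are purified
#' together across baits, so their average-spectral-count profiles over the
#' bait panel correlate. Profiles are correlated pairwise (Pearson, over the
#' full bait panel including zeros), p-values come from the standard
#' t-transform, q-values from Benjamini-Hochberg across all computed pairs,
#' and edges are retained at signed r > 0.7 and q < 0.01. Connected
#' components of the retained-edge graph with at least 3 members are the
#' co-association clusters, which are then matched against curated complex
#' definitions at >= 60% subunit coverage.
NULL

#' Build the prey-by-bait average-count profile matrix
#'
#' Entry (prey, bait) is the prey's average spectral count under that bait if
#' the pair is an HCI in the requested stratum, else 0. Preys with fewer than
#' `min_baits` non-zero entries are dropped (their correlations would be
#' degenerate).
#'
#' @param hcis Merged HCI tibble with a `detection` column.
#' @param counts Spectral-count tibble covering the HCIs' baits.
#' @param stratum `"APMS"` or `"BIOID"`.
#' @param min_baits Minimum non-zero profile entries per prey.
#' @return A numeric matrix, rows = preys, columns = baits.
#' @export
prey_profile_matrix <- function(hcis, counts, stratum = c("APMS", "BIOID"),
                                min_baits = 3L) {
  stratum <- match.arg(stratum)
  wanted <- c(paste0(stratum, "_ONLY"), "BOTH")
  hh <- as_tibble(hcis) |>
    filter(.data$detection %in% wanted) |>
    distinct(.data$bait, .data$prey)
  baits <- sort(unique(as_tibble(hcis)$bait))
  if (nrow(hh) == 0) {
    return(matrix(numeric(), nrow = 0, ncol = length(baits),
                  dimnames = list(NULL, baits)))
  }
  counts <- as_tibble(counts)
  cc <- counts[!counts$bait %in% control_tag() &
                 counts$method == stratum, ]
  n_rep <- cc |>
    distinct(.data$bait, .data$replicate) |>
    count(.data$bait, name = "n_replicates")
  avg <- cc |>
    group_by(.data$bait, .data$prey) |>
    summarise(total = sum(.data$spectral_count), .groups = "drop") |>
    left_join(n_rep, by = "bait") |>
    mutate(avg_count = .data$total / .data$n_replicates)
  prof <- hh |>
    left_join(avg[, c("bait", "prey", "avg_count")],
              by = c("bait", "prey")) |>
    mutate(avg_count = tidyr::replace_na(.data$avg_count, 0))
  preys <- sort(unique(prof$prey))
  mat <- matrix(0, nrow = length(preys), ncol = length(baits),
                dimnames = list(preys, baits))
  mat[cbind(prof$prey, prof$bait)] <- prof$avg_count
  keep <- rowSums(mat > 0) >= min_baits
  mat[keep, , drop = FALSE]
}

#' Correlate prey profiles into an association edge list
#'
#' All unordered row pairs are scored with the Pearson product-moment
#' correlation over all baits (zeros included); two-sided p-values use the
#' t-transform with n - 2 degrees of freedom; q-values are
#' Benjamini-Hochberg across all computed pairs (the same routine as the
#' enrichment module). Edges with signed r > `config$corr_r_min` and
#' q < `config$corr_q_max` are retained, so anti-correlations are excluded.
#' Zero-variance rows are skipped with a warning.
#'
#' @param mat Profile matrix from [prey_profile_matrix()] (>= 2 rows,
#'   >= 3 columns).
#' @param config A [pipeline_config()] list.
#' @param stratum Stratum label attached to the edges.
#' @param keep_all Return all computed pairs with a `retained` flag instead
#'   of only retained edges.
#' @return A tibble of association edges: `prey_a`, `prey_b` (canonical
#'   order), `r`, `p`, `q`, `stratum`.
#' @export
correlate_preys <- function(mat, config = pipeline_config(),
                            stratum = "APMS", keep_all = FALSE) {
  if (nrow(mat) < 2 || ncol(mat) < 3) {
    stop_rtk("profile matrix needs at least 2 preys and 3 baits",
             class = "rtkscape_config_error")
  }
  sds <- apply(mat, 1, sd)
  if (any(sds == 0)) {
    warn(sprintf("skipping %d zero-variance profile(s)", sum(sds == 0)),
         class = "rtkscape_zero_variance")
    mat <- mat[sds > 0, , drop = FALSE]
    if (nrow(mat) < 2) {
      return(tibble(prey_a = character(), prey_b = character(),
                    r = numeric(), p = numeric(), q = numeric(),
                    stratum = character()))
    }
  }
  n <- ncol(mat)
  cm <- cor(t(mat), method = "pearson")
  idx <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[idx]
  df <- n - 2
  tstat <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df)
  p[abs(r) >= 1] <- 0
  rn <- rownames(mat)
  cp <- canonical_pair(rn[idx[, 1]], rn[idx[, 2]])
  out <- tibble(prey_a = cp$a, prey_b = cp$b, r = r, p = p,
                q = benjamini_hochberg(p), stratum = stratum) |>
    mutate(retained = .data$r > config$corr_r_min &
             .data$q < config$corr_q_max) |>
    arrange(.data$prey_a, .data$prey_b)
  if (keep_all) out else select(filter(out, .data$retained), -"retained")
}

#' Extract co-association clusters from retained edges
#'
#' Clusters are the connected components of the retained-edge graph;
#' components smaller than `min_size` are discarded. Clusters within a
#' stratum are disjoint by construction and each induces a connected
#' subgraph.
#'
#' @param edges Association-edge tibble (one stratum).
#' @param min_size Minimum cluster size.
#' @return A tibble: `cluster_id`, `members` (list), `size`, `stratum`.
#' @export
extract_clusters <- function(edges, min_size = 3L) {
  if (nrow(edges) == 0) {
    return(tibble(cluster_id = character(), members = list(),
                  size = integer(), stratum = character()))
  }
  stratum <- unique(edges$stratum)
  if (length(stratum) > 1) {
    stop_rtk("edges must come from a single stratum",
             class = "rtkscape_validation_error")
  }
  g <- igraph::graph_from_data_frame(
    edges[, c("prey_a", "prey_b")], directed = FALSE)
  comp <- igraph::components(g)
  memb <- split(names(comp$membership), comp$membership)
  memb <- memb[purrr::map_int(memb, length) >= min_size]
  memb <- memb[order(-purrr::map_int(memb, length),
                     purrr::map_chr(memb, ~ sort(.x)[1]))]
  tibble(
    cluster_id = sprintf("%s_C%02d", stratum, seq_along(memb)),
    members = purrr::map(unname(memb), sort),
    size = purrr::map_int(memb, length),
    stratum = stratum %||% NA_character_
  )
}

#' Call curated complexes covered by an identified protein set
#'
#' Coverage is the fraction of a complex's subunits present in
#' `protein_set`. Complexes under `config$complex_coverage_min` are dropped
#' ("less than 60% identified" semantics: exactly 60% is kept); the
#' remainder is accepted greedily in order of coverage (descending), subunit
#' count (descending) and complex id (ascending), rejecting any complex that
#' shares an *identified* subunit with an already-accepted one, so the more
#' complete of two overlapping complexes wins.
#'
#' @param protein_set Character vector of identified proteins (e.g. cluster
#'   members).
#' @param corum_collection Complex tibble from [read_corum()] (or
#'   [simulate_annotations()]), complexes with >= 2 subunits.
#' @param config A [pipeline_config()] list.
#' @return A tibble of accepted complex calls: `complex_id`, `name`,
#'   `n_subunits`, `identified_subunits` (list), `n_identified`, `coverage`.
#' @export
complex_coverage <- function(protein_set, corum_collection,
                             config = pipeline_config()) {
  protein_set <- unique(protein_set)
  calls <- as_tibble(corum_collection) |>
    mutate(identified_subunits =
             purrr::map(.data$subunits, ~ sort(intersect(.x, protein_set))),
           n_identified = purrr::map_int(.data$identified_subunits, length),
           coverage = .data$n_identified / .data$n_subunits) |>
    filter(.data$coverage >= config$complex_coverage_min,
           .data$n_identified > 0) |>
    arrange(desc(.data$coverage), desc(.data$n_subunits), .data$complex_id)
  if (nrow(calls) == 0) {
    return(tibble(complex_id = character(), name = character(),
                  n_subunits = integer(), identified_subunits = list(),
                  n_identified = integer(), coverage = numeric()))
  }
  taken <- character(0)
  accept <- logical(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    ids <- calls$identified_subunits[[i]]
    if (!any(ids %in% taken)) {
      accept[i] <- TRUE
      taken <- c(taken, ids)
    }
  }
  calls[accept, c("complex_id", "name", "n_subunits", "identified_subunits",
                  "n_identified", "coverage")]
}
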