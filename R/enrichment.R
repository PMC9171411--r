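#' @name rtk-enrichment
#' @title Fisher exact annotation enrichment with Benjamini-Hochberg control
#'
#' @description One shared statistical engine for every annotation analysis
#' in the pipeline: right-tail Fisher exact (hypergeometric) enrichment of a
#' query protein set against a configurable background, fold change
#' `(k/n) / (K/N)`, and Benjamini-Hochberg q-values computed within one
#' collection per query (the multiple-testing family is the annotation
#' collection). The default background is the set of all proteins identified
#' before any filtering; a whole-proteome background can be supplied to
#' mirror reference-proteome fold changes. Only enrichment (not depletion)
#' is tested.
NULL

#' Benjamini-Hochberg step-up q-values
#'
#' Implements the step-up definition directly:
#' `q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j)`, clipped to
#' 1, with input order preserved; the result is monotone along sorted p.
#' This single routine serves both the enrichment and the prey-prey
#' correlation modules.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values in input order.
#' @export
#' @examples
#' benjamini_hochberg(c(0.01, 0.02, 0.03))
benjamini_hochberg <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_rtk("p-values must lie in [0, 1] and be non-missing",
             class = "rtkscape_validation_error")
  }
  m <- length(p_values)
  ord <- order(p_values)
  ranked <- p_values[ord] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(ranked)))
  q_sorted <- pmin(q_sorted, 1)
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

#' Right-tail Fisher exact enrichment of a query set in a collection
#'
#' For each term with at least one background member: `k` = query hits,
#' `n` = query size, `K` = background hits, `N` = background size;
#' `fold_change = (k/n) / (K/N)`; `p = P(X >= k)` for hypergeometric `X`
#' (the one-sided Fisher exact test); `q` = Benjamini-Hochberg across all
#' terms of the collection. Terms with no background member are omitted.
#'
#' @param query_set Character vector, must be a subset of `background_set`.
#' @param background_set Character vector (the pre-filter identification
#'   universe, or a whole proteome).
#' @param collection Annotation tibble (see [read_gmt()]).
#' @param config A [pipeline_config()] list; `enrichment_q_max` populates the
#'   `significant` flag.
#' @param min_log2_fc Optional display filter: additionally require
#'   `log2(fold_change)` above this value for significance.
#' @return A tibble ordered by q then descending fold change: `term_id`,
#'   `name`, `category`, `k`, `n`, `K`, `N`, `fold_change`, `log2_fc`, `p`,
#'   `q`, `significant`.
#' @export
fisher_enrichment <- function(query_set, background_set, collection,
                              config = pipeline_config(),
                              min_log2_fc = NULL) {
  query_set <- unique(query_set)
  background_set <- unique(background_set)
  stray <- setdiff(query_set, background_set)
  if (length(stray)) {
    stop_rtk(sprintf(
      "query proteins missing from the background set: %s%s",
      paste(head(stray, 5), collapse = ", "),
      if (length(stray) > 5) sprintf(" (and %d more)", length(stray) - 5)
      else ""),
      class = "rtkscape_validation_error")
  }
  n <- length(query_set)
  N <- length(background_set)
  res <- as_tibble(collection) |>
    mutate(K = purrr::map_int(.data$members,
                              ~ sum(background_set %in% .x)),
           k = purrr::map_int(.data$members, ~ sum(query_set %in% .x))) |>
    filter(.data$K > 0) |>
    mutate(n = n, N = N,
           fold_change = (.data$k / .data$n) / (.data$K / .data$N),
           log2_fc = log2(.data$fold_change),
           p = phyper(.data$k - 1, .data$K, .data$N - .data$K, .data$n,
                      lower.tail = FALSE))
  res$q <- benjamini_hochberg(res$p)
  res <- res |>
    mutate(significant = .data$q < config$enrichment_q_max &
             (if (is.null(min_log2_fc)) TRUE
              else .data$log2_fc > min_log2_fc)) |>
    select("term_id", "name", "category", "k", "n", "K", "N",
           "fold_change", "log2_fc", "p", "q", "significant") |>
    arrange(.data$q, desc(.data$fold_change), .data$term_id)
  res
}

#' Domain occurrence summary over an HCI table
#'
#' For each domain in a Pfam-style collection, `total` counts every
#' (bait, prey) HCI row whose prey carries the domain (a prey interacting
#' with several baits is counted once per bait), while `unique_proteins`
#' counts the distinct preys carrying it.
#'
#' @param hci_table HCI tibble with `bait` and `prey`.
#' @param pfam_collection Annotation tibble mapping domains to member
#'   proteins.
#' @return A tibble: `term_id`, `name`, `total`, `unique_proteins`, sorted
#'   by descending total.
#' @export
domain_count_summary <- function(hci_table, pfam_collection) {
  rows <- distinct(as_tibble(hci_table)[, c("bait", "prey")])
  out <- as_tibble(pfam_collection) |>
    mutate(total = purrr::map_int(.data$members,
                                  ~ sum(rows$prey %in% .x)),
           unique_proteins = purrr::map_int(
             .data$members, ~ dplyr::n_distinct(rows$prey[rows$prey %in% .x]))
    ) |>
    filter(.data$total > 0) |>
    select("term_id", "name", "total", "unique_proteins") |>
    arrange(desc(.data$total), .data$term_id)
  out
}
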