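#' @name rtk-phospho
#' @title In-vitro kinase assay phosphosite post-processing
#'
#' @description Phosphotyrosine sites from recombinant-kinase assays are
#' filtered on localization probability (>= 0.75 kept) and against
#' no-kinase control runs, tabulated into unique sites, kinase-substrate
#' pairs and kinase-site relations, annotated against known-site databases
#' (including +/-7-residue window identity), matched to phosphorylation
#' motifs, and clustered by binary substrate-site profiles with Ward (D2)
#' linkage on Jaccard distances.
NULL

#' Extract the +/-7-residue sequence window around a site
#'
#' Returns the 15-character window centred on `position` (1-based), padded
#' with `_` beyond the sequence termini — the common phosphoproteomics
#' convention. Vectorized over sequences and positions.
#'
#' @param sequence Character vector of protein sequences.
#' @param position Integer vector of 1-based residue positions.
#' @param flank Residues on each side (default 7).
#' @return Character vector of windows of length `2 * flank + 1`.
#' @export
#' @examples
#' extract_window("MYSA", 2)
extract_window <- function(sequence, position, flank = 7L) {
  len <- nchar(sequence)
  if (any(position < 1 | position > len)) {
    bad <- which(position < 1 | position > len)[1]
    stop_rtk(sprintf("position %d out of range for sequence of length %d",
                     position[bad], len[bad]),
             class = "rtkscape_validation_error")
  }
  pad <- strrep("_", flank)
  padded <- paste0(pad, sequence, pad)
  substr(padded, position, position + 2L * flank)
}

#' Filter phosphosites on localization probability and control runs
#'
#' Drops sites with localization probability below `config$loc_prob_min`
#' (exactly 0.75 is kept: "under 0.75" semantics) and any site whose
#' (substrate, position) appears in *any* control experiment, regardless of
#' probability. Sites on non-tyrosine residues are dropped first with a
#' warning (the assay is phosphotyrosine-specific). Retention order is
#' stable.
#'
#' @param sites Phosphosite tibble (`kinase`, `substrate`, `position`,
#'   `residue`, `localization_probability`, ...).
#' @param control_sites Tibble of control-run sites keyed by `substrate`,
#'   `position` (may be empty or `NULL`).
#' @param config A [pipeline_config()] list.
#' @param keep_all Return all rows with a `retained` flag and a `drop_reason`
#'   column instead of only retained rows.
#' @return The retained sites (or annotated full table when `keep_all`).
#' @export
filter_sites <- function(sites, control_sites = NULL,
                         config = pipeline_config(), keep_all = FALSE) {
  sites <- as_tibble(sites)
  non_y <- sites$residue != "Y"
  if (any(non_y)) {
    warn(sprintf("dropping %d site(s) on non-tyrosine residues", sum(non_y)),
         class = "rtkscape_non_tyrosine")
  }
  ctrl_key <- if (is.null(control_sites) || nrow(control_sites) == 0) {
    character(0)
  } else {
    paste(control_sites$substrate, control_sites$position, sep = "\r")
  }
  key <- paste(sites$substrate, sites$position, sep = "\r")
  low_prob <- sites$localization_probability < config$loc_prob_min
  in_control <- key %in% ctrl_key
  out <- sites |>
    mutate(retained = !non_y & !low_prob & !in_control,
           drop_reason = dplyr::case_when(
             non_y ~ "non_tyrosine",
             in_control ~ "seen_in_control",
             low_prob ~ "low_localization_probability",
             TRUE ~ NA_character_
           ))
  if (keep_all) out
  else select(filter(out, .data$retained), -"retained", -"drop_reason")
}

#' Tabulate kinase-substrate phosphorylation relations
#'
#' Unique sites are keyed by (substrate, position); kinase-substrate pairs
#' by (kinase, substrate); kinase-site relations by (kinase, substrate,
#' position). On any input, `n_unique_sites <= n_relations` and
#' `n_pairs <= n_relations`.
#'
#' @param sites Filtered phosphosite tibble.
#' @return A list: `n_unique_sites`, `n_pairs`, `n_relations`, `per_kinase`
#'   (tibble kinase / n_sites).
#' @export
tabulate_relations <- function(sites) {
  sites <- as_tibble(sites)
  rel <- distinct(sites[, c("kinase", "substrate", "position")])
  list(
    n_unique_sites = nrow(distinct(rel[, c("substrate", "position")])),
    n_pairs = nrow(distinct(rel[, c("kinase", "substrate")])),
    n_relations = nrow(rel),
    per_kinase = count(rel, .data$kinase, name = "n_sites")
  )
}

#' Annotate sites against a known-phosphosite database
#'
#' Flags each site: `known_site` if its (substrate, position) is in the
#' database; `known_kinase_site` if a database row for that site also names
#' the same kinase; `window_identity_match` if the site's +/-7 window string
#' equals a database window recorded for a *different* site; `novel` if none
#' of these hold.
#'
#' @param sites Phosphosite tibble with a `window` column.
#' @param known_site_db Tibble with `substrate`, `position` and optional
#'   `kinase` and `window` columns.
#' @return `sites` with the four logical flags appended.
#' @export
annotate_known_sites <- function(sites, known_site_db) {
  sites <- as_tibble(sites)
  if (is.null(known_site_db) || nrow(known_site_db) == 0) {
    return(mutate(sites, known_site = FALSE, known_kinase_site = FALSE,
                  window_identity_match = FALSE, novel = TRUE))
  }
  db <- as_tibble(known_site_db)
  if (!"kinase" %in% names(db)) db$kinase <- NA_character_
  if (!"window" %in% names(db)) db$window <- NA_character_
  site_key <- paste(sites$substrate, sites$position, sep = "\r")
  db_key <- paste(db$substrate, db$position, sep = "\r")
  kin_key <- paste(site_key, sites$kinase, sep = "\r")
  db_kin_key <- paste(db_key, db$kinase, sep = "\r")

  known_site <- site_key %in% db_key
  known_kinase_site <- kin_key %in% db_kin_key[!is.na(db$kinase)]
  window_identity_match <- purrr::map_lgl(seq_len(nrow(sites)), function(i) {
    w <- sites$window[i]
    if (is.na(w)) return(FALSE)
    hit <- !is.na(db$window) & db$window == w & db_key != site_key[i]
    any(hit)
  })
  sites |>
    mutate(known_site = known_site,
           known_kinase_site = known_kinase_site,
           window_identity_match = window_identity_match,
           novel = !known_site & !window_identity_match)
}

#' Parse a phosphorylation motif pattern
#'
#' Patterns are `-`-separated tokens: an upper-case residue letter, the
#' wildcard `x`, an alternative set such as `[LIV]`, and exactly one
#' lower-case acceptor residue (e.g. `y`). Example: `E-x-y-x-[LIV]`.
#'
#' @param pattern Motif pattern string.
#' @return A tibble with `offset` (relative to the acceptor), `type`
#'   (`acceptor`, `wildcard`, `residue`, `set`) and `residues` (list).
#' @export
parse_motif <- function(pattern) {
  toks <- str_split(pattern, "-")[[1]]
  toks <- str_trim(toks)
  if (!length(toks) || any(!nzchar(toks))) {
    stop_rtk(sprintf("empty token in motif pattern '%s'", pattern),
             class = "rtkscape_parse_error")
  }
  parsed <- purrr::map(toks, function(t) {
    if (t == "x" || t == "X") {
      list(type = "wildcard", residues = character())
    } else if (grepl("^\\[[A-Z]+\\]$", t)) {
      res <- strsplit(gsub("\\[|\\]", "", t), "")[[1]]
      list(type = "set", residues = res)
    } else if (grepl("^[a-wyz]$", t)) {
      list(type = "acceptor", residues = toupper(t))
    } else if (grepl("^[A-Z]\\*$", t)) {
      list(type = "acceptor", residues = substr(t, 1, 1))
    } else if (grepl("^[A-Z]$", t)) {
      list(type = "residue", residues = t)
    } else {
      stop_rtk(sprintf("cannot parse motif token '%s' in '%s'", t, pattern),
               class = "rtkscape_parse_error")
    }
  })
  types <- purrr::map_chr(parsed, "type")
  acc <- which(types == "acceptor")
  if (length(acc) != 1L) {
    stop_rtk(sprintf(
      "motif '%s' must contain exactly one acceptor token, found %d",
      pattern, length(acc)), class = "rtkscape_parse_error")
  }
  if (any(types == "set" &
          purrr::map_int(parsed, ~ length(.x$residues)) == 0)) {
    stop_rtk(sprintf("empty alternative set in motif '%s'", pattern),
             class = "rtkscape_parse_error")
  }
  tibble(offset = seq_along(toks) - acc,
         type = types,
         residues = purrr::map(parsed, "residues"))
}

#' Match sequence windows against phosphorylation motifs
#'
#' The motif's acceptor aligns to the window centre. The match fraction is
#' the number of satisfied constrained positions (residue or alternative-set
#' tokens) divided by the number of constrained positions; acceptor and
#' wildcard tokens are excluded from both counts, and `_` padding never
#' matches. A motif with no constrained positions matches with fraction 1 by
#' convention (vacuous truth).
#'
#' @param windows Character vector of odd-length windows (typically 15).
#' @param motifs Motif tibble (`name`, `kinase`, `pattern`) as from
#'   [read_motifs()] or [simulate_phospho()].
#' @return A tibble with one row per (window, motif): `window`, `motif`,
#'   `kinase`, `n_constrained`, `n_matched`, `fraction`.
#' @export
match_motifs <- function(windows, motifs) {
  if (!length(windows)) {
    return(tibble(window = character(), motif = character(),
                  kinase = character(), n_constrained = integer(),
                  n_matched = integer(), fraction = numeric()))
  }
  wlen <- unique(nchar(windows))
  if (length(wlen) != 1L || wlen %% 2L == 0L) {
    stop_rtk("all windows must share one odd length",
             class = "rtkscape_validation_error")
  }
  centre <- (wlen + 1L) %/% 2L
  res <- purrr::pmap(
    list(motifs$name, motifs$kinase, motifs$pattern),
    function(nm, kin, pat) {
      m <- parse_motif(pat)
      cons <- m[m$type %in% c("residue", "set"), ]
      if (any(abs(cons$offset) > centre - 1L)) {
        stop_rtk(sprintf("motif '%s' spans beyond the +/-%d window", nm,
                         centre - 1L), class = "rtkscape_validation_error")
      }
      nc <- nrow(cons)
      if (nc == 0L) {
        return(tibble(window = windows, motif = nm, kinase = kin,
                      n_constrained = 0L, n_matched = 0L, fraction = 1))
      }
      matched <- rep(0L, length(windows))
      for (j in seq_len(nc)) {
        ch <- substr(windows, centre + cons$offset[j],
                     centre + cons$offset[j])
        matched <- matched + (ch %in% cons$residues[[j]] & ch != "_")
      }
      tibble(window = windows, motif = nm, kinase = kin,
             n_constrained = nc, n_matched = matched,
             fraction = matched / nc)
    })
  bind_rows(res)
}

#' Per-kinase motif match profile of a site table
#'
#' For each filtered site, computes the match fraction of its +/-7 window
#' against its own kinase's motif and records the best-matching motif
#' overall, giving the per-kinase distribution of best-match fractions that
#' the motif analysis reports.
#'
#' @param sites Filtered phosphosite tibble with `kinase` and `window`.
#' @param motifs Motif tibble.
#' @return `sites` with `own_motif_fraction`, `best_motif`, `best_fraction`.
#' @export
site_motif_profile <- function(sites, motifs) {
  sites <- as_tibble(sites)
  mm <- match_motifs(sites$window, motifs) |>
    distinct(.data$window, .data$motif, .keep_all = TRUE)
  own <- mm |>
    inner_join(distinct(sites[, c("kinase", "window")]),
               by = c("kinase", "window")) |>
    select("kinase", "window", own_motif_fraction = "fraction")
  best <- mm |>
    group_by(.data$window) |>
    arrange(desc(.data$fraction), .data$motif, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("window", best_motif = "motif", best_fraction = "fraction")
  sites |>
    left_join(own, by = c("kinase", "window")) |>
    left_join(best, by = "window")
}

#' Cluster kinases by their substrate-site profiles
#'
#' Builds the binary kinase-by-site incidence matrix, computes pairwise
#' Jaccard distances between kinase site sets and agglomerates with Ward's
#' D2 linkage. Kinases with no sites are excluded with a warning; at least
#' 3 kinases are required.
#'
#' @param sites Filtered phosphosite tibble.
#' @param linkage Agglomeration method passed to [stats::hclust()].
#' @return An object of class `rtk_dendrogram`: `hclust`, `phylo` (ape tree
#'   with branch lengths from merge heights), `newick` string, and the
#'   incidence `matrix`.
#' @export
cluster_substrate_profiles <- function(sites, linkage = "ward.D2") {
  sites <- as_tibble(sites)
  rel <- distinct(sites[, c("kinase", "substrate", "position")])
  rel$site <- paste(rel$substrate, rel$position, sep = ":")
  kin <- sort(unique(rel$kinase))
  if (length(kin) < 3L) {
    stop_rtk("need at least 3 kinases with sites to cluster",
             class = "rtkscape_config_error")
  }
  site_ids <- sort(unique(rel$site))
  mat <- matrix(0L, nrow = length(kin), ncol = length(site_ids),
                dimnames = list(kin, site_ids))
  mat[cbind(rel$kinase, rel$site)] <- 1L
  # dist(method = "binary") is the Jaccard distance on binary profiles
  d <- dist(mat, method = "binary")
  hc <- hclust(d, method = linkage)
  phy <- ape::as.phylo(hc)
  structure(list(hclust = hc, phylo = phy,
                 newick = ape::write.tree(phy), matrix = mat),
            class = "rtk_dendrogram")
}

#' @export
print.rtk_dendrogram <- function(x, ...) {
  cat(sprintf("<rtk_dendrogram> %d kinases x %d sites; %s linkage\n",
              nrow(x$matrix), ncol(x$matrix), x$hclust$method))
  invisible(x)
}

as_phylo_tree <- function(tree) {
  if (inherits(tree, "rtk_dendrogram")) return(tree$phylo)
  if (inherits(tree, "phylo")) return(tree)
  if (inherits(tree, "hclust")) return(ape::as.phylo(tree))
  if (is.character(tree) && length(tree) == 1L) {
    return(ape::read.tree(text = tree))
  }
  stop_rtk("cannot interpret tree input",
           class = "rtkscape_validation_error")
}

#' Compare two dendrograms over the same leaves
#'
#' Computes the correlation of the two cophenetic distance matrices over all
#' leaf pairs, plus a per-leaf paired-position table for tanglegram-style
#' side-by-side rendering.
#'
#' @param tree_a,tree_b Trees (`rtk_dendrogram`, `phylo`, `hclust` or Newick
#'   strings) on identical leaf sets.
#' @return A list: `cophenetic_correlation`, `alignment` (tibble leaf /
#'   position_a / position_b).
#' @export
compare_dendrograms <- function(tree_a, tree_b) {
  a <- as_phylo_tree(tree_a)
  b <- as_phylo_tree(tree_b)
  sym_diff <- c(setdiff(a$tip.label, b$tip.label),
                setdiff(b$tip.label, a$tip.label))
  if (length(sym_diff)) {
    stop_rtk(sprintf("leaf sets differ: %s",
                     paste(sort(unique(sym_diff)), collapse = ", ")),
             class = "rtkscape_validation_error")
  }
  da <- ape::cophenetic.phylo(a)
  db <- ape::cophenetic.phylo(b)
  leaves <- sort(a$tip.label)
  da <- da[leaves, leaves]
  db <- db[leaves, leaves]
  ut <- upper.tri(da)
  r <- if (sd(da[ut]) == 0 || sd(db[ut]) == 0) NA_real_
       else cor(da[ut], db[ut])
  alignment <- tibble(
    leaf = leaves,
    position_a = match(leaves, tip_plot_order(a)),
    position_b = match(leaves, tip_plot_order(b))
  )
  list(cophenetic_correlation = r, alignment = alignment)
}

tip_plot_order <- function(phy) {
  edge <- ape::reorder.phylo(phy, "cladewise")$edge
  tips <- edge[edge[, 2] <= length(phy$tip.label), 2]
  phy$tip.label[tips]
}
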