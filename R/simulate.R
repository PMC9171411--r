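#' @name rtk-simulate
#' @title Synthetic study generator with planted ground truth
#'
#' @description Generates every input the pipeline consumes — replicate-level
#' spectral counts with GFP control runs, a contaminant-frequency table, a
#' multi-source known-interaction database, annotation collections and
#' in-vitro kinase assay phosphosite tables — from a planted ground truth, so
#' every downstream stage can be exercised and its error rates measured
#' without any external data. All generators are pure functions of their
#' parameters and seed.
NULL

#' Simulate a bait-prey interactome with subfamily sharing structure
#'
#' Plants a ground-truth interactome: `n_baits` receptor baits partitioned
#' into `n_subfamilies` subfamilies, each bait receiving `edges_per_bait`
#' true preys. A fraction `within_subfamily_sharing` of each bait's preys is
#' its subfamily's shared prey set, attached in full to every bait of the
#' subfamily (shared effectors bind all family members, which is what makes
#' their bait profiles correlate); a fraction `cross_subfamily_sharing` is
#' drawn from a global pool with Zipf popularity weights, so a few hub
#' adaptors recur across many subfamilies; the remainder is unique to the
#' bait. Each true edge is assigned to the
#' AP-MS stratum, the BioID stratum, or both, with probabilities
#' `stratum_probs`; a `kd_dependent_fraction` of edges is flagged as
#' kinase-activity dependent (lost in kinase-dead runs). A
#' `contaminant_fraction` of the prey universe becomes frequent contaminants
#' with per-protein detection probabilities drawn uniformly from
#' `contam_detect_range` and Poisson rate `lambda_contam`; contaminants are
#' the only preys that appear in control runs.
#'
#' @param n_baits,n_subfamilies,n_preys Study scale (defaults mirror a
#'   50-bait, 20-subfamily, 2,000-prey design).
#' @param edges_per_bait True preys planted per bait.
#' @param within_subfamily_sharing,cross_subfamily_sharing Fractions in
#'   \[0, 1\] of each bait's preys taken from the subfamily shared set /
#'   drawn from the weighted global hub pool.
#' @param stratum_probs Named probabilities for `APMS`, `BIOID`, `BOTH`.
#' @param kd_dependent_fraction Fraction of edges lost in KD condition.
#' @param rtk_rtk_per_bait Expected number of bait-bait (receptor
#'   heterodimer) edges planted per bait; drawn between random bait pairs,
#'   biased toward same-subfamily partners.
#' @param contaminant_fraction Fraction of the prey universe that is a
#'   frequent contaminant.
#' @param lambda_contam Poisson rate of contaminant spectral counts.
#' @param contam_detect_range Range of per-contaminant detection
#'   probabilities.
#' @param seed Integer seed.
#'
#' @return An object of class `rtk_ground_truth`: a list with `true_edges`
#'   (tibble: bait, prey, stratum, kd_dependent), `contaminants` (tibble:
#'   prey, detect_prob, rate), `subfamilies` (tibble: rtk, subfamily),
#'   `prey_universe`, `baits`, `planted_clusters` (list of prey sets shared
#'   by several baits), `params` and `seed`.
#' @export
#' @examples
#' truth <- simulate_interactome(n_baits = 6, n_subfamilies = 3,
#'                               n_preys = 200, edges_per_bait = 10,
#'                               seed = 1)
#' nrow(truth$true_edges)
simulate_interactome <- function(n_baits = 50L,
                                 n_subfamilies = 20L,
                                 n_preys = 2000L,
                                 edges_per_bait = 30L,
                                 within_subfamily_sharing = 0.30,
                                 cross_subfamily_sharing = 0.10,
                                 stratum_probs = c(APMS = 0.19, BIOID = 0.74,
                                                   BOTH = 0.07),
                                 kd_dependent_fraction = 0.30,
                                 rtk_rtk_per_bait = 1.5,
                                 contaminant_fraction = 0.10,
                                 lambda_contam = 0.5,
                                 contam_detect_range = c(0.05, 0.95),
                                 seed = 1L) {
  if (n_baits < n_subfamilies || n_subfamilies < 1L) {
    stop_rtk("need n_baits >= n_subfamilies >= 1",
             class = "rtkscape_config_error")
  }
  for (f in c(within_subfamily_sharing, cross_subfamily_sharing,
              kd_dependent_fraction, contaminant_fraction)) {
    if (f < 0 || f > 1) {
      stop_rtk("sharing/contaminant fractions must lie in [0, 1]",
               class = "rtkscape_config_error")
    }
  }
  set.seed(seed)
  baits <- sprintf("RTK%03d", seq_len(n_baits))
  preys <- sprintf("PREY%04d", seq_len(n_preys))
  subfam <- tibble(
    rtk = baits,
    subfamily = sprintf("SF%02d", rep_len(seq_len(n_subfamilies), n_baits))
  )

  n_within <- round(edges_per_bait * within_subfamily_sharing)
  n_cross <- round(edges_per_bait * cross_subfamily_sharing)
  n_unique <- edges_per_bait - n_within - n_cross
  if (n_unique < 0) {
    stop_rtk("sharing fractions sum to more than 1",
             class = "rtkscape_config_error")
  }

  # Partition the universe into a global cross-subfamily pool, per-subfamily
  # pools and a remainder for bait-unique preys.
  shuffled <- sample(preys)
  cross_pool_size <- if (n_cross > 0) max(n_cross, 2L * edges_per_bait) else 0L
  pool_size <- n_within
  need <- cross_pool_size + pool_size * n_subfamilies +
    n_unique * n_baits
  if (need > n_preys) {
    stop_rtk(sprintf(
      "prey universe too small: need %d preys for the requested structure",
      need), class = "rtkscape_config_error")
  }
  idx <- 0L
  take <- function(k) {
    out <- shuffled[idx + seq_len(k)]
    idx <<- idx + k
    out
  }
  cross_pool <- take(cross_pool_size)
  cross_weight <- if (cross_pool_size > 0) 1 / seq_len(cross_pool_size)
                  else numeric()
  sf_pools <- setNames(
    purrr::map(seq_len(n_subfamilies), ~ take(pool_size)),
    sprintf("SF%02d", seq_len(n_subfamilies)))

  edge_list <- purrr::map(seq_len(n_baits), function(i) {
    sf <- subfam$subfamily[i]
    prey_set <- c(
      sf_pools[[sf]],
      if (n_cross > 0) sample(cross_pool, n_cross, prob = cross_weight)
      else character(),
      if (n_unique > 0) take(n_unique) else character()
    )
    tibble(bait = baits[i], prey = unique(prey_set))
  })
  edges <- bind_rows(edge_list)

  # Bait-bait heterodimer edges: the prey slot holds another bait.
  n_bb <- round(rtk_rtk_per_bait * n_baits)
  if (n_bb > 0 && n_baits > 1) {
    same_sf <- tidyr::crossing(i = seq_len(n_baits), j = seq_len(n_baits)) |>
      filter(.data$i < .data$j)
    w <- if_else(subfam$subfamily[same_sf$i] == subfam$subfamily[same_sf$j],
                 3, 1)
    pick <- sample.int(nrow(same_sf), min(n_bb, nrow(same_sf)), prob = w)
    bb <- tibble(bait = baits[same_sf$i[pick]],
                 prey = baits[same_sf$j[pick]])
    edges <- bind_rows(edges, bb)
  }

  strata <- sample(names(stratum_probs), nrow(edges), replace = TRUE,
                   prob = stratum_probs)
  edges$stratum_class <- strata
  edges$kd_dependent <- runif(nrow(edges)) < kd_dependent_fraction
  true_edges <- edges |>
    mutate(stratum = purrr::map(.data$stratum_class, function(s) {
      if (s == "BOTH") c("APMS", "BIOID") else s
    })) |>
    tidyr::unnest("stratum") |>
    select("bait", "prey", "stratum", "kd_dependent")

  n_contam <- round(contaminant_fraction * n_preys)
  contam <- tibble(
    prey = sample(preys, n_contam),
    detect_prob = runif(n_contam, contam_detect_range[1],
                        contam_detect_range[2]),
    rate = lambda_contam
  )

  pools_used <- c(sf_pools[purrr::map_int(sf_pools, length) > 0],
                  if (cross_pool_size > 0) list(cross = cross_pool))
  structure(list(
    true_edges = true_edges,
    contaminants = contam,
    subfamilies = subfam,
    prey_universe = preys,
    baits = baits,
    planted_clusters = unname(pools_used),
    params = list(n_baits = n_baits, n_subfamilies = n_subfamilies,
                  n_preys = n_preys, edges_per_bait = edges_per_bait,
                  within_subfamily_sharing = within_subfamily_sharing,
                  cross_subfamily_sharing = cross_subfamily_sharing,
                  stratum_probs = stratum_probs,
                  kd_dependent_fraction = kd_dependent_fraction,
                  contaminant_fraction = contaminant_fraction,
                  lambda_contam = lambda_contam),
    seed = as.integer(seed)
  ), class = "rtk_ground_truth")
}

#' @export
print.rtk_ground_truth <- function(x, ...) {
  cat(sprintf(
    "<rtk_ground_truth> %d baits / %d subfamilies, %d preys, %d true edges, %d contaminants (seed %d)\n",
    length(x$baits), dplyr::n_distinct(x$subfamilies$subfamily),
    length(x$prey_universe), nrow(x$true_edges), nrow(x$contaminants),
    x$seed))
  invisible(x)
}

#' Simulate replicate-level spectral counts from a planted interactome
#'
#' True bait-prey pairs in each stratum draw Poisson counts at rate
#' `lambda_true`, zeroed with probability `dropout` per replicate.
#' Contaminants appear in bait runs *and* GFP control runs with their
#' per-protein detection probability and Poisson rate; controls contain no
#' planted edges. Bait-run rows with zero counts are omitted (sparse table);
#' control-run contaminant rows are always emitted, so control runs are
#' visible even when all their counts are zero. Under `condition = "KD"`
#' the kinase-activity-dependent edges are suppressed.
#'
#' @param truth An `rtk_ground_truth` object.
#' @param lambda_true Poisson rate for true interactions.
#' @param lambda_contam Optional override of the contaminant rate stored in
#'   `truth` (default `NULL` keeps the stored rates, which is what keeps the
#'   simulated contaminant-frequency table consistent with the counts).
#' @param dropout Per-replicate probability that a true pair yields zero.
#' @param n_replicates Biological replicates per bait run.
#' @param n_controls GFP control runs per stratum.
#' @param nonspecific_per_run One-hit nonspecific identifications per bait
#'   run: preys drawn uniformly from the universe that appear with a single
#'   spectral count, emulating the breadth of pre-filter identification
#'   lists. They are run-specific carryover, not repository contaminants,
#'   so they never enter control runs.
#' @param condition Experimental condition label for the emitted rows.
#' @param seed Integer seed.
#' @return A validated spectral-count tibble (see [read_spectral_counts()]).
#' @export
simulate_counts <- function(truth, lambda_true = 25, lambda_contam = NULL,
                            dropout = 0.1, n_replicates = 2L,
                            n_controls = 4L, nonspecific_per_run = 20L,
                            condition = "WT", seed = 1L) {
  stopifnot(inherits(truth, "rtk_ground_truth"))
  contam <- truth$contaminants
  if (!is.null(lambda_contam)) contam$rate <- lambda_contam
  if (any(lambda_true <= contam$rate) && nrow(contam) > 0) {
    stop_rtk("lambda_true must exceed the contaminant rate",
             class = "rtkscape_config_error")
  }
  if (dropout < 0 || dropout >= 1) {
    stop_rtk("dropout must lie in [0, 1)", class = "rtkscape_config_error")
  }
  set.seed(seed)

  edges <- truth$true_edges
  if (condition == "KD") edges <- edges[!edges$kd_dependent, ]

  true_rows <- tidyr::crossing(edges[, c("bait", "prey", "stratum")],
                               replicate = seq_len(n_replicates))
  n_t <- nrow(true_rows)
  true_rows$spectral_count <-
    rpois(n_t, lambda_true) * (runif(n_t) >= dropout)

  contam_bait <- tidyr::crossing(
    tibble(bait = truth$baits),
    tibble(stratum = METHOD_LEVELS),
    tibble(replicate = seq_len(n_replicates)),
    contam
  )
  n_cb <- nrow(contam_bait)
  contam_bait$spectral_count <-
    (runif(n_cb) < contam_bait$detect_prob) *
    rztpois(n_cb, contam_bait$rate)

  control_rows <- tidyr::crossing(
    tibble(bait = control_tag()),
    tibble(stratum = METHOD_LEVELS),
    tibble(replicate = seq_len(n_controls)),
    contam
  )
  n_ct <- nrow(control_rows)
  control_rows$spectral_count <-
    (runif(n_ct) < control_rows$detect_prob) *
    rztpois(n_ct, control_rows$rate)

  nonspec <- tibble(bait = character(), stratum = character(),
                    replicate = integer(), prey = character(),
                    spectral_count = numeric())
  if (nonspecific_per_run > 0) {
    runs <- tidyr::crossing(tibble(bait = truth$baits),
                            tibble(stratum = METHOD_LEVELS),
                            tibble(replicate = seq_len(n_replicates)))
    nonspec <- runs |>
      mutate(prey = purrr::map(seq_len(dplyr::n()), function(i) {
        sample(truth$prey_universe, nonspecific_per_run)
      })) |>
      tidyr::unnest("prey") |>
      mutate(spectral_count = 1)
  }

  bait_rows <- bind_rows(
    true_rows[, c("bait", "stratum", "replicate", "prey", "spectral_count")],
    contam_bait[, c("bait", "stratum", "replicate", "prey",
                    "spectral_count")],
    nonspec
  ) |>
    group_by(.data$bait, .data$stratum, .data$replicate, .data$prey) |>
    summarise(spectral_count = sum(.data$spectral_count), .groups = "drop") |>
    filter(.data$spectral_count > 0)

  out <- bind_rows(
    bait_rows,
    control_rows[, c("bait", "stratum", "replicate", "prey",
                     "spectral_count")]
  ) |>
    mutate(method = .data$stratum, condition = condition,
           replicate = as.integer(.data$replicate)) |>
    select("bait", "method", "condition", "replicate", "prey",
           "spectral_count") |>
    arrange(.data$bait, .data$method, .data$condition, .data$replicate,
            .data$prey)
  validate_counts(out)
}

#' Simulate a contaminant-frequency table consistent with the count model
#'
#' Contaminant counts in [simulate_counts()] are a Bernoulli detection
#' indicator times a zero-truncated Poisson count, so a contaminant's
#' detection fraction is exactly its planted detection probability and the
#' repository-style average spectral count *where detected* is the
#' zero-truncated Poisson mean `rate / (1 - exp(-rate))`. Every other prey
#' in the universe reports zero for both, so the compound filter's frequency
#' and fold-change branches are both exercised.
#'
#' @param truth An `rtk_ground_truth` object.
#' @return A contaminant-frequency tibble covering the full prey universe.
#' @export
simulate_crapome <- function(truth) {
  stopifnot(inherits(truth, "rtk_ground_truth"))
  tibble(prey = truth$prey_universe) |>
    left_join(truth$contaminants, by = "prey") |>
    mutate(detection_fraction = tidyr::replace_na(.data$detect_prob, 0),
           mean_spectral_count = tidyr::replace_na(
             ifelse(.data$rate > 0,
                    .data$rate / (1 - exp(-.data$rate)), 0), 0)) |>
    select("prey", "detection_fraction", "mean_spectral_count")
}

#' Simulate a merged known-interaction database over several pseudo-sources
#'
#' A `coverage` fraction of the planted true edges (as unordered pairs) is
#' marked known. Each known pair gets one primary source uniformly among
#' `n_sources` pseudo-databases, and each further source independently with
#' probability `source_overlap`, so the per-pair source-count histogram is
#' dominated by single-source pairs. `spurious_rate` adds that fraction (of
#' the known-pair count) of random pairs between non-interacting proteins.
#'
#' @param truth An `rtk_ground_truth` object.
#' @param coverage Fraction of true edges present in the database.
#' @param n_sources Number of pseudo-source databases (six in the study
#'   design this emulates).
#' @param source_overlap Probability that a known pair appears in each
#'   additional source.
#' @param spurious_rate Spurious pairs added, as a fraction of known pairs.
#' @param seed Integer seed.
#' @return A canonical known-interaction tibble (`a`, `b`, `sources`,
#'   `n_sources`); spurious pairs are recorded in attribute `spurious_pairs`.
#' @export
simulate_known_db <- function(truth, coverage = 0.5, n_sources = 6L,
                              source_overlap = 0.10, spurious_rate = 0.05,
                              seed = 1L) {
  stopifnot(inherits(truth, "rtk_ground_truth"))
  for (f in c(coverage, source_overlap, spurious_rate)) {
    if (f < 0 || f > 1) {
      stop_rtk("coverage, source_overlap and spurious_rate must lie in [0, 1]",
               class = "rtkscape_config_error")
    }
  }
  set.seed(seed)
  src_names <- sprintf("SOURCE%d", seq_len(n_sources))
  pairs <- distinct(canonical_pair(truth$true_edges$bait,
                                   truth$true_edges$prey))
  n_known <- round(coverage * nrow(pairs))
  known <- pairs[sample.int(nrow(pairs), n_known), , drop = FALSE]

  n_spur <- round(spurious_rate * n_known)
  spurious <- tibble(a = character(), b = character())
  if (n_spur > 0) {
    universe <- c(truth$baits, truth$prey_universe)
    true_key <- paste(pairs$a, pairs$b, sep = "\r")
    got <- 0L
    acc <- list()
    while (got < n_spur) {
      cand <- canonical_pair(sample(universe, n_spur * 2, replace = TRUE),
                             sample(universe, n_spur * 2, replace = TRUE))
      cand <- cand[cand$a != cand$b, ]
      cand <- cand[!(paste(cand$a, cand$b, sep = "\r") %in% true_key), ]
      cand <- distinct(cand)
      acc <- c(acc, list(cand))
      got <- nrow(distinct(bind_rows(acc)))
    }
    spurious <- distinct(bind_rows(acc))[seq_len(n_spur), ]
  }

  all_pairs <- bind_rows(known, spurious)
  if (nrow(all_pairs) == 0) {
    out <- tibble(a = character(), b = character(), sources = list(),
                  n_sources = integer())
    attr(out, "spurious_pairs") <- spurious
    return(out)
  }
  primary <- sample(src_names, nrow(all_pairs), replace = TRUE)
  extra <- matrix(runif(nrow(all_pairs) * n_sources) < source_overlap,
                  nrow = nrow(all_pairs))
  sources <- purrr::map(seq_len(nrow(all_pairs)), function(i) {
    sort(unique(c(primary[i], src_names[extra[i, ]])))
  })
  out <- all_pairs |>
    mutate(sources = sources,
           n_sources = purrr::map_int(sources, length)) |>
    distinct(.data$a, .data$b, .keep_all = TRUE) |>
    arrange(.data$a, .data$b)
  attr(out, "spurious_pairs") <- spurious
  out
}

#' Simulate annotation collections matched to the planted interactome
#'
#' Builds a GMT-style term table whose informative terms are the planted
#' shared-prey pools (so enrichment has signal to find) plus random terms,
#' and a CORUM-style complex table whose complexes are subsets of planted
#' pools plus random complexes.
#'
#' @param truth An `rtk_ground_truth` object.
#' @param n_random_terms,n_random_complexes Number of uninformative terms /
#'   complexes drawn uniformly from the prey universe.
#' @param term_size,complex_size Size range of the random terms / complexes.
#' @param seed Integer seed.
#' @return A list with `terms` (as from [read_gmt()]) and `complexes` (as
#'   from [read_corum()]).
#' @export
simulate_annotations <- function(truth, n_random_terms = 40L,
                                 n_random_complexes = 15L,
                                 term_size = c(10L, 40L),
                                 complex_size = c(3L, 8L), seed = 1L) {
  stopifnot(inherits(truth, "rtk_ground_truth"))
  set.seed(seed)
  pools <- truth$planted_clusters
  pool_terms <- tibble(
    term_id = sprintf("POOL%02d", seq_along(pools)),
    name = sprintf("planted shared pool %d", seq_along(pools)),
    category = "OTHER",
    members = pools
  )
  rand_terms <- tibble(
    term_id = sprintf("RAND%03d", seq_len(n_random_terms)),
    name = sprintf("random term %d", seq_len(n_random_terms)),
    category = "OTHER",
    members = purrr::map(seq_len(n_random_terms), function(i) {
      sample(truth$prey_universe,
             sample(seq(term_size[1], term_size[2]), 1))
    })
  )
  terms <- bind_rows(pool_terms, rand_terms) |>
    mutate(n_members = purrr::map_int(.data$members, length))

  pool_cx <- purrr::imap(pools, function(pool, i) {
    k <- min(length(pool), sample(seq(complex_size[1], complex_size[2]), 1))
    tibble(complex_id = sprintf("CPXPOOL%02d", i),
           name = sprintf("planted complex %d", i),
           subunits = list(sample(pool, k)))
  })
  rand_cx <- purrr::map(seq_len(n_random_complexes), function(i) {
    k <- sample(seq(complex_size[1], complex_size[2]), 1)
    tibble(complex_id = sprintf("CPXRAND%02d", i),
           name = sprintf("random complex %d", i),
           subunits = list(sample(truth$prey_universe, k)))
  })
  complexes <- bind_rows(pool_cx, rand_cx) |>
    mutate(n_subunits = purrr::map_int(.data$subunits, length))
  list(terms = terms, complexes = complexes)
}

# Zero-truncated Poisson draws (count given detection); rate 0 gives 0.
rztpois <- function(n, rate) {
  out <- numeric(n)
  pos <- rate > 0
  if (any(pos)) {
    p0 <- exp(-rate[pos])
    u <- p0 + runif(sum(pos)) * (1 - p0)
    out[pos] <- stats::qpois(u, rate[pos])
  }
  out
}

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
MOTIF_RESIDUES <- c("E", "D", "P", "L", "I", "V", "R", "K", "G")

random_motif <- function(kinase) {
  offs <- sort(sample(c(-4:-1, 1:4), 2))
  toks <- purrr::map_chr(offs, function(o) {
    if (runif(1) < 0.5) {
      sample(MOTIF_RESIDUES, 1)
    } else {
      paste0("[", paste(sample(MOTIF_RESIDUES, 2), collapse = ""), "]")
    }
  })
  span <- seq(min(c(offs, 0L)), max(c(offs, 0L)))
  pattern <- purrr::map_chr(span, function(o) {
    if (o == 0L) return("y")
    i <- match(o, offs)
    if (is.na(i)) "x" else toks[i]
  })
  tibble(name = paste0(kinase, "_motif"), kinase = kinase,
         pattern = paste(pattern, collapse = "-"))
}

#' Simulate an in-vitro kinase assay phosphosite dataset
#'
#' Each kinase gets a planted phosphorylation motif (two constrained
#' positions around a central tyrosine acceptor). Kinases phosphorylate
#' tyrosines whose +/-7 windows match their motif with probability
#' `motif_strength` and random tyrosines otherwise. A `loc_prob_noise`
#' fraction of sites receives a localization probability below 0.75, and a
#' `control_leak_rate` fraction of sites also appears in no-kinase control
#' runs. With `groups`, kinases in the same group draw a `site_sharing`
#' fraction of their sites from a shared per-group pool, planting block
#' structure recoverable by substrate-profile clustering.
#'
#' @param kinases Character vector of kinase identifiers (defaults to 45
#'   recombinant kinases, the scale of the assay this emulates).
#' @param substrate_fasta Optional named character vector (or FASTA path) of
#'   substrate sequences; by default `n_substrates` random sequences of
#'   length `substrate_length` are generated. Substrates without a tyrosine
#'   are skipped with a warning.
#' @param sites_per_kinase Sites planted per kinase.
#' @param motif_strength Probability that a planted site's window matches its
#'   kinase's motif.
#' @param loc_prob_noise Fraction of sites with localization probability
#'   below 0.75.
#' @param control_leak_rate Fraction of (substrate, position) sites that also
#'   appear in control runs.
#' @param groups Optional named vector/list mapping kinase to group label.
#' @param site_sharing Fraction of a kinase's sites drawn from its group's
#'   shared pool (requires `groups`).
#' @param n_substrates,substrate_length Scale of internally generated
#'   substrates.
#' @param seed Integer seed.
#' @return A list of class `rtk_phospho_sim`: `sites` (tibble with kinase,
#'   substrate, position, residue, localization_probability, window and the
#'   ground-truth `motif_match` flag), `control_sites`, `motifs`,
#'   `sequences`, `seed`.
#' @export
simulate_phospho <- function(kinases = sprintf("RTK%03d", 1:45),
                             substrate_fasta = NULL,
                             sites_per_kinase = 30L,
                             motif_strength = 0.8,
                             loc_prob_noise = 0.1,
                             control_leak_rate = 0.02,
                             groups = NULL,
                             site_sharing = 0,
                             n_substrates = 150L,
                             substrate_length = 300L,
                             seed = 1L) {
  set.seed(seed)
  n_k <- length(kinases)
  flank <- 7L

  if (is.null(substrate_fasta)) {
    seqs <- setNames(
      purrr::map_chr(seq_len(n_substrates), function(i) {
        paste(sample(AA20, substrate_length, replace = TRUE), collapse = "")
      }),
      sprintf("SUB%04d", seq_len(n_substrates)))
  } else {
    seqs <- if (is.character(substrate_fasta) &&
                length(substrate_fasta) == 1L &&
                file.exists(substrate_fasta)) {
      read_fasta_seqs(substrate_fasta)
    } else {
      substrate_fasta
    }
    no_y <- !str_detect(seqs, "Y")
    if (any(no_y)) {
      warn(sprintf("skipping %d substrate(s) without any tyrosine",
                   sum(no_y)), class = "rtkscape_no_tyrosine")
      seqs <- seqs[!no_y]
    }
    if (!length(seqs)) {
      stop_rtk("no usable substrate sequences",
               class = "rtkscape_config_error")
    }
  }
  seq_chars <- purrr::map(seqs, ~ strsplit(.x, "")[[1]])

  # Candidate anchor slots: spaced so motif writes never collide.
  slots <- bind_rows(purrr::imap(seq_chars, function(ch, nm) {
    pos <- seq(flank + 1L, length(ch) - flank, by = 2L * flank + 1L)
    tibble(substrate = nm, position = pos)
  }))
  slots <- slots[sample.int(nrow(slots)), ]

  n_shared <- if (!is.null(groups)) round(site_sharing * sites_per_kinase)
              else 0L
  n_own <- sites_per_kinase - n_shared
  grp <- if (is.null(groups)) setNames(kinases, kinases)
         else unlist(groups)[kinases]
  grp_levels <- unique(grp)
  need <- n_own * n_k + n_shared * length(grp_levels)
  if (need > nrow(slots)) {
    stop_rtk(sprintf(
      "not enough substrate positions: need %d anchor slots, have %d",
      need, nrow(slots)), class = "rtkscape_config_error")
  }
  idx <- 0L
  take_slots <- function(k) {
    out <- slots[idx + seq_len(k), ]
    idx <<- idx + k
    out
  }
  group_pools <- setNames(purrr::map(grp_levels, ~ take_slots(n_shared)),
                          grp_levels)

  motifs <- bind_rows(purrr::map(kinases, random_motif))
  parsed <- purrr::map(motifs$pattern, parse_motif)
  names(parsed) <- kinases

  site_rows <- purrr::map(kinases, function(k) {
    own <- take_slots(n_own)
    shared <- group_pools[[grp[[k]]]]
    bind_rows(own, shared) |> mutate(kinase = k)
  })
  sites <- bind_rows(site_rows)
  sites$motif_match <- runif(nrow(sites)) < motif_strength

  # Write acceptor tyrosines and, for matching sites, the motif residues.
  # Each slot is written by at most one kinase's motif (first writer wins),
  # which only matters for group-shared slots.
  written <- character(0)
  for (i in seq_len(nrow(sites))) {
    s <- sites$substrate[i]
    p <- sites$position[i]
    key <- paste(s, p)
    if (key %in% written) next
    written <- c(written, key)
    seq_chars[[s]][p] <- "Y"
    if (sites$motif_match[i]) {
      m <- parsed[[sites$kinase[i]]]
      cons <- m[m$type == "residue" | m$type == "set", ]
      for (j in seq_len(nrow(cons))) {
        res <- sample(cons$residues[[j]], 1)
        seq_chars[[s]][p + cons$offset[j]] <- res
      }
    }
  }
  seqs_final <- purrr::map_chr(seq_chars, paste, collapse = "")

  n_s <- nrow(sites)
  below <- runif(n_s) < loc_prob_noise
  lp <- ifelse(below, runif(n_s, 0, 0.7499), runif(n_s, 0.75, 1))
  sites <- sites |>
    mutate(residue = "Y",
           localization_probability = lp,
           window = extract_window(seqs_final[.data$substrate],
                                   .data$position)) |>
    select("kinase", "substrate", "position", "residue",
           "localization_probability", "window", "motif_match") |>
    arrange(.data$kinase, .data$substrate, .data$position)

  uniq <- distinct(sites[, c("substrate", "position")])
  n_leak <- round(control_leak_rate * nrow(uniq))
  control_sites <- uniq[sample.int(nrow(uniq), n_leak), , drop = FALSE] |>
    mutate(residue = "Y") |>
    arrange(.data$substrate, .data$position)

  structure(list(sites = sites, control_sites = control_sites,
                 motifs = motifs, sequences = seqs_final,
                 seed = as.integer(seed)),
            class = "rtk_phospho_sim")
}

#' @export
print.rtk_phospho_sim <- function(x, ...) {
  cat(sprintf(
    "<rtk_phospho_sim> %d sites, %d kinases, %d substrates, %d control sites (seed %d)\n",
    nrow(x$sites), dplyr::n_distinct(x$sites$kinase), length(x$sequences),
    nrow(x$control_sites), x$seed))
  invisible(x)
}

#' Generate the full synthetic input bundle for one study
#'
#' Convenience wrapper tying the individual generators together with
#' sub-seeds derived from one master seed: planted interactome, WT (and
#' optionally KD) spectral counts in both strata, contaminant-frequency
#' table, known-interaction database, annotation collections and a
#' phosphosite dataset.
#'
#' @param seed Master integer seed.
#' @param interactome,counts,known_db,annotations,phospho Named lists of
#'   overrides passed to the corresponding `simulate_*` generator.
#' @param kd Also simulate kinase-dead counts?
#' @return A list with elements `truth`, `counts_wt`, `counts_kd` (or
#'   `NULL`), `crapome`, `known_db`, `annotations`, `phospho`, `seed`.
#' @export
simulate_study <- function(seed = 1L, interactome = list(),
                           counts = list(), known_db = list(),
                           annotations = list(), phospho = list(),
                           kd = FALSE) {
  set.seed(seed)
  sub <- sample.int(.Machine$integer.max - 1L, 6L)
  truth <- do.call(simulate_interactome,
                   modifyList(list(seed = sub[1]), interactome))
  counts_wt <- do.call(simulate_counts,
                       modifyList(list(truth = truth, seed = sub[2],
                                       condition = "WT"), counts))
  counts_kd <- if (kd) {
    do.call(simulate_counts,
            modifyList(list(truth = truth, seed = sub[3], condition = "KD"),
                       counts))
  }
  crapome <- simulate_crapome(truth)
  kdb <- do.call(simulate_known_db,
                 modifyList(list(truth = truth, seed = sub[4]), known_db))
  ann <- do.call(simulate_annotations,
                 modifyList(list(truth = truth, seed = sub[5]), annotations))
  ph <- do.call(simulate_phospho,
                modifyList(list(seed = sub[6]), phospho))
  list(truth = truth, counts_wt = counts_wt, counts_kd = counts_kd,
       crapome = crapome, known_db = kdb, annotations = ann, phospho = ph,
       seed = as.integer(seed))
}
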