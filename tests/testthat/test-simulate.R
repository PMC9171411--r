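test_that("simulate_interactome plants the requested structure", {
  truth <- simulate_interactome(n_baits = 8L, n_subfamilies = 4L,
                                n_preys = 400L, edges_per_bait = 10L,
                                seed = 7L)
  expect_s3_class(truth, "rtk_ground_truth")
  expect_length(truth$baits, 8L)
  expect_equal(dplyr::n_distinct(truth$subfamilies$subfamily), 4L)
  # Every bait has its full quota of distinct planted preys (bait-bait
  # heterodimer edges come on top of the quota).
  planted <- unique(truth$true_edges[!truth$true_edges$prey %in% truth$baits,
                                     c("bait", "prey")])
  expect_true(all(table(planted$bait) == 10L))
  # Strata labels are valid and kd flags are logical.
  expect_true(all(truth$true_edges$stratum %in% c("APMS", "BIOID")))
  expect_type(truth$true_edges$kd_dependent, "logical")
  # The subfamily shared set is attached in full to every member bait.
  sf <- truth$subfamilies$subfamily[1]
  members <- truth$subfamilies$rtk[truth$subfamilies$subfamily == sf]
  pool <- truth$planted_clusters[[1]]
  for (b in members) {
    expect_true(all(pool %in%
                      truth$true_edges$prey[truth$true_edges$bait == b]))
  }
  # Determinism.
  again <- simulate_interactome(n_baits = 8L, n_subfamilies = 4L,
                                n_preys = 400L, edges_per_bait = 10L,
                                seed = 7L)
  expect_identical(truth$true_edges, again$true_edges)
})

test_that("simulate_interactome validates its arguments", {
  expect_error(simulate_interactome(n_baits = 3, n_subfamilies = 5),
               class = "rtkscape_config_error")
  expect_error(simulate_interactome(within_subfamily_sharing = 1.2),
               class = "rtkscape_config_error")
  expect_error(
    simulate_interactome(n_baits = 10, n_subfamilies = 5, n_preys = 50,
                         edges_per_bait = 30),
    class = "rtkscape_config_error")  # universe too small
})

test_that("simulate_counts emits controls, respects KD suppression", {
  truth <- tiny_truth()
  counts <- tiny_counts(truth)
  expect_true(all(c("bait", "method", "condition", "replicate", "prey",
                    "spectral_count", "is_control") %in% names(counts)))
  # Control runs are present in both strata even if all-zero.
  ctrl <- counts[counts$is_control, ]
  expect_setequal(unique(ctrl$method), c("APMS", "BIOID"))
  expect_equal(max(ctrl$replicate), 3L)
  # Only planted contaminants ever appear in controls.
  expect_true(all(ctrl$prey %in% truth$contaminants$prey))
  # KD condition loses the kd-dependent edges entirely.
  kd <- simulate_counts(truth, condition = "KD", dropout = 0,
                        nonspecific_per_run = 0L, seed = 3L)
  dep <- truth$true_edges[truth$true_edges$kd_dependent &
                            !truth$true_edges$prey %in%
                              truth$contaminants$prey, ]
  kd_keys <- paste(kd$bait, kd$prey, kd$method)
  expect_false(any(paste(dep$bait, dep$prey, dep$stratum) %in% kd_keys))
})

test_that("simulated crapome matches the zero-truncated count model", {
  truth <- tiny_truth()
  crap <- simulate_crapome(truth)
  expect_equal(nrow(crap), length(truth$prey_universe))
  cont <- crap[crap$prey %in% truth$contaminants$prey, ]
  rest <- crap[!crap$prey %in% truth$contaminants$prey, ]
  expect_true(all(rest$detection_fraction == 0))
  expect_true(all(rest$mean_spectral_count == 0))
  # Detection fraction is the planted detection probability; the mean where
  # detected is the zero-truncated Poisson mean rate / (1 - exp(-rate)).
  m <- merge(cont, truth$contaminants, by = "prey")
  expect_equal(m$detection_fraction, m$detect_prob)
  expect_equal(m$mean_spectral_count, m$rate / (1 - exp(-m$rate)))
})

test_that("simulate_known_db covers true edges and never self-pairs", {
  truth <- tiny_truth()
  db <- simulate_known_db(truth, coverage = 0.5, seed = 5L)
  expect_true(all(db$a < db$b))
  pairs <- canonical_pair(truth$true_edges$bait, truth$true_edges$prey)
  true_key <- paste(pairs$a, pairs$b)
  db_key <- paste(db$a, db$b)
  spur <- attr(db, "spurious_pairs")
  spur_key <- paste(spur$a, spur$b)
  expect_true(all(db_key %in% c(true_key, spur_key)))
  # Roughly half the distinct true pairs are known (exact count by design).
  expect_equal(sum(db_key %in% true_key),
               round(0.5 * length(unique(true_key))))
  # Spurious pairs never duplicate true edges.
  expect_false(any(spur_key %in% true_key))
  expect_true(all(db$n_sources >= 1L))
})

test_that("simulate_annotations exposes planted pools as terms/complexes", {
  truth <- tiny_truth()
  ann <- simulate_annotations(truth, seed = 2L)
  pool_terms <- ann$terms[grepl("^POOL", ann$terms$term_id), ]
  expect_equal(nrow(pool_terms), length(truth$planted_clusters))
  expect_identical(pool_terms$members, truth$planted_clusters)
  pool_cx <- ann$complexes[grepl("^CPXPOOL", ann$complexes$complex_id), ]
  for (i in seq_len(nrow(pool_cx))) {
    expect_true(all(pool_cx$subunits[[i]] %in% truth$planted_clusters[[i]]))
  }
})

test_that("simulate_phospho plants consistent windows and motifs", {
  sim <- simulate_phospho(kinases = sprintf("K%02d", 1:6),
                          sites_per_kinase = 10L, n_substrates = 40L,
                          substrate_length = 200L, seed = 11L)
  expect_s3_class(sim, "rtk_phospho_sim")
  s <- sim$sites
  expect_true(all(s$residue == "Y"))
  expect_true(all(nchar(s$window) == 15L))
  # The window column is consistent with the final sequences.
  expect_equal(s$window, extract_window(sim$sequences[s$substrate],
                                        s$position))
  # The acceptor itself is a tyrosine in the sequence.
  expect_true(all(substr(s$window, 8, 8) == "Y"))
  # Sites flagged motif_match really match their kinase's motif fully.
  matched <- s[s$motif_match, ]
  mm <- match_motifs(matched$window, sim$motifs)
  own <- merge(matched[, c("kinase", "window")],
               mm[, c("kinase", "window", "fraction")],
               by = c("kinase", "window"))
  expect_true(all(own$fraction == 1))
  # Control sites are a subset of observed site keys.
  expect_true(all(paste(sim$control_sites$substrate,
                        sim$control_sites$position) %in%
                    paste(s$substrate, s$position)))
})

test_that("simulate_phospho external substrates without tyrosine warn", {
  seqs <- c(A = paste(rep("A", 60), collapse = ""),
            B = paste(rep(c("Y", "A", "C", "D"), 15), collapse = ""))
  expect_warning(
    sim <- simulate_phospho(kinases = sprintf("K%02d", 1:3),
                            substrate_fasta = seqs, sites_per_kinase = 1L,
                            seed = 1L),
    class = "rtkscape_no_tyrosine")
  expect_true(all(sim$sites$substrate == "B"))
})

test_that("simulate_study is deterministic in its master seed", {
  a <- simulate_study(seed = 9L,
                      interactome = list(n_baits = 6L, n_subfamilies = 3L,
                                         n_preys = 300L,
                                         edges_per_bait = 10L),
                      phospho = list(kinases = sprintf("K%02d", 1:5),
                                     sites_per_kinase = 8L,
                                     n_substrates = 30L))
  b <- simulate_study(seed = 9L,
                      interactome = list(n_baits = 6L, n_subfamilies = 3L,
                                         n_preys = 300L,
                                         edges_per_bait = 10L),
                      phospho = list(kinases = sprintf("K%02d", 1:5),
                                     sites_per_kinase = 8L,
                                     n_substrates = 30L))
  expect_identical(a$counts_wt, b$counts_wt)
  expect_identical(a$known_db, b$known_db)
  expect_identical(a$phospho$sites, b$phospho$sites)
})
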