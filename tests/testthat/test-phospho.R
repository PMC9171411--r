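test_that("extract_window pads termini with underscores", {
  # Frozen worked example: position 2 of 'MYSA' in a +/-7 window.
  expect_equal(extract_window("MYSA", 2), "______MYSA_____")
  expect_equal(nchar(extract_window("MYSA", 2)), 15L)
  # Interior positions need no padding.
  seq20 <- paste(rep("ACDEF", 4), collapse = "")
  w <- extract_window(seq20, 10)
  expect_equal(w, substr(seq20, 3, 17))
  # Vectorized and range-checked.
  expect_equal(extract_window(c("MYSA", "MYSA"), c(1, 4)),
               c("_______MYSA____", "____MYSA_______"))
  expect_error(extract_window("MYSA", 5),
               class = "rtkscape_validation_error")
  expect_error(extract_window("MYSA", 0),
               class = "rtkscape_validation_error")
  # Other flanks work too.
  expect_equal(extract_window("MYSA", 2, flank = 1L), "MYS")
})

test_that("filter_sites boundary, control removal and residue guard", {
  sites <- tibble::tibble(
    kinase = "K1",
    substrate = paste0("S", 1:6),
    position = rep(10L, 6),
    residue = c("Y", "Y", "Y", "Y", "Y", "S"),
    localization_probability = c(0.75, 0.7499999, 0.9, 0.2, 0.99, 0.99))
  ctrl <- tibble::tibble(substrate = "S5", position = 10L, residue = "Y")
  expect_warning(kept <- filter_sites(sites, ctrl, pipeline_config()),
                 class = "rtkscape_non_tyrosine")
  # Exactly 0.75 is kept; just below is dropped; control sites are dropped
  # regardless of probability; non-tyrosine rows are dropped.
  expect_equal(kept$substrate, c("S1", "S3"))
  expect_warning(
    ann <- filter_sites(sites, ctrl, pipeline_config(), keep_all = TRUE),
    class = "rtkscape_non_tyrosine")
  expect_equal(ann$drop_reason,
               c(NA, "low_localization_probability", NA,
                 "low_localization_probability", "seen_in_control",
                 "non_tyrosine"))
  # NULL / empty control tables are fine (row 2 still fails the
  # localization-probability cut).
  expect_equal(nrow(filter_sites(sites[1:3, ], NULL)), 2L)
})

test_that("tabulate_relations identities hold", {
  sites <- tibble::tibble(
    kinase = c("K1", "K1", "K2", "K2", "K1"),
    substrate = c("S1", "S1", "S1", "S2", "S1"),
    position = c(5L, 9L, 5L, 5L, 5L))  # last row duplicates the first
  tab <- tabulate_relations(sites)
  expect_equal(tab$n_unique_sites, 3L)  # S1:5, S1:9, S2:5
  expect_equal(tab$n_pairs, 3L)         # K1-S1, K2-S1, K2-S2
  expect_equal(tab$n_relations, 4L)
  expect_lte(tab$n_unique_sites, tab$n_relations)
  expect_lte(tab$n_pairs, tab$n_relations)
  expect_equal(tab$per_kinase$n_sites[tab$per_kinase$kinase == "K1"], 2L)
})

test_that("annotate_known_sites distinguishes the annotation tiers", {
  sites <- tibble::tibble(
    kinase = c("K1", "K1", "K2"),
    substrate = c("S1", "S2", "S3"),
    position = c(10L, 20L, 30L),
    window = c("AAAAAAAYAAAAAAA", "CCCCCCCYCCCCCCC", "DDDDDDDYDDDDDDD"))
  db <- tibble::tibble(
    substrate = c("S1", "S9"),
    position = c(10L, 99L),
    kinase = c("K9", NA),
    window = c(NA, "CCCCCCCYCCCCCCC"))
  ann <- annotate_known_sites(sites, db)
  expect_equal(ann$known_site, c(TRUE, FALSE, FALSE))
  # Same site known, but under a different kinase.
  expect_equal(ann$known_kinase_site, c(FALSE, FALSE, FALSE))
  # S2's window equals a database window recorded for a different site.
  expect_equal(ann$window_identity_match, c(FALSE, TRUE, FALSE))
  expect_equal(ann$novel, c(FALSE, FALSE, TRUE))
  # Empty database: everything novel.
  ann0 <- annotate_known_sites(sites, NULL)
  expect_true(all(ann0$novel))
})

test_that("parse_motif implements the token grammar", {
  m <- parse_motif("E-x-y-x-[LIV]")
  expect_equal(m$offset, c(-2L, -1L, 0L, 1L, 2L))
  expect_equal(m$type, c("residue", "wildcard", "acceptor", "wildcard",
                         "set"))
  expect_equal(m$residues[[1]], "E")
  expect_equal(m$residues[[3]], "Y")
  expect_equal(m$residues[[5]], c("L", "I", "V"))
  expect_error(parse_motif("E-x-x"), class = "rtkscape_parse_error")
  expect_error(parse_motif("y-x-y"), class = "rtkscape_parse_error")
  expect_error(parse_motif("E--y"), class = "rtkscape_parse_error")
  expect_error(parse_motif("E-#-y"), class = "rtkscape_parse_error")
})

test_that("match_motifs scores constrained positions only", {
  motifs <- tibble::tibble(name = c("m1", "m2"), kinase = c("K1", "K2"),
                           pattern = c("E-x-y-x-[LIV]", "x-y-x"))
  # Window: centre Y at position 8, E at offset -2, V at offset +2.
  w_full <- "AAAAAEAYAVAAAAA"
  w_half <- "AAAAAEAYAQAAAAA"   # +2 is Q: only 1 of 2 constraints met
  w_none <- "AAAAAQAYAQAAAAA"
  mm <- match_motifs(c(w_full, w_half, w_none), motifs)
  m1 <- mm[mm$motif == "m1", ]
  expect_equal(m1$n_constrained, rep(2L, 3))
  expect_equal(m1$fraction, c(1, 0.5, 0))
  # All-wildcard motifs match vacuously with fraction 1.
  m2 <- mm[mm$motif == "m2", ]
  expect_equal(m2$fraction, rep(1, 3))
  expect_equal(m2$n_constrained, rep(0L, 3))
  # Padding underscores never satisfy a constraint.
  pad_hit <- extract_window("YA", 1)            # E position falls in padding
  mp <- match_motifs(pad_hit, motifs[1, ])
  expect_equal(mp$fraction, 0)
  # Guards: mixed lengths and over-long motifs.
  expect_error(match_motifs(c(w_full, "SHORT"), motifs),
               class = "rtkscape_validation_error")
  long_motif <- tibble::tibble(
    name = "m3", kinase = "K3",
    pattern = paste(c("y", rep("x", 8), "E"), collapse = "-"))
  expect_error(match_motifs(w_full, long_motif),
               class = "rtkscape_validation_error")
})

test_that("site_motif_profile reports own and best motif fractions", {
  motifs <- tibble::tibble(name = c("K1_motif", "K2_motif"),
                           kinase = c("K1", "K2"),
                           pattern = c("E-x-y", "y-x-P"))
  sites <- tibble::tibble(
    kinase = c("K1", "K2"),
    substrate = c("S1", "S2"), position = c(8L, 8L),
    window = c("AAAAAEAYAAAAAAA",   # matches K1's motif, not K2's
               "AAAAAEAYAPAAAAA"))  # matches both
  prof <- site_motif_profile(sites, motifs)
  expect_equal(prof$own_motif_fraction, c(1, 1))
  expect_equal(prof$best_fraction, c(1, 1))
  expect_equal(prof$best_motif[1], "K1_motif")  # ties broken by name
})

test_that("cluster_substrate_profiles builds a Ward/Jaccard dendrogram", {
  sites <- tibble::tibble(
    kinase = rep(c("K1", "K2", "K3", "K4"), each = 3),
    substrate = c("S1", "S2", "S3",  "S1", "S2", "S4",
                  "S7", "S8", "S9",  "S7", "S8", "S5"),
    position = rep(10L, 12))
  dend <- cluster_substrate_profiles(sites)
  expect_s3_class(dend, "rtk_dendrogram")
  expect_equal(dend$hclust$method, "ward.D2")
  expect_equal(sort(rownames(dend$matrix)), c("K1", "K2", "K3", "K4"))
  # The binary distance is the Jaccard distance: K1 vs K2 share 2 of 4.
  d <- dist(dend$matrix, method = "binary")
  expect_equal(as.matrix(d)["K1", "K2"], 0.5)
  # K1/K2 and K3/K4 pair up.
  grp <- cutree(dend$hclust, k = 2)
  expect_equal(grp[["K1"]], grp[["K2"]])
  expect_equal(grp[["K3"]], grp[["K4"]])
  expect_false(grp[["K1"]] == grp[["K3"]])
  # Newick string round-trips through ape.
  phy <- ape::read.tree(text = dend$newick)
  expect_setequal(phy$tip.label, c("K1", "K2", "K3", "K4"))
  expect_error(cluster_substrate_profiles(sites[1:6, ]),
               class = "rtkscape_config_error")
})

test_that("compare_dendrograms on identical trees gives correlation 1", {
  # Shared within-group sites give non-degenerate (varying) distances.
  kin <- sprintf("K%02d", 1:8)
  sim <- simulate_phospho(kinases = kin,
                          sites_per_kinase = 6L, n_substrates = 30L,
                          substrate_length = 200L, seed = 3L,
                          groups = setNames(rep(c("G1", "G2"), each = 4),
                                            kin),
                          site_sharing = 0.5)
  dend <- cluster_substrate_profiles(sim$sites)
  cmp <- compare_dendrograms(dend, dend$newick)
  expect_equal(cmp$cophenetic_correlation, 1)
  expect_equal(nrow(cmp$alignment), 8L)
  expect_equal(cmp$alignment$position_a, cmp$alignment$position_b)
  other <- cluster_substrate_profiles(
    simulate_phospho(kinases = sprintf("K%02d", 2:9),
                     sites_per_kinase = 6L, n_substrates = 30L,
                     substrate_length = 200L, seed = 4L)$sites)
  expect_error(compare_dendrograms(dend, other),
               class = "rtkscape_validation_error")
})
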