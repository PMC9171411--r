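test_that("prey_profile_matrix averages counts and applies min_baits", {
  hcis <- tibble::tibble(
    bait = c("B1", "B2", "B3", "B1", "B2", "B1"),
    prey = c("P1", "P1", "P1", "P2", "P2", "P3"),
    detection = c("BIOID_ONLY", "BIOID_ONLY", "BOTH", "BIOID_ONLY",
                  "BIOID_ONLY", "APMS_ONLY"))
  counts <- tibble::tibble(
    bait = c("B1", "B1", "B2", "B3", "B1", "B2", "B1", "B3"),
    method = c(rep("BIOID", 6), "APMS", "APMS"),
    condition = "WT",
    replicate = c(1L, 2L, 1L, 1L, 1L, 1L, 1L, 1L),
    prey = c("P1", "P1", "P1", "P1", "P2", "P2", "P3", "P1"),
    spectral_count = c(10, 14, 8, 6, 5, 7, 9, 4))
  mat <- prey_profile_matrix(hcis, counts, stratum = "BIOID", min_baits = 2L)
  expect_equal(sort(rownames(mat)), c("P1", "P2"))
  expect_equal(colnames(mat), c("B1", "B2", "B3"))
  # B1 ran two BIOID replicates: averages are over all replicates of the
  # bait run, so P2's single observation of 5 averages to 2.5.
  expect_equal(mat["P1", ], c(B1 = 12, B2 = 8, B3 = 6))
  expect_equal(mat["P2", ], c(B1 = 2.5, B2 = 7, B3 = 0))
  # min_baits = 3 drops P2 (two non-zero entries).
  mat3 <- prey_profile_matrix(hcis, counts, stratum = "BIOID", min_baits = 3L)
  expect_equal(rownames(mat3), "P1")
  # APMS stratum sees only the APMS_ONLY/BOTH pairs.
  mata <- prey_profile_matrix(hcis, counts, stratum = "APMS", min_baits = 1L)
  expect_setequal(rownames(mata), c("P1", "P3"))
  expect_equal(mata["P1", ], c(B1 = 0, B2 = 0, B3 = 4))
})

test_that("correlate_preys matches the direct Pearson/t computation", {
  set.seed(31)
  mat <- matrix(rpois(5 * 8, 10), nrow = 5,
                dimnames = list(paste0("P", 1:5), paste0("B", 1:8)))
  out <- correlate_preys(mat, pipeline_config(), stratum = "BIOID",
                         keep_all = TRUE)
  expect_equal(nrow(out), choose(5, 2))
  for (i in seq_len(nrow(out))) {
    x <- mat[out$prey_a[i], ]
    y <- mat[out$prey_b[i], ]
    r <- cor(x, y)
    expect_equal(out$r[i], r)
    tt <- r * sqrt(6 / (1 - r^2))
    expect_equal(out$p[i], 2 * pt(-abs(tt), 6))
  }
  expect_equal(out$q, benjamini_hochberg(out$p))
  expect_equal(out$retained, out$r > 0.7 & out$q < 0.01)
  # Canonical pair order.
  expect_true(all(out$prey_a < out$prey_b))
})

test_that("correlate_preys boundary and degenerate inputs", {
  mat <- rbind(P1 = c(1, 2, 3), P2 = c(2, 4, 6), P3 = c(5, 5, 5))
  expect_warning(out <- correlate_preys(mat, keep_all = TRUE),
                 class = "rtkscape_zero_variance")
  expect_equal(nrow(out), 1L)   # only P1-P2 remains
  expect_equal(out$r, 1)
  expect_equal(out$p, 0)        # |r| = 1 handled explicitly
  expect_error(correlate_preys(mat[1, , drop = FALSE]),
               class = "rtkscape_config_error")
  expect_error(correlate_preys(mat[, 1:2]),
               class = "rtkscape_config_error")
  # Anti-correlation is never retained, whatever its q-value.
  m2 <- rbind(P1 = c(1, 5, 2, 8, 3), P2 = c(9, 2, 8, 1, 7),
              P3 = c(1, 5, 2, 8, 3.1))
  full <- correlate_preys(m2, keep_all = TRUE)
  anti <- full[full$r < 0, ]
  expect_true(all(!anti$retained))
})

test_that("extract_clusters returns disjoint connected components", {
  edges <- tibble::tibble(
    prey_a = c("A", "B", "A", "X", "Y", "M"),
    prey_b = c("B", "C", "C", "Y", "Z", "N"),
    stratum = "BIOID")
  cl <- extract_clusters(edges, min_size = 3L)
  expect_equal(nrow(cl), 2L)  # the M-N pair is below min_size
  expect_equal(cl$cluster_id, c("BIOID_C01", "BIOID_C02"))
  members <- unlist(cl$members)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(members, c("A", "B", "C", "X", "Y", "Z"))
  expect_equal(sort(cl$size, decreasing = TRUE), cl$size)
  # Single-stratum guard and empty input.
  mixed <- edges
  mixed$stratum[1] <- "APMS"
  expect_error(extract_clusters(mixed), class = "rtkscape_validation_error")
  expect_equal(nrow(extract_clusters(edges[0, ])), 0L)
})

test_that("complex_coverage keeps >= 60% and resolves overlaps greedily", {
  cx <- tibble::tibble(
    complex_id = c("CPX1", "CPX2", "CPX3", "CPX4"),
    name = paste("complex", 1:4),
    subunits = list(c("A", "B", "C", "D", "E"),   # 3/5 = 0.6 identified
                    c("A", "B", "C"),             # 3/3 = 1, overlaps CPX1
                    c("F", "G", "H", "I", "J"),   # 2/5 = 0.4: dropped
                    c("K", "L")),                 # 2/2 = 1, disjoint
    n_subunits = c(5L, 3L, 5L, 2L))
  found <- c("A", "B", "C", "F", "G", "K", "L")
  calls <- complex_coverage(found, cx, pipeline_config())
  # CPX2 (coverage 1) wins over the overlapping CPX1; CPX4 is independent.
  expect_setequal(calls$complex_id, c("CPX2", "CPX4"))
  expect_equal(calls$coverage[calls$complex_id == "CPX2"], 1)
  # Exactly 60% coverage is kept when there is no overlap conflict.
  solo <- complex_coverage(c("A", "B", "C"), cx[1, ], pipeline_config())
  expect_equal(solo$complex_id, "CPX1")
  expect_equal(solo$coverage, 0.6)
})
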