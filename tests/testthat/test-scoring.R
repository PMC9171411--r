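test_that("bfdr_from_posterior implements the cumulative-mean convention", {
  # Frozen worked example: posteriors 0.99, 0.90, 0.50 ranked descending give
  # cumulative means of (1 - posterior): 0.01, 0.055, 0.203333...
  expect_equal(bfdr_from_posterior(c(0.99, 0.90, 0.50)),
               c(0.01, 0.055, 61 / 300))
  expect_equal(bfdr_from_posterior(numeric(0)), numeric(0))
  expect_equal(bfdr_from_posterior(rep(1, 4)), rep(0, 4))
  expect_error(bfdr_from_posterior(c(0.5, 1.2)),
               class = "rtkscape_validation_error")
  # Monotone non-decreasing along any descending-posterior ranking.
  p <- sort(runif(50), decreasing = TRUE)
  expect_true(all(diff(bfdr_from_posterior(p)) >= 0))
})

test_that("posterior equals the prior when signal equals background", {
  # Bait counts at or below the control mean give lambda1 == lambda0, a log
  # likelihood ratio of zero, and therefore posterior == prior exactly.
  counts <- hand_counts()  # P2: bait avg 1, control mean 10
  scored <- score_interactions(counts, prior_true = 0.05)
  p2 <- scored[scored$prey == "P2", ]
  expect_equal(p2$lambda0, 10)
  expect_equal(p2$posterior_true, 0.05)
  # P1 (avg 25 vs pseudo-rate background) is effectively certain.
  p1 <- scored[scored$prey == "P1", ]
  expect_gt(p1$posterior_true, 0.999)
  expect_lt(p1$bfdr, 0.001)
})

test_that("scorer matches a hand computation on the two-prey example", {
  scored <- score_interactions(hand_counts(), prior_true = 0.05,
                               pseudo_rate = 0.1)
  p1 <- scored[scored$prey == "P1", ]
  lambda0 <- 0.1   # P1 absent from controls -> pseudo-rate floor
  lambda1 <- 25    # (20 + 30) / 2
  llr <- 50 * log(lambda1 / lambda0) - 2 * (lambda1 - lambda0)
  post <- 1 / (1 + (0.95 / 0.05) * exp(-llr))
  expect_equal(p1$posterior_true, post)
  expect_equal(p1$avg_count, 25)
  # BFDR of the top-ranked pair is 1 - its posterior.
  expect_equal(p1$bfdr, 1 - post)
})

test_that("scorer requires controls and groups BFDR per bait run", {
  counts <- hand_counts()
  expect_error(score_interactions(counts[!counts$bait == control_tag(), ]),
               class = "rtkscape_config_error")
  expect_error(score_interactions(hand_counts(), prior_true = 0),
               class = "rtkscape_config_error")
  # BFDRs are computed within (bait, method, condition): each group's
  # sequence is the cumulative mean of its own 1 - posterior.
  truth <- tiny_truth()
  scored <- score_interactions(tiny_counts(truth))
  grp <- split(scored, paste(scored$bait, scored$method, scored$condition))
  for (g in grp[1:5]) {
    expect_equal(g$bfdr, bfdr_from_posterior(g$posterior_true))
  }
})

test_that("HCI filter boundary semantics are strict", {
  crapome <- tibble::tibble(
    prey = c("FREQ_HI", "FREQ_EDGE", "FREQ_LO"),
    detection_fraction = c(0.9, 0.20, 0.05),
    mean_spectral_count = c(10, 10, 10))
  scored <- tibble::tibble(
    bait = "B1",
    prey = c("FREQ_HI", "FREQ_HI", "FREQ_EDGE", "FREQ_EDGE", "FREQ_LO",
             "ABSENT", "ABSENT"),
    avg_count = c(30.0000001, 30, 30.0000001, 30, 2, 5, 5),
    bfdr = c(0.01, 0.01, 0.01, 0.01, 0.01, 0.049999, 0.05))
  out <- apply_hci_filter(scored, crapome, pipeline_config(),
                          keep_all = TRUE)
  expect_equal(out$retained,
               c(TRUE,    # fc 3.0000.. > 3 rescues the frequent prey
                 FALSE,   # fc exactly 3 does not rescue
                 TRUE,    # frequency exactly 0.20 needs the rescue, fc > 3
                 FALSE,   # frequency exactly 0.20, fc exactly 3: dropped
                 TRUE,    # rare prey kept regardless of fold change
                 TRUE,    # bfdr strictly below 0.05
                 FALSE))  # bfdr exactly 0.05: dropped
  # Preys absent from the repository get frequency 0 and the pseudo-rate
  # denominator.
  ab <- out[out$prey == "ABSENT", ][1, ]
  expect_equal(ab$crapome_frequency, 0)
  expect_equal(ab$crapome_fold_change, 5 / 0.1)
})

test_that("merge_strata labels detection classes and known pairs", {
  apms <- tibble::tibble(bait = c("B1", "B1"), prey = c("P1", "P2"),
                         avg_count = c(10, 5), bfdr = c(0.01, 0.02))
  bioid <- tibble::tibble(bait = c("B1", "B1"), prey = c("P2", "P3"),
                          avg_count = c(7, 3), bfdr = c(0.01, 0.03))
  db <- build_known_db(tibble::tibble(a = "P3", b = "B1", source = "S1"))
  merged <- merge_strata(apms, bioid, db)
  expect_equal(merged$detection[match(c("P1", "P2", "P3"), merged$prey)],
               c("APMS_ONLY", "BOTH", "BIOID_ONLY"))
  expect_equal(merged$known[match(c("P1", "P2", "P3"), merged$prey)],
               c(FALSE, FALSE, TRUE))
  expect_equal(merged$known_sources[[match("P3", merged$prey)]], "S1")
  # Detection classes partition the merged set.
  expect_equal(nrow(merged), 3L)
  expect_false(any(is.na(merged$detection)))
})

test_that("compare_conditions splits shared and specific pairs", {
  a <- tibble::tibble(bait = "B1", prey = c("P1", "P2", "P3", "P4"),
                      avg_count = c(10, 20, 30, 40))
  b <- tibble::tibble(bait = "B1", prey = c("P2", "P3", "P4", "P5"),
                      avg_count = c(22, 28, 44, 9))
  cmp <- compare_conditions(a, b, label_a = "WT", label_b = "KD")
  expect_s3_class(cmp, "rtk_condition_comparison")
  expect_equal(nrow(cmp$shared), 3L)
  expect_equal(cmp$a_only$prey, "P1")
  expect_equal(cmp$b_only$prey, "P5")
  expect_equal(cmp$r, cor(c(20, 30, 40), c(22, 28, 44)))
  g <- generics::glance(cmp)
  expect_equal(g$n_shared, 3L)
  # Fewer than 3 shared pairs: r undefined.
  expect_message(
    cmp2 <- compare_conditions(a[1:2, ], b[3:4, ]),
    "fewer than 3 shared pairs")
  expect_true(is.na(cmp2$r))
})
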