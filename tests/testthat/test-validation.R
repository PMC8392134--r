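test_that("all printed WES truth variants are recovered without a window", {
  fx <- build_table1_fixture()
  summary <- compare_to_truth(fx$calls, fx$truth)
  expect_equal(summary$tp, 13L)
  expect_equal(summary$fn, 0L)
  expect_equal(summary$sensitivity, 100)
})

test_that("confusion counts match the brute-force oracle on small instances", {
  for (seed in 1:6) {
    universe <- random_calls(30, seed = seed)
    truth_idx <- withr::with_seed(seed + 100, sample.int(30, 8))
    truth <- truth_from_calls(universe, truth_idx)
    kept_idx <- withr::with_seed(seed + 200, sample.int(30, 15))
    kept <- universe[kept_idx, ]
    got <- compare_to_truth(kept, truth, universe = universe)
    want <- oracle_confusion(kept, truth, universe = universe)
    expect_equal(got$tp, want$tp)
    expect_equal(got$fp, want$fp)
    expect_equal(got$fn, want$fn)
    expect_equal(got$tn, want$tn)
  }
})

test_that("empty call set yields pure false negatives", {
  calls <- random_calls(5, seed = 1)
  truth <- truth_from_calls(calls, 1)
  summary <- compare_to_truth(calls[0, ], truth)
  expect_equal(summary$fn, 1L)
  expect_equal(summary$sensitivity, 0)
})

test_that("duplicate truth records are rejected", {
  calls <- random_calls(5, seed = 1)
  truth <- truth_from_calls(calls, c(1, 1))
  expect_error(compare_to_truth(calls, truth), "duplicate truth")
})

test_that("indel representations are normalized before matching", {
  # a padded SNV matches its minimal representation after prefix trimming
  calls <- variant_calls("s", "chr1", 100, "TTG", "TTA", 10, 10)
  truth <- truth_records("s", "chr1", 102, "G", "A")
  summary <- compare_to_truth(calls, truth)
  expect_equal(summary$tp, 1L)
  expect_equal(summary$fn, 0L)
  # a deletion padded with a trailing reference base matches the minimal form
  del <- variant_calls("s", "chr1", 100, "GAT", "GT", 10, 10)
  del_truth <- truth_records("s", "chr1", 100, "GA", "G")
  expect_equal(compare_to_truth(del, del_truth)$tp, 1L)
  # delins forms annotated with different padding match after normalization
  calls2 <- variant_calls("s", "chr1", 200, "CAACTGGT", "CGGAGT", 10, 10)
  truth2 <- truth_records("s", "chr1", 201, "AACTGG", "GGAG")
  expect_equal(compare_to_truth(calls2, truth2)$tp, 1L)
})

test_that("per-position mode counts negatives over wild-type spans", {
  calls <- variant_calls("s", "chr1", c(100, 300), "A", "G", 10, 10)
  truth <- dplyr::bind_rows(
    truth_records("s", "chr1", 100, "A", "G"),
    truth_records("s", "chr1", status = "wildtype_confirmed",
                  span_start = 200, span_end = 3768) # 3569 bases
  )
  summary <- compare_to_truth(calls, truth, mode = "per_position")
  expect_equal(summary$tp, 1L)
  expect_equal(summary$fp, 1L) # the call at 300 inside the wild-type span
  expect_equal(summary$tn, 3569L - 1L)
})

test_that("window grid reproduces the printed platform comparison", {
  fx <- build_table1_fixture()
  grid <- window_grid(fx$calls, fx$truth,
                      list(afr_window(30, 70), afr_window(41.1, 58.8)))
  cg_wide <- grid[grid$platform == "Complete Genomics" &
                    grid$window == "30-70", ]
  expect_equal(cg_wide$false_negative, 1L) # the 0.27 frameshift call
  expect_equal(cg_wide$detected, 7L)
  cg_narrow <- grid[grid$platform == "Complete Genomics" &
                      grid$window == "41.1-58.8", ]
  expect_equal(cg_narrow$false_negative, 5L) # over the 8 printed calls
  # a vacuous window never loses a called variant
  full <- window_grid(fx$calls, fx$truth, list(afr_window(0, 100)))
  expect_true(all(full$false_negative == 0L))
  expect_true(all(full$sensitivity == 100))
})

test_that("sensitivity is non-increasing as the window narrows", {
  for (seed in 1:5) {
    calls <- random_calls(25, seed = seed)
    truth <- truth_from_calls(calls, 1:10)
    widths <- seq(50, 2, by = -4)
    windows <- lapply(widths, function(d) afr_window(50 - d, 50 + d))
    grid <- window_grid(calls, truth, windows)
    # grid rows are emitted in window order within the single platform
    expect_true(all(diff(grid$sensitivity) <= 1e-9))
  }
})

test_that("optimized window restores 100% sensitivity, one step narrower fails", {
  fx <- build_table1_fixture()
  for (p in unique(fx$calls$platform)) {
    calls <- fx$calls[fx$calls$platform == p, ]
    truth <- fx$truth[fx$truth$sample_id %in% calls$sample_id, ]
    win <- optimize_window(calls, truth, "one_decimal")
    grid <- window_grid(calls, truth, list(win))
    expect_equal(grid$sensitivity, 100)
    narrower <- afr_window(win$lower_pct + 0.1, win$upper_pct - 0.1)
    grid2 <- window_grid(calls, truth, list(narrower))
    expect_lt(grid2$sensitivity, 100)
  }
  expect_error(
    optimize_window(fx$calls[-1, ], fx$truth),
    "no corresponding call"
  )
})

test_that("diagnostic yield reproduces the cohort summaries", {
  cohorts <- build_cohort_fixtures()
  ep2 <- diagnostic_yield(cohorts$table3, panel_version = "EP2.0")
  expect_equal(ep2$n_tested, 37L)
  expect_equal(ep2$n_carriers, 10L)
  expect_equal(ep2$yield_pct, 27)

  ep1p <- diagnostic_yield(cohorts$table3, panel_version = "EP1.0P",
                           count_mode = "gene_carrier",
                           genes = c("SDHB", "NF1"), digits = 1)
  expect_equal(ep1p$n_tested, 24L)
  expect_equal(ep1p$n_carriers, 9L)
  expect_equal(ep1p$yield_pct, 37.5)

  ep1v <- diagnostic_yield(cohorts$table3, panel_version = "EP1.0V")
  expect_equal(ep1v$n_carriers, 10L) # the verified-mutation carriers

  # the combined prospective yield (19/61 = 31.1%) adds the two cohorts
  # under their own counting conventions: gene-carrier for the first panel
  # version (one NF1 carrier's variant is classified VUS but counted),
  # clinical class for the second
  n_prosp <- ep1p$n_tested + ep2$n_tested
  n_carriers <- ep1p$n_carriers + ep2$n_carriers
  expect_equal(n_prosp, 61L)
  expect_equal(n_carriers, 19L)
  expect_equal(round_half_up(100 * n_carriers / n_prosp, 1), 31.1)

  expect_error(diagnostic_yield(cohorts$table3, panel_version = "EP9"),
               "empty cohort")
})

test_that("novel-variant counting tallies clinical classes", {
  cohorts <- build_cohort_fixtures()
  res <- count_novel(cohorts$table4, known_index = character())
  expect_equal(nrow(res$novel), 8L)
  tally <- res$class_tally
  n_plp <- sum(tally$n[tally$clinical_class %in%
                         c("pathogenic", "likely_pathogenic")])
  expect_equal(n_plp, 5L)
  expect_equal(sum(tally$n[tally$clinical_class == "vus"]), 3L)
  # known variants are excluded from the novel list
  res2 <- count_novel(cohorts$table4,
                      known_index = cohorts$table4$hgvs[1])
  expect_equal(nrow(res2$novel), 7L)
  # unusable HGVS strings are flagged, not dropped
  with_bad <- dplyr::bind_rows(
    cohorts$table4,
    tibble::tibble(hgvs = NA_character_, clinical_class = "vus")
  )
  res3 <- count_novel(with_bad)
  expect_equal(nrow(res3$flagged), 1L)
  expect_equal(nrow(count_novel(cohorts$table4[0, ])$novel), 0L)
})
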