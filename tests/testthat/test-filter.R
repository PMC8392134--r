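pad_call <- function(pos, consequence = "missense", hgvs_c = NA, ...) {
  variant_calls(
    sample_id = "s", chrom = "chr1", pos = pos, ref_allele = "A",
    alt_allele = "G", ref_reads = 25, alt_reads = 25,
    consequence = consequence, hgvs_c = hgvs_c, ...
  )
}

test_that("region filter applies inclusive intronic padding", {
  panel <- test_panel(pad = 30L)
  # interval [100, 200) covers 1-based positions 101..200; padded: 71..230
  expect_equal(nrow(filter_region(pad_call(230), panel)$kept), 1L) # 30 bp in
  expect_equal(nrow(filter_region(pad_call(231), panel)$kept), 0L) # 31 bp out
  expect_equal(nrow(filter_region(pad_call(71), panel)$kept), 1L)
  expect_equal(nrow(filter_region(pad_call(70), panel)$kept), 0L)
})

test_that("region filter keeps exactly the calls the generator placed on-target", {
  sim <- simulate_calls(
    simulation_spec(n_samples = 10, true_variants_per_sample = 5,
                    artifact_rate = 5, reference_mismatch_locus = NULL,
                    seed = 7)
  )
  res <- filter_region(sim$calls, sim$panel)
  expect_equal(nrow(res$kept), nrow(sim$calls)) # generator places on-target
  # shift half the calls far off-target and expect exactly those removed
  shifted <- sim$calls
  off <- seq_len(nrow(shifted)) %% 2 == 0
  shifted$chrom[off] <- "chrUn"
  res2 <- filter_region(shifted, sim$panel)
  expect_equal(nrow(res2$removed), sum(off))
})

test_that("consequence filter drops UTR/intronic/synonymous but rescues splice sites", {
  cfg <- filter_config()
  expect_equal(nrow(filter_consequence(pad_call(1, "synonymous"), cfg)$kept),
               0L)
  expect_equal(nrow(filter_consequence(pad_call(1, "utr"), cfg)$kept), 0L)
  expect_equal(nrow(filter_consequence(pad_call(1, "missense"), cfg)$kept),
               1L)
  # a +2 splice-site call is never dropped as intronic
  splice <- pad_call(1, "intronic", hgvs_c = "c.286+2T>A")
  expect_equal(nrow(filter_consequence(splice, cfg)$kept), 1L)
  splice2 <- pad_call(1, "splice", hgvs_c = "c.888+2T>G")
  expect_equal(nrow(filter_consequence(splice2, cfg)$kept), 1L)
  deep <- pad_call(1, "intronic", hgvs_c = "c.286+25T>A")
  expect_equal(nrow(filter_consequence(deep, cfg)$kept), 0L)
  # unknown consequence is kept and flagged
  unk <- pad_call(1)
  unk$consequence <- NA_character_
  res <- filter_consequence(unk, cfg)
  expect_equal(nrow(res$kept), 1L)
  expect_true(res$kept$flag_unknown_consequence)
})

test_that("common filter is strict >1% with unknown MAF retained", {
  cfg <- filter_config()
  expect_equal(nrow(filter_common(pad_call(1, population_maf = 0.02),
                                  cfg)$kept), 0L)
  expect_equal(nrow(filter_common(pad_call(1, population_maf = 0.01),
                                  cfg)$kept), 1L) # exactly 1% passes
  expect_equal(nrow(filter_common(pad_call(1), cfg)$kept), 1L) # unknown
  mixed <- random_calls(10, seed = 3)
  mixed$population_maf <- c(rep(0.05, 3), rep(0.001, 4), rep(NA, 3))
  expect_equal(nrow(filter_common(mixed, cfg)$kept), 7L)
})

test_that("benign filter requires concordant ACMG, PolyPhen and SIFT evidence", {
  cfg <- filter_config()
  benign <- pad_call(1, acmg_class = "benign", polyphen_category = "benign",
                     sift_score = 0.8)
  expect_equal(nrow(filter_benign(benign, cfg)$kept), 0L)
  vus <- pad_call(1, acmg_class = "vus", polyphen_category = "benign",
                  sift_score = 0.8)
  expect_equal(nrow(filter_benign(vus, cfg)$kept), 1L)
  discordant <- pad_call(1, acmg_class = "benign",
                         polyphen_category = "probably_damaging",
                         sift_score = 0.8)
  expect_equal(nrow(filter_benign(discordant, cfg)$kept), 1L)
  # a deleterious SIFT score blocks the benign call under the default rule
  sift_del <- pad_call(1, acmg_class = "benign", polyphen_category = "benign",
                       sift_score = 0.01)
  expect_equal(nrow(filter_benign(sift_del, cfg)$kept), 1L)
  cfg_flip <- filter_config(sift_deleterious_is_benign = TRUE)
  expect_equal(nrow(filter_benign(sift_del, cfg_flip)$kept), 0L)
  # unknown ACMG class is always kept
  unk <- pad_call(1, polyphen_category = "benign", sift_score = 0.8)
  expect_equal(nrow(filter_benign(unk, cfg)$kept), 1L)
})

test_that("depth filter tests both alleles for hets, alt only for homs", {
  panel_profile <- platform_profile("panel", 20)
  wgs_profile <- platform_profile("wgs", 5)
  het_thin <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 24,
                            alt_reads = 9)
  expect_equal(nrow(filter_depth(het_thin, panel_profile)$kept), 0L) # 9 < 20
  expect_equal(nrow(filter_depth(het_thin, wgs_profile)$kept), 1L) # 9 >= 5
  het_ok <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 27,
                          alt_reads = 23)
  expect_equal(nrow(filter_depth(het_ok, wgs_profile)$kept), 1L)
  hom <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 0,
                       alt_reads = 45, zygosity_claim = "hom")
  expect_equal(nrow(filter_depth(hom, panel_profile)$kept), 1L)
  no_alt <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 50,
                          alt_reads = 0)
  expect_equal(nrow(filter_depth(no_alt, wgs_profile)$kept), 0L)
})

test_that("blacklist removal is exact-match and annotated", {
  bl <- reference_mismatch_locus()
  cfg <- filter_config(blacklist = bl)
  hit <- variant_calls("s", bl$chrom, bl$pos, bl$ref_allele, bl$alt_allele,
                       ref_reads = 25, alt_reads = 25)
  res <- apply_blacklist(hit, cfg)
  expect_equal(nrow(res$kept), 0L)
  expect_match(res$removed$blacklist_note, "reference-mismatch")
  other_alt <- variant_calls("s", bl$chrom, bl$pos, bl$ref_allele, "G",
                             ref_reads = 25, alt_reads = 25)
  expect_equal(nrow(apply_blacklist(other_alt, cfg)$kept), 1L)
  no_bl <- filter_config()
  expect_equal(nrow(apply_blacklist(hit, no_bl)$kept), 1L) # empty blacklist
})

test_that("afr filter keeps in-window fractions inclusively", {
  cfg <- filter_config() # window 30-70
  out <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 24,
                       alt_reads = 9) # 0.27
  expect_equal(nrow(filter_afr(out, cfg)$kept), 0L)
  mid <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 20,
                       alt_reads = 20)
  expect_equal(nrow(filter_afr(mid, cfg)$kept), 1L)
  edge <- variant_calls("s", "chr1", 1, "A", "G", ref_reads = 70,
                        alt_reads = 30) # exactly 0.30
  expect_equal(nrow(filter_afr(edge, cfg)$kept), 1L)
})

test_that("cascade audit telescopes and conserves every call", {
  fx <- build_v1_validation_fixture()
  cfg <- filter_config(blacklist = fx$blacklist)
  res <- run_cascade(fx$calls, panel = fx$panel, profile = fx$profile,
                     config = cfg)
  a <- res$audit
  expect_equal(a$n_out, a$n_in - a$n_removed)
  expect_equal(a$n_in[-1], a$n_out[-nrow(a)])
  expect_equal(nrow(res$kept) + nrow(res$removed), nrow(fx$calls))
  expect_equal(sum(a$n_removed), nrow(res$removed))
  # every input call lands exactly once in kept or one stage's removals
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$alt_allele)
  expect_setequal(c(key(res$kept), key(res$removed)), key(fx$calls))
  expect_false(any(duplicated(c(key(res$kept), key(res$removed)))))
})

test_that("final surviving set is invariant under stage order", {
  fx <- build_v1_validation_fixture()
  cfg <- filter_config(blacklist = fx$blacklist)
  base <- run_cascade(fx$calls, panel = fx$panel, profile = fx$profile,
                      config = cfg)
  key <- function(df) paste(df$sample_id, df$chrom, df$pos, df$alt_allele)
  for (seed in 1:4) {
    perm <- withr::with_seed(seed, sample(cascade_stages))
    surviving <- fx$calls
    for (stage in perm) {
      res <- switch(stage,
        region = filter_region(surviving, fx$panel),
        consequence = filter_consequence(surviving, cfg),
        common = filter_common(surviving, cfg),
        benign = filter_benign(surviving, cfg),
        depth = filter_depth(surviving, fx$profile, cfg),
        blacklist = apply_blacklist(surviving, cfg),
        afr = filter_afr(surviving, cfg)
      )
      surviving <- res$kept
    }
    expect_setequal(key(surviving), key(base$kept))
  }
})

test_that("no filter removes a truth variant on a clean simulated fixture", {
  spec <- simulation_spec(n_samples = 8, true_variants_per_sample = 4,
                          artifact_rate = 6, clean = TRUE, seed = 21)
  sim <- simulate_calls(spec)
  cfg <- filter_config(blacklist = reference_mismatch_locus())
  res <- run_cascade(sim$calls, panel = sim$panel,
                     profile = spec$platform_profiles[[1]], config = cfg)
  summary <- compare_to_truth(res$kept, sim$truth, universe = sim$calls)
  expect_equal(summary$fn, 0L)
  expect_equal(summary$sensitivity, 100)
})

test_that("disabled cascade and empty input are identities", {
  calls <- random_calls(12, seed = 9)
  cfg <- filter_config(enabled = character())
  res <- run_cascade(calls, config = cfg)
  expect_equal(nrow(res$kept), nrow(calls))
  expect_equal(nrow(res$audit), 0L)
  empty <- run_cascade(calls[0, ], panel = test_panel(),
                       config = filter_config(enabled = cascade_stages))
  expect_equal(nrow(empty$kept), 0L)
  expect_true(all(empty$audit$n_removed == 0L))
})

test_that("filter config validates and loads from YAML", {
  expect_error(filter_config(maf_threshold = 0), "maf_threshold")
  expect_error(filter_config(enabled = "bogus"), "unknown stage")
  yaml_path <- withr::local_tempfile(fileext = ".yaml")
  bl_path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(reference_mismatch_locus(), bl_path)
  writeLines(c(
    "maf_threshold: 0.05",
    "afr_window: 41.1-58.8",
    "min_reads_per_allele: 10",
    paste0("blacklist: ", bl_path)
  ), yaml_path)
  cfg <- read_filter_config(yaml_path)
  expect_equal(cfg$maf_threshold, 0.05)
  expect_equal(cfg$afr_window$upper_pct, 58.8)
  expect_equal(cfg$min_reads_per_allele, 10L)
  expect_equal(nrow(cfg$blacklist), 1L)
})
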