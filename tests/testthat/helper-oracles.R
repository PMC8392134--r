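# Shared generators and independent oracles for property-style tests.

bases <- c("A", "C", "G", "T")

# random but structurally valid call table; positions are drawn without
# replacement so (sample, locus) keys never collide
random_calls <- function(n, seed, n_samples = 3, max_reads = 80) {
  withr::with_seed(seed, {
    ref_reads <- sample.int(max_reads, n, replace = TRUE)
    alt_reads <- sample.int(max_reads, n, replace = TRUE)
    ref_idx <- sample.int(4, n, replace = TRUE)
    alt_idx <- (ref_idx + sample.int(3, n, replace = TRUE) - 1L) %% 4L + 1L
    variant_calls(
      sample_id = sample(sprintf("R%02d", seq_len(n_samples)), n,
                         replace = TRUE),
      chrom = "chr1",
      pos = sample.int(100000, n, replace = FALSE),
      ref_allele = bases[ref_idx],
      alt_allele = bases[alt_idx],
      gene = sample(c("SDHB", "VHL", "RET"), n, replace = TRUE),
      ref_reads = ref_reads,
      alt_reads = alt_reads,
      consequence = sample(consequence_levels, n, replace = TRUE),
      population_maf = ifelse(runif(n) < 0.3, runif(n, 0, 0.1), NA_real_),
      acmg_class = sample(acmg_levels, n, replace = TRUE),
      polyphen_category = sample(polyphen_levels, n, replace = TRUE),
      sift_score = ifelse(runif(n) < 0.5, runif(n), NA_real_),
      zygosity_claim = sample(c("het", "hom"), n, replace = TRUE),
      platform = "sim"
    )
  })
}

# truth records matching a random subset of a call table
truth_from_calls <- function(calls, idx) {
  truth_records(
    sample_id = calls$sample_id[idx], chrom = calls$chrom[idx],
    pos = calls$pos[idx], ref_allele = calls$ref_allele[idx],
    alt_allele = calls$alt_allele[idx]
  )
}

# brute-force narrowest symmetric window on the reporting grid that
# contains every call's alt fraction (grid scan, independent of the
# max-deviation implementation)
oracle_tightest_window <- function(calls, step) {
  f_pct <- 100 * calls$alt_reads / (calls$ref_reads + calls$alt_reads)
  for (d in seq(0, 50, by = step)) {
    if (all(f_pct >= 50 - d - 1e-9 & f_pct <= 50 + d + 1e-9)) {
      return(c(50 - d, 50 + d))
    }
  }
  c(0, 100)
}

# brute-force confusion counts: quadratic double loop over calls and truth
oracle_confusion <- function(calls, truth, universe = NULL) {
  tv <- truth[truth$status == "variant_present", , drop = FALSE]
  match_one <- function(df, i, t, j) {
    df$sample_id[i] == t$sample_id[j] && df$chrom[i] == t$chrom[j] &&
      df$pos[i] == t$pos[j] && df$ref_allele[i] == t$ref_allele[j] &&
      df$alt_allele[i] == t$alt_allele[j]
  }
  in_truth <- function(df, i) {
    any(vapply(seq_len(nrow(tv)), function(j) match_one(df, i, tv, j),
               logical(1)))
  }
  called <- function(j) {
    any(vapply(seq_len(nrow(calls)), function(i) match_one(calls, i, tv, j),
               logical(1)))
  }
  tp <- sum(vapply(seq_len(nrow(calls)), function(i) in_truth(calls, i),
                   logical(1)))
  fp <- nrow(calls) - tp
  fn <- sum(!vapply(seq_len(nrow(tv)), called, logical(1)))
  tn <- NA_integer_
  if (!is.null(universe)) {
    art <- which(!vapply(seq_len(nrow(universe)), function(i) {
      in_truth(universe, i)
    }, logical(1)))
    surviving <- vapply(art, function(i) {
      any(vapply(seq_len(nrow(calls)), function(k) {
        calls$sample_id[k] == universe$sample_id[i] &&
          calls$chrom[k] == universe$chrom[i] &&
          calls$pos[k] == universe$pos[i] &&
          calls$ref_allele[k] == universe$ref_allele[i] &&
          calls$alt_allele[k] == universe$alt_allele[i]
      }, logical(1)))
    }, logical(1))
    tn <- sum(!surviving)
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn)
}

# small fixed panel used across filter tests
test_panel <- function(pad = 30L) {
  panel_design(
    "test",
    tibble::tibble(
      chrom = c("chr1", "chr1", "chr2"),
      start = c(100L, 1000L, 500L),
      end = c(200L, 1100L, 600L),
      gene = c("SDHB", "SDHB", "VHL")
    ),
    intronic_padding_bp = pad
  )
}
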