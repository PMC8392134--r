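# Synthetic call sets and deterministic validation fixtures.
#
# Two kinds of data live here. The simulator draws call sets with the
# statistical structure the pipeline assumes: negative-binomial depth,
# binomial or beta-binomial heterozygous allele fractions (wider spread =
# higher intra-class correlation rho), artifact calls with fractions skewed
# away from 0.5, and a reference-mismatch locus called in every sample. The
# fixture builders deterministically reconstruct the printed per-variant data
# of a published panel-validation study (read-count pairs, aggregate
# true/false-positive counts, cohort tables) so every stage is verifiable at
# desk scale. All fixture genomic coordinates are synthetic placeholders.

v1_panel_genes <- c("EGLN1", "EPAS1", "FH", "KIF1B", "MAX", "MEN1", "NF1",
                    "RET", "SDHA", "SDHAF2", "SDHB", "SDHC", "SDHD",
                    "TMEM127", "VHL")

# deterministic synthetic coordinate space: gene i occupies
# chr{i}:[i*1e6, i*1e6 + len) except MEN1, which is pinned near the
# real rs2959656 neighbourhood so the blacklist entry reads naturally
synthetic_panel <- function(genes = v1_panel_genes, gene_length = 1000L,
                            name = "synthetic-panel") {
  idx <- seq_along(genes)
  start <- as.integer(idx * 1e6)
  chrom <- paste0("chr", idx)
  men1 <- which(genes == "MEN1")
  if (length(men1) == 1) {
    chrom[men1] <- "chr11"
    start[men1] <- 64570000L
  }
  panel_design(name, tibble(
    chrom = chrom,
    start = start,
    end = start + as.integer(gene_length),
    gene = genes
  ))
}

#' The reference-mismatch artifact locus used by the packaged fixtures
#'
#' A synthetic analog of a position where the reference genome carries the
#' minor allele, so essentially every sample yields a spurious heterozygous
#' call there (the MEN1 rs2959656 phenomenon). Packaged as a one-row
#' blacklist.
#'
#' @return A one-row blacklist tibble.
#' @export
reference_mismatch_locus <- function() {
  tibble(
    chrom = "chr11", pos = 64570557L, ref_allele = "T", alt_allele = "C",
    note = "reference-mismatch artifact (MEN1 rs2959656 analog, synthetic)"
  )
}

#' Specify a simulation
#'
#' @param platform_profiles A list of [platform_profile()] objects; samples
#'   are assigned to profiles round-robin.
#' @param n_samples Total number of samples.
#' @param true_variants_per_sample True heterozygous variants per sample.
#' @param artifact_rate Expected artifact calls per sample (Poisson).
#' @param reference_mismatch_locus A one-row blacklist tibble emitted as a
#'   genuine-looking heterozygous call in every sample, or `NULL`.
#' @param in_window_artifact_fraction Fraction of artifact alt fractions
#'   drawn inside `[0.3, 0.7]`; the rest fall outside, so an allele-fraction
#'   window removes most artifacts. Default 0.15.
#' @param depressed_genes,depression_factor Genes whose simulated depth is
#'   multiplied by `depression_factor` (capture-bias emulation); default
#'   none.
#' @param clean When `TRUE`, true calls are emitted perfectly balanced and
#'   adequately covered, so no filter can remove a truth variant; used for
#'   conservation properties.
#' @param seed Integer seed; a fixed seed makes the output byte-identical.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(platform_profiles = list(
                              platform_profile("panel", 20,
                                               mean_depth = 120,
                                               depth_dispersion = 10)
                            ),
                            n_samples = 15,
                            true_variants_per_sample = 3,
                            artifact_rate = 7,
                            reference_mismatch_locus =
                              panelval::reference_mismatch_locus(),
                            in_window_artifact_fraction = 0.15,
                            depressed_genes = character(),
                            depression_factor = 1,
                            clean = FALSE,
                            seed = 1L) {
  if (inherits(platform_profiles, "platform_profile")) {
    platform_profiles <- list(platform_profiles)
  }
  stopifnot(length(platform_profiles) >= 1,
            all(vapply(platform_profiles, inherits, logical(1),
                       "platform_profile")))
  if (n_samples < 1) abort("n_samples must be >= 1")
  if (true_variants_per_sample < 0 || artifact_rate < 0) {
    abort("counts and rates must be non-negative")
  }
  if (in_window_artifact_fraction < 0 || in_window_artifact_fraction > 1) {
    abort("in_window_artifact_fraction must lie in [0, 1]")
  }
  if (depression_factor <= 0 || depression_factor > 1) {
    abort("depression_factor must lie in (0, 1]")
  }
  structure(
    list(
      platform_profiles = platform_profiles,
      n_samples = as.integer(n_samples),
      true_variants_per_sample = as.integer(true_variants_per_sample),
      artifact_rate = artifact_rate,
      reference_mismatch_locus = reference_mismatch_locus,
      in_window_artifact_fraction = in_window_artifact_fraction,
      depressed_genes = depressed_genes,
      depression_factor = depression_factor,
      clean = isTRUE(clean),
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

sample_depth <- function(n, profile) {
  if (is.infinite(profile$depth_dispersion)) {
    rep(as.integer(round(profile$mean_depth)), n)
  } else {
    pmax(4L, rnbinom(n, size = profile$depth_dispersion,
                     mu = profile$mean_depth))
  }
}

# heterozygous alt reads: binomial at rho = 0, beta-binomial otherwise,
# with intra-class correlation rho = 1 / (2a + 1), i.e. a = (1 - rho) / (2 rho)
sample_het_alt <- function(depth, rho) {
  if (rho == 0) {
    rbinom(length(depth), depth, 0.5)
  } else {
    a <- (1 - rho) / (2 * rho)
    p <- rbeta(length(depth), a, a)
    rbinom(length(depth), depth, p)
  }
}

#' Simulate platform call sets with known truth
#'
#' Per true heterozygous call, total depth is negative-binomial around the
#' platform mean and alt reads are binomial(depth, 0.5), or beta-binomial
#' with the platform's intra-class correlation when
#' `af_overdispersion_rho > 0` (wider allele-fraction spread). Artifact calls
#' get alt fractions drawn mostly outside `[0.3, 0.7]`, so an allele-fraction
#' window removes most of them. The reference-mismatch locus, when
#' configured, is emitted as a balanced heterozygous call in every sample.
#' Truth records are consistent with the generated true calls by
#' construction. Per-base depth tables are generated for one sample per
#' platform. Output is a deterministic function of the spec (including its
#' seed).
#'
#' @param spec A [simulation_spec()].
#' @param panel A [panel_design()]; defaults to a synthetic 15-gene panel
#'   with 1 kb of CDS per gene.
#' @return A list: `calls`, `truth`, `panel`, `depth`.
#' @export
simulate_calls <- function(spec, panel = synthetic_panel()) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_calls_impl(spec, panel))
}

simulate_calls_impl <- function(spec, panel) {
  profiles <- spec$platform_profiles
  n_prof <- length(profiles)
  regions <- panel$regions
  calls <- list()
  truth <- list()
  bases <- c("A", "C", "G", "T")
  for (s in seq_len(spec$n_samples)) {
    profile <- profiles[[(s - 1L) %% n_prof + 1L]]
    sid <- sprintf("SIM%02d", s)
    n_true <- spec$true_variants_per_sample
    n_art <- stats::rpois(1, spec$artifact_rate)
    n_tot <- n_true + n_art
    if (n_tot > 0) {
      # sample n_tot distinct positions from the panel's base space so a
      # sample never carries two calls (or two truth records) at one locus
      len <- regions$end - regions$start
      base_map <- rep(seq_len(nrow(regions)), len)
      idx <- sample.int(sum(len), n_tot, replace = FALSE)
      reg_idx <- base_map[idx]
      pos <- regions$start[reg_idx] +
        (idx - c(0L, cumsum(len))[reg_idx])
      ref <- sample(bases, n_tot, replace = TRUE)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1),
                    character(1))
      depth <- sample_depth(n_tot, profile)
      is_true <- seq_len(n_tot) <= n_true
      alt_reads <- integer(n_tot)
      if (n_true > 0) {
        if (spec$clean) {
          depth[is_true] <- pmax(depth[is_true],
                                 2L * profile$min_reads_per_allele)
          alt_reads[is_true] <- as.integer(round(depth[is_true] / 2))
        } else {
          alt_reads[is_true] <- sample_het_alt(depth[is_true],
                                               profile$af_overdispersion_rho)
        }
      }
      if (n_art > 0) {
        inside <- stats::runif(n_art) < spec$in_window_artifact_fraction
        low <- stats::runif(n_art) < 0.5
        f <- ifelse(inside, stats::runif(n_art, 0.3, 0.7),
                    ifelse(low, stats::runif(n_art, 0.02, 0.28),
                           stats::runif(n_art, 0.72, 0.98)))
        alt_reads[!is_true] <- pmin(depth[!is_true] - 1L,
                                    pmax(1L, as.integer(round(
                                      f * depth[!is_true]))))
      }
      calls[[length(calls) + 1L]] <- variant_calls(
        sample_id = sid,
        chrom = regions$chrom[reg_idx],
        pos = pos,
        ref_allele = ref,
        alt_allele = alt,
        gene = regions$gene[reg_idx],
        ref_reads = depth - alt_reads,
        alt_reads = alt_reads,
        consequence = "missense",
        zygosity_claim = "het",
        platform = profile$name
      )
      if (n_true > 0) {
        truth[[length(truth) + 1L]] <- truth_records(
          sample_id = sid,
          chrom = regions$chrom[reg_idx[is_true]],
          pos = pos[is_true],
          ref_allele = ref[is_true],
          alt_allele = alt[is_true]
        )
      }
    }
    if (!is.null(spec$reference_mismatch_locus)) {
      rml <- spec$reference_mismatch_locus
      d <- sample_depth(1, profile)
      a <- rbinom(1, d, 0.5)
      calls[[length(calls) + 1L]] <- variant_calls(
        sample_id = sid, chrom = rml$chrom[1], pos = rml$pos[1],
        ref_allele = rml$ref_allele[1], alt_allele = rml$alt_allele[1],
        gene = "MEN1", ref_reads = d - a, alt_reads = a,
        consequence = "missense", zygosity_claim = "het",
        platform = profile$name
      )
    }
  }
  depth_tabs <- list()
  for (p in seq_len(n_prof)) {
    profile <- profiles[[p]]
    per_gene <- lapply(seq_len(nrow(regions)), function(i) {
      mu <- profile$mean_depth
      if (regions$gene[i] %in% spec$depressed_genes) {
        mu <- mu * spec$depression_factor
      }
      pos <- seq.int(regions$start[i] + 1L, regions$end[i])
      tibble(
        chrom = regions$chrom[i],
        pos = pos,
        depth = if (is.infinite(profile$depth_dispersion)) {
          rep(as.integer(round(mu)), length(pos))
        } else {
          rnbinom(length(pos), size = profile$depth_dispersion, mu = mu)
        },
        sample_id = sprintf("SIM%02d", p)
      )
    })
    depth_tabs[[p]] <- bind_rows(per_gene) |> mutate(platform = profile$name)
  }
  list(
    calls = if (length(calls)) bind_rows(calls) else
      variant_calls(character(), character(), integer(), character(),
                    character(), integer(), integer()),
    truth = if (length(truth)) bind_rows(truth) else
      truth_records(character(), character(), integer()),
    panel = panel,
    depth = bind_rows(depth_tabs)
  )
}

#' Write a simulated data set to files
#'
#' Emits `calls.tsv` (package TSV dialect), `calls.vcf` (minimal VCF v4.2
#' with FORMAT/AD), `truth.tsv`, `panel.bed` and `depth.tsv` under `dir`.
#'
#' @param sim Output of [simulate_calls()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_calls(sim$calls, file.path(dir, "calls.tsv"))
  write_calls_vcf(sim$calls, file.path(dir, "calls.vcf"))
  readr::write_tsv(sim$truth, file.path(dir, "truth.tsv"), progress = FALSE)
  r <- sim$panel$regions
  writeLines(paste(r$chrom, r$start, r$end, r$gene, sep = "\t"),
             file.path(dir, "panel.bed"))
  readr::write_tsv(sim$depth, file.path(dir, "depth.tsv"), progress = FALSE)
  invisible(dir)
}

# minimal single-record-per-call VCF emission (one sample column per
# sample_id, calls serialized as biallelic records with GT/AD/DP)
write_calls_vcf <- function(calls, path) {
  calls <- validate_calls(calls)
  samples <- unique(calls$sample_id)
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  rows <- character(nrow(calls))
  for (i in seq_len(nrow(calls))) {
    gt <- rep(".", length(samples))
    j <- match(calls$sample_id[i], samples)
    gt[j] <- paste0(
      if (calls$zygosity_claim[i] == "hom") "1/1" else "0/1", ":",
      calls$ref_reads[i], ",", calls$alt_reads[i], ":",
      calls$ref_reads[i] + calls$alt_reads[i]
    )
    rows[i] <- paste(c(calls$chrom[i], calls$pos[i], ".",
                       calls$ref_allele[i], calls$alt_allele[i], ".",
                       "PASS", ".", "GT:AD:DP", gt), collapse = "\t")
  }
  writeLines(c(header, rows), path)
  invisible(path)
}

# Printed per-variant fixture ------------------------------------------------

#' Reconstruct the printed WES per-variant fixture
#'
#' Twenty whole-exome-sequenced samples across three library preparations
#' (Agilent SureSelect, Complete Genomics / BGI, Illumina Rapid Capture).
#' Thirteen samples carry a Sanger-verified mutation, emitted with the exact
#' printed wild-type/mutant read-count pairs; seven are mutation negative and
#' contribute no calls. Genomic coordinates are synthetic placeholders
#' derived from the HGVS coding positions; read counts, genes, transcripts,
#' HGVS strings and classifications are the printed ones.
#'
#' @return A list: `calls` (13 calls), `truth` (13 variant_present records),
#'   `samples` (tibble of all 20 sample ids with platform labels).
#' @export
build_table1_fixture <- function() {
  gene_base <- c(SDHB = 17350000L, SDHC = 161300000L, SDHD = 111957000L)
  gene_chrom <- c(SDHB = "chr1", SDHC = "chr1", SDHD = "chr11")
  tab <- tibble(
    sample_id = c("P01", "P02", "P05", "P06", "P07", "P08", "P09", "P10",
                  "P11", "P12", "P18", "P19", "P20"),
    platform = c(rep("Agilent SureSelect", 2),
                 rep("Complete Genomics", 8),
                 rep("Illumina Rapid Capture", 3)),
    gene = c("SDHB", "SDHB", "SDHB", "SDHB", "SDHB", "SDHB", "SDHB", "SDHC",
             "SDHD", "SDHD", "SDHB", "SDHB", "SDHB"),
    transcript = c("NM_003000.3", "NM_003000.3", "NM_003000.2",
                   "NM_003000.2", "NM_003000.3", "NM_003000.2",
                   "NM_003000.2", "NM_003001.3", "NM_003002.4",
                   "NM_003002.4", "NM_003000.3", "NM_003000.3",
                   "NM_003000.3"),
    hgvs_c = c("c.586T>G", "c.586T>G", "c.649C>T", "c.758G>A", "c.728G>A",
               "c.286+1G>A", "c.607G>T", "c.405+1G>T", "c.147_148dupA",
               "c.149A>G", "c.586T>C", "c.586T>C", "c.586T>C"),
    hgvs_p = c("p.Cys196Gly", "p.Cys196Gly", "p.Arg217Cys", "p.Cys253Tyr",
               "p.Cys243Tyr", NA, "p.Gly203Ter", NA, "p.His50fs",
               "p.His50Arg", "p.Cys196Arg", "p.Cys196Arg", "p.Cys196Arg"),
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "splice", "nonsense", "splice", "frameshift",
                    "missense", "missense", "missense", "missense"),
    acmg_class = c(rep("pathogenic", 9), "vus", rep("pathogenic", 3)),
    ref_reads = c(27L, 26L, 36L, 23L, 14L, 17L, 21L, 29L, 24L, 19L,
                  84L, 53L, 93L),
    alt_reads = c(23L, 32L, 23L, 33L, 23L, 17L, 12L, 21L, 9L, 17L,
                  101L, 49L, 77L)
  )
  cnum <- as.integer(sub("^c\\.([0-9]+).*", "\\1", tab$hgvs_c))
  pos <- gene_base[tab$gene] + cnum
  ref <- sub(".*([ACGT])>.*", "\\1", tab$hgvs_c)
  alt <- sub(".*>([ACGT]).*", "\\1", tab$hgvs_c)
  dup <- !grepl(">", tab$hgvs_c)
  ref[dup] <- "T"
  alt[dup] <- "TA"
  calls <- variant_calls(
    sample_id = tab$sample_id, chrom = gene_chrom[tab$gene], pos = pos,
    ref_allele = ref, alt_allele = alt, gene = tab$gene,
    transcript = tab$transcript, hgvs_c = tab$hgvs_c, hgvs_p = tab$hgvs_p,
    ref_reads = tab$ref_reads, alt_reads = tab$alt_reads,
    consequence = tab$consequence, acmg_class = tab$acmg_class,
    zygosity_claim = "het", platform = tab$platform
  )
  truth <- truth_records(
    sample_id = calls$sample_id, chrom = calls$chrom, pos = calls$pos,
    ref_allele = calls$ref_allele, alt_allele = calls$alt_allele
  )
  samples <- tibble(
    sample_id = sprintf("P%02d", 1:20),
    platform = c(rep("Agilent SureSelect", 4),
                 rep("Complete Genomics", 12),
                 rep("Illumina Rapid Capture", 4)),
    mutation_positive = sprintf("P%02d", 1:20) %in% calls$sample_id
  )
  list(calls = calls, truth = truth, samples = samples)
}

# Panel v1.0 validation fixture ----------------------------------------------

#' Reconstruct the panel v1.0 analytical-validation fixture
#'
#' Fifteen samples and 155 coding calls, built so the full cascade reproduces
#' the validation aggregates: 41 calls match true variants (12
#' pathogenic-classified -- the verified mutation set --, 2 VUS, 25
#' benign-classified true polymorphisms, and 2 common polymorphisms removed
#' by the MAF stage and not counted against sensitivity) and 114 are
#' artifacts, of which 15 are the reference-mismatch locus (one per sample)
#' and exactly one of the remaining 99 has an in-window allele fraction. The
#' cascade therefore retains 40 calls (12 + 2 + 25 + 1 artifact), yielding
#' 100% sensitivity over the verified pathogenic truth set and specificity
#' 113/114 = 99.1% over the artifact universe. All constants are explicit in
#' this builder; coordinates are synthetic.
#'
#' @return A list: `calls` (155 rows), `truth` (41 variant_present records
#'   with a `verified_pathogenic` flag), `blacklist` (1 row), `panel`,
#'   `profile`.
#' @export
build_v1_validation_fixture <- function() {
  panel <- synthetic_panel(v1_panel_genes, gene_length = 10000L,
                           name = "hereditary-endocrine-panel v1.0 (synthetic)")
  profile <- platform_profile("targeted panel", min_reads_per_allele = 20,
                              mean_depth = 120)
  regions <- panel$regions
  gene_pos <- function(gene, offset) {
    i <- match(gene, regions$gene)
    tibble(chrom = regions$chrom[i], pos = regions$start[i] + offset)
  }
  samples <- sprintf("S%02d", 1:15)
  calls <- list()
  truth <- list()
  add_call <- function(sample, gene, offset, ref, alt, ref_reads, alt_reads,
                       consequence = "missense", maf = NA_real_,
                       acmg = "unknown", polyphen = "unknown",
                       hgvs_c = NA_character_) {
    loc <- gene_pos(gene, offset)
    calls[[length(calls) + 1L]] <<- variant_calls(
      sample_id = sample, chrom = loc$chrom, pos = loc$pos,
      ref_allele = ref, alt_allele = alt, gene = gene, hgvs_c = hgvs_c,
      ref_reads = ref_reads, alt_reads = alt_reads,
      consequence = consequence, population_maf = maf, acmg_class = acmg,
      polyphen_category = polyphen, zygosity_claim = "het",
      platform = "targeted panel"
    )
    invisible(NULL)
  }
  add_truth <- function(sample, gene, offset, ref, alt, verified) {
    loc <- gene_pos(gene, offset)
    rec <- truth_records(sample_id = sample, chrom = loc$chrom,
                         pos = loc$pos, ref_allele = ref, alt_allele = alt)
    rec$verified_pathogenic <- verified
    truth[[length(truth) + 1L]] <<- rec
    invisible(NULL)
  }

  # 12 pathogenic-classified calls: the 10 verified mutations
  # (2 RET, 5 SDHB, 2 TMEM127, 1 VHL) plus 2 further pathogenic calls,
  # matching the aggregate count of pathogenic calls the cascade retains
  pathogenic <- tibble(
    sample = c("S01", "S03", "S06", "S07", "S09", "S10", "S11", "S12",
               "S13", "S14", "S02", "S04"),
    gene = c("SDHB", "SDHB", "RET", "TMEM127", "SDHB", "SDHB", "SDHB",
             "RET", "TMEM127", "VHL", "SDHB", "RET"),
    offset = c(100L, 110L, 120L, 130L, 140L, 150L, 160L, 170L, 180L, 190L,
               200L, 210L),
    ref = c("T", "T", "G", "G", "T", "C", "G", "T", "G", "T", "C", "C"),
    alt = c("G", "A", "A", "A", "C", "T", "A", "C", "T", "G", "T", "G")
  )
  for (i in seq_len(nrow(pathogenic))) {
    alt_reads <- 23L + (i - 1L) %% 6L # fractions 0.46..0.56, depth 50
    add_call(pathogenic$sample[i], pathogenic$gene[i], pathogenic$offset[i],
             pathogenic$ref[i], pathogenic$alt[i],
             ref_reads = 50L - alt_reads, alt_reads = alt_reads,
             acmg = "pathogenic", polyphen = "probably_damaging")
    add_truth(pathogenic$sample[i], pathogenic$gene[i], pathogenic$offset[i],
              pathogenic$ref[i], pathogenic$alt[i], verified = TRUE)
  }

  # 2 variants of uncertain significance, retained by the cascade
  vus <- tibble(sample = c("S05", "S08"), gene = c("SDHA", "MAX"),
                offset = c(300L, 310L), ref = c("A", "G"), alt = c("G", "C"))
  for (i in seq_len(nrow(vus))) {
    add_call(vus$sample[i], vus$gene[i], vus$offset[i], vus$ref[i],
             vus$alt[i], ref_reads = 24L, alt_reads = 24L, acmg = "vus",
             polyphen = "possibly_damaging")
    add_truth(vus$sample[i], vus$gene[i], vus$offset[i], vus$ref[i],
              vus$alt[i], verified = FALSE)
  }

  # 25 benign-classified true polymorphisms (rare, so the MAF stage keeps
  # them; ACMG likely_benign, so the strict benign conjunction keeps them)
  for (i in seq_len(25)) {
    sample <- samples[(i - 1L) %% 15L + 1L]
    gene <- v1_panel_genes[(i - 1L) %% 15L + 1L]
    offset <- 1000L + 10L * i
    add_call(sample, gene, offset, "C", "T", ref_reads = 27L,
             alt_reads = 25L, maf = 0.005, acmg = "likely_benign",
             polyphen = "benign")
    add_truth(sample, gene, offset, "C", "T", verified = FALSE)
  }

  # 2 true common polymorphisms removed by the MAF stage (not counted
  # against sensitivity: the truth set for sensitivity is the verified
  # pathogenic subset)
  common <- tibble(sample = c("S05", "S08"), gene = c("EPAS1", "KIF1B"),
                   offset = c(2000L, 2010L))
  for (i in seq_len(nrow(common))) {
    add_call(common$sample[i], common$gene[i], common$offset[i], "G", "A",
             ref_reads = 26L, alt_reads = 24L, maf = 0.02,
             acmg = "likely_benign", polyphen = "benign")
    add_truth(common$sample[i], common$gene[i], common$offset[i], "G", "A",
              verified = FALSE)
  }

  # 15 reference-mismatch artifact calls: the same MEN1-analog locus in
  # every sample, balanced reads (it looks like a genuine heterozygote)
  blacklist <- reference_mismatch_locus()
  for (s in samples) {
    calls[[length(calls) + 1L]] <- variant_calls(
      sample_id = s, chrom = blacklist$chrom[1], pos = blacklist$pos[1],
      ref_allele = blacklist$ref_allele[1],
      alt_allele = blacklist$alt_allele[1], gene = "MEN1",
      hgvs_c = "c.1636A>G", hgvs_p = "p.Thr546Ala",
      ref_reads = 26L, alt_reads = 26L, consequence = "missense",
      zygosity_claim = "het", platform = "targeted panel"
    )
  }

  # 99 further artifact calls: 98 with out-of-window fractions (alternating
  # low ~0.23-0.29 and high ~0.71-0.75, all with >= 20 reads per allele so
  # only the allele-fraction window removes them) and exactly 1 in-window
  for (i in seq_len(98)) {
    sample <- samples[(i - 1L) %% 15L + 1L]
    gene <- v1_panel_genes[(i * 7L) %% 15L + 1L]
    offset <- 5000L + 10L * i
    if (i %% 2L == 1L) {
      ref_reads <- 52L + 4L * (i %% 5L) # fraction 20/(72..88) = 0.29..0.23
      alt_reads <- 20L
    } else {
      ref_reads <- 20L # fraction (52..68)/(72..88) = 0.72..0.77
      alt_reads <- 52L + 4L * (i %% 5L)
    }
    add_call(sample, gene, offset, "A", "C", ref_reads = ref_reads,
             alt_reads = alt_reads)
  }
  add_call("S15", "FH", 8000L, "T", "A", ref_reads = 25L, alt_reads = 25L,
           acmg = "vus")

  list(
    calls = bind_rows(calls),
    truth = bind_rows(truth),
    blacklist = blacklist,
    panel = panel,
    profile = profile
  )
}

# Cohort fixtures -------------------------------------------------------------

#' Load the packaged cohort tables
#'
#' Machine-readable transcriptions of the study's cohort summaries: one row
#' per reported variant (patients without reportable variants appear once
#' with `NA` variant fields). `table3` covers all 76 panel-tested patients
#' across the validation group (`EP1.0V`), the first prospective group
#' (`EP1.0P`) and the upgraded-panel prospective group (`EP2.0`); `table4`
#' lists the novel variants with their clinical classifications.
#'
#' @return A list of tibbles: `table3`, `table4`.
#' @export
build_cohort_fixtures <- function() {
  t3 <- system.file("extdata", "cohort_table3.tsv", package = "panelval",
                    mustWork = TRUE)
  t4 <- system.file("extdata", "cohort_table4.tsv", package = "panelval",
                    mustWork = TRUE)
  list(
    table3 = readr::read_tsv(t3, show_col_types = FALSE, progress = FALSE),
    table4 = readr::read_tsv(t4, show_col_types = FALSE, progress = FALSE)
  )
}
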