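#' @keywords internal
"_PACKAGE"

#' @importFrom rlang abort warn .data %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange bind_rows left_join anti_join
#'   semi_join distinct group_by summarise ungroup n rename all_of across
#' @importFrom stats rbinom rnbinom rbeta sd setNames
#' @importFrom utils head
NULL

# Controlled vocabularies shared by all stages -------------------------------

#' Controlled vocabularies for variant annotations
#'
#' Allowed values for the annotation fields of a variant-call table:
#' functional consequence, five-tier clinical (ACMG) class, PolyPhen-2
#' category and zygosity claim. `"unknown"` is a first-class value everywhere;
#' filters must state how they treat it rather than silently passing or
#' dropping unannotated calls.
#'
#' @format Character vectors of allowed values.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
consequence_levels <- c(
  "missense", "nonsense", "frameshift", "inframe_indel", "splice",
  "synonymous", "utr", "intronic", "complex"
)

#' @rdname vocabularies
#' @export
acmg_levels <- c(
  "pathogenic", "likely_pathogenic", "vus", "likely_benign", "benign",
  "unknown"
)

#' @rdname vocabularies
#' @export
polyphen_levels <- c(
  "benign", "possibly_damaging", "probably_damaging", "unknown"
)

#' @rdname vocabularies
#' @export
zygosity_levels <- c("het", "hom", "unknown")

variant_call_cols <- c(
  "sample_id", "chrom", "pos", "ref_allele", "alt_allele", "gene",
  "transcript", "hgvs_c", "hgvs_p", "ref_reads", "alt_reads", "consequence",
  "population_maf", "acmg_class", "polyphen_category", "sift_score",
  "zygosity_claim", "platform"
)

# Constructors and validators ------------------------------------------------

#' Build a validated variant-call table
#'
#' One row per called variant per sample. Read counts are per-allele depths
#' (the `AD` quantity of a VCF), not total site depth; every allele-fraction
#' statistic downstream is computed from them. Annotation fields that are not
#' supplied default to `"unknown"` (or `NA` for numeric annotations), never to
#' a value that would pass an annotation-based filter.
#'
#' @param sample_id,chrom,pos,ref_allele,alt_allele Locus and alleles
#'   (`pos` is 1-based).
#' @param ref_reads,alt_reads Non-negative per-allele read counts.
#' @param gene,transcript,hgvs_c,hgvs_p Optional annotation strings.
#' @param consequence One of [consequence_levels].
#' @param population_maf Population minor-allele frequency in `[0, 1]`,
#'   `NA` when unknown.
#' @param acmg_class One of [acmg_levels].
#' @param polyphen_category One of [polyphen_levels].
#' @param sift_score SIFT score in `[0, 1]`, `NA` when unknown.
#' @param zygosity_claim One of [zygosity_levels].
#' @param platform Optional library-preparation / platform label.
#' @return A tibble with one row per call, validated by [validate_calls()].
#' @export
#' @examples
#' variant_calls(
#'   sample_id = "P1", chrom = "chr1", pos = 17371320,
#'   ref_allele = "T", alt_allele = "G",
#'   ref_reads = 27, alt_reads = 23, gene = "SDHB"
#' )
variant_calls <- function(sample_id, chrom, pos, ref_allele, alt_allele,
                          ref_reads, alt_reads,
                          gene = NA_character_, transcript = NA_character_,
                          hgvs_c = NA_character_, hgvs_p = NA_character_,
                          consequence = "missense",
                          population_maf = NA_real_,
                          acmg_class = "unknown",
                          polyphen_category = "unknown",
                          sift_score = NA_real_,
                          zygosity_claim = "het",
                          platform = NA_character_) {
  calls <- tibble(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    gene = as.character(gene),
    transcript = as.character(transcript),
    hgvs_c = as.character(hgvs_c),
    hgvs_p = as.character(hgvs_p),
    ref_reads = as.integer(ref_reads),
    alt_reads = as.integer(alt_reads),
    consequence = as.character(consequence),
    population_maf = as.numeric(population_maf),
    acmg_class = as.character(acmg_class),
    polyphen_category = as.character(polyphen_category),
    sift_score = as.numeric(sift_score),
    zygosity_claim = as.character(zygosity_claim),
    platform = as.character(platform)
  )
  validate_calls(calls)
}

#' Validate a variant-call table
#'
#' Checks the structural invariants of a call table: required columns present,
#' positions >= 1, non-negative read counts, REF != ALT, annotation values
#' inside their controlled vocabularies, and known MAF / SIFT inside `[0, 1]`.
#'
#' @param calls A data frame of variant calls.
#' @return The table, invisibly coerced to a tibble, or an error.
#' @export
validate_calls <- function(calls) {
  calls <- as_tibble(calls)
  missing_cols <- setdiff(variant_call_cols, names(calls))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "variant-call table is missing columns: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(calls) == 0) {
    return(calls)
  }
  if (any(calls$pos < 1L)) abort("variant positions must be >= 1 (1-based)")
  if (any(calls$ref_reads < 0L) || any(calls$alt_reads < 0L)) {
    abort("read counts must be non-negative")
  }
  if (any(calls$ref_allele == calls$alt_allele)) {
    abort("ref_allele must differ from alt_allele")
  }
  check_enum(calls$consequence, consequence_levels, "consequence")
  check_enum(calls$acmg_class, acmg_levels, "acmg_class")
  check_enum(calls$polyphen_category, polyphen_levels, "polyphen_category")
  check_enum(calls$zygosity_claim, zygosity_levels, "zygosity_claim")
  maf <- calls$population_maf
  if (any(!is.na(maf) & (maf < 0 | maf > 1))) {
    abort("known population_maf must lie in [0, 1]")
  }
  sift <- calls$sift_score
  if (any(!is.na(sift) & (sift < 0 | sift > 1))) {
    abort("known sift_score must lie in [0, 1]")
  }
  calls
}

check_enum <- function(x, levels, what) {
  bad <- setdiff(unique(x[!is.na(x)]), levels)
  if (length(bad) > 0) {
    abort(paste0(
      "invalid ", what, " value(s): ", paste(bad, collapse = ", "),
      " (allowed: ", paste(levels, collapse = ", "), ")"
    ))
  }
  invisible(x)
}

#' Build a validated truth-record table
#'
#' Ground truth established by an orthogonal method (Sanger sequencing):
#' `variant_present` rows name a confirmed variant; `wildtype_confirmed` rows
#' name a region confirmed wild type, used as the negative reference when
#' specificity is computed per position.
#'
#' @param sample_id,chrom,pos,ref_allele,alt_allele Locus and alleles; `pos`
#'   and alleles may be `NA` for `wildtype_confirmed` rows.
#' @param status `"variant_present"` or `"wildtype_confirmed"`.
#' @param span_start,span_end Optional 1-based inclusive span for
#'   `wildtype_confirmed` rows.
#' @return A validated tibble.
#' @export
truth_records <- function(sample_id, chrom, pos = NA_integer_,
                          ref_allele = NA_character_,
                          alt_allele = NA_character_,
                          status = "variant_present",
                          span_start = NA_integer_, span_end = NA_integer_) {
  truth <- tibble(
    sample_id = as.character(sample_id),
    chrom = as.character(chrom),
    pos = as.integer(pos),
    ref_allele = as.character(ref_allele),
    alt_allele = as.character(alt_allele),
    status = as.character(status),
    span_start = as.integer(span_start),
    span_end = as.integer(span_end)
  )
  validate_truth(truth)
}

#' @rdname truth_records
#' @param truth A data frame of truth records.
#' @export
validate_truth <- function(truth) {
  truth <- as_tibble(truth)
  required <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                "status")
  missing_cols <- setdiff(required, names(truth))
  if (length(missing_cols) > 0) {
    abort(paste0("truth table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"span_start" %in% names(truth)) truth$span_start <- NA_integer_
  if (!"span_end" %in% names(truth)) truth$span_end <- NA_integer_
  if (nrow(truth) == 0) {
    return(truth)
  }
  check_enum(truth$status, c("variant_present", "wildtype_confirmed"),
             "truth status")
  vp <- truth$status == "variant_present"
  bad_vp <- which(vp & (is.na(truth$alt_allele) | truth$alt_allele == ""))
  if (length(bad_vp) > 0) {
    abort(paste0("variant_present truth row(s) without an alt allele: row ",
                 paste(bad_vp, collapse = ", ")))
  }
  wt <- !vp
  bad_wt <- which(wt & (is.na(truth$span_start) | is.na(truth$span_end) |
                          truth$span_end < truth$span_start))
  if (length(bad_wt) > 0) {
    abort(paste0("wildtype_confirmed truth row(s) need a span of >= 1 base: ",
                 "row ", paste(bad_wt, collapse = ", ")))
  }
  truth
}

#' Describe a targeted panel design
#'
#' A panel is a set of half-open, 0-based genomic intervals (BED convention)
#' with gene labels, plus the intronic padding applied around each interval
#' when calls are tested for on-target status. The default padding of 30 bp
#' matches hybridization designs that tile every exon plus/minus 30 bp of
#' flanking intron.
#'
#' @param name Panel name.
#' @param regions A data frame with columns `chrom`, `start`, `end` (0-based
#'   half-open) and optionally `gene`.
#' @param intronic_padding_bp Non-negative padding in bases, default 30.
#' @return A `panel_design` object (list with `name`, `genes`, `regions`,
#'   `intronic_padding_bp`).
#' @export
panel_design <- function(name, regions, intronic_padding_bp = 30L) {
  regions <- as_tibble(regions)
  required <- c("chrom", "start", "end")
  if (!all(required %in% names(regions))) {
    abort("panel regions need columns chrom, start, end")
  }
  if (!"gene" %in% names(regions)) regions$gene <- NA_character_
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (nrow(regions) > 0 && any(regions$end <= regions$start)) {
    abort("panel intervals must satisfy end > start (0-based half-open)")
  }
  if (intronic_padding_bp < 0) abort("intronic_padding_bp must be >= 0")
  genes <- unique(regions$gene[!is.na(regions$gene)])
  structure(
    list(
      name = name,
      genes = genes,
      regions = regions[, c("chrom", "start", "end", "gene")],
      intronic_padding_bp = as.integer(intronic_padding_bp)
    ),
    class = "panel_design"
  )
}

#' @export
print.panel_design <- function(x, ...) {
  cat("<panel_design> ", x$name, ": ", nrow(x$regions), " intervals, ",
      length(x$genes), " genes, +/-", x$intronic_padding_bp,
      " bp intronic padding\n", sep = "")
  invisible(x)
}

#' Describe a sequencing platform / library-preparation profile
#'
#' Captures what the pipeline needs to know about a platform: the minimum
#' per-allele read depth it requires for a confident call, and the depth and
#' allele-fraction dispersion used when the platform is simulated.
#'
#' @param name Platform label.
#' @param min_reads_per_allele Minimum reads supporting each allele of a
#'   heterozygous call (e.g. 5 for a high-depth WGS service, 10 for exome,
#'   20 for a targeted panel).
#' @param mean_depth Mean total depth used by the simulator.
#' @param depth_dispersion Negative-binomial size parameter for simulated
#'   depth; `Inf` means every simulated site gets exactly `round(mean_depth)`
#'   reads.
#' @param af_overdispersion_rho Intra-class correlation of the beta-binomial
#'   allele-fraction model in `[0, 1)`; 0 is a pure binomial heterozygote.
#' @return A `platform_profile` object.
#' @export
platform_profile <- function(name, min_reads_per_allele, mean_depth = 100,
                             depth_dispersion = 10,
                             af_overdispersion_rho = 0) {
  if (min_reads_per_allele < 1) abort("min_reads_per_allele must be >= 1")
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (depth_dispersion <= 0) abort("depth_dispersion must be positive")
  if (af_overdispersion_rho < 0 || af_overdispersion_rho >= 1) {
    abort("af_overdispersion_rho must lie in [0, 1)")
  }
  structure(
    list(
      name = name,
      min_reads_per_allele = as.integer(min_reads_per_allele),
      mean_depth = mean_depth,
      depth_dispersion = depth_dispersion,
      af_overdispersion_rho = af_overdispersion_rho
    ),
    class = "platform_profile"
  )
}

#' @export
print.platform_profile <- function(x, ...) {
  cat("<platform_profile> ", x$name, ": >=", x$min_reads_per_allele,
      " reads/allele, mean depth ", x$mean_depth, ", rho ",
      x$af_overdispersion_rho, "\n", sep = "")
  invisible(x)
}

# Readers --------------------------------------------------------------------

#' Read variant calls from TSV or VCF
#'
#' The TSV dialect has one call per row with a mandatory header whose columns
#' match the fields of [variant_calls()]; missing annotation columns default
#' to unknown. The VCF dialect (v4.2) requires per-sample `FORMAT/AD` allelic
#' depths, because every allele-balance statistic downstream is computed from
#' per-allele read counts; multi-allelic records are decomposed into one call
#' per ALT allele sharing the REF depth.
#'
#' @param path Path to the file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A validated variant-call tibble.
#' @export
read_calls <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  if (dialect == "tsv") read_calls_tsv(path) else read_calls_vcf(path)
}

# explicit column types everywhere: single-letter alleles ("T") must never
# be parsed as logicals
call_col_types <- readr::cols(
  sample_id = readr::col_character(), chrom = readr::col_character(),
  pos = readr::col_integer(), ref_allele = readr::col_character(),
  alt_allele = readr::col_character(), gene = readr::col_character(),
  transcript = readr::col_character(), hgvs_c = readr::col_character(),
  hgvs_p = readr::col_character(), ref_reads = readr::col_integer(),
  alt_reads = readr::col_integer(), consequence = readr::col_character(),
  population_maf = readr::col_double(), acmg_class = readr::col_character(),
  polyphen_category = readr::col_character(),
  sift_score = readr::col_double(),
  zygosity_claim = readr::col_character(),
  platform = readr::col_character()
)

# restrict a cols() spec to the columns actually present in the file so
# readr does not warn about absent optional columns
types_for_file <- function(path, spec) {
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  spec$cols <- spec$cols[intersect(names(spec$cols), hdr)]
  spec
}

read_calls_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = types_for_file(path,
                                                          call_col_types),
                         progress = FALSE)
  problems <- readr::problems(raw)
  if (nrow(problems) > 0) {
    abort(paste0("malformed record in ", path, " at line ",
                 problems$row[1] + 1L, ": expected ", problems$expected[1]))
  }
  required <- c("sample_id", "chrom", "pos", "ref_allele", "alt_allele",
                "ref_reads", "alt_reads")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("call TSV ", path, " is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  defaults <- list(
    gene = NA_character_, transcript = NA_character_, hgvs_c = NA_character_,
    hgvs_p = NA_character_, consequence = "unknown_default",
    population_maf = NA_real_, acmg_class = "unknown",
    polyphen_category = "unknown", sift_score = NA_real_,
    zygosity_claim = "unknown", platform = NA_character_
  )
  for (col in names(defaults)) {
    if (!col %in% names(raw)) raw[[col]] <- defaults[[col]]
  }
  # consequence has no "unknown" level; an absent column becomes "complex"
  # would be wrong, so absent consequence is an error the caller can see
  if (identical(unique(raw$consequence), "unknown_default")) {
    abort(paste0("call TSV ", path, " has no consequence column"))
  }
  validate_calls(raw[, variant_call_cols])
}

read_calls_vcf <- function(path) {
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) abort(paste0("failed to parse VCF ", path, ": ",
                                     conditionMessage(e)))
  )
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) {
    return(variant_calls(character(), character(), integer(), character(),
                         character(), integer(), integer()))
  }
  fmt_keys <- unique(unlist(strsplit(vcf@gt[, "FORMAT"], ":", fixed = TRUE)))
  if (!"AD" %in% fmt_keys) {
    abort(paste0("VCF ", path, " has no allele depths: FORMAT/AD is required",
                 " (allele-fraction stages cannot run without per-allele",
                 " read counts)"))
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(ad)
  out <- vector("list", nrow(fix) * length(samples))
  k <- 0L
  for (i in seq_len(nrow(fix))) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    for (s in samples) {
      gts <- gt[i, s]
      if (is.na(gts) || gts %in% c("./.", ".")) next
      ads <- ad[i, s]
      if (is.na(ads)) {
        abort(paste0("VCF ", path, " record at line for ", fix$CHROM[i], ":",
                     fix$POS[i], ", sample ", s, " has no AD value"))
      }
      depths <- suppressWarnings(
        as.integer(strsplit(ads, ",", fixed = TRUE)[[1]])
      )
      if (anyNA(depths) || length(depths) < length(alts) + 1L) {
        abort(paste0("malformed AD '", ads, "' for ", fix$CHROM[i], ":",
                     fix$POS[i], ", sample ", s))
      }
      for (a in seq_along(alts)) {
        k <- k + 1L
        out[[k]] <- tibble(
          sample_id = s, chrom = fix$CHROM[i],
          pos = as.integer(fix$POS[i]),
          ref_allele = fix$REF[i], alt_allele = alts[a],
          ref_reads = depths[1L], alt_reads = depths[1L + a]
        )
      }
    }
  }
  base <- bind_rows(out[seq_len(k)])
  if (nrow(base) == 0) {
    return(variant_calls(character(), character(), integer(), character(),
                         character(), integer(), integer()))
  }
  variant_calls(
    sample_id = base$sample_id, chrom = base$chrom, pos = base$pos,
    ref_allele = base$ref_allele, alt_allele = base$alt_allele,
    ref_reads = base$ref_reads, alt_reads = base$alt_reads,
    consequence = "complex", zygosity_claim = "unknown"
  ) |>
    mutate(consequence = "complex")
}

#' Write variant calls to the package TSV dialect
#'
#' @param calls A validated variant-call tibble.
#' @param path Output path.
#' @return `path`, invisibly. Writing then reading reproduces all fields.
#' @export
write_calls <- function(calls, path) {
  calls <- validate_calls(calls)
  readr::write_tsv(calls, path, progress = FALSE)
  invisible(path)
}

#' Read a truth-record TSV
#'
#' Columns: `sample_id`, `chrom`, `pos`, `ref_allele`, `alt_allele`, `status`
#' (`variant_present` / `wildtype_confirmed`), optional `span_start`,
#' `span_end`. Rows violating the truth invariants are rejected with their
#' row number.
#'
#' @param path Path to the TSV.
#' @return A validated truth tibble.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  truth_types <- readr::cols(
    sample_id = readr::col_character(), chrom = readr::col_character(),
    pos = readr::col_integer(), ref_allele = readr::col_character(),
    alt_allele = readr::col_character(), status = readr::col_character(),
    span_start = readr::col_integer(), span_end = readr::col_integer()
  )
  raw <- readr::read_tsv(path, col_types = types_for_file(path, truth_types),
                         progress = FALSE)
  validate_truth(raw)
}

#' Read a panel design from BED
#'
#' BED3 or BED4 (0-based, half-open); the optional 4th column is the gene
#' symbol. Gene symbols are deduplicated in input order. Overlapping
#' intervals are kept as given; merging is the caller's choice.
#'
#' @param path Path to the BED file.
#' @param name Panel name; defaults to the file name.
#' @param intronic_padding_bp Padding passed to [panel_design()].
#' @return A `panel_design`.
#' @export
read_panel_bed <- function(path, name = basename(path),
                           intronic_padding_bp = 30L) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(panel_design(name, tibble(chrom = character(), start = integer(),
                                     end = integer(), gene = character()),
                        intronic_padding_bp))
  }
  parts <- strsplit(lines, "\t|[ ]+")
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 3)) {
    abort(paste0("BED line(s) with fewer than 3 columns: line ",
                 paste(which(ncols < 3), collapse = ", ")))
  }
  regions <- tibble(
    chrom = vapply(parts, `[[`, character(1), 1L),
    start = as.integer(vapply(parts, `[[`, character(1), 2L)),
    end = as.integer(vapply(parts, `[[`, character(1), 3L)),
    gene = vapply(parts, function(p) {
      if (length(p) >= 4) p[[4]] else NA_character_
    }, character(1))
  )
  bad <- which(regions$end <= regions$start)
  if (length(bad) > 0) {
    abort(paste0("BED interval with end <= start at line ",
                 paste(bad, collapse = ", ")))
  }
  panel_design(name, regions, intronic_padding_bp)
}

# Report writing -------------------------------------------------------------

#' Write a result table to TSV or JSON with deterministic formatting
#'
#' Column order is preserved as given; floating-point columns are rendered at
#' fixed precision so that identical results produce byte-identical files:
#' percentage columns (named `sensitivity`, `specificity`, `yield_pct`, or
#' ending in `_pct`) to 1 decimal place, other non-integer numeric columns to
#' 2 decimal places.
#'
#' @param results A data frame (any stage's output), or an object with an
#'   `as_tibble` method.
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  results <- as_tibble(results)
  fmt <- format_report_columns(results)
  if (format == "tsv") {
    readr::write_tsv(fmt, path, progress = FALSE)
  } else {
    jsonlite::write_json(fmt, path, dataframe = "rows", na = "null",
                         auto_unbox = FALSE, digits = NA)
  }
  invisible(path)
}

format_report_columns <- function(df) {
  pct_cols <- grepl("_pct$", names(df)) |
    names(df) %in% c("sensitivity", "specificity")
  for (j in seq_along(df)) {
    x <- df[[j]]
    if (!is.numeric(x) || all(is.na(x))) next
    if (pct_cols[j]) {
      df[[j]] <- round_half_up(x, 1)
    } else if (!all(x[!is.na(x)] == floor(x[!is.na(x)]))) {
      df[[j]] <- round_half_up(x, 2)
    }
  }
  df
}
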