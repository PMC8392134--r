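# Multi-stage variant filter cascade with a per-stage audit trail.
#
# Stage order: region -> consequence -> common -> benign -> depth ->
# blacklist -> afr. Each stage is a pure set predicate, so the final
# surviving set is invariant under stage permutation; the fixed order exists
# only to make audit counts reproducible. Unknown annotations are retained
# (a diagnostic pipeline must not discard unassessed variants): unknown MAF
# and unknown ACMG class pass their stages, unknown consequence is kept and
# flagged.

#' Configure the variant filter cascade
#'
#' @param maf_threshold Calls with known population MAF strictly above this
#'   are removed as common polymorphisms. Default 0.01 (>1% MAF).
#' @param afr_window Allele-fraction acceptance window; default
#'   `afr_window(30, 70)`.
#' @param min_reads_per_allele Minimum reads per allele; usually taken from
#'   the platform profile, default 20 (targeted panel).
#' @param drop_consequences Consequence classes removed as non-reportable;
#'   default UTR, intronic and synonymous. Splice-site calls (intronic offset
#'   within 2 bp of an exon boundary, e.g. `c.286+2T>A`) are never dropped as
#'   intronic.
#' @param sift_benign_max A call counts as SIFT-consistent-with-benign when
#'   its score is at least this value (SIFT scores below 0.05 predict a
#'   deleterious substitution). Set `sift_deleterious_is_benign = TRUE` to
#'   invert the direction.
#' @param sift_deleterious_is_benign Direction switch for the SIFT clause of
#'   the benign rule; default `FALSE`.
#' @param blacklist Tibble of known artifact loci with columns `chrom`,
#'   `pos`, `ref_allele`, `alt_allele`, `note`; e.g. reference-mismatch
#'   positions where the reference genome carries a minor allele, so every
#'   sample yields a spurious heterozygous call.
#' @param enabled Character vector of stages to run; default all of
#'   `c("region", "consequence", "common", "benign", "depth", "blacklist",
#'   "afr")`.
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 0.01,
                          afr_window = panelval::afr_window(30, 70),
                          min_reads_per_allele = 20L,
                          drop_consequences = c("utr", "intronic",
                                                "synonymous"),
                          sift_benign_max = 0.05,
                          sift_deleterious_is_benign = FALSE,
                          blacklist = NULL,
                          enabled = cascade_stages) {
  if (maf_threshold <= 0 || maf_threshold > 1) {
    abort("maf_threshold must lie in (0, 1]")
  }
  if (min_reads_per_allele < 1) abort("min_reads_per_allele must be >= 1")
  bad_cons <- setdiff(drop_consequences, consequence_levels)
  if (length(bad_cons) > 0) {
    abort(paste0("unknown consequence(s) in drop_consequences: ",
                 paste(bad_cons, collapse = ", ")))
  }
  bad_stage <- setdiff(enabled, cascade_stages)
  if (length(bad_stage) > 0) {
    abort(paste0("unknown stage(s): ", paste(bad_stage, collapse = ", ")))
  }
  if (is.null(blacklist)) {
    blacklist <- tibble(chrom = character(), pos = integer(),
                        ref_allele = character(), alt_allele = character(),
                        note = character())
  }
  blacklist <- as_tibble(blacklist)
  if (!"note" %in% names(blacklist)) blacklist$note <- NA_character_
  structure(
    list(
      maf_threshold = maf_threshold,
      afr_window = afr_window,
      min_reads_per_allele = as.integer(min_reads_per_allele),
      drop_consequences = drop_consequences,
      sift_benign_max = sift_benign_max,
      sift_deleterious_is_benign = sift_deleterious_is_benign,
      blacklist = blacklist,
      enabled = enabled
    ),
    class = "filter_config"
  )
}

#' @rdname filter_config
#' @export
cascade_stages <- c("region", "consequence", "common", "benign", "depth",
                    "blacklist", "afr")

#' Read a filter configuration from YAML
#'
#' Recognized keys mirror the arguments of [filter_config()]; `afr_window`
#' is given as a `"L-U"` string and `blacklist` as a path to a TSV with
#' columns `chrom`, `pos`, `ref_allele`, `alt_allele`, `note`.
#'
#' @param path YAML file path.
#' @return A `filter_config`.
#' @export
read_filter_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  y <- yaml::read_yaml(path)
  args <- list()
  for (key in c("maf_threshold", "min_reads_per_allele", "sift_benign_max",
                "sift_deleterious_is_benign", "drop_consequences",
                "enabled")) {
    if (!is.null(y[[key]])) args[[key]] <- y[[key]]
  }
  if (!is.null(y$afr_window)) args$afr_window <- parse_afr_window(y$afr_window)
  if (!is.null(y$blacklist)) args$blacklist <- read_blacklist(y$blacklist)
  do.call(filter_config, args)
}

#' Read an artifact blacklist TSV
#'
#' @param path TSV with columns `chrom`, `pos`, `ref_allele`, `alt_allele`
#'   and optional `note`.
#' @return A tibble.
#' @export
read_blacklist <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  bl_types <- readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    ref_allele = readr::col_character(),
    alt_allele = readr::col_character(), note = readr::col_character()
  )
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  bl_types$cols <- bl_types$cols[intersect(names(bl_types$cols), hdr)]
  bl <- readr::read_tsv(path, col_types = bl_types, progress = FALSE)
  required <- c("chrom", "pos", "ref_allele", "alt_allele")
  missing_cols <- setdiff(required, names(bl))
  if (length(missing_cols) > 0) {
    abort(paste0("blacklist is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"note" %in% names(bl)) bl$note <- NA_character_
  bl
}

stage_result <- function(kept, removed, reason) {
  if (nrow(removed) > 0) {
    removed$removed_by <- reason
  } else {
    removed$removed_by <- character(0)
  }
  list(kept = kept, removed = removed)
}

split_by <- function(calls, keep, reason) {
  stage_result(calls[keep, , drop = FALSE], calls[!keep, , drop = FALSE],
               reason)
}

#' Keep calls inside the padded panel regions
#'
#' A call at 1-based position `p` is on-target when it falls inside any panel
#' interval `[start, end)` (0-based half-open) expanded by the panel's
#' intronic padding, i.e. `start - pad < p <= end + pad`. The padding is
#' inclusive: with 30 bp padding a call 30 bp into the intron is kept, 31 bp
#' is removed.
#'
#' @param calls A validated variant-call tibble.
#' @param panel A [panel_design()].
#' @return `list(kept, removed)`; `removed` carries a `removed_by` column.
#' @export
filter_region <- function(calls, panel) {
  calls <- validate_calls(calls)
  stopifnot(inherits(panel, "panel_design"))
  if (nrow(panel$regions) == 0) {
    return(split_by(calls, rep(FALSE, nrow(calls)), "region"))
  }
  pad <- panel$intronic_padding_bp
  keep <- vapply(seq_len(nrow(calls)), function(i) {
    r <- panel$regions
    any(r$chrom == calls$chrom[i] &
          r$start - pad < calls$pos[i] &
          calls$pos[i] <= r$end + pad)
  }, logical(1))
  if (nrow(calls) == 0) keep <- logical(0)
  split_by(calls, keep, "region")
}

# splice-site rescue: consequence "splice", or an HGVS c. offset of +/-1 or
# +/-2 from an exon boundary (c.286+2T>A, c.2991-1G>C, ...)
is_splice_site <- function(calls) {
  by_class <- calls$consequence == "splice"
  by_hgvs <- !is.na(calls$hgvs_c) &
    grepl("[0-9][+-][12](?![0-9])", calls$hgvs_c, perl = TRUE)
  by_class | by_hgvs
}

#' Drop non-reportable consequence classes
#'
#' Removes UTR, intronic and synonymous calls (configurable). Splice-site
#' calls within 2 bp of an exon boundary are never removed as intronic, and
#' calls with `NA` consequence are kept and flagged (`flag_unknown_consequence`
#' column) rather than silently passed or dropped.
#'
#' @inheritParams filter_region
#' @param config A [filter_config()].
#' @return `list(kept, removed)`.
#' @export
filter_consequence <- function(calls, config = filter_config()) {
  calls <- validate_calls(calls)
  unknown <- is.na(calls$consequence)
  drop <- !unknown & calls$consequence %in% config$drop_consequences &
    !is_splice_site(calls)
  calls$flag_unknown_consequence <- unknown
  split_by(calls, !drop, "consequence")
}

#' Drop common polymorphisms
#'
#' Removes calls whose known population MAF is strictly above the threshold
#' (default >1%). Unknown MAF is retained: rarity cannot be assumed.
#'
#' @inheritParams filter_consequence
#' @return `list(kept, removed)`.
#' @export
filter_common <- function(calls, config = filter_config()) {
  calls <- validate_calls(calls)
  drop <- !is.na(calls$population_maf) &
    calls$population_maf > config$maf_threshold
  split_by(calls, !drop, "common")
}

#' Drop calls annotated benign by concordant evidence
#'
#' The benign rule is a conjunction: ACMG class benign AND PolyPhen-2
#' category benign AND a SIFT score consistent with benign (by default a
#' score of at least `sift_benign_max`, since low SIFT scores predict
#' deleterious substitutions; the direction is switchable). Calls with
#' unknown ACMG class, unknown PolyPhen, or unknown SIFT never match the rule.
#'
#' @inheritParams filter_consequence
#' @return `list(kept, removed)`.
#' @export
filter_benign <- function(calls, config = filter_config()) {
  calls <- validate_calls(calls)
  sift_ok <- if (config$sift_deleterious_is_benign) {
    !is.na(calls$sift_score) & calls$sift_score < config$sift_benign_max
  } else {
    !is.na(calls$sift_score) & calls$sift_score >= config$sift_benign_max
  }
  drop <- calls$acmg_class == "benign" &
    calls$polyphen_category == "benign" &
    sift_ok
  split_by(calls, !drop, "benign")
}

#' Drop under-covered calls
#'
#' For claimed heterozygotes both alleles must reach the per-allele minimum
#' (`min(ref_reads, alt_reads) >= min_reads_per_allele`); for claimed
#' homozygotes only the alt allele is tested (the reference allele is absent
#' by construction). Unknown zygosity is treated like a homozygote so that a
#' missing zygosity annotation cannot remove a call the het rule would keep.
#'
#' @inheritParams filter_region
#' @param profile A [platform_profile()], or `NULL` to use
#'   `config$min_reads_per_allele`.
#' @param config A [filter_config()].
#' @return `list(kept, removed)`.
#' @export
filter_depth <- function(calls, profile = NULL, config = filter_config()) {
  calls <- validate_calls(calls)
  min_reads <- if (!is.null(profile)) {
    stopifnot(inherits(profile, "platform_profile"))
    profile$min_reads_per_allele
  } else {
    config$min_reads_per_allele
  }
  het <- calls$zygosity_claim == "het"
  keep <- ifelse(het,
                 pmin(calls$ref_reads, calls$alt_reads) >= min_reads,
                 calls$alt_reads >= min_reads)
  if (nrow(calls) == 0) keep <- logical(0)
  split_by(calls, keep, "depth")
}

#' Remove known artifact loci
#'
#' Exact-match removal on (chrom, pos, ref, alt) against the configured
#' blacklist; a different alt allele at a blacklisted position is kept.
#' Removed calls carry the blacklist entry's note. The canonical use is a
#' reference-mismatch locus -- a position where the reference genome carries
#' the minor allele, so nearly every sample produces a spurious heterozygous
#' call (the MEN1 rs2959656 phenomenon).
#'
#' @inheritParams filter_consequence
#' @return `list(kept, removed)`.
#' @export
apply_blacklist <- function(calls, config = filter_config()) {
  calls <- validate_calls(calls)
  bl <- config$blacklist
  if (nrow(bl) == 0 || nrow(calls) == 0) {
    return(split_by(calls, rep(TRUE, nrow(calls)), "blacklist"))
  }
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = "\r")
  call_key <- key(calls$chrom, calls$pos, calls$ref_allele, calls$alt_allele)
  bl_key <- key(bl$chrom, bl$pos, bl$ref_allele, bl$alt_allele)
  hit <- call_key %in% bl_key
  res <- split_by(calls, !hit, "blacklist")
  if (nrow(res$removed) > 0) {
    idx <- match(key(res$removed$chrom, res$removed$pos,
                     res$removed$ref_allele, res$removed$alt_allele), bl_key)
    res$removed$blacklist_note <- bl$note[idx]
  }
  res
}

#' Apply the allele-fraction window filter
#'
#' Keeps calls whose alt-read fraction lies inside the configured window,
#' bounds inclusive (the exclusion rule is strictly below / strictly above).
#'
#' @inheritParams filter_consequence
#' @return `list(kept, removed)`.
#' @export
filter_afr <- function(calls, config = filter_config()) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) {
    return(split_by(calls, logical(0), "afr"))
  }
  f_pct <- 100 * alt_fraction(calls$ref_reads, calls$alt_reads)
  split_by(calls, in_window(f_pct, config$afr_window), "afr")
}

#' Run the full filter cascade with an audit trail
#'
#' Applies the enabled stages in the fixed order region, consequence, common,
#' benign, depth, blacklist, afr. Every input call ends up exactly once in
#' either the survivors or one stage's removals, and the audit counts
#' telescope: each stage's survivors are the next stage's input.
#'
#' @param calls A validated variant-call tibble.
#' @param panel A [panel_design()], required when the `region` stage is
#'   enabled.
#' @param profile A [platform_profile()] supplying the depth minimum, or
#'   `NULL` to use the config's.
#' @param config A [filter_config()].
#' @return A `cascade_result` list: `kept` (surviving calls), `removed` (all
#'   removed calls with `removed_by`), `audit` (tibble of per-stage
#'   `n_in`, `n_removed`, `n_out`).
#' @export
run_cascade <- function(calls, panel = NULL, profile = NULL,
                        config = filter_config()) {
  calls <- validate_calls(calls)
  stages <- config$enabled
  if ("region" %in% stages && is.null(panel)) {
    abort("the region stage needs a panel design")
  }
  current <- calls
  removed_all <- list()
  audit <- list()
  for (stage in cascade_stages) {
    if (!stage %in% stages) next
    res <- switch(stage,
      region = filter_region(current, panel),
      consequence = filter_consequence(current, config),
      common = filter_common(current, config),
      benign = filter_benign(current, config),
      depth = filter_depth(current, profile, config),
      blacklist = apply_blacklist(current, config),
      afr = filter_afr(current, config)
    )
    audit[[stage]] <- tibble(
      stage = stage,
      n_in = nrow(current),
      n_removed = nrow(res$removed),
      n_out = nrow(res$kept)
    )
    removed_all[[stage]] <- res$removed
    current <- res$kept
  }
  structure(
    list(
      kept = current,
      removed = bind_rows(removed_all),
      audit = bind_rows(audit)
    ),
    class = "cascade_result"
  )
}

#' @export
print.cascade_result <- function(x, ...) {
  cat("<cascade_result> ", nrow(x$kept), " surviving call(s)\n", sep = "")
  print(x$audit)
  invisible(x)
}
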