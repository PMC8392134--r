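# Truth-set concordance, window sensitivity grids, and cohort summaries.

# Allele normalization: trim the shared suffix, then the shared prefix,
# shifting pos right as prefix bases are removed. This canonicalizes padded
# indel and delins representations so that calls annotated differently by
# different tools compare equal; full left-alignment against a reference
# genome is out of scope (no reference is consumed).
normalize_variant <- function(pos, ref, alt) {
  pos <- as.integer(pos)
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]
    if (is.na(r) || is.na(a)) next
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1, nchar(r) - 1)
      a <- substr(a, 1, nchar(a) - 1)
    }
    while (nchar(r) > 1 && nchar(a) > 1 &&
           substr(r, 1, 1) == substr(a, 1, 1)) {
      r <- substr(r, 2, nchar(r))
      a <- substr(a, 2, nchar(a))
      pos[i] <- pos[i] + 1L
    }
    ref[i] <- r; alt[i] <- a
  }
  list(pos = pos, ref = ref, alt = alt)
}

variant_key <- function(sample_id, chrom, pos, ref, alt) {
  n <- normalize_variant(pos, ref, alt)
  paste(sample_id, chrom, n$pos, n$ref, n$alt, sep = "\r")
}

#' Summarize concordance of a filtered call set against a truth set
#'
#' Calls are matched to truth by (sample, chrom, pos, ref, alt) after allele
#' normalization. In `per_variant` mode: TP are surviving calls matching a
#' `variant_present` truth record, FN are truth variants with no surviving
#' call, FP are surviving calls matching no truth variant, and TN are the
#' artifact calls that were eliminated -- which requires the pre-filter call
#' `universe` so removed artifacts are known. In `per_position` mode TN is
#' instead the number of wild-type-confirmed bases (from the truth spans)
#' minus the false positives falling inside them.
#'
#' @param calls Surviving (post-filter) calls.
#' @param truth A validated truth table.
#' @param mode `"per_variant"` or `"per_position"`.
#' @param universe The pre-filter call set (required for `per_variant` TN;
#'   without it TN is `NA`).
#' @return A `confusion_summary`: a one-row tibble with `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity` (percent, `NA` when undefined) and
#'   `mode`.
#' @export
compare_to_truth <- function(calls, truth,
                             mode = c("per_variant", "per_position"),
                             universe = NULL) {
  mode <- match.arg(mode)
  calls <- validate_calls(calls)
  truth <- validate_truth(truth)
  tv <- truth[truth$status == "variant_present", , drop = FALSE]
  tkey <- variant_key(tv$sample_id, tv$chrom, tv$pos, tv$ref_allele,
                      tv$alt_allele)
  if (anyDuplicated(tkey)) {
    abort("duplicate truth records for one sample/locus/allele")
  }
  ckey <- variant_key(calls$sample_id, calls$chrom, calls$pos,
                      calls$ref_allele, calls$alt_allele)
  tp <- sum(ckey %in% tkey)
  fp <- sum(!ckey %in% tkey)
  fn <- sum(!tkey %in% ckey)
  tn <- NA_integer_
  if (mode == "per_variant") {
    if (!is.null(universe)) {
      universe <- validate_calls(universe)
      ukey <- variant_key(universe$sample_id, universe$chrom, universe$pos,
                          universe$ref_allele, universe$alt_allele)
      artifacts <- !ukey %in% tkey
      surviving_artifacts <- ukey %in% ckey[!ckey %in% tkey]
      tn <- sum(artifacts & !surviving_artifacts)
    }
  } else {
    wt <- truth[truth$status == "wildtype_confirmed", , drop = FALSE]
    n_wt_bases <- sum(wt$span_end - wt$span_start + 1L)
    fp_in_spans <- 0L
    if (nrow(wt) > 0 && fp > 0) {
      fp_calls <- calls[!ckey %in% tkey, , drop = FALSE]
      fp_in_spans <- sum(vapply(seq_len(nrow(fp_calls)), function(i) {
        any(wt$sample_id == fp_calls$sample_id[i] &
              wt$chrom == fp_calls$chrom[i] &
              wt$span_start <= fp_calls$pos[i] &
              fp_calls$pos[i] <= wt$span_end)
      }, logical(1)))
    }
    tn <- n_wt_bases - fp_in_spans
  }
  confusion_summary(tp = tp, fp = fp, fn = fn, tn = tn, mode = mode)
}

#' Assemble a confusion summary from counts
#'
#' @param tp,fp,fn,tn Non-negative counts; `tn` may be `NA` when no negative
#'   universe is defined.
#' @param mode Counting mode label.
#' @return A one-row `confusion_summary` tibble with sensitivity
#'   `100 * tp / (tp + fn)` and specificity `100 * tn / (tn + fp)` (percent,
#'   `NA` when the denominator is 0 or unknown).
#' @export
confusion_summary <- function(tp, fp, fn, tn = NA_integer_,
                              mode = "per_variant") {
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (!is.na(tn) && tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  out <- tibble(
    tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
    tn = as.integer(tn), sensitivity = sens, specificity = spec,
    mode = mode
  )
  class(out) <- c("confusion_summary", class(out))
  out
}

#' Sensitivity grid over platforms and allele-fraction windows
#'
#' For each platform and window, applies only the allele-fraction filter to
#' that platform's calls and tabulates detected true variants, false
#' negatives, false positives and sensitivity against the truth set --
#' the platform-comparison grid used to choose a window.
#'
#' @param calls Calls labelled with a `platform` column (the pre-AFR call
#'   set: true-variant calls plus any artifact calls).
#' @param truth A validated truth table (variant_present rows are matched by
#'   sample/locus/allele).
#' @param windows A list of [afr_window()] objects.
#' @return A tibble with one row per platform x window: `platform`, `window`,
#'   `true_variants`, `detected`, `false_positive`, `false_negative`,
#'   `sensitivity`.
#' @export
window_grid <- function(calls, truth, windows) {
  if (length(windows) == 0) abort("window_grid needs at least one window")
  if (inherits(windows, "afr_window")) windows <- list(windows)
  calls <- validate_calls(calls)
  truth <- validate_truth(truth)
  if (any(is.na(calls$platform))) {
    abort("window_grid needs a platform label on every call")
  }
  tv <- truth[truth$status == "variant_present", , drop = FALSE]
  tkey <- variant_key(tv$sample_id, tv$chrom, tv$pos, tv$ref_allele,
                      tv$alt_allele)
  rows <- list()
  for (platform in unique(calls$platform)) {
    pc <- calls[calls$platform == platform, , drop = FALSE]
    pckey <- variant_key(pc$sample_id, pc$chrom, pc$pos, pc$ref_allele,
                         pc$alt_allele)
    is_true <- pckey %in% tkey
    truth_samples <- unique(pc$sample_id)
    n_true <- sum(tkey %in% pckey |
                    (tv$sample_id %in% truth_samples & !tkey %in% pckey))
    f_pct <- 100 * alt_fraction(pc$ref_reads, pc$alt_reads)
    for (w in windows) {
      inside <- in_window(f_pct, w)
      detected <- sum(is_true & inside)
      rows[[length(rows) + 1L]] <- tibble(
        platform = platform,
        window = format(w),
        true_variants = n_true,
        detected = detected,
        false_positive = sum(!is_true & inside),
        false_negative = n_true - detected,
        sensitivity = if (n_true > 0) 100 * detected / n_true else NA_real_
      )
    }
  }
  bind_rows(rows)
}

#' Optimize the allele-fraction window for 100% sensitivity
#'
#' Returns the tightest symmetric window containing every call that matches a
#' truth variant -- the narrowest symmetric acceptance region at which no
#' true variant is lost. Errors if any truth variant has no corresponding
#' call (no window can recover an uncalled variant).
#'
#' @param calls Calls including one per truth variant.
#' @param truth A validated truth table.
#' @param rounding Passed to [tightest_symmetric_window()].
#' @return An `afr_window`.
#' @export
optimize_window <- function(calls, truth,
                            rounding = c("integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  calls <- validate_calls(calls)
  truth <- validate_truth(truth)
  tv <- truth[truth$status == "variant_present", , drop = FALSE]
  tkey <- variant_key(tv$sample_id, tv$chrom, tv$pos, tv$ref_allele,
                      tv$alt_allele)
  ckey <- variant_key(calls$sample_id, calls$chrom, calls$pos,
                      calls$ref_allele, calls$alt_allele)
  if (!all(tkey %in% ckey)) {
    abort("cannot optimize: some truth variants have no corresponding call")
  }
  tightest_symmetric_window(calls[ckey %in% tkey, , drop = FALSE], rounding)
}

#' Diagnostic yield of a tested cohort
#'
#' Counts patients carrying at least one qualifying variant. In
#' `"clinical_class"` mode (default) a qualifying variant is one whose
#' clinical classification is pathogenic or likely pathogenic; in
#' `"gene_carrier"` mode any reported variant in the named `genes` qualifies,
#' regardless of class (the counting convention used when a cohort is
#' summarized by carrier status of specific genes).
#'
#' @param cohort A cohort tibble with one row per reported variant (patients
#'   without variants appear as rows with `NA` variant fields); columns
#'   `patient_id`, `gene`, `clinical_class`, optionally `panel`.
#' @param panel_version If given, restrict to rows with this `panel` value.
#' @param count_mode `"clinical_class"` or `"gene_carrier"`.
#' @param genes Gene symbols for `"gene_carrier"` mode.
#' @param digits Decimal places for the reported percentage (0 = integer
#'   percent).
#' @return A one-row tibble `cohort`, `n_tested`, `n_carriers`, `yield_pct`,
#'   with attribute `"per_gene"` (carrier counts per gene).
#' @export
diagnostic_yield <- function(cohort, panel_version = NULL,
                             count_mode = c("clinical_class", "gene_carrier"),
                             genes = NULL, digits = 0) {
  count_mode <- match.arg(count_mode)
  cohort <- as_tibble(cohort)
  required <- c("patient_id", "gene", "clinical_class")
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  label <- panel_version %||% "all"
  if (!is.null(panel_version)) {
    if (!"panel" %in% names(cohort)) abort("cohort table has no panel column")
    cohort <- cohort[cohort$panel == panel_version, , drop = FALSE]
  }
  n_tested <- length(unique(cohort$patient_id))
  if (n_tested == 0) abort("diagnostic yield is undefined for an empty cohort")
  qualifying <- if (count_mode == "clinical_class") {
    !is.na(cohort$clinical_class) &
      cohort$clinical_class %in% c("pathogenic", "likely_pathogenic")
  } else {
    if (is.null(genes)) abort("gene_carrier mode needs a gene list")
    !is.na(cohort$gene) & cohort$gene %in% genes
  }
  carriers <- unique(cohort$patient_id[qualifying])
  per_gene <- cohort[qualifying, , drop = FALSE] |>
    distinct(.data$patient_id, .data$gene) |>
    dplyr::count(.data$gene, name = "n_carriers")
  out <- tibble(
    cohort = label,
    n_tested = n_tested,
    n_carriers = length(carriers),
    yield_pct = round_half_up(100 * length(carriers) / n_tested, digits)
  )
  attr(out, "per_gene") <- per_gene
  out
}

#' Count novel variants against a known-variant index
#'
#' A variant is novel when its normalized HGVS string (whitespace stripped,
#' case preserved) is absent from the supplied index; no online lookup is
#' performed. Unparseable (empty or `NA`) HGVS strings are flagged, not
#' silently dropped.
#'
#' @param variants A tibble with columns `hgvs` (transcript-level HGVS,
#'   e.g. `"SDHB(NM_003000.3):c.263C>T"`) and `clinical_class`.
#' @param known_index Character vector of known HGVS strings.
#' @return A list: `novel` (tibble of novel variants), `class_tally` (tibble
#'   of novel counts per clinical class), `flagged` (rows with unusable
#'   HGVS).
#' @export
count_novel <- function(variants, known_index = character()) {
  variants <- as_tibble(variants)
  if (!all(c("hgvs", "clinical_class") %in% names(variants))) {
    abort("variants need columns hgvs and clinical_class")
  }
  norm <- function(x) gsub("[[:space:]]+", "", x)
  usable <- !is.na(variants$hgvs) & nzchar(trimws(variants$hgvs))
  flagged <- variants[!usable, , drop = FALSE]
  v <- variants[usable, , drop = FALSE]
  novel <- v[!norm(v$hgvs) %in% norm(known_index), , drop = FALSE]
  tally <- novel |> dplyr::count(.data$clinical_class, name = "n")
  list(novel = novel, class_tally = tally, flagged = flagged)
}
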