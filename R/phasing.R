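# Read-backed cis/trans phasing of co-occurring variants.
#
# When several variants are called close together in one patient, reads
# spanning two or more of the sites tell whether the variants sit on the same
# chromosome copy (cis: reads are all-mutant or all-normal at the sites they
# cover, half and half for a heterozygous haplotype) or on opposite copies
# (trans: each read carries the alternate allele of at most one variant).

#' Build a read-support matrix
#'
#' @param support A tibble with columns `read_id`, `variant_id`, `support`
#'   (`"alt"`, `"ref"` or `"none"`), one row per read x variant.
#' @return A `read_support_matrix`: a character matrix with reads as rows,
#'   variants as columns and cells in `{alt, ref, none}`.
#' @export
read_support_matrix <- function(support) {
  support <- as_tibble(support)
  required <- c("read_id", "variant_id", "support")
  missing_cols <- setdiff(required, names(support))
  if (length(missing_cols) > 0) {
    abort(paste0("support table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  check_enum(support$support, c("alt", "ref", "none"), "read support")
  reads <- unique(support$read_id)
  vars <- unique(support$variant_id)
  if (length(vars) < 2) abort("phasing needs at least two variants")
  if (length(reads) < 1) abort("phasing needs at least one read")
  m <- matrix("none", nrow = length(reads), ncol = length(vars),
              dimnames = list(reads, vars))
  m[cbind(match(support$read_id, reads),
          match(support$variant_id, vars))] <- support$support
  covered <- rowSums(m != "none")
  if (any(covered == 0)) {
    abort("every read in the matrix must cover at least one variant")
  }
  structure(m, class = c("read_support_matrix", class(m)))
}

#' Read a support-matrix TSV
#'
#' Columns `read_id`, `variant_id`, `support` in `{alt, ref, none}`.
#'
#' @param path TSV path.
#' @return A `read_support_matrix`.
#' @export
read_support_tsv <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  read_support_matrix(
    readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  )
}

#' Decide cis / trans / ambiguous from read-level support
#'
#' Informative reads are those covering at least two variant sites. A read is
#' *concordant* when it shows the same state (all alt or all ref) at every
#' site it covers, and *discordant* otherwise. The verdict is:
#'
#' * `cis` -- at least `concordance_threshold` of informative reads are
#'   concordant, and both the all-alt and all-ref classes hold at least
#'   `min_informative_reads` reads (the heterozygous-haplotype pattern:
#'   half mutant, half normal);
#' * `trans` -- at least `concordance_threshold` of informative reads are
#'   discordant with alt support at exactly one of their covered sites
#'   (alt-supporting reads of different variants are near-disjoint), each
#'   variant having at least `min_informative_reads` alt-supporting
#'   informative reads;
#' * `ambiguous` -- anything else, including too few informative reads.
#'
#' The statistic depends only on co-segregation, so permuting reads or
#' variants, or relabeling alt/ref at all sites simultaneously, cannot change
#' a cis verdict.
#'
#' @param matrix A [read_support_matrix()].
#' @param concordance_threshold Fraction in `(0.5, 1]`; default 0.9, tolerant
#'   of sequencing error while requiring strong co-segregation.
#' @param min_informative_reads Minimum reads per evidence class; default 5.
#' @return A `phase_verdict` list: `verdict`, and `evidence` (a tibble of
#'   informative-read counts: total, all-alt, all-ref, discordant).
#' @export
phase <- function(matrix, concordance_threshold = 0.9,
                  min_informative_reads = 5) {
  stopifnot(inherits(matrix, "read_support_matrix"))
  if (concordance_threshold <= 0.5 || concordance_threshold > 1) {
    abort("concordance_threshold must lie in (0.5, 1]")
  }
  covered <- matrix != "none"
  informative <- rowSums(covered) >= 2
  m <- matrix[informative, , drop = FALSE]
  n_inf <- nrow(m)
  n_alt <- vapply(seq_len(n_inf), function(i) {
    sum(m[i, ] == "alt")
  }, integer(1))
  n_site <- rowSums(m != "none")
  all_alt <- n_inf > 0 & n_alt == n_site
  all_ref <- n_inf > 0 & n_alt == 0
  discordant <- !(all_alt | all_ref)
  single_alt <- discordant & n_alt == 1
  evidence <- tibble(
    informative = n_inf,
    all_alt = sum(all_alt),
    all_ref = sum(all_ref),
    discordant = sum(discordant)
  )
  verdict <- "ambiguous"
  if (n_inf > 0) {
    concordance <- (sum(all_alt) + sum(all_ref)) / n_inf
    if (concordance >= concordance_threshold &&
        sum(all_alt) >= min_informative_reads &&
        sum(all_ref) >= min_informative_reads) {
      verdict <- "cis"
    } else {
      per_variant_alt <- colSums(m == "alt" & single_alt)
      if (sum(single_alt) / n_inf >= concordance_threshold &&
          all(per_variant_alt >= min_informative_reads)) {
        verdict <- "trans"
      }
    }
  }
  structure(list(verdict = verdict, evidence = evidence),
            class = "phase_verdict")
}

#' @export
print.phase_verdict <- function(x, ...) {
  cat("<phase_verdict> ", x$verdict, "\n", sep = "")
  print(x$evidence)
  invisible(x)
}
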