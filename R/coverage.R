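# Per-gene depth-of-coverage over CDS intervals.
#
# Mean depth follows bedcov semantics: the sum of per-base depth over the
# gene's (merged) intervals divided by total interval length, with positions
# absent from the depth table contributing zero. Overlapping intervals for a
# gene are merged first so a base contributes once.

#' Read a per-base depth TSV
#'
#' Three or four columns: `chrom`, `pos` (1-based), `depth`, optional
#' `sample_id` (a samtools-depth-like table).
#'
#' @param path TSV path (header mandatory).
#' @return A tibble of depth records.
#' @export
read_depth <- function(path) {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  depth_types <- readr::cols(
    chrom = readr::col_character(), pos = readr::col_integer(),
    depth = readr::col_double(), sample_id = readr::col_character()
  )
  hdr <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  depth_types$cols <- depth_types$cols[intersect(names(depth_types$cols),
                                                 hdr)]
  d <- readr::read_tsv(path, col_types = depth_types, progress = FALSE)
  required <- c("chrom", "pos", "depth")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols) > 0) {
    abort(paste0("depth table is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"sample_id" %in% names(d)) d$sample_id <- NA_character_
  if (any(d$depth < 0)) abort("depth must be non-negative")
  d
}

# merge possibly-overlapping half-open intervals per chromosome
merge_intervals <- function(regions) {
  out <- list()
  for (chrom in unique(regions$chrom)) {
    r <- regions[regions$chrom == chrom, , drop = FALSE]
    r <- r[order(r$start, r$end), , drop = FALSE]
    starts <- r$start[1]; ends <- r$end[1]
    if (nrow(r) > 1) {
      for (i in 2:nrow(r)) {
        j <- length(starts)
        if (r$start[i] <= ends[j]) {
          ends[j] <- max(ends[j], r$end[i])
        } else {
          starts <- c(starts, r$start[i])
          ends <- c(ends, r$end[i])
        }
      }
    }
    out[[chrom]] <- tibble(chrom = chrom, start = starts, end = ends)
  }
  bind_rows(out)
}

#' Mean depth of coverage of one gene
#'
#' Computes the per-base depth vector over the gene's merged CDS intervals
#' (zero for uncovered positions), and reports its mean, its population
#' standard deviation, and the fraction of bases at or above
#' `depth_threshold`.
#'
#' @param depth A depth tibble from [read_depth()] (one sample, or
#'   pre-filtered to one sample).
#' @param panel A [panel_design()] whose regions carry gene labels.
#' @param gene Gene symbol.
#' @param depth_threshold Threshold for `fraction_above_threshold`
#'   (default 20).
#' @param platform Optional platform label copied to the output.
#' @return A one-row tibble: `gene`, `platform`, `mean_depth`, `sd_depth`,
#'   `fraction_above_threshold`, `n_bases`.
#' @export
gene_mean_depth <- function(depth, panel, gene, depth_threshold = 20,
                            platform = NA_character_) {
  stopifnot(inherits(panel, "panel_design"))
  regions <- panel$regions[!is.na(panel$regions$gene) &
                             panel$regions$gene == gene, , drop = FALSE]
  if (nrow(regions) == 0) {
    abort(paste0("gene ", gene, " has no intervals in panel ", panel$name))
  }
  merged <- merge_intervals(regions)
  per_base <- unlist(lapply(seq_len(nrow(merged)), function(i) {
    pos <- seq.int(merged$start[i] + 1L, merged$end[i]) # 1-based positions
    d <- depth[depth$chrom == merged$chrom[i], , drop = FALSE]
    out <- numeric(length(pos))
    hit <- match(pos, d$pos)
    out[!is.na(hit)] <- d$depth[hit[!is.na(hit)]]
    out
  }))
  n <- length(per_base)
  m <- mean(per_base)
  tibble(
    gene = gene,
    platform = platform,
    mean_depth = m,
    sd_depth = sqrt(mean((per_base - m)^2)),
    fraction_above_threshold = mean(per_base >= depth_threshold),
    n_bases = n
  )
}

#' Coverage summary for every gene in a panel
#'
#' @inheritParams gene_mean_depth
#' @return A tibble with one row per gene, sorted by gene.
#' @export
panel_coverage <- function(depth, panel, depth_threshold = 20,
                           platform = NA_character_) {
  stopifnot(inherits(panel, "panel_design"))
  bind_rows(lapply(sort(panel$genes), function(g) {
    gene_mean_depth(depth, panel, g, depth_threshold, platform)
  }))
}

#' Flag under-covered genes
#'
#' A gene is flagged when its mean depth falls below `min_mean_depth` or the
#' fraction of bases at or above the depth threshold falls below
#' `min_fraction`. Flagged genes are returned sorted by mean depth ascending
#' (worst first).
#'
#' @param records Coverage records from [panel_coverage()] /
#'   [gene_mean_depth()].
#' @param min_mean_depth Minimum acceptable mean depth.
#' @param min_fraction Minimum acceptable `fraction_above_threshold`.
#' @return The flagged subset of `records`, worst-covered first.
#' @export
flag_undercovered <- function(records, min_mean_depth = 0,
                              min_fraction = 0) {
  records <- as_tibble(records)
  flagged <- records[records$mean_depth < min_mean_depth |
                       records$fraction_above_threshold < min_fraction, ,
                     drop = FALSE]
  flagged[order(flagged$mean_depth), , drop = FALSE]
}
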