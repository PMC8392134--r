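# Allele-fraction statistics for heterozygote quality control.
#
# Germline variants in dominant tumor-predisposition genes are expected to be
# heterozygous, so a true call should show roughly balanced reads on the two
# alleles. Two statistics quantify the balance: the alt-read fraction
# alt/(ref+alt), which drives all window logic, and the min/max count ratio,
# a symmetric 0-100% balance score. They are deterministic functions of each
# other but are reported on different scales, so both are exposed.

#' Round half away from zero
#'
#' Fixed-precision decimal rounding with ties going up (2.5 -> 3), matching
#' how clinical reports round, rather than R's round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Alt-read fraction of a call
#'
#' `alt_reads / (ref_reads + alt_reads)`, unrounded. This is the quantity the
#' allele-fraction windows are defined on; reporting layers round it to 2
#' decimal places.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorized).
#' @return Fractions in `[0, 1]`.
#' @export
#' @examples
#' alt_fraction(27, 23) # 0.46
alt_fraction <- function(ref_reads, alt_reads) {
  total <- ref_reads + alt_reads
  if (any(total <= 0)) {
    abort("no coverage: a call with zero total reads has no allele fraction")
  }
  alt_reads / total
}

#' Allele-balance ratio of a call
#'
#' `100 * min(ref_reads, alt_reads) / max(ref_reads, alt_reads)`: 100% is a
#' perfectly balanced heterozygote, small values indicate allelic imbalance.
#' For a call with 15 and 20 reads on the two alleles the balance is 75%.
#'
#' @param ref_reads,alt_reads Non-negative read counts (vectorized).
#' @return Percentages in `[0, 100]`.
#' @export
balance_ratio <- function(ref_reads, alt_reads) {
  if (any(pmax(ref_reads, alt_reads) <= 0)) {
    abort("no coverage: a call with zero reads on both alleles has no balance")
  }
  100 * pmin(ref_reads, alt_reads) / pmax(ref_reads, alt_reads)
}

#' Define an allele-fraction window
#'
#' A window `[lower_pct, upper_pct]` in percent within which a heterozygous
#' call's alt-read fraction is accepted. A window is symmetric when its bounds
#' mirror around 50% (to 1-decimal reporting precision).
#'
#' @param lower_pct,upper_pct Bounds in `[0, 100]`, `lower_pct <= upper_pct`.
#' @return An `afr_window` object.
#' @export
#' @examples
#' afr_window(30, 70)
afr_window <- function(lower_pct, upper_pct) {
  if (lower_pct > upper_pct) abort("window lower bound exceeds upper bound")
  if (lower_pct < 0 || upper_pct > 100) {
    abort("window bounds must lie in [0, 100]")
  }
  structure(
    list(
      lower_pct = lower_pct,
      upper_pct = upper_pct,
      symmetric = abs(lower_pct + upper_pct - 100) < 0.05
    ),
    class = "afr_window"
  )
}

#' @export
print.afr_window <- function(x, ...) {
  cat("<afr_window> [", x$lower_pct, ", ", x$upper_pct, "]%",
      if (x$symmetric) " (symmetric)" else "", "\n", sep = "")
  invisible(x)
}

#' @export
format.afr_window <- function(x, ...) {
  paste0(x$lower_pct, "-", x$upper_pct)
}

#' Parse a window string like "30-70" or "44.8-55.2"
#'
#' @param spec A string `"LOWER-UPPER"` in percent.
#' @return An `afr_window`.
#' @export
parse_afr_window <- function(spec) {
  m <- regmatches(spec, regexec("^([0-9.]+)-([0-9.]+)$", spec))[[1]]
  if (length(m) != 3) abort(paste0("cannot parse window '", spec, "'"))
  afr_window(as.numeric(m[2]), as.numeric(m[3]))
}

#' Test window membership of alt-read fractions
#'
#' Bounds are inclusive: the exclusion rule is strictly below the lower bound
#' or strictly above the upper bound, so a fraction of exactly 0.30 passes a
#' 30-70% window.
#'
#' @param alt_fraction_pct Alt-read fractions in percent (vectorized).
#' @param window An [afr_window()].
#' @return Logical vector.
#' @export
in_window <- function(alt_fraction_pct, window) {
  stopifnot(inherits(window, "afr_window"))
  alt_fraction_pct >= window$lower_pct & alt_fraction_pct <= window$upper_pct
}

#' Per-call allele-fraction assessment
#'
#' Adds the alt-read fraction (percent), the min/max balance ratio (percent)
#' and the deviation from the ideal 50% heterozygous fraction to a call table.
#'
#' @param calls A validated variant-call tibble with positive total reads.
#' @return The call table with columns `alt_fraction_pct`,
#'   `balance_ratio_pct`, `deviation_pct` appended.
#' @export
afr_assess <- function(calls) {
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) {
    calls$alt_fraction_pct <- numeric(0)
    calls$balance_ratio_pct <- numeric(0)
    calls$deviation_pct <- numeric(0)
    return(calls)
  }
  f <- alt_fraction(calls$ref_reads, calls$alt_reads)
  calls$alt_fraction_pct <- 100 * f
  calls$balance_ratio_pct <- balance_ratio(calls$ref_reads, calls$alt_reads)
  calls$deviation_pct <- abs(calls$alt_fraction_pct - 50)
  calls
}

#' Tightest symmetric allele-fraction window containing all calls
#'
#' Computes the maximum deviation `d = max |alt_fraction - 0.5|` over the
#' calls and returns the symmetric window `[50 - 100 d, 50 + 100 d]` percent,
#' the narrowest symmetric window that accepts every input call. Bounds are
#' computed from unrounded fractions and then rounded outward (lower bound
#' down, upper bound up) at the requested reporting precision, so the
#' reported window still contains every call and equals the narrowest
#' containing window on the reporting grid. All calls attaining the maximum
#' deviation are recorded as the binding calls (attribute `"binding"`), in
#' input order.
#'
#' @param calls A validated variant-call tibble; all calls need positive total
#'   reads.
#' @param rounding `"integer"` (whole percent) or `"one_decimal"`.
#' @return An `afr_window` with attribute `"binding"` (row indices of the
#'   calls that set the bound).
#' @export
#' @examples
#' calls <- variant_calls(
#'   sample_id = c("a", "b"), chrom = "chr1", pos = c(100, 200),
#'   ref_allele = "A", alt_allele = "G",
#'   ref_reads = c(27, 26), alt_reads = c(23, 32)
#' )
#' tightest_symmetric_window(calls, "one_decimal") # 44.8-55.2
tightest_symmetric_window <- function(calls,
                                      rounding = c("integer", "one_decimal")) {
  rounding <- match.arg(rounding)
  calls <- validate_calls(calls)
  if (nrow(calls) == 0) {
    abort("tightest window is undefined for an empty call set")
  }
  f <- alt_fraction(calls$ref_reads, calls$alt_reads)
  dev <- abs(f - 0.5)
  d <- max(dev)
  scale <- if (rounding == "integer") 1 else 10
  # outward rounding with a float-noise guard so exact-grid bounds stay put
  win <- afr_window(
    floor((50 - 100 * d) * scale + 1e-9) / scale,
    ceiling((50 + 100 * d) * scale - 1e-9) / scale
  )
  attr(win, "binding") <- which(dev == d)
  win
}
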