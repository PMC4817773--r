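## Substitution spectrum, equal-error-rate FDR, and editing-level summaries.

SUBST_TYPES <- {
  g <- expand.grid(ref = BASES, alt = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, ]
  sort(paste0(g$ref, ">", g$alt))
}

#' Equal-error-rate false-discovery-rate estimate
#'
#' Treats all non-A-to-G RNA-DNA variant calls as false positives and
#' assumes the error rate is identical across the 12 substitution types, so
#' the expected number of false A-to-G calls is the non-A-to-G count divided
#' by the 11 other types: `FDR = (n_non / 11) / n_ag`.
#'
#' @param n_ag Number of A-to-G sites (transcript orientation).
#' @param n_non Number of non-A-to-G sites.
#' @return A list of class `"fg_fdr"`: `n_ag`, `n_non`, `n_types_non`
#'   (11), `fdr` (fraction), and `fdr_percent` (percentage rounded to two
#'   decimals).
#' @export
#' @examples
#' estimate_fdr(26056, 1245)$fdr_percent  # 0.43
estimate_fdr <- function(n_ag, n_non) {
  if (n_ag <= 0) stopf("FDR is undefined for n_ag = 0")
  if (n_non < 0) stopf("n_non must be >= 0")
  fdr <- (n_non / 11) / n_ag
  structure(list(n_ag = n_ag, n_non = n_non, n_types_non = 11L,
                 fdr = fdr, fdr_percent = round(100 * fdr, 2)),
            class = "fg_fdr")
}

#' @export
print.fg_fdr <- function(x, ...) {
  cat(sprintf("Equal-error-rate FDR: %.2f%% (%d A-to-G, %d non-A-to-G over 11 types)\n",
              x$fdr_percent, x$n_ag, x$n_non))
  invisible(x)
}

#' Substitution spectrum of variant sites
#'
#' Tallies sites over the 12 ordered substitution types (transcript
#' orientation) and normalizes per million mapped unduplicated reads.
#'
#' @param sites A `fg_sites` data frame (one condition).
#' @param total_unduplicated_mapped_reads Library size used for the
#'   per-million normalization.
#' @return A 12-row data frame: subst, n, per_million.
#' @export
spectrum <- function(sites, total_unduplicated_mapped_reads) {
  if (total_unduplicated_mapped_reads <= 0) {
    stopf("cannot normalize by a non-positive mapped-read count")
  }
  n <- table(factor(sites$subst, levels = SUBST_TYPES))
  out <- data.frame(subst = SUBST_TYPES, n = as.integer(n),
                    stringsAsFactors = FALSE)
  out$per_million <- out$n / (total_unduplicated_mapped_reads / 1e6)
  out
}

#' Editing-level summary and binning
#'
#' Summarizes per-site editing levels with the three-bin partition used for
#' level-stratified analyses: `< 30\%`, `30--60\%` (boundaries inclusive)
#' and `> 60\%`.
#'
#' @param sites A `fg_sites` data frame, or a numeric vector of levels.
#' @return A list of class `"fg_levels"`: `levels`, `median`, and
#'   `bin_fractions` (named `low`, `mid`, `high`; sums to one).
#' @export
level_summary <- function(sites) {
  lv <- if (is.numeric(sites)) sites else sites$level
  if (!length(lv)) stopf("empty site set: no levels to summarize")
  bins <- level_bins(lv)
  frac <- as.vector(table(bins)) / length(lv)
  structure(list(levels = lv, median = stats::median(lv),
                 bin_fractions = stats::setNames(frac, levels(bins))),
            class = "fg_levels")
}

## Shared editing-level binning: <30%, 30-60% (both boundaries in the middle
## bin), >60%.
level_bins <- function(lv) {
  factor(ifelse(lv < 0.3, "low", ifelse(lv <= 0.6, "mid", "high")),
         levels = c("low", "mid", "high"))
}

#' @export
print.fg_levels <- function(x, ...) {
  cat(sprintf("Editing levels: n = %d, median = %.1f%%\n",
              length(x$levels), 100 * x$median))
  cat(sprintf("  <30%%: %.1f%%   30-60%%: %.1f%%   >60%%: %.1f%%\n",
              100 * x$bin_fractions["low"], 100 * x$bin_fractions["mid"],
              100 * x$bin_fractions["high"]))
  invisible(x)
}
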