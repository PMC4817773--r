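#' Write annotated editing sites as TSV (and optionally VCF)
#'
#' The TSV reports sites in transcript orientation (edits appear as A-to-G)
#' with per-replicate counts, editing level and any annotation columns
#' present; the VCF reports REF/ALT in genomic plus-strand orientation with
#' the transcribed strand in INFO, per VCF convention.
#'
#' @param sites A `fg_sites` data frame (annotated or not).
#' @param path Output TSV path.
#' @param vcf_path Optional output VCF path.
#' @export
write_sites <- function(sites, path, vcf_path = NULL) {
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(vcf_path)) {
    con <- file(vcf_path, "wt")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "##INFO=<ID=STRAND,Number=1,Type=String,Description=\"Transcribed strand\">",
                 "##INFO=<ID=LEVEL,Number=1,Type=Float,Description=\"Editing level\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(sites)) {
      gref <- ifelse(sites$strand == "-", COMP[sites$ref], sites$ref)
      galt <- ifelse(sites$strand == "-", COMP[sites$alt], sites$alt)
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tSTRAND=%s;LEVEL=%.4f",
                         sites$contig, sites$pos, gref, galt, sites$strand,
                         sites$level), con)
    }
  }
  invisible(path)
}

#' @rdname write_sites
#' @export
read_sites <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(df) <- c("fg_sites", "data.frame")
  df
}
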