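#' Write / read SAM alignment records
#'
#' `write_sam()` emits an unsorted SAM file with `@HD`/`@SQ` header lines
#' from the alignment data frame produced by [simulate_reads()];
#' `read_sam()` parses such a file (eleven mandatory columns; CIGAR with
#' M/N operations) back into the same representation.
#'
#' @param sam A `fg_sam` data frame (see [simulate_reads()]).
#' @param path File path.
#' @export
write_sam <- function(sam, path) {
  seqinfo <- attr(sam, "seqinfo")
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  if (!is.null(seqinfo)) {
    writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqinfo),
                       as.integer(seqinfo)), con)
  }
  if (nrow(sam)) {
    writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                       sam$qname, sam$flag, sam$rname, sam$pos, sam$mapq,
                       sam$cigar, sam$rnext, sam$pnext, sam$tlen, sam$seq,
                       sam$qual), con)
  }
  invisible(path)
}

#' @rdname write_sam
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@")]
  sq <- hdr[startsWith(hdr, "@SQ")]
  seqinfo <- NULL
  if (length(sq)) {
    sn <- sub(".*\tSN:([^\t]+).*", "\\1", sq)
    ln <- as.integer(sub(".*\tLN:([0-9]+).*", "\\1", sq))
    seqinfo <- stats::setNames(ln, sn)
  }
  if (!length(body)) {
    sam <- empty_sam()
  } else {
    f <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(f) < 11L)
    if (length(bad)) stopf("malformed SAM record at line %d",
                           bad[1] + length(hdr))
    get <- function(i) vapply(f, `[[`, character(1), i)
    sam <- data.frame(qname = get(1), flag = as.integer(get(2)),
                      rname = get(3), pos = as.integer(get(4)),
                      mapq = as.integer(get(5)), cigar = get(6),
                      rnext = get(7), pnext = as.integer(get(8)),
                      tlen = as.integer(get(9)), seq = get(10),
                      qual = get(11), stringsAsFactors = FALSE)
  }
  attr(sam, "seqinfo") <- seqinfo
  class(sam) <- c("fg_sam", "data.frame")
  sam
}
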