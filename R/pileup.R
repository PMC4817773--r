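#' Strand-resolved base-count pileup from paired-end alignments
#'
#' Converts alignment records into per-position, per-transcript-orientation
#' base counts after PCR-duplicate removal.  Duplicates are collapsed on the
#' fragment key (contig, leftmost position, mate leftmost position,
#' transcript orientation), keeping one fragment per key.  Each read is then
#' assigned to the plus- or minus-strand transcript orientation according to
#' the declared strand protocol, and its bases (forward-genomic
#' representation, CIGAR M/N aware) are tallied per reference position.
#' Reads below the mapping-quality floor and bases below the base-quality
#' floor are excluded.
#'
#' @param alignments A `fg_sam` data frame ([simulate_reads()]) or a path to
#'   a SAM file.
#' @param genome Named character vector of contig sequences.
#' @param strand_protocol `"dUTP_read2_sense"` (default; read 2 carries the
#'   sense strand) or `"read1_sense"`.
#' @param min_baseq,min_mapq Quality floors (Phred), both default 20.
#' @param condition,replicate Labels attached to the output rows.
#' @param dedup Collapse PCR duplicates (default `TRUE`).
#' @return A data frame of class `"fg_pileup"`: contig, pos (1-based), ref
#'   (genomic plus-strand base), strand (transcript orientation), counts A,
#'   C, G, T of forward-genomic read bases, condition, replicate.  The
#'   attribute `"mapped_unduplicated"` records the number of reads counted.
#' @export
pileup_from_alignments <- function(alignments, genome,
                                   strand_protocol = "dUTP_read2_sense",
                                   min_baseq = 20L, min_mapq = 20L,
                                   condition = "unknown", replicate = 1L,
                                   dedup = TRUE) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  sam <- alignments
  if (!strand_protocol %in% c("dUTP_read2_sense", "read1_sense")) {
    stopf("unknown strand protocol '%s'", strand_protocol)
  }
  bad <- !sam$rname %in% names(genome)
  if (any(bad)) stopf("alignments reference contig '%s' absent from genome",
                      sam$rname[which(bad)[1]])
  sam <- sam[sam$mapq >= min_mapq, , drop = FALSE]
  ## flat per-read base quality: drop reads whose quality char is below floor
  if (nrow(sam)) {
    q <- utf8ToInt(paste(substr(sam$qual, 1, 1), collapse = "")) - 33L
    sam <- sam[q >= min_baseq, , drop = FALSE]
  }
  is_rev <- bitwAnd(sam$flag, 16L) > 0L
  is_read2 <- bitwAnd(sam$flag, 128L) > 0L
  if (strand_protocol == "dUTP_read2_sense") {
    sense <- (is_read2 & !is_rev) | (!is_read2 & is_rev)
  } else {
    sense <- (!is_read2 & !is_rev) | (is_read2 & is_rev)
  }
  tx_strand <- ifelse(sense, "+", "-")

  if (dedup && nrow(sam)) {
    key <- paste(sam$rname, pmin(sam$pos, sam$pnext),
                 pmax(sam$pos, sam$pnext), tx_strand, sep = ":")
    ## collapse whole fragments: both mates of a fragment share the key, so
    ## keeping the first qname per key keeps exactly one intact pair
    first_q <- tapply(sam$qname, key, function(x) x[1])
    keep <- sam$qname %in% unname(first_q)
    sam <- sam[keep, , drop = FALSE]
    tx_strand <- tx_strand[keep]
  }
  n_reads <- nrow(sam)

  out <- do.call(rbind, lapply(names(genome), function(ctg) {
    sel <- sam$rname == ctg
    if (!any(sel)) return(NULL)
    pileup_contig(sam[sel, , drop = FALSE], tx_strand[sel],
                  genome[[ctg]], ctg, condition, replicate)
  }))
  if (is.null(out)) {
    out <- data.frame(contig = character(0), pos = integer(0),
                      ref = character(0), strand = character(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), condition = character(0),
                      replicate = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "mapped_unduplicated") <- n_reads
  class(out) <- c("fg_pileup", "data.frame")
  out
}

## Per-contig tally.  Reads are expanded to (position, base) pairs; simple
## "<n>M" alignments are expanded vectorized, junction CIGARs in a loop.
pileup_contig <- function(sam, tx_strand, contig_seq, ctg, condition,
                          replicate) {
  len <- nchar(contig_seq)
  simple <- grepl("^[0-9]+M$", sam$cigar)
  pos_list <- vector("list", 2)
  base_list <- vector("list", 2)
  strand_list <- vector("list", 2)

  if (any(simple)) {
    rl <- nchar(sam$seq[simple])
    stopifnot(length(unique(rl)) <= 1)
    R <- rl[1]
    n <- sum(simple)
    pos_list[[1]] <- rep(sam$pos[simple], each = R) +
      rep.int(0:(R - 1L), n)
    base_list[[1]] <- utf8ToInt(paste(sam$seq[simple], collapse = ""))
    strand_list[[1]] <- rep(tx_strand[simple], each = R)
  }
  if (any(!simple)) {
    js <- which(!simple)
    pl <- vector("list", length(js))
    for (i in seq_along(js)) {
      r <- js[i]
      ops <- cigar_ops(sam$cigar[r])
      p <- sam$pos[r]
      pp <- integer(0)
      for (j in seq_len(nrow(ops))) {
        if (ops[j, 2] == 1L) {          # M
          pp <- c(pp, p:(p + ops[j, 1] - 1L))
          p <- p + ops[j, 1]
        } else {                        # N
          p <- p + ops[j, 1]
        }
      }
      pl[[i]] <- pp
    }
    pos_list[[2]] <- unlist(pl, use.names = FALSE)
    base_list[[2]] <- utf8ToInt(paste(sam$seq[js], collapse = ""))
    strand_list[[2]] <- rep(tx_strand[js], times = lengths(pl))
  }
  pos <- c(pos_list[[1]], pos_list[[2]])
  bint <- c(base_list[[1]], base_list[[2]])
  strnd <- c(strand_list[[1]], strand_list[[2]])
  lut <- integer(128); lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  bidx <- lut[bint]
  ok <- bidx > 0L & pos >= 1L & pos <= len
  pos <- pos[ok]; bidx <- bidx[ok]; strnd <- strnd[ok]

  res <- lapply(c("+", "-"), function(sd) {
    s <- strnd == sd
    if (!any(s)) return(NULL)
    code <- (pos[s] - 1L) * 4L + bidx[s]
    tab <- tabulate(code, nbins = 4L * len)
    mat <- matrix(tab, ncol = 4, byrow = TRUE)
    covered <- which(rowSums(mat) > 0)
    data.frame(contig = ctg, pos = covered,
               ref = substring(contig_seq, covered, covered),
               strand = sd,
               A = mat[covered, 1], C = mat[covered, 2],
               G = mat[covered, 3], T = mat[covered, 4],
               condition = condition, replicate = replicate,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

cigar_ops <- function(cigar) {
  n <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  op <- regmatches(cigar, gregexpr("[A-Z]", cigar))[[1]]
  if (!all(op %in% c("M", "N"))) stopf("unsupported CIGAR op in '%s'", cigar)
  cbind(n, ifelse(op == "M", 1L, 2L))
}
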