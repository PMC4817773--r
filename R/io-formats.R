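#' Read and write genome FASTA
#'
#' Thin wrappers over [Biostrings::readDNAStringSet()] /
#' [Biostrings::writeXStringSet()] that move between files and the plain
#' named-character-vector genome representation used internally.
#'
#' @param path File path.
#' @return `read_genome_fasta()`: named character vector of contig
#'   sequences.
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  out <- as.character(ss)
  names(out) <- sub("\\s.*$", "", names(ss))
  out
}

#' @param genome Named character vector of contig sequences.
#' @rdname read_genome_fasta
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(unlist(genome))
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write gene models as GFF3
#'
#' Emits a deterministic GFF3 v3 file with `gene`, `mRNA`, `exon` and `CDS`
#' rows (1-based inclusive coordinates, CDS phase per GFF3).
#'
#' @param models A `fg_genes` object.
#' @param path Output path.
#' @export
write_gff3 <- function(models, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in models) {
    span <- c(min(g$exons), max(g$exons))
    gid <- g$gene_id
    mid <- paste0(gid, ".t1")
    rows <- c(
      sprintf("%s\tfungedit\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
              g$contig, span[1], span[2], g$strand, gid),
      sprintf("%s\tfungedit\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
              g$contig, span[1], span[2], g$strand, mid, gid),
      sprintf("%s\tfungedit\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
              g$contig, g$exons[, 1], g$exons[, 2], g$strand, mid),
      sprintf("%s\tfungedit\tCDS\t%d\t%d\t.\t%s\t%d\tID=%s.cds;Parent=%s",
              g$contig, g$cds[, 1], g$cds[, 2], g$strand, g$cds[, 3],
              mid, mid)
    )
    writeLines(rows, con)
  }
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses a GFF3 file with gene/mRNA/exon/CDS features (one transcript per
#' gene) into a `fg_genes` object, using [rtracklayer::import()] for the
#' format itself.  Where a gene has several transcripts the one with the
#' longest CDS is kept.
#'
#' @param path GFF3 file path.
#' @return A `fg_genes` object.
#' @export
read_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  mrna <- df[df$type == "mRNA", , drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(mrna))) {
    mid <- mrna$ID[i]
    gid <- unlist(mrna$Parent[i])
    kids <- df[vapply(df$Parent, function(p) mid %in% unlist(p), logical(1)), ,
               drop = FALSE]
    ex <- kids[kids$type == "exon", c("start", "end"), drop = FALSE]
    cd <- kids[kids$type == "CDS", c("start", "end", "phase"), drop = FALSE]
    if (nrow(cd) == 0) next
    prev <- out[[gid]]
    cand <- gene_model(gid, mrna$seqnames[i], mrna$strand[i],
                       as.matrix(ex), as.matrix(cd))
    if (is.null(prev) ||
        sum(cand$cds[, 2] - cand$cds[, 1]) > sum(prev$cds[, 2] - prev$cds[, 1])) {
      out[[gid]] <- cand
    }
  }
  as_fg_genes(unname(out))
}
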