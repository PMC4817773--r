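#' Gene model objects
#'
#' A `fg_gene` is a light container for one protein-coding gene model:
#' gene id, contig, strand, exon intervals and CDS intervals (1-based
#' inclusive, genomic ascending order) with GFF3 phases, plus the genomic
#' coordinates of the start and stop codons.  A `fg_genes` object is a named
#' list of `fg_gene` records.
#'
#' Exons are non-overlapping; in transcript orientation they run 5'->3'
#' (ascending genomic order on the plus strand, descending on the minus
#' strand).  The CDS is contained in the exons and its spliced length is
#' divisible by three after phase adjustment.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (`start`, `end`), ascending.
#' @param cds Three-column matrix (`start`, `end`, `phase`), ascending.
#' @param fake_intron Optional `c(start, end)` of a spurious annotated
#'   intron that is in reality coding (simulator bookkeeping).
#' @param is_pseudogene Logical flag used by the simulator.
#' @return An object of class `"fg_gene"`.
#' @export
gene_model <- function(gene_id, contig, strand, exons, cds,
                       fake_intron = NULL, is_pseudogene = FALSE) {
  stopifnot(strand %in% c("+", "-"))
  exons <- matrix(as.integer(exons), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  exons <- exons[order(exons[, 1]), , drop = FALSE]
  if (nrow(exons) > 1 && any(exons[-1, 1] <= exons[-nrow(exons), 2])) {
    stopf("gene %s: overlapping exons", gene_id)
  }
  cds <- matrix(as.integer(cds), ncol = 3,
                dimnames = list(NULL, c("start", "end", "phase")))
  cds <- cds[order(cds[, 1]), , drop = FALSE]
  len <- sum(cds[, 2] - cds[, 1] + 1L)
  if (len %% 3L != 0L) stopf("gene %s: CDS length %d not divisible by 3", gene_id, len)
  g <- list(gene_id = gene_id, contig = contig, strand = strand,
            exons = exons, cds = cds,
            fake_intron = fake_intron, is_pseudogene = isTRUE(is_pseudogene))
  class(g) <- "fg_gene"
  g
}

#' @export
print.fg_gene <- function(x, ...) {
  cat(sprintf("<fg_gene %s> %s:%d-%d (%s), %d exon(s), CDS %d nt%s\n",
              x$gene_id, x$contig, min(x$exons), max(x$exons), x$strand,
              nrow(x$exons), sum(x$cds[, 2] - x$cds[, 1] + 1L),
              if (x$is_pseudogene) ", pseudogene-like" else ""))
  invisible(x)
}

as_fg_genes <- function(models) {
  names(models) <- vapply(models, function(g) g$gene_id, character(1))
  class(models) <- "fg_genes"
  models
}

#' @export
print.fg_genes <- function(x, ...) {
  cat(sprintf("<fg_genes> %d gene models on %d contig(s)\n", length(x),
              length(unique(vapply(x, function(g) g$contig, character(1))))))
  invisible(x)
}

## Genomic positions of the (spliced) transcript in 5'->3' transcript order.
## retained = TRUE additionally includes a pseudogene's fake intron, i.e. the
## biologically real transcript.
tx_positions <- function(model, retained = FALSE) {
  ex <- model$exons
  if (retained && !is.null(model$fake_intron)) {
    ex <- merge_interval(ex, model$fake_intron)
  }
  pos <- unlist(lapply(seq_len(nrow(ex)),
                       function(i) ex[i, 1]:ex[i, 2]), use.names = FALSE)
  if (model$strand == "-") pos <- rev(pos)
  pos
}

merge_interval <- function(ex, iv) {
  ex <- rbind(ex, matrix(as.integer(iv), ncol = 2))
  ex <- ex[order(ex[, 1]), , drop = FALSE]
  out <- ex[1, , drop = FALSE]
  for (i in seq_len(nrow(ex))[-1]) {
    if (ex[i, 1] <= out[nrow(out), 2] + 1L) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], ex[i, 2])
    } else {
      out <- rbind(out, ex[i, , drop = FALSE])
    }
  }
  colnames(out) <- c("start", "end")
  out
}

## Spliced transcript sequence in transcript orientation.
transcript_seq <- function(genome, model, retained = FALSE) {
  contig <- genome[[model$contig]]
  pos <- tx_positions(model, retained = retained)
  b <- substring(contig, pos, pos)
  if (model$strand == "-") b <- comp_base(b)
  paste(b, collapse = "")
}

## CDS sequence in transcript orientation (phase-adjusted start).
cds_seq <- function(genome, model) {
  contig <- genome[[model$contig]]
  cds <- model$cds
  segs <- vapply(seq_len(nrow(cds)),
                 function(i) substr(contig, cds[i, 1], cds[i, 2]), character(1))
  if (model$strand == "-") {
    s <- paste(rev(vapply(segs, revcomp, character(1))), collapse = "")
    phase0 <- cds[nrow(cds), 3]
  } else {
    s <- paste(segs, collapse = "")
    phase0 <- cds[1, 3]
  }
  if (phase0 > 0) s <- substr(s, phase0 + 1L, nchar(s))
  s
}

## Genomic positions of CDS bases in transcript (translation) order.
cds_positions <- function(model) {
  cds <- model$cds
  pos <- unlist(lapply(seq_len(nrow(cds)),
                       function(i) cds[i, 1]:cds[i, 2]), use.names = FALSE)
  if (model$strand == "-") pos <- rev(pos)
  phase0 <- if (model$strand == "-") cds[nrow(cds), 3] else cds[1, 3]
  if (phase0 > 0) pos <- pos[-seq_len(phase0)]
  pos
}

## Annotated introns (gaps between consecutive exons), genomic ascending.
intron_intervals <- function(model) {
  ex <- model$exons
  if (nrow(ex) < 2) {
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  cbind(start = ex[-nrow(ex), 2] + 1L, end = ex[-1, 1] - 1L)
}

## Genomic coordinates of the start/stop codon ends used by UTR proxies:
## the most 5' and most 3' CDS base in transcript orientation.
cds_bounds_tx <- function(model) {
  if (model$strand == "+") {
    c(five = min(model$cds[, 1]), three = max(model$cds[, 2]))
  } else {
    c(five = max(model$cds[, 2]), three = min(model$cds[, 1]))
  }
}

translate_dna <- function(x) {
  as.character(Biostrings::translate(Biostrings::DNAStringSet(x),
                                     if.fuzzy.codon = "X"))
}
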