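#' Detect PUK1-like pseudogenes from intronic stop-codon editing
#'
#' Searches for genes whose annotated introns conceal editable in-frame
#' premature stop codons: automated annotation sometimes introduces a
#' spurious intron to avoid in-frame UAG stops that are in reality removed
#' by stage-specific UAG-to-UGG editing.  For every intronic A-to-G site,
#' the upstream CDS reading frame is extended through the retained intron; a
#' call is made when the edited A is codon position 2 of an in-frame UAG
#' (the edit yields UGG tryptophan) and the retained-intron frame is open —
#' codon-aligned (length divisible by three) with no remaining in-frame stop
#' inside the intron once all evidence edits are applied.  Tandem stops in
#' one intron (the PUK1 pattern, UAGUAG) are grouped into a single call.
#'
#' @param sites Annotated sites ([annotate_sites()]); rows with feature
#'   `"intronic"` and substitution A>G are examined.
#' @param models A `fg_genes` object.
#' @param genome Named character vector of contig sequences.
#' @return A data frame of class `"fg_pseudogene_calls"` (gene_id,
#'   intron_start, intron_end, stop_pos — comma-joined genomic positions of
#'   the edited A's —, n_evidence, orf_open), restricted to open-frame
#'   calls.  Calls failing the open-frame test are kept in
#'   `attr(, "rejected")`; corrected gene models (intron retained as CDS)
#'   in `attr(, "corrected_models")`, a `fg_genes` object.
#' @export
detect_puk1_like <- function(sites, models, genome) {
  if (is.null(sites$feature)) {
    stopf("sites must be annotated (run annotate_sites() first)")
  }
  cand <- sites[sites$feature == "intronic" & sites$subst == "A>G" &
                  !is.na(sites$gene_id), , drop = FALSE]
  calls <- list()
  rejected <- list()
  corrected <- list()
  if (nrow(cand)) {
    for (gid in unique(cand$gene_id)) {
      g <- models[[gid]]
      if (is.null(g)) next
      introns <- intron_intervals(g)
      gs <- cand[cand$gene_id == gid, , drop = FALSE]
      for (k in seq_len(nrow(introns))) {
        iv <- introns[k, ]
        in_iv <- gs$pos >= iv[1] & gs$pos <= iv[2]
        if (!any(in_iv)) next
        res <- examine_retained_intron(g, iv, gs[in_iv, , drop = FALSE],
                                       genome)
        if (is.null(res)) next
        if (res$orf_open) {
          calls[[length(calls) + 1L]] <- res$row
          corrected[[gid]] <- res$model
        } else {
          rejected[[length(rejected) + 1L]] <- res$row
        }
      }
    }
  }
  empty <- data.frame(gene_id = character(0), intron_start = integer(0),
                      intron_end = integer(0), stop_pos = character(0),
                      n_evidence = integer(0), orf_open = logical(0),
                      stringsAsFactors = FALSE)
  out <- if (length(calls)) do.call(rbind, calls) else empty
  rownames(out) <- NULL
  attr(out, "rejected") <- if (length(rejected)) do.call(rbind, rejected) else empty
  attr(out, "corrected_models") <- as_fg_genes(unname(corrected))
  class(out) <- c("fg_pseudogene_calls", "data.frame")
  out
}

## Extend the CDS frame through one retained intron and test the evidence
## sites.  Returns NULL when no site is an editable in-frame UAG.
examine_retained_intron <- function(g, intron, gsites, genome) {
  if (any(g$cds[, 1] >= intron[1] & g$cds[, 1] <= intron[2])) return(NULL)
  model2 <- retained_model(g, intron)
  pos_map <- cds_positions(model2)
  s <- cds_seq(genome, model2)
  b <- strsplit(s, "")[[1]]
  idx <- match(gsites$pos, pos_map)
  if (anyNA(idx)) {
    stopf("cannot establish the reading frame through the intron of %s",
          g$gene_id)
  }
  cp <- (idx - 1L) %% 3L + 1L
  cstart <- idx - cp + 1L
  codon <- paste0(b[cstart], b[cstart + 1L], b[cstart + 2L])
  is_evidence <- cp == 2L & codon == "TAG"
  if (!any(is_evidence)) return(NULL)
  ev_idx <- idx[is_evidence]
  ## apply the evidence edits, then scan for remaining in-frame stops whose
  ## codons overlap the retained intron
  b2 <- b
  b2[ev_idx] <- "G"
  in_intron_cds <- which(pos_map >= intron[1] & pos_map <= intron[2])
  codon_starts <- seq(1L, length(b2) - 2L, by = 3L)
  touches <- codon_starts[(codon_starts + 2L) >= min(in_intron_cds) &
                            codon_starts <= max(in_intron_cds)]
  cods <- paste0(b2[touches], b2[touches + 1L], b2[touches + 2L])
  open <- (intron[2] - intron[1] + 1L) %% 3L == 0L &&
    !any(cods %in% STOP_CODONS)
  row <- data.frame(gene_id = g$gene_id,
                    intron_start = unname(intron[1]),
                    intron_end = unname(intron[2]),
                    stop_pos = paste(sort(gsites$pos[is_evidence]),
                                     collapse = ","),
                    n_evidence = sum(is_evidence), orf_open = open,
                    stringsAsFactors = FALSE)
  list(row = row, orf_open = open, model = model2)
}

## Gene model with one annotated intron retained as coding sequence.  Built
## without the whole-codon validation of gene_model(): a retained intron of
## length not divisible by three legitimately breaks the downstream frame
## (that is exactly what the open-frame test detects).
retained_model <- function(g, intron) {
  ex <- merge_interval(g$exons, intron)
  cds <- merge_interval(g$cds[, 1:2, drop = FALSE], intron)
  cds <- cbind(cds, phase = exon_phases(cds, g$strand))
  colnames(cds) <- c("start", "end", "phase")
  m <- list(gene_id = g$gene_id, contig = g$contig, strand = g$strand,
            exons = ex, cds = cds, fake_intron = NULL, is_pseudogene = TRUE)
  class(m) <- "fg_gene"
  m
}

#' Write pseudogene calls and corrected models
#'
#' @param calls Output of [detect_puk1_like()].
#' @param tsv_path Path for the calls TSV.
#' @param gff3_path Optional path for corrected gene models as GFF3.
#' @export
write_pseudogene_calls <- function(calls, tsv_path, gff3_path = NULL) {
  utils::write.table(as.data.frame(calls), tsv_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(gff3_path)) {
    write_gff3(attr(calls, "corrected_models"), gff3_path)
  }
  invisible(tsv_path)
}
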