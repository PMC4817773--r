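#' Plant editing sites, SNPs and expression profiles
#'
#' Chooses `n_edit_sites` adenosine positions on transcribed strands,
#' assigns each a true editing level drawn uniformly from
#' `editing_level_range` and the configured editing condition, and places
#' `n_genomic_snps` homozygous SNPs at positions disjoint from edit sites.
#' The tandem stop-codon adenosines of every PUK1-like pseudogene are
#' planted as one haplotype group (all sites of a group are co-edited on the
#' same molecule) at `pseudogene_edit_level`; any other pair of planted
#' sites falling within one codon (<= 3 nt apart on the same transcript)
#' also shares a haplotype group.  Gene expression weights are drawn so that
#' `n_specific_genes` genes (preferring pseudogenes) are expressed
#' essentially only in the editing condition.
#'
#' @param config A [sim_config()] object.
#' @param genome,models Output of [make_genome()].
#' @return A list of class `"fg_truth"` with data frames `edits` (contig,
#'   pos, strand, gene_id, tx_pos, level, condition, hap_group), `snps`
#'   (contig, pos, ref, alt), `pseudogenes` (gene_id, stop A positions,
#'   intron bounds) and `expression` (gene_id, condition, weight).
#' @export
plant_truth <- function(config, genome, models) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "truth"), {
    edits <- plant_edit_sites(config, genome, models)
    pseudo <- plant_pseudogene_sites(config, genome, models)
    if (nrow(pseudo$edits)) {
      edits <- rbind(pseudo$edits, edits)
    }
    snps <- plant_snps(config, genome, edits)
    expr <- plant_expression(config, models)
    tt <- list(edits = edits, snps = snps, pseudogenes = pseudo$calls,
               expression = expr)
    class(tt) <- "fg_truth"
    tt
  })
}

empty_edits <- function() {
  data.frame(contig = character(0), pos = integer(0), strand = character(0),
              gene_id = character(0), tx_pos = integer(0), level = numeric(0),
              condition = character(0), hap_group = character(0),
              stringsAsFactors = FALSE)
}

plant_edit_sites <- function(config, genome, models) {
  n <- config$n_edit_sites
  if (n == 0) return(empty_edits())
  ## candidate A positions per transcript (true transcript: retained introns
  ## for pseudogenes), away from transcript ends so fragments can cover them
  pool <- do.call(rbind, lapply(models, function(g) {
    pos <- tx_positions(g, retained = TRUE)
    txseq <- transcript_seq(genome, g, retained = TRUE)
    b <- strsplit(txseq, "")[[1]]
    idx <- which(b == "A")
    margin <- config$fragment_length
    idx <- idx[idx > margin & idx <= length(pos) - margin]
    if (!is.null(config$edit_context)) {
      ctx <- paste0(b[idx - 1L], "A", b[idx + 1L])
      idx <- idx[ctx %in% config$edit_context]
    }
    ## keep clear of the pseudogene stop codons (planted separately)
    if (g$is_pseudogene && !is.null(g$fake_intron)) {
      idx <- idx[!(pos[idx] >= g$fake_intron[1] & pos[idx] <= g$fake_intron[2])]
    }
    if (!length(idx)) return(NULL)
    data.frame(contig = g$contig, pos = pos[idx], strand = g$strand,
               gene_id = g$gene_id, tx_pos = idx, stringsAsFactors = FALSE)
  }))
  if (is.null(pool) || nrow(pool) < n) {
    stopf("not enough eligible A positions (%d) to plant %d edit sites",
          if (is.null(pool)) 0L else nrow(pool), n)
  }
  sel <- pool[sample(nrow(pool), n), , drop = FALSE]
  sel <- sel[order(sel$gene_id, sel$tx_pos), , drop = FALSE]
  lr <- config$editing_level_range
  sel$level <- stats::runif(n, lr[1], lr[2])
  sel$condition <- config$editing_condition
  ## sites within one codon on the same transcript share a haplotype group
  sel$hap_group <- NA_character_
  for (gid in unique(sel$gene_id)) {
    i <- which(sel$gene_id == gid)
    if (length(i) < 2) next
    d <- diff(sel$tx_pos[i])
    grp <- cumsum(c(TRUE, d > 3L))
    for (gno in unique(grp[duplicated(grp) | duplicated(grp, fromLast = TRUE)])) {
      j <- i[grp == gno]
      sel$hap_group[j] <- sprintf("%s.hap%d", gid, gno)
      sel$level[j] <- sel$level[j[1]]
    }
  }
  rownames(sel) <- NULL
  sel
}

plant_pseudogene_sites <- function(config, genome, models) {
  pg <- Filter(function(g) g$is_pseudogene, models)
  edits <- empty_edits()
  calls <- data.frame(gene_id = character(0), intron_start = integer(0),
                      intron_end = integer(0), stop_pos = character(0),
                      stringsAsFactors = FALSE)
  for (g in pg) {
    pos <- tx_positions(g, retained = TRUE)
    txseq <- transcript_seq(genome, g, retained = TRUE)
    ## the two TAGs are in-frame codons of the retained CDS; find them inside
    ## the fake intron
    b <- strsplit(txseq, "")[[1]]
    in_intron <- pos >= g$fake_intron[1] & pos <= g$fake_intron[2]
    codon_starts <- seq(1L, length(b) - 2L, by = 3L)
    tags <- codon_starts[b[codon_starts] == "T" & b[codon_starts + 1L] == "A" &
                           b[codon_starts + 2L] == "G" & in_intron[codon_starts]]
    a_tx <- tags + 1L                     # edited A = codon position 2
    edits <- rbind(edits, data.frame(
      contig = g$contig, pos = pos[a_tx], strand = g$strand,
      gene_id = g$gene_id, tx_pos = a_tx,
      level = config$pseudogene_edit_level,
      condition = config$editing_condition,
      hap_group = sprintf("%s.stop", g$gene_id), stringsAsFactors = FALSE))
    calls <- rbind(calls, data.frame(
      gene_id = g$gene_id, intron_start = g$fake_intron[1],
      intron_end = g$fake_intron[2],
      stop_pos = paste(sort(pos[a_tx]), collapse = ","),
      stringsAsFactors = FALSE))
  }
  list(edits = edits, calls = calls)
}

plant_snps <- function(config, genome, edits) {
  n <- config$n_genomic_snps
  contig <- names(genome)[1]
  seqlen <- nchar(genome[[1]])
  out <- data.frame(contig = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    stringsAsFactors = FALSE)
  if (n == 0) return(out)
  taken <- edits$pos
  pos <- integer(0)
  while (length(pos) < n) {
    cand <- sample(seqlen, n * 2L)
    cand <- setdiff(cand, c(taken, pos))
    pos <- c(pos, cand)[seq_len(min(n, length(pos) + length(cand)))]
  }
  pos <- sort(pos[seq_len(n)])
  ref <- substring(genome[[1]], pos, pos)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), character(1))
  data.frame(contig = contig, pos = pos, ref = ref, alt = unname(alt),
             stringsAsFactors = FALSE)
}

plant_expression <- function(config, models) {
  ids <- vapply(models, function(g) g$gene_id, character(1))
  is_pseudo <- vapply(models, function(g) g$is_pseudogene, logical(1))
  nspec <- min(config$n_specific_genes, length(ids))
  ## stage-specific genes (pseudogenes first, PUK1-style) are silent outside
  ## the editing condition; the next block of genes is up-regulated in it
  spec <- ids[order(!is_pseudo)][seq_len(nspec)]
  nup <- min(nspec, length(ids) - nspec)
  up_genes <- setdiff(ids[order(!is_pseudo)], spec)[seq_len(nup)]
  grid <- expand.grid(gene_id = ids, condition = config$conditions,
                      stringsAsFactors = FALSE)
  base <- stats::setNames(stats::rlnorm(length(ids), 0, 0.4), ids)
  grid$weight <- base[grid$gene_id]
  off <- grid$gene_id %in% spec & grid$condition != config$editing_condition
  grid$weight[off] <- 0
  up <- grid$gene_id %in% up_genes & grid$condition == config$editing_condition
  grid$weight[up] <- grid$weight[up] * 4
  grid
}

#' @export
print.fg_truth <- function(x, ...) {
  cat(sprintf("<fg_truth> %d edit sites (%d haplotype-grouped), %d SNPs, %d pseudogenes\n",
              nrow(x$edits), sum(!is.na(x$edits$hap_group)), nrow(x$snps),
              nrow(x$pseudogenes)))
  invisible(x)
}

#' Write / read a truth table as TSV
#'
#' Serializes the edit-site table of a truth object (1-based genomic
#' coordinates, transcribed strand, true level, condition, haplotype group)
#' together with SNPs and pseudogene records into one TSV with a `record`
#' discriminator column.
#'
#' @param truth A `fg_truth` object.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  ed <- truth$edits
  ed$record <- "edit"
  sn <- truth$snps
  cols <- c("record", "contig", "pos", "strand", "gene_id", "tx_pos",
            "level", "condition", "hap_group", "ref", "alt")
  for (nm in setdiff(cols, names(ed))) ed[[nm]] <- NA
  if (nrow(sn)) {
    sn$record <- "snp"
    for (nm in setdiff(cols, names(sn))) sn[[nm]] <- NA
  } else sn <- NULL
  out <- rbind(ed[cols], if (!is.null(sn)) sn[cols])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  edits <- df[df$record == "edit",
              c("contig", "pos", "strand", "gene_id", "tx_pos", "level",
                "condition", "hap_group")]
  snps <- df[df$record == "snp", c("contig", "pos", "ref", "alt")]
  rownames(edits) <- rownames(snps) <- NULL
  tt <- list(edits = edits, snps = snps,
             pseudogenes = data.frame(), expression = data.frame())
  class(tt) <- "fg_truth"
  tt
}
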