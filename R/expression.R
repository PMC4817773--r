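#' Quantify gene expression from one alignment library
#'
#' Counts deduplicated fragments per gene (fragment span overlapping the
#' gene's exons on the matching transcript strand, duplicate collapsing as
#' in [pileup_from_alignments()]) and derives FPKM (fragments per kb of
#' exon per million mapped fragments) and CPM (counts per million).
#'
#' @param alignments A `fg_sam` data frame or SAM path.
#' @param models A `fg_genes` object.
#' @param condition,replicate Labels for the output rows.
#' @param strand_protocol See [pileup_from_alignments()].
#' @param dedup Collapse PCR duplicates first (default `TRUE`).
#' @return Data frame: gene_id, condition, replicate, fragments, fpkm, cpm.
#' @export
quantify <- function(alignments, models, condition = "unknown",
                     replicate = 1L, strand_protocol = "dUTP_read2_sense",
                     dedup = TRUE) {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  sam <- alignments
  is_rev <- bitwAnd(sam$flag, 16L) > 0L
  is_read2 <- bitwAnd(sam$flag, 128L) > 0L
  sense <- if (strand_protocol == "dUTP_read2_sense") {
    (is_read2 & !is_rev) | (!is_read2 & is_rev)
  } else (!is_read2 & !is_rev) | (is_read2 & is_rev)
  tx_strand <- ifelse(sense, "+", "-")
  lo <- pmin(sam$pos, sam$pnext)
  hi <- pmax(sam$pos, sam$pnext)
  frag <- !is_read2                     # one record per fragment
  f <- data.frame(contig = sam$rname[frag], lo = lo[frag],
                  hi = hi[frag] + nchar(sam$seq[frag]) - 1L,
                  strand = tx_strand[frag], stringsAsFactors = FALSE)
  if (dedup) {
    f <- f[!duplicated(paste(f$contig, f$lo, f$hi, f$strand, sep = ":")), ,
           drop = FALSE]
  }
  total <- nrow(f)
  counts <- vapply(models, function(g) {
    exlen <- sum(g$exons[, 2] - g$exons[, 1] + 1L)
    if (exlen == 0) stopf("gene %s has zero exon length", g$gene_id)
    span <- c(min(g$exons), max(g$exons))
    sum(f$contig == g$contig & f$strand == g$strand &
          f$lo <= span[2] & f$hi >= span[1])
  }, numeric(1))
  exkb <- vapply(models, function(g)
    sum(g$exons[, 2] - g$exons[, 1] + 1L) / 1000, numeric(1))
  mfrag <- max(total, 1L) / 1e6
  data.frame(gene_id = names(counts), condition = condition,
             replicate = replicate, fragments = as.integer(counts),
             fpkm = counts / exkb / mfrag, cpm = counts / mfrag,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Stage-specificity categories per gene
#'
#' Averages FPKM/CPM across replicates per condition and classifies each
#' gene relative to the focal (editing) condition: `specific` (expressed,
#' CPM > `cpm_expressed`, in the focal condition and below `cpm_absent` in
#' every other condition), `up` (expressed in the focal condition with FPKM
#' at least `fold` times the maximum of the other conditions, computed with
#' pseudo-count 0.1), else `other`.
#'
#' @param records Row-bound output of [quantify()] across all conditions
#'   and replicates.
#' @param focal Condition of interest (e.g. `"perithecia"`).
#' @param cpm_expressed Expressed threshold (CPM > 10).
#' @param cpm_absent Absence ceiling for the specificity rule (CPM < 1).
#' @param fold Up-regulation fold change (default 2).
#' @return Data frame: gene_id, category, expressed (CPM > threshold in
#'   focal), plus mean focal FPKM/CPM.
#' @export
stage_categories <- function(records, focal, cpm_expressed = 10,
                             cpm_absent = 1, fold = 2) {
  if (length(unique(records$condition)) < 2) {
    stopf("stage categories need records from at least two conditions")
  }
  if (!focal %in% records$condition) {
    stopf("condition '%s' missing from the expression records", focal)
  }
  agg <- stats::aggregate(records[, c("fpkm", "cpm")],
                          by = list(gene_id = records$gene_id,
                                    condition = records$condition), mean)
  genes <- unique(agg$gene_id)
  foc <- agg[agg$condition == focal, ]
  oth <- agg[agg$condition != focal, ]
  fi <- match(genes, foc$gene_id)
  expressed <- foc$cpm[fi] > cpm_expressed
  max_oth_fpkm <- vapply(genes, function(g)
    max(c(oth$fpkm[oth$gene_id == g], 0)), numeric(1))
  max_oth_cpm <- vapply(genes, function(g)
    max(c(oth$cpm[oth$gene_id == g], 0)), numeric(1))
  specific <- expressed & max_oth_cpm < cpm_absent
  up <- expressed & !specific &
    (foc$fpkm[fi] + 0.1) >= fold * (max_oth_fpkm + 0.1)
  category <- ifelse(specific, "specific", ifelse(up, "up", "other"))
  data.frame(gene_id = genes, category = category, expressed = expressed,
             fpkm_focal = foc$fpkm[fi], cpm_focal = foc$cpm[fi],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cross-tabulate editing levels with expression categories
#'
#' For each editing-level bin (<30\%, 30--60\%, >60\%), counts the genes
#' having at least one site in the bin and reports the fraction that are
#' stage-specific or up-regulated.  Also reports the median focal FPKM per
#' bin (support for the expression-vs-level null observation).
#'
#' @param sites Sites with `gene_id` and `level`.
#' @param categories Output of [stage_categories()].
#' @return Data frame: bin, n_genes, n_specific, n_up, frac_specific_or_up,
#'   median_fpkm.
#' @export
crosstab_editing_expression <- function(sites, categories) {
  ok <- !is.na(sites$gene_id)
  s <- sites[ok, , drop = FALSE]
  if (!nrow(s)) {
    return(data.frame(bin = character(0), n_genes = integer(0),
                      n_specific = integer(0), n_up = integer(0),
                      frac_specific_or_up = numeric(0),
                      median_fpkm = numeric(0)))
  }
  bins <- level_bins(s$level)
  do.call(rbind, lapply(levels(bins), function(bn) {
    genes <- unique(s$gene_id[bins == bn])
    cat_g <- categories$category[match(genes, categories$gene_id)]
    fpkm <- categories$fpkm_focal[match(genes, categories$gene_id)]
    data.frame(bin = bn, n_genes = length(genes),
               n_specific = sum(cat_g == "specific", na.rm = TRUE),
               n_up = sum(cat_g == "up", na.rm = TRUE),
               frac_specific_or_up =
                 if (length(genes)) mean(cat_g %in% c("specific", "up"))
                 else NA_real_,
               median_fpkm = stats::median(fpkm, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
}
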