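## Synthetic genome + annotation generator.

SENSE_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES, stringsAsFactors = FALSE), 1, paste,
        collapse = ""),
  c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate an annotated toy genome
#'
#' Places `n_genes` non-overlapping protein-coding genes (start codon `ATG`,
#' in-frame sense codons, proper stop codon) on a single contig, on both
#' strands, separated by random intergenic sequence.  A fraction of genes
#' carry one real `GT..AG` intron.  The first `n_pseudogenes` genes are
#' PUK1-like: their true coding sequence contains two tandem in-frame `TAG`
#' stop codons, and the emitted annotation conceals a codon-aligned window
#' around them as a spurious `GT..AG` intron, mimicking the way automated
#' annotation hides editable premature stops.  Output is deterministic for a
#' fixed seed.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genome` (named character vector, one
#'   contig) and `models` (a `fg_genes` object; pseudogenes carry
#'   `fake_intron` coordinates and `is_pseudogene = TRUE`).
#' @export
#' @examples
#' gn <- make_genome(sim_config(seed = 7, n_genes = 4, n_pseudogenes = 1))
#' gn$models
make_genome <- function(config) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "genome"), {
    n <- config$n_genes
    strands <- ifelse(stats::runif(n) < config$strand_balance, "-", "+")
    pieces <- character(0)
    cursor <- 0L
    models <- vector("list", n)
    for (i in seq_len(n)) {
      gap <- paste(sample(BASES, sample(700:1400, 1), replace = TRUE),
                   collapse = "")
      pieces <- c(pieces, gap)
      cursor <- cursor + nchar(gap)
      gene <- build_gene(config, i, strands[i])
      gstart <- cursor + 1L
      pieces <- c(pieces, gene$seq)
      cursor <- cursor + nchar(gene$seq)
      models[[i]] <- offset_gene(gene, gstart)
    }
    tail_gap <- paste(sample(BASES, 800, replace = TRUE), collapse = "")
    pieces <- c(pieces, tail_gap)
    genome <- c(chr1 = paste(pieces, collapse = ""))
    list(genome = genome, models = as_fg_genes(models))
  })
}

## Build one gene in local (1-based, plus-orientation-of-gene) coordinates,
## then orient.  Returns local exon/cds intervals relative to the gene
## sequence as placed on the contig.
build_gene <- function(config, index, strand) {
  is_pseudo <- index <= config$n_pseudogenes
  lr <- config$gene_length_range
  n_codons <- max(60L, as.integer(round(stats::runif(1, lr[1], lr[2]) / 3)))
  codons <- c("ATG",
              sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
              sample(STOP_CODONS, 1))
  fake_local <- NULL
  if (is_pseudo) {
    ## tandem TAG TAG at codons k, k+1; fake intron = codons (k-2)..(k+2):
    ## GTx ... TAGTAG ... xAG -> starts GT, ends AG, length 15 (codon-aligned)
    k <- sample(seq(20L, n_codons - 20L), 1)
    codons[k - 2L] <- "GTA"
    codons[k - 1L] <- sample(SENSE_CODONS, 1)
    codons[k] <- "TAG"
    codons[k + 1L] <- "TAG"
    codons[k + 2L] <- "AAG"
    fake_local <- c((k - 3L) * 3L + 1L, (k + 2L) * 3L)
  }
  tx <- paste(codons, collapse = "")
  L <- nchar(tx)
  ## Optionally insert one real intron at a codon boundary (never inside the
  ## fake-intron window of a pseudogene).
  intron_at <- NULL
  if (!is_pseudo && stats::runif(1) < config$intron_probability) {
    j <- sample(seq(10L, n_codons - 10L), 1) * 3L  # after base j
    ilen <- sample(60:120, 1)
    intron <- paste0("GT",
                     paste(sample(BASES, ilen - 4L, replace = TRUE),
                           collapse = ""), "AG")
    tx <- paste0(substr(tx, 1, j), intron, substr(tx, j + 1L, L))
    intron_at <- c(j + 1L, j + ilen)  # local genomic interval of intron
  }
  glen <- nchar(tx)
  if (is.null(intron_at)) {
    exons_local <- matrix(c(1L, glen), ncol = 2)
  } else {
    exons_local <- rbind(c(1L, intron_at[1] - 1L), c(intron_at[2] + 1L, glen))
  }
  if (!is.null(fake_local)) {
    ## annotation masks the fake window as an intron
    exons_local <- rbind(c(1L, fake_local[1] - 1L), c(fake_local[2] + 1L, glen))
  }
  if (strand == "-") {
    exons_local <- cbind(glen - exons_local[, 2] + 1L,
                         glen - exons_local[, 1] + 1L)
    exons_local <- exons_local[order(exons_local[, 1]), , drop = FALSE]
    if (!is.null(fake_local)) {
      fake_local <- c(glen - fake_local[2] + 1L, glen - fake_local[1] + 1L)
    }
    tx <- revcomp(tx)
  }
  list(seq = tx, strand = strand, exons_local = exons_local,
       fake_local = fake_local, is_pseudo = is_pseudo,
       gene_id = sprintf("gene%03d", index))
}

offset_gene <- function(gene, gstart) {
  ex <- gene$exons_local + gstart - 1L
  phases <- exon_phases(ex, gene$strand)
  cds <- cbind(ex, phase = phases)
  fake <- if (is.null(gene$fake_local)) NULL else gene$fake_local + gstart - 1L
  gene_model(gene$gene_id, "chr1", gene$strand, ex, cds,
             fake_intron = fake, is_pseudogene = gene$is_pseudo)
}

## GFF3 phases for CDS segments that coincide with exons (CDS covers the
## full transcript here).
exon_phases <- function(ex, strand) {
  lens <- ex[, 2] - ex[, 1] + 1L
  ord <- if (strand == "+") seq_len(nrow(ex)) else rev(seq_len(nrow(ex)))
  ph <- integer(nrow(ex))
  before <- 0L
  for (i in ord) {
    ph[i] <- (3L - before %% 3L) %% 3L
    before <- before + lens[i]
  }
  ph
}
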