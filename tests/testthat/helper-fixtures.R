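## Shared fixtures, built once per test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

## A moderately sized two-condition simulation reused across test files.
shared_sim <- function() {
  cached("shared_sim", {
    cfg <- sim_config(seed = 42, n_genes = 12, n_pseudogenes = 2,
                      n_edit_sites = 40, coverage_mean = 40,
                      n_genomic_snps = 6)
    gn <- make_genome(cfg)
    truth <- plant_truth(cfg, gn$genome, gn$models)
    sams <- list()
    pups <- list()
    for (cond in cfg$conditions) {
      for (r in 1:2) {
        k <- paste(cond, r, sep = ".")
        sams[[k]] <- simulate_reads(cfg, gn$genome, gn$models, truth, cond, r)
        pups[[k]] <- pileup_from_alignments(sams[[k]], gn$genome,
                                            condition = cond, replicate = r)
      }
    }
    dna <- simulate_dna_pileup(cfg, gn$genome, truth)
    cand <- call_candidates(pups[c("perithecia.1", "perithecia.2")],
                            gn$genome)
    sites <- apply_filters(cand, dna, filter_config())
    ann <- annotate_sites(sites[sites$subst == "A>G", , drop = FALSE],
                          gn$models, gn$genome)
    list(cfg = cfg, genome = gn$genome, models = gn$models, truth = truth,
         sams = sams, pileups = pups, dna = dna, candidates = cand,
         sites = sites, annotated = ann)
  })
}

## A clean (error-free, duplicate-free, SNP-free) simulation for exactness
## checks.
clean_sim <- function() {
  cached("clean_sim", {
    cfg <- sim_config(seed = 7, n_genes = 8, n_pseudogenes = 1,
                      n_edit_sites = 25, coverage_mean = 40,
                      error_rate = 0, duplicate_rate = 0, n_genomic_snps = 0,
                      conditions = "perithecia",
                      editing_condition = "perithecia")
    gn <- make_genome(cfg)
    truth <- plant_truth(cfg, gn$genome, gn$models)
    sams <- lapply(1:2, function(r)
      simulate_reads(cfg, gn$genome, gn$models, truth, "perithecia", r))
    pups <- lapply(1:2, function(r)
      pileup_from_alignments(sams[[r]], gn$genome, condition = "perithecia",
                             replicate = r))
    cand <- call_candidates(pups, gn$genome)
    list(cfg = cfg, genome = gn$genome, models = gn$models, truth = truth,
         sams = sams, pileups = pups, candidates = cand)
  })
}

## Build a single-gene genome from explicit codons, on either strand, with
## flanking sequence; returns genome + fg_genes.  Used for codon-level
## oracle tests.
toy_gene <- function(codons, strand = "+", flank = 600) {
  cds <- paste(codons, collapse = "")
  left <- strrep("C", flank)
  right <- strrep("C", flank)
  gseq <- if (strand == "+") cds else fungedit:::revcomp(cds)
  genome <- c(chr1 = paste0(left, gseq, right))
  ex <- matrix(c(flank + 1L, flank + nchar(cds)), ncol = 2)
  g <- gene_model("toy", "chr1", strand, ex, cbind(ex, 0L))
  list(genome = genome, models = fungedit:::as_fg_genes(list(g)), gene = g)
}

## Genomic position of codon `ci` (1-based), codon position `cp` for a
## toy_gene on either strand.
toy_pos <- function(tg, ci, cp) {
  idx <- (ci - 1L) * 3L + cp
  pm <- fungedit:::cds_positions(tg$gene)
  pm[idx]
}

## Random balanced dot-bracket generator for fuzz tests (independent of the
## package's folding code).
random_dotbracket <- function(n, p_open = 0.3, minloop = 0) {
  ch <- character(n)
  open <- integer(0)
  for (i in seq_len(n)) {
    r <- stats::runif(1)
    if (r < p_open && n - i > length(open)) {
      ch[i] <- "("
      open <- c(open, i)
    } else if (length(open) && r < 0.65) {
      ch[i] <- ")"
      open <- open[-length(open)]
    } else {
      ch[i] <- "."
    }
  }
  while (length(open)) {           # close what is left
    ch[open[length(open)]] <- "."
    open <- open[-length(open)]
  }
  paste(ch, collapse = "")
}
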