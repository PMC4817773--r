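#' Simulation configuration for the synthetic editing genome
#'
#' Builds the configuration object consumed by [make_genome()],
#' [plant_truth()], [simulate_reads()] and [simulate_dna_pileup()].  The
#' defaults describe the biological situation the generator emulates: a
#' compact fungal genome expressed in two developmental stages (vegetative
#' `"hyphae"` and sexual `"perithecia"`), with A-to-I editing confined to the
#' sexual stage, per-site editing levels spanning 3\%--100\%, two biological
#' replicates per stage, 150-bp paired-end reads from a dUTP-style
#' strand-specific library, PCR duplicates, uniform sequencing error, genomic
#' SNPs as confounders, and a handful of PUK1-like pseudogenes whose tandem
#' in-frame UAG stops are concealed by a spurious annotated intron.
#'
#' @param seed Integer RNG seed; every emitter is bit-reproducible given the
#'   seed.
#' @param n_genes Number of genes to place on the toy genome.
#' @param gene_length_range Length range (nt) for the coding part of each
#'   gene (rounded to whole codons).
#' @param intron_probability Probability that a gene carries one real intron.
#' @param strand_balance Fraction of genes placed on the minus strand.
#' @param conditions Character vector of condition labels.
#' @param editing_condition The condition in which planted editing is active
#'   (must be one of `conditions`); all other conditions receive no editing,
#'   mirroring stage-specific editing during sexual reproduction.
#' @param replicates_per_condition Biological replicates per condition.
#' @param coverage_mean Target read depth (reads per transcript base).
#' @param read_length Read length (nt).
#' @param fragment_length Fragment (insert) length (nt); must exceed
#'   `read_length`.
#' @param error_rate Per-base uniform substitution error probability.
#' @param duplicate_rate Fraction of fragments duplicated as exact PCR
#'   copies.
#' @param n_edit_sites Number of regular editing sites to plant (pseudogene
#'   stop-codon sites are planted in addition).
#' @param editing_level_range Range from which per-site editing levels are
#'   drawn uniformly; must lie within \[0, 1\].
#' @param edit_context Optional character vector of NAN triplets (DNA
#'   alphabet, e.g. `c("TAG", "TAA")`); when given, regular edit sites are
#'   planted only at adenosines whose immediate context matches one of these
#'   triplets.
#' @param n_genomic_snps Number of homozygous genomic SNPs to plant.
#' @param n_pseudogenes Number of PUK1-like pseudogenes (in-frame tandem TAG
#'   TAG concealed by a fake annotated intron).
#' @param pseudogene_edit_level Editing level shared by the tandem stop-codon
#'   sites of each pseudogene (they form one haplotype group).
#' @param n_specific_genes Number of genes expressed (essentially) only in
#'   the editing condition, to exercise stage-specificity calls.
#' @param phred Flat base quality written to simulated reads.
#'
#' @return A list of class `"fg_sim_config"`.
#' @seealso [make_genome()], [plant_truth()], [simulate_reads()]
#' @export
#' @examples
#' cfg <- sim_config(seed = 7, n_genes = 6, n_edit_sites = 20)
#' cfg$conditions
sim_config <- function(seed = 1L,
                       n_genes = 20L,
                       gene_length_range = c(900L, 2400L),
                       intron_probability = 0.7,
                       strand_balance = 0.5,
                       conditions = c("hyphae", "perithecia"),
                       editing_condition = "perithecia",
                       replicates_per_condition = 2L,
                       coverage_mean = 50,
                       read_length = 150L,
                       fragment_length = 300L,
                       error_rate = 0.001,
                       duplicate_rate = 0.1,
                       n_edit_sites = 100L,
                       editing_level_range = c(0.03, 1.0),
                       edit_context = NULL,
                       n_genomic_snps = 10L,
                       n_pseudogenes = 2L,
                       pseudogene_edit_level = 0.9,
                       n_specific_genes = 4L,
                       phred = 37L) {
  cfg <- list(
    seed = as.integer(seed),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    intron_probability = intron_probability,
    strand_balance = strand_balance,
    conditions = as.character(conditions),
    editing_condition = editing_condition,
    replicates_per_condition = as.integer(replicates_per_condition),
    coverage_mean = coverage_mean,
    read_length = as.integer(read_length),
    fragment_length = as.integer(fragment_length),
    error_rate = error_rate,
    duplicate_rate = duplicate_rate,
    n_edit_sites = as.integer(n_edit_sites),
    editing_level_range = editing_level_range,
    edit_context = edit_context,
    n_genomic_snps = as.integer(n_genomic_snps),
    n_pseudogenes = as.integer(n_pseudogenes),
    pseudogene_edit_level = pseudogene_edit_level,
    n_specific_genes = as.integer(n_specific_genes),
    phred = as.integer(phred)
  )
  class(cfg) <- "fg_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "fg_sim_config"))
  if (length(cfg$editing_level_range) != 2 ||
      cfg$editing_level_range[1] < 0 || cfg$editing_level_range[2] > 1 ||
      diff(cfg$editing_level_range) < 0) {
    stopf("editing_level_range must be an increasing range within [0, 1]")
  }
  counts <- c(cfg$n_genes, cfg$replicates_per_condition, cfg$n_edit_sites,
              cfg$n_genomic_snps, cfg$n_pseudogenes, cfg$n_specific_genes)
  if (any(counts < 0)) stopf("all counts must be >= 0")
  if (cfg$read_length >= cfg$fragment_length) {
    stopf("read_length (%d) must be smaller than fragment_length (%d)",
          cfg$read_length, cfg$fragment_length)
  }
  if (!cfg$editing_condition %in% cfg$conditions) {
    stopf("editing_condition '%s' is not among conditions", cfg$editing_condition)
  }
  if (cfg$n_pseudogenes > cfg$n_genes) {
    stopf("n_pseudogenes cannot exceed n_genes")
  }
  if (cfg$intron_probability < 0 || cfg$intron_probability > 1 ||
      cfg$strand_balance < 0 || cfg$strand_balance > 1 ||
      cfg$error_rate < 0 || cfg$error_rate > 1 ||
      cfg$duplicate_rate < 0 || cfg$duplicate_rate > 1) {
    stopf("probabilities must lie in [0, 1]")
  }
  invisible(cfg)
}

#' @export
print.fg_sim_config <- function(x, ...) {
  cat("Synthetic editing-genome configuration\n")
  cat(sprintf("  %d genes (%d PUK1-like pseudogenes), seed %d\n",
              x$n_genes, x$n_pseudogenes, x$seed))
  cat(sprintf("  conditions: %s (editing in '%s'), %d replicates each\n",
              paste(x$conditions, collapse = ", "), x$editing_condition,
              x$replicates_per_condition))
  cat(sprintf("  %d edit sites, levels U[%.2f, %.2f]; %d SNPs\n",
              x$n_edit_sites, x$editing_level_range[1],
              x$editing_level_range[2], x$n_genomic_snps))
  cat(sprintf("  %gx coverage, %d-bp paired reads, %d-bp fragments, error %g, dup %g\n",
              x$coverage_mean, x$read_length, x$fragment_length,
              x$error_rate, x$duplicate_rate))
  invisible(x)
}
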