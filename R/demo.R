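#' Run the full pipeline end-to-end on synthetic data
#'
#' Generates a toy genome with planted editing, simulates strand-specific
#' RNA-seq for every condition and replicate plus a DNA pileup, calls and
#' filters editing sites in the editing condition, and runs every
#' characterization stage: substitution spectrum and equal-error-rate FDR,
#' level summary, feature/consequence annotation, pseudogene detection,
#' context preference, structure context, and stage-specific expression.
#' All outputs are written under `outdir` together with a JSON manifest
#' recording the configuration, seeds and output checksums.
#'
#' @param seed Master seed.
#' @param outdir Output directory (created if missing).
#' @param config Optional [sim_config()]; defaults to `sim_config(seed)`.
#' @param skip Character vector of stages to skip (any of `"structure"`,
#'   `"context"`, `"expression"`).
#' @param fold_backend Folding backend for the structure stage.
#' @return (Invisibly) a list with all in-memory results plus
#'   `manifest_path`.
#' @export
run_demo <- function(seed = 1L, outdir = tempfile("fungedit_demo"),
                     config = NULL, skip = character(0),
                     fold_backend = default_fold_backend()) {
  t0 <- Sys.time()
  if (is.null(config)) config <- sim_config(seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pth <- function(...) file.path(outdir, ...)

  ## simulate
  gn <- make_genome(config)
  truth <- plant_truth(config, gn$genome, gn$models)
  write_genome_fasta(gn$genome, pth("genome.fa"))
  write_gff3(gn$models, pth("annotation.gff3"))
  write_truth(truth, pth("truth.tsv"))
  dna <- simulate_dna_pileup(config, gn$genome, truth)

  libs <- list()
  for (cond in config$conditions) {
    for (r in seq_len(config$replicates_per_condition)) {
      sam <- simulate_reads(config, gn$genome, gn$models, truth, cond, r)
      write_sam(sam, pth(sprintf("%s_rep%d.sam", cond, r)))
      libs[[paste(cond, r, sep = ".")]] <- sam
    }
  }

  ## call + filter in the editing condition
  cond <- config$editing_condition
  pups <- lapply(seq_len(config$replicates_per_condition), function(r)
    pileup_from_alignments(libs[[paste(cond, r, sep = ".")]], gn$genome,
                           condition = cond, replicate = r))
  mapped <- sum(vapply(pups, function(p) attr(p, "mapped_unduplicated"),
                       numeric(1)))
  cand <- call_candidates(pups, gn$genome)
  sites <- apply_filters(cand, dna, filter_config())

  ## statistics
  spec_tab <- spectrum(sites, mapped)
  ag <- sites[sites$subst == "A>G", , drop = FALSE]
  fdr <- estimate_fdr(max(nrow(ag), 1L), nrow(sites) - nrow(ag))
  lv <- if (nrow(ag)) level_summary(ag) else NULL
  utils::write.table(spec_tab, pth("spectrum.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ## annotation + pseudogenes
  ann <- annotate_sites(ag, gn$models, gn$genome)
  write_sites(ann, pth("sites.tsv"), vcf_path = pth("sites.vcf"))
  pg <- detect_puk1_like(ann, gn$models, gn$genome)
  write_pseudogene_calls(pg, pth("pseudogenes.tsv"),
                         gff3_path = pth("corrected_models.gff3"))

  ## context preference
  ctx <- str_ctx <- NULL
  cdna <- transcript_sequences(gn$genome, gn$models)
  tx_sites <- map_sites_to_tx(ann, gn$models)
  tx_sites <- tx_sites[!is.na(tx_sites$tx_pos), , drop = FALSE]
  if (!"context" %in% skip && nrow(tx_sites)) {
    n_ctl <- min(5000L, sum(vapply(cdna, function(s)
      sum(strsplit(s, "")[[1]] == "A"), integer(1))))
    ctl <- sample_control(cdna, n_ctl, seed = derive_seed(seed, "control"))
    ctx <- list(
      enrichment = position_enrichment(tx_sites, ctl, cdna,
                                       preference_config(control_n = n_ctl)),
      triplets = triplet_percentages(tx_sites, cdna))
    utils::write.table(ctx$enrichment, pth("enrichment.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(ctx$triplets, pth("triplets.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  ## structure context
  if (!"structure" %in% skip && nrow(tx_sites)) {
    str_ctx <- structure_context(tx_sites, cdna, backend = fold_backend)
    utils::write.table(as.data.frame(str_ctx), pth("structure.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## expression
  expr <- NULL
  if (!"expression" %in% skip) {
    recs <- do.call(rbind, lapply(names(libs), function(k) {
      parts <- strsplit(k, ".", fixed = TRUE)[[1]]
      quantify(libs[[k]], gn$models, condition = parts[1],
               replicate = as.integer(parts[2]))
    }))
    cats <- stage_categories(recs, focal = cond)
    expr <- list(records = recs, categories = cats,
                 crosstab = crosstab_editing_expression(ann, cats))
    utils::write.table(recs, pth("expression.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr$crosstab, pth("crosstab.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    tool = "fungedit",
    version = as.character(utils::packageVersion("fungedit")),
    seed = seed,
    config = config[setdiff(names(config), "code")],
    stages_skipped = skip,
    mapped_unduplicated = mapped,
    outputs = manifest_outputs(outdir),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(config = config, genome = gn$genome, models = gn$models,
                 truth = truth, dna = dna, pileups = pups,
                 candidates = cand, sites = sites, spectrum = spec_tab,
                 fdr = fdr, levels = lv, annotated = ann, pseudogenes = pg,
                 context = ctx, structure = str_ctx, expression = expr,
                 outdir = outdir, manifest_path = pth("manifest.json")))
}

manifest_outputs <- function(outdir) {
  fs <- sort(setdiff(list.files(outdir), "manifest.json"))
  lapply(stats::setNames(fs, fs), function(f)
    list(path = f, md5 = unname(tools::md5sum(file.path(outdir, f)))))
}
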