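test_that("at level 1.0 with no error every covering read carries G", {
  cfg <- sim_config(seed = 21, n_genes = 3, n_pseudogenes = 0,
                    n_edit_sites = 5, editing_level_range = c(1, 1),
                    error_rate = 0, duplicate_rate = 0, n_genomic_snps = 0,
                    coverage_mean = 50, conditions = "perithecia",
                    editing_condition = "perithecia")
  gn <- make_genome(cfg)
  tt <- plant_truth(cfg, gn$genome, gn$models)
  sam <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
  pu <- pileup_from_alignments(sam, gn$genome, condition = "perithecia",
                               dedup = FALSE)
  for (i in seq_len(nrow(tt$edits))) {
    row <- pu[pu$pos == tt$edits$pos[i] & pu$strand == tt$edits$strand[i], ]
    cnt <- unlist(row[, c("A", "C", "G", "T")])
    alt_g <- if (tt$edits$strand[i] == "+") "G" else "C"  # genomic base
    expect_gt(sum(cnt), 10)
    expect_identical(unname(sum(cnt) - cnt[alt_g]), 0L)
  }
})

test_that("per-read editing follows the planted binomial level", {
  ## one gene, one site at level 0.2; repeat small simulations and compare
  ## the mean alt fraction with its binomial standard error
  fracs <- vapply(1:12, function(r) {
    cfg <- sim_config(seed = 100 + r, n_genes = 2, n_pseudogenes = 0,
                      n_edit_sites = 1, editing_level_range = c(0.2, 0.2),
                      error_rate = 0, duplicate_rate = 0, n_genomic_snps = 0,
                      coverage_mean = 60, conditions = "perithecia",
                      editing_condition = "perithecia")
    gn <- make_genome(cfg)
    tt <- plant_truth(cfg, gn$genome, gn$models)
    sam <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
    pu <- pileup_from_alignments(sam, gn$genome, dedup = FALSE)
    row <- pu[pu$pos == tt$edits$pos[1] & pu$strand == tt$edits$strand[1], ]
    cnt <- unlist(row[, c("A", "C", "G", "T")])
    alt_g <- if (tt$edits$strand[1] == "+") "G" else "C"
    cnt[alt_g] / sum(cnt)
  }, numeric(1))
  ## mean depth per site is ~60 reads x 12 runs; 3 SE band around 0.2
  se <- sqrt(0.2 * 0.8 / (12 * 55))
  expect_lt(abs(mean(fracs) - 0.2), 3 * se + 0.01)
})

test_that("genomic SNPs appear near-fixed in RNA reads", {
  sim <- shared_sim()
  pu <- sim$pileups[["perithecia.1"]]
  hits <- 0
  for (i in seq_len(nrow(sim$truth$snps))) {
    rows <- pu[pu$pos == sim$truth$snps$pos[i], , drop = FALSE]
    if (!nrow(rows)) next  # intergenic SNP, no RNA coverage
    cnt <- colSums(rows[, c("A", "C", "G", "T"), drop = FALSE])
    if (sum(cnt) < 10) next
    frac <- cnt[sim$truth$snps$alt[i]] / sum(cnt)
    expect_gt(frac, 0.95)
    hits <- hits + 1
  }
  expect_gt(hits, 0)
})

test_that("error-free reads match the reference outside planted events", {
  sim <- clean_sim()
  pu <- sim$pileups[[1]]
  cnt <- as.matrix(pu[, c("A", "C", "G", "T")])
  ref_n <- cnt[cbind(seq_len(nrow(pu)), match(pu$ref, c("A", "C", "G", "T")))]
  mism <- which(rowSums(cnt) != ref_n)
  bad <- setdiff(pu$pos[mism], sim$truth$edits$pos)
  expect_length(bad, 0)
})

test_that("simulated alignments are reproducible and SAM round-trips", {
  cfg <- sim_config(seed = 33, n_genes = 3, n_edit_sites = 5,
                    n_pseudogenes = 0, coverage_mean = 15)
  gn <- make_genome(cfg)
  tt <- plant_truth(cfg, gn$genome, gn$models)
  s1 <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
  s2 <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
  expect_identical(s1, s2)
  d <- withr::local_tempdir()
  p <- file.path(d, "r.sam")
  write_sam(s1, p)
  back <- read_sam(p)
  expect_equal(as.data.frame(back), as.data.frame(s1))
  expect_error(simulate_reads(cfg, gn$genome, gn$models, tt, "mycelium", 1),
               "unknown condition")
})

test_that("haplotype groups are co-edited on the same fragments", {
  cfg <- sim_config(seed = 51, n_genes = 4, n_pseudogenes = 1,
                    n_edit_sites = 0, error_rate = 0, duplicate_rate = 0,
                    n_genomic_snps = 0, coverage_mean = 80,
                    pseudogene_edit_level = 0.6,
                    conditions = "perithecia",
                    editing_condition = "perithecia")
  gn <- make_genome(cfg)
  tt <- plant_truth(cfg, gn$genome, gn$models)
  pair <- tt$edits[grepl("\\.stop$", tt$edits$hap_group), ]
  expect_identical(nrow(pair), 2L)
  sam <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
  co <- haplotype_cooccurrence(sam, list(contig = pair$contig[1],
                                         pos = pair$pos,
                                         strand = pair$strand[1]))
  expect_gt(co$n, 50)
  se <- sqrt(0.6 * 0.4 / co$n)
  ## with error 0, editing is all-or-none across the pair
  expect_lt(abs(co$both - 0.6), 3 * se)
  expect_equal(co$both, co$either)
})
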