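## Minimal pileup row constructor (transcript-orientation tests go through
## real genomes elsewhere; here the arithmetic contracts).
pu_row <- function(pos, strand, A = 0, C = 0, G = 0, T = 0, rep = 1,
                   ref = "A", contig = "chr1") {
  data.frame(contig = contig, pos = pos, ref = ref, strand = strand,
             A = A, C = C, G = G, T = T, condition = "perithecia",
             replicate = rep, stringsAsFactors = FALSE)
}

test_that("candidate calling reports pooled counts and editing level", {
  genome <- c(chr1 = strrep("A", 100))
  pu <- pu_row(10, "+", A = 85, G = 15)
  cand <- call_candidates(pu, genome)
  expect_identical(nrow(cand), 1L)
  expect_identical(cand$subst, "A>G")
  expect_equal(cand$level, 0.15)
  ## no alternate reads, no candidate
  cand0 <- call_candidates(pu_row(10, "+", A = 100), genome)
  expect_identical(nrow(cand0), 0L)
  ## minus-orientation site: genomic T>C appears as transcript A>G
  genome2 <- c(chr1 = strrep("T", 100))
  cand2 <- call_candidates(pu_row(10, "-", T = 80, C = 20, ref = "T"),
                           genome2)
  expect_identical(cand2$subst, "A>G")
  expect_equal(cand2$level, 0.2)
  expect_error(call_candidates(pu_row(10, "+", A = 5, contig = "chrZ"),
                               genome), "absent from genome")
})

test_that("error-free simulation yields exactly the planted candidates", {
  sim <- clean_sim()
  cand <- sim$candidates
  expect_identical(nrow(as.data.frame(cand)), nrow(sim$truth$edits))
  expect_true(all(cand$subst == "A>G"))
  expect_setequal(cand$pos, sim$truth$edits$pos)
})

test_that("filters remove SNPs and sub-threshold sites, keeping an audit", {
  genome <- c(chr1 = strrep("A", 100))
  pu1 <- rbind(pu_row(10, "+", A = 85, G = 15),
               pu_row(20, "+", A = 98, G = 2),    # level 0.02
               pu_row(30, "+", A = 2, G = 98))    # genomic SNP
  pu2 <- pu1; pu2$replicate <- 2
  cand <- call_candidates(list(pu1, pu2), genome)
  dna <- data.frame(contig = "chr1", pos = c(10, 20, 30), ref = "A",
                    A = c(50, 50, 0), C = 0, G = c(0, 0, 50), T = 0,
                    stringsAsFactors = FALSE)
  out <- apply_filters(cand, dna, filter_config())
  expect_identical(out$pos, 10L)
  audit <- attr(out, "audit")
  expect_setequal(audit$pos, c(20L, 30L))
  expect_match(audit$failed_filters[audit$pos == 20], "min_level")
  expect_match(audit$failed_filters[audit$pos == 30], "dna_variant")
  expect_error(apply_filters(cand, NULL, filter_config()),
               "no DNA pileup")
})

test_that("the filter cascade equals the intersection of its predicates", {
  ## order independence: pure predicates, so the surviving set must equal
  ## the sites passing each enabled filter checked independently
  sim <- shared_sim()
  cand <- sim$candidates
  cfg <- filter_config()
  out <- apply_filters(cand, sim$dna, cfg)
  pass_cov <- cand$depth >= cfg$min_coverage
  pass_alt <- cand$alt_n >= cfg$min_alt_reads
  pass_lvl <- cand$level >= cfg$min_level
  pass_rep <- cand$alt_rep1 >= 1 & cand$alt_rep2 >= 1
  purity <- ifelse(cand$alt_n + cand$opp_alt_n > 0,
                   cand$alt_n / (cand$alt_n + cand$opp_alt_n), 1)
  pass_pur <- purity >= cfg$strand_purity
  dk <- paste(sim$dna$contig, sim$dna$pos)
  mi <- match(paste(cand$contig, cand$pos), dk)
  gal <- ifelse(cand$strand == "-", fungedit:::COMP[cand$alt], cand$alt)
  daf <- mapply(function(i, b) {
    if (is.na(i)) return(0)
    tot <- sum(sim$dna[i, c("A", "C", "G", "T")])
    if (tot == 0) return(0)
    sim$dna[[b]][i] / tot
  }, mi, gal)
  pass_dna <- daf < cfg$dna_alt_threshold
  keep <- pass_cov & pass_alt & pass_lvl & pass_rep & pass_pur & pass_dna
  expect_setequal(paste(out$pos, out$strand),
                  paste(cand$pos[keep], cand$strand[keep]))
})

test_that("precision is perfect on clean data and levels track truth", {
  sim <- clean_sim()
  pu1 <- sim$pileups[[1]]; pu2 <- sim$pileups[[2]]
  dna <- simulate_dna_pileup(sim$cfg, sim$genome, sim$truth)
  out <- apply_filters(sim$candidates, dna, filter_config())
  key_t <- paste(sim$truth$edits$contig, sim$truth$edits$pos)
  key_o <- paste(out$contig, out$pos)
  expect_true(all(key_o %in% key_t))    # precision 1.0
  m <- merge(as.data.frame(out), sim$truth$edits, by = c("contig", "pos"))
  n <- m$ref_n + m$alt_n
  se <- sqrt(pmax(m$level.y * (1 - m$level.y), 1e-6) / n)
  expect_gt(mean(abs(m$level.x - m$level.y) <= 3 * se + 1e-9), 0.95)
})

test_that("a condition without editing shows no A-to-G enrichment", {
  sim <- shared_sim()
  cand <- call_candidates(sim$pileups[c("hyphae.1", "hyphae.2")],
                          sim$genome)
  tab <- table(factor(cand$subst,
                      levels = fungedit:::SUBST_TYPES))
  expect_gt(nrow(as.data.frame(cand)), 20)  # sequencing errors only
  ## A>G must not dominate: chi-square uniformity not rejected wildly;
  ## specifically A>G is within the spread of the other 11 types
  ag <- tab["A>G"]
  others <- tab[names(tab) != "A>G"]
  expect_lte(ag, max(others) + 3 * sqrt(max(others) + 1))
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 1e-4)
})

test_that("co-occurrence fractions behave for shared and independent sites", {
  ## all co-covering reads G at both -> (1, 1)
  g <- paste(rep("G", 30), collapse = "")
  sam <- data.frame(qname = c("f1", "f1"), flag = c(83L, 163L),
                    rname = "chr1", pos = c(1L, 1L), mapq = 60L,
                    cigar = "30M", rnext = "=", pnext = c(1L, 1L),
                    tlen = 0L, seq = g, qual = strrep("F", 30),
                    stringsAsFactors = FALSE)
  class(sam) <- c("fg_sam", "data.frame")
  co <- haplotype_cooccurrence(sam, list(contig = "chr1", pos = c(5L, 9L),
                                         strand = "+"))
  expect_equal(co$both, 1)
  expect_equal(co$either, 1)
  expect_warning(
    haplotype_cooccurrence(sam, list(contig = "chr1", pos = c(500L, 900L),
                                     strand = "+")),
    "no fragments")

  ## independent sites at level 0.5: both-edited ~ 0.25
  cfg <- sim_config(seed = 77, n_genes = 2, n_pseudogenes = 0,
                    n_edit_sites = 0, error_rate = 0, duplicate_rate = 0,
                    n_genomic_snps = 0, coverage_mean = 120,
                    conditions = "perithecia",
                    editing_condition = "perithecia")
  gn <- make_genome(cfg)
  tt <- plant_truth(cfg, gn$genome, gn$models)
  g1 <- gn$models[[1]]
  pm <- fungedit:::tx_positions(g1)
  s <- fungedit:::transcript_seq(gn$genome, g1)
  a_idx <- which(strsplit(s, "")[[1]] == "A")
  a_idx <- a_idx[a_idx > 400 & a_idx < 500]
  pick <- a_idx[c(1, length(a_idx))]   # two well-separated A's, same reads
  expect_gt(diff(pick), 5)
  tt$edits <- data.frame(contig = g1$contig, pos = pm[pick],
                         strand = g1$strand, gene_id = g1$gene_id,
                         tx_pos = pick, level = 0.5,
                         condition = "perithecia",
                         hap_group = NA_character_,
                         stringsAsFactors = FALSE)
  sam2 <- simulate_reads(cfg, gn$genome, gn$models, tt, "perithecia", 1)
  co2 <- haplotype_cooccurrence(sam2, list(contig = g1$contig,
                                           pos = sort(tt$edits$pos),
                                           strand = g1$strand))
  expect_gt(co2$n, 40)
  se <- sqrt(0.25 * 0.75 / co2$n)
  expect_lt(abs(co2$both - 0.25), 4 * se)
  expect_lt(abs(co2$either - 0.75), 4 * se)
})
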