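## Codon-level oracle cases on hand-built single-gene genomes.
codons_base <- c("ATG", "AAA", "TCT", "CGA", "GGG", "TAA")

site_at <- function(tg, ci, cp) {
  list(contig = "chr1", pos = toy_pos(tg, ci, cp), strand = tg$gene$strand,
       alt = "G")
}

test_that("stop-codon edits classify as stop-loss or stop-retained", {
  ## UAG -> UGG (Trp): translation continues, stop-loss
  tg <- toy_gene(c("ATG", "AAA", "TAG", "GGG", "TAA"))
  cc <- codon_consequence(site_at(tg, 3, 2), tg$gene, tg$genome)
  expect_identical(cc$category, "stop_loss")
  expect_identical(cc$codon_from, "UAG")
  expect_identical(cc$codon_to, "UGG")
  expect_identical(cc$aa_to, "W")
  ## UAA -> UGA and UAA -> UAG: still stops
  tg2 <- toy_gene(c("ATG", "AAA", "TAA", "GGG", "TAA"))
  cc2 <- codon_consequence(site_at(tg2, 3, 2), tg2$gene, tg2$genome)
  expect_identical(cc2$category, "stop_retained")
  expect_identical(cc2$codon_to, "UGA")
  cc3 <- codon_consequence(site_at(tg2, 3, 3), tg2$gene, tg2$genome)
  expect_identical(cc3$category, "stop_retained")
  expect_identical(cc3$codon_to, "UAG")
})

test_that("missense and synonymous edits are recognized with class changes", {
  tg <- toy_gene(codons_base)
  ## AAA -> GAA: Lys (basic) -> Glu (acidic), cross-class missense
  cc <- codon_consequence(site_at(tg, 2, 1), tg$gene, tg$genome)
  expect_identical(cc$category, "missense")
  expect_identical(c(cc$aa_from, cc$aa_to), c("K", "E"))
  expect_true(cc$cross_class)
  ## CGA -> CGG: Arg -> Arg synonymous
  cc2 <- codon_consequence(site_at(tg, 4, 3), tg$gene, tg$genome)
  expect_identical(cc2$category, "synonymous")
  ## AGU -> GGU: Ser (polar) -> Gly (nonpolar), cross-class
  tg3 <- toy_gene(c("ATG", "AGT", "TCT", "TAA"))
  cc3 <- codon_consequence(site_at(tg3, 2, 1), tg3$gene, tg3$genome)
  expect_identical(c(cc3$aa_from, cc3$aa_to), c("S", "G"))
  expect_true(cc3$cross_class)
  expect_error(codon_consequence(list(contig = "chr1", pos = 1L,
                                      strand = "+", alt = "G"),
                                 tg$gene, tg$genome), "not inside the CDS")
})

test_that("consequences are strand-correct (metamorphic mirror)", {
  plus <- toy_gene(codons_base, strand = "+")
  minus <- toy_gene(codons_base, strand = "-")
  for (ci in 2:5) for (cp in 1:3) {
    codon <- codons_base[ci]
    if (substr(codon, cp, cp) != "A") next
    cc_p <- codon_consequence(site_at(plus, ci, cp), plus$gene, plus$genome)
    cc_m <- codon_consequence(site_at(minus, ci, cp), minus$gene,
                              minus$genome)
    expect_identical(cc_p$category, cc_m$category)
    expect_identical(cc_p$codon_to, cc_m$codon_to)
    expect_identical(cc_p$aa_to, cc_m$aa_to)
  }
})

test_that("no A-to-G edit of a sense codon can create a stop codon", {
  ## independent exhaustive oracle over the 64 codons
  code <- Biostrings::GENETIC_CODE
  found_nonsense <- FALSE
  for (codon in names(code)) {
    if (code[codon] == "*") next
    for (p in 1:3) {
      if (substr(codon, p, p) != "A") next
      to <- codon; substr(to, p, p) <- "G"
      if (code[to] == "*") found_nonsense <- TRUE
    }
  }
  expect_false(found_nonsense)
  ## and the package's enumeration agrees
  enum <- ag_edit_outcomes()
  expect_identical(sum(enum$category == "nonsense"), 0L)
  expect_setequal(unique(enum$category),
                  c("synonymous", "missense", "stop_loss", "stop_retained"))
  ## stop-codon outcomes: UAG>UGG and UGA>UGG lose the stop, UAA>UGA and
  ## UAA>UAG retain it
  st <- enum[enum$category %in% c("stop_loss", "stop_retained"), ]
  expect_setequal(paste(st$codon_from, st$codon_to),
                  c("UAG UGG", "UGA UGG", "UAA UGA", "UAA UAG"))
  expect_identical(st$category[st$codon_from == "UAA"],
                   rep("stop_retained", 2))
})

test_that("feature assignment partitions sites with CDS precedence", {
  sim <- shared_sim()
  ann <- sim$annotated
  expect_true(all(ann$feature %in% c("CDS", "intronic", "utr5", "utr3",
                                     "intergenic")))
  expect_equal(sum(table(ann$feature)), nrow(as.data.frame(ann)))
  expect_false(any(ann$consequence %in% "nonsense"))

  ## positional contract around one gene
  g <- sim$models[[which(vapply(sim$models, function(x) x$strand == "+",
                                logical(1)))[1]]]
  bd <- fungedit:::cds_bounds_tx(g)
  probe <- data.frame(contig = g$contig,
                      pos = c(bd["five"] + 5L,      # inside CDS
                              bd["five"] - 200L,    # 200 bp upstream
                              bd["three"] + 600L),  # beyond the 3' proxy
                      strand = "+", stringsAsFactors = FALSE)
  pf <- assign_feature(probe, sim$models)
  expect_identical(pf$feature[1], "CDS")
  expect_identical(pf$feature[2], "utr5")
  ## 600 bp downstream may fall into a neighbouring gene's territory, but
  ## never into this gene's UTR proxy
  expect_false(pf$feature[3] %in% "utr3" && pf$gene_id[3] %in% g$gene_id)
})

test_that("per-gene recoding histogram uses missense sites only", {
  ann <- data.frame(gene_id = c(rep("g1", 5), rep("g2", 2), "g3"),
                    consequence = c(rep("missense", 3), "synonymous",
                                    "synonymous", "missense", "missense",
                                    "missense"),
                    stringsAsFactors = FALSE)
  pr <- per_gene_recoding(ann)
  expect_identical(unname(pr$per_gene[c("g1", "g2", "g3")]), c(3L, 2L, 1L))
  expect_identical(unname(pr$histogram),
                   c(1L, 1L, 1L, 0L))
  expect_identical(unname(per_gene_recoding(ann[0, ])$histogram),
                   rep(0L, 4))
})

test_that("amino-acid change matrix counts and validates reachability", {
  ann <- data.frame(consequence = rep("missense", 4),
                    aa_from = c("K", "K", "K", "S"),
                    aa_to = c("E", "E", "E", "G"),
                    stringsAsFactors = FALSE)
  m <- aa_change_matrix(ann)
  expect_identical(m$matrix["K", "E"], 3L)
  expect_identical(m$matrix["S", "G"], 1L)
  expect_equal(m$cross_class_fraction, 1)
  bad <- data.frame(consequence = "missense", aa_from = "K", aa_to = "P",
                    stringsAsFactors = FALSE)
  expect_error(aa_change_matrix(bad), "not reachable")
})

test_that("median level by consequence is computable on annotated sites", {
  sim <- shared_sim()
  med <- level_by_consequence(sim$annotated)
  expect_true(all(med >= 0 & med <= 1))
})
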