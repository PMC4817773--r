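test_that("FPKM and CPM follow their definitions on simulated libraries", {
  sim <- clean_sim()
  recs <- quantify(sim$sams[[1]], sim$models, condition = "perithecia")
  ## recompute from first principles
  exkb <- vapply(sim$models, function(g)
    sum(g$exons[, 2] - g$exons[, 1] + 1L) / 1000, numeric(1))
  total <- sum(recs$fragments)
  expect_equal(recs$fpkm,
               unname(recs$fragments / exkb[recs$gene_id] / (total / 1e6)))
  expect_equal(recs$cpm, unname(recs$fragments / (total / 1e6)))
  expect_true(all(recs$fragments > 0))
})

test_that("FPKM is invariant to duplicating every fragment when dedup is on", {
  sim <- clean_sim()
  sam <- sim$sams[[1]]
  dup <- sam
  dup$qname <- paste0(dup$qname, ":pcr")
  doubled <- rbind(sam, dup)
  attr(doubled, "seqinfo") <- attr(sam, "seqinfo")
  class(doubled) <- c("fg_sam", "data.frame")
  r1 <- quantify(sam, sim$models)
  r2 <- quantify(doubled, sim$models)
  expect_equal(r1$fragments, r2$fragments)
  expect_equal(r1$fpkm, r2$fpkm)
  r0 <- quantify(sam, sim$models, dedup = FALSE)
  r3 <- quantify(doubled, sim$models, dedup = FALSE)
  expect_equal(r3$fragments, 2L * r0$fragments)
  expect_equal(r3$fpkm, r0$fpkm)   # per-million normalization cancels
})

test_that("stage-specificity rules classify constructed records", {
  mk <- function(gene, cond, fpkm, cpm)
    data.frame(gene_id = gene, condition = cond, replicate = 1,
               fragments = 0L, fpkm = fpkm, cpm = cpm,
               stringsAsFactors = FALSE)
  recs <- rbind(
    mk("gA", "perithecia", 50, 100), mk("gA", "hyphae", 0.3, 0.5),
    mk("gA", "conidia", 0.1, 0.2),
    mk("gB", "perithecia", 40, 80), mk("gB", "hyphae", 15, 30),
    mk("gB", "conidia", 10, 20),
    mk("gC", "perithecia", 20, 40), mk("gC", "hyphae", 20, 40),
    mk("gC", "conidia", 20, 40))
  cats <- stage_categories(recs, focal = "perithecia")
  expect_identical(cats$category[cats$gene_id == "gA"], "specific")
  expect_identical(cats$category[cats$gene_id == "gB"], "up")
  expect_identical(cats$category[cats$gene_id == "gC"], "other")
  expect_error(stage_categories(recs[recs$condition == "perithecia", ],
                                focal = "perithecia"), "two conditions")
  expect_error(stage_categories(recs, focal = "sclerotia"), "missing")
})

test_that("planted stage-specific genes are recovered from the simulation", {
  sim <- shared_sim()
  recs <- do.call(rbind, lapply(names(sim$sams), function(k) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    quantify(sim$sams[[k]], sim$models, condition = parts[1],
             replicate = as.integer(parts[2]))
  }))
  cats <- stage_categories(recs, focal = "perithecia")
  expr <- sim$truth$expression
  silent <- unique(expr$gene_id[expr$weight == 0])
  expect_gt(length(silent), 0)
  got <- cats$category[match(silent, cats$gene_id)]
  expect_true(all(got == "specific"))
  ## genes with boosted planted weight rank above unboosted genes in their
  ## perithecia-to-hyphae expression ratio (compositional FPKM damps the
  ## absolute fold change at toy library sizes, so compare ranks)
  wp <- expr[expr$condition == "perithecia", ]
  wh <- expr[expr$condition == "hyphae", ]
  boost <- wp$gene_id[wp$weight > 2 * wh$weight[match(wp$gene_id, wh$gene_id)] &
                        !wp$gene_id %in% silent]
  plain <- setdiff(wp$gene_id, c(boost, silent))
  agg <- stats::aggregate(recs$fpkm,
                          by = list(gene_id = recs$gene_id,
                                    condition = recs$condition), mean)
  ratio <- function(g) {
    p <- agg$x[agg$gene_id == g & agg$condition == "perithecia"]
    h <- agg$x[agg$gene_id == g & agg$condition == "hyphae"]
    (p + 0.1) / (h + 0.1)
  }
  expect_gt(min(vapply(boost, ratio, numeric(1))),
            stats::median(vapply(plain, ratio, numeric(1))))
})

test_that("the editing-level expression crosstab counts genes per bin", {
  sites <- data.frame(gene_id = c("g1", "g1", "g2", "g3", "g4"),
                      level = c(0.1, 0.8, 0.2, 0.5, 0.9),
                      stringsAsFactors = FALSE)
  cats <- data.frame(gene_id = paste0("g", 1:4),
                     category = c("specific", "other", "up", "specific"),
                     fpkm_focal = c(10, 20, 30, 40),
                     stringsAsFactors = FALSE)
  ct <- crosstab_editing_expression(sites, cats)
  expect_identical(ct$n_genes, c(2L, 1L, 2L))
  ## high bin holds g1 (specific) and g4 (specific)
  expect_equal(ct$frac_specific_or_up[ct$bin == "high"], 1)
  expect_equal(ct$frac_specific_or_up[ct$bin == "mid"], 1)  # g3 is "up"
  empty <- crosstab_editing_expression(sites[0, ], cats)
  expect_identical(nrow(empty), 0L)
})

test_that("a planted level-category association shows up monotonically", {
  ## construct sites where high-level edits sit in specific genes
  set.seed(4)
  genes <- paste0("g", 1:60)
  cats <- data.frame(gene_id = genes,
                     category = rep(c("specific", "other", "other"), 20),
                     fpkm_focal = 10, stringsAsFactors = FALSE)
  lv <- runif(300)
  spec_genes <- genes[cats$category == "specific"]
  gid <- ifelse(runif(300) < lv, sample(spec_genes, 300, replace = TRUE),
                sample(genes, 300, replace = TRUE))
  ct <- crosstab_editing_expression(
    data.frame(gene_id = gid, level = lv, stringsAsFactors = FALSE), cats)
  fr <- ct$frac_specific_or_up
  expect_true(fr[ct$bin == "high"] > fr[ct$bin == "low"])
})
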