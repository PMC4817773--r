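## Strand-specific paired-end RNA-seq simulator with planted editing.

## Apply homozygous SNP alternates to the reference, giving the genome the
## reads are actually drawn from.
apply_snps <- function(genome, snps) {
  if (!nrow(snps)) return(genome)
  for (i in seq_len(nrow(snps))) {
    ctg <- snps$contig[i]
    substr(genome[[ctg]], snps$pos[i], snps$pos[i]) <- snps$alt[i]
  }
  genome
}

## Vectorized single-base replacement in equal-length strings.
set_base_at <- function(x, at, base) {
  paste0(substr(x, 1L, at - 1L), base, substr(x, at + 1L, nchar(x)))
}

#' Simulate strand-specific paired-end RNA-seq alignments
#'
#' Draws fragments from the true transcripts of every gene (for PUK1-like
#' pseudogenes the transcript retains the spurious annotated intron, which
#' is in reality coding), applies planted editing, uniform sequencing error
#' and PCR duplication, and returns pre-computed SAM alignment records — no
#' aligner involved.  At every truth site active in `condition`, each
#' fragment carries G (transcript orientation) with probability equal to the
#' true editing level; all sites of a haplotype group are co-edited on the
#' same fragment.  The library follows the dUTP convention with read 2 on
#' the sense strand.  Duplicates are exact coordinate-and-sequence copies of
#' their parent fragment.
#'
#' @param config A [sim_config()] object.
#' @param genome,models Output of [make_genome()].
#' @param truth Output of [plant_truth()].
#' @param condition Condition label (must be in `config$conditions`).
#' @param replicate Replicate index.
#' @return A data frame of SAM records of class `"fg_sam"` (columns qname,
#'   flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual), with the
#'   contig lengths in `attr(, "seqinfo")`.
#' @export
simulate_reads <- function(config, genome, models, truth, condition,
                           replicate = 1L) {
  validate_sim_config(config)
  if (!condition %in% config$conditions) {
    stopf("unknown condition '%s'", condition)
  }
  sgenome <- apply_snps(genome, truth$snps)
  with_seed(derive_seed(config$seed, paste("reads", condition, replicate)), {
    per_gene <- lapply(models, function(g) {
      simulate_gene_reads(config, sgenome, g, truth, condition, replicate)
    })
    sam <- do.call(rbind, per_gene)
    if (is.null(sam)) sam <- empty_sam()
    rownames(sam) <- NULL
    attr(sam, "seqinfo") <- nchar(genome)
    class(sam) <- c("fg_sam", "data.frame")
    sam
  })
}

empty_sam <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), stringsAsFactors = FALSE)
}

simulate_gene_reads <- function(config, sgenome, g, truth, condition,
                                replicate) {
  R <- config$read_length
  FL <- config$fragment_length
  txseq <- transcript_seq(sgenome, g, retained = TRUE)
  L <- nchar(txseq)
  if (L < FL) return(NULL)
  m <- tx_positions(g, retained = TRUE)     # tx index -> genomic pos
  expr <- truth$expression
  w <- 1
  if (NROW(expr)) {
    hit <- expr$gene_id == g$gene_id & expr$condition == condition
    if (any(hit)) w <- expr$weight[hit][1]
  }
  n_frag <- as.integer(round(config$coverage_mean * w * (L - FL + 1) / (2 * R)))
  if (n_frag <= 0) return(NULL)
  s <- sample.int(L - FL + 1L, n_frag, replace = TRUE)

  ## read intervals in transcript coordinates (read2 = sense 5' mate)
  r2a <- s; r2b <- s + R - 1L
  r1a <- s + FL - R; r1b <- s + FL - 1L
  r2seq <- substring(txseq, r2a, r2b)
  r1seq <- substring(txseq, r1a, r1b)

  ## planted editing, co-edited per haplotype group
  ed <- truth$edits[truth$edits$gene_id == g$gene_id &
                      truth$edits$condition == condition, , drop = FALSE]
  if (nrow(ed)) {
    grp <- ifelse(is.na(ed$hap_group),
                  paste0("solo", seq_len(nrow(ed))), ed$hap_group)
    for (gk in unique(grp)) {
      rows <- which(grp == gk)
      edited <- stats::runif(n_frag) < ed$level[rows[1]]
      for (r in rows) {
        t <- ed$tx_pos[r]
        i2 <- which(edited & r2a <= t & t <= r2b)
        if (length(i2)) r2seq[i2] <- set_base_at(r2seq[i2], t - r2a[i2] + 1L, "G")
        i1 <- which(edited & r1a <= t & t <= r1b)
        if (length(i1)) r1seq[i1] <- set_base_at(r1seq[i1], t - r1a[i1] + 1L, "G")
      }
    }
  }

  ## uniform sequencing error over all bases of both mates
  if (config$error_rate > 0) {
    nerr <- stats::rbinom(1L, 2L * n_frag * R, config$error_rate)
    if (nerr > 0) {
      which_read <- sample.int(2L * n_frag, nerr, replace = TRUE)
      off <- sample.int(R, nerr, replace = TRUE)
      pick <- sample.int(3L, nerr, replace = TRUE)  # one of the 3 other bases
      for (k in seq_len(nerr)) {
        if (which_read[k] <= n_frag) {
          i <- which_read[k]
          cur <- substr(r2seq[i], off[k], off[k])
          r2seq[i] <- set_base_at(r2seq[i], off[k], setdiff(BASES, cur)[pick[k]])
        } else {
          i <- which_read[k] - n_frag
          cur <- substr(r1seq[i], off[k], off[k])
          r1seq[i] <- set_base_at(r1seq[i], off[k], setdiff(BASES, cur)[pick[k]])
        }
      }
    }
  }

  ## transcript -> forward-genomic representation
  plus <- g$strand == "+"
  if (plus) {
    g2pos <- m[r2a]; g2end <- m[r2b]
    g1pos <- m[r1a]; g1end <- m[r1b]
    seq2 <- r2seq; seq1 <- r1seq
    flag2 <- 163L; flag1 <- 83L
  } else {
    g2pos <- m[r2b]; g2end <- m[r2a]
    g1pos <- m[r1b]; g1end <- m[r1a]
    seq2 <- revcomp(r2seq); seq1 <- revcomp(r1seq)
    flag2 <- 147L; flag1 <- 99L
  }
  cig2 <- cigar_for(m, r2a, r2b, plus, R)
  cig1 <- cigar_for(m, r1a, r1b, plus, R)
  tlen_left <- pmin(g1pos, g2pos)
  tlen_right <- pmax(g1end, g2end)
  tl <- tlen_right - tlen_left + 1L
  tl2 <- ifelse(g2pos <= g1pos, tl, -tl)
  tl1 <- -tl2

  qual <- paste(rep(rawToChar(as.raw(config$phred + 33L)), R), collapse = "")
  qn <- sprintf("%s:%s:r%d:f%06d", g$gene_id, condition, replicate,
                seq_len(n_frag))
  sam <- data.frame(
    qname = c(qn, qn),
    flag = c(rep(flag1, n_frag), rep(flag2, n_frag)),
    rname = g$contig,
    pos = c(g1pos, g2pos),
    mapq = 60L,
    cigar = c(cig1, cig2),
    rnext = "=",
    pnext = c(g2pos, g1pos),
    tlen = c(tl1, tl2),
    seq = c(seq1, seq2),
    qual = qual,
    stringsAsFactors = FALSE)

  ## PCR duplicates: exact copies of whole fragments
  if (config$duplicate_rate > 0) {
    dup <- which(stats::runif(n_frag) < config$duplicate_rate)
    if (length(dup)) {
      rows <- c(dup, n_frag + dup)
      dd <- sam[rows, , drop = FALSE]
      dd$qname <- paste0(dd$qname, ":dup")
      sam <- rbind(sam, dd)
    }
  }
  sam
}

## CIGAR strings for reads covering transcript interval [a, b]; single-exon
## spans get "<R>M", junction reads get M/N blocks from the position map.
cigar_for <- function(m, a, b, plus, R) {
  gspan <- abs(m[b] - m[a])
  cig <- rep(sprintf("%dM", R), length(a))
  jn <- which(gspan != R - 1L)
  for (k in jn) {
    pv <- m[a[k]:b[k]]
    if (!plus) pv <- rev(pv)
    br <- which(diff(pv) != 1L)
    starts <- c(1L, br + 1L)
    ends <- c(br, length(pv))
    parts <- character(0)
    for (j in seq_along(starts)) {
      parts <- c(parts, sprintf("%dM", ends[j] - starts[j] + 1L))
      if (j < length(starts)) {
        parts <- c(parts, sprintf("%dN", pv[starts[j + 1L]] - pv[ends[j]] - 1L))
      }
    }
    cig[k] <- paste(parts, collapse = "")
  }
  cig
}

#' Simulate a genomic-DNA resequencing pileup
#'
#' Emulates whole-genome DNA resequencing of the same strain: homozygous
#' alternate alleles at planted SNP positions, reference elsewhere, with
#' uniform sequencing error at `config$error_rate` and Poisson depth at
#' `config$coverage_mean`.  Truth edit sites leave no signal in DNA.
#'
#' @inheritParams simulate_reads
#' @return A data frame of class `"fg_dna_pileup"` with columns contig, pos,
#'   ref and base counts A, C, G, T.
#' @export
simulate_dna_pileup <- function(config, genome, truth) {
  validate_sim_config(config)
  with_seed(derive_seed(config$seed, "dna"), {
    out <- do.call(rbind, lapply(names(genome), function(ctg) {
      len <- nchar(genome[[ctg]])
      refs <- strsplit(genome[[ctg]], "")[[1]]
      calls <- refs
      sn <- truth$snps[truth$snps$contig == ctg, , drop = FALSE]
      if (nrow(sn)) calls[sn$pos] <- sn$alt
      depth <- stats::rpois(len, config$coverage_mean)
      counts <- matrix(0L, nrow = len, ncol = 4, dimnames = list(NULL, BASES))
      nerr <- stats::rbinom(len, depth, config$error_rate)
      good <- depth - nerr
      bi <- match(calls, BASES)
      for (j in 1:4) {
        sel <- bi == j
        counts[sel, j] <- counts[sel, j] + good[sel]
      }
      ei <- which(nerr > 0)
      for (i in ei) {
        eb <- sample(setdiff(1:4, bi[i]), nerr[i], replace = TRUE)
        tb <- tabulate(eb, 4)
        counts[i, ] <- counts[i, ] + tb
      }
      data.frame(contig = ctg, pos = seq_len(len), ref = refs, counts,
                 stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    class(out) <- c("fg_dna_pileup", "data.frame")
    out
  })
}
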