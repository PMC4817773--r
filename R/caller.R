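#' Filter configuration for RNA-DNA variant calling
#'
#' Thresholds of the stringent filter cascade applied to candidate
#' RNA-DNA variant sites.  All filters are pure per-site predicates, so
#' their order of application is irrelevant.
#'
#' @param min_coverage Minimum pooled depth (ref + alt + other bases).
#' @param min_alt_reads Minimum pooled alternate-read count.
#' @param min_level Minimum pooled editing level (alt / (ref + alt));
#'   default 0.03, the floor of observed editing levels.
#' @param require_alt_in_all_replicates Demand at least one alternate read
#'   in every biological replicate.
#' @param exclude_dna_variants Remove sites that are variant in the genomic
#'   DNA pileup (SNPs); requires a DNA pileup in [apply_filters()].
#' @param dna_alt_threshold DNA alternate-allele fraction at or above which
#'   a position counts as a genomic variant.
#' @param strand_purity Minimum fraction of alternate-base evidence that
#'   must come from the transcribed strand.
#' @param binom_test Optionally require a one-sided binomial test of the
#'   alternate count against `binom_error_rate` at `binom_alpha`
#'   (off by default; the cascade is a set of hard filters, not tests).
#' @param binom_error_rate,binom_alpha See `binom_test`.
#' @return A list of class `"fg_filter_config"`.
#' @export
filter_config <- function(min_coverage = 10L, min_alt_reads = 3L,
                          min_level = 0.03,
                          require_alt_in_all_replicates = TRUE,
                          exclude_dna_variants = TRUE,
                          dna_alt_threshold = 0.05,
                          strand_purity = 0.9,
                          binom_test = FALSE, binom_error_rate = 0.001,
                          binom_alpha = 0.01) {
  stopifnot(min_coverage >= 0, min_alt_reads >= 0,
            min_level >= 0, min_level <= 1,
            strand_purity >= 0, strand_purity <= 1)
  structure(list(min_coverage = as.integer(min_coverage),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_level = min_level,
                 require_alt_in_all_replicates = require_alt_in_all_replicates,
                 exclude_dna_variants = exclude_dna_variants,
                 dna_alt_threshold = dna_alt_threshold,
                 strand_purity = strand_purity,
                 binom_test = binom_test,
                 binom_error_rate = binom_error_rate,
                 binom_alpha = binom_alpha),
            class = "fg_filter_config")
}

COMP <- c(A = "T", C = "G", G = "C", T = "A")

#' Call candidate RNA-DNA variant sites from replicate pileups
#'
#' Pools base counts across the replicates of one condition and emits one
#' candidate per (position, orientation) where at least one read supports a
#' base other than the reference.  Counts and alleles are reported in
#' transcript orientation (for minus-orientation sites the genomic
#' complement), so A-to-I editing always appears as an A-to-G substitution.
#' At multi-allelic positions only the most-supported alternate is kept
#' (others recorded in `attr(, "dropped_alleles")`).
#'
#' @param pileups A `fg_pileup` data frame or list of them (the replicates
#'   of one condition).
#' @param genome Named character vector of contig sequences.
#' @return A data frame of class `"fg_sites"`: contig, pos, strand, ref,
#'   alt (transcript orientation), subst (e.g. `"A>G"`), depth (pooled, all
#'   bases), ref_n, alt_n (pooled), level, opp_alt_n (alternate evidence on
#'   the opposite orientation, genomic), and per-replicate columns
#'   `ref_rep<i>` / `alt_rep<i>`.
#' @export
call_candidates <- function(pileups, genome) {
  if (is.data.frame(pileups)) pileups <- list(pileups)
  pu <- do.call(rbind, lapply(seq_along(pileups), function(i) {
    p <- pileups[[i]]
    p$rep_idx <- i
    p
  }))
  bad <- !pu$contig %in% names(genome)
  if (any(bad)) stopf("pileup references contig '%s' absent from genome",
                      pu$contig[which(bad)[1]])
  n_rep <- length(pileups)
  key <- paste(pu$contig, pu$pos, pu$strand, sep = ":")
  agg <- function(col) {
    v <- rowsum(pu[[col]], key)
    v[, 1]
  }
  A <- agg("A"); C <- agg("C"); G <- agg("G"); T <- agg("T")
  ks <- rownames(rowsum(pu$A, key))
  parts <- strsplit(ks, ":", fixed = TRUE)
  contig <- vapply(parts, `[[`, character(1), 1)
  pos <- as.integer(vapply(parts, `[[`, character(1), 2))
  strand <- vapply(parts, `[[`, character(1), 3)
  gref <- substring(genome[contig], pos, pos)

  cnt <- cbind(A = A, C = C, G = G, T = T)
  ## transcript-orientation counts: complement the base identity on minus
  tx_cnt <- cnt
  minus <- strand == "-"
  tx_cnt[minus, ] <- cnt[minus, c("T", "G", "C", "A")]
  tx_ref <- ifelse(minus, COMP[gref], gref)

  ref_i <- match(tx_ref, BASES)
  depth <- rowSums(tx_cnt)
  alt_cnt <- tx_cnt
  alt_cnt[cbind(seq_len(nrow(alt_cnt)), ref_i)] <- -1L
  alt_i <- max.col(alt_cnt, ties.method = "first")
  alt_n <- tx_cnt[cbind(seq_len(nrow(tx_cnt)), alt_i)]
  ref_n <- tx_cnt[cbind(seq_len(nrow(tx_cnt)), ref_i)]
  has_alt <- alt_n > 0L

  ## dropped secondary alternates at multi-allelic positions
  other_n <- depth - ref_n - alt_n
  dropped <- data.frame(contig = contig[has_alt & other_n > 0],
                        pos = pos[has_alt & other_n > 0],
                        strand = strand[has_alt & other_n > 0],
                        n = other_n[has_alt & other_n > 0],
                        stringsAsFactors = FALSE)

  sites <- data.frame(
    contig = contig[has_alt], pos = pos[has_alt], strand = strand[has_alt],
    ref = tx_ref[has_alt], alt = BASES[alt_i[has_alt]],
    depth = depth[has_alt], ref_n = ref_n[has_alt], alt_n = alt_n[has_alt],
    stringsAsFactors = FALSE)
  sites$subst <- if (nrow(sites)) paste0(sites$ref, ">", sites$alt)
                 else character(0)
  sites$level <- sites$alt_n / pmax(sites$ref_n + sites$alt_n, 1L)

  ## alternate evidence on the opposite orientation (same genomic base)
  gal <- ifelse(sites$strand == "-", COMP[sites$alt], sites$alt)
  opp_strand <- ifelse(sites$strand == "-", "+", "-")
  okey <- paste(sites$contig, sites$pos, opp_strand, sep = ":")
  oi <- match(okey, ks)
  opp <- rep(0L, nrow(sites))
  hit <- !is.na(oi)
  opp[hit] <- cnt[cbind(oi[hit], match(gal[hit], BASES))]
  sites$opp_alt_n <- opp

  ## per-replicate ref/alt counts in transcript orientation
  skey <- paste(sites$contig, sites$pos, sites$strand, sep = ":")
  for (i in seq_len(n_rep)) {
    pr <- pu[pu$rep_idx == i, , drop = FALSE]
    pk <- paste(pr$contig, pr$pos, pr$strand, sep = ":")
    mi <- match(skey, pk)
    rc <- ac <- integer(nrow(sites))
    hit <- !is.na(mi)
    rcnt <- as.matrix(pr[, BASES])
    txr <- ifelse(sites$strand == "-", COMP[sites$ref], sites$ref)
    txa <- ifelse(sites$strand == "-", COMP[sites$alt], sites$alt)
    rc[hit] <- rcnt[cbind(mi[hit], match(txr[hit], BASES))]
    ac[hit] <- rcnt[cbind(mi[hit], match(txa[hit], BASES))]
    sites[[paste0("ref_rep", i)]] <- rc
    sites[[paste0("alt_rep", i)]] <- ac
  }
  sites <- sites[order(sites$contig, sites$pos, sites$strand), , drop = FALSE]
  rownames(sites) <- NULL
  attr(sites, "n_replicates") <- n_rep
  attr(sites, "dropped_alleles") <- dropped
  class(sites) <- c("fg_sites", "data.frame")
  sites
}

#' Apply the stringent filter cascade to candidate sites
#'
#' Evaluates every enabled filter as an independent predicate on each
#' candidate and keeps sites passing all of them.  Removed sites, each with
#' the full list of failed filters, are kept in `attr(, "audit")`.
#'
#' @param candidates Output of [call_candidates()].
#' @param dna_pileup Optional `fg_dna_pileup`; required when
#'   `exclude_dna_variants` is enabled.
#' @param config A [filter_config()].
#' @return The surviving sites (class `"fg_sites"`), with the audit table
#'   of removals in `attr(, "audit")` and the configuration in
#'   `attr(, "filter_config")`.
#' @export
apply_filters <- function(candidates, dna_pileup = NULL,
                          config = filter_config()) {
  stopifnot(inherits(config, "fg_filter_config"))
  x <- candidates
  n <- nrow(x)
  fails <- vector("list", n)
  add_fail <- function(which, label) {
    for (i in which) fails[[i]] <<- c(fails[[i]], label)
    fails
  }
  fails <- add_fail(which(x$depth < config$min_coverage), "min_coverage")
  fails <- add_fail(which(x$alt_n < config$min_alt_reads), "min_alt_reads")
  fails <- add_fail(which(x$level < config$min_level), "min_level")
  if (config$require_alt_in_all_replicates) {
    reps <- attr(candidates, "n_replicates") %||% 1L
    alt_cols <- paste0("alt_rep", seq_len(reps))
    alt_cols <- alt_cols[alt_cols %in% names(x)]
    if (length(alt_cols)) {
      am <- as.matrix(x[, alt_cols, drop = FALSE])
      fails <- add_fail(which(apply(am, 1, min) < 1L), "replicate_support")
    }
  }
  tot_alt <- x$alt_n + x$opp_alt_n
  purity <- ifelse(tot_alt > 0, x$alt_n / tot_alt, 1)
  fails <- add_fail(which(purity < config$strand_purity), "strand_purity")
  if (config$exclude_dna_variants) {
    if (is.null(dna_pileup)) {
      stopf("exclude_dna_variants is enabled but no DNA pileup was given")
    }
    dk <- paste(dna_pileup$contig, dna_pileup$pos, sep = ":")
    mi <- match(paste(x$contig, x$pos, sep = ":"), dk)
    gal <- ifelse(x$strand == "-", COMP[x$alt], x$alt)
    hit <- !is.na(mi)
    dna_frac <- rep(0, n)
    if (any(hit)) {
      dm <- as.matrix(dna_pileup[mi[hit], BASES])
      dtot <- rowSums(dm)
      daf <- dm[cbind(seq_len(nrow(dm)), match(gal[hit], BASES))] /
        pmax(dtot, 1L)
      dna_frac[hit] <- daf
    }
    fails <- add_fail(which(dna_frac >= config$dna_alt_threshold),
                      "dna_variant")
  }
  if (config$binom_test) {
    p <- vapply(seq_len(n), function(i) {
      stats::binom.test(x$alt_n[i], x$ref_n[i] + x$alt_n[i],
                        p = config$binom_error_rate,
                        alternative = "greater")$p.value
    }, numeric(1))
    fails <- add_fail(which(p > config$binom_alpha), "binom_test")
  }
  failed <- lengths(fails) > 0
  audit <- x[failed, c("contig", "pos", "strand", "subst", "level"),
             drop = FALSE]
  audit$failed_filters <- vapply(fails[failed], paste, character(1),
                                 collapse = ",")
  rownames(audit) <- NULL
  out <- x[!failed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_replicates") <- attr(candidates, "n_replicates")
  attr(out, "audit") <- audit
  attr(out, "filter_config") <- config
  class(out) <- c("fg_sites", "data.frame")
  out
}

#' Co-occurrence of editing at two sites on shared molecules
#'
#' Measures, over deduplicated fragments whose reads cover both positions,
#' the fraction edited at both sites and the fraction edited at at least
#' one, to test whether tandem sites sit on a shared haplotype (the
#' PUK1-type pattern, where 90\% of covering transcripts carry both G's).
#'
#' @param alignments A `fg_sam` data frame or SAM path.
#' @param site_pair A list or data frame giving `contig`, `pos` (length-2
#'   integer vector) and `strand` of the transcribed strand.
#' @param strand_protocol See [pileup_from_alignments()].
#' @return A list with `both`, `either` (fractions), and `n` co-covering
#'   fragments.  With `n = 0` the fractions are `NA` (undefined).
#' @export
haplotype_cooccurrence <- function(alignments, site_pair,
                                   strand_protocol = "dUTP_read2_sense") {
  if (is.character(alignments)) alignments <- read_sam(alignments)
  sam <- alignments
  p1 <- min(site_pair$pos); p2 <- max(site_pair$pos)
  edited_base <- if (site_pair$strand == "+") "G" else "C"  # genomic G/C
  sam <- sam[sam$rname == site_pair$contig &
               sam$pos <= p1 & sam$pos + 10000L >= p2, , drop = FALSE]
  b1 <- read_base_at(sam, p1)
  b2 <- read_base_at(sam, p2)
  cov <- !is.na(b1) & !is.na(b2)
  if (!any(cov)) {
    warning("no fragments co-cover the site pair; fractions undefined")
    return(list(both = NA_real_, either = NA_real_, n = 0L))
  }
  ## one vote per fragment; duplicate fragments collapsed by coordinates
  key <- paste(sam$rname, pmin(sam$pos, sam$pnext),
               pmax(sam$pos, sam$pnext), sep = ":")[cov]
  e1 <- (b1 == edited_base)[cov]
  e2 <- (b2 == edited_base)[cov]
  keep <- !duplicated(key)
  e1 <- e1[keep]; e2 <- e2[keep]
  list(both = mean(e1 & e2), either = mean(e1 | e2), n = sum(keep))
}

## Base carried by each alignment record at genomic position gpos (NA when
## not covered by an M block).
read_base_at <- function(sam, gpos) {
  out <- rep(NA_character_, nrow(sam))
  cand <- which(sam$pos <= gpos)
  for (i in cand) {
    ops <- cigar_ops(sam$cigar[i])
    p <- sam$pos[i]; off <- 0L
    for (j in seq_len(nrow(ops))) {
      if (ops[j, 2] == 1L) {
        if (gpos >= p && gpos <= p + ops[j, 1] - 1L) {
          out[i] <- substr(sam$seq[i], off + gpos - p + 1L, off + gpos - p + 1L)
          break
        }
        off <- off + ops[j, 1]
        p <- p + ops[j, 1]
      } else {
        p <- p + ops[j, 1]
      }
    }
  }
  out
}

#' @export
print.fg_sites <- function(x, ...) {
  cat(sprintf("<fg_sites> %d variant site(s)", nrow(x)))
  if (nrow(x)) {
    tab <- sort(table(x$subst), decreasing = TRUE)
    cat(": ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
        sep = "")
  }
  cat("\n")
  if (!is.null(attr(x, "audit")) && nrow(attr(x, "audit"))) {
    cat(sprintf("  (%d removed by filters; see attr(, \"audit\"))\n",
                nrow(attr(x, "audit"))))
  }
  invisible(x)
}
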