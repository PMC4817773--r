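#' Annotation configuration
#'
#' @param utr_proxy_length Length (nt) of the regions upstream of the start
#'   codon and downstream of the stop codon used as 5'/3'-UTR proxies
#'   (default 500, for genomes where true UTRs are mostly unannotated).
#' @param code Named character vector genetic code (codon -> amino acid);
#'   defaults to the standard code, [Biostrings::GENETIC_CODE].
#' @return A list of class `"fg_annotation_config"`.
#' @export
annotation_config <- function(utr_proxy_length = 500L,
                              code = Biostrings::GENETIC_CODE) {
  stopifnot(utr_proxy_length > 0)
  structure(list(utr_proxy_length = as.integer(utr_proxy_length),
                 code = code),
            class = "fg_annotation_config")
}

#' Four-class amino-acid physicochemical scheme
#'
#' Maps the 20 amino acids to \{nonpolar, polar, acidic, basic\}; a missense
#' edit is "cross-class" when the two residues fall in different classes
#' (e.g. K (basic) to E (acidic), S (polar) to G (nonpolar)).  The scheme is
#' plain data and can be swapped.
#'
#' @format Named character vector, one entry per amino acid.
#' @export
AA_CLASSES <- c(
  G = "nonpolar", A = "nonpolar", V = "nonpolar", L = "nonpolar",
  I = "nonpolar", P = "nonpolar", F = "nonpolar", M = "nonpolar",
  W = "nonpolar",
  S = "polar", T = "polar", C = "polar", Y = "polar", N = "polar",
  Q = "polar",
  D = "acidic", E = "acidic",
  K = "basic", R = "basic", H = "basic")

FEATURE_LEVELS <- c("CDS", "intronic", "utr5", "utr3", "intergenic")

## Feature interval table used by assign_feature (one row per interval,
## with precedence rank and the CDS length for transcript tie-breaking).
feature_table <- function(models, config) {
  u <- config$utr_proxy_length
  do.call(rbind, lapply(models, function(g) {
    cdslen <- sum(g$cds[, 2] - g$cds[, 1] + 1L)
    rows <- data.frame(contig = g$contig, strand = g$strand,
                       start = g$cds[, 1], end = g$cds[, 2],
                       feature = "CDS", prio = 1L,
                       gene_id = g$gene_id, cds_len = cdslen,
                       stringsAsFactors = FALSE)
    intr <- intron_intervals(g)
    if (nrow(intr)) {
      rows <- rbind(rows, data.frame(contig = g$contig, strand = g$strand,
                                     start = intr[, 1], end = intr[, 2],
                                     feature = "intronic", prio = 2L,
                                     gene_id = g$gene_id, cds_len = cdslen,
                                     stringsAsFactors = FALSE))
    }
    bd <- cds_bounds_tx(g)
    if (g$strand == "+") {
      u5 <- c(bd["five"] - u, bd["five"] - 1L)
      u3 <- c(bd["three"] + 1L, bd["three"] + u)
    } else {
      u5 <- c(bd["five"] + 1L, bd["five"] + u)
      u3 <- c(bd["three"] - u, bd["three"] - 1L)
    }
    rbind(rows,
          data.frame(contig = g$contig, strand = g$strand,
                     start = max(1L, u5[1]), end = u5[2], feature = "utr5",
                     prio = 3L, gene_id = g$gene_id, cds_len = cdslen,
                     stringsAsFactors = FALSE),
          data.frame(contig = g$contig, strand = g$strand,
                     start = max(1L, u3[1]), end = u3[2], feature = "utr3",
                     prio = 4L, gene_id = g$gene_id, cds_len = cdslen,
                     stringsAsFactors = FALSE))
  }))
}

#' Assign each site to a genomic feature
#'
#' Assigns exactly one feature category per site among CDS, intronic, 5'-UTR
#' proxy, 3'-UTR proxy and intergenic, considering gene models on the site's
#' transcribed strand.  Where categories of different genes overlap,
#' precedence is CDS > intron > UTR proxy > intergenic; overlapping
#' transcripts resolve to the gene with the longest CDS.
#'
#' @param sites A `fg_sites` data frame (needs contig, pos, strand).
#' @param models A `fg_genes` object.
#' @param config An [annotation_config()].
#' @return `sites` with added columns `feature` and `gene_id`.
#' @export
assign_feature <- function(sites, models, config = annotation_config()) {
  ft <- feature_table(models, config)
  n <- nrow(sites)
  feature <- rep("intergenic", n)
  gene <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- which(ft$contig == sites$contig[i] &
                   ft$strand == sites$strand[i] &
                   ft$start <= sites$pos[i] & ft$end >= sites$pos[i])
    if (!length(hit)) next
    hit <- hit[order(ft$prio[hit], -ft$cds_len[hit])]
    feature[i] <- ft$feature[hit[1]]
    gene[i] <- ft$gene_id[hit[1]]
  }
  sites$feature <- feature
  sites$gene_id <- gene
  sites
}

#' Codon-level consequence of an A-to-G edit
#'
#' Locates the site in the phase-correct reading frame of the gene's CDS,
#' substitutes G at the edited codon position (transcript orientation) and
#' classifies the outcome: `synonymous`, `missense`, `stop_loss` (a stop
#' codon becomes a sense codon, e.g. UAG to UGG tryptophan),
#' `stop_retained` (UAA to UGA or UAG), or `nonsense` — which is provably
#' unreachable for A-to-G edits of sense codons (see [ag_edit_outcomes()]).
#'
#' @param site One-row data frame or list with contig, pos, strand (and alt,
#'   default `"G"`).
#' @param model The `fg_gene` whose CDS contains the site.
#' @param genome Named character vector of contig sequences.
#' @param config An [annotation_config()].
#' @return A list of class `"fg_consequence"`: category, codon_from,
#'   codon_to (RNA alphabet), aa_from, aa_to, codon_position (1-3),
#'   cross_class (NA for non-missense).
#' @export
codon_consequence <- function(site, model, genome,
                              config = annotation_config()) {
  pos_map <- cds_positions(model)
  i <- match(site$pos, pos_map)
  if (is.na(i)) stopf("site %s:%d is not inside the CDS of %s",
                      site$contig, site$pos, model$gene_id)
  s <- cds_seq(genome, model)
  if (nchar(s) %% 3L != 0L) stopf("broken CDS frame for %s", model$gene_id)
  ci <- (i - 1L) %/% 3L
  cp <- (i - 1L) %% 3L + 1L
  codon_from <- substr(s, ci * 3L + 1L, ci * 3L + 3L)
  if (substr(codon_from, cp, cp) != "A") {
    stopf("edited base of %s:%d (codon %s, position %d) is not A on the transcribed strand",
          site$contig, site$pos, codon_from, cp)
  }
  alt <- site$alt %||% "G"
  codon_to <- codon_from
  substr(codon_to, cp, cp) <- alt
  code <- config$code
  aa_from <- unname(code[codon_from])
  aa_to <- unname(code[codon_to])
  category <- if (aa_from == "*") {
    if (aa_to == "*") "stop_retained" else "stop_loss"
  } else if (aa_to == "*") {
    "nonsense"
  } else if (aa_from == aa_to) {
    "synonymous"
  } else "missense"
  cross <- if (category == "missense") {
    AA_CLASSES[aa_from] != AA_CLASSES[aa_to]
  } else NA
  structure(list(category = category,
                 codon_from = dna_to_rna(codon_from),
                 codon_to = dna_to_rna(codon_to),
                 aa_from = aa_from, aa_to = aa_to,
                 codon_position = cp, cross_class = unname(cross)),
            class = "fg_consequence")
}

#' Annotate sites with features and codon consequences
#'
#' Runs [assign_feature()] on all sites and [codon_consequence()] on those
#' in CDS, producing the fully annotated site table used by the downstream
#' summaries.
#'
#' @inheritParams assign_feature
#' @param genome Named character vector of contig sequences.
#' @return `sites` with columns feature, gene_id, consequence, codon_from,
#'   codon_to, aa_from, aa_to, cross_class.
#' @export
annotate_sites <- function(sites, models, genome,
                           config = annotation_config()) {
  sites <- assign_feature(sites, models, config)
  n <- nrow(sites)
  cons <- rep(NA_character_, n)
  cfrom <- cto <- afrom <- ato <- rep(NA_character_, n)
  cross <- rep(NA, n)
  idx <- which(sites$feature == "CDS")
  for (i in idx) {
    m <- models[[sites$gene_id[i]]]
    cc <- codon_consequence(sites[i, ], m, genome, config)
    cons[i] <- cc$category
    cfrom[i] <- cc$codon_from; cto[i] <- cc$codon_to
    afrom[i] <- cc$aa_from; ato[i] <- cc$aa_to
    cross[i] <- cc$cross_class
  }
  sites$consequence <- cons
  sites$codon_from <- cfrom; sites$codon_to <- cto
  sites$aa_from <- afrom; sites$aa_to <- ato
  sites$cross_class <- cross
  sites
}

#' Per-gene recoding counts and histogram
#'
#' Counts missense (recoding) edits per gene and bins genes by recoding
#' burden into \{1, 2, 3--9, >= 10\}.
#'
#' @param sites Annotated sites ([annotate_sites()]).
#' @return A list with `per_gene` (named counts) and `histogram` (named
#'   integer vector over the four bins).
#' @export
per_gene_recoding <- function(sites) {
  mis <- sites[!is.na(sites$consequence) & sites$consequence == "missense", ,
               drop = FALSE]
  if (!nrow(mis)) {
    return(list(per_gene = integer(0),
                histogram = c(`1` = 0L, `2` = 0L, `3-9` = 0L, `>=10` = 0L)))
  }
  per_gene <- table(mis$gene_id)
  bins <- cut(as.integer(per_gene), breaks = c(0, 1, 2, 9, Inf),
              labels = c("1", "2", "3-9", ">=10"))
  list(per_gene = stats::setNames(as.integer(per_gene), names(per_gene)),
       histogram = stats::setNames(as.integer(table(bins)), levels(bins)))
}

#' Amino-acid change matrix of missense edits
#'
#' Tallies missense edits into a 20x20 from-to amino-acid matrix and reports
#' the fraction changing physicochemical class under [AA_CLASSES].  Inputs
#' containing a substitution not reachable by a single A-to-G codon edit are
#' rejected.
#'
#' @param sites Annotated sites; only rows with consequence `"missense"` are
#'   used.
#' @param scheme Amino-acid class scheme (default [AA_CLASSES]).
#' @return A list with `matrix` (20x20 counts), `cross_class_fraction`, and
#'   `n`.
#' @export
aa_change_matrix <- function(sites, scheme = AA_CLASSES) {
  mis <- sites[!is.na(sites$consequence) & sites$consequence == "missense", ,
               drop = FALSE]
  aa <- sort(names(scheme))
  mat <- matrix(0L, 20, 20, dimnames = list(from = aa, to = aa))
  if (nrow(mis)) {
    reach <- ag_edit_outcomes()
    reach_pairs <- unique(paste(reach$aa_from, reach$aa_to)[
      reach$category == "missense"])
    pairs <- paste(mis$aa_from, mis$aa_to)
    bad <- !pairs %in% reach_pairs
    if (any(bad)) {
      stopf("substitution %s>%s is not reachable by a single A-to-G edit",
            mis$aa_from[which(bad)[1]], mis$aa_to[which(bad)[1]])
    }
    tab <- table(factor(mis$aa_from, aa), factor(mis$aa_to, aa))
    mat <- mat + unclass(tab)
  }
  cross <- scheme[mis$aa_from] != scheme[mis$aa_to]
  list(matrix = mat,
       cross_class_fraction = if (nrow(mis)) mean(cross) else NA_real_,
       n = nrow(mis))
}

#' Enumerate all possible A-to-G codon edits
#'
#' Exhaustively substitutes G at every adenosine position of all 64 codons
#' and classifies each outcome.  This enumeration shows that no sense codon
#' can become a stop codon under A-to-G editing, i.e. nonsense edits are
#' impossible and the annotator can never emit that category.
#'
#' @return A data frame with codon_from, codon_to (RNA alphabet), position,
#'   aa_from, aa_to, category.
#' @export
ag_edit_outcomes <- function() {
  code <- Biostrings::GENETIC_CODE
  out <- list()
  for (codon in names(code)) {
    for (p in 1:3) {
      if (substr(codon, p, p) != "A") next
      to <- codon
      substr(to, p, p) <- "G"
      aa1 <- unname(code[codon]); aa2 <- unname(code[to])
      category <- if (aa1 == "*") {
        if (aa2 == "*") "stop_retained" else "stop_loss"
      } else if (aa2 == "*") "nonsense"
      else if (aa1 == aa2) "synonymous" else "missense"
      out[[length(out) + 1L]] <- data.frame(
        codon_from = dna_to_rna(codon), codon_to = dna_to_rna(to),
        position = p, aa_from = aa1, aa_to = aa2, category = category,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Median editing level per consequence category
#'
#' Support for contrasting levels across consequence classes (e.g. missense
#' vs synonymous sites); values are data-dependent summaries, not tests.
#'
#' @param sites Annotated sites with a `level` column.
#' @return Named numeric vector of medians per consequence category.
#' @export
level_by_consequence <- function(sites) {
  ok <- !is.na(sites$consequence)
  tapply(sites$level[ok], sites$consequence[ok], stats::median)
}
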