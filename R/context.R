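## Nucleotide-context preference of edited adenosines.

#' Spliced transcript (cDNA) sequences for all gene models
#'
#' @param genome Named character vector of contig sequences.
#' @param models A `fg_genes` object.
#' @return Named character vector of transcript sequences (transcript
#'   orientation).
#' @export
transcript_sequences <- function(genome, models) {
  out <- vapply(models, function(g) transcript_seq(genome, g), character(1))
  names(out) <- vapply(models, function(g) g$gene_id, character(1))
  out
}

#' Map genomic sites onto transcript coordinates
#'
#' Adds `tx_id` and `tx_pos` (1-based position in the spliced transcript,
#' transcript orientation) for sites that fall in the exons of their
#' assigned gene; other sites get `NA`.
#'
#' @param sites Annotated sites with `gene_id`.
#' @param models A `fg_genes` object.
#' @return `sites` with columns `tx_id` and `tx_pos` added.
#' @export
map_sites_to_tx <- function(sites, models) {
  tx_id <- rep(NA_character_, nrow(sites))
  tx_pos <- rep(NA_integer_, nrow(sites))
  for (gid in unique(stats::na.omit(sites$gene_id))) {
    g <- models[[gid]]
    if (is.null(g)) next
    pm <- tx_positions(g)
    rows <- which(!is.na(sites$gene_id) & sites$gene_id == gid)
    hit <- match(sites$pos[rows], pm)
    tx_id[rows] <- ifelse(is.na(hit), NA, gid)
    tx_pos[rows] <- hit
  }
  sites$tx_id <- tx_id
  sites$tx_pos <- tx_pos
  sites
}

#' Context-preference configuration
#'
#' @param window Half-width of the nucleotide window around the edited A
#'   (default 5, i.e. positions -5..+5); must be at least 4 so the window
#'   covers -3..+4.
#' @param control_n Number of random adenosine control sites (default
#'   30000).
#' @param alpha Significance level for per-position enrichment calls.
#' @param control_seed Seed for control sampling.
#' @param test `"z"` (two-sample proportion z-test, default) or `"t"`
#'   (Welch t-test on the position-base indicator).
#' @param bonferroni Apply Bonferroni correction across position-base cells
#'   (off by default).
#' @return A list of class `"fg_pref_config"`.
#' @export
preference_config <- function(window = 5L, control_n = 30000L, alpha = 0.01,
                              control_seed = 1L, test = c("z", "t"),
                              bonferroni = FALSE) {
  stopifnot(window >= 4L, alpha > 0, alpha < 1)
  structure(list(window = as.integer(window),
                 control_n = as.integer(control_n), alpha = alpha,
                 control_seed = as.integer(control_seed),
                 test = match.arg(test), bonferroni = bonferroni),
            class = "fg_pref_config")
}

#' Sample random adenosine control sites from cDNA
#'
#' Uniform sample, without replacement, of adenosine positions across all
#' transcript sequences; deterministic for a fixed seed.
#'
#' @param cdna Named character vector of transcript sequences.
#' @param n Sample size.
#' @param seed RNG seed.
#' @return Data frame with `tx_id` and `tx_pos`.
#' @export
sample_control <- function(cdna, n, seed = 1L) {
  a_pos <- lapply(cdna, function(s) {
    which(strsplit(s, "")[[1]] == "A")
  })
  total <- sum(lengths(a_pos))
  if (n > total) {
    stopf("requested %d control adenosines but only %d exist in the cDNA set",
          n, total)
  }
  pool <- data.frame(
    tx_id = rep(names(cdna), lengths(a_pos)),
    tx_pos = unlist(a_pos, use.names = FALSE),
    stringsAsFactors = FALSE)
  with_seed(seed, pool[sample(nrow(pool), n), , drop = FALSE])
}

## Window matrix (rows = sites with a full window, cols = -w..+w) of bases.
context_windows <- function(sites, cdna, window) {
  L <- nchar(cdna)[sites$tx_id]
  ok <- !is.na(sites$tx_pos) & sites$tx_pos > window &
    sites$tx_pos <= L - window
  s <- sites[ok, , drop = FALSE]
  offs <- seq(-window, window)
  mat <- matrix(NA_character_, nrow(s), length(offs),
                dimnames = list(NULL, as.character(offs)))
  for (j in seq_along(offs)) {
    p <- s$tx_pos + offs[j]
    mat[, j] <- substring(cdna[s$tx_id], p, p)
  }
  attr(mat, "n_truncated") <- sum(!ok)
  mat
}

#' Per-position nucleotide enrichment around edited adenosines
#'
#' Compares base frequencies at every window position between edited sites
#' and a random-adenosine control (the two-sample-logo contrast), testing
#' each position-base cell with a two-sample proportion z-test (or Welch
#' t-test on indicators).  Sites too close to a transcript end for a full
#' window are dropped and counted.
#'
#' @param edited,control Data frames with `tx_id`, `tx_pos`.
#' @param cdna Named character vector of transcript sequences.
#' @param config A [preference_config()].
#' @return Data frame of class `"fg_enrichment"`: position, base,
#'   freq_edited, freq_control, diff, p, significant; counts of truncated
#'   sites in attributes.
#' @export
position_enrichment <- function(edited, control, cdna,
                                config = preference_config()) {
  w <- config$window
  em <- context_windows(edited, cdna, w)
  cm <- context_windows(control, cdna, w)
  if (nrow(em) == 0) {
    out <- data.frame(position = integer(0), base = character(0),
                      freq_edited = numeric(0), freq_control = numeric(0),
                      diff = numeric(0), p = numeric(0),
                      significant = logical(0))
    class(out) <- c("fg_enrichment", "data.frame")
    return(out)
  }
  offs <- setdiff(seq(-w, w), 0L)
  rows <- list()
  n_tests <- length(offs) * 4L
  for (off in offs) {
    eb <- em[, as.character(off)]
    cb <- cm[, as.character(off)]
    for (b in BASES) {
      x1 <- sum(eb == b); n1 <- length(eb)
      x2 <- sum(cb == b); n2 <- length(cb)
      f1 <- x1 / n1; f2 <- x2 / n2
      p <- prop_test_p(x1, n1, x2, n2, config$test)
      rows[[length(rows) + 1L]] <- data.frame(
        position = off, base = dna_to_rna(b), freq_edited = f1,
        freq_control = f2, diff = f1 - f2, p = p,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  alpha <- if (config$bonferroni) config$alpha / n_tests else config$alpha
  ## no significance calls from a degenerate edited set
  out$significant <- !is.na(out$p) & out$p < alpha & nrow(em) > 1
  attr(out, "n_edited") <- nrow(em)
  attr(out, "n_control") <- nrow(cm)
  attr(out, "n_truncated_edited") <- attr(em, "n_truncated")
  attr(out, "n_truncated_control") <- attr(cm, "n_truncated")
  class(out) <- c("fg_enrichment", "data.frame")
  out
}

prop_test_p <- function(x1, n1, x2, n2, test = "z") {
  if (n1 < 2 || n2 < 2) return(NA_real_)
  if (test == "z") {
    p_pool <- (x1 + x2) / (n1 + n2)
    se <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
    if (se == 0) return(1)
    2 * stats::pnorm(-abs(x1 / n1 - x2 / n2) / se)
  } else {
    v1 <- c(rep(1, x1), rep(0, n1 - x1))
    v2 <- c(rep(1, x2), rep(0, n2 - x2))
    if (stats::var(v1) == 0 && stats::var(v2) == 0) return(1)
    stats::t.test(v1, v2)$p.value
  }
}

#' NAN-triplet editing percentages
#'
#' For each of the 16 triplets centered on an adenosine (NAN), divides the
#' number of edited occurrences by the total occurrence of the triplet in
#' the cDNA set, and reports the median editing level of the edited
#' instances.
#'
#' @param edited Data frame with `tx_id`, `tx_pos` (and optionally `level`).
#' @param cdna Named character vector of transcript sequences.
#' @return A 16-row data frame: triplet (RNA alphabet), edited_n, total_n,
#'   percentage (fraction), median_level.
#' @export
triplet_percentages <- function(edited, cdna) {
  triplets <- as.vector(outer(BASES, BASES, function(a, b) paste0(a, "A", b)))
  triplets <- sort(triplets)
  total <- stats::setNames(integer(16), triplets)
  for (s in cdna) {
    b <- strsplit(s, "")[[1]]
    ctr <- which(b == "A")
    ctr <- ctr[ctr > 1 & ctr < length(b)]
    if (!length(ctr)) next
    tri <- paste0(b[ctr - 1L], "A", b[ctr + 1L])
    tab <- table(factor(tri, levels = triplets))
    total <- total + as.integer(tab)
  }
  ok <- !is.na(edited$tx_pos) & edited$tx_pos > 1 &
    edited$tx_pos < nchar(cdna)[edited$tx_id]
  e <- edited[ok, , drop = FALSE]
  etri <- paste0(substring(cdna[e$tx_id], e$tx_pos - 1L, e$tx_pos - 1L), "A",
                 substring(cdna[e$tx_id], e$tx_pos + 1L, e$tx_pos + 1L))
  edited_n <- as.integer(table(factor(etri, levels = triplets)))
  med <- rep(NA_real_, 16)
  if (!is.null(e$level)) {
    med <- vapply(triplets, function(tr) {
      lv <- e$level[etri == tr]
      if (length(lv)) stats::median(lv) else NA_real_
    }, numeric(1))
  }
  data.frame(triplet = dna_to_rna(triplets), edited_n = edited_n,
             total_n = as.integer(total),
             percentage = ifelse(total > 0, edited_n / total, NA),
             median_level = unname(med), stringsAsFactors = FALSE)
}
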