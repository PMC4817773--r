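## Small shared helpers (internal).

BASES <- c("A", "C", "G", "T")

#' Reverse-complement a DNA string
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, used throughout for transcript-orientation conversions.
#'
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @keywords internal
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

## Split a vector of equal-length sequences into a single base vector.
seq_to_bases <- function(x) {
  unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE)
}

## Deterministic sub-seed derivation: combine a master seed with a label so
## that independent stages (condition x replicate, control sampling, ...)
## use decoupled but reproducible streams.  Kept below 2^31 - 1.
derive_seed <- function(seed, label) {
  h <- utils::head(utf8ToInt(paste0(label)), 50)
  s <- (as.numeric(seed) + sum(h * seq_along(h) * 1009)) %% 2147483647
  as.integer(s)
}

## Run expr with a locally-set RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

## DNA -> RNA display alphabet for codons and windows.
dna_to_rna <- function(x) chartr("T", "U", x)
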