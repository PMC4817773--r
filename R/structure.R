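## Folding of 61-nt windows around edited A's and structural-element
## classification of the edited position.

ELEMENT_CLASSES <- c("hairpin_loop", "stem", "internal_or_bulge_loop",
                     "multibranch_loop", "exterior")

#' Choose the folding backend
#'
#' `"vienna"` uses the RNAfold program (nearest-neighbor thermodynamic
#' model, 37 degrees C, default parameters) when it is on the PATH;
#' `"bundled"` is a base-pair maximization folder with simple pair energies
#' (GC -3, AU -2, GU -1 kcal/mol, minimum hairpin loop 3) provided so the
#' pipeline runs without external software.  Element classification is a
#' pure function of the dot-bracket string and therefore backend
#' independent.
#'
#' @return `"vienna"` if RNAfold is available, else `"bundled"`.
#' @export
default_fold_backend <- function() {
  if (nzchar(Sys.which("RNAfold"))) "vienna" else "bundled"
}

#' Fold RNA sequences to minimum-free-energy structures
#'
#' @param seqs Character vector of sequences over \{A, C, G, U/T\}.
#' @param backend `"vienna"` or `"bundled"` (see [default_fold_backend()]).
#' @return Data frame with `structure` (dot-bracket) and `mfe` (kcal/mol).
#' @export
fold <- function(seqs, backend = default_fold_backend()) {
  seqs <- toupper(chartr("T", "U", seqs))
  bad <- grepl("[^ACGU]", seqs)
  if (any(bad)) stopf("sequence %d contains letters outside A/C/G/U",
                      which(bad)[1])
  backend <- match.arg(backend, c("vienna", "bundled"))
  if (backend == "vienna") fold_vienna(seqs) else fold_bundled(seqs)
}

fold_vienna <- function(seqs) {
  out <- system2("RNAfold", args = c("--noPS"), input = seqs, stdout = TRUE)
  sl <- out[seq(2, length(out), by = 2)]
  structure_ <- sub(" .*$", "", sl)
  mfe <- as.numeric(sub(".*\\((\\s*-?[0-9.]+)\\)\\s*$", "\\1", sl))
  data.frame(structure = structure_, mfe = mfe, stringsAsFactors = FALSE)
}

## Base-pair maximization (weighted Nussinov) with a 3-nt minimum hairpin
## loop; deterministic traceback.  Energies: GC -3, AU -2, GU -1.
pair_energy_ <- function(a, b) {
  key <- paste0(a, b)
  e <- c(GC = -3, CG = -3, AU = -2, UA = -2, GU = -1, UG = -1)
  unname(ifelse(key %in% names(e), e[key], 0))
}

fold_bundled <- function(seqs) {
  res <- lapply(seqs, fold_bundled_one)
  data.frame(structure = vapply(res, `[[`, character(1), "structure"),
             mfe = vapply(res, `[[`, numeric(1), "mfe"),
             stringsAsFactors = FALSE)
}

fold_bundled_one <- function(s) {
  b <- strsplit(s, "")[[1]]
  n <- length(b)
  minloop <- 3L
  if (n < minloop + 2L) return(list(structure = strrep(".", n), mfe = 0))
  E <- matrix(0, n, n)
  for (span in (minloop + 1L):(n - 1L)) {
    for (i in 1:(n - span)) {
      j <- i + span
      best <- E[i, j - 1L]              # j unpaired
      ks <- i:(j - minloop - 1L)
      pe <- pair_energy_(b[ks], b[j])
      pair_ok <- pe < 0
      if (any(pair_ok)) {
        kk <- ks[pair_ok]
        left <- ifelse(kk > i, E[cbind(rep(i, length(kk)), pmax(kk - 1L, 1L))], 0)
        inner <- E[cbind(kk + 1L, rep(j - 1L, length(kk)))]
        best <- min(best, left + inner + pe[pair_ok])
      }
      E[i, j] <- best
    }
  }
  db <- trace_bundled(E, b, 1L, n, rep(".", n), minloop)
  list(structure = paste(db, collapse = ""), mfe = E[1, n])
}

trace_bundled <- function(E, b, i, j, db, minloop) {
  while (i < j) {
    if (j - i <= minloop) return(db)
    if (E[i, j] == E[i, j - 1L]) { j <- j - 1L; next }
    ks <- i:(j - minloop - 1L)
    found <- FALSE
    for (k in ks) {
      pe <- pair_energy_(b[k], b[j])
      if (pe >= 0) next
      left <- if (k > i) E[i, k - 1L] else 0
      inner <- if (k + 1L <= j - 1L) E[k + 1L, j - 1L] else 0
      if (isTRUE(all.equal(E[i, j], left + inner + pe))) {
        db[k] <- "("; db[j] <- ")"
        if (k + 1L <= j - 1L) db <- trace_bundled(E, b, k + 1L, j - 1L, db, minloop)
        if (k > i) { j <- k - 1L } else return(db)
        found <- TRUE
        break
      }
    }
    if (!found) return(db)
  }
  db
}

## Pair table: for each position the index of its partner (NA if unpaired).
pair_table <- function(db) {
  b <- strsplit(db, "")[[1]]
  n <- length(b)
  pt <- rep(NA_integer_, n)
  stack <- integer(0)
  for (i in seq_len(n)) {
    if (b[i] == "(") {
      stack <- c(stack, i)
    } else if (b[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      pt[i] <- j; pt[j] <- i
    } else if (b[i] != ".") {
      stopf("invalid character '%s' in dot-bracket string", b[i])
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  pt
}

#' Classify every position of a dot-bracket structure
#'
#' Assigns each position exactly one of five element classes: `stem`
#' (paired), `hairpin_loop` (unpaired in a loop closed by a helix with no
#' inner helices), `internal_or_bulge_loop` (unpaired in a loop with
#' exactly one inner helix), `multibranch_loop` (unpaired in a loop with
#' two or more inner helices), and `exterior` (unpaired, not enclosed by
#' any pair).
#'
#' @param db Dot-bracket string (balanced).
#' @return Character vector of classes, one per position.
#' @export
classify_positions <- function(db) {
  pt <- pair_table(db)
  b <- strsplit(db, "")[[1]]
  n <- length(b)
  ## parent pair (id = index of its opening bracket) enclosing each position
  parent <- rep(NA_integer_, n)
  children <- integer(n)   # children[k] = helix branches inside pair opened at k
  stack <- integer(0)
  for (i in seq_len(n)) {
    top <- if (length(stack)) stack[length(stack)] else NA_integer_
    if (b[i] == "(") {
      parent[i] <- top
      ## count a branch only at the outermost pair of a helix
      if (is.na(top) || pt[top] != pt[i] + 1L || top != i - 1L) {
        if (!is.na(top)) children[top] <- children[top] + 1L
      }
      stack <- c(stack, i)
    } else if (b[i] == ")") {
      stack <- stack[-length(stack)]
    } else {
      parent[i] <- top
    }
  }
  out <- character(n)
  paired <- !is.na(pt)
  out[paired] <- "stem"
  un <- which(!paired)
  for (i in un) {
    p <- parent[i]
    if (is.na(p)) { out[i] <- "exterior"; next }
    ## the relevant loop is the one closed by the innermost enclosing pair
    nb <- children[p]
    out[i] <- if (nb == 0L) "hairpin_loop"
    else if (nb == 1L) "internal_or_bulge_loop"
    else "multibranch_loop"
  }
  out
}

#' @param position Position (1-based) to classify.
#' @rdname classify_positions
#' @export
classify_element <- function(db, position) {
  if (position < 1 || position > nchar(db)) {
    stopf("position %d outside structure of length %d", position, nchar(db))
  }
  classify_positions(db)[position]
}

#' Structural context of edited adenosines
#'
#' Extracts the 61-nt window (30 nt either side, truncated and flagged at
#' transcript ends) around each site in transcript orientation, folds it,
#' classifies the element containing the edited A, and, for hairpin-loop
#' sites, refolds the enclosing hairpin (maximal closing helix plus loop)
#' to obtain its MFE.
#'
#' @param sites Data frame with `tx_id`, `tx_pos` and optionally `level`.
#' @param cdna Named character vector of transcript sequences.
#' @param backend Folding backend (see [fold()]).
#' @param flank Window half-width in nt (default 30).
#' @return A data frame of class `"fg_structure"`: tx_id, tx_pos, level,
#'   window (RNA), site_offset, truncated, structure, mfe, element,
#'   hairpin_mfe (NA outside hairpin loops).
#' @export
structure_context <- function(sites, cdna, backend = default_fold_backend(),
                              flank = 30L) {
  ok <- !is.na(sites$tx_pos) & !is.na(sites$tx_id)
  s <- sites[ok, , drop = FALSE]
  L <- nchar(cdna)[s$tx_id]
  a <- pmax(1L, s$tx_pos - flank)
  b <- pmin(L, s$tx_pos + flank)
  win <- dna_to_rna(substring(cdna[s$tx_id], a, b))
  off <- s$tx_pos - a + 1L
  fd <- fold(win, backend = backend)
  el <- character(nrow(s))
  hp <- rep(NA_real_, nrow(s))
  for (i in seq_len(nrow(s))) {
    el[i] <- classify_element(fd$structure[i], off[i])
    if (el[i] == "hairpin_loop") {
      hp[i] <- hairpin_mfe(win[i], fd$structure[i], off[i], backend)
    }
  }
  out <- data.frame(tx_id = s$tx_id, tx_pos = s$tx_pos,
                    level = if (!is.null(s$level)) s$level else NA_real_,
                    window = win, site_offset = off,
                    truncated = (b - a) != 2L * flank,
                    structure = fd$structure, mfe = fd$mfe, element = el,
                    hairpin_mfe = hp, stringsAsFactors = FALSE)
  class(out) <- c("fg_structure", "data.frame")
  out
}

## Free energy of the enclosing hairpin: maximal helix stacking on the
## closing pair, plus the loop, refolded as an isolated sequence.
hairpin_mfe <- function(win, db, position, backend) {
  pt <- pair_table(db)
  ## innermost enclosing pair
  i <- position
  while (i >= 1 && is.na(pt[i])) i <- i - 1L
  lo <- i
  if (lo < 1) return(NA_real_)
  hi <- pt[lo]
  while (lo - 1L >= 1 && hi + 1L <= nchar(db) &&
         !is.na(pt[lo - 1L]) && pt[lo - 1L] == hi + 1L) {
    lo <- lo - 1L; hi <- hi + 1L
  }
  fold(substr(win, lo, hi), backend = backend)$mfe
}

#' Hairpin fraction and hairpin MFE by editing-level bin
#'
#' Stratifies structure contexts by the editing-level bins (<30\%,
#' 30--60\%, >60\%), reporting per bin the fraction of sites in hairpin
#' loops and the distribution of enclosing-hairpin MFEs; a matched control
#' set processed identically can be supplied for comparison.
#'
#' @param contexts A `fg_structure` data frame carrying editing levels.
#' @param control Optional `fg_structure` for random control adenosines.
#' @return A list with `by_bin` (data frame: bin, n, hairpin_fraction,
#'   median_hairpin_mfe), `hairpin_mfes` (list of per-bin MFE vectors),
#'   `overall_hairpin_fraction`, and optionally `control` (same shape).
#' @export
hairpin_mfe_strata <- function(contexts, control = NULL) {
  strat <- function(x, use_bins = TRUE) {
    bins <- if (use_bins && !all(is.na(x$level))) level_bins(x$level)
    else factor(rep("all", nrow(x)), levels = "all")
    by_bin <- do.call(rbind, lapply(levels(bins), function(bn) {
      xx <- x[bins == bn, , drop = FALSE]
      hf <- if (nrow(xx)) mean(xx$element == "hairpin_loop") else NA_real_
      data.frame(bin = bn, n = nrow(xx), hairpin_fraction = hf,
                 median_hairpin_mfe = stats::median(xx$hairpin_mfe,
                                                    na.rm = TRUE),
                 stringsAsFactors = FALSE)
    }))
    mfes <- lapply(stats::setNames(levels(bins), levels(bins)), function(bn) {
      v <- x$hairpin_mfe[bins == bn]
      v[!is.na(v)]
    })
    list(by_bin = by_bin, hairpin_mfes = mfes,
         overall_hairpin_fraction = mean(contexts$element == "hairpin_loop"))
  }
  out <- strat(contexts)
  if (!is.null(control)) {
    ctl <- strat(control, use_bins = FALSE)
    ctl$overall_hairpin_fraction <- mean(control$element == "hairpin_loop")
    out$control <- ctl
  }
  out
}
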