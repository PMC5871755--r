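# In-silico PCR: degenerate-primer matching (Hamming only, no gaps --
# standard virtual-PCR semantics), amplicon extraction, and the
# primer/GC bias audit against taxon abundances.

# lookup matrix: does window base w satisfy primer base p? (built lazily
# on first use and cached in the package namespace environment)
.iupac_cache <- new.env(parent = emptyenv())

.iupac_match_matrix <- function() {
  if (is.null(.iupac_cache$m)) {
    chars <- strsplit(IUPAC_CHARS, "")[[1L]]
    m <- matrix(FALSE, length(chars), length(chars),
                dimnames = list(primer = chars, window = chars))
    for (p in chars) {
      for (w in chars) {
        m[p, w] <- w %in% IUPAC_SETS[[p]] || w == p
      }
    }
    .iupac_cache$m <- m
  }
  .iupac_cache$m
}

#' Count IUPAC-aware mismatches between a primer and a window
#'
#' A window base matches when it belongs to the IUPAC set of the primer
#' base (N matches everything); everything else counts as one mismatch.
#'
#' @param primer Primer string (IUPAC, possibly degenerate).
#' @param window Equal-length window string.
#' @return Integer mismatch count.
#' @export
#' @examples
#' iupac_mismatches("AGRGTTYGATYMTGGCTCAG", "AGAGTTTGATCATGGCTCAG")  # 0
iupac_mismatches <- function(primer, window) {
  primer <- toupper(primer); window <- toupper(window)
  if (nchar(primer) != nchar(window)) {
    stop("primer and window must have equal length", call. = FALSE)
  }
  p <- strsplit(primer, "")[[1L]]
  w <- strsplit(window, "")[[1L]]
  sum(!.iupac_match_matrix()[cbind(p, w)])
}

# vectorized mismatch profile of a primer against all windows of seq
.window_mismatches <- function(seq_chars, primer) {
  p <- strsplit(toupper(primer), "")[[1L]]
  plen <- length(p)
  n_win <- length(seq_chars) - plen + 1L
  if (n_win < 1L) return(integer(0))
  counts <- integer(n_win)
  mm <- .iupac_match_matrix()
  for (k in seq_len(plen)) {
    counts <- counts + !mm[cbind(rep(p[k], n_win),
                                 seq_chars[k:(k + n_win - 1L)])]
  }
  counts
}

#' Locate primer binding sites on both strands
#'
#' All windows on the forward strand are matched against the primer, and
#' against its reverse complement for minus-strand hits. Positions are
#' 0-based half-open on the forward strand.
#'
#' @param seq Template sequence string.
#' @param primer A [primer] object or IUPAC string.
#' @param max_mismatch Maximum mismatches reported.
#' @return A data frame with columns `start`, `end`, `strand`,
#'   `mismatches`, sorted by `start`; empty when the primer is longer than
#'   the sequence.
#' @export
find_primer_sites <- function(seq, primer, max_mismatch = 0L) {
  pseq <- if (inherits(primer, "primer")) primer$seq else toupper(primer)
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1L]]
  plen <- nchar(pseq)
  out <- list()
  fwd <- .window_mismatches(chars, pseq)
  hit <- which(fwd <= max_mismatch)
  if (length(hit)) {
    out$fwd <- data.frame(start = hit - 1L, end = hit - 1L + plen,
                          strand = "+", mismatches = fwd[hit])
  }
  rev <- .window_mismatches(chars, revcomp(pseq))
  hit <- which(rev <= max_mismatch)
  if (length(hit)) {
    out$rev <- data.frame(start = hit - 1L, end = hit - 1L + plen,
                          strand = "-", mismatches = rev[hit])
  }
  if (!length(out)) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Extract the amplicon bracketed by a primer pair
#'
#' Finds the forward primer on the plus strand and the reverse primer as a
#' minus-strand match downstream. When several candidate pairs exist, the
#' shortest amplicon whose insert is at least `min_insert` long is chosen.
#' The insert excludes the primer bases (mimicking primer trimming); the
#' `full` field keeps them.
#'
#' @param record A [sequence_record].
#' @param fwd_primer,rev_primer [primer] objects or IUPAC strings.
#' @param max_mismatch Maximum mismatches per primer site.
#' @param min_insert Minimum insert length for a valid pair.
#' @return A list of class `amplicon` with `source_accession`, `insert`,
#'   `full` and `coords` (0-based half-open interval of `full` on the
#'   source), or `NULL` when no primer pair is found (failure state).
#' @export
extract_amplicon <- function(record, fwd_primer, rev_primer,
                             max_mismatch = 0L, min_insert = 50L) {
  stopifnot(inherits(record, "sequence_record"))
  f <- find_primer_sites(record$seq, fwd_primer, max_mismatch)
  f <- f[f$strand == "+", , drop = FALSE]
  r <- find_primer_sites(record$seq, rev_primer, max_mismatch)
  r <- r[r$strand == "-", , drop = FALSE]
  if (!nrow(f) || !nrow(r)) return(NULL)
  best <- NULL
  for (i in seq_len(nrow(f))) {
    for (j in seq_len(nrow(r))) {
      insert_len <- r$start[j] - f$end[i]
      if (insert_len < min_insert) next
      full_len <- r$end[j] - f$start[i]
      if (is.null(best) || full_len < best$full_len) {
        best <- list(f = i, r = j, full_len = full_len)
      }
    }
  }
  if (is.null(best)) return(NULL)
  fs <- f$start[best$f]; fe <- f$end[best$f]
  rs <- r$start[best$r]; re <- r$end[best$r]
  structure(list(
    source_accession = record$id,
    insert = substr(record$seq, fe + 1L, rs),
    full = substr(record$seq, fs + 1L, re),
    coords = c(fs, re)), class = "amplicon")
}

#' Virtual PCR of a reference database
#'
#' Reports, per taxon, the minimal mismatch count of each primer over all
#' windows (forward primer on the plus strand, reverse primer as a
#' minus-strand match) and whether the taxon is amplifiable at the given
#' mismatch allowance.
#'
#' @param db A `reference_db` or named sequence vector.
#' @param fwd_primer,rev_primer [primer] objects or IUPAC strings.
#' @param max_mismatch Mismatch allowance defining the `amplifiable` flag.
#' @return A data frame with columns `accession`, `fwd_mismatches`,
#'   `rev_mismatches`, `amplifiable`.
#' @export
virtual_pcr_table <- function(db, fwd_primer, rev_primer, max_mismatch = 3L) {
  seqs <- as_reference_seqs(db)
  if (!length(seqs)) stop("database is empty", call. = FALSE)
  fseq <- if (inherits(fwd_primer, "primer")) fwd_primer$seq else fwd_primer
  rseq <- if (inherits(rev_primer, "primer")) rev_primer$seq else rev_primer
  res <- t(vapply(seqs, function(s) {
    chars <- strsplit(toupper(s), "")[[1L]]
    fmm <- .window_mismatches(chars, fseq)
    rmm <- .window_mismatches(chars, revcomp(rseq))
    c(if (length(fmm)) min(fmm) else NA_integer_,
      if (length(rmm)) min(rmm) else NA_integer_)
  }, numeric(2)))
  out <- data.frame(accession = names(seqs),
                    fwd_mismatches = as.integer(res[, 1L]),
                    rev_mismatches = as.integer(res[, 2L]),
                    stringsAsFactors = FALSE)
  out$amplifiable <- !is.na(out$fwd_mismatches) &
    !is.na(out$rev_mismatches) &
    out$fwd_mismatches <= max_mismatch & out$rev_mismatches <= max_mismatch
  rownames(out) <- NULL
  out
}

#' GC content of a sequence
#'
#' Ambiguity codes are excluded from both numerator and denominator.
#'
#' @param seq Nucleotide string.
#' @return Fraction of G+C among unambiguous bases, in `[0, 1]`.
#' @export
gc_content <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  chars <- strsplit(toupper(seq), "")[[1L]]
  gc <- sum(chars %in% c("G", "C"))
  at <- sum(chars %in% c("A", "T"))
  if (gc + at == 0L) {
    stop("sequence contains no unambiguous bases", call. = FALSE)
  }
  gc / (gc + at)
}

#' Correlation between a primer/GC covariate and taxon abundance
#'
#' Spearman's rho with a label-permutation p-value, used to ask whether
#' primer mismatches or GC content predict observed taxon abundance
#' (amplification bias).
#'
#' @param values Numeric covariate per taxon (e.g. mismatch counts or GC).
#' @param abundance Numeric abundance per taxon, same order.
#' @param n_permutations Number of label permutations.
#' @param seed Integer seed for the permutations.
#' @return A list with `rho`, `p_value`, `n_permutations` and
#'   `computable`; for a constant covariate `rho` is `NA` and
#'   `computable` is `FALSE`.
#' @export
primer_bias_correlation <- function(values, abundance,
                                    n_permutations = 9999L, seed = 1L) {
  if (length(values) != length(abundance)) {
    stop("values and abundance must have equal length", call. = FALSE)
  }
  if (length(values) < 3L) stop("need at least 3 taxa", call. = FALSE)
  rho <- spearman_rho(values, abundance)
  if (is.na(rho)) {
    return(list(rho = NA_real_, p_value = NA_real_,
                n_permutations = 0L, computable = FALSE))
  }
  with_seed(seed, {
    exceed <- 0L
    for (i in seq_len(n_permutations)) {
      r <- suppressWarnings(spearman_rho(values, sample(abundance)))
      if (!is.na(r) && abs(r) >= abs(rho) - 1e-12) exceed <- exceed + 1L
    }
  })
  list(rho = rho, p_value = (1 + exceed) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations), computable = TRUE)
}
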