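# The two classification paths. (a) Long reads: best-hit semi-global
# alignment against the reference database with an 80% identity gate
# applied after best-hit selection. (b) Short reads: greedy centroid
# clustering at 97% identity followed by closed-reference assignment of
# the representatives into the same database namespace. A shared-k-mer
# prefilter shortlists references before the quadratic DP; when the
# shortlist is empty the scan falls back to the full database.

UNCLASSIFIED <- "unclassified"

.kmers_of <- function(seq, k = 8L) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, 1:(n - k + 1L), k:n))
}

.kmer_index <- function(seqs, k = 8L) lapply(seqs, .kmers_of, k = k)

# names of references sharing at least as many k-mers as the top-th best
.shortlist <- function(read_kmers, index, top = 3L) {
  counts <- vapply(index, function(ref_k) sum(read_kmers %in% ref_k),
                   integer(1))
  if (all(counts == 0L)) return(names(index))  # fallback: full scan
  cutoff <- sort(counts, decreasing = TRUE)[min(top, length(counts))]
  names(index)[counts >= max(cutoff, 1L)]
}

.best_hit <- function(seq, seqs, params, candidates = NULL) {
  refs <- if (is.null(candidates)) names(seqs) else candidates
  scores <- vapply(refs, function(a) .align_score(seq, seqs[[a]], params),
                   integer(1))
  top <- max(scores)
  winners <- sort(refs[scores == top])
  best_acc <- winners[1L]
  aln <- align_semi_global(seq, seqs[[best_acc]], params)
  list(accession = best_acc, score = top, identity = aln$identity,
       tie = length(winners) > 1L)
}

#' Classify one read by best-hit alignment
#'
#' The best-scoring reference wins; the identity gate is applied after
#' best-hit selection. A tie (two or more references sharing the top
#' score) is resolved deterministically to the lexicographically smallest
#' accession and flagged.
#'
#' @param read A [sequence_record] or sequence string.
#' @param db A `reference_db` or named sequence vector.
#' @param min_identity Identity gate in `[0, 1]`; below it the read is
#'   reported unclassified.
#' @param params [alignment_params].
#' @return A one-row data frame: `read_id`, `accession` (`NA` when
#'   unclassified), `identity`, `tie`, `score`.
#' @export
classify_read_best_hit <- function(read, db, min_identity = 0.80,
                                   params = alignment_params()) {
  seqs <- as_reference_seqs(db)
  if (!length(seqs)) stop("database is empty", call. = FALSE)
  id <- if (inherits(read, "sequence_record")) read$id else "query"
  seq <- if (inherits(read, "sequence_record")) read$seq else toupper(read)
  hit <- .best_hit(seq, seqs, params)
  assigned <- if (hit$identity >= min_identity) hit$accession else
    NA_character_
  data.frame(read_id = id, accession = assigned, identity = hit$identity,
             tie = hit$tie, score = hit$score, stringsAsFactors = FALSE)
}

#' Classify a set of reads by best-hit alignment
#'
#' Identical read sequences are dereplicated before alignment (the
#' classifier is deterministic, so duplicates share their result), and a
#' shared 8-mer prefilter shortlists candidate references per unique
#' sequence, falling back to a full database scan when no reference
#' shares a k-mer.
#'
#' @param reads List of [sequence_record] objects.
#' @inheritParams classify_read_best_hit
#' @param prefilter Use the k-mer shortlist (`TRUE`) or scan the full
#'   database for every read.
#' @param k K-mer size of the prefilter.
#' @param top Number of top-scoring shortlist entries kept (ties at the
#'   cutoff are all kept so the deterministic tie-break is unaffected).
#' @return A data frame with one row per read: `read_id`, `accession`,
#'   `identity`, `tie`.
#' @export
classify_reads <- function(reads, db, min_identity = 0.80,
                           params = alignment_params(), prefilter = TRUE,
                           k = 8L, top = 3L) {
  seqs <- as_reference_seqs(db)
  if (!length(seqs)) stop("database is empty", call. = FALSE)
  if (!length(reads)) stop("no reads to classify", call. = FALSE)
  read_seqs <- vapply(reads, `[[`, character(1), "seq")
  read_ids <- vapply(reads, `[[`, character(1), "id")
  uniq <- !duplicated(read_seqs)
  uniq_seqs <- read_seqs[uniq]
  index <- if (prefilter) .kmer_index(seqs, k) else NULL
  res <- lapply(uniq_seqs, function(s) {
    cand <- if (prefilter) .shortlist(.kmers_of(s, k), index, top) else NULL
    .best_hit(s, seqs, params, cand)
  })
  names(res) <- uniq_seqs
  out <- do.call(rbind, lapply(seq_along(reads), function(i) {
    h <- res[[read_seqs[i]]]
    data.frame(read_id = read_ids[i],
               accession = if (h$identity >= min_identity) h$accession else
                 NA_character_,
               identity = h$identity, tie = h$tie,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Greedy centroid clustering at an identity threshold
#'
#' Reads are dereplicated, then processed in order of decreasing
#' duplicate count, decreasing length, then id; each sequence joins the
#' first existing representative (in creation order) with identity at or
#' above the threshold, otherwise it founds a new cluster. The procedure
#' is deterministic. A shared-k-mer screen skips representatives that
#' cannot plausibly reach the threshold.
#'
#' @param reads List of [sequence_record] objects.
#' @param threshold Identity threshold (default 0.97).
#' @param params [alignment_params].
#' @param k K-mer size of the candidate screen.
#' @param min_kmer_frac Minimum shared-k-mer fraction below which a
#'   representative is skipped without alignment.
#' @return An object of class `cluster_set`: `representatives` (list of
#'   [sequence_record]), `members` (list of read-id vectors) and
#'   `threshold`.
#' @export
greedy_cluster <- function(reads, threshold = 0.97,
                           params = alignment_params(), k = 8L,
                           min_kmer_frac = 0.3) {
  if (!length(reads)) stop("no reads to cluster", call. = FALSE)
  read_seqs <- vapply(reads, `[[`, character(1), "seq")
  read_ids <- vapply(reads, `[[`, character(1), "id")
  tab <- split(read_ids, read_seqs)
  uniq <- data.frame(seq = names(tab), count = lengths(tab),
                     stringsAsFactors = FALSE)
  uniq$first_id <- vapply(tab, `[[`, character(1), 1L)
  ord <- order(-uniq$count, -nchar(uniq$seq), uniq$first_id)
  uniq <- uniq[ord, , drop = FALSE]
  reps <- list()
  rep_kmers <- list()
  members <- list()
  for (r in seq_len(nrow(uniq))) {
    s <- uniq$seq[r]
    skm <- .kmers_of(s, k)
    placed <- FALSE
    for (ci in seq_along(reps)) {
      shared <- sum(skm %in% rep_kmers[[ci]])
      if (shared < min_kmer_frac * max(length(skm), 1L)) next
      aln <- align_semi_global(s, reps[[ci]]$seq, params)
      if (aln$identity >= threshold) {
        members[[ci]] <- c(members[[ci]], tab[[s]])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- sequence_record(uniq$first_id[r], s)
      rep_kmers[[length(rep_kmers) + 1L]] <- skm
      members[[length(members) + 1L]] <- tab[[s]]
    }
  }
  structure(list(representatives = reps, members = members,
                 threshold = threshold), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d clusters over %d reads (threshold %.2f)\n",
              length(x$representatives), sum(lengths(x$members)),
              x$threshold))
  invisible(x)
}

#' Closed-reference assignment of cluster representatives
#'
#' Each representative is assigned by best hit against the database and
#' kept only when its identity reaches the threshold; clusters whose
#' representative fails the gate are discarded (their read counts are
#' dropped and reported). Counts of clusters assigned to the same
#' accession are summed.
#'
#' @param clusters A `cluster_set` from [greedy_cluster].
#' @param db A `reference_db` (lineages are taken from it when present).
#' @param threshold Identity threshold for assignment (default 0.97).
#' @param params [alignment_params].
#' @param sample_name Sample (column) name of the resulting table.
#' @inheritParams classify_reads
#' @return An [otu_table] with one sample; the number of reads discarded
#'   with unassignable clusters is attached as attribute
#'   `n_discarded_reads`.
#' @export
closed_reference_assign <- function(clusters, db, threshold = 0.97,
                                    params = alignment_params(),
                                    sample_name = "sample_1",
                                    prefilter = TRUE, k = 8L, top = 3L) {
  stopifnot(inherits(clusters, "cluster_set"))
  seqs <- as_reference_seqs(db)
  index <- if (prefilter) .kmer_index(seqs, k) else NULL
  counts <- integer(0)
  discarded <- 0L
  for (ci in seq_along(clusters$representatives)) {
    s <- clusters$representatives[[ci]]$seq
    cand <- if (prefilter) .shortlist(.kmers_of(s, k), index, top) else NULL
    hit <- .best_hit(s, seqs, params, cand)
    size <- length(clusters$members[[ci]])
    if (hit$identity >= threshold) {
      counts[hit$accession] <- sum(counts[hit$accession], size, na.rm = TRUE)
    } else {
      discarded <- discarded + size
    }
  }
  if (discarded > 0L) {
    message(discarded, " read(s) in unassignable clusters discarded ",
            "(closed-reference)")
  }
  lineages <- if (inherits(db, "reference_db")) db$lineages else {
    do.call(rbind, lapply(names(counts), function(a)
      taxonomy_lineage(a, UNASSIGNED)))
  }
  mat <- matrix(as.numeric(counts), ncol = 1L,
                dimnames = list(names(counts), sample_name))
  out <- otu_table(mat, lineages)
  attr(out, "n_discarded_reads") <- discarded
  out
}

#' Per-read and per-sample quality statistics
#'
#' The per-read statistic is the arithmetic mean of the per-base Phred
#' integers; sample summaries (mean and median of the per-read means) are
#' computed over reads.
#'
#' @param x A FASTQ path or a list of [sequence_record] objects with
#'   qualities.
#' @return A list with `per_read` (data frame `read_id`, `mean_quality`),
#'   `mean_quality`, `median_quality` and `n_reads`.
#' @export
read_quality_stats <- function(x) {
  reads <- if (is.character(x)) read_fastq(x) else x
  if (!length(reads)) stop("no reads", call. = FALSE)
  means <- vapply(reads, function(r) {
    if (is.null(r$quality)) {
      stop("read '", r$id, "' has no quality scores", call. = FALSE)
    }
    mean(r$quality)
  }, numeric(1))
  list(per_read = data.frame(
         read_id = vapply(reads, `[[`, character(1), "id"),
         mean_quality = means, stringsAsFactors = FALSE),
       mean_quality = mean(means), median_quality = median(means),
       n_reads = length(reads))
}
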