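# Cross-platform concordance and the "recreated dataset" bias audit:
# error-free database sequences of an identified community are pushed back
# through the two classification paths, once full-length and once reduced
# to the short-read V3-V4 target region, and compared to their original
# accessions. Taxa that are byte-identical over V3-V4 but distinct over
# the full gene are exactly the ones the short path cannot separate.

#' Concordant/discordant counts with the percentage identity
#'
#' @param n_total Number of compared sequences.
#' @param n_discordant Number classified into a different taxonomy.
#' @return An object of class `venn_counts` with `n_total`,
#'   `n_concordant`, `n_discordant` and `pct_discordant`
#'   (= 100 * n_discordant / n_total).
#' @export
#' @examples
#' venn_counts(1028, 258)$pct_discordant  # 25.097...
venn_counts <- function(n_total, n_discordant) {
  n_total <- as.integer(n_total)
  n_discordant <- as.integer(n_discordant)
  if (n_total < 1L || n_discordant < 0L || n_discordant > n_total) {
    stop("invalid counts", call. = FALSE)
  }
  structure(list(n_total = n_total,
                 n_concordant = n_total - n_discordant,
                 n_discordant = n_discordant,
                 pct_discordant = 100 * n_discordant / n_total),
            class = "venn_counts")
}

#' @export
print.venn_counts <- function(x, ...) {
  cat(sprintf("<venn_counts> %d/%d discordant (%.2f%%)\n",
              x$n_discordant, x$n_total, x$pct_discordant))
  invisible(x)
}

#' Recreate error-free sequences for a set of identified taxa
#'
#' @param db A `reference_db` or named sequence vector.
#' @param taxon_ids Accessions to recreate; duplicates are collapsed (with
#'   a message), unknown ids are an error.
#' @return A list of [sequence_record] objects, exact database sequences.
#' @export
recreate_reference_reads <- function(db, taxon_ids) {
  seqs <- as_reference_seqs(db)
  if (!length(taxon_ids)) stop("empty taxon id list", call. = FALSE)
  unknown <- setdiff(taxon_ids, names(seqs))
  if (length(unknown)) {
    stop("unknown taxon id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxon_ids)) {
    message(sum(duplicated(taxon_ids)), " duplicate taxon id(s) collapsed")
    taxon_ids <- unique(taxon_ids)
  }
  lapply(taxon_ids, function(a) sequence_record(a, seqs[[a]]))
}

.assignment_key <- function(x) ifelse(is.na(x), UNCLASSIFIED, x)

#' Bias audit of the recreated, error-free dataset
#'
#' Recreates the exact database sequences of `taxon_ids`, optionally cuts
#' them down to the region bracketed by `primer_pair` (the short-read
#' target), re-classifies them via the best-hit path and via the
#' cluster + closed-reference path, and counts sequences whose new
#' assignment differs from their original accession, plus the
#' disagreement between the two paths.
#'
#' @param db A `reference_db`.
#' @param taxon_ids Accessions of the identified community.
#' @param primer_pair `NULL` for full-length sequences, or a list with
#'   `fwd`/`rev` [primer]s to extract the target region first;
#'   non-amplifiable taxa are excluded with a message.
#' @param min_identity Identity gate of the best-hit path.
#' @param cluster_threshold Clustering/assignment threshold of the
#'   cluster path.
#' @param params [alignment_params].
#' @return A list with `best_hit`, `cluster` and `cross` [venn_counts],
#'   `n_unique_after_clustering` (number of post-clustering unique
#'   sequences), and the per-sequence `assignments` data frame.
#' @export
bias_audit <- function(db, taxon_ids, primer_pair = NULL,
                       min_identity = 0.80, cluster_threshold = 0.97,
                       params = alignment_params()) {
  recs <- recreate_reference_reads(db, taxon_ids)
  if (!is.null(primer_pair)) {
    regions <- lapply(recs, function(r) {
      amp <- extract_amplicon(r, primer_pair$fwd, primer_pair$rev)
      if (is.null(amp)) return(NULL)
      sequence_record(r$id, amp$insert)
    })
    dropped <- vapply(regions, is.null, logical(1))
    if (any(dropped)) {
      message(sum(dropped), " taxa not amplifiable by the primer pair, ",
              "excluded: ",
              paste(vapply(recs[dropped], `[[`, character(1), "id"),
                    collapse = ", "))
    }
    recs <- regions[!dropped]
    if (!length(recs)) stop("no amplifiable taxa left", call. = FALSE)
  }
  ids <- vapply(recs, `[[`, character(1), "id")

  best <- classify_reads(recs, db, min_identity = min_identity,
                         params = params)
  clusters <- greedy_cluster(recs, threshold = cluster_threshold,
                             params = params)
  rep_hits <- classify_reads(clusters$representatives, db,
                             min_identity = cluster_threshold,
                             params = params)
  cluster_assign <- rep(NA_character_, length(ids))
  names(cluster_assign) <- ids
  for (ci in seq_along(clusters$members)) {
    cluster_assign[clusters$members[[ci]]] <- rep_hits$accession[ci]
  }

  assignments <- data.frame(
    accession = ids,
    best_hit = best$accession,
    cluster = unname(cluster_assign[ids]),
    stringsAsFactors = FALSE)
  n <- length(ids)
  disc_best <- sum(.assignment_key(assignments$best_hit) != ids)
  disc_clus <- sum(.assignment_key(assignments$cluster) != ids)
  disc_cross <- sum(.assignment_key(assignments$best_hit) !=
                      .assignment_key(assignments$cluster))
  list(best_hit = venn_counts(n, disc_best),
       cluster = venn_counts(n, disc_clus),
       cross = venn_counts(n, disc_cross),
       n_unique_after_clustering = length(clusters$representatives),
       assignments = assignments)
}

#' Merge OTU tables from two platforms
#'
#' Samples are concatenated under platform-suffixed names, the rare-OTU
#' filter zeroes every taxon-sample cell below `min_count` (or, with
#' `filter = "row_sum"`, zeroes whole rows whose per-table total is below
#' `min_count`), and taxa left all-zero are dropped.
#'
#' @param table_a,table_b [otu_table]s sharing the accession namespace.
#' @param min_count Rare-OTU threshold (counts strictly below are
#'   removed).
#' @param suffix_a,suffix_b Suffixes appended to sample names.
#' @param filter `"cell"` (default) or `"row_sum"`.
#' @return The merged [otu_table].
#' @export
merge_platform_tables <- function(table_a, table_b, min_count = 4,
                                  suffix_a = "_A", suffix_b = "_B",
                                  filter = c("cell", "row_sum")) {
  stopifnot(inherits(table_a, "otu_table"), inherits(table_b, "otu_table"))
  filter <- match.arg(filter)
  apply_filter <- function(m) {
    if (filter == "cell") {
      m[m < min_count] <- 0
    } else {
      m[rowSums(m) < min_count, ] <- 0
    }
    m
  }
  a <- apply_filter(table_a$counts)
  b <- apply_filter(table_b$counts)
  colnames(a) <- paste0(colnames(a), suffix_a)
  colnames(b) <- paste0(colnames(b), suffix_b)
  samples <- c(colnames(a), colnames(b))
  if (anyDuplicated(samples)) {
    stop("duplicate sample names after suffixing", call. = FALSE)
  }
  taxa <- union(rownames(a), rownames(b))
  merged <- matrix(0, length(taxa), length(samples),
                   dimnames = list(taxa, samples))
  merged[rownames(a), colnames(a)] <- a
  merged[rownames(b), colnames(b)] <- b
  merged <- merged[rowSums(merged) > 0, , drop = FALSE]
  lineages <- rbind(table_a$lineages,
                    table_b$lineages[!(table_b$lineages$accession %in%
                                         table_a$lineages$accession), ,
                                     drop = FALSE])
  otu_table(merged, lineages)
}

#' Aggregate an OTU table at a taxonomic rank
#'
#' Counts are summed over taxa sharing the rank label (the "unassigned"
#' sentinel is kept as its own row) and normalized to relative abundance
#' per sample.
#'
#' @param table An [otu_table].
#' @param rank One of domain, phylum, class, order, family, genus,
#'   species.
#' @return An object of class `rank_abundance_table`: `rank` and
#'   `abundance`, a labels x samples matrix whose columns sum to 1.
#' @export
aggregate_rank <- function(table, rank) {
  stopifnot(inherits(table, "otu_table"))
  rank <- match.arg(rank, RANK_NAMES)
  if (nrow(table$counts) == 0L) stop("empty OTU table", call. = FALSE)
  totals <- colSums(table$counts)
  if (any(totals == 0)) {
    stop("sample(s) with zero total count: ",
         paste(colnames(table$counts)[totals == 0], collapse = ", "),
         call. = FALSE)
  }
  labels <- table$lineages[[rank]]
  summed <- rowsum(table$counts, group = labels)
  abundance <- sweep(summed, 2L, totals, "/")
  structure(list(rank = rank, abundance = abundance),
            class = "rank_abundance_table")
}

#' @export
print.rank_abundance_table <- function(x, ...) {
  cat(sprintf("<rank_abundance_table> %s: %d taxa x %d samples\n",
              x$rank, nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Spearman's rank correlation
#'
#' Average ranks for ties; equal to the Pearson correlation of the rank
#' vectors.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @return Rho in `[-1, 1]`, or `NA` (with a warning) when either vector
#'   is constant.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("constant vector: Spearman's rho is not computable")
    return(NA_real_)
  }
  cor(x, y, method = "spearman")
}

#' Per-rank Spearman correlation between platforms
#'
#' For each rank the merged table is aggregated, mean relative abundance
#' is taken within each platform's sample group, and Spearman's rho is
#' computed across all taxa present in either platform (absent taxa count
#' as 0 through the shared aggregation).
#'
#' @param merged A merged [otu_table].
#' @param samples_a,samples_b Sample names of the two platforms.
#' @param ranks Ranks to evaluate (default class through species).
#' @return Named numeric vector of rho per rank; `NA` where fewer than 3
#'   taxa exist at that rank.
#' @export
cross_platform_correlation <- function(merged, samples_a, samples_b,
                                       ranks = RANK_NAMES[3:7]) {
  stopifnot(inherits(merged, "otu_table"))
  if (!length(samples_a) || !length(samples_b)) {
    stop("both platform sample groups must be non-empty", call. = FALSE)
  }
  missing <- setdiff(c(samples_a, samples_b), otu_samples(merged))
  if (length(missing)) {
    stop("unknown sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vapply(ranks, function(rank) {
    agg <- aggregate_rank(merged, rank)$abundance
    if (nrow(agg) < 3L) return(NA_real_)
    mean_a <- rowMeans(agg[, samples_a, drop = FALSE])
    mean_b <- rowMeans(agg[, samples_b, drop = FALSE])
    suppressWarnings(spearman_rho(mean_a, mean_b))
  }, numeric(1))
}

#' Relative-abundance heatmap matrices across analysis paths
#'
#' For each rank, aggregates every table to overall relative abundance
#' (summed across its samples), keeps the taxa reaching `min_pct` percent
#' in at least one table, and reports percentages.
#'
#' @param tables Named list of [otu_table]s (e.g. original, cluster-path,
#'   best-hit-path).
#' @param ranks Ranks to emit (default order through species).
#' @param min_pct Inclusion threshold in percent.
#' @return A named list (per rank) of taxa x table percentage matrices.
#' @export
abundance_change_heatmap <- function(tables, ranks = RANK_NAMES[4:7],
                                     min_pct = 0.5) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  lapply(setNames(ranks, ranks), function(rank) {
    cols <- lapply(tables, function(t) {
      labels <- t$lineages[[rank]]
      tot <- rowsum(matrix(rowSums(t$counts), ncol = 1L), group = labels)
      setNames(100 * tot[, 1L] / sum(tot), rownames(tot))
    })
    taxa <- sort(unique(unlist(lapply(cols, names))))
    m <- matrix(0, length(taxa), length(tables),
                dimnames = list(taxa, names(tables)))
    for (j in seq_along(cols)) m[names(cols[[j]]), j] <- cols[[j]]
    m[apply(m, 1L, max) >= min_pct, , drop = FALSE]
  })
}

#' Taxa unique to one platform among highly similar reads
#'
#' For each representative sequence of platform A, reads of platform B
#' with identity at or above the threshold are collected; a taxonomy is
#' reported as unique to A when its representative has such near-identical
#' matches but its accession never occurs among the matched reads'
#' assignments.
#'
#' @param representatives Named character vector: accession (as assigned
#'   on platform A) -> representative sequence.
#' @param reads List of platform-B [sequence_record] objects.
#' @param read_assignments Named character vector read id -> accession on
#'   platform B (`NA` for unclassified).
#' @param identity_threshold Similarity cut-off (default 0.97).
#' @param params [alignment_params].
#' @return Sorted character vector of accessions unique to platform A.
#' @export
unique_taxa_by_similarity <- function(representatives, reads,
                                      read_assignments,
                                      identity_threshold = 0.97,
                                      params = alignment_params()) {
  if (!length(representatives) || !length(reads)) {
    stop("representatives and reads must be non-empty", call. = FALSE)
  }
  read_ids <- vapply(reads, `[[`, character(1), "id")
  unique_acc <- character(0)
  for (acc in unique(names(representatives))) {
    rep_seq <- representatives[[acc]]
    idents <- vapply(reads, function(r) {
      align_semi_global(rep_seq, r$seq, params)$identity
    }, numeric(1))
    matched <- read_ids[idents >= identity_threshold]
    if (!length(matched)) next
    their <- .assignment_key(read_assignments[matched])
    if (!(acc %in% their)) unique_acc <- c(unique_acc, acc)
  }
  sort(unique(unique_acc))
}
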