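# The OTU table is the pipeline's central exchange object: a taxa x samples
# count matrix with a 7-rank lineage per taxon. On disk it is a TSV with an
# "accession" column, one column per sample, and a semicolon-joined lineage
# as the final column.

#' Construct an OTU table
#'
#' @param counts Non-negative integer matrix, rows named by taxon
#'   accessions, columns by sample names.
#' @param lineages Data frame with columns `accession` and the 7 ranks
#'   (as from [parse_taxonomy_map]); must cover every taxon in `counts`.
#' @return An object of class `otu_table`.
#' @export
otu_table <- function(counts, lineages) {
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must have taxon rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate taxon accession in counts", call. = FALSE)
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample name in counts", call. = FALSE)
  }
  storage.mode(counts) <- "double"
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  missing <- setdiff(rownames(counts), lineages$accession)
  if (length(missing)) {
    stop("taxa without lineage entry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lineages <- lineages[match(rownames(counts), lineages$accession),
                       c("accession", RANK_NAMES), drop = FALSE]
  rownames(lineages) <- lineages$accession
  structure(list(counts = counts, lineages = lineages), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("<otu_table> %d taxa x %d samples, %s total counts\n",
              nrow(x$counts), ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Taxa and sample accessors for OTU tables
#'
#' @param table An [otu_table].
#' @return Character vector of taxon accessions or sample names.
#' @export
otu_taxa <- function(table) {
  rn <- rownames(table$counts)
  if (is.null(rn)) character(0) else rn
}

#' @rdname otu_taxa
#' @export
otu_samples <- function(table) colnames(table$counts)

#' Write an OTU table as TSV
#'
#' @param table An [otu_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(table, path) {
  stopifnot(inherits(table, "otu_table"))
  lineage_str <- apply(table$lineages[, RANK_NAMES, drop = FALSE], 1L,
                       paste, collapse = ";")
  df <- data.frame(accession = otu_taxa(table),
                   table$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df$lineage <- if (nrow(df)) unname(lineage_str) else character(0)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an OTU table from TSV
#'
#' @param path Path to a TSV written by [write_otu_table].
#' @return An [otu_table].
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (!identical(names(df)[1L], "accession") ||
      !identical(names(df)[length(df)], "lineage")) {
    stop("OTU table must have 'accession' first and 'lineage' last",
         call. = FALSE)
  }
  sample_names <- names(df)[-c(1L, length(df))]
  counts <- matrix(0, nrow = nrow(df), ncol = length(sample_names),
                   dimnames = list(df$accession, sample_names))
  for (j in seq_along(sample_names)) {
    vals <- suppressWarnings(as.numeric(df[[j + 1L]]))
    bad <- which(is.na(vals) | vals != round(vals))
    if (length(bad)) {
      stop(sprintf("malformed count '%s' at row %d, column '%s'",
                   df[[j + 1L]][bad[1L]], bad[1L], sample_names[j]),
           call. = FALSE)
    }
    neg <- which(vals < 0)
    if (length(neg)) {
      stop(sprintf("negative count at row %d, column '%s'", neg[1L],
                   sample_names[j]), call. = FALSE)
    }
    counts[, j] <- vals
  }
  ranks <- strsplit(df$lineage, ";", fixed = TRUE)
  lineages <- if (nrow(df)) {
    do.call(rbind, Map(taxonomy_lineage, df$accession, ranks))
  } else {
    empty <- data.frame(accession = character(0))
    for (r in RANK_NAMES) empty[[r]] <- character(0)
    empty
  }
  otu_table(counts, lineages)
}
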