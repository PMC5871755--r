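# MAF (multiple alignment format) parsing for pairwise alignment blocks as
# emitted by long-read aligners: one "a" line per block followed by exactly
# two "s" lines, reference first, query second. Coordinates are converted to
# the package-wide convention (0-based, half-open, forward strand) at the
# boundary; minus-strand query intervals are flipped here and nowhere else.

#' Construct a pairwise alignment record
#'
#' @param query_id,ref_id Sequence identifiers.
#' @param aligned_query,aligned_ref Equal-length gapped strings (`-` gaps).
#' @param score Alignment score.
#' @param query_span,ref_span Integer length-2 vectors, 0-based half-open
#'   intervals on the forward strand of the ungapped sequences.
#' @param strand `"+"` or `"-"` (strand of the query relative to the
#'   reference).
#' @return An object of class `pairwise_alignment_record`.
#' @export
pairwise_alignment_record <- function(query_id, ref_id, aligned_query,
                                      aligned_ref, score, query_span,
                                      ref_span, strand = "+") {
  if (nchar(aligned_query) != nchar(aligned_ref)) {
    stop("gapped query and reference strings differ in length",
         call. = FALSE)
  }
  qc <- strsplit(aligned_query, "", fixed = TRUE)[[1L]]
  rc <- strsplit(aligned_ref, "", fixed = TRUE)[[1L]]
  if (any(qc == "-" & rc == "-")) {
    stop("alignment column with a gap in both rows", call. = FALSE)
  }
  if (sum(qc != "-") != query_span[2L] - query_span[1L]) {
    stop("query span inconsistent with ungapped aligned query length",
         call. = FALSE)
  }
  if (sum(rc != "-") != ref_span[2L] - ref_span[1L]) {
    stop("reference span inconsistent with ungapped aligned reference length",
         call. = FALSE)
  }
  stopifnot(strand %in% c("+", "-"))
  structure(list(query_id = query_id, ref_id = ref_id,
                 aligned_query = aligned_query, aligned_ref = aligned_ref,
                 score = score,
                 query_span = as.integer(query_span),
                 ref_span = as.integer(ref_span), strand = strand),
            class = "pairwise_alignment_record")
}

.parse_maf_s_line <- function(line, lineno) {
  fields <- strsplit(trimws(line), "\\s+")[[1L]]
  if (length(fields) != 7L) {
    stop("MAF line ", lineno, ": expected 7 fields in 's' line",
         call. = FALSE)
  }
  list(src = fields[2L], start = as.integer(fields[3L]),
       size = as.integer(fields[4L]), strand = fields[5L],
       src_size = as.integer(fields[6L]), text = toupper(fields[7L]))
}

#' Parse a MAF file of pairwise alignment blocks
#'
#' Each block must contain a score (`a`) line and exactly two sequence
#' (`s`) lines, the reference first and the query second. Minus-strand
#' query coordinates are converted to forward-strand 0-based half-open
#' intervals (`start_fwd = src_size - start - size`).
#'
#' @param path Path to a MAF file.
#' @return A list of [pairwise_alignment_record] objects; empty list for an
#'   empty file.
#' @export
parse_maf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  records <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (!startsWith(line, "a")) {
      i <- i + 1L
      next
    }
    score <- NA_real_
    m <- regmatches(line, regexec("score=([-0-9.eE+]+)", line))[[1L]]
    if (length(m) == 2L) score <- as.numeric(m[2L])
    s_lines <- integer(0)
    j <- i + 1L
    while (j <= n && !startsWith(lines[j], "a")) {
      if (startsWith(lines[j], "s ")) s_lines <- c(s_lines, j)
      j <- j + 1L
    }
    if (length(s_lines) != 2L) {
      stop("MAF block starting at line ", i, " has ", length(s_lines),
           " sequence lines (expected 2)", call. = FALSE)
    }
    ref <- .parse_maf_s_line(lines[s_lines[1L]], s_lines[1L])
    qry <- .parse_maf_s_line(lines[s_lines[2L]], s_lines[2L])
    if (nchar(ref$text) != nchar(qry$text)) {
      stop("MAF block starting at line ", i,
           ": aligned rows differ in length", call. = FALSE)
    }
    to_forward <- function(s) {
      if (s$strand == "-") {
        c(s$src_size - s$start - s$size, s$src_size - s$start)
      } else {
        c(s$start, s$start + s$size)
      }
    }
    records[[length(records) + 1L]] <- pairwise_alignment_record(
      query_id = qry$src, ref_id = ref$src,
      aligned_query = qry$text, aligned_ref = ref$text, score = score,
      query_span = to_forward(qry), ref_span = to_forward(ref),
      strand = qry$strand)
    i <- j
  }
  records
}
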