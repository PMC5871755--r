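# FASTA / FASTQ input and output. Parsing is delegated to Biostrings; the
# wrappers enforce the package's validation contract (unique ids, IUPAC
# alphabet with error positions, Phred+33 qualities).

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of [sequence_record] objects, input order preserved,
#'   sequences uppercased. The record id is the first whitespace-delimited
#'   token of the header.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) {
                    stop("malformed FASTA file '", path, "': ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  Map(function(id, s) sequence_record(id, s), ids, unname(seqs),
      USE.NAMES = FALSE)
}

#' Write sequence records as FASTA
#'
#' @param records List of [sequence_record] objects.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  lines <- unlist(lapply(records, function(r) {
    n <- nchar(r$seq)
    starts <- seq(1L, n, by = width)
    c(paste0(">", r$id), substring(r$seq, starts, pmin(starts + width - 1L, n)))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33)
#'
#' @param path Path to a FASTQ file with 4-line records.
#' @return A list of [sequence_record] objects with integer Phred qualities.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  n_lines <- length(grep(".", readLines(path, warn = FALSE)))
  if (n_lines %% 4L != 0L) {
    stop("truncated FASTQ file '", path, "': ", n_lines,
         " lines is not a multiple of 4", call. = FALSE)
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      stop("malformed or truncated FASTQ file '", path, "': ",
           conditionMessage(e), call. = FALSE)
    })
  if (length(set) == 0L) stop("empty FASTQ file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate read id(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  quals <- as.character(S4Vectors::mcols(set)$qualities)
  Map(function(id, s, q) {
    if (nchar(s) != nchar(q)) {
      stop(sprintf("record '%s': sequence/quality length mismatch", id),
           call. = FALSE)
    }
    sequence_record(id, s, string_to_phred(q))
  }, ids, unname(seqs), unname(quals), USE.NAMES = FALSE)
}

#' Write sequence records as FASTQ (Phred+33)
#'
#' @param records List of [sequence_record] objects; all must carry
#'   qualities.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  lines <- unlist(lapply(records, function(r) {
    if (is.null(r$quality)) {
      stop("record '", r$id, "' has no quality scores", call. = FALSE)
    }
    c(paste0("@", r$id), r$seq, "+", phred_to_string(r$quality))
  }))
  writeLines(lines, path)
  invisible(path)
}
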