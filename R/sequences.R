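# Nucleotide alphabet, sequence records and small string utilities shared by
# every module. Sequences are stored as plain uppercase character strings;
# qualities as integer Phred vectors (Phred+33 on disk).

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"

# expansion of each IUPAC code into the concrete bases it stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_COMPLEMENT <- c(
  A = "T", C = "G", G = "C", T = "A",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B", N = "N"
)

RANK_NAMES <- c("domain", "phylum", "class", "order", "family", "genus",
                "species")
UNASSIGNED <- "unassigned"

.check_alphabet <- function(seq, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), seq)
  if (bad > 0L) {
    stop(sprintf("invalid character '%s' in %s at position %d",
                 substr(seq, bad, bad), what, bad), call. = FALSE)
  }
  invisible(TRUE)
}

#' Create a sequence record
#'
#' A sequence record couples an identifier with an uppercase IUPAC
#' nucleotide string and, optionally, per-base Phred quality scores.
#' It is the unit all read and reference handling works on.
#'
#' @param id Character identifier.
#' @param seq Nucleotide string (A/C/G/T plus IUPAC ambiguity codes).
#' @param quality Optional integer vector of per-base Phred scores, same
#'   length as `seq`.
#' @return An object of class `sequence_record`.
#' @export
#' @examples
#' sequence_record("read1", "ACGT", c(30L, 30L, 30L, 30L))
sequence_record <- function(id, seq, quality = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id),
            is.character(seq), length(seq) == 1L)
  if (!nzchar(seq)) stop("sequence must be non-empty", call. = FALSE)
  seq <- toupper(seq)
  .check_alphabet(seq, sprintf("sequence '%s'", id))
  if (!is.null(quality)) {
    quality <- as.integer(quality)
    if (length(quality) != nchar(seq)) {
      stop(sprintf("record '%s': quality length %d != sequence length %d",
                   id, length(quality), nchar(seq)), call. = FALSE)
    }
    if (any(quality < 0L)) stop("Phred scores must be >= 0", call. = FALSE)
  }
  structure(list(id = id, seq = seq, quality = quality),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s (%d nt%s)\n", x$id, nchar(x$seq),
              if (is.null(x$quality)) "" else ", with quality"))
  invisible(x)
}

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC alphabet (e.g. the complement of R is Y).
#'
#' @param seq Nucleotide string.
#' @return The reverse complement string.
#' @export
#' @examples
#' revcomp("ACGTR")
revcomp <- function(seq) {
  stopifnot(is.character(seq))
  comp <- chartr(paste(names(IUPAC_COMPLEMENT), collapse = ""),
                 paste(IUPAC_COMPLEMENT, collapse = ""),
                 toupper(seq))
  vapply(comp, function(s) rawToChar(rev(charToRaw(s))), character(1),
         USE.NAMES = FALSE)
}

# Phred+33 helpers -----------------------------------------------------------

phred_to_string <- function(q) intToUtf8(as.integer(q) + 33L)

string_to_phred <- function(s) utf8ToInt(s) - 33L

# run code with a temporary RNG seed, restoring the caller's stream
with_seed <- function(seed, code) {
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a global seed
#'
#' Every stochastic stage of the pipeline draws its own substream seed
#' from the single global seed and a stage name, so one knob controls all
#' randomness while stages stay independent. The result always fits a
#' 32-bit integer.
#'
#' @param seed Global integer seed.
#' @param stage Stage name string.
#' @return An integer seed in `[0, 2^31)`.
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage))) %% 100003
  as.integer((as.numeric(seed) %% 2147483647 * 1009 + h * 2411 + 1) %%
               2147483647)
}
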