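# SILVA-style two-column taxonomy maps: accession <TAB> semicolon-delimited
# lineage. Lineages are padded to the seven canonical ranks with the
# sentinel "unassigned" so that rank aggregation can group on it explicitly.

#' Construct a 7-rank taxonomy lineage
#'
#' @param accession Accession string (SILVA style, e.g. "EU328076.1.1447").
#' @param ranks Character vector of up to 7 rank names
#'   (domain, phylum, class, order, family, genus, species); shorter
#'   vectors are padded with `"unassigned"`.
#' @return A one-row data frame with columns `accession` and the 7 ranks.
#' @export
taxonomy_lineage <- function(accession, ranks) {
  stopifnot(is.character(accession), length(accession) == 1L,
            nzchar(accession))
  ranks <- trimws(as.character(ranks))
  ranks <- ranks[nzchar(ranks)]
  if (length(ranks) == 0L) {
    stop("empty lineage for accession '", accession, "'", call. = FALSE)
  }
  if (length(ranks) > 7L) {
    stop("lineage for '", accession, "' has more than 7 ranks",
         call. = FALSE)
  }
  ranks <- c(ranks, rep(UNASSIGNED, 7L - length(ranks)))
  out <- data.frame(accession = accession, t(ranks),
                    stringsAsFactors = FALSE)
  names(out) <- c("accession", RANK_NAMES)
  out
}

#' Parse a SILVA-style taxonomy map
#'
#' Each non-empty line must be `accession<TAB>rank1;rank2;...`. Lineages
#' shorter than 7 ranks are padded with `"unassigned"`.
#'
#' @param path Path to the taxonomy TSV.
#' @return A data frame with columns `accession`, `domain`, ..., `species`;
#'   one row per accession.
#' @export
parse_taxonomy_map <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty taxonomy map: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("taxonomy map line ", bad[1L], " has no tab separator",
         call. = FALSE)
  }
  acc <- trimws(vapply(parts, `[[`, character(1), 1L))
  dup <- acc[duplicated(acc)]
  if (length(dup)) {
    stop("duplicate accession(s) in taxonomy map: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  rows <- Map(function(a, p) taxonomy_lineage(a, strsplit(p[[2L]], ";")[[1L]]),
              acc, parts)
  out <- do.call(rbind, unname(rows))
  rownames(out) <- out$accession
  out
}

#' Write a taxonomy map in the SILVA-style two-column dialect
#'
#' The "unassigned" padding sentinel is trimmed from the tail of each
#' lineage on output, so a parse/write cycle is lossless.
#'
#' @param lineages Data frame as returned by [parse_taxonomy_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_taxonomy_map <- function(lineages, path) {
  stopifnot(all(c("accession", RANK_NAMES) %in% names(lineages)))
  lines <- vapply(seq_len(nrow(lineages)), function(i) {
    ranks <- as.character(lineages[i, RANK_NAMES])
    keep <- max(c(1L, which(ranks != UNASSIGNED)))
    paste0(lineages$accession[i], "\t",
           paste(ranks[seq_len(keep)], collapse = ";"))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
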