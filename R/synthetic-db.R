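# Synthetic full-length 16S-like reference databases. Each taxon is a
# ~1.4 kb sequence laid out as conserved blocks interleaved with nine
# variable regions (V1..V9). Both primer pairs' binding sites sit in
# conserved blocks with zero mismatches to the degenerate primers, so the
# long-read amplicon spans the whole gene and the short-read amplicon spans
# V3-V4 (440 bp including primers, 2 x 250 reads overlap by 60).
# "Confusable groups" are sets of taxa engineered to be byte-identical over
# the whole V3-V4 amplicon while diverging freely elsewhere -- the feature
# that makes short-read classification ambiguous but leaves full-length
# classification unambiguous.

#' Construct a primer
#'
#' @param name Primer name.
#' @param seq IUPAC string, possibly degenerate (R, Y, W, N, ...).
#' @return An object of class `primer`.
#' @export
primer <- function(name, seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("primer sequence must be non-empty", call. = FALSE)
  .check_alphabet(seq, sprintf("primer '%s'", name))
  structure(list(name = name, seq = seq), class = "primer")
}

#' The primer pairs used throughout the package
#'
#' The long-read pair (S-D-bact-0008-c-S20 / S-D-bact-1391-a-A-17) brackets
#' the near-full-length gene (V1-V9); the short-read pair is the V3-V4
#' locus-specific pair with library overhang adapters already trimmed
#' (overhangs do not bind the template, so only the 3' locus-specific parts
#' are ever matched).
#'
#' @return A list with elements `long` and `short`, each a list of `fwd`
#'   and `rev` [primer] objects.
#' @export
default_primers <- function() {
  list(
    long = list(
      fwd = primer("S-D-bact-0008-c-S20", "AGRGTTYGATYMTGGCTCAG"),
      rev = primer("S-D-bact-1391-a-A-17", "GACGGGCGGTGWGTRCA")),
    short = list(
      fwd = primer("Bakt_341F", "CCTACGGGNGGCWGCAG"),
      rev = primer("Bakt_805R", "GACTACHVGGGTATCTAATCC")))
}

# one fixed concretization of a degenerate primer (first base of each set)
concretize_primer <- function(seq) {
  chartr("RYSWKMBDHVN", "ACGAGACAAAA", toupper(seq))
}

# fixed coordinate layout of the synthetic gene (0-based half-open)
.synthetic_layout <- function() {
  segs <- list(
    c("primer_long_fwd", 20L), c("C1", 50L), c("V1", 90L), c("C2", 50L),
    c("V2", 90L), c("C3", 30L), c("primer_short_fwd", 17L),
    c("C4", 10L), c("V3", 170L), c("C5", 40L), c("V4", 172L),
    c("C6", 10L), c("primer_short_rev_rc", 21L), c("C7", 50L),
    c("V5", 80L), c("C8", 40L), c("V6", 80L), c("C9", 40L),
    c("V7", 80L), c("C10", 40L), c("V8", 80L), c("C11", 40L),
    c("V9", 80L), c("C12", 30L), c("primer_long_rev_rc", 17L))
  name <- vapply(segs, `[[`, character(1), 1L)
  len <- as.integer(vapply(segs, `[[`, character(1), 2L))
  end <- cumsum(len)
  data.frame(name = name, start = end - len, end = end,
             variable = grepl("^V[0-9]$", name), stringsAsFactors = FALSE)
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.synthetic_lineage <- function(i) {
  taxonomy_lineage(
    sprintf("SYN%05d.1.1427", i),
    c("Bacteria",
      sprintf("Phylum%d", (i - 1L) %/% 16L + 1L),
      sprintf("Class%d", (i - 1L) %/% 8L + 1L),
      sprintf("Order%d", (i - 1L) %/% 4L + 1L),
      sprintf("Family%d", (i - 1L) %/% 2L + 1L),
      sprintf("Genus%d", i),
      sprintf("Genus%d sp%d", i, i)))
}

#' Build a synthetic full-length reference database
#'
#' Generates `n_taxa` full-length sequences on a shared conserved scaffold
#' (identical conserved blocks and exact primer sites across taxa) with
#' independent random variable regions per taxon. The first
#' `n_confusable_groups * group_size` taxa are partitioned into groups
#' whose members share a byte-identical V3-V4 amplicon region but have
#' independent sequence everywhere else.
#'
#' @param n_taxa Number of taxa (>= 2).
#' @param n_confusable_groups Number of groups with identical V3-V4.
#' @param group_size Members per confusable group.
#' @param seed Integer seed; the database is a pure function of the
#'   arguments.
#' @return An object of class `reference_db`: a list with `sequences`
#'   (named character), `lineages` (7-rank data frame), `regions`
#'   (coordinate layout, shared by all taxa), `confusable_group` (named
#'   character, `NA` for ungrouped taxa) and `primers`.
#' @export
#' @examples
#' db <- build_reference_db(6, n_confusable_groups = 1, group_size = 2,
#'                          seed = 1)
build_reference_db <- function(n_taxa, n_confusable_groups = 0L,
                               group_size = 2L, seed = 1L) {
  n_taxa <- as.integer(n_taxa)
  n_confusable_groups <- as.integer(n_confusable_groups)
  group_size <- as.integer(group_size)
  if (n_taxa < 2L) stop("n_taxa must be >= 2", call. = FALSE)
  if (n_confusable_groups < 0L || group_size < 2L) {
    stop("invalid confusable-group parameters", call. = FALSE)
  }
  if (n_confusable_groups * group_size > n_taxa) {
    stop("n_confusable_groups * group_size exceeds n_taxa", call. = FALSE)
  }
  layout <- .synthetic_layout()
  primers <- default_primers()
  fixed <- list(
    primer_long_fwd = concretize_primer(primers$long$fwd$seq),
    primer_short_fwd = concretize_primer(primers$short$fwd$seq),
    primer_short_rev_rc = revcomp(concretize_primer(primers$short$rev$seq)),
    primer_long_rev_rc = revcomp(concretize_primer(primers$long$rev$seq)))
  # pad the 20 nt slot: the long forward primer itself is 20 nt
  stopifnot(nchar(fixed$primer_long_fwd) == 20L)

  with_seed(seed, {
    lens <- layout$end - layout$start
    conserved <- lapply(seq_len(nrow(layout)), function(k) {
      nm <- layout$name[k]
      if (nm %in% names(fixed)) fixed[[nm]]
      else if (!layout$variable[k]) .random_dna(lens[k])
      else NA_character_
    })
    group_of <- rep(NA_character_, n_taxa)
    if (n_confusable_groups > 0L) {
      idx <- seq_len(n_confusable_groups * group_size)
      group_of[idx] <- sprintf("group%02d",
                               rep(seq_len(n_confusable_groups),
                                   each = group_size))
    }
    # shared V3/V4 material per confusable group
    shared_v <- lapply(seq_len(max(n_confusable_groups, 0L)), function(g) {
      list(V3 = .random_dna(lens[layout$name == "V3"]),
           V4 = .random_dna(lens[layout$name == "V4"]))
    })
    seqs <- vapply(seq_len(n_taxa), function(i) {
      pieces <- vapply(seq_len(nrow(layout)), function(k) {
        nm <- layout$name[k]
        if (!layout$variable[k]) return(conserved[[k]])
        if (!is.na(group_of[i]) && nm %in% c("V3", "V4")) {
          g <- as.integer(sub("group", "", group_of[i]))
          return(shared_v[[g]][[nm]])
        }
        .random_dna(lens[k])
      }, character(1))
      paste(pieces, collapse = "")
    }, character(1))
  })

  lineages <- do.call(rbind, lapply(seq_len(n_taxa), .synthetic_lineage))
  rownames(lineages) <- lineages$accession
  names(seqs) <- lineages$accession
  names(group_of) <- lineages$accession
  structure(list(sequences = seqs, lineages = lineages, regions = layout,
                 confusable_group = group_of, primers = primers,
                 seed = as.integer(seed)),
            class = "reference_db")
}

#' @export
print.reference_db <- function(x, ...) {
  n_grp <- length(unique(stats::na.omit(x$confusable_group)))
  cat(sprintf("<reference_db> %d taxa of %d nt, %d confusable group(s)\n",
              length(x$sequences), nchar(x$sequences[[1L]]), n_grp))
  invisible(x)
}

# normalize the various db representations to a named character vector
as_reference_seqs <- function(db) {
  if (inherits(db, "reference_db")) return(db$sequences)
  if (is.character(db) && !is.null(names(db))) return(db)
  if (is.list(db) && all(vapply(db, inherits, logical(1), "sequence_record"))) {
    return(setNames(vapply(db, `[[`, character(1), "seq"),
                    vapply(db, `[[`, character(1), "id")))
  }
  stop("db must be a reference_db, a named character vector, or a list of ",
       "sequence records", call. = FALSE)
}

#' Sample a community abundance profile from a reference database
#'
#' @param db A `reference_db` (or named sequence vector).
#' @param model `"even"` (equal abundances), `"staggered"` (log-spaced
#'   abundances spanning 3 orders of magnitude) or `"lognormal"`.
#' @param n_taxa Number of taxa to include (<= database size).
#' @param seed Integer seed (taxon choice and abundance assignment).
#' @param sample_name Name attached to the profile.
#' @return An object of class `community_profile`: a list with
#'   `composition` (named abundances summing to 1) and `sample_name`.
#' @export
sample_community <- function(db, model = c("even", "staggered", "lognormal"),
                             n_taxa, seed = 1L, sample_name = "sample_1") {
  model <- match.arg(model)
  seqs <- as_reference_seqs(db)
  n_taxa <- as.integer(n_taxa)
  if (n_taxa < 1L || n_taxa > length(seqs)) {
    stop("n_taxa must be between 1 and the database size (",
         length(seqs), ")", call. = FALSE)
  }
  with_seed(seed, {
    taxa <- sample(names(seqs), n_taxa)
    ab <- switch(model,
      even = rep(1, n_taxa),
      staggered = 10 ^ seq(0, -3, length.out = n_taxa),
      lognormal = rlnorm(n_taxa, meanlog = 0, sdlog = 1.5))
  })
  ab <- ab / sum(ab)
  structure(list(composition = setNames(ab, taxa),
                 sample_name = sample_name, model = model),
            class = "community_profile")
}

#' @export
print.community_profile <- function(x, ...) {
  cat(sprintf("<community_profile> '%s': %d taxa (%s model)\n",
              x$sample_name, length(x$composition), x$model))
  invisible(x)
}
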