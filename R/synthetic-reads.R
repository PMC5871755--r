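# Platform read simulators. Reads are simulated from PCR amplicons (not
# genomes): the long platform emits single reads spanning the whole
# primer-to-primer amplicon (V1-V9) with a nanopore-like error process, the
# short platform emits 2 x read_length mate pairs from the V3-V4 amplicon
# with a low substitution-only error rate. Every generator is a pure
# function of (inputs, seed).

#' Read simulation configuration
#'
#' The long-read defaults encode a total per-base error of 5.4%
#' (substitution:insertion:deletion = 10:2.5:1), the error probability
#' implied by a mean Phred quality of 12.65 (Q = -10 log10 p), with emitted
#' qualities drawn around that mean. Short-read defaults are 2 x 250 with
#' 0.3% substitutions and qualities around Q35.
#'
#' @param platform `"long_single"` or `"short_paired"`.
#' @param n_reads Number of reads (or read pairs).
#' @param sub_rate,ins_rate,del_rate Per-base error probabilities in
#'   `[0, 1)`; their sum must stay below 0.5.
#' @param read_length Read length for the short platform.
#' @param quality_mean,quality_sd Per-base emitted Phred model.
#' @param seed Integer seed.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(platform = c("long_single", "short_paired"),
                            n_reads = 1000L,
                            sub_rate = NULL, ins_rate = NULL, del_rate = NULL,
                            read_length = 250L,
                            quality_mean = NULL, quality_sd = 3,
                            seed = 1L) {
  platform <- match.arg(platform)
  defaults <- if (platform == "long_single") {
    list(sub = 0.04, ins = 0.01, del = 0.004, qmean = 12.65)
  } else {
    list(sub = 0.003, ins = 0, del = 0, qmean = 35)
  }
  sub_rate <- if (is.null(sub_rate)) defaults$sub else sub_rate
  ins_rate <- if (is.null(ins_rate)) defaults$ins else ins_rate
  del_rate <- if (is.null(del_rate)) defaults$del else del_rate
  quality_mean <- if (is.null(quality_mean)) defaults$qmean else quality_mean
  rates <- c(sub_rate, ins_rate, del_rate)
  if (any(rates < 0) || any(rates >= 1) || sum(rates) >= 0.5) {
    stop("error rates must lie in [0, 1) and sum to < 0.5", call. = FALSE)
  }
  n_reads <- as.integer(n_reads)
  if (n_reads < 1L) stop("n_reads must be > 0", call. = FALSE)
  structure(list(platform = platform, n_reads = n_reads,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate, read_length = as.integer(read_length),
                 quality_mean = quality_mean, quality_sd = quality_sd,
                 seed = as.integer(seed)),
            class = "read_sim_config")
}

# apply the substitution/insertion/deletion process to one sequence
.mutate_sequence <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate == 0 && ins_rate == 0 && del_rate == 0) return(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(b)
  bases <- c("A", "C", "G", "T")
  del <- runif(n) < del_rate
  sub <- runif(n) < sub_rate & !del
  if (any(sub)) {
    # substitute with a uniformly chosen different base
    cur <- b[sub]
    repl <- vapply(cur, function(x) sample(setdiff(bases, x), 1L),
                   character(1), USE.NAMES = FALSE)
    b[sub] <- repl
  }
  b[del] <- ""
  ins <- runif(n) < ins_rate
  pre <- character(n)
  if (any(ins)) pre[ins] <- sample(bases, sum(ins), replace = TRUE)
  paste0(paste0(pre, b, collapse = ""), "")
}

.emit_quality <- function(len, qmean, qsd) {
  q <- as.integer(round(rnorm(len, qmean, qsd)))
  pmin(pmax(q, 1L), 41L)
}

.amplicons_for_profile <- function(db, profile, primer_pair,
                                   keep_primers = TRUE) {
  seqs <- as_reference_seqs(db)
  taxa <- names(profile$composition)
  missing <- setdiff(taxa, names(seqs))
  if (length(missing)) {
    stop("profile taxa not in database: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  amps <- lapply(taxa, function(a) {
    amp <- extract_amplicon(sequence_record(a, seqs[[a]]),
                            primer_pair$fwd, primer_pair$rev)
    if (is.null(amp)) {
      stop("taxon '", a, "' lacks primer sites for the requested amplicon",
           call. = FALSE)
    }
    if (keep_primers) amp$full else amp$insert
  })
  setNames(unlist(amps), taxa)
}

#' Simulate long single-end reads from a community
#'
#' Reads are drawn multinomially from the community profile; each read is
#' the full primer-to-primer amplicon of its source taxon passed through
#' the configured substitution/insertion/deletion process, with per-base
#' qualities drawn from the quality model.
#'
#' @param db A `reference_db` (or named sequence vector).
#' @param profile A `community_profile`.
#' @param config A `read_sim_config` with `platform = "long_single"`.
#' @param out_fastq Optional path; when given the reads are written there.
#' @return A list with `reads` (list of [sequence_record]) and
#'   `provenance` (data frame `read_id`, `accession`).
#' @export
simulate_long_reads <- function(db, profile, config, out_fastq = NULL) {
  stopifnot(inherits(config, "read_sim_config"))
  if (config$platform != "long_single") {
    stop("config platform must be 'long_single'", call. = FALSE)
  }
  primers <- if (inherits(db, "reference_db")) db$primers else
    default_primers()
  amps <- .amplicons_for_profile(db, profile, primers$long)
  taxa <- names(profile$composition)
  with_seed(config$seed, {
    counts <- as.vector(rmultinom(1L, config$n_reads,
                                  profile$composition))
    src <- rep(taxa, counts)
    reads <- vector("list", length(src))
    for (i in seq_along(src)) {
      s <- .mutate_sequence(amps[[src[i]]], config$sub_rate,
                            config$ins_rate, config$del_rate)
      reads[[i]] <- sequence_record(
        sprintf("long_%06d", i), s,
        .emit_quality(nchar(s), config$quality_mean, config$quality_sd))
    }
  })
  provenance <- data.frame(
    read_id = vapply(reads, `[[`, character(1), "id"),
    accession = src, stringsAsFactors = FALSE)
  if (!is.null(out_fastq)) write_fastq(reads, out_fastq)
  list(reads = reads, provenance = provenance)
}

#' Simulate short paired-end reads of the V3-V4 amplicon
#'
#' For each read pair, R1 is the first `read_length` bases of the V3-V4
#' amplicon (primers included) and R2 the reverse complement of its last
#' `read_length` bases, each passed independently through the error
#' process.
#'
#' @inheritParams simulate_long_reads
#' @param config A `read_sim_config` with `platform = "short_paired"`.
#' @param out_fastq_r1,out_fastq_r2 Optional FASTQ output paths.
#' @return A list with `r1`, `r2` (lists of [sequence_record]) and
#'   `provenance`.
#' @export
simulate_short_paired_reads <- function(db, profile, config,
                                        out_fastq_r1 = NULL,
                                        out_fastq_r2 = NULL) {
  stopifnot(inherits(config, "read_sim_config"))
  if (config$platform != "short_paired") {
    stop("config platform must be 'short_paired'", call. = FALSE)
  }
  primers <- if (inherits(db, "reference_db")) db$primers else
    default_primers()
  amps <- .amplicons_for_profile(db, profile, primers$short)
  taxa <- names(profile$composition)
  L <- config$read_length
  with_seed(config$seed, {
    counts <- as.vector(rmultinom(1L, config$n_reads,
                                  profile$composition))
    src <- rep(taxa, counts)
    r1 <- vector("list", length(src))
    r2 <- vector("list", length(src))
    for (i in seq_along(src)) {
      amp <- amps[[src[i]]]
      n <- nchar(amp)
      len <- min(L, n)
      fwd <- .mutate_sequence(substr(amp, 1L, len), config$sub_rate,
                              config$ins_rate, config$del_rate)
      rev <- .mutate_sequence(revcomp(substr(amp, n - len + 1L, n)),
                              config$sub_rate, config$ins_rate,
                              config$del_rate)
      id <- sprintf("short_%06d", i)
      r1[[i]] <- sequence_record(id, fwd,
        .emit_quality(nchar(fwd), config$quality_mean, config$quality_sd))
      r2[[i]] <- sequence_record(id, rev,
        .emit_quality(nchar(rev), config$quality_mean, config$quality_sd))
    }
  })
  provenance <- data.frame(
    read_id = vapply(r1, `[[`, character(1), "id"),
    accession = src, stringsAsFactors = FALSE)
  if (!is.null(out_fastq_r1)) write_fastq(r1, out_fastq_r1)
  if (!is.null(out_fastq_r2)) write_fastq(r2, out_fastq_r2)
  list(r1 = r1, r2 = r2, provenance = provenance)
}

#' Merge one mate pair by overlap
#'
#' Scans overlap lengths between the 3' end of R1 and the 5' end of the
#' reverse-complemented R2 and picks the candidate with the lowest
#' mismatch fraction (ties broken towards the longest overlap). Bases that
#' disagree inside the overlap are resolved to the higher-quality mate.
#'
#' @param r1,r2 [sequence_record] mates (R2 as sequenced, i.e. reverse
#'   strand).
#' @param min_overlap Minimum acceptable overlap length.
#' @param max_mismatch_frac Maximum mismatch fraction inside the overlap.
#' @return A merged [sequence_record], or `NULL` when no overlap
#'   qualifies (failure is a return state, not an error).
#' @export
merge_paired_reads <- function(r1, r2, min_overlap = 20L,
                               max_mismatch_frac = 0.1) {
  stopifnot(inherits(r1, "sequence_record"), inherits(r2, "sequence_record"))
  s1 <- charToRaw(r1$seq)
  s2 <- charToRaw(revcomp(r2$seq))
  q1 <- r1$quality
  q2 <- if (is.null(r2$quality)) NULL else rev(r2$quality)
  n1 <- length(s1); n2 <- length(s2)
  if (min(n1, n2) < min_overlap) return(NULL)
  best <- NULL
  for (o in seq(min(n1, n2), min_overlap)) {
    a <- s1[(n1 - o + 1L):n1]
    b <- s2[1L:o]
    mm <- sum(a != b)
    frac <- mm / o
    if (frac <= max_mismatch_frac &&
        (is.null(best) || frac < best$frac)) {
      best <- list(o = o, frac = frac)
      if (mm == 0L) break
    }
  }
  if (is.null(best)) return(NULL)
  o <- best$o
  ov1 <- (n1 - o + 1L):n1
  ov2 <- 1L:o
  take2 <- if (is.null(q1) || is.null(q2)) rep(FALSE, o) else
    q2[ov2] > q1[ov1]
  cons <- s1[ov1]
  cons[take2] <- s2[ov2][take2]
  merged_seq <- rawToChar(c(s1[seq_len(n1 - o)], cons,
                            s2[seq.int(o + 1L, length.out = n2 - o)]))
  merged_q <- if (is.null(q1) || is.null(q2)) NULL else
    c(q1[seq_len(n1 - o)], pmax(q1[ov1], q2[ov2]),
      q2[seq.int(o + 1L, length.out = n2 - o)])
  sequence_record(r1$id, merged_seq, merged_q)
}

#' Merge lists of mate pairs
#'
#' @param reads1,reads2 Lists of [sequence_record] mates in matching order.
#' @inheritParams merge_paired_reads
#' @return A list with `merged` (successfully merged records) and
#'   `failed` (ids of pairs with no qualifying overlap).
#' @export
merge_read_pairs <- function(reads1, reads2, min_overlap = 20L,
                             max_mismatch_frac = 0.1) {
  stopifnot(length(reads1) == length(reads2))
  merged <- list()
  failed <- character(0)
  for (i in seq_along(reads1)) {
    m <- merge_paired_reads(reads1[[i]], reads2[[i]], min_overlap,
                            max_mismatch_frac)
    if (is.null(m)) failed <- c(failed, reads1[[i]]$id)
    else merged[[length(merged) + 1L]] <- m
  }
  list(merged = merged, failed = failed)
}
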