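# Configuration-driven end-to-end orchestration: synthetic database and
# two communities -> platform read simulation -> both classification
# paths -> merged table -> concordance -> phylogenetic diversity ->
# perMANOVA, with every random draw derived from one global seed via
# per-stage substreams.

#' Default pipeline configuration
#'
#' All thresholds of the analysis in one place: the 80% long-read
#' identity gate, the 97% clustering threshold, the rare-OTU count
#' filter (< 4 removed), the 0.5% heatmap inclusion threshold, the
#' UniFrac variants and the perMANOVA permutation count.
#'
#' @param seed Global seed; every stochastic stage derives its own
#'   substream from it.
#' @return A nested list of class `pipeline_config`.
#' @export
default_config <- function(seed = 42L) {
  structure(list(
    general = list(seed = as.integer(seed)),
    reference = list(n_taxa = 20, n_confusable_groups = 4, group_size = 2),
    community = list(model = "staggered", n_taxa = 12),
    reads = list(n_long = 2000, n_short = 2000, read_length = 250),
    thresholds = list(min_identity = 0.80, cluster_identity = 0.97,
                      rare_count = 4, heatmap_min_pct = 0.5),
    permanova = list(n_permutations = 999)),
    class = "pipeline_config")
}

.config_types <- function(x) {
  if (is.character(x) && length(x) == 1L) {
    if (x %in% c("TRUE", "FALSE")) return(as.logical(x))
    num <- suppressWarnings(as.numeric(x))
    if (!is.na(num)) return(num)
  }
  x
}

#' Parse a plain-text key-value pipeline configuration
#'
#' Sections are `[name]` headers; entries are `key = value` lines;
#' `#` starts a comment. Values that parse as numbers or TRUE/FALSE are
#' typed accordingly.
#'
#' @param path Path to a config file.
#' @return A `pipeline_config` list of sections.
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  config <- list()
  section <- NULL
  for (line in lines) {
    if (grepl("^\\[.*\\]$", line)) {
      section <- gsub("^\\[|\\]$", "", line)
      config[[section]] <- list()
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(section)) {
        stop("config entry before any [section]: ", line, call. = FALSE)
      }
      kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
      key <- trimws(kv[1L])
      value <- trimws(paste(kv[-1L], collapse = "="))
      config[[section]][[key]] <- .config_types(value)
    } else {
      stop("unparseable config line: ", line, call. = FALSE)
    }
  }
  structure(config, class = "pipeline_config")
}

#' Serialize a pipeline configuration
#'
#' Inverse of [parse_config]: `serialize_config(parse_config(f))`
#' reproduces the configuration.
#'
#' @param config A `pipeline_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
serialize_config <- function(config, path) {
  lines <- character(0)
  for (section in names(config)) {
    lines <- c(lines, sprintf("[%s]", section))
    for (key in names(config[[section]])) {
      v <- config[[section]][[key]]
      lines <- c(lines, sprintf("%s = %s", key,
                                paste(format(v, digits = 15),
                                      collapse = ", ")))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

validate_config <- function(config) {
  need <- c("general", "reference", "community", "reads", "thresholds",
            "permanova")
  missing <- setdiff(need, names(config))
  if (length(missing)) {
    stop("config missing section(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  th <- config$thresholds
  if (th$min_identity <= 0 || th$min_identity > 1 ||
      th$cluster_identity <= 0 || th$cluster_identity > 1) {
    stop("identity thresholds must lie in (0, 1]", call. = FALSE)
  }
  if (is.null(config$general$seed)) {
    stop("config must carry a global seed", call. = FALSE)
  }
  invisible(config)
}

#' Generate the bundled synthetic fixture set
#'
#' A 20-taxon reference database with 4 confusable V3-V4 pairs, two
#' community profiles, and 2,000 reads per sample on each platform
#' (2 x 2 platform/sample grid), written as FASTA/FASTQ/TSV.
#'
#' @param seed Global seed.
#' @param outdir Output directory (created).
#' @param n_reads Reads per sample on each platform.
#' @return Invisibly, a list with the `db`, the two profiles and the
#'   output paths.
#' @export
make_fixtures <- function(seed = 42L, outdir = tempfile("fixtures"),
                          n_reads = 2000L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  db <- build_reference_db(20, n_confusable_groups = 4, group_size = 2,
                           seed = derive_seed(seed, "db"))
  profiles <- list(
    community_A = sample_community(db, "staggered", 12,
                                   seed = derive_seed(seed, "community_A"),
                                   sample_name = "community_A"),
    community_B = sample_community(db, "staggered", 12,
                                   seed = derive_seed(seed, "community_B"),
                                   sample_name = "community_B"))
  paths <- list(
    db_fasta = file.path(outdir, "reference_db.fasta"),
    taxonomy = file.path(outdir, "reference_taxonomy.tsv"))
  write_fasta(Map(sequence_record, names(db$sequences),
                  unname(db$sequences)), paths$db_fasta)
  write_taxonomy_map(db$lineages, paths$taxonomy)
  reads <- list()
  for (nm in names(profiles)) {
    long_cfg <- read_sim_config("long_single", n_reads = n_reads,
                                seed = derive_seed(seed,
                                                   paste0("long_", nm)))
    short_cfg <- read_sim_config("short_paired", n_reads = n_reads,
                                 seed = derive_seed(seed,
                                                    paste0("short_", nm)))
    paths[[paste0(nm, "_long")]] <- file.path(outdir,
                                              paste0(nm, "_long.fastq"))
    paths[[paste0(nm, "_r1")]] <- file.path(outdir, paste0(nm, "_R1.fastq"))
    paths[[paste0(nm, "_r2")]] <- file.path(outdir, paste0(nm, "_R2.fastq"))
    reads[[nm]] <- list(
      long = simulate_long_reads(db, profiles[[nm]], long_cfg,
                                 out_fastq = paths[[paste0(nm, "_long")]]),
      short = simulate_short_paired_reads(
        db, profiles[[nm]], short_cfg,
        out_fastq_r1 = paths[[paste0(nm, "_r1")]],
        out_fastq_r2 = paths[[paste0(nm, "_r2")]]))
    write.table(reads[[nm]]$long$provenance,
                file.path(outdir, paste0(nm, "_long_provenance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(reads[[nm]]$short$provenance,
                file.path(outdir, paste0(nm, "_short_provenance.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(db = db, profiles = profiles, reads = reads,
                 paths = paths, outdir = outdir))
}

.classify_sample_long <- function(reads, db, min_identity, params) {
  hits <- classify_reads(reads, db, min_identity = min_identity,
                         params = params)
  assigned <- hits$accession[!is.na(hits$accession)]
  counts <- table(assigned)
  mat <- matrix(as.numeric(counts), ncol = 1L,
                dimnames = list(names(counts), "sample"))
  list(table = otu_table(mat, db$lineages), hits = hits)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages in dependency order: reference simulation, read
#' simulation for two communities on both platforms, long-read best-hit
#' classification, short-read merge + cluster + closed-reference
#' assignment, platform table merging with the rare-OTU filter, per-rank
#' cross-platform correlation, the recreated-dataset bias audit,
#' NJ tree + midpoint rooting on alignment distances, UniFrac matrices,
#' PCoA and perMANOVA. All tabular outputs are written under `outdir`
#' together with a manifest; a rerun with the same config is
#' byte-identical.
#'
#' @param config A `pipeline_config` (see [default_config]); a path to a
#'   config file is also accepted.
#' @param outdir Output directory.
#' @return Invisibly, a list with the main result objects.
#' @export
run_pipeline <- function(config = default_config(),
                         outdir = tempfile("amplicross_run")) {
  if (is.character(config)) config <- parse_config(config)
  validate_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$general$seed
  params <- alignment_params()
  manifest <- list(config = unclass(config), stages = list())
  log_stage <- function(name, ...) {
    message("[amplicross] stage: ", name)
    manifest$stages[[name]] <<- list(...)
  }

  # 1. reference + communities + reads
  log_stage("simulate", seed = derive_seed(seed, "db"))
  fx <- make_fixtures(seed = seed, outdir = file.path(outdir, "fixtures"),
                      n_reads = config$reads$n_long)
  db <- fx$db

  # 2. long-read classification per community
  log_stage("classify_long")
  long_tables <- list()
  for (nm in names(fx$profiles)) {
    res <- .classify_sample_long(fx$reads[[nm]]$long$reads, db,
                                 config$thresholds$min_identity, params)
    colnames(res$table$counts) <- nm
    long_tables[[nm]] <- res$table
    write.table(res$hits,
                file.path(outdir, paste0("classify_long_", nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  long_table <- merge_platform_tables(long_tables[[1L]], long_tables[[2L]],
                                      min_count = 0, suffix_a = "",
                                      suffix_b = "")

  # 3. short-read path: merge pairs, cluster, closed-reference
  log_stage("cluster_short")
  short_tables <- list()
  for (nm in names(fx$profiles)) {
    pairs <- fx$reads[[nm]]$short
    merged_reads <- merge_read_pairs(pairs$r1, pairs$r2)
    clusters <- greedy_cluster(merged_reads$merged,
                               threshold = config$thresholds$cluster_identity,
                               params = params)
    tab <- closed_reference_assign(
      clusters, db, threshold = config$thresholds$cluster_identity,
      params = params, sample_name = nm)
    short_tables[[nm]] <- tab
  }
  short_table <- merge_platform_tables(short_tables[[1L]],
                                       short_tables[[2L]], min_count = 0,
                                       suffix_a = "", suffix_b = "")

  # 4. merged cross-platform table with the rare-OTU filter
  log_stage("merge")
  merged <- merge_platform_tables(short_table, long_table,
                                  min_count = config$thresholds$rare_count,
                                  suffix_a = "_illumina_like",
                                  suffix_b = "_nanopore_like")
  write_otu_table(merged, file.path(outdir, "merged_otu_table.tsv"))

  # 5. concordance: per-rank correlation + bias audit
  log_stage("concordance")
  rho <- cross_platform_correlation(
    merged,
    samples_a = grep("_illumina_like$", otu_samples(merged), value = TRUE),
    samples_b = grep("_nanopore_like$", otu_samples(merged), value = TRUE))
  write.table(data.frame(rank = names(rho), spearman_rho = rho),
              file.path(outdir, "cross_platform_rho.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  audit <- bias_audit(db, otu_taxa(merged),
                      primer_pair = db$primers$short,
                      min_identity = config$thresholds$min_identity,
                      cluster_threshold = config$thresholds$cluster_identity,
                      params = params)
  write.table(audit$assignments,
              file.path(outdir, "bias_audit_assignments.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # 6. diversity: tree, UniFrac, PCoA, perMANOVA
  log_stage("diversity")
  taxa <- otu_taxa(merged)
  dm <- matrix(0, length(taxa), length(taxa),
               dimnames = list(taxa, taxa))
  for (i in seq_along(taxa)) {
    for (j in seq_len(i - 1L)) {
      aln <- align_semi_global(db$sequences[[taxa[i]]],
                               db$sequences[[taxa[j]]], params)
      dm[i, j] <- dm[j, i] <- 1 - aln$identity
    }
  }
  tree <- midpoint_root(nj_tree(dm))
  writeLines(write_newick(tree), file.path(outdir, "reference_tree.nwk"))
  unifrac <- unifrac_matrix(merged, tree)
  for (v in names(unifrac)) {
    write.table(unifrac[[v]],
                file.path(outdir, paste0("unifrac_", v, ".tsv")),
                sep = "\t", quote = FALSE)
  }
  ord <- pcoa(unifrac$d_W)
  write.table(ord$coordinates, file.path(outdir, "pcoa_weighted.tsv"),
              sep = "\t", quote = FALSE)
  groups <- sub("_(illumina|nanopore)_like$", "", otu_samples(merged))
  perm <- permanova(unifrac$d_W, groups,
                    n_permutations = config$permanova$n_permutations,
                    seed = derive_seed(seed, "permanova"))

  # 7. rarefaction on the long-read community tables
  log_stage("rarefaction")
  total <- min(colSums(long_table$counts))
  depths <- unique(pmax(1L, round(seq(1, total, length.out = 10L))))
  rare <- rarefaction_curve(long_table$counts[, 1L], depths,
                            n_reps = 10L,
                            seed = derive_seed(seed, "rarefaction"))

  manifest$outputs <- list.files(outdir, recursive = TRUE)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(db = db, merged = merged, long_table = long_table,
                 short_table = short_table, rho = rho, audit = audit,
                 tree = tree, unifrac = unifrac, pcoa = ord,
                 permanova = perm, rarefaction = rare, outdir = outdir))
}
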