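make_lineages <- function(accs, genus = NULL, family = NULL) {
  do.call(rbind, lapply(seq_along(accs), function(i) {
    taxonomy_lineage(accs[i],
                     c("Bacteria", "P",
                       paste0("C", ceiling(i / 2)),
                       paste0("O", ceiling(i / 2)),
                       if (is.null(family)) paste0("F", i) else family[i],
                       if (is.null(genus)) paste0("G", i) else genus[i],
                       paste0("sp", i)))
  }))
}

test_that("venn counts keep their arithmetic identity", {
  v <- venn_counts(20, 4)
  expect_equal(v$n_concordant, 16L)
  expect_equal(v$pct_discordant, 20)
  expect_equal(v$n_concordant + v$n_discordant, v$n_total)
  for (i in 1:20) {
    n <- sample(10:2000, 1L)
    k <- sample(0:n, 1L)
    v <- venn_counts(n, k)
    expect_equal(v$pct_discordant, 100 * k / n)
  }
  expect_error(venn_counts(10, 11), "invalid")
})

test_that("recreated reads are exact database sequences", {
  db <- db_small()
  ids <- names(db$sequences)
  recs <- recreate_reference_reads(db, ids)
  expect_length(recs, length(ids))
  expect_equal(vapply(recs, `[[`, "", "seq"), unname(db$sequences))
  expect_message(recs2 <- recreate_reference_reads(db, c(ids[1L], ids[1L])),
                 "duplicate")
  expect_length(recs2, 1L)
  expect_error(recreate_reference_reads(db, "nope"), "unknown.*nope")
  expect_error(recreate_reference_reads(db, character(0)), "empty")
})

test_that("bias audit is clean when every V3-V4 region is unique", {
  db <- db_small()  # no confusable groups
  audit <- bias_audit(db, names(db$sequences),
                      primer_pair = db$primers$short)
  expect_equal(audit$best_hit$n_discordant, 0L)
  expect_equal(audit$cluster$n_discordant, 0L)
  expect_equal(audit$cross$n_discordant, 0L)
  expect_equal(audit$n_unique_after_clustering, length(db$sequences))
})

test_that("bias audit discordance grows with confusable groups", {
  discord <- vapply(c(0L, 2L, 4L), function(g) {
    db <- build_reference_db(20, n_confusable_groups = g, group_size = 2,
                             seed = 1)
    bias_audit(db, names(db$sequences),
               primer_pair = db$primers$short)$best_hit$n_discordant
  }, integer(1))
  expect_equal(discord, c(0L, 2L, 4L))
})

test_that("platform table merging applies the rare-OTU filter", {
  lin <- make_lineages(c("t1", "t2", "t3", "t4"))
  a <- otu_table(matrix(c(5, 3, 3, 10, 3, 2, 2, 12), 4L, 2L,
                        dimnames = list(c("t1", "t2", "t3", "t4"),
                                        c("s1", "s2"))), lin)
  b <- otu_table(matrix(c(7, 0), 1L, 2L,
                        dimnames = list("t4", c("s1", "s2"))), lin)
  m <- merge_platform_tables(a, b, min_count = 4)
  # cells < 4 zeroed: t1 = (5, 3) -> (5, 0)
  expect_equal(unname(m$counts["t1", c("s1_A", "s2_A")]), c(5, 0))
  # taxa below threshold everywhere are dropped
  expect_false("t2" %in% otu_taxa(m))
  expect_true(all(c("s1_A", "s2_A", "s1_B", "s2_B") %in% otu_samples(m)))
  # absent taxa fill with zero
  expect_equal(unname(m$counts["t1", "s1_B"]), 0)

  # row-sum variant keeps rows whose per-table total reaches the cut
  m2 <- merge_platform_tables(a, b, min_count = 4, filter = "row_sum")
  expect_equal(unname(m2$counts["t2", "s1_A"]), 3)

  expect_error(merge_platform_tables(a, a, suffix_a = "", suffix_b = ""),
               "duplicate sample names")
})

test_that("rank aggregation preserves per-sample totals", {
  lin <- make_lineages(c("t1", "t2", "t3"),
                       genus = c("G1", "G1", "G2"))
  tab <- otu_table(matrix(c(3, 1, 4), 3L, 1L,
                          dimnames = list(c("t1", "t2", "t3"), "s1")), lin)
  g <- aggregate_rank(tab, "genus")
  expect_equal(unname(g$abundance["G1", "s1"]), 0.5)
  sp <- aggregate_rank(tab, "species")
  expect_equal(unname(sp$abundance[c("sp1", "sp2"), "s1"]),
               c(0.375, 0.125))
  for (rank in c("domain", "phylum", "class", "order", "family",
                 "genus", "species")) {
    expect_equal(unname(colSums(aggregate_rank(tab, rank)$abundance)), 1)
  }
  # an all-unassigned rank collapses to a single full-weight row
  lin2 <- rbind(taxonomy_lineage("u1", "Bacteria"),
                taxonomy_lineage("u2", "Bacteria"))
  tab2 <- otu_table(matrix(c(2, 3), 2L, 1L,
                           dimnames = list(c("u1", "u2"), "s1")), lin2)
  agg2 <- aggregate_rank(tab2, "genus")
  expect_equal(nrow(agg2$abundance), 1L)
  expect_equal(unname(agg2$abundance["unassigned", "s1"]), 1)
})

test_that("Spearman's rho handles ties by average ranks", {
  expect_equal(spearman_rho(1:5, 1:5), 1)
  expect_equal(spearman_rho(1:5, 5:1), -1)
  # hand computation: ranks (1, 2.5, 2.5, 4) vs (1, 3, 2, 4)
  expect_equal(spearman_rho(c(1, 2, 2, 4), c(1, 3, 2, 4)),
               1.5 / sqrt(1.5 * 5 / 3))
  expect_warning(r <- spearman_rho(rep(1, 4), 1:4), "constant")
  expect_true(is.na(r))
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("cross-platform correlation is 1 for identical platforms", {
  lin <- make_lineages(sprintf("t%d", 1:6))
  counts <- matrix(rpois(12, 40) + 1, 6L, 2L,
                   dimnames = list(sprintf("t%d", 1:6), c("s1", "s2")))
  tab <- otu_table(counts, lin)
  m <- merge_platform_tables(tab, tab, min_count = 0,
                             suffix_a = "_ill", suffix_b = "_min")
  rho <- cross_platform_correlation(
    m, samples_a = c("s1_ill", "s2_ill"),
    samples_b = c("s1_min", "s2_min"))
  expect_equal(unname(rho), rep(1, 5L), tolerance = 1e-12)
})

test_that("cross-platform correlation is centred near 0 for independent tables", {
  set.seed(61)
  accs <- sprintf("t%d", 1:12)
  lin <- make_lineages(accs)
  rhos <- replicate(40, {
    mk <- function(s) otu_table(
      matrix(rpois(12, 30) + 1, 12L, 1L, dimnames = list(accs, s)), lin)
    m <- merge_platform_tables(mk("x"), mk("x"), min_count = 0,
                               suffix_a = "_a", suffix_b = "_b")
    cross_platform_correlation(m, "x_a", "x_b", ranks = "species")
  })
  expect_lt(abs(mean(rhos)), 0.2)
})

test_that("heatmap matrices apply the 0.5% inclusion threshold", {
  lin <- make_lineages(c("t1", "t2", "t3"))
  mk <- function(c1, c2, c3) otu_table(
    matrix(c(c1, c2, c3), 3L, 1L,
           dimnames = list(c("t1", "t2", "t3"), "s")), lin)
  tabs <- list(original = mk(600, 397, 3), other = mk(600, 396, 4))
  hm <- abundance_change_heatmap(tabs, ranks = "species", min_pct = 0.5)
  m <- hm$species
  # sp3 sits at 0.3/0.4%: excluded everywhere
  expect_false("sp3" %in% rownames(m))
  expect_equal(m["sp1", "original"], 60)
  # identical tables give identical columns
  hm2 <- abundance_change_heatmap(list(a = tabs$original,
                                       b = tabs$original),
                                  ranks = "species")
  expect_equal(hm2$species[, "a"], hm2$species[, "b"])
})

test_that("confusable-pair collapse concentrates abundance in the winner", {
  db <- db20()
  ids <- names(db$sequences)
  audit <- bias_audit(db, ids, primer_pair = db$primers$short)
  # in each confusable pair the cluster path assigns both members to the
  # lexicographically smaller accession
  pair1 <- ids[db$confusable_group == "group01" &
                 !is.na(db$confusable_group)]
  assigned <- audit$assignments$cluster[audit$assignments$accession %in%
                                          pair1]
  expect_equal(unique(assigned), min(pair1))

  counts_original <- setNames(rep(10, length(ids)), ids)
  tab_original <- otu_table(
    matrix(counts_original, ncol = 1L, dimnames = list(ids, "s")),
    db$lineages)
  collapsed <- table(audit$assignments$cluster) * 10
  tab_cluster <- otu_table(
    matrix(as.numeric(collapsed), ncol = 1L,
           dimnames = list(names(collapsed), "s")), db$lineages)
  hm <- abundance_change_heatmap(list(original = tab_original,
                                      cluster = tab_cluster),
                                 ranks = "species", min_pct = 0.5)
  winner_species <- db$lineages[min(pair1), "species"]
  loser_species <- db$lineages[setdiff(pair1, min(pair1)), "species"]
  expect_equal(hm$species[winner_species, "cluster"],
               hm$species[winner_species, "original"] +
                 hm$species[loser_species, "original"])
})

test_that("taxa unique to one platform are detected via 97% similarity", {
  db <- db20()
  ids <- names(db$sequences)
  pair <- ids[db$confusable_group == "group01" & !is.na(db$confusable_group)]
  primers <- db$primers$short
  region <- function(acc) extract_amplicon(
    sequence_record(acc, db$sequences[[acc]]),
    primers$fwd, primers$rev)$full
  # platform A (short) has representatives for both pair members; platform
  # B (long) assigned every read to the first member only
  reps <- setNames(c(region(pair[1L]), region(pair[2L])), pair)
  reads_b <- list(sequence_record("m1", db$sequences[[pair[1L]]]),
                  sequence_record("m2", db$sequences[[pair[1L]]]))
  assign_b <- c(m1 = pair[1L], m2 = pair[1L])
  uniq <- unique_taxa_by_similarity(reps, reads_b, assign_b)
  expect_equal(uniq, pair[2L])
  # identically classified platforms: nothing unique
  uniq2 <- unique_taxa_by_similarity(reps[1L], reads_b, assign_b)
  expect_length(uniq2, 0L)
})
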