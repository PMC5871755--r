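test_that("reference databases are deterministic and carry exact primer sites", {
  db1 <- build_reference_db(10, seed = 7)
  db2 <- build_reference_db(10, seed = 7)
  expect_identical(db1$sequences, db2$sequences)
  db3 <- build_reference_db(10, seed = 8)
  expect_false(identical(db1$sequences, db3$sequences))

  primers <- db1$primers
  vp_long <- virtual_pcr_table(db1, primers$long$fwd, primers$long$rev, 0)
  vp_short <- virtual_pcr_table(db1, primers$short$fwd, primers$short$rev, 0)
  expect_true(all(vp_long$fwd_mismatches == 0L))
  expect_true(all(vp_long$rev_mismatches == 0L))
  expect_true(all(vp_short$amplifiable))

  expect_error(build_reference_db(5, n_confusable_groups = 3,
                                  group_size = 2),
               "exceeds n_taxa")
})

test_that("confusable groups share V3-V4 exactly and diverge elsewhere", {
  db <- db20()
  primers <- db$primers$short
  amp <- function(i) {
    extract_amplicon(sequence_record(names(db$sequences)[i],
                                     db$sequences[[i]]),
                     primers$fwd, primers$rev)$full
  }
  groups <- split(seq_along(db$sequences),
                  db$confusable_group[names(db$sequences)])
  for (g in groups) {
    expect_identical(amp(g[1L]), amp(g[2L]))
    # full-length members remain clearly distinct (>= 3% divergence)
    aln <- align_semi_global(db$sequences[[g[1L]]], db$sequences[[g[2L]]])
    expect_lt(aln$identity, 0.97)
  }
  # taxa outside a shared group are distinguishable over V3-V4
  expect_false(identical(amp(1L), amp(3L)))
  expect_false(identical(amp(9L), amp(10L)))
  # and pairwise full-length identity stays below the 97% OTU threshold
  pairs <- list(c(1L, 3L), c(5L, 12L), c(9L, 20L))
  for (p in pairs) {
    aln <- align_semi_global(db$sequences[[p[1L]]], db$sequences[[p[2L]]])
    expect_lt(aln$identity, 0.97)
  }
})

test_that("community profiles follow the requested abundance model", {
  db <- db_small()
  even <- sample_community(db, "even", 4, seed = 1)
  expect_equal(unname(even$composition), rep(0.25, 4L))
  stag <- sample_community(db, "staggered", 4, seed = 1)
  expect_gte(max(stag$composition) / min(stag$composition), 1000 * (1 - 1e-9))
  expect_equal(sum(stag$composition), 1, tolerance = 1e-9)
  logn <- sample_community(db, "lognormal", 6, seed = 2)
  expect_equal(sum(logn$composition), 1, tolerance = 1e-9)
  expect_true(all(logn$composition > 0))
  expect_error(sample_community(db, "even", 99), "between 1 and")
})

test_that("zero-error long reads reproduce their source amplicon exactly", {
  db <- db_small()
  prof <- sample_community(db, "even", 4, seed = 5)
  cfg <- read_sim_config("long_single", n_reads = 40, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 11)
  sim <- simulate_long_reads(db, prof, cfg)
  for (i in seq_along(sim$reads)) {
    src <- db$sequences[[sim$provenance$accession[i]]]
    expect_true(grepl(sim$reads[[i]]$seq, src, fixed = TRUE))
  }
})

test_that("the long-read error process hits its configured error rate", {
  db <- db_small()
  prof <- sample_community(db, "even", 4, seed = 5)
  cfg <- read_sim_config("long_single", n_reads = 80, seed = 13)
  expect_equal(cfg$sub_rate + cfg$ins_rate + cfg$del_rate, 0.054)
  sim <- simulate_long_reads(db, prof, cfg)
  per_read <- mapply(function(r, acc) {
    src <- db$sequences[[acc]]
    utils::adist(r$seq, src) / nchar(src)
  }, sim$reads, sim$provenance$accession)
  se <- sd(per_read) / sqrt(length(per_read))
  expect_lt(abs(mean(per_read) - 0.054), 3 * se + 1e-3)
  # emitted qualities track the nanopore-like quality model
  qs <- read_quality_stats(sim$reads)
  expect_equal(qs$mean_quality, 12.65, tolerance = 0.05)
})

test_that("long-read sampling is multinomial in the community profile", {
  db <- db_small()
  prof <- sample_community(db, "even", 4, seed = 5)
  cfg <- read_sim_config("long_single", n_reads = 10000, sub_rate = 0,
                         ins_rate = 0, del_rate = 0, seed = 17)
  sim <- simulate_long_reads(db, prof, cfg)
  counts <- table(factor(sim$provenance$accession,
                         levels = names(prof$composition)))
  # multinomial 99% CI around 2,500
  half <- qnorm(0.995) * sqrt(10000 * 0.25 * 0.75)
  expect_true(all(abs(counts - 2500) <= half))
})

test_that("short mate pairs overlap by the amplicon arithmetic and merge", {
  db <- db_small()
  prof <- sample_community(db, "even", 3, seed = 5)
  cfg <- read_sim_config("short_paired", n_reads = 30, sub_rate = 0,
                         seed = 19)
  sim <- simulate_short_paired_reads(db, prof, cfg)
  # amplicon 440, reads 250 -> 60-base overlap; merged length 440
  merged <- merge_read_pairs(sim$r1, sim$r2)
  expect_length(merged$failed, 0L)
  lens <- vapply(merged$merged, function(r) nchar(r$seq), numeric(1))
  expect_true(all(lens == 440L))
  # zero error: the merged pair reconstructs the amplicon exactly
  primers <- db$primers$short
  for (i in seq_along(merged$merged)) {
    acc <- sim$provenance$accession[i]
    amp <- extract_amplicon(sequence_record(acc, db$sequences[[acc]]),
                            primers$fwd, primers$rev)$full
    expect_identical(merged$merged[[i]]$seq, amp)
  }
})

test_that("read simulation is byte-deterministic given the seed", {
  db <- db_small()
  prof <- sample_community(db, "even", 3, seed = 5)
  cfg <- read_sim_config("short_paired", n_reads = 25, seed = 23)
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  g1 <- withr::local_tempfile(fileext = ".fastq")
  g2 <- withr::local_tempfile(fileext = ".fastq")
  simulate_short_paired_reads(db, prof, cfg, f1, f2)
  simulate_short_paired_reads(db, prof, cfg, g1, g2)
  expect_identical(readLines(f1), readLines(g1))
  expect_identical(readLines(f2), readLines(g2))
})

test_that("pair merging resolves conflicts by quality and can fail", {
  # construct mates with a known 30-base overlap and one disagreement
  left <- random_dna(40)
  overlap <- random_dna(30)
  right <- random_dna(40)
  amplicon <- paste0(left, overlap, right)
  r1_seq <- substr(amplicon, 1, 70)
  r2_fwd <- substr(amplicon, 41, 110)
  # mismatch inside the overlap at forward position 50: R1 keeps the
  # truth with quality 40, R2 carries the error with quality 10
  r2_mut <- mutate_k(r2_fwd, 10L)
  q1 <- rep(40L, 70L)
  q2 <- rep(40L, 70L); q2[10L] <- 10L
  r1 <- sequence_record("p", r1_seq, q1)
  r2 <- sequence_record("p", revcomp(r2_mut), rev(q2))
  m <- merge_paired_reads(r1, r2, min_overlap = 20)
  expect_identical(m$seq, amplicon)

  # now give the erroneous base the higher quality: the error wins
  r1b <- sequence_record("p", r1_seq, rep(10L, 70L))
  r2b <- sequence_record("p", revcomp(r2_mut), rep(40L, 70L))
  m2 <- merge_paired_reads(r1b, r2b, min_overlap = 20)
  expect_identical(substr(m2$seq, 50L, 50L), substr(r2_mut, 10L, 10L))

  # disjoint mates: failure state, not an error
  expect_null(merge_paired_reads(sequence_record("a", random_dna(50)),
                                 sequence_record("a", random_dna(50)),
                                 min_overlap = 25))
})

test_that("simulation configs validate their rates", {
  expect_error(read_sim_config("long_single", sub_rate = 0.4,
                               ins_rate = 0.2), "sum to < 0.5")
  expect_error(read_sim_config("long_single", n_reads = 0), "n_reads")
  db <- db_small()
  prof <- sample_community(db, "even", 3, seed = 5)
  long_cfg <- read_sim_config("long_single", n_reads = 5)
  expect_error(simulate_short_paired_reads(db, prof, long_cfg),
               "short_paired")
})
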