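# amplicross

Cross-platform 16S rRNA amplicon analysis: full-length (nanopore-style)
versus short V3–V4 (Illumina-style) sequencing of the same bacterial
community, with a focus on *where and why the two platforms disagree*.

## The problem

Short-read 16S surveys sequence only the V3–V4 hypervariable regions
(~440 bp including primers). Distinct taxa whose V3–V4 regions are
identical — but whose sequences diverge elsewhere in the gene — are
indistinguishable to that assay, so short-read pipelines silently merge
them, biasing genus- and species-level abundances. Full-length reads
(V1–V9, ~1.4 kb) resolve those taxa but carry far higher per-base error,
which rules out the usual 97%-identity OTU machinery and calls for
alignment-based classification with a permissive identity gate.

`amplicross` implements both analysis paths and the audit that
quantifies the short-read bias:

* **Long-read path** — semi-global best-hit alignment of each read
  against a reference database (match +1, mismatch −1, gap open −1, gap
  extension −1), keeping hits with identity ≥ 0.80, where identity =
  matches / alignment columns over the aligned span.
* **Short-read path** — mate-pair merging by overlap, greedy centroid
  clustering at 97% identity, and closed-reference assignment of
  representatives into the same database namespace.
* **Recreated-dataset bias audit** — error-free database sequences of an
  identified community are re-classified through both paths, full-length
  and restricted to the V3–V4 target, and compared to their original
  accessions (concordant/discordant "Venn" counts per path and between
  paths).
* **In-silico PCR** — degenerate-primer (IUPAC) matching, amplicon
  extraction, per-taxon mismatch tables, and Spearman/permutation tests
  of primer- and GC-related amplification bias.
* **Cross-platform concordance** — platform table merging with the
  rare-OTU filter (counts < 4 removed), per-rank relative-abundance
  aggregation and Spearman's ρ between platforms.
* **Phylogenetic beta diversity** — generalized UniFrac
  d^(α) = Σᵢ bᵢ (p_Ai + p_Bi)^α |p_Ai − p_Bi| / (p_Ai + p_Bi)
  ÷ Σᵢ bᵢ (p_Ai + p_Bi)^α over tree branches i, plus unweighted and
  variance-adjusted variants, classical PCoA, and perMANOVA with a seeded
  permutation null; inverse Simpson (1/Σp²) rarefaction for alpha
  diversity.
* **Synthetic community generator** — full-length 16S-like references
  with nine designated variable regions, designated "confusable groups"
  that are byte-identical over V3–V4 yet distinct elsewhere, community
  abundance profiles, and platform-specific read simulators (nanopore-like
  5.4% indel/substitution errors around mean Phred 12.65; Illumina-like
  2 × 250 paired reads at ~Q35), so every stage is testable without
  downloads.

## Worked example: the V3–V4 confusability audit

```r
library(amplicross)

# 20 synthetic taxa; 4 pairs share an identical V3-V4 amplicon
db <- build_reference_db(20, n_confusable_groups = 4, group_size = 2,
                         seed = 1)

# error-free sequences, restricted to the V3-V4 target region
audit <- bias_audit(db, names(db$sequences),
                    primer_pair = db$primers$short)
audit$best_hit
#> <venn_counts> 4/20 discordant (20.00%)
audit$cluster
#> <venn_counts> 4/20 discordant (20.00%)
audit$n_unique_after_clustering
#> [1] 16

# the same sequences at full length classify perfectly
bias_audit(db, names(db$sequences))$best_hit
#> <venn_counts> 0/20 discordant (0.00%)
```

Reading: with only V3–V4 available, one member of each confusable pair
is forced onto the other member (best-hit ties resolve
deterministically to the lexicographically smaller accession), so 4 of
20 sequences (20.00%) change taxonomy and 97% clustering collapses the
20 sequences to 16 representatives — while the full-length path keeps
all 20 distinct. This is the mechanism by which short-read assays
misassign taxa that long reads separate.

An end-to-end run (simulation → both classification paths → merged
table → concordance → UniFrac/PCoA/perMANOVA) is one call:

```r
res <- run_pipeline(default_config(seed = 42), outdir = "run1")
res$rho          # per-rank cross-platform Spearman correlation
res$permanova    # community-difference test on weighted UniFrac
```

A thin command-line wrapper lives at `inst/cli/amplicross.R`
(`fixtures` and `run-all` subcommands).

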