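---
title: "Methods and design of amplicross"
output: rmarkdown::html_vignette
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`amplicross` compares two ways of surveying the same bacterial
community by 16S rRNA amplicon sequencing: full-length reads (V1–V9,
~1.4 kb) with a high per-base error rate, and accurate short paired
reads restricted to the V3–V4 hypervariable regions. This vignette
documents the models, conventions, and design choices behind each
stage, and what the bundled synthetic data can and cannot show.

## The synthetic reference and what it emulates

Real 16S genes are a mosaic of conserved blocks and nine hypervariable
regions. The generator (`build_reference_db`) reproduces exactly the
features the analysis depends on:

* a fixed coordinate layout of conserved blocks interleaved with V1–V9,
  1,427 nt in total, shared across taxa so that primer binding is exact;
* both primer pairs embedded in conserved blocks with zero mismatches
  to the degenerate primers: the near-full-length pair
  S-D-bact-0008-c-S20 / S-D-bact-1391-a-A-17 bracketing the whole gene,
  and the V3–V4 locus-specific pair (stored with library overhang
  adapters trimmed — overhangs do not bind the template, so only the
  3' locus-specific parts are ever matched). The V3–V4 amplicon is
  440 bp including primers, so 2 × 250 mates overlap by 60 bases;
* independent random variable regions per taxon, which keeps every
  pairwise full-length identity far below the 97% OTU threshold;
* *confusable groups*: sets of taxa byte-identical over the entire
  V3–V4 amplicon but independent elsewhere. These are the engineered
  analogue of database taxa that short-read assays cannot separate, and
  they drive the bias audit.

What the generator does **not** emulate: real phylogenetic covariance
between regions (variable regions are i.i.d. random), chimeras, primer
amplification bias, GC-dependent coverage, and real SILVA lineage
structure (lineages follow a regular synthetic hierarchy). Passing
tests therefore demonstrate the correctness of the machinery and the
*mechanism* of V3–V4 confusability, not field-scale accuracy on real
communities.

## Read simulation

Reads are simulated from PCR amplicons, not genomes; chimera formation
is not modeled (no primer or GC amplification bias is emulated either,
so there is nothing for amplicon-level simulation to miss).

The long-read error model is calibrated from a mean Phred quality of
12.65: Q = −10·log10(p) gives p ≈ 0.054 per base, split
substitution:insertion:deletion = 10:2.5:1, i.e. rates 0.040 / 0.010 /
0.004. Only the mean quality is an observed quantity; the split is a
package choice that avoids overfitting unstated chemistry. Emitted
per-base qualities are drawn from a normal model (mean 12.65, sd 3,
clamped to [1, 41]). Short reads default to 2 × 250 with 0.3%
substitutions only and qualities around Q35 — standard modern-platform
behavior. Every simulator is a pure function of (inputs, seed).

Mate pairs are merged by scanning overlap lengths and choosing the
candidate with the lowest mismatch fraction (ties go to the longest
overlap); disagreeing bases resolve to the higher-quality mate, and a
pair with no overlap of ≥ 20 bases at ≤ 10% mismatches returns a
failure state rather than an error.

## Alignment and identity

The classifier uses semi-global dynamic programming (query end-to-end,
free leading/trailing gaps on the reference) with match +1, mismatch
−1, gap open −1, gap extension −1 — the scoring used for noisy
long-read 16S alignment. The mismatch score is a package default: the
published score set for this style of analysis states only match/gap
scores, and −1 is the companion mismatch penalty of the +1/−1 family.
Gap scoring charges the open penalty on the first gap base and the
extension on subsequent bases, so the defaults give a linear −1/base
gap cost.

Identity is defined as matches / alignment columns over the aligned
span, with free end gaps excluded and internal gap columns counting
against identity. This convention is load-bearing: it defines both the
80% long-read gate and the 97% clustering threshold. Traceback ties
prefer match/mismatch over gap moves, and best-hit score ties resolve
to the lexicographically smallest accession (flagged in the output), so
classification is deterministic. Sequences beyond a configurable cap
(5,000 nt) are rejected to guard against quadratic blowup.

A shared 8-mer prefilter shortlists references before the quadratic DP
(top 3 by shared-k-mer count, keeping all ties at the cutoff so the
deterministic tie-break is unaffected); when no reference shares a
k-mer the scan falls back to the full database. Like all centroid
heuristics this trades a guarantee for speed; the tests exercise both
the prefiltered and full-scan paths.

## The two classification paths

*Best-hit* (long reads): best score over all references, identity gate
applied after selection; reads below the gate are reported
unclassified.

*Cluster + closed reference* (short reads): after dereplication,
sequences are processed in order of decreasing duplicate count, then
decreasing length, then id, each joining the first existing
representative at ≥ 97% identity or founding a new cluster — a
deterministic reproduction of greedy centroid clustering without its
proprietary heuristics. Representatives are then assigned by best hit
at ≥ 97%; clusters that match nothing are discarded (closed-reference
semantics) with their read counts logged.

## The recreated-dataset bias audit

`bias_audit` recreates the exact (error-free) database sequences of an
identified community, optionally restricts them to the V3–V4 target
region, pushes them through both paths, and counts sequences whose new
assignment differs from their original accession. "Classified into the
original taxonomy" is read strictly as exact accession match; rank-level
agreement can be derived from the assignment table. The percentage
identity `pct_discordant = 100 · n_discordant / n_total` is enforced on
every output. On the bundled 20-taxon fixture with 4 confusable pairs
the audit is fully deterministic: each pair produces one forced
tie-break loss in the V3–V4 best-hit path and one collapsed
representative in the cluster path, while full-length reclassification
is perfectly concordant — the acceptance script recomputes these counts
on every run.

## Merging, the rare-OTU filter, and concordance

Platform tables are merged over the shared accession namespace (both
paths assign into the same database), with samples renamed under
platform suffixes. The rare-OTU rule "abundance < 4 removed" admits two
readings; the default zeroes each taxon-sample *cell* below 4, and a
`row_sum` flag zeroes whole rows below 4 instead. Rows left all-zero
are dropped.

Per-rank concordance aggregates counts by rank label (the sentinel
`"unassigned"` is kept as its own row — an explicit value, not an empty
string, so grouping is visible), normalizes per sample, and computes
Spearman's ρ (average ranks for ties, i.e. Pearson on ranks) between
platform means across all taxa present in either platform. Heatmap
matrices report relative-abundance percentages for taxa reaching 0.5%
in at least one analysis path.

## Phylogenetic diversity

Trees come either from an external Newick file (`parse_newick`, ape
semantics) or from neighbor joining on alignment-identity distances
(1 − identity), midpoint rooted. Negative NJ branch lengths are clamped
to zero with the deficit shifted to the sibling so the affected leaf
pair's path length is preserved — standard practice, logged when it
happens.

Generalized UniFrac follows

d^(α) = Σᵢ bᵢ (p_Ai + p_Bi)^α · |p_Ai − p_Bi| / (p_Ai + p_Bi) ÷
Σᵢ bᵢ (p_Ai + p_Bi)^α

over branches with p_Ai + p_Bi > 0, where bᵢ is branch length and p_Xi
the fraction of community X descending from branch i; α = 1 is the
classical weighted normalized form and α = 0 weights all occupied
branches equally. The unweighted variant uses presence/absence
indicators. Because figure legends and running text in this literature
attach the label "moderately weighted" both to α = 0.5 and to the
variance-adjusted form, `unifrac_matrix` emits both, labeled
distinctly: `d_0.5`, and `d_VAW` with each branch term normalized by
√(mᵢ(2 − mᵢ)), mᵢ = p_Ai + p_Bi.

PCoA is classical scaling: eigendecomposition of the double-centered
−D²/2, coordinates scaled by √λ, axes with negative eigenvalues
(expected for non-Euclidean UniFrac matrices) counted and dropped, and
a fixed sign convention (largest-magnitude loading positive). perMANOVA
computes the pseudo-F from squared distances via the standard partition
and a label-permutation p-value `(1 + #{F* ≥ F}) / (1 + n_perm)`; the
default 999 permutations give 0.001 resolution, the seed is mandatory,
and an exhaustive-enumeration mode covers small two-group designs. A
constant distance matrix returns p = 1 by convention.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere; MAF minus-strand
  intervals are converted at parse time and nowhere else.
* FASTQ is Phred+33 only.
* Primer matching is Hamming-only (no gaps) over IUPAC sets — standard
  virtual-PCR semantics; the default mismatch scan range is 0–3,
  configurable.
* Amplicon extraction picks the shortest candidate amplicon whose
  insert is at least 50 nt; the insert excludes primer bases (mimicking
  primer trimming) and the `full` field keeps them.
* Spearman's ρ on a constant vector, PCoA of a zero matrix, and
  perMANOVA of a constant matrix all return explicit not-computable /
  degenerate states instead of NaN surprises.
* One global seed drives everything; each stage derives a substream via
  `derive_seed(seed, stage_name)`, which hashes the stage name and
  always stays below 2³¹.

## Problem sizes

The bundled study conditions are a 20-taxon database with 4 confusable
V3–V4 pairs; simulation-based checks use 2,000 zero-error long reads
for the classification gate, 10,000 reads for mock-community recovery,
150 heavily degraded reads for the rejection side of the gate, and
1,000+ random tree/profile instances (≤ 8 leaves) for the UniFrac
oracle, with 200 simulated null data sets (999 permutations each) for
perMANOVA calibration. These sizes were chosen so the whole suite
exercises every code path at desk scale while each property retains
statistical power.

## Known limitations

* The aligner is O(nm); databases of thousands of references rely on
  the k-mer shortlist, which is a heuristic.
* The greedy clusterer reproduces the deterministic core of
  centroid-based OTU picking, not any particular tool's seeding
  heuristics.
* The synthetic lineages are regular; rank-aggregation behavior on
  ragged real taxonomies is exercised only through the `"unassigned"`
  padding path.
* Reproduction of published study numbers from real sequencing
  archives requires the original reads and reference database (large
  downloads) and is out of desk-scale scope; the acceptance script
  instead recomputes the package's own verifiable quantities.
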