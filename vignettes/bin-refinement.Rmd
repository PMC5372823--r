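---
title: "Refining metagenome bins by two-sample differential coverage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refining metagenome bins by two-sample differential coverage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binpolish)
```

## The problem

Automatic binning of a metagenome co-assembly groups scaffolds into
putative genomes, but preliminary bins routinely carry contaminating
fragments of other community members, and occasionally merge two
genomes. When the same community has been sequenced twice — two
extractions of one host's biofilm, two time points, two closely related
samples — every genome acquires a two-dimensional coverage profile, and
scaffolds that do not belong to a bin tend to betray themselves by a
profile that disagrees with the rest of the bin even when their absolute
coverage is unremarkable. `binpolish` implements a purification pipeline
built entirely on this signal, plus the surrounding plumbing: taxonomic
pre-filtering, strict read recruitment for targeted reassembly, and
post-hoc estimators (16S linking, relative abundance, tRNA completeness,
single-copy core-genome selection).

## The pipeline, stage by stage

For a bin $B$ with members $i$ and mean per-base depths $d_A(i)$,
$d_B(i)$ in the two datasets:

**1. LCA taxonomic filter.** Each scaffold's homology hits (protein- and
nucleotide-level searches pooled) are filtered to
$e \le 10^{-20}$ and, per source, to bitscores within 10% of that
scaffold's best hit; the surviving taxa are reduced to their lowest
common ancestor. A scaffold is removed only when that LCA lies *at or
below* rank phylum in a phylum different from the bin's expected one.
This operationalizes "unambiguously assigned to another phylum": an LCA
above phylum rank is ambiguous evidence and the scaffold is kept, as is
any scaffold without qualifying hits. The top-percent band (default
10%) is our addition — an LCA over all hits regardless of score would be
dominated by weak spurious alignments — and is exposed as a parameter
rather than asserted as part of the original protocol.

**2. Median-outlier filter.** Scaffolds with
$d(i) > 3 \times \mathrm{median}_B(d)$ in *any* dataset are removed,
with medians computed once on the input membership (a single filtering
pass; an iterative variant is behind a flag). OR semantics across
datasets is the conservative contaminant-removal reading; AND is
available via `all_datasets = TRUE`. A dataset whose median depth is
zero is skipped with a warning — with a zero median the rule would
remove every scaffold with any coverage at all.

**3. Inverse-profile split.** A merged bin containing two genomes that
are abundant in opposite datasets shows a bimodal log-ratio
$r_i = \log_2\frac{d_A(i)+0.1}{d_B(i)+0.1}$. We sort $r$, locate the
largest gap between consecutive values, and split there only if the gap
is at least `min_gap_log2` (default 2), both sides retain at least
`min_side` members (default 5), and the side means have opposite signs —
the sign condition encodes "high in A but low in B or vice versa", so a
mere abundance difference within the same direction never splits a bin.
The original description states the criterion but no algorithm; the
largest-gap rule is this package's operationalization.

**4. Read recruitment** (between pre-filtering and final purification,
for users who reassemble): only alignments spanning the entire read (no
soft or hard clipping; indels and mismatches allowed — end-to-end
semantics) count, read pairs are accepted only when both mates map full
length to the same bin, and merged pairs and orphans are accepted
individually. Cross-bin pairs are rejected for both bins. A paired
record whose mate record is missing or unmapped is downgraded to an
orphan and counted with a warning.

**5. Iterative z-score purification.** Depths of the current members are
standardized per dataset, $z(i) = (d(i) - \bar d)/s$ with the sample
standard deviation ($n-1$). The scaffold maximizing
$|z_A(i) - z_B(i)|$ above the cutoff is removed — one at a time, because
z-scores are recalculated after every single removal; ties go to the
lexicographically smallest id so results are order-invariant — and the
cutoff shrinks from 4 by steps of 1 to a final value of 2 once no member
exceeds it. On termination every survivor satisfies
$|z_A - z_B| \le 2$ on the final membership. A batch mode (all
offenders per round) exists for comparison behind `batch = TRUE`. If a
removal would leave fewer than `min_members` (default 4) scaffolds the
run stops early and is flagged: a standard deviation over three
scaffolds is not evidence. A zero-variance dataset yields all-zero
z-scores and drives no removals.

Stage order is LCA filter → median filter → split → purification, with
sub-bins from a split processed independently downstream.

## Estimators

* **Relative abundance** of a bin in dataset $k$ is the mass fraction
  $\sum_{i \in B} d_k(i)\,L_i \big/ \sum_{j \in D} d_k(j)\,L_j$ over a
  caller-chosen denominator set $D$ (typically all scaffolds classified
  bacterial). The denominator basis is always reported alongside the
  number, because the original tables print such percentages without a
  formula; this estimator is this package's operationalization. It is
  additive over disjoint bins and invariant to splitting a scaffold into
  halves of equal depth.
* **tRNA completeness** is $100 \times$ (distinct standard amino-acid
  isotypes)/20. Selenocysteine, pyrrolysine and undetermined isotypes
  are ignored. A full set prints as `">99"`: presence of all 20
  isotypes cannot distinguish a complete genome from a nearly complete
  one.
* **Unique core genome**: ortholog groups with copy count exactly 1 in
  every compared genome — the input for a concatenated MLSA. Alignment
  and tree building are out of scope here.
* **16S linking**: ribosomal scaffolds rarely survive strict binning, so
  they are linked back by coverage: Euclidean distance between
  $\log_2(d + 0.1)$ profiles of the 16S scaffold and each bin's mean
  member profile; a link is ambiguous when the runner-up distance is
  within `ambiguity_factor` (default 2) of the best, or ties it exactly.
  Output is labelled *coverage-only*: phylogenetic placement must
  corroborate a link before it is treated as a connection.

## The synthetic community generator

`sim_spec()`/`simulate_community()` emulate the two-dataset design with
fully labelled truth. Genome $g$ draws a base abundance
$m_g \sim \mathrm{Lognormal}(\log 20,\,0.7)$, scaled per dataset by an
independent lognormal factor (sdlog 0.5) — the genome-level differential
profile that coverage binning exploits. Per-scaffold depth multiplies
in two noise terms: a **shared** lognormal factor (sdlog 0.3) common to
both datasets, modelling coverage variation along the genome that
reproduces across samples (GC bias, repeats, copy number), and a smaller
**dataset-specific** factor (sdlog 0.05) for sampling noise. This split
is the load-bearing modelling choice: a final z-difference cutoff of 2
presumes that within-genome coverage profiles are correlated between
datasets; if per-scaffold noise were drawn independently per dataset,
$z_A - z_B$ would have standard deviation $\approx\sqrt 2$ for genuine
members and the procedure would shred clean bins.

Planted contaminants are drawn at the *host bin's* coverage scale —
matching overall coverage is precisely why an initial binner would have
co-binned them — and split between datasets by $\sqrt{f}$ up and down
(default fold $f = 8$), direction random. Sequences are i.i.d.
nucleotides at a genome-specific GC (drawn uniformly in 0.35–0.65); no
k-mer structure is simulated because no stage of this toolkit uses
composition. A strain-pair option derives genome 2 from genome 1 at a
configurable identity (default 0.97) to exercise strain-mixture
book-keeping. What passing tests on these communities do **not** show:
robustness to assembly chimeras, to composition-driven binning errors,
to coverage biases that differ systematically between datasets, or to
taxonomies with incomplete rank ladders.

`simulate_hits()` generates BLAST-like hits concentrated on each
scaffold's true species with configurable cross-phylum noise, bitscores
inside the 10% band, and a configurable fraction of e-values above the
$10^{-20}$ cutoff so the cutoff is actually exercised.

## Numerical and interface choices

* Mean scaffold coverage is the arithmetic mean of per-base depth
  (aligned reference bases / scaffold length); secondary and
  supplementary alignments are excluded.
* Median of an even-sized set is the mean of the two middle values.
* Even-handed tie-breaks everywhere by scaffold id, making every stage
  deterministic and independent of input order.
* GC excludes N positions from the denominator; an all-N scaffold has
  undefined (NA) GC, never 0.
* The depth-table reader accepts the common summarizer layout (name,
  length, an optional total-average column, per-sample means, ignored
  per-sample variance columns). Per-base depth input is 1-based;
  missing positions count as zero coverage.
* Pipeline reports exclude timestamps from the body (a sidecar carries
  them) so identical runs diff clean.

## Problem sizes in the shipped checks

The test suite and the acceptance script regenerate everything at run
time: 100 random fixtures of 10–200 scaffolds for the purification
oracle, a 200-node random taxonomy with 50 LCA queries, 20 simulated
communities of 5 genomes × 50 scaffolds with 10% contamination at 8×
differential fold for end-to-end recovery, and a 20-record hand-built
SAM fixture covering every recruitment rule. These sizes give stable
statistics while keeping a full run in well under a minute.

## Known limitations

The purification assumes exactly two datasets carry the differential
signal; with more, a pair is chosen explicitly. Contaminants whose
coverage profile matches the host bin in *both* datasets are invisible
to every stage here — that is a fundamental limit of coverage-based
refinement, not of this implementation — and composition-based screens
are deliberately out of scope. The LCA filter inherits the reference
database's biases: lineages absent from the database yield unassigned
or ambiguous scaffolds, which are always kept.

```{r example}
sim <- simulate_community(sim_spec(seed = 11, with_sequences = FALSE))
hits <- simulate_hits(sim$truth, sim$taxonomy, seed = 11)
res <- refine_bins(sim$contaminated_bins, sim$coverage, "A", "B",
                   hits = hits, tx = sim$taxonomy)
subset(res$report, bin == "bin1")
planted <- sim$truth$scaffold_id[sim$truth$contaminant]
c(recall = mean(planted %in% res$removed),
  precision = mean(res$removed %in% planted))
```
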