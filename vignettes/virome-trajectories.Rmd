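---
title: "Stage-wise gut-virome trajectory analysis with virotraj"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-wise gut-virome trajectory analysis with virotraj}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Viral metagenomes of the mammalian gut change as the host develops. A
stage-resolved fecal virome study — here modelled on a three-stage pig
design: lactation (L), nursery (N), fattening (F), with five animals per
stage — asks, for every viral operational taxonomic unit (vOTU), *how* its
presence changes across stages: does it appear only at one age, stay flat,
rise steadily, rise then fall, fall steadily, or fall then rise? virotraj
implements that analysis end to end on desk-scale tabular inputs: the
contig-level dereplication that defines vOTUs, abundance and coverage
normalization, diversity summaries, the six-category trajectory
classification itself, per-category functional enrichment, curation of viral
auxiliary metabolic genes (vAMGs), and temperate-versus-lytic abundance
contrasts. A seeded synthetic-study generator with planted, recoverable
structure makes every stage testable without any sequencing data.

```{r, eval = FALSE}
library(virotraj)
res <- run_pipeline(pipeline_config(outdir = "run", simulate = TRUE, seed = 7))
summarize_categories(res$trajectory)
```

## From contigs to vOTUs

Contigs are collapsed into vOTUs by greedy longest-first clustering
(`cluster_votus()`): contigs are visited in order of decreasing length (ties
broken by id), and each contig joins the first earlier cluster
*representative* it matches with identity ≥ 95% over an alignment covering
≥ 85% of the shorter sequence of the pair; otherwise it founds a new vOTU
whose representative it becomes. The shorter-sequence denominator is the
convention that merges contained fragments into their longer parent, which
is the point of dereplication. Both thresholds are inclusive (≥), and when a
pair reports several alignments the best one (highest identity, then longest
alignment) is used. Novelty calling (`classify_novelty()`) is a separate,
much looser screen: a vOTU is "reported" when any reference hit reaches 90%
identity over at least 5% of the vOTU length.

Two properties of this scheme deserve explicit mention.

* It is deterministic and independent of hit-table row order, because the
  visiting order is a pure function of lengths and ids.
* It is **not** monotone in its thresholds. Tightening a threshold usually
  increases the number of clusters, but not always: a contig that no longer
  joins an earlier representative founds its own cluster, and may then absorb
  contigs that previously founded theirs. The test suite pins a six-contig
  counterexample in which raising the coverage threshold from 0.75 to 0.90
  *reduces* the cluster count from five to four, with the implementation
  agreeing with a literal brute-force emulation of the greedy rule at both
  thresholds. Single-pass greedy clustering trades this global property for
  the longest-representative semantics; transitive-closure clustering would
  be monotone but produces chained clusters with no natural representative.

## Abundance: coverage breadth and TPM

Two per-vOTU, per-sample quantities drive everything downstream.

**Coverage breadth** (`compute_breadth()`) is the fraction of the vOTU
length covered by at least one aligned read: the length of the union of the
sample's alignment intervals divided by the vOTU length. Intervals are
0-based half-open, and the union is computed with `IRanges::reduce`, so
breadth is invariant under permutation, splitting and overlap of intervals.

**TPM** (`compute_tpm()`) is the length-normalized relative abundance

$$\mathrm{TPM}_i \;=\; \frac{N_i / L_i}{\sum_j N_j / L_j} \times 10^6,$$

with $N_i$ the mapped-read count and $L_i$ the vOTU length in bp, computed
per sample. Every sample with at least one mapped read sums to $10^6$
exactly (tested at $10^{-9}$ relative tolerance); an all-zero sample yields
an all-zero column with a warning rather than an error, because simulation
sweeps can legitimately produce one.

Trajectory classification runs on breadth; abundance contrasts (vAMG
profiles, lifestyle comparisons) run on TPM. Breadth is the more robust
presence signal for rank tests — it saturates rather than exploding with
depth — while TPM is the right scale for summing mass across vOTUs.

## The six-category trajectory classifier

For each vOTU, the per-sample breadth values are compared across the three
stages with a Kruskal–Wallis rank test (tie-corrected, via
`stats::kruskal.test`), followed by Dunn's (1964) post-hoc pairwise
comparisons with tie-corrected standard errors:

$$z_{ij} \;=\; \frac{\bar R_j - \bar R_i}
{\sqrt{\Bigl(\tfrac{N(N+1)}{12} - \tfrac{\sum (t^3 - t)}{12(N-1)}\Bigr)
\bigl(\tfrac{1}{n_i} + \tfrac{1}{n_j}\bigr)}},$$

where $\bar R$ are mean joint ranks, later stage minus earlier stage, so
$z > 0$ means an increase with age. No pre-installed package provides Dunn's
test, so it is implemented here and checked against a brute-force rank
oracle to $10^{-10}$.

The decision cascade in `classify_trajectory()`:

1. **a (stage-exclusive)** — all nonzero breadth values fall in exactly one
   stage. This structural check precedes any testing: a vOTU present in 5 of
   15 samples would otherwise be absorbed into the rise/fall categories.
2. **b (constant)** — the Kruskal–Wallis p-value is ≥ `alpha` (default
   0.05).
3. Otherwise, each developmental step (L→N and N→F) gets a direction sign:
   the sign of the later-stage median minus the earlier-stage median (means
   break median ties), but only when that step's Dunn p-value — by default
   Benjamini–Hochberg-adjusted within the vOTU's three comparisons — is
   below `alpha_dunn`; non-significant steps are 0. The sign pair maps
   `(+,+), (+,0), (0,+)` → **c** (continuous growth); `(−,−), (−,0), (0,−)`
   → **e** (continuous decline); `(+,−)` → **d** (growth then decline);
   `(−,+)` → **f** (decline then growth). A `(0,0)` pair with only the L–F
   comparison significant is resolved by the overall L→F direction (c or
   e); any remaining `(0,0)` falls back to **b**, so the six categories
   always partition the vOTUs — there is no "unclassified" bucket.

Because every ingredient is rank-based, the category is invariant under any
strictly increasing transform of the values, and reversing developmental
time (relabelling L↔F) maps c↔e exactly. Note that d and f are *fixed
points* of that reversal, not images of each other: both are palindromic in
time (low–high–low and high–low–high), and reversing the stage order negates
and swaps the two step signs, which maps (+,−) to (+,−) and (−,+) to (−,+).

Two choices here were genuinely open. The adjustment of Dunn p-values within
each vOTU is exposed as `dunn_adjust = "bh"` (default) or `"none"`; BH is
the conservative default because three dependent comparisons per vOTU are
tested. And directions are measured on stage medians rather than rank means
so that the reported sign matches what a reader sees in a box plot; the two
agree whenever the step is significant.

With five samples per stage, a perfectly separated adjacent step
(ranks 1–5 vs 11–15 with the third stage in between) yields $|z| = 1.77$,
p ≈ 0.077: an adjacent step alone cannot reach significance. Categories c
and e are then rescued by the L–F comparison ($|z| = 3.54$), and d and f are
detectable precisely because their two extreme stages interleave in rank,
pushing the adjacent-step $|z|$ to ≈ 2.65. This is a real small-sample
property of the procedure, not an implementation artifact, and it shapes the
fixtures used in the tests.

## Per-category enrichment

`enrich_terms()` reproduces the foreground/background design of per-category
functional enrichment: for each trajectory category, foreground genes are
the genes on that category's vOTUs and the background is all annotated
genes. Each term is tested with the upper-tail hypergeometric probability
$P(X \ge k)$ (genes, not vOTUs, are the sampling unit), and q-values are BH
adjusted across terms *within each category × term-level stratum*, matching
a report that presents term levels separately. Genes with no term are
excluded from both sets; term levels are taken from the annotation table as
given (no ontology propagation).

One consequence of stratified adjustment is worth knowing: the null
guarantee is per stratum. With six categories and two levels there are
twelve BH families, so under a completely null annotation table the chance
of *some* q < 0.05 anywhere is roughly $1 - 0.95^{12} \approx 46\%$, even
though each family's false-discovery rate is controlled at 5%. The null
test in the suite therefore checks the per-stratum any-discovery rate.

## vAMG curation and profiles

`filter_vamgs()` applies the standard retention rule to an annotation-tool
candidate table: auxiliary score < 4, metabolism flag (M) present, none of
the attachment (A), viral (V) or transposon (T) flags, gene id, gene
description and KEGG annotation present, carrier vOTU not flagged as
host-contaminated, and pathway not matching a blacklist of virus-expected
pathways (seeded with nucleotide metabolism, glycosyl transferases and
ribosomal proteins; case-insensitive substring match, editable, because such
manual lists are inherently non-exhaustive). Every rejected record carries
its first failing rule, which makes the filter auditable; the filter is
deterministic, order-independent and idempotent, and relaxing any single
rule can only grow the retained set.

`vamg_abundance_profile()` gives each retained gene the TPM of its carrier
vOTU, summed within stages, and reports log10 of the sums for heatmap use.
log10(0) is rendered as `NA` (a sentinel meaning "no mass", distinct from
small mass); an optional pseudocount can be added before the log instead. A
gene annotated to several pathways contributes to each of its pathway rows,
so pathway rows are sums of their genes' rows by construction.

## Lifestyle contrasts

`screen_lifestyle()` removes rows called `unclassified`, labelled `low`
quality, or not annotated as phage — separately for each of the two
predictors, whose streams are never merged (the second predictor's
complete-genome input set is a subset of the first's). For each predictor,
`lifestyle_abundance_compare()` sums TPM per sample within each lifestyle
class (the two class sums add up to the total called mass — checked as mass
conservation), log10-transforms the per-sample sums, and then: within each
stage, compares temperate vs virulent log-sums with a two-sided Welch t-test
(`pooled = TRUE` switches to the pooled-variance variant); across stages,
compares the per-sample lytic sums with a Kruskal–Wallis test. log10 of the
per-sample *class sum* is used — not the sum of per-vOTU logs — because the
class total is the quantity being contrasted; samples with zero class mass
are excluded from that t-test, and a stage with no temperate mass at all
reports its sums with the test skipped and a reason.

## The synthetic-study generator

`simulate_study()` and its companions generate a complete study with known
truth, emulating the *structure* of real stage-resolved virome data:

* **Counts**: negative binomial per vOTU × sample (mean–dispersion
  parameterization), the standard overdispersed model for metagenomic
  counts. Stage means realize the planted category: a multiplies the base
  mean into exactly one stage (structural zeros elsewhere — "exclusive"
  is literal); b is flat; c/e are geometric ladders `(1, φ, φ²)` up/down
  with fold-change φ; d/f are `(1, φ, 1)` and `(φ, 1, φ)`.
* **Breadth**: a saturating depth curve `1 − exp(−0.7·depth)` with ±15%
  multiplicative jitter, then forced monotone non-decreasing in the read
  count within each vOTU (equal counts share a value, zero count means zero
  breadth). Only the monotone count→breadth link matters downstream, since
  the classifier is rank-based; the exact curve is not asserted anywhere.
* **Intervals**: two disjoint intervals per covered cell whose union length
  realizes the breadth exactly, so `compute_breadth()` recovers the
  generator's breadth table bit-for-bit.
* **Annotations**: one term per gene per level; genes of a planted term's
  target category draw that term at `enrichment_factor / n_terms`
  (default 8× the uniform background rate).
* **vAMG candidates**: a pass fraction built to satisfy every retention
  rule; each failing record violates exactly one rule, assigned round-robin,
  so every rejection branch is exercised and the filter's output can be
  compared to truth exactly.
* **Lifestyle**: virulent calls with probability `lytic_fraction`, plus
  configurable unclassified/low-quality fractions for the screen to remove.

Defaults — 600 vOTUs, 5 samples per stage, category proportions
(a, b, c, d, e, f) = (0.1, 0.4, 0.2, 0.1, 0.1, 0.1), fold-change 8,
dispersion 5, base mean 20 reads, read length 150 bp, lognormal lengths
around 4 kb, lytic fraction 0.8 — are the package's frozen study
conditions: constant vOTUs most common with continuous growth next, few-kb
vOTUs, and a lytic majority, as in stage-resolved gut viromes. Everything is
deterministic under `seed` (each generator derives its own stream from it),
and same-seed runs are bit-identical.

What the generator does **not** emulate: sequence content (no reads, no
assembly artifacts), compositional coupling between vOTUs beyond the TPM
closure, phylogenetic structure, and between-animal covariance. Passing
tests therefore demonstrate that the procedures recover planted structure
under an idealized noise model — not that the biological claims of any real
study are reproduced.

## Numerical choices and degenerate inputs

* Kruskal–Wallis on identical values returns H = 0, p = 1 by convention
  (the tie correction is degenerate there).
* All-zero abundance vectors: richness 0, Shannon/Simpson `NaN` with a
  warning. Shannon uses natural log; Simpson is Gini–Simpson (1 − D) —
  the conventions of the vegan package, which performs the computation.
* PCoA reports the full eigenvalue spectrum, negative values included
  (Bray–Curtis is not Euclidean-embeddable in general); coordinates are
  returned for positive axes only, and Euclidean-embeddable inputs are
  reproduced to 1e-8.
* Tables are exchanged as TSV with doubles written at 17 significant
  digits and re-parsed with base R's correctly rounded reader, so
  write/read round trips are exact.
* A vOTU absent from every sample is an error in the classifier (it cannot
  leave dereplication), not a seventh category.

## Problem sizes used by the tests

The checks in `tests/testthat/` and `scripts/acceptance.R` run on sizes
chosen to give stable statistics at interactive runtimes: trajectory
recovery over 100 generator seeds of the default 600-vOTU study (the
acceptance script uses 25 seeds for its summary rate), a 1000-vOTU
exchangeable-null study for the type-I check, exhaustive enumeration of all
32,768 six-contig hit graphs against the greedy oracle, 100+ random
instances for the rank-test oracles, 50 seeds for the lytic-dominance power
check and several hundred for null rejection rates.

## Known limitations

* The trajectory categories are defined for exactly three stages; the rest
  of the pipeline is stage-count agnostic, but `classify_trajectory()`
  requires L/N/F.
* Greedy dereplication is threshold-non-monotone (see above) and, like all
  single-pass schemes, depends on the length ordering; both behaviors are
  deliberate and tested.
* Enrichment takes term levels as given and does not propagate the GO DAG.
* NMDS, rarefaction, UniFrac and the upstream read-processing stages
  (QC, assembly, viral identification, ORF calling, annotation itself) are
  out of scope; the pipeline starts from contigs, hit tables and
  annotation-tool outputs.
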