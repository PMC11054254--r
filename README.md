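# virotraj

Stage-wise gut-virome trajectory analysis in R.

Stage-resolved fecal virome studies ask how each viral operational taxonomic
unit (vOTU) behaves as the host grows — for instance across the lactation
(L), nursery (N) and fattening (F) stages of a pig cohort, five animals per
stage. virotraj implements that analysis as a tested, reusable pipeline over
desk-scale tabular and sequence inputs:

* **Dereplication** — greedy longest-first clustering of contigs into vOTUs
  at ≥ 95% identity over ≥ 85% of the shorter sequence, longest member as
  representative; novelty screening against a reference hit table at
  ≥ 90% identity / ≥ 5% coverage.
* **Abundance** — coverage breadth (interval-union fraction of the vOTU
  length) and TPM,
  `TPM_i = (N_i/L_i) · 10⁶ / Σ_j (N_j/L_j)` per sample, with `N_i` the
  mapped-read count and `L_i` the vOTU length.
* **Diversity** — richness, Shannon (natural log), Gini–Simpson; Bray–Curtis
  dissimilarity and PCoA with the full eigenvalue spectrum reported.
* **Trajectory classification** — per vOTU, a tie-corrected Kruskal–Wallis
  test across the three stages, Dunn's post-hoc pairwise z-tests
  (BH-adjusted within the vOTU), and a decision cascade into six categories:
  **a** stage-exclusive, **b** constant, **c** continuous growth, **d**
  growth then decline, **e** continuous decline, **f** decline then growth.
  The categories always partition the vOTUs.
* **Enrichment** — per-category hypergeometric over-representation of
  annotated genes against the all-genes background, BH q-values within each
  category × term-level stratum.
* **vAMG curation** — the standard retention rule for viral auxiliary
  metabolic genes (auxiliary score < 4, metabolism flag only, KEGG
  annotation present, virus-expected pathways blacklisted), with per-record
  verdicts and reasons, plus per-stage log10 TPM profiles.
* **Lifestyle contrasts** — screening of two phage-lifestyle predictor
  tables, within-stage Welch t-tests of temperate vs lytic log10 mass, and
  an across-stage Kruskal–Wallis test on lytic mass.
* **Synthetic studies** — a seeded generator that plants all of the above
  structure (negative-binomial counts realizing the six categories,
  enriched terms, vAMG pass/fail mixtures, a lytic majority) so every stage
  is testable end to end with known truth.

The methods vignette (`vignettes/virome-trajectories.Rmd`) documents the
models, defaults, numerical choices and known limitations, including two
deliberate properties worth reading about before use: greedy dereplication
is not monotone in its thresholds, and with five samples per stage an
adjacent-stage Dunn comparison alone cannot reach significance (the L–F
comparison and rank interleaving carry the cascade).

## Worked example

Simulate the default study (600 vOTUs, 5 samples per stage, planted
category proportions a–f = 0.1/0.4/0.2/0.1/0.1/0.1, stage-to-stage
fold-change 8, negative-binomial dispersion 5), then classify every vOTU's
trajectory from its coverage breadth:

```r
library(virotraj)

cfg   <- sim_config(seed = 7)
study <- simulate_study(cfg)
tpm   <- compute_tpm(study$counts, study$catalog,
                     samples = study$design$sample_id)
calls <- classify_trajectory(study$breadth, study$design)
summarize_categories(calls)
#> # A tibble: 6 × 3
#>   category     n fraction
#>   <chr>    <int>    <dbl>
#> 1 a           60    0.1
#> 2 b          233    0.388
#> 3 c          128    0.213
#> 4 d           54    0.09
#> 5 e           74    0.123
#> 6 f           51    0.085
```

The recovered proportions sit at the planted values: 60 of 600 vOTUs are
called stage-exclusive (exactly the planted 10%), constant vOTUs are the
largest class and continuous growth the second, and per-vOTU agreement with
the planted truth is 96.2% for this seed. Each call carries its evidence:

```r
head(calls[calls$category == "c", ], 3)
#> # A tibble: 3 × 9
#>   votu_id    category  kw_H    kw_p dunn_LN_p dunn_NF_p dunn_LF_p dir_LN dir_NF
#>   <chr>      <chr>    <dbl>   <dbl>     <dbl>     <dbl>     <dbl> <chr>  <chr>
#> 1 vOTU_00094 c         6.88 0.0321     0.498     0.0339  0.0954   0      +
#> 2 vOTU_00301 c        13.0  0.00151    0.0716    0.0716  0.000941 0      0
#> 3 vOTU_00302 c        13.0  0.00151    0.0716    0.0716  0.000941 0      0
```

vOTU_00094 rises significantly from nursery to fattening (`dir_NF = "+"`);
vOTU_00301 shows the small-sample pattern discussed in the vignette — no
single adjacent step is significant after adjustment, but the overall L→F
comparison is (p ≈ 0.0009), which the cascade resolves by the L→F direction.

Alpha diversity per sample, on the TPM matrix:

```r
head(alpha_diversity_table(tpm), 3)
#> # A tibble: 3 × 4
#>   sample_id richness shannon simpson
#>   <chr>        <int>   <dbl>   <dbl>
#> 1 F01            560    5.23   0.992
#> 2 F02            560    5.25   0.991
#> 3 F03            560    5.23   0.991
```

The whole chain — simulation or TSV inputs, breadth/TPM, diversity,
trajectories, enrichment, vAMGs, lifestyle — runs as one call writing every
stage's tables plus a JSON run manifest:

```r
run_pipeline(pipeline_config(outdir = "run", simulate = TRUE, seed = 7))
```

or from a shell via the thin wrapper:

```sh
Rscript inst/scripts/virotraj.R all --simulate --seed 7 --outdir run
```

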