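# dripdsb

Break-centered DRIP-seq analysis of damage-induced R-loops.

## The problem

In cells carrying an inducible AsiSI endonuclease, adding hydroxytamoxifen
(+OHT) cuts ~99 annotated genomic sites, creating a mapped set of
double-strand breaks (DSBs). DRIP-seq (DNA:RNA hybrid immunoprecipitation
with the S9.6 antibody) before and after induction asks whether breaks
trigger R-loop formation, and what drives it. `dripdsb` implements the
complete downstream quantification for anyone analysing such paired
(damaged vs undamaged) coverage data around a fixed set of anchor sites:

1. **Per-nucleotide coverage** in a 20-kb window centered on each cut
   site, from sorted BAM or BED read spans.
2. **Normalization** to total aligned reads per library, with a one-read
   pseudocount, and the per-nucleotide log2 fold change

   `lfc(x) = log2( (d+OHT(x) + 1) / N+OHT ) − log2( (d−OHT(x) + 1) / N−OHT )`

3. **Induction score** per site: the mean `lfc` over the 1-kb region
   centered on the break (−500 … +500 nt).
4. **Grouped statistics**: unpaired Wilcoxon rank-sum tests of the scores
   by repair pathway (HR vs NHEJ), genic status and high vs low
   transcriptional activity, Bonferroni-corrected; plus a Pearson
   correlation of score against relative transcriptional activity (RNAPII
   S2P occupancy).
5. **Aggregate views**: 200-nt-smoothed metagene curves, a heatmap matrix
   ordered by descending activity, and paired 200-kb browser-style tracks
   (500-nt smoothing, 200-nt bins, no ratio).
6. A **simulator** of the underlying model — activity-proportional
   canonical R-loops, ~100-kb transcriptional shutdown after damage, a
   sharp activity-scaled Gaussian peak at the cut, a non-responder
   minority — so every stage is testable with known ground truth.

## Worked example

```r
library(dripdsb)

sim <- simulate_experiment(simulation_params(), seed = 1)
profiles <- fold_change_profiles(sim$minus, sim$plus, sim$sites)
scores <- score_sites(profiles, sim$sites)
correlate_activity(scores)[c("r", "p", "n")]
#> $r
#> [1] 0.4112106
#> $p
#> [1] 2.35625e-05
#> $n
#> [1] 99

run_comparisons(scores)[, c("comparison", "n_a", "n_b", "alternative",
                            "p_raw", "p_adjusted")]
#>   comparison n_a n_b alternative       p_raw p_adjusted
#> 1   activity  49  50     greater 0.004737196 0.01421159
#> 2    pathway  45  54   two.sided 0.918793225 1.00000000
#> 3      genic  53  46   two.sided 0.944036373 1.00000000
```

The induction score correlates positively with transcriptional activity
(r ≈ 0.41, p ≈ 2e-05 on this seed) and the high-activity group scores
significantly higher than the low-activity group after Bonferroni
correction, while repair-pathway preference shows no effect — the
transcription-dependence signature the simulator encodes. On the paired
real libraries the same calls run unchanged:

```r
sites <- read_anchor_sites("asisi_sites.bed")     # BED6+3 with metadata
minus <- read_alignments("minusOHT.bam", "minusOHT")
plus  <- read_alignments("plusOHT.bam", "plusOHT")
```

An orchestrated run (`run_pipeline("config.yaml")`, or the
`inst/scripts/drip-dsb.R` wrapper) writes all tables, bedGraph tracks,
figures and a checksum manifest to the configured output directory; see
`inst/extdata/config_example.yaml`.

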