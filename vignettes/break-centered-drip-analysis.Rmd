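---
title: "Break-centered DRIP-seq analysis: model, parameters and design"
author: "dripdsb authors"
output: rmarkdown::html_document
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope

`dripdsb` quantifies DNA:RNA hybrid (R-loop) dynamics around
endonuclease-induced double-strand breaks from paired DRIP-seq libraries:
an undamaged (−OHT) and a damaged (+OHT) condition, plus an annotation of
AsiSI cut sites carrying per-site transcriptional activity (elongating
RNAPII occupancy), repair-pathway preference (HR/NHEJ) and genic status.
The pipeline starts from aligned reads; trimming and alignment are
upstream concerns, and DRIP-seq here is treated as strictly unstranded —
strand fields are discarded wherever they appear.

# The quantification model

## Coverage, normalization, fold change

For each anchor site the per-nucleotide read depth is computed over a
window of ±`half_width` nt around the cut (default 10,000, i.e. a 20-kb
window at single-nucleotide resolution; position 0 is the cut site, BED
0-based convention). Each condition is normalized to its total aligned
library size $N$, with a pseudocount of one read:

$$\mathrm{lfc}(x) \;=\; \log_2\frac{(d_{+}(x)+c)/N_{+}}{(d_{-}(x)+c)/N_{-}},
\qquad c = 1\ \text{read}.$$

The pseudocount policy deserves a word. Per-base depths of zero are
common, and a raw log-ratio would be undefined there; adding one read to
every position *before* normalization keeps the profile finite, makes the
transform exactly antisymmetric under condition swap (implemented as a
difference of logs, so the negation is bit-for-bit), and vanishes when
the two libraries are identical. The pseudocount is configurable;
`pseudocount = 0` is allowed only where no ratio is formed (raw browser
tracks). A consequence worth knowing: at positions where depth ≪ 1 read
the pseudocount dominates and `lfc` is pulled toward
$\log_2(N_-/N_+)$ rather than 0, so library-size imbalance leaves a
small uniform offset in sparse regions. This does not affect the grouped
comparisons or the correlation (they compare sites against each other
within one experiment) but is visible in metagene baselines.

## Induction score and statistics

Each site is reduced to the mean `lfc` over the 1-kb region centered on
the break (−500…+500 nt, 1,001 values). Scores are then compared:

* **high vs low transcriptional activity** — one-sided unpaired Wilcoxon
  rank-sum (high > low), the transcription-dependence hypothesis;
* **HR vs NHEJ** and **intragenic vs intergenic** — two-sided;
* Bonferroni correction over the comparisons actually run (3 by
  default);
* **Pearson correlation** of score against activity, two-sided t-test on
  $n-2$ degrees of freedom, with the least-squares line reported for
  plotting.

The rank-sum implementation wraps the standard test with an explicit
exactness policy: exact enumeration only when the pooled sample holds at
most 12 observations with no ties, otherwise the normal approximation
with tie and continuity corrections. Midranks handle ties throughout.
The one-sided direction for the activity comparison and the two-sided
choice elsewhere are defaults, not assertions about how the original
analyses were configured, and can be overridden in the config.

The high/low activity split is a median split by default (strictly above
the median is "high"); a fixed threshold can be supplied instead so an
externally published classification can be reproduced exactly.

## Aggregates

* **Metagene**: each site's profile is smoothed with a 200-nt centered
  moving average, then averaged positionwise within groups, unweighted
  across sites. Smoothing precedes grouping.
* **Heatmap**: per-site profiles binned into 200-nt bins; rows ordered by
  strictly descending activity (ties broken by site id); no clustering.
* **Browser tracks**: over a 200-kb window the two conditions are kept as
  separate normalized coverage tracks — no ratio — smoothed with a 500-nt
  moving average and binned into 200-nt bins.

The moving average truncates at array edges (the window shrinks to the
available values) so output length equals input length and positions stay
aligned to genomic coordinates. Even window sizes extend one position
further left than right; all defaults are even-symmetric in practice
because they are applied to odd-length windows with odd/even sizes that
make the asymmetry irrelevant at the scales involved. The last bin of
`bin_mean` may be shorter than `bin_size` and is averaged over the values
it actually holds.

# The synthetic-data generator

No public per-site quantitative model exists for this system, so the
generator encodes the minimal model consistent with the observed
phenomenology, with Poisson read starts and fixed-length (100 nt)
single-end unstranded reads:

| component | −OHT rate (starts/nt) | +OHT rate (starts/nt) |
|---|---|---|
| background | $b$ | $\rho_L\, b$ |
| gene body (±5 kb) | $k\,a_i$ | $\rho_L\, s\,k\,a_i$ |
| induced peak | — | $\rho_L\, g\,a_i\, e^{-x^2/2\sigma^2}$ (responders) |

with defaults $b = 10^{-3}$, $k = 5\times10^{-4}$ per activity unit,
shutdown factor $s = 0.2$ inside ±100 kb of the break, peak amplitude
$g = 2\times10^{-3}$ per activity unit with $\sigma = 400$ nt, library
ratio $\rho_L = 1.2$, and activities $a_i \sim \mathrm{LogNormal}(0,1)$
over 99 sites. Ten percent of sites are non-responders ($g$ forced to 0),
a mixture representing the observed minority of active sites with no
visible induction. Pathway and genic labels are fair coin flips
independent of activity, so those two comparisons are true nulls.
Because read *starts* are drawn from the Gaussian peak, the coverage
maximum sits ~half a read length (50 nt) to the right of the cut — well
inside every ±1-kb check the aggregate analysis uses.

Sites are placed evenly along a single synthetic contig at ≥200-kb
spacing so shutdown zones never overlap; the default contig is 21 Mb,
the smallest round size that admits 99 sites at that spacing. The
generator refuses infeasible combinations and reports the maximum
feasible site count. A closed-form `expected_profile()` (rate convolved
with the read footprint, normalized by expected library size) serves as
the analytic oracle for estimator checks.

What the simulator does *not* emulate — real genome sequence and AsiSI
motif placement, mappability, GC bias, fragment-length variation,
replicates, sequencing error — bounds what passing tests mean: they
demonstrate the estimators and tests are correct for the stated
stochastic model, not that the biology is this simple.

## The null configuration

For type-I calibration the "damage changes nothing" configuration is
`null_params()`: peak amplitude 0, shutdown factor 1 **and** library
ratio 1. Setting only the peak to zero would leave the
activity-dependent shutdown in place, so the activity tests would
(correctly) reject — that is power against a real effect, not a false
positive rate.

## A known limitation: Pearson under the null

Under `null_params()` the induction score has mean zero at every
activity, but its *variance* roughly doubles from the low- to the
high-activity tercile: at the default sequencing depth the per-base
depth is ~0.1–0.6 reads, and the noise of $\log_2(d+1)$ grows with the
rate in that regime. Log-normal activities put exactly those
high-variance sites at high leverage, and the Pearson t-test —
which assumes homoscedastic errors — then rejects at roughly 15–20%
instead of the nominal 5% (Spearman on the same scores is calibrated at
5%). This is a real property of applying Pearson correlation to
heteroscedastic, skew-leverage data at low coverage, and the package
reports it honestly (`scripts/acceptance.R` includes the measured null
rejection rate) rather than swapping in a different test: the Pearson
test is retained because it is the field's standard choice for this
figure. Users correlating low-coverage induction scores against skewed
covariates should prefer rank-based correlation when calibration
matters.

# Problem sizes and determinism

Default analyses run 99 sites with 20-kb windows (≈2M positions per
condition). The test suite and the acceptance script use 100 replicate
simulations for recovery rates and 200 for null calibration, computing
replicate scores over ±600-nt windows — the induction score depends only
on the central ±500 nt, so these scores are identical to those from the
full windows at a fraction of the cost; single-experiment results and
aggregate shapes always use the full window (and ±50 kb for
shutdown-flank metagenes). Every stochastic path is seeded: identical
`(params, seed)` reproduce experiments bit-for-bit, and the orchestrated
pipeline writes an md5 manifest so reruns can be diffed.

# Degenerate inputs and tie-breaks

* Empty site files parse to an empty set with a warning; empty libraries
  yield `total_aligned = 0` and normalization then refuses to divide.
* A chromosome absent from a library gives an all-zero window with a
  warning, not an error, so a few unplaced sites do not abort a run.
* All-equal activities make a median split label every site "low", with
  a warning.
* Heatmap row ties on activity fall back to site-id order; group labels
  never reorder within a group.
* A comparison with an empty group is skipped with a warning and the
  Bonferroni family shrinks accordingly.
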