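---
title: "Copy-number analysis of chromosomal instability: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Copy-number analysis of chromosomal instability: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`cinscope` quantifies chromosomal instability from binned read counts in
two regimes: shallow single-cell whole-genome sequencing of cell
populations, and ultra-low-pass whole-genome sequencing of FFPE
tumour/normal pairs. This vignette explains the models behind each stage,
the tunable parameters and their defaults, what the synthetic-data
generator does and does not emulate, and the design decisions taken where
the design was genuinely open.

## The synthetic data generator

The generator is first-class, tested code: it defines the study conditions
under which every downstream guarantee is measured.

**Genome.** The default desk-scale genome (`toy_genome()`) has 22
autosomes with human-proportioned lengths scaled by 1/30, tiled with fixed
500 kb half-open bins (about 200 bins; the bulk preset uses 100 kb bins,
about 960). Keeping the bin *width* at real-data values while scaling the
chromosome lengths preserves the per-bin coverage regime, but it shrinks
the number of bins per chromosome and per segment by the same factor — a
point that matters repeatedly below.

**Clones.** `simulate_clones()` grows each clone from a diploid ancestor:
shared events first, then whole-genome doubling (WGD) for flagged clones,
then private events — the order mirrors a doubled ancestor that continues
to acquire alterations, which is how a higher-ploidy subclone arises inside
a population. Events are contiguous ±1-copy runs confined to one
chromosome, placed on chromosomes in proportion to length, clipped to
`[0, max_state]`. Every event is logged so tests can replay the profile
exactly.

**Counts.** Single-cell counts are negative binomial. The mean follows the
proportionality law `mu_b ∝ state_b × width_b × gc_effect(gc_b) ×
mappability_b`, scaled to a per-cell depth drawn uniformly from
`reads_per_cell` (default: the 0.5–3 million reads/cell window, scaled with
the genome). The dispersion default (`overdispersion = 100`, i.e. variance
about twice Poisson at typical depth) describes a well-behaved single-cell
library; empirical dispersions for any particular platform vary, and the
parameter is exposed rather than claimed to be universal. A configurable
fraction of cells (`dropout_rate`, default 0.13 in the single-cell preset)
is emitted far below the read minimum, emulating wells that fail to yield
coverage. Bulk mixtures follow `mu_b ∝ rho·state_b + 2(1−rho)` for tumour
cellularity `rho` against a diploid normal; FFPE mode multiplies the means
by a per-bin log-normal factor (`ffpe_sd = 0.08`) for the noisier coverage
of archival material.

**GC and mappability.** The simulated GC effect is quadratic in GC
fraction, normalised to mean 1 — the simplest smooth shape the correction
stage can invert. Per-bin GC is drawn near-independently (a weak AR(1)
squashed into 0.33–0.62). This is a deliberate scaled-genome choice: one
desk bin stands for roughly 15 Mb of real genome, across which GC
autocorrelation has largely decayed, and strongly autocorrelated GC at
~200-bin scale would make GC strata coincide with copy-number segments,
rendering any GC fit unidentifiable.

**What the generator does not emulate:** read-level artefacts (duplicates,
mapping errors, adapter content), replication-timing waves, sequence-context
FFPE damage, subclonal structure within a bulk sample, and allele-specific
signal. Passing tests therefore demonstrate correctness of the
*quantitative machinery* under a faithful noise/bias model, not robustness
to every artefact of real libraries.

## Counts QC

**GC correction** fits a location curve of counts against GC over
equal-count GC quantile windows (at least ~25 usable bins per window) and
divides it out, preserving each cell's mean to within 1e-6 relative. Two
details depart from the most obvious construction, both forced by desk
scale. First, the per-window location estimate is a trimmed mean, not a
median: in a genome with mixed copy-number states the window *median*
snaps to whichever discrete state happens to dominate that window and the
fitted curve inherits up to two-fold jumps, while the mean averages the
state mixture consistently across windows so it cancels from the fitted
shape. Second, the fit is copy-number aware: a first pass yields rough
per-bin integer states, and the curve is refit on `count / state`. For
tumour/normal *mixtures* the integer rounding behind that refinement does
not hold (`cn_aware = FALSE`), and the bulk path instead iterates with
segment levels: correct blind → segment → refit the GC curve on
`count / segment-level` (free of copy-number structure, so a low-variance
robust quadratic is used) → resegment. Corrected values are also
width-normalised so the remainder bin at each chromosome end does not
masquerade as a loss.

**Cell filters** keep cells with total reads inside the configured window
(inclusive bounds — "between 0.5 and 3 million" is read conservatively) and
with even coverage. Evenness is measured as the coefficient of variation of
corrected bin values (`spikiness()`, default maximum 1.0): even cells score
~0.15, genuinely aneuploid cells ~0.3–0.6, and a cell with a fifth of its
reads in one bin scores ~2.7. A median-of-differences statistic was
rejected because it is blind to isolated spikes — exactly the failure mode
the filter exists to catch. The evenness criterion is a stand-in for an
unspecified upstream convention and is surfaced in the QC report.

## Segmentation and state calling

Change points are found per chromosome by hierarchical bisection on the
two-sample energy statistic (exponent `alpha = 1`): the accepted split is
always the argmax of `Q` over all valid splits of the segment, with at
least `min_seg_bins = 2` bins per side. Significance is a permutation test
(`n_permutations = 199`, threshold `p_threshold = 0.05`, the e-divisive
literature's default level).

The test statistic, however, is the maximum best-split energy over a
deterministic set of *seeded subintervals* (halving scales, 50 % overlap,
always including the full segment), compared against the identical
statistic under random relabelings. A plain full-segment statistic has
essentially no power when one segment holds several change points — on
desk-scale chromosomes of 4–17 bins the first split of a three-level
chromosome stalls at p ≈ 0.05–0.14 — while scanning subintervals isolates
each change. Because the permuted statistic is the same maximum, the test
stays exchangeable-valid: on pure noise, splits are accepted at no more
than the nominal rate. Split *placement* is untouched, so the argmax
contract holds exactly.

Integer states are then called by ploidy-grid scaling: segment means are
rescaled so their length-weighted mean equals a candidate ploidy `f`
(grid 1.5–6.0 by 0.05), scored by `sum(len × |scaled − round(scaled)|)`,
ties to the lowest ploidy. This makes the flat tetraploid genome
deliberately ambiguous (it calls as diploid) while a single odd-state
segment resolves the doubled scale — the correct behaviour for total-copy
data. Finally, maximal runs shorter than `min_cna_size = 0.8 Mb` whose
state differs from both flanks are absorbed into the longer flank,
iterated to a fixpoint.

## Absolute copy number from bulk profiles

Relative profiles are segment medians normalised by a refined modal level
(the weighted mean of all segments within 8 % of the weighted median — one
segment's median noise must not set the global scale). Each segment also
carries a robust standard error (MAD-based; no normal-theory efficiency
factor, which over-states the error for this right-skewed noise).

The cellularity/ploidy fit evaluates, on a `(rho, psi)` grid, the
chi-square of segment residuals against those standard errors after
mapping each segment to its nearest integer state under the mixture law.
The raw squared-error surface of the obvious construction is degenerate in
three distinct ways, and each safeguard answers one of them:

* **Noise interpolation.** At low cellularity the state lattice becomes
  dense enough to interpolate the noise, driving raw error to zero.
  Noise-normalised residuals plus an AIC-like complexity charge
  (`complexity = 3` chi-square units per *spanned* state) make every extra
  state cost more than the noise it absorbs.
* **State-multiple aliases.** Doubling all states (adjusting `rho`, `psi`)
  fits identically; sub-lattice solutions are detected outright (used
  states sharing a common step ≥ 2) and down-weighted, and a mild
  near-diploid parsimony prior (`1 + 0.3 (psi − 2)^2`) with a weak
  high-cellularity preference (`rho^-0.1`) resolves what remains. The
  genome-doubled alternative stays visible in the ranked minima, as it
  must for genuinely doubled tumours.
* **Grid phase error.** The grid never evaluates a candidate exactly at
  its optimum (at `rho = 0.2` the 0.01 grid step alone costs about one
  sigma per high-state segment), so the leading grid minima are polished
  by iterating state assignment with weighted linear least squares — the
  model is linear in `(rho/D, 2(1−rho)/D)` — before the final ranking.

The reported tumour ploidy inverts the *continuous* weighted mean level
through the mixture law rather than averaging discrete assignments, which
at low purity are individually unreliable. An additional per-segment
systematic component (residual normalisation error) is estimated from the
spread of the modal segments and folded into the standard errors, scaled
with the level.

Per-segment precision sets a hard identifiability limit: recovering
cellularity to ±0.05 at `rho = 0.2` requires relative segment precision
near 1 %, which real data achieves with segments of hundreds of bins. The
package's recovery experiments therefore simulate at 6.25 kb bins (about
15,000 bins — still several-fold coarser than a faithful scaling of the
real bin *count* onto the 1/30 genome) and the real per-sample depth,
while the pipeline presets keep 100/500 kb bins for desk cost. Under those
conditions recovery is exact across `rho` 0.2–0.8; at the preset's 100 kb
bins, low-cellularity fits are honestly reported as ranked alternatives
rather than forced.

The cellularity sweep reclassifies segments (gain/neutral/loss against
baseline `round(psi)`) across an assumed-cellularity range and reports the
length-weighted fraction that changes class relative to the reference.
Profiles pass through the 0.8 Mb CNA filter before classification —
sub-threshold alterations are excluded from analysis by convention, and at
an assumed cellularity of 0.1 the inversion amplifies modal noise
twenty-fold into exactly such single-segment flips.

## Heterogeneity metrics

FGA is the length fraction of non-masked genome deviating from baseline 2;
the ploidy-corrected variant uses the population's length-weighted mean
state rounded half-up (per-cell baselines are available via
`per_cell = TRUE`; the population baseline is the primary definition since
the corrected metric describes deviation from the population's own
ploidy). Per-cell Shannon entropy uses the length-share distribution over
states, in bits by default (the base is a parameter; the upstream
convention this metric follows does not pin it down). A per-bin population
entropy (`bin_entropy()`) is provided as a secondary statistic. Group
comparisons are two-sample t-tests, Welch by default, with the
pooled-variance variant available.

## Copy-number phylogenetics

Minimum consistent segmentation takes the union of all cells' segment
boundaries and merges adjacent shared segments with identical state
vectors; since every retained boundary is a state change in some cell, the
result is provably minimal among exact representations (verified against
exhaustive search in the tests). The minimum-event distance counts
contiguous ±1 events transforming one total-copy profile into another,
with states never below 0 and a zero-state segment never regaining copies;
it is computed in closed form from positive jumps of the gain and loss
requirement sequences, with zero-state positions splitting runs, per
chromosome. Directions can differ (zero-state loss is irreversible), so
the symmetrised distance is the minimum of the two; pairs infeasible in
both directions are flagged and given a finite surrogate (the same jump
count with the zero-increment rule relaxed) so trees remain buildable.
This single-step event model is a deliberate simplification: there is no
WGD event, so genome-doubled cells legitimately appear as distant clades.

Trees are neighbor joining; clades cut the tree's patristic distances with
k-medoids (PAM). Linkage-based cutting was rejected after measurement:
with called (hence noisy) profiles it hands whole clades to single outlier
cells, scoring near-zero adjusted Rand index even when between-clone
distances are twice within-clone ones; PAM on the identical distances
recovers the clones. `k` defaults to the silhouette optimum over 2–8 and
is overridable. Pseudobulks merge raw counts over a cell subset and rerun
the bulk path at cellularity 1.

## Focal events and the pipeline

Focal events are maximal constant-state runs no longer than
`max_focal_length` with state at least `2·round(psi) + 1` (amplification)
or at most `round(psi) − 2`, floored at 0 (deletion); touching qualifying
runs merge first. No numeric definition of "focal" is inherited from any
convention — the thresholds are declared defaults, config-exposed. On the
desk genome the preset focal cap is 5 Mb so that sub-arm events qualify
while whole-chromosome changes (whose chromosomes are only ~8 Mb at 1/30
scale) do not. Gene annotation is half-open interval overlap against a BED
table, reported in coordinate order whatever the file order, with a
configurable CIN-associated list.

`run_pipeline()` chains the stages for either preset, echoes the resolved
configuration, logs per-stage timings, and writes an MD5 manifest of every
output; identical config and seed reproduce identical checksums. Stage
randomness comes from per-cell RNG streams derived from the global seed
and the cell id, so results do not depend on evaluation order.

## Problem sizes and known limitations

The default test and acceptance runs use: 20 cells at 100 kb bins and
full per-cell depth for breakpoint recovery, 12 diploid cells for state
accuracy, 60 cells for clone recovery, 30 + 30 cells for the two-population
contrast, 10 FFPE tumours (20 injected focal events) with matched normals,
and 16-cell pipeline runs for determinism — sizes chosen so the whole
suite runs on a laptop in minutes while every estimate retains a
comfortable margin over its acceptance bound. Where a check needs the
per-segment information of the real data (cellularity recovery, the sweep,
breakpoint and focal recovery), the simulation keeps the real per-sample
read totals and bins fine enough to restore the real bins-per-segment,
rather than scaling both down with the genome; the pipeline presets keep
the coverage-preserving scaling for desk cost.

Known limitations: total-copy-number only (no allele-specific or phased
signal); the event distance approximates a full evolutionary model (no
WGD operation); cellularity/ploidy identification at or below 0.2 purity
is information-limited at coarse binning; and the evenness and focal
thresholds are declared conventions, not community standards.
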