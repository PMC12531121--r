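# cinscope

Quantifying chromosomal instability (CIN) from binned sequencing counts.

Cholangiocarcinoma and many other tumours continually gain and lose whole
chromosomes and chromosome arms. Two sequencing designs expose that
instability: shallow single-cell whole-genome sequencing (DLP-style, a few
hundred cells at 0.5-3 million reads each) shows cell-to-cell copy-number
heterogeneity directly, and ultra-low-pass whole-genome sequencing of FFPE
tumour/normal pairs (1-2 million reads per sample) shows the averaged
copy-number landscape of a cohort. `cinscope` implements the full analysis
path for both designs, starting from bin-level read counts, together with a
synthetic-data generator that emulates both designs with known ground truth
so that every stage is testable without any sequencing data.

The pipeline stages, each exposed as ordinary R functions:

* **Simulation** — clonal copy-number profiles built from a diploid ancestor
  (shared events, whole-genome doubling, private events), negative-binomial
  bin counts with GC/mappability bias, tumour/normal bulk mixtures with
  FFPE-style extra noise, focal-event injection over genes
  (`simulate_clones()`, `simulate_cell_counts()`, `simulate_bulk()`,
  `inject_focal_events()`).
* **Counts QC** — GC correction (trimmed-mean quantile windows with a
  copy-number-aware refinement), mappability correction, blacklisting, and
  the cell filters: 0.5-3M reads per cell and even coverage
  (`correct_gc()`, `correct_mappability()`, `filter_cells()`).
* **Segmentation and state calling** — e-divisive change-point detection on
  the energy statistic

      Q(tau) = (m k / (m + k)) (2 E|X - Y|^a - E|X - X'|^a - E|Y - Y'|^a)

  with permutation significance, followed by integer copy-number calling by
  ploidy-grid scaling and a 0.8 Mb minimum-CNA filter
  (`edivisive_segment()`, `call_states()`, `filter_small_cnas()`).
* **Absolute copy number** — relative segment profiles, grid fitting of
  cellularity rho and tumour ploidy psi under the mixture law

      E(n; rho, psi) = (rho n + 2 (1 - rho)) / (rho psi + 2 (1 - rho))

  with ranked alternative solutions (including genome-doubled aliases), and
  a cellularity sensitivity sweep (`fit_absolute()`, `to_absolute()`,
  `cellularity_sweep()`).
* **Heterogeneity metrics** — fraction of genome altered (FGA), FGA
  corrected for the population's mean ploidy, per-cell Shannon entropy,
  per-bin gain/loss frequencies, and two-sample group comparisons
  (`fga()`, `shannon_entropy()`, `cna_frequency()`, `compare_groups()`).
* **Copy-number phylogenetics** — minimum consistent segmentation, the
  minimum-event distance on total copy numbers (contiguous +-1 events,
  state 0 absorbing), neighbor-joining trees, clade assignment, and
  per-clade pseudobulks (`minimum_consistent_segmentation()`,
  `event_distance()`, `build_tree()`, `pseudobulk()`).
* **Focal events** — short high-amplitude amplification/deletion calling on
  absolute profiles and gene annotation against a BED table with a
  CIN-associated gene list (`call_focal_events()`, `annotate_genes()`).

`run_pipeline()` orchestrates everything from a single validated config
(`pipeline_config()`, presets `"single-cell"` and `"bulk-ffpe"`), writing
TSV/BED/Newick outputs, a resolved-config echo, a stage log, and a checksum
manifest. A thin command-line wrapper lives at `inst/cli/cinscope.R`.

## Worked example

Simulate a three-clone cell population on the desk-scale genome, call
per-cell copy numbers, and measure its heterogeneity:

```r
library(cinscope)

genome <- toy_genome()                       # 22 autosomes, 1/30 scale
track  <- make_bin_track(genome, seed = 7)
clones <- simulate_clones(genome, n_clones = 3, n_shared_events = 3,
                          n_private_events = 12,
                          event_length_range = c(4e6, 8e6), seed = 301)
noise  <- noise_model(reads_per_cell = c(2e6, 3e6) / 30)
cells  <- simulate_cell_counts(clones, n_cells = 24, noise, track,
                               seed = 302)
cells
#> cell_counts: 24 cells x 202 bins; reads/cell 67577-99596 (median 78658)

corrected <- correct_mappability(correct_gc(cells, track), track)
profiles <- lapply(seq_len(24), function(i)
  segment_profile(corrected[i, ], genome, seed = 300 + i))
profiles[[1]]
#> cn_profile: 202 bins, 24 segments, mean ploidy 1.91

pop <- cn_population(profiles,
                     groups = paste0("clone", cells$truth$clone))
report <- heterogeneity_report(pop)
round(tapply(report$per_cell$fga, report$per_cell$group, mean), 3)
#> clone1 clone2 clone3
#>  0.506  0.258  0.373

tree <- build_tree(event_distance_matrix(
  minimum_consistent_segmentation(pop)), k = 3)
table(tree$clades, cells$truth$clone)
#>    
#>      1  2  3
#>   1  0  9  0
#>   2 10  0  0
#>   3  0  0  5
```

Each clade contains cells of exactly one simulated clone (clade labels are
arbitrary); the per-clone mean FGA values are the fractions of the genome
each clone's cells deviate from copy number 2.

The whole pipeline, end to end:

```r
cfg <- pipeline_config("single-cell", n_cells = 48, seed = 1L)
run_pipeline(cfg, "out_sc")      # counts, QC, segments, metrics, tree, ...
```

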