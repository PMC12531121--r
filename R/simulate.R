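#' Noise model for simulated count data
#'
#' Bundles the count-noise parameters used by [simulate_cell_counts()] and
#' [simulate_bulk()]. Counts are negative-binomial: the mean follows the
#' copy-number proportionality law and the variance is
#' `mu + mu^2 / overdispersion`, so `overdispersion -> Inf` recovers Poisson.
#'
#' @param reads_per_cell Length-2 numeric, min and max total reads per cell.
#'   Each cell's target depth is drawn uniformly from this range.
#' @param gc_bias_coeffs Quadratic coefficients `c(c0, c1, c2)` of the GC
#'   effect `c0 + c1*gc + c2*gc^2`, normalised to mean 1 over usable bins.
#' @param overdispersion Negative-binomial size parameter (> 0).
#' @param dropout_rate Fraction of cells emitted as dropouts (total reads
#'   below the minimum), in `[0, 1)`.
#' @param ffpe_sd Standard deviation of the extra per-bin log-normal noise
#'   applied in FFPE bulk mode; 0 disables it.
#' @return A `noise_model` list.
#' @export
noise_model <- function(reads_per_cell = c(0.5e6, 3e6) / 30,
                        gc_bias_coeffs = c(-1.5, 11, -11),
                        overdispersion = 100,
                        dropout_rate = 0,
                        ffpe_sd = 0.08) {
  if (length(reads_per_cell) != 2L || reads_per_cell[1] >= reads_per_cell[2]) {
    stop("reads_per_cell must be (min, max) with min < max")
  }
  if (overdispersion <= 0) stop("overdispersion must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(reads_per_cell = reads_per_cell,
                 gc_bias_coeffs = gc_bias_coeffs,
                 overdispersion = overdispersion,
                 dropout_rate = dropout_rate,
                 ffpe_sd = ffpe_sd),
            class = "noise_model")
}

gc_effect <- function(gc, coeffs, usable = rep(TRUE, length(gc))) {
  eff <- coeffs[1] + coeffs[2] * gc + coeffs[3] * gc^2
  eff <- pmax(eff, 0.05)
  eff / mean(eff[usable])
}

#' Simulate clonal copy-number profiles
#'
#' Builds `n_clones` integer copy-number profiles from a diploid ancestor.
#' Shared events are applied to the ancestor first; clones flagged for
#' whole-genome doubling (WGD) then have all states doubled; private events
#' are applied last, mirroring a doubled ancestor that keeps acquiring CNAs.
#' Each event is a contiguous run of bins on one chromosome (events never
#' cross chromosome boundaries) shifted by +1 or -1 copy; states are clipped
#' to `[0, max_state]`.
#'
#' @param genome A `genome_layout`.
#' @param n_clones Number of clones (>= 1).
#' @param n_shared_events Events shared by all clones (applied pre-WGD).
#' @param n_private_events Private events per clone.
#' @param event_length_range Length-2 numeric, event length range in bp.
#' @param wgd_clones Integer indices of clones with whole-genome doubling.
#' @param proportions Clone proportions; default equal. Must sum to 1.
#' @param max_state Maximum copy-number state.
#' @param seed Integer seed; output is fully reproducible.
#' @return A `clone_set`: list with `profiles` (clones x bins integer matrix),
#'   `proportions`, `wgd`, `events` (data.frame log of every event applied:
#'   clone, scope, chrom, start bp, end bp, bin indices, delta).
#' @export
simulate_clones <- function(genome, n_clones = 3, n_shared_events = 5,
                            n_private_events = 5,
                            event_length_range = c(1e6, 8e6),
                            wgd_clones = integer(0),
                            proportions = NULL,
                            max_state = 10, seed = 1L) {
  if (n_clones < 1) stop("n_clones must be >= 1")
  if (event_length_range[1] < genome$bin_size) {
    stop("event lengths must be at least one bin")
  }
  if (event_length_range[2] > max(genome$chromosomes$length)) {
    stop("event length exceeds the longest chromosome")
  }
  if (is.null(proportions)) proportions <- rep(1 / n_clones, n_clones)
  if (abs(sum(proportions) - 1) > 1e-9) stop("proportions must sum to 1")
  rng <- local_rng(seed, "clones")
  nb <- n_bins(genome)
  bins <- genome$bins

  draw_event <- function() {
    len <- rng$runif(1, event_length_range[1], event_length_range[2])
    n_ev_bins <- max(1L, round(len / genome$bin_size))
    repeat {
      # chromosome weighted by length; reject if the event does not fit
      ci <- rng$sample(nrow(genome$chromosomes), 1,
                       prob = genome$chromosomes$length)
      idx <- which(as.integer(bins$chrom) == ci)
      if (length(idx) >= n_ev_bins) break
    }
    s <- idx[rng$sample_int(length(idx) - n_ev_bins + 1L, 1L)]
    delta <- if (rng$runif(1) < 0.5) -1L else 1L
    list(bin_from = s, bin_to = s + n_ev_bins - 1L, delta = delta)
  }

  apply_event <- function(profile, ev) {
    span <- ev$bin_from:ev$bin_to
    pmin(pmax(profile[span] + ev$delta, 0L), as.integer(max_state)) ->
      profile[span]
    profile
  }

  log_rows <- list()
  add_log <- function(clone, scope, ev) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      clone = clone, scope = scope,
      chrom = as.character(bins$chrom[ev$bin_from]),
      start = bins$start[ev$bin_from], end = bins$end[ev$bin_to],
      bin_from = ev$bin_from, bin_to = ev$bin_to, delta = ev$delta)
  }

  ancestor <- rep(2L, nb)
  if (n_shared_events > 0) {
    for (k in seq_len(n_shared_events)) {
      ev <- draw_event()
      ancestor <- apply_event(ancestor, ev)
      add_log(NA_integer_, "shared", ev)
    }
  }
  profiles <- matrix(0L, nrow = n_clones, ncol = nb,
                     dimnames = list(paste0("clone", seq_len(n_clones)), NULL))
  for (cl in seq_len(n_clones)) {
    p <- ancestor
    if (cl %in% wgd_clones) p <- pmin(p * 2L, as.integer(max_state))
    if (n_private_events > 0) {
      for (k in seq_len(n_private_events)) {
        ev <- draw_event()
        p <- apply_event(p, ev)
        add_log(cl, "private", ev)
      }
    }
    profiles[cl, ] <- p
  }
  structure(list(profiles = profiles, proportions = proportions,
                 wgd = seq_len(n_clones) %in% wgd_clones,
                 events = if (length(log_rows)) do.call(rbind, log_rows)
                          else data.frame(),
                 genome = genome),
            class = "clone_set")
}

#' Simulate single-cell binned read counts
#'
#' Assigns each cell to a clone (multinomially by clone proportion) and draws
#' negative-binomial counts per bin. The expected count in bin `b` is
#' proportional to `state_b * width_b * gc_effect(gc_b) * mappability_b`,
#' scaled so the cell's expected total equals a depth drawn uniformly from
#' the noise model's `reads_per_cell` range. Dropout cells (probability
#' `dropout_rate`) are emitted with a total well below the minimum, mimicking
#' wells that fail to yield coverage. Blacklisted bins are emitted normally;
#' masking them is the QC stage's job.
#'
#' @param clones A `clone_set` from [simulate_clones()].
#' @param n_cells Number of cells.
#' @param noise A `noise_model`.
#' @param track A `bin_track` aligned with the clone set's genome.
#' @param seed Integer seed.
#' @return A `cell_counts` object (see [cell_counts()]) carrying the
#'   ground-truth clone assignment in `$truth`.
#' @export
simulate_cell_counts <- function(clones, n_cells, noise, track, seed = 1L) {
  if (!inherits(clones, "clone_set") || nrow(clones$profiles) == 0) {
    stop("empty clone list")
  }
  rng <- local_rng(seed, "cell_counts")
  genome <- clones$genome
  nb <- n_bins(genome)
  stopifnot(nrow(track) == nb)
  usable <- !track$blacklisted
  eff <- gc_effect(track$gc, noise$gc_bias_coeffs, usable) * track$mappability
  w <- bin_widths(genome) / genome$bin_size

  clone_of <- rng$sample(nrow(clones$profiles), n_cells, replace = TRUE,
                         prob = clones$proportions)
  dropout <- rng$runif(n_cells) < noise$dropout_rate
  depth <- rng$runif(n_cells, noise$reads_per_cell[1], noise$reads_per_cell[2])
  depth[dropout] <- rng$runif(sum(dropout), 0.02, 0.5) * noise$reads_per_cell[1]

  counts <- matrix(0L, nrow = n_cells, ncol = nb)
  for (i in seq_len(n_cells)) {
    lambda <- clones$profiles[clone_of[i], ] * w * eff
    mu <- lambda / sum(lambda) * depth[i]
    counts[i, ] <- rng$rnbinom(nb, size = noise$overdispersion, mu = mu)
  }
  ids <- sprintf("cell%03d", seq_len(n_cells))
  rownames(counts) <- ids
  cc <- cell_counts(counts, genome)
  cc$truth <- list(clone = clone_of, dropout = dropout,
                   clone_profiles = clones$profiles,
                   events = clones$events)
  cc
}

#' Simulate low-pass bulk counts for a tumour/normal mixture
#'
#' Expected count per bin follows the mixture law
#' `mu_b \propto (rho * state_b + 2 * (1 - rho)) * gc_effect * mappability`,
#' where `rho` is the tumour cellularity and the contaminating normal is
#' diploid. In FFPE mode an extra log-normal per-bin factor (sd
#' `noise$ffpe_sd`) models the noisier coverage of archival material.
#'
#' @param tumour_profile Integer copy-number state per bin.
#' @param genome A `genome_layout`.
#' @param cellularity Tumour cell fraction `rho` in `(0, 1]`; `rho` may be 0
#'   only through `simulate_bulk(..., cellularity = 0)` being rejected — use
#'   a diploid profile for a pure normal.
#' @param total_reads Expected total read count for the sample.
#' @param noise A `noise_model`.
#' @param track A `bin_track`.
#' @param ffpe Logical, add FFPE-style extra bin noise.
#' @param seed Integer seed.
#' @return Integer vector of counts per bin, with the expected per-bin mean
#'   in attribute `"mu"`.
#' @export
simulate_bulk <- function(tumour_profile, genome, cellularity, total_reads,
                          noise, track, ffpe = TRUE, seed = 1L) {
  if (cellularity < 0 || cellularity > 1) {
    stop("cellularity must be in [0, 1]")
  }
  rng <- local_rng(seed, "bulk")
  nb <- n_bins(genome)
  stopifnot(length(tumour_profile) == nb, nrow(track) == nb)
  usable <- !track$blacklisted
  eff <- gc_effect(track$gc, noise$gc_bias_coeffs, usable) * track$mappability
  w <- bin_widths(genome) / genome$bin_size
  mix <- cellularity * tumour_profile + 2 * (1 - cellularity)
  lambda <- mix * w * eff
  mu <- lambda / sum(lambda) * total_reads
  if (ffpe && noise$ffpe_sd > 0) {
    mu <- mu * exp(rng$rnorm(nb, -noise$ffpe_sd^2 / 2, noise$ffpe_sd))
  }
  out <- rng$rnbinom(nb, size = noise$overdispersion, mu = mu)
  attr(out, "mu") <- mu
  out
}

#' Inject focal amplifications and deletions over genes
#'
#' Places `n_amps` focal amplifications and `n_dels` focal deletions on a
#' copy-number profile, each overlapping a randomly chosen gene from
#' `genes`. Event intervals cover the gene and extend by a random margin, up
#' to `max_len` bp, without crossing chromosome boundaries.
#'
#' @param profile Integer copy-number state per bin.
#' @param genome A `genome_layout`.
#' @param genes Gene table: data.frame with `chrom`, `start`, `end`, `name`
#'   (0-based half-open, BED-style).
#' @param n_amps,n_dels Numbers of amplifications and deletions.
#' @param amp_state Copy-number state assigned to amplifications.
#' @param del_state State assigned to deletions (default 0, homozygous loss).
#' @param max_len Maximum event length in bp.
#' @param min_len Minimum event length in bp (events are widened
#'   symmetrically to reach it, so they stay above downstream size filters).
#' @param seed Integer seed.
#' @return List with `profile` (modified states) and `events` (data.frame
#'   log: type, chrom, start, end, state, gene).
#' @export
inject_focal_events <- function(profile, genome, genes, n_amps = 1,
                                n_dels = 0, amp_state = 8, del_state = 0,
                                max_len = 3e6, min_len = 1e6, seed = 1L) {
  rng <- local_rng(seed, "focal")
  bins <- genome$bins
  log <- list()
  place <- function(type, state) {
    g <- genes[rng$sample(nrow(genes), 1L), ]
    idx <- which(as.character(bins$chrom) == g$chrom)
    gene_bins <- idx[bins$start[idx] < g$end & bins$end[idx] > g$start]
    if (length(gene_bins) == 0L) stop("gene outside binned genome: ", g$name)
    span <- range(gene_bins)
    max_extra <- max(0L, floor(max_len / genome$bin_size) -
                       (span[2] - span[1] + 1L))
    lo <- max(min(idx), span[1] - rng$sample_int(max_extra + 1L, 1L) + 1L)
    hi <- min(max(idx), span[2] + rng$sample_int(max_extra + 1L, 1L) - 1L)
    min_bins <- ceiling(min_len / genome$bin_size)
    while (hi - lo + 1L < min_bins && (lo > min(idx) || hi < max(idx))) {
      if (lo > min(idx)) lo <- lo - 1L
      if (hi - lo + 1L < min_bins && hi < max(idx)) hi <- hi + 1L
    }
    # a chromosome flank shorter than the downstream minimum-CNA size would
    # be absorbed into the event anyway; make the truth own it
    reserve <- ceiling(0.8e6 / genome$bin_size)
    if (lo - min(idx) < reserve) lo <- min(idx)
    if (max(idx) - hi < reserve) hi <- max(idx)
    profile[lo:hi] <<- as.integer(state)
    log[[length(log) + 1L]] <<- data.frame(
      type = type, chrom = g$chrom, start = bins$start[lo], end = bins$end[hi],
      state = as.integer(state), gene = g$name)
  }
  if (n_amps > 0) for (k in seq_len(n_amps)) place("amp", amp_state)
  if (n_dels > 0) for (k in seq_len(n_dels)) place("del", del_state)
  list(profile = profile,
       events = if (length(log)) do.call(rbind, log) else
         data.frame(type = character(), chrom = character(),
                    start = numeric(), end = numeric(),
                    state = integer(), gene = character()))
}

#' Toy cancer-gene table for the desk-scale genome
#'
#' Gene intervals on the scaled toy genome, placed at positions proportional
#' to the corresponding human genes' GRCh38 coordinates. Includes the
#' CIN-associated genes highlighted by the focal-event screen (CCNE1, BRCA1,
#' MDM2, KRAS, CDK6, CDK13) plus common cancer-census genes.
#'
#' @param genome A `genome_layout` from [toy_genome()].
#' @param scale The same scale factor used for the genome.
#' @return BED-style data.frame: `chrom`, `start`, `end`, `name`.
#' @export
toy_genes <- function(genome, scale = 1 / 30) {
  # (chrom, approximate GRCh38 midpoint in Mb, name)
  tbl <- data.frame(
    chrom = c("chr12", "chr12", "chr7", "chr7", "chr17", "chr19",
              "chr8", "chr17", "chr9", "chr3", "chr5", "chr18"),
    mid_mb = c(68.8, 25.2, 92.6, 40.1, 43.1, 29.8,
               127.7, 7.6, 21.9, 178.9, 1.3, 51.0),
    name = c("MDM2", "KRAS", "CDK6", "CDK13", "BRCA1", "CCNE1",
             "MYC", "TP53", "CDKN2A", "PIK3CA", "TERT", "SMAD4")
  )
  start <- round(tbl$mid_mb * 1e6 * scale - 5e4)
  chrom_len <- stats::setNames(genome$chromosomes$length,
                               genome$chromosomes$name)
  start <- pmax(0, pmin(start, chrom_len[tbl$chrom] - 1e5))
  data.frame(chrom = tbl$chrom, start = start, end = start + 1e5,
             name = tbl$name, row.names = NULL)
}
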