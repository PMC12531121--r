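# Independent oracles and small fixture builders used across the suite.

# Brute-force energy statistic for every split: direct double-sum evaluation,
# independent of the cumulative-sum implementation under test.
brute_energy_splits <- function(x, alpha = 1, min_seg_bins = 2) {
  n <- length(x)
  vapply(seq_len(n - 1), function(tau) {
    m <- tau; k <- n - tau
    if (m < min_seg_bins || k < min_seg_bins) return(-Inf)
    l <- x[1:tau]; r <- x[(tau + 1):n]
    cross <- mean(abs(outer(l, r, "-"))^alpha)
    wl <- if (m > 1) sum(abs(outer(l, l, "-"))^alpha) / (m * (m - 1)) else 0
    wr <- if (k > 1) sum(abs(outer(r, r, "-"))^alpha) / (k * (k - 1)) else 0
    (m * k / (m + k)) * (2 * cross - wl - wr)
  }, numeric(1))
}

# Minimum-event-distance oracle: breadth-first search over the event graph.
# Events add +1/-1 on a contiguous run; -1 needs all states >= 1 in the run,
# +1 needs all states >= 1 too (a 0-state segment can never be regained).
# Encodes states in base (max_state+1); built once per (length, max_state)
# as a directed igraph and queried in C.
event_graph <- local({
  cache <- list()
  function(len, max_state) {
    key <- paste(len, max_state)
    if (!is.null(cache[[key]])) return(cache[[key]])
    base <- max_state + 1L
    n_nodes <- base^len
    codes <- 0:(n_nodes - 1)
    dec <- sapply(seq_len(len), function(i) (codes %/% base^(i - 1)) %% base)
    dec <- matrix(dec, ncol = len)
    from <- integer(0); to <- integer(0)
    for (lo in seq_len(len)) for (hi in lo:len) {
      run <- lo:hi
      ok_min <- rowSums(dec[, run, drop = FALSE] >= 1) == length(run)
      up_ok <- ok_min & rowSums(dec[, run, drop = FALSE] <= max_state - 1) ==
        length(run)
      delta <- sum(base^(run - 1))
      from <- c(from, codes[up_ok], codes[ok_min])
      to <- c(to, codes[up_ok] + delta, codes[ok_min] - delta)
    }
    gr <- igraph::graph_from_edgelist(cbind(from + 1, to + 1), directed = TRUE)
    res <- list(graph = gr, base = base, len = len)
    cache[[key]] <<- res
    res
  }
})

encode_state <- function(v, base) sum(v * base^(seq_along(v) - 1)) + 1

bfs_event_distance <- function(a, b, max_state = max(c(a, b, 1))) {
  stopifnot(length(a) == length(b))
  eg <- event_graph(length(a), max_state)
  d_ab <- igraph::distances(eg$graph, v = encode_state(a, eg$base),
                            to = encode_state(b, eg$base), mode = "out")[1, 1]
  d_ba <- igraph::distances(eg$graph, v = encode_state(b, eg$base),
                            to = encode_state(a, eg$base), mode = "out")[1, 1]
  min(d_ab, d_ba)
}

# Exhaustive minimum consistent segmentation: try all boundary subsets.
brute_mcs_count <- function(states) {   # states: cells x bins matrix
  nb <- ncol(states)
  if (nb == 1) return(1L)
  cuts <- nb - 1L
  best <- nb
  for (mask in 0:(2^cuts - 1)) {
    bnd <- which(bitwAnd(mask, 2^(0:(cuts - 1))) > 0)
    starts <- c(1L, bnd + 1L)
    ends <- c(bnd, nb)
    ok <- TRUE
    for (s in seq_along(starts)) {
      seg <- states[, starts[s]:ends[s], drop = FALSE]
      if (any(seg != seg[, 1])) { ok <- FALSE; break }
    }
    if (ok && length(starts) < best) best <- length(starts)
  }
  best
}

# True breakpoints (segment starts per chromosome) from a truth profile.
truth_breakpoints <- function(truth, genome) {
  bps <- list()
  for (ch in levels(genome$bins$chrom)) {
    idx <- which(genome$bins$chrom == ch)
    bps[[ch]] <- idx[c(1L, which(diff(truth[idx]) != 0) + 1L)]
  }
  bps
}

# Designed balanced bulk test profile: states 0-6, mean ploidy 2, every
# non-diploid state represented on several chromosomes.
designed_bulk_profile <- function(genome) {
  prof <- rep(2L, nrow(genome$bins))
  set_block <- function(ch, st, frac) {
    idx <- which(genome$bins$chrom == ch)
    prof[idx[1:floor(length(idx) * frac)]] <<- as.integer(st)
  }
  set_block("chr1", 1, 0.7); set_block("chr3", 1, 0.7)
  set_block("chr5", 1, 0.7); set_block("chr9", 1, 0.6)
  set_block("chr6", 0, 0.5); set_block("chr17", 0, 0.5)
  set_block("chr2", 3, 0.6); set_block("chr7", 3, 0.6)
  set_block("chr12", 3, 0.5)
  set_block("chr4", 4, 0.5); set_block("chr15", 4, 0.5)
  set_block("chr8", 6, 0.3); set_block("chr19", 6, 0.3)
  prof
}

# Shared small fixtures
tiny_genome <- function(n_chrom = 1, chrom_len = 1e7, bin_size = 5e5) {
  make_genome(stats::setNames(rep(chrom_len, n_chrom),
                              paste0("chr", seq_len(n_chrom))), bin_size)
}

flat_track <- function(genome) {
  structure(data.frame(gc = rep(0.45, nrow(genome$bins)),
                       mappability = 1,
                       blacklisted = FALSE),
            class = c("bin_track", "data.frame"))
}

make_profile <- function(states, genome, masked = rep(FALSE, length(states))) {
  cn_profile(as.integer(states), genome, masked = masked)
}
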