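#' Build a binned genome layout
#'
#' Tiles each chromosome with fixed-width, half-open `[start, end)` bins.
#' Every bin has width `bin_size` except possibly the last bin of each
#' chromosome, which absorbs the remainder.
#'
#' @param chrom_lengths Numeric vector of chromosome lengths in bp. Names are
#'   used as chromosome names; unnamed vectors get `"chr1"`, `"chr2"`, ...
#' @param bin_size Bin width in bp.
#' @return An object of class `genome_layout`: a list with `chromosomes`
#'   (data.frame of `name`, `length`), `bin_size`, and `bins` (data.frame of
#'   `chrom`, `start`, `end`, 0-based half-open, in chromosome order then
#'   coordinate order).
#' @examples
#' g <- make_genome(c(chrA = 1.2e6), bin_size = 5e5)
#' g$bins
#' @export
make_genome <- function(chrom_lengths, bin_size) {
  if (length(chrom_lengths) < 1L || any(!is.finite(chrom_lengths)) ||
      any(chrom_lengths <= 0)) {
    stop("chromosome lengths must be positive and finite")
  }
  if (!is.finite(bin_size) || bin_size <= 0) {
    stop("bin_size must be positive")
  }
  nm <- names(chrom_lengths)
  if (is.null(nm)) nm <- paste0("chr", seq_along(chrom_lengths))
  bins <- do.call(rbind, lapply(seq_along(chrom_lengths), function(i) {
    len <- chrom_lengths[[i]]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = nm[i], start = starts,
               end = pmin(starts + bin_size, len))
  }))
  rownames(bins) <- NULL
  bins$chrom <- factor(bins$chrom, levels = nm)
  structure(list(
    chromosomes = data.frame(name = nm, length = unname(chrom_lengths)),
    bin_size = bin_size,
    bins = bins
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %d bins of %s bp (%.1f Mb total)\n",
              nrow(x$chromosomes), nrow(x$bins),
              format(x$bin_size, big.mark = ","),
              sum(x$chromosomes$length) / 1e6))
  invisible(x)
}

n_bins <- function(layout) nrow(layout$bins)

bin_widths <- function(layout) layout$bins$end - layout$bins$start

#' Default desk-scale toy genome
#'
#' 22 autosomes with GRCh38-proportioned lengths scaled down by `scale`
#' (default 1/30), binned at `bin_size`. The default yields roughly 200 bins,
#' preserving multi-chromosome structure at desk cost.
#'
#' @param scale Length scale factor relative to the human autosomes.
#' @param bin_size Bin width in bp.
#' @return A `genome_layout`.
#' @export
toy_genome <- function(scale = 1 / 30, bin_size = 5e5) {
  # GRCh38 autosome lengths, Mb, rounded
  hs <- c(249, 242, 198, 190, 182, 171, 159, 145, 138, 134, 135, 133,
          114, 107, 102, 90, 83, 80, 59, 64, 47, 51) * 1e6
  names(hs) <- paste0("chr", 1:22)
  make_genome(round(hs * scale), bin_size = bin_size)
}

#' Convert layout bins to GRanges
#'
#' @param layout A `genome_layout`.
#' @return A [GenomicRanges::GRanges] with one range per bin (1-based closed,
#'   as GRanges requires; bin `[s, e)` maps to `s+1..e`).
#' @export
bins_granges <- function(layout) {
  b <- layout$bins
  GenomicRanges::GRanges(
    seqnames = as.character(b$chrom),
    ranges = IRanges::IRanges(start = b$start + 1L, end = b$end)
  )
}

#' Simulate a per-bin annotation track
#'
#' Generates GC fraction, mappability, and a blacklist flag for every bin of
#' a layout. GC is drawn near-independently per bin (weak AR(1), squashed
#' into `gc_range`): at desk scale each bin stands for a large stretch of
#' real genome, across which GC autocorrelation has largely decayed, and
#' independent GC keeps GC strata from coinciding with copy-number segments.
#' Mappability is near 1 with occasional low-mappability bins; a small
#' fraction of bins is blacklisted.
#'
#' @param layout A `genome_layout`.
#' @param gc_range Range of GC fractions.
#' @param blacklist_frac Fraction of bins flagged as blacklisted.
#' @param low_map_frac Fraction of bins given reduced mappability.
#' @param seed Integer seed; the track is reproducible given the seed.
#' @return A `bin_track` data.frame with columns `gc`, `mappability`,
#'   `blacklisted`, one row per bin.
#' @export
make_bin_track <- function(layout, gc_range = c(0.33, 0.62),
                           blacklist_frac = 0.02, low_map_frac = 0.03,
                           seed = 1L) {
  nb <- n_bins(layout)
  rng <- local_rng(seed, "bin_track")
  gc <- numeric(nb)
  for (ch in levels(layout$bins$chrom)) {
    idx <- which(layout$bins$chrom == ch)
    e <- rng$rnorm(length(idx), 0, 1)
    z <- as.numeric(stats::filter(e, 0.3, method = "recursive"))
    gc[idx] <- gc_range[1] + diff(gc_range) * stats::plogis(1.2 * z)
  }
  mappability <- rep(1, nb)
  nlow <- round(low_map_frac * nb)
  if (nlow > 0) {
    low <- rng$sample(nb, nlow)
    mappability[low] <- rng$runif(nlow, 0.3, 0.9)
  }
  blacklisted <- rep(FALSE, nb)
  nbl <- round(blacklist_frac * nb)
  if (nbl > 0) blacklisted[rng$sample(nb, nbl)] <- TRUE
  structure(data.frame(gc = gc, mappability = mappability,
                       blacklisted = blacklisted),
            class = c("bin_track", "data.frame"))
}

# Deterministic child RNG streams: every stochastic stage draws from its own
# stream derived from (seed, label), so stages are reproducible independently
# of call order and of each other.
local_rng <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  # fold the label into a 31-bit child seed
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  child <- (as.double(seed) * 69091 + h * 2531) %% 2147483647
  env <- new.env(parent = emptyenv())
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(as.integer(child))
    s <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
    s
  }
  draw <- function(fn) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv()) else assign(".Random.seed", old, globalenv())
      })
      fn(...)
    }
  }
  list(
    rnorm = draw(stats::rnorm),
    runif = draw(stats::runif),
    rpois = draw(stats::rpois),
    rnbinom = draw(stats::rnbinom),
    rbinom = draw(stats::rbinom),
    sample = draw(function(x, size, replace = FALSE, prob = NULL)
      sample(x, size, replace = replace, prob = prob)),
    sample_int = draw(sample.int)
  )
}
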