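#' Cell-by-bin count container
#'
#' @param counts Integer matrix, cells in rows, bins in columns. Row names
#'   are cell ids.
#' @param genome A `genome_layout` whose bins match the columns.
#' @return A `cell_counts` object: list with `counts`, `cell_ids`,
#'   `total_reads` (row sums), `genome`, and an initially empty `qc` table.
#' @export
cell_counts <- function(counts, genome) {
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (ncol(counts) != n_bins(genome)) stop("counts/bin mismatch")
  storage.mode(counts) <- "integer"
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell%03d", seq_len(nrow(counts)))
  }
  structure(list(counts = counts,
                 cell_ids = rownames(counts),
                 total_reads = rowSums(counts),
                 genome = genome,
                 qc = NULL,
                 truth = NULL),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d cells x %d bins; reads/cell %.0f-%.0f (median %.0f)\n",
              nrow(x$counts), ncol(x$counts), min(x$total_reads),
              max(x$total_reads), stats::median(x$total_reads)))
  invisible(x)
}

#' Write a counts matrix as TSV
#'
#' Rows are bins (`chrom`, `start`, `end`, 0-based half-open) and remaining
#' columns are cells, matching the loader's schema.
#'
#' @param x A `cell_counts`.
#' @param path Output file.
#' @export
write_counts <- function(x, path) {
  df <- cbind(x$genome$bins[, c("chrom", "start", "end")],
              as.data.frame(t(x$counts)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Load a counts TSV
#'
#' Validates the schema strictly: bins must be sorted within chromosome,
#' non-overlapping, and counts must be non-negative integers. The genome
#' layout is reconstructed from the bin columns (bin size taken as the modal
#' bin width).
#'
#' @param path Counts TSV written by [write_counts()].
#' @return A `cell_counts`.
#' @export
load_counts <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(df)[1:3])) stop("counts file: bad header")
  chroms <- unique(df$chrom)
  for (ch in chroms) {
    b <- df[df$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) {
      stop("counts file: bins out of coordinate order on ", ch)
    }
    if (any(b$start[-1] < b$end[-nrow(b)])) {
      stop("counts file: overlapping bins on ", ch)
    }
    if (any(b$end <= b$start)) stop("counts file: empty bin on ", ch)
  }
  m <- as.matrix(df[, -(1:3), drop = FALSE])
  if (any(m != round(m)) || any(m < 0)) {
    stop("counts file: non-integer or negative counts")
  }
  widths <- df$end - df$start
  bin_size <- as.numeric(names(sort(table(widths), decreasing = TRUE))[1])
  lens <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), numeric(1))
  genome <- make_genome(stats::setNames(lens, chroms), bin_size)
  if (!identical(nrow(genome$bins), nrow(df)) ||
      any(genome$bins$start != df$start)) {
    stop("counts file: bins do not tile the genome at a fixed width")
  }
  counts <- t(m)
  storage.mode(counts) <- "integer"
  rownames(counts) <- colnames(df)[-(1:3)]
  cell_counts(counts, genome)
}

#' GC-bias correction
#'
#' Per cell, fits a smooth function of GC fraction to the observed counts —
#' a trimmed-mean location estimate over equal-count GC windows, linearly
#' interpolated between window centres — divides counts by the fit, and
#' rescales so each cell's mean over usable bins is preserved. The trimmed
#' mean (rather than the median) is used because in a genome with mixed
#' copy-number states the window median snaps to whichever discrete state
#' happens to dominate that window, while the mean averages the state
#' mixture consistently across windows and so cancels out of the fitted GC
#' shape. The number of windows adapts downward so each window keeps at
#' least ~25 usable bins. Blacklisted bins are excluded from the fit and set
#' to `NA`.
#'
#' @details
#' The fit is copy-number aware (two passes): a first-pass correction gives
#' rough per-bin integer states (nearest state at an assumed near-diploid
#' scale); the GC curve is then refit on count / state, which removes the
#' confounding between copy-number structure and GC composition that a
#' single pass suffers on genomes with few bins. Bins whose rough state is
#' 0 are excluded from the refit. Set `cn_aware = FALSE` for tumour/normal
#' *mixtures*, whose bin values sit at fractional multiples of the median
#' (the integer rounding behind the refit only holds for pure samples).
#'
#' @param x A `cell_counts`.
#' @param track A `bin_track`.
#' @param n_windows Maximum number of equal-count GC windows.
#' @param trim Trim fraction of the per-window mean.
#' @param cn_aware Run the copy-number-aware second pass (pure samples
#'   only).
#' @param levels Optional per-bin expected relative levels (e.g. segment
#'   medians from a first pass); when given, the GC curve is fitted on
#'   `count / level`, which carries no copy-number structure, and
#'   `cn_aware` is ignored.
#' @return Numeric matrix (cells x bins) of corrected values, `NA` on
#'   blacklisted bins. Cells with no usable bins are all-`NA` and listed in
#'   attribute `"failed_cells"`.
#' @export
correct_gc <- function(x, track, n_windows = 20, trim = 0.1,
                       cn_aware = TRUE, levels = NULL) {
  stopifnot(nrow(track) == ncol(x$counts))
  usable <- !track$blacklisted & !is.na(track$gc)
  gc <- track$gc
  out <- matrix(NA_real_, nrow(x$counts), ncol(x$counts),
                dimnames = dimnames(x$counts))
  failed <- character(0)
  # equal-count GC windows shared across cells; >= ~25 bins per window
  nw <- max(4L, min(n_windows, floor(sum(usable) / 25)))
  qs <- stats::quantile(gc[usable], probs = seq(0, 1, length.out = nw + 1),
                        names = FALSE, type = 7)
  win <- if (length(unique(qs)) < 3) {
    factor(rep("w1", length(gc)))   # constant GC: nothing to fit
  } else {
    cut(gc, breaks = unique(qs), include.lowest = TRUE)
  }

  fit_curve <- function(yy, ok) {
    loc <- tapply(yy[ok], droplevels(win[ok]), mean, trim = trim)
    centres <- tapply(gc[ok], droplevels(win[ok]), stats::median)
    keep <- is.finite(loc) & loc > 0
    if (sum(keep) < 2) return(NULL)
    stats::approx(centres[keep], loc[keep], xout = gc, rule = 2)$y
  }

  # width-normalise so remainder bins at chromosome ends are comparable
  wfac <- bin_widths(x$genome) / x$genome$bin_size
  for (i in seq_len(nrow(x$counts))) {
    y <- as.numeric(x$counts[i, ]) / wfac
    ok <- usable & is.finite(y)
    if (!any(ok) || sum(y[ok]) == 0) {
      failed <- c(failed, x$cell_ids[i])
      next
    }
    if (!is.null(levels)) {
      okl <- ok & is.finite(levels) & levels > 0
      # the level-normalised signal carries no copy-number structure, so a
      # low-order parametric curve (robust quadratic in GC) can be fitted
      # directly with minimal estimation variance
      fit <- tryCatch({
        rf <- MASS::rlm(z ~ g + I(g^2),
                        data = data.frame(z = y[okl] / levels[okl],
                                          g = gc[okl]),
                        maxit = 50)
        p <- stats::predict(rf, newdata = data.frame(g = gc))
        pmax(p, 0.05 * mean(p, na.rm = TRUE))
      }, error = function(e) NULL)
      if (is.null(fit)) fit <- fit_curve(y / ifelse(okl, levels, 1), okl)
      if (is.null(fit)) fit <- fit_curve(y, ok)
      if (is.null(fit)) { out[i, ok] <- y[ok]; next }
      corrected <- y / fit
      corrected[!ok] <- NA_real_
      corrected <- corrected * mean(y[ok]) / mean(corrected[ok])
      out[i, ] <- corrected
      next
    }
    fit1 <- fit_curve(y, ok)
    if (is.null(fit1)) {              # flat input: nothing to correct
      out[i, ok] <- y[ok]
      next
    }
    # rough per-bin states at an assumed near-diploid scale, then refit the
    # curve on count / state so copy-number structure cancels out of it
    fit <- fit1
    if (cn_aware) {
      c1 <- y / fit1
      rough <- round(2 * c1 / stats::median(c1[ok]))
      ok2 <- ok & rough >= 1
      fit2 <- if (sum(ok2) >= nw * 5) fit_curve(y / pmax(rough, 1), ok2)
              else NULL
      if (!is.null(fit2)) fit <- fit2
    }
    corrected <- y / fit
    corrected[!ok] <- NA_real_
    # preserve the cell's mean over usable bins
    corrected <- corrected * mean(y[ok]) / mean(corrected[ok])
    out[i, ] <- corrected
  }
  attr(out, "failed_cells") <- failed
  out
}

#' Mappability correction
#'
#' Divides values by per-bin mappability; bins below `threshold` are treated
#' as blacklisted and set to `NA`.
#'
#' @param values Matrix (cells x bins) or vector of per-bin values.
#' @param track A `bin_track`.
#' @param threshold Minimum usable mappability.
#' @return Corrected values with low-mappability bins masked.
#' @export
correct_mappability <- function(values, track, threshold = 0.2) {
  m <- track$mappability
  mask <- m < threshold | track$blacklisted
  if (is.matrix(values)) {
    out <- sweep(values, 2, m, "/")
    out[, mask] <- NA_real_
  } else {
    out <- values / m
    out[mask] <- NA_real_
  }
  out
}

#' Coverage spikiness of one cell
#'
#' Scale-free unevenness statistic: the coefficient of variation of the
#' (GC-corrected) bin values. Evenly covered genomes score well below 1
#' even with several copy-number states; a cell with reads piled into one
#' or a few bins scores far above it. (A median-of-differences statistic is
#' blind to isolated spikes, which is precisely the failure mode this
#' filter must catch.)
#'
#' @param values Numeric per-bin values for one cell (`NA` allowed on masked
#'   bins).
#' @return Non-negative scalar (Inf for degenerate input).
#' @export
spikiness <- function(values) {
  v <- values[is.finite(values)]
  if (length(v) < 2) return(Inf)
  m <- mean(v)
  if (m <= 0) return(Inf)
  stats::sd(v) / m
}

#' Cell-level quality filtering
#'
#' Keeps cells whose total read count lies inside `[min_reads, max_reads]`
#' (inclusive bounds) and whose coverage [spikiness()] does not exceed
#' `max_spikiness`. Filtering is idempotent: re-filtering kept cells changes
#' nothing.
#'
#' @param x A `cell_counts`.
#' @param track A `bin_track` (used to GC-correct before measuring evenness).
#' @param min_reads,max_reads Inclusive total-read bounds.
#' @param max_spikiness Maximum allowed spikiness.
#' @param corrected Optional pre-computed [correct_gc()] matrix, to avoid
#'   re-fitting.
#' @return The `cell_counts` restricted to kept cells, with a `qc` data.frame
#'   (cell_id, total_reads, spikiness, kept, reason) covering *all* input
#'   cells. The truth sidecar, if any, is subset alongside.
#' @export
filter_cells <- function(x, track, min_reads, max_reads,
                         max_spikiness = 1.0, corrected = NULL) {
  if (min_reads >= max_reads) stop("min_reads must be < max_reads")
  if (is.null(corrected)) corrected <- correct_gc(x, track)
  spk <- apply(corrected, 1, spikiness)
  tot <- x$total_reads
  reason <- rep("", length(tot))
  reason[tot < min_reads] <- "low_reads"
  reason[tot > max_reads] <- "high_reads"
  reason[reason == "" & spk > max_spikiness] <- "uneven_coverage"
  kept <- reason == ""
  qc <- data.frame(cell_id = x$cell_ids, total_reads = tot,
                   spikiness = spk, kept = as.integer(kept),
                   reason = ifelse(kept, "pass", reason),
                   row.names = NULL)
  out <- x
  out$counts <- x$counts[kept, , drop = FALSE]
  out$cell_ids <- x$cell_ids[kept]
  out$total_reads <- tot[kept]
  out$qc <- qc
  if (!is.null(x$truth)) {
    out$truth <- x$truth
    out$truth$clone <- x$truth$clone[kept]
    out$truth$dropout <- x$truth$dropout[kept]
  }
  out
}
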