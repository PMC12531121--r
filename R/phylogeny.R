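#' Minimum consistent segmentation of a cell population
#'
#' Finds the fewest shared segments that exactly represent every cell's
#' per-bin copy-number states: take the union of all cells' segment
#' boundaries, then merge adjacent shared segments whose state vectors
#' across all cells are identical. Because every retained boundary is a
#' state change in at least one cell, the result is minimal among all
#' segmentations that reconstruct every profile exactly.
#'
#' @param population A `cn_population`.
#' @return A `consistent_segmentation`: `segments` (data.frame `chrom`,
#'   `start`, `end`, `n_bins`, `bin_from`, `bin_to`), `states` (cells x
#'   segments integer matrix), `genome`.
#' @export
minimum_consistent_segmentation <- function(population) {
  st <- population$states
  b <- population$genome$bins
  rows <- list()
  state_cols <- list()
  for (ch in levels(b$chrom)) {
    idx <- which(b$chrom == ch)
    sub <- st[, idx, drop = FALSE]
    # boundary before bin j iff any cell changes state between j-1 and j
    change <- colSums(sub[, -1, drop = FALSE] !=
                        sub[, -length(idx), drop = FALSE]) > 0
    starts <- c(1L, which(change) + 1L)
    bounds <- c(starts, length(idx) + 1L)
    for (j in seq_len(length(bounds) - 1L)) {
      span <- idx[bounds[j]:(bounds[j + 1L] - 1L)]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = b$start[span[1]], end = b$end[span[length(span)]],
        n_bins = length(span), bin_from = span[1], bin_to = span[length(span)])
      state_cols[[length(state_cols) + 1L]] <- st[, span[1]]
    }
  }
  segs <- do.call(rbind, rows)
  rownames(segs) <- NULL
  states <- do.call(cbind, state_cols)
  rownames(states) <- rownames(st)
  structure(list(segments = segs, states = states,
                 genome = population$genome),
            class = "consistent_segmentation")
}

#' Reconstruct per-bin states from a consistent segmentation
#'
#' @param x A `consistent_segmentation`.
#' @return Cells x bins integer matrix.
#' @export
expand_segmentation <- function(x) {
  nb <- n_bins(x$genome)
  out <- matrix(NA_integer_, nrow(x$states), nb,
                dimnames = list(rownames(x$states), NULL))
  for (s in seq_len(nrow(x$segments))) {
    out[, x$segments$bin_from[s]:x$segments$bin_to[s]] <- x$states[, s]
  }
  out
}

# Directed minimum-event distance for one chromosome's segment states.
# Events add +1 or -1 to a contiguous run of segments; states never drop
# below 0 and a state-0 segment can never be incremented, so zero positions
# split runs. Infeasible iff a is 0 somewhere b is positive.
directed_event_distance <- function(a, b) {
  if (any(a == 0 & b > 0)) return(Inf)
  d <- b - a
  run_id <- cumsum(a == 0)
  total <- 0
  for (r in split(seq_along(a)[a > 0], run_id[a > 0])) {
    g <- pmax(d[r], 0)
    l <- pmax(-d[r], 0)
    total <- total + sum(pmax(diff(c(0, g)), 0)) + sum(pmax(diff(c(0, l)), 0))
  }
  total
}

#' Minimum-event distance between two total-copy-number profiles
#'
#' The smallest number of segmental events — each adding +1 or -1 to one
#' contiguous run of segments, with states never going below 0 and a
#' segment at state 0 never regaining copies — needed to transform one
#' profile into the other. Computed in closed form on the difference profile
#' as the sum of positive jumps of the gain-requirement sequence plus the
#' analogous loss term, with zero-state positions splitting runs. Both
#' directions are evaluated and the minimum taken (zero-state loss is
#' irreversible, so the directions can differ). If both directions are
#' infeasible the pair is flagged blocked and a surrogate distance — the
#' same jump count with the zero-increment rule relaxed — is returned.
#'
#' @param a,b Integer state vectors on the same shared segments.
#' @param chrom Optional factor splitting positions into chromosomes; events
#'   never span chromosome boundaries.
#' @return Numeric distance with attribute `"blocked"` (logical).
#' @export
event_distance <- function(a, b, chrom = NULL) {
  stopifnot(length(a) == length(b))
  if (is.null(chrom)) chrom <- rep(1L, length(a))
  pieces_a <- split(as.numeric(a), chrom)
  pieces_b <- split(as.numeric(b), chrom)
  dab <- sum(vapply(seq_along(pieces_a), function(i)
    directed_event_distance(pieces_a[[i]], pieces_b[[i]]), numeric(1)))
  dba <- sum(vapply(seq_along(pieces_a), function(i)
    directed_event_distance(pieces_b[[i]], pieces_a[[i]]), numeric(1)))
  d <- min(dab, dba)
  blocked <- !is.finite(d)
  if (blocked) {
    # relaxed surrogate: split runs only where both profiles are 0
    d <- sum(vapply(seq_along(pieces_a), function(i) {
      ai <- pieces_a[[i]]; bi <- pieces_b[[i]]
      di <- bi - ai
      run_id <- cumsum(ai == 0 & bi == 0)
      keep <- !(ai == 0 & bi == 0)
      tot <- 0
      for (r in split(seq_along(ai)[keep], run_id[keep])) {
        g <- pmax(di[r], 0); l <- pmax(-di[r], 0)
        tot <- tot + sum(pmax(diff(c(0, g)), 0)) +
          sum(pmax(diff(c(0, l)), 0))
      }
      tot
    }, numeric(1)))
  }
  attr(d, "blocked") <- blocked
  d
}

#' Pairwise minimum-event distance matrix
#'
#' @param segmentation A `consistent_segmentation`.
#' @return An `event_distance_matrix`: list with `d` (symmetric numeric
#'   matrix, zero diagonal) and `blocked` (logical matrix).
#' @export
event_distance_matrix <- function(segmentation) {
  st <- segmentation$states
  chrom <- factor(segmentation$segments$chrom,
                  levels = unique(segmentation$segments$chrom))
  n <- nrow(st)
  d <- matrix(0, n, n, dimnames = list(rownames(st), rownames(st)))
  blocked <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dij <- event_distance(st[i, ], st[j, ], chrom)
      d[i, j] <- d[j, i] <- as.numeric(dij)
      blocked[i, j] <- blocked[j, i] <- attr(dij, "blocked")
    }
  }
  structure(list(d = d, blocked = blocked), class = "event_distance_matrix")
}

#' Neighbor-joining tree and clade assignment
#'
#' Builds a neighbor-joining tree from the event-distance matrix and cuts it
#' into `k` clades by k-medoids (PAM) on the tree's patristic distances —
#' medoid-based grouping keeps a single noisy outlier cell from claiming a
#' whole clade, which linkage-based cutting is prone to. When `k` is `NULL`
#' it is chosen by maximising the mean silhouette width over `k = 2..max_k`
#' against the original distances. Ties and orderings are deterministic
#' given the matrix and cell-id order.
#'
#' Cells whose copy-number calls failed (for instance at a wrong overall
#' scale) sit far from every other cell and corrupt both the tree and the
#' clades; with `drop_outliers` such cells — median distance to all others
#' beyond `outlier_mad` robust deviations of the population's — are set
#' aside before the tree is built and appear with clade `NA`.
#'
#' @param distances An `event_distance_matrix` (or plain symmetric matrix).
#' @param k Number of clades, or `NULL` for silhouette selection.
#' @param max_k Largest `k` tried during selection.
#' @param drop_outliers Exclude far-from-everything cells before building.
#' @param outlier_mad Robust deviations defining an outlier cell.
#' @return A `cn_tree`: list with `tree` (ape `phylo`), `clades` (named
#'   integer vector over *all* input cells, `NA` for dropped ones),
#'   `dropped` (character vector of excluded cell ids), `k`, `silhouette`
#'   (data.frame of candidate scores, when selected).
#' @export
build_tree <- function(distances, k = NULL, max_k = 8,
                       drop_outliers = TRUE, outlier_mad = 4) {
  d_full <- if (inherits(distances, "event_distance_matrix")) distances$d
            else as.matrix(distances)
  dropped <- character(0)
  d <- d_full
  if (drop_outliers && nrow(d_full) >= 8) {
    med_d <- apply(d_full, 1, stats::median)
    cut <- stats::median(med_d) + outlier_mad * stats::mad(med_d)
    bad <- med_d > cut
    if (any(bad) && sum(!bad) >= 4) {
      dropped <- rownames(d_full)[bad]
      d <- d_full[!bad, !bad, drop = FALSE]
    }
  }
  tree <- ape::nj(stats::as.dist(d))
  pat <- stats::as.dist(ape::cophenetic.phylo(tree)[rownames(d), rownames(d)])
  cut_k <- function(kk) {
    cl <- cluster::pam(pat, k = kk, diss = TRUE, pamonce = 5)$clustering
    stats::setNames(cl, rownames(d))
  }
  sil_tab <- NULL
  if (is.null(k)) {
    ks <- 2:min(max_k, nrow(d) - 1)
    scores <- vapply(ks, function(kk) {
      mean(cluster::silhouette(cut_k(kk), stats::as.dist(d))[, "sil_width"])
    }, numeric(1))
    sil_tab <- data.frame(k = ks, mean_silhouette = scores)
    k <- ks[which.max(scores)]
  }
  clades_kept <- cut_k(k)
  clades <- stats::setNames(rep(NA_integer_, nrow(d_full)),
                            rownames(d_full))
  clades[names(clades_kept)] <- clades_kept
  structure(list(tree = tree, clades = clades, dropped = dropped, k = k,
                 silhouette = sil_tab),
            class = "cn_tree")
}

#' @export
print.cn_tree <- function(x, ...) {
  cat(sprintf("cn_tree: %d tips, %d clades (sizes: %s)%s\n",
              length(x$tree$tip.label), x$k,
              paste(table(x$clades), collapse = ", "),
              if (length(x$dropped)) paste0("; ", length(x$dropped),
                                            " outlier cell(s) dropped")
              else ""))
  invisible(x)
}

#' Write a tree in Newick format
#'
#' @param x A `cn_tree`.
#' @param path Output file.
#' @export
write_tree_newick <- function(x, path) {
  ape::write.tree(x$tree, file = path)
  invisible(path)
}

#' Pseudobulk profile from a subset of cells
#'
#' Sums raw counts over the subset and pushes the merged sample through the
#' bulk path: GC and mappability correction, e-divisive segmentation,
#' relative profile, and absolute calling at cellularity 1 (cell lines are
#' pure). Merging counts before re-segmentation mirrors merging aligned
#' reads.
#'
#' @param x A `cell_counts`.
#' @param cells Indices or ids of the cells to merge.
#' @param track A `bin_track`.
#' @param psi Tumour ploidy for the absolute call; `NULL` fits it by grid
#'   search at cellularity 1.
#' @param seed Integer seed for segmentation permutations.
#' @param ... Passed to [segment_genome()].
#' @return List with `counts` (summed vector), `corrected`, `relative`
#'   (`relative_profile`), `fit` (`absolute_fit` or `NULL`), `profile`
#'   (`cn_profile`).
#' @export
pseudobulk <- function(x, cells, track, psi = NULL, seed = 1L, ...) {
  if (is.character(cells)) cells <- match(cells, x$cell_ids)
  stopifnot(length(cells) >= 1, !anyNA(cells))
  summed <- colSums(x$counts[cells, , drop = FALSE])
  merged <- cell_counts(matrix(as.integer(summed), nrow = 1,
                               dimnames = list("pseudobulk", NULL)),
                        x$genome)
  corrected <- correct_mappability(correct_gc(merged, track), track)[1, ]
  bps <- segment_genome(corrected, x$genome, seed = seed, ...)
  rel <- make_relative_profile(corrected, bps, x$genome)
  fit <- NULL
  if (is.null(psi)) {
    fit <- fit_absolute(rel, rho_grid = 1)
    psi <- fit$best$psi
  }
  prof <- to_absolute(rel, rho = 1, psi = psi)
  list(counts = summed, corrected = corrected, relative = rel,
       fit = fit, profile = prof)
}
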