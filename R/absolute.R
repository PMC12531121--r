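weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1]]
}

#' Build a relative copy-number profile from corrected bulk values
#'
#' Segment medians of the corrected values, normalised by the genome-wide
#' weighted median so the typical segment sits at 1. Scale-free: multiplying
#' all input values by a positive constant leaves the profile unchanged.
#'
#' @param values Per-bin corrected values (`NA` on masked bins).
#' @param breakpoints Output of [segment_genome()] on the same values.
#' @param genome A `genome_layout`.
#' @return A `relative_profile`: list with `segments` (data.frame `chrom`,
#'   `start`, `end`, `r` median relative value, `w` usable-bin weight),
#'   `seg_of_bin`, `masked`, `genome`.
#' @export
make_relative_profile <- function(values, breakpoints, genome) {
  seg_id <- integer(n_bins(genome))
  rows <- list()
  s <- 0L
  b <- genome$bins
  for (ch in levels(b$chrom)) {
    idx <- which(b$chrom == ch)
    starts <- breakpoints[[ch]]
    if (is.null(starts)) starts <- idx[1]
    starts[1] <- idx[1]   # a masked leading bin still belongs to segment 1
    bounds <- c(starts, max(idx) + 1L)
    for (j in seq_len(length(bounds) - 1L)) {
      s <- s + 1L
      span <- bounds[j]:(bounds[j + 1L] - 1L)
      seg_id[span] <- s
      v <- values[span]
      nv <- sum(is.finite(v))
      rows[[s]] <- data.frame(
        chrom = ch, start = b$start[span[1]], end = b$end[span[length(span)]],
        r = stats::median(v, na.rm = TRUE), w = nv,
        # robust standard error of the segment median: MAD-based spread
        # (outlier bins inflate sd but barely move the median); for the
        # right-skewed count noise the median is no less efficient than the
        # mean, so no normal-theory efficiency factor is applied
        se = if (nv > 1) stats::mad(v, na.rm = TRUE) / sqrt(nv) else NA)
    }
  }
  seg <- do.call(rbind, rows)
  usable <- seg$w > 0 & is.finite(seg$r)
  norm <- weighted_median(seg$r[usable], seg$w[usable])
  # refine the scale over all segments near the modal level, so one
  # segment's median noise does not propagate into the global scale
  modal <- usable & abs(seg$r / norm - 1) < 0.08
  if (sum(seg$w[modal]) >= 10) {
    norm <- sum(seg$w[modal] * seg$r[modal]) / sum(seg$w[modal])
  }
  seg$r <- seg$r / norm
  seg$se <- seg$se / norm
  structure(list(segments = seg, seg_of_bin = seg_id,
                 masked = !is.finite(values), genome = genome),
            class = "relative_profile")
}

#' Expected relative value of an integer copy-number state
#'
#' Under the tumour/normal mixture model a segment at tumour state `n` in a
#' sample of cellularity `rho` and tumour ploidy `psi` has expected relative
#' value `(rho n + 2 (1 - rho)) / (rho psi + 2 (1 - rho))`; a diploid segment
#' at `psi = 2` sits at 1 for every `rho`.
#'
#' @param n Integer state(s).
#' @param rho Cellularity in `(0, 1]`.
#' @param psi Tumour ploidy.
#' @return Expected relative value(s).
#' @export
expected_relative <- function(n, rho, psi) {
  (rho * n + 2 * (1 - rho)) / (rho * psi + 2 * (1 - rho))
}

#' Fit cellularity and ploidy by grid search
#'
#' For every grid point `(rho, psi)` each segment's relative value is mapped
#' to its nearest integer state (clipped to `[0, max_state]`) and the fit is
#' scored by the chi-square of the residuals against each
#' segment median's standard error plus an AIC-like complexity term
#' (`complexity` chi-square units per state spanned), normalised per
#' segment. Counting the spanned range rather than the states actually used
#' also rules out sub-lattice aliases, which posit intermediate copy-number
#' levels that no segment ever occupies.
#' The noise-normalised residuals stop low-cellularity solutions from
#' "beating noise" — a dense state lattice that interpolates the scatter
#' pays for every extra state it uses — while the complexity term is
#' indifferent between genuine state-multiple aliases, which are instead
#' resolved by a mild near-diploid parsimony prior
#' (`1 + penalty_ploidy (psi - 2)^2`) and a weak preference for high
#' cellularity (`rho^-penalty`). Segments shorter than `min_seg_bins`
#' usable bins are too noisy to constrain the lattice and are left out of
#' the score. The best fit is the global
#' minimum of the penalised surface; all local minima are ranked, so a
#' genome-doubled alternative (`~2 psi` at reduced `rho`) is reported even
#' when it is not the best.
#'
#' @param profile A `relative_profile`.
#' @param rho_grid,psi_grid Candidate cellularities and ploidies.
#' @param penalty Exponent of the `1 / rho^penalty` low-cellularity penalty.
#' @param penalty_ploidy Strength of the parsimony prior
#'   `1 + penalty_ploidy * (psi - 2)^2` that resolves exact state-multiple
#'   aliases toward the reduced (near-diploid) solution.
#' @param complexity Chi-square cost per spanned copy-number state.
#' @param max_state Largest integer state considered by the fit.
#' @param min_seg_bins Minimum usable bins for a segment to enter the score.
#' @return An `absolute_fit`: `best` (list `rho`, `psi`, `error`), `minima`
#'   (ranked data.frame of local minima), `surface` (penalised error matrix,
#'   rho x psi), the grids, and `identifiable` (FALSE when the error surface
#'   is essentially flat along rho, as for a CNA-free genome).
#' @export
fit_absolute <- function(profile, rho_grid = seq(0.05, 1, by = 0.01),
                         psi_grid = seq(1.5, 5.5, by = 0.05),
                         penalty = 0.1, penalty_ploidy = 0.3,
                         complexity = 3,
                         max_state = 12, min_seg_bins = 4) {
  seg <- profile$segments
  seg <- seg[seg$w >= min_seg_bins & is.finite(seg$r) & is.finite(seg$se), ]
  if (nrow(seg) == 0) stop("empty relative profile")
  r <- seg$r
  se <- pmax(seg$se, 1e-3)
  S <- nrow(seg)
  # Segment medians scatter more than their within-segment sampling error:
  # residual normalisation error (e.g. GC-curve interpolation) adds a
  # shared per-segment component. Estimate that excess empirically from
  # the spread of the modal (r ~ 1) segments and fold it into every se.
  modal <- abs(r - 1) < 0.04 & seg$w >= min_seg_bins
  if (sum(modal) >= 5) {
    excess <- max(0, stats::var(r[modal]) - mean(se[modal]^2))
    # the systematic component is relative to the level, so it scales with r
    se <- sqrt(se^2 + excess * r^2)
  }
  surface <- matrix(NA_real_, length(rho_grid), length(psi_grid),
                    dimnames = list(NULL, NULL))
  for (i in seq_along(rho_grid)) {
    rho <- rho_grid[i]
    d <- rho * psi_grid + 2 * (1 - rho)       # denominator per psi
    for (j in seq_along(psi_grid)) {
      n_star <- pmin(pmax(round((r * d[j] - 2 * (1 - rho)) / rho), 0),
                     max_state)
      resid <- r - (rho * n_star + 2 * (1 - rho)) / d[j]
      chi2 <- sum((resid / se)^2)
      k <- max(n_star) - min(n_star) + 1   # states spanned, not just used
      # a solution whose used states share a common step >= 2 is a
      # sub-lattice alias of a reduced solution; flag it decisively
      steps <- diff(sort(unique(n_star)))
      alias <- length(steps) > 0 && all(steps %% min(steps) == 0) &&
        min(steps) >= 2
      surface[i, j] <- (chi2 + complexity * k) / S *
        (1 + penalty_ploidy * (psi_grid[j] - 2)^2) *
        (if (alias) 2 else 1) / rho^penalty
    }
  }
  ibest <- arrayInd(which.min(surface), dim(surface))
  minima <- find_local_minima(surface, rho_grid, psi_grid)

  # The grid never evaluates a candidate exactly at its own optimum (at
  # rho = 0.2 the grid phase error alone costs ~1 sigma per high-state
  # segment), so each leading grid minimum is polished by iterating
  # {assign states | weighted linear LS for the lattice}: the model is
  # linear in (a, b) = (rho/D, 2(1-rho)/D) with D = rho psi + 2(1 - rho).
  score_at <- function(rho, psi) {
    d <- rho * psi + 2 * (1 - rho)
    n_star <- pmin(pmax(round((r * d - 2 * (1 - rho)) / rho), 0), max_state)
    resid <- r - (rho * n_star + 2 * (1 - rho)) / d
    chi2 <- sum((resid / se)^2)
    k <- max(n_star) - min(n_star) + 1
    steps <- diff(sort(unique(n_star)))
    alias <- length(steps) > 0 && all(steps %% min(steps) == 0) &&
      min(steps) >= 2
    list(score = (chi2 + complexity * k) / S *
           (1 + penalty_ploidy * (psi - 2)^2) * (if (alias) 2 else 1) /
           rho^penalty,
         chi2n = chi2 / S, k = k + (if (alias) k else 0),
         tiebreak = (1 + penalty_ploidy * (psi - 2)^2) / rho^penalty)
  }
  refine <- function(rho, psi) {
    for (it in 1:5) {
      d <- rho * psi + 2 * (1 - rho)
      n_star <- pmin(pmax(round((r * d - 2 * (1 - rho)) / rho), 0),
                     max_state)
      if (length(unique(n_star)) < 2) break
      fit <- stats::lm.wfit(cbind(1, n_star), r, w = 1 / se^2)
      b0 <- fit$coefficients[1]; a <- fit$coefficients[2]
      if (!is.finite(a) || !is.finite(b0) || a <= 0 || b0 < 0) break
      rho_new <- min(max(2 * a / (2 * a + b0), 0.01), 1)
      psi_new <- (1 - b0) / a
      if (!is.finite(psi_new) || psi_new < 1 || psi_new > 8) break
      if (abs(rho_new - rho) < 1e-4 && abs(psi_new - psi) < 1e-4) {
        rho <- rho_new; psi <- psi_new; break
      }
      rho <- rho_new; psi <- psi_new
    }
    c(rho, psi)
  }
  implied_ploidy <- function(rho, psi) {
    # invert the continuous weighted mean level through the mixture law:
    # exact for the true lattice and free of per-segment assignment noise
    d <- rho * psi + 2 * (1 - rho)
    rbar <- sum(seg$w * r) / sum(seg$w)
    (rbar * d - 2 * (1 - rho)) / rho
  }
  top <- utils::head(minima, 25)
  refined <- do.call(rbind, lapply(seq_len(nrow(top)), function(m) {
    rp <- refine(top$rho[m], top$psi[m])
    # report the length-weighted mean copy number implied by the solution
    # as its tumour ploidy (inverted from the continuous mean level)
    sc <- score_at(rp[1], rp[2])
    data.frame(rho = rp[1], psi = implied_ploidy(rp[1], rp[2]),
               psi_param = rp[2], error = sc$score, chi2n = sc$chi2n,
               k = sc$k)
  }))
  refined <- refined[!duplicated(round(refined[, c("rho", "psi")], 3)), ]
  refined <- refined[order(refined$error), ]
  refined$rank <- seq_len(nrow(refined))
  rownames(refined) <- NULL

  # a genome whose best solution uses a single state carries no
  # cellularity signal at all
  flat_rho <- refined$k[1] <= 1
  structure(list(
    best = list(rho = refined$rho[1], psi = refined$psi[1],
                error = refined$error[1]),
    minima = refined,
    grid_minima = minima,
    surface = surface,
    rho_grid = rho_grid, psi_grid = psi_grid,
    penalty = penalty, penalty_ploidy = penalty_ploidy,
    max_state = max_state,
    identifiable = !flat_rho,
    profile = profile
  ), class = "absolute_fit")
}

find_local_minima <- function(surface, rho_grid, psi_grid) {
  nr <- nrow(surface); nc <- ncol(surface)
  rows <- list()
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      nb <- surface[max(1, i - 1):min(nr, i + 1),
                    max(1, j - 1):min(nc, j + 1)]
      if (surface[i, j] <= min(nb)) {
        rows[[length(rows) + 1L]] <- data.frame(
          rho = rho_grid[i], psi = psi_grid[j], error = surface[i, j])
      }
    }
  }
  m <- do.call(rbind, rows)
  m <- m[order(m$error), ]
  m$rank <- seq_len(nrow(m))
  rownames(m) <- NULL
  m
}

#' @export
print.absolute_fit <- function(x, ...) {
  cat(sprintf("absolute_fit: best rho = %.2f, psi = %.2f (error %.4g)%s\n",
              x$best$rho, x$best$psi, x$best$error,
              if (x$identifiable) "" else "  [flat surface: non-identifiable]"))
  cat(sprintf("  %d local minima; next best: %s\n", nrow(x$minima),
              if (nrow(x$minima) > 1)
                sprintf("rho = %.2f, psi = %.2f (error %.4g)",
                        x$minima$rho[2], x$minima$psi[2], x$minima$error[2])
              else "none"))
  invisible(x)
}

#' @exportS3Method base::summary
summary.absolute_fit <- function(object, n = 5, ...) {
  utils::head(object$minima, n)
}

#' @exportS3Method graphics::plot
plot.absolute_fit <- function(x, ...) {
  graphics::image(x$rho_grid, x$psi_grid, log10(x$surface),
                  xlab = "cellularity (rho)", ylab = "tumour ploidy (psi)",
                  main = "log10 penalised fit error", ...)
  graphics::points(x$best$rho, x$best$psi, pch = 4, cex = 2)
  invisible(x)
}

#' Convert a relative profile to absolute integer copy numbers
#'
#' Inverts the mixture law: `n_s = round((r_s (rho psi + 2 (1 - rho)) -
#' 2 (1 - rho)) / rho)`, clipped at 0 (with a warning when clipping occurs).
#'
#' @param profile A `relative_profile`.
#' @param rho Cellularity in `(0, 1]`.
#' @param psi Tumour ploidy.
#' @param max_state Cap on the returned states.
#' @return A `cn_profile` on the profile's genome.
#' @export
to_absolute <- function(profile, rho, psi, max_state = 20) {
  if (rho <= 0 || rho > 1) stop("cellularity must be in (0, 1]")
  seg <- profile$segments
  d <- rho * psi + 2 * (1 - rho)
  raw <- (seg$r * d - 2 * (1 - rho)) / rho
  if (any(raw < -0.5, na.rm = TRUE)) {
    warning("negative copy-number estimates clipped to 0")
  }
  n_s <- pmin(pmax(round(raw), 0), max_state)
  states <- n_s[profile$seg_of_bin]
  states[is.na(states)] <- 2L
  cn_profile(as.integer(states), profile$genome, masked = profile$masked,
             fitted_ploidy = psi)
}

#' Sensitivity of absolute calls to the assumed cellularity
#'
#' Recomputes absolute profiles over a range of cellularities and measures,
#' for each, the length-weighted fraction of segments whose gain / neutral /
#' loss classification (relative to baseline `round(psi)`) differs from the
#' reference-cellularity calls. A high-amplitude tumour should classify
#' almost identically across the sweep.
#'
#' Before classification each absolute profile passes the pipeline's
#' minimum-CNA-size filter, mirroring the analysis convention that
#' alterations below that size are excluded; without it the inversion at
#' very low assumed cellularity amplifies modal noise into spurious
#' single-segment flips.
#'
#' @param profile A `relative_profile`.
#' @param rho_values Cellularities to sweep.
#' @param psi Tumour ploidy used throughout.
#' @param reference_rho Cellularity of the reference calls.
#' @param min_cna_size Minimum CNA size (bp) applied before classification.
#' @return List with `profiles` (named list of `cn_profile`),
#'   `change_fraction` (named numeric per rho), `reference_rho`.
#' @export
cellularity_sweep <- function(profile, rho_values = seq(0.1, 1, by = 0.1),
                              psi = 2, reference_rho = 0.3,
                              min_cna_size = 0.8e6) {
  call_at <- function(rho) {
    filter_small_cnas(to_absolute(profile, rho, psi), min_cna_size)
  }
  classify <- function(p) {
    first_bin <- match(seq_len(nrow(profile$segments)), profile$seg_of_bin)
    sign(p$states[first_bin] - round(psi))
  }
  ref_cls <- classify(call_at(reference_rho))
  w <- profile$segments$w
  profiles <- list()
  change <- numeric(length(rho_values))
  names(change) <- format(rho_values)
  for (k in seq_along(rho_values)) {
    p <- call_at(rho_values[k])
    profiles[[format(rho_values[k])]] <- p
    cls <- classify(p)
    change[k] <- sum(w * (cls != ref_cls)) / sum(w)
  }
  list(profiles = profiles, change_fraction = change,
       reference_rho = reference_rho)
}

#' Corrected, segmented relative profile for one bulk sample
#'
#' The standard bulk path with an iterated normalisation: GC and mappability
#' correction blind to copy number, e-divisive segmentation, then a second
#' GC fit on count / segment-level (free of copy-number structure), a final
#' segmentation of the recorrected values, and the relative profile. The
#' iteration removes the residual coupling between the GC curve and the
#' copy-number composition of the GC strata, which otherwise biases
#' high-amplitude segments at high cellularity.
#'
#' @param x A `cell_counts` (one or more samples).
#' @param sample Row index or id of the sample.
#' @param track A `bin_track`.
#' @param mappability_threshold Bins below it are masked.
#' @param rng Optional RNG stream for segmentation permutations.
#' @param seed Integer seed (used when `rng` is `NULL`).
#' @param ... Passed to [segment_genome()].
#' @return A `relative_profile` with the corrected values in attribute
#'   `"corrected"`.
#' @export
bulk_relative_profile <- function(x, sample = 1, track,
                                  mappability_threshold = 0.2,
                                  rng = NULL, seed = 1L, ...) {
  if (is.character(sample)) sample <- match(sample, x$cell_ids)
  if (is.null(rng)) rng <- local_rng(seed, paste0("bulk_profile_", sample))
  one <- cell_counts(x$counts[sample, , drop = FALSE], x$genome)
  v1 <- correct_mappability(correct_gc(one, track, cn_aware = FALSE),
                            track, mappability_threshold)[1, ]
  bps1 <- segment_genome(v1, x$genome, rng = rng, ...)
  rel1 <- make_relative_profile(v1, bps1, x$genome)
  levels <- rel1$segments$r[rel1$seg_of_bin]
  v2 <- correct_mappability(correct_gc(one, track, levels = levels),
                            track, mappability_threshold)[1, ]
  bps2 <- segment_genome(v2, x$genome, rng = rng, ...)
  rel <- make_relative_profile(v2, bps2, x$genome)
  attr(rel, "corrected") <- v2
  rel
}
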