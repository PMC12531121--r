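#' Population of copy-number profiles
#'
#' @param profiles List of `cn_profile` objects on the same genome.
#' @param groups Optional character vector of group labels (e.g. cell line)
#'   per profile.
#' @param ids Optional cell ids.
#' @return A `cn_population`: `states` matrix (cells x bins), `masked`
#'   matrix, `genome`, `groups`, `ids`.
#' @export
cn_population <- function(profiles, groups = NULL, ids = NULL) {
  stopifnot(length(profiles) >= 1)
  g0 <- profiles[[1]]$genome
  for (p in profiles) {
    if (!identical(p$genome$bins$start, g0$bins$start)) {
      stop("profiles are on mismatched genome layouts")
    }
  }
  states <- do.call(rbind, lapply(profiles, function(p) p$states))
  masked <- do.call(rbind, lapply(profiles, function(p) p$masked))
  if (is.null(ids)) ids <- sprintf("cell%03d", seq_along(profiles))
  rownames(states) <- ids
  structure(list(states = states, masked = masked, genome = g0,
                 groups = groups, ids = ids),
            class = "cn_population")
}

#' @export
print.cn_population <- function(x, ...) {
  cat(sprintf("cn_population: %d cells x %d bins%s\n",
              nrow(x$states), ncol(x$states),
              if (is.null(x$groups)) "" else
                sprintf(" (%d groups)", length(unique(x$groups)))))
  invisible(x)
}

#' Fraction of genome altered
#'
#' Length fraction of the (non-masked) genome whose copy-number state
#' deviates from `baseline`. Invariant to how segments are subdivided,
#' because it is computed per bin weighted by bin width.
#'
#' @param profile A `cn_profile`.
#' @param baseline Integer baseline state (2 for the uncorrected FGA).
#' @return Fraction in `[0, 1]`.
#' @export
fga <- function(profile, baseline = 2) {
  ok <- !profile$masked & !is.na(profile$states)
  w <- bin_widths(profile$genome)[ok]
  sum(w * (profile$states[ok] != baseline)) / sum(w)
}

#' Population mean-ploidy baseline
#'
#' Length-weighted mean state over all non-masked bins of all cells, rounded
#' half-up to the nearest integer (x.5 rounds up).
#'
#' @param population A `cn_population`.
#' @return Integer baseline ploidy.
#' @export
population_baseline <- function(population) {
  w <- bin_widths(population$genome)
  ok <- !population$masked & !is.na(population$states)
  wm <- matrix(w, nrow(population$states), ncol(population$states),
               byrow = TRUE)
  mp <- sum(wm[ok] * population$states[ok]) / sum(wm[ok])
  as.integer(floor(mp + 0.5))
}

#' Ploidy-corrected fraction of genome altered
#'
#' FGA against the population's rounded mean ploidy instead of 2, so a clean
#' whole-genome-doubled cell in a tetraploid population scores 0. Set
#' `per_cell = TRUE` to use each cell's own rounded mean ploidy instead.
#'
#' @param profile A `cn_profile`.
#' @param population The `cn_population` providing the baseline.
#' @param per_cell Use the cell's own mean ploidy as baseline.
#' @return Fraction in `[0, 1]`.
#' @export
fga_ploidy_corrected <- function(profile, population, per_cell = FALSE) {
  baseline <- if (per_cell) as.integer(floor(mean_ploidy(profile) + 0.5))
              else population_baseline(population)
  fga(profile, baseline = baseline)
}

#' Shannon entropy of a copy-number profile
#'
#' Diversity of the per-cell state distribution: `H = -sum_k p_k log(p_k)`
#' where `p_k` is the length fraction of the non-masked genome in state `k`.
#' A single-state genome scores 0; `K` states at equal length share score
#' `log(K)`.
#'
#' @param profile A `cn_profile`.
#' @param base Logarithm base; 2 (bits) by default.
#' @return Non-negative entropy.
#' @export
shannon_entropy <- function(profile, base = 2) {
  ok <- !profile$masked & !is.na(profile$states)
  w <- bin_widths(profile$genome)[ok]
  p <- tapply(w, profile$states[ok], sum) / sum(w)
  -sum(p * log(p)) / log(base)
}

#' Per-bin population entropy
#'
#' Secondary diversity statistic: for each bin, the Shannon entropy of the
#' state distribution across cells.
#'
#' @param population A `cn_population`.
#' @param base Logarithm base.
#' @return Numeric vector, one entropy per bin.
#' @export
bin_entropy <- function(population, base = 2) {
  apply(population$states, 2, function(col) {
    col <- col[!is.na(col)]
    if (!length(col)) return(NA_real_)
    p <- table(col) / length(col)
    -sum(p * log(p)) / log(base)
  })
}

#' Per-bin gain and loss frequency
#'
#' For each bin, the fraction of cells whose state exceeds (gain) or falls
#' below (loss) the ploidy-corrected baseline.
#'
#' @param population A `cn_population`.
#' @param baseline Integer baseline; defaults to [population_baseline()].
#' @return Data.frame with the genome's bin coordinates plus `gain_freq` and
#'   `loss_freq`.
#' @export
cna_frequency <- function(population, baseline = NULL) {
  if (is.null(baseline)) baseline <- population_baseline(population)
  st <- population$states
  st[population$masked] <- NA
  n_called <- colSums(!is.na(st))
  gain <- colSums(st > baseline, na.rm = TRUE) / pmax(n_called, 1)
  loss <- colSums(st < baseline, na.rm = TRUE) / pmax(n_called, 1)
  cbind(population$genome$bins,
        data.frame(gain_freq = gain, loss_freq = loss))
}

#' Per-cell heterogeneity report
#'
#' Computes FGA, ploidy-corrected FGA, and Shannon entropy for every cell,
#' with per-group summaries.
#'
#' @param population A `cn_population`.
#' @param base Entropy logarithm base.
#' @return A `heterogeneity_report`: `per_cell` data.frame (cell_id, group,
#'   fga, fga_ploidy_corrected, entropy, mean_ploidy) and `per_group`
#'   summary (mean, sd, n per metric).
#' @export
heterogeneity_report <- function(population, base = 2) {
  profs <- lapply(seq_len(nrow(population$states)), function(i) {
    cn_profile(population$states[i, ], population$genome,
               masked = population$masked[i, ])
  })
  per_cell <- data.frame(
    cell_id = population$ids,
    group = if (is.null(population$groups)) NA_character_ else population$groups,
    fga = vapply(profs, fga, numeric(1)),
    fga_ploidy_corrected = vapply(profs, fga_ploidy_corrected, numeric(1),
                                  population = population),
    entropy = vapply(profs, shannon_entropy, numeric(1), base = base),
    mean_ploidy = vapply(profs, mean_ploidy, numeric(1)),
    row.names = NULL)
  per_group <- NULL
  if (!is.null(population$groups)) {
    agg <- function(metric) {
      do.call(rbind, lapply(split(per_cell[[metric]], per_cell$group),
        function(v) data.frame(mean = mean(v), sd = stats::sd(v),
                               n = length(v))))
    }
    per_group <- list(fga = agg("fga"),
                      fga_ploidy_corrected = agg("fga_ploidy_corrected"),
                      entropy = agg("entropy"))
  }
  structure(list(per_cell = per_cell, per_group = per_group),
            class = "heterogeneity_report")
}

#' @export
print.heterogeneity_report <- function(x, ...) {
  cat("heterogeneity_report:", nrow(x$per_cell), "cells\n")
  print(utils::head(x$per_cell))
  invisible(x)
}

#' Two-sample comparison of a heterogeneity metric
#'
#' Independent two-sample t-test on per-cell metric values between two
#' groups; Welch (default) and pooled-variance variants.
#'
#' @param report A `heterogeneity_report`.
#' @param metric One of `"fga"`, `"fga_ploidy_corrected"`, `"entropy"`.
#' @param group_a,group_b Group labels to compare.
#' @param pooled Use the pooled-variance (classic Student) test instead of
#'   Welch.
#' @return The `htest` object from [stats::t.test()].
#' @export
compare_groups <- function(report, metric = "fga", group_a, group_b,
                           pooled = FALSE) {
  pc <- report$per_cell
  a <- pc[[metric]][pc$group == group_a]
  b <- pc[[metric]][pc$group == group_b]
  if (!length(a) || !length(b)) stop("unknown group label")
  if (identical(a, b)) {
    # degenerate identical samples: t = 0 by definition
    return(structure(list(statistic = c(t = 0), p.value = 1,
                          estimate = c(mean(a), mean(b)),
                          method = "t-test (degenerate: identical groups)"),
                     class = "htest"))
  }
  stats::t.test(a, b, var.equal = pooled)
}
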