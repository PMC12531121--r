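#' Call focal amplifications and deletions on an absolute profile
#'
#' Scans the profile's maximal constant-state runs for short, high-amplitude
#' events relative to the sample's ploidy: amplifications at state >=
#' `amp_min_state` and deletions at state <= `del_max_state`, keeping only
#' events spanning at most `max_focal_length` bp (arm- and chromosome-scale
#' changes are not focal). Touching qualifying runs of the same type are
#' merged before the length cap is applied.
#'
#' The defaults tie the thresholds to the fitted ploidy `psi`:
#' `amp_min_state = 2 * round(psi) + 1` and
#' `del_max_state = max(0, round(psi) - 2)`.
#'
#' @param profile A `cn_profile`.
#' @param max_focal_length Maximum focal event length in bp.
#' @param amp_min_state,del_max_state State thresholds; `NULL` derives them
#'   from `psi`.
#' @param psi Sample ploidy; defaults to the profile's fitted ploidy, else
#'   its mean ploidy.
#' @return Data.frame of `focal_event`s: `chrom`, `start`, `end` (bp,
#'   half-open), `type` ("amp"/"del"), `state`, `length`.
#' @export
call_focal_events <- function(profile, max_focal_length = 20e6,
                              amp_min_state = NULL, del_max_state = NULL,
                              psi = NULL) {
  if (is.null(psi)) {
    psi <- if (!is.null(profile$fitted_ploidy)) profile$fitted_ploidy
           else mean_ploidy(profile)
  }
  if (is.null(amp_min_state)) amp_min_state <- 2 * round(psi) + 1
  if (is.null(del_max_state)) del_max_state <- max(0, round(psi) - 2)
  seg <- profile_segments(profile)
  seg$type <- NA_character_
  seg$type[seg$state >= amp_min_state] <- "amp"
  seg$type[seg$state <= del_max_state] <- "del"
  out <- list()
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    i <- 1L
    while (i <= nrow(s)) {
      if (is.na(s$type[i])) { i <- i + 1L; next }
      j <- i
      while (j < nrow(s) && !is.na(s$type[j + 1L]) &&
             s$type[j + 1L] == s$type[i] &&
             s$start[j + 1L] == s$end[j]) j <- j + 1L
      ev_state <- if (s$type[i] == "amp") max(s$state[i:j]) else min(s$state[i:j])
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = s$start[i], end = s$end[j],
        type = s$type[i], state = ev_state,
        length = s$end[j] - s$start[i])
      i <- j + 1L
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               type = character(), state = numeric(), length = numeric())
  ev <- ev[ev$length <= max_focal_length, , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

#' Annotate focal events with overlapping genes
#'
#' Interval overlap (any overlap counts, half-open coordinates: an event
#' ending exactly where a gene starts does not overlap it) against a
#' BED-style gene table. Overlapping genes are reported in coordinate-sorted
#' BED order regardless of the input file's row order; genes on the
#' configured CIN-associated list set `cin_flag`.
#'
#' @param events Data.frame from [call_focal_events()].
#' @param genes BED-style data.frame: `chrom`, `start`, `end`, `name`.
#' @param cin_list Character vector of CIN-associated gene names.
#' @return `events` with added `genes` (comma-separated names) and
#'   `cin_flag` (any overlapped gene on the list).
#' @export
annotate_genes <- function(events, genes,
                           cin_list = c("CCNE1", "BRCA1", "MDM2", "KRAS",
                                        "CDK6", "CDK13")) {
  genes <- genes[order(genes$chrom, genes$start), ]
  if (nrow(events) == 0) {
    events$genes <- character(0)
    events$cin_flag <- logical(0)
    return(events)
  }
  ev_gr <- GenomicRanges::GRanges(events$chrom,
    IRanges::IRanges(events$start + 1L, events$end))
  gn_gr <- GenomicRanges::GRanges(genes$chrom,
    IRanges::IRanges(genes$start + 1L, genes$end))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(ev_gr, gn_gr))
  events$genes <- ""
  events$cin_flag <- FALSE
  for (i in seq_len(nrow(events))) {
    g <- genes$name[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]]
    events$genes[i] <- paste(g, collapse = ",")
    events$cin_flag[i] <- any(g %in% cin_list)
  }
  events
}

#' Read a BED file of gene intervals
#'
#' Minimal BED3+name reader (0-based half-open, tab-separated, no header).
#'
#' @param path BED file.
#' @return Data.frame `chrom`, `start`, `end`, `name`.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 4) stop("gene BED needs at least 4 columns (chrom, start, end, name)")
  stats::setNames(df[, 1:4], c("chrom", "start", "end", "name"))
}

#' Write gene intervals as BED
#'
#' @param genes Data.frame `chrom`, `start`, `end`, `name`.
#' @param path Output file.
#' @export
write_gene_bed <- function(genes, path) {
  utils::write.table(genes[, c("chrom", "start", "end", "name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
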