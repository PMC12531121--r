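pipeline_defaults <- function(preset = c("single-cell", "bulk-ffpe")) {
  preset <- match.arg(preset)
  scale <- 1 / 30
  common <- list(
    preset = preset, seed = 1L,
    genome_scale = scale, bin_size = 5e5,
    blacklist_frac = 0.02, low_map_frac = 0.03,
    gc_bias_coeffs = c(-1.5, 11, -11), overdispersion = 100,
    mappability_threshold = 0.2, max_spikiness = 1.0,
    alpha = 1, p_threshold = 0.05, n_permutations = 199, min_seg_bins = 2,
    ploidy_grid = seq(1.5, 6, by = 0.05), max_state = 10,
    min_cna_size = 0.8e6,
    entropy_base = 2,
    rho_grid = seq(0.05, 1, by = 0.01), psi_grid = seq(1.5, 5.5, by = 0.05),
    penalty = 0.1,
    k_clades = NULL,
    cin_genes = c("CCNE1", "BRCA1", "MDM2", "KRAS", "CDK6", "CDK13")
  )
  if (preset == "single-cell") {
    c(common, list(
      n_cells = 96, n_clones = 3, n_shared_events = 5, n_private_events = 5,
      event_length_range = c(1e6, 8e6), wgd_clones = 3L,
      proportions = c(0.5, 0.3, 0.2),
      # the 0.5-3M reads/cell DLP regime, scaled with the genome
      reads_per_cell = c(0.5e6, 3e6) * scale,
      dropout_rate = 0.13, ffpe_sd = 0,
      min_reads = 0.5e6 * scale, max_reads = 3e6 * scale,
      max_focal_length = 5e6, amp_min_state = NULL, del_max_state = NULL
    ))
  } else {
    common$bin_size <- 1e5   # the finer binning used for bulk profiles
    c(common, list(
      n_tumours = 33, n_focal_carriers = 8,
      n_shared_events = 0, n_tumour_events = 8,
      event_length_range = c(1e6, 6e6),
      n_focal_amps = 1, n_focal_dels = 1, amp_state = 8,
      focal_max_len = 2.5e6,
      cellularity = 0.3, total_reads = 1.5e6 * scale,
      reads_per_cell = c(0.1e6, 10e6) * scale,  # loose sample-level bounds
      dropout_rate = 0, ffpe_sd = 0.08,
      min_reads = 0.1e6 * scale, max_reads = 10e6 * scale,
      sweep_rho = seq(0.1, 1, by = 0.1),
      max_focal_length = 5e6, amp_min_state = NULL, del_max_state = NULL
    ))
  }
}

#' Pipeline configuration
#'
#' Resolves a full parameter set for [run_pipeline()] from a preset plus
#' overrides. Unknown keys are rejected so typos cannot silently fall back
#' to defaults.
#'
#' @param preset `"single-cell"` (DLP-style cell population) or
#'   `"bulk-ffpe"` (tumour/normal low-pass cohort).
#' @param ... Named overrides of any default key.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(preset = "single-cell", ...) {
  cfg <- pipeline_defaults(preset)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

write_config <- function(cfg, path) {
  txt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    sprintf("%s: %s", k,
            if (is.null(v)) "null" else paste(format(v, digits = 10),
                                              collapse = ", "))
  }, character(1))
  writeLines(txt, path)
  invisible(path)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate -> qc -> segment -> fit -> metrics -> phylo ->
#' focal (the bulk preset skips phylo), writing every stage's outputs, a
#' resolved-config echo, a structured log with per-stage timings, and a
#' manifest of output checksums. A stage failure leaves prior outputs in
#' place with a `FAILED` marker naming the stage.
#'
#' @param config A `pipeline_config`.
#' @param outdir Output directory (created if needed).
#' @param stages Stages to run (a prefix of the standard order).
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config, outdir,
                         stages = c("simulate", "qc", "segment", "fit",
                                    "metrics", "phylo", "focal")) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(outdir, "pipeline_log.txt")
  cat("", file = log_path)
  log_line <- function(...) {
    cat(sprintf(...), "\n", sep = "", file = log_path, append = TRUE)
  }
  res <- new.env(parent = emptyenv())
  current <- "init"
  run_stage <- function(name, fn) {
    if (!(name %in% stages)) return(invisible(NULL))
    current <<- name
    t0 <- proc.time()[["elapsed"]]
    fn()
    log_line("stage=%s elapsed=%.2fs seed=%d preset=%s", name,
             proc.time()[["elapsed"]] - t0, config$seed, config$preset)
  }
  ok <- FALSE
  on.exit(if (!ok) {
    writeLines(paste("FAILED at stage:", current),
               file.path(outdir, "FAILED"))
  })
  write_config(config, file.path(outdir, "config_resolved.txt"))
  if (config$preset == "single-cell") {
    run_single_cell(config, outdir, res, run_stage)
  } else {
    run_bulk_ffpe(config, outdir, res, run_stage)
  }
  files <- setdiff(list.files(outdir), c("manifest.tsv", "FAILED"))
  sums <- tools::md5sum(file.path(outdir, files))
  write_tsv(data.frame(file = files, md5 = unname(sums)),
            file.path(outdir, "manifest.tsv"))
  ok <- TRUE
  invisible(as.list(res))
}

run_single_cell <- function(config, outdir, res, run_stage) {
  run_stage("simulate", function() {
    res$genome <- toy_genome(config$genome_scale, config$bin_size)
    res$track <- make_bin_track(res$genome,
                                blacklist_frac = config$blacklist_frac,
                                low_map_frac = config$low_map_frac,
                                seed = config$seed)
    res$clones <- simulate_clones(res$genome, config$n_clones,
                                  config$n_shared_events,
                                  config$n_private_events,
                                  config$event_length_range,
                                  wgd_clones = config$wgd_clones,
                                  proportions = config$proportions,
                                  max_state = config$max_state,
                                  seed = config$seed)
    noise <- noise_model(config$reads_per_cell, config$gc_bias_coeffs,
                         config$overdispersion, config$dropout_rate,
                         config$ffpe_sd)
    res$raw <- simulate_cell_counts(res$clones, config$n_cells, noise,
                                    res$track, seed = config$seed)
    write_counts(res$raw, file.path(outdir, "counts.tsv"))
    write_tsv(data.frame(cell_id = res$raw$cell_ids,
                         clone = res$raw$truth$clone,
                         dropout = as.integer(res$raw$truth$dropout)),
              file.path(outdir, "truth_cells.tsv"))
    write_tsv(cbind(res$genome$bins, t(res$clones$profiles)),
              file.path(outdir, "truth_clone_profiles.tsv"))
    write_tsv(res$clones$events, file.path(outdir, "truth_events.tsv"))
    write_gene_bed(toy_genes(res$genome, config$genome_scale),
                   file.path(outdir, "genes.bed"))
  })
  run_stage("qc", function() {
    res$corrected_all <- correct_gc(res$raw, res$track)
    res$kept <- filter_cells(res$raw, res$track, config$min_reads,
                             config$max_reads, config$max_spikiness,
                             corrected = res$corrected_all)
    write_tsv(res$kept$qc, file.path(outdir, "qc_report.tsv"))
    res$corrected <- res$corrected_all[res$kept$qc$kept == 1, , drop = FALSE]
  })
  run_stage("segment", function() {
    profs <- vector("list", nrow(res$corrected))
    for (i in seq_len(nrow(res$corrected))) {
      rng <- local_rng(config$seed, paste0("segment_", res$kept$cell_ids[i]))
      profs[[i]] <- segment_profile(res$corrected[i, ], res$kept$genome,
                                    alpha = config$alpha,
                                    p_threshold = config$p_threshold,
                                    n_permutations = config$n_permutations,
                                    min_seg_bins = config$min_seg_bins,
                                    ploidy_grid = config$ploidy_grid,
                                    max_state = config$max_state,
                                    min_cna_size = config$min_cna_size,
                                    rng = rng)
    }
    res$population <- cn_population(profs, ids = res$kept$cell_ids)
    seg_rows <- do.call(rbind, lapply(seq_along(profs), function(i) {
      s <- profile_segments(profs[[i]])
      s$cell_id <- res$kept$cell_ids[i]
      s[, c("chrom", "start", "end", "cell_id", "state", "n_bins")]
    }))
    write_tsv(seg_rows, file.path(outdir, "segments.tsv"))
  })
  run_stage("fit", function() {
    res$pseudobulk_all <- pseudobulk(res$kept, seq_along(res$kept$cell_ids),
                                     res$track, seed = config$seed,
                                     p_threshold = config$p_threshold,
                                     n_permutations = config$n_permutations)
    fit <- res$pseudobulk_all$fit
    write_tsv(data.frame(sample = "pseudobulk_all", rho = 1,
                         psi = fit$best$psi, error = fit$best$error,
                         rank = 1),
              file.path(outdir, "fit_report.tsv"))
  })
  run_stage("metrics", function() {
    grp <- paste0("clone", res$kept$truth$clone)
    res$population$groups <- grp
    res$report <- heterogeneity_report(res$population,
                                       base = config$entropy_base)
    write_tsv(res$report$per_cell, file.path(outdir, "metrics_per_cell.tsv"))
    write_tsv(cna_frequency(res$population),
              file.path(outdir, "cna_frequency.tsv"))
  })
  run_stage("phylo", function() {
    mcs <- minimum_consistent_segmentation(res$population)
    dm <- event_distance_matrix(mcs)
    res$tree <- build_tree(dm, k = config$k_clades)
    write_tree_newick(res$tree, file.path(outdir, "tree.nwk"))
    write_tsv(data.frame(cell_id = names(res$tree$clades),
                         clade = unname(res$tree$clades)),
              file.path(outdir, "clades.tsv"))
    write_tsv(cbind(mcs$segments[, c("chrom", "start", "end", "n_bins")],
                    as.data.frame(t(mcs$states))),
              file.path(outdir, "shared_segments.tsv"))
  })
  run_stage("focal", function() {
    ev <- call_focal_events(res$pseudobulk_all$profile,
                            max_focal_length = config$max_focal_length,
                            amp_min_state = config$amp_min_state,
                            del_max_state = config$del_max_state)
    ev <- annotate_genes(ev, toy_genes(res$genome, config$genome_scale),
                         cin_list = config$cin_genes)
    write_tsv(ev, file.path(outdir, "focal_events.tsv"))
  })
}

run_bulk_ffpe <- function(config, outdir, res, run_stage) {
  run_stage("simulate", function() {
    res$genome <- toy_genome(config$genome_scale, config$bin_size)
    res$track <- make_bin_track(res$genome,
                                blacklist_frac = config$blacklist_frac,
                                low_map_frac = config$low_map_frac,
                                seed = config$seed)
    res$genes <- toy_genes(res$genome, config$genome_scale)
    noise <- noise_model(config$reads_per_cell, config$gc_bias_coeffs,
                         config$overdispersion, config$dropout_rate,
                         config$ffpe_sd)
    nb <- n_bins(res$genome)
    profiles <- list(); counts <- list(); logs <- list()
    for (s in seq_len(config$n_tumours)) {
      cs <- simulate_clones(res$genome, 1, 0, config$n_tumour_events,
                            config$event_length_range,
                            max_state = config$max_state,
                            seed = config$seed + 1000L + s)
      prof <- cs$profiles[1, ]
      if (s <= config$n_focal_carriers) {
        inj <- inject_focal_events(prof, res$genome, res$genes,
                                   n_amps = config$n_focal_amps,
                                   n_dels = config$n_focal_dels,
                                   amp_state = config$amp_state,
                                   max_len = config$focal_max_len,
                                   seed = config$seed + 2000L + s)
        prof <- inj$profile
        if (nrow(inj$events)) {
          inj$events$sample <- sprintf("tumour%02d", s)
          logs[[length(logs) + 1L]] <- inj$events
        }
      }
      profiles[[sprintf("tumour%02d", s)]] <- prof
      counts[[sprintf("tumour%02d", s)]] <-
        simulate_bulk(prof, res$genome, config$cellularity,
                      config$total_reads, noise, res$track, ffpe = TRUE,
                      seed = config$seed + 3000L + s)
      counts[[sprintf("normal%02d", s)]] <-
        simulate_bulk(rep(2L, nb), res$genome, config$cellularity,
                      config$total_reads, noise, res$track, ffpe = TRUE,
                      seed = config$seed + 4000L + s)
    }
    res$truth_profiles <- profiles
    res$focal_log <- if (length(logs)) do.call(rbind, logs) else data.frame()
    m <- do.call(rbind, lapply(counts, as.integer))
    rownames(m) <- names(counts)
    res$raw <- cell_counts(m, res$genome)
    write_counts(res$raw, file.path(outdir, "counts.tsv"))
    write_tsv(cbind(res$genome$bins, as.data.frame(do.call(cbind, profiles))),
              file.path(outdir, "truth_profiles.tsv"))
    if (nrow(res$focal_log)) {
      write_tsv(res$focal_log, file.path(outdir, "truth_focal_events.tsv"))
    }
    write_gene_bed(res$genes, file.path(outdir, "genes.bed"))
  })
  run_stage("qc", function() {
    res$corrected <- correct_mappability(
      correct_gc(res$raw, res$track, cn_aware = FALSE),
      res$track, config$mappability_threshold)
    write_tsv(data.frame(sample = res$raw$cell_ids,
                         total_reads = res$raw$total_reads),
              file.path(outdir, "qc_report.tsv"))
  })
  run_stage("segment", function() {
    res$relative <- lapply(seq_len(nrow(res$corrected)), function(i) {
      rng <- local_rng(config$seed, paste0("bulkseg_", res$raw$cell_ids[i]))
      bps <- segment_genome(res$corrected[i, ], res$genome,
                            alpha = config$alpha,
                            p_threshold = config$p_threshold,
                            n_permutations = config$n_permutations,
                            min_seg_bins = config$min_seg_bins, rng = rng)
      make_relative_profile(res$corrected[i, ], bps, res$genome)
    })
    names(res$relative) <- res$raw$cell_ids
  })
  run_stage("fit", function() {
    rows <- list(); res$absolute <- list()
    for (nm in names(res$relative)) {
      fit <- fit_absolute(res$relative[[nm]], config$rho_grid,
                          config$psi_grid, config$penalty)
      # the cohort convention: call all samples at the fixed cellularity
      res$absolute[[nm]] <- to_absolute(res$relative[[nm]],
                                        config$cellularity, 2)
      rows[[nm]] <- data.frame(sample = nm, rho = fit$best$rho,
                               psi = fit$best$psi, error = fit$best$error,
                               rho_used = config$cellularity)
    }
    write_tsv(do.call(rbind, rows), file.path(outdir, "fit_report.tsv"))
    sw <- cellularity_sweep(res$relative[[1]], config$sweep_rho, psi = 2,
                            reference_rho = config$cellularity)
    write_tsv(data.frame(rho = config$sweep_rho,
                         change_fraction = unname(sw$change_fraction)),
              file.path(outdir, "cellularity_sweep.tsv"))
  })
  run_stage("metrics", function() {
    tum <- res$absolute[grep("^tumour", names(res$absolute))]
    pop <- cn_population(tum, ids = names(tum))
    write_tsv(cna_frequency(pop, baseline = 2),
              file.path(outdir, "cna_frequency.tsv"))
  })
  run_stage("focal", function() {
    rows <- list()
    for (nm in names(res$absolute)) {
      ev <- call_focal_events(res$absolute[[nm]],
                              max_focal_length = config$max_focal_length,
                              amp_min_state = config$amp_min_state,
                              del_max_state = config$del_max_state, psi = 2)
      if (nrow(ev)) {
        ev <- annotate_genes(ev, res$genes, cin_list = config$cin_genes)
        ev$sample <- nm
        rows[[nm]] <- ev
      }
    }
    out <- if (length(rows)) do.call(rbind, rows) else
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 type = character(), state = numeric(), length = numeric(),
                 genes = character(), cin_flag = logical(),
                 sample = character())
    write_tsv(out, file.path(outdir, "focal_events.tsv"))
    res$focal_calls <- out
  })
}
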