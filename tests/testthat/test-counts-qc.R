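test_that("counts round-trip through TSV bit-exactly", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 2)
  cs <- simulate_clones(g, 2, 2, 2, seed = 3)
  cc <- simulate_cell_counts(cs, 8, noise_model(), tr, seed = 4)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cc, path)
  back <- load_counts(path)
  expect_identical(unname(back$counts), unname(cc$counts))
  expect_identical(back$cell_ids, cc$cell_ids)
  expect_equal(back$genome$bins$start, g$bins$start)
})

test_that("malformed count files are rejected", {
  g <- make_genome(c(chrA = 2e6), 5e5)
  cc <- cell_counts(matrix(5L, 2, 4, dimnames = list(c("c1", "c2"), NULL)), g)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cc, path)
  df <- read.table(path, header = TRUE, sep = "\t")

  bad <- df[c(2, 1, 3, 4), ]                   # bins out of order
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts(p2), "order")

  bad2 <- df; bad2$c1[1] <- 2.5                # non-integer counts
  p3 <- withr::local_tempfile(fileext = ".tsv")
  write.table(bad2, p3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_counts(p3), "non-integer")
})

test_that("cell ids survive a 384-cell round trip in order", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 2)
  cs <- simulate_clones(g, 1, 0, 0, seed = 1)
  cc <- simulate_cell_counts(cs, 384, noise_model(), tr, seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_counts(cc, path)
  expect_identical(load_counts(path)$cell_ids, cc$cell_ids)
})

test_that("GC correction is near-identity without bias and decorrelates with it", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 11)
  cs <- simulate_clones(g, 1, 0, 0, seed = 1)   # diploid cells
  # no GC bias: corrected should track raw within fit noise
  no_bias <- noise_model(reads_per_cell = c(2.8e6, 3e6) / 30,
                         gc_bias_coeffs = c(1, 0, 0))
  cc <- simulate_cell_counts(cs, 6, no_bias, tr, seed = 2)
  corr <- correct_gc(cc, tr)
  w <- bin_widths(g) / g$bin_size
  for (i in 1:6) {
    raw <- as.numeric(cc$counts[i, ]) / w
    ok <- is.finite(corr[i, ])
    rel_change <- abs(corr[i, ok] / raw[ok] - 1)
    expect_lt(median(rel_change), 0.02)
  }
  # strong quadratic bias: corrected values decorrelate from GC
  biased <- noise_model(reads_per_cell = c(2.8e6, 3e6) / 30)
  cc2 <- simulate_cell_counts(cs, 6, biased, tr, seed = 3)
  corr2 <- correct_gc(cc2, tr)
  for (i in 1:6) {
    ok <- is.finite(corr2[i, ])
    rho <- cor(corr2[i, ok], tr$gc[ok], method = "spearman")
    expect_lt(abs(rho), 0.05)
  }
})

test_that("GC correction preserves each cell's mean and masks blacklist", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 5)
  cs <- simulate_clones(g, 2, 3, 3, seed = 6)
  cc <- simulate_cell_counts(cs, 5, noise_model(), tr, seed = 7)
  corr <- correct_gc(cc, tr)
  w <- bin_widths(g) / g$bin_size
  usable <- !tr$blacklisted
  for (i in 1:5) {
    y <- as.numeric(cc$counts[i, ]) / w
    ok <- usable & is.finite(y)
    expect_equal(mean(corr[i, ok]), mean(y[ok]), tolerance = 1e-6)
  }
  expect_true(all(is.na(corr[, tr$blacklisted])))
})

test_that("constant counts stay constant through correction", {
  g <- make_genome(c(chrA = 1e8), 5e5)   # single chromosome, equal bins
  tr <- make_bin_track(g, blacklist_frac = 0, low_map_frac = 0, seed = 1)
  cc <- cell_counts(matrix(100L, 1, nrow(g$bins),
                           dimnames = list("c1", NULL)), g)
  corr <- correct_gc(cc, tr)
  expect_true(all(abs(corr[1, ] - 100) < 1e-9))
})

test_that("mappability correction divides and masks", {
  g <- make_genome(c(chrA = 2e6), 5e5)
  tr <- flat_track(g)
  v <- c(10, 10, 10, 10)
  expect_equal(correct_mappability(v, tr), v)        # all-1 mappability
  tr$mappability <- c(1, 0.5, 0.1, 1)
  out <- correct_mappability(v, tr, threshold = 0.2)
  expect_equal(out[2], 20)                            # doubled at 0.5
  expect_true(is.na(out[3]))                          # masked below 0.2
  expect_equal(out[c(1, 4)], c(10, 10))
})

test_that("cell filter applies inclusive read bounds and evenness", {
  g <- toy_genome()
  tr <- flat_track(g)
  nb <- nrow(g$bins)
  min_r <- 0.5e6; max_r <- 3e6
  totals <- c(0.4e6, 0.5e6, 1.0e6, 3.0e6, 3.1e6)
  counts <- t(vapply(totals, function(tt) {
    base <- rep(floor(tt / nb), nb)
    base[1] <- base[1] + tt - sum(base)
    as.integer(base)
  }, integer(nb)))
  rownames(counts) <- paste0("c", 1:5)
  cc <- cell_counts(counts, g)
  kept <- filter_cells(cc, tr, min_r, max_r)
  expect_equal(kept$qc$reason, c("low_reads", "pass", "pass", "pass",
                                 "high_reads"))
  expect_equal(sum(kept$qc$kept), 3)

  # a cell with 20% of reads in one bin is uneven
  uneven <- rep(3000L, nb)
  uneven[10] <- as.integer(round(0.2 * sum(uneven) / 0.8))
  cc2 <- cell_counts(rbind(even = rep(3000L, nb), uneven = uneven), g)
  kept2 <- filter_cells(cc2, tr, 1e5, 1e9)
  expect_equal(kept2$qc$reason, c("pass", "uneven_coverage"))
  expect_gt(spikiness(as.numeric(uneven)), 1)

  expect_error(filter_cells(cc, tr, 10, 10), "min_reads")
})

test_that("filtering is idempotent", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 9)
  cs <- simulate_clones(g, 2, 3, 3, seed = 2)
  cc <- simulate_cell_counts(cs, 40, noise_model(dropout_rate = 0.2), tr,
                             seed = 3)
  f1 <- filter_cells(cc, tr, 0.5e6 / 30, 3e6 / 30)
  f2 <- filter_cells(f1, tr, 0.5e6 / 30, 3e6 / 30)
  expect_identical(f1$cell_ids, f2$cell_ids)
  expect_identical(unname(f1$counts), unname(f2$counts))
  expect_true(all(f2$qc$kept == 1))
})
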