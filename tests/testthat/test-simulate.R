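test_that("clone simulation honours the diploid ancestor and WGD", {
  g <- toy_genome()
  c1 <- simulate_clones(g, 1, 0, 0, seed = 1)
  expect_true(all(c1$profiles == 2L))

  c2 <- simulate_clones(g, 1, 0, 0, wgd_clones = 1, seed = 1)
  expect_true(all(c2$profiles == 4L))
})

test_that("clone simulation is bit-identical under the same seed", {
  g <- toy_genome()
  a <- simulate_clones(g, 3, 5, 5, wgd_clones = 3, seed = 99)
  b <- simulate_clones(g, 3, 5, 5, wgd_clones = 3, seed = 99)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$events, b$events)
  d <- simulate_clones(g, 3, 5, 5, wgd_clones = 3, seed = 100)
  expect_false(identical(a$profiles, d$profiles))
})

test_that("clone profiles replay exactly from the logged event list", {
  g <- toy_genome()
  cs <- simulate_clones(g, 3, 5, 5, seed = 7)
  nb <- nrow(g$bins)
  replay <- function(clone) {
    p <- rep(2L, nb)
    ev <- cs$events
    shared <- ev[ev$scope == "shared", ]
    for (i in seq_len(nrow(shared))) {
      sp <- shared$bin_from[i]:shared$bin_to[i]
      p[sp] <- pmin(pmax(p[sp] + shared$delta[i], 0L), 10L)
    }
    priv <- ev[ev$scope == "private" & ev$clone == clone, ]
    for (i in seq_len(nrow(priv))) {
      sp <- priv$bin_from[i]:priv$bin_to[i]
      p[sp] <- pmin(pmax(p[sp] + priv$delta[i], 0L), 10L)
    }
    p
  }
  for (cl in 1:3) {
    expect_identical(unname(cs$profiles[cl, ]), replay(cl))
  }
  # pairwise Hamming distances follow from the replayed profiles
  for (a in 1:2) for (b in (a + 1):3) {
    expect_equal(sum(cs$profiles[a, ] != cs$profiles[b, ]),
                 sum(replay(a) != replay(b)))
  }
})

test_that("invalid clone arguments error", {
  g <- toy_genome()
  expect_error(simulate_clones(g, 0), "n_clones")
  expect_error(simulate_clones(g, 2, 1, 1, event_length_range = c(1e5, 2e5)),
               "at least one bin")
  expect_error(simulate_clones(g, 2, 1, 1, event_length_range = c(1e6, 9e9)),
               "longest chromosome")
  expect_error(simulate_clones(g, 2, proportions = c(0.6, 0.6)), "sum to 1")
})

test_that("expected counts follow the state proportionality law", {
  g <- toy_genome()
  tr <- flat_track(g)
  cs <- simulate_clones(g, 1, 0, 0, seed = 1)
  cs$profiles[1, 1:50] <- 4L          # half of chr1 region at state 4
  noise <- noise_model(reads_per_cell = c(0.9e6, 1.1e6) / 30,
                       gc_bias_coeffs = c(1, 0, 0), overdispersion = 1e8)
  cc <- simulate_cell_counts(cs, 100, noise, tr, seed = 5)
  w <- bin_widths(g) / g$bin_size
  norm <- sweep(cc$counts, 2, w, "/")
  m4 <- mean(norm[, 1:50])
  m2 <- mean(norm[, 101:150])
  expect_equal(m4 / m2, 2, tolerance = 0.02)
})

test_that("near-Poisson limit gives binomial-consistent per-bin means", {
  g <- toy_genome()
  tr <- flat_track(g)
  cs <- simulate_clones(g, 1, 0, 0, seed = 1)
  noise <- noise_model(reads_per_cell = c(0.999e6, 1.001e6),
                       gc_bias_coeffs = c(1, 0, 0), overdispersion = 1e8)
  cc <- simulate_cell_counts(cs, 50, noise, tr, seed = 2)
  w <- bin_widths(g) / g$bin_size
  expected <- 1e6 * w / sum(w)
  obs <- colMeans(cc$counts)
  se <- sqrt(expected / 50)
  expect_true(all(abs(obs - expected) < 4 * se))
})

test_that("dropout rate 0.13 on 384 cells yields about 50 dropouts", {
  g <- toy_genome()
  tr <- make_bin_track(g, seed = 3)
  cs <- simulate_clones(g, 1, 0, 0, seed = 1)
  noise <- noise_model(dropout_rate = 0.13)
  cc <- simulate_cell_counts(cs, 384, noise, tr, seed = 8)
  n_drop <- sum(cc$truth$dropout)
  # binomial 99.9% interval around 384 * 0.13 = 49.9
  expect_gt(n_drop, qbinom(0.0005, 384, 0.13))
  expect_lt(n_drop, qbinom(0.9995, 384, 0.13))
  # dropouts fall below the read minimum; all other cells are in range
  expect_true(all(cc$total_reads[cc$truth$dropout] <
                    noise$reads_per_cell[1]))
  inrange <- cc$total_reads[!cc$truth$dropout]
  # totals are Poisson-ish around a uniform draw within the range
  expect_true(mean(inrange > noise$reads_per_cell[1] * 0.95 &
                     inrange < noise$reads_per_cell[2] * 1.05) > 0.99)
})

test_that("bulk mixture follows the closed-form expected ratio", {
  g <- toy_genome()
  tr <- flat_track(g)
  prof <- rep(2L, nrow(g$bins))
  prof[1:10] <- 6L
  noise <- noise_model(gc_bias_coeffs = c(1, 0, 0), overdispersion = 1e8)
  counts <- simulate_bulk(prof, g, 0.3, 3e6, noise, tr, ffpe = FALSE,
                          seed = 4)
  w <- bin_widths(g) / g$bin_size
  norm <- as.numeric(counts) / w
  ratio <- mean(norm[1:10]) / mean(norm[which(prof == 2L)])
  expect_equal(ratio, (0.3 * 6 + 1.4) / (0.3 * 2 + 1.4), tolerance = 0.02)
})

test_that("degenerate bulk mixtures behave as pure populations", {
  g <- toy_genome()
  tr <- flat_track(g)
  prof <- rep(2L, nrow(g$bins)); prof[1:10] <- 6L
  noise <- noise_model(gc_bias_coeffs = c(1, 0, 0), overdispersion = 1e8)
  # rho = 0: indistinguishable from diploid in expectation
  c0 <- simulate_bulk(prof, g, 0, 3e6, noise, tr, ffpe = FALSE, seed = 4)
  w <- bin_widths(g) / g$bin_size
  norm <- as.numeric(c0) / w
  expect_equal(mean(norm[1:10]) / mean(norm[which(prof == 2L)]), 1,
               tolerance = 0.02)
  # rho = 1, diploid profile: flat expectation
  c1 <- simulate_bulk(rep(2L, nrow(g$bins)), g, 1, 3e6, noise, tr,
                      ffpe = FALSE, seed = 4)
  mu <- attr(c1, "mu")
  expect_lt(max(abs(mu / w - mean(mu / w))) / mean(mu / w), 1e-9)
  expect_error(simulate_bulk(prof, g, 1.2, 1e5, noise, tr), "cellularity")
})

test_that("focal injection logs the overlapped gene and is identity at 0", {
  g <- toy_genome()
  genes <- toy_genes(g)
  prof <- rep(2L, nrow(g$bins))
  same <- inject_focal_events(prof, g, genes, n_amps = 0, n_dels = 0,
                              seed = 1)
  expect_identical(same$profile, prof)
  expect_equal(nrow(same$events), 0)

  one <- inject_focal_events(prof, g, genes, n_amps = 1, n_dels = 0,
                             amp_state = 20, max_len = 2e6, seed = 3)
  ev <- one$events
  expect_equal(ev$type, "amp")
  expect_equal(ev$state, 20L)
  gene <- genes[genes$name == ev$gene, ]
  expect_lt(ev$start, gene$end)
  expect_gt(ev$end, gene$start)
  # the profile carries the event exactly over the logged interval
  bins <- g$bins
  hit <- bins$chrom == ev$chrom & bins$start >= ev$start & bins$end <= ev$end
  expect_true(all(one$profile[hit] == 20L))
  expect_true(all(one$profile[!hit] == 2L))
})

test_that("noise model validates its arguments", {
  expect_error(noise_model(reads_per_cell = c(2, 1)), "min < max")
  expect_error(noise_model(overdispersion = 0), "overdispersion")
  expect_error(noise_model(dropout_rate = 1), "dropout_rate")
  expect_error(simulate_cell_counts(list(), 5, noise_model(),
                                    flat_track(toy_genome())),
               "empty clone list")
})
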