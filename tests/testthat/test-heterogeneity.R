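test_that("FGA follows its definitional cases exactly", {
  g <- make_genome(c(chrA = 1e7, chrB = 1e7), 5e5)
  all2 <- make_profile(rep(2L, 40), g)
  expect_equal(fga(all2), 0)

  half3 <- make_profile(c(rep(3L, 20), rep(2L, 20)), g)
  expect_equal(fga(half3), 0.5)

  all4 <- make_profile(rep(4L, 40), g)
  expect_equal(fga(all4), 1)
})

test_that("FGA is invariant to segment subdivision and skips masked bins", {
  g <- make_genome(c(chrA = 1e7), 5e5)
  st <- c(rep(3L, 7), rep(2L, 13))
  p <- make_profile(st, g)
  # subdividing a constant-state stretch cannot change a per-bin quantity;
  # verify against the segment-level computation
  seg <- profile_segments(p)
  by_seg <- sum((seg$end - seg$start)[seg$state != 2]) /
    sum(seg$end - seg$start)
  expect_equal(fga(p), by_seg)

  masked <- rep(FALSE, 20); masked[1:2] <- TRUE
  pm <- make_profile(st, g, masked = masked)
  expect_equal(fga(pm), 5 / 18)
})

test_that("ploidy-corrected FGA uses the population baseline", {
  g <- make_genome(c(chrA = 1e7), 5e5)
  pop4 <- cn_population(replicate(6, make_profile(rep(4L, 20), g),
                                  simplify = FALSE))
  expect_equal(population_baseline(pop4), 4L)
  expect_equal(fga_ploidy_corrected(make_profile(rep(4L, 20), g), pop4), 0)
  # any uniform-c population scores zero for a matching cell
  for (c0 in c(1L, 3L, 5L)) {
    popc <- cn_population(replicate(4, make_profile(rep(c0, 20), g),
                                    simplify = FALSE))
    expect_equal(fga_ploidy_corrected(make_profile(rep(c0, 20), g), popc), 0)
  }

  # mean ploidy 3.9 rounds up to baseline 4
  profs <- c(replicate(9, make_profile(rep(4L, 20), g), simplify = FALSE),
             list(make_profile(rep(3L, 20), g)))
  pop39 <- cn_population(profs)
  expect_equal(mean(pop39$states), 3.9)
  expect_equal(population_baseline(pop39), 4L)

  # WGD cell with 10% of its genome at a private non-4 state
  wgd <- rep(4L, 20); wgd[1:2] <- 3L
  expect_equal(fga_ploidy_corrected(make_profile(wgd, g), pop4), 0.1)
})

test_that("Shannon entropy matches closed-form values", {
  g <- make_genome(c(chrA = 4e6), 5e5)     # 8 equal bins
  expect_equal(shannon_entropy(make_profile(rep(2L, 8), g)), 0)
  expect_equal(shannon_entropy(make_profile(c(rep(1L, 4), rep(2L, 4)), g)), 1)
  # shares 0.5 / 0.25 / 0.125 / 0.125 -> 1.75 bits
  p <- make_profile(c(rep(2L, 4), rep(3L, 2), 4L, 5L), g)
  expect_equal(shannon_entropy(p), 1.75)
  # natural-log base option
  expect_equal(shannon_entropy(p, base = exp(1)), 1.75 * log(2))
})

test_that("entropy is permutation invariant and maximal at equal shares", {
  g <- make_genome(c(chrA = 6e6), 5e5)     # 12 equal bins
  st <- c(rep(1L, 4), rep(2L, 4), rep(3L, 4))
  h <- shannon_entropy(make_profile(st, g))
  expect_equal(h, log2(3))
  set.seed(2)
  for (k in 1:5) {
    expect_equal(shannon_entropy(make_profile(sample(st), g)), h)
  }
  # unequal shares fall below log2 K
  st2 <- c(rep(1L, 7), rep(2L, 4), 3L)
  expect_lt(shannon_entropy(make_profile(st2, g)), log2(3))
})

test_that("CNA frequency counts gains and losses per bin", {
  g <- make_genome(c(chrA = 5e6), 5e5)
  profs <- replicate(10, make_profile(rep(2L, 10), g), simplify = FALSE)
  pop <- cn_population(profs)
  fr <- cna_frequency(pop)
  expect_true(all(fr$gain_freq == 0) && all(fr$loss_freq == 0))

  for (i in 1:3) profs[[i]]$states[4] <- 3L
  for (i in 1:2) profs[[i]]$states[7] <- 1L
  pop2 <- cn_population(profs)
  fr2 <- cna_frequency(pop2)
  expect_equal(fr2$gain_freq[4], 0.3)
  expect_equal(fr2$loss_freq[7], 0.2)
  expect_equal(fr2$gain_freq[7], 0)
})

test_that("population frequencies reproduce clone mixtures", {
  g <- toy_genome()
  cs <- simulate_clones(g, 3, 4, 4, seed = 17)
  noise <- noise_model(reads_per_cell = c(2e6, 3e6) / 30)
  tr <- make_bin_track(g, seed = 18)
  cc <- simulate_cell_counts(cs, 150, noise, tr, seed = 19)
  # truth-profile population: frequency = clone-indicator mixture
  profs <- lapply(cc$truth$clone, function(cl)
    make_profile(cs$profiles[cl, ], g))
  pop <- cn_population(profs)
  fr <- cna_frequency(pop, baseline = 2)
  p_clone <- tabulate(cc$truth$clone, 3) / length(cc$truth$clone)
  exp_gain <- colSums((cs$profiles > 2) * p_clone)
  # binomial error at n = 150
  tol <- 4 * sqrt(pmax(exp_gain * (1 - exp_gain), 0.002) / 150)
  expect_true(all(abs(fr$gain_freq - exp_gain) <= tol))
})

test_that("group comparison matches the hand-computed t statistic", {
  g <- make_genome(c(chrA = 5e6), 5e5)
  mkp <- function(n3) {
    st <- rep(2L, 10); if (n3 > 0) st[seq_len(n3)] <- 3L
    make_profile(st, g)
  }
  profs <- lapply(c(1, 2, 3, 5, 6, 7), mkp)
  pop <- cn_population(profs, groups = rep(c("a", "b"), each = 3))
  rep_ <- heterogeneity_report(pop)
  expect_equal(rep_$per_cell$fga, c(1, 2, 3, 5, 6, 7) / 10)

  # pooled-variance two-sample t on the toy table, computed from scratch
  a <- c(1, 2, 3) / 10; b <- c(5, 6, 7) / 10
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_manual <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  ht <- compare_groups(rep_, "fga", "a", "b", pooled = TRUE)
  expect_equal(unname(ht$statistic), t_manual)

  # identical groups: t = 0, p = 1
  pop_same <- cn_population(lapply(c(2, 3, 2, 3), mkp),
                            groups = c("a", "a", "b", "b"))
  ht0 <- compare_groups(heterogeneity_report(pop_same), "fga", "a", "b")
  expect_equal(unname(ht0$statistic), 0)
  expect_equal(ht0$p.value, 1)

  # well-separated groups at n = 50 are overwhelmingly significant
  set.seed(4)
  f1 <- rnorm(50, 0.2, 0.02); f2 <- rnorm(50, 0.3, 0.02)
  fake <- list(per_cell = data.frame(
    cell_id = paste0("c", 1:100), group = rep(c("a", "b"), each = 50),
    fga = c(f1, f2)))
  class(fake) <- "heterogeneity_report"
  expect_lt(compare_groups(fake, "fga", "a", "b")$p.value, 1e-10)
})
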