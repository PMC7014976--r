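test_that("MD table computes log ratios over the union of nonzero pixels", {
  g <- toy_genome(c(chr1 = 10L))
  m1 <- contact_matrix(data.frame(chrom = "chr1", bin1 = c(0L, 1L, 2L),
                                  bin2 = c(3L, 4L, 6L), count = c(7, 0, 3)), g)
  m2 <- contact_matrix(data.frame(chrom = "chr1", bin1 = c(0L, 1L),
                                  bin2 = c(3L, 4L), count = c(15, 4)), g)
  tab <- md_table(m1, m2)
  expect_equal(nrow(tab), 3L)          # (1,4) kept: nonzero in m2 only
  expect_equal(tab$M[tab$bin1 == 0], log2(16 / 8))
  expect_equal(tab$M[tab$bin1 == 1], log2(5 / 1))
  expect_equal(tab$M[tab$bin1 == 2], log2(1 / 4))
  expect_equal(tab$D, tab$bin2 - tab$bin1)

  # identity gives M = 0 everywhere
  sim <- default_sim()
  tab_same <- md_table(sim$cm1, sim$cm1)
  expect_true(all(tab_same$M == 0))

  # doubling large counts gives M close to 1
  big <- contact_matrix(data.frame(chrom = "chr1", bin1 = 0:4, bin2 = 3:7,
                                   count = 1000), g)
  big2 <- contact_matrix(data.frame(chrom = "chr1", bin1 = 0:4, bin2 = 3:7,
                                    count = 2000), g)
  expect_equal(md_table(big, big2)$M, rep(log2(2001 / 1001), 5))
})

test_that("loess joint normalization absorbs distance-dependent bias", {
  g <- toy_genome(c(chr1 = 100L))
  # constant M = 1 at all distances: the fit absorbs the depth difference
  px <- data.frame(chrom = "chr1", bin1 = rep(0:79, each = 1),
                   bin2 = rep(0:79) + rep(1:20, 4), count = 64)
  m1 <- contact_matrix(px, g)
  m2 <- contact_matrix(transform(px, count = 2 * 64 + 1 - 1), g)
  tab <- loess_joint_normalize(md_table(m1, m2, pseudocount = 1))
  expect_lt(max(abs(tab$adj_M)), 1e-9)

  # a smooth trend is removed: residual spread shrinks
  set.seed(1)
  n <- 4000
  D <- sample(1:99, n, replace = TRUE)
  M <- sin(D / 10) + rnorm(n, 0, 0.05)
  t_syn <- structure(tibble::tibble(chrom = "chr1", bin1 = 0L, bin2 = D,
                                    count1 = 1, count2 = 1, D = D, M = M),
                     class = c("pixel_pair_table", class(tibble::tibble())),
                     genome = g, pseudocount = 1, normalized = FALSE)
  out <- loess_joint_normalize(t_syn, span = 0.3)
  expect_lt(stats::sd(out$adj_M), stats::sd(out$M))

  expect_error(loess_joint_normalize(md_table(m1, m2), span = 1e-4),
               "larger span")
  few <- t_syn[t_syn$D %in% 1:5, ]
  expect_error(loess_joint_normalize(few), "at least 10 distinct distances")
})

test_that("null depth-ratio pairs stay centred after normalization", {
  sim <- cached("sim_null_r15",
                simulate_pair(null_config(seed = 3, bins = 400, depth_ratio = 1.5,
                                          depth = 1000)))
  tab <- cached("tab_null_r15", loess_joint_normalize(md_table(sim$cm1, sim$cm2)))
  dec <- tapply(tab$adj_M, cut(tab$D, stats::quantile(tab$D, 0:10 / 10),
                               include.lowest = TRUE), mean)
  expect_lt(max(abs(dec)), 0.02)
})

test_that("identical matrices yield no differential contacts", {
  sim <- default_sim()
  tab <- loess_joint_normalize(md_table(sim$cm1, sim$cm1))
  # degenerate: every M is 0, scales are 0 -> no pixel can reach significance
  dc <- detect_differential(tab)
  expect_equal(nrow(dc$hits), 0L)
  expect_equal(nrow(dc$regions), 0L)
})

test_that("BH nesting, antisymmetry and region bookkeeping hold", {
  sim <- cached("sim_diff", simulate_pair(
    simulation_config(seed = 5, n_flip_blocks = 0L, n_shift_boundaries = 0L,
                      n_gained_loops = 0L, n_lost_loops = 0L)))
  tab <- cached("tab_diff", loess_joint_normalize(md_table(sim$cm1, sim$cm2)))
  dc05 <- cached("dc05", detect_differential(tab, fdr = 0.05))
  dc01 <- detect_differential(tab, fdr = 0.01)
  key <- function(h) paste(h$chrom, h$bin1, h$bin2)
  expect_true(all(key(dc01$hits) %in% key(dc05$hits)))

  # swapping conditions negates adjusted M and keeps the flagged set
  tab_swap <- loess_joint_normalize(md_table(sim$cm2, sim$cm1))
  dc_swap <- detect_differential(tab_swap, fdr = 0.05)
  j <- dplyr::inner_join(tab, tab_swap, by = c("chrom", "bin1", "bin2"),
                         suffix = c("", ".s"))
  expect_lt(max(abs(j$adj_M + j$adj_M.s)), 1e-6)
  expect_setequal(key(dc_swap$hits), key(dc05$hits))

  # every region traces back to a retained anchor bin
  anchors <- unique(paste(rep(dc05$hits$chrom, 2),
                          c(dc05$hits$bin1, dc05$hits$bin2)))
  for (r in seq_len(nrow(dc05$regions))) {
    bins <- dc05$regions$start_bin[r]:(dc05$regions$end_bin[r] - 1L)
    expect_true(all(paste(dc05$regions$chrom[r], bins) %in% anchors))
  }
})

test_that("programmed 3-fold pixels are detected with high precision", {
  sim <- cached("sim_diff", simulate_pair(
    simulation_config(seed = 5, n_flip_blocks = 0L, n_shift_boundaries = 0L,
                      n_gained_loops = 0L, n_lost_loops = 0L)))
  dc <- cached("dc05", detect_differential(
    cached("tab_diff", loess_joint_normalize(md_table(sim$cm1, sim$cm2)))))
  dp <- sim$truth$differential_pixels
  hitkey <- paste(dc$hits$chrom, dc$hits$bin1, dc$hits$bin2)
  dpkey <- paste(dp$chrom, dp$bin1, dp$bin2)
  expect_gte(mean(dpkey %in% hitkey), 0.8)
  expect_gte(mean(hitkey %in% dpkey), 0.7)   # single-seed precision floor
})
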