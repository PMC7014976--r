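# deterministic decay map with two adjacent domain blocks, counts rounded
two_domain_cm <- function(n = 60, depth = 400, alpha = 1, t = 2,
                          d1 = c(20, 30), d2 = c(30, 40)) {
  D <- abs(outer(1:n, 1:n, `-`))
  mu <- depth * (D + 1)^(-alpha)
  for (dom in list(d1, d2)) {
    ix <- (dom[1] + 1):dom[2]
    mu[ix, ix] <- mu[ix, ix] * t
  }
  cm_from_dense(round(mu), toy_genome(stats::setNames(as.integer(n), "chr1")))
}

test_that("insulation dips at the boundary between adjacent domains", {
  b <- balance(two_domain_cm(), mask_quantile = 0)
  tr <- insulation_track(b, window = 5e4)
  s <- tr$score
  # the shared boundary lies at bin 30; the minimum must be within 1 bin
  interior <- 10:50
  expect_lte(abs(interior[which.min(s[interior + 1])] - 30), 1)
})

test_that("insulation handles degenerate chromosomes and bad windows", {
  g <- binned_genome(c("chr1", "chr2"), c(6e5, 6e5), 1e4)
  M <- matrix(10, 60, 60)
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  px <- data.frame(chrom = "chr1", bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   count = M[idx])
  m <- contact_matrix(px, g)      # chr2 has no contacts at all
  b <- balance(m, mask_quantile = 0)
  tr <- insulation_track(b)
  expect_true(all(is.na(tr$score[tr$chrom == "chr2"])))
  expect_error(insulation_track(b, window = 5e6), "larger than chromosome")
  expect_error(insulation_track(b, window = 12345), "multiple of the resolution")
})

test_that("arrowhead transform implements the signed contrast", {
  n <- 21
  M <- matrix(2, n, n)
  i <- 11; d <- 3
  M[i, i - d] <- M[i - d, i] <- 3
  M[i, i + d] <- M[i + d, i] <- 1
  A <- arrowhead_transform(fake_balanced(M), "chr1", max_d = 5)
  expect_equal(A[i, d], (3 - 1) / (3 + 1))
  expect_equal(A[i, d + 1], 0)   # symmetric values cancel
})

test_that("programmed domains are recovered by both callers", {
  sim <- cached("sim_domains", simulate_pair(simulation_config(seed = 3, comp_contrast = 0)))
  b <- cached("bal_domains", balance(sim$cm1))
  d_ins <- call_domains(b)
  d_arr <- call_domains(b, method = "arrowhead")
  truth <- sim$truth$domains[sim$truth$domains$condition == 1, ]
  tb <- dplyr::distinct(tibble::tibble(chrom = rep(truth$chrom, 2),
                                       bin = c(truth$start_bin, truth$end_bin)))
  bi <- attr(d_ins, "boundaries")
  recall <- mean(vapply(seq_len(nrow(tb)), function(i)
    any(bi$chrom == tb$chrom[i] & abs(bi$bin - tb$bin[i]) <= 1), logical(1)))
  spurious <- mean(vapply(seq_len(nrow(bi)), function(i)
    !any(tb$chrom == bi$chrom[i] & abs(tb$bin - bi$bin[i]) <= 1), logical(1)))
  expect_gte(recall, 0.9)
  expect_lte(spurious, 0.1)

  ba <- attr(d_arr, "boundaries")
  agreement <- mean(vapply(seq_len(nrow(bi)), function(i)
    any(ba$chrom == bi$chrom[i] & abs(ba$bin - bi$bin[i]) <= 1), logical(1)))
  expect_gte(agreement, 0.8)

  expect_error(call_domains(b, method = "nonsense"))
})

test_that("a decay-only map yields no domains", {
  sim <- cached("sim_null400", simulate_pair(null_config(seed = 6, bins = 400,
                                                         depth_ratio = 1)))
  b <- cached("bal_null400", balance(sim$cm1))
  expect_equal(nrow(call_domains(b)), 0L)
  s <- insulation_track(b)$score
  expect_lte(stats::sd(s, na.rm = TRUE), 0.06)
})

test_that("domain comparison matches, detects deletions and shifted edges", {
  g <- toy_genome(c(chr1 = 100L))
  d1 <- domain_set(data.frame(chrom = "chr1",
                              start_bin = c(10L, 30L, 60L),
                              end_bin = c(20L, 40L, 70L)), g)
  cmp_same <- compare_domains(d1, d1)
  expect_equal(cmp_same$n_common, 3L)
  expect_equal(cmp_same$n_changed1 + cmp_same$n_changed2, 0L)

  d2 <- domain_set(tibble::as_tibble(d1)[-2, c("chrom", "start_bin", "end_bin")], g)
  cmp_del <- compare_domains(d1, d2)
  expect_equal(cmp_del$n_common, 2L)
  expect_equal(cmp_del$changed1$start_bin, 30L)
  expect_equal(cmp_del$n_changed2, 0L)

  # 3-bin shift on a 10-bin domain: reciprocal overlap 10/13 < 0.8 -> changed
  d3 <- domain_set(data.frame(chrom = "chr1",
                              start_bin = c(10L, 30L, 60L),
                              end_bin = c(20L, 43L, 70L)), g)
  cmp_shift <- compare_domains(d1, d3)
  expect_equal(cmp_shift$changed1$start_bin, 30L)
  expect_equal(cmp_shift$changed2$end_bin, 43L)

  # per-bin classes partition all bins
  expect_equal(sum(cmp_shift$summary$n_bins), sum(n_bins(g)))
})

test_that("domain statistics are exact arithmetic", {
  g <- binned_genome("chr1", 1e6, 1e4)
  d <- domain_set(data.frame(chrom = "chr1", start_bin = c(10L, 50L),
                             end_bin = c(20L, 62L)), g)
  st <- domain_stats(d)
  expect_equal(st$n, 2L)
  expect_equal(st$median_length, 110e3)
  expect_equal(st$coverage, 0.22)

  empty <- domain_set(data.frame(chrom = character(), start_bin = integer(),
                                 end_bin = integer()), g)
  st0 <- domain_stats(empty)
  expect_equal(st0$n, 0L)
  expect_equal(st0$coverage, 0)
  expect_true(is.na(st0$median_length))

  # coverage of disjoint sets is additive
  d2 <- domain_set(data.frame(chrom = "chr1", start_bin = 80L, end_bin = 90L), g)
  both <- domain_set(rbind(tibble::as_tibble(d)[, 1:3], tibble::as_tibble(d2)[, 1:3]), g)
  expect_equal(domain_stats(both)$coverage,
               domain_stats(d)$coverage + domain_stats(d2)$coverage)
})

test_that("gene profiles around boundaries reflect placement", {
  g <- toy_genome(c(chr1 = 100L))
  d <- domain_set(data.frame(chrom = "chr1", start_bin = c(20L, 60L),
                             end_bin = c(30L, 72L)), g)
  # genes exactly on the boundary bins
  bnd <- c(20, 29, 60, 71)
  genes <- gene_table(data.frame(gene = paste0("g", seq_along(bnd)),
                                 chrom = "chr1", start = bnd * 1e4 + 10,
                                 end = bnd * 1e4 + 900, strand = "+"))
  prof <- gene_profile_around_boundaries(d, genes, flank = 5e4)
  expect_equal(prof$offset[which.max(prof$mean_genes)], 0L)

  empty <- domain_set(data.frame(chrom = character(), start_bin = integer(),
                                 end_bin = integer()), g)
  expect_error(gene_profile_around_boundaries(empty, genes), "empty domain set")
})

test_that("boundary vs interior density test matches the Welch oracle", {
  g <- toy_genome(c(chr1 = 20L))
  d <- domain_set(data.frame(chrom = "chr1", start_bin = c(2L, 10L),
                             end_bin = c(8L, 16L)), g)
  # per-bin gene counts: boundary bins dense, interior sparse, with spread
  counts <- c("2" = 3, "7" = 4, "10" = 3, "15" = 2,
              "3" = 1, "4" = 2, "5" = 1, "6" = 1, "11" = 1, "12" = 2,
              "13" = 1, "14" = 1)
  rows <- do.call(rbind, lapply(names(counts), function(bn) {
    data.frame(bin = as.integer(bn), idx = seq_len(counts[[bn]]))
  }))
  genes <- gene_table(data.frame(
    gene = paste0("g", seq_len(nrow(rows))), chrom = "chr1",
    start = rows$bin * 1e4 + rows$idx * 100,
    end = rows$bin * 1e4 + rows$idx * 100 + 50 + 1, strand = "+"))
  res <- boundary_vs_interior_density(d, genes)
  oracle <- stats::t.test(c(3, 4, 3, 2), c(1, 2, 1, 1, 1, 2, 1, 1))
  expect_equal(res$test$statistic, unname(oracle$statistic), tolerance = 1e-12)
  expect_equal(res$test$p.value, oracle$p.value, tolerance = 1e-12)

  # simulator design: boundary-rich gene placement is detected
  sim <- default_sim()
  truth <- sim$truth$domains[sim$truth$domains$condition == 1, ]
  dtruth <- domain_set(truth[, c("chrom", "start_bin", "end_bin")],
                       attr(sim$cm1, "genome"))
  bs <- boundary_vs_interior_density(dtruth, sim$genes)
  expect_gt(bs$mean_boundary, bs$mean_interior)
  expect_lt(bs$test$p.value, 0.01)
})
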