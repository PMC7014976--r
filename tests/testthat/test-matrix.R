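test_that("read_contacts folds symmetric duplicates and validates input", {
  g <- toy_genome(c(chr1 = 4L))
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("chr1\t0\t10000\t5", "chr1\t10000\t0\t5"), f)
  m <- read_contacts(f, g)
  expect_equal(nrow(m), 1L)
  expect_equal(m$bin1, 0L)
  expect_equal(m$bin2, 1L)
  expect_equal(m$count, 10)

  writeLines(character(), f)
  expect_equal(nrow(read_contacts(f, g)), 0L)

  writeLines("chr1\t1500\t10000\t2", f)
  expect_error(read_contacts(f, g), "line 1.*multiple of resolution")

  writeLines("chrX\t0\t10000\t2", f)
  expect_error(read_contacts(f, g), "line 1.*unknown chromosome")

  writeLines("chr1\t0\t10000\t-2", f)
  expect_error(read_contacts(f, g), "line 1.*negative")
})

test_that("contact matrix TSV round-trips through write_contacts", {
  sim <- default_sim()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_contacts(sim$cm1, f)
  back <- read_contacts(f, attr(sim$cm1, "genome"))
  expect_equal(as.data.frame(back)[, c("chrom", "bin1", "bin2", "count")],
               as.data.frame(sim$cm1)[, c("chrom", "bin1", "bin2", "count")])
})

test_that("balancing leaves an equal-marginal matrix unchanged up to scale", {
  M <- matrix(1, 6, 6)          # every marginal equal
  b <- balance(cm_from_dense(M), mask_quantile = 0)
  bias <- b$bias$chr1
  expect_lt(diff(range(bias)) / mean(bias), 1e-8)
  expect_equal(b$iterations, 0L)
})

test_that("balancing matches the dense Sinkhorn oracle", {
  # fixed 4x4 toy with unequal marginals
  M <- matrix(c(4, 2, 1, 1,
                2, 6, 2, 1,
                1, 2, 8, 3,
                1, 1, 3, 10), 4, 4)
  b <- balance(cm_from_dense(M), tol = 1e-12, max_iter = 5000, mask_quantile = 0)
  o <- sinkhorn_oracle(M)
  ratio <- b$bias$chr1 / o$bias
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)

  # random symmetric 10x10 matrices
  set.seed(42)
  for (rep in 1:5) {
    A <- matrix(rpois(100, 20), 10, 10)
    A <- A + t(A)
    b <- balance(cm_from_dense(A), tol = 1e-12, max_iter = 5000, mask_quantile = 0)
    o <- sinkhorn_oracle(A)
    ratio <- b$bias$chr1 / o$bias
    expect_lt(diff(range(ratio)) / mean(ratio), 1e-6)
  }
})

test_that("all-zero bins are masked and the rest balanced", {
  M <- matrix(5, 5, 5)
  M[3, ] <- 0; M[, 3] <- 0
  b <- balance(cm_from_dense(M), mask_quantile = 0)
  expect_true(b$mask$chr1[3])
  expect_true(is.na(b$bias$chr1[3]))
  expect_false(any(b$mask$chr1[-3]))
  expect_lte(b$cv, 1e-6)
})

test_that("balancing is idempotent and conserves raw counts", {
  b <- default_balanced()
  # conservation: balanced * bias_i * bias_j == raw
  px <- b$pixels
  bi <- purrr::map2_dbl(px$chrom, px$bin1, ~ b$bias[[.x]][.y + 1])
  bj <- purrr::map2_dbl(px$chrom, px$bin2, ~ b$bias[[.x]][.y + 1])
  expect_lt(max(abs(px$balanced * bi * bj - px$count) / pmax(px$count, 1)), 1e-9)

  # idempotence: re-balancing the balanced values moves nothing beyond tol
  g <- b$genome
  reb <- balance(contact_matrix(
    dplyr::transmute(px, chrom = .data$chrom, bin1 = .data$bin1,
                     bin2 = .data$bin2, count = .data$balanced), g),
    mask_quantile = 0)
  joined <- dplyr::inner_join(px, reb$pixels, by = c("chrom", "bin1", "bin2"),
                              suffix = c("", ".re"))
  rel <- abs(joined$balanced.re - joined$balanced) / pmax(joined$balanced, 1e-12)
  expect_lt(stats::quantile(rel, 0.99), 1e-3)
})

test_that("expected profile averages each distance stratum, zeros included", {
  M <- matrix(0, 3, 3)
  diag(M) <- 4
  M[1, 2] <- M[2, 1] <- 2; M[2, 3] <- M[3, 2] <- 2
  M[1, 3] <- M[3, 1] <- 1
  e <- expected_profile(fake_balanced(M))
  expect_equal(e$expected, c(4, 2, 1))

  # constant on each diagonal: profile equals the constants exactly
  n <- 10
  D <- abs(outer(1:n, 1:n, `-`))
  M2 <- 32 / (D + 1)
  e2 <- expected_profile(fake_balanced(M2))
  expect_equal(e2$expected, 32 / (1:n), tolerance = 1e-12)
})

test_that("O/E transform divides by the distance expectation", {
  n <- 10
  D <- abs(outer(1:n, 1:n, `-`))
  M <- 32 / (D + 1)
  b <- fake_balanced(M)
  oe <- oe_transform(b)
  expect_true(all(abs(oe$oe - 1) < 1e-12))

  # balanced 6 at a stratum with expected 2 gives O/E 3
  M2 <- matrix(0, 6, 6); diag(M2) <- 5
  M2[1, 3] <- M2[3, 1] <- 2; M2[2, 4] <- M2[4, 2] <- 2
  M2[3, 5] <- M2[5, 3] <- 2; M2[4, 6] <- M2[6, 4] <- 6
  b2 <- fake_balanced(M2)
  e2 <- expected_profile(b2)
  oe2 <- oe_transform(b2, e2)
  expect_equal(oe2$oe[oe2$bin1 == 3 & oe2$bin2 == 5],
               6 / e2$expected[e2$distance == 2])

  # genome mismatch is an error
  e_other <- expected_profile(fake_balanced(M2, genome = toy_genome(c(chr1 = 6L), res = 5e3)))
  expect_error(oe_transform(b2, e_other), "genomes differ")
})

test_that("simulated decay slope is recovered from the expected profile", {
  sim <- cached("sim_null400", simulate_pair(null_config(seed = 6, bins = 400,
                                                         depth_ratio = 1)))
  b <- cached("bal_null400", balance(sim$cm1))
  e <- expected_profile(b)
  sel <- e$distance >= 1 & e$distance <= 100
  slope <- coef(lm(log(expected) ~ log(distance + 1), data = e[sel, ]))[2]
  expect_lt(abs(slope - (-1)), 0.1)
})

test_that("O/E separates same- from cross-compartment pairs", {
  sim <- default_sim()
  b <- default_balanced()
  oe <- oe_transform(b)
  M <- chromarch:::oe_dense(oe, "chr1")
  cfg <- simulation_config(seed = 1)
  s <- chromarch:::comp_signs(cfg, "chr1")
  ss <- outer(s, s)
  d <- abs(row(M) - col(M))
  sel <- d >= 5 & d <= 100 & !is.na(M)
  expect_gt(mean(M[sel & ss > 0]), mean(M[sel & ss < 0]))
})

test_that("replicate correlation behaves under identity, scaling and noise", {
  sim <- default_sim()
  expect_equal(replicate_correlation(sim$cm1, sim$cm1), 1.0)

  scaled <- contact_matrix(
    dplyr::mutate(tibble::as_tibble(sim$cm1), count = .data$count * 2),
    attr(sim$cm1, "genome"))
  expect_gte(replicate_correlation(sim$cm1, scaled), 0.999)

  # independent Poisson replicates of one high-depth mean map
  cfg <- cached("cfg_deep", simulation_config(seed = 4, depth = 2000,
                                              chrom_bins = c(chr1 = 300L)))
  r1 <- cached("rep1", simulate_pair(cfg, noise_seed = 101))
  r2 <- cached("rep2", simulate_pair(cfg, noise_seed = 202))
  expect_gte(replicate_correlation(r1$cm1, r2$cm1, max_distance = 1e6), 0.95)

  tiny <- contact_matrix(data.frame(chrom = "chr1", bin1 = 0L, bin2 = 1L, count = 3),
                         toy_genome(c(chr1 = 4L)))
  expect_error(replicate_correlation(tiny, tiny), "fewer than 3")
})
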