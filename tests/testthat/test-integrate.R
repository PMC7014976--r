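test_that("DEG filtering applies both thresholds two-sidedly", {
  t <- deg_table(data.frame(gene = c("a", "b", "c"),
                            log2fc = c(1.3, 3, -1.0),
                            fdr = c(0.04, 0.06, 0.01)))
  kept <- filter_degs(t)
  expect_true("a" %in% kept)      # both thresholds met
  expect_false("b" %in% kept)     # FDR too high despite large fold
  expect_true("c" %in% kept)      # 2-fold down counts
})

test_that("promoters are strand-aware and clipped", {
  g <- gene_table(data.frame(gene = c("p", "m", "edge"),
                             chrom = "chr1",
                             start = c(10000, 10000, 500),
                             end = c(20000, 20000, 2000),
                             strand = c("+", "-", "+")))
  pr <- promoters(g, upstream = 2000, downstream = 500)
  expect_equal(unlist(pr[pr$gene == "p", c("start", "end")], use.names = FALSE),
               c(8000, 10500))
  expect_equal(unlist(pr[pr$gene == "m", c("start", "end")], use.names = FALSE),
               c(19500, 22000))
  expect_equal(pr$start[pr$gene == "edge"], 0)
  expect_error(promoters(g, upstream = 0, downstream = 0))
})

test_that("interval overlap counting is half-open and matches brute force", {
  a <- data.frame(chrom = "chr1", start = 0, end = 10)
  b <- data.frame(chrom = "chr1", start = 10, end = 20)
  expect_equal(overlap_count(a, b)$n_a_hit, 0L)       # touching, no overlap
  b2 <- data.frame(chrom = "chr1", start = 9, end = 20)
  expect_equal(overlap_count(a, b2)$n_a_hit, 1L)

  set.seed(11)
  ra <- data.frame(chrom = sample(c("chr1", "chr2"), 60, TRUE),
                   start = sample(0:500, 60, TRUE))
  ra$end <- ra$start + sample(1:50, 60, TRUE)
  rb <- data.frame(chrom = sample(c("chr1", "chr2"), 40, TRUE),
                   start = sample(0:500, 40, TRUE))
  rb$end <- rb$start + sample(1:50, 40, TRUE)
  res <- overlap_count(ra, rb)
  # independent O(n^2) oracle
  hits_a <- logical(nrow(ra)); hits_b <- logical(nrow(rb)); pairs <- 0L
  for (i in seq_len(nrow(ra))) for (j in seq_len(nrow(rb))) {
    if (ra$chrom[i] == rb$chrom[j] && ra$start[i] < rb$end[j] &&
        rb$start[j] < ra$end[i]) {
      hits_a[i] <- TRUE; hits_b[j] <- TRUE; pairs <- pairs + 1L
    }
  }
  expect_equal(res$n_a_hit, sum(hits_a))
  expect_equal(res$n_b_hit, sum(hits_b))
  expect_equal(nrow(res$pairs), pairs)
})

test_that("hypergeometric upper tail matches enumeration and phyper", {
  expect_equal(hypergeom_enrichment(10, 4, 5, 0)$p, 1)
  expect_equal(hypergeom_enrichment(10, 4, 5, 4)$p, 6 / 252, tolerance = 1e-12)

  # full enumeration oracle over a moderate population range
  worst <- 0
  for (N in 1:30) for (K in 0:N) for (n in 0:N) {
    lo <- max(0, n + K - N); hi <- min(K, n)
    terms <- choose(K, lo:hi) * choose(N - K, n - (lo:hi)) / choose(N, n)
    oracle <- rev(cumsum(rev(terms)))
    mine <- hyper_upper_tail(N, K, n, lo:hi)
    worst <- max(worst, abs(mine - oracle) / pmax(oracle, 1e-300))
  }
  expect_lt(worst, 1e-12)

  # spot-check against the survival function used in the field
  set.seed(2)
  for (i in 1:200) {
    N <- sample(5:500, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    k <- sample(max(0, n + K - N):min(K, n), 1)
    expect_equal(hyper_upper_tail(N, K, n, k),
                 stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-10)
  }

  # monotone decreasing in k
  ps <- hyper_upper_tail(60, 20, 30, 0:20)
  expect_true(all(diff(ps) <= 1e-15))

  expect_error(hypergeom_enrichment(10, 4, 5, 5), "infeasible")
})

toy_classes <- function() {
  g <- toy_genome(c(chr1 = 20L))
  bins <- genome_bins(g)
  bins$comp_class <- rep(c("changed", "common-A"), each = 10)
  bins$domain_class <- rep("non-TAD", 20)
  bins$combined_class <- rep(c("changed", "common"), each = 10)
  structure(bins, class = c("region_class_map", class(tibble::tibble())),
            genome = g)
}

test_that("gene-set enrichment reduces to the identity when set = universe", {
  cls <- toy_classes()
  genes <- gene_table(data.frame(gene = paste0("g", 1:40), chrom = "chr1",
                                 start = rep(0:19, 2) * 1e4 + 100,
                                 end = rep(0:19, 2) * 1e4 + 1100,
                                 strand = "+"))
  res <- enrich_genes_in_classes(genes$gene, genes, cls, "comp_class")
  expect_true(all(res$fold == 1))
  expect_true(all(res$p == 1))
  expect_error(enrich_genes_in_classes("nope", genes, cls), "subset")
})

test_that("two-class enrichment is antisymmetric around fold 1", {
  cls <- toy_classes()
  genes <- gene_table(data.frame(gene = paste0("g", 1:40), chrom = "chr1",
                                 start = rep(0:19, 2) * 1e4 + 100,
                                 end = rep(0:19, 2) * 1e4 + 1100,
                                 strand = "+"))
  # gene set concentrated in the changed half
  set <- genes$gene[c(1:10, 21:26)]
  res <- enrich_genes_in_classes(set, genes, cls, "combined_class")
  f_changed <- res$fold[res$class == "changed"]
  f_common <- res$fold[res$class == "common"]
  expect_gt(f_changed, 1)
  expect_lt(f_common, 1)
})

test_that("differential-anchor enrichment counts bins", {
  cls <- toy_classes()
  hits <- tibble::tibble(chrom = "chr1", bin1 = c(1L, 3L), bin2 = c(5L, 8L))
  dc <- structure(list(hits = hits,
                       regions = tibble::tibble(),
                       pixels = hits, fdr = 0.05,
                       genome = attr(cls, "genome")),
                  class = "differential_contacts")
  res <- enrich_pixels_in_classes(dc, cls, "comp_class")
  row <- res[res$class == "changed", ]
  expect_equal(row$n, 4L)        # four distinct anchor bins
  expect_equal(row$k, 4L)        # all inside the changed half -> maximal fold
  expect_equal(row$fold, row$N / row$K)
})

test_that("promoter density contrast flags empty backgrounds", {
  g <- binned_genome("chr1", 1e6, 1e4)
  regions <- tibble::tibble(chrom = "chr1", start_bin = 10L, end_bin = 20L,
                            start = 1e5, end = 2e5)
  dc <- structure(list(hits = tibble::tibble(chrom = "chr1", bin1 = 10L, bin2 = 19L),
                       regions = regions, fdr = 0.05, genome = g),
                  class = "differential_contacts")
  proms <- tibble::tibble(gene = c("a", "b"), chrom = "chr1",
                          start = c(1.2e5, 1.5e5), end = c(1.25e5, 1.55e5),
                          strand = "+")
  res <- promoter_density_contrast(proms, dc, g)
  expect_true(is.infinite(res$ratio))
  expect_equal(res$density_background, 0)

  dc_empty <- structure(list(hits = tibble::tibble(),
                             regions = regions[0, ], fdr = 0.05, genome = g),
                        class = "differential_contacts")
  expect_error(promoter_density_contrast(proms, dc_empty, g), "no differential")
})

test_that("virtual-4C profiles peak at loop partners and stay flat on nulls", {
  sim <- default_sim()
  oe <- cached("oe1", oe_transform(default_balanced()))
  tl <- sim$truth$loops[sim$truth$loops$condition == 1, ][1, ]
  g <- attr(sim$cm1, "genome")
  anchor_gene <- gene_table(data.frame(
    gene = "anchor", chrom = tl$chrom, start = tl$bin1 * 1e4 + 5000,
    end = tl$bin1 * 1e4 + 6000, strand = "+"))
  prof <- gene_interaction_profile("anchor", oe, anchor_gene, flank = 8e5)
  expect_lte(abs(prof$bin[which.max(prof$oe)] - tl$bin2), 1)

  expect_error(gene_interaction_profile("anchor", oe, anchor_gene, flank = 100),
               "smaller than one bin")
  expect_error(gene_interaction_profile("missing", oe, anchor_gene), "not found")

  nullsim <- cached("sim_null400", simulate_pair(null_config(seed = 6, bins = 400,
                                                             depth_ratio = 1)))
  oen <- oe_transform(cached("bal_null400", balance(nullsim$cm1)))
  gn <- attr(nullsim$cm1, "genome")
  mid_gene <- gene_table(data.frame(gene = "mid", chrom = "chr1",
                                    start = 200 * 1e4 + 100, end = 200 * 1e4 + 1100,
                                    strand = "+"))
  profn <- gene_interaction_profile("mid", oen, mid_gene, flank = 5e5)
  expect_lt(abs(mean(profn$oe[profn$offset != 0], na.rm = TRUE) - 1), 0.1)
})

test_that("region class map dimensions partition classified bins", {
  sim <- default_sim()
  t1 <- cached("track1", call_compartments(oe_transform(default_balanced()), sim$genes))
  t2 <- cached("track2", call_compartments(oe_transform(default_balanced(cond = 2)),
                                           sim$genes))
  cc <- compare_compartments(t1, t2)
  d1 <- cached("dom1", call_domains(default_balanced()))
  d2 <- cached("dom2", call_domains(default_balanced(cond = 2)))
  dcmp <- compare_domains(d1, d2)
  cls <- region_class_map(cc, dcmp)
  expect_true(all(!is.na(cls$domain_class)))
  expect_true(all(cls$comp_class %in% c("common-A", "common-B", "changed", NA)))
  expect_true(all(is.na(cls$comp_class) == is.na(cls$combined_class) |
                    !is.na(cls$combined_class)))
})
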