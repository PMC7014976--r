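# shared fixtures, all built in code

toy_genome <- function(bins = c(chr1 = 8L), res = 1e4) {
  binned_genome(names(bins), bins * res, res)
}

# contact matrix from a dense symmetric matrix (single chromosome)
cm_from_dense <- function(M, genome = toy_genome(stats::setNames(nrow(M), "chr1")),
                          chrom = "chr1") {
  idx <- which(upper.tri(M, diag = TRUE), arr.ind = TRUE)
  px <- data.frame(chrom = chrom, bin1 = idx[, 1] - 1L, bin2 = idx[, 2] - 1L,
                   count = M[idx])
  contact_matrix(px[px$count != 0, ], genome)
}

# hand-built balanced matrix with unit biases (for transforms that only
# need balanced values)
fake_balanced <- function(M, genome = toy_genome(stats::setNames(nrow(M), "chr1")),
                          chrom = "chr1") {
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  pixels <- tibble::tibble(chrom = chrom, bin1 = as.integer(idx[, 1] - 1L),
                           bin2 = as.integer(idx[, 2] - 1L),
                           count = M[idx], balanced = M[idx])
  structure(list(pixels = pixels,
                 bias = stats::setNames(list(rep(1, nrow(M))), chrom),
                 mask = stats::setNames(list(rep(FALSE, nrow(M))), chrom),
                 iterations = 0L, cv = 0, converged = TRUE,
                 genome = genome, sample = "toy", condition = NA_character_),
            class = "balanced_matrix")
}

# hand-built O/E object with unit expected everywhere
fake_oe <- function(M, genome = toy_genome(stats::setNames(nrow(M), "chr1")),
                    chrom = "chr1") {
  nb <- nrow(M)
  idx <- which(upper.tri(M, diag = TRUE) & M != 0, arr.ind = TRUE)
  px <- tibble::tibble(chrom = chrom, bin1 = as.integer(idx[, 1] - 1L),
                       bin2 = as.integer(idx[, 2] - 1L), oe = M[idx])
  e <- structure(tibble::tibble(chrom = chrom, distance = 0:(nb - 1),
                                expected = 1, n_pairs = nb:1L),
                 class = c("expected_profile", class(tibble::tibble())),
                 genome = genome)
  structure(px, class = c("oe_matrix", class(tibble::tibble())),
            genome = genome, mask = stats::setNames(list(rep(FALSE, nb)), chrom),
            expected = e, sample = "toy", condition = NA_character_)
}

# naive dense Sinkhorn iterative-scaling oracle (independent of balance())
sinkhorn_oracle <- function(M, tol = 1e-10, max_iter = 10000) {
  b <- rep(1, nrow(M))
  B <- M
  for (it in seq_len(max_iter)) {
    s <- rowSums(B)
    if (stats::sd(s) / mean(s) <= tol) break
    s <- s / mean(s)
    B <- B / outer(s, s)
    b <- b * s
  }
  list(bias = b, balanced = B)
}

# fraction of truth pairs with a called pair within tol bins (and reverse)
pair_recall <- function(called, truth, tol = 1) {
  if (nrow(truth) == 0) return(NA_real_)
  mean(vapply(seq_len(nrow(truth)), function(i) {
    any(called$chrom == truth$chrom[i] &
          abs(called$bin1 - truth$bin1[i]) <= tol &
          abs(called$bin2 - truth$bin2[i]) <= tol)
  }, logical(1)))
}

# session-level cache for expensive simulations
.fixture_cache <- new.env(parent = emptyenv())
cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_sim <- function(seed = 1) {
  cached(paste0("sim", seed), simulate_pair(simulation_config(seed = seed)))
}
default_balanced <- function(seed = 1, cond = 1) {
  cached(paste0("bal", seed, "_", cond), {
    sim <- default_sim(seed)
    balance(if (cond == 1) sim$cm1 else sim$cm2)
  })
}
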