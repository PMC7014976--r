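#' Balance a contact matrix by iterative correction (ICE)
#'
#' Iterative proportional fitting of per-bin biases so that, over unmasked
#' bins, the marginal sums of the balanced matrix are equal:
#' `balanced[i, j] = raw[i, j] / (bias[i] * bias[j])`. Bins with too few
#' nonzero pixels (low coverage) are masked before iteration and excluded
#' throughout. Biases are rescaled at the end so the overall count scale of
#' the raw matrix is preserved.
#'
#' @param m A `contact_matrix`.
#' @param max_iter Maximum iterations (default 200).
#' @param tol Convergence tolerance on the coefficient of variation of the
#'   unmasked marginals (default 1e-6).
#' @param min_nnz Bins with fewer nonzero pixels than this are masked
#'   (default 1, i.e. only all-zero bins are forced out).
#' @param mask_quantile Additionally mask bins in this lower quantile of
#'   nonzero-pixel counts (default 0.02).
#'
#' @return An object of class `balanced_matrix`: a list with `pixels`
#'   (tibble `chrom`, `bin1`, `bin2`, `count`, `balanced`), `bias` and
#'   `mask` (per-chromosome vectors; masked bins have `NA` bias),
#'   `iterations`, `cv`, `converged`, and the genome/sample/condition
#'   carried over from `m`.
#' @export
balance <- function(m, max_iter = 200, tol = 1e-6, min_nnz = 1, mask_quantile = 0.02) {
  stopifnot(inherits(m, "contact_matrix"))
  g <- attr(m, "genome")
  if (nrow(m) == 0) stop("cannot balance an empty contact matrix")

  per_chrom <- purrr::map(g$chroms, function(ch) {
    M <- cm_dense(m, ch)
    nb <- nrow(M)
    nnz <- rowSums(M > 0)   # M is dense symmetric, so this is per-bin nnz
    masked <- nnz < min_nnz | nnz == 0
    pos <- nnz[!masked & nnz > 0]
    if (length(pos) > 0 && mask_quantile > 0) {
      thr <- stats::quantile(pos, mask_quantile, type = 1)
      masked <- masked | (nnz <= thr & nnz < max(nnz))
    }
    if (all(masked)) {
      return(list(chrom = ch, bias = rep(NA_real_, nb), mask = masked,
                  B = matrix(NA_real_, nb, nb), iter = 0L, cv = NA_real_))
    }
    keep <- which(!masked)
    W <- M[keep, keep, drop = FALSE]
    b <- rep(1, length(keep))
    cv <- Inf
    iter <- 0L
    for (it in seq_len(max_iter)) {
      s <- rowSums(W)
      mu <- mean(s)
      cv <- stats::sd(s) / mu
      if (is.na(cv)) cv <- 0
      if (cv <= tol) { iter <- it - 1L; break }
      s <- s / mu
      W <- W / outer(s, s)
      b <- b * s
      iter <- it
    }
    # preserve the raw count scale: make mean balanced marginal = mean raw marginal
    k <- mean(rowSums(W)) / mean(rowSums(M[keep, keep, drop = FALSE]))
    if (is.finite(k) && k > 0) {
      W <- W / k
      b <- b * sqrt(k)
    }
    bias <- rep(NA_real_, nb)
    bias[keep] <- b
    B <- matrix(NA_real_, nb, nb)
    B[keep, keep] <- W
    list(chrom = ch, bias = bias, mask = masked, B = B, iter = iter, cv = cv)
  })

  if (all(purrr::map_lgl(per_chrom, ~ all(.x$mask)))) {
    stop("all bins masked on every chromosome; nothing to balance")
  }

  cv_all <- max(purrr::map_dbl(per_chrom, "cv"), na.rm = TRUE)
  iter_all <- max(purrr::map_int(per_chrom, ~ as.integer(.x$iter)))
  converged <- cv_all <= tol
  if (!converged) {
    warning(sprintf("balancing did not reach tol=%g in %d iterations (final CV %.3g)",
                    tol, max_iter, cv_all))
  }

  pixels <- purrr::map_dfr(per_chrom, function(pc) {
    px <- dense_to_pixels(pc$B, pc$chrom, value = "balanced")
    raw <- cm_dense(m, pc$chrom)
    px$count <- raw[cbind(px$bin1 + 1L, px$bin2 + 1L)]
    px[, c("chrom", "bin1", "bin2", "count", "balanced")]
  })

  structure(
    list(
      pixels = pixels,
      bias = stats::setNames(purrr::map(per_chrom, "bias"), g$chroms),
      mask = stats::setNames(purrr::map(per_chrom, "mask"), g$chroms),
      iterations = iter_all,
      cv = cv_all,
      converged = converged,
      genome = g,
      sample = attr(m, "sample"),
      condition = attr(m, "condition")
    ),
    class = "balanced_matrix"
  )
}

#' @export
print.balanced_matrix <- function(x, ...) {
  cat("<balanced_matrix> sample=", x$sample,
      " | ", nrow(x$pixels), " pixels, ",
      sum(purrr::map_int(x$mask, ~ sum(.x))), " masked bins, ",
      x$iterations, " iterations, marginal CV ",
      format(x$cv, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
tidy.balanced_matrix <- function(x, ...) x$pixels

#' @export
glance.balanced_matrix <- function(x, ...) {
  tibble::tibble(
    n_pixels = nrow(x$pixels),
    n_bins = sum(x$genome$n_bins),
    n_masked = sum(purrr::map_int(x$mask, ~ sum(.x))),
    iterations = x$iterations,
    marginal_cv = x$cv,
    converged = x$converged
  )
}

# dense balanced matrix for one chromosome; masked bins NA, absent pixels 0
bm_dense <- function(b, chrom) {
  g <- b$genome
  nb <- g$n_bins[[chrom]]
  M <- matrix(0, nb, nb)
  px <- b$pixels[b$pixels$chrom == chrom, , drop = FALSE]
  if (nrow(px) > 0) {
    idx <- cbind(px$bin1 + 1L, px$bin2 + 1L)
    M[idx] <- px$balanced
    M[idx[, c(2, 1), drop = FALSE]] <- px$balanced
  }
  msk <- b$mask[[chrom]]
  M[msk, ] <- NA_real_
  M[, msk] <- NA_real_
  M
}

#' Distance-decay expected profile of a balanced matrix
#'
#' For each chromosome and genomic separation `d` (in bins), the mean
#' balanced value over all unmasked bin pairs at that separation, counting
#' absent pixels as zero. This is the "expected" of the observed/expected
#' transform.
#'
#' @param b A `balanced_matrix`.
#' @return A tibble of class `expected_profile` with columns `chrom`,
#'   `distance` (bins), `expected`, `n_pairs` (unmasked pairs in the
#'   stratum); strata with no unmasked pairs carry `NA` expected.
#' @export
expected_profile <- function(b) {
  stopifnot(inherits(b, "balanced_matrix"))
  g <- b$genome
  out <- purrr::map_dfr(g$chroms, function(ch) {
    M <- bm_dense(b, ch)
    nb <- nrow(M)
    d <- row(M) - col(M)
    keep <- d <= 0          # upper triangle incl. diagonal
    dist <- -d[keep]
    vals <- M[keep]
    ok <- !is.na(vals)
    n_pairs <- tapply(ok, dist, sum)
    sums <- tapply(ifelse(ok, vals, 0), dist, sum)
    dd <- as.integer(names(n_pairs))
    tibble::tibble(
      chrom = ch, distance = dd,
      expected = as.vector(ifelse(n_pairs > 0, sums / n_pairs, NA_real_)),
      n_pairs = as.vector(as.integer(n_pairs))
    ) |>
      tidyr::complete(chrom, distance = 0:(nb - 1),
                      fill = list(expected = NA_real_, n_pairs = 0L))
  })
  structure(out, class = c("expected_profile", class(tibble::tibble())),
            genome = g)
}

#' Observed/expected transform
#'
#' Divides each balanced value by the expected value at its genomic
#' separation. Masked bins and strata whose expected value is zero or
#' unavailable propagate as `NA`.
#'
#' @param b A `balanced_matrix`.
#' @param e An `expected_profile`, usually `expected_profile(b)`.
#' @return A tibble of class `oe_matrix` (columns `chrom`, `bin1`, `bin2`,
#'   `oe`) with attributes `genome`, `mask` and `expected`. Pixels with no
#'   recorded contact are implicitly O/E 0 where the stratum is defined.
#' @export
oe_transform <- function(b, e = expected_profile(b)) {
  stopifnot(inherits(b, "balanced_matrix"), inherits(e, "expected_profile"))
  check_same_genome(b$genome, attr(e, "genome"))
  px <- b$pixels
  key <- paste(px$chrom, px$bin2 - px$bin1)
  ekey <- paste(e$chrom, e$distance)
  exp_val <- e$expected[match(key, ekey)]
  oe <- ifelse(!is.na(exp_val) & exp_val > 0, px$balanced / exp_val, NA_real_)
  out <- tibble::tibble(chrom = px$chrom, bin1 = px$bin1, bin2 = px$bin2, oe = oe)
  out <- out[!is.na(out$oe), , drop = FALSE]
  structure(out, class = c("oe_matrix", class(tibble::tibble())),
            genome = b$genome, mask = b$mask, expected = e,
            sample = b$sample, condition = b$condition)
}

# dense O/E for one chromosome: 0 where defined-but-absent, NA where masked
# or the distance stratum is undefined
oe_dense <- function(oe, chrom) {
  g <- attr(oe, "genome")
  nb <- g$n_bins[[chrom]]
  e <- attr(oe, "expected")
  M <- matrix(0, nb, nb)
  ech <- e[e$chrom == chrom, , drop = FALSE]
  bad_d <- ech$distance[is.na(ech$expected) | ech$expected == 0]
  if (length(bad_d) > 0) {
    d <- abs(row(M) - col(M))
    M[d %in% bad_d] <- NA_real_
  }
  px <- oe[oe$chrom == chrom, , drop = FALSE]
  if (nrow(px) > 0) {
    idx <- cbind(px$bin1 + 1L, px$bin2 + 1L)
    M[idx] <- px$oe
    M[idx[, c(2, 1), drop = FALSE]] <- px$oe
  }
  msk <- attr(oe, "mask")[[chrom]]
  M[msk, ] <- NA_real_
  M[, msk] <- NA_real_
  M
}
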