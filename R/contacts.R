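#' Construct a contact matrix from a pixel table
#'
#' A contact matrix stores intra-chromosomal Hi-C counts as sparse
#' upper-triangle triplets `(chrom, bin1, bin2, count)` with `bin1 <= bin2`;
#' symmetry is implied. Lower-triangle records are reflected and duplicate
#' pixels are summed.
#'
#' @param pixels Data frame with columns `chrom`, `bin1`, `bin2`, `count`
#'   (0-based bin indices within each chromosome).
#' @param genome A `binned_genome`.
#' @param sample Sample label.
#' @param condition Condition label (e.g. `"m-bud"`, `"g-bud"`).
#'
#' @return A tibble of class `contact_matrix` with attributes `genome`,
#'   `sample`, `condition`.
#' @export
contact_matrix <- function(pixels, genome, sample = "sample", condition = NA_character_) {
  stopifnot(inherits(genome, "binned_genome"))
  pixels <- tibble::as_tibble(pixels)
  required <- c("chrom", "bin1", "bin2", "count")
  if (!all(required %in% names(pixels))) {
    stop("pixels must have columns ", paste(required, collapse = ", "))
  }
  if (nrow(pixels) > 0) {
    if (any(!pixels$chrom %in% genome$chroms)) {
      bad <- setdiff(unique(pixels$chrom), genome$chroms)
      stop("unknown chromosome(s): ", paste(bad, collapse = ", "))
    }
    if (any(!is.finite(pixels$count)) || any(pixels$count < 0)) {
      stop("counts must be finite and >= 0")
    }
    nb <- genome$n_bins[pixels$chrom]
    if (any(pixels$bin1 < 0 | pixels$bin2 < 0 | pixels$bin1 >= nb | pixels$bin2 >= nb)) {
      stop("bin index outside chromosome bounds")
    }
    # reflect to upper triangle, collapse duplicates by summation
    lo <- pmin(pixels$bin1, pixels$bin2)
    hi <- pmax(pixels$bin1, pixels$bin2)
    chrom <- pixels$chrom
    count <- as.numeric(pixels$count)
    key <- paste(chrom, lo, hi)
    if (anyDuplicated(key)) {
      sums <- rowsum(count, key)
      first <- !duplicated(key)
      chrom <- chrom[first]; lo <- lo[first]; hi <- hi[first]
      count <- unname(sums[key[first], 1])
    }
    ord <- order(match(chrom, genome$chroms), lo, hi)
    pixels <- tibble::tibble(chrom = chrom[ord], bin1 = as.integer(lo[ord]),
                             bin2 = as.integer(hi[ord]), count = count[ord])
  } else {
    pixels <- tibble::tibble(chrom = character(), bin1 = integer(),
                             bin2 = integer(), count = numeric())
  }
  structure(pixels,
            class = c("contact_matrix", class(tibble::tibble())),
            genome = genome, sample = sample, condition = condition)
}

#' Read a sparse bin-pair TSV into a contact matrix
#'
#' Expected format: four tab-separated columns `chrom`, `start1`, `start2`,
#' `count` where the starts are bp coordinates of the two bins (0-based,
#' multiples of the genome resolution). A header line is detected and
#' skipped. Records given as `(j, i)` are folded onto `(i, j)`.
#'
#' @param path Path to the TSV file.
#' @param genome A `binned_genome`.
#' @inheritParams contact_matrix
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, genome, sample = basename(path), condition = NA_character_) {
  stopifnot(inherits(genome, "binned_genome"))
  lines <- readr::read_lines(path)
  skip <- length(lines) > 0 && grepl("^(chrom|#)", lines[1])
  df <- readr::read_tsv(path,
                        col_names = c("chrom", "start1", "start2", "count"),
                        col_types = "cddd", skip = as.integer(skip),
                        progress = FALSE)
  if (nrow(df) == 0) {
    return(contact_matrix(
      tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer(), count = numeric()),
      genome, sample = sample, condition = condition))
  }
  line_no <- seq_len(nrow(df)) + as.integer(skip)
  res <- genome$resolution
  bad_chrom <- !df$chrom %in% genome$chroms
  if (any(bad_chrom)) {
    stop(sprintf("line %d: unknown chromosome '%s'",
                 line_no[which(bad_chrom)[1]], df$chrom[which(bad_chrom)[1]]))
  }
  misaligned <- df$start1 %% res != 0 | df$start2 %% res != 0
  if (any(misaligned)) {
    stop(sprintf("line %d: start not a multiple of resolution %g",
                 line_no[which(misaligned)[1]], res))
  }
  neg <- df$count < 0 | !is.finite(df$count)
  if (any(neg)) {
    stop(sprintf("line %d: negative or non-finite count", line_no[which(neg)[1]]))
  }
  bin1 <- pos_to_bin(genome, df$chrom, df$start1)
  bin2 <- pos_to_bin(genome, df$chrom, df$start2)
  oob <- is.na(bin1) | is.na(bin2)
  if (any(oob)) {
    stop(sprintf("line %d: position outside chromosome", line_no[which(oob)[1]]))
  }
  contact_matrix(tibble::tibble(chrom = df$chrom, bin1 = bin1, bin2 = bin2, count = df$count),
                 genome, sample = sample, condition = condition)
}

#' Write a contact matrix as sparse bin-pair TSV
#' @param m A `contact_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contacts <- function(m, path) {
  g <- attr(m, "genome")
  out <- tibble::tibble(chrom = m$chrom,
                        start1 = m$bin1 * g$resolution,
                        start2 = m$bin2 * g$resolution,
                        count = m$count)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# dense symmetric per-chromosome matrix (counts or any value column)
cm_dense <- function(m, chrom, value = "count") {
  g <- attr(m, "genome")
  nb <- g$n_bins[[chrom]]
  M <- matrix(0, nb, nb)
  px <- m[m$chrom == chrom, , drop = FALSE]
  if (nrow(px) > 0) {
    idx1 <- cbind(px$bin1 + 1L, px$bin2 + 1L)
    M[idx1] <- px[[value]]
    M[idx1[, c(2, 1), drop = FALSE]] <- px[[value]]
  }
  M
}

# dense matrix back to upper-triangle triplets (drops zeros and NAs)
dense_to_pixels <- function(M, chrom, value = "count") {
  ut <- upper.tri(M, diag = TRUE)
  keep <- ut & !is.na(M) & M != 0
  idx <- which(keep, arr.ind = TRUE)
  out <- tibble::tibble(chrom = chrom,
                        bin1 = as.integer(idx[, 1] - 1L),
                        bin2 = as.integer(idx[, 2] - 1L))
  out[[value]] <- M[keep]
  out
}

#' @export
print.contact_matrix <- function(x, ...) {
  g <- attr(x, "genome")
  cat("<contact_matrix> sample=", attr(x, "sample"),
      " condition=", attr(x, "condition"),
      " | ", nrow(x), " pixels, ", length(g$chroms), " chromosome(s), res ",
      format(g$resolution, big.mark = ","), " bp\n", sep = "")
  NextMethod()
}

#' Correlation between two replicate contact matrices
#'
#' Computes the Pearson correlation of `log(1 + x)`-transformed counts over
#' the union of nonzero pixels of the two matrices, restricted to pairs
#' closer than `max_distance`. Used to check that biological replicates
#' agree before pooling.
#'
#' @param m1,m2 `contact_matrix` objects on the same genome.
#' @param max_distance Maximum genomic separation in bp (default 2 Mb).
#' @return A single correlation coefficient in \[-1, 1\].
#' @export
replicate_correlation <- function(m1, m2, max_distance = 2e6) {
  g <- attr(m1, "genome")
  check_same_genome(g, attr(m2, "genome"))
  max_d_bins <- floor(max_distance / g$resolution)
  joined <- dplyr::full_join(
    tibble::as_tibble(m1)[, c("chrom", "bin1", "bin2", "count")],
    tibble::as_tibble(m2)[, c("chrom", "bin1", "bin2", "count")],
    by = c("chrom", "bin1", "bin2"), suffix = c("1", "2")
  ) |>
    tidyr::replace_na(list(count1 = 0, count2 = 0)) |>
    dplyr::filter(.data$bin2 - .data$bin1 <= max_d_bins)
  if (nrow(joined) < 3) stop("fewer than 3 shared pixels within max_distance")
  stats::cor(log1p(joined$count1), log1p(joined$count2), method = "pearson")
}
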