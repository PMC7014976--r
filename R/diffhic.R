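#' MD table of two contact matrices
#'
#' Builds the per-pixel comparison table behind the MD plot: over the union
#' of nonzero pixels of the two matrices, the genomic separation
#' `D = bin2 - bin1` (bins) and the log ratio
#' `M = log2((count2 + pseudocount) / (count1 + pseudocount))`. Pixels
#' where both counts are zero are excluded.
#'
#' @param m1,m2 `contact_matrix` objects on the same genome (condition 1
#'   and condition 2).
#' @param pseudocount Added to both counts before the ratio (default 1).
#' @return A tibble of class `pixel_pair_table` with columns `chrom`,
#'   `bin1`, `bin2`, `count1`, `count2`, `D`, `M`; attribute `genome`.
#' @export
md_table <- function(m1, m2, pseudocount = 1) {
  g <- attr(m1, "genome")
  check_same_genome(g, attr(m2, "genome"))
  t1 <- tibble::as_tibble(m1)[, c("chrom", "bin1", "bin2", "count")]
  t2 <- tibble::as_tibble(m2)[, c("chrom", "bin1", "bin2", "count")]
  tab <- dplyr::full_join(t1, t2, by = c("chrom", "bin1", "bin2"),
                          suffix = c("1", "2")) |>
    tidyr::replace_na(list(count1 = 0, count2 = 0)) |>
    dplyr::filter(.data$count1 > 0 | .data$count2 > 0) |>
    dplyr::mutate(D = .data$bin2 - .data$bin1,
                  M = log2((.data$count2 + pseudocount) / (.data$count1 + pseudocount))) |>
    dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
  structure(tab, class = c("pixel_pair_table", class(tibble::tibble())),
            genome = g, pseudocount = pseudocount, normalized = FALSE)
}

#' Joint loess normalization on the MD plot
#'
#' Fits a tricube-weighted local linear regression of `M` on distance `D`
#' and subtracts the fit, removing distance-dependent bias (including any
#' global depth difference) between the two conditions. This is the joint
#' normalization step of the MD-plot differential procedure.
#'
#' @param t A `pixel_pair_table` from [md_table()].
#' @param span Loess span (default 0.4).
#' @return The table with added columns `M_fit` and `adj_M = M - M_fit`;
#'   attribute `normalized` set.
#' @export
loess_joint_normalize <- function(t, span = 0.4) {
  stopifnot(inherits(t, "pixel_pair_table"))
  if (dplyr::n_distinct(t$D) < 10) stop("need at least 10 distinct distances for loess")
  # fit on per-distance means weighted by pixel count: identical limit to a
  # pixel-level fit but much cheaper on dense union tables
  per_d <- t |>
    dplyr::group_by(.data$D) |>
    dplyr::summarise(mbar = mean(.data$M), w = dplyr::n(), .groups = "drop")
  fit <- tryCatch(
    stats::loess(mbar ~ D, data = per_d, weights = per_d$w,
                 span = span, degree = 1,
                 control = stats::loess.control(surface = "direct")),
    error = function(e) stop("loess fit failed (span too small for the data density? ",
                             "try a larger span): ", conditionMessage(e), call. = FALSE)
  )
  per_d$M_fit <- stats::predict(fit, newdata = per_d)
  out <- t |>
    dplyr::left_join(per_d[, c("D", "M_fit")], by = "D") |>
    dplyr::mutate(adj_M = .data$M - .data$M_fit)
  structure(out, class = c("pixel_pair_table", class(tibble::tibble())),
            genome = attr(t, "genome"), pseudocount = attr(t, "pseudocount"),
            normalized = TRUE, span = span)
}

#' Detect differential contacts
#'
#' Within each distance stratum (strata with fewer than `min_stratum`
#' pixels pooled with their neighbours), loess-adjusted log ratios are
#' converted to Z-scores, `Z = (adj_M - centre) / scale` with the stratum
#' mean and standard deviation (or median and scaled MAD with
#' `robust = TRUE`; the MAD underestimates the tail scale of discrete
#' Poisson log ratios and inflates the false-positive rate),
#' given two-sided normal p-values and Benjamini-Hochberg corrected across
#' all tested pixels. Pixels with mean count below `min_avg` are kept in
#' the table but not tested (`NA` p): log ratios of very low counts are
#' discrete and heavy-tailed relative to the normal reference, and such
#' pixels carry no usable evidence. Retained pixels (adjusted p <= `fdr`)
#' are reported together with merged 1-D "differential contact regions"
#' formed from their anchor bins.
#'
#' @param t A loess-normalized `pixel_pair_table`.
#' @param fdr BH threshold (default 0.05).
#' @param min_stratum Minimum pixels per distance stratum before pooling
#'   (default 100).
#' @param min_avg Minimum `(count1 + count2) / 2` for a pixel to be tested
#'   (default 15).
#' @param robust Use median/MAD instead of mean/SD (default `FALSE`).
#' @return An object of class `differential_contacts`: `pixels` (the full
#'   table with `Z`, `p`, `p_adj`, `significant`), `hits` (retained
#'   pixels), `regions` (merged anchor-bin intervals), `fdr`, `genome`.
#' @export
detect_differential <- function(t, fdr = 0.05, min_stratum = 100,
                                min_avg = 15, robust = FALSE) {
  stopifnot(inherits(t, "pixel_pair_table"))
  if (!isTRUE(attr(t, "normalized")) || !"adj_M" %in% names(t)) {
    stop("table must be loess-normalized first (see loess_joint_normalize)")
  }
  if (nrow(t) == 0) stop("no pixels to test")
  g <- attr(t, "genome")
  untested <- t[(t$count1 + t$count2) / 2 < min_avg, , drop = FALSE]
  tt <- t[(t$count1 + t$count2) / 2 >= min_avg, , drop = FALSE]
  if (nrow(tt) == 0) stop("no pixels pass the min_avg filter")

  # pool sparse distance strata with neighbours (ascending D, greedy)
  d_sizes <- tt |> dplyr::count(.data$D) |> dplyr::arrange(.data$D)
  stratum_of <- integer(0)
  cur <- 1L; acc <- 0L
  strata <- integer(nrow(d_sizes))
  for (r in seq_len(nrow(d_sizes))) {
    strata[r] <- cur
    acc <- acc + d_sizes$n[r]
    if (acc >= min_stratum) { cur <- cur + 1L; acc <- 0L }
  }
  if (acc > 0 && acc < min_stratum && cur > 1L) {
    strata[strata == cur] <- cur - 1L    # fold the short tail back
  }
  d_sizes$stratum <- strata

  tab <- tt |>
    dplyr::left_join(d_sizes[, c("D", "stratum")], by = "D") |>
    dplyr::group_by(.data$stratum) |>
    dplyr::mutate(
      .ctr = if (robust) stats::median(.data$adj_M) else mean(.data$adj_M),
      .scl = if (robust) stats::mad(.data$adj_M) else stats::sd(.data$adj_M)
    ) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      .scl = pmax(.data$.scl, 1e-8),
      Z = (.data$adj_M - .data$.ctr) / .data$.scl,
      p = 2 * stats::pnorm(-abs(.data$Z)),
      p_adj = stats::p.adjust(.data$p, method = "BH"),
      significant = .data$p_adj <= fdr
    ) |>
    dplyr::select(-".ctr", -".scl", -"stratum")
  if (nrow(untested) > 0) {
    untested$Z <- NA_real_; untested$p <- NA_real_
    untested$p_adj <- NA_real_; untested$significant <- FALSE
    tab <- dplyr::bind_rows(tab, untested) |>
      dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
  }

  hits <- tab |> dplyr::filter(.data$significant)
  anchors <- dplyr::distinct(tibble::tibble(
    chrom = rep(hits$chrom, 2), bin = c(hits$bin1, hits$bin2)))
  regions <- merge_bin_runs(anchors$chrom, anchors$bin, g)

  structure(list(pixels = tab, hits = hits, regions = regions,
                 fdr = fdr, genome = g),
            class = "differential_contacts")
}

#' @export
print.differential_contacts <- function(x, ...) {
  cat("<differential_contacts> ", nrow(x$hits), " of ", nrow(x$pixels),
      " pixels at FDR <= ", x$fdr, "; ", nrow(x$regions),
      " merged differential contact regions\n", sep = "")
  invisible(x)
}

#' @export
tidy.differential_contacts <- function(x, ...) x$pixels

#' @export
glance.differential_contacts <- function(x, ...) {
  tibble::tibble(n_pixels = nrow(x$pixels), n_significant = nrow(x$hits),
                 n_regions = nrow(x$regions), fdr = x$fdr)
}
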