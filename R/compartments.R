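#' Welch's two-sample t-test (unequal variances)
#'
#' The test used throughout the package for group contrasts of per-bin gene
#' counts: `t = (mean1 - mean2) / sqrt(s1^2/n1 + s2^2/n2)` with the
#' Welch–Satterthwaite degrees of freedom and a two-sided p-value.
#'
#' @param x,y Numeric vectors (each of length >= 2).
#' @return An object of class `welch_test` with fields `estimate1`,
#'   `estimate2`, `statistic`, `df`, `p.value`.
#' @export
welch_t_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations")
  }
  n1 <- length(x); n2 <- length(y)
  m1 <- mean(x); m2 <- mean(y)
  v1 <- stats::var(x); v2 <- stats::var(y)
  se2 <- v1 / n1 + v2 / n2
  if (se2 == 0) {
    t_stat <- 0
    df <- n1 + n2 - 2
    p <- 1
  } else {
    t_stat <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p <- 2 * stats::pt(-abs(t_stat), df)
  }
  structure(list(estimate1 = m1, estimate2 = m2, statistic = t_stat,
                 df = df, p.value = p, n1 = n1, n2 = n2),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch two-sample t-test: t = %.4g, df = %.2f, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  cat(sprintf("  group means: %.4g vs %.4g (n = %d, %d)\n",
              x$estimate1, x$estimate2, x$n1, x$n2))
  invisible(x)
}

#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(estimate1 = x$estimate1, estimate2 = x$estimate2,
                 statistic = x$statistic, df = x$df, p.value = x$p.value)
}

#' @export
glance.welch_test <- function(x, ...) tidy.welch_test(x)

# per-bin gene (TSS) counts for a gene table on a binned genome
gene_bin_counts <- function(genes, genome) {
  bins <- genome_bins(genome)
  tss <- gene_tss(genes)
  tss$bin <- pos_to_bin(genome, tss$chrom, tss$tss)
  counts <- tss |>
    dplyr::filter(!is.na(.data$bin)) |>
    dplyr::count(.data$chrom, .data$bin, name = "genes")
  bins |>
    dplyr::left_join(counts, by = c("chrom", "bin")) |>
    tidyr::replace_na(list(genes = 0L))
}

#' Call A/B compartments from an O/E matrix
#'
#' Per chromosome, the Pearson correlation matrix of the O/E columns over
#' unmasked bins is computed and its first principal component extracted
#' (the Lieberman-Aiden eigenvector convention). The sign is oriented so
#' that positive bins have the higher mean gene density; positive bins are
#' labelled A (active, gene-rich), negative bins B.
#'
#' @param oe An `oe_matrix` (see [oe_transform()]).
#' @param genes A gene table (see [gene_table()]) used for sign
#'   orientation; if `NULL` the raw eigenvector sign is kept.
#' @param min_bins Chromosomes with fewer unmasked bins are set to `NA`
#'   (default 10).
#' @return A tibble of class `eigen_track` with columns `chrom`, `bin`,
#'   `start`, `end`, `eigen`, `label` (`"A"`, `"B"` or `NA`) and an
#'   `orientation` attribute recording the gene-density evidence.
#' @export
call_compartments <- function(oe, genes = NULL, min_bins = 10) {
  stopifnot(inherits(oe, "oe_matrix"))
  g <- attr(oe, "genome")
  gene_counts <- if (!is.null(genes)) gene_bin_counts(genes, g) else NULL

  orientation <- list()
  tracks <- purrr::map(g$chroms, function(ch) {
    M <- oe_dense(oe, ch)
    nb <- nrow(M)
    ev <- rep(NA_real_, nb)
    usable <- which(colSums(!is.na(M)) > 0)
    # drop zero-variance columns (no signal to correlate)
    if (length(usable) > 0) {
      v <- apply(M[usable, usable, drop = FALSE], 2, stats::var, na.rm = TRUE)
      usable <- usable[!is.na(v) & v > 0]
    }
    if (length(usable) < min_bins) {
      warning(sprintf("chromosome %s: fewer than %d usable bins, compartments set NA",
                      ch, min_bins))
      return(ev)
    }
    C <- suppressWarnings(stats::cor(M[usable, usable, drop = FALSE],
                                     use = "pairwise.complete.obs"))
    C[!is.finite(C)] <- 0
    pc1 <- prcomp(C, center = TRUE, scale. = FALSE)$rotation[, 1]
    ev[usable] <- pc1
    ev
  })

  bins <- genome_bins(g)
  eigen_val <- unlist(tracks, use.names = FALSE)
  out <- bins
  out$eigen <- eigen_val

  # orient per chromosome by mean gene count in positive vs negative bins
  if (!is.null(gene_counts)) {
    out <- out |> dplyr::left_join(gene_counts[, c("chrom", "bin", "genes")],
                                   by = c("chrom", "bin"))
    for (ch in g$chroms) {
      sel <- out$chrom == ch & !is.na(out$eigen)
      if (!any(sel)) next
      pos_mean <- mean(out$genes[sel & out$eigen > 0])
      neg_mean <- mean(out$genes[sel & out$eigen < 0])
      orientation[[ch]] <- c(pos = pos_mean, neg = neg_mean)
      if (is.finite(pos_mean) && is.finite(neg_mean)) {
        if (pos_mean < neg_mean) {
          out$eigen[out$chrom == ch] <- -out$eigen[out$chrom == ch]
          orientation[[ch]] <- c(pos = neg_mean, neg = pos_mean)
        } else if (pos_mean == neg_mean) {
          warning(sprintf("chromosome %s: gene densities tied, keeping computed sign", ch))
        }
      }
    }
    out$genes <- NULL
  }

  out$label <- dplyr::case_when(
    is.na(out$eigen) ~ NA_character_,
    out$eigen > 0 ~ "A",
    out$eigen < 0 ~ "B",
    TRUE ~ NA_character_
  )
  structure(out, class = c("eigen_track", class(tibble::tibble())),
            genome = g, orientation = orientation)
}

#' Compare two compartment tracks bin by bin
#'
#' @param t1,t2 `eigen_track` objects on the same genome (reference first).
#' @param min_run Minimum run length (bins) for a sign-discordant stretch to
#'   be reported as a changed region (default 1).
#' @return A tibble of class `compartment_comparison` with per-bin
#'   `class` in `common-A`, `common-B`, `A->B`, `B->A` or `NA`, plus
#'   attributes `summary` (class counts) and `changed_regions` (merged
#'   intervals of discordant bins).
#' @export
compare_compartments <- function(t1, t2, min_run = 1) {
  stopifnot(inherits(t1, "eigen_track"), inherits(t2, "eigen_track"))
  g <- attr(t1, "genome")
  check_same_genome(g, attr(t2, "genome"))
  out <- tibble::tibble(
    chrom = t1$chrom, bin = t1$bin, start = t1$start, end = t1$end,
    label1 = t1$label, label2 = t2$label
  )
  out$class <- dplyr::case_when(
    is.na(out$label1) | is.na(out$label2) ~ NA_character_,
    out$label1 == "A" & out$label2 == "A" ~ "common-A",
    out$label1 == "B" & out$label2 == "B" ~ "common-B",
    out$label1 == "A" & out$label2 == "B" ~ "A->B",
    TRUE ~ "B->A"
  )
  changed <- !is.na(out$class) & out$class %in% c("A->B", "B->A")
  regions <- merge_bin_runs(out$chrom[changed], out$bin[changed], g, min_run = min_run)
  summary <- out |>
    dplyr::filter(!is.na(.data$class)) |>
    dplyr::count(.data$class, name = "n_bins")
  structure(out, class = c("compartment_comparison", class(tibble::tibble())),
            genome = g, summary = summary, changed_regions = regions)
}

# merge sorted bin indices into maximal runs; drop runs shorter than min_run
merge_bin_runs <- function(chrom, bin, genome, min_run = 1) {
  if (length(bin) == 0) {
    return(tibble::tibble(chrom = character(), start_bin = integer(),
                          end_bin = integer(), start = numeric(), end = numeric()))
  }
  df <- tibble::tibble(chrom = chrom, bin = bin) |>
    dplyr::arrange(match(.data$chrom, genome$chroms), .data$bin)
  df |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1L, diff(.data$bin) != 1L))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(start_bin = min(.data$bin), end_bin = max(.data$bin) + 1L,
                     .groups = "drop") |>
    dplyr::filter(.data$end_bin - .data$start_bin >= min_run) |>
    dplyr::mutate(start = .data$start_bin * genome$resolution,
                  end = pmin(.data$end_bin * genome$resolution,
                             genome$lengths[.data$chrom])) |>
    dplyr::select("chrom", "start_bin", "end_bin", "start", "end")
}

#' Gene density contrast between A and B compartments
#'
#' Splits per-bin gene (TSS) counts by compartment label and applies
#' Welch's two-sample t-test, reproducing the standard gene-rich-A check.
#'
#' @param track An oriented `eigen_track`.
#' @param genes A gene table.
#' @return A list of class `compartment_gene_stats`: `test` (a
#'   [welch_t_test()] result), `bins` (per-bin counts with labels), and
#'   group means.
#' @export
compartment_gene_stats <- function(track, genes) {
  stopifnot(inherits(track, "eigen_track"))
  g <- attr(track, "genome")
  counts <- gene_bin_counts(genes, g) |>
    dplyr::left_join(tibble::as_tibble(track)[, c("chrom", "bin", "label")],
                     by = c("chrom", "bin"))
  a <- counts$genes[counts$label %in% "A"]
  b <- counts$genes[counts$label %in% "B"]
  test <- welch_t_test(a, b)
  structure(list(test = test, bins = counts,
                 mean_A = mean(a), mean_B = mean(b),
                 n_A = length(a), n_B = length(b)),
            class = "compartment_gene_stats")
}

#' @export
print.compartment_gene_stats <- function(x, ...) {
  cat(sprintf("Gene density A vs B: %.3f vs %.3f genes/bin (n = %d, %d)\n",
              x$mean_A, x$mean_B, x$n_A, x$n_B))
  print(x$test)
  invisible(x)
}

#' @export
tidy.compartment_gene_stats <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mean_A = x$mean_A, mean_B = x$mean_B,
                                  n_A = x$n_A, n_B = x$n_B),
                   tidy.welch_test(x$test)[, c("statistic", "df", "p.value")])
}
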