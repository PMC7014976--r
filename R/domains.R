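#' Insulation-score track
#'
#' For each bin `i`, the mean balanced signal in the square of pixels
#' connecting the `w` bins upstream with the `w` bins downstream of `i`
#' (`w = window / resolution`), expressed as the log2 ratio to the
#' chromosome-wide mean of that statistic and corrected for the slow
#' positional trend (running median over `4w + 1` bins) that marginal
#' balancing introduces near chromosome ends. Contact-depleted positions —
#' TAD boundaries — appear as local minima. `NA` within `w` bins of the
#' chromosome ends and over masked bins.
#'
#' @param b A `balanced_matrix`.
#' @param window Window size in bp; must be a multiple of the resolution
#'   and span at least 2 bins (default 50 kb).
#' @return A tibble of class `insulation_track` with columns `chrom`,
#'   `bin`, `start`, `end`, `score`.
#' @export
insulation_track <- function(b, window = 5e4) {
  stopifnot(inherits(b, "balanced_matrix"))
  g <- b$genome
  w <- window / g$resolution
  if (w != round(w) || w < 2) stop("window must be a multiple of the resolution spanning >= 2 bins")
  w <- as.integer(w)
  out <- purrr::map_dfr(g$chroms, function(ch) {
    nb <- g$n_bins[[ch]]
    if (nb <= 2 * w) stop(sprintf("window larger than chromosome %s", ch))
    M <- bm_dense(b, ch)
    raw <- rep(NA_real_, nb)
    for (i in (w + 1):(nb - w)) {
      if (isTRUE(b$mask[[ch]][i])) next
      sq <- M[(i - w):(i - 1), (i + 1):(i + w)]
      if (all(is.na(sq))) next
      raw[i] <- mean(sq, na.rm = TRUE)
    }
    mu <- mean(raw, na.rm = TRUE)
    score <- if (!is.finite(mu) || mu <= 0) rep(NA_real_, nb) else log2(raw / mu)
    score[!is.finite(score)] <- NA_real_
    # remove the slow positional trend (balancing upweights chromosome ends)
    ok <- !is.na(score)
    if (sum(ok) > 4 * w + 1) {
      trend <- stats::runmed(score[ok], k = 4L * w + 1L, endrule = "median")
      score[ok] <- score[ok] - trend
    }
    bins <- genome_bins(g) |> dplyr::filter(.data$chrom == ch)
    bins$score <- score
    bins
  })
  structure(out, class = c("insulation_track", class(tibble::tibble())),
            genome = g, window = window)
}

#' Arrowhead transform of a balanced chromosome matrix
#'
#' `A(i, d) = (M(i, i-d) - M(i, i+d)) / (M(i, i-d) + M(i, i+d))`: positive
#' when contacts upstream of `i` dominate (bin `i` sits at the downstream
#' end of a domain), negative at the upstream end. The distance-decay
#' factor cancels in the ratio.
#'
#' @param b A `balanced_matrix`.
#' @param chrom Chromosome name.
#' @param max_d Maximum separation in bins (default 10).
#' @return An `n x max_d` matrix; `A[i, d]` is `NA` where undefined.
#' @export
arrowhead_transform <- function(b, chrom, max_d = 10) {
  M <- bm_dense(b, chrom)
  nb <- nrow(M)
  A <- matrix(NA_real_, nb, max_d)
  for (d in seq_len(max_d)) {
    i <- (d + 1):(nb - d)
    up <- M[cbind(i, i - d)]
    dn <- M[cbind(i, i + d)]
    s <- up + dn
    A[i, d] <- ifelse(!is.na(s) & s > 0, (up - dn) / s, NA_real_)
  }
  A
}

# local extrema of a signed score beyond an absolute threshold; plateaus and
# adjacent hits collapse to the strongest position
signed_extrema <- function(s, tau, side = c("min", "max")) {
  side <- match.arg(side)
  if (side == "max") s <- -s
  n <- length(s)
  hits <- integer()
  for (i in 2:(n - 1)) {
    if (is.na(s[i]) || s[i] > -tau) next
    lft <- s[i - 1]; rgt <- s[i + 1]
    if (!is.na(lft) && s[i] > lft) next
    if (!is.na(rgt) && s[i] > rgt) next
    hits <- c(hits, i)
  }
  if (length(hits) > 1) {
    run <- cumsum(c(1L, diff(hits) > 2L))
    hits <- vapply(split(hits, run), function(ix) ix[which.min(s[ix])], integer(1))
  }
  unname(hits)
}

# local minima of a score vector with prominence >= delta within +/- reach
local_minima <- function(s, delta, reach) {
  n <- length(s)
  hits <- integer()
  for (i in 2:(n - 1)) {
    if (is.na(s[i])) next
    lft <- s[i - 1]; rgt <- s[i + 1]
    if (!is.na(lft) && s[i] > lft) next
    if (!is.na(rgt) && s[i] > rgt) next
    li <- max(1, i - reach):(i - 1)
    ri <- (i + 1):min(n, i + reach)
    lmax <- suppressWarnings(max(s[li], na.rm = TRUE))
    rmax <- suppressWarnings(max(s[ri], na.rm = TRUE))
    if (!is.finite(lmax) || !is.finite(rmax)) next
    if (min(lmax, rmax) - s[i] >= delta) hits <- c(hits, i)
  }
  # collapse plateaus / adjacent hits to a single minimum
  if (length(hits) > 1) {
    run <- cumsum(c(1L, diff(hits) > 1L))
    hits <- vapply(split(hits, run), function(ix) ix[which.min(s[ix])], integer(1))
  }
  unname(hits)
}

#' Call TAD-like domains
#'
#' Two callers over a balanced matrix. `insulation` (default): boundaries
#' at local minima of the insulation track with prominence at least
#' `delta`; candidate domains are the inter-boundary intervals and are
#' retained when the mean interior O/E exceeds `oe_floor` times the mean
#' O/E of the flanking off-diagonal blocks at comparable distances (a
#' local contrast, robust to the positional O/E bow that balancing
#' produces near chromosome ends). `arrowhead`: boundaries at signed
#' extrema of the mean arrowhead statistic `mean_d A(i, d)` (strong
#' negative = domain start, strong positive = end), domains filtered the
#' same way.
#'
#' @param b A `balanced_matrix` (typically at 10 kb resolution).
#' @param method `"insulation"` or `"arrowhead"`.
#' @param window Insulation window / arrowhead depth in bp (default 50 kb).
#' @param delta Minimum boundary prominence, log2 units for insulation
#'   (default 0.15); minimum `|mean A|` for arrowhead (default 0.15).
#' @param oe_floor Minimum ratio of mean interior O/E to mean flanking
#'   O/E for an interval to be called a domain (default 1.2).
#' @param max_domain_bins Intervals longer than this are not domains
#'   (default 50 bins).
#' @return A tibble of class `domain_set` with columns `chrom`,
#'   `start_bin`, `end_bin` (half-open), `start`, `end` (bp),
#'   `mean_oe`; attributes `genome`, `params`, `boundaries` (tibble of all
#'   called boundary bins).
#' @export
call_domains <- function(b, method = c("insulation", "arrowhead"),
                         window = 5e4, delta = NULL, oe_floor = 1.2,
                         max_domain_bins = 50) {
  method <- match.arg(method)
  stopifnot(inherits(b, "balanced_matrix"))
  g <- b$genome
  w <- as.integer(window / g$resolution)
  if (is.null(delta)) delta <- 0.15
  oe <- oe_transform(b)

  boundaries <- purrr::map_dfr(g$chroms, function(ch) {
    if (method == "insulation") {
      tr <- insulation_track(b, window = window)
      s <- tr$score[tr$chrom == ch]
      hits <- local_minima(s, delta = delta, reach = 2L * w)
    } else {
      A <- arrowhead_transform(b, ch, max_d = w)
      s <- rowMeans(A, na.rm = TRUE)
      s[is.nan(s)] <- NA_real_
      # signed extrema: strong negative = domain start, strong positive = end
      hits <- sort(c(signed_extrema(s, delta, "min"),
                     signed_extrema(s, delta, "max")))
    }
    tibble::tibble(chrom = ch, bin = as.integer(hits - 1L))
  })

  domains <- purrr::map_dfr(g$chroms, function(ch) {
    bb <- sort(boundaries$bin[boundaries$chrom == ch])
    if (length(bb) < 2) {
      return(tibble::tibble(chrom = character(), start_bin = integer(),
                            end_bin = integer(), mean_oe = numeric()))
    }
    Moe <- oe_dense(oe, ch)
    nb <- nrow(Moe)
    purrr::map_dfr(seq_len(length(bb) - 1), function(k) {
      a <- bb[k]; z <- bb[k + 1]
      if (z - a < 2 || z - a > max_domain_bins) return(NULL)
      sub <- Moe[(a + 1):z, (a + 1):z]
      interior <- sub[upper.tri(sub)]
      m_oe <- mean(interior, na.rm = TRUE)
      # flanking off-diagonal blocks at comparable distances
      L <- z - a
      flank <- c(
        if (z + 1 <= nb) Moe[(a + 1):z, (z + 1):min(z + L, nb)],
        if (a >= 1) Moe[max(1, a - L + 1):a, (a + 1):z]
      )
      m_flank <- mean(flank, na.rm = TRUE)
      contrast <- if (is.finite(m_flank) && m_flank > 0) m_oe / m_flank else m_oe
      if (!is.finite(contrast) || contrast < oe_floor) return(NULL)
      tibble::tibble(chrom = ch, start_bin = a, end_bin = z,
                     mean_oe = m_oe, oe_contrast = contrast)
    })
  })

  # the domain set's boundary set is the edges of retained domains; raw
  # candidate minima are kept separately for inspection
  out <- domain_set(domains, g,
                    params = list(method = method, window = window, delta = delta,
                                  oe_floor = oe_floor,
                                  max_domain_bins = max_domain_bins))
  attr(out, "candidates") <- boundaries
  out
}

#' Construct a domain set from intervals
#' @param domains Data frame with `chrom`, `start_bin`, `end_bin`
#'   (half-open bin intervals); extra columns kept.
#' @param genome A `binned_genome`.
#' @param params Optional list of caller parameters.
#' @param boundaries Optional tibble of boundary bins; derived from the
#'   domain edges when omitted.
#' @return A tibble of class `domain_set`.
#' @export
domain_set <- function(domains, genome, params = list(), boundaries = NULL) {
  domains <- tibble::as_tibble(domains)
  if (nrow(domains) > 0) {
    stopifnot(all(domains$end_bin > domains$start_bin),
              all(domains$start_bin >= 0),
              all(domains$end_bin <= genome$n_bins[domains$chrom]))
    domains <- dplyr::arrange(domains, match(.data$chrom, genome$chroms),
                              .data$start_bin)
    domains$start <- domains$start_bin * genome$resolution
    domains$end <- pmin(domains$end_bin * genome$resolution,
                        genome$lengths[domains$chrom])
  } else {
    domains <- tibble::tibble(chrom = character(), start_bin = integer(),
                              end_bin = integer(), start = numeric(), end = numeric())
  }
  if (is.null(boundaries)) {
    boundaries <- dplyr::distinct(tibble::tibble(
      chrom = rep(domains$chrom, 2),
      bin = c(domains$start_bin, domains$end_bin)
    ))
  }
  structure(domains, class = c("domain_set", class(tibble::tibble())),
            genome = genome, params = params, boundaries = boundaries)
}

#' Summary statistics of a domain set
#' @param d A `domain_set`.
#' @return One-row tibble: `n`, `median_length` (bp; `NA` when empty),
#'   `coverage` (union length over genome length).
#' @export
domain_stats <- function(d) {
  stopifnot(inherits(d, "domain_set"))
  g <- attr(d, "genome")
  if (nrow(d) == 0) {
    return(tibble::tibble(n = 0L, median_length = NA_real_, coverage = 0))
  }
  lens <- d$end - d$start
  cov_bp <- d |>
    tibble::as_tibble() |>
    dplyr::group_by(.data$chrom) |>
    dplyr::group_map(~ {
      iv <- dplyr::arrange(.x, .data$start)
      merged_len <- 0; cur_s <- -1; cur_e <- -1
      for (r in seq_len(nrow(iv))) {
        if (iv$start[r] > cur_e) {
          merged_len <- merged_len + max(0, cur_e - cur_s)
          cur_s <- iv$start[r]; cur_e <- iv$end[r]
        } else cur_e <- max(cur_e, iv$end[r])
      }
      merged_len + max(0, cur_e - cur_s)
    }) |>
    purrr::flatten_dbl() |>
    sum()
  tibble::tibble(n = nrow(d),
                 median_length = stats::median(lens),
                 coverage = cov_bp / sum(g$lengths))
}

#' Compare two domain sets
#'
#' Greedy one-to-one matching by reciprocal overlap: two domains match when
#' the overlap covers at least `min_reciprocal_overlap` of both. Unmatched
#' domains are "changed". Bins are classified into
#' `common-TAD-interior` / `changed-TAD-interior` / `common-boundary` /
#' `changed-boundary` / `non-TAD`, with boundary regions the
#' `boundary_width` bins at each domain edge (changed beats common,
#' boundary beats interior when classes collide).
#'
#' @param d1,d2 `domain_set` objects on the same genome.
#' @param min_reciprocal_overlap Fraction in (0, 1\] (default 0.8).
#' @param boundary_width Bins flanking each domain edge (default 1).
#' @return A list of class `domain_comparison`: `matches` (tibble of paired
#'   domain indices and overlaps), `changed1`, `changed2` (unmatched
#'   domains), `bins` (per-bin class tibble), `summary`.
#' @export
compare_domains <- function(d1, d2, min_reciprocal_overlap = 0.8, boundary_width = 1) {
  stopifnot(inherits(d1, "domain_set"), inherits(d2, "domain_set"))
  g <- attr(d1, "genome")
  check_same_genome(g, attr(d2, "genome"))

  cand <- tidyr::crossing(i = seq_len(max(nrow(d1), 1L)), j = seq_len(max(nrow(d2), 1L)))
  matches <- tibble::tibble(i = integer(), j = integer(), ro = numeric())
  if (nrow(d1) > 0 && nrow(d2) > 0) {
    cand <- cand |>
      dplyr::filter(d1$chrom[.data$i] == d2$chrom[.data$j]) |>
      dplyr::mutate(
        ov = pmax(0, pmin(d1$end_bin[.data$i], d2$end_bin[.data$j]) -
                    pmax(d1$start_bin[.data$i], d2$start_bin[.data$j])),
        ro = pmin(.data$ov / (d1$end_bin[.data$i] - d1$start_bin[.data$i]),
                  .data$ov / (d2$end_bin[.data$j] - d2$start_bin[.data$j]))
      ) |>
      dplyr::filter(.data$ro >= min_reciprocal_overlap) |>
      dplyr::arrange(dplyr::desc(.data$ro))
    used_i <- logical(nrow(d1)); used_j <- logical(nrow(d2))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      matches <- dplyr::bind_rows(matches,
                                  tibble::tibble(i = i, j = j, ro = cand$ro[r]))
    }
  }
  changed1 <- if (nrow(d1) > 0) d1[setdiff(seq_len(nrow(d1)), matches$i), , drop = FALSE] else d1
  changed2 <- if (nrow(d2) > 0) d2[setdiff(seq_len(nrow(d2)), matches$j), , drop = FALSE] else d2

  # per-bin classification
  bins <- genome_bins(g)
  cls <- rep("non-TAD", nrow(bins))
  rank <- c("non-TAD" = 0, "common-TAD-interior" = 1, "common-boundary" = 2,
            "changed-TAD-interior" = 3, "changed-boundary" = 4)
  paint <- function(cls, dset, status) {
    if (nrow(dset) == 0) return(cls)
    for (r in seq_len(nrow(dset))) {
      sb <- dset$start_bin[r]; eb <- dset$end_bin[r]; ch <- dset$chrom[r]
      all_bins <- sb:(eb - 1)
      bnd <- unique(c(utils::head(all_bins, boundary_width), utils::tail(all_bins, boundary_width)))
      for (bn in all_bins) {
        lab <- paste0(status, if (bn %in% bnd) "-boundary" else "-TAD-interior")
        idx <- which(bins$chrom == ch & bins$bin == bn)
        if (rank[[lab]] > rank[[cls[idx]]]) cls[idx] <- lab
      }
    }
    cls
  }
  cls <- paint(cls, dplyr::bind_rows(
    if (nrow(matches) > 0) d1[matches$i, , drop = FALSE],
    if (nrow(matches) > 0) d2[matches$j, , drop = FALSE]), "common")
  cls <- paint(cls, dplyr::bind_rows(changed1, changed2), "changed")
  bins$class <- cls

  summary <- bins |> dplyr::count(.data$class, name = "n_bins")
  structure(list(matches = matches, changed1 = changed1, changed2 = changed2,
                 bins = bins, summary = summary,
                 n_common = nrow(matches),
                 n_changed1 = nrow(changed1), n_changed2 = nrow(changed2)),
            class = "domain_comparison")
}

#' @export
print.domain_comparison <- function(x, ...) {
  cat("<domain_comparison> ", x$n_common, " matched, ",
      x$n_changed1, " changed in set 1, ", x$n_changed2, " changed in set 2\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' Mean gene density around TAD boundaries
#'
#' For every domain boundary, counts gene TSSs in bins at offsets
#' `-flank .. +flank` from the boundary bin, oriented so positive offsets
#' point into the domain interior, then averages over boundaries.
#'
#' @param d A non-empty `domain_set`.
#' @param genes A gene table.
#' @param flank Flank in bp, a multiple of the resolution (default 50 kb).
#' @return A tibble with `offset` (bins), `offset_bp`, `mean_genes`,
#'   `n_boundaries` contributing at each offset.
#' @export
gene_profile_around_boundaries <- function(d, genes, flank = 5e4) {
  stopifnot(inherits(d, "domain_set"))
  if (nrow(d) == 0) stop("empty domain set: no boundaries to profile")
  g <- attr(d, "genome")
  f <- flank / g$resolution
  if (f != round(f)) stop("flank must be a multiple of the resolution")
  f <- as.integer(f)
  counts <- gene_bin_counts(genes, g)
  key <- paste(counts$chrom, counts$bin)
  offsets <- -f:f
  acc <- matrix(NA_real_, nrow = 2 * nrow(d), ncol = length(offsets))
  r <- 0
  for (k in seq_len(nrow(d))) {
    ch <- d$chrom[k]
    for (edge in c("start", "end")) {
      r <- r + 1
      bnd <- if (edge == "start") d$start_bin[k] else d$end_bin[k] - 1L
      dirn <- if (edge == "start") 1L else -1L   # +offset points into interior
      bins_at <- bnd + dirn * offsets
      vals <- counts$genes[match(paste(ch, bins_at), key)]
      acc[r, ] <- vals
    }
  }
  tibble::tibble(
    offset = offsets,
    offset_bp = offsets * g$resolution,
    mean_genes = colMeans(acc, na.rm = TRUE),
    n_boundaries = colSums(!is.na(acc))
  )
}

#' Gene density: TAD boundary vs interior bins
#'
#' Splits per-bin gene (TSS) counts into boundary bins (the
#' `boundary_width` bins at each domain edge) and interior bins, and runs
#' Welch's two-sample t-test.
#'
#' @param d A non-empty `domain_set`.
#' @param genes A gene table.
#' @param boundary_width Bins at each edge counted as boundary (default 1).
#' @return A list of class `boundary_density_stats` with the per-group
#'   means and the `welch_test`.
#' @export
boundary_vs_interior_density <- function(d, genes, boundary_width = 1) {
  stopifnot(inherits(d, "domain_set"))
  if (nrow(d) == 0) stop("empty domain set")
  g <- attr(d, "genome")
  counts <- gene_bin_counts(genes, g)
  key <- paste(counts$chrom, counts$bin)
  boundary <- numeric(); interior <- numeric()
  for (k in seq_len(nrow(d))) {
    all_bins <- d$start_bin[k]:(d$end_bin[k] - 1L)
    bnd <- unique(c(utils::head(all_bins, boundary_width),
                    utils::tail(all_bins, boundary_width)))
    int <- setdiff(all_bins, bnd)
    boundary <- c(boundary, counts$genes[match(paste(d$chrom[k], bnd), key)])
    interior <- c(interior, counts$genes[match(paste(d$chrom[k], int), key)])
  }
  test <- welch_t_test(boundary, interior)
  structure(list(test = test,
                 mean_boundary = mean(boundary, na.rm = TRUE),
                 mean_interior = mean(interior, na.rm = TRUE),
                 n_boundary = length(boundary), n_interior = length(interior)),
            class = "boundary_density_stats")
}

#' @export
print.boundary_density_stats <- function(x, ...) {
  cat(sprintf("Gene density boundary vs interior: %.3f vs %.3f genes/bin\n",
              x$mean_boundary, x$mean_interior))
  print(x$test)
  invisible(x)
}

#' @export
tidy.boundary_density_stats <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(mean_boundary = x$mean_boundary, mean_interior = x$mean_interior),
    tidy.welch_test(x$test)[, c("statistic", "df", "p.value")]
  )
}
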