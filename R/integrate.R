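#' Construct a gene table
#'
#' @param genes Data frame with columns `gene`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`); extra columns kept. Coordinates are 0-based
#'   half-open.
#' @return A tibble of class `gene_table`.
#' @export
gene_table <- function(genes) {
  genes <- tibble::as_tibble(genes)
  required <- c("gene", "chrom", "start", "end", "strand")
  if (!all(required %in% names(genes))) {
    stop("gene table needs columns ", paste(required, collapse = ", "))
  }
  stopifnot(all(genes$start < genes$end), all(genes$strand %in% c("+", "-")))
  if (anyDuplicated(genes$gene)) stop("gene ids must be unique")
  structure(genes, class = c("gene_table", class(tibble::tibble())))
}

# strand-aware TSS: start on +, end - 1 on -
gene_tss <- function(genes) {
  dplyr::mutate(tibble::as_tibble(genes),
                tss = ifelse(.data$strand == "+", .data$start, .data$end - 1))
}

#' Read a gene annotation BED file
#'
#' Six-column BED (`chrom start end name score strand`); name becomes the
#' gene id.
#' @param path BED path.
#' @return A `gene_table`.
#' @export
read_gene_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "gene",
                                            "score", "strand"),
                        col_types = "cddccc", comment = "#", progress = FALSE)
  gene_table(df[, c("gene", "chrom", "start", "end", "strand")])
}

#' Read a differential-expression table
#'
#' TSV with columns `gene`, `log2fc`, `fdr` (header optional).
#' @param path TSV path.
#' @return A tibble of class `deg_table`.
#' @export
read_deg_table <- function(path) {
  first <- readr::read_lines(path, n_max = 1)
  skip <- grepl("^gene\\b", first)
  df <- readr::read_tsv(path, col_names = c("gene", "log2fc", "fdr"),
                        col_types = "cdd", skip = as.integer(skip),
                        progress = FALSE)
  deg_table(df)
}

#' Construct a DEG table
#' @param df Data frame with `gene`, `log2fc`, `fdr`.
#' @return A tibble of class `deg_table`.
#' @export
deg_table <- function(df) {
  df <- tibble::as_tibble(df)
  stopifnot(all(c("gene", "log2fc", "fdr") %in% names(df)),
            all(df$fdr >= 0 & df$fdr <= 1))
  structure(df, class = c("deg_table", class(tibble::tibble())))
}

#' Filter differentially expressed genes
#'
#' Keeps genes with `fdr <= max_fdr` and `|log2fc| >= log2(min_fold)`
#' (two-sided: a 2-fold drop qualifies like a 2-fold gain).
#'
#' @param t A `deg_table`.
#' @param max_fdr FDR ceiling (default 0.05).
#' @param min_fold Minimum linear fold change (default 2).
#' @return Character vector of gene ids.
#' @export
filter_degs <- function(t, max_fdr = 0.05, min_fold = 2) {
  stopifnot(inherits(t, "deg_table"))
  t$gene[t$fdr <= max_fdr & abs(t$log2fc) >= log2(min_fold)]
}

#' Promoter intervals of a gene table
#'
#' Strand-aware window around the TSS: `[TSS - upstream, TSS + downstream)`
#' on `+`, mirrored on `-`, clipped at position 0.
#'
#' @param g A `gene_table`.
#' @param upstream Bases upstream of the TSS (default 2000).
#' @param downstream Bases downstream (default 200).
#' @param genome Optional `binned_genome` used to clip at chromosome ends.
#' @return A tibble with `gene`, `chrom`, `start`, `end`, `strand`.
#' @export
promoters <- function(g, upstream = 2000, downstream = 200, genome = NULL) {
  stopifnot(inherits(g, "gene_table"), upstream >= 0, downstream >= 0,
            upstream + downstream > 0)
  tss <- gene_tss(g)
  out <- tibble::tibble(
    gene = tss$gene, chrom = tss$chrom,
    start = ifelse(tss$strand == "+", tss$tss - upstream, tss$tss - downstream + 1),
    end = ifelse(tss$strand == "+", tss$tss + downstream, tss$tss + upstream + 1),
    strand = tss$strand
  )
  out$start <- pmax(out$start, 0)
  if (!is.null(genome)) out$end <- pmin(out$end, genome$lengths[out$chrom])
  out
}

#' Count overlaps between two interval sets
#'
#' Half-open intervals overlap when they share at least one base. Returns
#' the number of distinct intervals on each side with at least one partner
#' and the full pair list.
#'
#' @param a,b Data frames with `chrom`, `start`, `end` (0-based half-open).
#' @return A list: `n_a_hit`, `n_b_hit`, `pairs` (tibble of row indices
#'   `a_idx`, `b_idx`).
#' @export
overlap_count <- function(a, b) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  pairs <- tibble::tibble(a_idx = integer(), b_idx = integer())
  if (nrow(a) > 0 && nrow(b) > 0) {
    for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
      ia <- which(a$chrom == ch); ib <- which(b$chrom == ch)
      hit <- outer(a$start[ia], b$end[ib], `<`) & outer(a$end[ia], b$start[ib], `>`)
      idx <- which(hit, arr.ind = TRUE)
      if (nrow(idx) > 0) {
        pairs <- dplyr::bind_rows(pairs, tibble::tibble(a_idx = ia[idx[, 1]],
                                                        b_idx = ib[idx[, 2]]))
      }
    }
  }
  list(n_a_hit = dplyr::n_distinct(pairs$a_idx),
       n_b_hit = dplyr::n_distinct(pairs$b_idx),
       pairs = dplyr::arrange(pairs, .data$a_idx, .data$b_idx))
}

#' Hypergeometric enrichment test (upper tail)
#'
#' Probability of drawing at least `k` class members in `n` draws without
#' replacement from a population of `N` containing `K` members, computed
#' stably in log space. Fold enrichment is `(k/n) / (K/N)`.
#'
#' @param N Population size.
#' @param K Class size.
#' @param n Draw size.
#' @param k Observed members in the draw.
#' @return One-row tibble of class `enrichment_result`: `N`, `K`, `n`, `k`,
#'   `fold`, `p`.
#' @export
hypergeom_enrichment <- function(N, K, n, k) {
  stopifnot(N >= 0, K >= 0, n >= 0, k >= 0, K <= N, n <= N)
  if (k > min(K, n)) stop("infeasible overlap: k > min(K, n)")
  p <- hyper_upper_tail(N, K, n, k)
  fold <- if (n > 0 && K > 0) (k / n) / (K / N) else NA_real_
  structure(tibble::tibble(N = N, K = K, n = n, k = k, fold = fold, p = p),
            class = c("enrichment_result", class(tibble::tibble())))
}

#' Upper-tail hypergeometric probabilities, log-space
#'
#' `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`, vectorised over `k`.
#' Terms are accumulated with a log-sum-exp suffix scan for numerical
#' stability; `k <= max(0, n + K - N)` returns exactly 1.
#'
#' @param N,K,n Population, class and draw sizes (scalars).
#' @param k Vector of observed overlaps.
#' @return Numeric vector of upper-tail probabilities.
#' @export
hyper_upper_tail <- function(N, K, n, k) {
  lo <- max(0, n + K - N)
  hi <- min(K, n)
  if (hi < lo) return(rep(NaN, length(k)))
  x <- lo:hi
  logs <- lchoose(K, x) + lchoose(N - K, n - x) - lchoose(N, n)
  m <- max(logs)
  # suffix log-sum-exp: tail[i] = log sum_{j >= i} exp(logs[j])
  tail_p <- rev(cumsum(rev(exp(logs - m))))
  vapply(k, function(kk) {
    if (kk <= lo) 1
    else if (kk > hi) 0
    else min(1, exp(m + log(tail_p[kk - lo + 1])))
  }, numeric(1))
}

#' Per-bin architecture class map
#'
#' Combines a compartment comparison and a domain comparison into the
#' integration layer's bin classification: one dimension for compartments
#' (`common-A`, `common-B`, `changed`), one for domains (`common-boundary`,
#' `common-TAD-interior`, `changed-boundary`, `changed-TAD-interior`,
#' `non-TAD`).
#'
#' A third, derived dimension `combined_class` marks a bin `changed` when
#' either dimension reports a change and `common` otherwise — the union of
#' altered architecture used for headline enrichment contrasts.
#'
#' @param comp A `compartment_comparison` (or `NULL`).
#' @param dom A `domain_comparison` (or `NULL`).
#' @param genome Required if both inputs are `NULL`-free sources of it.
#' @return A tibble of class `region_class_map` with columns `chrom`,
#'   `bin`, `start`, `end`, `comp_class`, `domain_class`, `combined_class`.
#' @export
region_class_map <- function(comp = NULL, dom = NULL, genome = NULL) {
  if (is.null(genome)) {
    if (!is.null(comp)) genome <- attr(comp, "genome")
    else stop("supply a genome when no compartment comparison is given")
  }
  bins <- genome_bins(genome)
  bins$comp_class <- NA_character_
  bins$domain_class <- NA_character_
  if (!is.null(comp)) {
    cls <- comp$class[match(paste(bins$chrom, bins$bin), paste(comp$chrom, comp$bin))]
    bins$comp_class <- dplyr::case_when(
      is.na(cls) ~ NA_character_,
      cls %in% c("A->B", "B->A") ~ "changed",
      TRUE ~ cls
    )
  }
  if (!is.null(dom)) {
    db <- dom$bins
    bins$domain_class <- db$class[match(paste(bins$chrom, bins$bin),
                                        paste(db$chrom, db$bin))]
  }
  comp_changed <- !is.na(bins$comp_class) & bins$comp_class == "changed"
  dom_changed <- !is.na(bins$domain_class) &
    bins$domain_class %in% c("changed-boundary", "changed-TAD-interior")
  any_classified <- !is.na(bins$comp_class) | !is.na(bins$domain_class)
  bins$combined_class <- dplyr::case_when(
    comp_changed | dom_changed ~ "changed",
    any_classified ~ "common",
    TRUE ~ NA_character_
  )
  structure(bins, class = c("region_class_map", class(tibble::tibble())),
            genome = genome)
}

# shared core: hypergeometric enrichment of a unit set across bin classes
enrich_units_in_classes <- function(unit_bins, unit_in_set, classes, dimension) {
  cls_col <- classes[[dimension]]
  key <- paste(classes$chrom, classes$bin)
  unit_cls <- cls_col[match(unit_bins, key)]
  classified <- !is.na(unit_cls)
  N <- sum(classified)
  levels <- sort(unique(stats::na.omit(cls_col)))
  purrr::map_dfr(levels, function(lv) {
    K <- sum(unit_cls[classified] == lv)
    in_set <- unit_in_set[classified]
    n <- sum(in_set)
    k <- sum(in_set & unit_cls[classified] == lv)
    if (N == 0 || K == 0 || n == 0) {
      warning(sprintf("class '%s': empty population/class/draw, skipped", lv))
      return(NULL)
    }
    res <- hypergeom_enrichment(N, K, n, k)
    res$class <- lv
    res[, c("class", "N", "K", "n", "k", "fold", "p")]
  }) |>
    dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH"))
}

#' Enrichment of a gene set in architecture classes
#'
#' Hypergeometric test per class: the population is all universe genes
#' whose TSS falls on a classified bin, the class members are those on
#' bins of that class, the draw is the gene set.
#'
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param universe A `gene_table` (all annotated genes).
#' @param classes A `region_class_map`.
#' @param dimension `"comp_class"` or `"domain_class"`.
#' @return Tibble of class `enrichment_result` rows: `class`, `N`, `K`,
#'   `n`, `k`, `fold`, `p`, `p_adj` (BH across classes).
#' @export
enrich_genes_in_classes <- function(gene_set, universe, classes,
                                    dimension = c("comp_class", "domain_class",
                                                  "combined_class")) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(classes, "region_class_map"))
  if (!all(gene_set %in% universe$gene)) stop("gene set must be a subset of the universe")
  g <- attr(classes, "genome")
  tss <- gene_tss(universe)
  tss$bin <- pos_to_bin(g, tss$chrom, tss$tss)
  ok <- !is.na(tss$bin)
  enrich_units_in_classes(paste(tss$chrom[ok], tss$bin[ok]),
                          tss$gene[ok] %in% gene_set, classes, dimension)
}

#' Enrichment of differential-contact anchor bins in architecture classes
#'
#' Unit = bin: the population is all classified bins, the draw the
#' distinct anchor bins of the retained differential pixels.
#'
#' @param dc A `differential_contacts` object.
#' @param classes A `region_class_map`.
#' @param dimension `"comp_class"` or `"domain_class"`.
#' @return As [enrich_genes_in_classes()].
#' @export
enrich_pixels_in_classes <- function(dc, classes,
                                     dimension = c("comp_class", "domain_class",
                                                   "combined_class")) {
  dimension <- match.arg(dimension)
  stopifnot(inherits(dc, "differential_contacts"),
            inherits(classes, "region_class_map"))
  anchors <- unique(paste(rep(dc$hits$chrom, 2), c(dc$hits$bin1, dc$hits$bin2)))
  all_bins <- paste(classes$chrom, classes$bin)
  enrich_units_in_classes(all_bins, all_bins %in% anchors, classes, dimension)
}

#' Promoter density inside vs outside differential contact regions
#'
#' Counts promoters (by midpoint) per Mb inside the merged differential
#' regions and in the genomic complement, and reports the ratio.
#'
#' @param proms Promoter tibble from [promoters()].
#' @param dc A `differential_contacts` object.
#' @param genome A `binned_genome`.
#' @return One-row tibble: `density_regions`, `density_background`
#'   (promoters per Mb), `ratio` (`Inf` when the background is empty),
#'   `n_regions`, `region_bp`.
#' @export
promoter_density_contrast <- function(proms, dc, genome) {
  stopifnot(inherits(dc, "differential_contacts"))
  regions <- dc$regions
  if (nrow(regions) == 0) stop("no differential contact regions")
  region_bp <- sum(regions$end - regions$start)
  total_bp <- sum(genome$lengths)
  mid <- (proms$start + proms$end) / 2
  inside <- logical(nrow(proms))
  for (r in seq_len(nrow(regions))) {
    inside <- inside | (proms$chrom == regions$chrom[r] &
                          mid >= regions$start[r] & mid < regions$end[r])
  }
  n_in <- sum(inside); n_out <- sum(!inside)
  d_in <- n_in / (region_bp / 1e6)
  d_out <- n_out / ((total_bp - region_bp) / 1e6)
  tibble::tibble(density_regions = d_in, density_background = d_out,
                 ratio = ifelse(d_out == 0, Inf, d_in / d_out),
                 n_regions = nrow(regions), region_bp = region_bp)
}

#' Virtual-4C interaction profile of a gene
#'
#' The O/E row anchored at the bin containing the gene's TSS, over all
#' bins within `flank` of the anchor. Peaks mark loci the gene contacts
#' more than expected at that distance.
#'
#' @param gene_id Gene id present in `genes`.
#' @param oe An `oe_matrix`.
#' @param genes A `gene_table`.
#' @param flank Flank in bp (at least one bin).
#' @return A tibble with `chrom`, `bin`, `start`, `end`, `offset` (bins
#'   from the anchor), `oe` (`NA` over masked bins).
#' @export
gene_interaction_profile <- function(gene_id, oe, genes, flank = 5e5) {
  stopifnot(inherits(oe, "oe_matrix"))
  g <- attr(oe, "genome")
  if (flank < g$resolution) stop("flank smaller than one bin")
  row <- genes[genes$gene == gene_id, , drop = FALSE]
  if (nrow(row) == 0) stop("gene not found: ", gene_id)
  tss <- gene_tss(row)
  anchor <- pos_to_bin(g, tss$chrom, tss$tss)
  ch <- tss$chrom
  if (is.na(anchor) || isTRUE(attr(oe, "mask")[[ch]][anchor + 1L])) {
    stop("gene TSS maps to a masked or invalid bin")
  }
  M <- oe_dense(oe, ch)
  f <- as.integer(flank / g$resolution)
  nb <- g$n_bins[[ch]]
  bins <- max(0L, anchor - f):min(nb - 1L, anchor + f)
  tibble::tibble(
    chrom = ch, bin = bins,
    start = bins * g$resolution,
    end = pmin((bins + 1) * g$resolution, g$lengths[[ch]]),
    offset = bins - anchor,
    oe = M[anchor + 1L, bins + 1L]
  )
}
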