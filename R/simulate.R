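#' Configure a two-condition Hi-C simulation
#'
#' Builds the full generative layout for a paired-condition experiment:
#' per-pixel Poisson means follow a multiplicative block model
#' `mu[i,j] = depth * (|i-j|+1)^(-alpha) * (1 + c*s_i*s_j) * t^[same domain]
#' * lambda^[loop] * f^[differential pixel, condition 2]`, with condition 2
#' additionally applying compartment-block flips, domain-boundary shifts,
#' loop gains/losses and a global depth ratio. Gene positions are drawn
#' with class-dependent density (A vs B compartments, boundary vs interior
#' bins) and a DEG table is generated so that programmed DEGs pass the
#' standard thresholds (FDR <= 0.05, fold >= 2) and the rest fail.
#'
#' All layouts (blocks, domains, loops, alterations) are materialised here,
#' deterministically from `seed`, so the config doubles as the ground-truth
#' record blueprint.
#'
#' @param seed Integer seed controlling layout and count noise.
#' @param chrom_bins Named integer vector of bins per chromosome.
#' @param resolution Bin size in bp.
#' @param alpha Distance-decay exponent.
#' @param depth Expected count on the diagonal (distance 0).
#' @param comp_block_bins Compartment block size in bins.
#' @param comp_contrast Checkerboard contrast `c`.
#' @param n_domains Domains per chromosome.
#' @param domain_fold Within-domain contact fold `t`.
#' @param n_loops Loops per chromosome.
#' @param loop_fold Loop enrichment `lambda`.
#' @param n_flip_blocks Compartment blocks flipped per chromosome in
#'   condition 2.
#' @param n_shift_boundaries Domain end-boundaries shifted per chromosome.
#' @param boundary_shift Shift size in bins.
#' @param n_gained_loops,n_lost_loops Loop gains/losses (genome-wide).
#' @param n_diff_pixels Pixels scaled by `diff_fold` in condition 2
#'   (genome-wide), placed at separations `diff_distance` bins.
#' @param diff_fold Differential pixel fold `f`.
#' @param diff_distance Integer range of allowed separations.
#' @param depth_ratio Condition-2 global depth multiplier `r`.
#' @param gene_rate Mean genes per bin before class multipliers.
#' @param comp_gene_ratio A:B gene-density ratio.
#' @param boundary_gene_ratio Boundary:interior gene-density ratio.
#' @param n_degs Programmed DEGs.
#' @param deg_enrichment_fold Placement weight of DEGs on altered bins
#'   (flipped compartment blocks and differential-pixel anchors;
#'   1 = uniform placement).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1,
                              chrom_bins = c(chr1 = 400L, chr2 = 400L),
                              resolution = 1e4,
                              alpha = 1.0,
                              depth = 400,
                              comp_block_bins = 25L,
                              comp_contrast = 0.15,
                              n_domains = 12L,
                              domain_fold = 2.0,
                              n_loops = 10L,
                              loop_fold = 4.0,
                              n_flip_blocks = 2L,
                              n_shift_boundaries = 3L,
                              boundary_shift = 4L,
                              n_gained_loops = 5L,
                              n_lost_loops = 5L,
                              n_diff_pixels = 30L,
                              diff_fold = 3.0,
                              diff_distance = 1:8,
                              depth_ratio = 1.0,
                              gene_rate = 3,
                              comp_gene_ratio = 2,
                              boundary_gene_ratio = 2,
                              n_degs = 100L,
                              deg_enrichment_fold = 3) {
  stopifnot(all(chrom_bins >= 20), resolution > 0, depth > 0, alpha >= 0,
            comp_contrast >= 0, comp_contrast < 1,
            domain_fold > 0, loop_fold > 0, diff_fold > 0, depth_ratio > 0,
            deg_enrichment_fold > 0)
  chroms <- names(chrom_bins)
  if (is.null(chroms)) chroms <- paste0("chr", seq_along(chrom_bins))
  genome <- binned_genome(chroms, chrom_bins * resolution, resolution)

  layout <- with_seed(seed, {
    blocks <- purrr::map_dfr(chroms, function(ch) {
      nb <- chrom_bins[[ch]]
      starts <- seq(0L, nb - 1L, by = comp_block_bins)
      tibble::tibble(chrom = ch, block = seq_along(starts),
                     start_bin = starts,
                     end_bin = pmin(starts + comp_block_bins, nb),
                     sign = rep_len(c(1, -1), length(starts)))
    })
    domains <- purrr::map_dfr(chroms, function(ch) {
      nb <- chrom_bins[[ch]]
      pos <- sample(8:20, 1)
      out <- list()
      for (k in seq_len(n_domains)) {
        len <- sample(8:15, 1)
        if (pos + len > nb - 8) break
        out[[k]] <- tibble::tibble(chrom = ch, start_bin = pos, end_bin = pos + len)
        pos <- pos + len + sample(8:20, 1)
      }
      dplyr::bind_rows(out)
    })
    loops <- purrr::map_dfr(chroms, function(ch) {
      nb <- chrom_bins[[ch]]
      if (n_loops > 0 && nb < 48) stop("chromosomes need >= 48 bins to place loops")
      sep_max <- min(60L, nb - 16L)
      picked <- tibble::tibble(bin1 = integer(), bin2 = integer())
      tries <- 0
      while (nrow(picked) < n_loops && tries < 500) {
        tries <- tries + 1
        sep <- sample(15:sep_max, 1)
        i <- sample(8:(nb - 8 - sep), 1)
        j <- i + sep
        if (nrow(picked) > 0 &&
            any(abs(picked$bin1 - i) <= 4 & abs(picked$bin2 - j) <= 4)) next
        picked <- dplyr::bind_rows(picked, tibble::tibble(bin1 = i, bin2 = j))
      }
      dplyr::mutate(picked, chrom = ch, .before = 1)
    })
    # condition-2 alterations
    flipped <- blocks |>
      dplyr::group_by(.data$chrom) |>
      dplyr::slice_sample(n = n_flip_blocks) |>
      dplyr::ungroup()
    shifted <- domains |>
      dplyr::group_by(.data$chrom) |>
      dplyr::group_modify(~ dplyr::slice_sample(.x, n = min(n_shift_boundaries, nrow(.x)))) |>
      dplyr::ungroup() |>
      dplyr::mutate(shift = boundary_shift)
    empty_px <- tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer())
    gained <- if (n_gained_loops == 0) empty_px else
      purrr::map_dfr(sample(chroms, n_gained_loops, replace = TRUE), function(ch) {
      nb <- chrom_bins[[ch]]
      sep_max <- min(60L, nb - 16L)
      repeat {
        sep <- sample(15:sep_max, 1)
        i <- sample(8:(nb - 8 - sep), 1)
        cand <- tibble::tibble(chrom = ch, bin1 = i, bin2 = i + sep)
        clash <- loops |> dplyr::filter(.data$chrom == ch,
                                        abs(.data$bin1 - cand$bin1) <= 4,
                                        abs(.data$bin2 - cand$bin2) <= 4)
        if (nrow(clash) == 0) return(cand)
      }
    })
    lost <- loops |> dplyr::slice_sample(n = min(n_lost_loops, nrow(loops)))
    diff_px <- if (n_diff_pixels == 0) dplyr::mutate(empty_px, fold = numeric()) else
      purrr::map_dfr(sample(chroms, n_diff_pixels, replace = TRUE), function(ch) {
      nb <- chrom_bins[[ch]]
      repeat {
        d <- sample(diff_distance, 1)
        i <- sample(1:(nb - 1 - d), 1)
        cand <- tibble::tibble(chrom = ch, bin1 = i, bin2 = i + d)
        near_loop <- dplyr::bind_rows(loops, gained) |>
          dplyr::filter(.data$chrom == ch,
                        abs(.data$bin1 - cand$bin1) <= 2,
                        abs(.data$bin2 - cand$bin2) <= 2)
        if (nrow(near_loop) == 0) return(cand)
      }
    }) |> dplyr::distinct(.data$chrom, .data$bin1, .data$bin2) |>
      dplyr::mutate(fold = diff_fold)
    list(blocks = blocks, domains = domains, loops = loops,
         flipped_blocks = flipped, shifted_domains = shifted,
         gained_loops = gained, lost_loops = lost, diff_pixels = diff_px)
  })

  structure(c(list(seed = seed, genome = genome, chrom_bins = chrom_bins,
                   resolution = resolution, alpha = alpha, depth = depth,
                   comp_block_bins = comp_block_bins, comp_contrast = comp_contrast,
                   n_domains = n_domains, domain_fold = domain_fold,
                   n_loops = n_loops, loop_fold = loop_fold,
                   n_flip_blocks = n_flip_blocks,
                   n_shift_boundaries = n_shift_boundaries,
                   boundary_shift = boundary_shift,
                   n_gained_loops = n_gained_loops, n_lost_loops = n_lost_loops,
                   n_diff_pixels = n_diff_pixels, diff_fold = diff_fold,
                   diff_distance = diff_distance, depth_ratio = depth_ratio,
                   gene_rate = gene_rate, comp_gene_ratio = comp_gene_ratio,
                   boundary_gene_ratio = boundary_gene_ratio,
                   n_degs = n_degs, deg_enrichment_fold = deg_enrichment_fold),
              layout),
            class = "simulation_config")
}

#' Null (structure-free) simulation config
#'
#' Pure power-law decay with no compartments, domains, loops or programmed
#' alterations: the two conditions share one mean map up to a global depth
#' ratio. Used for calibration checks.
#'
#' @param seed Integer seed.
#' @param bins Bins on the single chromosome (default 200).
#' @param depth_ratio Condition-2 depth multiplier (default 1.5).
#' @param depth Diagonal depth (default 400).
#' @return A `simulation_config`.
#' @export
null_config <- function(seed = 1, bins = 200L, depth_ratio = 1.5, depth = 400) {
  simulation_config(seed = seed, chrom_bins = c(chr1 = as.integer(bins)),
                    depth = depth,
                    comp_contrast = 0, domain_fold = 1, loop_fold = 1,
                    n_loops = 0L, n_flip_blocks = 0L, n_shift_boundaries = 0L,
                    n_gained_loops = 0L, n_lost_loops = 0L, n_diff_pixels = 0L,
                    depth_ratio = depth_ratio, deg_enrichment_fold = 1)
}

# per-bin compartment sign vector for one chromosome under a block table
comp_signs <- function(cfg, ch, flipped = FALSE) {
  nb <- cfg$chrom_bins[[ch]]
  s <- numeric(nb)
  bl <- cfg$blocks[cfg$blocks$chrom == ch, , drop = FALSE]
  for (r in seq_len(nrow(bl))) s[(bl$start_bin[r] + 1):bl$end_bin[r]] <- bl$sign[r]
  if (flipped) {
    fl <- cfg$flipped_blocks[cfg$flipped_blocks$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(fl))) {
      s[(fl$start_bin[r] + 1):fl$end_bin[r]] <- -s[(fl$start_bin[r] + 1):fl$end_bin[r]]
    }
  }
  s
}

# condition-specific domain table
cond_domains <- function(cfg, condition) {
  d <- cfg$domains
  if (condition == 2 && nrow(cfg$shifted_domains) > 0) {
    key <- paste(d$chrom, d$start_bin, d$end_bin)
    sh <- cfg$shifted_domains
    idx <- match(paste(sh$chrom, sh$start_bin, sh$end_bin), key)
    d$end_bin[idx] <- d$end_bin[idx] + sh$shift
  }
  d
}

# condition-specific loop table
cond_loops <- function(cfg, condition) {
  if (condition == 1) return(cfg$loops)
  lost_key <- paste(cfg$lost_loops$chrom, cfg$lost_loops$bin1, cfg$lost_loops$bin2)
  keep <- !(paste(cfg$loops$chrom, cfg$loops$bin1, cfg$loops$bin2) %in% lost_key)
  dplyr::bind_rows(cfg$loops[keep, , drop = FALSE], cfg$gained_loops) |>
    dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
}

# dense Poisson mean matrix for one chromosome and condition
mean_matrix <- function(cfg, ch, condition) {
  nb <- cfg$chrom_bins[[ch]]
  D <- abs(outer(seq_len(nb), seq_len(nb), `-`))
  mu <- cfg$depth * (D + 1)^(-cfg$alpha)
  s <- comp_signs(cfg, ch, flipped = condition == 2)
  mu <- mu * (1 + cfg$comp_contrast * outer(s, s))
  dd <- cond_domains(cfg, condition)
  dd <- dd[dd$chrom == ch, , drop = FALSE]
  for (r in seq_len(nrow(dd))) {
    ix <- (dd$start_bin[r] + 1):dd$end_bin[r]
    mu[ix, ix] <- mu[ix, ix] * cfg$domain_fold
  }
  lp <- cond_loops(cfg, condition)
  lp <- lp[lp$chrom == ch, , drop = FALSE]
  for (r in seq_len(nrow(lp))) {
    i <- lp$bin1[r] + 1L; j <- lp$bin2[r] + 1L
    mu[i, j] <- mu[i, j] * cfg$loop_fold
    mu[j, i] <- mu[i, j]
  }
  if (condition == 2) {
    dp <- cfg$diff_pixels[cfg$diff_pixels$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(dp))) {
      i <- dp$bin1[r] + 1L; j <- dp$bin2[r] + 1L
      mu[i, j] <- mu[i, j] * dp$fold[r]
      mu[j, i] <- mu[i, j]
    }
    mu <- mu * cfg$depth_ratio
  }
  mu
}

# bins preferential DEG placement targets: flipped compartment blocks and
# the anchor bins of programmed differential pixels
altered_bins <- function(cfg) {
  fl <- cfg$flipped_blocks
  comp_bins <- purrr::map2_dfr(seq_len(nrow(fl)), fl$chrom, function(r, ch) {
    tibble::tibble(chrom = ch, bin = fl$start_bin[r]:(fl$end_bin[r] - 1L))
  })
  px <- cfg$diff_pixels
  px_bins <- tibble::tibble(chrom = rep(px$chrom, 2), bin = c(px$bin1, px$bin2))
  dplyr::distinct(dplyr::bind_rows(comp_bins, px_bins))
}

#' Simulate a paired-condition Hi-C experiment
#'
#' Draws independent Poisson counts for both conditions from the
#' multiplicative mean model of the config, places genes with
#' class-dependent density, and generates the DEG table (DEGs
#' preferentially on altered bins when `deg_enrichment_fold > 1`).
#' Identical seeds give bit-identical output.
#'
#' @param cfg A `simulation_config`.
#' @param noise_seed Seed for the Poisson count noise and gene placement
#'   (default `cfg$seed + 1`); varying it while keeping `cfg` fixed gives
#'   independent replicate draws of the same underlying truth.
#' @return A list of class `simulation`: `cm1`, `cm2` (contact matrices),
#'   `genes` (`gene_table`), `degs` (`deg_table`), `truth` (see
#'   [simulation_truth()]).
#' @export
simulate_pair <- function(cfg, noise_seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "simulation_config"))
  g <- cfg$genome
  truth <- simulation_truth(cfg)

  res <- with_seed(noise_seed, {
    px <- purrr::map(1:2, function(cond) {
      purrr::map_dfr(g$chroms, function(ch) {
        mu <- mean_matrix(cfg, ch, cond)
        ut <- which(upper.tri(mu, diag = TRUE), arr.ind = TRUE)
        counts <- stats::rpois(nrow(ut), mu[ut])
        keep <- counts > 0
        tibble::tibble(chrom = ch,
                       bin1 = as.integer(ut[keep, 1] - 1L),
                       bin2 = as.integer(ut[keep, 2] - 1L),
                       count = as.numeric(counts[keep]))
      })
    })

    # genes: class-dependent per-bin Poisson rates (condition-1 layout)
    rA <- 2 * cfg$comp_gene_ratio / (1 + cfg$comp_gene_ratio)
    rB <- 2 / (1 + cfg$comp_gene_ratio)
    rBnd <- 2 * cfg$boundary_gene_ratio / (1 + cfg$boundary_gene_ratio)
    rInt <- 2 / (1 + cfg$boundary_gene_ratio)
    bins <- genome_bins(g)
    rate <- numeric(nrow(bins))
    for (ch in g$chroms) {
      sel <- bins$chrom == ch
      s <- comp_signs(cfg, ch, flipped = FALSE)
      r_ch <- cfg$gene_rate * ifelse(s > 0, rA, rB)
      dd <- cfg$domains[cfg$domains$chrom == ch, , drop = FALSE]
      for (r in seq_len(nrow(dd))) {
        ix <- (dd$start_bin[r] + 1):dd$end_bin[r]
        bnd <- c(dd$start_bin[r] + 1, dd$end_bin[r])
        r_ch[ix] <- r_ch[ix] * rInt
        r_ch[bnd] <- r_ch[bnd] / rInt * rBnd
      }
      rate[sel] <- r_ch
    }
    n_per_bin <- stats::rpois(nrow(bins), rate)
    gene_rows <- bins[rep(seq_len(nrow(bins)), n_per_bin), , drop = FALSE]
    n_genes <- nrow(gene_rows)
    offs <- floor(stats::runif(n_genes, 0, cfg$resolution - 1))
    gstart <- gene_rows$start + offs
    gend <- pmin(gstart + 1000, g$lengths[gene_rows$chrom])
    genes <- gene_table(tibble::tibble(
      gene = sprintf("gene%05d", seq_len(n_genes)),
      chrom = gene_rows$chrom, start = gstart, end = gend,
      strand = sample(c("+", "-"), n_genes, replace = TRUE)
    ))

    # DEGs preferentially on altered bins
    tssb <- gene_tss(genes)
    tssb$bin <- pos_to_bin(g, tssb$chrom, tssb$tss)
    alt <- altered_bins(cfg)
    on_alt <- paste(tssb$chrom, tssb$bin) %in% paste(alt$chrom, alt$bin)
    w <- ifelse(on_alt, cfg$deg_enrichment_fold, 1)
    n_degs <- min(cfg$n_degs, n_genes)
    deg_ids <- sample(genes$gene, n_degs, prob = w)
    is_deg <- genes$gene %in% deg_ids
    # DEG magnitudes ~ N(2, 0.25^2), floored just above the 2-fold cutoff so
    # every programmed DEG passes the thresholds and no non-DEG does
    lfc <- ifelse(is_deg,
                  sample(c(-1, 1), n_genes, replace = TRUE) *
                    pmax(stats::rnorm(n_genes, 2, 0.25), 1.05),
                  stats::rnorm(n_genes, 0, 0.3))
    fdr <- ifelse(is_deg, stats::runif(n_genes, 0, 0.05),
                  stats::runif(n_genes, 0.06, 1))
    degs <- deg_table(tibble::tibble(gene = genes$gene, log2fc = lfc, fdr = fdr))

    list(px = px, genes = genes, degs = degs,
         deg_ids = deg_ids, deg_on_altered = on_alt[match(deg_ids, genes$gene)])
  })

  truth$deg_ids <- res$deg_ids
  truth$deg_on_altered <- res$deg_on_altered

  structure(list(
    cm1 = contact_matrix(res$px[[1]], g, sample = "cond1", condition = "cond1"),
    cm2 = contact_matrix(res$px[[2]], g, sample = "cond2", condition = "cond2"),
    genes = res$genes, degs = res$degs, truth = truth
  ), class = "simulation")
}

#' Ground-truth record of a simulation config
#'
#' Deterministic bookkeeping of everything the generator programs:
#' per-condition compartment labels, domains and loops; between-condition
#' changed compartment bins, changed domains and differential pixels.
#' Regenerating it from the same config is exactly reproducible.
#'
#' @param cfg A `simulation_config`.
#' @return A list of class `simulation_truth`.
#' @export
simulation_truth <- function(cfg) {
  g <- cfg$genome
  comp <- purrr::map_dfr(1:2, function(cond) {
    purrr::map_dfr(g$chroms, function(ch) {
      s <- comp_signs(cfg, ch, flipped = cond == 2)
      tibble::tibble(condition = cond, chrom = ch,
                     bin = seq_along(s) - 1L, sign = s,
                     label = ifelse(s > 0, "A", "B"))
    })
  })
  doms <- purrr::map_dfr(1:2, function(cond) {
    dplyr::mutate(cond_domains(cfg, cond), condition = cond, .before = 1)
  })
  loops <- purrr::map_dfr(1:2, function(cond) {
    dplyr::mutate(cond_loops(cfg, cond), condition = cond, .before = 1)
  })
  fl <- cfg$flipped_blocks
  changed_comp <- if (nrow(fl) == 0) {
    tibble::tibble(chrom = character(), bin = integer())
  } else {
    purrr::map_dfr(seq_len(nrow(fl)), function(r) {
      tibble::tibble(chrom = fl$chrom[r], bin = fl$start_bin[r]:(fl$end_bin[r] - 1L))
    })
  }
  structure(list(
    genome = g,
    compartments = comp,
    domains = doms,
    boundaries = doms |>
      tidyr::pivot_longer(c("start_bin", "end_bin"), values_to = "bin") |>
      dplyr::distinct(.data$condition, .data$chrom, .data$bin),
    loops = loops,
    changed_compartment_bins = changed_comp,
    changed_domains = cfg$shifted_domains,
    gained_loops = cfg$gained_loops,
    lost_loops = cfg$lost_loops,
    differential_pixels = cfg$diff_pixels
  ), class = "simulation_truth")
}
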