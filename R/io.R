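#' Write intervals as BED
#'
#' 0-based half-open `chrom start end [name [score]]`, no header.
#' @param df Data frame with `chrom`, `start`, `end` and optionally
#'   `name`, `score`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score"), names(df))
  readr::write_tsv(tibble::as_tibble(df)[, cols], path, col_names = FALSE,
                   progress = FALSE)
  invisible(path)
}

#' Read a BED file
#' @param path BED path.
#' @return Tibble with `chrom`, `start`, `end` and, when present, `name`,
#'   `score`.
#' @export
read_bed <- function(path) {
  df <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                        progress = FALSE, show_col_types = FALSE)
  names(df) <- c("chrom", "start", "end", "name", "score")[seq_len(ncol(df))]
  df
}

#' Write bin pairs as BEDPE
#'
#' `chrom1 start1 end1 chrom2 start2 end2 name score`, 0-based half-open.
#' @param df Data frame with `chrom`, `bin1`, `bin2` plus optional `name`,
#'   `score` columns.
#' @param genome A `binned_genome` used to convert bins to bp.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(df, genome, path) {
  res <- genome$resolution
  out <- tibble::tibble(
    chrom1 = df$chrom, start1 = df$bin1 * res, end1 = (df$bin1 + 1) * res,
    chrom2 = df$chrom, start2 = df$bin2 * res, end2 = (df$bin2 + 1) * res,
    name = if ("name" %in% names(df)) df$name else ".",
    score = if ("score" %in% names(df)) df$score else "."
  )
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a BEDPE file back to bin pairs
#' @param path BEDPE path.
#' @param genome A `binned_genome`.
#' @return Tibble with `chrom`, `bin1`, `bin2`, `name`, `score`.
#' @export
read_bedpe <- function(path, genome) {
  df <- readr::read_tsv(path, col_names = c("chrom1", "start1", "end1",
                                            "chrom2", "start2", "end2",
                                            "name", "score"),
                        progress = FALSE, show_col_types = FALSE)
  tibble::tibble(chrom = df$chrom1,
                 bin1 = pos_to_bin(genome, df$chrom1, df$start1),
                 bin2 = pos_to_bin(genome, df$chrom2, df$start2),
                 name = df$name, score = df$score)
}

#' Write a per-bin track as bedGraph
#' @param track Data frame with `chrom`, `start`, `end` and a value column.
#' @param path Output path.
#' @param value Name of the value column (default the last column).
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path, value = NULL) {
  if (is.null(value)) value <- names(track)[ncol(track)]
  out <- tibble::tibble(chrom = track$chrom, start = track$start,
                        end = track$end, value = track[[value]])
  out <- out[!is.na(out$value), , drop = FALSE]
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Write the ground-truth record of a simulation to files
#'
#' Emits the same dialects the pipeline itself uses, so truth and calls
#' can be diffed file-to-file: per-condition compartment labels and
#' domains as BED, loops and differential pixels as BEDPE, changed
#' compartment regions as BED, DEG ids as TSV.
#'
#' @param truth A `simulation_truth` (with `deg_ids` if produced by
#'   [simulate_pair()]).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the files written, invisibly.
#' @export
write_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "simulation_truth"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  g <- truth$genome
  res <- g$resolution
  files <- character()
  for (cond in 1:2) {
    comp <- truth$compartments[truth$compartments$condition == cond, ]
    f <- file.path(dir, sprintf("compartments_cond%d.bed", cond))
    write_bed(tibble::tibble(chrom = comp$chrom, start = comp$bin * res,
                             end = pmin((comp$bin + 1) * res, g$lengths[comp$chrom]),
                             name = comp$label), f)
    files[sprintf("compartments_cond%d", cond)] <- f

    dom <- truth$domains[truth$domains$condition == cond, ]
    f <- file.path(dir, sprintf("domains_cond%d.bed", cond))
    write_bed(tibble::tibble(chrom = dom$chrom, start = dom$start_bin * res,
                             end = dom$end_bin * res, name = "domain"), f)
    files[sprintf("domains_cond%d", cond)] <- f

    lp <- truth$loops[truth$loops$condition == cond, ]
    f <- file.path(dir, sprintf("loops_cond%d.bedpe", cond))
    write_bedpe(dplyr::mutate(lp, name = "loop"), g, f)
    files[sprintf("loops_cond%d", cond)] <- f
  }
  f <- file.path(dir, "changed_compartment_regions.bed")
  ccb <- truth$changed_compartment_bins
  regions <- merge_bin_runs(ccb$chrom, ccb$bin, g)
  write_bed(tibble::tibble(chrom = regions$chrom, start = regions$start,
                           end = regions$end, name = "changed-compartment"), f)
  files["changed_compartment_regions"] <- f

  f <- file.path(dir, "differential_pixels.bedpe")
  write_bedpe(dplyr::mutate(truth$differential_pixels, name = "differential"),
              g, f)
  files["differential_pixels"] <- f

  f <- file.path(dir, "degs.tsv")
  readr::write_tsv(tibble::tibble(gene = truth$deg_ids %||% character()), f,
                   progress = FALSE)
  files["degs"] <- f
  invisible(files)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an eigen track as bedGraph plus A/B interval BED
#' @param track An `eigen_track`.
#' @param bedgraph_path,bed_path Output paths.
#' @return Invisibly, the two paths.
#' @export
export_eigen_track <- function(track, bedgraph_path, bed_path) {
  write_bedgraph(track, bedgraph_path, value = "eigen")
  ab <- track[!is.na(track$label), , drop = FALSE]
  write_bed(tibble::tibble(chrom = ab$chrom, start = ab$start, end = ab$end,
                           name = ab$label), bed_path)
  invisible(c(bedgraph_path, bed_path))
}
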