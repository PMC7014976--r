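#' Define a binned genome
#'
#' A binned genome fixes the coordinate system every other object in the
#' package uses: an ordered set of chromosomes, their lengths in bp, and a
#' bin size. Bins are 0-based and half-open; position `p` falls in bin
#' `floor(p / resolution)` and chromosome `c` has `ceiling(length_c /
#' resolution)` bins.
#'
#' @param chroms Character vector of chromosome names (order is kept).
#' @param lengths Numeric vector of chromosome lengths in bp, same order.
#' @param resolution Bin size in bp (> 0).
#'
#' @return An object of class `binned_genome`.
#' @examples
#' gen <- binned_genome(c("chr1", "chr2"), c(1e6, 5e5), 1e4)
#' n_bins(gen)
#' @export
binned_genome <- function(chroms, lengths, resolution) {
  stopifnot(is.character(chroms), length(chroms) >= 1,
            length(lengths) == length(chroms),
            all(lengths > 0), length(resolution) == 1, resolution > 0)
  if (anyDuplicated(chroms)) stop("duplicated chromosome names")
  structure(
    list(
      chroms = chroms,
      lengths = stats::setNames(as.numeric(lengths), chroms),
      resolution = as.numeric(resolution),
      n_bins = stats::setNames(as.integer(ceiling(lengths / resolution)), chroms)
    ),
    class = "binned_genome"
  )
}

#' @export
print.binned_genome <- function(x, ...) {
  cat("<binned_genome> ", length(x$chroms), " chromosome(s), resolution ",
      format(x$resolution, big.mark = ","), " bp, ",
      sum(x$n_bins), " bins total\n", sep = "")
  invisible(x)
}

#' Bins per chromosome
#' @param genome A `binned_genome`.
#' @return Named integer vector of bin counts.
#' @export
n_bins <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  genome$n_bins
}

#' Enumerate the bins of a binned genome as a tibble
#'
#' @param genome A `binned_genome`.
#' @return A tibble with columns `chrom`, `bin` (0-based), `start`, `end` (bp,
#'   half-open; the last bin is clipped to the chromosome length).
#' @export
genome_bins <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  purrr::map_dfr(genome$chroms, function(ch) {
    nb <- genome$n_bins[[ch]]
    bin <- seq_len(nb) - 1L
    tibble::tibble(
      chrom = ch,
      bin = bin,
      start = bin * genome$resolution,
      end = pmin((bin + 1) * genome$resolution, genome$lengths[[ch]])
    )
  })
}

#' Map bp positions to bin indices
#' @param genome A `binned_genome`.
#' @param chrom Chromosome name(s), recycled against `pos`.
#' @param pos 0-based bp position(s).
#' @return Integer bin indices (0-based); NA outside the chromosome.
#' @export
pos_to_bin <- function(genome, chrom, pos) {
  stopifnot(inherits(genome, "binned_genome"))
  bin <- as.integer(floor(pos / genome$resolution))
  nb <- genome$n_bins[chrom]
  bin[is.na(nb) | bin < 0L | bin >= nb] <- NA_integer_
  bin
}

same_genome <- function(g1, g2) {
  identical(g1$chroms, g2$chroms) &&
    isTRUE(all.equal(unname(g1$lengths), unname(g2$lengths))) &&
    g1$resolution == g2$resolution
}

check_same_genome <- function(g1, g2) {
  if (!same_genome(g1, g2)) {
    stop("genomes differ (chromosomes, lengths or resolution); ",
         "objects must share one binned genome", call. = FALSE)
  }
  invisible(TRUE)
}

# save/restore .Random.seed around seeded code so library calls do not
# perturb the caller's RNG stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
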