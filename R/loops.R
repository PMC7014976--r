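#' Call focal chromatin loops with a donut local background
#'
#' For each candidate pixel (O/E at least `min_fold`, separation greater
#' than twice `donut_width` so the donut clears the diagonal, donut fully
#' inside the matrix), the local expected value is the distance-corrected
#' mean O/E over two neighbourhoods: the donut (square of halfwidth
#' `donut_width` minus the central peak box of halfwidth `peak_width`,
#' excluding the candidate's own row and column bands) and the lower-left
#' box (between the pixel and the diagonal), the stricter (larger) of the
#' two taken. The lower-left kernel stops domain corners — where the donut
#' alone spans outside the domain and under-estimates the background —
#' from being called as loops. Significance is a Poisson upper tail on
#' raw-count equivalents (balanced values times the bias product), BH
#' corrected across all tested pixels. Retained pixels must also clear
#' `min_fold` over the local expected and an absolute count floor
#' `min_obs` (low-count pixels can reach extreme Poisson tails through a
#' handful of reads). Adjacent significant pixels are merged, keeping the
#' strongest.
#'
#' @param b A `balanced_matrix`.
#' @param e An `expected_profile` (default: computed from `b`).
#' @param peak_width Peak box halfwidth in bins (default 1).
#' @param donut_width Donut halfwidth in bins (default 5).
#' @param fdr BH threshold (default 0.05).
#' @param min_sep Minimum anchor separation in bins (default 2; the
#'   effective floor is `2 * donut_width + 1`).
#' @param min_fold Minimum observed/local-expected fold (default 2).
#' @param min_obs Minimum raw-equivalent observed count (default 15).
#' @return A tibble of class `loop_set` with columns `chrom`, `bin1`,
#'   `bin2`, `observed` (raw-equivalent count), `expected_local`, `fold`,
#'   `p`, `p_adj`; attributes `genome`, `params`.
#' @export
call_loops <- function(b, e = expected_profile(b), peak_width = 1,
                       donut_width = 5, fdr = 0.05, min_sep = 2, min_fold = 2,
                       min_obs = 15) {
  stopifnot(inherits(b, "balanced_matrix"))
  g <- b$genome
  oe <- oe_transform(b, e)
  R <- donut_width; pw <- peak_width

  res <- purrr::map_dfr(g$chroms, function(ch) {
    Moe <- oe_dense(oe, ch)
    nb <- nrow(Moe)
    bias <- b$bias[[ch]]
    ech <- e[e$chrom == ch, , drop = FALSE]
    exp_d <- rep(NA_real_, nb)
    exp_d[ech$distance + 1L] <- ech$expected

    Q <- Moe; Q[is.na(Q)] <- 0
    W <- matrix(as.numeric(!is.na(Moe)), nb, nb)
    # summed-area tables, padded with a zero first row/column
    sat <- function(A) {
      P <- matrix(0, nb + 1, nb + 1)
      P[-1, -1] <- apply(apply(A, 2, cumsum), 1, cumsum) |> t()
      P
    }
    PQ <- sat(Q); PW <- sat(W)
    rect <- function(P, r1, r2, c1, c2) {
      P[cbind(r2 + 1, c2 + 1)] - P[cbind(r1, c2 + 1)] -
        P[cbind(r2 + 1, c1)] + P[cbind(r1, c1)]
    }

    # test every eligible pixel so the per-stratum BH correction is over the
    # full family, not a high-O/E preselection
    cand <- which(!is.na(Moe), arr.ind = TRUE)
    if (nrow(cand) == 0) return(NULL)
    i <- cand[, 1]; j <- cand[, 2]
    keep <- (j - i) > max(2 * R, min_sep) & i - R >= 1 & j + R <= nb
    i <- i[keep]; j <- j[keep]
    if (length(i) == 0) return(NULL)

    region <- function(P) {
      sq_R <- rect(P, i - R, i + R, j - R, j + R)
      sq_p <- rect(P, i - pw, i + pw, j - pw, j + pw)
      row_band <- rect(P, i, i, j - R, j + R) - rect(P, i, i, j - pw, j + pw)
      col_band <- rect(P, i - R, i + R, j, j) - rect(P, i - pw, i + pw, j, j)
      donut <- sq_R - sq_p - row_band - col_band
      lleft <- rect(P, i + pw, i + R, j - R, j - pw) -
        rect(P, i + pw, i + pw, j - pw, j - pw)
      list(donut = donut, lleft = lleft)
    }
    q <- region(PQ); w <- region(PW)
    donut_rel <- ifelse(w$donut >= 4, q$donut / w$donut, NA_real_)
    lleft_rel <- ifelse(w$lleft >= 4, q$lleft / w$lleft, NA_real_)
    local_rel <- pmax(donut_rel, lleft_rel, na.rm = TRUE)
    local_rel[is.na(donut_rel) & is.na(lleft_rel)] <- NA_real_

    d0 <- j - i
    e0 <- exp_d[d0 + 1L]
    bb <- bias[i] * bias[j]
    lambda_raw <- local_rel * e0 * bb
    obs_raw <- Moe[cbind(i, j)] * e0 * bb
    ok <- is.finite(lambda_raw) & lambda_raw > 0 & is.finite(obs_raw)
    if (!any(ok)) return(NULL)
    tibble::tibble(chrom = ch, bin1 = i[ok] - 1L, bin2 = j[ok] - 1L,
                   observed = obs_raw[ok], expected_local = lambda_raw[ok],
                   fold = obs_raw[ok] / lambda_raw[ok], distance = d0[ok],
                   p = stats::ppois(ceiling(obs_raw[ok]) - 1, lambda_raw[ok],
                                    lower.tail = FALSE))
  })

  if (is.null(res) || nrow(res) == 0) {
    res <- tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                          observed = numeric(), expected_local = numeric(),
                          fold = numeric(), distance = integer(),
                          p = numeric(), p_adj = numeric())
  } else {
    res <- res |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::filter(.data$p_adj <= fdr, .data$fold >= min_fold,
                    .data$observed >= min_obs) |>
      dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
    res <- merge_adjacent_loops(res)
  }
  res$distance <- NULL
  structure(res, class = c("loop_set", class(tibble::tibble())),
            genome = g,
            params = list(peak_width = peak_width, donut_width = donut_width,
                          fdr = fdr, min_sep = min_sep, min_fold = min_fold,
                          min_obs = min_obs))
}

# cluster significant pixels within Chebyshev distance 1 and keep the
# strongest (max observed) pixel of each cluster
merge_adjacent_loops <- function(px) {
  if (nrow(px) <= 1) return(px)
  keep <- rep(TRUE, nrow(px))
  comp <- seq_len(nrow(px))
  for (a in seq_len(nrow(px) - 1)) {
    for (z in (a + 1):nrow(px)) {
      if (px$chrom[a] == px$chrom[z] &&
          abs(px$bin1[a] - px$bin1[z]) <= 1 && abs(px$bin2[a] - px$bin2[z]) <= 1) {
        comp[comp == comp[z]] <- comp[a]
      }
    }
  }
  px |>
    dplyr::mutate(.comp = comp) |>
    dplyr::group_by(.data$.comp) |>
    dplyr::slice_max(.data$observed, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::select(-".comp") |>
    dplyr::arrange(.data$chrom, .data$bin1, .data$bin2)
}

#' Construct a loop set from bin pairs
#' @param loops Data frame with `chrom`, `bin1`, `bin2`; extra columns kept.
#' @param genome A `binned_genome`.
#' @param params Optional parameter list.
#' @return A tibble of class `loop_set`.
#' @export
loop_set <- function(loops, genome, params = list()) {
  loops <- tibble::as_tibble(loops)
  structure(loops, class = c("loop_set", class(tibble::tibble())),
            genome = genome, params = params)
}

#' Aggregate peak analysis (APA)
#'
#' Averages the O/E submatrices of halfwidth `half_window` centred on each
#' loop pixel; the APA score is the centre value divided by the mean of
#' the 3x3 lower-left corner block (short-distance background). Scores
#' near 1 indicate no aggregate enrichment; true loop sets score well
#' above 1.
#'
#' @param oe An `oe_matrix`.
#' @param loops A `loop_set` (or tibble with `chrom`, `bin1`, `bin2`).
#' @param half_window Halfwidth in bins (default 5, an 11x11 aggregate).
#' @return A list of class `apa_result`: `matrix` (aggregate), `score`,
#'   `n_used`, `n_dropped`.
#' @export
apa <- function(oe, loops, half_window = 5) {
  stopifnot(inherits(oe, "oe_matrix"))
  g <- attr(oe, "genome")
  k <- as.integer(half_window)
  agg <- matrix(0, 2 * k + 1, 2 * k + 1)
  cnt <- matrix(0, 2 * k + 1, 2 * k + 1)
  used <- 0L; dropped <- 0L
  for (ch in unique(loops$chrom)) {
    M <- oe_dense(oe, ch)
    nb <- nrow(M)
    lp <- loops[loops$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(lp))) {
      i <- lp$bin1[r] + 1L; j <- lp$bin2[r] + 1L
      if (i - k < 1 || j + k > nb || i + k > nb || j - k < 1 || (j - i) <= 2 * k) {
        dropped <- dropped + 1L
        next
      }
      sub <- M[(i - k):(i + k), (j - k):(j + k)]
      ok <- !is.na(sub)
      agg[ok] <- agg[ok] + sub[ok]
      cnt[ok] <- cnt[ok] + 1
      used <- used + 1L
    }
  }
  if (used == 0) stop("no usable loop pixel after edge/diagonal filtering")
  mat <- agg / cnt
  mat[cnt == 0] <- NA_real_
  centre <- mat[k + 1, k + 1]
  corner <- mat[(2 * k - 1):(2 * k + 1), 1:3]
  score <- centre / mean(corner, na.rm = TRUE)
  structure(list(matrix = mat, score = score, n_used = used, n_dropped = dropped,
                 half_window = k),
            class = "apa_result")
}

#' @export
print.apa_result <- function(x, ...) {
  cat(sprintf("<apa_result> score %.3f over %d loop pixel(s) (%d dropped)\n",
              x$score, x$n_used, x$n_dropped))
  invisible(x)
}

#' @export
glance.apa_result <- function(x, ...) {
  tibble::tibble(score = x$score, n_used = x$n_used, n_dropped = x$n_dropped)
}

#' Compare two loop sets
#'
#' Greedy one-to-one matching: two loops match when both anchors are
#' within `tol` bins, nearest pairs first.
#'
#' @param l1,l2 `loop_set` objects on the same genome.
#' @param tol Anchor tolerance in bins (default 1).
#' @return A list of class `loop_comparison`: `common` (matched pairs with
#'   coordinates from both sets), `specific1`, `specific2`.
#' @export
compare_loops <- function(l1, l2, tol = 1) {
  g <- attr(l1, "genome")
  if (!is.null(attr(l2, "genome"))) check_same_genome(g, attr(l2, "genome"))
  matches <- tibble::tibble(i = integer(), j = integer())
  if (nrow(l1) > 0 && nrow(l2) > 0) {
    cand <- tidyr::crossing(i = seq_len(nrow(l1)), j = seq_len(nrow(l2))) |>
      dplyr::filter(l1$chrom[.data$i] == l2$chrom[.data$j]) |>
      dplyr::mutate(d1 = abs(l1$bin1[.data$i] - l2$bin1[.data$j]),
                    d2 = abs(l1$bin2[.data$i] - l2$bin2[.data$j])) |>
      dplyr::filter(.data$d1 <= tol, .data$d2 <= tol) |>
      dplyr::arrange(.data$d1 + .data$d2)
    used_i <- logical(nrow(l1)); used_j <- logical(nrow(l2))
    for (r in seq_len(nrow(cand))) {
      i <- cand$i[r]; j <- cand$j[r]
      if (used_i[i] || used_j[j]) next
      used_i[i] <- TRUE; used_j[j] <- TRUE
      matches <- dplyr::bind_rows(matches, tibble::tibble(i = i, j = j))
    }
  }
  common <- if (nrow(matches) > 0) {
    dplyr::bind_cols(
      tibble::as_tibble(l1)[matches$i, c("chrom", "bin1", "bin2")],
      stats::setNames(tibble::as_tibble(l2)[matches$j, c("bin1", "bin2")],
                      c("bin1_2", "bin2_2"))
    )
  } else {
    tibble::tibble(chrom = character(), bin1 = integer(), bin2 = integer(),
                   bin1_2 = integer(), bin2_2 = integer())
  }
  structure(list(
    common = common,
    specific1 = if (nrow(l1) > 0) tibble::as_tibble(l1)[setdiff(seq_len(nrow(l1)), matches$i), ] else tibble::as_tibble(l1),
    specific2 = if (nrow(l2) > 0) tibble::as_tibble(l2)[setdiff(seq_len(nrow(l2)), matches$j), ] else tibble::as_tibble(l2),
    tol = tol
  ), class = "loop_comparison")
}

#' @export
print.loop_comparison <- function(x, ...) {
  cat("<loop_comparison> ", nrow(x$common), " common, ",
      nrow(x$specific1), " specific to set 1, ",
      nrow(x$specific2), " specific to set 2 (tol ", x$tol, " bins)\n", sep = "")
  invisible(x)
}
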