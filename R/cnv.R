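#' Ratio of two windowed depth profiles
#'
#' Both profiles are median-normalized genome-wide before dividing, which
#' removes library-size differences. Windows where the normalized reference
#' depth is zero yield `NA`.
#'
#' @param test,reference Depth tibbles (chrom, start, end, depth) on an
#'   identical window grid.
#' @return The grid with a `ratio` column.
#' @export
depth_ratio <- function(test, reference) {
  same_grid <- nrow(test) == nrow(reference) &&
    all(test$chrom == reference$chrom) &&
    all(test$start == reference$start) && all(test$end == reference$end)
  if (!same_grid) stop("window grids differ", call. = FALSE)
  t_norm <- test$depth / stats::median(test$depth)
  r_norm <- reference$depth / stats::median(reference$depth)
  out <- tibble::as_tibble(test[, c("chrom", "start", "end")])
  out$ratio <- ifelse(r_norm > 0, t_norm / r_norm, NA_real_)
  out
}

#' Segment a depth-ratio track into copy-number calls
#'
#' Maximal runs of at least `min_windows` consecutive windows with ratio
#' above `gain_threshold` (duplication) or below `loss_threshold`
#' (deletion) merge into one call, bounded by the first and last qualifying
#' window. Missing-ratio windows never qualify.
#'
#' @param ratio_track Output of [depth_ratio()].
#' @param gain_threshold Duplication threshold (default 1.5).
#' @param loss_threshold Deletion threshold (default 0.75).
#' @param min_windows Minimum run length (default 3).
#' @return A tibble of calls: chrom, start, end, n_windows, mean_ratio,
#'   call (`duplication`/`deletion`).
#' @export
segment_cnv <- function(ratio_track, gain_threshold = 1.5,
                        loss_threshold = 0.75, min_windows = 3L) {
  calls <- list()
  for (ch in unique(ratio_track$chrom)) {
    tr <- ratio_track[ratio_track$chrom == ch, , drop = FALSE]
    state <- dplyr::case_when(
      is.na(tr$ratio) ~ "none",
      tr$ratio > gain_threshold ~ "duplication",
      tr$ratio < loss_threshold ~ "deletion",
      TRUE ~ "none"
    )
    r <- rle(state)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values != "none" & r$lengths >= min_windows
    for (i in which(keep)) {
      w <- starts[i]:ends[i]
      calls[[length(calls) + 1L]] <- tibble::tibble(
        chrom = ch, start = tr$start[starts[i]], end = tr$end[ends[i]],
        n_windows = length(w), mean_ratio = mean(tr$ratio[w]),
        call = r$values[i]
      )
    }
  }
  if (!length(calls)) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_windows = integer(),
                          mean_ratio = numeric(), call = character()))
  }
  dplyr::bind_rows(calls)
}

#' Assess whether a CNV call segregates as causal in the selected pool
#'
#' A clone CNV inherited heterozygously in the backcross and segregating
#' neutrally is carried by half the selected spores, so its expected pool
#' copy ratio is (clone_ratio + 1) / 2 -- a 2x clone duplication shows only
#' a 50% pool increase. A CNV retained by selection keeps the clone ratio
#' in the pool. The decision picks whichever expectation is closer to the
#' observed pool ratio.
#'
#' @param calls Calls from [segment_cnv()] on the clone/ancestor ratio.
#' @param pool_ratio_track [depth_ratio()] of pool vs ancestor, on the same
#'   grid the calls were made from.
#' @return The calls with `pool_ratio` and `causality`
#'   (`non_causal`/`possibly_causal`) appended.
#' @export
assess_causality <- function(calls, pool_ratio_track) {
  if (nrow(calls) == 0L) stop("no CNV calls to assess", call. = FALSE)
  pool_ratio <- vapply(seq_len(nrow(calls)), function(i) {
    sel <- pool_ratio_track$chrom == calls$chrom[i] &
      pool_ratio_track$start >= calls$start[i] &
      pool_ratio_track$end <= calls$end[i]
    mean(pool_ratio_track$ratio[sel], na.rm = TRUE)
  }, numeric(1))
  out <- tibble::as_tibble(calls)
  out$pool_ratio <- pool_ratio
  neutral_expect <- (out$mean_ratio + 1) / 2
  out$causality <- ifelse(
    abs(out$pool_ratio - neutral_expect) <=
      abs(out$pool_ratio - out$mean_ratio),
    "non_causal", "possibly_causal"
  )
  out
}
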