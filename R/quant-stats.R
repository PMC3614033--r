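#' Adjusted-Wald (Agresti-Coull style) binomial confidence interval
#'
#' Adds two successes and two failures before applying the Wald formula:
#' p~ = (x + 2) / (n + 4), half-width z * sqrt(p~ (1 - p~) / (n + 4)),
#' bounds clipped to [0, 1]. z is fixed at 1.96 for the default 95% level;
#' other levels use exact normal quantiles.
#'
#' @param successes,trials Binomial counts (trials > 0).
#' @param confidence Confidence level (default 0.95).
#' @return A tibble with estimate, lower, upper.
#' @export
#' @examples
#' adjusted_wald_ci(24, 24)
adjusted_wald_ci <- function(successes, trials, confidence = 0.95) {
  stopifnot(all(trials > 0), all(successes >= 0), all(successes <= trials))
  z <- if (isTRUE(all.equal(confidence, 0.95))) 1.96
       else stats::qnorm(1 - (1 - confidence) / 2)
  p_adj <- (successes + 2) / (trials + 4)
  half <- z * sqrt(p_adj * (1 - p_adj) / (trials + 4))
  tibble::tibble(
    estimate = successes / trials,
    lower = pmax(0, p_adj - half),
    upper = pmin(1, p_adj + half)
  )
}

#' Relative expression fold change by the delta-delta-Ct method
#'
#' Fold change = 2^-((Ct_target,test - Ct_ref,test) -
#' (Ct_target,ctrl - Ct_ref,ctrl)).
#'
#' @param ct_target_test,ct_ref_test Target and reference-gene cycle
#'   thresholds in the test sample.
#' @param ct_target_ctrl,ct_ref_ctrl Same in the control sample.
#' @return Fold change (1 = no change).
#' @export
#' @examples
#' ddct_fold_change(20, 15, 23, 15)   # 8-fold up
ddct_fold_change <- function(ct_target_test, ct_ref_test,
                             ct_target_ctrl, ct_ref_ctrl) {
  ddct <- (ct_target_test - ct_ref_test) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}

#' Generations implied by serial-dilution passages
#'
#' Each growth cycle regrows a dilution back to saturation, so one factor-F
#' dilution costs log2(F) doublings. The standard spore-selection protocol
#' (one 100:1 dilution plus three 500:1 dilutions) gives ~34 generations;
#' six 200:1 passages give 46.
#'
#' @param dilution_factors Positive factors, each > 1.
#' @return A list with `total` (exact sum of log2 factors) and `rounded`.
#' @export
#' @examples
#' generations_from_dilutions(c(100, 500, 500, 500))
generations_from_dilutions <- function(dilution_factors) {
  if (any(dilution_factors <= 1)) {
    stop("dilution factors must exceed 1", call. = FALSE)
  }
  total <- sum(log2(dilution_factors))
  list(total = total, rounded = as.integer(round(total)))
}

#' Score a pairwise competition qualitatively
#'
#' Maps replicate outcomes to the symbols ++++ ... ----. Elimination
#' (zero cells of one strain with more than 30 of the other) in a mean of
#' 1-2 cycles scores ++++, 3-4 +++, 5-6 ++ (mirrored with minus signs when
#' strain 2 eliminates strain 1; the mean cycle is rounded half-up before
#' banding). Without elimination, `+` (or `-`) requires one strain to
#' exceed 75% of the population after six cycles in at least two of three
#' replicates; otherwise the competition is a tie, `0`. Replicates with
#' eliminations in both directions trigger a warning and majority rule.
#'
#' @param outcomes Tibble with one row per replicate: `winner` (1, 2, or
#'   NA for none), `cycles_to_elimination` (NA when no elimination), and
#'   `final_majority_fraction` (strain 1's final share, used when no
#'   elimination occurred).
#' @param majority
#'   Fraction one strain must exceed to win a full-length competition
#'   (default 0.75).
#' @return A single string from `++++`, `+++`, `++`, `+`, `0`, `-`, `--`,
#'   `---`, `----`.
#' @export
score_competition <- function(outcomes, majority = 0.75) {
  stopifnot(nrow(outcomes) >= 1L)
  elim <- !is.na(outcomes$cycles_to_elimination)
  if (any(elim)) {
    winners <- outcomes$winner[elim]
    if (dplyr::n_distinct(winners) > 1L) {
      warning("eliminations in both directions; applying majority rule",
              call. = FALSE)
      win <- as.integer(names(which.max(table(winners))))
      keep <- elim & outcomes$winner == win
    } else {
      win <- winners[1L]
      keep <- elim
    }
    mean_cycle <- floor(mean(outcomes$cycles_to_elimination[keep]) + 0.5)
    band <- if (mean_cycle <= 2) 4L else if (mean_cycle <= 4) 3L else 2L
    sym <- strrep(if (win == 1L) "+" else "-", band)
    return(sym)
  }
  frac <- outcomes$final_majority_fraction
  wins1 <- sum(frac > majority, na.rm = TRUE)
  wins2 <- sum(frac < 1 - majority, na.rm = TRUE)
  need <- 2L
  if (wins1 >= need) "+" else if (wins2 >= need) "-" else "0"
}
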