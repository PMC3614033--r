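#' Allele fraction from Sanger trace peak heights
#'
#' The mutant-allele fraction is the mutant peak height divided by the sum
#' of the mutant and ancestral peak heights. In time-course mode
#' (`clamp = TRUE`), values below 5% (the approximate trace background) are
#' set to 0 and values above 95% to 1; exactly 5% or 95% is left unclamped.
#' Segregation mode (`clamp = FALSE`) reports the raw ratio.
#'
#' @param h_mut,h_anc Non-negative peak heights (arbitrary fluorescence
#'   units). A pair that is both zero is uncallable and returns `NA`.
#' @param clamp Apply the 5%/95% background clamp.
#' @return Fractions in [0, 1].
#' @export
#' @examples
#' peak_fraction(30, 970)            # 0 after clamping
#' peak_fraction(30, 970, clamp = FALSE)
peak_fraction <- function(h_mut, h_anc, clamp = TRUE) {
  if (any(h_mut < 0, na.rm = TRUE) || any(h_anc < 0, na.rm = TRUE)) {
    stop("peak heights must be non-negative", call. = FALSE)
  }
  total <- h_mut + h_anc
  f <- ifelse(total > 0, h_mut / total, NA_real_)
  if (clamp) {
    f <- ifelse(!is.na(f) & f < 0.05, 0, f)
    f <- ifelse(!is.na(f) & f > 0.95, 1, f)
  }
  f
}

#' Assemble an allele-frequency time course from trace peak heights
#'
#' Applies [peak_fraction()] in clamp (time-course) mode to every
#' (allele, time point) row. No smoothing or interpolation is applied:
#' missing time points stay missing and raw estimates are reported.
#'
#' @param series Tibble with columns allele, time_point, h_mut, h_anc.
#' @return A tibble with allele, time_point, frequency.
#' @export
build_timecourse <- function(series) {
  stopifnot(all(c("allele", "time_point", "h_mut", "h_anc") %in%
                  names(series)))
  tibble::tibble(
    allele = series$allele,
    time_point = series$time_point,
    frequency = peak_fraction(series$h_mut, series$h_anc, clamp = TRUE)
  ) |>
    dplyr::arrange(.data$allele, .data$time_point)
}
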