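# Tabular assay computations: SOCE normalization, DNA-content
# normalization, XBP1 splicing ratio.

#' Normalized maximal SOCE response
#'
#' Normalizes a calcium re-addition trace to its pre-readdition baseline:
#' `F0` is the mean fluorescence over the `baseline_window_s` seconds
#' immediately preceding Ca2+ re-addition, and the statistic is the maximum
#' post-readdition fluorescence divided by `F0` (the `F/F0` form; the
#' `dFF0` option returns `(Fmax - F0)/F0` instead).
#'
#' @param trace A [soce_trace()] with a `readdition` phase mark.
#' @param baseline_window_s Baseline window length in s before re-addition
#'   (default 60).
#' @param form `"F/F0"` (default) or `"dFF0"`.
#' @param smooth Apply a 3-point running median to the post-readdition
#'   samples before taking the maximum (default `FALSE`).
#'
#' @return A one-row tibble: `F0`, `F_max`, `normalized_max`, `form`,
#'   `baseline_window_s`.
#' @export
soce_normalized_max <- function(trace, baseline_window_s = 60,
                                form = c("F/F0", "dFF0"), smooth = FALSE) {
  form <- match.arg(form)
  stopifnot(inherits(trace, "soce_trace"))
  check_scalar_number(baseline_window_s, "baseline_window_s", min = 0,
                      strict_min = TRUE)
  readd <- attr(trace, "phase_marks")[["readdition"]]
  base_idx <- trace$time_s >= readd - baseline_window_s & trace$time_s < readd
  if (!any(base_idx)) stop_domain("baseline window contains no samples")
  f0 <- mean(trace$F[base_idx])
  if (f0 <= 0) stop_domain("baseline F0 must be positive")
  post <- trace$F[trace$time_s >= readd]
  if (length(post) == 0) stop_domain("no samples after Ca2+ re-addition")
  if (smooth && length(post) >= 3) post <- stats::runmed(post, 3)
  fmax <- max(post)
  tibble(
    F0 = f0, F_max = fmax,
    normalized_max = if (form == "F/F0") fmax / f0 else (fmax - f0) / f0,
    form = form, baseline_window_s = baseline_window_s
  )
}

#' Normalize assay readouts by DNA content
#'
#' Elementwise `value / dna`, the standard normalization for oxygen
#' consumption (OCR), extracellular acidification (ECAR) and ATP readouts
#' from 3D constructs of unequal cellularity.
#'
#' @param data Data frame with one row per sample.
#' @param value Column of raw readouts (tidy-eval).
#' @param dna Column of DNA amounts, all positive (tidy-eval).
#' @param name Name of the added column (default `"normalized"`).
#'
#' @return The input tibble with the normalized column appended.
#' @export
normalize_by_dna <- function(data, value, dna, name = "normalized") {
  if (!is.data.frame(data)) stop_domain("`data` must be a data frame")
  d <- dplyr::pull(data, {{ dna }})
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop_domain("DNA amounts must be positive")
  }
  dplyr::mutate(as_tibble(data), "{name}" := {{ value }} / {{ dna }})
}

#' XBP1 splicing ratio
#'
#' Fraction of spliced XBP1 over total XBP1, where total is defined as
#' unspliced plus spliced band intensity: `s / (u + s)`. Vectorized.
#'
#' @param u Unspliced band intensity (a.u., >= 0; the 205 bp product).
#' @param s Spliced band intensity (a.u., >= 0; the 179 bp product).
#'
#' @return Numeric ratio(s) in `[0, 1]`.
#' @export
xbp1_splicing_ratio <- function(u, s) {
  if (length(u) != length(s)) stop_domain("`u` and `s` lengths differ")
  if (any(u < 0) || any(s < 0)) stop_domain("band intensities must be >= 0")
  if (any(u + s <= 0)) stop_domain("u + s must be positive")
  s / (u + s)
}
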