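# Colocalization and ER-on-mitochondria distribution mapping.

threshold_level <- function(x, method = c("otsu", "fixed", "zero"),
                            fixed = NULL) {
  method <- match.arg(method)
  switch(method,
    zero = 0,
    fixed = {
      if (is.null(fixed)) stop_config("fixed threshold requested without a level")
      fixed
    },
    otsu = {
      mx <- max(x)
      if (mx <= 0) stop_domain("cannot threshold an all-zero channel")
      # flatten so stacks get one global threshold, not one per slice
      flat <- matrix(as.vector(x) / mx, ncol = 1)
      as.numeric(EBImage::otsu(EBImage::Image(flat), range = c(0, 1),
                               levels = 256)) * mx
    }
  )
}

#' Thresholded Manders colocalization coefficients
#'
#' `M1` is the fraction of channel-1 signal that lies over the thresholded
#' channel-2 mask (`sum(ch1[ch2 > t2]) / sum(ch1)`); `M2` is defined
#' symmetrically. The thresholded form is used: each channel's mask comes
#' from its own threshold (`otsu` by default; `zero` reproduces the classic
#' unthresholded coefficients on non-negative images).
#'
#' @param ch1,ch2 Numeric arrays of equal shape with non-negative
#'   intensities.
#' @param threshold_method `"otsu"` (default), `"fixed"` or `"zero"`.
#' @param thresholds Numeric length-2 `(t1, t2)` when
#'   `threshold_method = "fixed"`.
#'
#' @return A one-row tibble: `M1`, `M2`, `threshold_method`, `threshold1`,
#'   `threshold2`.
#' @export
manders <- function(ch1, ch2, threshold_method = c("otsu", "fixed", "zero"),
                    thresholds = NULL) {
  threshold_method <- match.arg(threshold_method)
  if (!identical(dim(ch1), dim(ch2))) stop_domain("channel shapes differ")
  if (any(ch1 < 0) || any(ch2 < 0)) stop_domain("intensities must be >= 0")
  if (sum(ch1) == 0 || sum(ch2) == 0) {
    stop_domain("cannot compute Manders coefficients on an all-zero channel")
  }
  t1 <- threshold_level(ch1, threshold_method, thresholds[1])
  t2 <- threshold_level(ch2, threshold_method, thresholds[2])
  tibble(
    M1 = sum(ch1[ch2 > t2]) / sum(ch1),
    M2 = sum(ch2[ch1 > t1]) / sum(ch2),
    threshold_method = threshold_method,
    threshold1 = t1,
    threshold2 = t2
  )
}

#' Map normalized ER signal onto the mitochondrial mask
#'
#' Segments mitochondria by thresholding the mitochondria channel,
#' normalizes the ER channel to its per-image maximum, and maps the
#' normalized ER intensity onto the mitochondrial mask. The summary
#' statistic is the mean normalized ER intensity over the mask, in
#' `[0, 1]`.
#'
#' @param er_image,mito_image Numeric arrays of equal shape.
#' @param mito_threshold_method Threshold method for the mitochondria
#'   channel (`"otsu"`, `"fixed"`, `"zero"`).
#' @param mito_threshold Fixed level when requested.
#'
#' @return An object of class `er_mito_map`: `map` (normalized ER intensity,
#'   `NA` off the mask), `mito_mask`, `mito_threshold`,
#'   `mean_normalized_er_on_mito`.
#' @export
er_on_mito_map <- function(er_image, mito_image,
                           mito_threshold_method = c("otsu", "fixed", "zero"),
                           mito_threshold = NULL) {
  mito_threshold_method <- match.arg(mito_threshold_method)
  if (!identical(dim(er_image), dim(mito_image))) {
    stop_domain("channel shapes differ")
  }
  t_mito <- threshold_level(mito_image, mito_threshold_method, mito_threshold)
  mask <- mito_image > t_mito
  if (!any(mask)) {
    abort("empty mitochondria mask after thresholding",
          class = "ermechquant_segmentation_error")
  }
  er_max <- max(er_image)
  if (er_max <= 0) stop_domain("ER channel is all zero")
  norm <- er_image / er_max
  map <- norm
  map[!mask] <- NA_real_
  structure(
    list(map = map, mito_mask = mask, mito_threshold = t_mito,
         mean_normalized_er_on_mito = mean(norm[mask])),
    class = "er_mito_map"
  )
}

#' @export
print.er_mito_map <- function(x, ...) {
  cat("<er_mito_map> ", sum(x$mito_mask), " mitochondrial px; mean ",
      "normalized ER on mitochondria = ",
      signif(x$mean_normalized_er_on_mito, 4), "\n", sep = "")
  invisible(x)
}
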