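# F-actin organization: long-axis alignment, structure-tensor orientation,
# axial dispersion and intensity density.
#
# Angle convention throughout: 0 degrees is vertical (along image rows),
# 90 degrees is horizontal. Orientations are axial (180-degree periodic);
# statistics use the angle-doubling transform.

#' Rotate an image so the cell's long axis is vertical
#'
#' Computes the principal axis of the cell mask from its second moments and
#' rotates image and mask together so that axis becomes vertical. Nearly
#' isotropic masks (axis ratio below `min_axis_ratio`) have no meaningful
#' long axis and raise a degeneracy error asking for a manual angle.
#'
#' @param image Numeric matrix (single channel).
#' @param cell_mask Non-empty logical mask, same shape.
#' @param min_axis_ratio Minimum major/minor axis ratio (default 1.05).
#'
#' @return A list with `image` (rotated), `mask` (rotated, logical) and
#'   `rotation_angle_deg` (the angle the long axis made with vertical).
#' @export
align_long_axis <- function(image, cell_mask, min_axis_ratio = 1.05) {
  check_matrix(image, "image")
  cell_mask <- check_mask(cell_mask, "cell_mask", dim(image))
  if (!any(cell_mask)) stop_domain("cell mask is empty")
  ax <- mask_principal_axis(cell_mask)
  if (ax$axis_ratio < min_axis_ratio) {
    abort(sprintf(paste0(
      "cell mask is nearly isotropic (axis ratio %.3f < %.2f); ",
      "supply a rotation angle manually"), ax$axis_ratio, min_axis_ratio),
      class = "ermechquant_degeneracy_error")
  }
  angle <- ax$angle_deg
  if (angle > 90) angle <- angle - 180  # rotate by the smaller magnitude
  rot_img <- as.matrix(EBImage::rotate(EBImage::Image(image), -angle,
                                       bg.col = 0))
  rot_mask <- as.matrix(EBImage::rotate(EBImage::Image(cell_mask * 1), -angle,
                                        bg.col = 0)) > 0.5
  list(image = rot_img, mask = rot_mask, rotation_angle_deg = angle)
}

#' Per-pixel fiber orientation from the structure tensor
#'
#' Estimates local axial orientation from the eigenstructure of the
#' Gaussian-smoothed structure tensor (the smoothed outer product of the
#' image gradients). Returns, per pixel, the axial angle relative to
#' vertical and a coherence score in `[0, 1]` (eigenvalue contrast; 1 for
#' perfectly oriented texture, 0 for isotropic).
#'
#' @param image Numeric matrix.
#' @param mask Non-empty logical mask of pixels to analyze.
#' @param tensor_sigma Gaussian smoothing of the tensor components, px
#'   (default 2).
#' @param gradient_sigma Gaussian pre-smoothing before differentiation, px.
#'
#' @return An object of class `orientation_field` with fields `angle_image`
#'   (degrees in `[0, 90]`, the folded display convention; `NA` outside the
#'   mask), `axial_image` (degrees in `[0, 180)`, used for circular
#'   statistics), `coherence_image`, `intensity_image`, `mask`,
#'   `tensor_sigma`.
#' @export
orientation_field <- function(image, mask = NULL, tensor_sigma = 2,
                              gradient_sigma = 1) {
  check_matrix(image, "image")
  if (is.null(mask)) mask <- matrix(TRUE, nrow(image), ncol(image))
  mask <- check_mask(mask, "mask", dim(image))
  if (!any(mask)) stop_domain("mask is empty")
  if (!is.numeric(tensor_sigma) || tensor_sigma <= 0) {
    stop_config("`tensor_sigma` must be positive")
  }

  sm <- if (gradient_sigma > 0) {
    as.matrix(EBImage::gblur(EBImage::Image(image), sigma = gradient_sigma))
  } else {
    image
  }
  nr <- nrow(sm); nc <- ncol(sm)
  # central differences along rows (gy) and columns (gx)
  gy <- (rbind(sm[-1, ], sm[nr, ]) - rbind(sm[1, ], sm[-nr, ])) / 2
  gx <- (cbind(sm[, -1], sm[, nc]) - cbind(sm[, 1], sm[, -nc])) / 2

  blur <- function(m) as.matrix(EBImage::gblur(EBImage::Image(m),
                                               sigma = tensor_sigma))
  jxx <- blur(gx * gx); jyy <- blur(gy * gy); jxy <- blur(gx * gy)

  theta_grad <- 0.5 * atan2(2 * jxy, jxx - jyy)   # gradient orientation
  # structure axis angle from vertical, signed toward increasing columns
  axial <- (-rad2deg(theta_grad)) %% 180
  folded <- pmin(axial, 180 - axial)
  tr <- jxx + jyy
  coherence <- ifelse(tr > 1e-12, sqrt((jxx - jyy)^2 + 4 * jxy^2) / tr, 0)
  coherence <- pmin(pmax(coherence, 0), 1)

  axial[!mask] <- NA_real_
  folded[!mask] <- NA_real_
  coherence[!mask] <- NA_real_

  structure(
    list(angle_image = folded, axial_image = axial,
         coherence_image = coherence, intensity_image = image,
         mask = mask, tensor_sigma = tensor_sigma,
         gradient_sigma = gradient_sigma),
    class = "orientation_field"
  )
}

#' @export
print.orientation_field <- function(x, ...) {
  cat("<orientation_field> ", nrow(x$angle_image), " x ", ncol(x$angle_image),
      " px, ", sum(x$mask), " masked px, tensor sigma ", x$tensor_sigma,
      " px\n", sep = "")
  invisible(x)
}

# Weighted axial circular statistics on angles in degrees ([0, 180)).
axial_stats <- function(angles_deg, w = NULL) {
  ok <- is.finite(angles_deg)
  angles_deg <- angles_deg[ok]
  w <- if (is.null(w)) rep(1, length(angles_deg)) else w[ok]
  if (sum(w) <= 0) stop_domain("weights sum to zero")
  a2 <- deg2rad(2 * angles_deg)
  C <- sum(w * cos(a2)) / sum(w)
  S <- sum(w * sin(a2)) / sum(w)
  R <- sqrt(C^2 + S^2)
  list(
    mean_deg = (rad2deg(atan2(S, C)) / 2) %% 180,
    R = R,
    circular_variance = 1 - R,
    # angular deviation of the doubled angles, halved back to the axial
    # scale; 0 for parallel data, sqrt(2)/2 rad (~40.51 deg) for uniform
    dispersion_deg = rad2deg(sqrt(2 * (1 - R)) / 2),
    n = length(angles_deg)
  )
}

#' Orientation dispersion of a fiber field
#'
#' Circular spread of the axial orientation distribution, computed on
#' doubled angles (axial statistics). The score is the angular deviation
#' `sqrt(2 * (1 - R))` of the doubled angles, halved back to the axial
#' scale and reported in degrees: 0 for perfectly parallel fibers, rising
#' to the closed-form maximum `sqrt(2)/2` rad (about 40.51 degrees) for a
#' uniform axial distribution (mean resultant length `R = 0`).
#'
#' @param x An [orientation_field()] or a numeric vector of axial angles in
#'   degrees.
#' @param mask Optional logical mask restricting the field.
#' @param weighting `"coherence"` (default for fields), `"intensity"` or
#'   `"none"`.
#' @param min_pixels Minimum number of contributing pixels (default 100).
#'
#' @return A one-row tibble: `dispersion_deg`, `circular_variance`,
#'   `mean_resultant`, `mean_angle_deg`, `n`, `weighting`.
#' @export
fiber_dispersion <- function(x, mask = NULL,
                             weighting = c("coherence", "intensity", "none"),
                             min_pixels = 100) {
  weighting <- match.arg(weighting)
  if (inherits(x, "orientation_field")) {
    m <- x$mask & is.finite(x$axial_image)
    if (!is.null(mask)) m <- m & check_mask(mask, "mask", dim(x$mask))
    if (sum(m) < min_pixels) {
      stop_domain(sprintf("fewer than %d masked pixels", min_pixels))
    }
    angles <- x$axial_image[m]
    w <- switch(weighting,
      coherence = x$coherence_image[m],
      intensity = x$intensity_image[m],
      none = rep(1, sum(m))
    )
    if (weighting == "intensity" && all(w == 0)) {
      stop_domain("intensity weighting requested but all intensities are zero")
    }
  } else {
    angles <- as.numeric(x)
    if (length(angles) == 0) stop_domain("no angles supplied")
    w <- rep(1, length(angles))
    weighting <- "none"
  }
  st <- axial_stats(angles, w)
  tibble(
    dispersion_deg = st$dispersion_deg,
    circular_variance = st$circular_variance,
    mean_resultant = st$R,
    mean_angle_deg = st$mean_deg,
    n = st$n,
    weighting = weighting
  )
}

#' Fluorescence intensity density over a cell mask
#'
#' Total masked intensity divided by the masked pixel count (a.u. per px),
#' also reported per square micrometre when a pixel size is supplied.
#'
#' @param image Numeric matrix or [cell_image()].
#' @param cell_mask Non-empty logical mask.
#' @param pixel_size_nm Pixel size in nm (taken from the [cell_image()] when
#'   available).
#' @param channel Channel name for [cell_image()] inputs.
#'
#' @return A one-row tibble: `mean_intensity_per_px`, `intensity_per_um2`,
#'   `n_pixels`.
#' @export
intensity_density <- function(image, cell_mask, pixel_size_nm = NA_real_,
                              channel = NULL) {
  if (inherits(image, "cell_image") && is.na(pixel_size_nm)) {
    pixel_size_nm <- image$pixel_size_nm
  }
  m <- extract_channel(image, channel)
  cell_mask <- check_mask(cell_mask, "cell_mask", dim(m))
  n <- sum(cell_mask)
  if (n == 0) stop_domain("cell mask is empty")
  per_px <- sum(m[cell_mask]) / n
  tibble(
    mean_intensity_per_px = per_px,
    intensity_per_um2 = if (is.na(pixel_size_nm)) NA_real_ else
      per_px / (pixel_size_nm / 1000)^2,
    n_pixels = n
  )
}
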