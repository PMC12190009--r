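# ER sheet/tubule segmentation and radial sheet-percentage morphometry.

#' Construct an ER segmentation from a label image
#'
#' Wraps an existing per-pixel labeling (0 = background, 1 = tubule,
#' 2 = sheet) in the container returned by [segment_er()], e.g. to profile
#' ground-truth label masks.
#'
#' @param label_image Integer matrix of labels in `{0, 1, 2}`.
#' @param threshold_er,threshold_sheet 8-bit threshold levels (default `NA`);
#'   `threshold_sheet` must be at least `threshold_er` when both are given.
#' @param pixel_size_nm Pixel size in nm.
#'
#' @return An object of class `er_segmentation`.
#' @export
er_segmentation <- function(label_image, threshold_er = NA_integer_,
                            threshold_sheet = NA_integer_,
                            pixel_size_nm = NA_real_) {
  if (!is.matrix(label_image) || !all(label_image %in% 0:2)) {
    stop_domain("`label_image` must be a matrix of labels in {0, 1, 2}")
  }
  if (!is.na(threshold_er) && !is.na(threshold_sheet) &&
      threshold_sheet < threshold_er) {
    stop_domain("`threshold_sheet` must be >= `threshold_er`")
  }
  structure(
    list(label_image = matrix(as.integer(label_image), nrow(label_image)),
         threshold_er = as.integer(threshold_er),
         threshold_sheet = as.integer(threshold_sheet),
         strategy = "external", mode = NA_character_,
         width_cutoff_px = NA_real_, pixel_size_nm = pixel_size_nm),
    class = "er_segmentation"
  )
}

# Principal axis of a binary mask from second moments. Returns the axis
# angle in degrees from vertical (folded to [0, 180)) and the axis ratio.
mask_principal_axis <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3L) stop_domain("mask has too few pixels for an axis")
  cv <- stats::cov(idx)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]  # (row, col) components of the major axis
  angle <- rad2deg(atan2(v[2], v[1])) %% 180
  ratio <- sqrt(max(eg$values[1], 1e-12) / max(eg$values[2], 1e-12))
  list(angle_deg = angle, axis_ratio = ratio,
       centroid = colMeans(idx))
}

extract_channel <- function(image, channel = NULL) {
  if (inherits(image, "cell_image")) {
    ch <- channel %||% image$channel_names[1]
    m <- image$channels[[ch]]
    if (is.null(m)) stop_domain(sprintf("no channel '%s' in image", ch))
    m
  } else {
    image
  }
}

#' Segment ER into background, tubules and sheets
#'
#' Two-stage segmentation of a single-channel ER image. A first
#' Renyi-entropy threshold separates ER signal from background. Sheets are
#' then separated from tubules either by a second Renyi threshold computed
#' within the ER mask's intensity histogram (`"double_renyi"`, default:
#' sheets image brighter/denser than tubules) or by local structure
#' thickness (`"renyi_plus_thickness"`: ER regions wider than
#' `width_cutoff_px` become sheet).
#'
#' Under `double_renyi` a bimodality guard prevents a unimodal ER intensity
#' distribution (an image with no sheets) from being split in half: if the
#' two intensity classes within the ER mask are separated by less than twice
#' the sum of their within-class spreads, no sheet class is declared.
#'
#' @param image 8-bit single-channel image (matrix of integers 0..255), a
#'   raw intensity matrix (converted via [to_8bit()]), or a [cell_image()].
#' @param strategy `"double_renyi"` (default) or `"renyi_plus_thickness"`.
#' @param mode Renyi threshold mode, see [renyi_threshold()].
#' @param width_cutoff_px Structure-width cutoff for the thickness strategy.
#' @param channel Channel name when `image` is a [cell_image()].
#'
#' @return An object of class `er_segmentation` with fields `label_image`
#'   (0 = background, 1 = tubule, 2 = sheet), `threshold_er`,
#'   `threshold_sheet`, `strategy`, `pixel_size_nm`.
#' @export
segment_er <- function(image, strategy = c("double_renyi",
                                           "renyi_plus_thickness"),
                       mode = "three_alpha_combination",
                       width_cutoff_px = 4, channel = NULL) {
  strategy <- match.arg(strategy)
  pixel_size_nm <- if (inherits(image, "cell_image")) image$pixel_size_nm
                   else NA_real_
  m <- extract_channel(image, channel)
  if (length(dim(m)) != 2L) stop_domain("segment_er expects a 2D image")
  if (any(m != round(m)) || any(m < 0 | m > 255)) m <- to_8bit(m)
  storage.mode(m) <- "integer"

  t_er <- renyi_threshold(m, mode = mode)
  er_mask <- m > t_er
  if (!any(er_mask)) {
    abort("empty ER mask: no pixels above the ER/background threshold",
          class = "ermechquant_segmentation_error")
  }

  if (strategy == "double_renyi") {
    vals <- m[er_mask]
    t_sheet <- if (length(unique(vals)) < 2L) 255L else {
      renyi_threshold(tabulate(vals + 1L, nbins = 256L), mode = mode)
    }
    sheet <- er_mask & m > t_sheet
    if (any(sheet) && any(er_mask & !sheet)) {
      lo <- m[er_mask & !sheet]; hi <- m[sheet]
      spread <- function(x) if (length(x) > 1) sd(x) else 0
      if ((mean(hi) - mean(lo)) < 2 * (spread(lo) + spread(hi))) {
        sheet[] <- FALSE          # unimodal ER intensities: no sheet class
        t_sheet <- 255L
      }
    }
  } else {
    dm <- as.matrix(EBImage::distmap(EBImage::Image(er_mask * 1)))
    seeds <- dm > width_cutoff_px / 2
    if (any(seeds)) {
      brush <- EBImage::makeBrush(2 * ceiling(width_cutoff_px / 2) + 1,
                                  shape = "disc")
      sheet <- as.matrix(EBImage::dilate(EBImage::Image(seeds * 1),
                                         brush)) > 0 & er_mask
    } else {
      sheet <- er_mask & FALSE
    }
    t_sheet <- t_er
  }

  labels <- matrix(0L, nrow(m), ncol(m))
  labels[er_mask] <- 1L
  labels[sheet] <- 2L
  structure(
    list(label_image = labels, threshold_er = as.integer(t_er),
         threshold_sheet = as.integer(t_sheet), strategy = strategy,
         mode = mode, width_cutoff_px = width_cutoff_px,
         pixel_size_nm = pixel_size_nm),
    class = "er_segmentation"
  )
}

#' @export
print.er_segmentation <- function(x, ...) {
  n <- tabulate(x$label_image + 1L, 3L)
  cat("<er_segmentation> ", nrow(x$label_image), " x ", ncol(x$label_image),
      " px; thresholds ER > ", x$threshold_er, ", sheet > ",
      x$threshold_sheet, " (", x$strategy, ")\n",
      "  background ", n[1], " px, tubule ", n[2], " px, sheet ", n[3],
      " px\n", sep = "")
  invisible(x)
}

#' @method tidy er_segmentation
#' @export
tidy.er_segmentation <- function(x, ...) {
  n <- tabulate(x$label_image + 1L, 3L)
  er <- n[2] + n[3]
  tibble(
    class = c("background", "tubule", "sheet"),
    pixels = n,
    fraction_of_er = c(NA, n[2] / er, n[3] / er)
  )
}

#' Sheet percentage along radial line segments
#'
#' Places three wide line segments (rectangles, default width 56 px) running
#' from the nuclear envelope toward the cell periphery and computes, per
#' segment, the percentage of ER pixels that are sheet:
#' `100 * sheet_pixels / er_pixels`.
#'
#' With `directions = "auto"` the segments are placed at 120-degree spacing
#' starting from the cell's long axis; numeric directions (degrees from
#' vertical, clockwise positive toward increasing columns) may be given
#' instead.
#'
#' @param seg An [er_segmentation()].
#' @param nucleus_mask Logical mask of the nucleus (non-empty, interior to
#'   the image).
#' @param cell_mask Optional logical cell mask bounding the segments; the
#'   image edge bounds them otherwise.
#' @param directions `"auto"` or a numeric vector of angles in degrees.
#' @param width Segment width in px (default 56).
#'
#' @return A tibble with one row per segment: `segment_index`, `angle_deg`,
#'   `width_px`, `sheet_pixels`, `er_pixels`, `sheet_percentage` (`NA` with
#'   a warning when a segment contains no ER pixels).
#' @export
sample_line_segments <- function(seg, nucleus_mask, cell_mask = NULL,
                                 directions = "auto", width = 56) {
  stopifnot(inherits(seg, "er_segmentation"))
  labels <- seg$label_image
  nucleus_mask <- check_mask(nucleus_mask, "nucleus_mask", dim(labels))
  if (!any(nucleus_mask)) stop_domain("nucleus mask is empty")
  idx <- which(nucleus_mask, arr.ind = TRUE)
  if (min(idx) <= 1 || max(idx[, 1]) >= nrow(labels) ||
      max(idx[, 2]) >= ncol(labels)) {
    stop_domain("nucleus mask must be interior to the image")
  }
  if (!is.null(cell_mask)) {
    cell_mask <- check_mask(cell_mask, "cell_mask", dim(labels))
  }
  if (identical(directions, "auto")) {
    ax_mask <- cell_mask %||% (labels > 0L)
    base <- mask_principal_axis(ax_mask)$angle_deg
    directions <- base + c(0, 120, 240)
  }
  if (!is.numeric(directions) || length(directions) != 3L) {
    stop_config("`directions` must be \"auto\" or 3 angles in degrees")
  }

  ctr <- colMeans(which(nucleus_mask, arr.ind = TRUE))
  R <- matrix(seq_len(nrow(labels)), nrow(labels), ncol(labels))
  C <- matrix(seq_len(ncol(labels)), nrow(labels), ncol(labels), byrow = TRUE)
  vr <- R - ctr[1]; vc <- C - ctr[2]

  purrr::map_dfr(seq_along(directions), function(k) {
    th <- deg2rad(directions[k])
    u <- c(-cos(th), sin(th))  # 0 degrees points "up" the image
    proj <- vr * u[1] + vc * u[2]
    perp <- vr * u[2] - vc * u[1]
    rect <- proj > 0 & abs(perp) <= width / 2 & !nucleus_mask
    if (!is.null(cell_mask)) rect <- rect & cell_mask
    er <- sum(labels[rect] > 0L)
    sheet <- sum(labels[rect] == 2L)
    pct <- if (er > 0) 100 * sheet / er else {
      warn(sprintf("segment %d contains no ER pixels", k))
      NA_real_
    }
    tibble(segment_index = k, angle_deg = directions[k] %% 360,
           width_px = width, sheet_pixels = sheet, er_pixels = er,
           sheet_percentage = pct)
  })
}

#' ER area normalized by cytoplasm area
#'
#' Fraction of the examined cytoplasm occupied by ER:
#' `(ER pixels inside the cytoplasm mask) / (cytoplasm pixels)`.
#'
#' @param seg An [er_segmentation()].
#' @param cytoplasm_mask Non-empty logical mask of the cytoplasm examined.
#'
#' @return A single number in `[0, 1]`.
#' @export
er_area_fraction <- function(seg, cytoplasm_mask) {
  stopifnot(inherits(seg, "er_segmentation"))
  cytoplasm_mask <- check_mask(cytoplasm_mask, "cytoplasm_mask",
                               dim(seg$label_image))
  n_cyto <- sum(cytoplasm_mask)
  if (n_cyto == 0) stop_domain("cytoplasm mask is empty")
  sum(seg$label_image[cytoplasm_mask] > 0L) / n_cyto
}
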