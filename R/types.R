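#' Multi-channel cell image container
#'
#' Light-weight container for 2D images or 3D stacks with named channels,
#' a physical pixel size and optional binary masks (nucleus, cell, cytoplasm).
#' All channels must share one shape; pixel coordinates are row-major with
#' the first array index running down image rows.
#'
#' @param channels Named list of numeric matrices (2D) or 3D arrays, one per
#'   channel, all of identical shape with non-negative intensities.
#' @param pixel_size_nm In-plane pixel size in nanometres (isotropic).
#' @param z_step_nm Axial step in nanometres for 3D stacks (`NA` for 2D).
#' @param masks Optional named list of logical masks sharing the image shape.
#'   When both `cytoplasm` and `nucleus` are present the cytoplasm mask must
#'   exclude the nucleus.
#'
#' @return An object of class `cell_image`.
#' @export
cell_image <- function(channels, pixel_size_nm, z_step_nm = NA_real_,
                       masks = list()) {
  if (!is.list(channels) || length(channels) == 0L ||
      is.null(names(channels)) || any(!nzchar(names(channels)))) {
    stop_domain("`channels` must be a non-empty named list of arrays.")
  }
  shape <- dim(channels[[1]]) %||% length(channels[[1]])
  for (nm in names(channels)) {
    ch <- channels[[nm]]
    if (!is.numeric(ch)) stop_domain(sprintf("channel '%s' is not numeric", nm))
    if (!identical(dim(ch) %||% length(ch), shape)) {
      stop_domain("all channels must share one shape")
    }
    if (any(ch < 0, na.rm = TRUE)) {
      stop_domain(sprintf("channel '%s' has negative intensities", nm))
    }
  }
  check_scalar_number(pixel_size_nm, "pixel_size_nm", min = 0, strict_min = TRUE)
  masks <- lapply(masks, check_mask, name = "mask", dim_ref = shape)
  if (!is.null(masks$cytoplasm) && !is.null(masks$nucleus) &&
      any(masks$cytoplasm & masks$nucleus)) {
    stop_domain("cytoplasm mask must exclude the nucleus mask")
  }
  structure(
    list(
      channels = channels,
      channel_names = names(channels),
      pixel_size_nm = pixel_size_nm,
      z_step_nm = z_step_nm,
      masks = masks
    ),
    class = "cell_image"
  )
}

#' @export
print.cell_image <- function(x, ...) {
  shp <- paste(dim(x$channels[[1]]) %||% length(x$channels[[1]]),
               collapse = " x ")
  cat("<cell_image> ", shp, " px, ", length(x$channels), " channel(s): ",
      paste(x$channel_names, collapse = ", "),
      "; pixel size ", x$pixel_size_nm, " nm\n", sep = "")
  if (length(x$masks)) {
    cat("  masks: ", paste(names(x$masks), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Ground-truth record attached to synthetic fixtures
#'
#' Every synthetic generator returns one of these alongside its fixture. It
#' records the generator name, the full parameter set (with units encoded in
#' the parameter names, e.g. `tau1_ns`) and the seed, which together
#' regenerate the fixture bit-for-bit.
#'
#' @param generator_name Name of the generating function.
#' @param parameters Named list of generator parameters; numeric entries carry
#'   units in their names.
#' @param seed Non-negative integer seed used for all randomness.
#'
#' @return An object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(generator_name, parameters, seed) {
  if (!is.character(generator_name) || length(generator_name) != 1L) {
    stop_domain("`generator_name` must be a single string.")
  }
  if (!is.list(parameters) || (length(parameters) && is.null(names(parameters)))) {
    stop_domain("`parameters` must be a named list.")
  }
  seed <- as_seed(seed)
  structure(
    list(generator_name = generator_name, parameters = parameters, seed = seed),
    class = "synthetic_truth"
  )
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> ", x$generator_name, " (seed ", x$seed, ")\n", sep = "")
  str(x$parameters, no.list = TRUE, give.attr = FALSE)
  invisible(x)
}

#' TCSPC photon-decay histogram
#'
#' Binned photon arrival times for one region of interest or pixel, the raw
#' material of fluorescence-lifetime fitting. Bin edges must be uniform and
#' strictly increasing; at least 8 bins are required for a biexponential fit
#' to be meaningful.
#'
#' @param bin_edges Numeric vector of bin edges in nanoseconds, length
#'   `n_bins + 1`, uniform width.
#' @param counts Non-negative integer photon counts per bin.
#'
#' @return An object of class `decay_histogram` with fields `bin_edges`,
#'   `counts`, `bin_width_ns` and `total_photons`.
#' @export
decay_histogram <- function(bin_edges, counts) {
  if (length(bin_edges) != length(counts) + 1L) {
    stop_domain("`bin_edges` must have length `length(counts) + 1`.")
  }
  if (length(counts) < 8L) stop_domain("a decay histogram needs at least 8 bins")
  widths <- diff(bin_edges)
  if (any(widths <= 0) || diff(range(widths)) > 1e-9 * mean(widths)) {
    stop_domain("`bin_edges` must be strictly increasing with uniform width.")
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_domain("`counts` must be non-negative integers.")
  }
  structure(
    list(
      bin_edges = as.numeric(bin_edges),
      counts = as.integer(round(counts)),
      bin_width_ns = mean(widths),
      total_photons = sum(as.numeric(counts))
    ),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat("<decay_histogram> ", length(x$counts), " bins x ",
      signif(x$bin_width_ns, 4), " ns, ", x$total_photons, " photons\n",
      sep = "")
  invisible(x)
}

#' Bin centres of a decay histogram (ns)
#' @param hist A [decay_histogram()].
#' @return Numeric vector of bin-centre times in ns.
#' @export
bin_centers <- function(hist) {
  stopifnot(inherits(hist, "decay_histogram"))
  (head(hist$bin_edges, -1) + tail(hist$bin_edges, -1)) / 2
}

#' Digitized membrane trace
#'
#' An ordered planar polyline in nanometre coordinates describing one
#' organelle membrane in a section (e.g. traced from transmission electron
#' microscopy). Traces are densified on construction so that consecutive
#' points are no farther apart than `max_spacing_nm`, which the contact-site
#' measurements rely on.
#'
#' @param points Two-column matrix or data frame of `(x_nm, y_nm)` coordinates
#'   in order along the membrane; at least 2 points.
#' @param organelle One of `"PM"`, `"ER"`, `"mitochondrion"`, `"lysosome"`.
#' @param closed Is the trace a closed contour?
#' @param max_spacing_nm Maximum spacing between consecutive points after
#'   densification (default 1 nm).
#'
#' @return An object of class `membrane_trace`.
#' @export
membrane_trace <- function(points, organelle = c("PM", "ER", "mitochondrion",
                                                 "lysosome"),
                           closed = FALSE, max_spacing_nm = 1) {
  organelle <- match.arg(organelle)
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  storage.mode(pts) <- "double"
  dimnames(pts) <- NULL
  if (nrow(pts) < 2L) stop_domain("a membrane trace needs at least 2 points")
  if (any(!is.finite(pts))) stop_domain("trace coordinates must be finite")
  check_scalar_number(max_spacing_nm, "max_spacing_nm", min = 0, strict_min = TRUE)
  if (closed && any(pts[1, ] != pts[nrow(pts), ])) {
    pts <- rbind(pts, pts[1, ])
  }
  pts <- densify_polyline(pts, max_spacing_nm)
  structure(
    list(points = pts, organelle = organelle, closed = closed,
         max_spacing_nm = max_spacing_nm),
    class = "membrane_trace"
  )
}

#' @export
print.membrane_trace <- function(x, ...) {
  cat("<membrane_trace> ", x$organelle, ", ", nrow(x$points), " points, ",
      signif(polyline_length(x$points), 5), " nm\n", sep = "")
  invisible(x)
}

# Insert intermediate points so consecutive spacing <= step; preserves
# original vertices exactly.
densify_polyline <- function(pts, step) {
  n <- nrow(pts)
  if (n < 2L) return(pts)
  segs <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    a <- pts[i, ]; b <- pts[i + 1L, ]
    len <- sqrt(sum((b - a)^2))
    k <- max(1L, ceiling(len / step))
    tt <- seq(0, 1, length.out = k + 1L)[-(k + 1L)]
    segs[[i]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]))
  }
  out <- do.call(rbind, segs)
  rbind(out, pts[n, , drop = FALSE])
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2L) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

#' Store-operated calcium entry (SOCE) trace
#'
#' A uniformly sampled fluorescence time course following the calcium
#' re-addition protocol: extracellular Ca2+ removal, ER store depletion with
#' thapsigargin, then rapid Ca2+ re-addition. Sampling is every 5 s as in the
#' acquisition protocol.
#'
#' @param time_s Strictly increasing sample times in seconds.
#' @param F Fluorescence values (arbitrary units, > 0).
#' @param phase_marks Named numeric vector with elements `ca_free_start`,
#'   `depletion_start`, `readdition` (seconds), ordered and within the record.
#'
#' @return A tibble of class `soce_trace` with columns `time_s`, `F` and a
#'   `phase_marks` attribute.
#' @export
soce_trace <- function(time_s, F, phase_marks) {
  if (length(time_s) != length(F)) stop_domain("time and F lengths differ")
  if (any(diff(time_s) <= 0)) stop_domain("`time_s` must be strictly increasing")
  if (any(F <= 0)) stop_domain("fluorescence must be positive")
  need <- c("ca_free_start", "depletion_start", "readdition")
  if (!all(need %in% names(phase_marks))) {
    stop_domain("`phase_marks` must name ca_free_start, depletion_start, readdition")
  }
  pm <- phase_marks[need]
  if (is.unsorted(pm) || pm[1] < min(time_s) || pm[3] > max(time_s)) {
    stop_domain("`phase_marks` must be ordered and within the record")
  }
  out <- tibble(time_s = as.numeric(time_s), F = as.numeric(F))
  attr(out, "phase_marks") <- pm
  class(out) <- c("soce_trace", class(out))
  out
}

#' @importFrom utils str
NULL
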