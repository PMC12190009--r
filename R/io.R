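# File formats: TIFF images with JSON sidecars, CSV traces, JSON polylines
# and truth records. All numeric image data are written as 16-bit TIFF
# (values 0..65535, rounded) with channel names, pixel size and intensity
# scale in a sidecar JSON next to the file.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a cell image as TIFF plus JSON sidecar
#'
#' Channels are written as frames of one 16-bit TIFF (values rounded to
#' integers, which round-trips integer-valued images exactly); channel
#' names, pixel size and z step go to `<path>.json`.
#'
#' @param img A [cell_image()] with 2D channels and values in 0..65535.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_cell_image <- function(img, path) {
  stopifnot(inherits(img, "cell_image"))
  frames <- lapply(img$channels, function(ch) {
    if (length(dim(ch)) != 2L) {
      stop_io("write_cell_image supports 2D channels; write stacks per-slice")
    }
    if (max(ch) > 65535 || min(ch) < 0) {
      stop_io("intensities must lie in 0..65535 for 16-bit TIFF output")
    }
    round(ch) / 65535
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  meta <- list(
    channel_names = img$channel_names,
    pixel_size_nm = img$pixel_size_nm,
    z_step_nm = img$z_step_nm,
    intensity_scale = 65535
  )
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a cell image written by [write_cell_image()]
#'
#' Pixel size precedence: an explicit `pixel_size_nm` argument (the
#' manifest) wins over the sidecar metadata; a conflict is logged as a
#' warning naming both values.
#'
#' @param path TIFF path.
#' @param expected_channels Optional channel count to enforce.
#' @param pixel_size_nm Optional manifest override for the pixel size.
#' @return A [cell_image()].
#' @export
read_cell_image <- function(path, expected_channels = NULL,
                            pixel_size_nm = NULL) {
  if (!file.exists(path)) stop_io(sprintf("no such image file: %s", path))
  frames <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(frames)) frames <- list(frames)
  meta <- if (file.exists(sidecar_path(path))) {
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  } else {
    list()
  }
  if (!is.null(expected_channels) && length(frames) != expected_channels) {
    stop_io(sprintf("%s has %d channel(s), expected %d", path,
                    length(frames), expected_channels))
  }
  nms <- meta$channel_names %||% paste0("ch", seq_along(frames))
  scale <- meta$intensity_scale %||% 65535
  ps_meta <- meta$pixel_size_nm
  ps <- pixel_size_nm %||% ps_meta %||%
    stop_io(sprintf("no pixel size in sidecar or manifest for %s", path))
  if (!is.null(pixel_size_nm) && !is.null(ps_meta) &&
      pixel_size_nm != ps_meta) {
    warn(sprintf("pixel size conflict for %s: metadata %g nm, manifest %g nm; using manifest",
                 path, ps_meta, pixel_size_nm))
  }
  channels <- stats::setNames(lapply(frames, function(f) round(f * scale)),
                              nms)
  cell_image(channels, pixel_size_nm = ps,
             z_step_nm = meta$z_step_nm %||% NA_real_)
}

#' Write / read a decay histogram as CSV
#'
#' Two-column CSV `bin_start_ns, count` (the bin width is inferred from the
#' uniform spacing of `bin_start_ns`).
#'
#' @param hist A [decay_histogram()].
#' @param path CSV path.
#' @return `path` (write) or a [decay_histogram()] (read).
#' @export
write_decay_csv <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  readr::write_csv(
    tibble(bin_start_ns = head(hist$bin_edges, -1), count = hist$counts),
    path
  )
  invisible(path)
}

#' @rdname write_decay_csv
#' @export
read_decay_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  if (!all(c("bin_start_ns", "count") %in% names(d))) {
    stop_io("decay CSV must have columns bin_start_ns, count")
  }
  w <- diff(d$bin_start_ns)
  decay_histogram(c(d$bin_start_ns, d$bin_start_ns[nrow(d)] + w[length(w)]),
                  d$count)
}

#' Write / read a SOCE trace as CSV
#'
#' Columns `time_s, F`; phase marks go to a `<path>.json` sidecar.
#'
#' @param trace A [soce_trace()].
#' @param path CSV path.
#' @return `path` (write) or a [soce_trace()] (read).
#' @export
write_soce_csv <- function(trace, path) {
  stopifnot(inherits(trace, "soce_trace"))
  readr::write_csv(tibble(time_s = trace$time_s, F = trace$F), path)
  jsonlite::write_json(as.list(attr(trace, "phase_marks")),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_soce_csv
#' @export
read_soce_csv <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  d <- readr::read_csv(path, col_types = "dd", progress = FALSE)
  pm <- unlist(jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE))
  soce_trace(d$time_s, d$F, pm)
}

#' Write / read a membrane trace as JSON
#'
#' Polyline stored as an ordered list of `[x_nm, y_nm]` pairs with the
#' organelle label.
#'
#' @param trace A [membrane_trace()].
#' @param path JSON path.
#' @return `path` (write) or a [membrane_trace()] (read).
#' @export
write_trace_json <- function(trace, path) {
  stopifnot(inherits(trace, "membrane_trace"))
  jsonlite::write_json(
    list(organelle = trace$organelle, closed = trace$closed,
         points_nm = unname(apply(trace$points, 1, as.numeric,
                                  simplify = FALSE))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_trace_json
#' @export
read_trace_json <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("no such file: %s", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  pts <- j$points_nm
  if (is.list(pts)) pts <- do.call(rbind, pts)
  membrane_trace(pts, organelle = j$organelle, closed = isTRUE(j$closed))
}
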