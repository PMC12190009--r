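#' Per-pixel decay histogram stack
#'
#' Container for per-pixel TCSPC histograms sharing one set of bin edges:
#' a 3D array of counts indexed `[row, col, bin]`.
#'
#' @param counts 3D non-negative integer array `[rows, cols, bins]`.
#' @param bin_edges Shared bin edges in ns, length `bins + 1`.
#'
#' @return An object of class `pixel_decay_stack`.
#' @export
pixel_decay_stack <- function(counts, bin_edges) {
  if (length(dim(counts)) != 3L) {
    abort("`counts` must be a 3D array [rows, cols, bins]",
          class = "ermechquant_format_error")
  }
  if (length(bin_edges) != dim(counts)[3] + 1L) {
    abort("`bin_edges` length must be `dim(counts)[3] + 1`",
          class = "ermechquant_format_error")
  }
  if (any(counts < 0)) stop_domain("counts must be non-negative")
  structure(list(counts = counts, bin_edges = as.numeric(bin_edges)),
            class = "pixel_decay_stack")
}

#' Fit a per-pixel lifetime map
#'
#' Spatially bins per-pixel histograms (summing counts over
#' `spatial_binning x spatial_binning` blocks), gates binned pixels by a
#' minimum photon count, and fits each surviving pixel with
#' [fit_biexponential()]. The map stores the reported long lifetime `tau1`.
#'
#' @param stack A [pixel_decay_stack()].
#' @param min_photons Minimum photons per binned pixel (default 100; below
#'   this a biexponential is unidentifiable and the pixel is left undefined).
#' @param spatial_binning Block size in px (default 1).
#' @param ... Passed to [fit_biexponential()] (e.g. `loss`,
#'   `fit_background`).
#'
#' @return An object of class `lifetime_map` with fields `tau1_image`
#'   (`NA` where gated out), `photon_count_image`, `min_photons`,
#'   `spatial_binning`, `bin_edges`.
#' @export
fit_lifetime_map <- function(stack, min_photons = 100, spatial_binning = 1,
                             ...) {
  stopifnot(inherits(stack, "pixel_decay_stack"))
  check_scalar_number(spatial_binning, "spatial_binning", min = 1)
  dims <- dim(stack$counts)
  nrb <- dims[1] %/% spatial_binning
  ncb <- dims[2] %/% spatial_binning
  if (nrb < 1 || ncb < 1) stop_domain("spatial_binning exceeds image size")

  binned <- array(0, c(nrb, ncb, dims[3]))
  for (i in seq_len(nrb)) {
    ri <- ((i - 1) * spatial_binning + 1):(i * spatial_binning)
    for (j in seq_len(ncb)) {
      ci <- ((j - 1) * spatial_binning + 1):(j * spatial_binning)
      block <- stack$counts[ri, ci, , drop = FALSE]
      binned[i, j, ] <- apply(block, 3, sum)
    }
  }

  photons <- apply(binned, c(1, 2), sum)
  tau1 <- matrix(NA_real_, nrb, ncb)
  for (i in seq_len(nrb)) {
    for (j in seq_len(ncb)) {
      if (photons[i, j] < min_photons) next
      h <- decay_histogram(stack$bin_edges, binned[i, j, ])
      fit <- fit_biexponential(h, min_photons = min_photons, n_starts = 3,
                               ...)
      if (fit$converged) tau1[i, j] <- fit$tau1_ns
    }
  }
  structure(
    list(tau1_image = tau1, photon_count_image = photons,
         min_photons = min_photons, spatial_binning = spatial_binning,
         bin_edges = stack$bin_edges),
    class = "lifetime_map"
  )
}

#' @export
print.lifetime_map <- function(x, ...) {
  cat("<lifetime_map> ", nrow(x$tau1_image), " x ", ncol(x$tau1_image),
      " px (binning ", x$spatial_binning, "), ",
      sum(!is.na(x$tau1_image)), " defined pixels, min_photons = ",
      x$min_photons, "\n", sep = "")
  invisible(x)
}

#' @method tidy lifetime_map
#' @export
tidy.lifetime_map <- function(x, ...) {
  d <- dim(x$tau1_image)
  tibble(
    row = rep(seq_len(d[1]), d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    tau1_ns = as.vector(x$tau1_image),
    photons = as.vector(x$photon_count_image)
  )
}
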