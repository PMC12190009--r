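# 3D connected-component labeling and SPLICS puncta counting.

neighbor_offsets_3d <- function(connectivity) {
  if (connectivity == 6) {
    rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  } else if (connectivity == 26) {
    off <- as.matrix(expand.grid(dr = -1:1, dc = -1:1, dz = -1:1))
    off <- off[!(off[, 1] == 0 & off[, 2] == 0 & off[, 3] == 0), ]
    # forward half-space: first nonzero coordinate positive
    keep <- apply(off, 1, function(o) {
      nz <- which(o != 0)[1]
      o[nz] > 0
    })
    off[keep, , drop = FALSE]
  } else {
    stop_config("`connectivity` must be 6 or 26")
  }
}

#' Label connected components in a 3D binary volume
#'
#' Union-find labeling under 6- or 26-connectivity. Used by
#' [count_splics_puncta()]; exported because labeled volumes are useful on
#' their own.
#'
#' @param mask Logical (or 0/1) 3D array.
#' @param connectivity 6 (face) or 26 (face, edge and corner neighbors).
#'
#' @return Integer array of component labels (0 = background), with
#'   attribute `n_components`.
#' @export
label_components_3d <- function(mask, connectivity = 26) {
  if (length(dim(mask)) != 3L) stop_domain("`mask` must be a 3D array")
  dims <- dim(mask)
  mask <- array(as.logical(mask), dims)
  fg <- which(mask)
  labels <- array(0L, dims)
  if (length(fg) == 0L) {
    attr(labels, "n_components") <- 0L
    return(labels)
  }
  idmap <- array(0L, dims)
  idmap[fg] <- seq_along(fg)
  coords <- arrayInd(fg, dims)
  parent <- seq_along(fg)
  find_root <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  offsets <- neighbor_offsets_3d(connectivity)
  for (o in seq_len(nrow(offsets))) {
    off <- offsets[o, ]
    nb <- sweep(coords, 2, off, "+")
    ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
      nb[, 2] >= 1 & nb[, 2] <= dims[2] &
      nb[, 3] >= 1 & nb[, 3] <= dims[3]
    nb_id <- idmap[nb[ok, , drop = FALSE]]
    a_id <- which(ok)[nb_id > 0]
    b_id <- nb_id[nb_id > 0]
    for (k in seq_along(a_id)) {
      ra <- find_root(a_id[k]); rb <- find_root(b_id[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  roots <- vapply(seq_along(fg), find_root, integer(1))
  comp <- match(roots, unique(roots))
  labels[fg] <- comp
  attr(labels, "n_components") <- length(unique(roots))
  labels
}

#' Count SPLICS puncta in a 3D stack
#'
#' Thresholds a z-stack, removes components smaller than `min_voxels`, and
#' counts the remaining connected components under the chosen connectivity.
#' A stack that is blank after thresholding yields a count of 0 (not an
#' error). Defaults (Otsu threshold, 26-connectivity, `min_voxels = 4`)
#' follow common practice for split-GFP contact-site sensors.
#'
#' @param zstack 3D numeric array or a 3D [cell_image()] (first channel).
#' @param threshold_method `"otsu"` (default) or `"fixed"`.
#' @param threshold Fixed level when `threshold_method = "fixed"`.
#' @param min_voxels Minimum component size in voxels (default 4).
#' @param connectivity 6 or 26 (default 26).
#'
#' @return An object of class `puncta_count` with fields `count`,
#'   `voxel_threshold`, `min_voxels`, `connectivity`, `component_sizes` and
#'   `labels` (the filtered label array).
#' @export
count_splics_puncta <- function(zstack,
                                threshold_method = c("otsu", "fixed"),
                                threshold = NULL, min_voxels = 4,
                                connectivity = 26) {
  threshold_method <- match.arg(threshold_method)
  if (inherits(zstack, "cell_image")) zstack <- zstack$channels[[1]]
  if (length(dim(zstack)) != 3L) stop_domain("`zstack` must be a 3D array")
  t <- if (threshold_method == "fixed") {
    if (is.null(threshold)) stop_config("fixed threshold requested without a level")
    threshold
  } else if (max(zstack) <= 0) {
    Inf  # blank stack: nothing above threshold
  } else {
    threshold_level(zstack, "otsu")
  }
  mask <- zstack > t
  labels <- label_components_3d(mask, connectivity)
  sizes <- if (attr(labels, "n_components") > 0) {
    tabulate(labels[labels > 0L], attr(labels, "n_components"))
  } else {
    integer(0)
  }
  keep <- which(sizes >= min_voxels)
  out <- array(0L, dim(labels))
  out[labels > 0L & labels %in% keep] <-
    match(labels[labels > 0L & labels %in% keep], keep)
  structure(
    list(count = length(keep), voxel_threshold = t, min_voxels = min_voxels,
         connectivity = connectivity, component_sizes = sizes[keep],
         labels = out),
    class = "puncta_count"
  )
}

#' @export
print.puncta_count <- function(x, ...) {
  cat("<puncta_count> ", x$count, " puncta (threshold ",
      signif(x$voxel_threshold, 4), ", min ", x$min_voxels, " voxels, ",
      x$connectivity, "-connectivity)\n", sep = "")
  invisible(x)
}
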