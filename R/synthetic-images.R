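# Synthetic microscopy image generators. Each emulates one input modality of
# the quantification pipeline and returns its fixture together with a
# synthetic_truth record sufficient to regenerate it bit-for-bit.

disk_mask <- function(shape, center, radius, aspect = c(1, 1)) {
  r <- matrix(seq_len(shape[1]), shape[1], shape[2])
  c_ <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  ((r - center[1]) / aspect[1])^2 + ((c_ - center[2]) / aspect[2])^2 <= radius^2
}

# Mark pixels along a polyline path (row/col coordinates), with given width.
stamp_path <- function(mask, rows, cols, width = 1) {
  shape <- dim(mask)
  if (width > 1) {
    off <- expand.grid(dr = -1:1, dc = -1:1)
    off <- off[off$dr^2 + off$dc^2 <= (width / 2)^2 + 0.26, ]
    rows <- rep(rows, each = nrow(off)) + off$dr
    cols <- rep(cols, each = nrow(off)) + off$dc
  }
  keep <- rows >= 1 & rows <= shape[1] & cols >= 1 & cols <= shape[2]
  mask[cbind(round(rows[keep]), round(cols[keep]))] <- TRUE
  mask
}

#' Simulate a GFP-ER cell image with sheet/tubule ground truth
#'
#' Draws a cell with a central disk nucleus, thin curvilinear ER tubules
#' (1-3 px wide) radiating from the nuclear envelope toward the cell
#' periphery, and compact ER sheet blobs. Sheets are added until the realized
#' sheet fraction (sheet px / ER px) reaches `sheet_fraction_target`. The
#' returned truth labels every pixel background/tubule/sheet; the realized
#' sheet fraction is recorded in the truth.
#'
#' Default geometry emulates a spread fibroblast-like cell imaged by confocal
#' microscopy at ~100 nm/px: an elliptical cell of ~110 px semi-major axis in
#' a 256 x 256 field, a 30 px nucleus, and ~60 tubules.
#'
#' @param image_shape Integer vector `c(rows, cols)`.
#' @param pixel_size_nm Pixel size in nm.
#' @param nucleus_radius Nucleus radius in px.
#' @param n_tubules Number of radiating tubules.
#' @param sheet_fraction_target Target sheet fraction of ER pixels, in `[0, 1]`.
#' @param intensity_levels Numeric `c(background, tubule, sheet)` with
#'   `background < tubule < sheet`.
#' @param noise_sd Gaussian noise SD added to the intensity image.
#' @param sheet_placement `"perinuclear"` (default; sheets concentrate near
#'   the nucleus as in most cells) or `"uniform"` (sheets spread over the
#'   whole cytoplasm, radially uniform).
#' @param seed Integer seed.
#'
#' @return A list with elements `image` (a [cell_image()] with channel `ER`
#'   and masks `nucleus`, `cell`, `cytoplasm`), `labels` (integer matrix,
#'   0 = background, 1 = tubule, 2 = sheet) and `truth`.
#' @export
gen_er_cell_image <- function(image_shape = c(256, 256), pixel_size_nm = 100,
                              nucleus_radius = 30, n_tubules = 60,
                              sheet_fraction_target = 0.3,
                              intensity_levels = c(20, 100, 220),
                              noise_sd = 10,
                              sheet_placement = c("perinuclear", "uniform"),
                              seed = 1) {
  sheet_placement <- match.arg(sheet_placement)
  if (length(intensity_levels) != 3L || is.unsorted(intensity_levels, strictly = TRUE)) {
    stop_domain("`intensity_levels` must be increasing (background, tubule, sheet).")
  }
  check_scalar_number(sheet_fraction_target, "sheet_fraction_target", 0, 1)
  check_scalar_number(noise_sd, "noise_sd", min = 0)
  center <- (image_shape + 1) / 2
  if (nucleus_radius >= min(image_shape) / 2) {
    stop_domain("nucleus larger than image")
  }
  cell_r <- 0.43 * min(image_shape)
  cell <- disk_mask(image_shape, center, cell_r, aspect = c(1.25, 0.95))
  nucleus <- disk_mask(image_shape, center, nucleus_radius)
  cyto <- cell & !nucleus

  res <- with_seed(seed, {
    tubule <- matrix(FALSE, image_shape[1], image_shape[2])
    for (i in seq_len(n_tubules)) {
      phi <- runif(1, 0, 2 * pi)
      pos <- center + (nucleus_radius + 1) * c(cos(phi), sin(phi))
      rows <- cols <- numeric(0)
      for (step in 1:200) {
        pos <- pos + 1.5 * c(cos(phi), sin(phi))
        phi <- phi + rnorm(1, sd = 0.12)
        if (pos[1] < 1 || pos[1] > image_shape[1] ||
            pos[2] < 1 || pos[2] > image_shape[2]) break
        if (!cell[round(pos[1]), round(pos[2])]) break
        rows <- c(rows, pos[1]); cols <- c(cols, pos[2])
      }
      if (length(rows)) {
        tubule <- stamp_path(tubule, rows, cols,
                             width = sample(1:2, 1))
      }
    }
    tubule <- tubule & cyto

    sheet <- matrix(FALSE, image_shape[1], image_shape[2])
    if (sheet_fraction_target > 0 && any(tubule)) {
      for (b in 1:400) {
        frac <- sum(sheet) / (sum(sheet) + sum(tubule & !sheet))
        if (frac >= sheet_fraction_target) break
        rad_lo <- nucleus_radius + 4
        rad_hi <- if (sheet_placement == "perinuclear") {
          nucleus_radius + 0.45 * (cell_r - nucleus_radius)
        } else {
          0.95 * cell_r
        }
        rr <- runif(1, rad_lo, rad_hi)
        phi <- runif(1, 0, 2 * pi)
        ctr <- center + rr * c(cos(phi), sin(phi))
        blob <- disk_mask(image_shape, ctr, runif(1, 4, 8),
                          aspect = c(1, runif(1, 0.7, 1.4)))
        sheet <- sheet | (blob & cyto)
      }
    }

    labels <- matrix(0L, image_shape[1], image_shape[2])
    labels[tubule] <- 1L
    labels[sheet] <- 2L  # sheet overrides tubule

    img <- matrix(intensity_levels[1], image_shape[1], image_shape[2])
    img[labels == 1L] <- intensity_levels[2]
    img[labels == 2L] <- intensity_levels[3]
    if (noise_sd > 0) {
      img <- img + matrix(rnorm(length(img), sd = noise_sd),
                          image_shape[1], image_shape[2])
      img <- pmax(img, 0)
    }
    list(labels = labels, img = img)
  })

  n_sheet <- sum(res$labels == 2L)
  n_er <- sum(res$labels > 0L)
  img <- cell_image(
    channels = list(ER = res$img),
    pixel_size_nm = pixel_size_nm,
    masks = list(nucleus = nucleus, cell = cell, cytoplasm = cyto)
  )
  truth <- synthetic_truth(
    "gen_er_cell_image",
    list(image_shape_px = image_shape, pixel_size_nm = pixel_size_nm,
         nucleus_radius_px = nucleus_radius, n_tubules = n_tubules,
         sheet_fraction_target = sheet_fraction_target,
         intensity_levels_au = intensity_levels, noise_sd_au = noise_sd,
         sheet_placement = sheet_placement,
         realized_sheet_fraction = if (n_er > 0) n_sheet / n_er else NA_real_,
         n_er_px = n_er, n_sheet_px = n_sheet),
    seed
  )
  list(image = img, labels = res$labels, truth = truth)
}

# von Mises sampler (Best & Fisher 1979 rejection scheme); kappa = 0 falls
# back to the uniform circular distribution.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-9) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      cc <- kappa * (r - f)
      if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(pmin(pmax(f, -1), 1)) + mu
        break
      }
    }
  }
  out %% (2 * pi)
}

#' Simulate an F-actin fiber image with known orientations
#'
#' Renders straight fibers whose axial angles are drawn from a von Mises
#' distribution on doubled angles (the standard construction for axial,
#' 180-degree-periodic data). Angles follow the convention that 0 degrees is
#' vertical and 90 degrees is horizontal. Fibers are lightly blurred to give
#' the smooth intensity gradients of diffraction-limited images.
#'
#' @param image_shape `c(rows, cols)`.
#' @param n_fibers Number of fibers (>= 1).
#' @param mean_angle_deg Mean axial angle in degrees from vertical.
#' @param concentration von Mises concentration kappa of the doubled-angle
#'   distribution; 0 gives a uniform axial distribution, large values give
#'   near-parallel fibers.
#' @param intensity Fiber intensity (a.u.).
#' @param noise_sd Gaussian noise SD.
#' @param blur_sigma_px Gaussian blur applied to the rendered fibers.
#' @param pixel_size_nm Pixel size in nm.
#' @param seed Integer seed.
#'
#' @return A list with `image` (a [cell_image()] with channel `actin` and a
#'   full-field `cell` mask), `angles_deg` (true axial angle of each fiber,
#'   in `[0, 180)`) and `truth`.
#' @export
gen_fiber_image <- function(image_shape = c(256, 256), n_fibers = 40,
                            mean_angle_deg = 0, concentration = 4,
                            intensity = 200, noise_sd = 10,
                            blur_sigma_px = 1, pixel_size_nm = 100,
                            seed = 1) {
  if (n_fibers < 1) stop_domain("`n_fibers` must be at least 1")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      is.na(concentration) || concentration < 0) {
    stop_domain("`concentration` must be a single number >= 0 (Inf allowed)")
  }
  res <- with_seed(seed, {
    if (is.finite(concentration)) {
      psi <- rvonmises(n_fibers, deg2rad(2 * mean_angle_deg), concentration)
      theta <- (psi / 2) %% pi
    } else {
      theta <- rep(deg2rad(mean_angle_deg) %% pi, n_fibers)
    }
    img <- matrix(0, image_shape[1], image_shape[2])
    hit <- matrix(FALSE, image_shape[1], image_shape[2])
    len <- 0.7 * min(image_shape)
    for (i in seq_len(n_fibers)) {
      ctr <- c(runif(1, 0.2, 0.8) * image_shape[1],
               runif(1, 0.2, 0.8) * image_shape[2])
      tt <- seq(-len / 2, len / 2, by = 0.4)
      rows <- ctr[1] + tt * cos(theta[i])   # 0 deg = vertical (along rows)
      cols <- ctr[2] + tt * sin(theta[i])
      hit <- stamp_path(hit, rows, cols, width = 1)
    }
    img[hit] <- intensity
    if (blur_sigma_px > 0) {
      img <- pmax(as.matrix(EBImage::gblur(EBImage::Image(img),
                                           sigma = blur_sigma_px)), 0)
    }
    if (noise_sd > 0) {
      img <- pmax(img + matrix(rnorm(length(img), sd = noise_sd),
                               image_shape[1], image_shape[2]), 0)
    }
    list(img = img, angles = rad2deg(theta))
  })
  img <- cell_image(
    channels = list(actin = res$img), pixel_size_nm = pixel_size_nm,
    masks = list(cell = matrix(TRUE, image_shape[1], image_shape[2]))
  )
  truth <- synthetic_truth(
    "gen_fiber_image",
    list(image_shape_px = image_shape, n_fibers = n_fibers,
         mean_angle_deg = mean_angle_deg, concentration = concentration,
         intensity_au = intensity, noise_sd_au = noise_sd,
         blur_sigma_px = blur_sigma_px, pixel_size_nm = pixel_size_nm,
         angles_deg = res$angles),
    seed
  )
  list(image = img, angles_deg = res$angles, truth = truth)
}

#' Simulate a 3D volume of well-separated fluorescent puncta
#'
#' Places `n_puncta` spheres by rejection sampling so that all centre-to-centre
#' distances are at least `min_separation` voxels, emulating the discrete
#' puncta produced by split-GFP contact-site sensors in a confocal z-stack.
#'
#' @param stack_shape `c(rows, cols, slices)`.
#' @param n_puncta Number of puncta (>= 0).
#' @param radius Sphere radius in voxels.
#' @param min_separation Minimum centre separation in voxels (default
#'   `4 * radius`).
#' @param intensity Punctum intensity (a.u.).
#' @param noise_sd Gaussian noise SD.
#' @param pixel_size_nm In-plane voxel size (nm).
#' @param z_step_nm Axial step (nm).
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling budget before failing.
#'
#' @return A list with `image` (a 3D [cell_image()], channel `SPLICS`),
#'   `centers` (matrix of voxel coordinates) and `truth`.
#' @export
gen_puncta_volume <- function(stack_shape = c(48, 48, 24), n_puncta = 5,
                              radius = 3, min_separation = 4 * radius,
                              intensity = 200, noise_sd = 5,
                              pixel_size_nm = 100, z_step_nm = 200,
                              seed = 1, max_attempts = 2000 * (n_puncta + 1)) {
  check_scalar_number(n_puncta, "n_puncta", min = 0)
  check_scalar_number(radius, "radius", min = 0.5)
  if (any(stack_shape < 2 * radius + 2)) {
    stop_domain("stack too small for the requested punctum radius")
  }
  res <- with_seed(seed, {
    centers <- matrix(numeric(0), 0, 3)
    attempts <- 0L
    while (nrow(centers) < n_puncta) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        abort(sprintf(paste0(
          "could not place %d puncta with min_separation = %g voxels in a ",
          "%s volume after %d attempts"),
          n_puncta, min_separation,
          paste(stack_shape, collapse = "x"), max_attempts),
          class = "ermechquant_generation_error")
      }
      cand <- c(runif(1, radius + 1, stack_shape[1] - radius),
                runif(1, radius + 1, stack_shape[2] - radius),
                runif(1, radius + 1, stack_shape[3] - radius))
      if (nrow(centers) == 0 ||
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) >= min_separation) {
        centers <- rbind(centers, cand)
      }
    }
    vol <- array(0, stack_shape)
    if (n_puncta > 0) {
      idx <- as.matrix(expand.grid(r = seq_len(stack_shape[1]),
                                   c = seq_len(stack_shape[2]),
                                   z = seq_len(stack_shape[3])))
      for (i in seq_len(nrow(centers))) {
        d2 <- (idx[, 1] - centers[i, 1])^2 + (idx[, 2] - centers[i, 2])^2 +
          (idx[, 3] - centers[i, 3])^2
        vol[idx[d2 <= radius^2, , drop = FALSE]] <- intensity
      }
    }
    if (noise_sd > 0) {
      vol <- pmax(vol + array(rnorm(length(vol), sd = noise_sd), stack_shape), 0)
    }
    list(vol = vol, centers = centers)
  })
  img <- cell_image(channels = list(SPLICS = res$vol),
                    pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm)
  truth <- synthetic_truth(
    "gen_puncta_volume",
    list(stack_shape_vx = stack_shape, n_puncta = n_puncta,
         radius_vx = radius, min_separation_vx = min_separation,
         intensity_au = intensity, noise_sd_au = noise_sd,
         pixel_size_nm = pixel_size_nm, z_step_nm = z_step_nm,
         centers_vx = res$centers),
    seed
  )
  list(image = img, centers = res$centers, truth = truth)
}
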