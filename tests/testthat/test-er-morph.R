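# 8-bit conversion, Renyi thresholding and ER sheet/tubule morphometry.

test_that("to_8bit maps endpoints and midpoint, preserves rank order", {
  expect_equal(as.vector(to_8bit(matrix(c(0, 0.5, 1), 1))), c(0L, 128L, 255L))

  full <- matrix(0:255, 16, 16)
  expect_equal(as.vector(to_8bit(full)), 0:255)

  withr::with_seed(5, {
    x <- matrix(rnorm(400), 20, 20)
    y8 <- to_8bit(x)
    z8 <- to_8bit(x^3)  # monotone transform of the input
    expect_true(all(diff(y8[order(x)]) >= 0))
    # order of distinct pixel values is preserved under the transform
    expect_true(all(diff(z8[order(x)]) >= 0))
  })

  expect_warning(out <- to_8bit(matrix(7, 4, 4)), "constant")
  expect_true(all(out == 0L))
  expect_true(attr(out, "degenerate"))
})

test_that("Renyi thresholds separate two-mode histograms and match the brute-force oracle", {
  twodelta <- rep(0L, 256); twodelta[51] <- 500L; twodelta[201] <- 300L
  for (mode in c("single_alpha", "three_alpha_combination")) {
    t <- renyi_threshold(twodelta, mode = mode, alpha = 2)
    expect_gte(t, 50); expect_lt(t, 200)
  }

  for (s in 1:20) {
    h <- random_bimodal_hist(s)
    for (a in c(0.5, 2)) {
      expect_identical(renyi_threshold(h, "single_alpha", alpha = a),
                       renyi_threshold_oracle(h, a))
    }
    # alpha -> 1 is the Shannon maximum-entropy threshold
    expect_identical(renyi_threshold(h, "single_alpha", alpha = 1),
                     shannon_threshold_oracle(h))
    # invariant to histogram duplication
    expect_identical(renyi_threshold(2L * h, "single_alpha", alpha = 1),
                     renyi_threshold(h, "single_alpha", alpha = 1))
  }

  single <- rep(0L, 256); single[100] <- 10L
  expect_error(renyi_threshold(single), class = "ermechquant_domain_error")
})

test_that("thresholding is equivariant under order-preserving relabelings", {
  # push occupied levels through a strictly increasing map: the selected
  # background set of occupied levels must be unchanged
  h <- random_bimodal_hist(99)
  occ <- which(h > 0) - 1L
  relabel <- seq_along(occ)  # rank map: strictly increasing, injective
  h2 <- rep(0L, 256)
  h2[relabel + 1L] <- h[occ + 1L]
  t1 <- renyi_threshold(h, "single_alpha", alpha = 1)
  t2 <- renyi_threshold(h2, "single_alpha", alpha = 1)
  expect_identical(occ[occ <= t1], occ[relabel <= t2])
})

test_that("ER segmentation recovers truth labels on separable and noisy images", {
  gn <- gen_er_cell_image(noise_sd = 0, seed = 2)
  seg0 <- segment_er(gn$image)
  expect_identical(seg0$label_image, gn$labels)

  for (s in 1:10) {
    g <- gen_er_cell_image(seed = s)
    seg <- segment_er(g$image)
    for (k in 0:2) {
      expect_gte(dice_coef(seg$label_image == k, g$labels == k), 0.90)
    }
    # label partition
    expect_identical(sum(tabulate(seg$label_image + 1L, 3L)),
                     length(seg$label_image))
  }

  # no sheets: sheet class empty or < 1% of ER pixels
  g0 <- gen_er_cell_image(sheet_fraction_target = 0, seed = 6)
  s0 <- segment_er(g0$image)
  expect_lt(sum(s0$label_image == 2L) / max(sum(s0$label_image > 0L), 1),
            0.01)
})

test_that("both segmentation strategies record their thresholds consistently", {
  g <- gen_er_cell_image(seed = 4)
  s1 <- segment_er(g$image, strategy = "double_renyi")
  expect_gte(s1$threshold_sheet, s1$threshold_er)
  s2 <- segment_er(g$image, strategy = "renyi_plus_thickness",
                   width_cutoff_px = 5)
  expect_identical(s2$strategy, "renyi_plus_thickness")
  expect_true(any(s2$label_image == 2L))  # wide blobs become sheet
})

test_that("line-segment sheet percentages follow the per-segment formula", {
  labels <- matrix(0L, 200, 200)
  nucleus <- ermechquant:::disk_mask(c(200, 200), c(100, 100), 12)

  # all-ER, all-sheet cytoplasm: every segment reads 100%
  labels[!nucleus] <- 2L
  seg <- er_segmentation(labels)
  prof <- sample_line_segments(seg, nucleus, directions = c(0, 120, 240),
                               width = 56)
  expect_equal(prof$sheet_percentage, c(100, 100, 100))

  # constructed 300 sheet / 700 tubule straight up from the nucleus
  labels2 <- matrix(0L, 200, 200)
  labels2[20:69, 80:93] <- 1L   # 700 tubule px in the upward rectangle
  labels2[20:69, 94:99] <- 2L   # 300 sheet px
  seg2 <- er_segmentation(labels2)
  prof2 <- suppressWarnings(
    sample_line_segments(seg2, nucleus, directions = c(0, 120, 240),
                         width = 56))
  expect_equal(prof2$sheet_percentage[1], 30)
  expect_equal(prof2$er_pixels[1], 1000L)
  # the other two segments contain no ER: undefined-marked with a warning
  expect_true(all(is.na(prof2$sheet_percentage[2:3])))
  suppressWarnings(
    expect_warning(sample_line_segments(seg2, nucleus,
                                        directions = c(0, 120, 240),
                                        width = 56),
                   "contains no ER"))

  expect_error(sample_line_segments(seg, matrix(FALSE, 200, 200)),
               class = "ermechquant_domain_error")
})

test_that("segment percentages are unbiased for radially uniform sheets", {
  devs <- vapply(1:10, function(s) {
    g <- gen_er_cell_image(sheet_placement = "uniform", seed = s)
    prof <- sample_line_segments(er_segmentation(g$labels),
                                 g$image$masks$nucleus,
                                 g$image$masks$cell)
    mean(prof$sheet_percentage, na.rm = TRUE) -
      100 * g$truth$parameters$realized_sheet_fraction
  }, numeric(1))
  expect_lt(abs(mean(devs)), 5)
})

test_that("sheet percentage is stable under 2x nearest-neighbor upsampling", {
  g <- gen_er_cell_image(sheet_placement = "uniform", seed = 2)
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  p1 <- sample_line_segments(er_segmentation(g$labels),
                             g$image$masks$nucleus,
                             g$image$masks$cell,
                             directions = c(10, 130, 250), width = 56)
  p2 <- sample_line_segments(er_segmentation(up(g$labels)),
                             up(g$image$masks$nucleus),
                             up(g$image$masks$cell),
                             directions = c(10, 130, 250), width = 112)
  expect_true(all(abs(p1$sheet_percentage - p2$sheet_percentage) <= 1))
})

test_that("ER area fraction is the ER share of the cytoplasm mask", {
  labels <- matrix(0L, 50, 50)
  cyto <- matrix(FALSE, 50, 50); cyto[1:40, 1:25] <- TRUE  # 1000 px
  labels[1:10, 1:25] <- 1L                                 # 250 ER px
  expect_equal(er_area_fraction(er_segmentation(labels), cyto), 0.25)

  labels2 <- matrix(0L, 50, 50); labels2[cyto] <- 2L
  expect_equal(er_area_fraction(er_segmentation(labels2), cyto), 1)

  g <- gen_er_cell_image(seed = 8)
  truth_frac <- sum(g$labels > 0L & g$image$masks$cytoplasm) /
    sum(g$image$masks$cytoplasm)
  expect_equal(er_area_fraction(er_segmentation(g$labels),
                                g$image$masks$cytoplasm), truth_frac)

  expect_error(er_area_fraction(er_segmentation(labels),
                                matrix(FALSE, 50, 50)),
               class = "ermechquant_domain_error")
})
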