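# Colocalization, ER-on-mitochondria mapping, contact extent, cortical-ER
# classes and SPLICS puncta counting.

test_that("Manders coefficients handle identical, disjoint and half-overlap channels", {
  a <- matrix(0, 32, 32); a[5:20, 5:20] <- 1
  expect_equal(manders(a, a, "zero")[, c("M1", "M2")],
               tibble::tibble(M1 = 1, M2 = 1))

  b <- matrix(0, 32, 32); b[25:30, 25:30] <- 1
  expect_equal(manders(a, b, "zero")$M1, 0)
  expect_equal(manders(a, b, "zero")$M2, 0)

  # ch1 uniform over a region exactly half-covered by ch2
  half <- matrix(0, 32, 32); half[5:20, 5:12] <- 7
  r <- manders(a, half, "zero")
  expect_equal(r$M1, 0.5)
  expect_equal(r$M2, 1)

  # channel-swap symmetry is exact
  withr::with_seed(2, {
    x <- matrix(rexp(400), 20, 20); y <- matrix(rexp(400), 20, 20)
    r1 <- manders(x, y, "otsu"); r2 <- manders(y, x, "otsu")
    expect_identical(r1$M1, r2$M2)
    expect_identical(r1$M2, r2$M1)
  })

  expect_error(manders(a, matrix(0, 32, 32), "zero"),
               class = "ermechquant_domain_error")
})

test_that("ER-on-mitochondria mapping normalizes to the ER maximum", {
  mito <- matrix(0, 40, 40); mito[10:25, 10:25] <- 100

  er_full <- matrix(1, 40, 40) * 50
  m1 <- er_on_mito_map(er_full, mito, "fixed", mito_threshold = 50)
  expect_equal(m1$mean_normalized_er_on_mito, 1)

  er_zero <- matrix(0, 40, 40); er_zero[1, 1] <- 80  # max off the mask
  m0 <- er_on_mito_map(er_zero, mito, "fixed", mito_threshold = 50)
  expect_equal(m0$mean_normalized_er_on_mito, 0)

  # ER at max on a known fraction of mitochondrial pixels
  for (s in 1:10) {
    f <- withr::with_seed(s, sample(seq(0.1, 0.9, by = 0.1), 1))
    er <- matrix(0, 40, 40)
    mito_px <- which(mito > 50)
    on <- withr::with_seed(s, sample(mito_px, round(f * length(mito_px))))
    er[on] <- 200
    m <- er_on_mito_map(er, mito, "fixed", mito_threshold = 50)
    expect_equal(m$mean_normalized_er_on_mito,
                 length(on) / length(mito_px))
  }

  expect_error(er_on_mito_map(er_full, mito, "fixed", mito_threshold = 1e5),
               class = "ermechquant_segmentation_error")
})

test_that("contact extent reproduces analytic parallel-trace fixtures", {
  p20 <- gen_membrane_pair(500, profile = list(name = "constant", gap_nm = 20))
  s20 <- contact_extent(p20$trace_a, p20$trace_b, max_gap_nm = 30)
  expect_equal(nrow(s20), 1L)
  expect_equal(s20$extent_nm, 500)
  expect_equal(s20$mean_gap_nm, 20, tolerance = 1e-6)

  p35 <- gen_membrane_pair(500, profile = list(name = "constant", gap_nm = 35))
  expect_equal(nrow(contact_extent(p35$trace_a, p35$trace_b,
                                   max_gap_nm = 30)), 0L)
})

test_that("sinusoidal-gap fixtures match the closed-form extent within 2 nm", {
  prof <- list(name = "sinusoid", gap_mean_nm = 25, gap_amplitude_nm = 10,
               period_nm = 2000, phase_nm = 0)
  g <- gen_membrane_pair(2000, profile = prof, cutoff_nm = 30)
  sites <- contact_extent(g$trace_a, g$trace_b, max_gap_nm = 30)
  expect_lt(abs(sum(sites$extent_nm) - g$analytic_extent_nm), 2)

  # total extent is symmetric in the trace order (within densification error)
  rev_sites <- contact_extent(g$trace_b, g$trace_a, max_gap_nm = 30)
  expect_lt(abs(sum(sites$extent_nm) - sum(rev_sites$extent_nm)), 2)
})

test_that("total contact extent is monotone in the gap cutoff", {
  for (s in 1:20) {
    prm <- withr::with_seed(s, list(m = runif(1, 20, 40), A = runif(1, 2, 12),
                                    TT = runif(1, 800, 3000),
                                    ph = runif(1, 0, 500)))
    g <- gen_membrane_pair(1500, profile = list(
      name = "sinusoid", gap_mean_nm = prm$m, gap_amplitude_nm = prm$A,
      period_nm = prm$TT, phase_nm = prm$ph))
    tot <- vapply(c(20, 25, 30, 35, 45), function(mg) {
      sum(contact_extent(g$trace_a, g$trace_b, max_gap_nm = mg,
                         min_run_nm = 0)$extent_nm)
    }, numeric(1))
    expect_true(all(diff(tot) >= 0))
  }
})

test_that("short grazes are suppressed by the minimum-run rule", {
  # gap dips below the cutoff only over ~63 nm around each sinusoid trough
  prof <- list(name = "sinusoid", gap_mean_nm = 32, gap_amplitude_nm = 3,
               period_nm = 400, phase_nm = 0)
  g <- gen_membrane_pair(1200, profile = prof, cutoff_nm = 30)
  few <- contact_extent(g$trace_a, g$trace_b, max_gap_nm = 30,
                        min_run_nm = 200)
  expect_equal(nrow(few), 0L)
  all_runs <- contact_extent(g$trace_a, g$trace_b, max_gap_nm = 30,
                             min_run_nm = 10)
  expect_gt(nrow(all_runs), 0L)

  expect_error(
    contact_extent(structure(list(points = matrix(0, 1, 2), organelle = "ER"),
                             class = "membrane_trace"),
                   g$trace_b),
    class = "ermechquant_domain_error")
})

test_that("cortical ER classes split at the width cutoff with a documented tie rule", {
  r <- classify_cortical_er(c(10, 50), thin_cutoff_nm = 30)
  expect_equal(r$segments$class, c("thin", "wide"))

  expect_equal(classify_cortical_er(30, 30)$segments$class, "wide")

  # bimodal widths recover the mixture weights
  w <- withr::with_seed(7, c(rlnorm(140, log(12), 0.25),
                             rlnorm(60, log(60), 0.25)))
  pr <- classify_cortical_er(w, 30)$proportions
  expect_lt(abs(pr$proportion[pr$class == "thin"] - 0.7), 0.05)

  expect_error(classify_cortical_er(numeric(0)),
               class = "ermechquant_domain_error")
  expect_error(classify_cortical_er(c(10, -4)),
               class = "ermechquant_domain_error")
})

test_that("puncta counts equal an independent flood-fill labeling", {
  for (s in 1:6) {
    g <- gen_puncta_volume(n_puncta = 5, seed = s)
    for (conn in c(6, 26)) {
      pc <- count_splics_puncta(g$image, connectivity = conn)
      oracle <- flood_fill_count_3d(
        g$image$channels$SPLICS > pc$voxel_threshold, conn)
      expect_identical(pc$count, oracle)
      expect_identical(pc$count, 5L)
    }
  }

  blank <- array(0, c(16, 16, 8))
  expect_identical(count_splics_puncta(blank)$count, 0L)
})

test_that("puncta counting is invariant to rescaling and axis permutation", {
  g <- gen_puncta_volume(n_puncta = 4, seed = 12)
  v <- g$image$channels$SPLICS
  c0 <- count_splics_puncta(v)$count
  expect_identical(count_splics_puncta(2.5 * v)$count, c0)
  expect_identical(count_splics_puncta(aperm(v, c(3, 1, 2)),
                                       connectivity = 26)$count, c0)
  expect_identical(count_splics_puncta(aperm(v, c(2, 3, 1)),
                                       connectivity = 6)$count,
                   count_splics_puncta(v, connectivity = 6)$count)
})

test_that("touching spheres merge under 26- but can split under 6-connectivity", {
  # two spheres whose shells meet only diagonally
  vol <- array(0, c(24, 24, 12))
  idx <- as.matrix(expand.grid(1:24, 1:24, 1:12))
  d1 <- sqrt((idx[, 1] - 8)^2 + (idx[, 2] - 8)^2 + (idx[, 3] - 6)^2)
  d2 <- sqrt((idx[, 1] - 14)^2 + (idx[, 2] - 14)^2 + (idx[, 3] - 6)^2)
  vol[idx[d1 <= 3.2, ]] <- 200
  vol[idx[d2 <= 3.2, ]] <- 200
  for (conn in c(6, 26)) {
    pc <- count_splics_puncta(vol, "fixed", threshold = 100,
                              connectivity = conn, min_voxels = 1)
    expect_identical(pc$count,
                     flood_fill_count_3d(vol > 100, conn))
  }
})
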