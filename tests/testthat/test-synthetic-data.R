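# Generators: determinism, ground-truth correctness, domain errors.

test_that("strain_to_displacement reproduces the worked examples and is linear", {
  expect_equal(strain_to_displacement(60, 9), 5.4)
  expect_equal(strain_to_displacement(60, 6), 3.6)
  expect_equal(strain_to_displacement(60, 0), 0)

  withr::with_seed(42, {
    L <- runif(20, 1, 200); s <- runif(20, 0, 15); k <- runif(20, 0.1, 4)
    expect_equal(strain_to_displacement(k * L, s),
                 k * strain_to_displacement(L, s))
    expect_equal(strain_to_displacement(L, k * s),
                 k * strain_to_displacement(L, s))
    expect_equal(strain_to_displacement(L + 1, s),
                 strain_to_displacement(L, s) + strain_to_displacement(1, s))
  })

  expect_error(strain_to_displacement(0, 9), class = "ermechquant_domain_error")
  expect_error(strain_to_displacement(-5, 9), class = "ermechquant_domain_error")
  expect_error(strain_to_displacement(60, -1), class = "ermechquant_domain_error")
})

test_that("decay generator matches the closed-form mixture mean and is deterministic", {
  # long window so truncation is negligible; compare the histogram mean
  # arrival time with the analytic mixture mean 0.6*6 + 0.4*2 = 4.4 ns
  g <- gen_decay_histogram(6, 2, 0.6, 1e5, bin_width_ns = 0.05,
                           n_bins = 2000, seed = 1)
  t_mid <- bin_centers(g$hist)
  m <- sum(t_mid * g$hist$counts) / g$hist$total_photons
  mix_mean <- 0.6 * 6 + 0.4 * 2
  mix_var <- (0.6 * 2 * 36 + 0.4 * 2 * 4) - mix_mean^2
  se <- sqrt(mix_var / g$hist$total_photons)
  expect_lt(abs(m - mix_mean), 3 * se)
  expect_lt(g$truth$parameters$truncation_fraction, 1e-3)

  # frac1 = 1 degenerates to a single exponential with lifetime tau1
  g1 <- gen_decay_histogram(6, 2, 1, 1e5, bin_width_ns = 0.05,
                            n_bins = 2000, seed = 2)
  m1 <- sum(bin_centers(g1$hist) * g1$hist$counts) / g1$hist$total_photons
  expect_lt(abs(m1 - 6), 3 * 6 / sqrt(g1$hist$total_photons))

  # bit-for-bit determinism in (parameters, seed)
  expect_identical(gen_decay_histogram(6, 2, 0.6, 1e4, seed = 7)$hist,
                   gen_decay_histogram(6, 2, 0.6, 1e4, seed = 7)$hist)
  expect_false(identical(gen_decay_histogram(6, 2, 0.6, 1e4, seed = 7)$hist,
                         gen_decay_histogram(6, 2, 0.6, 1e4, seed = 8)$hist))

  expect_error(gen_decay_histogram(2, 6, 0.6, 1e4),
               class = "ermechquant_domain_error")
  expect_error(gen_decay_histogram(6, 2, 0.6, 0),
               class = "ermechquant_domain_error")
})

test_that("ER cell generator hits its sheet-fraction target with consistent truth", {
  for (s in 1:10) {
    g <- gen_er_cell_image(seed = s)
    expect_lt(abs(g$truth$parameters$realized_sheet_fraction - 0.3), 0.05)
  }

  g0 <- gen_er_cell_image(sheet_fraction_target = 0, seed = 1)
  expect_identical(sum(g0$labels == 2L), 0L)

  gn <- gen_er_cell_image(noise_sd = 0, seed = 3)
  expect_setequal(unique(as.vector(gn$image$channels$ER)), c(20, 100, 220))
  # label partition: every pixel is exactly one of the three classes
  expect_identical(sum(tabulate(gn$labels + 1L, 3L)), length(gn$labels))
  # cytoplasm mask excludes nucleus by construction
  expect_false(any(gn$image$masks$cytoplasm & gn$image$masks$nucleus))

  expect_error(gen_er_cell_image(nucleus_radius = 300),
               class = "ermechquant_domain_error")
})

test_that("membrane-pair gap profiles carry exact analytic extents", {
  p <- gen_membrane_pair(500, profile = list(name = "constant", gap_nm = 20),
                         cutoff_nm = 30)
  expect_equal(p$analytic_extent_nm, 500)
  expect_equal(
    gen_membrane_pair(500, profile = list(name = "constant", gap_nm = 35),
                      cutoff_nm = 30)$analytic_extent_nm, 0)

  # sinusoid crossing the cutoff: closed form vs 0.01 nm numerical grid
  prof <- list(name = "sinusoid", gap_mean_nm = 25, gap_amplitude_nm = 10,
               period_nm = 2000, phase_nm = 137)
  g <- gen_membrane_pair(2000, profile = prof, cutoff_nm = 30)
  num <- numeric_extent_oracle(
    function(s) 25 + 10 * sin(2 * pi * (s + 137) / 2000), 2000, 30)
  expect_lt(abs(g$analytic_extent_nm - num), 0.05)

  # linear ramp crossing
  gl <- gen_membrane_pair(100, profile = list(name = "linear",
                                              gap_start_nm = 10,
                                              gap_end_nm = 50), cutoff_nm = 30)
  expect_equal(gl$analytic_extent_nm, 50)

  expect_error(gen_membrane_pair(100, profile = list(name = "sawtooth")),
               class = "ermechquant_config_error")
})

test_that("fiber generator follows the axial von Mises design and conventions", {
  gi <- gen_fiber_image(n_fibers = 5, mean_angle_deg = 37,
                        concentration = Inf, seed = 1)
  expect_true(all(gi$angles_deg == 37))

  # kappa = 0: uniform axial distribution, circular variance of doubled
  # angles near 1 (Monte-Carlo error ~ 1/sqrt(n))
  g0 <- gen_fiber_image(image_shape = c(64, 64), n_fibers = 500,
                        concentration = 0, seed = 4)
  a2 <- 2 * g0$angles_deg * pi / 180
  V <- 1 - sqrt(mean(cos(a2))^2 + mean(sin(a2))^2)
  expect_lt(abs(V - 1), 0.15)

  # a fiber at 90 degrees is a horizontal line: bright pixels span many
  # columns but few rows
  gh <- gen_fiber_image(image_shape = c(128, 128), n_fibers = 1,
                        mean_angle_deg = 90, concentration = Inf,
                        noise_sd = 0, blur_sigma_px = 0, seed = 2)
  bright <- which(gh$image$channels$actin > 100, arr.ind = TRUE)
  expect_lt(diff(range(bright[, 1])), 6)
  expect_gt(diff(range(bright[, 2])), 40)

  expect_error(gen_fiber_image(n_fibers = 0),
               class = "ermechquant_domain_error")
})

test_that("puncta generator packs separated spheres or fails loudly", {
  g0 <- gen_puncta_volume(n_puncta = 0, noise_sd = 0, seed = 1)
  expect_true(all(g0$image$channels$SPLICS == 0))

  g <- gen_puncta_volume(n_puncta = 5, radius = 3, min_separation = 12,
                         noise_sd = 0, seed = 3)
  expect_identical(flood_fill_count_3d(g$image$channels$SPLICS > 100, 26), 5L)
  d <- as.matrix(dist(g$centers))
  expect_gte(min(d[upper.tri(d)]), 12)

  err <- expect_error(
    gen_puncta_volume(stack_shape = c(16, 16, 8), n_puncta = 50, radius = 3,
                      max_attempts = 500),
    class = "ermechquant_generation_error")
  expect_match(conditionMessage(err), "min_separation")
})

test_that("SOCE generator reproduces the re-addition protocol phases", {
  flat <- gen_soce_trace(2, 2, noise_sd = 0, seed = 1)
  expect_true(all(flat$trace$F == 2))

  g <- gen_soce_trace(1, 3, noise_sd = 0, seed = 1)
  pm <- attr(g$trace, "phase_marks")
  expect_equal(unname(pm), c(0, 300, 2100))  # 5 min wash + 30 min depletion
  expect_equal(diff(g$trace$time_s), rep(5, nrow(g$trace) - 1))
  post <- g$trace$F[g$trace$time_s >= pm[["readdition"]]]
  expect_equal(max(post), 3)  # sampled maximum equals peak_F exactly

  expect_error(gen_soce_trace(0, 3), class = "ermechquant_domain_error")
  expect_error(gen_soce_trace(2, 1), class = "ermechquant_domain_error")
})
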