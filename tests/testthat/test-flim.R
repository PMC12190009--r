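# Biexponential decay fitting and the tension-lifetime report.

exact_biexp_hist <- function(tau1 = 6, tau2 = 2, frac1 = 0.6, scale = 1e6,
                             bin_width = 0.05, n_bins = 500) {
  edges <- seq(0, n_bins * bin_width, by = bin_width)
  t <- (head(edges, -1) + tail(edges, -1)) / 2
  mu <- frac1 * exp(-t / tau1) + (1 - frac1) * exp(-t / tau2)
  decay_histogram(edges, round(mu * scale))
}

test_that("noiseless model data are recovered to high precision", {
  h <- exact_biexp_hist()
  fit <- fit_biexponential(h, fit_background = FALSE)
  expect_true(fit$converged)
  expect_equal(fit$tau1_ns, 6, tolerance = 1e-4)
  expect_equal(fit$tau2_ns, 2, tolerance = 1e-4)
  expect_equal(fit$amp1 / (fit$amp1 + fit$amp2), 0.6, tolerance = 1e-3)
  expect_lt(fit$reduced_chi2, 0.01)
})

test_that("components are always reported in canonical tau1 >= tau2 order", {
  for (s in 1:8) {
    g <- gen_decay_histogram(6, 2, 0.6, 2e4, seed = s)
    fit <- fit_biexponential(g$hist)
    expect_gte(fit$tau1_ns, fit$tau2_ns)
    expect_gt(fit$tau2_ns, 0)
  }
})

test_that("weighted least squares is scale-equivariant on noiseless data", {
  h1 <- exact_biexp_hist(scale = 2e5)
  h4 <- decay_histogram(h1$bin_edges, 4L * h1$counts)
  f1 <- fit_biexponential(h1, fit_background = FALSE, loss = "weighted_lsq")
  f4 <- fit_biexponential(h4, fit_background = FALSE, loss = "weighted_lsq")
  expect_equal(f1$tau1_ns, f4$tau1_ns, tolerance = 1e-6)
  expect_equal(f1$tau2_ns, f4$tau2_ns, tolerance = 1e-6)
  expect_equal(4 * f1$amp1, f4$amp1, tolerance = 1e-4)
})

test_that("single-exponential input collapses to a flagged mono fit near truth", {
  g <- gen_decay_histogram(6, 2, 1, 1e5, seed = 11)  # frac1 = 1
  fit <- fit_biexponential(g$hist)
  expect_true(fit$flag == "effectively monoexponential" ||
                fit$amp2 < 0.01 * (fit$amp1 + fit$amp2))
  expect_equal(fit$tau1_ns, 6, tolerance = 0.02)
  # agree with an independently coded one-component fit
  expect_equal(fit$tau1_ns, mono_fit_oracle(g$hist), tolerance = 0.02)
})

test_that("photon gating rejects sparse histograms with a typed error", {
  g <- gen_decay_histogram(6, 2, 0.6, 500, seed = 1)
  expect_error(fit_biexponential(g$hist), class = "ermechquant_gating_error")
  expect_s3_class(fit_biexponential(g$hist, min_photons = 100), "biexp_fit")
})

test_that("tension report returns tau1 and flags amplitude-order violations", {
  g <- gen_decay_histogram(6, 2, 0.85, 1e5, seed = 3)
  fit <- fit_biexponential(g$hist)

  ok_fit <- fit
  ok_fit$amp1 <- 0.7; ok_fit$amp2 <- 0.3
  ok_fit$amplitude_order_consistent <- TRUE
  rep <- report_tension_lifetime(ok_fit)
  expect_equal(rep$tau_report_ns, ok_fit$tau1_ns)
  expect_identical(rep$flag, "ok")

  bad_fit <- fit
  bad_fit$amp1 <- 0.3; bad_fit$amp2 <- 0.7
  bad_fit$amplitude_order_consistent <- FALSE
  rep2 <- report_tension_lifetime(bad_fit)
  expect_equal(rep2$tau_report_ns, bad_fit$tau1_ns)  # still the longer one
  expect_identical(rep2$flag, "amplitude_order_violated")

  nc <- fit; nc$converged <- FALSE
  expect_error(report_tension_lifetime(nc),
               class = "ermechquant_usage_error")
})

test_that("amplitude-dominant long component yields no violation flags at high counts", {
  # frac1 = 0.85 puts the higher amplitude on the longer lifetime
  flags <- vapply(1:10, function(s) {
    g <- gen_decay_histogram(6, 2, 0.85, 1e5, seed = s)
    report_tension_lifetime(fit_biexponential(g$hist))$flag
  }, character(1))
  expect_true(all(flags == "ok"))
})

test_that("lifetime maps bin, gate and match the pooled-ROI fit", {
  edges <- seq(0, 25, by = 0.05)
  make_stack <- function(taus, photons_px) {
    counts <- array(0L, c(dim(taus), 500))
    for (i in seq_len(nrow(taus))) for (j in seq_len(ncol(taus))) {
      g <- gen_decay_histogram(taus[i, j], 2, 0.6, photons_px,
                               seed = 1000 + i * 37 + j)
      counts[i, j, ] <- g$hist$counts
    }
    pixel_decay_stack(counts, edges)
  }

  # homogeneous field (identical decay in every pixel): uniform map whose
  # mean equals the pooled-ROI fit
  g1 <- gen_decay_histogram(6, 2, 0.6, 2e4, seed = 77)
  counts <- array(rep(g1$hist$counts, each = 16), c(4, 4, 500))
  st <- pixel_decay_stack(counts, edges)
  map <- fit_lifetime_map(st, min_photons = 1000)
  expect_true(all(is.finite(map$tau1_image)))
  expect_lt(diff(range(map$tau1_image)), 1e-8)  # exactly uniform
  pooled <- fit_biexponential(
    decay_histogram(edges, apply(st$counts, 3, sum)))
  expect_equal(mean(map$tau1_image), pooled$tau1_ns, tolerance = 0.01)

  # two-region field separated by > 1 ns
  taus2 <- cbind(matrix(6, 4, 2), matrix(4, 4, 2))
  map2 <- fit_lifetime_map(make_stack(taus2, 1e4), min_photons = 1000)
  expect_gt(mean(map2$tau1_image[, 1:2]) - mean(map2$tau1_image[, 3:4]), 1)

  # everything below the gate: all-NA map, no error
  map3 <- fit_lifetime_map(make_stack(matrix(6, 2, 2), 200),
                           min_photons = 1e5)
  expect_true(all(is.na(map3$tau1_image)))

  expect_error(pixel_decay_stack(array(0L, c(2, 2, 10)), seq(0, 1, by = 0.2)),
               class = "ermechquant_format_error")
})

test_that("group summaries are exact and order-invariant", {
  d <- tibble::tibble(group = c("a", "a", "a", "b", "b", "b"),
                      tau = c(4, 4, 4, 2, 4, 6))
  s <- summarize_groups(d, tau, group)
  expect_equal(s$mean, c(4, 4))
  expect_equal(s$sem, c(0, 2 / sqrt(3)))
  expect_equal(s$n, c(3L, 3L))

  s2 <- summarize_groups(d[sample(6), ], tau, group)
  expect_equal(s2, s)

  expect_error(summarize_groups(d[0, ], tau, group),
               class = "ermechquant_domain_error")
})

test_that("tidy and glance methods expose the fit as tibbles", {
  fit <- fit_biexponential(exact_biexp_hist(), fit_background = FALSE)
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$term[1:2], c("tau1_ns", "tau2_ns"))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_true(gl$converged)
})
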