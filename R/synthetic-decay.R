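#' Convert applied strain to uniaxial displacement
#'
#' For a stretched domain of given length, the uniaxial displacement that
#' realizes a percent strain is `length * strain / 100` (e.g. 9% strain of a
#' 60 um domain is a 5.4 um displacement). Vectorized over both arguments.
#'
#' @param length_um Domain length in micrometres (> 0).
#' @param strain_pct Engineering strain in percent (>= 0).
#'
#' @return Displacement in micrometres.
#' @export
#'
#' @examples
#' strain_to_displacement(60, 9)  # 5.4
#' strain_to_displacement(60, 6)  # 3.6
strain_to_displacement <- function(length_um, strain_pct) {
  if (!is.numeric(length_um) || any(!is.finite(length_um)) ||
      any(length_um <= 0)) {
    stop_domain("`length_um` must be positive and finite.")
  }
  if (!is.numeric(strain_pct) || any(!is.finite(strain_pct)) ||
      any(strain_pct < 0)) {
    stop_domain("`strain_pct` must be non-negative and finite.")
  }
  length_um * strain_pct / 100
}

#' Simulate a TCSPC biexponential decay histogram
#'
#' Draws photon arrival times from a two-component exponential mixture with
#' optional uniform background and Gaussian instrument-response jitter, then
#' bins them into a finite acquisition window the way a TCSPC card would.
#' The total photon number is Poisson distributed around `n_photons`; arrivals
#' falling outside the window are discarded and the discarded fraction is
#' recorded in the truth (`truncation_fraction`).
#'
#' By package-wide convention `tau1` is the longer lifetime.
#'
#' @param tau1_ns Longer lifetime (ns), `tau1_ns > tau2_ns > 0`.
#' @param tau2_ns Shorter lifetime (ns).
#' @param frac1 Fraction of signal photons in component 1, in (0, 1].
#' @param n_photons Expected total photon count (>= 1).
#' @param bin_width_ns Histogram bin width (ns). Default 0.05 ns.
#' @param n_bins Number of bins. Default 500, giving a 25 ns acquisition
#'   window (a 40 MHz sync rate): roughly four long lifetimes of decay,
#'   enough to separate a ~6 ns tail from a constant background.
#' @param background_frac Fraction of photons that are uniform background,
#'   in `[0, 1)`.
#' @param irf_sigma_ns Gaussian instrument-response width (ns); 0 disables.
#' @param seed Integer seed.
#'
#' @return A list with elements `hist` (a [decay_histogram()]) and `truth`
#'   (a [synthetic_truth()] recording all parameters plus the realized
#'   photon number and truncation fraction).
#' @export
gen_decay_histogram <- function(tau1_ns, tau2_ns, frac1, n_photons,
                                bin_width_ns = 0.05, n_bins = 500,
                                background_frac = 0, irf_sigma_ns = 0,
                                seed = 1) {
  check_scalar_number(tau2_ns, "tau2_ns", min = 0, strict_min = TRUE)
  check_scalar_number(tau1_ns, "tau1_ns", min = 0, strict_min = TRUE)
  if (tau1_ns <= tau2_ns) {
    stop_domain("`tau1_ns` must exceed `tau2_ns`: tau1 is the longer lifetime.")
  }
  check_scalar_number(frac1, "frac1", min = 0, max = 1, strict_min = TRUE)
  check_scalar_number(n_photons, "n_photons", min = 1)
  check_scalar_number(bin_width_ns, "bin_width_ns", min = 0, strict_min = TRUE)
  check_scalar_number(n_bins, "n_bins", min = 8)
  check_scalar_number(background_frac, "background_frac", min = 0, max = 1 - 1e-12)
  check_scalar_number(irf_sigma_ns, "irf_sigma_ns", min = 0)

  window_ns <- bin_width_ns * n_bins
  sim <- with_seed(seed, {
    n_total <- rpois(1L, n_photons)
    is_bg <- runif(n_total) < background_frac
    n_bg <- sum(is_bg)
    n_sig <- n_total - n_bg
    comp1 <- runif(n_sig) < frac1
    t_sig <- ifelse(comp1, rexp(n_sig, rate = 1 / tau1_ns),
                    rexp(n_sig, rate = 1 / tau2_ns))
    if (irf_sigma_ns > 0) t_sig <- t_sig + rnorm(n_sig, sd = irf_sigma_ns)
    t_all <- c(t_sig, runif(n_bg, 0, window_ns))
    keep <- t_all >= 0 & t_all < window_ns
    list(t = t_all[keep], n_total = n_total,
         trunc_frac = if (n_total > 0) 1 - sum(keep) / n_total else 0)
  })

  counts <- tabulate(pmin(floor(sim$t / bin_width_ns) + 1L, n_bins),
                     nbins = n_bins)
  hist <- decay_histogram(seq(0, window_ns, by = bin_width_ns)[1:(n_bins + 1L)],
                          counts)
  truth <- synthetic_truth(
    "gen_decay_histogram",
    list(
      tau1_ns = tau1_ns, tau2_ns = tau2_ns, frac1 = frac1,
      n_photons_expected = n_photons, n_photons_realized = sim$n_total,
      bin_width_ns = bin_width_ns, n_bins = n_bins,
      window_ns = window_ns, background_frac = background_frac,
      irf_sigma_ns = irf_sigma_ns, truncation_fraction = sim$trunc_frac
    ),
    seed
  )
  list(hist = hist, truth = truth)
}

#' Simulate a store-operated calcium entry trace
#'
#' Emulates the calcium re-addition protocol on a 5-s sampling grid:
#' 5 min of Ca2+-free wash, 30 min of thapsigargin store depletion, then
#' Ca2+ re-addition producing a double-exponential influx transient whose
#' sampled maximum equals `peak_F`. Gaussian measurement noise is added on
#' top. Phase boundary times are recorded in the trace and the truth.
#'
#' @param baseline_F Baseline fluorescence (a.u., > 0).
#' @param peak_F Peak fluorescence after re-addition (>= `baseline_F`).
#' @param rise_tau_s Rise time constant of the transient (s).
#' @param decay_tau_s Decay time constant (s), greater than `rise_tau_s`.
#' @param noise_sd Gaussian noise standard deviation (a.u.).
#' @param seed Integer seed.
#' @param wash_s,depletion_s,post_s Phase durations in seconds (defaults
#'   300 s wash, 1800 s depletion, 600 s recorded after re-addition).
#'
#' @return A list with elements `trace` (a [soce_trace()]) and `truth`.
#' @export
gen_soce_trace <- function(baseline_F, peak_F, rise_tau_s = 15,
                           decay_tau_s = 120, noise_sd = 0, seed = 1,
                           wash_s = 300, depletion_s = 1800, post_s = 600) {
  check_scalar_number(baseline_F, "baseline_F", min = 0, strict_min = TRUE)
  check_scalar_number(peak_F, "peak_F", min = baseline_F)
  check_scalar_number(rise_tau_s, "rise_tau_s", min = 0, strict_min = TRUE)
  check_scalar_number(decay_tau_s, "decay_tau_s", min = rise_tau_s,
                      strict_min = TRUE)
  check_scalar_number(noise_sd, "noise_sd", min = 0)

  dt <- 5  # acquisition every 5 s, per protocol
  readd <- wash_s + depletion_s
  time_s <- seq(0, readd + post_s, by = dt)
  f <- rep(baseline_F, length(time_s))
  post <- time_s >= readd
  tp <- time_s[post] - readd
  g <- exp(-tp / decay_tau_s) - exp(-tp / rise_tau_s)
  gmax <- max(g)
  if (gmax > 0) f[post] <- baseline_F + (peak_F - baseline_F) * g / gmax
  if (noise_sd > 0) {
    f <- with_seed(seed, f + rnorm(length(f), sd = noise_sd))
    f <- pmax(f, 1e-6)  # fluorescence stays positive
  }
  trace <- soce_trace(time_s, f, c(ca_free_start = 0, depletion_start = wash_s,
                                   readdition = readd))
  truth <- synthetic_truth(
    "gen_soce_trace",
    list(baseline_F_au = baseline_F, peak_F_au = peak_F,
         rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
         noise_sd_au = noise_sd, sampling_s = dt,
         ca_free_start_s = 0, depletion_start_s = wash_s,
         readdition_s = readd,
         normalized_max_true = peak_F / baseline_F),
    seed
  )
  list(trace = trace, truth = truth)
}
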