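# Paired-membrane fixtures with an analytically known contact extent.

# Measure of {x in [a, b] : sin(x) <= q}, computed from the closed-form
# per-period crossing intervals.
measure_sin_le <- function(a, b, q) {
  if (q >= 1) return(b - a)
  if (q <= -1) return(0)
  alpha <- asin(q)
  # sin(x) <= q on [0, 2*pi): [0, alpha] u [pi - alpha, 2*pi) for q >= 0,
  # and [pi - alpha, 2*pi + alpha] (a single interval) for q < 0.
  region <- if (q >= 0) {
    rbind(c(0, alpha), c(pi - alpha, 2 * pi))
  } else {
    rbind(c(pi - alpha, 2 * pi + alpha))
  }
  per_period <- pi + 2 * alpha
  m_partial <- function(x) {  # measure on [0, x], 0 <= x <= 2*pi (+ eps)
    sum(pmax(0, pmin(region[, 2], x) - region[, 1]))
  }
  m0 <- function(x) {  # measure on [0, x], x >= 0
    k <- floor(x / (2 * pi))
    k * per_period + m_partial(x - k * 2 * pi)
  }
  shift <- ceiling(max(0, -a) / (2 * pi)) * 2 * pi
  m0(b + shift) - m0(a + shift)
}

profile_gap <- function(profile, s, span) {
  switch(profile$name,
    constant = rep(profile$gap_nm, length(s)),
    linear = profile$gap_start_nm +
      (profile$gap_end_nm - profile$gap_start_nm) * s / span,
    sinusoid = profile$gap_mean_nm + profile$gap_amplitude_nm *
      sin(2 * pi * (s + (profile$phase_nm %||% 0)) / profile$period_nm),
    stop_config(sprintf("unknown gap profile '%s'", profile$name))
  )
}

profile_extent <- function(profile, span, cutoff) {
  switch(profile$name,
    constant = if (profile$gap_nm <= cutoff) span else 0,
    linear = {
      g0 <- profile$gap_start_nm; g1 <- profile$gap_end_nm
      if (g0 == g1) {
        if (g0 <= cutoff) span else 0
      } else {
        s_star <- span * (cutoff - g0) / (g1 - g0)
        lo <- if (g0 <= cutoff) 0 else max(0, min(span, s_star))
        hi <- if (g1 <= cutoff) span else max(0, min(span, s_star))
        max(0, hi - lo)
      }
    },
    sinusoid = {
      A <- profile$gap_amplitude_nm
      if (A == 0) {
        if (profile$gap_mean_nm <= cutoff) span else 0
      } else {
        q <- (cutoff - profile$gap_mean_nm) / A
        omega <- 2 * pi / profile$period_nm
        x0 <- omega * (profile$phase_nm %||% 0)
        measure_sin_le(x0, x0 + omega * span, q) / omega
      }
    },
    stop_config(sprintf("unknown gap profile '%s'", profile$name))
  )
}

#' Generate a pair of membrane traces with a prescribed gap profile
#'
#' Builds two polylines: a straight reference membrane of length `span_nm`
#' and a partner whose normal offset follows a named gap profile (constant,
#' linear ramp or sinusoid). The arc length over which the profile gap is at
#' or below `cutoff_nm` is computed in closed form and returned as the
#' analytic contact extent, the oracle for [contact_extent()] recovery tests.
#'
#' For gently modulated profiles (slope much less than 1) the pointwise
#' profile gap and the true inter-membrane distance agree closely; steep
#' profiles make the analytic extent an approximation to the measured one.
#'
#' @param span_nm Trace length in nm.
#' @param sampling_step_nm Point spacing of the generated polylines (nm).
#' @param profile Named list describing the gap profile. One of
#'   `list(name = "constant", gap_nm =)`,
#'   `list(name = "linear", gap_start_nm =, gap_end_nm =)`,
#'   `list(name = "sinusoid", gap_mean_nm =, gap_amplitude_nm =, period_nm =,
#'   phase_nm = 0)`.
#' @param cutoff_nm Contact cutoff used for the analytic extent (default
#'   30 nm, the reciprocal-distance definition used for ER-mitochondria and
#'   PM-ER contact sites).
#' @param organelles Character vector of length 2 labelling the two traces.
#'
#' @return A list with `trace_a`, `trace_b` ([membrane_trace()] objects),
#'   `analytic_extent_nm` and `truth`.
#' @export
gen_membrane_pair <- function(span_nm = 500, sampling_step_nm = 1,
                              profile = list(name = "constant", gap_nm = 20),
                              cutoff_nm = 30,
                              organelles = c("ER", "mitochondrion")) {
  check_scalar_number(span_nm, "span_nm", min = 0, strict_min = TRUE)
  check_scalar_number(sampling_step_nm, "sampling_step_nm", min = 0,
                      strict_min = TRUE)
  if (is.null(profile$name)) stop_config("`profile` must carry a `name`")
  s <- seq(0, span_nm, by = sampling_step_nm)
  if (s[length(s)] < span_nm) s <- c(s, span_nm)
  gap <- profile_gap(profile, s, span_nm)
  if (any(gap <= 0)) stop_domain("gap profile must stay positive")
  trace_a <- membrane_trace(cbind(s, 0), organelle = organelles[1],
                            max_spacing_nm = sampling_step_nm)
  trace_b <- membrane_trace(cbind(s, gap), organelle = organelles[2],
                            max_spacing_nm = sampling_step_nm)
  extent <- profile_extent(profile, span_nm, cutoff_nm)
  truth <- synthetic_truth(
    "gen_membrane_pair",
    list(span_nm = span_nm, sampling_step_nm = sampling_step_nm,
         profile = profile, cutoff_nm = cutoff_nm,
         analytic_extent_nm = extent),
    seed = 0  # fully deterministic generator
  )
  list(trace_a = trace_a, trace_b = trace_b, analytic_extent_nm = extent,
       truth = truth)
}
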