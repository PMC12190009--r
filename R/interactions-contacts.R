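# Membrane contact-site extent from digitized membrane traces.

# Minimum distance from each point in P (n x 2) to the polyline with
# vertices Q (m x 2), computed against every segment, in row chunks to
# bound memory.
min_dist_to_polyline <- function(P, Q, chunk = 256L) {
  m <- nrow(Q)
  S <- Q[-m, , drop = FALSE]
  D <- Q[-1, , drop = FALSE] - S
  L2 <- pmax(rowSums(D^2), 1e-300)
  out <- numeric(nrow(P))
  for (start in seq(1L, nrow(P), by = chunk)) {
    ii <- start:min(start + chunk - 1L, nrow(P))
    ax <- P[ii, 1]; ay <- P[ii, 2]
    tx <- outer(ax, S[, 1], "-")
    ty <- outer(ay, S[, 2], "-")
    tt <- (sweep(tx, 2, D[, 1], "*") + sweep(ty, 2, D[, 2], "*"))
    tt <- pmin(pmax(sweep(tt, 2, L2, "/"), 0), 1)
    dx <- tx - sweep(tt, 2, D[, 1], "*")
    dy <- ty - sweep(tt, 2, D[, 2], "*")
    out[ii] <- sqrt(apply(dx * dx + dy * dy, 1, min))
  }
  out
}

#' Measure membrane contact sites between two traces
#'
#' For every point along `trace_a` the gap is the minimum Euclidean distance
#' to `trace_b`. Maximal runs of consecutive points with gap at or below
#' `max_gap_nm`, of arc length at least `min_run_nm`, become contact sites
#' whose extent is the run's arc length along `trace_a` (the planar
#' arc-length definition used for sectioned electron micrographs, with the
#' 30 nm reciprocal-distance convention as default).
#'
#' The `"reciprocal"` mode (default) additionally requires each contact
#' point on `trace_a` to lie within `max_gap_nm` of the set of `trace_b`
#' points that are themselves within `max_gap_nm` of `trace_a`, which
#' suppresses one-sided overhangs. `"one_sided"` skips that check.
#'
#' @param trace_a,trace_b [membrane_trace()] objects (internally densified
#'   to at most 1 nm point spacing).
#' @param max_gap_nm Contact gap cutoff in nm (default 30).
#' @param min_run_nm Minimum contact arc length in nm (default 10;
#'   suppresses single-point grazes).
#' @param mode `"reciprocal"` (default) or `"one_sided"`.
#'
#' @return A tibble with one row per contact site: `site_id`, `partner_a`,
#'   `partner_b`, `start_nm`, `end_nm` (arc positions along `trace_a`),
#'   `extent_nm`, `mean_gap_nm`, `max_gap_used_nm`. Zero rows when no
#'   contact exists.
#' @export
contact_extent <- function(trace_a, trace_b, max_gap_nm = 30,
                           min_run_nm = 10,
                           mode = c("reciprocal", "one_sided")) {
  mode <- match.arg(mode)
  stopifnot(inherits(trace_a, "membrane_trace"),
            inherits(trace_b, "membrane_trace"))
  check_scalar_number(max_gap_nm, "max_gap_nm", min = 0, strict_min = TRUE)
  check_scalar_number(min_run_nm, "min_run_nm", min = 0)

  A <- densify_polyline(trace_a$points, 1)
  B <- densify_polyline(trace_b$points, 1)
  if (nrow(A) < 2L || nrow(B) < 2L) stop_domain("degenerate trace (< 2 points)")

  gap_a <- min_dist_to_polyline(A, B)
  contact <- gap_a <= max_gap_nm
  if (mode == "reciprocal" && any(contact)) {
    gap_b <- min_dist_to_polyline(B, A)
    b_contact <- B[gap_b <= max_gap_nm, , drop = FALSE]
    if (nrow(b_contact) >= 2L) {
      back <- min_dist_to_polyline(A[contact, , drop = FALSE], b_contact)
      contact[contact] <- back <= max_gap_nm
    } else {
      contact[] <- FALSE
    }
  }

  arc <- c(0, cumsum(sqrt(rowSums(diff(A)^2))))
  empty <- tibble(
    site_id = integer(0), partner_a = character(0), partner_b = character(0),
    start_nm = numeric(0), end_nm = numeric(0), extent_nm = numeric(0),
    mean_gap_nm = numeric(0), max_gap_used_nm = numeric(0)
  )
  if (!any(contact)) return(empty)

  r <- rle(contact)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  sites <- purrr::map_dfr(runs, function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    tibble(start_nm = as.numeric(arc[i0]), end_nm = as.numeric(arc[i1]),
           extent_nm = as.numeric(arc[i1] - arc[i0]),
           mean_gap_nm = as.numeric(mean(gap_a[i0:i1])))
  })
  sites <- sites[sites$extent_nm >= min_run_nm, , drop = FALSE]
  if (nrow(sites) == 0L) return(empty)
  tibble(
    site_id = seq_len(nrow(sites)),
    partner_a = trace_a$organelle,
    partner_b = trace_b$organelle,
    start_nm = sites$start_nm,
    end_nm = sites$end_nm,
    extent_nm = sites$extent_nm,
    mean_gap_nm = sites$mean_gap_nm,
    max_gap_used_nm = max_gap_nm
  )
}

#' Classify cortical ER segments as thin or wide
#'
#' Cortical ER (ER apposed to the plasma membrane) appears in sections as
#' heterogeneous segments with narrow or dilated lumina. Segments with lumen
#' width below `thin_cutoff_nm` are `thin`; widths at or above the cutoff
#' are `wide` (boundary convention: exactly at the cutoff is wide).
#'
#' @param lumen_widths_nm Positive lumen widths, one per cortical-ER
#'   segment.
#' @param thin_cutoff_nm Class cutoff in nm (default 30).
#'
#' @return A list with `segments` (tibble: `width_nm`, `class`) and
#'   `proportions` (tibble: `class`, `n`, `proportion`; both classes always
#'   present).
#' @export
classify_cortical_er <- function(lumen_widths_nm, thin_cutoff_nm = 30) {
  if (length(lumen_widths_nm) == 0) stop_domain("no lumen widths supplied")
  if (any(!is.finite(lumen_widths_nm)) || any(lumen_widths_nm <= 0)) {
    stop_domain("lumen widths must be positive")
  }
  cls <- ifelse(lumen_widths_nm < thin_cutoff_nm, "thin", "wide")
  segments <- tibble(width_nm = as.numeric(lumen_widths_nm), class = cls)
  proportions <- tibble(class = c("thin", "wide")) |>
    dplyr::left_join(dplyr::count(segments, .data$class), by = "class") |>
    dplyr::mutate(
      n = dplyr::coalesce(.data$n, 0L),
      proportion = .data$n / length(lumen_widths_nm)
    )
  list(segments = segments, proportions = proportions)
}
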