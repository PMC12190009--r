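# Internal validation helpers. All user-facing errors go through rlang::abort
# with a class so callers can condition on them.

stop_domain <- function(msg, ...) abort(msg, class = "ermechquant_domain_error", ...)
stop_config <- function(msg, ...) abort(msg, class = "ermechquant_config_error", ...)
stop_io     <- function(msg, ...) abort(msg, class = "ermechquant_io_error", ...)

check_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                strict_min = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("`%s` must be a single finite number.", name))
  }
  if ((strict_min && x <= min) || (!strict_min && x < min) || x > max) {
    stop_domain(sprintf(
      "`%s` = %g is outside its allowed range (%s%g, %g].",
      name, x, if (strict_min) "(" else "[", min, max
    ))
  }
  invisible(x)
}

check_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_domain(sprintf("`%s` must be a numeric matrix.", name))
  }
  invisible(x)
}

check_mask <- function(mask, name, dim_ref = NULL) {
  if (!is.logical(mask) && !all(mask %in% c(0, 1, NA))) {
    stop_domain(sprintf("`%s` must be a logical (binary) mask.", name))
  }
  m <- array(as.logical(mask), dim = dim(mask))
  if (!is.null(dim_ref) && !identical(dim(m), as.integer(dim_ref))) {
    stop_domain(sprintf("`%s` must share the image shape.", name))
  }
  m
}

# Restricts a seed derived from arithmetic to the 32-bit integer range.
as_seed <- function(seed) {
  if (is.null(seed)) stop_config("A `seed` is required for reproducibility.")
  as.integer(abs(as.numeric(seed)) %% .Machine$integer.max)
}

# Every generator funnels its randomness through this wrapper so the caller's
# RNG state is never touched and identical (params, seed) reproduce bit-for-bit.
with_seed <- function(seed, code) {
  withr::with_seed(as_seed(seed), code)
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi
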