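#' Default echo-time grid
#'
#' The eight-echo turbo-spin-echo grid used throughout the package:
#' TE = 13, 26, ..., 104 ms (13 ms spacing).
#'
#' @return Numeric vector of echo times in milliseconds.
#' @export
default_echo_times <- function() {
  seq(13, 104, by = 13)
}

#' Validate an echo-time grid
#'
#' Echo times must be strictly increasing and positive.
#'
#' @param tes numeric vector of echo times (ms).
#' @return `tes`, invisibly, after validation.
#' @export
validate_echo_times <- function(tes) {
  if (!is.numeric(tes) || length(tes) < 1L || anyNA(tes)) {
    stop("echo times must be a non-empty numeric vector without NAs",
         call. = FALSE)
  }
  if (any(tes <= 0)) stop("echo times must be positive", call. = FALSE)
  if (is.unsorted(tes, strictly = TRUE)) {
    stop("echo times must be strictly increasing", call. = FALSE)
  }
  invisible(tes)
}

#' Biexponential parameter set
#'
#' Two-pool transverse-relaxation parameters: a short and a long T2
#' component, each with a non-negative amplitude. After fitting, components
#' are order-normalized so `t2_short <= t2_long`.
#'
#' @param amp_short,amp_long non-negative component amplitudes (arbitrary
#'   units; the phantom generator normalizes `amp_short + amp_long = 1` so
#'   amplitudes double as fractions).
#' @param t2_short,t2_long positive relaxation times (ms).
#' @return A list of class `biexp_params`.
#' @export
biexp_params <- function(amp_short, amp_long, t2_short, t2_long) {
  if (t2_short <= 0 || t2_long <= 0) {
    stop("T2 times must be positive", call. = FALSE)
  }
  if (amp_short < 0 || amp_long < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  structure(
    list(amp_short = amp_short, amp_long = amp_long,
         t2_short = t2_short, t2_long = t2_long),
    class = "biexp_params"
  )
}

#' Monoexponential parameter set
#'
#' @param amp non-negative amplitude.
#' @param t2 positive relaxation time (ms).
#' @return A list of class `mono_params`.
#' @export
mono_params <- function(amp, t2) {
  if (t2 <= 0) stop("T2 must be positive", call. = FALSE)
  if (amp < 0) stop("amplitude must be non-negative", call. = FALSE)
  structure(list(amp = amp, t2 = t2), class = "mono_params")
}

#' Biexponential decay signal
#'
#' Evaluates the two-pool decay model
#' `S(TE) = amp_short * exp(-TE / t2_short) + amp_long * exp(-TE / t2_long)`
#' at each echo time. At TE = 0 the signal would equal
#' `amp_short + amp_long`.
#'
#' @param params a [biexp_params()] object (or a list with the same fields).
#' @param tes echo times in ms.
#' @return Numeric vector of signal magnitudes, one per echo.
#' @export
biexp_signal <- function(params, tes) {
  validate_echo_times(tes)
  if (params$t2_short <= 0 || params$t2_long <= 0) {
    stop("T2 times must be positive", call. = FALSE)
  }
  params$amp_short * exp(-tes / params$t2_short) +
    params$amp_long * exp(-tes / params$t2_long)
}

#' Monoexponential decay signal
#'
#' `S(TE) = amp * exp(-TE / t2)`.
#'
#' @inheritParams biexp_signal
#' @param params a [mono_params()] object (or a list with fields `amp`, `t2`).
#' @return Numeric vector of signal magnitudes, one per echo.
#' @export
mono_signal <- function(params, tes) {
  validate_echo_times(tes)
  if (params$t2 <= 0) stop("T2 must be positive", call. = FALSE)
  params$amp * exp(-tes / params$t2)
}

#' Component fractions from amplitudes
#'
#' The short/long fractions are each amplitude's share of the amplitude sum;
#' they sum to 1 exactly.
#'
#' @param amp_short,amp_long non-negative component amplitudes.
#' @return Named numeric vector `c(frac_short, frac_long)`.
#' @export
fractions <- function(amp_short, amp_long) {
  if (amp_short < 0 || amp_long < 0) {
    stop("amplitudes must be non-negative", call. = FALSE)
  }
  total <- amp_short + amp_long
  if (total <= 0) {
    stop("fractions are undefined when both amplitudes are zero",
         call. = FALSE)
  }
  fs <- amp_short / total
  c(frac_short = fs, frac_long = 1 - fs)
}
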