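#' Window specification for online classification
#'
#' Fixed-length windows of `n` samples advancing by `n/2` (half-overlap), the
#' segmentation unit of the online protocol. `n` must be even so the stride
#' is integral; odd values are rounded down to even with a warning.
#'
#' @param n Window length, samples.
#' @param sample_rate Optional rate (Hz) to record the window length in ms.
#' @return Object of class `window_spec` with `n`, `stride`, `window_ms`.
#' @examples
#' window_spec(150, sample_rate = 600) # 250 ms at 600 Hz
#' @export
window_spec <- function(n, sample_rate = NULL) {
  stopifnot(is.numeric(n), n >= 2)
  n <- floor(n)
  if (n %% 2 == 1) {
    n <- n - 1
    warning("odd window length rounded down to ", n, " samples")
  }
  structure(list(n = as.integer(n), stride = as.integer(n / 2),
                 window_ms = if (is.null(sample_rate)) NA_real_ else 1000 * n / sample_rate),
            class = "window_spec")
}

#' Segment a signal into half-overlapping windows
#'
#' Windows start at sample offsets `0, n/2, n, ...` (0-based), each spanning
#' exactly `n` samples; trailing samples that do not fill a window are
#' dropped, giving `floor((P - n) / (n/2)) + 1` windows.
#'
#' @param signal Numeric sample vector (length P).
#' @param spec A [window_spec()] (or even integer n).
#' @return Matrix of dimension `count x n`; row k is window k.
#' @examples
#' segment_windows(1:4, window_spec(2)) # 3 windows
#' @export
segment_windows <- function(signal, spec) {
  if (!inherits(spec, "window_spec")) spec <- window_spec(spec)
  P <- length(signal)
  n <- spec$n
  if (n > P) {
    stop("window length ", n, " exceeds signal length ", P, call. = FALSE)
  }
  starts <- seq(1L, P - n + 1L, by = spec$stride)
  out <- matrix(0, length(starts), n)
  for (k in seq_along(starts)) out[k, ] <- signal[starts[k]:(starts[k] + n - 1L)]
  out
}

#' Number of half-overlapping windows in a signal
#' @param P Signal length, samples.
#' @param n Window length, samples (even).
#' @return Integer window count, `floor((P - n) / (n/2)) + 1`.
#' @export
window_count <- function(P, n) as.integer(floor((P - n) / (n / 2)) + 1)
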