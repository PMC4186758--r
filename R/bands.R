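#' Define a frequency band
#'
#' A band is a half-open passband for the Butterworth band-pass filter and
#' the analytic-signal stage. Edges are in Hz and must satisfy
#' `0 < lo < hi`; validity against a concrete sampling rate (`hi < fs/2`)
#' is checked where a recording is available.
#'
#' @param name Band label, e.g. `"alpha1"`.
#' @param lo Lower passband edge in Hz.
#' @param hi Upper passband edge in Hz.
#' @return An object of class `band_spec`.
#' @examples
#' band_spec("alpha1", 8, 10)
#' @export
band_spec <- function(name, lo, hi) {
  stopifnot(is.character(name), length(name) == 1L,
            is.numeric(lo), is.numeric(hi), length(lo) == 1L, length(hi) == 1L)
  if (!(lo > 0 && hi > lo))
    stop("band edges must satisfy 0 < lo < hi (got [", lo, ", ", hi, "] Hz)")
  structure(list(name = name, lo = as.numeric(lo), hi = as.numeric(hi)),
            class = "band_spec")
}

#' Canonical resting-state EEG bands
#'
#' Theta (4-8 Hz), alpha1 (8-10 Hz), alpha2 (10-13 Hz) and beta (13-30 Hz).
#'
#' @return Named list of [band_spec()] objects.
#' @export
default_bands <- function() {
  list(theta  = band_spec("theta", 4, 8),
       alpha1 = band_spec("alpha1", 8, 10),
       alpha2 = band_spec("alpha2", 10, 13),
       beta   = band_spec("beta", 13, 30))
}

#' @export
print.band_spec <- function(x, ...) {
  cat(sprintf("<band_spec> %s: %g-%g Hz\n", x$name, x$lo, x$hi))
  invisible(x)
}

check_band_vs_fs <- function(band, fs) {
  if (band$hi >= fs / 2)
    stop("band '", band$name, "' upper edge ", band$hi,
         " Hz violates the sampling theorem at fs = ", fs, " Hz")
  invisible(TRUE)
}
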