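#' Zero-phase Butterworth band-pass filter
#'
#' Designs a Butterworth band-pass of the requested order and applies it
#' forward-backward (`signal::filtfilt`) per channel and epoch, so the
#' filter contributes no phase lag that would bias phase-difference
#' measures. The design is rejected if numerically unstable (poles on or
#' outside the unit circle), which happens when the band is too narrow for
#' the order at the given sampling rate.
#'
#' @param rec An `epoched_recording`.
#' @param band A [band_spec()].
#' @param order Butterworth design order (default 4).
#' @return Filtered `epoched_recording` of identical shape.
#' @export
bandpass <- function(rec, band, order = 4L) {
  stopifnot(inherits(rec, "epoched_recording"), inherits(band, "band_spec"))
  check_band_vs_fs(band, rec$fs)
  bf <- signal::butter(order, c(band$lo, band$hi) / (rec$fs / 2),
                       type = "pass")
  poles <- polyroot(rev(bf$a))
  if (any(Mod(poles) >= 1 - 1e-8))
    stop("unstable Butterworth design: band [", band$lo, ", ", band$hi,
         "] Hz too narrow for order ", order, " at fs = ", rec$fs, " Hz")
  out <- rec$data
  for (e in seq_len(n_epochs(rec)))
    for (c in seq_len(n_channels(rec)))
      out[c, e, ] <- signal::filtfilt(bf, rec$data[c, e, ])
  epoched_recording(out, rec$fs, rec$montage, rec$meta)
}

#' Re-reference to the channel average
#'
#' Subtracts the instantaneous mean across channels from every channel,
#' sample by sample, so each sample's channel sum is zero. With dense
#' montages this approximates a neutral reference.
#'
#' @param rec An `epoched_recording` with at least 2 channels.
#' @return Re-referenced `epoched_recording`.
#' @export
average_reference <- function(rec) {
  stopifnot(inherits(rec, "epoched_recording"))
  if (n_channels(rec) < 2)
    stop("average reference requires >= 2 channels")
  m <- colMeans(rec$data)                 # epochs x samples
  out <- rec$data - rep(m, each = n_channels(rec))
  epoched_recording(out, rec$fs, rec$montage, rec$meta)
}

#' Analytic signal and instantaneous phase
#'
#' Computes the analytic signal per channel and epoch by the
#' frequency-domain construction (negative-frequency FFT bins zeroed,
#' positive bins doubled), optionally after a Hann taper of the epoch
#' (default on) to suppress spectral leakage from the epoch edges. The
#' instantaneous phase is the complex argument, in (-pi, pi].
#'
#' @param rec A band-passed `epoched_recording` with >= 64 samples/epoch.
#' @param band The [band_spec()] the recording was filtered to (carried as
#'   metadata).
#' @param taper Logical; apply a Hann taper before the transform.
#' @return An `analytic_epochs` object: list with complex array `analytic`
#'   (channels x epochs x samples), `phase` (its argument), `band`, `fs`,
#'   `montage`, `meta`.
#' @export
analytic_signal <- function(rec, band, taper = TRUE) {
  stopifnot(inherits(rec, "epoched_recording"))
  ns <- n_samples(rec)
  if (ns < 64) stop("analytic signal requires >= 64 samples per epoch")
  win <- if (taper) hann_window(ns) else rep(1, ns)
  h <- analytic_step(ns)
  nc <- n_channels(rec)
  analytic <- array(0i, dim = dim(rec$data))
  for (e in seq_len(n_epochs(rec))) {
    X <- t(rec$data[, e, , drop = TRUE]) * win        # samples x channels
    if (nc == 1) X <- matrix(rec$data[1, e, ] * win, ncol = 1)
    A <- stats::mvfft(stats::mvfft(X) * h, inverse = TRUE) / ns
    analytic[, e, ] <- t(A)
  }
  structure(list(analytic = analytic, phase = Arg(analytic), band = band,
                 fs = rec$fs, montage = rec$montage, meta = rec$meta),
            class = "analytic_epochs")
}

hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# one-sided spectrum step: keep DC and Nyquist, double positive bins
analytic_step <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' @export
print.analytic_epochs <- function(x, ...) {
  d <- dim(x$analytic)
  cat(sprintf("<analytic_epochs> %s band, %d ch x %d epochs x %d samples\n",
              x$band$name, d[1], d[2], d[3]))
  invisible(x)
}
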