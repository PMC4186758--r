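#' Coupling specification for synthetic recordings
#'
#' Describes the ground-truth interaction structure: directed channel pairs
#' with a fixed instantaneous phase lag and coupling strength, a zero-lag
#' common source mixed into every channel (a volume-conduction surrogate),
#' the oscillation band, and the signal-to-noise ratio of the coupled
#' component.
#'
#' @param pairs List of lists, each with elements `a`, `b` (channel
#'   indices), `lag` (radians in (-pi, pi]; the phase by which channel `b`
#'   trails channel `a`) and `strength` in \[0, 1\].
#' @param common_source_gain Scalar >= 0; amplitude of the shared zero-lag
#'   component added to all channels.
#' @param band A [band_spec()].
#' @param snr Linear signal-to-noise power ratio of the coupled component
#'   in the target channel (`Inf` = noiseless).
#' @param background Optional [band_spec()] for an independent broadband
#'   background component added to every channel; without it, channels
#'   carry energy only inside `band`, and analysis bands away from the
#'   coupling band would contain nothing but filter transients.
#' @param background_gain Amplitude of the background component.
#' @return A `coupling_spec`.
#' @export
coupling_spec <- function(pairs = list(), common_source_gain = 0,
                          band = band_spec("alpha1", 8, 10), snr = Inf,
                          background = NULL, background_gain = 0) {
  for (p in pairs) {
    stopifnot(all(c("a", "b", "lag", "strength") %in% names(p)))
    if (p$lag <= -pi || p$lag > pi)
      stop("lag must lie in (-pi, pi]")
    if (p$strength < 0 || p$strength > 1)
      stop("strength must lie in [0, 1]")
  }
  stopifnot(common_source_gain >= 0, snr > 0, background_gain >= 0)
  if (!is.null(background)) stopifnot(inherits(background, "band_spec"))
  structure(list(pairs = pairs, common_source_gain = common_source_gain,
                 band = band, snr = snr, background = background,
                 background_gain = background_gain),
            class = "coupling_spec")
}

#' Cohort specification
#'
#' Variance-components design for a multi-subject, multi-session cohort:
#' subject i's session s coupling strength is
#' `clip01(template + b_i + w_is)` with `b_i ~ N(0, sigma_between)` and
#' `w_is ~ N(0, sigma_within)`.
#'
#' @param n_subjects Number of subjects.
#' @param n_sessions Number of sessions per subject (>= 2).
#' @param sigma_between SD of the stable subject-level strength offset.
#' @param sigma_within SD of the session-level deviation.
#' @param seed Integer master seed.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects, n_sessions, sigma_between, sigma_within,
                        seed = 1L) {
  stopifnot(n_subjects >= 1, n_sessions >= 2,
            sigma_between >= 0, sigma_within >= 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sessions = as.integer(n_sessions),
                 sigma_between = sigma_between, sigma_within = sigma_within,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# deterministic per-(subject, session) seed, kept inside 32-bit range
derive_seed <- function(seed, i, s = 0L) {
  as.integer((as.double(seed) * 48271 + i * 10007 + s * 101) %% 2147483647)
}

#' Band-limited Gaussian noise
#'
#' White Gaussian noise restricted to `[lo, hi]` Hz by zeroing FFT bins
#' outside the band, scaled to unit variance. Perfectly band-limited
#' sources keep the imposed phase lags exact at every in-band frequency.
#'
#' @param n Number of samples.
#' @param band A [band_spec()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of length `n`, unit SD.
#' @keywords internal
narrowband_noise <- function(n, band, fs) {
  x <- stats::rnorm(n)
  X <- stats::fft(x)
  f <- fft_bin_freqs(n, fs)
  X[abs(f) < band$lo | abs(f) > band$hi] <- 0
  y <- Re(stats::fft(X, inverse = TRUE)) / n
  s <- stats::sd(y)
  if (s == 0) stop("band [", band$lo, ", ", band$hi,
                   "] Hz contains no FFT bin at n = ", n, ", fs = ", fs)
  y / s
}

fft_bin_freqs <- function(n, fs) {
  k <- 0:(n - 1)
  f <- k / n * fs
  f[f > fs / 2] <- f[f > fs / 2] - fs
  f
}

#' Constant phase rotation of a real signal
#'
#' Multiplies positive-frequency FFT bins by `exp(-1i * lag)` and negative
#' bins by the conjugate, so every spectral component is delayed by the
#' same phase angle `lag` (the rotated signal trails the original by `lag`
#' radians at all frequencies).
#'
#' @param x Real signal.
#' @param lag Phase angle in radians.
#' @return Rotated real signal.
#' @keywords internal
phase_rotate <- function(x, lag) {
  n <- length(x)
  X <- stats::fft(x)
  f <- fft_bin_freqs(n, 1)
  rot <- rep(1 + 0i, n)
  rot[f > 0] <- exp(-1i * lag)
  rot[f < 0] <- exp(1i * lag)
  Re(stats::fft(X * rot, inverse = TRUE)) / n
}

#' Simulate one epoched recording with known coupling
#'
#' Every channel receives an independent unit-variance narrowband source.
#' For each coupled pair (a, b), channel b's source is replaced by
#' `strength * phase_rotate(source_a, lag)` plus independent narrowband
#' noise with power `1/snr`. A single shared narrowband component scaled
#' by `common_source_gain` is added to all channels at zero lag, emulating
#' volume conduction / reference effects.
#'
#' @param montage A `montage`.
#' @param spec A [coupling_spec()].
#' @param n_epochs Number of epochs.
#' @param n_samples Samples per epoch (>= 64).
#' @param fs Sampling rate in Hz; must exceed twice the band's upper edge.
#' @param seed Integer seed; identical seeds give bit-identical arrays.
#' @return An `epoched_recording` with `meta$spec` recording the ground
#'   truth.
#' @export
simulate_recording <- function(montage, spec, n_epochs = 12L,
                               n_samples = 4096L, fs = 1024, seed = 1L) {
  stopifnot(inherits(spec, "coupling_spec"), n_epochs >= 1)
  if (n_samples < 64) stop("n_samples must be >= 64")
  check_band_vs_fs(spec$band, fs)
  if (!is.null(spec$background)) check_band_vs_fs(spec$background, fs)
  nc <- length(montage$labels)
  targets <- vapply(spec$pairs, function(p) as.integer(p$b), integer(1))
  if (anyDuplicated(targets))
    stop("a channel may be the target of at most one coupled pair")
  sigma <- if (is.finite(spec$snr)) sqrt(1 / spec$snr) else 0

  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  data <- array(0, dim = c(nc, n_epochs, n_samples))
  for (e in seq_len(n_epochs)) {
    src <- matrix(0, nc, n_samples)
    for (c in seq_len(nc))
      src[c, ] <- narrowband_noise(n_samples, spec$band, fs)
    X <- src
    for (p in spec$pairs) {
      X[p$b, ] <- p$strength * phase_rotate(src[p$a, ], p$lag) +
        sigma * src[p$b, ]
    }
    if (spec$common_source_gain > 0) {
      g <- narrowband_noise(n_samples, spec$band, fs)
      X <- X + rep(spec$common_source_gain * g, each = nc)
    }
    if (!is.null(spec$background) && spec$background_gain > 0) {
      for (c in seq_len(nc))
        X[c, ] <- X[c, ] + spec$background_gain *
          narrowband_noise(n_samples, spec$background, fs)
    }
    data[, e, ] <- X
  }
  epoched_recording(data, fs, montage, meta = list(seed = seed, spec = spec))
}

#' Draw per-session coupling strengths for a cohort
#'
#' @param cohort A [cohort_spec()].
#' @param template_strength Population-mean coupling strength.
#' @return n_subjects x n_sessions matrix of strengths clipped to \[0, 1\].
#' @export
draw_cohort_strengths <- function(cohort, template_strength) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(derive_seed(cohort$seed, 0L, 0L))
  b <- stats::rnorm(cohort$n_subjects, 0, cohort$sigma_between)
  w <- matrix(stats::rnorm(cohort$n_subjects * cohort$n_sessions, 0,
                           cohort$sigma_within),
              cohort$n_subjects, cohort$n_sessions)
  clip01(template_strength + b + w)
}

#' Simulate a multi-subject, multi-session cohort
#'
#' All coupled pairs of the template share the subject/session strength
#' drawn by [draw_cohort_strengths()]; recording seeds are derived
#' deterministically from `(cohort$seed, subject, session)`.
#'
#' @param montage A `montage`.
#' @param cohort A [cohort_spec()].
#' @param coupling_template A [coupling_spec()] whose pair strengths give
#'   the population mean (the first pair's strength is used as the
#'   template strength for all pairs).
#' @param n_epochs,n_samples,fs Recording geometry, as in
#'   [simulate_recording()].
#' @return List with `recordings` (list indexed `[[subject]][[session]]`)
#'   and `strengths` (subject x session matrix of realized strengths).
#' @export
simulate_cohort <- function(montage, cohort, coupling_template,
                            n_epochs = 12L, n_samples = 4096L, fs = 1024) {
  stopifnot(inherits(cohort, "cohort_spec"),
            length(coupling_template$pairs) >= 1)
  template_strength <- coupling_template$pairs[[1]]$strength
  strengths <- draw_cohort_strengths(cohort, template_strength)
  recordings <- vector("list", cohort$n_subjects)
  for (i in seq_len(cohort$n_subjects)) {
    recordings[[i]] <- vector("list", cohort$n_sessions)
    for (s in seq_len(cohort$n_sessions)) {
      spec_is <- coupling_template
      for (k in seq_along(spec_is$pairs))
        spec_is$pairs[[k]]$strength <- strengths[i, s]
      rec <- simulate_recording(montage, spec_is, n_epochs, n_samples, fs,
                                seed = derive_seed(cohort$seed, i, s))
      rec$meta$subject <- i
      rec$meta$session <- s
      recordings[[i]][[s]] <- rec
    }
  }
  list(recordings = recordings, strengths = strengths)
}
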