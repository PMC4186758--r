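#' Epoched multichannel recording
#'
#' Thin container for a channels x epochs x samples array with its sampling
#' rate, montage and subject/session labels. All downstream stages
#' (filtering, referencing, analytic signal, connectivity) operate on this
#' container.
#'
#' @param data Numeric array, channels x epochs x samples (microvolts).
#' @param fs Sampling rate in Hz.
#' @param montage A `montage` with one entry per channel.
#' @param meta Optional named list (subject, session, ...).
#' @return An `epoched_recording`.
#' @export
epoched_recording <- function(data, fs, montage, meta = list()) {
  stopifnot(is.array(data), length(dim(data)) == 3, is.numeric(fs), fs > 0)
  if (!all(is.finite(data)))
    stop("recording contains non-finite values")
  if (dim(data)[1] != length(montage$labels))
    stop("data has ", dim(data)[1], " channels but montage has ",
         length(montage$labels))
  structure(list(data = data, fs = as.numeric(fs), montage = montage,
                 meta = meta),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<epoched_recording> %d ch x %d epochs x %d samples @ %g Hz\n",
              d[1], d[2], d[3], x$fs))
  invisible(x)
}

n_channels <- function(rec) dim(rec$data)[1]
n_epochs   <- function(rec) dim(rec$data)[2]
n_samples  <- function(rec) dim(rec$data)[3]
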