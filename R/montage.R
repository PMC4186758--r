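#' Construct a synthetic high-density electrode montage
#'
#' Channels are laid out deterministically on the upper half of an ellipsoid
#' whose full axis lengths are `cap_dims` (width, length, height in cm),
#' using a Fibonacci spiral so that coverage is near-uniform. A subset of
#' channels near the sagittal midline and at the lower border is marked
#' `"excluded"`; the remaining channels are grouped into anatomically
#' plausible regions: contiguous anterior-posterior strips within each
#' hemisphere.
#'
#' @param n_channels Total channel count.
#' @param cap_dims Numeric length-3: full ellipsoid axis lengths
#'   (width, length, height) in cm.
#' @param n_regions Number of electrode regions (must be even; half per
#'   hemisphere).
#' @param n_regional Number of channels covered by regions; the remaining
#'   `n_channels - n_regional` channels (midline / border) are excluded
#'   from regional analysis but still carry signal.
#' @return An object of class `montage`: list with `labels` (character),
#'   `coords` (n x 3 matrix, cm), `region_of` (character vector, region id
#'   or `"excluded"`), `cap_dims`.
#' @seealso [make_default_montage()]
#' @export
make_montage <- function(n_channels, cap_dims, n_regions, n_regional) {
  stopifnot(n_channels >= 4, length(cap_dims) == 3, all(cap_dims > 0),
            n_regions >= 2, n_regions %% 2 == 0,
            n_regional <= n_channels, n_regional >= n_regions)
  semi <- cap_dims / 2
  i <- seq_len(n_channels)
  # Fibonacci spiral over the upper unit hemisphere, then scaled to the cap
  zu <- (i - 0.5) / n_channels
  golden <- pi * (3 - sqrt(5))
  th <- golden * i
  ru <- sqrt(pmax(0, 1 - zu^2))
  unit <- cbind(x = ru * cos(th), y = ru * sin(th), z = zu)
  coords <- sweep(unit, 2, semi, `*`)
  labels <- sprintf("E%03d", i)
  rownames(coords) <- labels

  n_excl <- n_channels - n_regional
  # exclusion: channels nearest the sagittal midline, then lowest on the cap
  n_mid <- ceiling(n_excl / 2)
  excl <- order(abs(unit[, "x"]))[seq_len(n_mid)]
  rest <- setdiff(i, excl)
  n_bord <- n_excl - n_mid
  if (n_bord > 0)
    excl <- c(excl, rest[order(unit[rest, "z"])][seq_len(n_bord)])
  included <- setdiff(i, excl)

  # region sizes: as equal as possible, larger regions first
  base <- n_regional %/% n_regions
  n_big <- n_regional - base * n_regions
  sizes <- c(rep(base + 1L, n_big), rep(base, n_regions - n_big))
  # deal sizes alternately to the two hemispheres so the split is balanced
  side_of_region <- rep_len(c(1L, 2L), n_regions)
  n_left <- sum(sizes[side_of_region == 1L])

  ord_x <- included[order(unit[included, "x"], included)]
  left <- ord_x[seq_len(n_left)]
  right <- ord_x[-seq_len(n_left)]

  region_of <- rep("excluded", n_channels)
  rid <- 0L
  for (side in 1:2) {
    chans <- if (side == 1L) left else right
    chans <- chans[order(unit[chans, "y"], chans)]  # posterior -> anterior strips
    for (sz in sizes[side_of_region == side]) {
      rid <- rid + 1L
      region_of[chans[seq_len(sz)]] <- sprintf("R%02d", rid)
      chans <- chans[-seq_len(sz)]
    }
  }
  names(region_of) <- labels
  structure(list(labels = labels, coords = coords, region_of = region_of,
                 cap_dims = as.numeric(cap_dims)),
            class = "montage")
}

#' Default 214-channel montage
#'
#' 214 channels on a cap of 15.3 x 19.5 x 19.3 cm, with 22 regions of 7 or
#' 8 channels covering 170 channels; the 44 channels nearest the midline
#' and the lower border are excluded from regional analysis.
#'
#' @return A `montage` object.
#' @export
make_default_montage <- function() {
  make_montage(n_channels = 214L, cap_dims = c(15.3, 19.5, 19.3),
               n_regions = 22L, n_regional = 170L)
}

#' @export
print.montage <- function(x, ...) {
  reg <- montage_regions(x)
  cat(sprintf("<montage> %d channels, %d regions covering %d channels (cap %s cm)\n",
              length(x$labels), length(reg), sum(lengths(reg)),
              paste(x$cap_dims, collapse = " x ")))
  invisible(x)
}

#' Channels per region
#'
#' @param montage A `montage`.
#' @return Named list mapping region id to integer channel indices;
#'   excluded channels appear in no region.
#' @export
montage_regions <- function(montage) {
  keep <- montage$region_of != "excluded"
  split(seq_along(montage$labels)[keep], montage$region_of[keep])
}

#' Write / read a montage as CSV
#'
#' Columns: `label`, `x_cm`, `y_cm`, `z_cm`, `region`.
#'
#' @param montage A `montage`.
#' @param path File path.
#' @return `read_montage` returns a `montage` (cap_dims recovered as twice
#'   the max absolute coordinate per axis).
#' @export
write_montage <- function(montage, path) {
  df <- data.frame(label = montage$labels,
                   x_cm = montage$coords[, 1], y_cm = montage$coords[, 2],
                   z_cm = montage$coords[, 3], region = montage$region_of)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  coords <- as.matrix(df[, c("x_cm", "y_cm", "z_cm")])
  rownames(coords) <- df$label
  region_of <- df$region
  names(region_of) <- df$label
  structure(list(labels = df$label, coords = coords, region_of = region_of,
                 cap_dims = 2 * apply(abs(coords), 2, max)),
            class = "montage")
}
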