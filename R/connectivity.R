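#' Wrap phase angles to (-pi, pi]
#'
#' @param x Angles in radians.
#' @return Wrapped angles.
#' @export
wrap_phase <- function(x) {
  y <- atan2(sin(x), cos(x))
  y[y == -pi] <- pi
  y
}

#' Phase lag index of one phase-difference series
#'
#' The PLI is the absolute mean of the signum of the per-sample phase
#' differences: `|< sign(dphi_k) >|`, with `sign(0) = 0`. It ranges over
#' \[0, 1\]: 0 for symmetric phase-difference distributions (including the
#' zero-lag case typical of a common source) and 1 for a perfectly
#' consistent non-zero lag.
#'
#' @param dphi Phase differences in radians, wrapped to (-pi, pi].
#' @return PLI in \[0, 1\].
#' @examples
#' pli_pair(c(0.1, 0.2, 0.3, -0.1))  # 0.5
#' @export
pli_pair <- function(dphi) {
  if (length(dphi) < 1) stop("empty phase-difference series")
  abs(mean(sign(dphi)))
}

#' Debiased weighted phase lag index of one cross-spectrum series
#'
#' Weights each sample's contribution by the magnitude of the imaginary
#' cross-spectral component, so near-zero lags contribute marginally. With
#' `s_k = Im(z_k)` the debiased squared estimator is
#' `q = ((sum s)^2 - sum s^2) / ((sum |s|)^2 - sum s^2)`; the returned
#' weight is `sqrt(max(q, 0))` so it lives in \[0, 1\] like the PLI. A
#' degenerate denominator (all `s_k = 0`, pure zero-lag) returns 0.
#'
#' @param cs Complex cross-terms `analytic_a * Conj(analytic_b)` per
#'   sample, or their imaginary parts as a numeric vector.
#' @return Debiased wPLI in \[0, 1\].
#' @export
wpli_pair <- function(cs) {
  if (length(cs) < 2) stop("wPLI requires >= 2 samples")
  s <- if (is.complex(cs)) Im(cs) else cs
  ss <- sum(s)
  s2 <- sum(s^2)
  den <- sum(abs(s))^2 - s2
  if (den <= 0) return(0)
  sqrt(max((ss^2 - s2) / den, 0))
}

new_conn_matrix <- function(w, measure, band, level, labels = NULL) {
  if (!is.null(labels)) dimnames(w) <- list(labels, labels)
  structure(w, class = c("conn_matrix", "matrix"),
            measure = measure, band = band, level = level)
}

check_conn_matrix <- function(m) {
  w <- unclass(m)
  stopifnot(is.matrix(w), nrow(w) == ncol(w))
  if (!isTRUE(all.equal(w, t(w), tolerance = 1e-10, check.attributes = FALSE)))
    stop("connectivity matrix must be symmetric")
  if (any(!is.finite(w))) stop("connectivity matrix has non-finite entries")
  if (any(diag(w) != 0)) stop("connectivity matrix must have zero diagonal")
  if (any(w < 0 | w > 1)) stop("weights must lie in [0, 1]")
  invisible(w)
}

#' Per-epoch and subject-average connectivity matrices
#'
#' For every unordered channel pair, PLI and/or debiased wPLI are computed
#' per epoch from the per-sample cross-terms of the analytic signals; the
#' subject matrix is the entrywise arithmetic mean over epochs. Both
#' measures share one pass over the cross-spectra.
#'
#' @param ae An `analytic_epochs` object.
#' @param measure `"pli"`, `"wpli"`, or `c("pli", "wpli")`.
#' @return Named list per measure; each element is a list with
#'   `per_epoch` (list of `conn_matrix`) and `average` (`conn_matrix`).
#' @export
connectivity_matrices <- function(ae, measure = c("pli", "wpli")) {
  stopifnot(inherits(ae, "analytic_epochs"))
  measure <- match.arg(measure, several.ok = TRUE)
  d <- dim(ae$analytic)
  nc <- d[1]; ne <- d[2]
  labels <- ae$montage$labels
  out <- lapply(measure, function(m)
    list(per_epoch = vector("list", ne), average = NULL))
  names(out) <- measure
  acc <- lapply(measure, function(m) matrix(0, nc, nc))
  names(acc) <- measure
  for (e in seq_len(ne)) {
    A <- t(ae$analytic[, e, , drop = TRUE])          # samples x channels
    if (nc == 1) A <- matrix(ae$analytic[1, e, ], ncol = 1)
    W <- lapply(measure, function(m) matrix(0, nc, nc))
    names(W) <- measure
    for (i in seq_len(nc - 1)) {
      idx <- (i + 1):nc
      s <- Im(Conj(A[, i]) * A[, idx, drop = FALSE]) # Im cross, b leads: s>0 when i leads
      if ("pli" %in% measure) {
        v <- abs(colMeans(sign(s)))
        W$pli[i, idx] <- v; W$pli[idx, i] <- v
      }
      if ("wpli" %in% measure) {
        ss <- colSums(s); s2 <- colSums(s^2)
        den <- colSums(abs(s))^2 - s2
        q <- ifelse(den > 0, (ss^2 - s2) / den, 0)
        v <- sqrt(pmax(q, 0))
        W$wpli[i, idx] <- v; W$wpli[idx, i] <- v
      }
    }
    for (m in measure) {
      out[[m]]$per_epoch[[e]] <- new_conn_matrix(W[[m]], m, ae$band,
                                                 "per-epoch", labels)
      acc[[m]] <- acc[[m]] + W[[m]]
    }
  }
  for (m in measure)
    out[[m]]$average <- new_conn_matrix(acc[[m]] / ne, m, ae$band,
                                        "subject-average", labels)
  out
}

#' Global connectivity
#'
#' Mean of all pairwise weights (strict upper triangle) of a connectivity
#' matrix.
#'
#' @param m A `conn_matrix` (or plain symmetric matrix).
#' @return Scalar mean weight.
#' @export
global_connectivity <- function(m) {
  w <- check_conn_matrix(m)
  mean(w[upper.tri(w)])
}

#' Regional degree
#'
#' For each region, the mean connectivity of its channels to all channels
#' of the other regions (within-region cells and excluded channels are
#' ignored).
#'
#' @param m A `conn_matrix` over the montage's channels.
#' @param montage A `montage` defining regions.
#' @return Named numeric vector, one value per region.
#' @export
regional_degree <- function(m, montage) {
  w <- check_conn_matrix(m)
  regions <- montage_regions(montage)
  if (length(regions) == 0 || any(lengths(regions) == 0))
    stop("montage must define non-empty regions")
  all_regional <- unlist(regions, use.names = FALSE)
  vapply(regions, function(idx) {
    mean(w[idx, setdiff(all_regional, idx)])
  }, numeric(1))
}

#' Inter-regional links
#'
#' Mean weight between the channels of every unordered pair of regions;
#' 22 regions give choose(22, 2) = 231 links.
#'
#' @inheritParams regional_degree
#' @return Data frame with `region_a`, `region_b`, `weight`.
#' @export
inter_regional_links <- function(m, montage) {
  w <- check_conn_matrix(m)
  regions <- montage_regions(montage)
  if (length(regions) < 2) stop("need >= 2 regions")
  cmb <- utils::combn(names(regions), 2)
  weight <- apply(cmb, 2, function(rs)
    mean(w[regions[[rs[1]]], regions[[rs[2]]]]))
  data.frame(region_a = cmb[1, ], region_b = cmb[2, ], weight = weight,
             stringsAsFactors = FALSE)
}

#' Connectivity versus inter-electrode distance
#'
#' Spearman rank correlation between the Euclidean 3D inter-electrode
#' distance and the pairwise weight, over all unordered channel pairs.
#' Ties get average ranks; an exact p-value is not attempted.
#'
#' @inheritParams regional_degree
#' @return List with `rho`, `p`, `n_pairs`, and `degenerate` (TRUE when
#'   all distances coincide, leaving rho undefined).
#' @export
distance_correlation <- function(m, montage) {
  w <- check_conn_matrix(m)
  d <- as.matrix(stats::dist(montage$coords))
  ut <- upper.tri(w)
  dv <- d[ut]; wv <- w[ut]
  if (max(dv) - min(dv) < 1e-12)
    return(list(rho = NA_real_, p = NA_real_, n_pairs = length(dv),
                degenerate = TRUE))
  ct <- suppressWarnings(stats::cor.test(dv, wv, method = "spearman",
                                         exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n_pairs = length(dv),
       degenerate = FALSE)
}

#' Strongest links and nodal degree
#'
#' Extracts the `ceiling(fraction * n_pairs)` largest-weight unordered
#' channel pairs (descending weight, ties broken lexicographically by
#' channel index) and each channel's mean weight to all others (nodal
#' degree), as used to display a connectome.
#'
#' @param m A `conn_matrix`.
#' @param fraction Fraction of pairs to keep, in (0, 1).
#' @return List with `edges` (data frame `chan_a`, `chan_b`, `weight`,
#'   `rank`) and `nodal_degree` (named numeric).
#' @export
top_links <- function(m, fraction = 0.03) {
  w <- check_conn_matrix(m)
  stopifnot(fraction > 0, fraction < 1)
  n <- nrow(w)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  wv <- w[upper.tri(w)]
  ord <- order(-wv, ut[, 1], ut[, 2])
  n_top <- ceiling(fraction * length(wv))
  sel <- ord[seq_len(n_top)]
  labels <- rownames(w)
  if (is.null(labels)) labels <- as.character(seq_len(n))
  nodal <- rowSums(w) / (n - 1)
  names(nodal) <- labels
  list(edges = data.frame(chan_a = labels[ut[sel, 1]],
                          chan_b = labels[ut[sel, 2]],
                          weight = wv[sel], rank = seq_len(n_top),
                          stringsAsFactors = FALSE),
       nodal_degree = nodal)
}
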