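#' Weighted clustering coefficient
#'
#' Intensity-based clustering for a symmetric weight matrix with zero
#' diagonal and weights in \[0, 1\]:
#' `C_i = sum_{k,l != i, k != l} w_ik w_il w_kl / sum_{k,l != i, k != l} w_ik w_il`,
#' i.e. total triangle intensity at node i over the total intensity of
#' open triples; `C_i = 0` where the denominator vanishes. `Cw` is the
#' mean over nodes, a global measure of functional segregation.
#'
#' @param W Symmetric weight matrix (or `conn_matrix`).
#' @return List with `C_i` (per-node) and `Cw` (mean).
#' @export
weighted_clustering <- function(W) {
  w <- check_conn_matrix(W)
  num <- diag(w %*% w %*% w)          # closed ordered triples through i
  s <- rowSums(w)
  den <- s^2 - rowSums(w^2)           # open ordered triples at i
  C_i <- ifelse(den > 0, num / den, 0)
  names(C_i) <- rownames(w)
  list(C_i = C_i, Cw = mean(C_i))
}

#' Harmonic-mean weighted path length
#'
#' Edge lengths are inverse weights (`1/w_ij` for `w_ij > 0`, no edge
#' otherwise); `L_ij` is the shortest-path distance. `Lw` is the harmonic
#' mean over all ordered pairs `i != j`,
#' `Lw = n_pairs / sum(1 / L_ij)`, so unconnected pairs (`L_ij = Inf`)
#' contribute zero rather than breaking the average. A fully disconnected
#' graph yields `Lw = Inf` with `disconnected = TRUE`.
#'
#' @param W Symmetric weight matrix with zero diagonal, weights in \[0,1\].
#' @return List with `L` (distance matrix, `Inf` off-diagonal where
#'   unconnected, 0 diagonal), `Lw`, and `disconnected`.
#' @export
weighted_path_length <- function(W) {
  w <- check_conn_matrix(W)
  n <- nrow(w)
  g <- igraph::graph_from_adjacency_matrix(w, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    L <- matrix(Inf, n, n); diag(L) <- 0
    return(list(L = L, Lw = Inf, disconnected = TRUE))
  }
  L <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / L[row(L) != col(L)]       # 1/Inf = 0 for unconnected pairs
  total <- sum(inv)
  Lw <- if (total == 0) Inf else (n * (n - 1)) / total
  list(L = L, Lw = Lw, disconnected = !is.finite(Lw) || any(!is.finite(L)))
}

#' Surrogate normalization of graph measures
#'
#' Builds surrogate random networks by uniformly permuting the
#' strict-upper-triangle weights of the original matrix (preserving the
#' weight distribution and network size, destroying structure), computes
#' Cw and Lw for each, and normalizes: `gamma = Cw / mean surrogate Cw`,
#' `lambda = Lw / mean surrogate Lw`, `swi = gamma / lambda`. The
#' denominator is the mean over `n_iterations` independent repetitions of
#' an `n_surrogates`-network ensemble.
#'
#' @param W Symmetric weight matrix.
#' @param n_surrogates Surrogates per ensemble (default 50).
#' @param n_iterations Ensemble repetitions (default 5).
#' @param seed Integer seed; results are reproducible.
#' @return List of class `normalized_graph_metrics`: `gamma`, `lambda`,
#'   `swi`, `Cw`, `Lw`, surrogate means and SDs (`surr_Cw_mean`,
#'   `surr_Cw_sd`, `surr_Lw_mean`, `surr_Lw_sd`), `n_surrogates`,
#'   `n_iterations`, `seed`.
#' @export
surrogate_normalize <- function(W, n_surrogates = 50L, n_iterations = 5L,
                                seed = 1L) {
  w <- check_conn_matrix(W)
  n <- nrow(w)
  ut <- upper.tri(w)
  wv <- w[ut]
  cw <- weighted_clustering(w)$Cw
  lw <- weighted_path_length(w)$Lw
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  surr_cw <- matrix(0, n_surrogates, n_iterations)
  surr_lw <- matrix(0, n_surrogates, n_iterations)
  for (it in seq_len(n_iterations)) {
    for (s in seq_len(n_surrogates)) {
      ws <- matrix(0, n, n)
      ws[ut] <- sample(wv)
      ws <- ws + t(ws)
      surr_cw[s, it] <- weighted_clustering(ws)$Cw
      surr_lw[s, it] <- weighted_path_length(ws)$Lw
    }
  }
  den_c <- mean(colMeans(surr_cw))
  den_l <- mean(colMeans(surr_lw))
  gamma <- cw / den_c
  lambda <- lw / den_l
  structure(list(gamma = gamma, lambda = lambda, swi = gamma / lambda,
                 Cw = cw, Lw = lw,
                 surr_Cw_mean = den_c, surr_Cw_sd = stats::sd(surr_cw),
                 surr_Lw_mean = den_l, surr_Lw_sd = stats::sd(surr_lw),
                 n_surrogates = n_surrogates, n_iterations = n_iterations,
                 seed = seed),
            class = "normalized_graph_metrics")
}

#' @export
print.normalized_graph_metrics <- function(x, ...) {
  cat(sprintf(
    "<graph metrics> Cw = %.4f, Lw = %.4f | gamma = %.4f, lambda = %.4f, SWI = %.4f\n",
    x$Cw, x$Lw, x$gamma, x$lambda, x$swi))
  invisible(x)
}

#' Full graph characterization of a subject-average matrix
#'
#' Raw and surrogate-normalized weighted graph measures for one
#' subject/band/measure. Intended for the epoch-averaged matrix, not
#' per-epoch matrices.
#'
#' @param subject_matrix Subject-average `conn_matrix`.
#' @inheritParams surrogate_normalize
#' @return List with `raw` (`C_i`, `Cw`, `Lw`, `disconnected`) and
#'   `normalized` (a `normalized_graph_metrics`).
#' @export
graph_pipeline <- function(subject_matrix, n_surrogates = 50L,
                           n_iterations = 5L, seed = 1L) {
  cl <- weighted_clustering(subject_matrix)
  pl <- weighted_path_length(subject_matrix)
  norm <- surrogate_normalize(subject_matrix, n_surrogates, n_iterations,
                              seed)
  list(raw = list(C_i = cl$C_i, Cw = cl$Cw, Lw = pl$Lw,
                  disconnected = pl$disconnected),
       normalized = norm)
}
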