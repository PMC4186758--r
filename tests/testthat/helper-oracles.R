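# Independent brute-force oracles and small fixture builders.

# weighted clustering by explicit triple enumeration
bf_clustering <- function(W) {
  n <- nrow(W)
  C_i <- numeric(n)
  for (i in seq_len(n)) {
    num <- 0; den <- 0
    for (k in seq_len(n)) {
      if (k == i) next
      for (l in seq_len(n)) {
        if (l == i || l == k) next
        num <- num + W[i, k] * W[i, l] * W[k, l]
        den <- den + W[i, k] * W[i, l]
      }
    }
    C_i[i] <- if (den > 0) num / den else 0
  }
  list(C_i = C_i, Cw = mean(C_i))
}

# all-pairs shortest paths by Floyd-Warshall on inverse-weight lengths
bf_pathlength <- function(W) {
  n <- nrow(W)
  D <- ifelse(W > 0, 1 / W, Inf)
  diag(D) <- 0
  for (k in seq_len(n))
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  inv <- 1 / D[row(D) != col(D)]
  total <- sum(inv)
  list(L = D, Lw = if (total == 0) Inf else n * (n - 1) / total)
}

random_weight_matrix <- function(n, density = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, n, n)
  ut <- upper.tri(W)
  w <- stats::runif(sum(ut))
  if (density < 1) w[stats::runif(length(w)) > density] <- 0
  W[ut] <- w
  W + t(W)
}

toy_montage <- function(n_channels = 12L, n_regions = 4L, n_regional = 8L) {
  make_montage(n_channels, c(15.3, 19.5, 19.3), n_regions, n_regional)
}

# pure sinusoid recording with one channel per requested phase offset
sinusoid_recording <- function(freq, fs, n_samples, phases = 0,
                               n_epochs = 1L, amplitude = 1) {
  t <- (0:(n_samples - 1)) / fs
  nc <- max(length(phases), 4L)
  arr <- array(0, c(nc, n_epochs, n_samples))
  for (e in seq_len(n_epochs))
    for (c in seq_len(nc)) {
      ph <- if (c <= length(phases)) phases[c] else 0
      arr[c, e, ] <- amplitude * cos(2 * pi * freq * t - ph)
    }
  epoched_recording(arr, fs, toy_montage(nc, 2L, min(nc, 4L)))
}

# cohort table built directly from a subjects x sessions value matrix
table_from_matrix <- function(Y, band = "alpha1", measure = "m") {
  data.frame(subject = rep(seq_len(nrow(Y)), ncol(Y)),
             session = rep(seq_len(ncol(Y)), each = nrow(Y)),
             band = band, measure = measure, value = as.vector(Y),
             stringsAsFactors = FALSE)
}

# variance-components cohort values: b_i + w_is around mu
vc_values <- function(n, k, mu, sigma_b, sigma_w, seed) {
  set.seed(seed)
  mu + rnorm(n, 0, sigma_b) + matrix(rnorm(n * k, 0, sigma_w), n, k)
}
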