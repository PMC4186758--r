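#' Reliability category for an ICC value
#'
#' `excellent` for ICC > 0.75, `good` for 0.60 <= ICC <= 0.75, `fair` for
#' 0.40 <= ICC < 0.60, `poor` for ICC < 0.40. The 0.75 boundary itself is
#' "good" because "excellent" requires a strict inequality.
#'
#' @param icc Numeric ICC value(s).
#' @return Character vector of categories.
#' @export
icc_category <- function(icc) {
  ifelse(icc > 0.75, "excellent",
         ifelse(icc >= 0.60, "good",
                ifelse(icc >= 0.40, "fair", "poor")))
}

new_reliability_result <- function(estimate, ci, n_boot, seed,
                                   category = NA_character_, n = NA_integer_,
                                   flagged = FALSE) {
  structure(list(estimate = estimate, ci_lo = ci[1], ci_hi = ci[2],
                 n_boot = n_boot, category = category, n = n, seed = seed,
                 flagged = flagged),
            class = "reliability_result")
}

#' @export
print.reliability_result <- function(x, ...) {
  cat(sprintf("<reliability> estimate = %.3f, 95%% CI [%.3f, %.3f]%s%s\n",
              x$estimate, x$ci_lo, x$ci_hi,
              if (!is.na(x$category)) paste0(", ", x$category) else "",
              if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Percentile bootstrap confidence interval
#'
#' Resamples subjects (rows of `data`) with replacement `n_boot` times,
#' applies `stat_fn` to each resample, and returns the 2.5/97.5 percentile
#' bounds. Flagged when the statistic is undefined (NA/NaN) on more than
#' 10% of resamples.
#'
#' @param stat_fn Function of a resampled `data` (same type as `data`)
#'   returning a scalar.
#' @param data Matrix or data frame with one row per subject, or a vector
#'   with one element per subject.
#' @param n_boot Number of resamples (>= 100).
#' @param seed Integer seed.
#' @return List with `lo`, `hi`, `reps` (all bootstrap replicates),
#'   `flagged`.
#' @export
bootstrap_ci <- function(stat_fn, data, n_boot = 10000L, seed = 1L) {
  stopifnot(n_boot >= 100)
  n <- if (is.null(dim(data))) length(data) else nrow(data)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    resample <- if (is.null(dim(data))) data[idx] else data[idx, , drop = FALSE]
    as.numeric(stat_fn(resample))
  }, numeric(1))
  bad <- mean(!is.finite(reps))
  qs <- stats::quantile(reps[is.finite(reps)], c(0.025, 0.975), names = FALSE,
                        type = 7)
  list(lo = qs[1], hi = qs[2], reps = reps, flagged = bad > 0.10)
}

#' Coefficient of variation across subjects
#'
#' Sample SD (n-1 denominator) over the mean of one value per subject,
#' with a subject-level percentile bootstrap 95% CI.
#'
#' @param values Numeric vector, one value per subject (n >= 3).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @return A `reliability_result` (no category; CoV has none). Flagged
#'   with `NA` estimate when the mean is zero.
#' @export
cov_reliability <- function(values, n_boot = 10000L, seed = 1L) {
  stopifnot(length(values) >= 3)
  cov_stat <- function(v) {
    m <- mean(v)
    if (abs(m) < .Machine$double.eps^0.5 * stats::sd(v) || m == 0)
      return(NA_real_)
    stats::sd(v) / m
  }
  est <- cov_stat(values)
  if (!is.finite(est))
    return(new_reliability_result(NA_real_, c(NA_real_, NA_real_), n_boot,
                                  seed, n = length(values), flagged = TRUE))
  bs <- bootstrap_ci(cov_stat, values, n_boot, seed)
  new_reliability_result(est, c(bs$lo, bs$hi), n_boot, seed,
                         n = length(values), flagged = bs$flagged)
}

# two-way mean squares of a complete subjects x sessions matrix
icc_mean_squares <- function(Y) {
  n <- nrow(Y); k <- ncol(Y)
  grand <- mean(Y)
  row_m <- rowMeans(Y)
  col_m <- colMeans(Y)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((Y - grand)^2)
  SSE <- SST - SSR - SSC
  list(n = n, k = k,
       MSR = SSR / (n - 1), MSC = SSC / (k - 1),
       MSE = SSE / ((n - 1) * (k - 1)),
       MSW = (SSC + SSE) / (n * (k - 1)))
}

#' Intra-class correlation of a wide subjects x sessions matrix
#'
#' Single-measure ICC from the two-way subject x session variance
#' decomposition. Forms: `"ICC3"` (two-way mixed, consistency; default),
#' `"ICC2"` (two-way random, absolute agreement), `"ICC1"` (one-way
#' random).
#'
#' @param Y Numeric matrix, subjects x sessions, complete.
#' @param form ICC form.
#' @return Scalar ICC.
#' @export
icc_point <- function(Y, form = c("ICC3", "ICC2", "ICC1")) {
  form <- match.arg(form)
  ms <- icc_mean_squares(Y)
  with(ms, switch(form,
    ICC3 = (MSR - MSE) / (MSR + (k - 1) * MSE),
    ICC2 = (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE)),
    ICC1 = (MSR - MSW) / (MSR + (k - 1) * MSW)))
}

#' Test-retest reliability (ICC) from a cohort table
#'
#' Pivots the long cohort table to a subjects x sessions matrix for one
#' measure (and band), drops subjects with any missing session (listwise),
#' and estimates the ICC with a subject-level percentile bootstrap 95% CI
#' and a reliability category.
#'
#' @param table Data frame with columns `subject`, `session`, `band`,
#'   `measure`, `value` (a cohort table), or a numeric subjects x
#'   sessions matrix used as-is.
#' @param measure_name Value of `measure` to select (ignored for matrix
#'   input).
#' @param band Optional band name to select (ignored for matrix input).
#' @param form ICC form, see [icc_point()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param seed Integer seed.
#' @return A `reliability_result` with `category`.
#' @export
icc <- function(table, measure_name = NULL, band = NULL, form = "ICC3",
                n_boot = 10000L, seed = 1L) {
  Y <- if (is.matrix(table)) table
       else cohort_wide(table, measure_name, band)
  keep <- stats::complete.cases(Y)
  if (sum(!keep) > 0)
    message("icc: dropping ", sum(!keep), " subject(s) with missing sessions")
  Y <- Y[keep, , drop = FALSE]
  if (ncol(Y) < 2) stop("ICC requires >= 2 sessions")
  if (nrow(Y) < 5) stop("ICC requires >= 5 complete subjects")
  est <- icc_point(Y, form)
  bs <- bootstrap_ci(function(y) icc_point(y, form), Y, n_boot, seed)
  new_reliability_result(est, c(bs$lo, bs$hi), n_boot, seed,
                         category = icc_category(est), n = nrow(Y),
                         flagged = bs$flagged)
}

cohort_wide <- function(table, measure_name, band = NULL) {
  stopifnot(all(c("subject", "session", "measure", "value") %in% names(table)))
  rows <- table$measure == measure_name
  if (!is.null(band)) rows <- rows & table$band == band
  tab <- table[rows, , drop = FALSE]
  if (nrow(tab) == 0) stop("no rows for measure '", measure_name, "'",
                           if (!is.null(band)) paste0(" in band '", band, "'"))
  if (anyDuplicated(tab[, c("subject", "session")]))
    stop("more than one value per (subject, session); select a band")
  subjects <- sort(unique(tab$subject))
  sessions <- sort(unique(tab$session))
  Y <- matrix(NA_real_, length(subjects), length(sessions),
              dimnames = list(subjects, sessions))
  Y[cbind(match(tab$subject, subjects), match(tab$session, sessions))] <-
    tab$value
  Y
}

#' Repeated-measures ANOVA across frequency bands
#'
#' One-way within-subject ANOVA of a measure across bands at one session
#' (subject as blocking factor): `F = MS_band / MS_error` with
#' `(k - 1), (n - 1)(k - 1)` degrees of freedom, plus uncorrected paired
#' t-tests between all band pairs.
#'
#' @param table Cohort table (see [icc()]).
#' @param measure_name Measure to analyze.
#' @param session Session to analyze (default 1, the baseline).
#' @return List with `F`, `p`, `df`, and `posthoc` (data frame of paired
#'   t-tests per band pair).
#' @export
band_anova <- function(table, measure_name, session = 1L) {
  tab <- table[table$measure == measure_name & table$session == session, ]
  if (length(unique(tab$band)) < 2) stop("need >= 2 bands")
  bands <- unique(tab$band)
  subjects <- sort(unique(tab$subject))
  Y <- matrix(NA_real_, length(subjects), length(bands),
              dimnames = list(subjects, bands))
  Y[cbind(match(tab$subject, subjects), match(tab$band, bands))] <- tab$value
  Y <- Y[stats::complete.cases(Y), , drop = FALSE]
  ms <- icc_mean_squares(Y)
  # degenerate layouts: no band variability at all means no band effect
  Fval <- if (ms$MSC <= 0) 0
          else if (ms$MSE <= 0) Inf
          else ms$MSC / ms$MSE
  df <- c(ms$k - 1, (ms$n - 1) * (ms$k - 1))
  p <- stats::pf(Fval, df[1], df[2], lower.tail = FALSE)
  cmb <- utils::combn(bands, 2)
  posthoc <- data.frame(band_a = cmb[1, ], band_b = cmb[2, ],
                        t = NA_real_, p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(cmb))) {
    tt <- stats::t.test(Y[, cmb[1, j]], Y[, cmb[2, j]], paired = TRUE)
    posthoc$t[j] <- unname(tt$statistic)
    posthoc$p[j] <- tt$p.value
  }
  list(F = Fval, p = p, df = df, posthoc = posthoc)
}

# vectorized within-subject F across bands for every channel
# Y: subjects x bands x channels
rm_f_channels <- function(Y) {
  n <- dim(Y)[1]; k <- dim(Y)[2]; C <- dim(Y)[3]
  gm <- colMeans(Y, dims = 2)                          # per channel
  band_m <- colMeans(Y)                                # k x C
  subj_m <- colMeans(aperm(Y, c(2, 1, 3)))             # n x C
  SSC <- n * colSums((band_m - rep(gm, each = k))^2)
  SSR <- k * colSums((subj_m - rep(gm, each = n))^2)
  SST <- colSums((matrix(Y, n * k, C) - rep(gm, each = n * k))^2)
  SSE <- SST - SSC - SSR
  (SSC / (k - 1)) / (SSE / ((n - 1) * (k - 1)))
}

#' Topographic permutation ANOVA across bands
#'
#' Per-channel repeated-measures F across bands, with family-wise error
#' control by the max-F permutation distribution: band labels are permuted
#' within subject (the same permutation for all channels of a subject),
#' and the corrected p-value of a channel is the add-one proportion of
#' permutations whose maximum F across channels reaches its observed F.
#'
#' @param Y Numeric array subjects x bands x channels.
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param seed Integer seed.
#' @return List with `F` (per channel), `p_corrected` (per channel),
#'   `max_f_null` (the permutation distribution), `n_perm`, `seed`.
#' @export
permutation_anova_topographic <- function(Y, n_perm = 1000L, seed = 1L) {
  stopifnot(is.array(Y), length(dim(Y)) == 3)
  if (n_perm < 100) warning("n_perm < 100 gives a very coarse p-value grid")
  n <- dim(Y)[1]; k <- dim(Y)[2]; C <- dim(Y)[3]
  f_obs <- rm_f_channels(Y)
  # all k! within-subject relabelings, sampled per subject per permutation
  perms <- permutations_of(k)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  chan_off <- rep((0:(C - 1)) * n * k, each = n * k)
  max_f <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    P <- perms[sample.int(nrow(perms), n, replace = TRUE), , drop = FALSE]
    flat <- as.vector(seq_len(n) + (P - 1L) * n)       # n x k flat indices
    Yp <- array(Y[flat + chan_off], dim = c(n, k, C))
    max_f[b] <- max(rm_f_channels(Yp))
  }
  p_corr <- vapply(f_obs, function(f) (1 + sum(max_f >= f)) / (n_perm + 1),
                   numeric(1))
  list(F = f_obs, p_corrected = p_corr, max_f_null = max_f,
       n_perm = n_perm, seed = seed)
}

permutations_of <- function(k) {
  if (k == 1) return(matrix(1L, 1, 1))
  sub <- permutations_of(k - 1L)
  out <- matrix(0L, 0, k)
  for (pos in seq_len(k)) {
    block <- cbind(sub[, seq_len(pos - 1), drop = FALSE], k,
                   sub[, seq(pos, k - 1)[seq_len(k - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  out
}
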