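alpha1 <- band_spec("alpha1", 8, 10)

test_that("PLI matches hand-computed sign averages", {
  expect_equal(pli_pair(c(0.1, 0.2, 0.3, -0.1)), 0.5)
  expect_equal(pli_pair(rep(0, 100)), 0)
  expect_equal(pli_pair(rep(pi / 4, 64)), 1)
  expect_error(pli_pair(numeric(0)), "empty")
  # symmetric uniform phase differences: PLI within binomial sampling error
  set.seed(8)
  dphi <- runif(4096, -pi, pi)
  expect_lt(pli_pair(dphi), 4 / sqrt(4096))
})

test_that("debiased wPLI matches hand evaluation and degenerate rules", {
  # constant positive imaginary part: num = den -> 1
  expect_equal(wpli_pair(complex(real = 0, imaginary = rep(2, 10))), 1)
  # all-zero imaginary parts (pure zero lag): defined as 0
  expect_equal(wpli_pair(complex(real = 1:5, imaginary = 0)), 0)
  # s = [1, 1, -1]: num = 3^2... (1+1-1)^2 - 3 = -2 -> clipped to 0
  expect_equal(wpli_pair(c(1, 1, -1)), 0)
  # hand case with unequal magnitudes: s = [2, 1]:
  # num = 9 - 5 = 4; den = 9 - 5 = 4 -> 1
  expect_equal(wpli_pair(c(2, 1)), 1)
  # s = [2, -1]: num = 1 - 5 = -4 -> 0
  expect_equal(wpli_pair(c(2, -1)), 0)
  expect_error(wpli_pair(1), ">= 2")
})

test_that("matrix pipeline equals naive per-pair recomputation", {
  set.seed(14)
  arr <- array(rnorm(8 * 3 * 512), c(8, 3, 512))
  rec <- bandpass(epoched_recording(arr, 128, toy_montage(8L, 2L, 6L)),
                  alpha1)
  ae <- analytic_signal(rec, alpha1)
  cm <- connectivity_matrices(ae, c("pli", "wpli"))
  for (e in 1:3) {
    for (i in 1:7) for (j in (i + 1):8) {
      cs <- ae$analytic[i, e, ] * Conj(ae$analytic[j, e, ])
      expect_equal(cm$pli$per_epoch[[e]][i, j],
                   pli_pair(wrap_phase(Arg(cs))), tolerance = 1e-12)
      expect_equal(cm$wpli$per_epoch[[e]][i, j], wpli_pair(cs),
                   tolerance = 1e-12)
    }
  }
  # subject average is the entrywise epoch mean
  avg <- (unclass(cm$pli$per_epoch[[1]]) + unclass(cm$pli$per_epoch[[2]]) +
            unclass(cm$pli$per_epoch[[3]])) / 3
  expect_equal(unclass(cm$pli$average), avg, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("connectivity is equivariant under channel relabeling", {
  set.seed(15)
  arr <- array(rnorm(6 * 2 * 512), c(6, 2, 512))
  mont <- toy_montage(6L, 2L, 4L)
  ae <- analytic_signal(bandpass(epoched_recording(arr, 128, mont), alpha1),
                        alpha1)
  perm <- c(3, 1, 6, 2, 5, 4)
  ae_p <- analytic_signal(bandpass(epoched_recording(arr[perm, , ], 128, mont),
                                   alpha1), alpha1)
  m <- connectivity_matrices(ae, "pli")$pli$average
  m_p <- connectivity_matrices(ae_p, "pli")$pli$average
  expect_equal(unclass(m_p), unclass(m)[perm, perm], ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("PLI/wPLI are symmetric in the pair and amplitude-invariant", {
  set.seed(16)
  n <- 1024
  a <- complex(real = rnorm(n), imaginary = rnorm(n))
  b <- complex(real = rnorm(n), imaginary = rnorm(n))
  dab <- wrap_phase(Arg(a * Conj(b)))
  dba <- wrap_phase(Arg(b * Conj(a)))
  expect_equal(pli_pair(dab), pli_pair(dba), tolerance = 1e-12)
  expect_equal(wpli_pair(a * Conj(b)), wpli_pair(b * Conj(a)),
               tolerance = 1e-12)
  # positive rescaling of either channel changes nothing
  expect_equal(wpli_pair((3.7 * a) * Conj(3.7 * b)), wpli_pair(a * Conj(b)),
               tolerance = 1e-12)
  expect_equal(pli_pair(wrap_phase(Arg((2.5 * a) * Conj(b)))), pli_pair(dab),
               tolerance = 1e-12)
})

test_that("subject-average PLI is nondecreasing in coupling strength", {
  mont <- toy_montage(4L, 2L, 4L)
  plis <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(s) {
    spec <- coupling_spec(list(list(a = 1, b = 2, lag = pi / 4,
                                    strength = s)),
                          common_source_gain = 0, band = alpha1, snr = 5)
    rec <- simulate_recording(mont, spec, n_epochs = 6, n_samples = 1024,
                              fs = 256, seed = 77)
    ae <- analytic_signal(rec, alpha1)
    connectivity_matrices(ae, "pli")$pli$average[1, 2]
  }, numeric(1))
  expect_true(all(diff(plis) >= 0))
  expect_gt(plis[5], plis[1] + 0.5)   # strong coupling clearly separates
})

test_that("global, regional and link aggregation match brute force", {
  mont <- toy_montage(12L, 4L, 8L)
  set.seed(17)
  W <- random_weight_matrix(12)
  m <- phaselag:::new_conn_matrix(W, "pli", alpha1, "subject-average",
                                  mont$labels)
  # global: mean of strict upper triangle
  expect_equal(global_connectivity(m), mean(W[upper.tri(W)]))
  W3 <- matrix(0.3, 3, 3); diag(W3) <- 0
  expect_equal(global_connectivity(W3), 0.3)
  W3[upper.tri(W3)] <- c(0.2, 0.4, 0.6); W3[lower.tri(W3)] <- t(W3)[lower.tri(W3)]
  expect_equal(global_connectivity(W3), 0.4)
  # regional degree: brute-force double loop over (i, j)
  reg <- montage_regions(mont)
  rd <- regional_degree(m, mont)
  all_reg <- unlist(reg)
  for (r in names(reg)) {
    vals <- c()
    for (i in reg[[r]]) for (j in setdiff(all_reg, reg[[r]]))
      vals <- c(vals, W[i, j])
    expect_equal(unname(rd[r]), mean(vals))
  }
  # constant matrix: every regional degree equals the constant
  Wc <- matrix(0.4, 12, 12); diag(Wc) <- 0
  expect_equal(unname(regional_degree(Wc, mont)), rep(0.4, 4))
  # weights only inside regions: regional degrees all zero
  Win <- matrix(0, 12, 12)
  for (r in reg) Win[r, r] <- 0.5
  diag(Win) <- 0
  expect_equal(unname(regional_degree(Win, mont)), rep(0, 4))
  # inter-regional links: brute force + count
  lk <- inter_regional_links(m, mont)
  expect_equal(nrow(lk), choose(4, 2))
  for (row in seq_len(nrow(lk))) {
    i <- reg[[lk$region_a[row]]]; j <- reg[[lk$region_b[row]]]
    expect_equal(lk$weight[row], mean(W[i, j]))
  }
})

test_that("22 regions yield 231 inter-regional links", {
  mont <- make_default_montage()
  W <- matrix(0.2, 214, 214); diag(W) <- 0
  lk <- inter_regional_links(W, mont)
  expect_equal(nrow(lk), 231L)
  expect_equal(lk$weight, rep(0.2, 231))
})

test_that("distance correlation recovers monotone weight-distance maps", {
  mont <- toy_montage(12L, 4L, 8L)
  d <- as.matrix(dist(mont$coords))
  w_neg <- exp(-d); diag(w_neg) <- 0
  dc <- distance_correlation(w_neg / max(w_neg), mont)
  expect_equal(dc$rho, -1)
  w_pos <- d / max(d); diag(w_pos) <- 0
  expect_equal(distance_correlation(w_pos, mont)$rho, 1)
  # weight independent of distance: rho near zero
  set.seed(18)
  dc0 <- distance_correlation(random_weight_matrix(12), mont)
  expect_lt(abs(dc0$rho), 2 / sqrt(dc0$n_pairs))
  # degenerate distances flagged
  mont2 <- mont; mont2$coords[] <- 1
  expect_true(distance_correlation(w_pos, mont2)$degenerate)
})

test_that("top links obey the count and tie rules", {
  # 214 channels at 3%: ceil(0.03 * 22791) = 684 edges
  W <- matrix(0.2, 214, 214); diag(W) <- 0
  tl <- top_links(W, 0.03)
  expect_equal(nrow(tl$edges), 684L)
  # all-equal weights: lexicographic order by (i, j)
  expect_equal(tl$edges$chan_a[1:3], rep("1", 3))
  expect_equal(tl$edges$chan_b[1:3], c("2", "3", "4"))
  # a dominant edge ranks first
  W[3, 7] <- W[7, 3] <- 0.9
  expect_equal(top_links(W, 0.001)$edges[1, c("chan_a", "chan_b")],
               data.frame(chan_a = "3", chan_b = "7"), ignore_attr = TRUE)
  # nodal degree is the row mean excluding the diagonal
  set.seed(19)
  Wr <- random_weight_matrix(6)
  nd <- top_links(Wr, 0.5)$nodal_degree
  expect_equal(unname(nd), rowSums(Wr) / 5)
})
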