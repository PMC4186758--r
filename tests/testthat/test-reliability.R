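test_that("coefficient of variation matches forced arithmetic", {
  expect_equal(cov_reliability(c(5, 5, 5, 5), n_boot = 100)$estimate, 0)
  r <- cov_reliability(c(1, 2, 3), n_boot = 100, seed = 1)
  expect_equal(r$estimate, 0.5)   # sd 1, mean 2
  expect_true(r$ci_lo <= r$estimate && r$estimate <= r$ci_hi)
  # zero mean: undefined, flagged
  z <- cov_reliability(c(-1, 0, 1), n_boot = 100)
  expect_true(z$flagged)
  expect_true(is.na(z$estimate))
  expect_error(cov_reliability(c(1, 2)), "length")
})

test_that("ICC point estimates agree with an lm-based oracle", {
  Y <- vc_values(12, 3, 0.5, 0.1, 0.05, seed = 31)
  # oracle: mean squares from a two-way fixed-effects fit
  df <- data.frame(y = as.vector(Y),
                   subj = factor(rep(seq_len(12), 3)),
                   sess = factor(rep(1:3, each = 12)))
  an <- anova(lm(y ~ subj + sess, df))
  MSR <- an["subj", "Mean Sq"]; MSC <- an["sess", "Mean Sq"]
  MSE <- an["Residuals", "Mean Sq"]
  k <- 3; n <- 12
  expect_equal(icc_point(Y, "ICC3"), (MSR - MSE) / (MSR + (k - 1) * MSE),
               tolerance = 1e-12)
  expect_equal(icc_point(Y, "ICC2"),
               (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE)),
               tolerance = 1e-12)
  MSW <- (an["sess", "Sum Sq"] + an["Residuals", "Sum Sq"]) / (n * (k - 1))
  expect_equal(icc_point(Y, "ICC1"), (MSR - MSW) / (MSR + (k - 1) * MSW),
               tolerance = 1e-12)
})

test_that("ICC hits its deterministic extremes and categories", {
  # sessions identical per subject, subjects differ: ICC = 1, excellent
  Y <- matrix(rep(seq(0.1, 1, length.out = 8), 3), 8, 3)
  r <- icc(Y, n_boot = 200, seed = 1)
  expect_equal(r$estimate, 1)
  expect_equal(r$category, "excellent")
  # i.i.d. values: ICC near zero, poor
  set.seed(32)
  Y0 <- matrix(rnorm(120), 40, 3)
  r0 <- icc(Y0, n_boot = 200, seed = 1)
  expect_lt(abs(r0$estimate), 2 / sqrt(40))
  expect_equal(r0$category, "poor")
  # guards
  expect_error(icc(Y[, 1, drop = FALSE], n_boot = 200), ">= 2 sessions")
  expect_error(icc(Y[1:3, ], n_boot = 200), ">= 5")
})

test_that("ICC works from long cohort tables with listwise deletion", {
  Y <- vc_values(10, 3, 0.5, 0.1, 0.05, seed = 33)
  tab <- table_from_matrix(Y, measure = "pli_global")
  r_tab <- icc(tab, "pli_global", band = "alpha1", n_boot = 200, seed = 2)
  r_mat <- icc(Y, n_boot = 200, seed = 2)
  expect_equal(r_tab$estimate, r_mat$estimate)
  # drop one subject's session: that subject removed, others unchanged
  tab2 <- tab[!(tab$subject == 4 & tab$session == 2), ]
  expect_message(r2 <- icc(tab2, "pli_global", n_boot = 200, seed = 2),
                 "dropping 1")
  expect_equal(r2$n, 9L)
  expect_equal(r2$estimate, icc_point(Y[-4, ], "ICC3"))
})

test_that("ICC is shift-invariant; CoV is not", {
  Y <- vc_values(15, 3, 0.5, 0.1, 0.05, seed = 34)
  expect_equal(icc_point(Y + 10), icc_point(Y), tolerance = 1e-10)
  v <- Y[, 1]
  expect_false(isTRUE(all.equal(cov_reliability(v + 10, n_boot = 100)$estimate,
                                cov_reliability(v, n_boot = 100)$estimate)))
})

test_that("category thresholds behave at their boundaries", {
  expect_equal(icc_category(c(0.76, 0.75, 0.60, 0.5999, 0.40, 0.3999)),
               c("excellent", "good", "good", "fair", "fair", "poor"))
})

test_that("bootstrap CI is seeded, degenerate-safe and close to the t-interval", {
  v <- rep(2, 10)
  bs <- bootstrap_ci(mean, v, n_boot = 200, seed = 5)
  expect_equal(bs$lo, 2); expect_equal(bs$hi, 2)
  set.seed(35)
  x <- rnorm(40, 10, 2)
  b1 <- bootstrap_ci(mean, x, n_boot = 2000, seed = 6)
  b2 <- bootstrap_ci(mean, x, n_boot = 2000, seed = 6)
  expect_identical(b1$lo, b2$lo)
  # half-width within 10% of the closed-form t-interval
  t_half <- qt(0.975, 39) * sd(x) / sqrt(40)
  boot_half <- (b1$hi - b1$lo) / 2
  expect_lt(abs(boot_half - t_half) / t_half, 0.10)
  expect_error(bootstrap_ci(mean, x, n_boot = 50), "n_boot")
})

test_that("bootstrap CI width shrinks as subjects are added", {
  widths <- vapply(c(20, 80, 320), function(n) {
    Y <- vc_values(n, 3, 0.5, 0.1, 0.05, seed = 36)
    r <- icc(Y, n_boot = 400, seed = 7)
    r$ci_hi - r$ci_lo
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("band ANOVA matches aov and behaves at its extremes", {
  set.seed(37)
  n <- 10
  Y <- cbind(rnorm(n, 1), rnorm(n, 1.5), rnorm(n, 3))
  tab <- do.call(rbind, lapply(1:3, function(b)
    data.frame(subject = 1:n, session = 1, band = paste0("b", b),
               measure = "m", value = Y[, b])))
  res <- band_anova(tab, "m")
  fit <- summary(aov(value ~ band + Error(factor(subject) / band), tab))
  Ftab <- fit[["Error: factor(subject):band"]][[1]]
  expect_equal(res$F, Ftab["band", "F value"], tolerance = 1e-10)
  expect_equal(res$p, Ftab["band", "Pr(>F)"], tolerance = 1e-10)
  expect_equal(nrow(res$posthoc), 3L)
  # identical values across bands: F ~ 0, p ~ 1
  tab0 <- tab; tab0$value <- rep(Y[, 1], 3)
  res0 <- band_anova(tab0, "m")
  expect_equal(res0$F, 0)
  expect_equal(res0$p, 1)
  # huge separation: tiny p
  tabX <- tab; tabX$value <- tabX$value + 100 * as.integer(factor(tabX$band))
  expect_lt(band_anova(tabX, "m")$p, 1e-6)
})

test_that("topographic permutation ANOVA is seeded and detects one channel", {
  set.seed(38)
  n <- 12; k <- 3; C <- 6
  Y <- array(rnorm(n * k * C), c(n, k, C))
  Y[, 2, 4] <- Y[, 2, 4] + 10      # one channel with a massive band effect
  p1 <- permutation_anova_topographic(Y, n_perm = 200, seed = 9)
  p2 <- permutation_anova_topographic(Y, n_perm = 200, seed = 9)
  expect_identical(p1$p_corrected, p2$p_corrected)
  expect_lte(p1$p_corrected[4], 1 / 200)
  expect_true(all(p1$p_corrected >= 1 / 201))
  # the per-channel F agrees with the scalar RM-ANOVA
  tab <- do.call(rbind, lapply(1:k, function(b)
    data.frame(subject = 1:n, session = 1, band = paste0("b", b),
               measure = "m", value = Y[, b, 4])))
  expect_equal(p1$F[4], band_anova(tab, "m")$F, tolerance = 1e-10)
  expect_warning(permutation_anova_topographic(Y, n_perm = 50, seed = 1),
                 "coarse")
})
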