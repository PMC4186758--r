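test_that("weighted clustering matches closed forms", {
  # complete constant-weight graph: C_i = w at every node
  for (w in c(0.2, 0.7, 1)) {
    W <- matrix(w, 5, 5); diag(W) <- 0
    cl <- weighted_clustering(W)
    expect_equal(unname(cl$C_i), rep(w, 5))
    expect_equal(cl$Cw, w)
  }
  # binary triangle: Cw = 1
  tri <- matrix(1, 3, 3); diag(tri) <- 0
  expect_equal(weighted_clustering(tri)$Cw, 1)
  # star: no closed triangles, Cw = 0
  star <- matrix(0, 5, 5); star[1, 2:5] <- star[2:5, 1] <- 0.8
  expect_equal(weighted_clustering(star)$Cw, 0)
  # invalid inputs rejected
  bad <- matrix(runif(16), 4, 4)
  expect_error(weighted_clustering(bad), "symmetric")
  neg <- matrix(0, 3, 3); neg[1, 2] <- neg[2, 1] <- -0.5
  expect_error(weighted_clustering(neg), "\\[0, 1\\]")
})

test_that("clustering and path length equal brute-force enumeration", {
  set.seed(20)
  for (r in 1:20) {
    n <- sample(6:8, 1)
    W <- random_weight_matrix(n, density = runif(1, 0.5, 1))
    cl <- weighted_clustering(W)
    bf <- bf_clustering(W)
    expect_equal(unname(cl$C_i), bf$C_i, tolerance = 1e-12)
    pl <- weighted_path_length(W)
    bfp <- bf_pathlength(W)
    expect_equal(pl$L, bfp$L, ignore_attr = TRUE, tolerance = 1e-12)
    expect_equal(pl$Lw, bfp$Lw, tolerance = 1e-12)
  }
})

test_that("path length matches hand-computed cases", {
  # single edge: Lw = 1/w
  W <- matrix(0, 4, 4)  # first the 2-node case embedded alone
  W2 <- matrix(0, 2, 2); W2[1, 2] <- W2[2, 1] <- 0.5
  expect_equal(weighted_path_length(W2)$Lw, 2)
  # 3-node chain a-b (1), b-c (1), a-c (0): L_ac = 2, Lw = 1.2
  ch <- matrix(0, 3, 3)
  ch[1, 2] <- ch[2, 1] <- 1; ch[2, 3] <- ch[3, 2] <- 1
  pl <- weighted_path_length(ch)
  expect_equal(pl$L[1, 3], 2)
  expect_equal(pl$Lw, 1.2)
  # fully disconnected: explicit Inf sentinel, never silently 0
  empty <- matrix(0, 4, 4)
  pe <- weighted_path_length(empty)
  expect_true(is.infinite(pe$Lw))
  expect_true(pe$disconnected)
})

test_that("surrogate normalization is exact for constant graphs and seeded", {
  W <- matrix(0.6, 8, 8); diag(W) <- 0
  sn <- surrogate_normalize(W, n_surrogates = 5, n_iterations = 2, seed = 3)
  expect_equal(sn$gamma, 1)
  expect_equal(sn$lambda, 1)
  expect_equal(sn$swi, 1)
  # determinism
  set.seed(21)
  Wr <- random_weight_matrix(10)
  a <- surrogate_normalize(Wr, 10, 2, seed = 7)
  b <- surrogate_normalize(Wr, 10, 2, seed = 7)
  expect_identical(a$gamma, b$gamma)
  expect_identical(a$lambda, b$lambda)
  # swi is exactly gamma/lambda
  expect_identical(a$swi, a$gamma / a$lambda)
})

test_that("an i.i.d.-weight random graph normalizes to about 1", {
  set.seed(22)
  W <- random_weight_matrix(16)
  sn <- surrogate_normalize(W, 25, 2, seed = 9)
  # within 3 surrogate-ensemble SDs of 1
  expect_lt(abs(sn$Cw - sn$surr_Cw_mean), 3 * sn$surr_Cw_sd)
  expect_lt(abs(sn$Lw - sn$surr_Lw_mean), 3 * sn$surr_Lw_sd)
})

test_that("graph measures transform correctly under relabeling and scaling", {
  set.seed(23)
  W <- random_weight_matrix(9)
  perm <- sample(9)
  Wp <- W[perm, perm]
  expect_equal(weighted_clustering(Wp)$Cw, weighted_clustering(W)$Cw,
               tolerance = 1e-12)
  expect_equal(weighted_path_length(Wp)$Lw, weighted_path_length(W)$Lw,
               tolerance = 1e-12)
  # scaling by alpha: C_i scales by alpha, Lw by 1/alpha
  a <- 0.37
  expect_equal(weighted_clustering(a * W)$C_i, a * weighted_clustering(W)$C_i,
               tolerance = 1e-12)
  expect_equal(weighted_path_length(a * W)$Lw,
               weighted_path_length(W)$Lw / a, tolerance = 1e-12)
  # gamma/lambda are scale-invariant (surrogates scale identically)
  s1 <- surrogate_normalize(W, 10, 2, seed = 5)
  s2 <- surrogate_normalize(a * W, 10, 2, seed = 5)
  expect_equal(s2$gamma, s1$gamma, tolerance = 1e-10)
  expect_equal(s2$lambda, s1$lambda, tolerance = 1e-10)
})

test_that("graph pipeline separates small-world from random topology", {
  # weighted ring lattice with a few shortcuts: high clustering, short paths
  n <- 20
  W <- matrix(0, n, n)
  for (i in seq_len(n)) for (d in 1:2) {
    j <- ((i + d - 1) %% n) + 1
    W[i, j] <- W[j, i] <- 0.9
  }
  set.seed(24)
  for (s in 1:4) {
    i <- sample(n, 1); j <- sample(setdiff(seq_len(n), i), 1)
    W[i, j] <- W[j, i] <- 0.9
  }
  gp <- graph_pipeline(W, n_surrogates = 20, n_iterations = 2, seed = 11)
  expect_gt(gp$normalized$swi, 1)
  # identical input, identical metrics
  gp2 <- graph_pipeline(W, n_surrogates = 20, n_iterations = 2, seed = 11)
  expect_identical(gp$normalized$swi, gp2$normalized$swi)
  # i.i.d. random graph: swi near 1
  Wr <- random_weight_matrix(16, seed = 25)
  gpr <- graph_pipeline(Wr, n_surrogates = 20, n_iterations = 2, seed = 12)
  expect_lt(abs(gpr$normalized$swi - 1), 0.1)
})
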