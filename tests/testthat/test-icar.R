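# ICAR precision algebra, conditionals, log density and constrained
# sampling.

test_that("ICAR precision is tau * (D - A) with zero row sums", {
  g <- path_graph(3)
  Q <- as.matrix(icar_precision(g, 1))
  expect_equal(unname(Q),
               matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE))
  Q2 <- as.matrix(icar_precision(g, 2.5))
  expect_equal(Q2, 2.5 * Q)
  expect_error(icar_precision(g, 0), "positive")

  for (s in 1:10) {
    g <- random_soi_graph(sample(5:50, 1), seed = 2000 + s)
    Q <- as.matrix(icar_precision(g, 2.5))
    expect_equal(Q, t(Q))
    expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
    # off-diagonal sparsity pattern equals the adjacency
    expect_identical(unname(Q != 0 & row(Q) != col(Q)),
                     graph_adjacency(g))
    # spectral rank: exactly c zero eigenvalues
    ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
    expect_equal(sum(abs(ev) < 1e-8), g$n_components)
  }
})

test_that("full conditional is N(neighbour mean, 1/(n_i tau))", {
  # unit 2 of a path has neighbours {1, 3} holding {1, 3}: mean 2,
  # variance 1/(2*4)
  g <- path_graph(3)
  cond <- icar_conditional(c(1, 0, 3), g, tau = 4, i = 2)
  expect_equal(cond$mean, 2)
  expect_equal(cond$variance, 1 / 8)
  # all neighbours zero
  expect_equal(icar_conditional(c(0, 5, 0), g, 1, 2)$mean, 0)
  # single neighbour with value v, tau = 1
  cond <- icar_conditional(c(0, 7, 0), g, 1, 1)
  expect_equal(cond$mean, 7)
  expect_equal(cond$variance, 1)
  # isolated node errors
  g0 <- graph_from_edges(3, list(c(1, 2)))
  expect_error(icar_conditional(c(0, 0, 0), g0, 1, 3), "isolated")
})

test_that("log density matches the quadratic form through Q", {
  g <- path_graph(3)
  # values (-1, 0, 1), tau 1: pairwise term (1 + 1)/2 * ... = sum over
  # unordered pairs (b_i - b_j)^2 / 2 * tau = (1 + 1)/2 = 1; rank term 0
  expect_equal(icar_logdensity(c(-1, 0, 1), g, 1), -1)
  # all zeros: only the rank term remains
  expect_equal(icar_logdensity(rep(0, 3), g, 2), 0.5 * 2 * log(2))
  expect_error(icar_logdensity(c(1, 1, 1), g, 1), "sum-to-zero")

  # differences between two vectors equal the 1/2 v'Qv difference
  for (s in 1:5) {
    g <- random_soi_graph(20, seed = 3000 + s)
    tau <- runif(1, 0.5, 3)
    Q <- as.matrix(icar_precision(g, tau))
    center <- function(v) {
      for (cc in unique(g$components)) {
        idx <- g$components == cc
        v[idx] <- v[idx] - mean(v[idx])
      }
      v
    }
    v1 <- center(rnorm(20)); v2 <- center(rnorm(20))
    expect_equal(
      icar_logdensity(v1, g, tau) - icar_logdensity(v2, g, tau),
      -0.5 * (drop(v1 %*% Q %*% v1) - drop(v2 %*% Q %*% v2)),
      tolerance = 1e-10)
  }
})

test_that("log density is consistent with the single-site conditional", {
  # the full conditional extracted from the joint must match the stated
  # Normal: compare log-density differences in beta_i against dnorm
  g <- random_soi_graph(12, seed = 77)
  tau <- 1.7
  set.seed(1)
  v <- drop(ricar(1, g, tau))
  i <- 5L
  cond <- icar_conditional(v, g, tau, i)
  for (a in c(-0.4, 0.1, 0.6)) {
    v2 <- v
    v2[i] <- v[i] + a
    ld_joint <- icar_logdensity(v2, g, tau, check = FALSE) -
      icar_logdensity(v, g, tau, check = FALSE)
    ld_cond <- dnorm(v2[i], cond$mean, sqrt(cond$variance), log = TRUE) -
      dnorm(v[i], cond$mean, sqrt(cond$variance), log = TRUE)
    expect_equal(ld_joint, ld_cond, tolerance = 1e-8)
  }
})

test_that("constrained sampling has zero component means and the right covariances", {
  g <- random_soi_graph(10, seed = 4)
  set.seed(2)
  draws <- ricar(200, g, tau = 2)
  cm <- sapply(unique(g$components), function(cc)
    max(abs(rowMeans(draws[, g$components == cc, drop = FALSE]))))
  expect_lt(max(cm), 1e-10)

  # Var(b_1 - b_n) against the generalized-inverse oracle on a path
  gp <- path_graph(3)
  L <- matrix(c(1, -1, 0, -1, 2, -1, 0, -1, 1), 3, byrow = TRUE)
  Vg <- MASS::ginv(L)  # tau = 1
  target <- Vg[1, 1] + Vg[3, 3] - 2 * Vg[1, 3]
  set.seed(3)
  d <- ricar(100000, gp, tau = 1)
  v13 <- var(d[, 1] - d[, 3])
  se <- target * sqrt(2 / 100000)
  expect_lt(abs(v13 - target), 3 * se + 1e-3)

  # doubling tau halves every pairwise-difference variance
  set.seed(4)
  d1 <- ricar(60000, gp, tau = 1)
  set.seed(4)
  d2 <- ricar(60000, gp, tau = 2)
  expect_equal(var(d1[, 1] - d1[, 2]) / var(d2[, 1] - d2[, 2]), 2,
               tolerance = 0.05)
  expect_error(ricar(1, gp, tau = -1), "positive")
})

test_that("Gibbs sweeps with recentring match direct constrained sampling", {
  # single-site Gibbs from the conditionals, recentred per sweep, must
  # reproduce the pairwise-difference covariances of the spectral sampler
  g <- path_graph(5)
  tau <- 1.5
  set.seed(5)
  n_sweep <- 20000
  v <- rep(0, 5)
  acc <- matrix(NA_real_, n_sweep, 5)
  for (s in seq_len(n_sweep)) {
    for (i in 1:5) {
      cond <- icar_conditional(v, g, tau, i)
      v[i] <- rnorm(1, cond$mean, sqrt(cond$variance))
    }
    v <- v - mean(v)
    acc[s, ] <- v
  }
  keep <- acc[-(1:500), ]
  set.seed(6)
  direct <- ricar(n_sweep, g, tau)
  for (pair in list(c(1, 5), c(2, 4), c(1, 2))) {
    vg <- var(keep[, pair[1]] - keep[, pair[2]])
    vd <- var(direct[, pair[1]] - direct[, pair[2]])
    expect_equal(vg, vd, tolerance = 0.1)
  }
})
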