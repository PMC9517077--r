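# Linear predictor assembly, NB likelihood, joint posterior and VIF.

test_that("linear predictor matches hand computation for all variants", {
  lp <- nbsvc:::linear_predictor
  X <- cbind(`(Intercept)` = 1, x = c(0.5, -1, 2))
  beta <- c(1, 2)
  expect_equal(lp(X, beta, variant = "nonspatial"),
               c(1 + 1, 1 - 2, 1 + 4))
  u <- c(0.1, -0.2, 0.1)
  expect_equal(lp(X, beta, u, "besag"), drop(X %*% beta) + u)
  # svc: eta_i = sum_p (beta_p + b_pi) x_pi, hand-evaluated
  f1 <- c(0.1, 0, -0.1); f2 <- c(-0.3, 0.3, 0)
  eta_hand <- c((1 + 0.1) * 1 + (2 - 0.3) * 0.5,
                (1 + 0) * 1 + (2 + 0.3) * -1,
                (1 - 0.1) * 1 + (2 + 0) * 2)
  expect_equal(lp(X, beta, list(f1, f2), "svc"), eta_hand)
  # all-zero fields reduce svc to the nonspatial predictor
  z <- list(rep(0, 3), rep(0, 3))
  expect_equal(lp(X, beta, z, "svc"), lp(X, beta, variant = "nonspatial"))
  # one unit, intercept only
  expect_equal(exp(lp(matrix(1, 1, 1), 1.5, variant = "nonspatial")),
               exp(1.5))
  expect_error(lp(X, 1, variant = "nonspatial"), "length")
})

test_that("NB log likelihood: closed form, Poisson limit, normalization", {
  # y = 0, mu = 1, k = 1: log(k/(k+mu)) * k = log(1/2)
  expect_equal(nb_loglik(0, 1, 1), log(0.5))
  expect_equal(nb_loglik(1, 1, 1e8), dpois(1, 1, log = TRUE),
               tolerance = 1e-6)
  for (par in list(c(1, 1), c(5, 2))) {
    total <- sum(exp(nb_loglik(0:500, par[1], par[2])))
    expect_equal(total, 1, tolerance = 1e-8)
  }
  expect_error(nb_loglik(-1, 1, 1), "nonnegative")
  expect_error(nb_loglik(1, -1, 1), "positive")
  expect_error(nb_loglik(1, 1, 0), "positive")
})

test_that("joint log posterior equals an independent block summation", {
  set.seed(10)
  g <- random_soi_graph(5, seed = 11)
  X <- cbind(`(Intercept)` = 1, x = rnorm(5))
  y <- c(2, 0, 5, 1, 3)
  pr <- nbsvc_priors()
  center <- function(v) v - mean(v)
  st <- list(beta = c(0.5, -0.2), k = 1.3,
             fields = list(center(rnorm(5)), center(rnorm(5))),
             tau = c(2, 5))
  got <- nbsvc:::joint_logposterior(y, X, g, "svc", st, pr)
  # independent re-summation of the four blocks
  eta <- X %*% st$beta + st$fields[[1]] * X[, 1] + st$fields[[2]] * X[, 2]
  want <- sum(dnbinom(y, size = st$k, mu = exp(eta), log = TRUE)) +
    sum(dnorm(st$beta, 0, 100, log = TRUE)) +
    dgamma(st$k, 0.01, rate = 0.01, log = TRUE) +
    icar_logdensity(st$fields[[1]], g, 2) +
    icar_logdensity(st$fields[[2]], g, 5) +
    (log(pr$lambda / 2) - 1.5 * log(2) - pr$lambda / sqrt(2)) +
    (log(pr$lambda / 2) - 1.5 * log(5) - pr$lambda / sqrt(5))
  expect_equal(got, drop(want))

  # removing a zero field (besag -> nonspatial) changes the value exactly
  # by that field's prior terms
  st0 <- list(beta = st$beta, k = st$k, fields = list(rep(0, 5)), tau = 2)
  lp_besag <- nbsvc:::joint_logposterior(y, X, g, "besag", st0, pr)
  lp_plain <- nbsvc:::joint_logposterior(
    y, X, variant = "nonspatial",
    state = list(beta = st$beta, k = st$k), priors = pr)
  expect_equal(lp_besag - lp_plain,
               icar_logdensity(rep(0, 5), g, 2) +
                 (log(pr$lambda / 2) - 1.5 * log(2) - pr$lambda / sqrt(2)))

  # invariance to a consistent permutation of units
  perm <- c(3, 1, 5, 2, 4)  # new row j holds old unit perm[j]
  nb_perm <- lapply(seq_len(5), function(j)
    sort(match(g$nb[[perm[j]]], perm)))
  gperm <- nbsvc:::new_areal_graph(nb_perm)
  stp <- list(beta = st$beta, k = st$k,
              fields = lapply(st$fields, function(f) f[perm]),
              tau = st$tau)
  got_perm <- nbsvc:::joint_logposterior(y[perm], X[perm, ], gperm, "svc",
                                         stp, pr)
  expect_equal(got_perm, got)
})

test_that("likelihood block is maximized near mu = y", {
  y <- c(3, 7, 1)
  k <- 2
  at_y <- sum(nb_loglik(y, y, k))
  for (s in 1:20) {
    mu <- y * exp(rnorm(3, sd = 0.3))
    expect_lte(sum(nb_loglik(y, mu, k)), at_y + 1e-12)
  }
})

test_that("VIF: orthogonal, duplicated and correlated designs", {
  n <- 400
  # exactly orthogonal pair
  x1 <- rep(c(1, -1), n / 2); x2 <- rep(c(1, 1, -1, -1), n / 4)
  v <- vif(cbind(a = x1, b = x2))
  expect_equal(unname(v), c(1, 1), tolerance = 1e-12)
  # duplicated covariate: infinite VIF, no exception
  v <- vif(cbind(a = x1, b = x1, c = x2))
  expect_true(is.infinite(v[["a"]]) && is.infinite(v[["b"]]))
  # known correlation rho = 0.8 -> VIF = 1/(1 - 0.64)
  set.seed(20)
  z <- rnorm(n)
  a <- z; b <- 0.8 * z + sqrt(1 - 0.64) * rnorm(n)
  rho <- cor(a, b)
  v <- vif(cbind(a, b))
  expect_equal(unname(v), rep(1 / (1 - rho^2), 2), tolerance = 1e-10)
  # intercept column is ignored
  expect_equal(vif(cbind(`(Intercept)` = 1, a = a, b = b)), vif(cbind(a, b)))
})

test_that("VIF agrees with the car package on a realistic design", {
  sim <- sim_areal_data(sim_scenario(n_units = 80, truth = "nonspatial",
                                     seed = 21))
  X <- sim$data[, c("pop", "mhi", "pcthisp", "pctaa", "alc", "tbc", "abdp")]
  ours <- vif(X)
  ref <- car::vif(lm(rnorm(80) ~ ., data = X))
  expect_equal(unname(ours), unname(ref[names(ours)]), tolerance = 1e-8)
})
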