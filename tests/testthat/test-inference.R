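# Posterior sampling, summaries, and varying-coefficient output.

test_that("intercept-only fit recovers a known mean", {
  set.seed(30)
  df <- data.frame(crimes = rnbinom(200, size = 2, mu = 5))
  fit <- nbsvc(crimes ~ 1, df, variant = "nonspatial",
               control = quick_control(4000, 2000, n_chains = 2), seed = 2)
  sm <- summary(fit)$fixed
  expect_lt(abs(sm[1, "Mean"] - log(5)), 3 * sm[1, "sd"])
  expect_true(all(sm[, "0.025 Quant"] <= sm[, "0.5 Quant"]))
  expect_true(all(sm[, "0.5 Quant"] <= sm[, "0.975 Quant"]))
})

test_that("chains are exactly reproducible under a fixed seed", {
  sim <- sim_areal_data(sim_scenario(n_units = 40, seed = 31))
  f <- crimes ~ pop + mhi
  fit1 <- nbsvc(f, sim$data, sim$graph, "svc",
                control = quick_control(800, 400), seed = 9)
  fit2 <- nbsvc(f, sim$data, sim$graph, "svc",
                control = quick_control(800, 400), seed = 9)
  expect_identical(fit1$chains[[1]]$beta, fit2$chains[[1]]$beta)
  expect_identical(fit1$chains[[1]]$fields, fit2$chains[[1]]$fields)
  fit3 <- nbsvc(f, sim$data, sim$graph, "svc",
                control = quick_control(800, 400), seed = 10)
  expect_false(identical(fit1$chains[[1]]$beta, fit3$chains[[1]]$beta))
})

test_that("svc with fields clamped at zero reproduces the nonspatial chain", {
  sim <- sim_areal_data(sim_scenario(n_units = 40, seed = 32))
  f <- crimes ~ pop + mhi
  fit_m1 <- nbsvc(f, sim$data, sim$graph, "nonspatial",
                  control = quick_control(1000, 500), seed = 3)
  fit_m3 <- nbsvc(f, sim$data, sim$graph, "svc",
                  control = quick_control(1000, 500, fix_fields = TRUE),
                  seed = 3)
  expect_identical(fit_m1$chains[[1]]$beta, fit_m3$chains[[1]]$beta)
})

test_that("sampler matches an independent generic MH run on a small fixture", {
  set.seed(33)
  n <- 30
  X <- cbind(`(Intercept)` = 1, x = rnorm(n))
  y <- rnbinom(n, size = 2, mu = exp(1 + 0.5 * X[, "x"]))
  pr <- nbsvc_priors()
  df <- data.frame(crimes = y, x = X[, "x"])
  fit <- nbsvc(crimes ~ x, df, variant = "nonspatial", priors = pr,
               control = quick_control(8000, 2000, n_chains = 2), seed = 4)
  ours <- colMeans(nbsvc:::pooled_beta(fit))
  ours_k <- mean(log(nbsvc:::pooled_k(fit)))
  set.seed(34)
  ref <- generic_mh_nonspatial(y, X, pr, n_iter = 60000,
                               init_beta = c(1, 0.5))
  ref <- ref[-(1:10000), ]
  # agreement within Monte-Carlo error of both samplers
  expect_equal(unname(ours), colMeans(ref[, 1:2]), tolerance = 0.05)
  expect_equal(ours_k, mean(ref[, 3]), tolerance = 0.15)
})

test_that("summaries have the documented schema and hand-checkable values", {
  # draws {1, 2, 3}: mean 2, sd 1, t = 2
  sr <- nbsvc:::summary_row(c(1, 2, 3))
  expect_equal(unname(sr["Mean"]), 2)
  expect_equal(unname(sr["sd"]), 1)
  expect_equal(names(sr),
               c("Mean", "sd", "0.025 Quant", "0.5 Quant", "0.975 Quant"))
  # quantiles cross-checked against an independent type-7 implementation
  set.seed(35)
  z <- rnorm(1000)
  for (p in c(0.025, 0.5, 0.975))
    expect_equal(unname(quantile(z, p, type = 7)), quantile7_oracle(z, p))
})

test_that("varying coefficients report b, t and significance; degenerate sd flagged", {
  sim <- sim_areal_data(sim_scenario(n_units = 40, truth = "svc", seed = 36))
  fit <- nbsvc(crimes ~ pop + mhi, sim$data, sim$graph, "svc",
               control = quick_control(1200, 600), seed = 5)
  vc <- varying_coefficients(fit)
  expect_equal(nrow(vc), 40 * 3)
  expect_setequal(unique(vc$covariate), c("(Intercept)", "pop", "mhi"))
  expect_equal(vc$significant, !is.na(vc$t) & abs(vc$t) >= 2)
  # threshold logic
  expect_equal(abs(vc$t) >= 1 | is.na(vc$t),
               varying_coefficients(fit, t_threshold = 1)$significant |
                 is.na(vc$t))
  # mask shape
  m <- varying_significance_mask(fit)
  expect_equal(dim(m), c(40L, 3L))
  expect_type(m, "logical")
  # non-svc fit errors
  fit1 <- nbsvc(crimes ~ pop, sim$data, sim$graph, "nonspatial",
                control = quick_control(400, 200), seed = 5)
  expect_error(varying_coefficients(fit1), "svc")
  # degenerate constant draws: t is NA, not infinite
  fitc <- fit
  for (f in seq_along(fitc$chains[[1]]$fields)) {
    fitc$chains[[1]]$fields[[f]][] <- 0
  }
  fitc$chains[[1]]$beta[] <- 1
  fitc$chains <- fitc$chains[1]
  vc2 <- varying_coefficients(fitc)
  expect_true(all(is.na(vc2$t)))
  expect_true(!any(vc2$significant))
})

test_that("diagnostics: same-seed chains identical, different seeds converge", {
  sim <- sim_areal_data(sim_scenario(n_units = 60, truth = "nonspatial",
                                     seed = 37))
  fit <- nbsvc(crimes ~ pop + mhi + pctaa, sim$data, sim$graph,
               "nonspatial", control = quick_control(4000, 2000,
                                                     n_chains = 2),
               seed = 11)
  rh <- fit$diagnostics$rhat
  expect_true(all(rh[1:4] < 1.05))
  expect_true(all(fit$diagnostics$ess > 50))
})

test_that("summary errors on empty draw sets", {
  sim <- sim_areal_data(sim_scenario(n_units = 40, seed = 38))
  fit <- nbsvc(crimes ~ pop, sim$data, sim$graph, "nonspatial",
               control = quick_control(400, 200), seed = 5)
  fit$chains <- lapply(fit$chains, function(c) {
    c$beta <- c$beta[0, , drop = FALSE]; c })
  expect_error(summary(fit), "no post-burn-in draws")
})
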