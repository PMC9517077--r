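# Model fitting: the nbsvc() front end and its S3 methods.

#' MCMC settings for `nbsvc`
#'
#' @param n_chains number of chains (each gets its own seed offset and
#'   jittered initial values).
#' @param n_iter iterations per chain, including burn-in.
#' @param n_burnin burn-in iterations discarded per chain; proposal scales
#'   adapt only during burn-in (targets: 0.44 for single-site updates,
#'   0.23 for the joint fixed-effect block).
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param fix_fields if `TRUE`, spatial fields (and their precisions) are
#'   clamped at zero and never updated; an `svc` fit then samples exactly
#'   the nonspatial posterior.  Mainly for degenerate-configuration checks.
#' @param update_dispersion sample the NB dispersion `k`?  If `FALSE`, `k`
#'   stays at its initial value.
#' @return an object of class `nbsvc_control`.
#' @export
nbsvc_control <- function(n_chains = 2L, n_iter = 6000L, n_burnin = 3000L,
                          thin = 3L, fix_fields = FALSE,
                          update_dispersion = TRUE) {
  stopifnot(n_chains >= 1L, n_iter > n_burnin, n_burnin >= 0L, thin >= 1L)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter),
                 n_burnin = as.integer(n_burnin),
                 thin = as.integer(thin),
                 fix_fields = isTRUE(fix_fields),
                 update_dispersion = isTRUE(update_dispersion)),
            class = "nbsvc_control")
}

#' Fit Bayesian negative binomial areal models
#'
#' Fits one of three hierarchical negative binomial regressions for areal
#' count data by adaptive Metropolis-within-Gibbs sampling:
#'
#' * `"nonspatial"`: \eqn{\eta_i = \sum_p \beta_p x_{pi}};
#' * `"besag"`: adds a single ICAR (Besag) structured spatial random
#'   effect, \eqn{\eta_i = \sum_p \beta_p x_{pi} + u_i};
#' * `"svc"`: a spatially varying coefficient model where every
#'   design-matrix column (including the intercept, whose field doubles as
#'   the structured spatial effect) carries its own ICAR modifier,
#'   \eqn{\eta_i = \sum_p (\beta_p + \beta_{pi}) x_{pi}}.
#'
#' Counts are modelled as \eqn{y_i \sim} NegBin(\eqn{\mu_i = e^{\eta_i}},
#' size \eqn{k}).  Fixed effects get Normal(0, `fixed_variance`) priors,
#' every ICAR precision a PC prior calibrated by
#' \eqn{P(\sigma > U) = \alpha}, and the dispersion a wide Gamma prior.
#' ICAR fields are kept sum-to-zero within each graph component by
#' recentring after every sweep.
#'
#' @param formula model formula, e.g. `crimes ~ pop + mhi + pcthisp`.
#'   Covariates are used as provided (no silent standardization).
#' @param data data frame containing the outcome and covariates, one row
#'   per areal unit, in the same order as the graph.
#' @param graph an [soi_graph()] `areal_graph`; required for the spatial
#'   variants, its `n` must match `nrow(data)`.
#' @param variant one of `"nonspatial"`, `"besag"`, `"svc"`.
#' @param priors an [nbsvc_priors()] object.
#' @param control an [nbsvc_control()] object.
#' @param seed integer seed; chain `j` runs under `seed + j - 1`.  Fits are
#'   exactly reproducible given seed and configuration.
#' @return An object of class `nbsvc` with posterior draws, acceptance
#'   rates and split-R-hat / effective-sample-size diagnostics.  Use
#'   [summary.nbsvc()], [coef.nbsvc()], [DIC()], [varying_coefficients()].
#' @examples
#' sim <- sim_areal_data(sim_scenario(n_units = 40, truth = "nonspatial",
#'                                    seed = 1))
#' fit <- nbsvc(crimes ~ pop + mhi, data = sim$data, graph = sim$graph,
#'              variant = "nonspatial",
#'              control = nbsvc_control(n_chains = 1, n_iter = 600,
#'                                      n_burnin = 300, thin = 1),
#'              seed = 1)
#' coef(fit)
#' @export
nbsvc <- function(formula, data, graph = NULL,
                  variant = c("nonspatial", "besag", "svc"),
                  priors = nbsvc_priors(), control = nbsvc_control(),
                  seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(priors, "nbsvc_priors"),
            inherits(control, "nbsvc_control"))
  mf <- model.frame(formula, data)
  y <- model.response(mf)
  if (any(is.na(y)) || any(y < 0) || any(y != floor(y)))
    stop("outcome must be nonnegative integer counts without NA")
  y <- as.numeric(y)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- length(y)
  P <- ncol(X)

  if (variant != "nonspatial" || !is.null(graph)) {
    if (is.null(graph))
      stop("variant '", variant, "' needs a neighbourhood graph")
    stopifnot(inherits(graph, "areal_graph"))
    if (graph$n != n)
      stop("graph has ", graph$n, " units but data has ", n, " rows")
  }

  # field multipliers: besag = a single additive effect (multiplier 1);
  # svc = one field per design-matrix column
  fix <- control$fix_fields
  FX <- switch(variant,
               nonspatial = matrix(0, n, 0L),
               besag = if (fix) matrix(0, n, 0L) else matrix(1, n, 1L),
               svc = if (fix) matrix(0, n, 0L) else X)
  field_names <- switch(variant,
                        nonspatial = character(0),
                        besag = if (fix) character(0) else "spatial",
                        svc = if (fix) character(0) else colnames(X))

  # initial values: crude moment fit
  beta0 <- numeric(P)
  icpt <- match("(Intercept)", colnames(X))
  if (!is.na(icpt)) beta0[icpt] <- log(mean(y) + 0.5)
  tau0 <- (1 / priors$U)^2
  k0 <- 1

  chains <- vector("list", control$n_chains)
  for (ch in seq_len(control$n_chains)) {
    set.seed(as.integer(seed) + ch - 1L)
    b_init <- beta0
    if (ch > 1L) b_init <- b_init + rnorm(P, sd = 0.05)
    chains[[ch]] <- run_chain_cpp(
      y = y, X = X, FX = FX,
      nb = if (is.null(graph)) rep(list(integer(0)), n) else graph$nb,
      comp = if (is.null(graph)) seq_len(n) else graph$components,
      ncomp = if (is.null(graph)) n else graph$n_components,
      pc_lambda = priors$lambda, fixed_var = priors$fixed_variance,
      disp_shape = priors$dispersion_shape,
      disp_rate = priors$dispersion_rate,
      n_iter = control$n_iter, n_burnin = control$n_burnin,
      thin = control$thin,
      beta_init = b_init, k_init = k0, tau_init = tau0,
      update_k = control$update_dispersion)
    colnames(chains[[ch]]$beta) <- colnames(X)
  }

  fit <- structure(
    list(call = match.call(), formula = formula, variant = variant,
         y = y, X = X, graph = graph, priors = priors, control = control,
         seed = as.integer(seed), field_names = field_names,
         chains = chains, n = n, P = P),
    class = "nbsvc")
  fit$diagnostics <- fit_diagnostics(fit)
  fit
}

# ---- draw access helpers ----

# pooled post-burn-in draws of fixed effects (matrix draws x P)
pooled_beta <- function(fit) {
  do.call(rbind, lapply(fit$chains, `[[`, "beta"))
}

pooled_k <- function(fit) {
  unlist(lapply(fit$chains, `[[`, "k"), use.names = FALSE)
}

pooled_tau <- function(fit) {
  nf <- length(fit$field_names)
  if (nf == 0L) return(matrix(numeric(0), 0L, 0L))
  m <- do.call(rbind, lapply(fit$chains, function(c)
    c$tau[, seq_len(nf), drop = FALSE]))
  colnames(m) <- fit$field_names
  m
}

# pooled draws of field f (draws x n)
pooled_field <- function(fit, f) {
  do.call(rbind, lapply(fit$chains, function(c) c$fields[[f]]))
}

# posterior draws of eta (n x draws)
eta_draws <- function(fit) {
  beta <- pooled_beta(fit)
  eta <- fit$X %*% t(beta)
  nf <- length(fit$field_names)
  if (nf > 0L) {
    FXcol <- switch(fit$variant,
                    besag = list(rep(1, fit$n)),
                    svc = lapply(seq_len(fit$P), function(p) fit$X[, p]))
    for (f in seq_len(nf))
      eta <- eta + FXcol[[f]] * t(pooled_field(fit, f))
  }
  eta
}

# ---- convergence diagnostics ----

split_rhat <- function(chain_list) {
  half <- lapply(chain_list, function(v) {
    m <- length(v) %/% 2L
    list(v[seq_len(m)], v[m + seq_len(m)])
  })
  segs <- unlist(half, recursive = FALSE)
  segs <- segs[lengths(segs) >= 2L]
  if (length(segs) < 2L) return(NA_real_)
  m <- length(segs); nn <- length(segs[[1L]])
  means <- vapply(segs, mean, numeric(1L))
  vars <- vapply(segs, var, numeric(1L))
  W <- mean(vars)
  B <- nn * var(means)
  if (W <= 0) return(1)
  sqrt(((nn - 1) / nn * W + B / nn) / W)
}

ess_basic <- function(v) {
  nn <- length(v)
  if (nn < 10L || var(v) == 0) return(nn)
  a <- acf(v, lag.max = min(nn - 1L, 200L), plot = FALSE)$acf[-1L]
  # sum rho until first negative pair (Geyer initial positive sequence)
  s <- 0
  i <- 1L
  while (i < length(a)) {
    pair <- a[i] + a[i + 1L]
    if (pair < 0) break
    s <- s + pair
    i <- i + 2L
  }
  max(1, nn / (1 + 2 * s))
}

fit_diagnostics <- function(fit) {
  P <- fit$P
  scalar_chains <- function(extract) lapply(fit$chains, extract)
  params <- list()
  for (p in seq_len(P))
    params[[colnames(fit$X)[p]]] <- scalar_chains(function(c) c$beta[, p])
  nf <- length(fit$field_names)
  for (f in seq_len(nf))
    params[[paste0("log_tau[", fit$field_names[f], "]")]] <-
      scalar_chains(function(c) log(c$tau[, f]))
  if (fit$control$update_dispersion)
    params[["log_k"]] <- scalar_chains(function(c) log(c$k))
  rhat <- vapply(params, split_rhat, numeric(1L))
  ess <- vapply(params, function(ch)
    sum(vapply(ch, ess_basic, numeric(1L))), numeric(1L))
  accept <- lapply(fit$chains, `[[`, "accept")
  list(rhat = rhat, ess = ess, accept = accept)
}

# ---- methods ----

#' @export
print.nbsvc <- function(x, ...) {
  lab <- c(nonspatial = "non-spatial negative binomial",
           besag = "negative binomial + Besag (ICAR) spatial effect",
           svc = "negative binomial with ICAR spatially varying coefficients")
  cat("nbsvc fit:", lab[[x$variant]], "\n")
  cat("  units:", x$n, " covariates (incl. intercept):", x$P, "\n")
  cat(sprintf("  chains: %d x %d iterations (%d burn-in, thin %d)\n",
              x$control$n_chains, x$control$n_iter, x$control$n_burnin,
              x$control$thin))
  cat("  posterior means of fixed effects:\n")
  print(round(coef(x), 4))
  rh <- x$diagnostics$rhat
  cat(sprintf("  max split-Rhat: %.3f   min ESS: %.0f\n",
              max(rh, na.rm = TRUE), min(x$diagnostics$ess, na.rm = TRUE)))
  invisible(x)
}

#' @export
coef.nbsvc <- function(object, ...) {
  colMeans(pooled_beta(object))
}

#' @export
fitted.nbsvc <- function(object, ...) {
  rowMeans(exp(eta_draws(object)))
}

#' @export
residuals.nbsvc <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  mu <- fitted(object)
  r <- object$y - mu
  if (type == "pearson") {
    k <- mean(pooled_k(object))
    r <- r / sqrt(mu + mu^2 / k)
  }
  r
}

#' @export
predict.nbsvc <- function(object, newdata = NULL,
                          type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- rowMeans(eta_draws(object))
  } else {
    if (object$variant != "nonspatial")
      stop("prediction on new units is only defined for the nonspatial ",
           "variant; spatial fields are tied to the fitted lattice")
    tt <- stats::delete.response(terms(object$formula))
    Xn <- model.matrix(tt, model.frame(tt, newdata))
    eta <- drop(Xn %*% coef(object))
  }
  if (type == "response") exp(eta) else eta
}

#' @export
simulate.nbsvc <- function(object, nsim = 1L, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  eta <- eta_draws(object)
  k <- pooled_k(object)
  idx <- sample.int(ncol(eta), nsim, replace = nsim > ncol(eta))
  out <- vapply(idx, function(d)
    rnbinom(object$n, size = k[d], mu = exp(eta[, d])), numeric(object$n))
  as.data.frame(out, col.names = paste0("sim_", seq_len(nsim)))
}

#' @export
plot.nbsvc <- function(x, which = c("trace", "fit"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    P <- min(x$P, 8L)
    op <- graphics::par(mfrow = c(ceiling(P / 2), 2), mar = c(3, 3, 2, 1))
    on.exit(graphics::par(op))
    for (p in seq_len(P)) {
      draws <- lapply(x$chains, function(c) c$beta[, p])
      graphics::matplot(do.call(cbind, draws), type = "l", lty = 1,
                        main = colnames(x$X)[p], xlab = "", ylab = "")
    }
  } else {
    graphics::plot(fitted(x), x$y, xlab = "posterior mean mu",
                   ylab = "observed count")
    graphics::abline(0, 1, lty = 2)
  }
  invisible(x)
}
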