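# Likelihood and linear-predictor assembly for the three model variants:
#   nonspatial  eta_i = sum_p beta_p x_pi
#   besag       eta_i = sum_p beta_p x_pi + u_i      (one ICAR field u)
#   svc         eta_i = sum_p (beta_p + beta_pi) x_pi (one field per column)
# with y_i ~ NegBin(mu_i = exp(eta_i), size k), Var = mu + mu^2/k.

#' Negative binomial log likelihood
#'
#' Log probability mass of the negative binomial in its mean/size
#' parametrization: mean `mu`, dispersion (size) `size`, variance
#' `mu + mu^2/size`.  `size -> Inf` recovers the Poisson.
#'
#' @param y nonnegative integer count(s).
#' @param mu positive mean(s).
#' @param size positive dispersion parameter `k`.
#' @return log pmf value(s).
#' @export
nb_loglik <- function(y, mu, size) {
  if (any(y < 0) || any(y != floor(y)))
    stop("y must contain nonnegative integers")
  if (any(!is.finite(mu)) || any(mu <= 0)) stop("mu must be positive")
  if (any(!is.finite(size)) || any(size <= 0)) stop("size must be positive")
  dnbinom(y, size = size, mu = mu, log = TRUE)
}

# eta for a given variant; fields is NULL, a single vector (besag) or a
# list of per-column vectors (svc, in design-matrix column order)
linear_predictor <- function(X, beta, fields = NULL,
                             variant = c("nonspatial", "besag", "svc")) {
  variant <- match.arg(variant)
  if (length(beta) != ncol(X)) stop("length(beta) must equal ncol(X)")
  eta <- drop(X %*% beta)
  if (variant == "besag") {
    u <- if (is.list(fields)) fields[[1L]] else fields
    if (length(u) != nrow(X)) stop("besag field length must equal n")
    eta <- eta + u
  } else if (variant == "svc") {
    if (!is.list(fields) || length(fields) != ncol(X))
      stop("svc needs one field per design-matrix column")
    for (p in seq_along(fields)) {
      if (length(fields[[p]]) != nrow(X))
        stop("field ", p, " has wrong length")
      eta <- eta + fields[[p]] * X[, p]
    }
  }
  eta
}

# joint log posterior (up to a constant), summed over the four blocks:
# NB likelihood + fixed-effect priors + ICAR field priors (with their PC
# precision priors) + dispersion prior.  state is a list with elements
# beta, k, and for spatial variants fields (list) and tau (vector).
joint_logposterior <- function(y, X, graph = NULL,
                               variant = c("nonspatial", "besag", "svc"),
                               state, priors = nbsvc_priors()) {
  variant <- match.arg(variant)
  fields <- state$fields
  eta <- linear_predictor(X, state$beta, fields, variant)
  lp <- sum(nb_loglik(y, exp(eta), state$k)) +
    sum(fixed_effect_logpdf(state$beta, priors$fixed_variance)) +
    dgamma(state$k, shape = priors$dispersion_shape,
           rate = priors$dispersion_rate, log = TRUE)
  if (variant != "nonspatial") {
    if (is.null(graph)) stop("spatial variants need a graph")
    flist <- if (is.list(fields)) fields else list(fields)
    for (f in seq_along(flist)) {
      lp <- lp + icar_logdensity(flist[[f]], graph, state$tau[f]) +
        pc_prec_logpdf_lambda(state$tau[f], priors$lambda)
    }
  }
  lp
}

#' Variance inflation factors
#'
#' Standard VIF diagnostic for a covariate set: each covariate is regressed
#' on all the others (with an intercept, outcome excluded) and
#' \eqn{VIF_p = 1/(1 - R^2_p)}.  An exactly collinear covariate yields an
#' infinite VIF rather than an error.
#'
#' @param x a numeric matrix or data frame of covariates.  A constant
#'   intercept column, if present, is dropped before computation.
#' @return named vector of VIFs, one per covariate.
#' @examples
#' X <- cbind(a = rnorm(50), b = rnorm(50))
#' vif(X)  # near 1 for independent covariates
#' @export
vif <- function(x) {
  X <- as.matrix(x)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2L, function(v) var(v) > 0)
  X <- X[, keep, drop = FALSE]
  if (ncol(X) < 2L)
    stop("need at least 2 non-constant covariates for VIF")
  out <- vapply(seq_len(ncol(X)), function(p) {
    fit <- lm(X[, p] ~ X[, -p, drop = FALSE])
    # collinear designs trigger a harmless perfect-fit warning here
    r2 <- suppressWarnings(summary(fit)$r.squared)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1L))
  names(out) <- colnames(X)
  out
}
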