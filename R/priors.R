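# Prior specification: penalized complexity (PC) priors on random-effect
# precisions, a weakly-informative Gaussian prior on fixed effects and a
# wide Gamma prior on the negative binomial dispersion.

#' PC prior rate for a precision
#'
#' The penalized complexity prior for a random-effect precision \eqn{\tau}
#' is calibrated through the standard deviation \eqn{\sigma = \tau^{-1/2}}:
#' \eqn{\sigma} gets an Exponential(\eqn{\lambda}) prior with
#' \eqn{\lambda = -\log(\alpha)/U}, so that \eqn{P(\sigma > U) = \alpha}.
#' `U` is the soft upper bound on the random-effect standard deviation
#' (default 0.3 here, with 0.1 and 0.5 as sensitivity settings).
#'
#' @param U upper-bound standard deviation, `> 0`.
#' @param alpha tail probability `P(sigma > U)`, in `(0, 1)`.
#' @return the rate \eqn{\lambda}.
#' @examples
#' pc_prec_lambda(0.3, 0.01)  # ~15.35
#' @export
pc_prec_lambda <- function(U, alpha) {
  if (!is.numeric(U) || length(U) != 1L || !is.finite(U) || U <= 0)
    stop("U must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly between 0 and 1")
  -log(alpha) / U
}

#' PC prior density for a precision
#'
#' Density of the PC precision prior, a type-2 Gumbel on \eqn{\tau}:
#' \deqn{\pi(\tau) = (\lambda/2)\,\tau^{-3/2}\exp(-\lambda\tau^{-1/2}),}
#' equivalent to \eqn{\sigma = \tau^{-1/2} \sim} Exponential(\eqn{\lambda}).
#'
#' @param tau precision value(s), `> 0`.
#' @inheritParams pc_prec_lambda
#' @param log return the log density? Default `TRUE`.
#' @return (log) density values.
#' @export
dpc_prec <- function(tau, U = 0.3, alpha = 0.01, log = TRUE) {
  lam <- pc_prec_lambda(U, alpha)
  if (any(!is.finite(tau)) || any(tau <= 0))
    stop("tau must be positive and finite")
  ld <- base::log(lam / 2) - 1.5 * base::log(tau) - lam / sqrt(tau)
  if (log) ld else exp(ld)
}

pc_prec_logpdf_lambda <- function(tau, lam) {
  log(lam / 2) - 1.5 * log(tau) - lam / sqrt(tau)
}

# Gaussian fixed-effect log prior, mean 0 (non-informative at the default
# variance 1e4)
fixed_effect_logpdf <- function(beta, variance = 1e4) {
  dnorm(beta, mean = 0, sd = sqrt(variance), log = TRUE)
}

#' Prior settings for `nbsvc` models
#'
#' Bundles the prior configuration: the PC prior on every ICAR precision
#' (through `U` and `alpha`), the zero-mean Gaussian prior variance on
#' fixed effects, and the Gamma prior on the negative binomial dispersion
#' `k`.  The defaults are `U = 0.3` (soft upper bound on the spatial
#' random-effect standard deviation; 0.1 and 0.5 are conventional
#' sensitivity settings), `alpha = 0.01`, fixed-effect variance `1e4`, and
#' a wide Gamma(0.01, 0.01) on the dispersion.
#'
#' @param U PC prior upper-bound standard deviation.
#' @param alpha PC prior tail probability `P(sigma > U)`.
#' @param fixed_variance variance of the Normal(0, .) fixed-effect prior.
#' @param dispersion_shape,dispersion_rate Gamma prior on the NB size `k`.
#' @return an object of class `nbsvc_priors`.
#' @export
nbsvc_priors <- function(U = 0.3, alpha = 0.01, fixed_variance = 1e4,
                         dispersion_shape = 0.01, dispersion_rate = 0.01) {
  lam <- pc_prec_lambda(U, alpha)
  stopifnot(fixed_variance > 0, dispersion_shape > 0, dispersion_rate > 0)
  structure(list(U = U, alpha = alpha, lambda = lam,
                 fixed_variance = fixed_variance,
                 dispersion_shape = dispersion_shape,
                 dispersion_rate = dispersion_rate),
            class = "nbsvc_priors")
}

#' @export
print.nbsvc_priors <- function(x, ...) {
  cat("nbsvc prior settings\n")
  cat(sprintf("  PC precision prior: U = %g, alpha = %g (lambda = %.4f)\n",
              x$U, x$alpha, x$lambda))
  cat(sprintf("  fixed effects: Normal(0, %g)\n", x$fixed_variance))
  cat(sprintf("  NB dispersion: Gamma(%g, %g)\n",
              x$dispersion_shape, x$dispersion_rate))
  invisible(x)
}
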