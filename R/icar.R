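# Intrinsic CAR (Besag) Gaussian Markov random field machinery.
#
# The ICAR prior on a surface beta_1..beta_n over a graph G is specified by
# its full conditionals  beta_i | beta_{-i} ~ N(mean of neighbours,
# 1/(n_i * tau)), which corresponds to the improper joint density
#   log pi(beta | tau) = ((n - c)/2) log tau
#                        - (tau/2) sum_{i~j} (beta_i - beta_j)^2 + const,
# the sum running over unordered neighbour pairs.  The precision matrix is
# Q = tau (D - A) with rank n - c, c the number of connected components;
# the null space is spanned by per-component constants, so the field is
# identified by a sum-to-zero constraint within each component.

#' ICAR precision matrix
#'
#' Returns the intrinsic CAR precision matrix \eqn{Q = \tau (D - A)}, where
#' \eqn{D} is the diagonal matrix of neighbour counts and \eqn{A} the
#' adjacency indicator of the graph.  \eqn{Q} is symmetric with zero row
#' sums and rank \eqn{n - c}, where \eqn{c} is the number of connected
#' components.
#'
#' @param graph an [`soi_graph()`]-style `areal_graph`.
#' @param tau precision hyperparameter, `> 0`.
#' @return A sparse symmetric `Matrix::dgCMatrix` of dimension `n x n`.
#' @export
icar_precision <- function(graph, tau) {
  stopifnot(inherits(graph, "areal_graph"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0)
    stop("tau must be a single positive number")
  n <- graph$n
  e <- graph_edges(graph)
  Q <- Matrix::sparseMatrix(
    i = c(seq_len(n), e[, 1L], e[, 2L]),
    j = c(seq_len(n), e[, 2L], e[, 1L]),
    x = c(as.numeric(graph$degrees), rep(-1, 2L * nrow(e))),
    dims = c(n, n))
  Matrix::drop0(tau * Q)
}

# dense graph Laplacian D - A (tau = 1), used by spectral sampling
graph_laplacian <- function(graph) {
  as.matrix(icar_precision(graph, 1))
}

#' ICAR full conditional of one site
#'
#' The full conditional of site `i` given the rest of an ICAR field is
#' Normal with mean the average of its neighbours' values and variance
#' \eqn{1/(n_i \tau)}.
#'
#' @param values numeric field vector, one value per unit.
#' @param graph the `areal_graph` the field lives on.
#' @param tau precision hyperparameter.
#' @param i unit index.
#' @return list with components `mean` and `variance`.
#' @export
icar_conditional <- function(values, graph, tau, i) {
  stopifnot(inherits(graph, "areal_graph"),
            length(values) == graph$n)
  if (tau <= 0) stop("tau must be positive")
  i <- as.integer(i)
  ni <- graph$degrees[i]
  if (ni < 1L)
    stop("unit ", i, " is isolated; the ICAR conditional is undefined ",
         "(SOI graphs never have isolated units, user-supplied graphs can)")
  list(mean = mean(values[graph$nb[[i]]]), variance = 1 / (ni * tau))
}

#' ICAR log density
#'
#' Log density of an ICAR field on the sum-to-zero-per-component subspace,
#' up to an additive constant that does not depend on `values` or `tau`:
#' \eqn{((n-c)/2)\log\tau - (\tau/2)\sum_{i\sim j}(\beta_i-\beta_j)^2},
#' the sum over unordered neighbour pairs (equal to
#' \eqn{\frac12 \beta' Q \beta} at \eqn{\tau = 1} scaling).  The rank uses
#' the general \eqn{n - c} generalized-determinant form; on a connected
#' graph this is the familiar \eqn{n - 1}.
#'
#' @inheritParams icar_conditional
#' @param check if `TRUE` (default) error when the per-component means
#'   exceed the constraint tolerance `1e-8`.
#' @return scalar log density (constant omitted).
#' @export
icar_logdensity <- function(values, graph, tau, check = TRUE) {
  stopifnot(inherits(graph, "areal_graph"), length(values) == graph$n)
  if (tau <= 0) stop("tau must be positive")
  if (check) {
    cm <- tapply(values, graph$components, mean)
    if (any(abs(cm) > 1e-8))
      stop("sum-to-zero constraint violated: component mean(s) ",
           paste(signif(cm[abs(cm) > 1e-8], 3), collapse = ", "))
  }
  e <- graph_edges(graph)
  S <- sum((values[e[, 1L]] - values[e[, 2L]])^2)
  0.5 * (graph$n - graph$n_components) * log(tau) - 0.5 * tau * S
}

#' Sample ICAR fields
#'
#' Draws from the intrinsic CAR distribution restricted to the
#' sum-to-zero-per-component subspace, by spectral decomposition of the
#' graph Laplacian \eqn{D - A}: coordinates along eigenvectors with
#' eigenvalue \eqn{\lambda_k > 0} are independent
#' \eqn{N(0, 1/(\tau\lambda_k))}; null-space coordinates are fixed at zero,
#' which makes the within-component means exactly zero.
#'
#' @param n number of draws.
#' @param graph an `areal_graph`.
#' @param tau precision hyperparameter, `> 0`.
#' @return an `n x graph$n` matrix of draws (one row per draw).
#' @export
ricar <- function(n, graph, tau) {
  stopifnot(inherits(graph, "areal_graph"))
  if (tau <= 0) stop("tau must be positive")
  L <- graph_laplacian(graph)
  es <- eigen(L, symmetric = TRUE)
  tol <- max(es$values) * 1e-10
  pos <- which(es$values > tol)
  Z <- matrix(rnorm(n * length(pos)), nrow = n)
  Z <- sweep(Z, 2L, sqrt(tau * es$values[pos]), "/")
  Z %*% t(es$vectors[, pos, drop = FALSE])
}

# diag of the generalized inverse of D - A: marginal variances of the
# constrained ICAR at tau = 1.  Used to calibrate simulated fields.
icar_marginal_var <- function(graph) {
  L <- graph_laplacian(graph)
  es <- eigen(L, symmetric = TRUE)
  tol <- max(es$values) * 1e-10
  pos <- es$values > tol
  V <- es$vectors[, pos, drop = FALSE]
  rowSums(sweep(V^2, 2L, es$values[pos], "/"))
}
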