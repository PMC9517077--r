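# Independent oracles and small fixture builders shared across tests.

# brute-force O(n^2) SOI adjacency: edge iff d(i,j) <= r_i + r_j
soi_oracle_adjacency <- function(xy) {
  n <- nrow(xy)
  d <- matrix(0, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      d[i, j] <- sqrt(sum((xy[i, ] - xy[j, ])^2))
  r <- numeric(n)
  for (i in seq_len(n)) r[i] <- min(d[i, -i])
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j && d[i, j] <= r[i] + r[j] + 1e-9) adj[i, j] <- TRUE
  adj
}

graph_adjacency <- function(g) {
  adj <- matrix(FALSE, g$n, g$n)
  for (i in seq_len(g$n)) adj[i, g$nb[[i]]] <- TRUE
  adj
}

# build an areal_graph from an explicit edge list (for hand fixtures)
graph_from_edges <- function(n, edges) {
  nb <- rep(list(integer(0)), n)
  for (e in edges) {
    nb[[e[1]]] <- c(nb[[e[1]]], e[2])
    nb[[e[2]]] <- c(nb[[e[2]]], e[1])
  }
  nbsvc:::new_areal_graph(nb)
}

path_graph <- function(n) {
  graph_from_edges(n, lapply(seq_len(n - 1), function(i) c(i, i + 1)))
}

random_soi_graph <- function(n, seed) {
  set.seed(seed)
  soi_graph(data.frame(unit_id = seq_len(n),
                       x = runif(n), y = runif(n)))
}

# type-7 quantile, written independently of stats::quantile
quantile7_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# generic random-walk Metropolis over the joint log posterior, used as an
# independent sampler to cross-check run_chain_cpp on tiny fixtures
generic_mh_nonspatial <- function(y, X, priors, n_iter, scale = 0.15,
                                  init_beta = NULL) {
  P <- ncol(X)
  beta <- if (is.null(init_beta)) rep(0, P) else init_beta
  logk <- 0
  lp <- nbsvc:::joint_logposterior(
    y, X, variant = "nonspatial",
    state = list(beta = beta, k = exp(logk)), priors = priors)
  draws <- matrix(NA_real_, n_iter, P + 1)
  for (it in seq_len(n_iter)) {
    prop_beta <- beta + rnorm(P, sd = scale)
    prop_logk <- logk + rnorm(1, sd = scale)
    lp_prop <- nbsvc:::joint_logposterior(
      y, X, variant = "nonspatial",
      state = list(beta = prop_beta, k = exp(prop_logk)), priors = priors)
    # log-scale Jacobian for k
    if (log(runif(1)) < lp_prop - lp + (prop_logk - logk)) {
      beta <- prop_beta; logk <- prop_logk; lp <- lp_prop
    }
    draws[it, ] <- c(beta, logk)
  }
  draws
}

default_formula <- crimes ~ pop + mhi + pcthisp + pctaa + alc + tbc + abdp

quick_control <- function(n_iter = 2000, n_burnin = 1000, n_chains = 1,
                          thin = 1, ...) {
  nbsvc_control(n_chains = n_chains, n_iter = n_iter, n_burnin = n_burnin,
                thin = thin, ...)
}
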