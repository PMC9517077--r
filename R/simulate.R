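# Synthetic areal data generator.  Emulates the structure of a
# census-block-group crime study: ~105 areal units, seven covariates
# (total population, median household income, % Hispanic, % African
# American, alcohol outlets, tobacco outlets, abandoned properties) built
# as spatially smooth fields, ICAR-distributed coefficient surfaces, and
# overdispersed negative binomial counts.  The generating truth is
# retained so fits can be checked for parameter recovery.

default_fixed_effects <- function() {
  c(`(Intercept)` = 0.6, pop = 0.22, mhi = -0.021, pcthisp = 1.6,
    pctaa = 2.0, alc = 0.05, tbc = 0.1, abdp = 0.005)
}

#' Simulation scenario
#'
#' Describes one synthetic study.  Defaults emulate a mid-sized city
#' analysed at the census-block-group level: 105 units on a jittered grid,
#' seven covariates, fixed effects whose signs and magnitudes are patterned
#' on published block-group crime regressions (population and income in
#' thousands, percentages in `[0, 1]`, outlet/abandoned-property counts as
#' small integers), negative binomial dispersion 2, and per-covariate
#' spatial coefficient modifiers whose contribution to the linear predictor
#' has standard deviation `field_sd` (default 0.3, the same soft bound the
#' PC prior encodes; each field's own sd is `field_sd / sd(x_p)` so the
#' modifier effects are comparable across covariate scales).
#'
#' @param n_units number of areal units (default 105).
#' @param layout `"grid"` (jittered grid, default) or `"uniform"` points.
#' @param truth generating variant: `"svc"`, `"besag"` or `"nonspatial"`.
#' @param fixed_effects named vector of generating fixed effects;  names
#'   must be `"(Intercept)"` plus covariate names.
#' @param field_sd sd of each spatial modifier's contribution to the
#'   linear predictor (ignored for `"nonspatial"`).
#' @param dispersion NB size parameter `k` of the generated counts.
#' @param jitter grid jitter amplitude as a fraction of the grid spacing,
#'   `< 0.5` so the SOI graph stays connected with high probability.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_units = 105L, layout = c("grid", "uniform"),
                         truth = c("svc", "besag", "nonspatial"),
                         fixed_effects = default_fixed_effects(),
                         field_sd = 0.3, dispersion = 2,
                         jitter = 0.3, seed = 1L) {
  layout <- match.arg(layout)
  truth <- match.arg(truth)
  stopifnot(n_units >= 2L, field_sd >= 0, dispersion > 0,
            jitter >= 0, jitter < 0.5)
  if (is.null(names(fixed_effects)) ||
      !"(Intercept)" %in% names(fixed_effects))
    stop("fixed_effects must be named and include \"(Intercept)\"")
  structure(list(n_units = as.integer(n_units), layout = layout,
                 truth = truth, fixed_effects = fixed_effects,
                 field_sd = field_sd, dispersion = dispersion,
                 jitter = jitter, seed = as.integer(seed)),
            class = "sim_scenario")
}

#' Simulate unit centroids
#'
#' Generates a reproducible planar point set: either the first `n` cells of
#' a \eqn{\lceil\sqrt n\rceil} grid with uniform jitter (default), or
#' uniform random points on a square.
#'
#' @param n number of points, `>= 2`.
#' @param layout `"grid"` or `"uniform"`.
#' @param jitter jitter amplitude as a fraction of the unit grid spacing.
#' @param seed optional seed (`set.seed` is called when non-NULL).
#' @return data frame with columns `unit_id`, `x`, `y`.
#' @export
sim_map <- function(n, layout = c("grid", "uniform"), jitter = 0.3,
                    seed = NULL) {
  layout <- match.arg(layout)
  if (n < 2L) stop("need n >= 2 units")
  if (!is.null(seed)) set.seed(seed)
  if (layout == "grid") {
    s <- ceiling(sqrt(n))
    gx <- (seq_len(n) - 1L) %% s
    gy <- (seq_len(n) - 1L) %/% s
    x <- gx + runif(n, -jitter, jitter)
    y <- gy + runif(n, -jitter, jitter)
  } else {
    side <- sqrt(n)
    x <- runif(n, 0, side)
    y <- runif(n, 0, side)
  }
  data.frame(unit_id = paste0("bg", seq_len(n)), x = x, y = y,
             stringsAsFactors = FALSE)
}

# one ICAR draw normalized to unit average marginal sd
smooth_field <- function(graph, norm_sd) {
  drop(ricar(1L, graph, tau = 1)) / norm_sd
}

#' Simulate covariates
#'
#' Builds the seven-covariate design emulated by the package: spatially
#' smooth ICAR base fields mapped through monotone transforms to plausible
#' ranges.  `pop` (total population) and `mhi` (median household income)
#' are in thousands; `pcthisp` and `pctaa` are proportions in `[0, 1]`
#' and share a latent field with `pop` so that local collinearity between
#' ethnicity shares and population is present; `alc`, `tbc` and `abdp`
#' (alcohol outlets, tobacco outlets, abandoned properties) are small
#' nonnegative Poisson counts with spatially smooth rates.
#'
#' @param graph the `areal_graph` of the units (fixes the smoothness
#'   structure).
#' @return data frame of covariates, `graph$n` rows.
#' @export
sim_covariates <- function(graph) {
  ns <- sqrt(mean(icar_marginal_var(graph)))
  z <- replicate(7L, smooth_field(graph, ns))
  n <- graph$n
  data.frame(
    pop = 1.4 * exp(0.35 * z[, 1L]),
    mhi = 35 * exp(0.25 * z[, 2L]),
    pcthisp = stats::plogis(0.4 + 1.1 * (0.6 * z[, 1L] + 0.8 * z[, 3L])),
    pctaa = stats::plogis(-1.0 + 1.1 * (0.4 * z[, 1L] + 0.9 * z[, 4L])),
    alc = rpois(n, exp(0.5 + 0.7 * z[, 5L])),
    tbc = rpois(n, exp(1.1 + 0.6 * z[, 6L])),
    abdp = rpois(n, exp(2.3 + 0.7 * z[, 7L])))
}

#' Simulate a full areal dataset
#'
#' Runs the whole generative pipeline of a scenario: centroid map, SOI
#' graph, smooth covariates, ICAR coefficient-modifier fields per the truth
#' variant (none for `"nonspatial"`, a single additive field for
#' `"besag"`, one per design column for `"svc"`), linear predictor
#' \eqn{\eta_i = \sum_p (\beta_p + \beta_{pi}) x_{pi}} and negative
#' binomial counts.  The generating truth (fixed effects, fields,
#' dispersion) is retained for recovery checks.  Errors if any
#' \eqn{\eta_i > 30} (an overflow guard; use smaller effect sizes).
#'
#' @param scenario a [sim_scenario()].
#' @param fields optional named list overriding the generated modifier
#'   fields (names: `"(Intercept)"` or covariate names; values: length-n
#'   vectors).  Covariates without an entry keep a zero field.  Only used
#'   for `truth = "svc"`.
#' @return an object of class `nbsvc_sim`: list with `data` (data frame:
#'   `unit_id`, `x`, `y`, `crimes`, covariates), `graph`, `truth` and
#'   `scenario`.
#' @export
sim_areal_data <- function(scenario = sim_scenario(), fields = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  set.seed(scenario$seed)
  map <- sim_map(scenario$n_units, scenario$layout, scenario$jitter)
  graph <- soi_graph(map)
  covs <- sim_covariates(graph)

  beta <- scenario$fixed_effects
  covnames <- setdiff(names(beta), "(Intercept)")
  miss <- setdiff(covnames, names(covs))
  if (length(miss) > 0L)
    stop("fixed_effects name(s) not among generated covariates: ",
         paste(miss, collapse = ", "))
  X <- cbind(`(Intercept)` = 1,
             as.matrix(covs[, covnames, drop = FALSE]))
  n <- graph$n
  ns <- sqrt(mean(icar_marginal_var(graph)))

  field_list <- NULL
  if (scenario$truth == "besag") {
    field_list <- list(scenario$field_sd * smooth_field(graph, ns))
  } else if (scenario$truth == "svc") {
    field_list <- lapply(seq_len(ncol(X)), function(p) {
      sdx <- sd(X[, p])
      scale_p <- scenario$field_sd / ifelse(sdx > 0, sdx, 1)
      scale_p * smooth_field(graph, ns)
    })
    names(field_list) <- colnames(X)
    if (!is.null(fields)) {
      bad <- setdiff(names(fields), colnames(X))
      if (length(bad) > 0L)
        stop("unknown field override name(s): ", paste(bad, collapse = ", "))
      # overridden fields replace the drawn ones; the rest are zeroed so
      # the injected signal is the only varying structure
      field_list <- lapply(colnames(X), function(nm) {
        if (nm %in% names(fields)) as.numeric(fields[[nm]]) else
          numeric(n)
      })
      names(field_list) <- colnames(X)
    }
  }

  eta <- linear_predictor(X, beta[colnames(X)], field_list,
                          variant = scenario$truth)
  if (any(eta > 30))
    stop("linear predictor exceeds 30 (mu overflow); ",
         "use smaller effect sizes or field_sd")
  y <- rnbinom(n, size = scenario$dispersion, mu = exp(eta))

  data <- cbind(map, crimes = y, covs)
  structure(list(data = data, graph = graph,
                 truth = list(variant = scenario$truth,
                              beta = beta[colnames(X)],
                              fields = field_list,
                              eta = eta,
                              dispersion = scenario$dispersion),
                 scenario = scenario),
            class = "nbsvc_sim")
}

#' @export
print.nbsvc_sim <- function(x, ...) {
  cat("Synthetic areal dataset (truth: ", x$truth$variant, ")\n", sep = "")
  cat("  units:", nrow(x$data), " covariates:",
      ncol(x$data) - 4L, "\n")
  cat("  count summary: ")
  print(summary(x$data$crimes))
  invisible(x)
}

# formula covering all generated covariates, used by tests and examples
sim_formula <- function(sim) {
  covs <- setdiff(names(sim$data), c("unit_id", "x", "y", "crimes"))
  as.formula(paste("crimes ~", paste(covs, collapse = " + ")))
}
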