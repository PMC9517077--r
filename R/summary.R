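# Posterior summaries: fixed-effect tables (mean, sd, 0.025/0.5/0.975
# quantiles), per-unit varying coefficients b_pi with pseudo-t values, and
# the seven-number distributional summary per covariate.

summary_row <- function(draws) {
  qs <- quantile(draws, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  c(Mean = mean(draws), sd = sd(draws),
    `0.025 Quant` = qs[1L], `0.5 Quant` = qs[2L], `0.975 Quant` = qs[3L])
}

#' Summarize an `nbsvc` fit
#'
#' Produces the posterior summary tables: for every fixed effect and
#' hyperparameter, the posterior mean, sd and 0.025/0.5/0.975 quantiles
#' (type-7 empirical quantiles of the pooled post-burn-in draws).  For the
#' `svc` variant it additionally computes, per unit and covariate, the
#' total coefficient \eqn{b_{pi}} (posterior mean of
#' \eqn{\beta_p + \beta_{pi}}) and the pseudo-t value \eqn{t_{pi}}
#' (posterior mean divided by posterior sd of the same total), plus a
#' distributional summary of each across units (N, Mean, Std. Dev., Min,
#' 25th/75th percentile, Max).  A degenerate (constant) draw set yields
#' `t = NA` rather than an infinite value.
#'
#' @param object an `nbsvc` fit.
#' @param t_threshold |t| cutoff used to flag significant spatial
#'   variation; default 2.
#' @param ... unused.
#' @return an object of class `summary.nbsvc`.
#' @export
summary.nbsvc <- function(object, t_threshold = 2, ...) {
  beta <- pooled_beta(object)
  if (nrow(beta) == 0L) stop("no post-burn-in draws to summarize")
  fixed <- t(apply(beta, 2L, summary_row))

  hyper <- NULL
  tau <- pooled_tau(object)
  if (ncol(tau) > 0L) {
    sd_rows <- t(apply(1 / sqrt(tau), 2L, summary_row))
    rownames(sd_rows) <- paste0("sd(", colnames(tau), ")")
    hyper <- sd_rows
  }
  if (object$control$update_dispersion) {
    krow <- matrix(summary_row(pooled_k(object)), nrow = 1L,
                   dimnames = list("dispersion k", colnames(fixed)))
    hyper <- rbind(hyper, krow)
  }

  vc <- NULL
  vc_summary <- NULL
  if (object$variant == "svc" && length(object$field_names) > 0L) {
    vc <- varying_coefficients(object, t_threshold = t_threshold)
    vc_summary <- varying_summary_table(vc)
  }

  structure(list(variant = object$variant, fixed = fixed, hyper = hyper,
                 varying = vc, varying_summary = vc_summary,
                 t_threshold = t_threshold,
                 diagnostics = object$diagnostics),
            class = "summary.nbsvc")
}

#' @export
print.summary.nbsvc <- function(x, digits = 3, ...) {
  cat("Fixed effects (posterior):\n")
  print(round(x$fixed, digits))
  if (!is.null(x$hyper)) {
    cat("\nHyperparameters:\n")
    print(round(x$hyper, digits))
  }
  if (!is.null(x$varying_summary)) {
    cat("\nSpatially varying coefficients across units",
        "(b = total coefficient, t = pseudo-t):\n")
    print(round_df(x$varying_summary, digits))
    nsig <- sum(x$varying$significant)
    cat(sprintf("\nunits with |t| >= %g: %d of %d unit-covariate pairs\n",
                x$t_threshold, nsig, nrow(x$varying)))
  }
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}

#' Per-unit varying coefficients and t-values
#'
#' For an `svc` fit, returns one row per unit and covariate with the
#' posterior mean `b` of the total coefficient
#' \eqn{\beta_p + \beta_{pi}}, its posterior sd, the pseudo-t value
#' `t = b / sd`, and a significance flag `|t| >= t_threshold`.  The output
#' is keyed by `unit_id` so it can be joined to polygons in a GIS for
#' choropleth mapping.
#'
#' @param fit an `nbsvc` fit with `variant = "svc"`.
#' @param t_threshold significance cutoff on |t|; default 2.
#' @return a data frame with columns `unit_id`, `covariate`, `b`, `sd`,
#'   `t`, `significant`.
#' @export
varying_coefficients <- function(fit, t_threshold = 2) {
  stopifnot(inherits(fit, "nbsvc"))
  if (fit$variant != "svc" || length(fit$field_names) == 0L)
    stop("varying coefficients are only defined for an svc fit ",
         "(with fields not clamped)")
  beta <- pooled_beta(fit)
  ids <- if (!is.null(fit$graph)) fit$graph$ids else
    as.character(seq_len(fit$n))
  out <- vector("list", fit$P)
  for (p in seq_len(fit$P)) {
    total <- beta[, p] + pooled_field(fit, p)  # draws x n
    b <- colMeans(total)
    s <- apply(total, 2L, sd)
    t <- ifelse(s > 0, b / s, NA_real_)
    out[[p]] <- data.frame(unit_id = ids,
                           covariate = colnames(fit$X)[p],
                           b = b, sd = s, t = t,
                           significant = !is.na(t) & abs(t) >= t_threshold,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# seven-number summary of b and t across units, one row per covariate
# and quantity (the Table-style layout: N, Mean, Std. Dev., Min,
# Pctl. 25, Pctl. 75, Max)
varying_summary_table <- function(vc) {
  pieces <- lapply(split(vc, vc$covariate), function(d) {
    sev <- function(v) {
      qs <- quantile(v, c(0.25, 0.75), names = FALSE, type = 7,
                     na.rm = TRUE)
      data.frame(N = sum(!is.na(v)), Mean = mean(v, na.rm = TRUE),
                 `Std. Dev.` = sd(v, na.rm = TRUE),
                 Min = min(v, na.rm = TRUE), `Pctl. 25` = qs[1L],
                 `Pctl. 75` = qs[2L], Max = max(v, na.rm = TRUE),
                 check.names = FALSE)
    }
    rbind(cbind(Variable = paste0(d$covariate[1L], ".b"), sev(d$b)),
          cbind(Variable = paste0(d$covariate[1L], ".t"), sev(d$t)))
  })
  res <- do.call(rbind, pieces)
  rownames(res) <- NULL
  res
}

#' Significance mask for spatially varying patterns
#'
#' Boolean per-unit, per-covariate indicator of `|t| >= threshold`,
#' suitable for mapping which units show a significant spatially varying
#' association.
#'
#' @inheritParams varying_coefficients
#' @param threshold |t| cutoff, default 2.
#' @return a logical matrix, units x covariates.
#' @export
varying_significance_mask <- function(fit, threshold = 2) {
  vc <- varying_coefficients(fit, t_threshold = threshold)
  covs <- unique(vc$covariate)
  m <- sapply(covs, function(cv) {
    t <- vc$t[vc$covariate == cv]
    !is.na(t) & abs(t) >= threshold
  })
  rownames(m) <- vc$unit_id[vc$covariate == covs[1L]]
  m
}
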