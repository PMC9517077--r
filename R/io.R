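# File input/output: areal CSV tables, GeoJSON centroids and result
# writers.  Outputs are plain CSV keyed by unit_id so a GIS can join and
# map them; no map rendering happens here.

#' Read an areal dataset from CSV
#'
#' Reads and validates a one-row-per-unit table.  Required columns:
#' `unit_id`, `x`, `y`, the outcome, and (if named) the covariates.  Unit
#' order follows file order.  Missing cells, non-integer or negative
#' outcomes, and non-finite coordinates produce errors naming the row and
#' column.
#'
#' @param path CSV file with a header row.
#' @param outcome name of the count outcome column (default `"crimes"`).
#' @param covariates character vector of covariate column names; default
#'   all columns other than `unit_id`, `x`, `y` and the outcome.
#' @return a validated data frame (attributes `outcome` and `covariates`
#'   record the roles).
#' @export
read_areal_csv <- function(path, outcome = "crimes", covariates = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  req <- c("unit_id", "x", "y", outcome)
  miss <- setdiff(req, names(df))
  if (length(miss) > 0L)
    stop("missing column(s) in ", path, ": ", paste(miss, collapse = ", "))
  if (is.null(covariates))
    covariates <- setdiff(names(df), req)
  miss <- setdiff(covariates, names(df))
  if (length(miss) > 0L)
    stop("missing covariate column(s): ", paste(miss, collapse = ", "))
  for (cl in c("x", "y", outcome, covariates)) {
    v <- df[[cl]]
    if (!is.numeric(v))
      stop("column ", cl, " is not numeric")
    bad <- which(!is.finite(v))
    if (length(bad) > 0L)
      stop("missing or non-finite value at row ", bad[1L],
           ", column ", cl)
  }
  yv <- df[[outcome]]
  bad <- which(yv < 0 | yv != floor(yv))
  if (length(bad) > 0L)
    stop("non-integer or negative outcome at row ", bad[1L],
         ", column ", outcome)
  if (anyDuplicated(df$unit_id))
    stop("duplicate unit_id values in ", path)
  attr(df, "outcome") <- outcome
  attr(df, "covariates") <- covariates
  df
}

#' Read polygon centroids from GeoJSON
#'
#' Parses a GeoJSON `FeatureCollection` of `Polygon`/`MultiPolygon`
#' features and returns one representative interior point per feature (the
#' area-weighted centroid of the outer ring, by the shoelace formula).
#' Intended for deriving unit centroids when only polygons are available;
#' coordinates are treated as planar, so project lon/lat upstream.
#'
#' @param path GeoJSON file.
#' @param id_property name of the feature property holding the unit id;
#'   when absent, features are numbered in file order.
#' @return data frame with columns `unit_id`, `x`, `y`.
#' @export
read_geojson_centroids <- function(path, id_property = "unit_id") {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features))
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(seq_along(gj$features), function(i) {
    ft <- gj$features[[i]]
    geom <- ft$geometry
    ring <- switch(geom$type,
                   Polygon = geom$coordinates[[1L]],
                   MultiPolygon = geom$coordinates[[1L]][[1L]],
                   stop("feature ", i, ": unsupported geometry type ",
                        geom$type))
    m <- do.call(rbind, lapply(ring, function(p)
      c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))))
    ct <- polygon_centroid(m)
    id <- ft$properties[[id_property]]
    data.frame(unit_id = if (is.null(id)) as.character(i) else
      as.character(id), x = ct[1L], y = ct[2L],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# area-weighted centroid of a closed ring (shoelace); falls back to the
# vertex mean for degenerate (zero-area) rings
polygon_centroid <- function(m) {
  x <- m[, 1L]; y <- m[, 2L]
  n <- length(x)
  if (x[1L] != x[n] || y[1L] != y[n]) { x <- c(x, x[1L]); y <- c(y, y[1L]) }
  i <- seq_len(length(x) - 1L)
  cr <- x[i] * y[i + 1L] - x[i + 1L] * y[i]
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(c(mean(m[, 1L]), mean(m[, 2L])))
  c(sum((x[i] + x[i + 1L]) * cr) / (6 * a),
    sum((y[i] + y[i + 1L]) * cr) / (6 * a))
}

#' Write fit results to a directory
#'
#' Writes GIS-joinable result files for a fit:
#' `fixed_effects.csv` (Mean, sd, 0.025/0.5/0.975 quantiles per fixed
#' effect), for `svc` fits `varying_coefficients.csv` (`unit_id`,
#' `covariate`, `b`, `t`, `significant`) and `varying_summary.csv` (the
#' seven-number per-covariate summary), `dic.json` (Dbar, pD, DIC) and
#' `run_log.txt` (configuration echo, seed, diagnostics).  Re-running the
#' same fit under the same seed reproduces the files byte for byte.
#'
#' @param fit an `nbsvc` fit.
#' @param dir output directory (created if missing).
#' @param dic optional precomputed [DIC()] report; computed when `NULL`.
#' @return invisibly, the vector of files written.
#' @export
write_results <- function(fit, dir, dic = NULL) {
  stopifnot(inherits(fit, "nbsvc"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (is.null(dic)) dic <- DIC(fit)
  sm <- summary(fit)
  files <- character(0)

  f <- file.path(dir, "fixed_effects.csv")
  fx <- data.frame(Variable = rownames(sm$fixed), sm$fixed,
                   check.names = FALSE)
  write.csv(fx, f, row.names = FALSE)
  files <- c(files, f)

  if (!is.null(sm$varying)) {
    f <- file.path(dir, "varying_coefficients.csv")
    write.csv(sm$varying[, c("unit_id", "covariate", "b", "t",
                             "significant")], f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(dir, "varying_summary.csv")
    write.csv(sm$varying_summary, f, row.names = FALSE)
    files <- c(files, f)
  }

  f <- file.path(dir, "dic.json")
  jsonlite::write_json(list(Dbar = dic$Dbar, pD = dic$pD, DIC = dic$DIC),
                       f, auto_unbox = TRUE, digits = NA)
  files <- c(files, f)

  f <- file.path(dir, "run_log.txt")
  lines <- c(
    paste("variant:", fit$variant),
    paste("n_units:", fit$n),
    paste("covariates:", paste(colnames(fit$X), collapse = ", ")),
    sprintf("chains: %d x %d (burnin %d, thin %d)",
            fit$control$n_chains, fit$control$n_iter,
            fit$control$n_burnin, fit$control$thin),
    paste("seed:", fit$seed),
    sprintf("priors: PC(U = %g, alpha = %g), fixed var %g",
            fit$priors$U, fit$priors$alpha, fit$priors$fixed_variance),
    sprintf("max split-Rhat: %.4f",
            max(fit$diagnostics$rhat, na.rm = TRUE)),
    sprintf("min ESS: %.1f", min(fit$diagnostics$ess, na.rm = TRUE)),
    sprintf("saturated DIC: %.4f (pD %.4f)", dic$DIC, dic$pD))
  writeLines(lines, f)
  files <- c(files, f)
  invisible(files)
}
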