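# Sphere-of-influence neighbourhood graphs over areal-unit centroids.
# The labelled graph G = (V, E) built here drives every Gaussian Markov
# random field in the package: the adjacency fixes the sparsity pattern of
# the ICAR precision matrix and the degrees n_i enter its conditionals.

new_areal_graph <- function(nb, ids = NULL) {
  n <- length(nb)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  nb <- lapply(nb, function(v) sort(unique(as.integer(v))))
  comp <- graph_components_internal(nb)
  structure(
    list(n = n, ids = as.character(ids), nb = nb,
         degrees = lengths(nb),
         components = comp$membership,
         n_components = comp$no),
    class = "areal_graph")
}

graph_components_internal <- function(nb) {
  g <- igraph::graph_from_adj_list(nb, mode = "all")
  comp <- igraph::components(g)
  list(membership = as.integer(comp$membership), no = comp$no)
}

#' Sphere-of-influence neighbourhood graph
#'
#' Builds the sphere-of-influence (SOI) neighbourhood graph over a set of
#' areal-unit centroids.  Let \eqn{r_i} be the distance from unit \eqn{i} to
#' its nearest other unit and \eqn{C_i} the circle of radius \eqn{r_i}
#' centred on \eqn{i}.  Units \eqn{i} and \eqn{j} are SOI neighbours when
#' \eqn{C_i} and \eqn{C_j} intersect, i.e. when
#' \eqn{d(i,j) \le r_i + r_j}; tangency counts as intersection (decided with
#' an absolute tolerance of `1e-9` on floating-point distances).  Every unit
#' is an SOI neighbour of its nearest neighbour, so the graph has no
#' isolated nodes.
#'
#' Coordinates must be planar (projected); geographic lon/lat should be
#' projected upstream, since distances are Euclidean.
#'
#' @param points a `data.frame` with columns `unit_id`, `x`, `y` (extra
#'   columns are ignored), or a two-column numeric matrix of coordinates.
#' @return An object of class `areal_graph`: a list with elements `n`,
#'   `ids`, `nb` (neighbour index list), `degrees`, `components`
#'   (per-unit connected-component label) and `n_components`.
#' @examples
#' pts <- data.frame(unit_id = 1:3, x = c(0, 1, 3), y = 0)
#' g <- soi_graph(pts)
#' g$nb   # complete graph on three collinear points
#' @export
soi_graph <- function(points) {
  p <- as_unit_points(points)
  n <- nrow(p)
  if (n < 2L)
    stop("need at least 2 points to build an SOI graph, got ", n)
  d <- as.matrix(stats::dist(p[, c("x", "y")]))
  dup <- which(d == 0 & upper.tri(d), arr.ind = TRUE)
  if (nrow(dup) > 0L) {
    bad <- paste0("(", p$unit_id[dup[, 1]], ", ", p$unit_id[dup[, 2]], ")",
                  collapse = ", ")
    stop("coincident coordinates for unit pairs ", bad,
         "; the SOI rule is degenerate at distance 0")
  }
  diag(d) <- Inf
  r <- apply(d, 1L, min)
  tol <- 1e-9
  adj <- d <= outer(r, r, "+") + tol
  nb <- lapply(seq_len(n), function(i) which(adj[i, ]))
  new_areal_graph(nb, ids = p$unit_id)
}

as_unit_points <- function(points) {
  if (is.matrix(points)) {
    if (ncol(points) < 2L) stop("coordinate matrix needs two columns")
    ids <- rownames(points)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))
    points <- data.frame(unit_id = ids,
                         x = points[, 1L], y = points[, 2L])
  }
  req <- c("unit_id", "x", "y")
  miss <- setdiff(req, names(points))
  if (length(miss) > 0L)
    stop("points input lacks column(s): ", paste(miss, collapse = ", "))
  p <- data.frame(unit_id = as.character(points$unit_id),
                  x = as.numeric(points$x), y = as.numeric(points$y),
                  stringsAsFactors = FALSE)
  if (anyDuplicated(p$unit_id))
    stop("duplicate unit_id values: ",
         paste(unique(p$unit_id[duplicated(p$unit_id)]), collapse = ", "))
  if (!all(is.finite(p$x)) || !all(is.finite(p$y)))
    stop("non-finite coordinates in points input")
  p
}

#' @export
print.areal_graph <- function(x, ...) {
  cat("Areal neighbourhood graph\n")
  cat("  units:", x$n, "\n")
  cat("  edges:", sum(x$degrees) / 2L, "\n")
  cat("  degree range: [", min(x$degrees), ", ", max(x$degrees), "]\n",
      sep = "")
  cat("  connected components:", x$n_components, "\n")
  invisible(x)
}

# unordered edge list (i < j), used by the ICAR quadratic form
graph_edges <- function(graph) {
  ii <- rep.int(seq_len(graph$n), graph$degrees)
  jj <- unlist(graph$nb, use.names = FALSE)
  keep <- ii < jj
  cbind(i = ii[keep], j = jj[keep])
}

#' Write or read a neighbourhood graph file
#'
#' Serializes an `areal_graph` in a plain-text adjacency dialect: line 1
#' holds the unit count `n`; then one line per unit, in id order, of the
#' form `<1-based index> <n_i> <space-separated 1-based neighbour indices,
#' ascending>`.  `read_graph_file()` parses the same dialect, validating
#' indices, self-edges and symmetry, and reports the offending line number
#' on failure.  The round trip `read_graph_file(write_graph_file(g))`
#' preserves the adjacency exactly.
#'
#' @param graph an `areal_graph`.
#' @param path file path.
#' @return `read_graph_file()` returns an `areal_graph`;
#'   `write_graph_file()` returns `path` invisibly.
#' @export
write_graph_file <- function(graph, path) {
  stopifnot(inherits(graph, "areal_graph"))
  lines <- c(as.character(graph$n),
             vapply(seq_len(graph$n), function(i) {
               paste(c(i, graph$degrees[i], graph$nb[[i]]), collapse = " ")
             }, character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph_file
#' @export
read_graph_file <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("graph file is empty: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L)
    stop("graph file line 1: expected a positive unit count, got '",
         lines[1L], "'")
  if (length(lines) < n + 1L)
    stop("graph file declares ", n, " units but has only ",
         length(lines) - 1L, " adjacency lines")
  nb <- vector("list", n)
  for (i in seq_len(n)) {
    ln <- i + 1L
    tok <- suppressWarnings(as.integer(strsplit(trimws(lines[ln]),
                                                "[[:space:]]+")[[1L]]))
    if (anyNA(tok) || length(tok) < 2L)
      stop("graph file line ", ln, ": malformed adjacency line")
    if (tok[1L] != i)
      stop("graph file line ", ln, ": expected unit index ", i,
           ", found ", tok[1L])
    deg <- tok[2L]
    nbrs <- tok[-(1:2)]
    if (length(nbrs) != deg)
      stop("graph file line ", ln, ": declares ", deg,
           " neighbours but lists ", length(nbrs))
    if (any(nbrs < 1L | nbrs > n))
      stop("graph file line ", ln, ": neighbour index out of range 1..", n)
    if (any(nbrs == i))
      stop("graph file line ", ln, ": self-edge on unit ", i)
    nb[[i]] <- nbrs
  }
  for (i in seq_len(n)) {
    for (j in nb[[i]]) {
      if (!(i %in% nb[[j]]))
        stop("graph file line ", j + 1L, ": asymmetric adjacency, unit ",
             i, " lists ", j, " but not vice versa")
    }
  }
  new_areal_graph(nb)
}
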