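#' Pairwise Pearson correlation of binarized activity
#'
#' Standard Pearson correlation between the 0/1 frame vectors of every neuron
#' pair. Constant columns produce undefined coefficients: those entries are
#' stored as `NA` and excluded from all derived statistics (percentiles,
#' means, degree counts); their count is recorded for provenance.
#'
#' @param raster a [binary_raster()] with at least 2 neurons.
#' @param threshold_grid ascending threshold grid used by the network-degree
#'   sweep (default 0 to 0.3 in steps of 0.05).
#' @return An object of class `correlation_graph`: list with `matrix`
#'   (symmetric neurons x neurons, unit diagonal, `NA` where undefined),
#'   `method` (binarization method of the raster), `threshold_grid`, and
#'   `n_undefined` (count of undefined unordered pairs).
#' @export
pairwise_pearson <- function(raster, threshold_grid = seq(0, 0.3, by = 0.05)) {
  stopifnot(inherits(raster, "binary_raster"))
  if (ncol(raster) < 2) stop("need at least 2 neurons")
  if (any(diff(threshold_grid) <= 0)) stop("threshold grid must be ascending")
  vals <- unclass(raster)
  storage.mode(vals) <- "double"
  sds <- apply(vals, 2, stats::sd)
  m <- suppressWarnings(stats::cor(vals))
  const <- which(sds == 0)
  if (length(const) > 0) {
    m[const, ] <- NA_real_
    m[, const] <- NA_real_
  }
  diag(m) <- 1
  dimnames(m) <- list(attr(raster, "neuron_ids"), attr(raster, "neuron_ids"))
  n_undef <- sum(is.na(m[upper.tri(m)]))
  structure(
    list(matrix = m, method = attr(raster, "method"),
         threshold_grid = threshold_grid, n_undefined = n_undef),
    class = "correlation_graph"
  )
}

#' @export
print.correlation_graph <- function(x, ...) {
  r <- offdiag_values(x)
  cat(sprintf(
    "Correlation graph: %d neurons (%s method), mean r = %.3f, %d undefined pair(s)\n",
    nrow(x$matrix), x$method, mean(r), x$n_undefined
  ))
  invisible(x)
}

# Off-diagonal coefficients, one value per unordered pair, NAs dropped.
offdiag_values <- function(graph) {
  v <- graph$matrix[upper.tri(graph$matrix)]
  v[!is.na(v)]
}

#' Mean correlation above a threshold
#'
#' Mean of the off-diagonal Pearson coefficients strictly above `threshold`.
#' An empty selection returns `NA` (undefined), never 0.
#'
#' @param graph a [pairwise_pearson()] result.
#' @param threshold value in `[-1, 1]`.
#' @return mean coefficient, or `NA_real_` when no pair qualifies.
#' @export
mean_correlation_above <- function(graph, threshold) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (threshold < -1 || threshold > 1) stop("threshold must be in [-1, 1]")
  r <- offdiag_values(graph)
  sel <- r[r > threshold]
  if (length(sel) == 0) return(NA_real_)
  mean(sel)
}

#' Network degree over a threshold grid
#'
#' For each threshold `t` in the graph's grid, the fraction of unordered
#' neuron pairs whose Pearson coefficient exceeds `t`, out of all defined
#' pairs.
#'
#' @param graph a [pairwise_pearson()] result.
#' @param thresholds thresholds to evaluate; defaults to the graph's grid.
#' @return named numeric vector of fractions in `[0, 1]`.
#' @export
network_degree <- function(graph, thresholds = graph$threshold_grid) {
  stopifnot(inherits(graph, "correlation_graph"))
  if (length(thresholds) == 0) stop("threshold grid is empty")
  r <- offdiag_values(graph)
  if (length(r) == 0) stop("no defined pair correlations")
  out <- vapply(thresholds, function(t) mean(r > t), numeric(1))
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Data-derived strong-correlation threshold
#'
#' For each baseline recording's correlation graph, takes the 95th percentile
#' (linear interpolation between order statistics) of the off-diagonal
#' coefficients; averages those percentiles across recordings; and rounds the
#' mean to the nearest multiple of `grid_step` (ties round up). On the data
#' this procedure was designed for it yields 0.3.
#'
#' @param graphs list of [pairwise_pearson()] results (baseline recordings).
#' @param percentile percentile in `(0, 100)` (default 95).
#' @param grid_step rounding grid (default 0.05).
#' @return a single threshold value.
#' @export
strong_threshold <- function(graphs, percentile = 95, grid_step = 0.05) {
  if (inherits(graphs, "correlation_graph")) graphs <- list(graphs)
  if (length(graphs) == 0) stop("need at least one baseline graph")
  p <- vapply(graphs, function(g) {
    r <- offdiag_values(g)
    if (length(r) == 0) stop("graph has no defined pair correlations")
    unname(stats::quantile(r, percentile / 100, type = 7))
  }, numeric(1))
  m <- mean(p)
  # nearest grid multiple, half-way cases rounded up
  grid_step * floor(m / grid_step + 0.5 + 1e-12)
}

#' Per-neuron connectivity
#'
#' Percentage of other neurons each neuron is connected to, where a
#' connection is a pair coefficient strictly above `threshold`. Undefined
#' pairs count as unconnected but are removed from the denominator.
#'
#' @param graph a [pairwise_pearson()] result.
#' @param threshold correlation threshold.
#' @return named numeric vector of percentages.
#' @export
connectivity <- function(graph, threshold = 0.3) {
  stopifnot(inherits(graph, "correlation_graph"))
  m <- graph$matrix
  n <- nrow(m)
  if (n < 2) stop("need at least 2 neurons")
  out <- vapply(seq_len(n), function(i) {
    r <- m[i, -i]
    denom <- sum(!is.na(r))
    if (denom == 0) return(NA_real_)
    100 * sum(r > threshold, na.rm = TRUE) / denom
  }, numeric(1))
  names(out) <- rownames(m)
  out
}

#' Cluster neurons by strong mutual correlation
#'
#' A pair of neurons is linked when its coefficient is stronger than 80% of
#' all connections in the network, i.e. strictly above the 80th percentile of
#' the off-diagonal coefficients. Clusters are the connected components of
#' the resulting link graph with at least two members; everything else is
#' unclustered (`NA` label).
#'
#' @param graph a [pairwise_pearson()] result.
#' @param percentile percentile cut (default 80).
#' @return named integer vector: neuron id -> cluster label (`NA` for
#'   unclustered), with attribute `cut` holding the percentile value used.
#' @export
cluster_assign <- function(graph, percentile = 80) {
  stopifnot(inherits(graph, "correlation_graph"))
  m <- graph$matrix
  n <- nrow(m)
  if (n < 2) stop("need at least 2 neurons")
  r <- offdiag_values(graph)
  cut <- unname(stats::quantile(r, percentile / 100, type = 7))
  adj <- !is.na(m) & m > cut
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)
  labels <- comp$membership
  sizes <- comp$csize[labels]
  labels[sizes < 2] <- NA_integer_
  # relabel surviving clusters 1..k in order of first appearance
  surv <- unique(labels[!is.na(labels)])
  out <- match(labels, surv)
  names(out) <- rownames(m)
  attr(out, "cut") <- cut
  out
}

#' Intra- and intercluster correlation
#'
#' For each cluster from [cluster_assign()]: the intracluster value is the
#' mean coefficient over within-cluster pairs; the intercluster value is the
#' mean coefficient over (member, non-member) pairs. Defined pairs only.
#'
#' @param graph a [pairwise_pearson()] result.
#' @param assignment result of [cluster_assign()].
#' @return data.frame with `cluster`, `n_members`, `intra`, `inter` (one row
#'   per cluster; zero rows when nothing clustered; `inter` is `NA` when a
#'   cluster spans every neuron).
#' @export
intra_inter_cluster <- function(graph, assignment) {
  stopifnot(inherits(graph, "correlation_graph"))
  m <- graph$matrix
  labs <- sort(unique(assignment[!is.na(assignment)]))
  if (length(labs) == 0) {
    return(data.frame(cluster = integer(0), n_members = integer(0),
                      intra = numeric(0), inter = numeric(0)))
  }
  do.call(rbind, lapply(labs, function(l) {
    inside <- which(!is.na(assignment) & assignment == l)
    outside <- setdiff(seq_len(nrow(m)), inside)
    within <- m[inside, inside][upper.tri(diag(length(inside)))]
    between <- if (length(outside) > 0) as.vector(m[inside, outside]) else NA_real_
    data.frame(
      cluster = l, n_members = length(inside),
      intra = mean(within, na.rm = TRUE),
      inter = if (all(is.na(between))) NA_real_ else mean(between, na.rm = TRUE)
    )
  }))
}
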