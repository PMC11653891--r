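#' Canonical ensemble-state feature schema
#'
#' Fixed, ordered list of the features a recording is summarized by: for each
#' binarization method, the mean burst rate, mean network spike rate, network
#' spike peak, network spike duration at each threshold, mean pairwise
#' correlation, network degree at each grid threshold, mean connectivity,
#' intra/intercluster correlation means, mean pairwise active accuracy, and
#' mean Euclidean/radial distances for the weak and strong correlation bands.
#'
#' @param methods binarization methods included.
#' @param nsd_thresholds network-spike-duration thresholds (percent).
#' @param degree_grid network-degree threshold grid.
#' @return character vector of feature names, in canonical order.
#' @export
metric_schema <- function(methods = c("spike", "full", "signal", "diff"),
                          nsd_thresholds = c(2.5, 5, 10, 15, 20, 25),
                          degree_grid = seq(0, 0.3, by = 0.05)) {
  per_method <- c(
    "burst_rate_mean", "nsr_mean", "nsp",
    paste0("nsd_", format(nsd_thresholds, trim = TRUE)),
    "corr_mean",
    paste0("degree_", format(degree_grid, trim = TRUE)),
    "connectivity_mean", "intra_mean", "inter_mean",
    "active_accuracy_mean",
    "dist_weak_euclid", "dist_weak_radial",
    "dist_strong_euclid", "dist_strong_radial"
  )
  as.vector(vapply(methods, function(m) paste(m, per_method, sep = "."),
                   character(length(per_method))))
}

# Mean intersection-over-union of active frames over all unordered pairs.
mean_active_accuracy <- function(raster) {
  vals <- unclass(raster)
  n <- ncol(vals)
  if (n < 2) return(NA_real_)
  storage.mode(vals) <- "double"
  inter <- crossprod(vals)
  tot <- colSums(vals)
  uni <- outer(tot, tot, "+") - inter
  iou <- ifelse(uni == 0, 0, inter / uni)
  mean(iou[upper.tri(iou)])
}

#' Build the metric vector of one recording
#'
#' Computes every feature in [metric_schema()] from a recording's traces and
#' neuron map: traces are binarized by each method and all activity,
#' correlation, cluster and spatial statistics are reduced to scalar
#' summaries (means). Features that are undefined for a recording (e.g. an
#' empty strong band) are `NA` and are imputed downstream by [pca_project()].
#'
#' @param traces a [trace_matrix()].
#' @param map neuron map covering the trace's neurons.
#' @param methods binarization methods to include.
#' @param strong_thr strong-correlation threshold for connectivity and the
#'   spatial bands.
#' @param nsd_thresholds,degree_grid passed through to the metric functions.
#' @return named numeric vector following [metric_schema()] exactly.
#' @export
build_metric_vector <- function(traces, map,
                                methods = c("spike", "full", "signal", "diff"),
                                strong_thr = 0.3,
                                nsd_thresholds = c(2.5, 5, 10, 15, 20, 25),
                                degree_grid = seq(0, 0.3, by = 0.05)) {
  stopifnot(inherits(traces, "trace_matrix"))
  out <- numeric(0)
  for (method in methods) {
    raster <- binarize(traces, method)
    prof <- activity_profile(raster, nsd_thresholds)
    graph <- pairwise_pearson(raster, degree_grid)
    r_off <- offdiag_values(graph)
    corr_mean <- if (length(r_off) > 0) mean(r_off) else NA_real_
    deg <- if (length(r_off) > 0) {
      network_degree(graph, degree_grid)
    } else rep(NA_real_, length(degree_grid))
    conn <- connectivity(graph, strong_thr)
    assign_ <- if (length(r_off) > 0) cluster_assign(graph) else
      structure(rep(NA_integer_, ncol(raster)))
    cl <- intra_inter_cluster(graph, assign_)
    bands <- band_distance_summary(graph, map, strong_thr)
    feats <- c(
      mean(prof$burst_rate),
      mean(prof$nsr),
      prof$nsp,
      unname(prof$nsd),
      corr_mean,
      unname(deg),
      mean(conn, na.rm = TRUE),
      if (nrow(cl) > 0) mean(cl$intra, na.rm = TRUE) else NA_real_,
      if (nrow(cl) > 0 && !all(is.na(cl$inter))) mean(cl$inter, na.rm = TRUE)
      else NA_real_,
      mean_active_accuracy(raster),
      bands$mean_euclidean_px[bands$band == "weak"],
      bands$mean_radial_px[bands$band == "weak"],
      bands$mean_euclidean_px[bands$band == "strong"],
      bands$mean_radial_px[bands$band == "strong"]
    )
    out <- c(out, feats)
  }
  names(out) <- metric_schema(methods, nsd_thresholds, degree_grid)
  out
}

#' Project recordings into a low-dimensional ensemble-state space by PCA
#'
#' Features are standardized to zero mean and unit variance; zero-variance
#' features are dropped (logged in the result); missing entries are imputed
#' with the feature's cross-recording mean (zero after standardization);
#' standard PCA follows. Component signs are fixed by making the
#' largest-magnitude loading of each component positive, so projections are
#' reproducible bit-for-bit.
#'
#' @param vectors matrix (recordings x features) or list of equal-schema
#'   metric vectors from [build_metric_vector()].
#' @param n_components number of components to retain.
#' @return An object of class `state_projection`: list with `scores`
#'   (recordings x components), `loadings` (features x components),
#'   `explained` (variance fractions, all components), `dropped_features`,
#'   `n_imputed`.
#' @export
pca_project <- function(vectors, n_components = 2) {
  if (is.list(vectors) && !is.matrix(vectors)) {
    vectors <- do.call(rbind, vectors)
  }
  x <- as.matrix(vectors)
  if (nrow(x) < 2) stop("need at least 2 recordings")
  mu <- colMeans(x, na.rm = TRUE)
  sdv <- apply(x, 2, stats::sd, na.rm = TRUE)
  keep <- is.finite(sdv) & sdv > 0
  dropped <- colnames(x)[!keep]
  if (sum(keep) < 1) {
    # all recordings identical: everything projects to one point
    scores <- matrix(0, nrow(x), n_components,
                     dimnames = list(rownames(x), paste0("PC", seq_len(n_components))))
    return(structure(
      list(scores = scores,
           loadings = matrix(numeric(0), 0, n_components),
           explained = rep(NA_real_, n_components),
           dropped_features = dropped, n_imputed = sum(is.na(x))),
      class = "state_projection"
    ))
  }
  xs <- sweep(sweep(x[, keep, drop = FALSE], 2, mu[keep]), 2, sdv[keep], "/")
  n_imputed <- sum(is.na(xs))
  xs[is.na(xs)] <- 0
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  rot <- pc$rotation
  scores <- pc$x
  for (c_ in seq_len(ncol(rot))) {
    top <- which.max(abs(rot[, c_]))
    if (rot[top, c_] < 0) {
      rot[, c_] <- -rot[, c_]
      scores[, c_] <- -scores[, c_]
    }
  }
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      scores = scores[, seq_len(k), drop = FALSE],
      loadings = rot[, seq_len(k), drop = FALSE],
      explained = expl,
      dropped_features = dropped,
      n_imputed = n_imputed
    ),
    class = "state_projection"
  )
}

#' @export
print.state_projection <- function(x, ...) {
  cat(sprintf("Ensemble-state projection: %d recordings, %d component(s)\n",
              nrow(x$scores), ncol(x$scores)))
  if (!all(is.na(x$explained))) {
    cat(sprintf("  variance explained: %s\n",
                paste(sprintf("PC%d %.1f%%", seq_len(ncol(x$scores)),
                              100 * x$explained[seq_len(ncol(x$scores))]),
                      collapse = ", ")))
  }
  invisible(x)
}

#' @export
plot.state_projection <- function(x, labels = NULL, ...) {
  if (ncol(x$scores) < 2) stop("projection has fewer than 2 components")
  col <- if (is.null(labels)) 1 else as.integer(factor(labels)) + 1L
  graphics::plot(x$scores[, 1], x$scores[, 2], col = col, pch = 19,
                 xlab = sprintf("PC1 (%.1f%%)", 100 * x$explained[1]),
                 ylab = sprintf("PC2 (%.1f%%)", 100 * x$explained[2]), ...)
  if (!is.null(labels)) {
    graphics::legend("topright", legend = levels(factor(labels)),
                     col = seq_along(levels(factor(labels))) + 1L, pch = 19)
  }
  invisible(x)
}

#' Ranked feature loadings of a projection
#'
#' @param projection a [pca_project()] result.
#' @param top_k number of features to report per component.
#' @param component component index (default 1).
#' @return data.frame with `feature`, `loading`, `abs_loading`, ordered by
#'   decreasing absolute loading.
#' @export
loading_report <- function(projection, top_k = 10, component = 1) {
  stopifnot(inherits(projection, "state_projection"))
  if (nrow(projection$loadings) == 0) {
    return(data.frame(feature = character(0), loading = numeric(0),
                      abs_loading = numeric(0)))
  }
  l <- projection$loadings[, component]
  ord <- order(abs(l), decreasing = TRUE)
  head_ <- ord[seq_len(min(top_k, length(ord)))]
  data.frame(
    feature = rownames(projection$loadings)[head_],
    loading = unname(l[head_]),
    abs_loading = unname(abs(l[head_])),
    stringsAsFactors = FALSE
  )
}
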