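#' Euclidean distance between two neurons' centroids
#'
#' @param map neuron map data.frame (`neuron_id`, `x_px`, `y_px`).
#' @param i,j neuron ids.
#' @return straight-line distance in pixels.
#' @export
euclidean_pair_distance <- function(map, i, j) {
  pi_ <- map_lookup(map, i)
  pj_ <- map_lookup(map, j)
  sqrt(sum((pi_ - pj_)^2))
}

#' Radial distance between two neurons
#'
#' The absolute difference of the two neurons' distances from the center of
#' mass of all neurons in the map (unweighted centroid mean): how much
#' further one sits from the population center than the other.
#'
#' @inheritParams euclidean_pair_distance
#' @return radial distance in pixels.
#' @export
radial_pair_distance <- function(map, i, j) {
  if (nrow(map) < 1) stop("empty neuron map")
  ctr <- c(mean(map$x_px), mean(map$y_px))
  ri <- sqrt(sum((map_lookup(map, i) - ctr)^2))
  rj <- sqrt(sum((map_lookup(map, j) - ctr)^2))
  abs(ri - rj)
}

map_lookup <- function(map, id) {
  k <- match(as.character(id), map$neuron_id)
  if (is.na(k)) stop("unknown neuron id: ", id)
  c(map$x_px[k], map$y_px[k])
}

#' Distance summaries for weakly and strongly correlated neuron pairs
#'
#' Splits unordered neuron pairs by correlation band — strong: `r >
#' strong_threshold`; weak: `r` inside `weak_band` (default `(0,
#' strong_threshold]`) — and reports the mean Euclidean and radial centroid
#' distances per band. Pairs with undefined correlation are skipped. Empty
#' bands yield `NA` means with `n_pairs = 0`.
#'
#' @param graph a [pairwise_pearson()] result.
#' @param map neuron map covering all graph neurons.
#' @param strong_threshold lower bound (strict) for the strong band.
#' @param weak_band length-2 numeric: the weak band as (lo, hi], strict at
#'   the lower edge.
#' @return data.frame with one row per band: `band`, `n_pairs`,
#'   `mean_euclidean_px`, `mean_radial_px`.
#' @export
band_distance_summary <- function(graph, map, strong_threshold = 0.3,
                                  weak_band = c(0, strong_threshold)) {
  stopifnot(inherits(graph, "correlation_graph"))
  m <- graph$matrix
  ids <- rownames(m)
  if (!all(ids %in% map$neuron_id)) stop("map does not cover all graph neurons")
  ctr <- c(mean(map$x_px), mean(map$y_px))
  k <- match(ids, map$neuron_id)
  xs <- map$x_px[k]; ys <- map$y_px[k]
  rad <- sqrt((xs - ctr[1])^2 + (ys - ctr[2])^2)

  n <- length(ids)
  pairs <- which(upper.tri(m), arr.ind = TRUE)
  r <- m[pairs]
  ok <- !is.na(r)
  pairs <- pairs[ok, , drop = FALSE]; r <- r[ok]
  eu <- sqrt((xs[pairs[, 1]] - xs[pairs[, 2]])^2 +
             (ys[pairs[, 1]] - ys[pairs[, 2]])^2)
  ra <- abs(rad[pairs[, 1]] - rad[pairs[, 2]])

  in_strong <- r > strong_threshold
  in_weak <- r > weak_band[1] & r <= weak_band[2]
  band_row <- function(name, sel) {
    data.frame(
      band = name, n_pairs = sum(sel),
      mean_euclidean_px = if (any(sel)) mean(eu[sel]) else NA_real_,
      mean_radial_px = if (any(sel)) mean(ra[sel]) else NA_real_,
      stringsAsFactors = FALSE
    )
  }
  rbind(band_row("weak", in_weak), band_row("strong", in_strong))
}
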