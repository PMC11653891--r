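#' Per-neuron burst rate
#'
#' Number of activations (contiguous active runs) per minute for each neuron.
#'
#' @param raster a [binary_raster()].
#' @param fps frame rate; defaults to the raster's own.
#' @return named numeric vector, events per minute per neuron.
#' @export
burst_rate <- function(raster, fps = attr(raster, "fps")) {
  stopifnot(inherits(raster, "binary_raster"))
  if (nrow(raster) == 0 || ncol(raster) == 0) stop("empty raster")
  counts <- apply(unclass(raster), 2, count_activations)
  rates <- counts * 60 * fps / nrow(raster)
  names(rates) <- attr(raster, "neuron_ids")
  rates
}

# Left-closed right-open binning starting at 0; returns percent per bin.
bin_percent <- function(x, bin_width, upper = NULL) {
  if (length(x) == 0) {
    return(data.frame(bin_lo = numeric(0), bin_hi = numeric(0),
                      percent = numeric(0)))
  }
  n_bins <- if (is.null(upper)) {
    max(1L, as.integer(floor(max(x) / bin_width)) + 1L)
  } else {
    # fixed-range binning: a value exactly at `upper` stays in the last bin
    max(1L, as.integer(ceiling(upper / bin_width)))
  }
  idx <- pmin(as.integer(floor(x / bin_width)), n_bins - 1L)
  counts <- tabulate(idx + 1L, nbins = n_bins)
  data.frame(
    bin_lo = (seq_len(n_bins) - 1L) * bin_width,
    bin_hi = seq_len(n_bins) * bin_width,
    percent = 100 * counts / length(x)
  )
}

#' Histogram of per-neuron burst rates
#'
#' Percent of neurons per burst-rate bin, left-closed right-open bins of width
#' `bin_width` starting at 0 (default 1/3 events/min, matching the standard
#' 0.33-wide presentation of these distributions).
#'
#' @param rates numeric vector of per-neuron rates (events/min).
#' @param bin_width bin width in events/min.
#' @return data.frame with `bin_lo`, `bin_hi`, `percent`; percents sum to 100
#'   (empty input gives a zero-row frame).
#' @export
burst_rate_histogram <- function(rates, bin_width = 1 / 3) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  bin_percent(rates, bin_width)
}

#' Network spike rate
#'
#' The recording is divided into consecutive intervals of `interval_s`
#' seconds; a neuron counts as active in an interval if it has at least one
#' active frame inside it. The network spike rate of an interval is the
#' percentage of neurons active in it. A trailing partial interval is
#' dropped.
#'
#' @param raster a [binary_raster()].
#' @param interval_s interval length in seconds (default 1).
#' @return numeric vector, one percentage per interval.
#' @export
network_spike_rate <- function(raster, interval_s = 1) {
  stopifnot(inherits(raster, "binary_raster"))
  fps <- attr(raster, "fps")
  frames_per <- as.integer(floor(interval_s * fps))
  if (frames_per < 1) stop("interval shorter than one frame")
  n_int <- nrow(raster) %/% frames_per
  if (n_int == 0) return(numeric(0))
  vals <- unclass(raster)
  vapply(seq_len(n_int), function(k) {
    rows <- ((k - 1L) * frames_per + 1L):(k * frames_per)
    100 * mean(colSums(vals[rows, , drop = FALSE]) > 0)
  }, numeric(1))
}

#' Histogram of network spike rate values
#'
#' Percent of intervals per NSR bin, left-closed right-open bins of width
#' `bin_width` percentage points over `[0, 100]` (an NSR of exactly 100 falls
#' in the last bin).
#'
#' @param nsr numeric vector of per-interval NSR percentages.
#' @param bin_width bin width in percentage points (default 2.5).
#' @return data.frame with `bin_lo`, `bin_hi`, `percent`.
#' @export
network_spike_rate_histogram <- function(nsr, bin_width = 2.5) {
  if (bin_width <= 0) stop("bin_width must be > 0")
  bin_percent(nsr, bin_width, upper = 100)
}

#' Network spike peak
#'
#' Maximum percentage of simultaneously active neurons over all intervals —
#' the maximum of the [network_spike_rate()] vector.
#'
#' @inheritParams network_spike_rate
#' @return a percentage in `[0, 100]`.
#' @export
network_spike_peak <- function(raster, interval_s = 1) {
  nsr <- network_spike_rate(raster, interval_s)
  if (length(nsr) == 0) stop("no complete interval in raster")
  max(nsr)
}

#' Network spike duration
#'
#' Total time the network spike rate stays above each threshold, reported in
#' seconds (number of supra-threshold intervals times `interval_s`). Set
#' `as_percent = TRUE` to report the percent of intervals instead.
#'
#' @inheritParams network_spike_rate
#' @param thresholds NSR thresholds in percent, each in `(0, 100]`.
#' @param as_percent report percent of the recording rather than seconds.
#' @return named numeric vector, one value per threshold.
#' @export
network_spike_duration <- function(raster,
                                   thresholds = c(2.5, 5, 10, 15, 20, 25),
                                   interval_s = 1, as_percent = FALSE) {
  if (any(thresholds <= 0 | thresholds > 100)) {
    stop("thresholds must be in (0, 100]")
  }
  nsr <- network_spike_rate(raster, interval_s)
  out <- vapply(thresholds, function(t) {
    k <- sum(nsr > t)
    if (as_percent) {
      if (length(nsr) == 0) 0 else 100 * k / length(nsr)
    } else {
      k * interval_s
    }
  }, numeric(1))
  names(out) <- format(thresholds, trim = TRUE)
  out
}

#' Summarize activity metrics of one raster
#'
#' Convenience wrapper computing the per-neuron burst rates, the NSR vector,
#' the network spike peak and the per-threshold network spike durations.
#'
#' @inheritParams network_spike_duration
#' @return list with `burst_rate`, `nsr`, `nsp`, `nsd`.
#' @export
activity_profile <- function(raster, thresholds = c(2.5, 5, 10, 15, 20, 25),
                             interval_s = 1) {
  list(
    burst_rate = burst_rate(raster),
    nsr = network_spike_rate(raster, interval_s),
    nsp = network_spike_peak(raster, interval_s),
    nsd = network_spike_duration(raster, thresholds, interval_s)
  )
}
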