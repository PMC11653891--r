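#' Construct a binary raster
#'
#' A `binary_raster` is a frames x neurons 0/1 matrix marking the active
#' state of each neuron at each frame, together with the binarization method
#' and its parameters (kept for provenance).
#'
#' @param states numeric/integer matrix over {0, 1}.
#' @param fps frame rate, frames per second.
#' @param neuron_ids unique neuron identifiers.
#' @param method name of the binarization method that produced the raster.
#' @param params list of method parameters.
#' @return A matrix of class `binary_raster`.
#' @export
binary_raster <- function(states, fps, neuron_ids = NULL,
                          method = "unknown", params = list()) {
  states <- as.matrix(states)
  if (!all(states %in% c(0, 1))) stop("raster states must be 0 or 1")
  storage.mode(states) <- "integer"
  if (is.null(neuron_ids)) {
    neuron_ids <- colnames(states)
    if (is.null(neuron_ids)) neuron_ids <- sprintf("n%03d", seq_len(ncol(states)))
  }
  dimnames(states) <- list(NULL, neuron_ids)
  structure(states, fps = fps, neuron_ids = as.character(neuron_ids),
            method = method, params = params, class = "binary_raster")
}

#' @export
print.binary_raster <- function(x, ...) {
  cat(sprintf(
    "Binary raster: %d frames x %d neurons (%s method), %.1f%% frames active\n",
    nrow(x), ncol(x), attr(x, "method"), 100 * mean(x)
  ))
  invisible(x)
}

# Centered moving average with edge truncation: the window shrinks at the
# boundaries instead of padding, so the result is shift-free and
# deterministic. Even windows cover floor((w-1)/2) frames back and
# floor(w/2) frames forward.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  back <- (window - 1L) %/% 2L
  fwd <- window %/% 2L
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Run-length view of a logical vector: data.frame(start, end, active).
runs_of <- function(mask) {
  r <- rle(as.logical(mask))
  ends <- cumsum(r$lengths)
  data.frame(start = ends - r$lengths + 1L, end = ends, active = r$values)
}

# Apply cold/warm run filtering to a logical activity mask:
# 1) delete active runs shorter than `cold` frames (cold = minimum duration
#    of the active phase);
# 2) merge active runs separated by passive gaps shorter than `warm` frames
#    (warm = minimum duration of the passive phase).
filter_runs <- function(mask, cold, warm) {
  n <- length(mask)
  if (cold > 0 && any(mask)) {
    rr <- runs_of(mask)
    for (k in which(rr$active & (rr$end - rr$start + 1L) < cold)) {
      mask[rr$start[k]:rr$end[k]] <- FALSE
    }
  }
  if (warm > 0 && any(mask)) {
    rr <- runs_of(mask)
    act <- which(rr$active)
    if (length(act) >= 2) {
      for (k in seq_len(length(act) - 1L)) {
        gap_start <- rr$end[act[k]] + 1L
        gap_end <- rr$start[act[k + 1L]] - 1L
        if (gap_end - gap_start + 1L < warm) mask[gap_start:gap_end] <- TRUE
      }
    }
  }
  mask
}

# Robust scale of the smoothed first difference; ~0 on noiseless traces so
# the rise criterion reduces to a strict positive derivative there.
diff_noise_scale <- function(d) {
  stats::mad(d, center = stats::median(d))
}

#' Binarize one trace by the spike (rapid-rise) method
#'
#' Marks the phase of rapid growth of the fluorescence signal. The trace is
#' smoothed by a centered moving average over `window` frames; candidate
#' active frames are those where the first difference of the smoothed trace
#' exceeds a noise-adaptive positive bound (`z_slope` times the MAD-based
#' scale of the differenced trace — zero for noiseless traces, so the rule is
#' then a strict positive derivative). Active runs shorter than `cold` frames
#' are deleted, and passive gaps shorter than `warm` frames merge their
#' flanking runs.
#'
#' @param trace numeric vector, one neuron's fluorescence trace.
#' @param window smoothing span in frames (default 10).
#' @param cold minimum duration of the active phase, frames (default 0).
#' @param warm minimum duration of the passive phase, frames (default 50):
#'   shorter gaps are absorbed into the surrounding activation.
#' @param z_slope multiplier on the robust noise scale of the differenced
#'   smoothed trace used as the rise-detection bound.
#' @return integer 0/1 vector, same length as `trace`.
#' @export
binarize_spike <- function(trace, window = 10, cold = 0, warm = 50,
                           z_slope = 4) {
  if (length(trace) <= window) stop("trace too short for spike binarization")
  if (window < 1 || cold < 0 || warm < 0) stop("invalid spike parameters")
  sm <- moving_average(as.numeric(trace), window)
  d <- diff(sm)
  thr <- z_slope * diff_noise_scale(d)
  mask <- c(FALSE, d > thr)
  as.integer(filter_runs(mask, cold, warm))
}

#' Binarize one trace by the full (supra-threshold) method
#'
#' Marks every frame where the trace exceeds `median + k_mad * MAD`. When the
#' MAD is zero the threshold falls back to `mean + k_mad * SD`; when the SD is
#' also zero (constant trace) the result is all zeros.
#'
#' @param trace numeric vector.
#' @param k_mad threshold multiplier (default 3).
#' @return integer 0/1 vector.
#' @export
binarize_full <- function(trace, k_mad = 3) {
  trace <- as.numeric(trace)
  m <- stats::mad(trace)
  if (m > 0) {
    thr <- stats::median(trace) + k_mad * m
  } else {
    s <- stats::sd(trace)
    if (!is.finite(s) || s == 0) return(integer(length(trace)))
    thr <- mean(trace) + k_mad * s
  }
  as.integer(trace > thr)
}

#' Binarize one trace by the signal (intensity z-score) method
#'
#' Marks frames where the standardized fluorescence intensity exceeds `z`.
#' Only the raw intensity is used — no derivative — making this the least
#' strict of the four methods. A zero-variance trace yields all zeros.
#'
#' @param trace numeric vector.
#' @param z z-score threshold (default 2).
#' @return integer 0/1 vector.
#' @export
binarize_signal <- function(trace, z = 2) {
  trace <- as.numeric(trace)
  s <- stats::sd(trace)
  if (!is.finite(s) || s == 0) return(integer(length(trace)))
  as.integer((trace - mean(trace)) / s > z)
}

#' Binarize one trace by the diff (derivative z-score) method
#'
#' Marks frames where the standardized first difference of the fluorescence
#' exceeds `z`, i.e. frames of steep signal increase. Frame 0 is always
#' inactive; a constant-derivative trace (zero variance of the differences)
#' yields all zeros.
#'
#' @param trace numeric vector of length >= 2.
#' @param z z-score threshold (default 2).
#' @return integer 0/1 vector, same length as `trace`.
#' @export
binarize_diff <- function(trace, z = 2) {
  trace <- as.numeric(trace)
  if (length(trace) < 2) stop("trace too short for diff binarization")
  d <- diff(trace)
  s <- stats::sd(d)
  # near-constant derivative (e.g. a linear ramp) has no rise structure
  if (!is.finite(s) || s <= 1e-10 * max(abs(d), 1)) {
    return(integer(length(trace)))
  }
  as.integer(c(FALSE, (d - mean(d)) / s > z))
}

#' Binarize a whole trace matrix
#'
#' Applies one of the four binarization methods column-wise and returns a
#' [binary_raster()] carrying the method name and parameters for provenance.
#'
#' @param traces a [trace_matrix()].
#' @param method one of `"spike"`, `"full"`, `"signal"`, `"diff"`.
#' @param ... parameters forwarded to the per-trace binarizer
#'   ([binarize_spike()], [binarize_full()], [binarize_signal()],
#'   [binarize_diff()]).
#' @return A [binary_raster()].
#' @export
binarize <- function(traces, method = c("spike", "full", "signal", "diff"),
                     ...) {
  stopifnot(inherits(traces, "trace_matrix"))
  method <- match.arg(method)
  fn <- switch(method,
    spike = binarize_spike, full = binarize_full,
    signal = binarize_signal, diff = binarize_diff
  )
  vals <- unclass(traces)
  states <- vapply(seq_len(ncol(vals)), function(j) fn(vals[, j], ...),
                   integer(nrow(vals)))
  defaults <- switch(method,
    spike = list(window = 10, cold = 0, warm = 50, z_slope = 4),
    full = list(k_mad = 3),
    signal = list(z = 2),
    diff = list(z = 2)
  )
  params <- utils::modifyList(defaults, list(...))
  binary_raster(states, fps = attr(traces, "fps"),
                neuron_ids = attr(traces, "neuron_ids"),
                method = method, params = params)
}

#' Active-accuracy overlap of two binary activity vectors
#'
#' Intersection-over-union of the active frame sets of two neurons:
#' `|a & b| / |a | b|`, with `0/0` defined as 0.
#'
#' @param a,b equal-length 0/1 vectors.
#' @return ratio in `[0, 1]`.
#' @export
active_accuracy <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  a <- as.logical(a); b <- as.logical(b)
  u <- sum(a | b)
  if (u == 0) return(0)
  sum(a & b) / u
}

#' Count activations in a binary vector
#'
#' An activation is one contiguous active run: the number of 0 -> 1
#' transitions, with a run starting at the first frame counted.
#'
#' @param x 0/1 vector.
#' @return integer event count.
#' @export
count_activations <- function(x) {
  x <- as.integer(as.logical(x))
  if (length(x) == 0) return(0L)
  sum(diff(c(0L, x)) == 1L)
}
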