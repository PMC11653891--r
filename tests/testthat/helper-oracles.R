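# Brute-force reference implementations, kept deliberately naive (explicit
# loops, no shared code with the package) so they can arbitrate the fast
# implementations on small instances.

oracle_count_activations <- function(x) {
  n <- 0L
  prev <- 0L
  for (v in x) {
    if (v == 1L && prev == 0L) n <- n + 1L
    prev <- v
  }
  n
}

oracle_burst_rate <- function(states, fps) {
  out <- numeric(ncol(states))
  for (j in seq_len(ncol(states))) {
    out[j] <- oracle_count_activations(states[, j]) * 60 * fps / nrow(states)
  }
  out
}

oracle_nsr <- function(states, fps, interval_s = 1) {
  fp <- floor(interval_s * fps)
  n_int <- nrow(states) %/% fp
  out <- numeric(n_int)
  for (k in seq_len(n_int)) {
    active <- 0L
    for (j in seq_len(ncol(states))) {
      seg <- states[((k - 1) * fp + 1):(k * fp), j]
      if (any(seg == 1L)) active <- active + 1L
    }
    out[k] <- 100 * active / ncol(states)
  }
  out
}

oracle_nsd <- function(states, fps, thresholds, interval_s = 1) {
  nsr <- oracle_nsr(states, fps, interval_s)
  out <- numeric(length(thresholds))
  for (k in seq_along(thresholds)) {
    cnt <- 0L
    for (v in nsr) if (v > thresholds[k]) cnt <- cnt + 1L
    out[k] <- cnt * interval_s
  }
  out
}

oracle_pearson <- function(states) {
  n <- ncol(states)
  m <- matrix(NA_real_, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- states[, i]; b <- states[, j]
      if (stats::sd(a) == 0 || stats::sd(b) == 0) next
      m[i, j] <- sum((a - mean(a)) * (b - mean(b))) /
        ((length(a) - 1) * stats::sd(a) * stats::sd(b))
    }
  }
  diag(m) <- 1
  m
}

oracle_offdiag <- function(m) {
  out <- c()
  for (i in seq_len(nrow(m) - 1)) {
    for (j in (i + 1):ncol(m)) if (!is.na(m[i, j])) out <- c(out, m[i, j])
  }
  out
}

oracle_degree <- function(m, thr) {
  vals <- oracle_offdiag(m)
  sum(vals > thr) / length(vals)
}

oracle_connectivity <- function(m, thr) {
  n <- nrow(m)
  out <- numeric(n)
  for (i in seq_len(n)) {
    cnt <- 0L; denom <- 0L
    for (j in seq_len(n)) {
      if (j == i || is.na(m[i, j])) next
      denom <- denom + 1L
      if (m[i, j] > thr) cnt <- cnt + 1L
    }
    out[i] <- if (denom == 0) NA_real_ else 100 * cnt / denom
  }
  out
}

# Connected components over the strictly-above-80th-percentile edge set,
# grown by repeated sweeps; clusters need >= 2 members.
oracle_clusters <- function(m) {
  n <- nrow(m)
  cut <- stats::quantile(oracle_offdiag(m), 0.8, type = 7)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && !is.na(m[i, j]) && m[i, j] > cut &&
            comp[j] != comp[i]) {
          old <- comp[j]
          comp[comp == old] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  for (c_ in names(sizes)) {
    if (sizes[[c_]] < 2) comp[comp == as.integer(c_)] <- NA_integer_
  }
  comp
}

oracle_euclid <- function(map, i, j) {
  a <- which(map$neuron_id == i); b <- which(map$neuron_id == j)
  sqrt((map$x_px[a] - map$x_px[b])^2 + (map$y_px[a] - map$y_px[b])^2)
}

oracle_radial <- function(map, i, j) {
  cx <- mean(map$x_px); cy <- mean(map$y_px)
  a <- which(map$neuron_id == i); b <- which(map$neuron_id == j)
  ra <- sqrt((map$x_px[a] - cx)^2 + (map$y_px[a] - cy)^2)
  rb <- sqrt((map$x_px[b] - cx)^2 + (map$y_px[b] - cy)^2)
  abs(ra - rb)
}

# Random small binary raster with mixed sparsity; may contain constant columns.
random_raster <- function(n_frames, n_neurons, fps = 15) {
  p <- stats::runif(n_neurons, 0, 0.4)
  states <- sapply(seq_len(n_neurons),
                   function(j) stats::rbinom(n_frames, 1, p[j]))
  binary_raster(states, fps = fps)
}

random_map <- function(ids, field = 500, min_sep = 0) {
  sample_positions(length(ids), c(field, field), min_sep, ids)
}
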