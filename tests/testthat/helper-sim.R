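# Shared simulation shortcuts for tests.

# Clean (noiseless, fixed-amplitude) trace with transients at given onsets.
clean_trace <- function(onsets, n_frames, fps = 15,
                        rise_tau_s = 0.1, decay_tau_s = 0.6) {
  t <- seq(0, 6 * decay_tau_s, by = 1 / fps)
  k <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  t_peak <- rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
  k <- k / (exp(-t_peak / decay_tau_s) - exp(-t_peak / rise_tau_s))
  x <- numeric(n_frames)
  for (on in onsets) {
    idx <- (on + 1):min(on + length(k), n_frames)
    x[idx] <- x[idx] + k[seq_along(idx)]
  }
  x
}

# Match detected run-start frames to planted onsets within a frame tolerance;
# returns c(precision, recall).
onset_precision_recall <- function(raster, truth, tol_frames = 15) {
  tp <- 0L; fp <- 0L; fn <- 0L
  for (i in seq_len(ncol(raster))) {
    det <- which(diff(c(0L, raster[, i])) == 1L) - 1L
    on <- truth$event_onsets[[i]]
    used <- logical(length(on))
    for (d in det) {
      k <- which(!used & abs(on - d) <= tol_frames)
      if (length(k) > 0) {
        used[k[which.min(abs(on[k] - d))]] <- TRUE
        tp <- tp + 1L
      } else {
        fp <- fp + 1L
      }
    }
    fn <- fn + sum(!used)
  }
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}

# Mean silhouette of a two-group labelling on a 1-D coordinate.
silhouette_1d <- function(x, labels) {
  labels <- as.character(labels)
  s <- vapply(seq_along(x), function(i) {
    same <- x[setdiff(which(labels == labels[i]), i)]
    other <- x[labels != labels[i]]
    a <- mean(abs(x[i] - same))
    b <- mean(abs(x[i] - other))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}
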