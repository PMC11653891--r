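#' Simulation configuration for a synthetic calcium-imaging recording
#'
#' Bundles all parameters of the synthetic recording generator. Defaults
#' emulate a typical miniscope session of CA1 pyramidal neurons expressing a
#' fast calcium indicator (GCaMP6f-like kinetics), recorded at 15 frames/s
#' for 5 minutes with a mean activation rate of 1.27 events/min.
#'
#' @param n_neurons number of simulated neurons.
#' @param duration_s recording length in seconds.
#' @param fps acquisition frame rate, frames per second.
#' @param rate_per_min per-neuron activation-event rate, events per minute.
#'   Scalar (shared) or length-`n_neurons` vector.
#' @param rise_tau_s transient rise time constant, seconds.
#' @param decay_tau_s transient decay time constant, seconds.
#' @param noise_sd standard deviation of additive Gaussian noise, in units of
#'   the unit-peak transient amplitude.
#' @param amp_sdlog log-scale SD of per-event LogNormal amplitudes; 0 makes
#'   every transient identical with unit peak.
#' @param field_size_px width and height of the imaged field, pixels.
#' @param min_separation_px minimum centroid distance between placed neurons,
#'   pixels. Somata are extended objects: source extraction cannot yield two
#'   cells closer than roughly one soma diameter, so positions are drawn
#'   uniformly with this exclusion radius.
#' @param coupled_pairs list of `c(i, j, f)` triples: neuron `j` shares a
#'   fraction `f` in `[0, 1]` of its activation events with neuron `i`
#'   (same-frame copies), giving controllable pairwise co-activation.
#' @param seed integer seed; every random draw in the generator flows from it.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_events()], [render_traces()], [simulate_recording()]
#' @export
sim_config <- function(n_neurons = 100,
                       duration_s = 300,
                       fps = 15,
                       rate_per_min = 1.27,
                       rise_tau_s = 0.1,
                       decay_tau_s = 0.6,
                       noise_sd = 0.1,
                       amp_sdlog = 0.25,
                       field_size_px = c(600, 600),
                       min_separation_px = 10,
                       coupled_pairs = list(),
                       seed = 1L) {
  n_neurons <- as.integer(n_neurons)
  if (n_neurons < 1) stop("n_neurons must be >= 1")
  if (!is.numeric(duration_s) || duration_s <= 0) stop("duration_s must be > 0")
  if (!is.numeric(fps) || fps <= 0) stop("fps must be > 0")
  if (any(!is.finite(rate_per_min)) || any(rate_per_min < 0)) {
    stop("rate_per_min must be non-negative and finite")
  }
  if (!length(rate_per_min) %in% c(1L, n_neurons)) {
    stop("rate_per_min must be scalar or length n_neurons")
  }
  if (rise_tau_s <= 0 || decay_tau_s <= 0) stop("time constants must be > 0")
  if (rise_tau_s >= decay_tau_s) stop("rise_tau_s must be < decay_tau_s")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (amp_sdlog < 0) stop("amp_sdlog must be >= 0")
  if (length(field_size_px) != 2 || any(field_size_px <= 0)) {
    stop("field_size_px must be two positive numbers")
  }
  if (min_separation_px < 0) stop("min_separation_px must be >= 0")
  for (p in coupled_pairs) {
    if (length(p) != 3) stop("each coupled pair must be c(i, j, fraction)")
    if (p[1] < 1 || p[1] > n_neurons || p[2] < 1 || p[2] > n_neurons) {
      stop("coupled pair indices out of range")
    }
    if (p[1] == p[2]) stop("coupled pair must name two distinct neurons")
    if (p[3] < 0 || p[3] > 1) stop("sharing fraction must be in [0, 1]")
  }
  structure(
    list(
      n_neurons = n_neurons, duration_s = duration_s, fps = fps,
      rate_per_min = rep_len(rate_per_min, n_neurons),
      rise_tau_s = rise_tau_s, decay_tau_s = decay_tau_s,
      noise_sd = noise_sd, amp_sdlog = amp_sdlog,
      field_size_px = as.numeric(field_size_px),
      min_separation_px = min_separation_px,
      coupled_pairs = coupled_pairs, seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Sample neuron centroid positions over the imaged field
#'
#' Uniform dart-throwing with an exclusion radius: positions are drawn
#' uniformly and rejected while closer than `min_separation_px` to an
#' accepted neuron, reflecting that somata occupy space and source extraction
#' cannot resolve two cells closer than about one soma diameter.
#'
#' @param n number of neurons.
#' @param field_size_px width and height of the field, pixels.
#' @param min_separation_px exclusion radius, pixels.
#' @param ids neuron identifiers.
#' @return data.frame with `neuron_id`, `x_px`, `y_px`.
#' @export
sample_positions <- function(n, field_size_px = c(600, 600),
                             min_separation_px = 10,
                             ids = sprintf("n%03d", seq_len(n))) {
  xs <- numeric(n); ys <- numeric(n)
  placed <- 0L
  tries <- 0L
  max_tries <- 1000L * n
  while (placed < n) {
    if ((tries <- tries + 1L) > max_tries) {
      stop("could not place neurons with the requested minimum separation")
    }
    x <- stats::runif(1, 0, field_size_px[1])
    y <- stats::runif(1, 0, field_size_px[2])
    if (placed == 0L ||
        min((xs[seq_len(placed)] - x)^2 + (ys[seq_len(placed)] - y)^2) >=
        min_separation_px^2) {
      placed <- placed + 1L
      xs[placed] <- x; ys[placed] <- y
    }
  }
  data.frame(neuron_id = ids, x_px = xs, y_px = ys, stringsAsFactors = FALSE)
}

#' Simulate activation events and neuron positions
#'
#' Draws homogeneous-Poisson activation onsets per neuron (thinned to unique
#' frames), applies pairwise event coupling, and places neurons uniformly at
#' random over the imaged field. This is the ground truth against which
#' detection and metric recovery are judged.
#'
#' Coupling for a triple `(i, j, f)`: neuron `j` keeps each of its own onsets
#' with probability `1 - f` and receives a same-frame copy of each of `i`'s
#' onsets with probability `f`. At `f = 1` the two onset lists are identical;
#' at equal rates the expected fraction of `j`'s onsets shared with `i` is `f`.
#'
#' @param config a [sim_config()].
#' @return An object of class `sim_truth`: list with `event_onsets` (per-neuron
#'   integer vector of 0-based onset frames, strictly increasing), `positions`
#'   (data.frame `neuron_id`, `x_px`, `y_px`), `rate_per_min` (realized
#'   events/min per neuron), `pair_sharing` (realized shared fraction per
#'   coupled pair), `n_frames`, `fps`.
#' @export
simulate_events <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_frames <- as.integer(round(config$duration_s * config$fps))
  lambda_frames <- config$rate_per_min * config$duration_s / 60

  onsets <- lapply(seq_len(config$n_neurons), function(i) {
    k <- stats::rpois(1L, lambda_frames[i])
    if (k == 0L) return(integer(0))
    sort(unique(sample.int(n_frames, min(k, n_frames)) - 1L))
  })

  for (p in config$coupled_pairs) {
    i <- as.integer(p[1]); j <- as.integer(p[2]); f <- p[3]
    keep <- onsets[[j]][stats::runif(length(onsets[[j]])) >= f]
    take <- onsets[[i]][stats::runif(length(onsets[[i]])) < f]
    onsets[[j]] <- sort(unique(c(keep, take)))
  }

  ids <- sprintf("n%03d", seq_len(config$n_neurons))
  positions <- sample_positions(config$n_neurons, config$field_size_px,
                                config$min_separation_px, ids)

  pair_sharing <- vapply(config$coupled_pairs, function(p) {
    oj <- onsets[[as.integer(p[2])]]
    if (length(oj) == 0) return(NA_real_)
    mean(oj %in% onsets[[as.integer(p[1])]])
  }, numeric(1))

  names(onsets) <- ids
  structure(
    list(
      event_onsets = onsets,
      positions = positions,
      rate_per_min = vapply(onsets, length, integer(1)) * 60 / config$duration_s,
      pair_sharing = pair_sharing,
      n_frames = n_frames,
      fps = config$fps
    ),
    class = "sim_truth"
  )
}

# Unit-peak difference-of-exponentials transient sampled at frame times.
# Peak occurs at t* = tr*td/(td-tr) * log(td/tr); the kernel is scaled so its
# continuous-time maximum is 1.
transient_kernel <- function(rise_tau_s, decay_tau_s, fps,
                             length_s = 6 * decay_tau_s) {
  t <- seq(0, length_s, by = 1 / fps)
  k <- exp(-t / decay_tau_s) - exp(-t / rise_tau_s)
  t_peak <- rise_tau_s * decay_tau_s / (decay_tau_s - rise_tau_s) *
    log(decay_tau_s / rise_tau_s)
  peak <- exp(-t_peak / decay_tau_s) - exp(-t_peak / rise_tau_s)
  k / peak
}

#' Render fluorescence traces from simulated events
#'
#' Each activation onset contributes a unit-peak difference-of-exponentials
#' transient (fast rise, slower decay) scaled by a per-event LogNormal
#' amplitude; overlapping transients sum. Additive Gaussian noise with SD
#' `config$noise_sd` is applied to every frame.
#'
#' @param truth a `sim_truth` from [simulate_events()].
#' @param config the [sim_config()] used to generate `truth`.
#' @return A [trace_matrix()] of dimension frames x neurons.
#' @export
render_traces <- function(truth, config) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  n_frames <- truth$n_frames
  if (any(unlist(truth$event_onsets) >= n_frames)) {
    stop("onset frame beyond recording length")
  }
  set.seed(config$seed + 1L)
  kern <- transient_kernel(config$rise_tau_s, config$decay_tau_s, config$fps)
  lk <- length(kern)
  vals <- matrix(0, nrow = n_frames, ncol = config$n_neurons)
  for (i in seq_len(config$n_neurons)) {
    for (on in truth$event_onsets[[i]]) {
      amp <- if (config$amp_sdlog > 0) {
        stats::rlnorm(1, 0, config$amp_sdlog)
      } else 1
      idx <- (on + 1L):min(on + lk, n_frames)
      vals[idx, i] <- vals[idx, i] + amp * kern[seq_along(idx)]
    }
  }
  if (config$noise_sd > 0) {
    vals <- vals + stats::rnorm(length(vals), 0, config$noise_sd)
  }
  trace_matrix(vals, fps = config$fps, neuron_ids = names(truth$event_onsets))
}

#' Simulate one complete recording (events plus rendered traces)
#'
#' Convenience wrapper around [simulate_events()] and [render_traces()].
#'
#' @param config a [sim_config()].
#' @return list with `traces` (a `trace_matrix`), `truth` (a `sim_truth`) and
#'   `positions` (the neuron map as a data.frame).
#' @export
simulate_recording <- function(config) {
  truth <- simulate_events(config)
  list(
    traces = render_traces(truth, config),
    truth = truth,
    positions = truth$positions
  )
}

#' Configuration for a multi-session simulated experiment
#'
#' Describes a series of sessions per mouse (e.g. five baseline days, a
#' stress session, a 3-h and a 10-day follow-up) sharing one underlying
#' neuron population. Per-state rate multipliers shift activation rates;
#' centroid jitter and random dropout emulate imperfect day-to-day
#' registration of the field of view.
#'
#' Default multipliers follow the relative shifts in mean activation rate the
#' generator is meant to emulate: stress roughly doubles the baseline rate,
#' the 3-h state stays close to stress, and 10 days returns to baseline.
#'
#' @param base a [sim_config()] shared by all sessions.
#' @param state_multipliers named numeric vector, state label -> rate
#'   multiplier (> 0).
#' @param centroid_jitter_px SD of per-session Gaussian positional jitter.
#' @param dropout_fraction fraction of neurons absent from each non-reference
#'   session, in `[0, 1)`.
#' @param n_mice number of simulated mice (independent populations).
#' @return An object of class `session_series_config`.
#' @export
session_series_config <- function(base = sim_config(),
                                  state_multipliers = c(
                                    baseline_d1 = 1, baseline_d2 = 1,
                                    baseline_d3 = 1, baseline_d4 = 1,
                                    baseline_d5 = 1,
                                    stress = 1.95, `3h` = 1.83,
                                    `10days` = 1.07
                                  ),
                                  centroid_jitter_px = 2,
                                  dropout_fraction = 0.1,
                                  n_mice = 1L) {
  stopifnot(inherits(base, "sim_config"))
  if (length(state_multipliers) == 0) stop("at least one state label required")
  if (is.null(names(state_multipliers)) || any(names(state_multipliers) == "")) {
    stop("state_multipliers must be a named vector")
  }
  if (any(state_multipliers <= 0)) stop("multipliers must be > 0")
  if (centroid_jitter_px < 0) stop("centroid_jitter_px must be >= 0")
  if (dropout_fraction < 0 || dropout_fraction >= 1) {
    stop("dropout_fraction must be in [0, 1)")
  }
  structure(
    list(
      base = base, state_multipliers = state_multipliers,
      centroid_jitter_px = centroid_jitter_px,
      dropout_fraction = dropout_fraction, n_mice = as.integer(n_mice)
    ),
    class = "session_series_config"
  )
}

#' Simulate a multi-session series of recordings
#'
#' Generates one recording per (mouse, state). Within a mouse, all sessions
#' share the same base neuron population and positions; each session scales
#' activation rates by its state multiplier, jitters centroids by
#' `centroid_jitter_px`, and removes a random `dropout_fraction` of neurons.
#' The ground-truth cross-session identity is retained in each session's
#' neuron ids, so registration accuracy can be scored exactly.
#'
#' @param series_config a [session_series_config()].
#' @return An object of class `session_set`: list with `records` (data.frame
#'   `mouse_id`, `state`, `session_id`) and `sessions` (named list, one
#'   element per session with `traces`, `positions`, `truth`,
#'   `rate_multiplier`).
#' @export
simulate_session_series <- function(series_config) {
  stopifnot(inherits(series_config, "session_series_config"))
  base <- series_config$base
  states <- names(series_config$state_multipliers)
  records <- list()
  sessions <- list()
  for (m in seq_len(series_config$n_mice)) {
    mouse_seed <- base$seed + 1000L * m
    set.seed(mouse_seed)
    base_positions <- sample_positions(base$n_neurons, base$field_size_px,
                                       base$min_separation_px)
    for (s in seq_along(states)) {
      state <- states[s]
      mult <- series_config$state_multipliers[[state]]
      cfg <- sim_config(
        n_neurons = base$n_neurons, duration_s = base$duration_s,
        fps = base$fps, rate_per_min = base$rate_per_min * mult,
        rise_tau_s = base$rise_tau_s, decay_tau_s = base$decay_tau_s,
        noise_sd = base$noise_sd, amp_sdlog = base$amp_sdlog,
        field_size_px = base$field_size_px,
        min_separation_px = base$min_separation_px,
        coupled_pairs = base$coupled_pairs,
        seed = mouse_seed + s
      )
      rec <- simulate_recording(cfg)

      set.seed(mouse_seed + 100L * s)
      pos <- base_positions
      if (series_config$centroid_jitter_px > 0) {
        pos$x_px <- pos$x_px +
          stats::rnorm(nrow(pos), 0, series_config$centroid_jitter_px)
        pos$y_px <- pos$y_px +
          stats::rnorm(nrow(pos), 0, series_config$centroid_jitter_px)
      }
      keep <- rep(TRUE, nrow(pos))
      if (series_config$dropout_fraction > 0) {
        keep <- stats::runif(nrow(pos)) >= series_config$dropout_fraction
        if (!any(keep)) keep[1] <- TRUE
      }
      sid <- sprintf("m%d_%s", m, state)
      sessions[[sid]] <- list(
        traces = subset_traces(rec$traces, which(keep)),
        positions = pos[keep, , drop = FALSE],
        truth = rec$truth,
        kept = pos$neuron_id[keep],
        rate_multiplier = mult
      )
      records[[length(records) + 1L]] <- data.frame(
        mouse_id = sprintf("m%d", m), state = state, session_id = sid,
        stringsAsFactors = FALSE
      )
    }
  }
  structure(
    list(records = do.call(rbind, records), sessions = sessions),
    class = "session_set"
  )
}

# Column subset of a trace_matrix preserving attributes.
subset_traces <- function(traces, cols) {
  trace_matrix(unclass(traces)[, cols, drop = FALSE],
               fps = attr(traces, "fps"),
               neuron_ids = attr(traces, "neuron_ids")[cols])
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Simulation config: %d neurons, %.0f s at %g fps, mean rate %.2f /min\n",
    x$n_neurons, x$duration_s, x$fps, mean(x$rate_per_min)
  ))
  cat(sprintf(
    "  transient tau_r=%.2fs tau_d=%.2fs, noise sd %.2f, %d coupled pair(s)\n",
    x$rise_tau_s, x$decay_tau_s, x$noise_sd, length(x$coupled_pairs)
  ))
  invisible(x)
}

#' @export
print.session_set <- function(x, ...) {
  cat(sprintf("Session set: %d session(s), %d mouse/mice\n",
              nrow(x$records), length(unique(x$records$mouse_id))))
  print(x$records)
  invisible(x)
}
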