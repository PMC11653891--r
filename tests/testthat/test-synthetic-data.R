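test_that("config validation rejects malformed parameters", {
  expect_error(sim_config(rate_per_min = -1), "non-negative")
  expect_error(sim_config(n_neurons = 2, coupled_pairs = list(c(1, 3, 0.5))),
               "out of range")
  expect_error(sim_config(n_neurons = 2, coupled_pairs = list(c(1, 2, 1.5))),
               "fraction")
  expect_error(sim_config(duration_s = 0), "duration")
  expect_error(sim_config(rise_tau_s = 0.7, decay_tau_s = 0.6), "rise_tau_s")
})

test_that("zero rate yields no events and a flat noiseless trace", {
  cfg <- sim_config(n_neurons = 5, rate_per_min = 0, noise_sd = 0, seed = 1)
  truth <- simulate_events(cfg)
  expect_true(all(lengths(truth$event_onsets) == 0))
  traces <- render_traces(truth, cfg)
  expect_true(all(unclass(traces) == 0))
})

test_that("realized event rates match the Poisson target within 3 SE", {
  cfg <- sim_config(n_neurons = 100, rate_per_min = 1.27, duration_s = 300,
                    seed = 11)
  truth <- simulate_events(cfg)
  # per-neuron count ~ Poisson(lambda * T / 60); SE of the mean rate follows
  lambda <- 1.27
  se_mean <- sqrt(lambda * 300 / 60) * (60 / 300) / sqrt(100)
  expect_lt(abs(mean(truth$rate_per_min) - lambda), 3 * se_mean)
  expect_true(all(vapply(truth$event_onsets,
                         function(o) all(diff(o) > 0), logical(1))))
  expect_true(all(unlist(truth$event_onsets) < truth$n_frames))
})

test_that("event counts are Poisson-dispersed across neurons", {
  cfg <- sim_config(n_neurons = 500, rate_per_min = 1, duration_s = 300,
                    seed = 5)
  counts <- lengths(simulate_events(cfg)$event_onsets)
  fano <- stats::var(counts) / mean(counts)
  expect_gt(fano, 0.8)
  expect_lt(fano, 1.2)
})

test_that("full coupling copies the partner's onsets exactly", {
  cfg <- sim_config(n_neurons = 4, rate_per_min = 3,
                    coupled_pairs = list(c(1, 2, 1)), seed = 2)
  truth <- simulate_events(cfg)
  expect_identical(truth$event_onsets[[1]], truth$event_onsets[[2]])
  expect_equal(truth$pair_sharing, 1)
})

test_that("realized sharing fraction tracks the requested fraction", {
  f <- 0.5
  shares <- vapply(1:20, function(s) {
    cfg <- sim_config(n_neurons = 2, rate_per_min = 4, duration_s = 300,
                      coupled_pairs = list(c(1, 2, f)), seed = 100 + s)
    simulate_events(cfg)$pair_sharing
  }, numeric(1))
  # ~20 onsets per repeat; binomial SE of the pooled mean
  se <- sqrt(f * (1 - f) / (20 * 20))
  expect_lt(abs(mean(shares, na.rm = TRUE) - f), 3 * se + 0.02)
})

test_that("same seed gives bit-identical recordings", {
  cfg <- sim_config(n_neurons = 10, seed = 77)
  a <- simulate_recording(cfg)
  b <- simulate_recording(cfg)
  expect_identical(a$truth$event_onsets, b$truth$event_onsets)
  expect_identical(unclass(a$traces), unclass(b$traces))
  expect_identical(a$positions, b$positions)
})

test_that("rendered transient peaks shortly after its onset", {
  cfg <- sim_config(n_neurons = 1, rate_per_min = 0, noise_sd = 0,
                    amp_sdlog = 0, seed = 1)
  truth <- simulate_events(cfg)
  truth$event_onsets[[1]] <- 100L
  tr <- render_traces(truth, cfg)
  peak_frame <- which.max(tr[, 1]) - 1L  # 0-based
  expect_gte(peak_frame, 100)
  expect_lte(peak_frame, 100 + ceiling(5 * cfg$rise_tau_s * cfg$fps))
  expect_equal(max(tr[, 1]), 1, tolerance = 0.01)  # unit-peak kernel
})

test_that("overlapping transients superpose", {
  cfg <- sim_config(n_neurons = 1, rate_per_min = 0, noise_sd = 0,
                    amp_sdlog = 0, duration_s = 60, seed = 1)
  truth <- simulate_events(cfg)
  truth$event_onsets[[1]] <- c(100L, 104L)  # second onset within decay
  two <- render_traces(truth, cfg)
  truth$event_onsets[[1]] <- 100L
  one <- render_traces(truth, cfg)
  expect_gt(max(two[105:140, 1]), max(one[, 1]))
})

test_that("session series honours multipliers, jitter and dropout", {
  base <- sim_config(n_neurons = 60, rate_per_min = 1.5, duration_s = 200,
                     noise_sd = 0, seed = 4)
  ident <- session_series_config(
    base, state_multipliers = c(a = 1, b = 1), centroid_jitter_px = 0,
    dropout_fraction = 0
  )
  ss <- simulate_session_series(ident)
  expect_equal(ss$sessions[[1]]$positions, ss$sessions[[2]]$positions)
  expect_equal(nrow(ss$sessions[[1]]$positions), 60)

  doubled <- session_series_config(
    base, state_multipliers = c(baseline = 1, stress = 2),
    centroid_jitter_px = 0, dropout_fraction = 0
  )
  rates <- vapply(1:6, function(s) {
    b2 <- sim_config(n_neurons = 60, rate_per_min = 1.5, duration_s = 200,
                     noise_sd = 0, seed = 4 + 10 * s)
    ss <- simulate_session_series(session_series_config(
      b2, state_multipliers = c(baseline = 1, stress = 2),
      centroid_jitter_px = 0, dropout_fraction = 0
    ))
    c(mean(ss$sessions$m1_baseline$truth$rate_per_min),
      mean(ss$sessions$m1_stress$truth$rate_per_min))
  }, numeric(2))
  ratio <- mean(rates[2, ]) / mean(rates[1, ])
  expect_lt(abs(ratio - 2), 0.25)

  dropped <- simulate_session_series(session_series_config(
    sim_config(n_neurons = 100, seed = 6), state_multipliers = c(x = 1),
    centroid_jitter_px = 0, dropout_fraction = 0.1
  ))
  n_kept <- nrow(dropped$sessions[[1]]$positions)
  # Binomial(100, 0.9): 3 SD band around 90
  expect_gt(n_kept, 90 - 3 * sqrt(100 * 0.9 * 0.1))
  expect_lt(n_kept, 90 + 3 * sqrt(100 * 0.9 * 0.1))

  expect_error(session_series_config(base, state_multipliers = numeric(0)),
               "at least one state")
})
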