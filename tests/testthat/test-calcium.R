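test_that("ratio computation is exact and guards its denominator", {
  f380 <- rep(100, 50); f340 <- 2 * f380
  tr <- compute_ratio(f340, f380)
  expect_true(all(tr$ratio == 2))
  # subtracting a denominator background of half the signal doubles the ratio
  tr2 <- compute_ratio(f340, f380, bg340 = 0, bg380 = 50)
  expect_true(all(tr2$ratio == 2 * tr$ratio))
  expect_error(compute_ratio(f340, f380[-1]), "equal length")
  expect_error(compute_ratio(f340, f380, bg380 = 200),
               "non-positive at sample 1")
})

test_that("segmentation yields one full window per stimulus", {
  tr <- generate_calcium_trace(calcium_trace_spec(duration_s = 10,
                                                  pacing_hz = 0.5,
                                                  seed = 1))
  w <- segment_transients(tr)
  expect_length(w, 5)
  expect_equal(vapply(w, function(x) x$start_s, numeric(1)),
               seq(0, 8, by = 2))
  expect_equal(diff(range(w[[1]]$time_s)), 2 - 0.02, tolerance = 1e-9)

  flat <- as_calcium_trace(seq(0, 10, 0.02), rep(1, 501), pacing_hz = 0.5)
  expect_warning(wf <- segment_transients(flat), "no beats")
  expect_length(wf, 0)

  stim <- as_calcium_trace(seq(0, 10, 0.02), rep(1, 501),
                           pacing_hz = 0.5,
                           stimulus_times_s = c(1, 3, 5))
  ws <- segment_transients(stim)
  expect_equal(vapply(ws, function(x) x$start_s, numeric(1)), c(1, 3, 5))
})

test_that("noiseless transient metrics recover the generator truth", {
  tr <- generate_calcium_trace(calcium_trace_spec(
    amplitude = 0.5, tau_decay_s = 0.4, noise_sd = 0, seed = 1))
  beats <- do.call(rbind, lapply(segment_transients(tr), transient_metrics))
  expect_equal(median(beats$amplitude), 0.5, tolerance = 0.02)
  expect_equal(median(beats$tau_decay_s), 0.4, tolerance = 0.05)
  expect_true(all(beats$t50_decay_s <= beats$t90_decay_s))
})

test_that("t50 equals tau log 2 for a pure monoexponential decay", {
  t <- seq(0, 2, by = 0.02)
  tau <- 0.35
  win <- list(time_s = t, ratio = 1 + 0.5 * exp(-t / tau), start_s = 0)
  m <- transient_metrics(win)
  expect_equal(m$t50_decay_s, tau * log(2), tolerance = 0.06)
  expect_equal(m$t90_decay_s, tau * log(10), tolerance = 0.06)
})

test_that("metrics are shift-equivariant in the baseline", {
  tr <- generate_calcium_trace(calcium_trace_spec(noise_sd = 0.02,
                                                  seed = 3))
  shifted <- as_calcium_trace(tr$time_s, tr$ratio + 0.7,
                              pacing_hz = tr$pacing_hz,
                              stimulus_times_s = tr$stimulus_times_s)
  a <- analyze_calcium_trace(tr)$cell
  b <- analyze_calcium_trace(shifted)$cell
  expect_equal(b$baseline_ratio, a$baseline_ratio + 0.7, tolerance = 1e-6)
  expect_equal(b$amplitude, a$amplitude, tolerance = 1e-6)
  expect_equal(b$tau_decay_s, a$tau_decay_s, tolerance = 1e-6)
})

test_that("per-cell aggregation is robust to corrupt beats", {
  one <- data.frame(baseline_ratio = 1, amplitude = 0.5,
                    time_to_peak_s = 0.15, tau_decay_s = 0.4,
                    t50_decay_s = 0.3, t90_decay_s = 0.9, fit_r2 = 0.99)
  same <- do.call(rbind, replicate(3, one, simplify = FALSE))
  agg <- aggregate_cell(same)
  expect_equal(agg$amplitude, 0.5)
  expect_equal(agg$n_beats, 3)

  corrupt <- rbind(same, transform(one, amplitude = NA_real_))
  agg2 <- aggregate_cell(corrupt)
  expect_equal(agg2$n_beats, 3)

  excl <- aggregate_cell(data.frame())
  expect_true(excl$excluded)
  expect_match(excl$reason, "no beats")
})
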