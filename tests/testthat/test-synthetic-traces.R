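test_that("paced trace carries one transient per stimulus", {
  tr <- generate_calcium_trace(calcium_trace_spec(duration_s = 10,
                                                  pacing_hz = 0.5,
                                                  seed = 1))
  expect_equal(nrow(tr$truth), 5)          # floor(10 s x 0.5 Hz)
  expect_equal(tr$stimulus_times_s, seq(0, 8, by = 2))
})

test_that("noiseless peak equals the specified amplitude", {
  tr <- generate_calcium_trace(calcium_trace_spec(
    duration_s = 4, pacing_hz = 0.25, baseline_ratio = 1, amplitude = 0.5,
    noise_sd = 0, seed = 1))
  # the sampled maximum sits within one sample of the analytic peak
  expect_equal(max(tr$ratio) - 1, 0.5, tolerance = 0.005)
  flat <- generate_calcium_trace(calcium_trace_spec(amplitude = 0,
                                                    noise_sd = 0, seed = 1))
  expect_true(all(abs(flat$ratio - flat$spec$baseline_ratio) < 1e-12))
})

test_that("overlapping transients and undersampling are rejected", {
  expect_error(calcium_trace_spec(pacing_hz = 1, tau_decay_s = 1.5),
               "overlap")
  expect_error(calcium_trace_spec(sample_rate_hz = 5, pacing_hz = 0.5),
               "sample_rate")
})

test_that("trace generation is deterministic given the seed", {
  a <- generate_calcium_trace(calcium_trace_spec(seed = 9))
  b <- generate_calcium_trace(calcium_trace_spec(seed = 9))
  expect_identical(a$ratio, b$ratio)
})
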