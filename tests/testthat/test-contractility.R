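test_that("identical frames give zero displacement on all valid blocks", {
  tex <- random_texture(64, 64, seed = 1)
  frames <- array(c(tex, tex), dim = c(64, 64, 2))
  mf <- block_match_motion(frames, block_px = 16, search_px = 4)
  expect_true(any(mf$valid[, , 1]))
  expect_true(all(mf$dx[, , 1][mf$valid[, , 1]] == 0))
  expect_true(all(mf$dy[, , 1][mf$valid[, , 1]] == 0))
})

test_that("a global 3 px shift is recovered exactly on valid blocks", {
  tex <- random_texture(80, 96, seed = 2)
  # B[r, c] = tex[r, c - 3]: every feature moves 3 px toward higher
  # column index, so blocks of A are found in B at dx = +3
  A <- tex[, 4:83]; B <- tex[, 1:80]
  frames <- array(c(A, B), dim = c(80, 80, 2))
  mf <- block_match_motion(frames, block_px = 16, search_px = 8)
  v <- mf$valid[, , 1]
  expect_true(any(v))
  expect_true(all(mf$dx[, , 1][v] == 3))
  expect_true(all(mf$dy[, , 1][v] == 0))
  expect_false(any(mf$saturated[, , 1][v]))
})

test_that("shifts beyond the search radius saturate and are flagged", {
  tex <- random_texture(96, 120, seed = 3)
  A <- tex[, 1:96]; B <- tex[, 13:108]    # true shift 12 px
  frames <- array(c(A, B), dim = c(96, 96, 2))
  mf <- block_match_motion(frames, block_px = 16, search_px = 8)
  v <- mf$valid[, , 1]
  expect_true(any(mf$saturated[, , 1][v]))
  expect_true(all(abs(mf$dx[, , 1][v]) <= 8))
})

test_that("block matching equals the exhaustive naive oracle", {
  tex <- random_texture(72, 88, seed = 4)
  for (shift in list(c(0, 0), c(2, 0), c(-3, 0))) {
    A <- tex[5:68, 9:72]
    B <- tex[5:68 + shift[1], 9:72 + shift[2]]
    frames <- array(c(A, B), dim = c(64, 64, 2))
    mf <- block_match_motion(frames, block_px = 16, search_px = 4)
    oracle <- naive_block_match(A, B, 16, 4)
    v <- mf$valid[, , 1] & !is.na(oracle$dx)
    expect_true(any(v))
    expect_equal(mf$dx[, , 1][v], oracle$dx[v])
    expect_equal(mf$dy[, , 1][v], oracle$dy[v])
  }
})

test_that("motion metrics are invariant to global intensity scaling", {
  v <- generate_beating_video(beating_video_spec(
    duration_s = 4, frame_rate_hz = 25, amplitude_px = 3,
    search_px_declared = 4, seed = 5))
  mf1 <- block_match_motion(v, block_px = 16, search_px = 4)
  scaled <- v
  scaled$frames <- v$frames * 4.2
  mf2 <- block_match_motion(scaled, block_px = 16, search_px = 4)
  expect_identical(mf1$dx, mf2$dx)
  expect_identical(mf1$dy, mf2$dy)
  m1 <- motion_beat_metrics(mf1); m2 <- motion_beat_metrics(mf2)
  expect_equal(m1$peak_contraction_um_s, m2$peak_contraction_um_s)
})

test_that("beat metrics recover pulse count and speed from truth", {
  v <- generate_beating_video(beating_video_spec(
    duration_s = 10, frame_rate_hz = 25, amplitude_px = 3,
    search_px_declared = 4, seed = 6))
  m <- motion_beat_metrics(block_match_motion(v, block_px = 16,
                                              search_px = 4))
  expect_equal(m$n_beats, v$truth$n_pulses)
  expect_equal(m$beat_rate_hz, 0.5, tolerance = 0.02)
  expect_equal(m$peak_contraction_um_s,
               mean(v$truth$pulse_peak_speed_um_s), tolerance = 0.1)
  # static video: no beats
  tex <- random_texture(64, 64, seed = 7)
  static <- array(rep(tex, 20), dim = c(64, 64, 20))
  m0 <- motion_beat_metrics(block_match_motion(static, 16, 4,
                                               frame_rate_hz = 25,
                                               pixel_size_um = 1))
  expect_equal(m0$n_beats, 0L)
  expect_equal(max(m0$speed_um_s), 0)
})

test_that("doubling an explicit displacement doubles peak velocity", {
  t <- (0:99) / 25                       # one entry per frame at 25 fps
  d <- numeric(length(t))
  for (on in c(0.2, 2.2)) {
    k <- t >= on & t <= on + 0.6
    d[k] <- 3 * sin(pi * (t[k] - on) / 0.6)^2
  }
  d <- round(d)
  run <- function(mult) {
    v <- generate_beating_video(beating_video_spec(
      duration_s = 4, frame_rate_hz = 25, displacement_px = mult * d,
      seed = 8))
    motion_beat_metrics(block_match_motion(v, 16, 6))
  }
  m1 <- run(1); m2 <- run(2)
  expect_equal(m2$peak_contraction_um_s, 2 * m1$peak_contraction_um_s)
})

test_that("cantilever force follows the printed formula exactly", {
  geom <- eht_geometry()    # E = 1.7 MPa, r = 0.5 mm, L = 10 mm
  expect_equal(deflection_to_force(0, geom), 0)
  expect_equal(deflection_to_force(1e-4, geom),
               3 * pi * 1e-4 * 1.7e6 * (5e-4)^4 / (4 * (1e-2)^3),
               tolerance = 1e-12)
  expect_equal(deflection_to_force(1e-4, geom), 2.5034e-5,
               tolerance = 1e-4)
  expect_error(deflection_to_force(-1e-5, geom), "nonnegative")

  set.seed(1)
  for (i in 1:20) {
    d <- stats::runif(1, 1e-5, 1e-3)
    g <- eht_geometry(elastic_modulus_Pa = stats::runif(1, 1e5, 1e7),
                      post_radius_m = stats::runif(1, 1e-4, 1e-3),
                      post_length_m = stats::runif(1, 5e-3, 2e-2))
    expect_equal(deflection_to_force(2 * d, g),
                 2 * deflection_to_force(d, g), tolerance = 1e-12)
    g2 <- g; g2$post_radius_m <- 2 * g$post_radius_m
    expect_equal(deflection_to_force(d, g2),
                 16 * deflection_to_force(d, g), tolerance = 1e-12)
  }
})

test_that("per-beat force tracks rests under baseline drift", {
  t <- seq(0, 10, by = 0.01)
  defl <- numeric(length(t))
  for (on in seq(0.5, 9, by = 2)) {
    k <- t >= on & t <= on + 0.6
    defl[k] <- 1e-4 * sin(pi * (t[k] - on) / 0.6)^2
  }
  res <- eht_force_per_beat(t, defl)
  expect_equal(res$summary$n_beats, 5)
  expect_equal(res$summary$mean_force_N, 2.5034e-5, tolerance = 1e-3)

  drift <- 1e-5 * t / 10
  res2 <- eht_force_per_beat(t, defl + drift)
  expect_equal(res2$summary$mean_force_N, res$summary$mean_force_N,
               tolerance = 0.02)

  flat <- eht_force_per_beat(t, rep(2e-5, length(t)))
  expect_equal(flat$summary$n_beats, 0L)
})
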