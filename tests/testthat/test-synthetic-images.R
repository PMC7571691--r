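test_that("image generation is deterministic given the seed", {
  spec <- sarcomere_image_spec(size_px = c(64, 64), seed = 42)
  a <- generate_sarcomere_image(spec)
  b <- generate_sarcomere_image(spec)
  expect_identical(a$intensity, b$intensity)
  c <- generate_sarcomere_image(sarcomere_image_spec(size_px = c(64, 64),
                                                     seed = 43))
  expect_false(identical(a$intensity, c$intensity))
})

test_that("degenerate spec yields background plus noise only", {
  img <- generate_sarcomere_image(sarcomere_image_spec(
    size_px = c(128, 128), organized_fraction = 0, stripe_amplitude = 0,
    background_level = 100, noise_sd = 5, seed = 1))
  expect_equal(mean(img$intensity), 100, tolerance = 0.01)
  expect_equal(stats::sd(as.vector(img$intensity)), 5, tolerance = 0.05)
  flat <- generate_sarcomere_image(sarcomere_image_spec(
    size_px = c(64, 64), organized_fraction = 0, stripe_amplitude = 0,
    background_level = 7, noise_sd = 0, seed = 1))
  expect_true(all(flat$intensity == 7))
})

test_that("striation autocorrelation peaks at the period in pixels", {
  # period 1.8 um at 0.1 um/px = 18 px; stripes along x (orientation 0)
  img <- generate_sarcomere_image(sarcomere_image_spec(
    size_px = c(128, 216), pixel_size_um = 0.1, period_um = 1.8,
    orientation_deg = 0, organized_fraction = 1, noise_sd = 0, seed = 2))
  rowac <- function(lag) {
    m <- img$intensity
    stats::cor(as.vector(m[, 1:(ncol(m) - lag)]),
               as.vector(m[, (lag + 1):ncol(m)]))
  }
  expect_gt(rowac(18), 0.9)
  expect_gt(rowac(18), rowac(9) + 0.5)   # half-period is anticorrelated
})

test_that("unresolvable periods are rejected", {
  expect_error(sarcomere_image_spec(period_um = 0.3, pixel_size_um = 0.1),
               "resolved")
  expect_error(sarcomere_image_spec(organized_fraction = 1.2), "<= 1")
})
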