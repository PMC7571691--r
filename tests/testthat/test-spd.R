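test_that("constant ROI has power only at DC", {
  img <- matrix(5, 220, 220)
  sp <- compute_power_spectrum(img, pixel_size_um = 0.1,
                               roi_origin = c(1, 1), window = FALSE)
  p <- sp$power
  p[1, 1] <- 0   # DC
  expect_lt(max(p), 1e-12)
})

test_that("a pure grating concentrates power at its spatial frequency", {
  x <- outer(rep(1, 220), 0:219)
  g <- 2 + cos(2 * pi * x / 18)          # period 18 px = 1.8 um at 0.1 um/px
  sp <- compute_power_spectrum(g, pixel_size_um = 0.1,
                               roi_origin = c(1, 1), window = FALSE)
  i <- which(sp$power == max(sp$power), arr.ind = TRUE)[1, ]
  fr <- sqrt(sp$fy[i[1]]^2 + sp$fx[i[2]]^2)
  expect_equal(fr, 1 / 1.8, tolerance = 0.05)   # within one frequency bin
})

test_that("unwindowed total power obeys Parseval's relation", {
  set.seed(1)
  img <- matrix(stats::rnorm(250 * 250), 250, 250)
  sp <- compute_power_spectrum(img, pixel_size_um = 0.1,
                               roi_origin = c(11, 21), window = FALSE)
  roi <- img[11:210, 21:220]; roi <- roi - mean(roi)
  # sum |F|^2 = N^2 * sum of squared (mean-subtracted) pixel values
  expect_equal(sum(sp$power), sum(roi^2) * 200^2, tolerance = 1e-10)
})

test_that("wedge profile recovers orientation and flags isotropy", {
  img <- generate_sarcomere_image(sarcomere_image_spec(
    size_px = c(220, 220), orientation_deg = 30, seed = 5))
  prof <- wedge_profile(compute_power_spectrum(img))
  expect_lt(abs(prof$orientation_deg - 30), 1.01)
  expect_false(prof$low_confidence)

  set.seed(2)
  wn <- matrix(stats::rnorm(220 * 220, 100, 10), 220, 220)
  pw <- wedge_profile(compute_power_spectrum(wn, pixel_size_um = 0.1))
  expect_true(pw$low_confidence)
  # white-noise profile is approximately flat away from DC
  mid <- pw$power[pw$f > 0.5 & pw$f < 4]
  expect_lt(max(mid) / stats::median(mid), 5)
})

test_that("fit recovers exact model parameters from a clean profile", {
  truth <- list(a0 = 2, b0 = 0.8, a1 = 6, b1 = 0.008, a2 = 1.5,
                b2 = 0.012, f0 = 0.5556)
  f <- seq(0.05, 2.2, by = 0.0125)
  pow <- truth$a0 * exp(-f / truth$b0) +
    truth$a1 * exp(-(f - truth$f0)^2 / truth$b1) +
    truth$a2 * exp(-(f - 2 * truth$f0)^2 / truth$b2)
  prof <- structure(list(f = f, power = pow, orientation_deg = 0,
                         wedge_halfwidth_deg = 15, low_confidence = FALSE,
                         f_min = 0.05),
                    class = "radial_profile")
  fit <- fit_spd_model(prof)
  for (nm in names(truth))
    expect_equal(fit[[nm]], truth[[nm]], tolerance = 1e-4)
})

test_that("a pure exponential profile yields near-zero packing density", {
  f <- seq(0.05, 2.2, by = 0.0125)
  prof <- structure(list(f = f, power = 3 * exp(-f / 0.6),
                         orientation_deg = 0, wedge_halfwidth_deg = 15,
                         low_confidence = TRUE, f_min = 0.05),
                    class = "radial_profile")
  fit <- fit_spd_model(prof)
  expect_lt(sarcomere_metrics(fit)$SPD, 1e-3)
})

test_that("metrics match closed forms and handle degenerate parameters", {
  p <- spd_params(a0 = 1, b0 = 1, a1 = 0.5, b1 = 0.02, a2 = 0.2,
                  b2 = 0.02, f0 = 0.5556)
  m <- sarcomere_metrics(p)
  expect_equal(m$SL_um, 1 / 0.5556)
  closed <- 0.7 * sqrt(0.02 * pi) / (1 + 0.7 * sqrt(0.02 * pi))
  expect_equal(m$SPD, closed, tolerance = 1e-6)
  expect_equal(m$SPD, spd_closed_form(p), tolerance = 1e-6)

  none <- spd_params(a0 = 1, b0 = 1, a1 = 0, b1 = 0.02, a2 = 0,
                     b2 = 0.02, f0 = 0.5)
  expect_equal(sarcomere_metrics(none)$SPD, 0, tolerance = 1e-12)
  all_p <- spd_params(a0 = 0, b0 = 1, a1 = 0.5, b1 = 0.02, a2 = 0,
                      b2 = 0.02, f0 = 0.5)
  expect_equal(sarcomere_metrics(all_p)$SPD, 1, tolerance = 1e-12)
  expect_error(sarcomere_metrics(spd_params(a0 = 0, b0 = 1, a1 = 0,
                                            b1 = 1, a2 = 0, b2 = 1,
                                            f0 = 0.5)),
               "undefined")
})

test_that("SPD is invariant under intensity scaling of the image", {
  img <- generate_sarcomere_image(sarcomere_image_spec(
    size_px = c(220, 220), organized_fraction = 0.6, seed = 6))
  a <- analyze_image(img)
  b <- analyze_image(img$intensity * 7.3, pixel_size_um = 0.1)
  expect_equal(a$metrics$SPD, b$metrics$SPD, tolerance = 1e-6)
  expect_equal(a$metrics$SL_um, b$metrics$SL_um, tolerance = 1e-9)
})

test_that("images smaller than the ROI are rejected", {
  img <- matrix(1, 150, 150)
  expect_error(compute_power_spectrum(img, pixel_size_um = 0.1),
               "smaller than")
  expect_error(compute_power_spectrum(matrix(1, 220, 220),
                                      pixel_size_um = 0.1,
                                      roi_origin = c(100, 100)),
               "out of bounds")
})
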