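# Sarcomere length and sarcomere packing density from 2D Fourier spectra.
#
# The 1D wedge profile of the power spectrum of a striated cell decomposes
# into an aperiodic exponential decay plus Gaussian peaks at the sarcomere
# spatial frequency f0 and its second harmonic:
#   G(f)  = Gap(f) + Gp(f)
#   Gap(f) = a0 * exp(-f / b0)
#   Gp(f)  = sum_{k=1,2} ak * exp(-(f - k*f0)^2 / bk)
# Sarcomere length SL = 1/f0; packing density SPD = int(Gp) / int(G).

ROI_SIZE <- 200L

#' 2D Fourier power spectrum of a 200x200 region of interest
#'
#' The ROI is mean-subtracted and (by default) tapered with a 2D Hann
#' window before the discrete Fourier transform; the squared magnitude is
#' returned with frequency axes in cycles per micrometre.
#'
#' @param image a `sarcomere_image` or a numeric matrix.
#' @param pixel_size_um pixel size; required when `image` is a bare matrix.
#' @param roi_origin `"auto"` (default) to pick the highest-variance
#'   200x200 window on a coarse grid, or an integer pair (row, col) of the
#'   ROI's top-left corner.
#' @param window apply the Hann taper (disable for Parseval checks).
#' @return object of class `power_spectrum`: `power` (matrix), `fy`, `fx`
#'   (cycles/um along rows and columns), `roi_origin`, `pixel_size_um`,
#'   `windowed`, and `roi_variance`.
#' @export
compute_power_spectrum <- function(image, pixel_size_um = NULL,
                                   roi_origin = "auto", window = TRUE) {
  if (inherits(image, "sarcomere_image")) {
    pixel_size_um <- image$pixel_size_um
    m <- image$intensity
  } else {
    m <- image
    if (is.null(pixel_size_um)) abort("pixel_size_um required")
  }
  if (!is.matrix(m) || any(!is.finite(m)))
    abort("image must be a finite numeric matrix")
  n <- ROI_SIZE
  if (nrow(m) < n || ncol(m) < n)
    abort("image (%d x %d) smaller than the %d x %d analysis ROI",
          nrow(m), ncol(m), n, n)
  if (identical(roi_origin, "auto")) {
    roi_origin <- best_roi_origin(m, n)
  } else {
    roi_origin <- as.integer(roi_origin)
    if (length(roi_origin) != 2 ||
        roi_origin[1] < 1 || roi_origin[2] < 1 ||
        roi_origin[1] + n - 1 > nrow(m) || roi_origin[2] + n - 1 > ncol(m))
      abort("roi_origin out of bounds")
  }
  roi <- m[roi_origin[1]:(roi_origin[1] + n - 1),
           roi_origin[2]:(roi_origin[2] + n - 1)]
  v <- stats::var(as.vector(roi))
  roi <- roi - mean(roi)
  if (window) {
    h <- 0.5 * (1 - cos(2 * pi * seq(0, n - 1) / (n - 1)))
    roi <- roi * outer(h, h)
  }
  p <- Mod(stats::fft(roi))^2
  structure(list(power = p,
                 fy = fft_freq(n, pixel_size_um),
                 fx = fft_freq(n, pixel_size_um),
                 roi_origin = roi_origin,
                 pixel_size_um = pixel_size_um,
                 windowed = window,
                 roi_variance = v),
            class = "power_spectrum")
}

# highest-variance n x n window on a coarse grid (integral-image variance)
best_roi_origin <- function(m, n, stride = 20L) {
  nr <- nrow(m); nc <- ncol(m)
  rows <- unique(c(seq(1L, nr - n + 1L, by = stride), nr - n + 1L))
  cols <- unique(c(seq(1L, nc - n + 1L, by = stride), nc - n + 1L))
  # integral images padded with a leading zero row/col
  cs <- function(x) {
    z <- apply(x, 2, cumsum); z <- t(apply(z, 1, cumsum))
    rbind(0, cbind(0, z))[1:(nrow(x) + 1), 1:(ncol(x) + 1)]
  }
  I1 <- cs(m); I2 <- cs(m * m)
  boxsum <- function(I, r, c) {
    I[r + n, c + n] - I[r, c + n] - I[r + n, c] + I[r, c]
  }
  best <- c(1L, 1L); bestv <- -Inf
  for (r in rows) for (c in cols) {
    s1 <- boxsum(I1, r, c); s2 <- boxsum(I2, r, c)
    v <- s2 / (n * n) - (s1 / (n * n))^2
    if (v > bestv) { bestv <- v; best <- c(r, c) }
  }
  best
}

#' Wedge-averaged 1D radial profile of a power spectrum
#'
#' Estimates the preferential striation orientation as the argmax of a
#' 1-degree angular histogram of spectral power in a radial band (default
#' 0.3-0.8 cycles/um, the physiological sarcomere-frequency range), then
#' averages power per radial-frequency bin over a +/-15-degree wedge.
#' Angles are taken modulo 180 degrees, which folds the two
#' point-symmetric (Hermitian-redundant) halves of the spectrum together.
#' DC and frequencies below `f_min` are excluded. When no angular bin
#' stands clearly above the typical bin (ratio below 1.5), the orientation
#' is flagged low-confidence; ties break to the smallest angle.
#'
#' @param spectrum a `power_spectrum`.
#' @param wedge_halfwidth_deg half-width of the wedge (default 15).
#' @param orientation_deg optional fixed orientation override.
#' @param f_min lowest retained frequency in cycles/um (default 0.05).
#' @param orientation_band radial band used for orientation detection.
#' @return object of class `radial_profile`: `f`, `power`,
#'   `orientation_deg`, `wedge_halfwidth_deg`, `low_confidence`.
#' @export
wedge_profile <- function(spectrum, wedge_halfwidth_deg = 15,
                          orientation_deg = NULL, f_min = 0.05,
                          orientation_band = c(0.3, 0.8)) {
  stopifnot(inherits(spectrum, "power_spectrum"))
  p <- spectrum$power
  fr <- sqrt(outer(spectrum$fy^2, spectrum$fx^2, `+`))
  ang <- outer(spectrum$fy, spectrum$fx,
               function(fy, fx) atan2(fy, fx)) * 180 / pi
  ang <- ang %% 180

  low_confidence <- FALSE
  if (is.null(orientation_deg)) {
    inband <- fr >= orientation_band[1] & fr <= orientation_band[2]
    if (!any(inband)) abort("orientation band outside spectral range")
    bins <- pmin(floor(ang[inband]) + 1L, 180L)
    hist <- vapply(split(p[inband], factor(bins, levels = 1:180)),
                   function(v) if (length(v)) mean(v) else 0, numeric(1))
    hist[is.na(hist)] <- 0
    orientation_deg <- which.max(hist) - 1L  # ties -> smallest angle
    # confidence: share of band power inside the selected wedge; an
    # isotropic spectrum puts ~wedge/180 (= 1/6 for 30 degrees) there
    dd <- abs(ang - orientation_deg) %% 180
    dd <- pmin(dd, 180 - dd)
    share <- sum(p[inband & dd <= wedge_halfwidth_deg]) / sum(p[inband])
    if (share < 1.8 * (2 * wedge_halfwidth_deg / 180))
      low_confidence <- TRUE
  }

  d <- abs(ang - orientation_deg) %% 180
  d <- pmin(d, 180 - d)
  sel <- d <= wedge_halfwidth_deg & fr > 0
  df <- 1 / (nrow(p) * spectrum$pixel_size_um)   # spectral resolution
  bin <- round(fr[sel] / df)
  keep <- bin >= 1
  agg <- tapply(p[sel][keep], bin[keep], mean)
  f <- as.numeric(names(agg)) * df
  ord <- order(f)
  f <- f[ord]; pw <- as.numeric(agg)[ord]
  retain <- f >= f_min
  structure(list(f = f[retain], power = pw[retain],
                 orientation_deg = orientation_deg,
                 wedge_halfwidth_deg = wedge_halfwidth_deg,
                 low_confidence = low_confidence,
                 f_min = f_min),
            class = "radial_profile")
}

# model pieces
spd_model_aperiodic <- function(f, a0, b0) a0 * exp(-f / b0)
spd_model_periodic <- function(f, a1, b1, a2, b2, f0) {
  a1 * exp(-(f - f0)^2 / b1) + a2 * exp(-(f - 2 * f0)^2 / b2)
}
spd_model <- function(f, a0, b0, a1, b1, a2, b2, f0) {
  spd_model_aperiodic(f, a0, b0) +
    spd_model_periodic(f, a1, b1, a2, b2, f0)
}

#' Construct a sarcomere spectral-model parameter set
#'
#' @param a0,b0 amplitude and decay frequency scale of the aperiodic term.
#' @param a1,b1 amplitude and squared-width of the fundamental peak.
#' @param a2,b2 amplitude and squared-width of the second harmonic.
#' @param f0 fundamental spatial frequency in cycles/um.
#' @param residual_norm residual norm of the fit that produced the
#'   parameters (0 for exact constructions).
#' @return object of class `spd_params`.
#' @export
spd_params <- function(a0, b0, a1, b1, a2, b2, f0, residual_norm = 0) {
  for (nm in c("a0", "a1", "a2"))
    check_scalar(get(nm), nm, 0)
  for (nm in c("b0", "b1", "b2"))
    check_scalar(get(nm), nm, 0, strict_lower = TRUE)
  check_scalar(f0, "f0", 0, strict_lower = TRUE)
  structure(list(a0 = a0, b0 = b0, a1 = a1, b1 = b1, a2 = a2, b2 = b2,
                 f0 = f0, residual_norm = residual_norm),
            class = "spd_params")
}

#' Fit the aperiodic + two-harmonic spectral model to a radial profile
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) in linear power,
#' multistarted with f0 seeded at the strongest local maxima of the
#' profile inside the physiological band; the aperiodic term is
#' initialized from a log-linear fit to off-peak bins. The lowest-residual
#' fit wins; ties break to smaller f0.
#'
#' @param profile a `radial_profile`.
#' @param f0_band allowed f0 range in cycles/um; default 1/3.0 to 1/1.3
#'   (sarcomere lengths 1.3-3.0 um).
#' @param n_starts number of candidate-peak starts (default 3).
#' @return an `spd_params` object (amplitudes on the profile's power
#'   scale) with the achieved `residual_norm`.
#' @export
fit_spd_model <- function(profile, f0_band = c(1 / 3.0, 1 / 1.3),
                          n_starts = 3, f_fit_max = 2.2,
                          weighting = c("linear", "relative")) {
  stopifnot(inherits(profile, "radial_profile"))
  weighting <- match.arg(weighting)
  keep <- profile$f <= f_fit_max
  f <- profile$f[keep]; y <- profile$power[keep]
  if (length(f) < 30) abort("profile needs >= 30 bins for a stable fit")
  # normalize to median power so the aperiodic term is O(1) in fit units
  scale <- stats::median(y[y > 0])
  if (!is.finite(scale) || scale <= 0) scale <- max(y)
  if (scale <= 0) abort("profile has no power")
  w <- y / scale

  # candidate f0 values: local maxima inside the band, by height
  inband <- which(f >= f0_band[1] & f <= f0_band[2])
  if (!length(inband)) abort("no profile bins inside the f0 band")
  locmax <- inband[vapply(inband, function(i) {
    lo <- max(1, i - 1); hi <- min(length(w), i + 1)
    w[i] >= max(w[lo:hi])
  }, logical(1))]
  if (!length(locmax)) locmax <- inband[which.max(w[inband])]
  cand <- locmax[order(w[locmax], decreasing = TRUE)]
  cand <- utils::head(cand, n_starts)

  # aperiodic initialization from off-peak bins
  offpeak <- rep(TRUE, length(f))
  for (i in cand)
    offpeak <- offpeak & abs(f - f[i]) > 0.08 & abs(f - 2 * f[i]) > 0.08
  if (sum(offpeak) < 5) offpeak <- rep(TRUE, length(f))
  lf <- stats::lm(log(pmax(w[offpeak], 1e-12)) ~ f[offpeak])
  a0_init <- min(max(exp(stats::coef(lf)[1]), 1e-6), 10)
  slope <- stats::coef(lf)[2]
  b0_init <- if (is.finite(slope) && slope < -1e-6) min(-1 / slope, 10) else 2

  # residuals weighted by 1/power: periodogram bin noise has sd
  # proportional to its mean (chi-squared), so relative residuals give
  # the properly weighted least squares; the floor at the median (1 in
  # fit units) keeps noise-floor bins from dominating
  wt <- if (weighting == "relative") pmax(w, 1) else rep(1, length(w))
  model_resid <- function(p) {
    (w - (p[1] * exp(-f / p[2]) + p[3] * exp(-(f - p[7])^2 / p[4]) +
            p[5] * exp(-(f - 2 * p[7])^2 / p[6]))) / wt
  }
  # peak widths bounded at b = 0.05 (sd ~0.16 cycles/um): sarcomere peaks
  # are narrow; wide Gaussians would absorb the aperiodic background
  lower <- c(0, 1e-4, 0, 1e-6, 0, 1e-6, f0_band[1])
  upper <- c(Inf, 100, Inf, 0.05, Inf, 0.05, f0_band[2])
  starts <- list()
  for (i in cand) {
    f0_init <- min(max(f[i], f0_band[1]), f0_band[2])
    ap_at_peak <- a0_init * exp(-f0_init / b0_init)
    a1_init <- max(w[i] - ap_at_peak, 0.01)
    starts[[length(starts) + 1]] <-
      c(a0_init, b0_init, a1_init, 0.01, a1_init / 4, 0.01, f0_init)
    # background-anchored start: peaks nearly absent, so the aperiodic
    # term is not abandoned when the profile is dominated by it
    starts[[length(starts) + 1]] <-
      c(a0_init, b0_init, 0.01, 0.01, 0.01, 0.01, f0_init)
  }
  fits <- list()
  for (start in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(
        par = start, fn = model_resid, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 500,
                                             ftol = 1e-13, ptol = 1e-13)),
      error = function(e) NULL)
    if (!is.null(fit) && all(is.finite(fit$par)))
      fits[[length(fits) + 1]] <- fit
  }
  if (!length(fits))
    abort("spectral model fit failed on all %d starts", length(starts))
  rss <- vapply(fits, function(ft) sum(ft$fvec^2), numeric(1))
  f0s <- vapply(fits, function(ft) ft$par[7], numeric(1))
  best <- which(rss <= min(rss) * (1 + 1e-9))
  best <- best[which.min(f0s[best])]       # ties -> smaller f0
  cf <- fits[[best]]$par
  spd_params(a0 = cf[1] * scale, b0 = cf[2],
             a1 = cf[3] * scale, b1 = cf[4],
             a2 = cf[5] * scale, b2 = cf[6],
             f0 = cf[7],
             residual_norm = sqrt(rss[best]) * scale)
}

#' Sarcomere length and packing density from fitted model parameters
#'
#' SL = 1/f0. SPD = int(Gp)/int(G), evaluated by adaptive quadrature of
#' the fitted analytic model on [0, Inf); for peaks well separated from
#' zero this agrees with the closed forms int(Gap) = a0*b0 and
#' int(Gp) = sum(ak * sqrt(pi * bk)) (see [spd_closed_form()]).
#'
#' @param params an `spd_params` object.
#' @return object of class `sarcomere_metrics`: list with `SL_um` and
#'   `SPD`.
#' @export
sarcomere_metrics <- function(params) {
  stopifnot(inherits(params, "spd_params"))
  if (params$a0 == 0 && params$a1 == 0 && params$a2 == 0)
    abort("all amplitudes zero: SPD undefined (0/0)")
  ip <- stats::integrate(function(f)
    spd_model_periodic(f, params$a1, params$b1, params$a2, params$b2,
                       params$f0),
    0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  iap <- stats::integrate(function(f)
    spd_model_aperiodic(f, params$a0, params$b0),
    0, Inf, rel.tol = 1e-10, abs.tol = 0)$value
  spd <- ip / (ip + iap)
  structure(list(SL_um = 1 / params$f0,
                 SPD = min(max(spd, 0), 1)),
            class = "sarcomere_metrics")
}

#' Closed-form SPD for peaks far from zero frequency
#'
#' Uses int(Gap) = a0*b0 and int(Gp) = a1*sqrt(pi*b1) + a2*sqrt(pi*b2)
#' (full-line Gaussian integrals, valid when f0 is several peak widths
#' above zero).
#'
#' @param params an `spd_params` object.
#' @return the closed-form SPD value.
#' @export
spd_closed_form <- function(params) {
  ip <- params$a1 * sqrt(pi * params$b1) + params$a2 * sqrt(pi * params$b2)
  iap <- params$a0 * params$b0
  ip / (ip + iap)
}

#' End-to-end sarcomere analysis of one image
#'
#' Chains ROI power spectrum, wedge profile, model fit, and metrics, and
#' returns a QC record of the intermediate choices.
#'
#' @param image a `sarcomere_image` or numeric matrix.
#' @param pixel_size_um required for bare matrices.
#' @param roi_origin,window passed to [compute_power_spectrum()].
#' @param orientation_deg optional fixed orientation for the wedge.
#' @param f0_band passed to [fit_spd_model()].
#' @return list with `metrics` (a `sarcomere_metrics`), `params`
#'   (`spd_params`) and `qc` (roi origin, orientation, residual, flags).
#' @export
analyze_image <- function(image, pixel_size_um = NULL, roi_origin = "auto",
                          window = TRUE, orientation_deg = NULL,
                          f0_band = c(1 / 3.0, 1 / 1.3)) {
  sp <- compute_power_spectrum(image, pixel_size_um = pixel_size_um,
                               roi_origin = roi_origin, window = window)
  prof <- wedge_profile(sp, orientation_deg = orientation_deg)
  params <- fit_spd_model(prof, f0_band = f0_band)
  metrics <- sarcomere_metrics(params)
  list(metrics = metrics,
       params = params,
       qc = list(roi_origin = sp$roi_origin,
                 orientation_deg = prof$orientation_deg,
                 orientation_low_confidence = prof$low_confidence,
                 residual_norm = params$residual_norm,
                 windowed = sp$windowed))
}
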