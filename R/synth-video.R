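#' Specification for a synthetic beating-monolayer video
#'
#' Frames are a fixed random texture translated by a time-varying
#' displacement along the x axis: a raised-cosine contraction pulse at each
#' pacing stimulus, rounded to whole pixels so the applied motion is known
#' exactly. Defaults mirror the recording protocol used for monolayer
#' contractility (10 s at 75 frames per second).
#'
#' @param frame_px integer pair, frame size (rows, cols).
#' @param duration_s recording duration in seconds.
#' @param frame_rate_hz frame rate (default 75).
#' @param pacing_hz beat rate of the simulated monolayer (default 0.5).
#' @param amplitude_px peak displacement of each contraction in pixels.
#' @param pulse_width_s duration of one contraction-relaxation pulse.
#' @param texture_scale_px correlation length of the random texture.
#' @param texture_amplitude texture contrast; must be positive.
#' @param pixel_size_um pixel size, used to convert motion to um/s.
#' @param search_px_declared nominal block-matching search radius; motion
#'   exceeding it between consecutive frames is flagged in the metadata.
#' @param displacement_px optional explicit per-frame displacement vector
#'   (px, rounded to integers); overrides the pulse train.
#' @param seed integer seed.
#' @return an object of class `video_spec`.
#' @export
beating_video_spec <- function(frame_px = c(64L, 64L),
                               duration_s = 10,
                               frame_rate_hz = 75,
                               pacing_hz = 0.5,
                               amplitude_px = 4,
                               pulse_width_s = 0.6,
                               texture_scale_px = 3,
                               texture_amplitude = 100,
                               pixel_size_um = 1,
                               search_px_declared = 8,
                               displacement_px = NULL,
                               seed = 1L) {
  if (length(frame_px) != 2 || any(frame_px < 16))
    abort("`frame_px` must be two integers >= 16")
  check_scalar(texture_amplitude, "texture_amplitude", 0,
               strict_lower = TRUE)
  check_scalar(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar(frame_rate_hz, "frame_rate_hz", 0, strict_lower = TRUE)
  check_scalar(pacing_hz, "pacing_hz", 0, strict_lower = TRUE)
  check_scalar(amplitude_px, "amplitude_px", 0)
  structure(list(frame_px = as.integer(frame_px), duration_s = duration_s,
                 frame_rate_hz = frame_rate_hz, pacing_hz = pacing_hz,
                 amplitude_px = amplitude_px, pulse_width_s = pulse_width_s,
                 texture_scale_px = texture_scale_px,
                 texture_amplitude = texture_amplitude,
                 pixel_size_um = pixel_size_um,
                 search_px_declared = search_px_declared,
                 displacement_px = displacement_px,
                 seed = as.integer(seed)),
            class = "video_spec")
}

# Circularly shift a matrix by d columns (positive = content moves right).
shift_cols <- function(m, d) {
  nc <- ncol(m)
  d <- ((d %% nc) + nc) %% nc
  if (d == 0) return(m)
  m[, c((nc - d + 1L):nc, 1L:(nc - d))]
}

#' Generate a synthetic beating video with ground-truth motion
#'
#' @param spec a [beating_video_spec()] object.
#' @return an object of class `beating_video`: list with `frames` (array
#'   rows x cols x n_frames), `frame_rate_hz`, `pixel_size_um`, `truth`
#'   (per-frame displacement, per-pair frame-to-frame displacement, speed
#'   trace in um/s, pulse count and times), and `flags` (in particular
#'   `exceeds_search` when frame-to-frame motion exceeds the declared
#'   search radius).
#' @export
generate_beating_video <- function(spec) {
  stopifnot(inherits(spec, "video_spec"))
  nr <- spec$frame_px[1]; nc <- spec$frame_px[2]
  with_seed(spec$seed, 303L, {
    n_frames <- max(2L, floor(spec$duration_s * spec$frame_rate_hz))
    t <- (seq_len(n_frames) - 1) / spec$frame_rate_hz

    if (is.null(spec$displacement_px)) {
      n_pulses <- floor(spec$duration_s * spec$pacing_hz)
      pulse_times <- (seq_len(n_pulses) - 1) / spec$pacing_hz + 0.2
      d <- numeric(n_frames)
      for (on in pulse_times) {
        inpulse <- t >= on & t <= on + spec$pulse_width_s
        d[inpulse] <- d[inpulse] + spec$amplitude_px *
          sin(pi * (t[inpulse] - on) / spec$pulse_width_s)^2
      }
      d <- round(d)
    } else {
      d <- round(spec$displacement_px)
      if (length(d) != n_frames)
        abort("displacement_px must have one entry per frame (%d)", n_frames)
      n_pulses <- NA_integer_; pulse_times <- numeric(0)
    }

    # smooth random texture on a canvas wide enough that every frame is
    # an exact crop (no wrap-around artifacts at the edges)
    margin <- max(abs(d)) + 1L
    ncw <- nc + 2L * margin
    raw <- matrix(rnorm(nr * ncw), nr, ncw)
    s <- spec$texture_scale_px
    w <- ceiling(3 * s)
    kern <- exp(-(seq(-w, w))^2 / (2 * s^2)); kern <- kern / sum(kern)
    blur1 <- function(m) {
      pad <- function(v) c(rep(v[1], w), v, rep(v[length(v)], w))
      nr2 <- nrow(m); nc2 <- ncol(m)
      m2 <- apply(m, 2, function(v) stats::filter(pad(v), kern)[(w + 1):(w + nr2)])
      t(apply(t(m2), 2, function(v) stats::filter(pad(v), kern)[(w + 1):(w + nc2)]))
    }
    tex <- blur1(raw)
    tex <- spec$texture_amplitude * (tex - min(tex)) / diff(range(tex)) + 10

    frames <- array(0, dim = c(nr, nc, n_frames))
    for (k in seq_len(n_frames)) {
      left <- margin + 1L - d[k]
      frames[, , k] <- tex[, left:(left + nc - 1L)]
    }

    delta <- diff(d)
    speed <- abs(delta) * spec$frame_rate_hz * spec$pixel_size_um
    # per-pulse peak speed of the applied (rounded) displacement
    pulse_peak_speed <- vapply(pulse_times, function(on) {
      kk <- which(t[-1] >= on & t[-1] <= on + spec$pulse_width_s)
      if (!length(kk)) 0 else max(speed[kk])
    }, numeric(1))
    flags <- list(exceeds_search =
                    any(abs(delta) > spec$search_px_declared))
    structure(list(frames = frames,
                   frame_rate_hz = spec$frame_rate_hz,
                   pixel_size_um = spec$pixel_size_um,
                   truth = list(displacement_px = d,
                                delta_px = delta,
                                speed_um_s = speed,
                                n_pulses = n_pulses,
                                pulse_times_s = pulse_times,
                                pulse_peak_speed_um_s = pulse_peak_speed),
                   flags = flags,
                   spec = spec),
              class = "beating_video")
  })
}
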