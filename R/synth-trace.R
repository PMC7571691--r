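#' Specification for a synthetic paced ratiometric calcium trace
#'
#' Emulates Fura-2 340/380 ratio recordings of field-stimulated
#' cardiomyocytes: a baseline ratio plus one transient per pacing stimulus,
#' each transient the product of a saturating rise and a monoexponential
#' decay, with additive Gaussian noise.
#'
#' @param duration_s trace duration in seconds.
#' @param sample_rate_hz sampling rate; must be at least 20 x `pacing_hz`.
#' @param pacing_hz field-stimulation rate in Hz (default 0.5, the paced
#'   protocol used throughout).
#' @param baseline_ratio diastolic 340/380 ratio.
#' @param amplitude peak ratio increase above baseline per transient.
#' @param tau_rise_s rise time constant in seconds.
#' @param tau_decay_s decay time constant in seconds (the ground-truth
#'   decay tau scored against fitted values).
#' @param noise_sd additive Gaussian noise sd on the ratio.
#' @param seed integer seed.
#' @return an object of class `trace_spec`.
#' @export
calcium_trace_spec <- function(duration_s = 10,
                               sample_rate_hz = 50,
                               pacing_hz = 0.5,
                               baseline_ratio = 1.0,
                               amplitude = 0.5,
                               tau_rise_s = 0.08,
                               tau_decay_s = 0.4,
                               noise_sd = 0.01,
                               seed = 1L) {
  check_scalar(duration_s, "duration_s", 0, strict_lower = TRUE)
  check_scalar(sample_rate_hz, "sample_rate_hz", 0, strict_lower = TRUE)
  check_scalar(pacing_hz, "pacing_hz", 0, strict_lower = TRUE)
  check_scalar(baseline_ratio, "baseline_ratio", 0)
  check_scalar(amplitude, "amplitude", 0)
  check_scalar(tau_rise_s, "tau_rise_s", 0, strict_lower = TRUE)
  check_scalar(tau_decay_s, "tau_decay_s", 0, strict_lower = TRUE)
  check_scalar(noise_sd, "noise_sd", 0)
  if (1 / pacing_hz <= tau_rise_s + tau_decay_s)
    abort(paste("transients overlap: pacing period %.3g s must exceed",
                "tau_rise + tau_decay = %.3g s"),
          1 / pacing_hz, tau_rise_s + tau_decay_s)
  if (sample_rate_hz < 20 * pacing_hz)
    abort("sample_rate_hz must be >= 20 x pacing_hz")
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 pacing_hz = pacing_hz, baseline_ratio = baseline_ratio,
                 amplitude = amplitude, tau_rise_s = tau_rise_s,
                 tau_decay_s = tau_decay_s, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

# Time of the peak of (1 - exp(-t/tr)) * exp(-t/td) after onset.
transient_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * log(1 + tau_decay / tau_rise)
}

# Unit-peak transient shape evaluated at times t >= 0 after onset.
transient_shape <- function(t, tau_rise, tau_decay) {
  s <- (1 - exp(-t / tau_rise)) * exp(-t / tau_decay)
  s[t < 0] <- 0
  tp <- transient_peak_time(tau_rise, tau_decay)
  speak <- (1 - exp(-tp / tau_rise)) * exp(-tp / tau_decay)
  s / speak
}

#' Generate a synthetic paced calcium trace with per-beat ground truth
#'
#' @param spec a [calcium_trace_spec()] object.
#' @return an object of class `calcium_trace`: list with `time_s`, `ratio`,
#'   `pacing_hz`, `stimulus_times_s`, and `truth` (a data frame of per-beat
#'   onset, amplitude, tau_rise, tau_decay and peak time).
#' @export
generate_calcium_trace <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  with_seed(spec$seed, 202L, {
    t <- seq(0, spec$duration_s, by = 1 / spec$sample_rate_hz)
    t <- t[t < spec$duration_s]
    n_beats <- floor(spec$duration_s * spec$pacing_hz)
    onsets <- (seq_len(n_beats) - 1) / spec$pacing_hz
    ratio <- rep(spec$baseline_ratio, length(t))
    for (on in onsets) {
      ratio <- ratio + spec$amplitude *
        transient_shape(t - on, spec$tau_rise_s, spec$tau_decay_s)
    }
    if (spec$noise_sd > 0)
      ratio <- ratio + rnorm(length(t), 0, spec$noise_sd)
    truth <- data.frame(
      beat = seq_len(n_beats),
      onset_s = onsets,
      amplitude = rep(spec$amplitude, n_beats),
      tau_rise_s = rep(spec$tau_rise_s, n_beats),
      tau_decay_s = rep(spec$tau_decay_s, n_beats),
      peak_time_s = onsets +
        transient_peak_time(spec$tau_rise_s, spec$tau_decay_s))
    structure(list(time_s = t, ratio = ratio, pacing_hz = spec$pacing_hz,
                   stimulus_times_s = onsets, truth = truth, spec = spec),
              class = "calcium_trace")
  })
}
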