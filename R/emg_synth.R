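#' Parameters for synthetic stimulus-locked EMG sweeps
#'
#' Describes one synthetic surface-EMG sweep recorded during tonic contraction:
#' band-limited Gaussian background activity at a target RMS (30% MVC level by
#' default), a deterministic biphasic motor evoked potential (MEP) inserted at
#' a fixed latency after the stimulus, and a cortical silent period — the
#' background is attenuated to `silence_floor` from MEP onset until
#' `csp_duration` after MEP offset, then ramps linearly back to full level over
#' `recovery_ramp`. Defaults match the recording and group-mean morphology this
#' package emulates: 8 kHz sampling, 20-250 Hz band, MEP 0.49 mV peak-to-peak
#' and 35 ms duration at 22 ms latency, CSP 106 ms.
#'
#' @param fs Sampling rate in Hz (default 8000).
#' @param duration Sweep length in ms (default 600).
#' @param stim_time Stimulus time within the sweep, ms (default 200).
#' @param tonic_rms Background EMG RMS in mV at the tonic contraction level
#'   (default 0.05).
#' @param mvc_rms Background RMS at maximal contraction, mV (default
#'   `tonic_rms / 0.3`, i.e. the tonic level is 30% MVC).
#' @param band Length-2 numeric, band limits of the background EMG in Hz
#'   (default `c(20, 250)`).
#' @param mep_amp_pp MEP peak-to-peak amplitude, mV (default 0.49).
#' @param mep_duration MEP support, ms (default 35).
#' @param mep_latency Stimulus-to-MEP-onset latency, ms (default 22).
#' @param csp_duration Ground-truth silent period (MEP offset to activity
#'   return), ms (default 106).
#' @param silence_floor Residual background fraction during the silent period
#'   (default 0.02).
#' @param recovery_ramp Linear ramp back to full background, ms (default 10).
#'
#' @return An object of class `emg_params`.
#' @export
emg_params <- function(fs = 8000, duration = 600, stim_time = 200,
                       tonic_rms = 0.05, mvc_rms = tonic_rms / 0.3,
                       band = c(20, 250), mep_amp_pp = 0.49,
                       mep_duration = 35, mep_latency = 22,
                       csp_duration = 106, silence_floor = 0.02,
                       recovery_ramp = 10) {
  p <- list(fs = fs, duration = duration, stim_time = stim_time,
            tonic_rms = tonic_rms, mvc_rms = mvc_rms, band = band,
            mep_amp_pp = mep_amp_pp, mep_duration = mep_duration,
            mep_latency = mep_latency, csp_duration = csp_duration,
            silence_floor = silence_floor, recovery_ramp = recovery_ramp)
  stop_positive_scalar(p$fs, "fs")
  stop_positive_scalar(p$duration, "duration")
  if (length(p$band) != 2L || p$band[1] <= 0 || p$band[1] >= p$band[2]) {
    stop("band must be an ordered positive length-2 numeric (Hz)")
  }
  if (p$fs <= 2 * p$band[2]) {
    stop("fs must exceed twice the band's upper edge")
  }
  for (f in c("mep_duration", "mep_latency", "csp_duration",
              "recovery_ramp")) {
    if (p[[f]] < 0) stop(sprintf("'%s' must be non-negative", f))
  }
  if (p$stim_time + p$mep_latency + p$mep_duration + p$csp_duration >=
      p$duration) {
    stop("stim_time + mep_latency + mep_duration + csp_duration must be < duration")
  }
  if (p$silence_floor < 0 || p$silence_floor > 1) {
    stop("silence_floor must be in [0, 1] (1 disables the silencing)")
  }
  structure(p, class = "emg_params")
}

#' Stimulus-locked EMG sweep container
#'
#' @param samples Numeric vector of EMG samples in mV.
#' @param fs Sampling rate in Hz.
#' @param stim_time Stimulus time within the sweep, ms. Sample `i` is taken to
#'   occur at `(i - 1) / fs * 1000` ms.
#' @param metadata Named list of carried metadata (participant id, pulse
#'   index, stimulation intensity in % rMT, rMT in % maximum stimulator
#'   output, ...). Never enters any computation.
#' @return An object of class `emg_trace`.
#' @export
emg_trace <- function(samples, fs, stim_time, metadata = list()) {
  if (!is.numeric(samples) || !all(is.finite(samples))) {
    stop("samples must be finite numeric")
  }
  stop_positive_scalar(fs, "fs")
  n <- length(samples)
  if (stim_time < 0 || stim_time > (n - 1) / fs * 1000) {
    stop("stim_time must lie within the sweep")
  }
  structure(list(samples = as.numeric(samples), fs = fs,
                 stim_time = stim_time, metadata = metadata),
            class = "emg_trace")
}

# Band-limited Gaussian noise, scaled to an exact target RMS. Uses a 4th-order
# Butterworth band-pass run forward-backward (zero phase); generation padding
# absorbs filter transients.
bandlimited_noise <- function(n, fs, band, rms) {
  pad <- 2000L
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  x <- stats::rnorm(n + 2L * pad)
  y <- signal::filtfilt(bf, x)[(pad + 1L):(pad + n)]
  y * rms / sqrt(mean(y^2))
}

# Deterministic biphasic MEP: sign(sin)*|sin|^shape over one period, scaled to
# an exact peak-to-peak amplitude. The sub-unity exponent gives the steep
# rise/fall of a compound muscle action potential, so the waveform's support
# is sharply delimited relative to threshold detectors.
mep_waveform <- function(n_samples, amp_pp, shape = 0.4) {
  u <- (seq_len(n_samples) - 0.5) / n_samples
  s <- sin(2 * pi * u)
  w <- sign(s) * abs(s)^shape
  if (n_samples < 2L || max(w) == min(w)) return(w * 0)
  w * amp_pp / (max(w) - min(w))
}

#' Synthesize one stimulus-locked EMG sweep with known ground truth
#'
#' Builds a sweep from [emg_params()]: band-limited tonic background at
#' `tonic_rms`, a biphasic MEP of exact peak-to-peak `mep_amp_pp` spanning
#' `[stim_time + mep_latency, + mep_duration]`, and a silent period during
#' which the background is attenuated to `silence_floor`. The background
#' attenuation spans from MEP onset (voluntary activity ceases during the
#' compound potential) to `csp_duration` after MEP offset — the ground-truth
#' silent period itself is the interval from MEP offset to activity return —
#' followed by a linear ramp back over `recovery_ramp`.
#'
#' @param params An [emg_params()].
#' @param seed Integer seed; bit-identical output for identical inputs.
#' @param participant_id,pulse_index Metadata carried on the trace.
#' @param rmt_pct_mso Resting motor threshold metadata (% maximum stimulator
#'   output), carried only.
#' @return A list with `trace` (an [emg_trace()]) and `truth` — a list with
#'   `true_mep_onset`, `true_mep_offset` (ms within sweep), `true_csp` (ms)
#'   and `true_csp_end` (ms within sweep).
#' @examples
#' sw <- synthesize_emg_trial(emg_params(), seed = 1)
#' sw$truth$true_csp
#' @export
synthesize_emg_trial <- function(params, seed, participant_id = "P01",
                                 pulse_index = 1L, rmt_pct_mso = NA_real_) {
  stopifnot(inherits(params, "emg_params"))
  n <- round(params$duration * params$fs / 1000)
  t_ms <- (seq_len(n) - 1) / params$fs * 1000

  m_on <- params$stim_time + params$mep_latency
  m_off <- m_on + params$mep_duration
  c_end <- m_off + params$csp_duration

  noise <- with_seed(seed, bandlimited_noise(n, params$fs, params$band,
                                             params$tonic_rms))
  gain <- rep(1, n)
  gain[t_ms >= m_on & t_ms < c_end] <- params$silence_floor
  ramp <- t_ms >= c_end & t_ms < c_end + params$recovery_ramp
  gain[ramp] <- params$silence_floor +
    (1 - params$silence_floor) * (t_ms[ramp] - c_end) / params$recovery_ramp

  mep <- numeric(n)
  in_mep <- t_ms >= m_on & t_ms < m_off
  if (any(in_mep)) {
    mep[in_mep] <- mep_waveform(sum(in_mep), params$mep_amp_pp)
  }

  trace <- emg_trace(noise * gain + mep, params$fs, params$stim_time,
                     metadata = list(participant_id = participant_id,
                                     pulse_index = pulse_index,
                                     stim_intensity_pct_rmt = 120,
                                     rmt_pct_mso = rmt_pct_mso))
  truth <- list(true_mep_onset = m_on, true_mep_offset = m_off,
                true_csp = params$csp_duration, true_csp_end = c_end)
  list(trace = trace, truth = truth)
}

#' Synthesize a maximal-voluntary-contraction calibration trace
#'
#' Band-limited Gaussian EMG at the maximal-contraction RMS (`params$mvc_rms`),
#' with no stimulus events; used to exercise [compute_mvc()] the way the
#' three 3 s calibration recordings are used in practice.
#'
#' @param params An [emg_params()].
#' @param seed Integer seed.
#' @param duration_ms Trace length in ms (default 3000).
#' @return An [emg_trace()].
#' @export
synthesize_mvc_trial <- function(params, seed, duration_ms = 3000) {
  stopifnot(inherits(params, "emg_params"))
  n <- round(duration_ms * params$fs / 1000)
  x <- with_seed(seed, bandlimited_noise(n, params$fs, params$band,
                                         params$mvc_rms))
  emg_trace(x, params$fs, stim_time = 0,
            metadata = list(kind = "mvc_calibration"))
}
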