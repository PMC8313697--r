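# MEP and cortical-silent-period extraction from stimulus-locked EMG sweeps.
#
# The pipeline per sweep is: rectified moving-average envelope -> pre-stimulus
# baseline statistics -> MEP onset/offset by threshold crossing on the
# rectified raw signal -> silent-period end by sustained return of the
# envelope toward the pre-stimulus level.

#' Configuration for MEP/CSP extraction
#'
#' @param baseline_window Length-2 numeric, window for baseline statistics in
#'   ms relative to the stimulus (default `c(-110, -10)`; half-open, entirely
#'   pre-stimulus).
#' @param smoothing_window Width of the centered moving average applied to the
#'   rectified signal, ms (default 5).
#' @param k_sd Threshold multiplier on the baseline SD (default 2; the
#'   "pre-stimulus level +/- 2 SD" rule).
#' @param artifact_blank Post-stimulus blanking before MEP search, ms
#'   (default 5).
#' @param mep_search_window Length-2 numeric, MEP onset search window in ms
#'   post-stimulus (default `c(10, 60)`).
#' @param mep_dwell Dwell time a threshold crossing must sustain to count as
#'   MEP onset/offset, ms (default 3; suppresses single-cycle noise
#'   excursions and the sub-threshold instant at the biphasic zero crossing).
#' @param sustain Dwell time the envelope must stay at the pre-stimulus level
#'   to count as the end of the silent period, ms (default 10).
#' @param csp_floor_frac Lower floor of the return threshold, as a fraction
#'   of the baseline envelope mean (default 0.25). The nominal threshold is
#'   `baseline_mean - k_sd * baseline_sd`; because a rectified envelope is
#'   nonnegative, a floor of zero would make the return condition vacuous
#'   whenever the baseline SD exceeds half the mean, so the floor is kept at
#'   a fixed fraction of the pre-stimulus level instead.
#' @param contraction_band Length-2 numeric, accepted pre-stimulus contraction
#'   range as a fraction of MVC (default `c(0.2, 0.4)`, i.e. the 30% MVC
#'   requirement with tolerance).
#' @return An object of class `csp_config`.
#' @export
csp_config <- function(baseline_window = c(-110, -10), smoothing_window = 5,
                       k_sd = 2, artifact_blank = 5,
                       mep_search_window = c(10, 60), mep_dwell = 3,
                       sustain = 10, csp_floor_frac = 0.25,
                       contraction_band = c(0.2, 0.4)) {
  cfg <- list(baseline_window = baseline_window,
              smoothing_window = smoothing_window, k_sd = k_sd,
              artifact_blank = artifact_blank,
              mep_search_window = mep_search_window, mep_dwell = mep_dwell,
              sustain = sustain, csp_floor_frac = csp_floor_frac,
              contraction_band = contraction_band)
  if (length(cfg$baseline_window) != 2L ||
      cfg$baseline_window[1] >= cfg$baseline_window[2] ||
      cfg$baseline_window[2] > 0) {
    stop("baseline_window must be ordered and entirely pre-stimulus")
  }
  if (length(cfg$mep_search_window) != 2L ||
      cfg$mep_search_window[1] >= cfg$mep_search_window[2] ||
      cfg$mep_search_window[1] < 0) {
    stop("mep_search_window must be ordered and post-stimulus")
  }
  stop_positive_scalar(cfg$smoothing_window, "smoothing_window")
  stop_positive_scalar(cfg$k_sd, "k_sd")
  if (cfg$sustain < 0 || cfg$mep_dwell < 0 || cfg$artifact_blank < 0) {
    stop("sustain, mep_dwell and artifact_blank must be non-negative")
  }
  if (cfg$csp_floor_frac < 0 || cfg$csp_floor_frac >= 1) {
    stop("csp_floor_frac must be in [0, 1)")
  }
  if (length(cfg$contraction_band) != 2L ||
      cfg$contraction_band[1] >= cfg$contraction_band[2] ||
      cfg$contraction_band[1] < 0) {
    stop("contraction_band must be an ordered non-negative length-2 numeric")
  }
  structure(cfg, class = "csp_config")
}

# sample index of time t (ms within sweep); sample i sits at (i-1)/fs*1000 ms
index_at <- function(t_ms, fs) as.integer(round(t_ms * fs / 1000)) + 1L

time_at <- function(i, fs) (i - 1) / fs * 1000

# half-open window [t0, t1) in ms relative to the stimulus -> sample indices
window_indices <- function(trace, t0, t1) {
  i0 <- index_at(trace$stim_time + t0, trace$fs)
  i1 <- index_at(trace$stim_time + t1, trace$fs) - 1L
  if (i0 < 1L || i1 > length(trace$samples) || i0 > i1) {
    stop("window outside the sweep or empty")
  }
  i0:i1
}

#' Rectified moving-average EMG envelope
#'
#' Full-wave rectification followed by a centered moving average of width
#' `smoothing_window` (rounded to the nearest odd number of samples; partial
#' windows at the sweep edges are renormalized). Same length as the input.
#'
#' @param trace An [emg_trace()].
#' @param config A [csp_config()].
#' @return Numeric vector, the envelope in mV.
#' @export
compute_envelope <- function(trace, config = csp_config()) {
  stopifnot(inherits(trace, "emg_trace"), inherits(config, "csp_config"))
  k <- as.integer(round(config$smoothing_window * trace$fs / 1000))
  if (k %% 2L == 0L) k <- k + 1L
  k <- max(k, 1L)
  moving_average(abs(trace$samples), k)
}

#' Pre-stimulus baseline statistics
#'
#' Mean and SD of the envelope, RMS of the raw signal, and mean and SD of the
#' rectified raw signal, all within the pre-stimulus baseline window. The
#' envelope statistics drive the silent-period return threshold; the
#' rectified-raw statistics drive the MEP threshold (the MEP detector compares
#' the rectified raw signal against statistics of the same quantity).
#'
#' @param trace An [emg_trace()].
#' @param config A [csp_config()].
#' @param envelope Optional precomputed [compute_envelope()] output.
#' @return List with `mean`, `sd` (envelope), `rms` (raw), `rect_mean`,
#'   `rect_sd` (rectified raw), and `n` (samples used).
#' @export
baseline_stats <- function(trace, config = csp_config(), envelope = NULL) {
  stopifnot(inherits(trace, "emg_trace"), inherits(config, "csp_config"))
  if (is.null(envelope)) envelope <- compute_envelope(trace, config)
  idx <- window_indices(trace, config$baseline_window[1],
                        config$baseline_window[2])
  e <- envelope[idx]
  raw <- trace$samples[idx]
  list(mean = mean(e), sd = stats::sd(e), rms = sqrt(mean(raw^2)),
       rect_mean = mean(abs(raw)), rect_sd = stats::sd(abs(raw)),
       n = length(idx))
}

#' Maximal voluntary contraction from calibration traces
#'
#' Splits each trace into non-overlapping 500 ms windows, takes the
#' peak-to-peak amplitude per window, averages within trial, and averages
#' across trials. Reported in microvolts, the conventional unit for this
#' measure. Also reports the mean per-window RMS in mV (`mvc_rms_mv`), the
#' form used to normalize pre-stimulus contraction levels (an RMS must be
#' compared against an RMS, not against a peak-to-peak excursion).
#'
#' @param traces List of [emg_trace()] objects (mV), each at least one window
#'   long.
#' @param window_ms Analysis window, ms (default 500).
#' @return List of class `mvc_result`: `mvc` (uV), `per_trial` (uV),
#'   `mvc_rms_mv` (mV).
#' @export
compute_mvc <- function(traces, window_ms = 500) {
  if (!is.list(traces) || length(traces) == 0L) {
    stop("traces must be a non-empty list of emg_trace objects")
  }
  per <- vapply(traces, function(tr) {
    stopifnot(inherits(tr, "emg_trace"))
    w <- as.integer(round(window_ms * tr$fs / 1000))
    n_win <- length(tr$samples) %/% w
    if (n_win < 1L) stop("trace shorter than one analysis window")
    p2p <- vapply(seq_len(n_win), function(j) {
      seg <- tr$samples[((j - 1L) * w + 1L):(j * w)]
      diff(range(seg))
    }, numeric(1))
    rmsw <- vapply(seq_len(n_win), function(j) {
      seg <- tr$samples[((j - 1L) * w + 1L):(j * w)]
      sqrt(mean(seg^2))
    }, numeric(1))
    c(mean(p2p), mean(rmsw))
  }, numeric(2))
  structure(list(mvc = mean(per[1, ]) * 1000,
                 per_trial = per[1, ] * 1000,
                 mvc_rms_mv = mean(per[2, ])),
            class = "mvc_result")
}

#' Detect the motor evoked potential in one sweep
#'
#' Onset is the first time within the MEP search window (and after the
#' post-stimulus artifact blank) where the rectified raw signal exceeds the
#' rectified-raw baseline mean + `k_sd` x SD and stays above for at least
#' `mep_dwell` ms. Offset is the first time after the rectified-raw peak
#' where the signal falls below the same threshold and stays below for
#' `mep_dwell` ms. Peak-to-peak amplitude is max - min of the raw signal
#' between onset and offset.
#'
#' @param trace An [emg_trace()].
#' @param config A [csp_config()].
#' @param baseline Optional precomputed [baseline_stats()].
#' @return List with `mep_onset`, `mep_offset` (ms within sweep),
#'   `mep_amp_pp` (mV), `mep_duration` (ms).
#' @export
detect_mep <- function(trace, config = csp_config(), baseline = NULL) {
  stopifnot(inherits(trace, "emg_trace"), inherits(config, "csp_config"))
  if (is.null(baseline)) baseline <- baseline_stats(trace, config)
  rect <- abs(trace$samples)
  th <- baseline$rect_mean + config$k_sd * baseline$rect_sd
  dwell <- max(1L, as.integer(round(config$mep_dwell * trace$fs / 1000)))

  s0 <- index_at(trace$stim_time +
                   max(config$artifact_blank, config$mep_search_window[1]),
                 trace$fs)
  s1 <- index_at(trace$stim_time + config$mep_search_window[2], trace$fs)
  s1 <- min(s1, length(rect))
  if (s0 > s1) stop("MEP search window outside the sweep")

  on_i <- first_sustained_run(rect >= th, s0, dwell, s1)
  if (is.na(on_i)) stop("no MEP detected")
  pk <- on_i - 1L + which.max(rect[on_i:s1])
  off_i <- first_sustained_run(rect < th, pk, dwell)
  if (is.na(off_i)) stop("no MEP offset detected")

  list(mep_onset = time_at(on_i, trace$fs),
       mep_offset = time_at(off_i, trace$fs),
       mep_amp_pp = diff(range(trace$samples[on_i:off_i])),
       mep_duration = time_at(off_i, trace$fs) - time_at(on_i, trace$fs))
}

csp_threshold <- function(baseline, config) {
  max(baseline$mean - config$k_sd * baseline$sd,
      config$csp_floor_frac * baseline$mean, 0)
}

#' Detect the end of the cortical silent period
#'
#' The silent period ends at the first time at or after the MEP offset where
#' the envelope has returned to the pre-stimulus level — at least
#' `baseline_mean - k_sd * baseline_sd` (floored at `csp_floor_frac` x
#' baseline mean) — continuously for at least `sustain` ms. The absolute CSP
#' is that time minus the MEP offset.
#'
#' @param trace An [emg_trace()].
#' @param config A [csp_config()].
#' @param mep_offset MEP offset in ms within the sweep (from [detect_mep()]).
#' @param baseline,envelope Optional precomputed intermediates.
#' @return List with `csp_end` (ms within sweep) and `csp_abs` (ms).
#' @export
detect_csp <- function(trace, config = csp_config(), mep_offset,
                       baseline = NULL, envelope = NULL) {
  stopifnot(inherits(trace, "emg_trace"), inherits(config, "csp_config"))
  if (is.null(envelope)) envelope <- compute_envelope(trace, config)
  if (is.null(baseline)) baseline <- baseline_stats(trace, config, envelope)
  th <- csp_threshold(baseline, config)
  sus <- max(1L, as.integer(round(config$sustain * trace$fs / 1000)))
  start_i <- index_at(mep_offset, trace$fs)
  if (start_i < 1L || start_i > length(envelope)) {
    stop("mep_offset outside the sweep")
  }
  end_i <- first_sustained_run(envelope >= th, start_i, sus)
  if (is.na(end_i)) stop("unterminated CSP")
  list(csp_end = time_at(end_i, trace$fs),
       csp_abs = time_at(end_i, trace$fs) - mep_offset)
}

#' Extract all per-pulse features from one sweep
#'
#' Runs baseline statistics, the contraction-level check, MEP detection and
#' CSP detection on one sweep. Rejection is data, not failure: a sweep whose
#' pre-stimulus contraction falls outside `contraction_band` (as a fraction of
#' the MVC RMS), or on which a detector fails, is returned flagged with a
#' reason instead of raising.
#'
#' @param trace An [emg_trace()].
#' @param config A [csp_config()].
#' @param mvc An [mvc_result][compute_mvc()] for the same participant.
#' @return One-row `data.frame` with `mep_amp_pp`, `mep_onset`, `mep_offset`,
#'   `mep_duration`, `csp_end`, `csp_abs`, `baseline_mean`, `baseline_sd`,
#'   `prestim_rms`, `rejected`, `reject_reason`.
#' @export
extract_trial_features <- function(trace, config = csp_config(), mvc) {
  stopifnot(inherits(trace, "emg_trace"), inherits(config, "csp_config"),
            inherits(mvc, "mvc_result"))
  out <- data.frame(
    participant_id = trace$metadata$participant_id %||% NA_character_,
    pulse_index = trace$metadata$pulse_index %||% NA_integer_,
    mep_amp_pp = NA_real_, mep_onset = NA_real_, mep_offset = NA_real_,
    mep_duration = NA_real_, csp_end = NA_real_, csp_abs = NA_real_,
    baseline_mean = NA_real_, baseline_sd = NA_real_, prestim_rms = NA_real_,
    rejected = FALSE, reject_reason = NA_character_,
    stringsAsFactors = FALSE
  )
  reject <- function(reason) {
    out$rejected <- TRUE
    out$reject_reason <- reason
    out
  }
  env <- compute_envelope(trace, config)
  bl <- tryCatch(baseline_stats(trace, config, env), error = function(e) NULL)
  if (is.null(bl)) return(reject("baseline window invalid"))
  out$baseline_mean <- bl$mean
  out$baseline_sd <- bl$sd
  out$prestim_rms <- bl$rms

  ratio <- bl$rms / mvc$mvc_rms_mv
  if (ratio < config$contraction_band[1] || ratio > config$contraction_band[2]) {
    return(reject("contraction out of band"))
  }
  mep <- tryCatch(detect_mep(trace, config, bl), error = function(e) e)
  if (inherits(mep, "error")) return(reject(conditionMessage(mep)))
  out$mep_amp_pp <- mep$mep_amp_pp
  out$mep_onset <- mep$mep_onset
  out$mep_offset <- mep$mep_offset
  out$mep_duration <- mep$mep_duration

  csp <- tryCatch(detect_csp(trace, config, mep$mep_offset, bl, env),
                  error = function(e) e)
  if (inherits(csp, "error")) return(reject(conditionMessage(csp)))
  out$csp_end <- csp$csp_end
  out$csp_abs <- csp$csp_abs
  out
}

#' Summarize per-pulse features for one participant
#'
#' Means of MEP amplitude, MEP duration and absolute CSP over the
#' non-rejected pulses, plus rejection bookkeeping. Invariant to pulse order.
#'
#' @param features `data.frame` of rows from [extract_trial_features()].
#' @return List with `csp`, `mep_amp`, `mep_dur` (means over retained
#'   pulses; NA if none), `n_pulses`, `n_rejected`.
#' @export
summarize_emg <- function(features) {
  stopifnot(is.data.frame(features))
  keep <- features[!features$rejected, , drop = FALSE]
  list(
    csp = if (nrow(keep)) mean(keep$csp_abs) else NA_real_,
    mep_amp = if (nrow(keep)) mean(keep$mep_amp_pp) else NA_real_,
    mep_dur = if (nrow(keep)) mean(keep$mep_duration) else NA_real_,
    n_pulses = nrow(features),
    n_rejected = sum(features$rejected)
  )
}
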