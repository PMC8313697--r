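#' Stop-signal task session design
#'
#' Describes the structure of one stop-signal task session: a practice block
#' followed by experimental blocks, the stop-trial count per block, the
#' maximum allowed reaction time, and the adaptive stop-signal-delay (SSD)
#' staircase (starting value, step, bounds). Defaults reproduce the study
#' design this package models: 1 practice block of 32 trials (8 stop) and
#' 5 experimental blocks of 96 trials (24 stop, i.e. 25%), go stimuli lasting
#' 1 s, SSD starting at 250 ms and moving in 50 ms steps.
#'
#' @param n_practice_trials Trials in the practice block (default 32).
#' @param n_practice_stop Stop trials in the practice block (default 8).
#' @param n_blocks Number of experimental blocks (default 5).
#' @param trials_per_block Trials per experimental block (default 96).
#' @param stop_per_block Stop trials per experimental block (default 24).
#' @param max_rt Maximum reaction time in ms; slower go processes count as
#'   omissions (default 1000).
#' @param ssd_start Initial SSD in ms (default 250).
#' @param ssd_step Staircase step in ms (default 50).
#' @param ssd_bounds Length-2 numeric, SSD clamp bounds in ms (default
#'   `c(0, 900)` so the stop signal stays displayable within the 1 s trial).
#' @param iti Inter-trial interval in ms, carried as metadata only
#'   (default 4000).
#'
#' @return An object of class `sst_design` (a validated list).
#' @examples
#' d <- sst_design()
#' d$ssd_start
#' @export
sst_design <- function(n_practice_trials = 32L, n_practice_stop = 8L,
                       n_blocks = 5L, trials_per_block = 96L,
                       stop_per_block = 24L, max_rt = 1000,
                       ssd_start = 250, ssd_step = 50,
                       ssd_bounds = c(0, 900), iti = 4000) {
  d <- list(
    n_practice_trials = as.integer(n_practice_trials),
    n_practice_stop = as.integer(n_practice_stop),
    n_blocks = as.integer(n_blocks),
    trials_per_block = as.integer(trials_per_block),
    stop_per_block = as.integer(stop_per_block),
    max_rt = max_rt, ssd_start = ssd_start, ssd_step = ssd_step,
    ssd_bounds = ssd_bounds, iti = iti
  )
  if (d$stop_per_block > d$trials_per_block) {
    stop("stop_per_block must not exceed trials_per_block")
  }
  if (d$n_practice_stop > d$n_practice_trials) {
    stop("n_practice_stop must not exceed n_practice_trials")
  }
  if (length(d$ssd_bounds) != 2L || d$ssd_bounds[1] > d$ssd_bounds[2]) {
    stop("ssd_bounds must be an ordered length-2 numeric")
  }
  if (d$ssd_start < d$ssd_bounds[1] || d$ssd_start > d$ssd_bounds[2]) {
    stop("ssd_start must lie within ssd_bounds")
  }
  stop_positive_scalar(d$ssd_step, "ssd_step")
  stop_positive_scalar(d$max_rt, "max_rt")
  structure(d, class = "sst_design")
}

#' Latent participant model for the independent horse race
#'
#' Parameterizes one simulated participant: an ex-Gaussian go-process finish
#' time (`go_mu`, `go_sigma`, `go_tau`), a Gaussian stop-process latency
#' truncated at zero (`stop_mu`, `stop_sigma`), plus lapse probabilities.
#' Go and stop processes race independently; a response is emitted on a stop
#' trial when the go process finishes before SSD + stop latency.
#'
#' Defaults are calibrated to the behavioral table this package emulates:
#' the ex-Gaussian (466, 68, 80) has mean 546 ms and SD 105 ms; `stop_mu`
#' 215 ms matches the group-mean stop latency; `p_omission` and
#' `p_choice_error` reproduce ~2% go omissions and 99.6% go accuracy.
#' `stop_sigma` (trial-to-trial stop variability) is set to 30 ms, a value
#' in the range reported for healthy adults.
#'
#' @param go_mu,go_sigma,go_tau Ex-Gaussian parameters of the go finish time
#'   (ms): Gaussian mean, Gaussian SD, exponential mean.
#' @param stop_mu,stop_sigma Mean and SD (ms) of the stop-process latency,
#'   truncated at 0.
#' @param p_omission Probability of a go-process lapse (no response).
#' @param p_choice_error Probability of responding with the wrong direction.
#' @param p_trigger_failure Probability the stop process fails to launch on a
#'   stop trial (default 0).
#'
#' @return An object of class `behavior_model`.
#' @examples
#' b <- behavior_model()
#' b$go_mu + b$go_tau  # expected mean go RT
#' @export
behavior_model <- function(go_mu = 466, go_sigma = 68, go_tau = 80,
                           stop_mu = 215, stop_sigma = 30,
                           p_omission = 0.015, p_choice_error = 0.004,
                           p_trigger_failure = 0) {
  b <- list(
    go_mu = go_mu, go_sigma = go_sigma, go_tau = go_tau,
    stop_mu = stop_mu, stop_sigma = stop_sigma,
    p_omission = p_omission, p_choice_error = p_choice_error,
    p_trigger_failure = p_trigger_failure
  )
  if (b$go_sigma < 0 || b$stop_sigma < 0 || b$go_tau < 0) {
    stop("go_sigma, go_tau and stop_sigma must be non-negative")
  }
  stop_probability(b$p_omission, "p_omission")
  stop_probability(b$p_choice_error, "p_choice_error")
  stop_probability(b$p_trigger_failure, "p_trigger_failure")
  structure(b, class = "behavior_model")
}
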