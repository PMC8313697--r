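#' Parameters for a simulated study population
#'
#' Describes the sampled cohort: group means and SDs of the true cortical
#' silent period (CSP) and of the true stop-process latency, the target latent
#' correlation between the two, the number of TMS pulses per participant, and
#' the per-participant behavior and session design. Defaults reproduce the
#' study conditions this package emulates: n = 27 participants, CSP
#' 106 +/- 26 ms, stop latency 215 +/- 21 ms, 20 pulses each. The default
#' latent coupling of 0.6 matches the magnitude of the observed CSP-SSRT
#' association the generator is designed to emulate.
#'
#' @param n_participants Cohort size (default 27; minimum 3).
#' @param csp_mean,csp_sd Between-subject mean and SD of the true CSP, ms.
#' @param stoplat_mean,stoplat_sd Between-subject mean and SD of the true
#'   stop-process latency, ms.
#' @param coupling_rho Target latent correlation between true CSP and true
#'   stop latency, in \[-1, 1\] (default 0.6).
#' @param pulses_per_participant TMS pulses (EMG sweeps) per participant
#'   (default 20).
#' @param pulse_jitter_sd Within-subject SD of the per-pulse CSP around the
#'   participant's true CSP, ms (default 8).
#' @param behavior_defaults A [behavior_model()] whose `stop_mu` is replaced
#'   per participant by the sampled true stop latency.
#' @param design An [sst_design()].
#' @param emg An [emg_params()] template for the synthesized sweeps.
#' @return An object of class `population_params`.
#' @export
population_params <- function(n_participants = 27L, csp_mean = 106,
                              csp_sd = 26, stoplat_mean = 215,
                              stoplat_sd = 21, coupling_rho = 0.6,
                              pulses_per_participant = 20L,
                              pulse_jitter_sd = 8,
                              behavior_defaults = behavior_model(),
                              design = sst_design(),
                              emg = emg_params()) {
  p <- list(n_participants = as.integer(n_participants), csp_mean = csp_mean,
            csp_sd = csp_sd, stoplat_mean = stoplat_mean,
            stoplat_sd = stoplat_sd, coupling_rho = coupling_rho,
            pulses_per_participant = as.integer(pulses_per_participant),
            pulse_jitter_sd = pulse_jitter_sd,
            behavior_defaults = behavior_defaults, design = design, emg = emg)
  if (p$n_participants < 3L) {
    stop("n_participants must be at least 3 (correlations undefined below)")
  }
  if (abs(p$coupling_rho) > 1) stop("coupling_rho must lie in [-1, 1]")
  if (p$csp_sd < 0 || p$stoplat_sd < 0 || p$pulse_jitter_sd < 0) {
    stop("csp_sd, stoplat_sd and pulse_jitter_sd must be non-negative")
  }
  stopifnot(inherits(p$behavior_defaults, "behavior_model"),
            inherits(p$design, "sst_design"), inherits(p$emg, "emg_params"))
  structure(p, class = "population_params")
}

#' Draw the latent traits of a simulated cohort
#'
#' Samples, per participant, a latent standard-normal trait `z` and builds
#' `true_csp = csp_mean + csp_sd * (lambda*z + sqrt(1-lambda^2)*eps)` and
#' `true_stop_mu = stoplat_mean + stoplat_sd * (s*lambda*z +
#' sqrt(1-lambda^2)*u)` with `lambda = sqrt(|coupling_rho|)` and the sign `s`
#' of the coupling applied to one loading, so that
#' `cor(true_csp, true_stop_mu) = coupling_rho` in expectation. A resting
#' motor threshold (metadata only, uncorrelated with everything) is drawn per
#' participant from the reported distribution (55% MSO, SD 4).
#'
#' @param pop A [population_params()].
#' @param seed Integer seed.
#' @return A `data.frame` with columns `participant_id`, `latent`,
#'   `true_csp`, `true_stop_mu`, `rmt`.
#' @examples
#' tr <- draw_population_traits(population_params(), seed = 1)
#' cor(tr$true_csp, tr$true_stop_mu)
#' @export
draw_population_traits <- function(pop, seed) {
  stopifnot(inherits(pop, "population_params"))
  with_seed(seed, {
    n <- pop$n_participants
    z <- stats::rnorm(n)
    eps <- stats::rnorm(n)
    u <- stats::rnorm(n)
    lam <- sqrt(abs(pop$coupling_rho))
    s <- if (pop$coupling_rho < 0) -1 else 1
    resid <- sqrt(max(0, 1 - lam^2))
    csp <- pop$csp_mean + pop$csp_sd * (lam * z + resid * eps)
    stop_mu <- pop$stoplat_mean + pop$stoplat_sd * (s * lam * z + resid * u)
    rmt <- stats::rnorm(n, 55, 4)
    data.frame(
      participant_id = sprintf("P%02d", seq_len(n)),
      latent = z,
      true_csp = pmax(csp, 0),
      true_stop_mu = pmax(stop_mu, 0),
      rmt = rmt,
      stringsAsFactors = FALSE
    )
  })
}

#' Generate a full coupled synthetic cohort
#'
#' Draws latent traits with [draw_population_traits()], then gives each
#' participant one simulated stop-signal session (their `behavior_model` uses
#' the sampled true stop latency as `stop_mu`), `pulses_per_participant`
#' synthetic EMG sweeps whose per-pulse ground-truth CSP is Gaussian-jittered
#' around the participant's true CSP (`pulse_jitter_sd`, floored at 0), and
#' three maximal-contraction calibration traces. The global seed is split
#' deterministically per participant, so any participant's data can be
#' regenerated without the others.
#'
#' @param pop A [population_params()].
#' @param seed Integer global seed.
#' @param include_emg,include_mvc Logical; generating sweeps and calibration
#'   traces can be switched off when only behavior is needed.
#' @return A list of class `synthetic_cohort`: `traits` (the trait table) and
#'   `participants`, a list where each element has `id`, `truth` (latent,
#'   true_csp, true_stop_mu, rmt), `session` (trial table), `sweeps` (list of
#'   [emg_trace()]), `sweep_truths` (per-pulse ground truth list) and
#'   `mvc_traces`.
#' @export
generate_population <- function(pop, seed, include_emg = TRUE,
                                include_mvc = include_emg) {
  stopifnot(inherits(pop, "population_params"))
  traits <- draw_population_traits(pop, seed)
  part_seeds <- split_seeds(seed + 1L, pop$n_participants)

  participants <- lapply(seq_len(pop$n_participants), function(i) {
    sub <- split_seeds(part_seeds[i], 2L + pop$pulses_per_participant + 3L)
    behavior <- pop$behavior_defaults
    behavior$stop_mu <- traits$true_stop_mu[i]
    session <- simulate_session(pop$design, behavior, seed = sub[1L],
                                participant_id = traits$participant_id[i])
    sweeps <- NULL
    sweep_truths <- NULL
    if (include_emg) {
      pulse_csp <- with_seed(sub[2L], pmax(
        traits$true_csp[i] +
          stats::rnorm(pop$pulses_per_participant) * pop$pulse_jitter_sd, 0))
      sw <- lapply(seq_len(pop$pulses_per_participant), function(k) {
        pk <- unclass(pop$emg)
        pk$csp_duration <- pulse_csp[k]
        pk <- do.call(emg_params, pk)
        synthesize_emg_trial(pk, seed = sub[2L + k],
                             participant_id = traits$participant_id[i],
                             pulse_index = k, rmt_pct_mso = traits$rmt[i])
      })
      sweeps <- lapply(sw, `[[`, "trace")
      sweep_truths <- lapply(sw, `[[`, "truth")
    }
    mvc_traces <- NULL
    if (include_mvc) {
      mvc_traces <- lapply(1:3, function(k) {
        synthesize_mvc_trial(pop$emg,
                             seed = sub[2L + pop$pulses_per_participant + k])
      })
    }
    list(id = traits$participant_id[i],
         truth = list(latent = traits$latent[i],
                      true_csp = traits$true_csp[i],
                      true_stop_mu = traits$true_stop_mu[i],
                      rmt = traits$rmt[i]),
         session = session, sweeps = sweeps, sweep_truths = sweep_truths,
         mvc_traces = mvc_traces)
  })
  structure(list(traits = traits, participants = participants,
                 pop = pop, seed = seed),
            class = "synthetic_cohort")
}
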