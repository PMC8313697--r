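# Behavioral stop-signal analysis: session descriptives, integration-method
# SSRT, and the consensus participant-exclusion screen.

experimental_trials <- function(trials) {
  if (!is.data.frame(trials)) stop("trials must be a trial table data.frame")
  if ("phase" %in% names(trials)) {
    trials <- trials[trials$phase == "experimental", , drop = FALSE]
  }
  trials
}

#' Estimate SSRT by the integration method with go-omission replacement
#'
#' Builds the go-RT distribution from all experimental go trials — responded
#' trials contribute their RT (choice errors included) and omissions are
#' replaced by the maximum observed go RT — sorts it ascending, and takes the
#' nth value with `n = clamp(round(p_respond_signal * N_go), 1, N_go)` using
#' round-half-away-from-zero. SSRT is that quantile minus the mean SSD over
#' all stop trials.
#'
#' @param trials A trial table (see [simulate_session()]); only experimental
#'   trials enter the estimate.
#' @return SSRT in ms. When `p(respond|signal)` is 0 or 1 the value is still
#'   returned but carries `attr(, "unreliable") = TRUE`.
#' @examples
#' tt <- simulate_session(sst_design(), behavior_model(), seed = 2)
#' estimate_ssrt_integration(tt)
#' @export
estimate_ssrt_integration <- function(trials) {
  tr <- experimental_trials(trials)
  go <- tr[tr$trial_type == "go", , drop = FALSE]
  stop_tr <- tr[tr$trial_type == "stop", , drop = FALSE]
  if (nrow(stop_tr) == 0L) stop("no stop trials: SSRT undefined")
  if (nrow(go) == 0L) stop("no go trials: SSRT undefined")
  responded_go <- !is.na(go$rt_ms)
  if (!any(responded_go)) stop("no responded go trials: SSRT undefined")

  max_go <- max(go$rt_ms[responded_go])
  go_set <- ifelse(responded_go, go$rt_ms, max_go)
  go_sorted <- sort(go_set)
  n_go <- length(go_sorted)

  p_respond <- mean(stop_tr$response != "none")
  idx <- min(max(round_half_away(p_respond * n_go), 1L), n_go)
  ssrt <- go_sorted[idx] - mean(stop_tr$ssd_ms)
  if (p_respond %in% c(0, 1)) attr(ssrt, "unreliable") <- TRUE
  ssrt
}

#' Descriptive statistics of one stop-signal session
#'
#' Computes the seven standard descriptives of a session over its
#' experimental trials: integration-method SSRT, mean SSD (over all stop
#' trials), mean go RT (responded go trials, choice errors included), the
#' probability of responding on a stop trial, the mean RT of go responses on
#' unsuccessful stop trials, the go-omission probability, and go accuracy
#' (correct direction among responded go trials).
#'
#' @param trials A trial table.
#' @return An object of class `sst_summary`: a list with `ssrt`, `mean_ssd`,
#'   `go_rt`, `p_respond_signal`, `s_rt` (NA if no stop trial drew a
#'   response), `miss`, `acc`, `n_go`, `n_stop`.
#' @examples
#' tt <- simulate_session(sst_design(), behavior_model(), seed = 3)
#' s <- summarize_session(tt)
#' c(s$ssrt, s$p_respond_signal)
#' @export
summarize_session <- function(trials) {
  tr <- experimental_trials(trials)
  go <- tr[tr$trial_type == "go", , drop = FALSE]
  stop_tr <- tr[tr$trial_type == "stop", , drop = FALSE]
  if (nrow(stop_tr) == 0L) stop("session has no experimental stop trials")
  if (nrow(go) == 0L) stop("session has no experimental go trials")
  if (anyNA(stop_tr$ssd_ms)) stop("stop trials without an SSD")

  responded_go <- !is.na(go$rt_ms)
  unsucc <- stop_tr$response != "none"
  s_rt <- if (any(unsucc)) mean(stop_tr$rt_ms[unsucc]) else NA_real_

  structure(list(
    ssrt = as.numeric(estimate_ssrt_integration(tr)),
    mean_ssd = mean(stop_tr$ssd_ms),
    go_rt = if (any(responded_go)) mean(go$rt_ms[responded_go]) else NA_real_,
    p_respond_signal = mean(unsucc),
    s_rt = s_rt,
    miss = mean(!responded_go),
    acc = if (any(responded_go)) {
      mean(go$response[responded_go] == go$direction[responded_go])
    } else NA_real_,
    n_go = nrow(go),
    n_stop = nrow(stop_tr)
  ), class = "sst_summary")
}

#' @export
print.sst_summary <- function(x, ...) {
  cat(sprintf(
    paste0("Stop-signal session summary (%d go, %d stop)\n",
           "  SSRT %.1f ms | mean SSD %.1f ms | goRT %.1f ms\n",
           "  p(respond|signal) %.3f | sRT %s ms | miss %.3f | acc %.3f\n"),
    x$n_go, x$n_stop, x$ssrt, x$mean_ssd, x$go_rt, x$p_respond_signal,
    ifelse(is.na(x$s_rt), "NA", sprintf("%.1f", x$s_rt)), x$miss, x$acc))
  invisible(x)
}

#' Apply the consensus participant-exclusion screen
#'
#' Flags a session on any of five criteria (all strict inequalities):
#' (1) probability of responding on stop trials below 40% or above 60%;
#' (2) go-omission probability above 25%; (3) choice-error rate on go trials
#' above 10%; (4) race-model violation — mean RT of go responses on
#' unsuccessful stop trials exceeding mean go RT; (5) SSRT negative or below
#' 50 ms.
#'
#' @param summary An [sst_summary][summarize_session()].
#' @param choice_error_rate Probability of a wrong-direction response among
#'   responded go trials (the complement of `summary$acc`).
#' @return An object of class `exclusion_report`: list with `flags` (named
#'   logicals `c1`..`c5`), `excluded` (any flag), and `values_checked`.
#' @examples
#' tt <- simulate_session(sst_design(), behavior_model(), seed = 4)
#' s <- summarize_session(tt)
#' apply_exclusion_criteria(s, choice_error_rate = 1 - s$acc)$excluded
#' @export
apply_exclusion_criteria <- function(summary, choice_error_rate) {
  stopifnot(inherits(summary, "sst_summary"))
  stop_probability(choice_error_rate, "choice_error_rate")
  flags <- c(
    c1 = summary$p_respond_signal < 0.40 || summary$p_respond_signal > 0.60,
    c2 = summary$miss > 0.25,
    c3 = choice_error_rate > 0.10,
    c4 = !is.na(summary$s_rt) && !is.na(summary$go_rt) &&
      summary$s_rt > summary$go_rt,
    c5 = summary$ssrt < 50
  )
  structure(list(
    flags = flags,
    excluded = any(flags),
    values_checked = list(p_respond_signal = summary$p_respond_signal,
                          miss = summary$miss,
                          choice_error_rate = choice_error_rate,
                          s_rt = summary$s_rt, go_rt = summary$go_rt,
                          ssrt = summary$ssrt)
  ), class = "exclusion_report")
}
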