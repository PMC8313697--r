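#' One step of the adaptive SSD staircase
#'
#' After a successful stop trial (no response) the stop-signal delay becomes
#' harder (SSD + step); after an unsuccessful stop trial (a response escaped)
#' it becomes easier (SSD - step). The result is clamped to the design's SSD
#' bounds. This one-up/one-down rule drives the probability of responding on
#' a stop trial toward 0.5.
#'
#' @param ssd Current SSD in ms; must lie within `design$ssd_bounds`.
#' @param responded_on_stop Logical; `TRUE` if a response was emitted on the
#'   stop trial (unsuccessful stop).
#' @param design An [sst_design()].
#' @return The updated SSD in ms.
#' @examples
#' d <- sst_design()
#' staircase_update(250, responded_on_stop = FALSE, d)  # 300
#' staircase_update(250, responded_on_stop = TRUE, d)   # 200
#' @export
staircase_update <- function(ssd, responded_on_stop, design) {
  stopifnot(inherits(design, "sst_design"))
  if (!is.numeric(ssd) || length(ssd) != 1L || is.na(ssd) ||
      ssd < design$ssd_bounds[1] || ssd > design$ssd_bounds[2]) {
    stop(sprintf("ssd (%s) outside staircase bounds [%g, %g]",
                 format(ssd), design$ssd_bounds[1], design$ssd_bounds[2]))
  }
  stopifnot(is.logical(responded_on_stop), length(responded_on_stop) == 1L)
  new <- if (responded_on_stop) ssd - design$ssd_step else ssd + design$ssd_step
  min(max(new, design$ssd_bounds[1]), design$ssd_bounds[2])
}

# Truncated-at-zero Gaussian draws via the inverse CDF (exact, no rejection).
rtnorm_pos <- function(n, mu, sigma) {
  if (sigma == 0) return(rep(max(mu, 0), n))
  lo <- stats::pnorm(0, mu, sigma)
  stats::qnorm(stats::runif(n, lo, 1), mu, sigma)
}

simulate_block <- function(design, behavior, block, phase, n_trials, n_stop,
                           ssd, participant_id) {
  stop_pos <- sort(sample.int(n_trials, n_stop))
  direction <- sample(c("left", "right"), n_trials, replace = TRUE)
  finish <- behavior$go_mu + stats::rnorm(n_trials) * behavior$go_sigma +
    stats::rexp(n_trials) * behavior$go_tau
  omit <- stats::runif(n_trials) < behavior$p_omission
  cherr <- stats::runif(n_trials) < behavior$p_choice_error

  is_stop <- seq_len(n_trials) %in% stop_pos
  ssd_ms <- rep(NA_real_, n_trials)
  response <- character(n_trials)
  rt_ms <- rep(NA_real_, n_trials)

  flip <- function(dir) if (dir == "left") "right" else "left"
  for (i in seq_len(n_trials)) {
    if (is_stop[i]) {
      ssd_ms[i] <- ssd
      ssl <- rtnorm_pos(1L, behavior$stop_mu, behavior$stop_sigma)
      trig_fail <- stats::runif(1L) < behavior$p_trigger_failure
      responded <- (trig_fail || finish[i] < ssd + ssl) &&
        finish[i] <= design$max_rt
      if (responded) {
        response[i] <- if (cherr[i]) flip(direction[i]) else direction[i]
        rt_ms[i] <- finish[i]
      } else {
        response[i] <- "none"
      }
      ssd <- staircase_update(ssd, responded, design)
    } else {
      responded <- !omit[i] && finish[i] <= design$max_rt
      if (responded) {
        response[i] <- if (cherr[i]) flip(direction[i]) else direction[i]
        rt_ms[i] <- finish[i]
      } else {
        response[i] <- "none"
      }
    }
  }

  correct <- ifelse(is_stop, as.integer(response == "none"),
                    as.integer(response == direction))
  tab <- data.frame(
    participant_id = participant_id,
    block = block,
    trial = seq_len(n_trials),
    phase = phase,
    trial_type = ifelse(is_stop, "stop", "go"),
    direction = direction,
    ssd_ms = ssd_ms,
    response = response,
    rt_ms = rt_ms,
    correct = correct,
    stringsAsFactors = FALSE
  )
  list(table = tab, ssd = ssd)
}

#' Simulate one stop-signal task session under the independent race model
#'
#' Generates a full session (practice block plus experimental blocks) for one
#' simulated participant. On every trial an ex-Gaussian go finish time is
#' drawn; on stop trials it races against SSD + a truncated-Gaussian stop
#' latency, and the SSD then follows the one-up/one-down staircase
#' ([staircase_update()]), carried continuously from the practice block into
#' the experimental blocks. Stop-trial positions are randomized within each
#' block at the design's stop fraction. Go responses slower than
#' `design$max_rt` are recorded as omissions.
#'
#' @param design An [sst_design()].
#' @param behavior A [behavior_model()].
#' @param seed Integer seed; the output is bit-identical for identical inputs.
#' @param participant_id Identifier written into the table (default "P01").
#'
#' @return A trial table (`data.frame`) with columns `participant_id`,
#'   `block` (0 = practice), `trial`, `phase` (`"practice"|"experimental"`),
#'   `trial_type` (`"go"|"stop"`), `direction`, `ssd_ms` (NA on go trials),
#'   `response` (`"left"|"right"|"none"`), `rt_ms` (NA when no response) and
#'   `correct` (0/1).
#' @examples
#' tt <- simulate_session(sst_design(), behavior_model(), seed = 1)
#' table(tt$phase, tt$trial_type)
#' @export
simulate_session <- function(design, behavior, seed, participant_id = "P01") {
  stopifnot(inherits(design, "sst_design"), inherits(behavior, "behavior_model"))
  with_seed(seed, {
    ssd <- design$ssd_start
    blocks <- vector("list", design$n_blocks + 1L)
    if (design$n_practice_trials > 0L) {
      pr <- simulate_block(design, behavior, 0L, "practice",
                           design$n_practice_trials, design$n_practice_stop,
                           ssd, participant_id)
      blocks[[1L]] <- pr$table
      ssd <- pr$ssd
    }
    for (b in seq_len(design$n_blocks)) {
      bl <- simulate_block(design, behavior, b, "experimental",
                           design$trials_per_block, design$stop_per_block,
                           ssd, participant_id)
      blocks[[b + 1L]] <- bl$table
      ssd <- bl$ssd
    }
    do.call(rbind, blocks[!vapply(blocks, is.null, logical(1))])
  })
}
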