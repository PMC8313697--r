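# Independent brute-force oracles and small fixture builders. These never
# share code with the implementation paths they check.

# Build a trial table row by row. Stop trials are marked by a non-NA ssd.
make_trials <- function(rt, ssd = rep(NA_real_, length(rt)),
                        direction = rep("left", length(rt)),
                        response = NULL, phase = "experimental",
                        participant_id = "T01") {
  n <- length(rt)
  trial_type <- ifelse(is.na(ssd), "go", "stop")
  if (is.null(response)) {
    response <- ifelse(is.na(rt), "none", direction)
  }
  correct <- ifelse(trial_type == "stop", as.integer(response == "none"),
                    as.integer(response == direction))
  data.frame(participant_id = participant_id, block = 1L, trial = seq_len(n),
             phase = phase, trial_type = trial_type, direction = direction,
             ssd_ms = ssd, response = response, rt_ms = rt, correct = correct,
             stringsAsFactors = FALSE)
}

# Exhaustive sample-by-sample scan for the silent-period end: first index at
# or after start_i where the envelope stays >= th for at least sus samples.
oracle_csp_scan <- function(envelope, start_i, th, sus) {
  n <- length(envelope)
  i <- start_i
  while (i + sus - 1L <= n) {
    if (all(envelope[i:(i + sus - 1L)] >= th)) return(i)
    i <- i + 1L
  }
  NA_integer_
}

# Plain-loop reimplementation of the projection-based outlier rule (MCD
# center + MAD-median cutoff, union over projections).
oracle_skipped_outliers <- function(x, y) {
  pts <- cbind(x, y)
  center <- tryCatch(MASS::cov.rob(pts, method = "mcd")$center,
                     error = function(e) apply(pts, 2, median))
  cutoff <- sqrt(qchisq(0.975, df = 2))
  n <- length(x)
  flagged <- rep(FALSE, n)
  for (i in seq_len(n)) {
    dx <- pts[i, 1] - center[1]
    dy <- pts[i, 2] - center[2]
    nd <- sqrt(dx^2 + dy^2)
    if (nd == 0) next
    s <- numeric(n)
    for (j in seq_len(n)) {
      s[j] <- ((pts[j, 1] - center[1]) * dx + (pts[j, 2] - center[2]) * dy) / nd
    }
    med <- median(s)
    madn <- mad(s)
    if (madn == 0) next
    for (j in seq_len(n)) {
      if (abs(s[j] - med) / madn > cutoff) flagged[j] <- TRUE
    }
  }
  which(flagged)
}

# Leave-one-out predictions by explicitly refitting lm() per fold.
oracle_loocv <- function(x, y) {
  n <- length(x)
  pred <- numeric(n)
  for (i in seq_len(n)) {
    fit <- lm(yy ~ xx, data = data.frame(xx = x[-i], yy = y[-i]))
    pred[i] <- predict(fit, newdata = data.frame(xx = x[i]))
  }
  pred
}

default_mvc <- function(seed = 99) {
  compute_mvc(lapply(1:3, function(k) {
    synthesize_mvc_trial(emg_params(), seed = seed + k)
  }))
}
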