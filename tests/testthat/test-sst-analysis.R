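test_that("session summary matches hand-computed descriptives", {
  tt <- make_trials(
    rt = c(500, 520, 540, 560, 480, NA),
    ssd = c(NA, NA, NA, NA, 250, 300)
  )
  s <- summarize_session(tt)
  expect_equal(s$go_rt, 530)
  expect_equal(s$p_respond_signal, 0.5)
  expect_equal(s$mean_ssd, 275)
  expect_equal(s$s_rt, 480)
  expect_equal(s$miss, 0)
  expect_equal(s$acc, 1.0)
  expect_equal(s$n_go, 4L)
  expect_equal(s$n_stop, 2L)
  # exactly the seven descriptives plus the two counts
  expect_named(unclass(s), c("ssrt", "mean_ssd", "go_rt", "p_respond_signal",
                             "s_rt", "miss", "acc", "n_go", "n_stop"))
})

test_that("summary errors name the missing trial class", {
  all_go <- make_trials(rt = c(500, 520, 540))
  expect_error(summarize_session(all_go), "stop trials")
  all_stop <- make_trials(rt = c(NA, NA), ssd = c(250, 300))
  expect_error(summarize_session(all_stop), "go trials")
})

test_that("integration SSRT follows the quantile-minus-mean-SSD rule", {
  # 10 go RTs, p(respond|signal) = 0.5 -> 5th sorted value 550, mean SSD 300
  go_rts <- seq(350, 800, by = 50)
  tt <- make_trials(rt = c(go_rts, 400, NA),
                    ssd = c(rep(NA, 10), 300, 300))
  expect_equal(estimate_ssrt_integration(tt), 550 - 300)

  # omission replaced by the max go RT: set {400, 500, 500}; p = 2/3 ->
  # index round(2) = 2 -> 500; minus mean SSD 200
  tt2 <- make_trials(rt = c(400, NA, 500, 450, 460, NA),
                     ssd = c(NA, NA, NA, 200, 250, 150))
  expect_equal(estimate_ssrt_integration(tt2), 500 - 200)
})

test_that("degenerate go distribution returns max minus mean SSD", {
  tt <- make_trials(rt = c(600, 600, 600, 600, 550, NA),
                    ssd = c(rep(NA, 4), 220, 280))
  expect_equal(estimate_ssrt_integration(tt), 600 - 250)
})

test_that("extreme stopping rates are flagged unreliable", {
  tt <- make_trials(rt = c(500, 520, NA, NA), ssd = c(NA, NA, 250, 300))
  est <- estimate_ssrt_integration(tt)
  expect_true(isTRUE(attr(est, "unreliable")))
  tt_resp <- make_trials(rt = c(500, 520, 480, 470), ssd = c(NA, NA, 250, 300))
  expect_true(isTRUE(attr(estimate_ssrt_integration(tt_resp), "unreliable")))
})

test_that("max-replacement of omissions never lowers the estimate", {
  # replacing omissions with the max go RT is order-preserving: against the
  # same table with omissions imputed at the median go RT, SSRT can only be
  # larger or equal (same p(respond|signal), same SSDs)
  set.seed(21)
  for (rep in 1:20) {
    n_go <- 40L
    rts <- round(rnorm(n_go, 550, 100))
    omit <- runif(n_go) < 0.2
    rt_max <- ifelse(omit, NA, rts)
    rt_med <- ifelse(omit, median(rts[!omit]), rts)
    ssd <- c(250, 300, 350, 300)
    stop_rt <- c(480, NA, 470, NA)
    t_max <- make_trials(rt = c(rt_max, stop_rt),
                         ssd = c(rep(NA, n_go), ssd))
    t_med <- make_trials(rt = c(rt_med, stop_rt),
                         ssd = c(rep(NA, n_go), ssd))
    expect_gte(estimate_ssrt_integration(t_max),
               estimate_ssrt_integration(t_med))
  }
})

test_that("exclusion criteria are the five printed strict inequalities", {
  tt <- make_trials(rt = c(500, 520, 540, 560, 480, NA),
                    ssd = c(NA, NA, NA, NA, 250, 300))
  s <- summarize_session(tt)

  s1 <- s; s1$p_respond_signal <- 0.35
  r1 <- apply_exclusion_criteria(s1, 0)
  expect_true(r1$flags[["c1"]]); expect_true(r1$excluded)

  s2 <- s; s2$p_respond_signal <- 0.40  # boundary: strict inequality
  s2$ssrt <- 200
  r2 <- apply_exclusion_criteria(s2, 0)
  expect_false(r2$flags[["c1"]])

  s3 <- s; s3$s_rt <- 560; s3$go_rt <- 546; s3$ssrt <- 200
  r3 <- apply_exclusion_criteria(s3, 0)
  expect_true(r3$flags[["c4"]])

  s4 <- s; s4$ssrt <- 30
  expect_true(apply_exclusion_criteria(s4, 0)$flags[["c5"]])
  s5 <- s; s5$ssrt <- -10
  expect_true(apply_exclusion_criteria(s5, 0)$flags[["c5"]])

  s6 <- s; s6$miss <- 0.30; s6$ssrt <- 200
  expect_true(apply_exclusion_criteria(s6, 0)$flags[["c2"]])
  expect_true(apply_exclusion_criteria(s6, 0.15)$flags[["c3"]])
  expect_false(apply_exclusion_criteria(s2, 0.10)$flags[["c3"]])

  # excluded <=> any flag
  nominal <- apply_exclusion_criteria(s2, 0)
  expect_equal(nominal$excluded, any(nominal$flags))
  expect_false(nominal$excluded)
})

test_that("integration estimate recovers the latent stop latency", {
  big <- sst_design(n_practice_trials = 0L, n_practice_stop = 0L,
                    n_blocks = 5L, trials_per_block = 800L,
                    stop_per_block = 200L)
  err <- vapply(1:5, function(s) {
    tt <- simulate_session(big, behavior_model(), seed = 600 + s)
    estimate_ssrt_integration(tt) - 215
  }, numeric(1))
  expect_lte(median(abs(err)), 10)
})

test_that("shifting the stop process shifts the estimate by the same amount", {
  big <- sst_design(n_practice_trials = 0L, n_practice_stop = 0L,
                    n_blocks = 5L, trials_per_block = 800L,
                    stop_per_block = 200L)
  shift <- vapply(1:5, function(s) {
    base <- estimate_ssrt_integration(
      simulate_session(big, behavior_model(stop_mu = 215), seed = 700 + s))
    up <- estimate_ssrt_integration(
      simulate_session(big, behavior_model(stop_mu = 255), seed = 700 + s))
    up - base
  }, numeric(1))
  expect_lte(median(abs(shift - 40)), 10)
})

test_that("the default cohort is rarely excluded by the screen", {
  rates <- vapply(1:15, function(s) {
    cohort <- generate_population(population_params(), seed = 800 + s,
                                  include_emg = FALSE)
    excl <- vapply(cohort$participants, function(p) {
      su <- summarize_session(p$session)
      tr <- p$session[p$session$phase == "experimental" &
                        p$session$trial_type == "go" &
                        !is.na(p$session$rt_ms), ]
      cer <- mean(tr$response != tr$direction)
      apply_exclusion_criteria(su, cer)$excluded
    }, logical(1))
    mean(excl)
  }, numeric(1))
  expect_lte(mean(rates), 2 / 27)
})
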