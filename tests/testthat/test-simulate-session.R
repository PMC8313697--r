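test_that("a default session has the designed trial counts and phases", {
  tt <- simulate_session(sst_design(), behavior_model(), seed = 101)
  exp <- tt[tt$phase == "experimental", ]
  pr <- tt[tt$phase == "practice", ]
  expect_equal(nrow(exp), 480L)
  expect_equal(sum(exp$trial_type == "stop"), 120L)
  expect_equal(nrow(pr), 32L)
  expect_equal(sum(pr$trial_type == "stop"), 8L)
  expect_equal(sum(exp$trial_type == "stop") / nrow(exp), 0.25)
  # per-block stop counts are exact, not just on average
  for (b in 1:5) {
    expect_equal(sum(exp$block == b & exp$trial_type == "stop"), 24L)
  }
})

test_that("trial records respect the task contract", {
  tt <- simulate_session(sst_design(), behavior_model(), seed = 102)
  expect_true(all(is.na(tt$ssd_ms[tt$trial_type == "go"])))
  expect_true(all(!is.na(tt$ssd_ms[tt$trial_type == "stop"])))
  expect_true(all(tt$ssd_ms[tt$trial_type == "stop"] >= 0))
  expect_true(all(tt$ssd_ms[tt$trial_type == "stop"] <= 900))
  responded <- tt$response != "none"
  expect_true(all(!is.na(tt$rt_ms[responded])))
  expect_true(all(tt$rt_ms[responded] <= 1000))
  expect_true(all(is.na(tt$rt_ms[!responded])))
})

test_that("identical seed and parameters give a bit-identical session", {
  a <- simulate_session(sst_design(), behavior_model(), seed = 103)
  b <- simulate_session(sst_design(), behavior_model(), seed = 103)
  expect_identical(a, b)
  c <- simulate_session(sst_design(), behavior_model(), seed = 104)
  expect_false(identical(a, c))
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(42)
  before <- runif(3)
  set.seed(42)
  invisible(simulate_session(sst_design(), behavior_model(), seed = 7))
  after <- runif(3)
  expect_identical(before, after)
})

test_that("race-model ordering holds: unsuccessful-stop RTs are faster than go RTs", {
  hits <- vapply(1:30, function(s) {
    tt <- simulate_session(sst_design(), behavior_model(), seed = 200 + s)
    exp <- tt[tt$phase == "experimental", ]
    s_rt <- mean(exp$rt_ms[exp$trial_type == "stop" & exp$response != "none"])
    go_rt <- mean(exp$rt_ms[exp$trial_type == "go" & exp$response != "none"])
    s_rt < go_rt
  }, logical(1))
  expect_true(all(hits))
})

test_that("race ordering also holds with a deterministic stop process", {
  b <- behavior_model(stop_sigma = 0)
  tt <- simulate_session(sst_design(), b, seed = 301)
  exp <- tt[tt$phase == "experimental", ]
  s_rt <- mean(exp$rt_ms[exp$trial_type == "stop" & exp$response != "none"])
  go_rt <- mean(exp$rt_ms[exp$trial_type == "go" & exp$response != "none"])
  expect_lt(s_rt, go_rt)
})

test_that("the staircase holds stopping success near one half per session", {
  p <- vapply(1:30, function(s) {
    tt <- simulate_session(sst_design(), behavior_model(), seed = 400 + s)
    exp <- tt[tt$phase == "experimental", ]
    mean(exp$response[exp$trial_type == "stop"] != "none")
  }, numeric(1))
  expect_gte(mean(p >= 0.42 & p <= 0.58), 0.95)
  expect_lt(abs(mean(p) - 0.5), 0.03)
})

test_that("trigger failures drag the staircase toward very short SSDs", {
  # with half the stop processes never launching, responses escape on half the
  # stop trials regardless of SSD, so the staircase must compensate by making
  # the remaining stops very easy
  mean_ssd <- function(b, seeds) {
    mean(vapply(seeds, function(s) {
      tt <- simulate_session(sst_design(), b, seed = 500 + s)
      exp <- tt[tt$phase == "experimental", ]
      mean(exp$ssd_ms[exp$trial_type == "stop"])
    }, numeric(1)))
  }
  ssd_tf <- mean_ssd(behavior_model(p_trigger_failure = 0.5), 1:5)
  ssd_default <- mean_ssd(behavior_model(), 1:5)
  expect_lt(ssd_tf, ssd_default - 150)
})
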