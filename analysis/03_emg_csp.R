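#!/usr/bin/env Rscript
# Step 3: MEP and cortical-silent-period extraction.
#
# Regenerates the cohort's EMG deterministically (same seed as step 1),
# extracts per-pulse MEP amplitude/duration and absolute CSP with the
# pre-stimulus +/- 2 SD return rule, and checks detector accuracy against the
# injected ground truth. Writes per-pulse features and per-participant EMG
# summaries.

suppressPackageStartupMessages(library(stopcsp))

seed <- 20260925
out_dir <- "results/emg"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pop <- population_params()
cohort <- generate_population(pop, seed = seed)
cfg <- csp_config()

feats <- list()
summaries <- list()
for (p in cohort$participants) {
  mvc <- compute_mvc(p$mvc_traces)
  f <- do.call(rbind, lapply(p$sweeps, extract_trial_features,
                             config = cfg, mvc = mvc))
  f$true_csp <- vapply(p$sweep_truths, `[[`, numeric(1), "true_csp")
  s <- summarize_emg(f)
  feats[[p$id]] <- f
  summaries[[p$id]] <- data.frame(
    participant_id = p$id, csp = s$csp, mep_amp = s$mep_amp,
    mep_dur = s$mep_dur, rmt = p$truth$rmt, n_pulses = s$n_pulses,
    n_rejected = s$n_rejected, true_csp = p$truth$true_csp,
    mvc_uv = mvc$mvc, stringsAsFactors = FALSE)
}
feats <- do.call(rbind, c(feats, make.row.names = FALSE))
summaries <- do.call(rbind, c(summaries, make.row.names = FALSE))

utils::write.csv(feats, file.path(out_dir, "pulse_features.csv"),
                 row.names = FALSE)
utils::write.csv(summaries, file.path(out_dir, "participant_emg.csv"),
                 row.names = FALSE)

ok <- !feats$rejected
err <- feats$csp_abs[ok] - feats$true_csp[ok]
fit <- lm(feats$csp_abs[ok] ~ feats$true_csp[ok])
cat(sprintf("pulses: %d analyzed, %d rejected\n", sum(ok), sum(!ok)))
cat(sprintf("grand-mean CSP %.1f ms | MEP %.3f mV, %.1f ms\n",
            mean(feats$csp_abs[ok]), mean(feats$mep_amp_pp[ok]),
            mean(feats$mep_duration[ok])))
cat(sprintf("detector vs truth: median |error| %.2f ms, slope %.3f\n",
            median(abs(err)), coef(fit)[2]))
cat(sprintf("participant-mean CSP vs true CSP: r = %.3f\n",
            cor(summaries$csp, summaries$true_csp)))
cat("written:", file.path(out_dir, c("pulse_features.csv",
                                     "participant_emg.csv")), "\n")
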