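#!/usr/bin/env Rscript
# Step 1: generate the synthetic study cohort.
#
# 27 participants, each with one adaptive stop-signal session (5 x 96 trials,
# 25% stop, staircased SSD) and 20 stimulus-locked EMG sweeps with known
# MEP/CSP ground truth, coupled through a latent trait (rho = 0.6) linking
# true CSP to true stop latency. Writes the trial tables, the ground-truth
# trait table and two example sweeps under results/synthetic/.

suppressPackageStartupMessages(library(stopcsp))

seed <- 20260925
out_dir <- "results/synthetic"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

pop <- population_params()   # n = 27, coupling 0.6, 20 pulses each
cohort <- generate_population(pop, seed = seed, include_emg = FALSE)

trials <- do.call(rbind, lapply(cohort$participants, `[[`, "session"))
write_trial_table(trials, file.path(out_dir, "trials.csv"))
utils::write.csv(cohort$traits, file.path(out_dir, "traits_ground_truth.csv"),
                 row.names = FALSE)

# two example sweeps (the full EMG set is regenerated deterministically by
# step 3; sweeps are bulky, ground truth is not)
ex <- synthesize_emg_trial(pop$emg, seed = seed + 1L,
                           participant_id = "example", pulse_index = 1L)
write_emg_sweep(ex$trace, file.path(out_dir, "example_sweep_01.csv"))
ex0 <- synthesize_emg_trial(emg_params(silence_floor = 0, csp_duration = 120),
                            seed = seed + 2L,
                            participant_id = "example", pulse_index = 2L)
write_emg_sweep(ex0$trace, file.path(out_dir, "example_sweep_02_noiseless_csp.csv"))

exp_tr <- trials[trials$phase == "experimental", ]
cat(sprintf("cohort: %d participants, %d experimental trials (%d stop, %.0f%%)\n",
            pop$n_participants, nrow(exp_tr),
            sum(exp_tr$trial_type == "stop"),
            100 * mean(exp_tr$trial_type == "stop")))
cat(sprintf("latent coupling %.2f; sample cor(true CSP, true stop latency) = %.3f\n",
            pop$coupling_rho,
            cor(cohort$traits$true_csp, cohort$traits$true_stop_mu)))
cat("written:", file.path(out_dir, c("trials.csv", "traits_ground_truth.csv")),
    "\n")
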