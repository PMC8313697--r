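#!/usr/bin/env Rscript
# Step 2: behavioral analysis of the stop-signal sessions.
#
# Reads the trial tables written by step 1, computes each participant's
# descriptives and integration-method SSRT, applies the five-criterion
# exclusion screen, and writes the per-participant table plus the group
# means +/- SDs (the Table-1 analogue of this synthetic study).

suppressPackageStartupMessages(library(stopcsp))

in_csv <- "results/synthetic/trials.csv"
out_dir <- "results/behavior"
if (!file.exists(in_csv)) stop("run analysis/01_simulate.R first")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

trials <- read_trial_table(in_csv)

rows <- lapply(split(trials, trials$participant_id), function(tt) {
  s <- summarize_session(tt)
  go <- tt[tt$phase == "experimental" & tt$trial_type == "go" &
             !is.na(tt$rt_ms), ]
  cer <- if (nrow(go)) mean(go$response != go$direction) else 0
  ex <- apply_exclusion_criteria(s, cer)
  data.frame(participant_id = tt$participant_id[1], ssrt = s$ssrt,
             mean_ssd = s$mean_ssd, go_rt = s$go_rt,
             p_respond_signal = s$p_respond_signal, s_rt = s$s_rt,
             miss = s$miss, acc = s$acc, choice_error_rate = cer,
             excluded = ex$excluded,
             flags = paste(names(ex$flags)[ex$flags], collapse = ";"),
             stringsAsFactors = FALSE)
})
per <- do.call(rbind, rows)
utils::write.csv(per, file.path(out_dir, "participant_summaries.csv"),
                 row.names = FALSE)

keep <- per[!per$excluded, ]
meas <- c("ssrt", "mean_ssd", "go_rt", "p_respond_signal", "s_rt", "miss", "acc")
group <- data.frame(
  measure = meas,
  mean = vapply(meas, function(m) mean(keep[[m]], na.rm = TRUE), numeric(1)),
  sd = vapply(meas, function(m) sd(keep[[m]], na.rm = TRUE), numeric(1)),
  row.names = NULL)
utils::write.csv(group, file.path(out_dir, "group_descriptives.csv"),
                 row.names = FALSE)

cat(sprintf("%d of %d participants retained (%d excluded)\n",
            nrow(keep), nrow(per), sum(per$excluded)))
cat("group descriptives (retained participants):\n")
print(transform(group, mean = round(mean, 3), sd = round(sd, 3)),
      row.names = FALSE)
cat("written:", file.path(out_dir, c("participant_summaries.csv",
                                     "group_descriptives.csv")), "\n")
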