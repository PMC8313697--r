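#!/usr/bin/env Rscript
# Step 4: brain-behavior inference.
#
# Joins the behavioral SSRTs (step 2) with the EMG summaries (step 3) and
# runs the inference chain on retained participants: four Pearson
# correlations (CSP, rMT, MEP amplitude, MEP duration vs SSRT) against a
# Bonferroni-adjusted alpha, the skipped (robust) Pearson correlation with a
# 2000-resample percentile bootstrap for the CSP-SSRT pair, and the
# leave-one-out cross-validation permutation test (5000 shuffles).

suppressPackageStartupMessages(library(stopcsp))

seed <- 20260925
beh_csv <- "results/behavior/participant_summaries.csv"
emg_csv <- "results/emg/participant_emg.csv"
if (!file.exists(beh_csv) || !file.exists(emg_csv)) {
  stop("run analysis/02_behavior.R and analysis/03_emg_csp.R first")
}
out_dir <- "results/inference"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

beh <- utils::read.csv(beh_csv, stringsAsFactors = FALSE)
emg <- utils::read.csv(emg_csv, stringsAsFactors = FALSE)
dat <- merge(beh, emg, by = "participant_id")
keep <- dat[!dat$excluded & !is.na(dat$csp), ]
cat(sprintf("%d of %d participants enter inference\n", nrow(keep), nrow(dat)))

screen <- pearson_family(
  list(csp = keep$csp, rmt = keep$rmt, mep_amp = keep$mep_amp,
       mep_dur = keep$mep_dur),
  keep$ssrt, alpha = 0.05)
cat("\nPearson screen vs SSRT (Bonferroni-adjusted alpha 0.0125):\n")
print(transform(screen, r = round(r, 3), p = signif(p, 3),
                ci_lo = round(ci_lo, 3), ci_hi = round(ci_hi, 3)),
      row.names = FALSE)

sk <- skipped_pearson(keep$csp, keep$ssrt, n_boot = 2000L, seed = seed)
cat("\n"); print(sk)

cv <- loocv_permutation_test(keep$csp, keep$ssrt, n_perm = 5000L, seed = seed)
print(cv)

utils::write.csv(screen, file.path(out_dir, "pearson_screen.csv"),
                 row.names = FALSE)
report <- list(
  n_analyzed = nrow(keep),
  pearson = screen,
  skipped = list(r = sk$r, p = sk$p, ci = sk$ci, n_boot = sk$n_boot,
                 outlier_indices = sk$outlier_indices),
  loocv = list(r_pred_obs = cv$r_pred_obs, p_perm = cv$p_perm,
               n_perm = cv$n_perm),
  seed = seed
)
jsonlite::write_json(report, file.path(out_dir, "inference_report.json"),
                     auto_unbox = TRUE, digits = NA, na = "null")
cat("\nwritten:", file.path(out_dir, c("pearson_screen.csv",
                                       "inference_report.json")), "\n")
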