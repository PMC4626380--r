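#!/usr/bin/env Rscript
# Simulate the synthetic study cohort and write it to disk.
#
# Every downstream step reads the files written here, so the whole
# analysis is reproducible from this script alone. The generator draws a
# healthy middle-aged population (ages 35-56, both sexes) with known
# per-subject ground truth and realistic measurement noise on both
# channels (tonometry-calibrated carotid-type pressure, Doppler-like
# zero-diastole flow).

suppressMessages(library(hemowave))

out_dir <- "results/cohort"
cfg <- cohort_config(n = 120, seed = 2026)

message("Simulating ", cfg$n, " subjects (seed ", cfg$seed, ") ...")
coh <- simulate_cohort(cfg, dir = out_dir)

gt <- coh$truth
message(sprintf("  %d male / %d female, ages %d-%d",
                sum(gt$sex == "male"), sum(gt$sex == "female"),
                min(gt$age), max(gt$age)))
message(sprintf("  MAP %.1f (%.1f) mmHg, HR %.1f (%.1f) bpm, SV %.1f (%.1f) ml",
                mean(gt$map), sd(gt$map), mean(gt$hr), sd(gt$hr),
                mean(gt$sv), sd(gt$sv)))
message(sprintf("  true Zc %.3f (%.3f) mmHg*s/ml, SVR %.2f (%.2f), reflection %.2f (%.2f)",
                mean(gt$zc), sd(gt$zc), mean(gt$svr), sd(gt$svr),
                mean(gt$gamma), sd(gt$gamma)))
message("Cohort written to ", out_dir)
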