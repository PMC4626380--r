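#!/usr/bin/env Rscript
# Method comparison between the two arms.
#
# Bland-Altman agreement (model minus measured), Pearson correlation and
# the regression line per parameter; agreement with the generator ground
# truth; PWV comparison against the simulated carotid-femoral reference
# with its validation-society grading; subgroup means by age quartile and
# sex.

suppressMessages(library(hemowave))

coh <- read_cohort("results/cohort")
meas <- utils::read.csv("results/measured_arm.csv")
mod <- utils::read.csv("results/model_arm.csv")

params <- c("zc", "sv", "svr", "rm", "pf_amp", "pb_amp")
ba <- compare_arms(meas, mod, params)
utils::write.csv(ba, "results/comparison_arms.csv", row.names = FALSE)
message("Model arm vs measured arm (difference = model - measured):")
print(format(as.data.frame(ba)[, c("parameter", "mean_a", "mean_b",
                                   "mean_diff", "sd_diff", "loa_low",
                                   "loa_high", "pearson_r")], digits = 3),
      row.names = FALSE)

# agreement with generator ground truth
gt <- coh$truth
rel <- function(est, tru) stats::median(abs(est - tru) / abs(tru)) * 100
message(sprintf(paste0("\nMedian |relative error| vs ground truth:\n",
                       "  measured arm: Zc %.1f%%, SVR %.1f%%, SV %.1f%%, RM %.1f%%\n",
                       "  model arm:    Zc %.1f%%, SVR %.1f%%, SV %.1f%%, RM %.1f%%"),
                rel(meas$zc, gt$zc), rel(meas$svr, gt$svr),
                rel(meas$sv, gt$sv), rel(meas$rm, gt$rm),
                rel(mod$zc, gt$zc), rel(mod$svr, gt$svr),
                rel(mod$sv, gt$sv), rel(mod$rm, gt$rm)))

# PWV vs the simulated carotid-femoral reference
cf <- vapply(coh$subjects, `[[`, numeric(1), "cfpwv_ms")
pwv_ba <- bland_altman(cf, mod$pwv, parameter = "pwv_vs_cf")
grade <- artery_rating(pwv_ba$mean_diff, pwv_ba$sd_diff)
message(sprintf("\nPWV model vs reference: diff %.2f (%.2f SD) m/s, r = %.2f -> %s",
                pwv_ba$mean_diff, pwv_ba$sd_diff, pwv_ba$pearson_r, grade))
utils::write.csv(pwv_ba, "results/comparison_pwv.csv", row.names = FALSE)

# subgroup summaries by age quartile and sex (both arms)
sub_meas <- subgroup_summary(transform(meas, age = gt$age, sex = gt$sex),
                             c("pf_amp", "pb_amp", "rm"))
sub_mod <- subgroup_summary(transform(mod, age = gt$age, sex = gt$sex),
                            c("pf_amp", "pb_amp", "rm", "pwv"))
sub_meas$arm <- "measured"; sub_mod$arm <- "model"
sub <- merge(sub_meas, sub_mod, by = "group", suffixes = c("_meas", "_mod"))
utils::write.csv(sub, "results/subgroups.csv", row.names = FALSE)
message("\nWritten: results/comparison_arms.csv, results/comparison_pwv.csv, results/subgroups.csv")
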