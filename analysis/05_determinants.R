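#!/usr/bin/env Rscript
# Determinants of characteristic impedance.
#
# Stepwise linear regression (enter if p < 0.05, remove if p > 0.10) of
# each arm's Zc — and of their difference — on gender (male = 1,
# female = 2), age, height, BMI, heart rate and carotid pulse pressure.

suppressMessages(library(hemowave))

coh <- read_cohort("results/cohort")
meas <- utils::read.csv("results/measured_arm.csv")
mod <- utils::read.csv("results/model_arm.csv")

covs <- data.frame(
  id = vapply(coh$subjects, `[[`, character(1), "id"),
  gender = ifelse(vapply(coh$subjects, `[[`, character(1), "sex") == "male", 1, 2),
  age = vapply(coh$subjects, `[[`, numeric(1), "age"),
  height = vapply(coh$subjects, `[[`, numeric(1), "height_cm"),
  bmi = vapply(coh$subjects, `[[`, numeric(1), "bmi")
)
d <- merge(merge(covs, meas[c("id", "zc", "hr", "pp")], by = "id"),
           mod[c("id", "zc")], by = "id", suffixes = c("_meas", "_mod"))
d$zc_diff <- d$zc_mod - d$zc_meas
predictors <- c("gender", "age", "height", "bmi", "hr", "pp")

sink("results/determinants.txt")
for (resp in c("zc_meas", "zc_mod", "zc_diff")) {
  cat("=== Stepwise model for", resp, "===\n")
  print(stepwise_regression(d, resp, predictors))
  cat("\n")
}
sink()
writeLines(readLines("results/determinants.txt"))
message("Written: results/determinants.txt")
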